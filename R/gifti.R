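# Minimal GIFTI (XML) reader/writer: POINTSET/TRIANGLE surfaces, metric
# arrays and label maps.  ASCII, Base64Binary and GZipBase64Binary
# encodings are read; ASCII is written.  Only the pieces of the format the
# package consumes are handled; anything else is a format error, not a
# silent guess.

gifti_dtype <- list(
  NIFTI_TYPE_FLOAT32 = list(what = "double", size = 4L),
  NIFTI_TYPE_FLOAT64 = list(what = "double", size = 8L),
  NIFTI_TYPE_INT32 = list(what = "integer", size = 4L),
  NIFTI_TYPE_UINT8 = list(what = "integer", size = 1L))

read_gifti_array <- function(da) {
  at <- xml2::xml_attrs(da)
  dt <- gifti_dtype[[at[["DataType"]]]]
  if (is.null(dt)) stop("unsupported GIFTI DataType: ", at[["DataType"]])
  dim0 <- as.integer(at[["Dim0"]])
  dim1 <- if ("Dim1" %in% names(at)) as.integer(at[["Dim1"]]) else 1L
  n <- dim0 * dim1
  enc <- at[["Encoding"]]
  txt <- xml2::xml_text(xml2::xml_find_first(da, ".//d1:Data",
    c(d1 = "http://www.nitrc.org/frs/?group_id=75")))
  if (is.na(txt) || !nzchar(txt))
    txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
  vals <- switch(enc,
    ASCII = {
      v <- scan(text = txt, what = double(), quiet = TRUE)
      if (dt$what == "integer") as.integer(v) else v
    },
    Base64Binary = ,
    GZipBase64Binary = {
      raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
      if (enc == "GZipBase64Binary")
        raw <- memDecompress(raw, type = "gzip")
      endian <- if (identical(at[["Endian"]], "BigEndian"))
        "big" else "little"
      readBin(raw, dt$what, n = n, size = dt$size, endian = endian)
    },
    stop("unsupported GIFTI Encoding: ", enc))
  if (length(vals) != n)
    stop("GIFTI data array is truncated (expected ", n, " values, got ",
         length(vals), ")")
  order <- if ("ArrayIndexingOrder" %in% names(at))
    at[["ArrayIndexingOrder"]] else "RowMajorOrder"
  if (dim1 > 1L) {
    if (order == "RowMajorOrder")
      matrix(vals, nrow = dim0, ncol = dim1, byrow = TRUE)
    else
      matrix(vals, nrow = dim0, ncol = dim1)
  } else {
    vals
  }
}

read_gifti <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("not a readable GIFTI/XML file: ",
                                           path, " (", conditionMessage(e),
                                           ")"))
  doc <- xml2::xml_ns_strip(doc)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  if (!length(das)) stop("no DataArray elements in ", path)
  arrays <- lapply(das, function(da) {
    list(intent = xml2::xml_attr(da, "Intent"),
         data = read_gifti_array(da))
  })
  labtab <- xml2::xml_find_all(doc, ".//LabelTable/Label")
  labels <- NULL
  if (length(labtab)) {
    labels <- data.frame(
      key = as.integer(xml2::xml_attr(labtab, "Key")),
      name = xml2::xml_text(labtab))
  }
  list(arrays = arrays, labels = labels)
}

gifti_ascii_chunk <- function(x, per_line = 6L) {
  txt <- format(x, trim = TRUE, scientific = FALSE, digits = 10)
  paste(vapply(split(txt, ceiling(seq_along(txt) / per_line)),
               paste, "", collapse = " "), collapse = "\n")
}

write_gifti <- function(path, arrays, label_table = NULL) {
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sprintf('<GIFTI Version="1.0" NumberOfDataArrays="%d">',
                     length(arrays)))
  if (!is.null(label_table)) {
    lines <- c(lines, "<LabelTable>",
               sprintf('<Label Key="%d" Red="%.3f" Green="%.3f" Blue="%.3f" Alpha="1"><![CDATA[%s]]></Label>',
                       label_table$key, label_table$red, label_table$green,
                       label_table$blue, label_table$name),
               "</LabelTable>")
  }
  for (a in arrays) {
    d <- a$data
    if (is.matrix(d)) {
      dims <- sprintf('Dimensionality="2" Dim0="%d" Dim1="%d"',
                      nrow(d), ncol(d))
      flat <- as.vector(t(d))
    } else {
      dims <- sprintf('Dimensionality="1" Dim0="%d"', length(d))
      flat <- d
    }
    lines <- c(lines,
      sprintf('<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" %s Encoding="ASCII" Endian="LittleEndian" ExternalFileName="" ExternalFileOffset="">',
              a$intent, a$dtype, dims),
      "<Data>", gifti_ascii_chunk(flat), "</Data>", "</DataArray>")
  }
  writeLines(c(lines, "</GIFTI>"), path)
  invisible(path)
}

#' Read and write surface geometry (GIFTI `.surf.gii` or TSV pair)
#'
#' `read_surface` accepts a GIFTI surface file holding a
#' `NIFTI_INTENT_POINTSET` and a `NIFTI_INTENT_TRIANGLE` array (GIFTI
#' triangles are 0-based and are converted to 1-based indices).
#'
#' @param path File path.
#' @param radius Optional sphere radius to record on the mesh.
#' @return A [surface_mesh()].
#' @export
read_surface <- function(path, radius = NULL) {
  g <- read_gifti(path)
  intents <- vapply(g$arrays, `[[`, "", "intent")
  ip <- match("NIFTI_INTENT_POINTSET", intents)
  it <- match("NIFTI_INTENT_TRIANGLE", intents)
  if (is.na(ip) || is.na(it))
    stop("surface file must contain POINTSET and TRIANGLE arrays: ", path)
  surface_mesh(g$arrays[[ip]]$data, g$arrays[[it]]$data + 1L,
               radius = radius)
}

#' @rdname read_surface
#' @param mesh A [surface_mesh()].
#' @export
write_surface <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  write_gifti(path, list(
    list(intent = "NIFTI_INTENT_POINTSET",
         dtype = "NIFTI_TYPE_FLOAT32", data = mesh$vertices),
    list(intent = "NIFTI_INTENT_TRIANGLE",
         dtype = "NIFTI_TYPE_INT32", data = mesh$faces - 1L)))
}

#' Read and write parcellations (GIFTI `.label.gii` or one-column TSV)
#'
#' Label key 0 is reserved for unassigned vertices (medial wall).  TSV
#' fixtures hold one integer label per line under a `label` header.
#'
#' @param path File path; format chosen by extension (`.gii` vs anything
#'   else = TSV).
#' @param n_vertices Optional expected vertex count; a mismatch is a
#'   format error.
#' @return A [parcellation()].
#' @export
read_parcellation <- function(path, n_vertices = NULL) {
  if (grepl("\\.gii$", path)) {
    g <- read_gifti(path)
    lab <- g$arrays[[1]]$data
    if (is.matrix(lab)) lab <- as.vector(lab)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#")
    if (!"label" %in% names(tab))
      stop("parcellation TSV must have a 'label' column")
    lab <- tab$label
  }
  if (any(lab != round(lab)))
    stop("non-integer parcel labels in ", path)
  if (!is.null(n_vertices) && length(lab) != n_vertices)
    stop("parcellation has ", length(lab), " vertices, expected ",
         n_vertices)
  parcellation(lab, name = sub("\\.(label\\.)?gii$|\\.tsv$", "",
                               basename(path)))
}

#' @rdname read_parcellation
#' @param parc A [parcellation()].
#' @export
write_parcellation <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  labels <- unclass(parc)
  if (grepl("\\.gii$", path)) {
    keys <- sort(unique(c(0L, labels)))
    set.seed(1)  # reproducible label colours only
    lt <- data.frame(key = keys,
                     name = ifelse(keys == 0L, "???",
                                   sprintf("parcel_%d", keys)),
                     red = stats::runif(length(keys)),
                     green = stats::runif(length(keys)),
                     blue = stats::runif(length(keys)))
    write_gifti(path, list(list(intent = "NIFTI_INTENT_LABEL",
                                dtype = "NIFTI_TYPE_INT32",
                                data = labels)),
                label_table = lt)
  } else {
    writeLines(c("label", as.character(labels)), path)
  }
  invisible(path)
}

#' Read and write functional profiles (GIFTI `.func.gii` or TSV matrix)
#'
#' Metric files carry one data array per condition (or one matrix array);
#' several files may be combined.  Rows containing any non-finite value
#' are masked invalid.
#'
#' @param path One or more file paths; multiple GIFTI metric files are
#'   column-bound.
#' @return A [functional_profiles()].
#' @export
read_profiles <- function(path) {
  read_one <- function(p) {
    if (grepl("\\.gii$", p)) {
      g <- read_gifti(p)
      cols <- lapply(g$arrays, function(a)
        if (is.matrix(a$data)) a$data else matrix(a$data, ncol = 1))
      nv <- unique(vapply(cols, nrow, 1L))
      if (length(nv) != 1L)
        stop("metric arrays in ", p, " have mismatched vertex counts")
      do.call(cbind, cols)
    } else {
      as.matrix(utils::read.table(p, header = TRUE, sep = "\t",
                                  comment.char = "#"))
    }
  }
  mats <- lapply(path, read_one)
  nv <- unique(vapply(mats, nrow, 1L))
  if (length(nv) != 1L)
    stop("profile files have mismatched vertex counts")
  m <- do.call(cbind, mats)
  if (ncol(m) < 2L)
    stop("profiles need at least 2 conditions, got ", ncol(m))
  functional_profiles(m)
}

#' @rdname read_profiles
#' @param profiles A [functional_profiles()].
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "functional_profiles"))
  if (grepl("\\.gii$", path)) {
    write_gifti(path, list(list(intent = "NIFTI_INTENT_NONE",
                                dtype = "NIFTI_TYPE_FLOAT32",
                                data = profiles$values)))
  } else {
    df <- as.data.frame(profiles$values)
    names(df) <- sprintf("cond_%03d", seq_len(ncol(df)))
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
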