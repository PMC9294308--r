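#' Sparse geodesic distance matrix
#'
#' Constructor for the triplet form of a cutoff-limited pairwise
#' distance matrix.  Entries are stored once per unordered pair with
#' `i < j`, in canonical (i, j) order; pairs beyond the cutoff are absent
#' and are never evaluated by any criterion.
#'
#' @param i,j Integer vertex indices, `i < j` elementwise.
#' @param d Numeric distances in mm, all in `(0, cutoff]`.
#' @param cutoff Cutoff in mm.
#' @param n_vertices Vertex count of the source mesh.
#' @return An object of class `sparse_dist`.
#' @export
sparse_dist <- function(i, j, d, cutoff, n_vertices) {
  i <- as.integer(i); j <- as.integer(j); d <- as.numeric(d)
  stopifnot(length(i) == length(j), length(j) == length(d))
  if (any(i >= j)) stop("sparse_dist requires i < j")
  if (length(d) && (any(d <= 0) || any(d > cutoff + 1e-9)))
    stop("distances must lie in (0, cutoff]")
  ord <- order(i, j)   # canonical pair order
  i <- i[ord]; j <- j[ord]; d <- d[ord]
  structure(list(i = i, j = j, d = d,
                 cutoff = as.numeric(cutoff),
                 n_vertices = as.integer(n_vertices)),
            class = "sparse_dist")
}

#' @export
print.sparse_dist <- function(x, ...) {
  cat("sparse_dist:", length(x$d), "vertex pairs within",
      x$cutoff, "mm over", x$n_vertices, "vertices\n")
  invisible(x)
}

#' @export
n_vertices.sparse_dist <- function(x) x$n_vertices

#' Geodesic (graph shortest-path) distances with a cutoff
#'
#' Computes shortest-path distances between all vertex pairs along the
#' triangle edge graph (Dijkstra semantics, delegated to
#' [igraph::distances()]), keeping only pairs whose distance does not exceed
#' `cutoff`.  The graph metric approximates on-surface geodesic distance;
#' the cutoff (50 mm by default, matching the evaluation range of the
#' boundary criterion plus margin) bounds memory and run time.
#'
#' Distances are computed in vertex blocks so the dense all-pairs matrix is
#' never held in memory at once.
#'
#' @param mesh A [surface_mesh()].
#' @param cutoff Positive cutoff in mm (default 50).
#' @param block Number of source vertices per Dijkstra block (tuning knob;
#'   does not affect results).
#' @return A `sparse_dist` object.
#' @examples
#' sph <- geodesic_sphere(2)
#' d <- geodesic_distances(sph, cutoff = 60)
#' @export
geodesic_distances <- function(mesh, cutoff = 50, block = 512L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("`cutoff` must be a positive scalar (mm)")
  eg <- build_edge_graph(mesh)
  n <- eg$n_vertices
  g <- igraph::graph_from_edgelist(eg$edges, directed = FALSE)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  if (igraph::components(g)$no != 1L)
    stop("mesh edge graph is not connected")
  ii <- jj <- list(); dd <- list(); nb <- 0L
  starts <- seq(1L, n, by = block)
  for (s in starts) {
    rows <- s:min(s + block - 1L, n)
    D <- igraph::distances(g, v = rows, weights = eg$lengths,
                           algorithm = "dijkstra")
    keep <- which(D <= cutoff &
                    outer(rows, seq_len(n), `<`), arr.ind = TRUE)
    nb <- nb + 1L
    ii[[nb]] <- rows[keep[, 1]]
    jj[[nb]] <- keep[, 2]
    dd[[nb]] <- D[keep]
  }
  sparse_dist(unlist(ii), unlist(jj), unlist(dd), cutoff, n)
}

#' Exact great-circle distances on a spherical mesh
#'
#' For synthetic spheres the true on-surface geodesic distance between two
#' vertices is the great-circle arc, available in closed form.  Simulations
#' on spherical surrogates use these exact distances: the Dijkstra graph
#' metric of [geodesic_distances()] is the right tool for arbitrary
#' cortical surfaces (where no closed form exists) and converges to the
#' arc as the mesh is refined, but on a coarse regular mesh its
#' direction-dependent overshoot is systematic, which would contaminate
#' distance-matched statistics with a mesh artifact.
#'
#' @param mesh A spherical [surface_mesh()] (radius set or detectable).
#' @param cutoff Positive cutoff in mm.
#' @param block Vertices per block (memory tuning only).
#' @return A `sparse_dist` object.
#' @export
sphere_arc_distances <- function(mesh, cutoff = 50, block = 1024L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("`cutoff` must be a positive scalar (mm)")
  r <- check_sphere(mesh)
  u <- mesh$vertices / r
  n <- nrow(u)
  ii <- jj <- dd <- list(); k <- 0L
  for (s in seq(1L, n, by = block)) {
    rows <- s:min(s + block - 1L, n)
    D <- r * acos(pmin(1, pmax(-1, u[rows, , drop = FALSE] %*% t(u))))
    dim(D) <- c(length(rows), n)
    keep <- which(D <= cutoff & outer(rows, seq_len(n), `<`),
                  arr.ind = TRUE)
    k <- k + 1L
    ii[[k]] <- rows[keep[, 1]]
    jj[[k]] <- keep[, 2]
    dd[[k]] <- D[keep]
  }
  sparse_dist(unlist(ii), unlist(jj), unlist(dd), cutoff, n)
}

#' Average several sparse distance matrices
#'
#' Entrywise available-case mean: a pair is present in the result if it is
#' present in at least one input, and its value is the mean over the inputs
#' in which it is present.  Used to pool per-subject (or per-hemisphere)
#' surface distances into a single template matrix; available-case
#' averaging avoids shrinking coverage when cutoff-induced missingness
#' differs slightly between subjects.  All inputs must share the vertex
#' count and cutoff (i.e. come from meshes with matched vertex indexing).
#'
#' @param matrices List of `sparse_dist` objects.
#' @return A `sparse_dist`.
#' @export
average_distance_matrices <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L ||
        !all(vapply(matrices, inherits, TRUE, "sparse_dist")))
    stop("`matrices` must be a non-empty list of sparse_dist objects")
  nv <- unique(vapply(matrices, function(m) m$n_vertices, 1L))
  co <- unique(vapply(matrices, function(m) m$cutoff, 1.0))
  if (length(nv) != 1L)
    stop("distance matrices have mismatched vertex counts")
  if (length(co) != 1L)
    stop("distance matrices have mismatched cutoffs")
  key <- unlist(lapply(matrices, function(m)
    (m$i - 1) * as.double(nv) + m$j))
  val <- unlist(lapply(matrices, function(m) m$d))
  s <- rowsum(val, key)
  cnt <- rowsum(rep(1, length(key)), key)
  k <- as.numeric(rownames(s))
  i <- floor((k - 1) / nv) + 1
  j <- k - (i - 1) * nv
  ord <- order(i, j)
  sparse_dist(i[ord], j[ord], (s / cnt)[ord], co, nv)
}

#' Look up stored distances for given pairs
#'
#' @param dist A `sparse_dist`.
#' @param i,j Vertex index vectors (any order within a pair).
#' @return Numeric vector of distances; `NA` where the pair is absent
#'   (beyond cutoff).
#' @export
dist_lookup <- function(dist, i, j) {
  stopifnot(inherits(dist, "sparse_dist"))
  lo <- pmin(i, j); hi <- pmax(i, j)
  nv <- as.double(dist$n_vertices)
  key <- (dist$i - 1) * nv + dist$j
  m <- match((lo - 1) * nv + hi, key)
  dist$d[m]
}

#' Write / read a sparse distance matrix as TSV
#'
#' Triplet text format: comment header lines `# cutoff_mm:` and
#' `# n_vertices:`, then tab-separated columns `i`, `j`, `distance_mm`.
#'
#' @param dist A `sparse_dist`.
#' @param path File path.
#' @return `write_distances` returns `path` invisibly; `read_distances`
#'   returns a `sparse_dist`.
#' @export
write_distances <- function(dist, path) {
  stopifnot(inherits(dist, "sparse_dist"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cutoff_mm: %.10g", dist$cutoff),
               sprintf("# n_vertices: %d", dist$n_vertices),
               "i\tj\tdistance_mm"), con)
  utils::write.table(
    data.frame(i = dist$i, j = dist$j, distance_mm = dist$d),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distances
#' @export
read_distances <- function(path) {
  hdr <- readLines(path, n = 10L)
  getnum <- function(tag) {
    ln <- grep(paste0("^# ", tag, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("missing '# ", tag, ":' header in ", path)
    as.numeric(sub(paste0("^# ", tag, ":\\s*"), "", ln[1]))
  }
  cutoff <- getnum("cutoff_mm")
  nv <- getnum("n_vertices")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  if (!all(c("i", "j", "distance_mm") %in% names(tab)))
    stop("distance TSV must have columns i, j, distance_mm")
  sparse_dist(tab$i, tab$j, tab$distance_mm, cutoff, nv)
}
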