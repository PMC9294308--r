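#' Triangulated surface mesh
#'
#' Construct a `surface_mesh` from vertex coordinates and triangle faces.
#' This is the geometric substrate on which geodesic distances, surface
#' smoothing and parcel adjacency are defined.
#'
#' @param vertices Numeric matrix with one row per vertex and three columns
#'   (x, y, z coordinates in mm).
#' @param faces Integer matrix with one row per triangle and three columns of
#'   1-based vertex indices.
#' @param radius Optional sphere radius in mm.  Set for synthetic spheres;
#'   left `NULL` for arbitrary (e.g. cortical) surfaces.
#'
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices`, `faces` and `radius`.
#' @examples
#' m <- surface_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
#'                   matrix(c(1, 2, 3), 1))
#' n_vertices(m)
#' @export
surface_mesh <- function(vertices, faces, radius = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L)
    stop("`vertices` must have three columns (x, y, z in mm)")
  if (ncol(faces) != 3L)
    stop("`faces` must have three columns of vertex indices")
  if (nrow(faces) == 0L)
    stop("mesh has no faces")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
    stop("degenerate faces (repeated vertex within a triangle)")
  if (!all(is.finite(vertices)))
    stop("non-finite vertex coordinates")
  m <- structure(list(vertices = vertices, faces = faces,
                      radius = radius),
                 class = "surface_mesh")
  if (!is.null(radius)) {
    nrm <- sqrt(rowSums(vertices^2))
    if (any(abs(nrm - radius) > 1e-6 * radius))
      stop("vertices do not lie on the stated sphere radius")
  }
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces")
  if (!is.null(x$radius)) cat(", sphere radius", x$radius, "mm")
  cat("\n")
  invisible(x)
}

#' Number of vertices of a mesh-like object
#' @param x A `surface_mesh`, `parcellation`, `functional_profiles` or
#'   `sparse_dist` object.
#' @return Integer vertex count.
#' @export
n_vertices <- function(x) UseMethod("n_vertices")

#' @export
n_vertices.surface_mesh <- function(x) nrow(x$vertices)

# unique undirected triangle edges as a 2-column matrix (i < j)
triangle_edges <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  swap <- e[, 1] > e[, 2]
  e[swap, ] <- e[swap, c(2L, 1L)]
  e[!duplicated(e), , drop = FALSE]
}

#' Weighted edge graph of a mesh
#'
#' Extracts the unique undirected triangle edges with Euclidean lengths.
#' This graph is the substrate for Dijkstra shortest-path distances and for
#' neighbourhood smoothing.
#'
#' @param mesh A [surface_mesh()].
#' @return An object of class `edge_graph`: list with integer matrix
#'   `edges` (one unordered pair per row, first index smaller) and numeric
#'   `lengths` (mm).
#' @examples
#' m <- surface_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
#'                   matrix(c(1, 2, 3), 1))
#' build_edge_graph(m)$lengths  # 3, 4, 5
#' @export
build_edge_graph <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  e <- triangle_edges(mesh$faces)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
  if (any(len <= 0)) stop("zero-length edge: coincident vertices")
  structure(list(edges = e, lengths = len,
                 n_vertices = nrow(mesh$vertices)),
            class = "edge_graph")
}

#' @export
print.edge_graph <- function(x, ...) {
  cat("edge_graph:", nrow(x$edges), "edges over", x$n_vertices,
      "vertices; mean length", signif(mean(x$lengths), 4), "mm\n")
  invisible(x)
}

# base icosahedron on the unit sphere; fixed canonical vertex/face order
icosahedron_unit <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v / sqrt(1 + phi^2), faces = f)
}

#' Geodesic sphere (subdivided icosahedron)
#'
#' Builds the frequency-`frequency` geodesic sphere: every icosahedral face
#' is subdivided into `frequency^2` triangles and all vertices are projected
#' onto a sphere of the requested radius.  The result has
#' `10 * frequency^2 + 2` vertices and `20 * frequency^2` faces.  Vertex
#' ordering is canonical and deterministic: the 12 icosahedron vertices
#' first, then edge-interior points (30 edges in index order, points ordered
#' from the lower- to the higher-indexed endpoint), then face-interior
#' points (20 faces in canonical order).
#'
#' These spheres serve both as synthetic cortical surfaces and as the
#' scaffold of icosahedral parcellations (42, 162, 362, 642, 1002 parcels at
#' frequencies 2, 4, 6, 8, 10).
#'
#' @param frequency Positive integer subdivision frequency.
#' @param radius Sphere radius in mm (default 100, the standard-template
#'   sphere radius).
#' @return A [surface_mesh()] with `radius` set.
#' @examples
#' n_vertices(geodesic_sphere(2))  # 42
#' @export
geodesic_sphere <- function(frequency, radius = 100) {
  if (length(frequency) != 1L || is.na(frequency) || frequency < 1 ||
        frequency != round(frequency))
    stop("`frequency` must be a positive integer")
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("`radius` must be a positive scalar (mm)")
  frequency <- as.integer(frequency)
  ico <- icosahedron_unit()
  nv_base <- 12L
  base_edges <- triangle_edges(ico$faces)            # 30 edges, i < j
  ord <- order(base_edges[, 1], base_edges[, 2])
  base_edges <- base_edges[ord, , drop = FALSE]
  f <- frequency

  n_edge_pts <- 30L * (f - 1L)
  n_face_pts <- 20L * ((f - 1L) * (f - 2L)) %/% 2L
  n_total <- nv_base + n_edge_pts + n_face_pts
  verts <- matrix(NA_real_, n_total, 3)
  verts[1:12, ] <- ico$vertices

  # id of the t-th interior point (t = 1..f-1) on edge (u,v), measured u -> v
  edge_key <- paste(base_edges[, 1], base_edges[, 2])
  edge_pt <- function(u, v, t) {
    if (u > v) { tmp <- u; u <- v; v <- tmp; t <- f - t }
    k <- match(paste(u, v), edge_key)
    nv_base + (k - 1L) * (f - 1L) + t
  }

  faces_out <- matrix(0L, 20L * f^2, 3)
  nf <- 0L
  face_base <- nv_base + n_edge_pts
  per_face_int <- ((f - 1L) * (f - 2L)) %/% 2L

  for (t in seq_len(20L)) {
    abc <- ico$faces[t, ]
    A <- ico$vertices[abc[1], ]; B <- ico$vertices[abc[2], ]
    C <- ico$vertices[abc[3], ]
    # grid id lookup: barycentric (f - i - j, i, j) over A, B, C
    idx <- matrix(0L, f + 1L, f + 1L)
    idx[1L, 1L] <- abc[1]
    idx[f + 1L, 1L] <- abc[2]
    idx[1L, f + 1L] <- abc[3]
    if (f > 1L) {
      for (i in 1:(f - 1L)) {
        idx[i + 1L, 1L] <- edge_pt(abc[1], abc[2], i)        # A -> B
        idx[1L, i + 1L] <- edge_pt(abc[1], abc[3], i)        # A -> C
        idx[f - i + 1L, i + 1L] <- edge_pt(abc[2], abc[3], i) # B -> C
      }
    }
    if (per_face_int > 0L) {
      off <- 0L
      for (i in 1:(f - 2L)) for (j in 1:(f - 1L - i)) {
        off <- off + 1L
        idx[i + 1L, j + 1L] <- face_base + (t - 1L) * per_face_int + off
      }
    }
    # fill coordinates for every grid point owned so far
    for (i in 0:f) for (j in 0:(f - i)) {
      id <- idx[i + 1L, j + 1L]
      if (is.na(verts[id, 1])) {
        p <- ((f - i - j) * A + i * B + j * C) / f
        verts[id, ] <- p / sqrt(sum(p^2))
      }
    }
    for (i in 0:(f - 1L)) for (j in 0:(f - 1L - i)) {
      nf <- nf + 1L
      faces_out[nf, ] <- c(idx[i + 1L, j + 1L], idx[i + 2L, j + 1L],
                           idx[i + 1L, j + 2L])
      if (j < f - 1L - i) {
        nf <- nf + 1L
        faces_out[nf, ] <- c(idx[i + 2L, j + 1L], idx[i + 2L, j + 2L],
                             idx[i + 1L, j + 2L])
      }
    }
  }
  surface_mesh(verts * radius, faces_out, radius = radius)
}
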