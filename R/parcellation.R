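#' Vertex-wise parcellation
#'
#' A parcellation assigns every surface vertex a non-negative integer label;
#' label 0 marks unassigned vertices (e.g. the medial wall) which are
#' excluded from every evaluation.
#'
#' @param labels Integer vector, one non-negative label per vertex.
#' @param name Optional free-text name.
#' @param n_parcels Optional total number of parcel slots (labels may be
#'   empty, e.g. after rotation); defaults to `max(labels)`.
#' @return An object of class `parcellation` (an integer vector with
#'   attributes `name` and `n_parcels`).
#' @export
parcellation <- function(labels, name = "", n_parcels = NULL) {
  if (any(!is.finite(labels)) || any(labels < 0) ||
        any(labels != round(labels)))
    stop("labels must be non-negative integers")
  labels <- as.integer(labels)
  if (is.null(n_parcels)) n_parcels <- max(labels, 0L)
  structure(labels, name = as.character(name),
            n_parcels = as.integer(n_parcels),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  nz <- unique(x[x > 0L])
  cat("parcellation ", if (nzchar(attr(x, "name")))
    paste0("'", attr(x, "name"), "' ") else "",
    ": ", length(x), " vertices, ", length(nz),
    " non-empty parcels (of ", attr(x, "n_parcels"), "), ",
    sum(x == 0L), " unassigned\n", sep = "")
  invisible(x)
}

#' @export
n_vertices.parcellation <- function(x) length(unclass(x))

# frequency for a 10 nu^2 + 2 parcel count, or stop
parcel_frequency <- function(n_parcels) {
  nu <- sqrt((n_parcels - 2) / 10)
  if (n_parcels < 12 || abs(nu - round(nu)) > 1e-9)
    stop("`n_parcels` must be of the form 10*nu^2 + 2 ",
         "(e.g. 12, 42, 162, 362, 642, 1002)")
  as.integer(round(nu))
}

check_sphere <- function(mesh) {
  nrm <- sqrt(rowSums(mesh$vertices^2))
  r <- if (!is.null(mesh$radius)) mesh$radius else mean(nrm)
  if (any(abs(nrm - r) > 1e-4 * r))
    stop("mesh is not a sphere centred at the origin")
  r
}

# nearest-centre labels; 3D dot product gives the same ordering as
# great-circle distance on a common sphere; ties -> lowest centre index
nearest_center_labels <- function(vertices, centers) {
  max.col(vertices %*% t(centers), ties.method = "first")
}

#' Icosahedral parcellation of a sphere
#'
#' Labels every vertex of a spherical mesh by the nearest vertex of a
#' frequency-\eqn{\nu} geodesic sphere, giving the regular "hexagonal"
#' parcellations with \eqn{10\nu^2+2} parcels (42, 162, 362, 642, 1002 at
#' \eqn{\nu} = 2, 4, 6, 8, 10).
#'
#' @param mesh A spherical [surface_mesh()].
#' @param n_parcels Parcel count of the form `10 * nu^2 + 2`.
#' @return A [parcellation()].
#' @export
icosahedron_parcellation <- function(mesh, n_parcels) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nu <- parcel_frequency(n_parcels)
  r <- check_sphere(mesh)
  centers <- geodesic_sphere(nu, radius = r)$vertices
  parcellation(nearest_center_labels(mesh$vertices, centers),
               name = sprintf("icosahedron-%d", n_parcels),
               n_parcels = n_parcels)
}

#' Random rotation specification
#'
#' Three rotation angles drawn independently and uniformly on \eqn{[0,
#' 2\pi)} for the x, y and z axes, composed in the fixed order
#' \eqn{R = R_z R_y R_x}.  Note this scheme (three independent uniform
#' Euler angles) is not the uniform (Haar) measure on the rotation group;
#' it is kept as specified for the null model.
#'
#' @param seed Integer seed; the three angles are drawn reproducibly from
#'   it.  Alternatively pass explicit `angles`.
#' @param angles Optional numeric length-3 vector (x, y, z angles in
#'   radians) overriding the draw.
#' @return Object of class `rotation_spec`: list with `angles` and the
#'   3x3 rotation `matrix`.
#' @export
rotation_spec <- function(seed = NULL, angles = NULL) {
  if (is.null(angles)) {
    if (is.null(seed)) stop("give either `seed` or `angles`")
    angles <- withr_seed(seed, stats::runif(3, 0, 2 * pi))
  }
  stopifnot(length(angles) == 3, all(is.finite(angles)))
  ax <- angles[1]; ay <- angles[2]; az <- angles[3]
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  structure(list(angles = angles, matrix = Rz %*% Ry %*% Rx),
            class = "rotation_spec")
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old))
    rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Rotate an icosahedral parcellation on its sphere
#'
#' Rotates the parcel centres by the given rotation and re-assigns every
#' mesh vertex to the nearest rotated centre.  Parcel identities are kept:
#' label k always refers to the k-th centre, so parcels left empty by the
#' rotation stay empty rather than being renumbered.
#'
#' @param parc A [parcellation()] produced by [icosahedron_parcellation()]
#'   (its parcel count determines the centre sphere).
#' @param mesh The spherical mesh the parcellation lives on.
#' @param rotation A [rotation_spec()].
#' @return A [parcellation()].
#' @export
rotate_parcellation <- function(parc, mesh, rotation) {
  stopifnot(inherits(parc, "parcellation"),
            inherits(mesh, "surface_mesh"),
            inherits(rotation, "rotation_spec"))
  r <- check_sphere(mesh)
  nu <- parcel_frequency(attr(parc, "n_parcels"))
  centers <- geodesic_sphere(nu, radius = r)$vertices
  rc <- centers %*% t(rotation$matrix)
  parcellation(nearest_center_labels(mesh$vertices, rc),
               name = attr(parc, "name"),
               n_parcels = attr(parc, "n_parcels"))
}

#' Set of randomly rotated icosahedral parcellations (null model)
#'
#' Generates `n_repeats` parcellations by independently rotating the
#' icosahedral parcellation with seeded random rotations.  These serve as
#' the spatial null model: they carve the sphere into parcels of realistic
#' size and shape whose boundaries are unrelated to any functional map, so
#' an unbiased boundary criterion should average zero over them.
#'
#' @param mesh Spherical [surface_mesh()].
#' @param n_parcels Parcel count of the form `10 * nu^2 + 2`.
#' @param n_repeats Number of parcellations.
#' @param seed Master seed; individual rotation seeds are derived from it
#'   reproducibly.
#' @return List of [parcellation()] objects.
#' @export
random_parcellation_set <- function(mesh, n_parcels, n_repeats, seed) {
  stopifnot(n_repeats >= 1)
  base <- icosahedron_parcellation(mesh, n_parcels)
  rot_seeds <- withr_seed(seed,
    sample.int(.Machine$integer.max, n_repeats))
  lapply(seq_len(n_repeats), function(k) {
    p <- rotate_parcellation(base, mesh, rotation_spec(seed = rot_seeds[k]))
    attr(p, "name") <- sprintf("%s-rot%03d", attr(base, "name"), k)
    p
  })
}

#' Parcel adjacency from mesh edges
#'
#' Two parcels are neighbours when at least one mesh edge joins a vertex of
#' one to a vertex of the other.  Label 0 (unassigned) is excluded
#' entirely.
#'
#' @param parc A [parcellation()].
#' @param mesh The [surface_mesh()] it is paired with.
#' @return Object of class `parcel_adjacency`: a named list mapping each
#'   non-empty parcel label to the sorted integer vector of its neighbour
#'   labels.
#' @export
parcel_adjacency <- function(parc, mesh) {
  stopifnot(inherits(parc, "parcellation"),
            inherits(mesh, "surface_mesh"))
  if (length(unclass(parc)) != nrow(mesh$vertices))
    stop("parcellation and mesh have different vertex counts")
  e <- triangle_edges(mesh$faces)
  la <- unclass(parc)[e[, 1]]; lb <- unclass(parc)[e[, 2]]
  keep <- la > 0L & lb > 0L & la != lb
  a <- pmin(la[keep], lb[keep]); b <- pmax(la[keep], lb[keep])
  labs <- sort(unique(unclass(parc)[unclass(parc) > 0L]))
  nb <- stats::setNames(lapply(labs, function(x) integer(0)),
                        as.character(labs))
  if (any(keep)) {
    pr <- unique(cbind(a, b))
    for (r in seq_len(nrow(pr))) {
      i <- as.character(pr[r, 1]); j <- as.character(pr[r, 2])
      nb[[i]] <- c(nb[[i]], pr[r, 2])
      nb[[j]] <- c(nb[[j]], pr[r, 1])
    }
    nb <- lapply(nb, function(x) sort(unname(x)))
  }
  structure(nb, class = "parcel_adjacency")
}

#' @export
print.parcel_adjacency <- function(x, ...) {
  cat("parcel_adjacency:", length(x), "parcels, mean",
      signif(mean(lengths(unclass(x))), 3), "neighbours\n")
  invisible(x)
}
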