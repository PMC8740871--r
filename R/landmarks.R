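#' Landmark configurations
#'
#' A single configuration is a numeric `p x 2` matrix of (x, y) coordinates
#' in centimetres, y-axis pointing up.  A set of configurations is a
#' `p x 2 x n` array with subject identifiers in `dimnames(A)[[3]]`.
#' These helpers construct and validate both forms.
#'
#' @param coords numeric `p x 2` matrix.
#' @param subject_id subject identifier.
#' @param scale_factor cm per raw digitizer unit used when the configuration
#'   was scaled (recorded for provenance; coordinates are already in cm).
#' @param digitized_by optional observer tag.
#' @return `landmark_config()` returns the coordinate matrix with
#'   attributes `subject_id`, `scale_factor` and `digitized_by`.
#' @export
landmark_config <- function(coords, subject_id = "subject",
                            scale_factor = 1, digitized_by = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("coords must have two columns (x, y)")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  if (!is.numeric(scale_factor) || scale_factor <= 0)
    stop("scale_factor must be > 0")
  structure(coords, subject_id = as.character(subject_id),
            scale_factor = scale_factor, digitized_by = digitized_by,
            class = c("landmark_config", "matrix", "array"))
}

#' @rdname landmark_config
#' @param configs list of configurations (matrices of equal dimension).
#' @param ids subject identifiers (defaults to list names).
#' @return `as_landmark_array()` returns a `p x 2 x n` array.
#' @export
as_landmark_array <- function(configs, ids = names(configs)) {
  if (is.array(configs) && length(dim(configs)) == 3) return(configs)
  stopifnot(is.list(configs), length(configs) >= 1)
  p <- nrow(configs[[1]])
  if (!all(vapply(configs, nrow, 0L) == p))
    stop("all configurations must have the same number of points")
  if (is.null(ids)) ids <- paste0("s", seq_along(configs))
  A <- array(unlist(lapply(configs, as.numeric)), dim = c(p, 2, length(configs)),
             dimnames = list(NULL, c("x", "y"), ids))
  A
}

#' @rdname landmark_config
#' @param A a `p x 2 x n` landmark array.
#' @return `landmark_list()` returns a plain list of `p x 2` matrices.
#' @export
landmark_list <- function(A) {
  lapply(seq_len(dim(A)[3]), function(i) A[, , i])
}

# check a configuration (or array) against a scheme's point count
check_against_scheme <- function(x, scheme, what = "configuration") {
  p <- if (length(dim(x)) == 3) dim(x)[1] else nrow(x)
  if (p != length(scheme$names))
    stop(what, " has ", p, " points but the scheme defines ",
         length(scheme$names))
  invisible(x)
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all points from their
#' centroid; the standard geometric size measure, in the units of the
#' coordinates (cm for scaled data).
#'
#' @param config numeric `p x 2` matrix, or a `p x 2 x n` array (a size per
#'   configuration is returned).
#' @return Numeric centroid size(s).
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' centroid_size(sq)  # sqrt(4 * 0.5)
#' @export
centroid_size <- function(config) {
  if (length(dim(config)) == 3)
    return(apply(config, 3, centroid_size))
  X <- sweep(config, 2, colMeans(config))
  cs <- sqrt(sum(X^2))
  if (cs <= .Machine$double.eps)
    stop("degenerate configuration: all points coincide")
  cs
}

#' Center a configuration at the origin
#' @param X numeric `p x 2` coordinate matrix.
#' @return The matrix with its centroid translated to (0, 0).
#' @export
center_config <- function(X) sweep(X, 2, colMeans(X))

# orthonormal basis (2p x 4) of the similarity directions (translation x/y,
# scaling, in-plane rotation) at a centered reference configuration; columns
# span the subspace removed by Procrustes alignment.  Coordinates are stacked
# (x1..xp, y1..yp).
similarity_basis <- function(ref) {
  p <- nrow(ref)
  X <- center_config(ref)
  tx <- c(rep(1, p), rep(0, p)) / sqrt(p)
  ty <- c(rep(0, p), rep(1, p)) / sqrt(p)
  sc <- c(X[, 1], X[, 2]); sc <- sc / sqrt(sum(sc^2))
  ro <- c(-X[, 2], X[, 1]); ro <- ro / sqrt(sum(ro^2))
  B <- cbind(tx, ty, sc, ro)
  qr.Q(qr(B))  # re-orthonormalize (sc and ro are orthogonal by construction)
}

# project stacked vectors (2p x k) onto the tangent space of ref
project_tangent <- function(v, basis) {
  v - basis %*% crossprod(basis, v)
}

# evaluate expr under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
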