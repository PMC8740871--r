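#' Symmetrize configurations with object symmetry
#'
#' For each configuration the reflected copy (x negated) is relabelled by
#' swapping left/right pairs, fitted back onto the original by ordinary
#' Procrustes rotation (reflection is the point here, so the relabelled
#' reflection is fitted with a proper rotation), and averaged with the
#' original.  The averaging is iterated to a fixed point, after which each
#' configuration is rotated so the symmetry axis (total-least-squares line
#' through the midline points and the bilateral pair midpoints) is exactly
#' the vertical axis `x = 0`: paired points are then exact mirror images
#' and midline points lie exactly on the axis.  This removes all
#' asymmetric shape variation, e.g. distortion from head posture in 2D
#' photographs.  The operation is idempotent.
#'
#' @param configs `p x 2 x n` array or single `p x 2` matrix.
#' @param scheme `landmark_scheme` declaring pairs and midline.
#' @param tol fixed-point tolerance.
#' @return Symmetrized configurations, same shape as the input (centered).
#' @export
symmetrize <- function(configs, scheme, tol = 1e-12) {
  if (is.null(scheme$pairs) || (!length(scheme$midline) && !nrow(scheme$pairs)))
    stop("scheme must declare bilateral pairs and/or midline points")
  single <- length(dim(configs)) != 3
  A <- if (single) array(configs, c(nrow(configs), 2, 1)) else configs
  check_against_scheme(A, scheme)
  p <- dim(A)[1]
  perm <- seq_len(p)
  perm[scheme$pairs[, 1]] <- scheme$pairs[, 2]
  perm[scheme$pairs[, 2]] <- scheme$pairs[, 1]
  for (i in seq_len(dim(A)[3])) {
    S <- center_config(A[, , i])
    for (k in seq_len(64)) {
      refl <- cbind(-S[, 1], S[, 2])[perm, , drop = FALSE]
      fit <- opa_align(refl, S, allow_reflection = FALSE)$aligned
      S_new <- (S + fit) / 2
      if (max(abs(S_new - S)) < tol) { S <- S_new; break }
      S <- S_new
    }
    # rotate the symmetry axis onto x = 0
    axis_pts <- rbind(S[scheme$midline, , drop = FALSE],
                      (S[scheme$pairs[, 1], , drop = FALSE] +
                       S[scheme$pairs[, 2], , drop = FALSE]) / 2)
    axis_pts <- sweep(axis_pts, 2, colMeans(axis_pts))
    e <- eigen(crossprod(axis_pts), symmetric = TRUE)
    v <- e$vectors[, 1]
    theta <- atan2(v[2], v[1])
    a <- pi / 2 - theta
    if (a > pi / 2) a <- a - pi
    if (a < -pi / 2) a <- a + pi              # smallest rotation to vertical
    R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)  # row-vector rotation
    S <- center_config(S %*% R)
    # exact snap (changes are below tol): midline on axis, pairs mirrored
    S[scheme$midline, 1] <- 0
    l <- scheme$pairs[, 1]; r <- scheme$pairs[, 2]
    hx <- (S[r, 1] - S[l, 1]) / 2
    my <- (S[l, 2] + S[r, 2]) / 2
    S[l, 1] <- -hx; S[r, 1] <- hx
    S[l, 2] <- my;  S[r, 2] <- my
    A[, , i] <- center_config(S)
  }
  if (single) A[, , 1] else A
}

# reflect and relabel a configuration (helper for asymmetry checks)
reflect_relabel <- function(X, scheme) {
  p <- nrow(X)
  perm <- seq_len(p)
  perm[scheme$pairs[, 1]] <- scheme$pairs[, 2]
  perm[scheme$pairs[, 2]] <- scheme$pairs[, 1]
  cbind(-X[, 1], X[, 2])[perm, , drop = FALSE]
}
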