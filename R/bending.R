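#' Thin-plate-spline bending energy model of a reference configuration
#'
#' Builds the TPS bending-energy matrix of a 2D reference: with kernel
#' `U(r) = r^2 log(r)` the full interpolation system is
#' `L = [[K, P], [P', 0]]` with `P = [1, x, y]`, and the bending matrix is
#' the upper-left `p x p` block of `L^{-1}`.  It is symmetric positive
#' semi-definite and annihilates affine displacement fields, whose bending
#' energy is therefore exactly zero.
#'
#' @param reference numeric `p x 2` configuration (no duplicated points).
#' @return Object of class `bending_energy_model`: list with `reference`
#'   and `energy_matrix` (`p x p`).
#' @export
bending_energy_model <- function(reference) {
  X <- as.matrix(reference)
  p <- nrow(X)
  if (anyDuplicated(round(X, 12)) > 0)
    stop("reference has duplicated points")
  K <- tps_kernel_matrix(X, X)
  P <- cbind(1, X)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  Linv <- solve(L)
  Lb <- Linv[seq_len(p), seq_len(p), drop = FALSE]
  Lb <- (Lb + t(Lb)) / 2  # enforce exact symmetry
  structure(list(reference = X, energy_matrix = Lb),
            class = "bending_energy_model")
}

# U(r) = r^2 log r, U(0) = 0, evaluated between row sets A (m x 2), B (p x 2)
tps_kernel_matrix <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  K <- 0.5 * d2 * log(pmax(d2, .Machine$double.xmin))
  K[d2 == 0] <- 0
  K
}

#' Bending energy of a target configuration relative to a reference
#'
#' Sum over the two coordinate axes of `t(v) %*% Lb %*% v`, where `Lb` is
#' the reference bending matrix.  Displacements and absolute target
#' coordinates give the same value because affine fields carry zero energy.
#'
#' @param model a [bending_energy_model()].
#' @param target numeric `p x 2` configuration (or displacement field).
#' @return Non-negative scalar.
#' @export
bending_energy <- function(model, target) {
  v <- as.matrix(target)
  Lb <- model$energy_matrix
  sum(v[, 1] * (Lb %*% v[, 1])) + sum(v[, 2] * (Lb %*% v[, 2]))
}

#' Slide semilandmarks by the minimum bending energy criterion
#'
#' Each semilandmark may move only along its tangent direction, the unit
#' chord between its slider neighbours in the current configuration.  The
#' sliding amounts minimize the bending energy (relative to the consensus
#' reference) of the deviation of the configuration from the consensus,
#' restricted to the tangent directions — a linear least-squares problem
#' solved exactly, so total bending energy never increases.  A singular
#' normal system falls back to a ridge-regularized solve with a message.
#'
#' @param configs `p x 2 x n` array (or single `p x 2` matrix).
#' @param consensus `p x 2` consensus the configurations are slid against.
#' @param scheme `landmark_scheme` providing the slider triples.
#' @param bending_model optional precomputed [bending_energy_model()] of the
#'   consensus.
#' @return Updated configurations, same shape as the input.
#' @export
slide_semilandmarks <- function(configs, consensus, scheme,
                                bending_model = NULL) {
  single <- length(dim(configs)) != 3
  A <- if (single) array(configs, c(nrow(configs), 2, 1)) else configs
  check_against_scheme(A, scheme)
  if (is.null(bending_model)) bending_model <- bending_energy_model(consensus)
  Lb <- bending_model$energy_matrix
  p <- dim(A)[1]
  sl <- scheme$sliders
  s <- nrow(sl)
  if (s == 0) return(configs)
  for (i in seq_len(dim(A)[3])) {
    X <- A[, , i]
    u <- X[sl[, "next"], , drop = FALSE] - X[sl[, "prev"], , drop = FALSE]
    u <- u / sqrt(rowSums(u^2))
    Wx <- matrix(0, p, s); Wy <- matrix(0, p, s)
    Wx[cbind(sl[, "self"], seq_len(s))] <- u[, 1]
    Wy[cbind(sl[, "self"], seq_len(s))] <- u[, 2]
    rx <- X[, 1] - consensus[, 1]; ry <- X[, 2] - consensus[, 2]
    LWx <- Lb %*% Wx; LWy <- Lb %*% Wy
    G <- crossprod(Wx, LWx) + crossprod(Wy, LWy)
    b <- crossprod(Wx, Lb %*% rx) + crossprod(Wy, Lb %*% ry)
    t_amt <- tryCatch(solve(G, -b), error = function(e) {
      message("sliding: singular system, using ridge-regularized solve")
      solve(G + diag(1e-8 * mean(diag(G)), s), -b)
    })
    X[, 1] <- X[, 1] + Wx %*% t_amt
    X[, 2] <- X[, 2] + Wy %*% t_amt
    A[, , i] <- X
  }
  if (single) A[, , 1] else A
}

#' Thin-plate-spline warp between two landmark configurations
#'
#' Solves the standard 2D TPS interpolation (kernel `r^2 log r` plus an
#' affine part) mapping `source` landmarks exactly onto `target` landmarks,
#' and evaluates the map at `query_points`.
#'
#' @param source numeric `p x 2` source landmarks (no duplicates).
#' @param target numeric `p x 2` target landmarks.
#' @param query_points numeric `m x 2` points to warp.
#' @return `m x 2` matrix of warped points.
#' @export
tps_warp <- function(source, target, query_points) {
  S <- as.matrix(source); Tg <- as.matrix(target)
  Q <- as.matrix(query_points)
  if (nrow(S) != nrow(Tg)) stop("source and target must have equal length")
  if (anyDuplicated(round(S, 12)) > 0) stop("duplicated source points")
  p <- nrow(S)
  K <- tps_kernel_matrix(S, S)
  P <- cbind(1, S)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(Tg, matrix(0, 3, 2))
  coefs <- solve(L, rhs)                     # (p+3) x 2
  W <- coefs[seq_len(p), , drop = FALSE]
  Aff <- coefs[p + 1:3, , drop = FALSE]
  U <- tps_kernel_matrix(Q, S)               # m x p
  cbind(1, Q) %*% Aff + U %*% W
}

#' Deformation grid between two configurations
#'
#' Builds a rectangular grid spanning the reference configuration (with a
#' margin) and warps its nodes by the TPS map reference -> target; the
#' classic D'Arcy Thompson transformation-grid visualization.
#'
#' @param reference `p x 2` reference configuration.
#' @param target `p x 2` target configuration.
#' @param n integer vector (columns, rows) of grid nodes.
#' @param margin fractional margin around the reference bounding box.
#' @return List with `nodes` (warped grid nodes), `n`, and the warped
#'   `target` landmarks, of class `deformation_grid`.
#' @export
tps_grid <- function(reference, target, n = c(24, 28), margin = 0.08) {
  R <- as.matrix(reference)
  rx <- range(R[, 1]); ry <- range(R[, 2])
  mx <- margin * diff(rx); my <- margin * diff(ry)
  gx <- seq(rx[1] - mx, rx[2] + mx, length.out = n[1])
  gy <- seq(ry[1] - my, ry[2] + my, length.out = n[2])
  nodes <- as.matrix(expand.grid(x = gx, y = gy))
  structure(list(nodes = tps_warp(R, target, nodes), n = n,
                 reference = R, target = as.matrix(target)),
            class = "deformation_grid")
}

#' Plot a deformation grid
#'
#' @param x a `deformation_grid`.
#' @param add_landmarks draw the target landmarks on top.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.deformation_grid <- function(x, add_landmarks = TRUE, ...) {
  nodes <- x$nodes; nc <- x$n[1]; nr <- x$n[2]
  graphics::plot(nodes, type = "n", asp = 1, xlab = "", ylab = "",
                 axes = FALSE, ...)
  for (r in seq_len(nr))
    graphics::lines(nodes[(r - 1) * nc + seq_len(nc), ], col = "grey60")
  for (cc in seq_len(nc))
    graphics::lines(nodes[cc + nc * (seq_len(nr) - 1), ], col = "grey60")
  if (add_landmarks)
    graphics::points(x$target, pch = 19, cex = 0.5, col = "steelblue4")
  invisible(x)
}
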