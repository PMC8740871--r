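#' Ordinary Procrustes alignment of one configuration onto a reference
#'
#' Finds the least-squares rotation (via the SVD of the cross-covariance
#' matrix) carrying the centered target onto the centered reference,
#' optionally with scaling.  Reflections are disallowed by default: if the
#' optimal orthogonal map is improper, the nearest proper rotation is used
#' and the result flagged.
#'
#' @param target numeric `p x 2` configuration to align.
#' @param reference numeric `p x 2` reference configuration.
#' @param allow_reflection permit an improper (reflecting) fit.
#' @param scale also scale the target to minimize distance.
#' @return List with `aligned` (centered, rotated target), `rotation`
#'   (2 x 2), `angle` (radians), `scale`, `reflected` flag, and `rss`
#'   (residual sum of squares against the centered reference).
#' @export
opa_align <- function(target, reference, allow_reflection = FALSE,
                      scale = FALSE) {
  X <- center_config(as.matrix(target))
  Y <- center_config(as.matrix(reference))
  if (nrow(X) != nrow(Y)) stop("target and reference must have equal point counts")
  M <- crossprod(X, Y)                       # 2 x 2
  sv <- svd(M)
  improper <- det(sv$u %*% t(sv$v)) < 0      # optimal orthogonal map reflects
  if (improper && !allow_reflection) {
    R <- sv$u %*% diag(c(1, -1)) %*% t(sv$v) # nearest proper rotation
  } else {
    R <- sv$u %*% t(sv$v)
  }
  beta <- 1
  if (scale) {
    beta <- sum(diag(crossprod(X %*% R, Y))) / sum(X^2)
    if (beta <= 0) beta <- .Machine$double.eps
  }
  aligned <- beta * X %*% R
  list(aligned = aligned, rotation = R,
       angle = atan2(R[1, 2], R[1, 1]),
       scale = beta,
       reflected = improper,
       rss = sum((aligned - Y)^2))
}

# rotate the whole aligned set so the consensus is in a deterministic
# orientation: first principal axis of the consensus vertical, with the
# sign chosen so the third moment of y is non-negative (faces: forehead
# and chin break the tie).  Makes GPA output invariant to the orientation
# of the inputs.
canonical_orientation <- function(consensus) {
  C <- center_config(consensus)
  e <- eigen(crossprod(C), symmetric = TRUE)
  v <- e$vectors[, 1]                        # major axis
  theta <- atan2(v[2], v[1])
  # post-multiplication matrix rotating row-vector points by angle a
  rot <- function(a) matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
  R <- rot(pi / 2 - theta)                   # major axis -> +y
  y3 <- sum((C %*% R)[, 2]^3)
  if (y3 < -1e-12) R <- R %*% rot(pi)        # flip if chin/forehead inverted
  R
}

#' Generalized Procrustes analysis with optional semilandmark sliding
#'
#' Iteratively centres, scales to unit centroid size, and rotates all
#' configurations onto an evolving consensus until the consensus stops
#' moving.  With `slide = TRUE`, semilandmarks are slid along their tangent
#' directions against the current consensus under the minimum bending
#' energy criterion once per iteration (see [slide_semilandmarks()]).
#' Centroid sizes (cm) are recorded before any scaling and are unaffected
#' by the slide option.  The final orientation is canonicalized (consensus
#' major axis vertical), so the result is invariant to rotation,
#' translation and scaling of the inputs.
#'
#' @param configs `p x 2 x n` landmark array or list of configurations.
#' @param scheme `landmark_scheme`; required when `slide = TRUE`.
#' @param slide slide semilandmarks by minimum bending energy.
#' @param slide_rounds maximum number of sliding rounds (sliding happens in
#'   the first `slide_rounds` superimposition iterations, after which plain
#'   alignment continues to convergence).
#' @param max_iter maximum superimposition iterations.
#' @param tol convergence tolerance on consensus movement (root mean square).
#' @return Object of class `gpa_fit`: list with `aligned` (`p x 2 x n`, unit
#'   centroid size), `consensus` (`p x 2`, unit size, centered), `centroid_sizes`
#'   (cm), `n_iterations`, `converged`, `scheme`.
#' @export
gpa <- function(configs, scheme = NULL, slide = !is.null(scheme),
                slide_rounds = 5L, max_iter = 100L, tol = 1e-8) {
  A <- as_landmark_array(configs)
  n <- dim(A)[3]; p <- dim(A)[1]
  if (n < 2) stop("need at least two configurations")
  if (slide && is.null(scheme)) stop("sliding requires a landmark scheme")
  if (!is.null(scheme)) check_against_scheme(A, scheme)
  cs <- numeric(n)
  for (i in seq_len(n)) {
    X <- center_config(A[, , i])
    cs[i] <- centroid_size(X)
    A[, , i] <- X / cs[i]
  }
  consensus <- A[, , 1]
  consensus <- consensus / centroid_size(consensus)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n))
      A[, , i] <- opa_align(A[, , i], consensus)$aligned
    if (slide && it <= slide_rounds) {
      bem <- bending_energy_model(consensus)
      A <- slide_semilandmarks(A, consensus, scheme, bem)
      for (i in seq_len(n)) {
        X <- center_config(A[, , i])
        A[, , i] <- opa_align(X / centroid_size(X), consensus)$aligned
      }
    }
    new_consensus <- apply(A, c(1, 2), mean)
    new_consensus <- center_config(new_consensus)
    new_consensus <- new_consensus / centroid_size(new_consensus)
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  R <- canonical_orientation(consensus)
  consensus <- center_config(consensus %*% R)
  for (i in seq_len(n))
    A[, , i] <- opa_align(A[, , i] %*% R, consensus)$aligned
  structure(list(aligned = A, consensus = consensus, centroid_sizes = cs,
                 n_iterations = it, converged = converged, scheme = scheme),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  d <- dim(x$aligned)
  cat("Generalized Procrustes fit:", d[3], "configurations x", d[1], "points;",
      x$n_iterations, "iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("Centroid size (cm): mean", round(mean(x$centroid_sizes), 2),
      "range", paste(round(range(x$centroid_sizes), 2), collapse = "-"), "\n")
  invisible(x)
}

#' Flatten aligned shapes into an observation-by-coordinate matrix
#'
#' @param fit a `gpa_fit` or a `p x 2 x n` array.
#' @return `n x 2p` numeric matrix (columns `x1, y1, x2, y2, ...`).
#' @export
shape_matrix <- function(fit) {
  A <- if (inherits(fit, "gpa_fit")) fit$aligned else as_landmark_array(fit)
  p <- dim(A)[1]; n <- dim(A)[3]
  Y <- t(apply(A, 3, function(X) as.vector(t(X))))
  dimnames(Y) <- list(dimnames(A)[[3]],
                      paste0(rep(c("x", "y"), p), rep(seq_len(p), each = 2)))
  Y
}

#' Serialize a Procrustes fit to CSV plus JSON metadata
#'
#' Writes the flattened aligned coordinates (one row per subject) to
#' `<stem>.csv` and the consensus, centroid sizes and convergence record to
#' `<stem>.json`.
#'
#' @param fit a `gpa_fit`.
#' @param stem output path without extension.
#' @return The two paths, invisibly.
#' @export
write_gpa <- function(fit, stem) {
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  Y <- shape_matrix(fit)
  utils::write.csv(data.frame(subject_id = rownames(Y), Y,
                              check.names = FALSE), csv, row.names = FALSE)
  jsonlite::write_json(
    list(consensus = unname(fit$consensus),
         centroid_sizes = unname(fit$centroid_sizes),
         subject_id = dimnames(fit$aligned)[[3]],
         n_iterations = fit$n_iterations, converged = fit$converged),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
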