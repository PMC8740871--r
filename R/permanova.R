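#' Sequential permutational MANOVA on shape (or any multivariate) data
#'
#' Euclidean-distance sequential decomposition of the total sum of squares
#' of a multivariate response: each term's SS is the incremental explained
#' sum of squares given all earlier terms (order matters), `R^2 = SS /
#' SS_total`, and the pseudo-F for every term uses the residual mean square
#' of the full model.  Significance comes from permutations of the raw
#' observation rows: `p = (#{F* >= F_obs} + 1) / (n_perm + 1)`.  With a
#' Euclidean metric on a one-column response this reproduces the classical
#' sequential ANOVA decomposition exactly.
#'
#' @param response numeric matrix, observations in rows (e.g. the flattened
#'   aligned coordinates from [shape_matrix()]).
#' @param predictors data.frame of predictors; column order defines the
#'   sequential term order.  Factors and character columns are treated as
#'   categorical, numeric columns as continuous.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations (required for reproducibility).
#' @param exact if `TRUE`, the single predictor must be a two-level factor
#'   and all distinct relabellings are enumerated instead of sampled;
#'   `p = #{F* >= F_obs} / n_distinct` (the identity is included).
#' @return Object of class `permanova_table`: data.frame with one row per
#'   term plus `Residual` and `Total` rows; columns `Df`, `SS`, `R2`,
#'   `pseudo_F`, `p`.
#' @export
permanova <- function(response, predictors, n_perm = 10000L, seed = NULL,
                      exact = FALSE) {
  Y <- as.matrix(response)
  storage.mode(Y) <- "double"
  predictors <- as.data.frame(predictors)
  n <- nrow(Y)
  if (nrow(predictors) != n) stop("predictors and response sizes differ")
  if (!exact && n_perm < 99L) warning("n_perm < 99: p-values are unstable")
  terms <- names(predictors)
  for (v in terms) {
    x <- predictors[[v]]
    if (is.character(x)) predictors[[v]] <- factor(x)
    if (length(unique(predictors[[v]])) < 2L)
      stop("constant predictor: ", v)
  }
  Yc <- sweep(Y, 2, colMeans(Y))
  ss_total <- sum(Yc^2)
  # incremental orthonormal bases per term (Gram-Schmidt against earlier)
  Qcur <- matrix(1 / sqrt(n), n, 1)
  Qterm <- list(); df <- integer(length(terms))
  for (k in seq_along(terms)) {
    x <- predictors[[terms[k]]]
    M <- if (is.factor(x)) stats::model.matrix(~x)[, -1, drop = FALSE]
         else matrix(as.numeric(x), ncol = 1)
    R <- M - Qcur %*% crossprod(Qcur, M)
    qrR <- qr(R)
    rank <- sum(abs(diag(qr.R(qrR))) > 1e-9 * sqrt(ss_total / n + 1))
    if (rank == 0L) stop("predictor ", terms[k],
                         " is collinear with earlier terms")
    Qk <- qr.Q(qrR)[, seq_len(rank), drop = FALSE]
    Qterm[[k]] <- Qk
    df[k] <- rank
    Qcur <- cbind(Qcur, Qk)
  }
  Qt <- do.call(cbind, Qterm)
  grp <- rep(seq_along(terms), df)
  df_res <- n - 1L - sum(df)
  ss_term <- function(Yp) {
    C <- crossprod(Qt, Yp)
    rowsum(rowSums(C^2), grp)[, 1]
  }
  ss_obs <- ss_term(Y)
  ss_res <- ss_total - sum(ss_obs)
  ms_res <- ss_res / df_res
  f_obs <- (ss_obs / df) / ms_res
  if (exact) {
    if (length(terms) != 1L) stop("exact enumeration supports a single term")
    x <- predictors[[1]]
    if (!is.factor(x) || nlevels(droplevels(factor(x))) != 2L)
      stop("exact enumeration requires a two-level factor")
    x <- droplevels(factor(x))
    n1 <- sum(x == levels(x)[1])
    combs <- utils::combn(n, n1)
    f_star <- apply(combs, 2, function(idx) {
      xi <- factor(ifelse(seq_len(n) %in% idx, "a", "b"))
      z <- as.numeric(xi == "a") - n1 / n
      q <- z / sqrt(sum(z^2))
      ssk <- sum((crossprod(q, Y))^2)
      (ssk / 1) / ((ss_total - ssk) / (n - 2))
    })
    pvals <- mean(f_star >= f_obs[1] - 1e-12)
    n_perm_used <- ncol(combs)
  } else {
    count <- with_seed(seed, {
      cnt <- numeric(length(terms))
      for (b in seq_len(n_perm)) {
        Yp <- Y[sample.int(n), , drop = FALSE]
        ss_b <- ss_term(Yp)
        res_b <- ss_total - sum(ss_b)
        f_b <- (ss_b / df) / (res_b / df_res)
        cnt <- cnt + (f_b >= f_obs - 1e-12)
      }
      cnt
    })
    pvals <- (count + 1) / (n_perm + 1)
    n_perm_used <- n_perm
  }
  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    Df = c(df, df_res, n - 1L),
    SS = c(ss_obs, ss_res, ss_total),
    R2 = c(ss_obs, ss_res, ss_total) / ss_total,
    pseudo_F = c(f_obs, NA, NA),
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE)
  structure(tab, class = c("permanova_table", "data.frame"),
            n_perm = n_perm_used, exact = exact)
}

#' @export
print.permanova_table <- function(x, digits = 4, ...) {
  cat("Sequential PERMANOVA (Euclidean),",
      attr(x, "n_perm"), if (isTRUE(attr(x, "exact"))) "exact relabellings\n"
      else "permutations\n")
  y <- as.data.frame(x)
  y$SS <- signif(y$SS, digits); y$R2 <- round(y$R2, digits)
  y$pseudo_F <- round(y$pseudo_F, 3); y$p <- signif(y$p, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Repeatability of landmark digitization from replicate observers
#'
#' One-way multivariate variance decomposition of jointly superimposed
#' shape coordinates over individuals: the among-individual variance
#' component is separated from the measurement-error (within-individual,
#' between-digitization) component via the expected mean squares of the
#' one-way layout, and repeatability is
#' `r = among / (among + error)`, truncated to `[0, 1]`.
#'
#' @param fit a `gpa_fit` of all digitizations superimposed together, or a
#'   `p x 2 x n` aligned array, or an `n x d` coordinate matrix.
#' @param individual factor of individual identity, one entry per
#'   digitization.
#' @param observer optional factor of observer identity; at least two
#'   observers are required when given, and at least two digitizations per
#'   individual in any case.
#' @return Object of class `repeatability_estimate`: list with `r`,
#'   `among_component`, `error_component`, and the mean squares.
#' @export
repeatability <- function(fit, individual, observer = NULL) {
  Y <- if (is.matrix(fit) && length(dim(fit)) == 2) fit else shape_matrix(fit)
  individual <- factor(individual)
  if (!is.null(observer) && nlevels(factor(observer)) < 2L)
    stop("at least two observers are required")
  k_i <- table(individual)
  if (any(k_i < 2L))
    stop("every individual needs at least two digitizations")
  n <- nrow(Y); a <- nlevels(individual)
  Yc <- sweep(Y, 2, colMeans(Y))
  means <- rowsum(Yc, individual) / as.vector(k_i)
  ss_among <- sum(as.vector(k_i) * rowSums(means^2))
  ss_within <- sum(Yc^2) - ss_among
  ms_among <- ss_among / (a - 1)
  ms_within <- ss_within / (n - a)
  k0 <- (n - sum(k_i^2) / n) / (a - 1)   # balanced: the common replicate count
  among <- (ms_among - ms_within) / k0
  error <- ms_within
  r <- among / (among + error)
  r <- min(max(r, 0), 1)
  structure(list(r = r, among_component = max(among, 0),
                 error_component = error,
                 ms_among = ms_among, ms_within = ms_within,
                 n_individuals = a, n_digitizations = n),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat("Digitization repeatability r =", round(x$r, 3), "(",
      x$n_individuals, "individuals,", x$n_digitizations, "digitizations )\n")
  invisible(x)
}

#' Allometry test: shape against a size measure
#'
#' Sequential PERMANOVA of the aligned shape coordinates on an optional
#' covariate (entered first) followed by the size measure, typically the
#' natural logarithm of facial centroid size or body height, run within one
#' sex at a time in the standard design.
#'
#' @param fit a `gpa_fit`.
#' @param size numeric size measure per subject (e.g. `log(fit$centroid_sizes)`).
#' @param covariate optional numeric covariate entered before size (e.g. BMI).
#' @param n_perm,seed passed to [permanova()].
#' @return A `permanova_table`.
#' @export
allometry_test <- function(fit, size, covariate = NULL, n_perm = 10000L,
                           seed = NULL) {
  Y <- shape_matrix(fit)
  if (length(size) != nrow(Y))
    stop("size measure and subjects do not match")
  pred <- if (is.null(covariate)) data.frame(size = size)
          else data.frame(covariate = covariate, size = size)
  permanova(Y, pred, n_perm = n_perm, seed = seed)
}

#' Per-group mean shapes
#'
#' Arithmetic mean of the aligned coordinates within each group,
#' re-centered.  The grand mean of the group means weighted by group size
#' equals the overall consensus (up to centering).
#'
#' @param fit a `gpa_fit` or aligned `p x 2 x n` array.
#' @param labels grouping factor of length n.
#' @return `p x 2 x n_groups` array, group names in `dimnames`.
#' @export
group_mean_shapes <- function(fit, labels) {
  A <- if (inherits(fit, "gpa_fit")) fit$aligned else as_landmark_array(fit)
  if (!is.factor(labels)) labels <- factor(labels)
  if (any(table(labels) == 0L)) stop("empty group")
  if (length(labels) != dim(A)[3]) stop("labels and configurations differ")
  out <- array(NA_real_, c(dim(A)[1], 2, nlevels(labels)),
               dimnames = list(NULL, c("x", "y"), levels(labels)))
  for (g in levels(labels)) {
    idx <- which(labels == g)
    M <- apply(A[, , idx, drop = FALSE], c(1, 2), mean)
    out[, , g] <- center_config(M)
  }
  out
}

#' Exaggerate a shape difference
#'
#' Linear extrapolation `reference + k * (target - reference)`; `k = 3` is
#' the conventional factor for making subtle mean-shape differences
#' visible in deformation grids.  Note the operation is not composable:
#' applying `k` twice is not the same as `k^2` once.
#'
#' @param reference `p x 2` reference shape.
#' @param target `p x 2` target shape (aligned with the reference).
#' @param k non-negative exaggeration factor.
#' @return `p x 2` configuration.
#' @export
exaggerate <- function(reference, target, k) {
  if (k < 0) stop("k must be >= 0")
  as.matrix(reference) + k * (as.matrix(target) - as.matrix(reference))
}
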