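#' Body mass index
#'
#' @param weight_kg body mass in kg.
#' @param height_cm body height in cm.
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight_kg, height_cm) weight_kg / (height_cm / 100)^2

#' Assign age cohorts
#'
#' Default bounds follow the three-cohort design: young adults 17-29,
#' mid-adults 30-50, elderly above 50 years.
#'
#' @param age numeric ages in years.
#' @param bounds upper bounds of the young and mid cohorts.
#' @return Factor with levels `young`, `mid`, `elderly`.
#' @export
assign_cohort <- function(age, bounds = c(29, 50)) {
  cut(age, breaks = c(-Inf, bounds, Inf),
      labels = c("young", "mid", "elderly"))
}

#' Validate a subjects table
#'
#' Checks column presence, the BMI identity `bmi == weight/(height/100)^2`
#' where all three are present, the study age range, and cohort/age
#' consistency.
#'
#' @param subjects data.frame of subject records.
#' @param bounds cohort bounds, as in [assign_cohort()].
#' @return The table, invisibly; errors on violation.
#' @export
validate_subjects <- function(subjects, bounds = c(29, 50)) {
  need <- c("subject_id", "sex", "age")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop("subjects table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(subjects$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (any(subjects$age < 17, na.rm = TRUE))
    stop("ages below the study range (17+) present")
  has <- c("weight", "height", "bmi") %in% names(subjects)
  if (all(has)) {
    cc <- stats::complete.cases(subjects[, c("weight", "height", "bmi")])
    if (any(abs(subjects$bmi[cc] -
                bmi(subjects$weight[cc], subjects$height[cc])) > 1e-9))
      stop("bmi inconsistent with weight/(height/100)^2")
  }
  if ("cohort" %in% names(subjects)) {
    expect <- assign_cohort(subjects$age, bounds)
    if (any(as.character(subjects$cohort) != as.character(expect), na.rm = TRUE))
      stop("cohort labels inconsistent with ages")
  }
  invisible(subjects)
}

# Levene's test on mean-centered absolute deviations (the variance-equality
# gate used before choosing the pooled- or separate-variance t test)
levene_test <- function(x, g) {
  g <- factor(g)
  z <- abs(x - stats::ave(x, g))
  a <- stats::anova(stats::lm(z ~ g))
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1])
}

#' Two-sample t test gated by Levene's test
#'
#' Levene's test for equality of variances (mean-centered) decides the
#' branch: pooled-variance Student t with `df = n1 + n2 - 2` when variances
#' are compatible (`p >= alpha_levene`), Welch t with Welch-Satterthwaite
#' df otherwise.  The t statistic is male minus female, so positive t means
#' larger male values.
#'
#' @param x_male,x_female numeric samples (n >= 2 each; NAs dropped).
#' @param alpha_levene significance level for the variance gate.
#' @return List with `t`, `df` (non-integer in the Welch branch), `p`
#'   (two-sided), `variant` (`"pooled"` or `"welch"`), and `levene_p`.
#' @export
ttest_with_levene <- function(x_male, x_female, alpha_levene = 0.05) {
  x_male <- x_male[!is.na(x_male)]; x_female <- x_female[!is.na(x_female)]
  n1 <- length(x_male); n2 <- length(x_female)
  if (n1 < 2 || n2 < 2) stop("each group needs at least two observations")
  if (stats::var(x_male) == 0 && stats::var(x_female) == 0 &&
      mean(x_male) == mean(x_female))
    stop("zero variance in both groups with equal means: t undefined")
  lev <- levene_test(c(x_male, x_female),
                     rep(c("m", "f"), c(n1, n2)))
  pooled <- !is.na(lev$p) && lev$p >= alpha_levene
  tt <- stats::t.test(x_male, x_female, var.equal = pooled)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, variant = if (pooled) "pooled" else "welch",
       levene_p = lev$p)
}

#' Hedges' g effect size (male minus female)
#'
#' Standardized mean difference using the pooled standard deviation and the
#' small-sample correction `J = 1 - 3/(4 df - 1)`, `df = n1 + n2 - 2`;
#' appropriate for unequal group sizes.  Negative values mean the female
#' mean exceeds the male mean.
#'
#' @param x_male,x_female numeric samples (n >= 2 each; NAs dropped).
#' @return Signed Hedges' g.
#' @export
hedges_g <- function(x_male, x_female) {
  x_male <- x_male[!is.na(x_male)]; x_female <- x_female[!is.na(x_female)]
  n1 <- length(x_male); n2 <- length(x_female)
  if (n1 < 2 || n2 < 2) stop("each group needs at least two observations")
  df <- n1 + n2 - 2
  s_pooled <- sqrt(((n1 - 1) * stats::var(x_male) +
                    (n2 - 1) * stats::var(x_female)) / df)
  if (s_pooled == 0) stop("pooled standard deviation is zero")
  J <- 1 - 3 / (4 * df - 1)
  (mean(x_male) - mean(x_female)) / s_pooled * J
}

#' Sex-dimorphism table of body parameters
#'
#' Per parameter: male/female mean and SD, the Levene-gated t test and
#' Hedges' g; complete cases per parameter (the per-row df records the
#' actual usable n).
#'
#' @param subjects data.frame with `sex` plus the parameter columns.
#' @param params character vector of parameter column names.
#' @return data.frame, one row per parameter.
#' @export
dimorphism_table <- function(subjects, params) {
  male <- subjects$sex == "male"
  rows <- lapply(params, function(pn) {
    xm <- subjects[[pn]][male]; xf <- subjects[[pn]][!male]
    tt <- ttest_with_levene(xm, xf)
    data.frame(parameter = pn,
               male_mean = mean(xm, na.rm = TRUE), male_sd = stats::sd(xm, na.rm = TRUE),
               female_mean = mean(xf, na.rm = TRUE), female_sd = stats::sd(xf, na.rm = TRUE),
               t = tt$t, df = tt$df, variant = tt$variant,
               hedges_g = hedges_g(xm, xf), p = tt$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' ANCOVA sex effect controlled for BMI
#'
#' Fits `dv ~ bmi + sex` on complete cases and reports the sex effect by
#' type III (drop-term) sums of squares: `F`, partial eta squared
#' `SS_sex / (SS_sex + SS_residual)`, and p.  With a single covariate and a
#' two-level factor the drop-term SS is exactly the type III SS.
#'
#' @param dv numeric dependent variable (a facial index).
#' @param bmi numeric covariate.
#' @param sex factor or character with two levels.
#' @return List with `F`, `partial_eta2`, `p`, `df`, `n`.
#' @export
ancova_sex_effect <- function(dv, bmi, sex) {
  sex <- factor(sex)
  if (nlevels(droplevels(sex)) < 2) stop("sex is constant")
  cc <- stats::complete.cases(dv, bmi, sex)
  d <- data.frame(dv = dv[cc], bmi = bmi[cc], sex = droplevels(sex[cc]))
  full <- stats::lm(dv ~ bmi + sex, data = d)
  red <- stats::lm(dv ~ bmi, data = d)
  ss_sex <- sum(stats::residuals(red)^2) - sum(stats::residuals(full)^2)
  ss_res <- sum(stats::residuals(full)^2)
  df_res <- full$df.residual
  Fval <- (ss_sex / 1) / (ss_res / df_res)
  list(F = Fval, partial_eta2 = ss_sex / (ss_sex + ss_res),
       p = stats::pf(Fval, 1, df_res, lower.tail = FALSE),
       df = c(1, df_res), n = nrow(d))
}

#' Per-index ANCOVA of facial traits on a body trait, BMI-controlled
#'
#' For each of the 12 facial indices fits `index ~ bmi + trait` and reports
#' the trait effect (type III, after BMI): F, partial eta squared, p, and a
#' Bonferroni significance flag at `alpha / 12` (the 12 tested variables).
#'
#' @param dvs data.frame or matrix of the 12 index columns.
#' @param bmi numeric covariate.
#' @param trait numeric trait of interest (e.g. facial centroid size,
#'   body height, upper arm circumference).
#' @param alpha family significance level before correction.
#' @return data.frame, one row per index, with `F`, `partial_eta2`, `p`,
#'   `bonferroni_significant`.
#' @export
mancova_trait_effects <- function(dvs, bmi, trait, alpha = 0.05) {
  dvs <- as.data.frame(dvs)
  want <- index_names()
  miss <- setdiff(want, names(dvs))
  if (length(miss)) stop("missing dependent variable column(s): ",
                         paste(miss, collapse = ", "))
  m <- length(want)
  rows <- lapply(want, function(v) {
    cc <- stats::complete.cases(dvs[[v]], bmi, trait)
    d <- data.frame(dv = dvs[[v]][cc], bmi = bmi[cc], trait = trait[cc])
    full <- stats::lm(dv ~ bmi + trait, data = d)
    red <- stats::lm(dv ~ bmi, data = d)
    ss_t <- sum(stats::residuals(red)^2) - sum(stats::residuals(full)^2)
    ss_res <- sum(stats::residuals(full)^2)
    Fv <- ss_t / (ss_res / full$df.residual)
    p <- stats::pf(Fv, 1, full$df.residual, lower.tail = FALSE)
    data.frame(index = v, F = Fv, partial_eta2 = ss_t / (ss_t + ss_res),
               p = p, bonferroni_significant = p < alpha / m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Rao score p-value for adding one term to a glm (the entry test of the
# forward-Wald stepwise procedure)
.score_entry <- function(fit0, formula1, data) {
  fit1 <- stats::glm(formula1, data = data, family = stats::binomial())
  a <- stats::anova(fit0, fit1, test = "Rao")
  list(stat = a$Rao[2], p = a$`Pr(>Chi)`[2], fit = fit1)
}

#' Stepwise binary logistic regression (forward Wald algorithm)
#'
#' Greedy forward selection for a binary outcome: at each step the
#' candidate with the most significant score (Rao) test enters if its p is
#' below `p_enter` (ties broken by the larger statistic, then input column
#' order); after each entry, included predictors whose Wald p exceeds
#' `p_remove` are removed.  Selection stops when no candidate enters.
#' Reported: coefficients B with Wald p, the likelihood-ratio model p,
#' Cox-Snell and Nagelkerke pseudo-R^2, and apparent classification
#' accuracy at the 0.5 cutoff (plus optional k-fold cross-validated
#' accuracy).  Perfect separation is detected and flagged.
#'
#' @param predictors data.frame of candidate predictors (column order is
#'   the deterministic tie-break).
#' @param outcome binary outcome (factor, logical, or 0/1); the second
#'   factor level (or 1) is the modelled event.
#' @param p_enter entry threshold for the score test.
#' @param p_remove removal threshold for the Wald test.
#' @param cv_folds if > 0, also report `cv_accuracy` from k-fold
#'   cross-validation refitting the *selected* model.
#' @param seed seed for the cross-validation fold assignment.
#' @return Object of class `stepwise_model`: list with `selected` (in entry
#'   order), `coefficients`, `coef_p`, `model_p`, `r2_nagelkerke`,
#'   `r2_coxsnell`, `accuracy`, `cv_accuracy`, `converged`, `steps`.
#' @export
stepwise_logistic <- function(predictors, outcome, p_enter = 0.05,
                              p_remove = 0.10, cv_folds = 0L, seed = NULL) {
  X <- as.data.frame(predictors)
  if (ncol(X) < 2) stop("need at least two candidate predictors")
  y <- if (is.factor(outcome)) as.integer(outcome) - 1L
       else as.integer(as.logical(outcome))
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2)
    stop("outcome must be binary with both classes present")
  d <- cbind(.y = y, X)
  cand <- names(X)
  selected <- character(0)
  steps <- list()
  fml <- function(vars) stats::as.formula(
    paste(".y ~", if (length(vars)) paste(vars, collapse = " + ") else "1"))
  fit0 <- stats::glm(fml(selected), data = d, family = stats::binomial())
  repeat {
    remaining <- setdiff(cand, selected)
    if (!length(remaining)) break
    trials <- lapply(remaining, function(v)
      .score_entry(fit0, fml(c(selected, v)), d))
    ps <- vapply(trials, `[[`, 0, "p")
    stat <- vapply(trials, `[[`, 0, "stat")
    ord <- order(ps, -stat, match(remaining, cand))
    best <- ord[1]
    if (is.na(ps[best]) || ps[best] >= p_enter) break
    entered_now <- remaining[best]
    selected <- c(selected, entered_now)
    fit0 <- trials[[best]]$fit
    steps[[length(steps) + 1]] <- list(entered = entered_now, p = ps[best])
    # perfect separation: Wald statistics are meaningless, keep the term,
    # flag non-convergence and stop selecting
    fv <- stats::fitted(fit0)
    if (any(abs(stats::coef(fit0)[-1]) > 20) ||
        all(fv < 1e-6 | fv > 1 - 1e-6)) {
      steps[[length(steps) + 1]] <- list(separation = entered_now)
      break
    }
    # backward Wald check
    repeat {
      sm <- summary(fit0)$coefficients
      wald_p <- sm[-1, "Pr(>|z|)"]
      if (!length(wald_p) || max(wald_p) <= p_remove) break
      worst <- names(which.max(wald_p))
      selected <- setdiff(selected, worst)
      steps[[length(steps) + 1]] <- list(removed = worst, p = max(wald_p))
      fit0 <- stats::glm(fml(selected), data = d, family = stats::binomial())
      if (!length(selected)) break
    }
    # entry/removal oscillation (e.g. under separation): stop selection
    if (!(entered_now %in% selected)) break
    if (length(steps) > 2L * length(cand) + 10L) break
  }
  final <- fit0
  n <- length(y)
  dev0 <- stats::glm(.y ~ 1, data = d, family = stats::binomial())$deviance
  cs <- 1 - exp((final$deviance - dev0) / n)
  nk <- cs / (1 - exp(-dev0 / n))
  fitted <- stats::fitted(final)
  sep <- any(abs(stats::coef(final)[-1]) > 20) ||
    (length(selected) && all(fitted < 1e-8 | fitted > 1 - 1e-8))
  coef_p <- if (length(selected))
    summary(final)$coefficients[, "Pr(>|z|)"] else NULL
  model_p <- if (length(selected))
    stats::pchisq(dev0 - final$deviance, length(stats::coef(final)) - 1,
                  lower.tail = FALSE) else NA_real_
  cv_acc <- NA_real_
  if (cv_folds > 0 && length(selected)) {
    fold <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
    pred <- numeric(n)
    for (f in seq_len(cv_folds)) {
      fitf <- stats::glm(fml(selected), data = d[fold != f, , drop = FALSE],
                         family = stats::binomial())
      pred[fold == f] <- stats::predict(fitf, d[fold == f, , drop = FALSE],
                                        type = "response")
    }
    cv_acc <- mean((pred > 0.5) == (y == 1))
  }
  structure(list(selected = selected,
                 coefficients = stats::coef(final),
                 coef_p = coef_p, model_p = model_p,
                 r2_nagelkerke = nk, r2_coxsnell = cs,
                 accuracy = mean((fitted > 0.5) == (y == 1)),
                 cv_accuracy = cv_acc,
                 converged = final$converged && !sep,
                 steps = steps, fit = final),
            class = "stepwise_model")
}

#' Stepwise linear regression (forward algorithm)
#'
#' Forward inclusion by the partial F-to-enter test at `p_enter`; ties are
#' broken by the larger F, then input column order, so the procedure is
#' deterministic.  With a single candidate this reduces to plain
#' regression.
#'
#' @param predictors data.frame of candidate predictors.
#' @param response numeric response.
#' @param p_enter entry threshold.
#' @return Object of class `stepwise_model`: `selected`, `coefficients`,
#'   `coef_p` (t-test), `model_p` (overall F), `r2`, `steps`.
#' @export
stepwise_linear <- function(predictors, response, p_enter = 0.05) {
  X <- as.data.frame(predictors)
  d <- cbind(.y = as.numeric(response), X)
  cand <- names(X)
  selected <- character(0)
  steps <- list()
  fml <- function(vars) stats::as.formula(
    paste(".y ~", if (length(vars)) paste(vars, collapse = " + ") else "1"))
  fit0 <- stats::lm(fml(selected), data = d)
  repeat {
    remaining <- setdiff(cand, selected)
    if (!length(remaining)) break
    stats_f <- vapply(remaining, function(v) {
      fit1 <- stats::lm(fml(c(selected, v)), data = d)
      a <- stats::anova(fit0, fit1)
      c(F = a$F[2], p = a$`Pr(>F)`[2])
    }, c(F = 0, p = 0))
    ps <- stats_f["p", ]; Fs <- stats_f["F", ]
    ps[is.na(ps)] <- Inf
    ord <- order(ps, -Fs, match(remaining, cand))
    best <- ord[1]
    if (!is.finite(ps[best]) || ps[best] >= p_enter) break
    selected <- c(selected, remaining[best])
    steps[[length(steps) + 1]] <- list(entered = remaining[best], p = ps[best])
    fit0 <- stats::lm(fml(selected), data = d)
  }
  sm <- summary(fit0)
  model_p <- if (length(selected)) {
    f <- sm$fstatistic
    stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  } else NA_real_
  structure(list(selected = selected,
                 coefficients = stats::coef(fit0),
                 coef_p = if (length(selected)) sm$coefficients[, "Pr(>|t|)"] else NULL,
                 model_p = unname(model_p), r2 = sm$r.squared,
                 steps = steps, fit = fit0),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat("Stepwise model:", if (length(x$selected))
    paste(x$selected, collapse = " + ") else "(empty)", "\n")
  if (!is.null(x$r2)) cat("R2 =", round(x$r2, 3), "\n")
  if (!is.null(x$r2_nagelkerke))
    cat("Nagelkerke R2 =", round(x$r2_nagelkerke, 3),
        "; apparent accuracy =", round(x$accuracy, 3), "\n")
  invisible(x)
}

#' Cubic age trend of a body parameter
#'
#' Least-squares fit of `y ~ age + age^2 + age^3`; reports the coefficient
#' vector, the coefficient of determination and the overall-model F test
#' p-value, the standard summary of nonlinear cross-sectional age
#' trajectories.
#'
#' @param y numeric response.
#' @param age numeric ages.
#' @return List with `r_squared`, `p`, `coefficients`.
#' @export
cubic_trend <- function(y, age) {
  cc <- stats::complete.cases(y, age)
  y <- y[cc]; age <- age[cc]
  if (length(y) <= 4) stop("need n > 4 for a cubic fit")
  X <- cbind(age, age^2, age^3)
  if (qr(cbind(1, X))$rank < 4)
    stop("age values too collinear/degenerate for a cubic fit")
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)
  f <- sm$fstatistic
  list(r_squared = sm$r.squared,
       p = unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE)),
       coefficients = stats::setNames(stats::coef(fit),
                                      c("intercept", "age", "age2", "age3")))
}
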