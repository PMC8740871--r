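#' Analysis configuration for the full dimorphism pipeline
#'
#' @param tps path to the TPS landmark file.
#' @param subjects path to the subjects CSV (columns `subject_id`, `sex`,
#'   `age`, and the body parameters).
#' @param scheme path to a scheme YAML, or a `landmark_scheme`; default the
#'   bundled 71-point scheme.
#' @param out output directory (created if needed).
#' @param n_perm permutations for all shape tests (>= 99).
#' @param seed root seed; every stochastic step derives from it.
#' @param cohort_bounds upper age bounds of the young and mid cohorts.
#' @param slide slide semilandmarks during superimposition.
#' @param symmetrize symmetrize configurations (then re-superimpose).
#' @param exaggeration factor k for the visual shape-difference targets.
#' @param bonferroni_m number of variables in the multiple-testing family.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(tps, subjects, scheme = NULL, out = "facedim_out",
                            n_perm = 10000L, seed = 1L,
                            cohort_bounds = c(29, 50), slide = TRUE,
                            symmetrize = TRUE, exaggeration = 3,
                            bonferroni_m = 12L) {
  if (n_perm < 99L) stop("n_perm must be at least 99")
  if (exaggeration < 0) stop("exaggeration must be >= 0")
  structure(list(tps = tps, subjects = subjects, scheme = scheme, out = out,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 cohort_bounds = cohort_bounds, slide = slide,
                 symmetrize = symmetrize, exaggeration = exaggeration,
                 bonferroni_m = as.integer(bonferroni_m)),
            class = "analysis_config")
}

.resolve_scheme <- function(scheme) {
  if (is.null(scheme)) default_scheme()
  else if (inherits(scheme, "landmark_scheme")) scheme
  else load_scheme(scheme)
}

.write_tab <- function(x, out, name, logmsg) {
  path <- file.path(out, paste0(name, ".csv"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  logmsg(paste("wrote", path))
  path
}

#' Run the full facial/body dimorphism analysis
#'
#' Orchestrates the whole pipeline on a landmark file plus subjects table:
#' superimposition (GPA with optional sliding, optional symmetrization with
#' re-superimposition), whole-sample sequential shape PERMANOVA (age before
#' sex), per-cohort sex and BMI-then-sex PERMANOVAs, the facial-index
#' dimorphism table (BMI-controlled ANCOVA), the body dimorphism table
#' (Levene-gated t, Hedges' g), the stepwise logistic sex model, per-sex
#' allometry (shape on log centroid size, BMI-controlled, and the
#' index-level MANCOVA), per-sex stepwise linear models of handgrip
#' strength, cubic age trends, and per-cohort sex mean shapes with
#' exaggerated difference targets (deformation-grid figures where the
#' graphics device allows).  All outputs are written as CSV (plus a JSON
#' run log) under `config$out`; the run is deterministic given the seed.
#'
#' @param config an [analysis_config()].
#' @return Invisible list with all result objects.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  logmsg <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  scheme <- .resolve_scheme(config$scheme)
  A <- read_tps(config$tps, scheme = scheme)
  subjects <- utils::read.csv(config$subjects, stringsAsFactors = FALSE)
  subjects$cohort <- assign_cohort(subjects$age, config$cohort_bounds)
  validate_subjects(subjects, config$cohort_bounds)
  ids <- dimnames(A)[[3]]
  common <- intersect(ids, subjects$subject_id)
  if (length(common) < length(ids))
    logmsg(paste("excluded", length(ids) - length(common),
              "configurations without subject records"))
  A <- A[, , match(common, ids), drop = FALSE]
  subjects <- subjects[match(common, subjects$subject_id), ]
  n <- length(common)
  logmsg(sprintf("n = %d subjects (%d male, %d female)", n,
              sum(subjects$sex == "male"), sum(subjects$sex == "female")))

  fit <- gpa(A, scheme, slide = config$slide)
  logmsg(sprintf("GPA: %d iterations, slide = %s", fit$n_iterations,
              config$slide))
  if (config$symmetrize) {
    A_sym <- symmetrize(fit$aligned, scheme)
    fit2 <- gpa(A_sym, scheme, slide = FALSE)
    fit2$centroid_sizes <- fit$centroid_sizes  # sizes recorded before scaling
    fit <- fit2
    logmsg("symmetrized and re-superimposed")
  }
  subjects$facial_cs <- fit$centroid_sizes
  Y <- shape_matrix(fit)
  results <- list(gpa = fit, subjects = subjects)
  write_gpa(fit, file.path(config$out, "gpa_aligned"))

  # whole-sample shape variance decomposition: age entered before sex
  results$permanova_whole <- permanova(
    Y, data.frame(age = subjects$age, sex = factor(subjects$sex)),
    n_perm = config$n_perm, seed = config$seed)
  .write_tab(results$permanova_whole, config$out, "permanova_whole_age_sex", logmsg)

  # per-cohort: sex alone, and BMI before sex
  results$permanova_cohort <- list()
  for (ch in levels(subjects$cohort)) {
    idx <- subjects$cohort == ch
    if (sum(idx) < 4 || length(unique(subjects$sex[idx])) < 2) next
    tab_sex <- permanova(Y[idx, , drop = FALSE],
                         data.frame(sex = factor(subjects$sex[idx])),
                         n_perm = config$n_perm, seed = config$seed + 1L)
    tab_bmi <- permanova(Y[idx, , drop = FALSE],
                         data.frame(bmi = subjects$bmi[idx],
                                    sex = factor(subjects$sex[idx])),
                         n_perm = config$n_perm, seed = config$seed + 2L)
    results$permanova_cohort[[ch]] <- list(sex = tab_sex, bmi_sex = tab_bmi)
    .write_tab(tab_sex, config$out, paste0("permanova_", ch, "_sex"), logmsg)
    .write_tab(tab_bmi, config$out, paste0("permanova_", ch, "_bmi_sex"), logmsg)
  }

  # facial indices and their BMI-controlled sex dimorphism (young + mid)
  idx_tab <- index_table(fit$aligned, scheme, subjects)
  results$indices <- idx_tab
  .write_tab(idx_tab, config$out, "facial_indices", logmsg)
  index_dimorphism <- list()
  for (ch in c("young", "mid")) {
    rows <- lapply(index_names(), function(v) {
      sel <- idx_tab$cohort == ch
      a <- ancova_sex_effect(idx_tab[[v]][sel], idx_tab$bmi[sel],
                             idx_tab$sex[sel])
      male <- sel & idx_tab$sex == "male"
      fem <- sel & idx_tab$sex == "female"
      data.frame(cohort = ch, index = v,
                 male_mean = mean(idx_tab[[v]][male]),
                 male_sd = stats::sd(idx_tab[[v]][male]),
                 female_mean = mean(idx_tab[[v]][fem]),
                 female_sd = stats::sd(idx_tab[[v]][fem]),
                 F = a$F, partial_eta2 = a$partial_eta2, p = a$p)
    })
    index_dimorphism[[ch]] <- do.call(rbind, rows)
  }
  results$index_dimorphism <- do.call(rbind, index_dimorphism)
  .write_tab(results$index_dimorphism, config$out, "index_dimorphism", logmsg)

  # body dimorphism (young + mid), per cohort
  body_params <- c("height", "weight", "bmi", "handgrip", "wrist",
                   "upper_arm", "triceps", "under_chest", "hips", "facial_cs")
  body_params <- intersect(body_params, names(subjects))
  body_dim <- lapply(c("young", "mid"), function(ch) {
    sel <- subjects$cohort == ch
    cbind(cohort = ch, dimorphism_table(subjects[sel, ], body_params))
  })
  results$body_dimorphism <- do.call(rbind, body_dim)
  .write_tab(results$body_dimorphism, config$out, "body_dimorphism", logmsg)

  # stepwise logistic sex model on young + mid adults
  am <- subjects$cohort %in% c("young", "mid")
  preds <- subjects[am, body_params]
  results$sex_model <- stepwise_logistic(
    preds, factor(subjects$sex[am], levels = c("male", "female")),
    cv_folds = 10L, seed = config$seed + 3L)
  logmsg(sprintf("logistic sex model: %s; apparent accuracy %.3f",
              paste(results$sex_model$selected, collapse = " + "),
              results$sex_model$accuracy))
  .write_tab(data.frame(predictor = names(results$sex_model$coefficients),
                        B = results$sex_model$coefficients,
                        p = c(results$sex_model$coef_p)),
             config$out, "sex_model_logistic", logmsg)

  # per-sex allometry on pooled young + mid adults
  results$allometry <- list()
  for (sx in c("male", "female")) {
    sel <- am & subjects$sex == sx
    if (sum(sel) < 5) next
    fit_s <- gpa(A[, , sel, drop = FALSE], scheme, slide = config$slide)
    tab <- allometry_test(fit_s, log(fit_s$centroid_sizes),
                          covariate = subjects$bmi[sel],
                          n_perm = config$n_perm, seed = config$seed + 4L)
    results$allometry[[sx]] <- tab
    .write_tab(tab, config$out, paste0("allometry_", sx), logmsg)
    manc <- mancova_trait_effects(
      idx_tab[idx_tab$subject_id %in% subjects$subject_id[sel],
              index_names()],
      subjects$bmi[sel], log(fit$centroid_sizes[sel]))
    results$allometry_indices[[sx]] <- manc
    .write_tab(manc, config$out, paste0("allometry_indices_", sx), logmsg)
  }

  # handgrip-strength predictors per sex (young + mid)
  hgs_preds <- c("height", "weight", "bmi", "wrist", "upper_arm",
                 "triceps", "under_chest", "hips", "facial_cs")
  results$hgs_model <- list()
  for (sx in c("male", "female")) {
    sel <- am & subjects$sex == sx
    m <- stepwise_linear(subjects[sel, intersect(hgs_preds, names(subjects))],
                         subjects$handgrip[sel])
    results$hgs_model[[sx]] <- m
    .write_tab(data.frame(sex = sx,
                          predictor = names(m$coefficients),
                          B = m$coefficients,
                          r2 = m$r2, model_p = m$model_p),
               config$out, paste0("hgs_stepwise_", sx), logmsg)
  }

  # cubic age trends per parameter and sex
  trend_rows <- list()
  for (sx in c("male", "female")) for (pv in body_params) {
    sel <- subjects$sex == sx
    tr <- cubic_trend(subjects[[pv]][sel], subjects$age[sel])
    trend_rows[[paste(sx, pv)]] <- data.frame(
      sex = sx, parameter = pv, r_squared = tr$r_squared, p = tr$p)
  }
  results$age_trends <- do.call(rbind, trend_rows)
  .write_tab(results$age_trends, config$out, "cubic_age_trends", logmsg)

  # per-cohort sex mean shapes and exaggerated difference targets
  grp <- interaction(subjects$cohort, subjects$sex, drop = TRUE)
  means <- group_mean_shapes(fit, grp)
  results$mean_shapes <- means
  for (ch in levels(subjects$cohort)) {
    fm <- paste0(ch, ".female"); mm <- paste0(ch, ".male")
    if (!all(c(fm, mm) %in% dimnames(means)[[3]])) next
    for (k in unique(c(1, config$exaggeration))) {
      target <- exaggerate(means[, , fm], means[, , mm], k)
      grid <- tps_grid(means[, , fm], target)
      fname <- file.path(config$out,
                         sprintf("grid_%s_k%g.svg", ch, k))
      ok <- tryCatch({
        grDevices::svg(fname, width = 5, height = 6)
        plot(grid, main = sprintf("%s: female -> male, k = %g", ch, k))
        grDevices::dev.off()
        TRUE
      }, error = function(e) FALSE)
      if (ok) logmsg(paste("wrote", fname))
      else logmsg(paste("svg device unavailable; skipped", fname))
    }
  }
  jsonlite::write_json(list(n = n, seed = config$seed, n_perm = config$n_perm,
                            slide = config$slide,
                            symmetrize = config$symmetrize, log = log_lines),
                       file.path(config$out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Simulate a synthetic dataset to disk
#'
#' Wraps [generate_cohort()] and writes the TPS landmark file, the subjects
#' CSV and a design echo (YAML) that reloads to an equal design.
#'
#' @param design a [synthetic_design()].
#' @param out output directory.
#' @param scheme the landmark scheme.
#' @return Invisible list of written paths.
#' @export
simulate_cohort <- function(design = synthetic_design(), out = "facedim_sim",
                            scheme = default_scheme()) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_cohort(design, scheme)
  tps <- file.path(out, "landmarks.tps")
  write_tps(gen$configs, tps, scale = 1)
  csv <- file.path(out, "subjects.csv")
  utils::write.csv(gen$subjects, csv, row.names = FALSE)
  dy <- file.path(out, "design.yaml")
  echo <- gen$design
  echo$body_correlation <- NULL
  yaml::write_yaml(lapply(unclass(echo), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x), dy)
  sy <- file.path(out, "scheme.yaml")
  write_scheme(scheme, sy)
  invisible(list(tps = tps, subjects = csv, design = dy, scheme = sy))
}

#' Reload a design echo written by [simulate_cohort()]
#'
#' @param path path to `design.yaml`.
#' @return A `synthetic_design`.
#' @export
read_design <- function(path) {
  y <- yaml::read_yaml(path)
  synthetic_design(
    n_male = unlist(y$n_male), n_female = unlist(y$n_female),
    sex_shape_R2 = y$sex_shape_R2, age_shape_R2 = y$age_shape_R2,
    bmi_effect = y$bmi_effect, landmark_noise_sd = y$landmark_noise_sd,
    target_repeatability = y$target_repeatability,
    cohort_bounds = unlist(y$cohort_bounds), max_age = y$max_age,
    jitter_pose = y$jitter_pose, seed = y$seed)
}
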