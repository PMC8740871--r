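#' Reference body-parameter moments per sex and age cohort
#'
#' Means and standard deviations of the nine anthropometric parameters and
#' facial centroid size for young-adult (17-29) and mid-adult (30-50) men
#' and women of a traditional East African pastoralist population; these are
#' the default calibration constants of the synthetic cohort generator.
#' The elderly cohort is a synthetic stand-in reusing the mid-adult moments
#' (no printed reference values exist for it).
#'
#' @return data.frame with columns `cohort`, `sex`, `parameter`, `mean`, `sd`.
#' @export
body_reference_params <- function() {
  par9 <- c("height", "bmi", "handgrip", "wrist", "upper_arm",
            "triceps", "under_chest", "hips", "facial_cs")
  young_m <- c(167.5, 19.8, 38.4, 55.9, 24.4, 8.7, 77.5, 87.4, 56.0)
  young_m_sd <- c(7.1, 2.2, 8.9, 3.6, 2.4, 5.4, 4.7, 6.3, 3.8)
  young_f <- c(155.3, 21.0, 26.2, 52.0, 24.2, 13.8, 72.8, 90.6, 51.6)
  young_f_sd <- c(5.4, 3.8, 4.7, 5.1, 2.5, 5.4, 4.9, 5.7, 3.4)
  mid_m <- c(168.1, 19.8, 37.9, 56.1, 24.9, 9.0, 79.9, 89.4, 57.9)
  mid_m_sd <- c(6.4, 2.4, 7.9, 3.7, 2.3, 8.3, 5.8, 6.3, 3.8)
  mid_f <- c(156.3, 21.7, 25.9, 53.2, 27.2, 16.6, 74.7, 93.8, 53.1)
  mid_f_sd <- c(6.1, 3.5, 5.4, 5.5, 9.2, 7.5, 7.8, 7.5, 3.4)
  rbind(
    data.frame(cohort = "young", sex = "male", parameter = par9,
               mean = young_m, sd = young_m_sd),
    data.frame(cohort = "young", sex = "female", parameter = par9,
               mean = young_f, sd = young_f_sd),
    data.frame(cohort = "mid", sex = "male", parameter = par9,
               mean = mid_m, sd = mid_m_sd),
    data.frame(cohort = "mid", sex = "female", parameter = par9,
               mean = mid_f, sd = mid_f_sd),
    data.frame(cohort = "elderly", sex = "male", parameter = par9,
               mean = mid_m, sd = mid_m_sd),
    data.frame(cohort = "elderly", sex = "female", parameter = par9,
               mean = mid_f, sd = mid_f_sd))
}

# raw coordinates (cm-scale before normalization) of the bundled 71-point
# template, in scheme order; bilaterally exact, proportions set so the
# classical indices take typical adult values (upper fWHR 1.85 etc.)
.template_coords <- function() {
  mid <- rbind(
    Tr = c(0, 8.8),   Gl = c(0, 5.079), N = c(0, 4.431), Prn = c(0, 0.9),
    Sn = c(0, 0),     Ls = c(0, -0.93), Sto = c(0, -1.969),
    Li = c(0, -3.01), Gn = c(0, -5.776))
  fp <- rbind(
    Zy = c(5.92, 2.6),  Go = c(4.736, -3.9), Ch = c(2.309, -1.969),
    Al = c(1.905, 0.25), Ex = c(4.3, 4.1),   En = c(1.55, 4.0),
    Ps = c(2.95, 4.47), Pi = c(2.95, 3.73),  Pu = c(2.95, 4.1),
    EbM = c(1.3, 5.35), EbL = c(4.45, 5.15), Chk = c(3.4, 1.2),
    Tmp = c(5.0, 7.0),  Nst = c(0.95, 0.12))
  outline <- rbind(c(2.3, 8.5), c(4.2, 7.55), c(5.35, 6.2), c(5.9, 4.5),
                   c(5.8, 1.4), c(5.5, -0.6), c(5.0, -2.2), c(4.1, -4.2),
                   c(2.8, -4.9), c(1.45, -5.5))
  brow <- rbind(c(2.25, 5.6), c(2.95, 5.7), c(3.7, 5.55))
  lipU <- rbind(c(1.55, -1.4), c(0.78, -1.05))
  lipL <- rbind(c(1.55, -2.55), c(0.78, -2.9))
  fixed_pairs <- matrix(NA_real_, 28, 2)
  for (k in seq_len(14)) {
    fixed_pairs[2 * k - 1, ] <- c(-fp[k, 1], fp[k, 2])
    fixed_pairs[2 * k, ] <- fp[k, ]
  }
  semis <- rbind(cbind(-outline[, 1], outline[, 2]), outline,
                 cbind(-brow[, 1], brow[, 2]), brow,
                 cbind(-lipU[, 1], lipU[, 2]), lipU,
                 cbind(-lipL[, 1], lipL[, 2]), lipL)
  X <- rbind(mid, fixed_pairs, semis)
  dimnames(X) <- list(.frontal71_names(), c("x", "y"))
  X
}

#' Deterministic symmetric mean-face template
#'
#' A bilaterally exact 71-point frontal-face template in cm, centered, with
#' centroid size 54 cm (between typical male and female facial centroid
#' sizes).  All twelve facial indices are finite and positive on it and it
#' is a fixed point of [symmetrize()].
#'
#' @param scheme the bundled [default_scheme()] (the template is only
#'   defined for it).
#' @return `p x 2` coordinate matrix.
#' @export
generate_mean_face <- function(scheme = default_scheme()) {
  X <- .template_coords()
  if (!identical(scheme$names, rownames(X)))
    stop("the mean-face template is defined for the bundled default scheme")
  X <- center_config(X)
  X * (54 / centroid_size(X))
}

# displacement fields (stacked x1..xp, y1..yp) used to plant effects ----

.field <- function(scheme, spec_list) {
  p <- length(scheme$names)
  v <- numeric(2 * p)
  for (s in spec_list) {
    i <- match(s$at, scheme$names)
    if (anyNA(i)) stop("unknown landmark in field: ",
                       paste(s$at[is.na(i)], collapse = ", "))
    v[i] <- v[i] + s$dx
    v[i + p] <- v[i + p] + s$dy
  }
  v
}

.both <- function(stub) c(paste0(stub, "_l"), paste0(stub, "_r"))

# male-minus-female shape direction: relatively narrower, vertically
# prolonged face, wider nose, narrower-set and lower eyebrows, wider mouth,
# higher forehead hairline
.sex_field <- function(scheme, template) {
  p <- length(scheme$names)
  x <- template[, 1]
  lateral <- c(.both("Zy"), .both("Go"), .both("Chk"), .both("Tmp"),
               paste0("out", 2:9, "_l"), paste0("out", 2:9, "_r"))
  brows <- c(.both("EbM"), .both("EbL"),
             paste0("brow", 1:3, "_l"), paste0("brow", 1:3, "_r"))
  nose <- c(.both("Al"), .both("Nst"))
  spec <- list(
    list(at = lateral, dx = -0.5 * sign(x[match(lateral, scheme$names)]), dy = 0),
    list(at = c("Gn", "Li", paste0("out", 9:10, "_l"), paste0("out", 9:10, "_r")),
         dx = 0, dy = -0.45),
    list(at = c("Tr", .both("out1")), dx = 0, dy = 0.4),
    list(at = nose, dx = 0.35 * sign(x[match(nose, scheme$names)]), dy = 0),
    list(at = brows, dx = -0.12 * sign(x[match(brows, scheme$names)]), dy = -0.35),
    list(at = .both("Ch"), dx = 0.25 * sign(x[match(.both("Ch"), scheme$names)]),
         dy = 0))
  .field(scheme, spec)
}

# cross-sectional aging field: drooping lower face and brows, lengthening
# nose, thinning lips
.age_field <- function(scheme, template) {
  x <- template[, 1]
  jaw <- c(.both("Go"), "Gn", paste0("out", 7:10, "_l"), paste0("out", 7:10, "_r"))
  brows <- c(.both("EbM"), .both("EbL"),
             paste0("brow", 1:3, "_l"), paste0("brow", 1:3, "_r"))
  spec <- list(
    list(at = jaw, dx = 0.18 * sign(x[match(jaw, scheme$names)]), dy = -0.4),
    list(at = brows, dx = 0, dy = -0.3),
    list(at = c("Sn", "Prn", .both("Al")), dx = 0, dy = -0.3),
    list(at = "Ls", dx = 0, dy = -0.18),
    list(at = "Li", dx = 0, dy = 0.18))
  .field(scheme, spec)
}

# adiposity field: widening of the cheeks and the bigonial region
.bmi_field <- function(scheme, template) {
  x <- template[, 1]
  cheeks <- c(.both("Chk"), .both("Go"),
              paste0("out", 5:8, "_l"), paste0("out", 5:8, "_r"))
  .field(scheme, list(
    list(at = cheeks, dx = 0.5 * sign(x[match(cheeks, scheme$names)]), dy = 0)))
}

# orthonormalize planted directions within the tangent space of the template
.planted_directions <- function(scheme, template) {
  basis <- similarity_basis(template)
  dirs <- cbind(sex = .sex_field(scheme, template),
                age = .age_field(scheme, template),
                bmi = .bmi_field(scheme, template))
  D <- project_tangent(dirs, basis)
  Q <- qr.Q(qr(D))
  # keep each column's overall orientation aligned with its raw field
  for (j in seq_len(ncol(Q)))
    if (sum(Q[, j] * dirs[, j]) < 0) Q[, j] <- -Q[, j]
  colnames(Q) <- colnames(dirs)
  list(directions = Q, basis = basis)
}

#' Analytic calibration of a planted two-group shape effect
#'
#' Closed-form magnitude `m` of a two-group mean shift `m * direction`
#' (unit direction) in isotropic noise such that the sequential-PERMANOVA
#' variance fraction for the group term equals `target_R2`.  With
#' `expectation = "estimator"` (default) the calibration targets the
#' expectation of the estimated R-squared, accounting for the noise that a
#' fitted term captures (`E[SS_term] = signal + sigma^2 * dim` per degree
#' of freedom); with `"population"` it targets the planted population
#' fraction `between / total` with `total = between + (n-1) * sigma^2 * dim`,
#' which over-recovers by about `1/(n-1)` at small effects.
#'
#' @param target_R2 variance fraction in `[0, 1)` for the group term.
#' @param n1,n2 group sizes.
#' @param noise_variance per-coordinate noise variance `sigma^2`.
#' @param dim number of (effective) response dimensions carrying noise.
#' @param n_model_terms total number of single-df terms fitted in the
#'   sequential model (including this one).
#' @param other_R2 summed target fractions of the other fitted terms.
#' @param expectation `"estimator"` or `"population"` (see above).
#' @return Shift magnitude `m >= 0`.
#' @export
calibrate_effect <- function(target_R2, n1, n2, noise_variance, dim,
                             n_model_terms = 1L, other_R2 = 0,
                             expectation = c("estimator", "population")) {
  expectation <- match.arg(expectation)
  if (target_R2 < 0 || target_R2 + other_R2 >= 1)
    stop("infeasible target: variance fractions must lie in [0, 1)")
  if (target_R2 == 0) return(0)
  n <- n1 + n2
  s2d <- noise_variance * dim
  between <- if (expectation == "population") {
    target_R2 / (1 - target_R2) * (n - 1) * s2d
  } else {
    total <- (n - 1 - n_model_terms) * s2d / (1 - target_R2 - other_R2)
    b <- target_R2 * total - s2d
    if (b <= 0)
      stop("target_R2 is below the null expectation of a fitted term ",
           "at this n and cannot be planted")
    b
  }
  sqrt(between * n / (n1 * n2))
}

# exact realized-design calibration for the [age, sex] sequential model:
# given centered age a and centered male indicator z, solve for the age
# slope beta and sex shift m so the expected sequential R2 equal the targets
.solve_planted <- function(a, z, t_age, t_sex, sigma2, d) {
  n <- length(z)
  s2d <- sigma2 * d
  active <- c(age = t_age > 0, sex = t_sex > 0)
  q <- sum(active)
  if (q == 0) return(list(beta = 0, m = 0))
  total <- (n - 1 - q) * s2d / (1 - t_age - t_sex)
  m <- beta <- 0
  if (active["sex"] && !active["age"]) {
    B_sex <- t_sex * total - s2d
    if (B_sex <= 0) stop("sex target below null expectation")
    m <- sqrt(B_sex / sum((z - mean(z))^2))
  } else if (active["age"] && !active["sex"]) {
    B_age <- t_age * total - s2d
    if (B_age <= 0) stop("age target below null expectation")
    beta <- sqrt(B_age / sum((a - mean(a))^2))
  } else {
    ac <- a - mean(a); zc <- z - mean(z)
    az <- sum(ac * zc); aa <- sum(ac^2)
    zperp <- zc - ac * az / aa
    B_age <- t_age * total - s2d
    B_sex <- t_sex * total - s2d
    if (B_age <= 0 || B_sex <= 0) stop("target below null expectation")
    m <- sqrt(B_sex / sum(zperp^2))
    b2 <- (B_age - m^2 * az^2 / aa) / aa
    if (b2 < 0) stop("age and sex too collinear to plant both targets")
    beta <- sqrt(b2)
  }
  list(beta = beta, m = m)
}

#' Synthetic cohort design
#'
#' Bundles the study-design constants of the synthetic generator: per-cohort
#' and per-sex sample sizes (defaults: young 72/46, mid 70/46, elderly 43/28
#' — the 185:120 sex ratio within cohorts of 118/116/71), the planted
#' whole-sample shape variance fractions for sex (1.8%) and age (6%), the
#' BMI shape coefficient (default 0 so that the planted sex/age
#' decomposition stays exactly identifiable), the landmark noise level, the
#' target digitization repeatability (0.91), and the cohort age bounds.
#'
#' @param n_male,n_female named integer vectors per cohort.
#' @param sex_shape_R2,age_shape_R2 planted variance fractions in `[0, 1)`.
#' @param bmi_effect cm of cheek/bigonial widening per kg/m^2 of BMI.
#' @param landmark_noise_sd per-coordinate individual shape noise, cm at
#'   template scale.
#' @param target_repeatability planted inter-observer agreement.
#' @param cohort_bounds upper age bounds of the young and mid cohorts.
#' @param max_age oldest age generated.
#' @param jitter_pose add random rotation/translation to each configuration
#'   (removed again by superimposition).
#' @param body_correlation optional 9 x 9 correlation matrix for the body
#'   parameters (order of [body_reference_params()]); default independent.
#' @param seed RNG seed; same seed, same cohort, byte for byte.
#' @return List of class `synthetic_design`.
#' @export
synthetic_design <- function(n_male = c(young = 72, mid = 70, elderly = 43),
                             n_female = c(young = 46, mid = 46, elderly = 28),
                             sex_shape_R2 = 0.018, age_shape_R2 = 0.06,
                             bmi_effect = 0, landmark_noise_sd = 0.25,
                             target_repeatability = 0.91,
                             cohort_bounds = c(29, 50), max_age = 90,
                             jitter_pose = TRUE, body_correlation = NULL,
                             seed = 1L) {
  if (sex_shape_R2 < 0 || sex_shape_R2 >= 1 ||
      age_shape_R2 < 0 || age_shape_R2 >= 1 ||
      sex_shape_R2 + age_shape_R2 >= 1)
    stop("variance fractions must lie in [0, 1) and sum below 1")
  if (any(c(n_male, n_female) < 2))
    stop("need n >= 2 per sex within every generated cohort")
  if (target_repeatability <= 0 || target_repeatability > 1)
    stop("target_repeatability must be in (0, 1]")
  structure(list(n_male = n_male, n_female = n_female,
                 sex_shape_R2 = sex_shape_R2, age_shape_R2 = age_shape_R2,
                 bmi_effect = bmi_effect,
                 landmark_noise_sd = landmark_noise_sd,
                 target_repeatability = target_repeatability,
                 cohort_bounds = cohort_bounds, max_age = max_age,
                 jitter_pose = jitter_pose,
                 body_correlation = body_correlation, seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Generate a synthetic landmark-and-body cohort
#'
#' Draws subjects per cohort and sex, samples their body parameters from
#' the per-sex/cohort reference normals (weight is derived from height and
#' BMI so the BMI identity holds exactly), and builds each face as the
#' symmetric template plus a calibrated sex mean-shift, a calibrated linear
#' age trajectory, an optional BMI widening, and isotropic individual shape
#' noise — all planted in the tangent (shape) space of the template, so the
#' effective noise dimension is `2p - 4` and Procrustes superimposition
#' recovers exactly the planted structure.  Effect magnitudes come from the
#' realized-design analogue of [calibrate_effect()], never from hand tuning.
#' Each configuration is scaled to its subject's drawn facial centroid size
#' and optionally pose-jittered.
#'
#' @param design a [synthetic_design()].
#' @param scheme the bundled [default_scheme()].
#' @return List with `configs` (`p x 2 x n` array, cm), `subjects`
#'   (data.frame with sex, age, cohort, the body parameters, BMI and facial
#'   centroid size), `design`, and `planted` (magnitudes and directions).
#' @export
generate_cohort <- function(design = synthetic_design(),
                            scheme = default_scheme()) {
  stopifnot(inherits(design, "synthetic_design"))
  with_seed(design$seed, .generate_cohort_impl(design, scheme))
}

.generate_cohort_impl <- function(design, scheme) {
  cohorts <- names(design$n_male)
  lo <- c(young = 17, mid = design$cohort_bounds[1] + 1e-9,
          elderly = design$cohort_bounds[2] + 1e-9)
  hi <- c(young = design$cohort_bounds[1], mid = design$cohort_bounds[2],
          elderly = design$max_age)
  ref <- body_reference_params()
  subj <- list()
  for (ch in cohorts) {
    for (sx in c("male", "female")) {
      nn <- if (sx == "male") design$n_male[[ch]] else design$n_female[[ch]]
      if (nn == 0) next
      age <- stats::runif(nn, lo[[ch]], hi[[ch]])
      pars <- ref[ref$cohort == ch & ref$sex == sx, ]
      draws <- matrix(stats::rnorm(nn * nrow(pars)), nn, nrow(pars))
      if (!is.null(design$body_correlation)) {
        R <- design$body_correlation
        draws <- draws %*% chol(R[seq_len(nrow(pars)), seq_len(nrow(pars))])
      }
      vals <- sweep(sweep(draws, 2, pars$sd, "*"), 2, pars$mean, "+")
      colnames(vals) <- pars$parameter
      subj[[length(subj) + 1]] <- data.frame(
        sex = sx, age = age, cohort = ch, vals,
        stringsAsFactors = FALSE)
    }
  }
  subjects <- do.call(rbind, subj)
  n <- nrow(subjects)
  subjects$subject_id <- sprintf("S%03d", seq_len(n))
  subjects$weight <- subjects$bmi * (subjects$height / 100)^2
  subjects$cohort <- factor(subjects$cohort, levels = cohorts)
  # planted shape structure
  template <- generate_mean_face(scheme)
  p <- nrow(template)
  d_eff <- 2 * p - 4
  pd <- .planted_directions(scheme, template)
  sigma <- design$landmark_noise_sd
  z <- as.numeric(subjects$sex == "male")
  planted <- .solve_planted(subjects$age, z,
                            design$age_shape_R2, design$sex_shape_R2,
                            sigma^2, d_eff)
  tvec <- c(template[, 1], template[, 2])
  E <- matrix(stats::rnorm(2 * p * n, sd = sigma), 2 * p, n)
  E <- project_tangent(E, pd$basis)
  ac <- subjects$age - mean(subjects$age)
  zc <- z - mean(z)
  bmic <- subjects$bmi - mean(subjects$bmi)
  V <- tvec +
    pd$directions[, "age", drop = FALSE] %*% rbind(planted$beta * ac) +
    pd$directions[, "sex", drop = FALSE] %*% rbind(planted$m * zc) +
    pd$directions[, "bmi", drop = FALSE] %*% rbind(design$bmi_effect * bmic) +
    E
  A <- array(NA_real_, c(p, 2, n),
             dimnames = list(scheme$names, c("x", "y"), subjects$subject_id))
  for (i in seq_len(n)) {
    X <- cbind(V[seq_len(p), i], V[p + seq_len(p), i])
    X <- X * (subjects$facial_cs[i] / centroid_size(X))
    if (design$jitter_pose) {
      th <- stats::runif(1, -pi / 60, pi / 60)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      X <- X %*% R
      X <- sweep(X, 2, stats::runif(2, -2, 2), "+")
    }
    A[, , i] <- X
  }
  subjects <- subjects[, c("subject_id", "sex", "age", "cohort", "height",
                           "weight", "bmi", "handgrip", "wrist", "upper_arm",
                           "triceps", "under_chest", "hips", "facial_cs")]
  list(configs = A, subjects = subjects, design = design,
       planted = c(planted, list(directions = pd$directions,
                                 noise_sd = sigma, dim = d_eff)))
}

#' Duplicate configurations with simulated digitization error
#'
#' Emulates two independent observers re-digitizing the same faces: each
#' configuration is copied twice, each copy perturbed by tangent-space
#' digitization noise whose variance is set from the planted
#' among-individual variance so that the population ratio
#' `among / (among + error)` equals `target_repeatability`.  Digitization
#' error scales with each face's size (it is a landmark-placement error on
#' the photograph).
#'
#' @param configs `p x 2 x n` array of single-digitization configurations.
#' @param target_repeatability planted agreement in `(0, 1]`; 1 gives
#'   identical copies.
#' @param among_sd per-coordinate among-individual shape noise (cm at
#'   reference size) that was used to generate the faces.
#' @param reference_size size at which `among_sd` is expressed; defaults to
#'   the mean centroid size of `configs`.
#' @param seed RNG seed.
#' @return List with `configs` (`p x 2 x 2n`), `individual` and `observer`
#'   factors of length 2n.
#' @export
add_observer_copies <- function(configs, target_repeatability,
                                among_sd = 0.25, reference_size = NULL,
                                seed = NULL) {
  if (target_repeatability <= 0 || target_repeatability > 1)
    stop("target_repeatability must be in (0, 1] (0 is degenerate)")
  A <- as_landmark_array(configs)
  p <- dim(A)[1]; n <- dim(A)[3]
  return(with_seed(seed, {
  cs <- centroid_size(A)
  if (is.null(reference_size)) reference_size <- mean(cs)
  sd_e <- among_sd * sqrt((1 - target_repeatability) / target_repeatability)
  ids <- dimnames(A)[[3]]
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  out <- array(NA_real_, c(p, 2, 2 * n),
               dimnames = list(dimnames(A)[[1]], c("x", "y"),
                               paste0(rep(ids, each = 2), "_obs", 1:2)))
  for (i in seq_len(n)) {
    X <- A[, , i]
    basis <- similarity_basis(X)
    for (o in 1:2) {
      eps <- matrix(stats::rnorm(2 * p, sd = sd_e * cs[i] / reference_size),
                    2 * p, 1)
      eps <- project_tangent(eps, basis)
      out[, , 2 * (i - 1) + o] <- X + cbind(eps[seq_len(p)], eps[p + seq_len(p)])
    }
  }
  list(configs = out,
       individual = factor(rep(ids, each = 2), levels = ids),
       observer = factor(rep(c("obs1", "obs2"), n)))
  }))
}
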