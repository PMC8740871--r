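sch <- default_scheme()

test_that("mean-face template: symmetric, valid indices, plausible size", {
  tmpl <- generate_mean_face(sch)
  expect_equal(centroid_size(tmpl), 54)
  expect_gte(centroid_size(tmpl), 51.6)
  expect_lte(centroid_size(tmpl), 57.9)
  expect_lt(max(abs(symmetrize(tmpl, sch) - tmpl)), 1e-9)
  idx <- compute_indices(tmpl, sch)
  expect_true(all(is.finite(idx)) && all(idx > 0))
  expect_equal(unname(idx["upper_fwhr_n_sto"]), 1.85, tolerance = 1e-6)
  # indices are invariant to similarity transforms of the template
  moved <- 2.7 * tmpl %*% rot2(0.6) + 10
  expect_equal(unname(compute_indices(moved, sch)), unname(idx),
               tolerance = 1e-12)
})

test_that("calibration oracle: trivial anchors and infeasible targets", {
  expect_equal(calibrate_effect(0, 50, 50, 1, 10), 0)
  expect_error(calibrate_effect(1, 50, 50, 1, 10), "infeasible")
  expect_error(calibrate_effect(0.5, 50, 50, 1, 10, other_R2 = 0.6),
               "infeasible")
  # below the null-expectation floor of a fitted term
  expect_error(calibrate_effect(1e-4, 20, 20, 1, 10), "null expectation")
  # population form: doubling m at fixed noise raises R2 toward 1
  m1 <- calibrate_effect(0.2, 40, 40, 1, 10, expectation = "population")
  m2 <- calibrate_effect(0.6, 40, 40, 1, 10, expectation = "population")
  expect_gt(m2, m1)
})

test_that("calibrated two-group shift recovers the target R2 in flat space", {
  # Monte-Carlo oracle: direct projection formula, no Procrustes machinery
  set.seed(167)
  n1 <- 185; n2 <- 120; n <- n1 + n2; d <- 30
  target <- 0.018
  m <- calibrate_effect(target, n1, n2, noise_variance = 1, dim = d)
  u <- rep(1 / sqrt(d), d)
  z <- rep(c(1, 0), c(n1, n2)); zc <- z - mean(z)
  r2 <- replicate(400, {
    Y <- outer(z * m, u) + matrix(rnorm(n * d), n)
    Yc <- sweep(Y, 2, colMeans(Y))
    q <- zc / sqrt(sum(zc^2))
    sum((crossprod(q, Yc))^2) / sum(Yc^2)
  })
  expect_lt(abs(mean(r2) - target), 0.003)  # within 0.3 pp
  # monotonicity: larger planted fractions recover larger mean R2
  grid <- c(0.01, 0.02, 0.04, 0.08, 0.15)
  mean_r2 <- vapply(grid, function(t) {
    mm <- calibrate_effect(t, n1, n2, 1, d)
    mean(replicate(60, {
      Y <- outer(z * mm, u) + matrix(rnorm(n * d), n)
      Yc <- sweep(Y, 2, colMeans(Y))
      q <- zc / sqrt(sum(zc^2))
      sum((crossprod(q, Yc))^2) / sum(Yc^2)
    }))
  }, 0)
  expect_true(all(diff(mean_r2) > 0))
})

test_that("generate_cohort: sizes, determinism, subject-record invariants", {
  des <- synthetic_design(seed = 11)
  gen <- generate_cohort(des, sch)
  expect_equal(dim(gen$configs), c(71, 2, 305))
  expect_equal(sum(gen$subjects$sex == "male"), 185)
  expect_equal(sum(gen$subjects$sex == "female"), 120)
  expect_equal(as.vector(table(gen$subjects$cohort)), c(118, 116, 71))
  expect_silent(validate_subjects(gen$subjects))
  # same seed, identical output
  gen2 <- generate_cohort(synthetic_design(seed = 11), sch)
  expect_identical(gen$configs, gen2$configs)
  expect_identical(gen$subjects, gen2$subjects)
  gen3 <- generate_cohort(synthetic_design(seed = 12), sch)
  expect_false(identical(gen$configs, gen3$configs))
})

test_that("generated body parameters match their target moments", {
  des <- synthetic_design(n_male = c(young = 4000), n_female = c(young = 4000),
                          sex_shape_R2 = 0, age_shape_R2 = 0, seed = 19)
  gen <- generate_cohort(des, sch)
  sb <- gen$subjects
  m <- sb$sex == "male"
  expect_lt(abs(mean(sb$height[m]) - 167.5), 0.4)
  expect_lt(abs(sd(sb$height[m]) - 7.1), 0.3)
  expect_lt(abs(mean(sb$height[!m]) - 155.3), 0.4)
  expect_lt(abs(mean(sb$bmi[!m]) - mean(sb$bmi[m]) - 1.2), 0.25)
  expect_lt(abs(mean(sb$facial_cs[m]) - 56.0), 0.3)
  # drawn facial CS is the centroid size of the generated configurations
  expect_equal(centroid_size(gen$configs[, , 1]),
               sb$facial_cs[1], tolerance = 1e-9)
})

test_that("mid-adult BMI dimorphism reproduces the reference difference", {
  set.seed(23)
  diffs <- replicate(10, {
    g <- generate_cohort(synthetic_design(
      n_male = c(mid = 70), n_female = c(mid = 46),
      sex_shape_R2 = 0, age_shape_R2 = 0, seed = sample.int(1e7, 1)), sch)
    mean(g$subjects$bmi[g$subjects$sex == "female"]) -
      mean(g$subjects$bmi[g$subjects$sex == "male"])
  })
  expect_lt(abs(mean(diffs) - 1.9), 0.35)
})

test_that("null sex design yields uniform PERMANOVA p-values downstream", {
  set.seed(29)
  ps <- replicate(60, {
    g <- generate_cohort(synthetic_design(
      n_male = c(young = 12), n_female = c(young = 12),
      sex_shape_R2 = 0, age_shape_R2 = 0, jitter_pose = FALSE,
      seed = sample.int(1e7, 1)), sch)
    fit <- gpa(g$configs, sch, slide = FALSE)
    permanova(shape_matrix(fit), data.frame(sex = factor(g$subjects$sex)),
              n_perm = 99, seed = 1)$p[1]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("observer copies: identical at r = 1, planted ratio recovered", {
  des <- synthetic_design(n_male = c(young = 10), n_female = c(young = 10),
                          sex_shape_R2 = 0, age_shape_R2 = 0, seed = 31)
  gen <- generate_cohort(des, sch)
  oc <- add_observer_copies(gen$configs, 1, seed = 1)
  expect_equal(oc$configs[, , seq(1, 39, 2)], oc$configs[, , seq(2, 40, 2)],
               ignore_attr = TRUE)
  expect_equal(length(oc$individual), 40)
  expect_error(add_observer_copies(gen$configs, 0), "degenerate")
  set.seed(37)
  r_hat <- replicate(15, {
    g <- generate_cohort(synthetic_design(
      n_male = c(young = 20), n_female = c(young = 20),
      sex_shape_R2 = 0, age_shape_R2 = 0, seed = sample.int(1e7, 1)), sch)
    oc <- add_observer_copies(g$configs, 0.5, among_sd = 0.25,
                              seed = sample.int(1e7, 1))
    fit <- gpa(oc$configs, sch, slide = FALSE)
    repeatability(fit, oc$individual, oc$observer)$r
  })
  expect_lt(abs(mean(r_hat) - 0.5), 0.05)
})

test_that("planted whole-sample variance fractions are recovered through the pipeline", {
  set.seed(41)
  res <- sapply(1:6, function(k) {
    g <- generate_cohort(synthetic_design(seed = sample.int(1e7, 1)), sch)
    fit <- gpa(g$configs, sch, slide = FALSE)
    tab <- permanova(shape_matrix(fit),
                     data.frame(age = g$subjects$age,
                                sex = factor(g$subjects$sex)),
                     n_perm = 99, seed = 1)
    tab$R2[1:2]
  })
  expect_lt(abs(mean(res[1, ]) - 0.06), 0.007)   # age, +-0.7 pp
  expect_lt(abs(mean(res[2, ]) - 0.018), 0.004)  # sex, +-0.4 pp
})
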