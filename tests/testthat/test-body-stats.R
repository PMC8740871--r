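test_that("BMI, cohorts, and subject validation", {
  expect_equal(bmi(56, 167.5), 56 / 1.675^2)
  expect_equal(as.character(assign_cohort(c(17, 29, 30, 50, 51, 90))),
               c("young", "young", "mid", "mid", "elderly", "elderly"))
  s <- data.frame(subject_id = "a", sex = "male", age = 25,
                  height = 170, bmi = 20, weight = 20 * 1.7^2)
  expect_silent(validate_subjects(s))
  s$weight <- 70
  expect_error(validate_subjects(s), "inconsistent")
  expect_error(validate_subjects(data.frame(subject_id = "a", sex = "boy",
                                            age = 25)), "male")
})

test_that("Levene gate picks the pooled vs Welch branch and matches hand computation", {
  # equal-variance toy data, 3 vs 3: hand-computed pooled t
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  res <- ttest_with_levene(x, y)
  sp <- sqrt(((2) * var(x) + (2) * var(y)) / 4)
  t_hand <- (mean(x) - mean(y)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(res$t, t_hand)
  expect_equal(res$df, 4)
  expect_equal(res$variant, "pooled")
  # identical groups
  z <- c(1, 2, 3, 4)
  same <- ttest_with_levene(z, z)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # grossly unequal variances trigger the Welch branch
  set.seed(107)
  a <- rnorm(60, sd = 8); b <- rnorm(60, sd = 0.5)
  res2 <- ttest_with_levene(a, b)
  expect_equal(res2$variant, "welch")
  expect_false(res2$df == 118)
  expect_error(ttest_with_levene(c(1, 1), c(1, 1)), "undefined")
})

test_that("mean-centered Levene matches car::leveneTest(center = mean)", {
  skip_if_not_installed("car")
  set.seed(109)
  x <- rnorm(30); y <- rnorm(25, sd = 2)
  mine <- facedim:::levene_test(c(x, y), rep(c("a", "b"), c(30, 25)))
  ref <- car::leveneTest(c(x, y), factor(rep(c("a", "b"), c(30, 25))),
                         center = mean)
  expect_equal(mine$F, ref$`F value`[1])
  expect_equal(mine$p, ref$`Pr(>F)`[1])
})

test_that("Hedges' g: zero at equal means, antisymmetric, scale invariant", {
  set.seed(113)
  x <- rnorm(20); y <- rnorm(30)
  expect_equal(hedges_g(x, x + 0), -hedges_g(x + 0, x))
  expect_equal(hedges_g(x, y), -hedges_g(y, x) * 1)  # antisymmetry up to sign of roles
  expect_equal(hedges_g(3 + 2 * x, 3 + 2 * y), hedges_g(x, y))
  tt1 <- ttest_with_levene(x, y); tt2 <- ttest_with_levene(5 * x - 1, 5 * y - 1)
  expect_equal(tt1$t, tt2$t)
  expect_error(hedges_g(c(1, 1), c(1, 1)), "zero")
  # known-population value: J-corrected standardized difference
  g <- hedges_g(c(0, 1, 2, 3), c(2, 3, 4, 5))
  sp <- sqrt((3 * var(c(0:3)) + 3 * var(c(2:5))) / 6)
  expect_equal(g, -2 / sp * (1 - 3 / 23))
})

test_that("ANCOVA sex effect: null scale, saturated case, hand-computed SS", {
  # dv equals the sex indicator exactly -> partial eta^2 = 1
  sex <- rep(c("male", "female"), each = 10)
  dv <- as.numeric(sex == "male")
  res <- ancova_sex_effect(dv, rnorm(20), sex)
  expect_equal(res$partial_eta2, 1, tolerance = 1e-9)
  # hand-computed 5+5 example with one covariate
  set.seed(127)
  bmi_v <- rnorm(10); sx <- rep(c("m", "f"), each = 5)
  y <- 0.5 * bmi_v + 0.8 * (sx == "m") + rnorm(10)
  res2 <- ancova_sex_effect(y, bmi_v, sx)
  rss_full <- sum(residuals(lm(y ~ bmi_v + sx))^2)
  rss_red <- sum(residuals(lm(y ~ bmi_v))^2)
  F_hand <- (rss_red - rss_full) / (rss_full / 7)
  expect_equal(res2$F, F_hand)
  expect_equal(res2$partial_eta2, (rss_red - rss_full) / rss_red)
  expect_error(ancova_sex_effect(y, bmi_v, rep("m", 10)), "constant")
})

test_that("type III drop-term SS matches car::Anova", {
  skip_if_not_installed("car")
  set.seed(131)
  d <- data.frame(bmi = rnorm(40), sex = factor(rep(c("m", "f"), 20)))
  d$y <- 0.3 * d$bmi + 0.5 * (d$sex == "m") + rnorm(40)
  mine <- ancova_sex_effect(d$y, d$bmi, d$sex)
  ref <- car::Anova(lm(y ~ bmi + sex, data = d), type = 3)
  expect_equal(mine$F, ref["sex", "F value"])
  expect_equal(mine$p, ref["sex", "Pr(>F)"])
})

test_that("per-index MANCOVA flags a planted linear dependence only", {
  set.seed(137)
  n <- 120
  trait <- rnorm(n); bmi_v <- rnorm(n)
  dvs <- as.data.frame(matrix(rnorm(n * 12), n))
  names(dvs) <- index_names()
  dvs$total_fwhr <- -0.8 * trait + rnorm(n, sd = 1)
  res <- mancova_trait_effects(dvs, bmi_v, trait)
  expect_true(res$bonferroni_significant[res$index == "total_fwhr"])
  expect_lt(sum(res$bonferroni_significant), 3)
  eta <- res$partial_eta2[res$index == "total_fwhr"]
  expect_gt(eta, 0.2)  # planted R2 ~ 0.39
  expect_error(mancova_trait_effects(dvs[, -2], bmi_v, trait), "missing")
})

test_that("stepwise logistic: informative predictor first, null sparsity, determinism", {
  set.seed(139)
  n <- 150
  X <- data.frame(noise1 = rnorm(n), signal = rnorm(n), noise2 = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * X$signal))
  m <- stepwise_logistic(X, y)
  expect_equal(m$selected[1], "signal")
  expect_true(m$converged)
  expect_gt(m$accuracy, 0.6)
  m2 <- stepwise_logistic(X, y)
  expect_identical(m$selected, m2$selected)
  expect_equal(m$coefficients, m2$coefficients)
  # empty model under the null in most replicates
  set.seed(149)
  empt <- replicate(30, {
    Xn <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
    length(stepwise_logistic(Xn, rbinom(60, 1, 0.5))$selected) == 0
  })
  expect_gte(mean(empt), 0.8)
})

test_that("stepwise logistic flags perfect separation", {
  X <- data.frame(x = c(rnorm(20, -4), rnorm(20, 4)), z = rnorm(40))
  y <- rep(c(0, 1), each = 20)
  m <- suppressWarnings(stepwise_logistic(X, y))
  expect_false(m$converged)
  expect_equal(m$accuracy, 1)
})

test_that("stepwise linear recovers a planted coefficient and breaks ties deterministically", {
  set.seed(151)
  n <- 100
  x1 <- rnorm(n)
  X <- data.frame(x1 = x1, dup = x1, noise = rnorm(n))
  y <- 2 * x1 + rnorm(n, sd = 0.5)
  m <- stepwise_linear(X, y)
  expect_equal(m$selected[1], "x1")     # tie with dup broken by input order
  expect_false("dup" %in% m$selected)   # exact duplicate cannot enter twice
  expect_lt(abs(unname(m$coefficients["x1"]) - 2), 0.2)
  # single-predictor stepwise equals plain regression
  m1 <- stepwise_linear(X[, "x1", drop = FALSE], y)
  pl <- lm(y ~ x1)
  expect_equal(unname(m1$coefficients), unname(coef(pl)))
  expect_equal(m1$r2, summary(pl)$r.squared)
})

test_that("cubic trend: exact fit, null expectation, degenerate input", {
  age <- seq(18, 80, length.out = 60)
  y <- 1 + 0.5 * age - 0.01 * age^2 + 1e-4 * age^3
  res <- suppressWarnings(cubic_trend(y, age))
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  set.seed(157)
  r2 <- replicate(300, cubic_trend(rnorm(40), runif(40, 18, 80))$r_squared)
  expect_lt(abs(mean(r2) - 3 / 39), 0.02)
  expect_error(cubic_trend(rnorm(4), 1:4), "n > 4")
  expect_error(cubic_trend(rnorm(10), rep(c(1, 2), 5)), "collinear|degenerate")
})

test_that("dimorphism table reproduces per-parameter t and g", {
  set.seed(163)
  s <- data.frame(sex = rep(c("male", "female"), c(40, 30)),
                  height = c(rnorm(40, 168, 7), rnorm(30, 156, 6)),
                  hips = c(rnorm(40, 88, 6), rnorm(30, 91, 6)))
  tab <- dimorphism_table(s, c("height", "hips"))
  expect_equal(tab$t[1],
               ttest_with_levene(s$height[s$sex == "male"],
                                 s$height[s$sex == "female"])$t)
  expect_gt(tab$hedges_g[1], 0)   # men taller
  expect_lt(tab$hedges_g[2], 0)   # women larger hips -> negative by convention
})
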