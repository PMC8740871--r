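test_that("centroid size: closed form, homogeneity, degenerate input", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2))
  expect_equal(centroid_size(sq * 3.7), 3.7 * centroid_size(sq))
  expect_equal(centroid_size(sq + 100), centroid_size(sq))  # translation invariant
  expect_error(centroid_size(matrix(1, 4, 2)), "degenerate")
})

test_that("OPA recovers a known rotation and flags required reflections", {
  X <- center_config(blob7())
  Y <- X %*% rot2(30 * pi / 180)
  fit <- opa_align(Y, X)
  expect_lt(fit$rss, 1e-18)
  expect_equal(abs(fit$angle), 30 * pi / 180, tolerance = 1e-10)
  # mirrored target: best proper rotation has strictly positive residual
  M <- cbind(-X[, 1], X[, 2])
  fit_m <- opa_align(M, X, allow_reflection = FALSE)
  expect_true(fit_m$reflected)
  expect_gt(fit_m$rss, 1e-4)
  fit_r <- opa_align(M, X, allow_reflection = TRUE)
  expect_lt(fit_r$rss, 1e-18)
})

test_that("OPA matches a brute-force grid search over rotation angle", {
  set.seed(21)
  for (rep in 1:3) {
    X <- center_config(matrix(rnorm(10), 5, 2))
    Y <- center_config(matrix(rnorm(10), 5, 2))
    fit <- opa_align(X, Y)
    angles <- seq(-pi, pi, by = 0.001 * pi / 180)
    rss <- vapply(angles, function(a) sum((X %*% rot2(a) - Y)^2), 0)
    best <- angles[which.min(rss)]
    d <- abs(((fit$angle - best + pi) %% (2 * pi)) - pi)
    expect_lt(d, 0.002 * pi / 180)
    expect_lte(fit$rss, min(rss) + 1e-10)
  }
})

test_that("GPA collapses similarity-transformed copies of one shape", {
  base <- center_config(blob7())
  A <- array(NA_real_, c(7, 2, 4))
  A[, , 1] <- base
  A[, , 2] <- 2.5 * base %*% rot2(1.1) + 3
  A[, , 3] <- 0.4 * base %*% rot2(-2.7)
  A[, , 4] <- base %*% rot2(0.3) - 10
  fit <- gpa(A, slide = FALSE)
  for (i in 2:4)
    expect_lt(max(abs(fit$aligned[, , i] - fit$aligned[, , 1])), 1e-8)
  expect_lt(opa_align(fit$consensus, base / centroid_size(base))$rss, 1e-16)
  # centroid sizes recorded before scaling
  expect_equal(fit$centroid_sizes[2] / fit$centroid_sizes[1], 2.5)
})

test_that("GPA consensus of two shapes is equidistant from both", {
  set.seed(5)
  A <- perturbed_set(blob7(), 2, sd = 0.4)
  fit <- gpa(A, slide = FALSE)
  d1 <- opa_align(fit$aligned[, , 1], fit$consensus)$rss
  d2 <- opa_align(fit$aligned[, , 2], fit$consensus)$rss
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("GPA agrees with explicit alternating minimization with random restarts", {
  set.seed(8)
  A <- perturbed_set(blob7(), 20, sd = 0.15)
  fit <- gpa(A, slide = FALSE)
  # independent oracle: alternate align-to-mean from several random initial
  # reference choices and random pre-rotations, keep the best total RSS
  best <- NULL
  for (restart in 1:5) {
    B <- A
    for (i in seq_len(20)) {
      X <- center_config(B[, , i] %*% rot2(runif(1, -pi, pi)))
      B[, , i] <- X / centroid_size(X)
    }
    cons <- B[, , sample(20, 1)]
    for (iter in 1:200) {
      for (i in 1:20) B[, , i] <- opa_align(B[, , i], cons)$aligned
      newc <- apply(B, c(1, 2), mean)
      newc <- center_config(newc) / centroid_size(center_config(newc))
      if (max(abs(newc - cons)) < 1e-12) break
      cons <- newc
    }
    rss <- sum(vapply(1:20, function(i) sum((B[, , i] - cons)^2), 0))
    if (is.null(best) || rss < best$rss) best <- list(cons = cons, rss = rss)
  }
  expect_lt(opa_align(best$cons, fit$consensus)$rss, 1e-10)
})

test_that("GPA output is invariant to similarity transforms of any input", {
  set.seed(13)
  A <- perturbed_set(blob7(), 6, sd = 0.2)
  fit1 <- gpa(A, slide = FALSE)
  B <- A
  B[, , 3] <- 3.1 * B[, , 3] %*% rot2(2.2) + 5
  B[, , 5] <- 0.2 * B[, , 5] %*% rot2(-0.7) - 2
  fit2 <- gpa(B, slide = FALSE)
  expect_lt(max(abs(fit1$aligned - fit2$aligned)), 1e-8)
  expect_lt(max(abs(fit1$consensus - fit2$consensus)), 1e-8)
})

# --- bending energy and sliding ---------------------------------------------

arc_scheme <- function() {
  landmark_scheme(
    names = paste0("p", 1:7),
    role = c("fixed", "fixed", rep("semilandmark", 3), "fixed", "fixed"),
    pairs = matrix(integer(0), ncol = 2), midline = 1:7,
    sliders = rbind(c(2L, 3L, 4L), c(3L, 4L, 5L), c(4L, 5L, 6L)))
}

arc_config <- function(jitter = 0) {
  th <- seq(0.2, pi - 0.2, length.out = 7)
  X <- cbind(2 * cos(th), 2 * sin(th))
  X[3:5, ] <- X[3:5, ] + jitter
  X
}

test_that("bending energy of affine displacement fields is zero; matrix PSD", {
  ref <- arc_config()
  bem <- bending_energy_model(ref)
  expect_lt(max(abs(bem$energy_matrix - t(bem$energy_matrix))), 1e-12)
  ev <- eigen(bem$energy_matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-9)
  aff <- cbind(0.3 + 1.2 * ref[, 1] - 0.4 * ref[, 2],
               -1 + 0.1 * ref[, 1] + 0.9 * ref[, 2])
  expect_lt(abs(bending_energy(bem, aff)), 1e-9)
  nonaff <- ref; nonaff[4, 2] <- nonaff[4, 2] + 0.5
  expect_gt(bending_energy(bem, nonaff), 1e-6)
})

test_that("sliding is zero at the consensus and undoes a tangential displacement", {
  sch <- arc_scheme()
  cons <- arc_config()
  bem <- bending_energy_model(cons)
  slid <- slide_semilandmarks(cons, cons, sch, bem)
  expect_lt(max(abs(slid - cons)), 1e-10)
  # displace one semilandmark along its own tangent
  X <- cons
  u <- X[5, ] - X[3, ]; u <- u / sqrt(sum(u^2))
  X[4, ] <- X[4, ] + 0.15 * u
  e_before <- bending_energy(bem, X - cons)
  slid <- slide_semilandmarks(X, cons, sch, bem)
  e_after <- bending_energy(bem, slid - cons)
  expect_lt(e_after, e_before)
  expect_lt(e_after, 1e-10)  # pure tangential deviation is fully removable
})

test_that("sliding solution matches a nested grid search over sliding amounts", {
  sch <- arc_scheme()
  cons <- arc_config()
  set.seed(31)
  X <- arc_config(jitter = 0)
  X[3:5, ] <- X[3:5, ] + matrix(rnorm(6, sd = 0.1), 3, 2)
  bem <- bending_energy_model(cons)
  slid <- slide_semilandmarks(X, cons, sch, bem)
  e_solver <- bending_energy(bem, slid - cons)
  # independent oracle: coarse-to-fine 3D grid over the sliding amounts,
  # final step 1e-4
  u <- t(vapply(1:3, function(k) {
    v <- X[sch$sliders[k, "next"], ] - X[sch$sliders[k, "prev"], ]
    v / sqrt(sum(v^2))
  }, numeric(2)))
  energy_at <- function(t3) {
    Y <- X
    Y[3:5, ] <- Y[3:5, ] + t3 * u
    bending_energy(bem, Y - cons)
  }
  ctr <- c(0, 0, 0); width <- 0.4
  repeat {
    g <- lapply(1:3, function(k) seq(ctr[k] - width, ctr[k] + width,
                                     length.out = 9))
    grid <- as.matrix(expand.grid(g))
    es <- apply(grid, 1, energy_at)
    ctr <- grid[which.min(es), ]
    width <- width / 3
    if (width < 1e-4 / 2) break
  }
  expect_lt(abs(energy_at(ctr) - e_solver), 1e-6)
})

test_that("sliding inside GPA never increases total bending energy", {
  set.seed(17)
  sch <- arc_scheme()
  A <- perturbed_set(arc_config(), 8, sd = 0.05)
  fit <- gpa(A, sch, slide = TRUE)
  bem <- bending_energy_model(fit$consensus)
  e_slid <- sum(vapply(1:8, function(i)
    bending_energy(bem, fit$aligned[, , i] - fit$consensus), 0))
  fit0 <- gpa(A, sch, slide = FALSE)
  bem0 <- bending_energy_model(fit0$consensus)
  e_raw <- sum(vapply(1:8, function(i)
    bending_energy(bem0, fit0$aligned[, , i] - fit0$consensus), 0))
  expect_lt(e_slid, e_raw)
})

# --- symmetrization ----------------------------------------------------------

test_that("symmetrize: fixed point, idempotence, exact mirror symmetry", {
  sch <- toy_scheme5()
  sym <- toy_config5()
  out <- symmetrize(sym, sch)
  expect_lt(opa_align(out, center_config(sym))$rss, 1e-18)
  set.seed(41)
  X <- toy_config5() + matrix(rnorm(12, sd = 0.15), 6, 2)
  S1 <- symmetrize(X, sch)
  S2 <- symmetrize(S1, sch)
  expect_lt(max(abs(S2 - S1)), 1e-9)
  expect_equal(S1[sch$midline, 1], rep(0, 2))
  expect_equal(S1[sch$pairs[, 1], 1], -S1[sch$pairs[, 2], 1])
  expect_equal(S1[sch$pairs[, 1], 2], S1[sch$pairs[, 2], 2])
  # reflect-relabel of the output equals itself after OPA
  refl <- facedim:::reflect_relabel(S1, sch)
  expect_lt(opa_align(refl, S1)$rss, 1e-18)
})

test_that("symmetrize equals the explicit reflect-relabel-fit-average oracle", {
  sch <- toy_scheme5()
  set.seed(43)
  X <- toy_config5() + matrix(rnorm(12, sd = 0.2), 6, 2)
  S <- symmetrize(X, sch)
  # independent construction: iterate the averaging by hand, no snapping
  perm <- c(1, 2, 4, 3, 6, 5)
  O <- center_config(X)
  for (k in 1:200) {
    refl <- cbind(-O[, 1], O[, 2])[perm, ]
    M <- crossprod(refl, O)
    sv <- svd(M)
    R <- if (det(sv$u %*% t(sv$v)) < 0)
      sv$u %*% diag(c(1, -1)) %*% t(sv$v) else sv$u %*% t(sv$v)
    O_new <- (O + center_config(refl) %*% R) / 2
    if (max(abs(O_new - O)) < 1e-14) break
    O <- O_new
  }
  expect_lt(opa_align(O, S)$rss, 1e-12)
})

test_that("GPA-then-symmetrize leaves no directional asymmetry in a sample", {
  set.seed(47)
  sch <- toy_scheme5()
  A <- perturbed_set(toy_config5(), 10, sd = 0.1)
  fit <- gpa(A, slide = FALSE)
  S <- symmetrize(fit$aligned, sch)
  for (i in 1:10) {
    refl <- facedim:::reflect_relabel(S[, , i], sch)
    expect_lt(opa_align(refl, S[, , i])$rss, 1e-16)
  }
})

# --- thin-plate-spline warps -------------------------------------------------

test_that("TPS warp: identity, affine maps, exact interpolation", {
  src <- blob7()
  q <- as.matrix(expand.grid(seq(-2, 2, 1), seq(-2, 2, 1)))
  expect_lt(max(abs(tps_warp(src, src, q) - q)), 1e-9)
  Aff <- rbind(c(0.9, -0.3), c(0.2, 1.1))
  tgt <- src %*% Aff + rep(c(1, -2), each = 7)
  expect_lt(max(abs(tps_warp(src, tgt, q) - (q %*% Aff + rep(c(1, -2), each = nrow(q))))),
            1e-8)
  bem <- bending_energy_model(src)
  expect_lt(bending_energy(bem, tgt), 1e-9)
  set.seed(53)
  tgt2 <- src + matrix(rnorm(14, sd = 0.3), 7, 2)
  expect_lt(max(abs(tps_warp(src, tgt2, src) - tgt2)), 1e-9)
  expect_error(tps_warp(rbind(src, src[1, ]), rbind(tgt2, tgt2[1, ]), q),
               "duplicated")
})

test_that("TPS warp matches an independently assembled linear system", {
  set.seed(59)
  src <- matrix(rnorm(16), 8, 2)
  tgt <- src + matrix(rnorm(16, sd = 0.2), 8, 2)
  q <- matrix(rnorm(40), 20, 2)
  got <- tps_warp(src, tgt, q)
  # independent assembly: solve the full (p+3) system per axis with a
  # different elimination (normal-equations-free, base solve on permuted rows)
  U <- function(r2) ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))
  K <- outer(seq_len(8), seq_len(8), Vectorize(function(i, j)
    U(sum((src[i, ] - src[j, ])^2))))
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  perm <- sample(11)
  want <- sapply(1:2, function(ax) {
    co <- solve(L[perm, ], c(tgt[, ax], 0, 0, 0)[perm])
    kq <- outer(seq_len(20), seq_len(8), Vectorize(function(i, j)
      U(sum((q[i, ] - src[j, ])^2))))
    kq %*% co[1:8] + cbind(1, q) %*% co[9:11]
  })
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("deformation grids warp nodes consistently with tps_warp", {
  src <- blob7()
  tgt <- src + matrix(c(rep(0.1, 7), rep(-0.2, 7)), 7, 2)
  g <- tps_grid(src, tgt, n = c(5, 6))
  expect_equal(nrow(g$nodes), 30)
  expect_equal(g$target, tgt)
})
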