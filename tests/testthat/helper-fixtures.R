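# Shared fixtures: tiny schemes and configurations built in code.

# 5-point toy scheme: midline top/bottom, one fixed pair, one semilandmark
# pair sliding between the midline points
toy_scheme5 <- function() {
  landmark_scheme(
    names = c("top", "bottom", "side_l", "side_r", "curve_l", "curve_r"),
    role = c("fixed", "fixed", "fixed", "fixed",
             "semilandmark", "semilandmark"),
    pairs = rbind(c(3L, 4L), c(5L, 6L)),
    midline = c(1L, 2L),
    sliders = rbind(c(1L, 5L, 2L), c(1L, 6L, 2L)))
}

toy_config5 <- function() {
  rbind(top = c(0, 2), bottom = c(0, -2), side_l = c(-1.5, 0),
        side_r = c(1.5, 0), curve_l = c(-0.8, 1), curve_r = c(0.8, 1))
}

# post-multiplication matrix rotating row-vector points by theta
rot2 <- function(theta) {
  matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
}

# n noisy variants of a base configuration (uniform landmark jitter)
perturbed_set <- function(base, n, sd = 0.05, seed = 1) {
  set.seed(seed)
  A <- array(NA_real_, c(nrow(base), 2, n))
  for (i in seq_len(n))
    A[, , i] <- base + matrix(rnorm(length(base), sd = sd), nrow(base), 2)
  dimnames(A) <- list(rownames(base), c("x", "y"), paste0("s", seq_len(n)))
  A
}

# face-like irregular pentagon used where degenerate symmetry must be avoided
blob7 <- function() {
  rbind(c(0, 3.2), c(1.8, 1.5), c(2.4, -1.1), c(0.6, -2.9),
        c(-1.7, -2.3), c(-2.6, 0.2), c(-1.2, 2.1))
}
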