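make_panel <- function(mats_by_subject, labels) {
  data <- lapply(mats_by_subject, function(sessions) sessions)
  ts_panel(data, roi_labels = labels)
}

test_that("prepare_subject discards, centres and concatenates", {
  labels <- c("a", "b")
  s1 <- cbind(a = rep(3, 120), b = seq_len(120))
  s2 <- cbind(a = rep(-1, 130), b = rep(2, 130))
  panel <- ts_panel(list(s1 = list(x = s1, y = s2)), labels)
  out <- prepare_subject(panel, "s1", n_discard = 100)
  expect_equal(nrow(out), (120 - 100) + (130 - 100))
  # constants vanish under mean-centering
  expect_equal(out[, "a"], rep(0, 50), ignore_attr = TRUE)
  # per-session blocks have zero column means to machine precision
  expect_equal(colMeans(out[1:20, ]), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(colMeans(out[21:50, ]), c(a = 0, b = 0), tolerance = 1e-12)
  expect_error(prepare_subject(panel, "s1", n_discard = 119),
               "n_discard")
  expect_error(prepare_subject(panel, "nope"), "not in panel")
})

test_that("partial betas recover exact and null dependence", {
  set.seed(1)
  n <- 10000
  x1 <- rnorm(n); x2 <- rnorm(n)
  x4 <- rnorm(n); x5 <- rnorm(n)
  x3 <- x1 + x2 + rnorm(n, sd = 1e-6)
  x <- scale(cbind(x1, x2, x3, x4, x5), scale = FALSE)
  b <- fit_partial_betas(x)
  expect_equal(b[1, 3], 1, tolerance = 1e-3)
  expect_equal(b[2, 3], 1, tolerance = 1e-3)
  expect_equal(diag(b), rep(0, 5), ignore_attr = TRUE)

  # independent white noise: |beta| < 4 / sqrt(n)
  set.seed(2)
  w <- scale(matrix(rnorm(n * 6), n, 6), scale = FALSE)
  bw <- fit_partial_betas(w)
  expect_lt(max(abs(bw)), 4 / sqrt(n))
})

test_that("betas match the normal-equations oracle", {
  set.seed(42)
  x <- scale(matrix(rnorm(50 * 6), 50, 6), scale = FALSE)
  expect_equal(fit_partial_betas(x), oracle_betas(x), ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("collinear designs raise a named error", {
  set.seed(3)
  x <- matrix(rnorm(60 * 4), 60, 4)
  x[, 4] <- 2 * x[, 2]
  colnames(x) <- c("r1", "r2", "r3", "r4")
  expect_error(fit_partial_betas(x), "rank-deficient.*r")
  expect_error(fit_partial_betas(matrix(rnorm(12), 3, 4)),
               "more time points")
})

test_that("beta signs agree with precision-matrix partial correlations", {
  # jointly Gaussian with known sparse precision
  set.seed(7)
  prec <- diag(6)
  prec[1, 2] <- prec[2, 1] <- -0.4
  prec[3, 4] <- prec[4, 3] <- 0.3
  sigma <- solve(prec)
  x <- matrix(rnorm(20000 * 6), ncol = 6) %*% chol(sigma)
  x <- scale(x, scale = FALSE)
  b <- fit_partial_betas(x)
  pc <- -prec / sqrt(outer(diag(prec), diag(prec)))
  for (i in 1:5) {
    for (j in (i + 1):6) {
      if (abs(pc[i, j]) > 0.05) {
        expect_equal(sign(b[i, j]), sign(pc[i, j]))
      }
    }
  }
})

test_that("group RFX thresholds, degenerate edges and monotonicity", {
  # all subjects identical beta 0.5 on one edge -> infinite-t sentinel,
  # flagged significant; all-zero edges stay out
  b <- matrix(0, 3, 3)
  b[1, 2] <- 0.5
  fc <- group_rfx(list(b, b, b), alpha = 0.05)
  expect_equal(fc$t_matrix[1, 2], Inf)
  expect_equal(fc$binary[1, 2], 1L)
  expect_equal(sum(fc$binary), 1)
  expect_equal(fc$weighted[1, 2], 1)  # normalized to max 1
  expect_error(group_rfx(list(b)), "2 subjects")

  # per-test threshold arithmetic: alpha / (N - 1)
  expect_equal(0.05 / 243, 2.0576e-4, tolerance = 1e-3)

  # null behaviour: fraction of significant edges ~ alpha after Bonferroni
  set.seed(10)
  nsub <- 24; nroi <- 12
  betas <- lapply(seq_len(nsub), function(s) {
    m <- matrix(rnorm(nroi^2), nroi, nroi); diag(m) <- 0; m
  })
  fc1 <- group_rfx(betas, alpha = 0.05)
  n_off <- nroi * (nroi - 1)
  # expected count n_off * alpha / (N-1) ~ 0.55; allow a loose Poisson band
  expect_lte(sum(fc1$binary), 5)

  # lowering alpha never adds edges
  fc2 <- group_rfx(betas, alpha = 0.01)
  expect_true(all(fc2$binary <= fc1$binary))

  # binary/weighted/t coupling invariant
  fc3 <- group_rfx(lapply(betas, function(m) m + 0.2), alpha = 0.05)
  expect_true(all((fc3$weighted != 0) == (fc3$binary == 1)))
  if (any(fc3$binary == 1)) expect_equal(max(abs(fc3$weighted)), 1)
})

test_that("phase randomization preserves spectrum, mean and variance", {
  set.seed(4)
  for (n in c(128, 129)) {  # even and odd lengths
    x <- as.numeric(arima.sim(list(ar = 0.6), n))
    y <- phase_randomize(x)
    expect_equal(Mod(fft(y)), Mod(fft(x)), tolerance = 1e-8)
    expect_equal(mean(y), mean(x), tolerance = 1e-8)
    expect_equal(var(y), var(x), tolerance = 1e-8)
  }
  expect_error(phase_randomize(1:3), "length")
})

test_that("phase randomization destroys cross-series dependence", {
  set.seed(5)
  z <- rnorm(256)
  x <- cbind(z, z)  # perfectly correlated pair
  rs <- replicate(200, cor(phase_randomize(x))[1, 2])
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs)), 3 * se + 1e-6)
})

test_that("surrogate test flags planted dependence and is reproducible", {
  spec <- small_planted_spec(seed = 21)
  panel <- simulate_panel(spec)
  rep1 <- surrogate_null_test(panel, n_surrogates = 100, n_discard = 10,
                              seed = 3)
  rep2 <- surrogate_null_test(panel, n_surrogates = 100, n_discard = 10,
                              seed = 3)
  expect_identical(rep1, rep2)
  expect_lt(rep1$p, 0.01)
  expect_gt(rep1$observed_mean, rep1$surrogate_mean)
  expect_error(surrogate_null_test(panel, n_surrogates = 1), "surrogates")
})
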