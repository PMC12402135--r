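test_that("bidirectional graph applies the strict AND rule", {
  set.seed(6)
  C <- matrix(rbinom(64, 1, 0.4), 8, 8)
  diag(C) <- 0
  rownames(C) <- colnames(C) <- sprintf("n%d", 1:8)
  inc <- bidirectional_graph(C, cortical_idx = 1:5, subcortical_idx = 6:8)
  both <- (C == 1) & (t(C) == 1)
  expect_equal(unname(inc), unname(both[1:5, 6:8] * 1L))

  C2 <- matrix(0, 3, 3)
  C2[1, 3] <- 1  # one direction only
  expect_equal(sum(bidirectional_graph(C2, 1:2, 3)), 0)

  C3 <- matrix(1, 4, 4); diag(C3) <- 0  # symmetric: AND == OR
  expect_equal(bidirectional_graph(C3, 1:2, 3:4),
               (symmetrize_adjacency(C3, "or")[1:2, 3:4]))

  expect_error(bidirectional_graph(C, 1:5, 5:8), "overlap")
})

test_that("convergence counts on the packaged table match printed values", {
  fx <- load_table1()
  counts <- convergence_counts(fx$incidence)
  get <- function(l) counts$n_converging[counts$sub_label == l]
  expect_equal(get("THA-VA2"), 0L)
  expect_equal(get("GPL-p"), 0L)
  expect_equal(get("AMY-m"), 16L)
  expect_equal(max(counts$n_converging), 16L)
  expect_equal(sum(counts$n_converging), 148L)
  # empty graph -> all zero
  e <- matrix(0L, 3, 2, dimnames = list(letters[1:3], c("s1", "s2")))
  expect_equal(convergence_counts(e)$n_converging, c(0L, 0L))
})

test_that("proportion convergence counts shared targets and normalizes", {
  # c1, c2 -> {s1, s2}; c3 -> {s1}
  inc <- matrix(0L, 3, 2, dimnames = list(c("c1", "c2", "c3"), c("s1", "s2")))
  inc["c1", ] <- 1L; inc["c2", ] <- 1L; inc["c3", "s1"] <- 1L
  o <- proportion_convergence(inc)
  expect_equal(o$shared, c(2L, 1L, 1L))
  expect_equal(o$o, c(0.5, 0.25, 0.25))
  expect_equal(sum(o$o), 1)

  # a node with no targets shares nothing
  inc2 <- inc; inc2["c3", ] <- 0L
  o2 <- proportion_convergence(inc2)
  expect_equal(o2$o[o2$i == "c3" | o2$j == "c3"], c(0, 0))

  # all-zero graph warns
  expect_warning(proportion_convergence(matrix(0L, 3, 2)), "zero")

  # normalization invariant on the packaged table
  fx <- load_table1()
  expect_equal(sum(proportion_convergence(fx$incidence)$o), 1,
               tolerance = 1e-12)
})

test_that("bilateral ROI distances follow the hemisphere-averaged rule", {
  parc <- parcellation(
    label = c("V1", "Area4", "Vermis"),
    class = c("cortical", "cortical", "cerebellar"),
    rsn = c("VIS", "SOM", "CER"),
    x1 = c(-5, -4, 2), y1 = c(-88, -25, -54), z1 = c(2, 56, -8),
    x2 = c(8, 4, NA), y2 = c(-92, -25, NA), z2 = c(-2, 58, NA)
  )
  expect_equal(roi_distance(parc, "V1", "V1"), 0)
  # hand evaluation: mean of the within-hemisphere distances
  dl <- sqrt(sum((c(-5, -88, 2) - c(-4, -25, 56))^2))
  dr <- sqrt(sum((c(8, -92, -2) - c(4, -25, 58))^2))
  expect_equal(roi_distance(parc, "V1", "Area4"), (dl + dr) / 2)
  expect_equal(roi_distance(parc, "V1", "Area4"), 86.5048, tolerance = 1e-4)
  # medial vs bilateral: average over both pairings
  dm <- mean(c(sqrt(sum((c(2, -54, -8) - c(-5, -88, 2))^2)),
               sqrt(sum((c(2, -54, -8) - c(8, -92, -2))^2))))
  expect_equal(roi_distance(parc, "Vermis", "V1"), dm)

  # translation invariance
  shifted <- parc
  for (cc in c("x1", "x2")) shifted[[cc]] <- shifted[[cc]] + 13
  for (cc in c("y1", "y2")) shifted[[cc]] <- shifted[[cc]] - 4
  expect_equal(roi_distance(shifted, "V1", "Area4"),
               roi_distance(parc, "V1", "Area4"), tolerance = 1e-12)

  parc$x1[2] <- NA
  expect_error(roi_distance(parc, "V1", "Area4"), "missing centroid")
})

test_that("distance matrix on random parcellations is a metric", {
  set.seed(19)
  n <- 8
  parc <- parcellation(
    label = sprintf("p%d", 1:n), class = "cortical",
    rsn = sample(c("VIS", "DMN"), n, TRUE),
    x1 = -abs(rnorm(n, 30, 10)), y1 = rnorm(n, 0, 30), z1 = rnorm(n, 0, 20),
    x2 = abs(rnorm(n, 30, 10)), y2 = rnorm(n, 0, 30), z2 = rnorm(n, 0, 20)
  )
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) d[i, j] <- roi_distance(parc, i, j)
  expect_true(isSymmetric(d))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
  }
})

test_that("FS/FD binning and the moment estimator behave", {
  pairs <- tibble::tibble(
    i = "a", j = "b", shared = 1L, o = c(0.5, 0.5),
    distance = c(3, 5), rsn_i = c("VIS", "VIS"), rsn_j = c("VIS", "DMN"),
    class = c("FS", "FD")
  )
  d1 <- fs_fd_distributions(pairs, bin_width = 8)
  expect_equal(nrow(d1$binned), 1)
  expect_equal(d1$binned$fs_weight, 0.5)
  expect_equal(d1$binned$fd_weight, 0.5)

  # estimator consistency: weighted moments recover N(50, 10^2)
  set.seed(23)
  n <- 4000
  dd <- rnorm(n, 50, 10)
  pr <- tibble::tibble(i = "x", j = "y", shared = 1L, o = rep(1 / n, n),
                       distance = dd, rsn_i = "VIS", rsn_j = "VIS",
                       class = "FS")
  suppressWarnings({
    fit <- fs_fd_distributions(pr, bin_width = 8)$fits
  })
  expect_equal(fit$mu[fit$class == "FS"], 50, tolerance = 0.5)
  expect_equal(fit$sigma[fit$class == "FS"], 10, tolerance = 0.5)

  # packaged-table grid spanning the cortical sheet gives 21 bins
  fx <- load_table1()
  tp <- convergence_pairs(fx$incidence, fx$cortical)
  dist <- fs_fd_distributions(tp, bin_width = 8, max_distance = 168)
  expect_equal(nrow(dist$binned), 21)
  expect_lt(max(tp$distance), 168)
  # every pair with positive weight is exactly one of FS/FD
  expect_true(all(tp$class[tp$o > 0] %in% c("FS", "FD")))
  expect_equal(sum(dist$binned$fs_weight) + sum(dist$binned$fd_weight), 1,
               tolerance = 1e-12)
})

test_that("paired bin-wise test matches the textbook formula", {
  base <- tibble::tibble(bin = 1:6, lower = 0:5 * 8, upper = 1:6 * 8)
  mk <- function(fs, fd) {
    structure(list(binned = dplyr::mutate(base, fs_weight = fs,
                                          fd_weight = fd),
                   bin_width = 8),
              class = "fs_fd_distributions")
  }
  expect_equal(fs_fd_paired_test(mk(rep(0.1, 6), rep(0.1, 6)))$t, 0)
  deg <- fs_fd_paired_test(mk(rep(0.1, 6), rep(0.11, 6)))
  expect_equal(deg$t, Inf)
  expect_equal(deg$p, 0)

  set.seed(31)
  fs <- runif(6); fd <- runif(6)
  res <- fs_fd_paired_test(mk(fs, fd))
  d <- fd - fs
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(6)), tolerance = 1e-10)
  expect_equal(res$dof, 5L)
})

test_that("network-level convergence percentages", {
  fx <- load_table1()
  nl <- network_level_convergence(
    fx$incidence,
    cortical_class = setNames(fx$cortical$network_class, fx$cortical$label),
    subcortical_network = setNames(fx$subcortical$sub_network,
                                   fx$subcortical$sub_label)
  )
  g <- function(nw, col) nl[[col]][nl$sub_network == nw]
  expect_equal(g("THA", "pct_primary"), 80)
  expect_equal(g("SLN", "pct_association"), 100 * 59 / 73)
  expect_equal(nl$pct_primary + nl$pct_association, rep(100, 3))

  # all-primary toy case
  inc <- matrix(1L, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  nl2 <- network_level_convergence(
    inc, cortical_class = c(a = "primary", b = "primary"),
    subcortical_network = c(s1 = "X", s2 = "X")
  )
  expect_equal(nl2$pct_primary, 100)
  # empty network reported as NA
  inc0 <- matrix(0L, 2, 1, dimnames = list(c("a", "b"), "s1"))
  nl3 <- network_level_convergence(
    inc0, cortical_class = c(a = "primary", b = "association"),
    subcortical_network = c(s1 = "X")
  )
  expect_true(is.na(nl3$pct_primary))
})
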