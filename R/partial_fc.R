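#' Prepare one subject's concatenated, mean-centred time series
#'
#' Per session: drop the first `n_discard` volumes (scanner steady-state),
#' subtract the per-ROI session mean (removes mean intensity differences
#' across sessions), then concatenate sessions row-wise.
#'
#' @param panel a [ts_panel].
#' @param subject subject id present in the panel.
#' @param n_discard leading volumes dropped per session.
#' @return numeric time x ROI matrix whose per-session blocks have zero
#'   column means.
#' @export
prepare_subject <- function(panel, subject, n_discard = 100) {
  stopifnot(inherits(panel, "ts_panel"))
  if (!subject %in% panel$subject_ids) {
    abort(sprintf("subject '%s' not in panel", subject))
  }
  blocks <- lapply(panel$session_ids, function(ses) {
    m <- panel$data[[subject]][[ses]]
    if (nrow(m) < n_discard + 2) {
      abort(sprintf("session '%s' has %d time points; need at least n_discard + 2 = %d",
                    ses, nrow(m), n_discard + 2))
    }
    m <- m[(n_discard + 1):nrow(m), , drop = FALSE]
    sweep(m, 2, colMeans(m), `-`)
  })
  do.call(rbind, blocks)
}

#' Partial-correlation betas by node-wise multiple regression
#'
#' For each target ROI i, the mean-centred series of all other N - 1 ROIs
#' enter an ordinary least-squares model for series i with no intercept;
#' entry (j, i) of the result is the coefficient of regressor j. The
#' coefficient quantifies the unique (partial) dependence of i on j,
#' controlling for every other ROI. Self-dependence is not modelled: the
#' diagonal is zero.
#'
#' @param x time x ROI matrix, more rows than columns, columns mean-centred.
#' @return N x N beta matrix, entry (j, i) = beta of regressor j in the
#'   model for target i.
#' @export
fit_partial_betas <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  n <- ncol(x)
  if (nrow(x) <= n) abort("need more time points than ROIs for regression")
  labels <- colnames(x)
  if (is.null(labels)) labels <- sprintf("V%d", seq_len(n))
  betas <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    fit <- stats::.lm.fit(x[, -i, drop = FALSE], x[, i])
    if (fit$rank < n - 1L) {
      bad <- labels[-i][fit$pivot[(fit$rank + 1L):(n - 1L)]]
      abort(sprintf("rank-deficient design for target '%s' (collinear columns near: %s)",
                    labels[i], paste(head(bad, 5), collapse = ", ")))
    }
    b <- numeric(n - 1L)
    b[fit$pivot] <- fit$coefficients  # undo the QR pivot
    betas[-i, i] <- b
  }
  betas
}

#' Group-level random-effects connectivity
#'
#' Entry-wise one-sample t-test of the subject betas (random-effects
#' analysis). An edge j -> i is significant when its two-sided p-value
#' falls below `alpha / n_comparisons` (Bonferroni over the regressors).
#' The binary matrix C records significance; the weighted matrix holds the
#' mean significant beta, rescaled by its maximum absolute value so weights
#' lie in \eqn{[-1, 1]}. Edges with zero between-subject variance and a
#' non-zero mean are degenerate t's and flagged significant (infinite-t
#' limit); all-zero edges are not.
#'
#' @param betas_by_subject list of N x N beta matrices, one per subject.
#' @param alpha nominal two-sided level before correction.
#' @param n_comparisons Bonferroni divisor; default N - 1 (the number of
#'   regressors per model).
#' @return an object of class `connectivity_result`.
#' @export
group_rfx <- function(betas_by_subject, alpha = 0.05, n_comparisons = NULL) {
  ns <- length(betas_by_subject)
  if (ns < 2) abort("need at least 2 subjects for a random-effects t-test")
  n <- nrow(betas_by_subject[[1]])
  if (is.null(n_comparisons)) n_comparisons <- n - 1L
  arr <- array(unlist(betas_by_subject), dim = c(n, n, ns))
  mu <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), sd)
  dof <- ns - 1L
  tmat <- matrix(0, n, n)
  nz <- s > 0
  tmat[nz] <- mu[nz] / (s[nz] / sqrt(ns))
  tmat[!nz & mu != 0] <- Inf * sign(mu[!nz & mu != 0])
  diag(tmat) <- 0
  p <- 2 * pt(-abs(tmat), df = dof)
  sig <- p < alpha / n_comparisons
  diag(sig) <- FALSE
  binary <- sig * 1L
  weighted <- mu * sig
  mx <- max(abs(weighted))
  if (mx > 0) weighted <- weighted / mx
  dimnames(tmat) <- dimnames(binary) <- dimnames(weighted) <-
    dimnames(betas_by_subject[[1]])
  structure(
    list(betas = betas_by_subject, t_matrix = tmat, dof = dof,
         binary = binary, weighted = weighted, alpha = alpha,
         n_comparisons = n_comparisons),
    class = "connectivity_result"
  )
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf(
    "<connectivity_result> %d ROIs, %d subjects, %d directed edges (alpha = %g / %d)\n",
    nrow(x$binary), x$dof + 1L, sum(x$binary), x$alpha, x$n_comparisons
  ))
  invisible(x)
}

#' Whole-pipeline subject-level connectivity
#'
#' Convenience wrapper: prepares every subject and fits the node-wise
#' regressions, returning the per-subject beta matrices.
#'
#' @inheritParams prepare_subject
#' @return named list of N x N beta matrices.
#' @export
fit_panel_betas <- function(panel, n_discard = 100) {
  out <- lapply(panel$subject_ids, function(s) {
    fit_partial_betas(prepare_subject(panel, s, n_discard = n_discard))
  })
  setNames(out, panel$subject_ids)
}

#' Phase-randomized surrogate series
#'
#' Randomizes Fourier phases of each column independently while keeping the
#' amplitude spectrum (hence the autocorrelation and the power) exactly,
#' destroying any genuine cross-series dependence. The DC component and,
#' for even lengths, the Nyquist component are kept real so the output is
#' real-valued.
#'
#' @param x numeric vector or time x ROI matrix, length >= 4.
#' @return surrogate of the same shape. Uses the current RNG state; seed
#'   with [set.seed()] for reproducibility.
#' @export
phase_randomize <- function(x) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(m)
  if (n < 4) abort("series must have length >= 4")
  half <- floor((n - 1) / 2)
  out <- m
  for (j in seq_len(ncol(m))) {
    f <- fft(m[, j])
    ph <- stats::runif(half, 0, 2 * pi)
    rot <- rep(1 + 0i, n)
    rot[2:(half + 1)] <- exp(1i * ph)
    rot[n:(n - half + 1)] <- Conj(rot[2:(half + 1)])
    out[, j] <- Re(fft(f * rot, inverse = TRUE)) / n
  }
  if (vec) out[, 1] else out
}

#' Surrogate-data test of genuine cross-series dependence
#'
#' Recomputes the partial-correlation magnitudes on phase-randomized
#' surrogate panels and compares the observed off-diagonal |beta| values
#' against the surrogate distribution. A significant result indicates
#' dependence beyond what autocorrelation alone produces.
#'
#' The primary p-value (`p`) is the permutation p-value of the observed
#' mean |beta| within the distribution of per-surrogate-panel means,
#' `(1 + #\{surrogate >= observed\}) / (n_surrogates + 1)`: under the null
#' of no cross-series dependence the observed panel is exchangeable with
#' its surrogates, so this p-value is calibrated. The pooled-variance
#' two-sample t over the raw |beta| values is also reported
#' (`t_pooled`, `dof_pooled`, `p_pooled`) for comparability, but |beta|
#' values within a panel are correlated, which makes the pooled test
#' anticonservative — it is recorded, not relied on.
#'
#' @inheritParams prepare_subject
#' @param n_surrogates number of surrogate panels (>= 2). The smallest
#'   achievable permutation p is `1 / (n_surrogates + 1)`.
#' @param seed RNG seed for the surrogate draws.
#' @return tibble with one row: p (permutation), observed and surrogate
#'   mean |beta|, pooled-t fields, n_surrogates, seed.
#' @export
surrogate_null_test <- function(panel, n_surrogates = 100, n_discard = 100,
                                seed = 1L) {
  if (n_surrogates < 2) abort("need at least 2 surrogates")
  prepared <- lapply(panel$subject_ids, function(s) {
    prepare_subject(panel, s, n_discard = n_discard)
  })
  off <- function(b) abs(b[row(b) != col(b)])
  obs <- unlist(lapply(prepared, function(m) off(fit_partial_betas(m))))
  set.seed(seed)
  sur_means <- numeric(n_surrogates)
  sur_all <- vector("list", n_surrogates)
  for (k in seq_len(n_surrogates)) {
    vals <- unlist(lapply(prepared, function(m) {
      off(fit_partial_betas(phase_randomize(m)))
    }))
    sur_means[k] <- mean(vals)
    sur_all[[k]] <- vals
  }
  sur <- unlist(sur_all)
  p_perm <- (1 + sum(sur_means >= mean(obs))) / (n_surrogates + 1)
  tt <- t.test(obs, sur, var.equal = TRUE)
  tibble::tibble(
    p = p_perm, observed_mean = mean(obs), surrogate_mean = mean(sur),
    t_pooled = unname(tt$statistic), dof_pooled = unname(tt$parameter),
    p_pooled = tt$p.value, n_surrogates = n_surrogates, seed = seed
  )
}
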