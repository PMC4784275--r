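# batch-means estimate of Var(mean(x)): ceiling(sqrt(n)) batches
batch_means_var <- function(x) {
  n <- length(x)
  nb <- ceiling(sqrt(n))
  b <- n %/% nb
  if (b < 1L) abort("segment too short for batch means")
  xm <- matrix(x[seq_len(nb * b)], nrow = b)
  bm <- colMeans(xm)
  v <- var(bm)
  if (!is.finite(v) || v == 0)
    abort("zero-variance segment; diagnostic undefined")
  v / nb
}

# spectral density of x at frequency zero via a Yule-Walker AR fit
# (variance of the mean is spectrum0(x)/n); 0 for a constant chain
spectrum0_ar <- function(x) {
  if (var(x) == 0) return(0)
  ord <- min(30L, length(x) %/% 4L)
  fit <- stats::ar(x, aic = TRUE, order.max = ord, method = "yule-walker",
                   demean = TRUE)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of an early segment of the chain with the mean of a
#' late segment: `z = (m1 - m2) / sqrt(v1 + v2)`, each segment's variance
#' of the mean estimated by batch means with `ceiling(sqrt(n))` batches.
#' Under stationarity z is approximately standard normal.
#'
#' @param x Numeric chain (length >= 100).
#' @param first Fraction of the chain forming the early segment
#'   (default 0.1).
#' @param last Fraction forming the late segment (default 0.5).
#' @return The z-score (numeric scalar).
#' @export
geweke_diag <- function(x, first = 0.1, last = 0.5) {
  n <- length(x)
  if (n < 100L) abort("chain must have at least 100 samples")
  if (first <= 0 || last <= 0 || first + last > 1)
    abort("`first` and `last` must be positive with first + last <= 1")
  x1 <- x[seq_len(floor(first * n))]
  x2 <- x[seq.int(n - floor(last * n) + 1L, n)]
  (mean(x1) - mean(x2)) / sqrt(batch_means_var(x1) + batch_means_var(x2))
}

# CDF of the Cramer-von Mises limiting distribution (standard series)
pcramer <- function(q, eps = 1e-5) {
  log_eps <- log(eps)
  vapply(q, function(qq) {
    if (qq <= 0) return(0)
    # the 4-term series loses accuracy far in the right tail, where the
    # limiting distribution carries < 1e-4 mass anyway
    if (qq >= 2) return(1)
    total <- 0
    for (k in 0:3) {
      z <- gamma(k + 0.5) * sqrt(4 * k + 1) /
        (gamma(k + 1) * pi^1.5 * sqrt(qq))
      u <- (4 * k + 1)^2 / (16 * qq)
      if (u <= -log_eps)
        total <- total + z * exp(-u) * besselK(u, nu = 0.25)
    }
    min(max(total, 0), 1)
  }, numeric(1))
}

#' Heidelberger-Welch convergence diagnostic
#'
#' Stationarity: a Cramer-von Mises test on the Brownian-bridge transform
#' of the cumulative sums, applied to the full chain and then, while it
#' rejects, to suffixes discarding successive 10% prefixes up to half the
#' chain. Halfwidth: on the retained part, the 95% confidence halfwidth of
#' the mean (spectral variance estimate from a Yule-Walker AR fit) must
#' not exceed `halfwidth_tol` times the absolute mean.
#'
#' @param x Numeric chain (length >= 100).
#' @param alpha Stationarity test level (default 0.05).
#' @param halfwidth_tol Relative halfwidth tolerance (default 0.1).
#' @return One-row tibble: `stationarity_pass`, `kept_fraction`,
#'   `halfwidth_pass`, `halfwidth`, `mean`, `cvm_p` (p-value at the
#'   accepted suffix, `NA` if none accepted).
#' @export
heidelberger_welch_diag <- function(x, alpha = 0.05, halfwidth_tol = 0.1) {
  n <- length(x)
  if (n < 100L) abort("chain must have at least 100 samples")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  kept_fraction <- 0
  stationary <- FALSE
  pval <- NA_real_
  kept <- numeric(0)
  for (start_frac in seq(0, 0.5, by = 0.1)) {
    xx <- x[seq.int(floor(start_frac * n) + 1L, n)]
    if (var(xx) == 0) { # constant suffix is trivially stationary
      stationary <- TRUE; kept_fraction <- 1 - start_frac
      kept <- xx; pval <- 1; break
    }
    nn <- length(xx)
    # spectral density from the second half only, so an early level shift
    # cannot inflate the variance estimate and mask itself
    S <- spectrum0_ar(xx[seq.int(nn %/% 2 + 1L, nn)])
    if (S == 0) S <- var(xx)
    Bk <- (cumsum(xx) - seq_len(nn) * mean(xx)) / sqrt(nn * S)
    cvm <- sum(Bk^2) / nn
    pval <- 1 - pcramer(cvm)
    if (pval > alpha) {
      stationary <- TRUE
      kept_fraction <- 1 - start_frac
      kept <- xx
      break
    }
  }
  if (stationary) {
    mk <- mean(kept)
    hw <- if (var(kept) == 0) 0 else
      1.96 * sqrt(spectrum0_ar(kept) / length(kept))
    hw_pass <- if (mk == 0) hw == 0 else (hw / abs(mk)) <= halfwidth_tol
  } else {
    mk <- NA_real_; hw <- NA_real_; hw_pass <- NA
  }
  tibble(stationarity_pass = stationary, kept_fraction = kept_fraction,
         halfwidth_pass = hw_pass, halfwidth = hw, mean = mk, cvm_p = pval)
}
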