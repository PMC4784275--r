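#' Highest posterior density interval
#'
#' The shortest interval containing `ceiling(mass * n)` of the sorted
#' samples.
#'
#' @param x Numeric vector of posterior samples.
#' @param mass Posterior mass in (0, 1), default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(x, mass = 0.95) {
  if (mass <= 0 || mass >= 1) abort("`mass` must lie strictly in (0, 1)")
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L) return(c(lower = x[1L], upper = x[n]))
  m <- min(n, ceiling(mass * n))
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- starts[which.min(widths)]
  c(lower = x[i], upper = x[i + m - 1L])
}

#' Posterior summary of a scalar chain
#'
#' Mean, median, standard deviation and highest-posterior-density bounds,
#' the summary layout conventional for reporting heritability posteriors.
#'
#' @param x Numeric vector of (thinned, post-burn-in) samples; at least
#'   100 are expected for a stable HPD.
#' @param mass HPD mass, default 0.95.
#' @return One-row tibble: `mean`, `median`, `sd`, `hpd_low`, `hpd_high`,
#'   `mass`.
#' @export
posterior_summary <- function(x, mass = 0.95) {
  if (mass <= 0 || mass >= 1) abort("`mass` must lie strictly in (0, 1)")
  if (length(x) < 2L) abort("need at least 2 samples")
  h <- hpd_interval(x, mass)
  tibble(mean = mean(x), median = median(x), sd = sd(x),
         hpd_low = unname(h[1L]), hpd_high = unname(h[2L]), mass = mass)
}

#' @describeIn gibbs_fit Posterior summaries (mean, median, SD, HPD) of
#'   `sigma2_a`, `sigma2_e` and `h2` as a tidy tibble.
#' @param x An `ssgblup_fit`.
#' @param mass HPD mass.
#' @param ... Unused.
#' @export
tidy.ssgblup_fit <- function(x, mass = 0.95, ...) {
  terms <- c("sigma2_a", "sigma2_e", "h2")
  dplyr::bind_cols(
    tibble(term = terms),
    dplyr::bind_rows(lapply(terms, function(tm)
      posterior_summary(x$chains[[tm]], mass)))
  )
}

#' @describeIn gibbs_fit One-row model overview with convergence
#'   diagnostics for the h2 chain.
#' @export
glance.ssgblup_fit <- function(x, ...) {
  hw <- heidelberger_welch_diag(x$chains$h2)
  tibble(
    n_records = x$meta$n_records,
    n_animals = x$meta$n_animals,
    n_genotyped = x$meta$n_genotyped,
    chain_length = x$meta$chain$length,
    burn_in = x$meta$chain$burn_in,
    thin = x$meta$chain$thin,
    n_samples = nrow(x$chains),
    geweke_z_h2 = geweke_diag(x$chains$h2),
    hw_stationary_h2 = hw$stationarity_pass,
    hw_kept_fraction_h2 = hw$kept_fraction
  )
}
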