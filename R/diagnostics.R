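#' Residual diagnostics: autocorrelation and stationarity
#'
#' Tools to decide whether a residual series is white. The sample ACF with
#' its 95% white-noise band flags serial correlation; the KPSS test flags a
#' remaining trend (level non-stationarity). Both feed the decision to model
#' residuals with ARIMA, and both are re-run on the whitened residuals to
#' confirm the correction worked.
#'
#' @name diagnostics
NULL

default_max_lag <- function(n) min(round(10 * log10(n)), n - 1L)

#' Sample autocorrelation function with white-noise band
#'
#' Standard biased estimator: covariance sums normalized by the lag-0 sum,
#' so the lag-0 value is exactly 1 and the usual +/- 1.96/sqrt(n) band
#' applies. Lags with |acf| above the band are flagged significant.
#'
#' @param series numeric vector, length >= 3.
#' @param max_lag highest lag; default `min(10*log10(n), n-1)` rounded.
#' @return object of class `tsgc_acf`: `lags` (0..L), `values`, `n`,
#'   `band` (1.96/sqrt(n)), `significant_lags` (lags > 0 outside the band).
#' @export
acf_series <- function(series, max_lag = NULL) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 3L) stop("series too short for ACF (need n >= 3)", call. = FALSE)
  if (stats::sd(series) == 0)
    stop("degenerate series: zero variance", call. = FALSE)
  if (is.null(max_lag)) max_lag <- default_max_lag(n)
  max_lag <- as.integer(max_lag)
  if (max_lag >= n) stop("max_lag must be < series length", call. = FALSE)
  vals <- as.numeric(stats::acf(series, lag.max = max_lag, plot = FALSE,
                                demean = TRUE)$acf)
  band <- 1.96 / sqrt(n)
  lags <- 0:max_lag
  sig <- lags[lags > 0L & abs(vals) > band]
  structure(list(lags = lags, values = vals, n = n, band = band,
                 significant_lags = sig), class = "tsgc_acf")
}

#' @export
print.tsgc_acf <- function(x, ...) {
  cat("ACF over lags 0..", max(x$lags), " (n = ", x$n, ", band = +/-",
      format(x$band, digits = 4), ")\n", sep = "")
  cat("Significant lags: ",
      if (length(x$significant_lags)) paste(x$significant_lags, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Whiteness report over per-subject residual series
#'
#' Computes the ACF per subject and the fraction of tested lags (1..L)
#' outside the 95% band. A subject passes when that fraction is at most
#' `threshold` (default 10% — under true whiteness about 5% of lags land
#' outside the band by chance); the panel passes when every subject passes.
#'
#' @param residuals named list of numeric residual series (one per subject),
#'   or a `tsgc_lmm` fit (its per-subject residuals are used).
#' @param max_lag highest tested lag (default as in [acf_series()]).
#' @param threshold maximal tolerated significant-lag fraction per subject.
#' @return object of class `tsgc_whiteness`: per-subject table
#'   (`subject`, `n_lags`, `n_significant`, `fraction`, `pass`), `acfs`
#'   (list of `tsgc_acf`), `mean_fraction`, `pass` (overall).
#' @export
whiteness_report <- function(residuals, max_lag = NULL, threshold = 0.10) {
  if (inherits(residuals, "tsgc_lmm")) residuals <- residual_series(residuals)
  stopifnot(is.list(residuals), length(residuals) >= 1L)
  if (is.null(names(residuals)))
    names(residuals) <- seq_along(residuals)
  acfs <- lapply(residuals, acf_series, max_lag = max_lag)
  tab <- do.call(rbind, lapply(names(acfs), function(s) {
    a <- acfs[[s]]
    nl <- length(a$lags) - 1L
    ns <- length(a$significant_lags)
    data.frame(subject = s, n_lags = nl, n_significant = ns,
               fraction = ns / nl, pass = (ns / nl) <= threshold,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(subjects = tab, acfs = acfs,
                 mean_fraction = mean(tab$fraction),
                 threshold = threshold, pass = all(tab$pass)),
            class = "tsgc_whiteness")
}

#' @export
print.tsgc_whiteness <- function(x, ...) {
  cat("Whiteness report: ", nrow(x$subjects), " subjects, ",
      sum(x$subjects$pass), " pass (threshold ",
      format(x$threshold), ")\n", sep = "")
  cat("Mean significant-lag fraction: ",
      format(x$mean_fraction, digits = 3), "\n", sep = "")
  cat("Overall: ", if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  invisible(x)
}

# KPSS critical values (level stationarity), upper-tail p in (0.01, 0.10)
.kpss_level_cval <- c(0.347, 0.463, 0.574, 0.739)
.kpss_level_p <- c(0.10, 0.05, 0.025, 0.01)

#' KPSS test for level stationarity
#'
#' Null hypothesis: the series is stationary around a constant level.
#' The statistic is \eqn{\sum_t S_t^2 / (n^2 \hat\omega^2)} with partial
#' sums \eqn{S_t} of the demeaned series and a Bartlett-kernel long-run
#' variance \eqn{\hat\omega^2} with truncation `trunc(3*sqrt(n)/13)` by
#' default. P-values are interpolated from the standard critical-value
#' table and truncated to [0.01, 0.10].
#'
#' @param series numeric vector, length >= 10.
#' @param nlags Bartlett truncation lag; default `trunc(3*sqrt(n)/13)`.
#' @return list with `statistic`, `p_value`, `nlags`, `reject_5pct`.
#' @export
kpss_level <- function(series, nlags = NULL) {
  y <- as.numeric(series)
  n <- length(y)
  if (n < 10L) stop("series too short for KPSS (need n >= 10)", call. = FALSE)
  if (is.null(nlags)) nlags <- trunc(3 * sqrt(n) / 13)
  e <- y - mean(y)
  S <- cumsum(e)
  s2 <- sum(e^2) / n
  lrv <- s2
  if (nlags > 0L) {
    for (l in seq_len(nlags)) {
      w <- 1 - l / (nlags + 1)
      lrv <- lrv + 2 * w * sum(e[1:(n - l)] * e[(l + 1):n]) / n
    }
  }
  if (lrv <= 0) lrv <- s2  # guard: kernel estimate can go nonpositive
  stat <- sum(S^2) / (n^2 * lrv)
  p <- stats::approx(.kpss_level_cval, .kpss_level_p, stat, rule = 2)$y
  list(statistic = stat, p_value = p, nlags = nlags,
       reject_5pct = stat > .kpss_level_cval[2L])
}

#' Flag a remaining trend in a residual series
#'
#' Screens a residual series for level non-stationarity (a surviving trend)
#' with the KPSS test: rejection at the given level raises the flag, which
#' is the signal to difference (d >= 1) in the ARIMA stage.
#'
#' @param series numeric vector, length >= 10.
#' @param alpha significance level of the screen (default 0.05).
#' @return list with `flag` (TRUE when a trend is indicated), `statistic`,
#'   `p_value`.
#' @export
trend_flag <- function(series, alpha = 0.05) {
  if (length(series) < 10L)
    stop("series too short for trend screening (need n >= 10)", call. = FALSE)
  k <- kpss_level(series)
  list(flag = k$p_value < alpha, statistic = k$statistic,
       p_value = k$p_value)
}
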