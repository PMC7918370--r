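#' Per-subject ARIMA modeling of trend-model residuals
#'
#' Second modeling stage: the residual series of each subject from the mixed
#' trend model may still carry autocorrelation and even a trend, which would
#' bias per-timepoint comparisons. Each subject's residual series
#' \eqn{\varepsilon_j} is therefore fitted with its own nonseasonal
#' ARIMA(p_j, d_j, q_j), selected automatically: the differencing order d by
#' repeated KPSS testing (with an enforceable minimum, default d >= 1 because
#' trends typically survive the trend model), and (p, q) by a stepwise
#' neighborhood search minimizing AICc in the style of the
#' Hyndman–Khandakar algorithm. The fitted one-step predictions
#' \eqn{\hat\varepsilon_j} become part of the combined model's fitted
#' values; the innovations \eqn{r_j = \varepsilon_j - \hat\varepsilon_j}
#' are the final, whitened residuals.
#'
#' The order container carries seasonal slots (P, D, Q, S) for interface
#' completeness, but the pipeline only fits nonseasonal models (S = 1).
#'
#' @name arima_stage
NULL

#' ARIMA order container
#'
#' @param p,d,q nonnegative integers; d <= 2.
#' @param P,D,Q,S seasonal order and period; must be all-zero (S = 1) in
#'   the nonseasonal pipeline.
#' @param drift include a drift/mean constant term.
#' @return object of class `tsgc_order`.
#' @export
arima_order <- function(p, d, q, P = 0L, D = 0L, Q = 0L, S = 1L,
                        drift = FALSE) {
  stopifnot(p >= 0, q >= 0, d >= 0, d <= 2)
  if (S <= 1L && (P > 0L || D > 0L || Q > 0L))
    stop("seasonal terms require a seasonal period S > 1", call. = FALSE)
  structure(list(p = as.integer(p), d = as.integer(d), q = as.integer(q),
                 P = as.integer(P), D = as.integer(D), Q = as.integer(Q),
                 S = as.integer(S), drift = isTRUE(drift)),
            class = "tsgc_order")
}

#' @export
print.tsgc_order <- function(x, ...) {
  cat("ARIMA(", x$p, ",", x$d, ",", x$q, ")",
      if (x$S > 1L) paste0("(", x$P, ",", x$D, ",", x$Q, ")[", x$S, "]"),
      if (x$drift) " with drift", "\n", sep = "")
  invisible(x)
}

#' Choose the differencing order by repeated KPSS testing
#'
#' Starting from `min_d` differences, tests the differenced series for
#' level stationarity with KPSS and keeps differencing (up to `max_d`)
#' while stationarity is rejected. The floor `min_d = 1` encodes the
#' observation that trends survive the trend-model stage and must be
#' removed before ARMA fitting.
#'
#' @param series numeric vector, length >= 20.
#' @param min_d minimal differencing order, 0..2 (default 1).
#' @param max_d maximal differencing order (default 2).
#' @param alpha KPSS level (default 0.05).
#' @return integer d in `min_d..max_d`.
#' @export
choose_d <- function(series, min_d = 1L, max_d = 2L, alpha = 0.05) {
  stopifnot(min_d >= 0L, min_d <= 2L, max_d >= min_d)
  if (length(series) < 20L)
    stop("series too short for differencing-order selection (need n >= 20)",
         call. = FALSE)
  d <- as.integer(min_d)
  x <- if (d > 0L) diff(series, differences = d) else series
  repeat {
    if (length(x) < 10L)
      stop("series too short after differencing", call. = FALSE)
    if (kpss_level(x)$p_value >= alpha || d >= max_d) break
    d <- d + 1L
    x <- diff(x)
  }
  d
}

# Single arima() fit with fallback estimation methods; NULL if all fail.
# constant: mean when d = 0, linear drift regressor when d = 1, none when d = 2.
.arima_try <- function(x, p, d, q, constant) {
  xreg <- NULL
  include_mean <- FALSE
  if (constant && d == 0L) include_mean <- TRUE
  if (constant && d == 1L) xreg <- matrix(seq_along(x), dimnames = list(NULL, "drift"))
  for (method in c("CSS-ML", "ML")) {
    fit <- tryCatch(
      suppressWarnings(stats::arima(x, order = c(p, d, q), xreg = xreg,
                                    include.mean = include_mean,
                                    method = method)),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  NULL
}

# Admissibility guard used during order selection: candidates whose fitted
# AR or MA polynomial has a root within 1.001 of the unit circle are
# near-nonstationary/noninvertible boundary fits (often spurious
# cancelling-root solutions with inflated likelihood) and are excluded.
.roots_admissible <- function(fit) {
  cf <- fit$coef
  ar <- cf[grep("^ar", names(cf))]
  ma <- cf[grep("^ma", names(cf))]
  if (length(ar) && any(Mod(polyroot(c(1, -ar))) < 1.001)) return(FALSE)
  if (length(ma) && any(Mod(polyroot(c(1, ma))) < 1.001)) return(FALSE)
  TRUE
}

.aicc_of <- function(fit, n_eff) {
  k <- length(fit$coef) + 1L  # + innovation variance
  if (n_eff - k - 1L <= 0L) return(Inf)
  fit$aic + 2 * k * (k + 1L) / (n_eff - k - 1L)
}

#' Fit an ARIMA model of given order
#'
#' Exact Gaussian maximum likelihood (CSS-initialized) through
#' [stats::arima()], with the drift constant for d = 1 handled as a linear
#' regressor. Fitted values are in-sample one-step-ahead predictions, so
#' `fitted + residuals` reconstructs the input series exactly.
#'
#' @param series numeric vector.
#' @param order a `tsgc_order` (its `drift` flag controls the constant),
#'   or a length-3 integer vector (p, d, q).
#' @return object of class `tsgc_arima`: `order`, `ar_coeffs`, `ma_coeffs`,
#'   `constant` (mean or drift coefficient, NA if absent), `sigma2`,
#'   `loglik`, `aic`, `aicc`, `bic`, `fitted`, `residuals`, `method`.
#' @export
fit_arima <- function(series, order) {
  if (is.numeric(order) && length(order) == 3L)
    order <- arima_order(order[1L], order[2L], order[3L])
  stopifnot(inherits(order, "tsgc_order"))
  x <- as.numeric(series)
  n <- length(x)
  if (n <= order$p + order$q + order$d + 1L)
    stop("series too short for ARIMA(", order$p, ",", order$d, ",",
         order$q, ")", call. = FALSE)
  constant <- order$drift && order$d <= 1L
  fit <- .arima_try(x, order$p, order$d, order$q, constant)
  if (is.null(fit))
    stop("ARIMA fit failed for order (", order$p, ",", order$d, ",",
         order$q, ")", call. = FALSE)
  cf <- stats::coef(fit)
  ar <- unname(cf[grep("^ar", names(cf))])
  ma <- unname(cf[grep("^ma", names(cf))])
  const <- cf[names(cf) %in% c("intercept", "drift")]
  res <- as.numeric(stats::residuals(fit))
  n_eff <- n - order$d
  structure(list(order = order,
                 ar_coeffs = ar, ma_coeffs = ma,
                 constant = if (length(const)) unname(const) else NA_real_,
                 sigma2 = fit$sigma2,
                 loglik = as.numeric(fit$loglik),
                 aic = fit$aic,
                 aicc = .aicc_of(fit, n_eff),
                 bic = fit$aic + (log(n_eff) - 2) * (length(cf) + 1L),
                 fitted = x - res,
                 residuals = res,
                 n = n,
                 method = "CSS-ML (stats::arima)"),
            class = "tsgc_arima")
}

#' @export
print.tsgc_arima <- function(x, ...) {
  print(x$order)
  if (length(x$ar_coeffs)) cat("AR:", format(x$ar_coeffs, digits = 4), "\n")
  if (length(x$ma_coeffs)) cat("MA:", format(x$ma_coeffs, digits = 4), "\n")
  cat("sigma2 ", format(x$sigma2, digits = 4), "  AICc ",
      format(x$aicc, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Stepwise ARIMA order search
#'
#' Neighborhood search over (p, q, constant) at fixed d, minimizing AICc
#' (AIC/BIC selectable): start from the four standard anchors (0,d,0),
#' (1,d,0), (0,d,1), (2,d,2), then repeatedly move to the best-scoring
#' neighbor obtained by changing p and/or q by one (within bounds) or
#' toggling the constant (only meaningful for d <= 1), until no neighbor
#' improves. Candidates whose fitted AR/MA roots sit within 1.001 of the
#' unit circle are excluded as spurious boundary fits. Exact ties are
#' broken toward smaller p + q, then smaller p.
#'
#' @param series numeric vector.
#' @param d differencing order (already chosen, e.g. by [choose_d()]).
#' @param p_max,q_max search bounds (default 5).
#' @param ic information criterion: "aicc" (default), "aic" or "bic".
#' @return the selected `tsgc_order`, with attribute `ic_value` (its
#'   criterion value) and `n_models` (number of candidate fits evaluated).
#' @export
stepwise_select <- function(series, d, p_max = 5L, q_max = 5L,
                            ic = c("aicc", "aic", "bic")) {
  ic <- match.arg(ic)
  x <- as.numeric(series)
  d <- as.integer(d)
  cache <- new.env(parent = emptyenv())
  score <- function(p, q, constant) {
    if (p < 0L || q < 0L || p > p_max || q > q_max) return(Inf)
    if (d > 1L && constant) return(Inf)
    key <- paste(p, q, constant)
    if (!is.null(cache[[key]])) return(cache[[key]])
    fit <- .arima_try(x, p, d, q, constant)
    if (!is.null(fit) && !.roots_admissible(fit)) fit <- NULL
    val <- if (is.null(fit)) Inf else switch(ic,
      aicc = .aicc_of(fit, length(x) - d),
      aic = fit$aic,
      bic = fit$aic + (log(length(x) - d) - 2) * (length(fit$coef) + 1L))
    cache[[key]] <- val
    val
  }
  better <- function(a, b) {  # candidate a strictly preferred over b
    if (a$val != b$val) return(a$val < b$val)
    if ((a$p + a$q) != (b$p + b$q)) return((a$p + a$q) < (b$p + b$q))
    a$p < b$p
  }
  cand <- function(p, q, constant)
    list(p = p, q = q, constant = constant, val = score(p, q, constant))

  const0 <- d <= 1L
  starts <- list(cand(0L, 0L, const0), cand(1L, 0L, const0),
                 cand(0L, 1L, const0),
                 cand(min(2L, p_max), min(2L, q_max), const0))
  if (const0) starts <- c(starts, list(cand(0L, 0L, FALSE)))
  best <- starts[[1L]]
  for (s in starts[-1L]) if (better(s, best)) best <- s
  if (is.infinite(best$val))
    stop("ARIMA order selection failed: no candidate model could be fitted",
         call. = FALSE)

  repeat {
    nb <- list(cand(best$p + 1L, best$q, best$constant),
               cand(best$p - 1L, best$q, best$constant),
               cand(best$p, best$q + 1L, best$constant),
               cand(best$p, best$q - 1L, best$constant),
               cand(best$p + 1L, best$q + 1L, best$constant),
               cand(best$p - 1L, best$q - 1L, best$constant),
               cand(best$p + 1L, best$q - 1L, best$constant),
               cand(best$p - 1L, best$q + 1L, best$constant))
    if (d <= 1L) nb <- c(nb, list(cand(best$p, best$q, !best$constant)))
    improved <- FALSE
    for (s in nb) if (better(s, best)) { best <- s; improved <- TRUE }
    if (!improved) break
  }
  out <- arima_order(best$p, d, best$q, drift = best$constant)
  attr(out, "ic_value") <- best$val
  attr(out, "n_models") <- length(ls(cache))
  out
}

#' Fit ARIMA models to every subject's trend-model residuals
#'
#' For each subject: choose d (KPSS with floor `min_d`), select (p, q) by
#' [stepwise_select()], fit the model, and collect the whitened residuals.
#' A whiteness report over the whitened residuals of all subjects is
#' attached — the check that the autocorrelation has actually been absorbed.
#'
#' @param lmm_fit a `tsgc_lmm`, or a named list of residual series.
#' @param min_d minimal differencing order (default 1).
#' @param p_max,q_max stepwise search bounds (default 5).
#' @param ic selection criterion (default "aicc").
#' @param max_lag,threshold passed to [whiteness_report()] for the final
#'   residuals.
#' @return object of class `tsgc_arima_set`: `fits` (named list of
#'   `tsgc_arima`), `orders` (summary data.frame), `whiteness`
#'   (a `tsgc_whiteness` on the whitened residuals).
#' @export
fit_all_residuals <- function(lmm_fit, min_d = 1L, p_max = 5L, q_max = 5L,
                              ic = "aicc", max_lag = NULL, threshold = 0.10) {
  series <- if (inherits(lmm_fit, "tsgc_lmm")) residual_series(lmm_fit)
            else lmm_fit
  if (!is.list(series) || length(series) == 0L)
    stop("no residual series to fit", call. = FALSE)
  fits <- list()
  failures <- character()
  for (s in names(series)) {
    fit <- tryCatch({
      d <- choose_d(series[[s]], min_d = min_d)
      ord <- stepwise_select(series[[s]], d, p_max = p_max, q_max = q_max,
                             ic = ic)
      fit_arima(series[[s]], ord)
    }, error = function(e) e)
    if (inherits(fit, "error")) failures <- c(failures, s)
    else fits[[s]] <- fit
  }
  if (length(failures)) {
    cond <- simpleError(paste0("ARIMA fitting failed for subject(s) ",
                               paste(failures, collapse = ", ")))
    cond$partial <- fits
    stop(cond)
  }
  orders <- do.call(rbind, lapply(names(fits), function(s) {
    f <- fits[[s]]
    data.frame(subject = s, p = f$order$p, d = f$order$d, q = f$order$q,
               drift = f$order$drift, sigma2 = f$sigma2, aicc = f$aicc,
               stringsAsFactors = FALSE)
  }))
  rownames(orders) <- NULL
  wh <- whiteness_report(lapply(fits, function(f) f$residuals),
                         max_lag = max_lag, threshold = threshold)
  structure(list(fits = fits, orders = orders, whiteness = wh),
            class = "tsgc_arima_set")
}

#' @export
print.tsgc_arima_set <- function(x, ...) {
  cat("Per-subject ARIMA fits (", length(x$fits), " subjects)\n", sep = "")
  ords <- paste0("(", x$orders$p, ",", x$orders$d, ",", x$orders$q, ")")
  print(table(order = ords))
  cat("Whitened-residual whiteness: ",
      if (x$whiteness$pass) "PASS" else "FAIL",
      " (mean significant-lag fraction ",
      format(x$whiteness$mean_fraction, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Export the per-subject model list
#'
#' @param arima_set a `tsgc_arima_set`.
#' @return data.frame with subject, order, drift, coefficients (comma-joined
#'   AR then MA), sigma2 and AICc — the shape of a supplementary model list.
#' @export
arima_model_table <- function(arima_set) {
  stopifnot(inherits(arima_set, "tsgc_arima_set"))
  tab <- arima_set$orders
  tab$ar <- vapply(arima_set$fits[tab$subject], function(f)
    paste(format(f$ar_coeffs, digits = 6), collapse = ","), "")
  tab$ma <- vapply(arima_set$fits[tab$subject], function(f)
    paste(format(f$ma_coeffs, digits = 6), collapse = ","), "")
  tab
}
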