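#' Per-timepoint group comparison with Bonferroni correction
#'
#' Final stage: the trend-model and ARIMA fitted parts are summed into the
#' combined per-observation fitted values; at each time index, every
#' unordered group pair is compared by a two-sample t-test on those fitted
#' values; and p-values are judged against the Bonferroni-corrected
#' per-timepoint threshold alpha / (number of pairs). Maximal runs of
#' consecutive significant indices become significance windows, reported in
#' minutes. A *naive* mode skips the ARIMA part — comparing on trend-model
#' fitted values alone — which demonstrates the false positives and false
#' negatives that uncorrected residual autocorrelation produces.
#'
#' @name inference
NULL

#' Combine trend-model and ARIMA fitted values
#'
#' Per observation: `final_fitted = lmm_fitted + arima_fitted` and
#' `residual = observed - final_fitted` (the whitened residual). In naive
#' mode the ARIMA part is identically zero, so the final residuals are the
#' raw trend-model residuals.
#'
#' @param lmm_fit a `tsgc_lmm`.
#' @param arima_fits a `tsgc_arima_set` covering every subject (required in
#'   corrected mode; ignored in naive mode).
#' @param mode `"corrected"` (default) or `"naive"`.
#' @return object of class `tsgc_combined`: `data` (per-observation
#'   data.frame with `subject`, `group`, `time`, `observed`, `lmm_fitted`,
#'   `arima_fitted`, `final_fitted`, `residual`), `mode`, `interval`,
#'   `group_residual_means`.
#' @export
combine_fits <- function(lmm_fit, arima_fits = NULL,
                         mode = c("corrected", "naive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(lmm_fit, "tsgc_lmm"))
  df <- lmm_fit$residuals[order(lmm_fit$residuals$subject,
                                lmm_fit$residuals$time), ]
  names(df)[names(df) == "fitted"] <- "lmm_fitted"
  names(df)[names(df) == "residual"] <- "lmm_residual"
  if (mode == "corrected") {
    if (is.null(arima_fits))
      stop("corrected mode requires ARIMA fits for every subject",
           call. = FALSE)
    if (inherits(arima_fits, "tsgc_arima_set")) arima_fits <- arima_fits$fits
    missing_subj <- setdiff(unique(df$subject), names(arima_fits))
    if (length(missing_subj))
      stop("completeness error: no ARIMA fit for subject(s) ",
           paste(missing_subj, collapse = ", "), call. = FALSE)
    df$arima_fitted <- unlist(lapply(split(df, df$subject), function(sd)
      arima_fits[[sd$subject[1L]]]$fitted), use.names = FALSE)
  } else {
    df$arima_fitted <- 0
  }
  df$final_fitted <- df$lmm_fitted + df$arima_fitted
  df$residual <- df$observed - df$final_fitted
  df$lmm_residual <- NULL
  rownames(df) <- NULL
  grm <- tapply(df$residual, df$group, mean)
  structure(list(data = df, mode = mode, interval = lmm_fit$interval,
                 group_residual_means = grm),
            class = "tsgc_combined")
}

#' @export
print.tsgc_combined <- function(x, ...) {
  cat("Combined fit (", x$mode, " mode): ", nrow(x$data),
      " observations\n", sep = "")
  cat("Per-group mean of final residuals:\n")
  print(round(x$group_residual_means, 6))
  invisible(x)
}

#' Two-sample t-test at one timepoint
#'
#' Pooled-variance two-sided t-test by default (Welch behind the flag).
#' Degenerate samples follow explicit conventions: both groups constant
#' with equal means gives p = 1; constant with unequal means gives p = 0
#' (flagged degenerate).
#'
#' @param a,b numeric vectors (the per-group fitted values at one
#'   timepoint), each of length >= 2.
#' @param var_equal pooled variance (TRUE, default) or Welch.
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
timepoint_test <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs >= 2 values at the timepoint", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2L,
                  degenerate = TRUE))
    return(list(t = Inf * sign(mean(a) - mean(b)), p = 0,
                df = length(a) + length(b) - 2L, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

#' Extract maximal significance windows from per-timepoint flags
#'
#' Converts a logical flag vector over the time grid into the maximal runs
#' of consecutive flagged indices, reported both as index ranges and in
#' minutes. A single flagged index is a width-one window.
#'
#' @param significant logical vector over time indices 1..T.
#' @param interval minutes per time step.
#' @return data.frame with `start_index`, `end_index`, `start_minutes`,
#'   `end_minutes` (zero rows when nothing is flagged).
#' @export
significance_windows <- function(significant, interval = 2) {
  significant <- as.logical(significant)
  if (!any(significant))
    return(data.frame(start_index = integer(), end_index = integer(),
                      start_minutes = numeric(), end_minutes = numeric()))
  r <- rle(significant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_index = starts[keep], end_index = ends[keep],
             start_minutes = interval * (starts[keep] - 1),
             end_minutes = interval * (ends[keep] - 1))
}

#' Per-timepoint pairwise tests and significance windows
#'
#' For each unordered group pair and each time index, tests the groups'
#' final fitted values with [timepoint_test()]; flags the index significant
#' when p is below the Bonferroni threshold alpha / (number of pairs)
#' (the per-timepoint family; e.g. 0.05/3 = 0.01667 for three groups).
#' Optionally the family can instead span all pairs x timepoints.
#'
#' @param combined a `tsgc_combined`.
#' @param alpha family-wise level per timepoint (default 0.05).
#' @param var_equal pooled (default) vs Welch tests.
#' @param across_time if TRUE, Bonferroni divides by pairs x timepoints
#'   instead of pairs only (off by default, matching the per-timepoint
#'   convention).
#' @return object of class `tsgc_report`: `tests` (pair, time, minutes,
#'   mean_a, mean_b, t, p, significant), `windows` (pair, start/end index
#'   and minutes), `alpha`, `threshold`, `n_pairs`.
#' @export
pairwise_windows <- function(combined, alpha = 0.05, var_equal = TRUE,
                             across_time = FALSE) {
  stopifnot(inherits(combined, "tsgc_combined"))
  df <- combined$data
  groups <- sort(unique(df$group))
  if (length(groups) < 2L)
    stop("nothing to compare: need >= 2 groups", call. = FALSE)
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  n_pairs <- length(pairs)
  times <- sort(unique(df$time))
  threshold <- alpha / (n_pairs * if (across_time) length(times) else 1L)

  tests <- do.call(rbind, lapply(pairs, function(pr) {
    da <- df[df$group == pr[1L], ]
    db <- df[df$group == pr[2L], ]
    va <- split(da$final_fitted, da$time)
    vb <- split(db$final_fitted, db$time)
    do.call(rbind, lapply(as.character(times), function(tt) {
      ht <- timepoint_test(va[[tt]], vb[[tt]], var_equal = var_equal)
      data.frame(pair = paste(pr, collapse = "-"),
                 time = as.integer(tt),
                 minutes = combined$interval * (as.integer(tt) - 1),
                 mean_a = mean(va[[tt]]), mean_b = mean(vb[[tt]]),
                 t = ht$t, p = ht$p, significant = ht$p < threshold,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(tests) <- NULL

  windows <- do.call(rbind, lapply(unique(tests$pair), function(pp) {
    sub <- tests[tests$pair == pp, ]
    sub <- sub[order(sub$time), ]
    w <- significance_windows(sub$significant, combined$interval)
    if (nrow(w)) cbind(pair = pp, w, stringsAsFactors = FALSE) else NULL
  }))
  if (is.null(windows))
    windows <- data.frame(pair = character(), start_index = integer(),
                          end_index = integer(), start_minutes = numeric(),
                          end_minutes = numeric())
  rownames(windows) <- NULL
  structure(list(tests = tests, windows = windows, alpha = alpha,
                 threshold = threshold, n_pairs = n_pairs,
                 mode = combined$mode), class = "tsgc_report")
}

#' @export
print.tsgc_report <- function(x, ...) {
  cat("Pairwise comparison report (", x$mode, " mode)\n", sep = "")
  cat("alpha ", x$alpha, ", ", x$n_pairs,
      " comparisons per timepoint, corrected threshold ",
      format(x$threshold, digits = 4), "\n", sep = "")
  if (nrow(x$windows)) {
    cat("Significance windows:\n")
    print(x$windows, row.names = FALSE)
  } else cat("No significant differences found.\n")
  invisible(x)
}

#' Run the pipeline in naive and corrected mode and tabulate discordance
#'
#' Fits the trend model once, then compares groups (a) on trend-model
#' fitted values alone (naive — residual autocorrelation untouched) and
#' (b) on the combined fitted values after per-subject ARIMA whitening
#' (corrected). The discordance table counts, per pair, timepoints flagged
#' only by the naive analysis (candidate false positives) and only by the
#' corrected one (signals the naive analysis misses).
#'
#' @param panel a `tsgc_panel`.
#' @param alpha family level per timepoint (default 0.05).
#' @param min_d,p_max,q_max ARIMA-stage settings (see
#'   [fit_all_residuals()]).
#' @param var_equal pooled (default) vs Welch tests.
#' @param lmm_fit optionally a pre-computed `tsgc_lmm` for this panel.
#' @return list with `naive` and `corrected` (`tsgc_report`s),
#'   `discordance` (per-pair counts), `lmm_fit`, `arima_fits`.
#' @export
naive_vs_corrected <- function(panel, alpha = 0.05, min_d = 1L,
                               p_max = 5L, q_max = 5L, var_equal = TRUE,
                               lmm_fit = NULL) {
  if (is.null(lmm_fit)) lmm_fit <- fit_lmm(panel)
  arima_fits <- fit_all_residuals(lmm_fit, min_d = min_d,
                                  p_max = p_max, q_max = q_max)
  rep_naive <- pairwise_windows(combine_fits(lmm_fit, mode = "naive"),
                                alpha = alpha, var_equal = var_equal)
  rep_corr <- pairwise_windows(combine_fits(lmm_fit, arima_fits),
                               alpha = alpha, var_equal = var_equal)
  key <- function(r) paste(r$tests$pair, r$tests$time)
  stopifnot(identical(key(rep_naive), key(rep_corr)))
  agree <- rep_naive$tests$significant == rep_corr$tests$significant
  disc <- do.call(rbind, lapply(unique(rep_naive$tests$pair), function(pp) {
    i <- rep_naive$tests$pair == pp
    data.frame(pair = pp,
               n_timepoints = sum(i),
               naive_only = sum(rep_naive$tests$significant[i] &
                                  !rep_corr$tests$significant[i]),
               corrected_only = sum(!rep_naive$tests$significant[i] &
                                      rep_corr$tests$significant[i]),
               agreement = mean(agree[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(disc) <- NULL
  list(naive = rep_naive, corrected = rep_corr, discordance = disc,
       lmm_fit = lmm_fit, arima_fits = arima_fits)
}
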