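# Fixtures and independent oracles shared across test files.

# Minimal long-format data frame: complete grid, n subjects x T timepoints.
tiny_panel_df <- function(n_subjects = 2, n_time = 3,
                          groups = rep("A", n_subjects),
                          values = NULL) {
  df <- expand.grid(time = seq_len(n_time), subject = paste0("s", seq_len(n_subjects)),
                    stringsAsFactors = FALSE)
  df$group <- groups[match(df$subject, paste0("s", seq_len(n_subjects)))]
  df$value <- if (is.null(values)) seq_len(nrow(df)) else values
  df[, c("subject", "group", "time", "value")]
}

# Deterministic quadratic panel with optional iid noise, >= 2 groups.
quad_panel <- function(n_per_group = 3, n_time = 30, offsets = c(A = 0, B = 0.5),
                       b = c(0.1, 0.05, -4e-4), noise_sd = 0, seed = 1) {
  set.seed(seed)
  t <- seq_len(n_time)
  rows <- list()
  for (g in names(offsets)) for (j in seq_len(n_per_group)) {
    val <- b[1] + b[2] * t + b[3] * t^2 + offsets[[g]] +
      stats::rnorm(n_time, 0, noise_sd)
    rows[[paste(g, j)]] <- data.frame(subject = paste0(g, j), group = g,
                                      time = t, value = val,
                                      stringsAsFactors = FALSE)
  }
  as_panel(do.call(rbind, rows))
}

# Double-loop ACF oracle: the standard biased estimator computed directly.
acf_oracle <- function(y, max_lag) {
  n <- length(y)
  m <- mean(y)
  denom <- sum((y - m)^2)
  vapply(0:max_lag, function(k) {
    s <- 0
    for (t in seq_len(n - k)) s <- s + (y[t] - m) * (y[t + k] - m)
    s / denom
  }, 0)
}

# Brute-force run scanner for significance windows.
runs_oracle <- function(flags) {
  out <- list()
  start <- NA
  for (i in seq_along(flags)) {
    if (flags[i] && is.na(start)) start <- i
    if (!flags[i] && !is.na(start)) {
      out[[length(out) + 1L]] <- c(start, i - 1L)
      start <- NA
    }
  }
  if (!is.na(start)) out[[length(out) + 1L]] <- c(start, length(flags))
  out
}

# Exhaustive ARMA(p,q) search oracle: minimal AICc over the bounded grid
# (with and without a mean), under the same admissibility rule as the
# stepwise search (no AR/MA roots within 1.001 of the unit circle).
exhaustive_aicc <- function(y, p_max = 3, q_max = 3) {
  grid <- expand.grid(p = 0:p_max, q = 0:q_max, const = c(TRUE, FALSE))
  min(apply(grid, 1, function(g) {
    fit <- tryCatch(suppressWarnings(
      stats::arima(y, order = c(g[["p"]], 0, g[["q"]]),
                   include.mean = as.logical(g[["const"]]))),
      error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    cf <- fit$coef
    ar <- cf[grep("^ar", names(cf))]
    ma <- cf[grep("^ma", names(cf))]
    if (length(ar) && any(Mod(polyroot(c(1, -ar))) < 1.001)) return(Inf)
    if (length(ma) && any(Mod(polyroot(c(1, ma))) < 1.001)) return(Inf)
    k <- length(cf) + 1
    fit$aic + 2 * k * (k + 1) / (length(y) - k - 1)
  }))
}

# Pooled-variance two-sample t statistic, textbook formula.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}
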