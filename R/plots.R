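#' @export
plot.tsgc_acf <- function(x, main = "ACF", ...) {
  graphics::plot(x$lags, x$values, type = "h", ylim = c(-1, 1),
                 xlab = "Lag", ylab = "ACF", main = main, ...)
  graphics::abline(h = 0)
  graphics::abline(h = c(-x$band, x$band), lty = 2, col = "blue")
}

#' Grid of per-subject ACF panels
#'
#' One panel per subject, titled "Group: Replicate: Experiment" when
#' subject metadata titles are supplied — the layout used to eyeball which
#' residual series still carry autocorrelation.
#'
#' @param whiteness a `tsgc_whiteness`.
#' @param titles optional named character vector (names = subject ids).
#' @export
plot_acf_grid <- function(whiteness, titles = NULL) {
  stopifnot(inherits(whiteness, "tsgc_whiteness"))
  ids <- names(whiteness$acfs)
  n <- length(ids)
  nc <- ceiling(sqrt(n))
  nr <- ceiling(n / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(2.5, 2.5, 2, 0.5),
                      mgp = c(1.5, 0.5, 0))
  on.exit(graphics::par(op))
  for (id in ids) {
    ttl <- if (!is.null(titles) && id %in% names(titles)) titles[[id]] else id
    plot(whiteness$acfs[[id]], main = ttl)
  }
  invisible(NULL)
}

#' @export
plot.tsgc_report <- function(x, naive = NULL, ...) {
  pairs <- unique(x$tests$pair)
  op <- graphics::par(mfrow = c(length(pairs), 1),
                      mar = c(3.5, 3.5, 2, 0.5), mgp = c(2, 0.6, 0))
  on.exit(graphics::par(op))
  for (pp in pairs) {
    sub <- x$tests[x$tests$pair == pp, ]
    sub <- sub[order(sub$time), ]
    ylim <- range(c(sub$mean_a, sub$mean_b))
    graphics::plot(sub$minutes, sub$mean_a, type = "l", col = "black",
                   ylim = ylim, xlab = "Minutes", ylab = "Group mean",
                   main = pp, ...)
    graphics::lines(sub$minutes, sub$mean_b, col = "grey40")
    w <- x$windows[x$windows$pair == pp, ]
    if (nrow(w))
      graphics::abline(v = c(w$start_minutes, w$end_minutes), lwd = 2)
    if (!is.null(naive)) {
      wn <- naive$windows[naive$windows$pair == pp, ]
      if (nrow(wn))
        graphics::abline(v = c(wn$start_minutes, wn$end_minutes),
                         lty = 2, col = "red")
    }
  }
  invisible(x)
}
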