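#' Panels of grouped time series
#'
#' A *panel* is a long-format collection of time series ("subjects", e.g.
#' individual seedlings) observed on a common, complete grid of integer time
#' indices `1..T`. Each subject belongs to a group (e.g. a genotype) and
#' carries replicate/experiment metadata. Panels are the input to the whole
#' pipeline: trend fitting, residual whitening and per-timepoint group
#' comparison.
#'
#' Internally a panel is a `data.frame` with columns `subject`, `group`,
#' `replicate`, `experiment`, `time`, `value`, plus attributes:
#' `interval` (minutes between consecutive time indices), `scaled` (has
#' baseline scaling been applied), and `reference` (the reference group
#' label, carried into the fixed-effect dummy coding).
#'
#' @name panel
NULL

.panel_cols <- c("subject", "group", "replicate", "experiment", "time", "value")

#' Construct and validate a panel
#'
#' Validates the completeness invariants every downstream stage relies on:
#' a common time grid `1..T` for every subject with no gaps or duplicates,
#' numeric values, and at least one group.
#'
#' @param data data.frame with columns `subject`, `group`, `replicate`,
#'   `experiment`, `time`, `value` (`replicate`/`experiment` may be absent;
#'   they default to 1).
#' @param interval minutes between consecutive time indices (default 2).
#' @param reference reference group label; defaults to the first group in
#'   sort order. The reference group carries no dummy in the fixed design.
#' @param scaled logical; has baseline scaling already been applied?
#' @return an object of class `tsgc_panel` (a data.frame).
#' @seealso [read_panel()], [scale_to_baseline()]
#' @export
as_panel <- function(data, interval = 2, reference = NULL, scaled = FALSE) {
  data <- as.data.frame(data)
  if (!("replicate" %in% names(data))) data$replicate <- 1L
  if (!("experiment" %in% names(data))) data$experiment <- 1L
  missing_cols <- setdiff(.panel_cols, names(data))
  if (length(missing_cols))
    stop("panel schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  data <- data[, .panel_cols]
  if (!is.numeric(data$value))
    stop("panel parse error: 'value' is not numeric", call. = FALSE)
  if (anyNA(data$value))
    stop("panel parse error: NA value at row(s) ",
         paste(utils::head(which(is.na(data$value)), 5L), collapse = ", "),
         call. = FALSE)
  data$time <- as.integer(data$time)
  if (any(data$time < 1L))
    stop("panel integrity error: time indices must be >= 1", call. = FALSE)
  data$subject <- as.character(data$subject)
  data$group <- as.character(data$group)

  key <- paste(data$subject, data$time, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- data$subject[duplicated(key)][1L]
    stop("panel integrity error: duplicate (subject, time) pairs, e.g. subject ",
         dup, call. = FALSE)
  }
  n_t <- max(data$time)
  tab <- table(data$subject)
  bad <- names(tab)[tab != n_t]
  if (length(bad))
    stop("panel integrity error: incomplete time grid (expected 1..", n_t,
         ") for subject(s) ", paste(bad, collapse = ", "), call. = FALSE)
  # counts match but indices could still be wrong (e.g. skipping an index
  # while duplicating none is impossible given uniqueness + max; gaps below max
  # would shrink counts) -- still verify each subject starts at 1
  if (min(data$time) != 1L)
    stop("panel integrity error: time grid must start at index 1", call. = FALSE)

  groups <- sort(unique(data$group))
  if (is.null(reference)) reference <- groups[1L]
  if (!(reference %in% groups))
    stop("panel configuration error: reference group '", reference,
         "' not present", call. = FALSE)
  data <- data[order(data$subject, data$time), ]
  rownames(data) <- NULL

  structure(data,
            interval = as.numeric(interval),
            scaled = isTRUE(scaled),
            reference = reference,
            class = c("tsgc_panel", "data.frame"))
}

#' Read a panel from CSV
#'
#' Reads a long-format CSV (UTF-8, header row) and validates it into a
#' [panel]. Column names can be remapped via `schema` for files that use
#' different headers.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping panel fields to file column
#'   names, e.g. `c(subject = "id", value = "chl")`. Unmapped fields use the
#'   default names `subject,group,replicate,experiment,time,value`.
#' @param log_transform take natural logs of the values after reading
#'   (default off).
#' @inheritParams as_panel
#' @return a `tsgc_panel`.
#' @export
read_panel <- function(path, schema = NULL, interval = 2, reference = NULL,
                       scaled = FALSE, log_transform = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  mapping <- stats::setNames(.panel_cols, .panel_cols)
  if (!is.null(schema)) {
    unknown <- setdiff(names(schema), .panel_cols)
    if (length(unknown))
      stop("panel schema error: unknown field(s) ", paste(unknown, collapse = ", "),
           call. = FALSE)
    mapping[names(schema)] <- schema
  }
  need <- mapping[c("subject", "group", "time", "value")]
  absent <- need[!(need %in% names(raw))]
  if (length(absent))
    stop("panel schema error: column(s) ", paste(absent, collapse = ", "),
         " not found in ", path, call. = FALSE)
  out <- data.frame(subject = raw[[mapping["subject"]]],
                    group = raw[[mapping["group"]]],
                    time = raw[[mapping["time"]]],
                    stringsAsFactors = FALSE)
  for (fld in c("replicate", "experiment"))
    if (mapping[fld] %in% names(raw)) out[[fld]] <- raw[[mapping[fld]]]
  val <- raw[[mapping["value"]]]
  if (!is.numeric(val)) {
    conv <- suppressWarnings(as.numeric(val))
    if (anyNA(conv) && !anyNA(val))
      stop("panel parse error: non-numeric value at row ",
           which(is.na(conv))[1L], call. = FALSE)
    val <- conv
  }
  out$value <- val
  if (log_transform) {
    if (any(out$value <= 0))
      stop("log transform requires strictly positive values", call. = FALSE)
    out$value <- log(out$value)
  }
  as_panel(out, interval = interval, reference = reference, scaled = scaled)
}

#' Write a panel to CSV
#'
#' Inverse of [read_panel()] for the default schema; values round-trip to
#' full double precision.
#'
#' @param panel a `tsgc_panel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "tsgc_panel"))
  df <- as.data.frame(panel)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Scale every series to its first time point
#'
#' Divides every value of each subject's series by that subject's value at
#' time index 1, so all series start at 1 and series with different raw
#' scales become comparable. Idempotent: scaling an already-scaled panel is
#' the identity.
#'
#' @param panel a `tsgc_panel`.
#' @return the scaled panel (attribute `scaled` set).
#' @export
scale_to_baseline <- function(panel) {
  stopifnot(inherits(panel, "tsgc_panel"))
  if (isTRUE(attr(panel, "scaled"))) return(panel)
  base <- panel$value[panel$time == 1L]
  names(base) <- panel$subject[panel$time == 1L]
  bad <- names(base)[base <= 0]
  if (length(bad))
    stop("degenerate baseline (value at time 1 <= 0) for subject(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  panel$value <- panel$value / base[panel$subject]
  attr(panel, "scaled") <- TRUE
  panel
}

#' Time axis of a panel
#'
#' @param panel a `tsgc_panel`.
#' @return list with `n_timepoints` and `interval` (minutes per step);
#'   minutes of index `i` are `interval * (i - 1)`, so index 1 is 0 min.
#' @export
time_axis <- function(panel) {
  stopifnot(inherits(panel, "tsgc_panel"))
  list(n_timepoints = max(panel$time), interval = attr(panel, "interval"))
}

#' Convert time indices to minutes
#'
#' Index 1 maps to 0 minutes, index 2 to one sampling interval, and so on.
#'
#' @param index integer time index (vectorized).
#' @param axis a time axis from [time_axis()], or a `tsgc_panel`.
#' @return minutes since the first measurement.
#' @export
minutes_of <- function(index, axis) {
  if (inherits(axis, "tsgc_panel")) axis <- time_axis(axis)
  if (any(index < 1L) || any(index > axis$n_timepoints))
    stop("time index out of range 1..", axis$n_timepoints, call. = FALSE)
  axis$interval * (index - 1)
}

#' @export
print.tsgc_panel <- function(x, ...) {
  ax <- time_axis(x)
  subj <- unique(x$subject)
  cat("Panel: ", length(subj), " subjects x ", ax$n_timepoints,
      " timepoints (", nrow(x), " observations)\n", sep = "")
  cat("Groups: ", paste(sort(unique(x$group)), collapse = ", "),
      " (reference: ", attr(x, "reference"), ")\n", sep = "")
  cat("Sampling interval: ", ax$interval, " min; scaled: ",
      attr(x, "scaled"), "\n", sep = "")
  invisible(x)
}

#' Per-subject metadata of a panel
#'
#' @param panel a `tsgc_panel`.
#' @return data.frame with one row per subject: `subject`, `group`,
#'   `replicate`, `experiment`.
#' @export
panel_subjects <- function(panel) {
  stopifnot(inherits(panel, "tsgc_panel"))
  first <- panel[panel$time == 1L, c("subject", "group", "replicate", "experiment")]
  rownames(first) <- NULL
  first
}
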