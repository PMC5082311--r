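#' Multichannel time-series panel
#'
#' A T-by-n matrix of observations (rows = time points, columns = channels)
#' with channel labels and an optional sampling interval (the fMRI TR, in
#' seconds).
#'
#' @param values numeric T-by-n matrix; all entries must be finite.
#' @param channel_labels character vector of n labels; defaults to column
#'   names or `ch1 ... chn`.
#' @param sampling_interval_s positive sampling interval in seconds, or
#'   `NULL` when the panel has no physical time base.
#'
#' @return An object of class `ts_panel`.
#' @export
#' @examples
#' ts_panel(matrix(rnorm(20), 10, 2), c("X", "Y"))
ts_panel <- function(values, channel_labels = NULL, sampling_interval_s = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L)
    stop_input("a panel needs at least one time point")
  if (!all(is.finite(values)))
    stop_input("panel values must all be finite")
  n <- ncol(values)
  if (is.null(channel_labels)) {
    channel_labels <- colnames(values)
    if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(n))
  }
  if (length(channel_labels) != n)
    stop_input("expected %d channel labels, got %d", n, length(channel_labels))
  if (!is.null(sampling_interval_s)) {
    if (!is_scalar_number(sampling_interval_s) || sampling_interval_s <= 0)
      stop_input("`sampling_interval_s` must be a positive number")
    sampling_interval_s <- as.numeric(sampling_interval_s)
  }
  colnames(values) <- channel_labels
  rownames(values) <- NULL
  structure(
    list(
      values = values,
      channel_labels = as.character(channel_labels),
      sampling_interval_s = sampling_interval_s
    ),
    class = "ts_panel"
  )
}

#' Coerce to a time-series panel
#'
#' @param x a `ts_panel`, matrix or data frame.
#' @param ... passed to [ts_panel()] for matrix-like input.
#' @return A `ts_panel`.
#' @export
as_ts_panel <- function(x, ...) {
  if (inherits(x, "ts_panel")) return(x)
  ts_panel(as.matrix(x), ...)
}

#' @export
as.matrix.ts_panel <- function(x, ...) x$values

#' @export
dim.ts_panel <- function(x) dim(x$values)

#' @export
print.ts_panel <- function(x, ...) {
  tr <- if (is.null(x$sampling_interval_s)) "no sampling interval"
        else sprintf("sampling interval %.4g s", x$sampling_interval_s)
  cat(sprintf("ts_panel: %d time points x %d channels (%s)\n",
              nrow(x$values), ncol(x$values), tr))
  cat("channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "))
  if (length(x$channel_labels) > 8) cat(", ...")
  cat("\n")
  invisible(x)
}

n_timepoints <- function(x) nrow(as_ts_panel(x)$values)
n_channels_of <- function(x) ncol(as_ts_panel(x)$values)

## Resolve a channel given as index or label to an index.
resolve_channel <- function(panel, ch) {
  labs <- panel$channel_labels
  if (is.character(ch)) {
    i <- match(ch, labs)
    if (is.na(i)) stop_input("unknown channel '%s'", ch)
    return(i)
  }
  if (!is_count(ch) || ch > length(labs))
    stop_input("channel index out of range: %s", format(ch))
  as.integer(ch)
}
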