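#' Read a time-series panel from TSV/CSV
#'
#' The canonical on-disk form is tab-separated text with an optional header
#' row of channel labels and one row per time point. A leading comment line
#' `# sampling_interval_s=<value>` carries the sampling interval; a sidecar
#' `<path>.json` with a `sampling_interval_s` field is honoured as well.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"tsv"` or `"csv"`.
#' @return A [ts_panel()].
#' @export
read_panel <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (format == "csv") "," else "\t"
  lines <- readLines(path)
  tr <- NULL
  is_comment <- grepl("^\\s*#", lines)
  for (cm in lines[is_comment]) {
    m <- regmatches(cm, regexec("sampling_interval_s\\s*=\\s*([0-9.eE+-]+)", cm))[[1]]
    if (length(m) == 2) tr <- as.numeric(m[2])
  }
  lines <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(lines) == 0) stop_input("empty panel file: %s", path)
  cells <- strsplit(lines, sep, fixed = TRUE)
  ncol <- length(cells[[1]])
  widths <- lengths(cells)
  if (any(widths != ncol))
    stop_input("ragged rows in %s: row %d has %d fields, expected %d",
               path, which(widths != ncol)[1], widths[widths != ncol][1], ncol)
  first <- suppressWarnings(as.numeric(cells[[1]]))
  has_header <- any(is.na(first))
  labels <- if (has_header) trimws(cells[[1]]) else NULL
  body <- if (has_header) cells[-1] else cells
  if (length(body) == 0) stop_input("no data rows in %s", path)
  values <- matrix(NA_real_, length(body), ncol)
  for (r in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[r]]))
    if (any(is.na(v))) {
      bad <- which(is.na(v))[1]
      stop_input("non-numeric cell in %s at data row %d, column %d ('%s')",
                 path, r, bad, body[[r]][bad])
    }
    values[r, ] <- v
  }
  if (is.null(tr)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      if (!is.null(meta$sampling_interval_s))
        tr <- as.numeric(meta$sampling_interval_s)
    }
  }
  ts_panel(values, channel_labels = labels, sampling_interval_s = tr)
}

#' Write a time-series panel to TSV
#'
#' Full-precision tab-separated output: an optional
#' `# sampling_interval_s=` comment line, a header of channel labels, then
#' one row per time point. [read_panel()] round-trips the result exactly.
#'
#' @param x a [ts_panel()] or matrix.
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(x, path) {
  panel <- as_ts_panel(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(panel$sampling_interval_s))
    writeLines(sprintf("# sampling_interval_s=%s",
                       format(panel$sampling_interval_s, digits = 17)), con)
  writeLines(paste(panel$channel_labels, collapse = "\t"), con)
  body <- apply(panel$values, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Write a sweep summary table to TSV
#'
#' Fixed column order, deterministic formatting at 6 significant digits.
#'
#' @param summary a `sweep_summary`, `roi_sweep_summary` or plain data frame.
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(summary, path) {
  df <- as.data.frame(summary)
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]]))
      fmt[[j]] <- formatC(fmt[[j]], digits = 6, format = "g")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0)
    writeLines(do.call(paste, c(fmt, sep = "\t")), con)
  invisible(path)
}

#' Read a sweep summary written by [write_summary()]
#'
#' @param path file to read.
#' @return A data frame.
#' @export
read_summary <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a JSON run manifest
#'
#' Records the parameters and seed of a run so it can be reproduced
#' bit-identically, plus the package version.
#'
#' @param params named list of run parameters.
#' @param path destination `.json` file.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(params, path) {
  params$package_version <-
    as.character(utils::packageVersion("signedgc"))
  params$r_version <- as.character(getRversion())
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
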