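#' Read a pressure or volume waveform from CSV
#'
#' Reads a uniformly sampled waveform in the package's CSV dialect
#' (comma-separated, header row, decimal point, UTF-8). The default column
#' names are `time_s` plus `pressure_mmhg` (aortic pressure) or `volume_ml`
#' (left-ventricular volume); other layouts can be mapped with `time_col` /
#' `value_col`. The sampling rate is inferred from the median time step and
#' the grid is required to be uniform.
#'
#' @param path Path to a CSV file with at least two rows.
#' @param value_col Name of the signal column in the file. Defaults to
#'   `"pressure_mmhg"`; use `"volume_ml"` for volume traces.
#' @param time_col Name of the time column (seconds). Default `"time_s"`.
#' @return A tibble with columns `time_s` and `value_col`, with the sampling
#'   rate (Hz) attached as attribute `"fs"`.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write.csv(data.frame(time_s = c(0, 0.005), pressure_mmhg = c(80, 81)),
#'           path, row.names = FALSE)
#' w <- read_waveform_csv(path)
#' attr(w, "fs") # 200
#' @export
read_waveform_csv <- function(path, value_col = "pressure_mmhg",
                              time_col = "time_s") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # base strtod parsing is correctly rounded, giving bit-exact round-trips
  raw <- tryCatch(utils::read.csv(path, fileEncoding = "UTF-8"),
                  error = function(e) stop("no samples in ", path,
                                           call. = FALSE))
  if (nrow(raw) == 0) stop("no samples in ", path, call. = FALSE)
  if (!all(c(time_col, value_col) %in% names(raw))) {
    stop("missing columns in ", path, ": need '", time_col, "' and '",
         value_col, "'", call. = FALSE)
  }
  wave <- tibble::tibble(time_s = as.numeric(raw[[time_col]]))
  wave[[value_col]] <- as.numeric(raw[[value_col]])
  fs <- validate_waveform(wave, value_col)
  attr(wave, "fs") <- fs
  wave
}

#' Write a waveform to CSV
#'
#' Inverse of [read_waveform_csv()]; numeric values are written with full
#' round-trip precision so write-then-read reproduces the samples exactly.
#'
#' @param wave Waveform tibble (`time_s` plus a signal column).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(wave, path) {
  out <- tibble::as_tibble(wave)
  # 17 significant digits guarantee exact double round-trip
  out[] <- lapply(out, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  })
  readr::write_csv(out, path)
  invisible(path)
}

#' Read an exclusion mask from CSV
#'
#' The mask lists time intervals (columns `start_s`, `end_s`) to drop before
#' any beat analysis, e.g. regions of catheter disturbance.
#'
#' @param path CSV with columns `start_s`, `end_s`.
#' @return Tibble with columns `start_s`, `end_s`, sorted by start time.
#' @export
read_exclusion_mask <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("start_s", "end_s") %in% names(m))) {
    stop("mask must have columns 'start_s' and 'end_s'", call. = FALSE)
  }
  dplyr::arrange(tibble::as_tibble(m), .data$start_s)
}

#' Drop excluded intervals and split a waveform into contiguous segments
#'
#' Removes the masked intervals (half-open, `[start_s, end_s)`) from the
#' recording and returns the remaining contiguous segments separately, so
#' that no beat analysis spans a cut. The segments plus the excluded
#' intervals tile the original support.
#'
#' @param wave Waveform tibble (`time_s` + signal column).
#' @param mask Data frame with columns `start_s`, `end_s`; intervals must be
#'   non-overlapping and within the recording extent. `NULL` or zero rows
#'   means no exclusions.
#' @return List of waveform tibbles, one per contiguous kept segment.
#' @export
apply_exclusions <- function(wave, mask = NULL) {
  value_col <- setdiff(names(wave), "time_s")[1]
  validate_waveform(wave, value_col)
  if (is.null(mask) || nrow(mask) == 0) return(list(tibble::as_tibble(wave)))
  mask <- dplyr::arrange(tibble::as_tibble(mask), .data$start_s)
  if (any(mask$end_s <= mask$start_s)) {
    stop("mask intervals must have end_s > start_s", call. = FALSE)
  }
  if (nrow(mask) > 1 && any(mask$start_s[-1] < mask$end_s[-nrow(mask)])) {
    stop("mask intervals overlap", call. = FALSE)
  }
  t <- wave$time_s
  if (any(mask$start_s > max(t)) || any(mask$end_s < min(t))) {
    stop("mask interval outside recording extent", call. = FALSE)
  }
  drop <- rep(FALSE, length(t))
  for (i in seq_len(nrow(mask))) {
    drop <- drop | (t >= mask$start_s[i] & t < mask$end_s[i])
  }
  keep <- which(!drop)
  if (length(keep) == 0) stop("no data left after exclusions", call. = FALSE)
  runs <- cumsum(c(1L, diff(keep) > 1L))
  segs <- lapply(split(keep, runs), function(ix) tibble::as_tibble(wave[ix, ]))
  unname(segs[vapply(segs, nrow, 1L) >= 2])
}
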