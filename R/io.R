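#' Write a waveform to CSV
#'
#' Writes two columns, `time_s` and the channel label, at full double
#' precision so a read/write round-trip is lossless.
#'
#' @param w A [waveform].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  df <- data.frame(time_s = sample_times(w), value = w$samples)
  names(df)[2] <- w$label
  lines <- c(
    paste(names(df), collapse = ","),
    paste(sprintf("%.17g", df$time_s), sprintf("%.17g", df[[2]]), sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a multichannel CSV record
#'
#' Expects a header row `time_s,<label>[,<label>...]`. The sampling rate is
#' inferred from the median spacing of the time column; spacing must be
#' uniform to within 1 ppm. Columns named `ecg`, `ppg`, `resp`/`resp_ref`
#' (case-insensitive) are mapped to the corresponding bundle slots; with a
#' single unrecognised column a one-channel bundle is returned with that
#' column as `ecg` unless `channel` says otherwise.
#'
#' @param path CSV file path.
#' @param subject_id Subject identifier for the bundle (default: file stem).
#' @param channel Slot name for a single unrecognised column
#'   (`"ecg"`, `"ppg"` or `"resp_ref"`).
#' @return A [record_bundle].
#' @export
read_record_csv <- function(path, subject_id = NULL, channel = "ecg") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) {
    stop("CSV must have a 'time_s' column", call. = FALSE)
  }
  tt <- df$time_s
  if (length(tt) < 2L) stop("record too short", call. = FALSE)
  dt <- diff(tt)
  if (any(dt <= 0)) stop("time column must be strictly increasing", call. = FALSE)
  dt0 <- stats::median(dt)
  if (max(abs(dt - dt0)) > 1e-6 * dt0) {
    stop("non-uniform time spacing (beyond 1 ppm tolerance)", call. = FALSE)
  }
  fs <- 1 / dt0
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  cols <- setdiff(names(df), "time_s")
  slots <- list(ecg = NULL, ppg = NULL, resp_ref = NULL)
  for (cn in cols) {
    slot <- switch(tolower(cn),
                   ecg = "ecg", ppg = "ppg",
                   resp = "resp_ref", resp_ref = "resp_ref",
                   NA_character_)
    if (is.na(slot)) {
      if (length(cols) == 1L) slot <- channel
      else stop("unrecognised channel column: ", cn, call. = FALSE)
    }
    slots[[slot]] <- waveform(df[[cn]], fs = fs, t0 = tt[1], label = cn)
  }
  record_bundle(subject_id, ecg = slots$ecg, ppg = slots$ppg,
                resp_ref = slots$resp_ref)
}

#' Read a single-channel CSV as a waveform
#'
#' Convenience wrapper around [read_record_csv()] returning the single
#' channel contained in the file.
#'
#' @param path CSV file path.
#' @return A [waveform].
#' @export
read_waveform_csv <- function(path) {
  b <- read_record_csv(path)
  ch <- Filter(Negate(is.null), list(b$ecg, b$ppg, b$resp_ref))
  if (length(ch) != 1L) stop("expected a single-channel CSV", call. = FALSE)
  ch[[1]]
}
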