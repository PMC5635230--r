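#' Write an ECG record to CSV
#'
#' Plain-text interchange format: header `t_s,mv`, one row per sample.
#'
#' @param rec an [ecg_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(rec, path) {
  df <- data.frame(t_s = record_time(rec), mv = rec$samples)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an ECG record from CSV
#'
#' @param path file written by [write_ecg_csv()].
#' @param subject_id,age optional metadata to attach.
#' @return an [ecg_record()]; the sampling rate is recovered from the time
#'   column.
#' @export
read_ecg_csv <- function(path, subject_id = NA_character_, age = NA_real_) {
  df <- read.csv(path)
  if (!all(c("t_s", "mv") %in% names(df))) {
    stop_data_error("ECG CSV must have columns t_s, mv")
  }
  dt <- median(diff(df$t_s))
  fs <- round(1 / dt)
  ecg_record(df$mv, fs = fs, duration = length(df$mv) / fs,
             subject_id = subject_id, age = age)
}

#' Write a cohort manifest to CSV
#'
#' @param manifest manifest data frame from [generate_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
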