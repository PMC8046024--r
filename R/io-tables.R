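# Tabular interchange: detection-result TSV, correlogram CSV dump, and the
# subject table feeding the attention analysis. All files are UTF-8, header
# row, '.' decimal separator.

#' Write detection results as TSV
#'
#' One row per recording: `peak_amplitude`, `latency_ms`, `phase_rad`,
#' `noise_floor`, `significant`, plus any identifier columns present.
#'
#' @param results A `dpoae_result` or a data.frame of such rows.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dpoae_tsv <- function(results, path) {
  if (inherits(results, "dpoae_result"))
    results <- data.frame(peak_amplitude = results$peak_amplitude,
                          latency_ms = 1000 * results$latency_s,
                          phase_rad = results$phase_rad,
                          noise_floor = results$noise_floor,
                          significant = results$significant)
  utils::write.table(results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Dump a correlogram as CSV
#'
#' Columns: `lag_ms`, `re`, `im`, `amp`, `amp_smoothed` (NA when the
#' correlogram has not been smoothed).
#'
#' @param cg A `correlogram`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlogram_csv <- function(cg, path) {
  df <- data.frame(lag_ms = 1000 * cg$lags_s,
                   re = Re(cg$values), im = Im(cg$values),
                   amp = Mod(cg$values),
                   amp_smoothed = if (is.null(cg$smoothed_amplitude))
                     NA_real_ else cg$smoothed_amplitude)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a subject table for the attention analysis
#'
#' Expected columns: `subject_id`, `voice` (male|female), `segment_id`,
#' `condition` (attended|ignored), `peak_amplitude`, `latency_ms`,
#' `significant`.
#'
#' @param path TSV path (or a data.frame, validated and returned).
#' @return The validated data.frame.
#' @export
read_subject_table <- function(path) {
  df <- if (is.data.frame(path)) path
        else utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "voice", "segment_id", "condition",
            "peak_amplitude", "latency_ms", "significant")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("subject table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("empty subject table")
  bad <- which(!df$condition %in% c("attended", "ignored"))
  if (length(bad))
    stop("invalid condition in rows: ", paste(bad, collapse = ", "))
  if (is.character(df$significant))
    df$significant <- toupper(df$significant) %in% c("TRUE", "T", "1")
  df
}
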