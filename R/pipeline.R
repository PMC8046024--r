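# End-to-end composition: configuration defaults, the detection pipeline
# (fundamental -> harmonics -> preprocess -> correlate -> smooth -> floor ->
# peak) and the attention report.

#' Pipeline configuration defaults
#'
#' Defaults mirror the measurement protocol: 44.1 kHz sampling, eliciting
#' harmonic pairs 9/11 (male voice) and 6/8 (female voice), 3 s trimmed
#' from each recording end, 199-sample envelope smoothing, noise windows
#' at +/-70..750 ms, peak search 0..7 ms, 10,000 bootstrap resamples.
#'
#' @param ... Named overrides of any default.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(rate_hz = 44100,
              harmonic_pair = list(male = c(9L, 11L), female = c(6L, 8L)),
              trim_s = 3,
              smoothing_len = 199L,
              noise_window_s = c(0.07, 0.75),
              peak_window_s = c(0, 0.007),
              max_lag_s = 0.75,
              bootstrap_n = 10000L,
              seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

resolve_wave <- function(x, rate_hz) {
  if (inherits(x, "wave")) x else read_wav(x, target_rate_hz = rate_hz)
}

#' Run the full speech-DPOAE detection pipeline
#'
#' Extracts the fundamental waveform of the stimulus, builds the eliciting
#' harmonic pair and the lower-sideband distortion-product template,
#' estimates and compensates the equipment delay, trims the transient
#' recording edges, and detects the emission by normalized complex
#' cross-correlation with envelope smoothing, off-peak noise floor and
#' 0-7 ms peak search.
#'
#' @param stimulus Speech stimulus: a [wave] or WAV path.
#' @param recording Ear-canal recording: a `mic_recording`, [wave] or WAV
#'   path.
#' @param pitch A [pitch_track], a pitch CSV path, or `NULL`/`"auto"` to
#'   run the built-in pitch tracker on the stimulus.
#' @param voice `"male"` (harmonics 9/11) or `"female"` (6/8); selects the
#'   eliciting pair from `cfg$harmonic_pair`.
#' @param cfg A [run_config].
#' @param equipment_delay_s Known equipment delay to compensate, or `NULL`
#'   to estimate it from the eliciting-waveform correlations, or 0 to skip.
#' @param out_prefix When given, writes `<prefix>_result.tsv`,
#'   `<prefix>_correlogram.csv` and `<prefix>_config.json`.
#' @param verbose Print each stage's key scalars.
#' @return List: `result` (a `dpoae_result`), `correlogram`,
#'   `equipment_delay_s`, `passband_hz`, `template_harmonic_n`, `config`.
#' @export
run_detect <- function(stimulus, recording, pitch = NULL, voice = "male",
                       cfg = run_config(), equipment_delay_s = NULL,
                       out_prefix = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  speech <- resolve_wave(stimulus, cfg$rate_hz)
  rec <- resolve_wave(recording, cfg$rate_hz)
  if (!inherits(rec, "mic_recording"))
    rec <- mic_recording(as.numeric(rec), rate_hz(rec))

  if (is.null(pitch) || identical(pitch, "auto")) {
    pitch <- estimate_pitch(speech)
    say("pitch: tracked f0 = %.1f +/- %.1f Hz",
        f0_stats(pitch)["mean"], f0_stats(pitch)["sd"])
  } else if (is.character(pitch)) {
    pitch <- load_pitch_track(pitch)
  }

  w0 <- extract_fundamental(speech, pitch)
  band <- passband_hz(w0)
  say("fundamental: passband %.1f-%.1f Hz", band[1], band[2])

  pair <- cfg$harmonic_pair[[voice]]
  if (is.null(pair)) stop("unknown voice: ", voice)
  elic <- list(harmonic(w0, pair[1]), harmonic(w0, pair[2]))
  template <- distortion_template(pair[1], pair[2], w0, "lower")
  say("harmonics: eliciting %d/%d, template %d",
      pair[1], pair[2], harmonic_n(template))

  if (is.null(equipment_delay_s)) {
    equipment_delay_s <- estimate_equipment_delay(rec, elic,
                                                  max_lag_s = cfg$max_lag_s)
    say("equipment delay: %.3f ms", 1000 * equipment_delay_s)
  }
  rec_p <- preprocess(rec, trim_s = cfg$trim_s, delay_s = equipment_delay_s)
  tmpl_p <- preprocess(template, trim_s = cfg$trim_s, delay_s = 0)

  cg <- complex_xcorr(rec_p, tmpl_p, max_lag_s = cfg$max_lag_s)
  cg <- smooth_envelope(cg, cfg$smoothing_len)
  floor_ <- noise_floor(cg, window_s = cfg$noise_window_s)
  res <- find_peak(cg, floor_, window_s = cfg$peak_window_s)
  say("detection: amplitude %.3g at %.2f ms vs floor %.3g (%s)",
      res$peak_amplitude, 1000 * res$latency_s, floor_,
      if (res$significant) "significant" else "not significant")

  if (!is.null(out_prefix)) {
    write_dpoae_tsv(res, paste0(out_prefix, "_result.tsv"))
    write_correlogram_csv(cg, paste0(out_prefix, "_correlogram.csv"))
    echo <- c(unclass(cfg),
              list(voice = voice, equipment_delay_s = equipment_delay_s,
                   passband_hz = as.numeric(band)))
    jsonlite::write_json(echo, paste0(out_prefix, "_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(result = res, correlogram = cg,
       equipment_delay_s = equipment_delay_s,
       passband_hz = band,
       template_harmonic_n = harmonic_n(template),
       config = cfg)
}

#' Run the attention analysis over a subject table
#'
#' Applies the configured exclusion filters, computes per-subject relative
#' attentional modulation coefficients (per voice), and performs the
#' group-level inference: two-tailed one-sample Wilcoxon signed-rank test
#' (with an outlier-removed rerun) and a percentile bootstrap of the mean.
#'
#' @param subject_table TSV path or data.frame (see [read_subject_table()]).
#' @param cfg A [run_config] (`bootstrap_n`, `seed`).
#' @param exclude_subjects Subject ids to drop (e.g. non-significant
#'   pure-tone DPOAE or chance-level comprehension).
#' @param require_significant Drop a subject/voice group when any of its
#'   recordings is non-significant (default TRUE).
#' @param out_json Optional path for the JSON report.
#' @return An `attention_report`: per-voice list with `subjects`
#'   (data.frame subject_id, A, latency_diff_s), `group` (a
#'   `group_test_result` or NULL), `bootstrap` (a `bootstrap_result` or
#'   NULL), `mean_A`, `mean_A_db`; plus `config`.
#' @export
run_attention <- function(subject_table, cfg = run_config(),
                          exclude_subjects = character(),
                          require_significant = TRUE,
                          out_json = NULL) {
  df <- read_subject_table(subject_table)
  df <- df[!df$subject_id %in% exclude_subjects, , drop = FALSE]
  if (nrow(df) == 0L) stop("no subjects left after exclusion")

  report <- list()
  for (v in unique(df$voice)) {
    dv <- df[df$voice == v, , drop = FALSE]
    if (require_significant) {
      ok <- tapply(dv$significant, dv$subject_id, all)
      dv <- dv[dv$subject_id %in% names(ok)[ok], , drop = FALSE]
    }
    if (nrow(dv) == 0L) {
      warning("no significant subjects for voice ", v)
      next
    }
    subjects <- do.call(rbind, lapply(split(dv, dv$subject_id), function(ds) {
      att <- ds[ds$condition == "attended", ]
      ign <- ds[ds$condition == "ignored", ]
      seg <- intersect(att$segment_id, ign$segment_id)
      if (length(seg) == 0L) return(NULL)
      att <- att[match(seg, att$segment_id), ]
      ign <- ign[match(seg, ign$segment_id), ]
      sm <- subject_modulation(data.frame(
        r_attended = att$peak_amplitude, r_ignored = ign$peak_amplitude,
        latency_attended_s = att$latency_ms / 1000,
        latency_ignored_s = ign$latency_ms / 1000))
      data.frame(subject_id = ds$subject_id[1L], A = sm$A,
                 latency_diff_s = sm$latency_diff_s)
    }))
    rownames(subjects) <- NULL
    grp <- boot <- NULL
    if (nrow(subjects) >= 5L) {
      grp <- group_tests(subjects$A)
      boot <- bootstrap_mean(subjects$A, n_resamples = cfg$bootstrap_n,
                             seed = cfg$seed)
    } else {
      warning("voice ", v, ": only ", nrow(subjects),
              " subject(s); group tests skipped")
    }
    report[[v]] <- list(subjects = subjects, group = grp, bootstrap = boot,
                        mean_A = mean(subjects$A),
                        mean_A_db = db_of_modulation(mean(subjects$A)))
  }
  report$config <- unclass(cfg)
  class(report) <- "attention_report"
  if (!is.null(out_json)) {
    ser <- lapply(report[setdiff(names(report), "config")], function(rv) {
      list(subjects = rv$subjects,
           mean_A = rv$mean_A, mean_A_db = rv$mean_A_db,
           p_wilcoxon = if (is.null(rv$group)) NA else rv$group$p_wilcoxon,
           p_wilcoxon_no_outliers = if (is.null(rv$group)) NA
             else rv$group$p_wilcoxon_no_outliers,
           bootstrap = if (is.null(rv$bootstrap)) NULL else
             rv$bootstrap[c("mean_estimate", "ci95", "p_one_sided",
                            "n_resamples")])
    })
    ser$config <- report$config
    jsonlite::write_json(ser, out_json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  report
}

#' @export
print.attention_report <- function(x, ...) {
  for (v in setdiff(names(x), "config")) {
    rv <- x[[v]]
    cat(sprintf("voice %s: n = %d, mean A = %.4f (%.2f dB)",
                v, nrow(rv$subjects), rv$mean_A, rv$mean_A_db))
    if (!is.null(rv$group))
      cat(sprintf(", Wilcoxon p = %.3g", rv$group$p_wilcoxon))
    if (!is.null(rv$bootstrap))
      cat(sprintf(", bootstrap CI [%.3f, %.3f]",
                  rv$bootstrap$ci95[1], rv$bootstrap$ci95[2]))
    cat("\n")
  }
  invisible(x)
}
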