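#' Stimulus protocol description
#'
#' A `stim_protocol` describes the stimulus set of one recording session:
#' four vocalizations presented in quiet and embedded in two masking noises
#' (a vocalization-shaped stationary noise and a naturalistic chorus noise)
#' at three signal-to-noise ratios, the two noises alone, and a block of
#' pure tones used to map the time-frequency response profile (TFRP).
#'
#' Analysis windows are stored here so every downstream statistic uses one
#' shared timing vocabulary: trial-relative seconds, trial start = 0, the
#' stimulus onset of each block stored on the block itself.
#'
#' @param vocalization_ids character vector of vocalization identifiers.
#' @param vocalization_durations_s durations (s) of each vocalization.
#' @param noise_types the two masker labels, default
#'   `c("stationary", "chorus")`.
#' @param snr_levels_db signal-to-noise ratios in dB, strictly decreasing;
#'   default `c(10, 0, -10)`.
#' @param n_trials_voc repetitions of every vocalization/noise condition
#'   (default 20).
#' @param tone_frequencies_hz pure-tone frequencies; default 129 values
#'   log-spaced over eight octaves, 0.14-36 kHz.
#' @param n_trials_tone repetitions per tone (default 8).
#' @param spontaneous_window_s pre-onset window used for spontaneous rate
#'   (default 0.200).
#' @param masker_analysis_period_s analysis period of the masker-alone
#'   response (default 0.564).
#' @param masker_initial_window_s first window of the masker used for the
#'   FRm200 descriptor (default 0.200).
#' @param signal_onset_in_masker_s time after masker onset at which the
#'   vocalization starts in the masked conditions (default 0.200).
#' @param signal_window_in_masker_s length of the window at which the signal
#'   occurs (or would have occurred, for FRm300) (default 0.300).
#' @param edge_window_s initial/final spike-count window of the masker
#'   (default 0.050).
#' @param psth_bin_s PSTH bin used by the extraction index (default 0.004).
#' @param corrcoef_kernel_s Gaussian kernel SD for the trial-to-trial
#'   reliability CorrCoef (default 0.010).
#'
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(vocalization_ids = paste0("voc", 1:4),
                          vocalization_durations_s = rep(0.3, 4),
                          noise_types = c("stationary", "chorus"),
                          snr_levels_db = c(10, 0, -10),
                          n_trials_voc = 20L,
                          tone_frequencies_hz = default_tone_frequencies(),
                          n_trials_tone = 8L,
                          spontaneous_window_s = 0.2,
                          masker_analysis_period_s = 0.564,
                          masker_initial_window_s = 0.2,
                          signal_onset_in_masker_s = 0.2,
                          signal_window_in_masker_s = 0.3,
                          edge_window_s = 0.05,
                          psth_bin_s = 0.004,
                          corrcoef_kernel_s = 0.010) {
  p <- list(
    vocalization_ids = as.character(vocalization_ids),
    vocalization_durations_s = as.numeric(vocalization_durations_s),
    noise_types = as.character(noise_types),
    snr_levels_db = as.numeric(snr_levels_db),
    n_trials_voc = as.integer(n_trials_voc),
    tone_frequencies_hz = as.numeric(tone_frequencies_hz),
    n_trials_tone = as.integer(n_trials_tone),
    spontaneous_window_s = spontaneous_window_s,
    masker_analysis_period_s = masker_analysis_period_s,
    masker_initial_window_s = masker_initial_window_s,
    signal_onset_in_masker_s = signal_onset_in_masker_s,
    signal_window_in_masker_s = signal_window_in_masker_s,
    edge_window_s = edge_window_s,
    psth_bin_s = psth_bin_s,
    corrcoef_kernel_s = corrcoef_kernel_s
  )
  class(p) <- "stim_protocol"
  validate_protocol(p)
  p
}

#' Default pure-tone frequency grid
#'
#' 129 frequencies log-spaced over eight octaves from 0.14 to 36 kHz
#' (0.0625-octave steps).
#'
#' @return Numeric vector of 129 frequencies in Hz, strictly increasing.
#' @export
default_tone_frequencies <- function() {
  140 * 2^seq(0, 8, length.out = 129)
}

validate_protocol <- function(p) {
  stopifnot(inherits(p, "stim_protocol"))
  if (length(p$vocalization_ids) < 1L ||
      anyDuplicated(p$vocalization_ids) > 0L)
    stop("vocalization_ids must be unique and nonempty")
  if (length(p$vocalization_durations_s) != length(p$vocalization_ids) ||
      any(p$vocalization_durations_s <= 0))
    stop("vocalization_durations_s must be positive, one per vocalization")
  if (length(p$noise_types) != 2L || anyDuplicated(p$noise_types) > 0L)
    stop("exactly 2 distinct noise types required")
  if (length(p$snr_levels_db) != 3L || any(diff(p$snr_levels_db) >= 0))
    stop("exactly 3 SNR levels in strictly decreasing order required")
  if (any(diff(p$tone_frequencies_hz) <= 0))
    stop("tone_frequencies_hz must be strictly increasing")
  windows <- c(p$spontaneous_window_s, p$masker_analysis_period_s,
               p$masker_initial_window_s, p$signal_onset_in_masker_s,
               p$signal_window_in_masker_s, p$edge_window_s,
               p$psth_bin_s, p$corrcoef_kernel_s)
  if (any(!is.finite(windows)) || any(windows <= 0))
    stop("all protocol windows must be positive and finite")
  if (p$n_trials_voc < 1L || p$n_trials_tone < 1L)
    stop("trial counts must be >= 1")
  invisible(p)
}

snr_label <- function(snr_db) {
  sprintf("%s%02d", ifelse(snr_db > 0, "p", ifelse(snr_db < 0, "m", "")),
          abs(round(snr_db)))
}

noise_code <- function(noise_type) {
  # short machine codes used in condition ids
  substr(noise_type, 1L, 4L)
}

#' Enumerate the conditions of a protocol
#'
#' One row per stimulus condition with its machine-readable `condition_id`
#' (e.g. `voc1_clean`, `voc1_stat_p10`, `noise_chor`, `tone_042`) and parsed
#' attributes.
#'
#' @param protocol a [stim_protocol()].
#' @return data.frame with columns `condition_id`, `class`
#'   (`clean_voc`, `noisy_voc`, `noise_alone`, `tone`), `voc_index`,
#'   `noise_type`, `snr_db`, `tone_index`, `tone_freq_hz`, `n_trials`.
#' @export
protocol_conditions <- function(protocol) {
  validate_protocol(protocol)
  nv <- length(protocol$vocalization_ids)
  rows <- list()
  for (v in seq_len(nv)) {
    rows[[length(rows) + 1L]] <- data.frame(
      condition_id = sprintf("voc%d_clean", v), class = "clean_voc",
      voc_index = v, noise_type = NA_character_, snr_db = NA_real_,
      tone_index = NA_integer_, tone_freq_hz = NA_real_,
      n_trials = protocol$n_trials_voc, stringsAsFactors = FALSE)
  }
  for (nt in protocol$noise_types) {
    for (v in seq_len(nv)) {
      for (s in protocol$snr_levels_db) {
        rows[[length(rows) + 1L]] <- data.frame(
          condition_id = sprintf("voc%d_%s_%s", v, noise_code(nt),
                                 snr_label(s)),
          class = "noisy_voc", voc_index = v, noise_type = nt, snr_db = s,
          tone_index = NA_integer_, tone_freq_hz = NA_real_,
          n_trials = protocol$n_trials_voc, stringsAsFactors = FALSE)
      }
    }
  }
  for (nt in protocol$noise_types) {
    rows[[length(rows) + 1L]] <- data.frame(
      condition_id = sprintf("noise_%s", noise_code(nt)),
      class = "noise_alone", voc_index = NA_integer_, noise_type = nt,
      snr_db = NA_real_, tone_index = NA_integer_, tone_freq_hz = NA_real_,
      n_trials = protocol$n_trials_voc, stringsAsFactors = FALSE)
  }
  nf <- length(protocol$tone_frequencies_hz)
  rows[[length(rows) + 1L]] <- data.frame(
    condition_id = sprintf("tone_%03d", seq_len(nf)), class = "tone",
    voc_index = NA_integer_, noise_type = NA_character_, snr_db = NA_real_,
    tone_index = seq_len(nf), tone_freq_hz = protocol$tone_frequencies_hz,
    n_trials = protocol$n_trials_tone, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write a protocol as YAML
#'
#' @param protocol a [stim_protocol()].
#' @param path file path.
#' @return `read_protocol()` returns a `stim_protocol`;
#'   `write_protocol()` returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  validate_protocol(protocol)
  x <- unclass(protocol)
  yaml::write_yaml(x, path, precision = 12L)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(stim_protocol, list(
    vocalization_ids = x$vocalization_ids,
    vocalization_durations_s = x$vocalization_durations_s,
    noise_types = x$noise_types,
    snr_levels_db = x$snr_levels_db,
    n_trials_voc = x$n_trials_voc,
    tone_frequencies_hz = x$tone_frequencies_hz,
    n_trials_tone = x$n_trials_tone,
    spontaneous_window_s = x$spontaneous_window_s,
    masker_analysis_period_s = x$masker_analysis_period_s,
    masker_initial_window_s = x$masker_initial_window_s,
    signal_onset_in_masker_s = x$signal_onset_in_masker_s,
    signal_window_in_masker_s = x$signal_window_in_masker_s,
    edge_window_s = x$edge_window_s,
    psth_bin_s = x$psth_bin_s,
    corrcoef_kernel_s = x$corrcoef_kernel_s))
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("Stimulus protocol:\n")
  cat(sprintf("  %d vocalizations x {clean, %s} x SNR {%s} dB, %d trials\n",
              length(x$vocalization_ids),
              paste(x$noise_types, collapse = "/"),
              paste(x$snr_levels_db, collapse = ", "), x$n_trials_voc))
  cat(sprintf("  %d tone frequencies (%.0f-%.0f Hz), %d trials\n",
              length(x$tone_frequencies_hz), min(x$tone_frequencies_hz),
              max(x$tone_frequencies_hz), x$n_trials_tone))
  cat(sprintf("  PSTH bin %.0f ms, CorrCoef kernel %.0f ms\n",
              1000 * x$psth_bin_s, 1000 * x$corrcoef_kernel_s))
  invisible(x)
}
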