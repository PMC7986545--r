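#' @importFrom stats median quantile rbinom rlnorm rnorm rpois runif sd var
#' @importFrom utils read.csv write.csv
NULL

#' The five auditory structures and the five response categories
#'
#' `structure_levels()` returns the brainstem-to-cortex structure labels
#' (CN cochlear nucleus, CNIC central nucleus of the inferior colliculus,
#' MGv ventral medial geniculate, A1 primary auditory cortex, VRB
#' ventrorostral belt). `category_levels()` returns the five noise-robustness
#' response categories ordered from most signal-faithful to most
#' masker-faithful.
#'
#' @return Character vector.
#' @export
structure_levels <- function() c("CN", "CNIC", "MGv", "A1", "VRB")

#' @rdname structure_levels
#' @export
category_levels <- function() {
  c("signal-like", "signal-dominated", "balanced", "insensitive",
    "masker-like")
}

#' Construct a trial block
#'
#' All repetitions of one stimulus condition for one recording. Spike times
#' are trial-relative seconds (trial start = 0); empty trials are legal and
#' kept as zero-length trains.
#'
#' @param condition_id machine-readable condition id (see
#'   [protocol_conditions()]).
#' @param trains list of numeric spike-time vectors, one per trial.
#' @param t_start,t_end trial window (s).
#' @param onset_s,offset_s stimulus onset/offset within the trial (s). For
#'   masked conditions the onset is the masker onset and the offset the end
#'   of the masker analysis period.
#' @return An object of class `trial_block`.
#' @export
trial_block <- function(condition_id, trains, t_start, t_end,
                        onset_s, offset_s) {
  b <- list(condition_id = as.character(condition_id),
            trains = lapply(trains, as.numeric),
            t_start = as.numeric(t_start), t_end = as.numeric(t_end),
            onset_s = as.numeric(onset_s), offset_s = as.numeric(offset_s))
  class(b) <- "trial_block"
  b
}

validate_block <- function(b, n_trials_expected = NULL) {
  if (!is.finite(b$t_start) || !is.finite(b$t_end) || b$t_end <= b$t_start)
    stop(sprintf("block %s: invalid trial window", b$condition_id))
  if (!is.null(n_trials_expected) && length(b$trains) != n_trials_expected)
    stop(sprintf("block %s: %d trials found, %d expected by protocol",
                 b$condition_id, length(b$trains), n_trials_expected))
  for (i in seq_along(b$trains)) {
    tt <- b$trains[[i]]
    if (length(tt)) {
      if (is.unsorted(tt))
        stop(sprintf("block %s trial %d: spike times not nondecreasing",
                     b$condition_id, i))
      if (tt[1L] < b$t_start - 1e-9 || tt[length(tt)] > b$t_end + 1e-9)
        stop(sprintf("block %s trial %d: spike time outside trial window",
                     b$condition_id, i))
    }
  }
  invisible(b)
}

#' Construct a recording
#'
#' One multiunit recording site: a complete map of trial blocks over the
#' protocol conditions, plus its anatomical structure label. Synthetic
#' recordings may carry a planted ground-truth category per noise type.
#'
#' @param recording_id unique identifier.
#' @param structure one of [structure_levels()].
#' @param blocks named list of [trial_block()]s keyed by condition id.
#' @param planted_category optional named list/vector mapping noise type to
#'   a [category_levels()] entry (synthetic data only).
#' @return An object of class `recording`.
#' @export
recording <- function(recording_id, structure, blocks,
                      planted_category = NULL) {
  r <- list(recording_id = as.character(recording_id),
            structure = as.character(structure),
            blocks = blocks,
            planted_category = planted_category)
  class(r) <- "recording"
  r
}

validate_recording <- function(r, protocol) {
  if (!r$structure %in% structure_levels())
    stop(sprintf("recording %s: unknown structure '%s'",
                 r$recording_id, r$structure))
  conds <- protocol_conditions(protocol)
  missing <- setdiff(conds$condition_id, names(r$blocks))
  if (length(missing))
    stop(sprintf("recording %s: missing conditions: %s", r$recording_id,
                 paste(utils::head(missing, 5L), collapse = ", ")))
  for (i in seq_len(nrow(conds))) {
    validate_block(r$blocks[[conds$condition_id[i]]], conds$n_trials[i])
  }
  invisible(r)
}

#' Construct a dataset
#'
#' @param protocol a [stim_protocol()].
#' @param recordings list of [recording()]s with unique ids.
#' @param validate run full validation (default TRUE).
#' @return An object of class `spike_dataset`.
#' @export
spike_dataset <- function(protocol, recordings, validate = TRUE) {
  ids <- vapply(recordings, function(r) r$recording_id, character(1L))
  if (anyDuplicated(ids) > 0L)
    stop("recording ids must be unique")
  names(recordings) <- ids
  d <- list(protocol = protocol, recordings = recordings)
  class(d) <- "spike_dataset"
  if (validate) validate_dataset(d)
  d
}

#' Validate a dataset against its protocol
#'
#' Checks protocol invariants, completeness of every recording's condition
#' map, per-condition trial counts, and spike-time sanity.
#'
#' @param dataset a [spike_dataset()].
#' @return The dataset, invisibly; errors describe the offending block.
#' @export
validate_dataset <- function(dataset) {
  validate_protocol(dataset$protocol)
  for (r in dataset$recordings) validate_recording(r, dataset$protocol)
  invisible(dataset)
}

#' @export
print.spike_dataset <- function(x, ...) {
  ns <- table(factor(vapply(x$recordings, function(r) r$structure,
                            character(1L)), levels = structure_levels()))
  cat(sprintf("Spike dataset: %d recordings (%s)\n", length(x$recordings),
              paste(sprintf("%s %d", names(ns), ns), collapse = ", ")))
  print(x$protocol)
  invisible(x)
}

#' @export
print.recording <- function(x, ...) {
  nsp <- sum(vapply(x$blocks, function(b)
    sum(lengths(b$trains)), numeric(1L)))
  cat(sprintf("Recording %s (%s): %d condition blocks, %d spikes\n",
              x$recording_id, x$structure, length(x$blocks), nsp))
  invisible(x)
}

# ---- plain-text serialization ------------------------------------------

#' Write a dataset to a directory of plain tables
#'
#' Emits `spikes.csv` (recording_id, condition_id, trial, spike_time_s with
#' six decimals), `trials.csv` (an explicit trial table, so empty trials are
#' representable), `recordings.csv` (structure labels and any planted
#' categories), and `protocol.yaml`.
#'
#' @param dataset a [spike_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_spike_events()]
#' @export
write_spike_events <- function(dataset, dir) {
  validate_dataset(dataset)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- list(); tr <- list()
  for (r in dataset$recordings) {
    for (b in r$blocks) {
      n <- length(b$trains)
      tr[[length(tr) + 1L]] <- data.frame(
        recording_id = r$recording_id, condition_id = b$condition_id,
        trial = seq_len(n), t_start_s = b$t_start, t_end_s = b$t_end,
        onset_s = b$onset_s, offset_s = b$offset_s,
        stringsAsFactors = FALSE)
      k <- lengths(b$trains)
      if (sum(k)) {
        sp[[length(sp) + 1L]] <- data.frame(
          recording_id = r$recording_id, condition_id = b$condition_id,
          trial = rep(seq_len(n), k),
          spike_time_s = sprintf("%.6f", unlist(b$trains, use.names = FALSE)),
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_sp <- data.frame(recording_id = character(), condition_id = character(),
                         trial = integer(), spike_time_s = character(),
                         stringsAsFactors = FALSE)
  empty_tr <- data.frame(recording_id = character(), condition_id = character(),
                         trial = integer(), t_start_s = numeric(),
                         t_end_s = numeric(), onset_s = numeric(),
                         offset_s = numeric(), stringsAsFactors = FALSE)
  write.csv(if (length(sp)) do.call(rbind, sp) else empty_sp,
            file.path(dir, "spikes.csv"), row.names = FALSE, quote = FALSE)
  write.csv(if (length(tr)) do.call(rbind, tr) else empty_tr,
            file.path(dir, "trials.csv"), row.names = FALSE, quote = FALSE)
  rec <- data.frame(
    recording_id = vapply(dataset$recordings, `[[`, character(1L),
                          "recording_id"),
    structure = vapply(dataset$recordings, `[[`, character(1L), "structure"),
    planted_category_stationary = vapply(dataset$recordings, function(r)
      planted_or_na(r, "stationary"), character(1L)),
    planted_category_chorus = vapply(dataset$recordings, function(r)
      planted_or_na(r, "chorus"), character(1L)),
    stringsAsFactors = FALSE)
  write.csv(rec, file.path(dir, "recordings.csv"), row.names = FALSE,
            quote = FALSE)
  write_protocol(dataset$protocol, file.path(dir, "protocol.yaml"))
  invisible(dir)
}

planted_or_na <- function(r, noise_type) {
  pc <- r$planted_category
  if (is.null(pc) || is.null(pc[[noise_type]])) NA_character_
  else as.character(pc[[noise_type]])
}

#' Read a dataset from a directory of plain tables
#'
#' Inverse of [write_spike_events()]: rebuilds the dataset from
#' `spikes.csv`, `trials.csv`, `recordings.csv` and `protocol.yaml`.
#' Round-trips are exact to the serialized precision (1 microsecond).
#' Unknown condition ids are a format error naming the offending rows;
#' trial-count mismatches against the protocol are a validation error
#' naming the block.
#'
#' @param dir directory written by [write_spike_events()].
#' @return A validated [spike_dataset()].
#' @export
read_spike_events <- function(dir) {
  protocol <- read_protocol(file.path(dir, "protocol.yaml"))
  conds <- protocol_conditions(protocol)
  spikes <- read.csv(file.path(dir, "spikes.csv"),
                     colClasses = c(recording_id = "character",
                                    condition_id = "character",
                                    trial = "integer",
                                    spike_time_s = "numeric"))
  trials <- read.csv(file.path(dir, "trials.csv"),
                     colClasses = c(recording_id = "character",
                                    condition_id = "character",
                                    trial = "integer"))
  recs <- read.csv(file.path(dir, "recordings.csv"),
                   colClasses = "character")
  bad <- !spikes$condition_id %in% conds$condition_id
  if (any(bad))
    stop(sprintf("spikes.csv: unknown condition id '%s' (first at row %d)",
                 spikes$condition_id[which(bad)[1L]], which(bad)[1L]))
  bad <- !trials$condition_id %in% conds$condition_id
  if (any(bad))
    stop(sprintf("trials.csv: unknown condition id '%s' (first at row %d)",
                 trials$condition_id[which(bad)[1L]], which(bad)[1L]))
  spike_key <- paste(spikes$recording_id, spikes$condition_id, sep = "\r")
  spl <- split(seq_len(nrow(spikes)), spike_key)
  recordings <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    rid <- recs$recording_id[i]
    rtrials <- trials[trials$recording_id == rid, , drop = FALSE]
    blocks <- list()
    for (cid in unique(rtrials$condition_id)) {
      bt <- rtrials[rtrials$condition_id == cid, , drop = FALSE]
      n <- max(bt$trial)
      trains <- rep(list(numeric(0L)), n)
      idx <- spl[[paste(rid, cid, sep = "\r")]]
      if (!is.null(idx)) {
        by_trial <- split(spikes$spike_time_s[idx], spikes$trial[idx])
        for (tn in names(by_trial))
          trains[[as.integer(tn)]] <- sort(by_trial[[tn]])
      }
      blocks[[cid]] <- trial_block(cid, trains, bt$t_start_s[1L],
                                   bt$t_end_s[1L], bt$onset_s[1L],
                                   bt$offset_s[1L])
    }
    planted <- NULL
    ps <- recs$planted_category_stationary[i]
    pc <- recs$planted_category_chorus[i]
    if (!is.na(ps) || !is.na(pc))
      planted <- list(stationary = if (is.na(ps)) NULL else ps,
                      chorus = if (is.na(pc)) NULL else pc)
    recordings[[i]] <- recording(rid, recs$structure[i], blocks, planted)
  }
  spike_dataset(protocol, recordings)
}
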