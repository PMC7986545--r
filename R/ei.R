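# The extraction index (EI): a noise-invariance statistic per SNR and
# noise type, its Poisson-surrogate significance thresholds, and the
# recording-selection criteria built on them.

#' Normalized-inner-product (cosine) distance
#'
#' `1 - p.q / (||p|| ||q||)`. For nonnegative inputs (PSTHs) the value lies
#' in `[0, 1]`. If exactly one vector is all-zero the distance is 1
#' (maximally dissimilar: a silent response shares nothing with an evoked
#' one); if both are all-zero it is undefined (NA).
#'
#' @param p,q equal-length numeric vectors.
#' @return Distance, or NA when undefined.
#' @export
cosine_distance <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch")
  np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
  if (np == 0 && nq == 0) return(NA_real_)
  if (np == 0 || nq == 0) return(1)
  1 - sum(p * q) / (np * nq)
}

#' Extraction index of one noisy-condition PSTH
#'
#' `EI = (D_n - D_v) / (D_n + D_v)` where `D_n` is the cosine distance of
#' the noisy-condition PSTH to the noise-alone PSTH and `D_v` its distance
#' to the clean-vocalization PSTH. Bounded in `[-1, 1]`: positive means the
#' response in noise is more vocalization-like, negative more masker-like.
#' Undefined (NA) when either distance is undefined or both are zero.
#'
#' @param psth_snr,psth_v,psth_n [compute_psth()] objects (or bare numeric
#'   vectors) on a shared bin and window length.
#' @return EI in `[-1, 1]`, or NA.
#' @export
extraction_index <- function(psth_snr, psth_v, psth_n) {
  v <- lapply(list(psth_snr, psth_v, psth_n), function(x) {
    if (inherits(x, "psth")) x else list(values = as.numeric(x),
                                         bin_s = NA_real_)
  })
  bins <- vapply(v, `[[`, numeric(1L), "bin_s")
  if (!all(is.na(bins)) && length(unique(bins[!is.na(bins)])) > 1L)
    stop("PSTH bin mismatch")
  lens <- lengths(lapply(v, `[[`, "values"))
  if (length(unique(lens)) > 1L)
    stop("PSTH window (length) mismatch")
  dn <- cosine_distance(v[[3L]]$values, v[[1L]]$values)
  dv <- cosine_distance(v[[2L]]$values, v[[1L]]$values)
  if (is.na(dn) || is.na(dv) || dn + dv == 0) return(NA_real_)
  (dn - dv) / (dn + dv)
}

# EI analysis windows: all three PSTHs of one comparison share the
# vocalization's window length; the noisy and noise-alone windows start
# where the signal occurs (or would have occurred) within the masker.
ei_windows <- function(protocol, voc_index, blocks) {
  dur <- protocol$vocalization_durations_s[voc_index]
  so <- protocol$signal_onset_in_masker_s
  clean <- blocks[[sprintf("voc%d_clean", voc_index)]]
  # clip to what the trial actually holds
  dur <- min(dur, clean$offset_s - clean$onset_s,
             protocol$masker_analysis_period_s - so)
  list(dur = dur, clean_start = clean$onset_s, masker_rel_start = so)
}

#' EI profile of a recording
#'
#' For every (noise type, SNR) pair the EI is computed per vocalization -
#' comparing the masked-vocalization PSTH against that vocalization's clean
#' PSTH and the noise-alone PSTH, all on the evoked window at the
#' protocol's EI bin - and then averaged over the vocalizations, skipping
#' undefined values (`aggregate = "mean"`). With `aggregate = "concat"` the
#' per-vocalization PSTHs are concatenated and a single EI computed.
#'
#' @param rec a [recording()].
#' @param protocol the [stim_protocol()].
#' @param bin_s PSTH bin (s), default `protocol$psth_bin_s`.
#' @param aggregate `"mean"` (default) or `"concat"`.
#' @return An object of class `ei_profile`: list with `ei` (noise x SNR
#'   matrix), `per_vocalization` (voc x noise x SNR array), `bin_s`.
#' @export
ei_profile <- function(rec, protocol, bin_s = protocol$psth_bin_s,
                       aggregate = c("mean", "concat")) {
  aggregate <- match.arg(aggregate)
  nts <- protocol$noise_types
  snrs <- protocol$snr_levels_db
  nv <- length(protocol$vocalization_ids)
  ei <- matrix(NA_real_, length(nts), length(snrs),
               dimnames = list(nts, snr_label(snrs)))
  per <- array(NA_real_, c(nv, length(nts), length(snrs)),
               dimnames = list(protocol$vocalization_ids, nts,
                               snr_label(snrs)))
  for (v in seq_len(nv)) {
    w <- ei_windows(protocol, v, rec$blocks)
    clean <- rec$blocks[[sprintf("voc%d_clean", v)]]
    pv <- compute_psth(clean, bin_s, c(w$clean_start, w$clean_start + w$dur))
    for (ni in seq_along(nts)) {
      nb <- rec$blocks[[sprintf("noise_%s", noise_code(nts[ni]))]]
      if (is.null(nb)) stop(sprintf("missing noise-alone block for %s",
                                    nts[ni]))
      m0 <- nb$onset_s + w$masker_rel_start
      pn <- compute_psth(nb, bin_s, c(m0, m0 + w$dur))
      for (si in seq_along(snrs)) {
        cid <- sprintf("voc%d_%s_%s", v, noise_code(nts[ni]),
                       snr_label(snrs[si]))
        blk <- rec$blocks[[cid]]
        if (is.null(blk)) stop(sprintf("missing block %s", cid))
        s0 <- blk$onset_s + w$masker_rel_start
        ps <- compute_psth(blk, bin_s, c(s0, s0 + w$dur))
        per[v, ni, si] <- extraction_index(ps, pv, pn)
      }
    }
  }
  if (aggregate == "mean") {
    for (ni in seq_along(nts)) for (si in seq_along(snrs)) {
      x <- per[, ni, si]
      ei[ni, si] <- if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }
  } else {
    ei[, ] <- concat_ei(rec, protocol, bin_s)
  }
  structure(list(ei = ei, per_vocalization = per, bin_s = bin_s),
            class = "ei_profile")
}

# concatenated-PSTH aggregation (config alternative to the mean)
concat_ei <- function(rec, protocol, bin_s) {
  nts <- protocol$noise_types
  snrs <- protocol$snr_levels_db
  nv <- length(protocol$vocalization_ids)
  out <- matrix(NA_real_, length(nts), length(snrs))
  for (ni in seq_along(nts)) {
    nb <- rec$blocks[[sprintf("noise_%s", noise_code(nts[ni]))]]
    for (si in seq_along(snrs)) {
      pvs <- c(); pns <- c(); pss <- c()
      for (v in seq_len(nv)) {
        w <- ei_windows(protocol, v, rec$blocks)
        clean <- rec$blocks[[sprintf("voc%d_clean", v)]]
        pvs <- c(pvs, compute_psth(clean, bin_s,
                 c(w$clean_start, w$clean_start + w$dur))$values)
        m0 <- nb$onset_s + w$masker_rel_start
        pns <- c(pns, compute_psth(nb, bin_s, c(m0, m0 + w$dur))$values)
        blk <- rec$blocks[[sprintf("voc%d_%s_%s", v, noise_code(nts[ni]),
                                   snr_label(snrs[si]))]]
        s0 <- blk$onset_s + w$masker_rel_start
        pss <- c(pss, compute_psth(blk, bin_s, c(s0, s0 + w$dur))$values)
      }
      out[ni, si] <- extraction_index(pss, pvs, pns)
    }
  }
  out
}

#' @export
print.ei_profile <- function(x, ...) {
  cat("EI profile (noise type x SNR):\n")
  print(round(x$ei, 3))
  invisible(x)
}

#' Poisson-surrogate significance thresholds for the EI
#'
#' For each surrogate replicate, every condition entering the EI (clean
#' vocalizations, noise alone, masked vocalizations) is replaced by
#' homogeneous Poisson activity matched to that condition's measured evoked
#' firing rate on the same window with the same trial count, and the EI
#' profile recomputed. The significance threshold per (noise type, SNR) is
#' the surrogate mean + 2 SD. Thresholds are undefined when every
#' condition's rate is zero.
#'
#' @param rec a [recording()].
#' @param protocol the [stim_protocol()].
#' @param n_surrogates number of replicates (default 100).
#' @param seed integer seed (deterministic output).
#' @param bin_s PSTH bin, default `protocol$psth_bin_s`.
#' @return List with `threshold` (noise x SNR matrix), `surrogate_ei`
#'   (replicate x noise x SNR array).
#' @export
surrogate_thresholds <- function(rec, protocol, n_surrogates = 100L,
                                 seed = 1L, bin_s = protocol$psth_bin_s) {
  stopifnot(n_surrogates >= 2L)
  set.seed(seed)
  nts <- protocol$noise_types
  snrs <- protocol$snr_levels_db
  nv <- length(protocol$vocalization_ids)
  ntr <- protocol$n_trials_voc
  # measured evoked rates on the EI windows
  rate_v <- numeric(nv); nb_bins <- integer(nv)
  rate_n <- matrix(0, nv, length(nts))
  rate_s <- array(0, c(nv, length(nts), length(snrs)))
  for (v in seq_len(nv)) {
    w <- ei_windows(protocol, v, rec$blocks)
    nb_bins[v] <- floor(w$dur / bin_s + 1e-9)
    clean <- rec$blocks[[sprintf("voc%d_clean", v)]]
    rate_v[v] <- mean(trial_rates(clean, c(w$clean_start,
                                           w$clean_start + w$dur)))
    for (ni in seq_along(nts)) {
      nb <- rec$blocks[[sprintf("noise_%s", noise_code(nts[ni]))]]
      m0 <- nb$onset_s + w$masker_rel_start
      rate_n[v, ni] <- mean(trial_rates(nb, c(m0, m0 + w$dur)))
      for (si in seq_along(snrs)) {
        blk <- rec$blocks[[sprintf("voc%d_%s_%s", v, noise_code(nts[ni]),
                                   snr_label(snrs[si]))]]
        s0 <- blk$onset_s + w$masker_rel_start
        rate_s[v, ni, si] <- mean(trial_rates(blk, c(s0, s0 + w$dur)))
      }
    }
  }
  if (all(rate_v == 0) && all(rate_n == 0) && all(rate_s == 0)) {
    thr <- matrix(NA_real_, length(nts), length(snrs),
                  dimnames = list(nts, snr_label(snrs)))
    return(list(threshold = thr, surrogate_ei = NULL))
  }
  sur <- array(NA_real_, c(n_surrogates, length(nts), length(snrs)),
               dimnames = list(NULL, nts, snr_label(snrs)))
  # Poisson bin counts of the pooled PSTH: distribution-identical to
  # binning n_trials homogeneous Poisson trains at the same rate; the
  # cosine distances are scale invariant, so raw counts are used directly.
  # One surrogate replicate per matrix row.
  draw_psth_rows <- function(rate, nb)
    matrix(rpois(n_surrogates * nb, ntr * rate * bin_s), n_surrogates)
  for (ni in seq_along(nts)) for (si in seq_along(snrs)) {
    eis <- matrix(NA_real_, n_surrogates, nv)
    for (v in seq_len(nv)) {
      PV <- draw_psth_rows(rate_v[v], nb_bins[v])
      PN <- draw_psth_rows(rate_n[v, ni], nb_bins[v])
      PS <- draw_psth_rows(rate_s[v, ni, si], nb_bins[v])
      dn <- cosine_distance_rows(PN, PS)
      dv <- cosine_distance_rows(PV, PS)
      ei <- (dn - dv) / (dn + dv)
      ei[!is.na(dn + dv) & dn + dv == 0] <- NA_real_
      eis[, v] <- ei
    }
    m <- rowMeans(eis, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    sur[, ni, si] <- m
  }
  thr <- apply(sur, c(2L, 3L), function(x)
    if (all(is.na(x))) NA_real_
    else mean(x, na.rm = TRUE) + 2 * sd(x, na.rm = TRUE))
  dimnames(thr) <- list(nts, snr_label(snrs))
  list(threshold = thr, surrogate_ei = sur)
}

#' Per-recording selection features
#'
#' Everything the Table-style selection needs for one recording: response
#' significance to at least one clean vocalization, TFRP significance, the
#' EI profile, surrogate thresholds, whether all six EI values are defined,
#' and whether at least one EI exceeds its surrogate threshold.
#'
#' @param rec a [recording()].
#' @param protocol the [stim_protocol()].
#' @param alpha evoked-response significance level.
#' @param n_surrogates,seed surrogate settings.
#' @return Named list of features (including the `ei_profile` object).
#' @export
recording_selection_features <- function(rec, protocol, alpha = 0.05,
                                         n_surrogates = 100L, seed = 1L) {
  nv <- length(protocol$vocalization_ids)
  voc_sig <- any(vapply(seq_len(nv), function(v)
    response_significant(rec$blocks[[sprintf("voc%d_clean", v)]],
                         alpha)$significant, logical(1L)))
  tf <- compute_tfrp(rec, protocol)
  prof <- ei_profile(rec, protocol)
  st <- surrogate_thresholds(rec, protocol, n_surrogates, seed)
  six_defined <- all(!is.na(prof$ei))
  any_sig <- any(prof$ei > st$threshold, na.rm = TRUE)
  list(recording_id = rec$recording_id, structure = rec$structure,
       voc_significant = voc_sig, tfrp_significant = tf$significant,
       profile = prof, thresholds = st$threshold,
       six_defined = six_defined, any_significant = any_sig, tfrp = tf)
}

#' Select recordings for the categorization analysis
#'
#' Applies, per recording: all six EI values defined; at least one EI above
#' its Poisson-surrogate threshold; and a response criterion - `"a"`:
#' significant response to at least one clean vocalization OR significant
#' TFRP; `"b"` (default): significant vocalization response AND significant
#' TFRP. Reports the count surviving each stage.
#'
#' @param dataset a [spike_dataset()].
#' @param criterion `"a"` or `"b"`.
#' @param alpha evoked-response significance level.
#' @param n_surrogates,seed surrogate settings (per-recording seeds derived
#'   from `seed`).
#' @param features optional precomputed list of
#'   [recording_selection_features()] (keyed by recording id) to avoid
#'   recomputation.
#' @return List with `selected` (recording ids), `table` (per-recording
#'   feature data.frame), `counts` (stage counts), `features`.
#' @export
select_recordings <- function(dataset, criterion = c("b", "a"),
                              alpha = 0.05, n_surrogates = 100L,
                              seed = 1L, features = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(features)) {
    features <- lapply(dataset$recordings, function(r)
      recording_selection_features(r, dataset$protocol, alpha, n_surrogates,
                                   derive_seed(seed, "surr",
                                               r$recording_id)))
  }
  tab <- do.call(rbind, lapply(features, function(f)
    data.frame(recording_id = f$recording_id, structure = f$structure,
               voc_significant = f$voc_significant,
               tfrp_significant = f$tfrp_significant,
               six_defined = f$six_defined,
               any_significant = f$any_significant,
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  crit <- if (criterion == "a")
    tab$voc_significant | tab$tfrp_significant
  else tab$voc_significant & tab$tfrp_significant
  keep <- tab$six_defined & tab$any_significant & crit
  counts <- data.frame(
    stage = c("total", "voc_significant", "tfrp_significant",
              sprintf("criterion_%s", criterion), "six_ei_defined",
              "ei_above_surrogate", "selected"),
    n = c(nrow(tab), sum(tab$voc_significant), sum(tab$tfrp_significant),
          sum(crit), sum(crit & tab$six_defined),
          sum(crit & tab$six_defined & tab$any_significant), sum(keep)))
  list(selected = tab$recording_id[keep], table = tab, counts = counts,
       features = features)
}

# rowwise cosine distance between two matrices of nonnegative vectors,
# with the same zero-vector policy as cosine_distance()
cosine_distance_rows <- function(A, B) {
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  d <- 1 - rowSums(A * B) / (na * nb)
  d[na == 0 | nb == 0] <- 1
  d[na == 0 & nb == 0] <- NA_real_
  d
}
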