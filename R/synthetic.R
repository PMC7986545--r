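# Synthetic spike-train generator.
#
# Every recording is an inhomogeneous Poisson process whose rate is built
# from three latent ingredients fixed per recording: a smooth random
# envelope per vocalization (sum of half-cosine bumps, mimicking whistle
# amplitude envelopes), a masker envelope per noise type (near-flat for the
# vocalization-shaped stationary noise, bumpy for the chorus noise), and a
# Gaussian log-frequency tuning bump for the pure tones. A category
# archetype mixes signal and masker envelopes with SNR-dependent weights;
# the archetypes are the generative inverse of the five EI-profile
# categories the analysis is meant to recover.

#' Category archetype
#'
#' Generative parameters for one planted response category. The weight
#' vectors give, per SNR (ordered as the protocol's decreasing SNR levels),
#' how strongly the noisy-vocalization rate follows the vocalization
#' envelope (`signal_weight_by_snr`) versus the masker envelope
#' (`masker_weight_by_snr`).
#'
#' @param name one of [category_levels()].
#' @param signal_weight_by_snr,masker_weight_by_snr numeric length-3
#'   weights in `[0, 1]`.
#' @param baseline_rate_hz spontaneous rate (spikes/s).
#' @param response_gain_hz peak evoked rate above baseline (spikes/s).
#' @param trial_gain_cv coefficient of variation of the lognormal
#'   trial-to-trial multiplicative gain (unit mean).
#' @param jitter_sd_s SD (s) of Gaussian spike-time jitter; controls
#'   temporal reliability.
#' @return An object of class `category_archetype`.
#' @export
category_archetype <- function(name, signal_weight_by_snr,
                               masker_weight_by_snr, baseline_rate_hz,
                               response_gain_hz, trial_gain_cv = 0.15,
                               jitter_sd_s = 0.003) {
  stopifnot(length(signal_weight_by_snr) == 3L,
            length(masker_weight_by_snr) == 3L,
            all(signal_weight_by_snr >= 0), all(signal_weight_by_snr <= 1),
            all(masker_weight_by_snr >= 0), all(masker_weight_by_snr <= 1),
            baseline_rate_hz >= 0, response_gain_hz >= 0,
            trial_gain_cv >= 0, jitter_sd_s >= 0)
  a <- list(name = name,
            signal_weight_by_snr = as.numeric(signal_weight_by_snr),
            masker_weight_by_snr = as.numeric(masker_weight_by_snr),
            baseline_rate_hz = baseline_rate_hz,
            response_gain_hz = response_gain_hz,
            trial_gain_cv = trial_gain_cv,
            jitter_sd_s = jitter_sd_s)
  class(a) <- "category_archetype"
  a
}

#' Default archetype set
#'
#' Named list of the five category archetypes under a preset:
#' \describe{
#'   \item{strong}{well-separated EI profiles, low trial noise - the
#'     parameter-recovery study condition.}
#'   \item{noisy}{same weight structure with higher jitter and
#'     trial-gain variability and lower gain - a harder cohort.}
#'   \item{null}{zero evoked gain everywhere - structureless Poisson
#'     recordings used for false-positive calibration.}
#' }
#'
#' @param preset `"strong"`, `"noisy"` or `"null"`.
#' @return Named list of [category_archetype()]s.
#' @export
default_archetypes <- function(preset = c("strong", "noisy", "null")) {
  preset <- match.arg(preset)
  base <- list(
    category_archetype("signal-like", c(1, 0.92, 0.85),
                       c(0.03, 0.08, 0.12), 3, 150, 0.15, 0.002),
    category_archetype("signal-dominated", c(0.75, 0.6, 0.45),
                       c(0.12, 0.25, 0.4), 3, 120, 0.15, 0.003),
    category_archetype("balanced", c(1, 0.5, 0.05), c(0.05, 0.5, 0.95),
                       3, 150, 0.15, 0.002),
    category_archetype("insensitive", c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2),
                       4, 50, 0.2, 0.006),
    category_archetype("masker-like", c(0.05, 0, 0), c(0.85, 0.95, 1),
                       3, 130, 0.15, 0.003))
  names(base) <- vapply(base, `[[`, character(1L), "name")
  if (preset == "noisy") {
    base <- lapply(base, function(a) {
      a$response_gain_hz <- 0.6 * a$response_gain_hz
      a$trial_gain_cv <- 0.5
      a$jitter_sd_s <- 0.01
      a
    })
  } else if (preset == "null") {
    base <- lapply(base, function(a) {
      a$response_gain_hz <- 0
      a
    })
  }
  base
}

# -- deterministic sub-seed derivation -----------------------------------

#' Derive a reproducible sub-seed
#'
#' Hashes the global seed with arbitrary string tags (stage name,
#' recording id, ...) so each recording/stage gets an independent stream
#' and adding recordings does not perturb existing ones. Result is a valid
#' 32-bit seed.
#'
#' @param seed integer global seed.
#' @param ... character tags.
#' @return Integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  s <- paste(c(format(seed), ...), collapse = "|")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483629
  as.integer((h + as.numeric(seed)) %% 2147483629)
}

# -- latent per-recording structure --------------------------------------

bump_envelope <- function(duration_s, dt, n_bumps_range = c(3L, 6L),
                          width_range = c(0.02, 0.05),
                          amp_range = c(0.3, 1)) {
  t <- seq(0, duration_s - dt / 2, by = dt) + dt / 2
  nb <- sample(seq(n_bumps_range[1L], n_bumps_range[2L]), 1L)
  e <- numeric(length(t))
  for (i in seq_len(nb)) {
    c0 <- runif(1L, 0, duration_s)
    w <- runif(1L, width_range[1L], width_range[2L])
    a <- runif(1L, amp_range[1L], amp_range[2L])
    sel <- abs(t - c0) < w
    e[sel] <- e[sel] + a * cospi((t[sel] - c0) / (2 * w))^2
  }
  if (max(e) > 0) e <- e / max(e)
  e
}

#' Latent generative state of one synthetic recording
#'
#' Draws, at the given seed, the per-vocalization envelopes, the two masker
#' envelopes (stationary: flat; chorus: bumpy), the tone-tuning bump
#' (center, width in octaves, gain), and the masker adaptation profile.
#'
#' @param protocol a [stim_protocol()].
#' @param seed integer seed.
#' @param adaptation apply exponential short-term adaptation to the masker
#'   response (floor 0.5, time constant 0.15 s).
#' @param tone_gain_hz peak tone-evoked rate above baseline.
#' @param dt rate-template resolution (s), default 0.001.
#' @return A list used by [make_rate_template()].
#' @export
recording_latent <- function(protocol, seed, adaptation = TRUE,
                             tone_gain_hz = 160, dt = 0.001) {
  set.seed(derive_seed(seed, "latent"))
  nv <- length(protocol$vocalization_ids)
  env_voc <- lapply(seq_len(nv), function(v)
    bump_envelope(protocol$vocalization_durations_s[v], dt))
  period <- protocol$masker_analysis_period_s
  tmask <- seq(0, period - dt / 2, by = dt) + dt / 2
  env_mask <- list()
  for (nt in protocol$noise_types) {
    if (nt == "chorus") {
      # bumpy, signal-like masker normalized to the same mean energy as
      # the flat stationary masker
      e <- 0.15 + 0.85 * bump_envelope(period, dt, c(5L, 9L),
                                       c(0.015, 0.05))
      env_mask[[nt]] <- e / mean(e)
    } else {
      env_mask[[nt]] <- rep(1, length(tmask))
    }
  }
  adapt <- if (adaptation) 0.5 + 0.5 * exp(-tmask / 0.15)
           else rep(1, length(tmask))
  fr <- protocol$tone_frequencies_hz
  lo <- log2(fr[max(1L, round(length(fr) * 0.15))])
  hi <- log2(fr[min(length(fr), round(length(fr) * 0.85))])
  list(dt = dt, env_voc = env_voc, env_mask = env_mask, adapt = adapt,
       tone_bf_hz = 2^runif(1L, lo, hi),
       tone_width_oct = runif(1L, 0.5, 1),
       tone_gain_hz = tone_gain_hz)
}

# trial layout used by the generator (seconds, trial start = 0)
trial_layout <- function(protocol, class, voc_index = NA) {
  sw <- protocol$spontaneous_window_s
  switch(class,
    clean_voc = {
      dur <- protocol$vocalization_durations_s[voc_index]
      list(onset = sw, offset = sw + dur, t_end = sw + dur + 0.1)
    },
    noisy_voc = ,
    noise_alone = {
      per <- protocol$masker_analysis_period_s
      list(onset = sw, offset = sw + per, t_end = sw + per + 0.1)
    },
    tone = list(onset = 0.05, offset = 0.1, t_end = 0.15),
    stop("unknown condition class"))
}

#' Piecewise-constant rate template for one condition
#'
#' Builds the trial-long firing-rate function (Hz, resolution `latent$dt`)
#' for a condition under an archetype:
#' clean vocalization `baseline + gain * e_v(t)`; noise alone
#' `baseline + gain * a(t) * e_n(t)`; masked vocalization at SNR s
#' `baseline + gain * [w_sig(s) * e_v(t) + w_mask(s) * a(t) * e_n(t)]`;
#' tone `baseline + tone_gain * G(f) * env(t)` with Gaussian log-frequency
#' tuning `G`.
#'
#' @param condition_id a condition id of the protocol.
#' @param archetype a [category_archetype()].
#' @param protocol a [stim_protocol()].
#' @param latent a [recording_latent()] (or a seed via `seed=` to draw one).
#' @param seed used only when `latent` is NULL.
#' @return An object of class `rate_template`: list with `rate` (Hz per
#'   `dt` step), `dt`, `t_end`, `onset`, `offset`, `condition_id`.
#' @export
make_rate_template <- function(condition_id, archetype, protocol,
                               latent = NULL, seed = NULL) {
  if (is.null(latent)) latent <- recording_latent(protocol, seed)
  conds <- protocol_conditions(protocol)
  ci <- conds[conds$condition_id == condition_id, , drop = FALSE]
  if (nrow(ci) != 1L) stop(sprintf("unknown condition id '%s'", condition_id))
  rate_template_row(ci, archetype, protocol, latent)
}

rate_template_row <- function(ci, archetype, protocol, latent) {
  dt <- latent$dt
  lay <- trial_layout(protocol, ci$class, ci$voc_index)
  n <- round(lay$t_end / dt)
  rate <- rep(archetype$baseline_rate_hz, n)
  g <- archetype$response_gain_hz
  i0 <- round(lay$onset / dt)
  if (ci$class == "clean_voc") {
    ev <- latent$env_voc[[ci$voc_index]]
    rate[i0 + seq_along(ev)] <- rate[i0 + seq_along(ev)] + g * ev
  } else if (ci$class == "noise_alone") {
    en <- latent$env_mask[[ci$noise_type]] * latent$adapt
    rate[i0 + seq_along(en)] <- rate[i0 + seq_along(en)] + g * en
  } else if (ci$class == "noisy_voc") {
    si <- which(abs(protocol$snr_levels_db - ci$snr_db) < 1e-9)
    en <- latent$env_mask[[ci$noise_type]] * latent$adapt
    mix <- archetype$masker_weight_by_snr[si] * en
    ev <- latent$env_voc[[ci$voc_index]]
    j0 <- round(protocol$signal_onset_in_masker_s / dt)
    idx <- j0 + seq_along(ev)
    idx <- idx[idx <= length(mix)]
    mix[idx] <- mix[idx] +
      archetype$signal_weight_by_snr[si] * ev[seq_along(idx)]
    rate[i0 + seq_along(mix)] <- rate[i0 + seq_along(mix)] + g * mix
  } else { # tone
    gf <- latent$tone_gain_hz *
      exp(-log2(ci$tone_freq_hz / latent$tone_bf_hz)^2 /
            (2 * latent$tone_width_oct^2))
    if (archetype$response_gain_hz == 0) gf <- 0 # null preset: flat
    tt <- seq_len(n) * dt - dt / 2 - lay$onset
    env <- ifelse(tt > 0.005 & tt < 0.045,
                  sin(pi * (tt - 0.005) / 0.04)^2, 0)
    rate <- rate + gf * env
  }
  structure(list(condition_id = ci$condition_id, rate = rate, dt = dt,
                 t_end = lay$t_end, onset = lay$onset, offset = lay$offset),
            class = "rate_template")
}

# core sampler: no seeding, vectorized over trials
sample_block_core <- function(tmpl, n_trials, trial_gain_cv, jitter_sd_s) {
  lam <- sum(tmpl$rate) * tmpl$dt
  gains <- if (trial_gain_cv > 0) {
    sdlog <- sqrt(log(1 + trial_gain_cv^2))
    rlnorm(n_trials, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else rep(1, n_trials)
  counts <- rpois(n_trials, gains * lam)
  total <- sum(counts)
  trains <- rep(list(numeric(0L)), n_trials)
  if (total > 0L) {
    bins <- sample.int(length(tmpl$rate), total, replace = TRUE,
                       prob = tmpl$rate)
    times <- (bins - 1L) * tmpl$dt + runif(total, 0, tmpl$dt)
    if (jitter_sd_s > 0) times <- times + rnorm(total, 0, jitter_sd_s)
    times <- pmin(pmax(times, 0), tmpl$t_end)
    trains <- lapply(split(times, rep(seq_len(n_trials), counts)), sort)
    full <- rep(list(numeric(0L)), n_trials)
    full[as.integer(names(trains))] <- trains
    trains <- full
  }
  trial_block(tmpl$condition_id, trains, 0, tmpl$t_end, tmpl$onset,
              tmpl$offset)
}

#' Sample spike trains from a rate template
#'
#' Each trial is an inhomogeneous Poisson draw from `gain_i * rate(t)` where
#' `gain_i` is a unit-mean lognormal trial gain; spike times are then
#' jittered with centered Gaussian noise and clipped to the trial window.
#'
#' @param tmpl a [make_rate_template()] result.
#' @param n_trials number of repetitions.
#' @param trial_gain_cv,jitter_sd_s see [category_archetype()].
#' @param seed integer seed (deterministic output).
#' @return A [trial_block()].
#' @export
sample_trials <- function(tmpl, n_trials, trial_gain_cv = 0,
                          jitter_sd_s = 0, seed = 1L) {
  stopifnot(n_trials >= 1L)
  set.seed(seed)
  sample_block_core(tmpl, n_trials, trial_gain_cv, jitter_sd_s)
}

# -- whole-dataset generation --------------------------------------------

#' Generator configuration
#'
#' @param protocol a [stim_protocol()].
#' @param n_per_category recordings per planted category (scalar or named
#'   vector over [category_levels()]).
#' @param switch_prob probability that a recording's chorus-noise category
#'   differs from its stationary-noise category (planted noise-type
#'   sensitivity); the switched-to category is drawn uniformly from the
#'   other four.
#' @param preset archetype preset passed to [default_archetypes()].
#' @param archetypes optional explicit archetype list overriding the preset.
#' @param structure_probs sampling weights of the five structures for the
#'   structure label of each recording (defaults shaped like the cohort
#'   sizes of a multi-structure survey: CN 389, CNIC 339, MGv 198, A1 261,
#'   VRB 80).
#' @param counts optional explicit data.frame with columns `structure`,
#'   `category_stationary`, `category_chorus`, `n` giving full control of
#'   the cohort composition (overrides `n_per_category`/`switch_prob`).
#' @param adaptation masker short-term adaptation on/off.
#' @param seed integer global seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(protocol = stim_protocol(),
                             n_per_category = 10L, switch_prob = 0,
                             preset = "strong", archetypes = NULL,
                             structure_probs = c(CN = 389, CNIC = 339,
                                                 MGv = 198, A1 = 261,
                                                 VRB = 80),
                             counts = NULL, adaptation = TRUE, seed = 1L) {
  if (is.null(archetypes)) archetypes <- default_archetypes(preset)
  stopifnot(all(category_levels() %in% names(archetypes)),
            switch_prob >= 0, switch_prob <= 1)
  cfg <- list(protocol = protocol, n_per_category = n_per_category,
              switch_prob = switch_prob, preset = preset,
              archetypes = archetypes, structure_probs = structure_probs,
              counts = counts, adaptation = adaptation,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

plan_cohort <- function(cfg) {
  cats <- category_levels()
  if (!is.null(cfg$counts)) {
    plan <- cfg$counts[rep(seq_len(nrow(cfg$counts)), cfg$counts$n), ,
                       drop = FALSE]
    plan$n <- NULL
  } else {
    npc <- cfg$n_per_category
    if (length(npc) == 1L && is.null(names(npc)))
      npc <- stats::setNames(rep(npc, 5L), cats)
    else {
      npc <- stats::setNames(as.integer(npc[cats]), cats)
      npc[is.na(npc)] <- 0L
    }
    set.seed(derive_seed(cfg$seed, "cohort"))
    rows <- list()
    for (cat in cats) {
      n <- npc[[cat]]
      if (n < 1L) next
      cs <- rep(cat, n)
      cc <- cs
      sw <- runif(n) < cfg$switch_prob
      if (any(sw))
        cc[sw] <- vapply(which(sw), function(i)
          sample(setdiff(cats, cat), 1L), character(1L))
      st <- sample(names(cfg$structure_probs), n, replace = TRUE,
                   prob = cfg$structure_probs)
      rows[[cat]] <- data.frame(structure = st, category_stationary = cs,
                                category_chorus = cc,
                                stringsAsFactors = FALSE)
    }
    plan <- do.call(rbind, rows)
  }
  if (is.null(plan) || nrow(plan) == 0L)
    return(data.frame(structure = character(),
                      category_stationary = character(),
                      category_chorus = character()))
  rownames(plan) <- NULL
  plan
}

generate_recording <- function(cfg, rid, structure, cat_by_noise) {
  protocol <- cfg$protocol
  latent <- recording_latent(protocol, derive_seed(cfg$seed, "gen", rid),
                             adaptation = cfg$adaptation)
  # rate scale / variability taken from the stationary-noise archetype;
  # noise-type-specific weights from each noise's own archetype
  arch_shared <- cfg$archetypes[[cat_by_noise[["stationary"]]]]
  conds <- protocol_conditions(protocol)
  set.seed(derive_seed(cfg$seed, "spikes", rid))
  blocks <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    cls <- conds$class[i]
    arch <- if (cls %in% c("noisy_voc", "noise_alone"))
      cfg$archetypes[[cat_by_noise[[conds$noise_type[i]]]]]
    else arch_shared
    # keep one shared rate scale so clean/tone responses do not depend on
    # which noise-specific archetype applies
    arch$baseline_rate_hz <- arch_shared$baseline_rate_hz
    if (cls != "noisy_voc" && cls != "noise_alone")
      arch$response_gain_hz <- arch_shared$response_gain_hz
    tmpl <- rate_template_row(conds[i, , drop = FALSE], arch, protocol,
                              latent)
    blocks[[i]] <- sample_block_core(tmpl, conds$n_trials[i],
                                     arch_shared$trial_gain_cv,
                                     arch_shared$jitter_sd_s)
  }
  names(blocks) <- conds$condition_id
  recording(rid, structure, blocks,
            planted_category = as.list(cat_by_noise))
}

#' Generate a synthetic dataset with planted categories
#'
#' Draws one recording per row of the cohort plan: structure label, planted
#' category per noise type, then the full block map (clean vocalizations,
#' masked vocalizations at every SNR and noise type, the two maskers alone,
#' and the 129-tone TFRP block). Bit-identical for identical config + seed.
#'
#' @param cfg a [generator_config()].
#' @return A [spike_dataset()]; each recording carries `planted_category`.
#' @export
make_dataset <- function(cfg) {
  plan <- plan_cohort(cfg)
  n <- nrow(plan)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    rid <- sprintf("rec%04d", i)
    recs[[i]] <- generate_recording(
      cfg, rid, plan$structure[i],
      c(stationary = plan$category_stationary[i],
        chorus = plan$category_chorus[i]))
  }
  spike_dataset(cfg$protocol, recs, validate = FALSE)
}

#' Noise-free EI profile of an archetype's rate templates
#'
#' Plugs the rate templates themselves in as PSTHs (no spiking noise):
#' the EI the archetype would produce with infinite data. Used to check
#' archetype fidelity against the intended category sign regions.
#'
#' @param archetype a [category_archetype()].
#' @param protocol a [stim_protocol()].
#' @param seed seed for the latent envelopes (or pass `latent`).
#' @param latent optional [recording_latent()].
#' @param bin_s EI bin (s).
#' @return noise x SNR matrix of EI values.
#' @export
template_ei_profile <- function(archetype, protocol, seed = 1L,
                                latent = NULL,
                                bin_s = protocol$psth_bin_s) {
  if (is.null(latent)) latent <- recording_latent(protocol, seed)
  conds <- protocol_conditions(protocol)
  nts <- protocol$noise_types
  snrs <- protocol$snr_levels_db
  nv <- length(protocol$vocalization_ids)
  tmpl_psth <- function(cid, w0, w1) {
    ci <- conds[conds$condition_id == cid, , drop = FALSE]
    tm <- rate_template_row(ci, archetype, protocol, latent)
    i0 <- round(w0 / tm$dt); i1 <- round(w1 / tm$dt)
    r <- tm$rate[(i0 + 1L):i1]
    nb <- floor((w1 - w0) / bin_s + 1e-9)
    colMeans(matrix(r[seq_len(nb * round(bin_s / tm$dt))],
                    nrow = round(bin_s / tm$dt)))
  }
  ei <- matrix(NA_real_, length(nts), length(snrs),
               dimnames = list(nts, snr_label(snrs)))
  for (ni in seq_along(nts)) for (si in seq_along(snrs)) {
    vals <- rep(NA_real_, nv)
    for (v in seq_len(nv)) {
      lay_c <- trial_layout(protocol, "clean_voc", v)
      lay_m <- trial_layout(protocol, "noisy_voc")
      dur <- min(protocol$vocalization_durations_s[v],
                 protocol$masker_analysis_period_s -
                   protocol$signal_onset_in_masker_s)
      s0 <- lay_m$onset + protocol$signal_onset_in_masker_s
      pv <- tmpl_psth(sprintf("voc%d_clean", v), lay_c$onset,
                      lay_c$onset + dur)
      pn <- tmpl_psth(sprintf("noise_%s", noise_code(nts[ni])), s0,
                      s0 + dur)
      ps <- tmpl_psth(sprintf("voc%d_%s_%s", v, noise_code(nts[ni]),
                              snr_label(snrs[si])), s0, s0 + dur)
      vals[v] <- extraction_index(ps, pv, pn)
    }
    ei[ni, si] <- mean(vals, na.rm = TRUE)
  }
  ei
}

#' Fully crossed cohort plan
#'
#' A counts table for [generator_config()] with every (stationary-noise
#' category x chorus-noise category) pair represented `n_per_pair` times:
#' each noise type then sees a balanced cohort (5 x n_per_pair recordings
#' per category per noise) while four fifths of the recordings are
#' noise-type sensitive, as in cohorts where category switching between
#' maskers is common. Structures are cycled deterministically over the
#' pairs.
#'
#' @param n_per_pair recordings per category pair (default 10).
#' @return data.frame with columns `structure`, `category_stationary`,
#'   `category_chorus`, `n`.
#' @export
crossed_cohort_counts <- function(n_per_pair = 10L) {
  cats <- category_levels()
  grid <- expand.grid(category_stationary = cats, category_chorus = cats,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$structure <- structure_levels()[(seq_len(nrow(grid)) - 1L) %% 5L + 1L]
  grid$n <- as.integer(n_per_pair)
  grid[, c("structure", "category_stationary", "category_chorus", "n")]
}
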