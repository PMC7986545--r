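test_that("PSTH arithmetic matches hand computation", {
  # 20 trials, one spike at 10 ms each: the 8-12 ms bin holds all mass
  blk <- block_of(rep(list(0.010), 20L), t_end = 0.1, onset = 0,
                  offset = 0.1)
  ps <- compute_psth(blk, 0.004, c(0, 0.1))
  expect_equal(ps$values[3L], 20 / (20 * 0.004))  # 250 spikes/s
  expect_equal(sum(ps$values), 250)
  expect_length(ps$values, 25L)
  # empty block
  ps0 <- compute_psth(block_of(rep(list(numeric(0L)), 5L)), 0.004,
                      c(0, 0.5))
  expect_true(all(ps0$values == 0))
})

test_that("PSTH spike mass is conserved under bin refinement", {
  set.seed(8)
  blk <- block_of(poisson_trains(10L, 40), t_end = 1, onset = 0, offset = 1)
  for (bin in c(0.02, 0.01, 0.005, 0.0025)) {
    ps <- compute_psth(blk, bin, c(0, 1))
    expect_equal(sum(ps$values) * bin * ps$n_trials,
                 sum(lengths(blk$trains)))
  }
})

test_that("PSTH rejects windows outside the trial", {
  blk <- block_of(list(c(0.1), c(0.2)), t_end = 0.5)
  expect_error(compute_psth(blk, 0.004, c(0, 0.6)), "outside trial")
})

test_that("evoked and spontaneous rates are plain window averages", {
  # 3 spikes per trial inside a 0.3-s stimulus, none before onset
  blk <- block_of(rep(list(c(0.25, 0.3, 0.45)), 8L), t_end = 1,
                  onset = 0.2, offset = 0.5)
  expect_equal(evoked_rate(blk), 10)
  expect_equal(spontaneous_rate(blk), 0)
  set.seed(3)
  flat <- block_of(poisson_trains(5000L, 10), t_end = 1, onset = 0.3,
                   offset = 0.8)
  se <- sqrt(10 / (0.5 * 5000))
  expect_lt(abs(evoked_rate(flat) - 10), 3 * se)
  expect_lt(abs(spontaneous_rate(flat) - 10), 3 * sqrt(10 / (0.2 * 5000)))
  expect_error(spontaneous_rate(block_of(list(0.05), onset = 0.1)),
               "spontaneous window")
})

test_that("evoked-response significance behaves at both extremes", {
  set.seed(14)
  # strong response: evoked 50 Hz vs spontaneous 10 Hz over 20 trials
  trains <- lapply(1:20, function(i)
    sort(c(runif(rpois(1L, 2), 0, 0.2),
           0.2 + runif(rpois(1L, 15), 0, 0.3))))
  blk <- block_of(trains, t_end = 0.6, onset = 0.2, offset = 0.5)
  expect_true(response_significant(blk)$significant)
  # exactly equal rates in every trial -> p = 1
  same <- block_of(rep(list(c(0.1, 0.35)), 10L), t_end = 0.6,
                   onset = 0.2, offset = 0.4)
  expect_equal(response_significant(same)$p_value, 1)
  expect_false(response_significant(same)$significant)
  expect_error(response_significant(block_of(list(c(0.1)))), ">= 2 trials")
})

test_that("permuted-null false-positive rate of the response test is calibrated", {
  set.seed(99)
  n_reps <- 400L
  fp <- mean(vapply(seq_len(n_reps), function(i) {
    blk <- block_of(poisson_trains(20L, 15, t_end = 0.5), t_end = 0.5,
                    onset = 0.2, offset = 0.4)
    response_significant(blk)$significant
  }, logical(1L)))
  # binomial 99% envelope around alpha = 0.05
  expect_lt(abs(fp - 0.05), 2.58 * sqrt(0.05 * 0.95 / n_reps) + 0.01)
})

test_that("CorrCoef scores identical trains 1 and matches a brute-force pairwise oracle", {
  tr <- sort(runif(12, 0.21, 0.49))
  blk <- block_of(rep(list(tr), 20L))
  expect_equal(corrcoef(blk)$corrcoef, 1)
  # 3 trains: two identical, one different
  set.seed(4)
  t3 <- list(tr, tr, sort(runif(10, 0.21, 0.49)))
  blk3 <- block_of(t3)
  got <- corrcoef(blk3)
  # oracle: mean of the three pairwise correlations of smoothed traces
  sm <- noisecat:::gaussian_smooth_rows(
    noisecat:::trial_bin_counts(blk3, 0.001, c(0.2, 0.5)), 10)
  cc <- cor(t(sm))
  expect_equal(got$corrcoef, mean(cc[upper.tri(cc)]))
  expect_equal(got$n_pairs, 3L)
})

test_that("CorrCoef is near zero for independent Poisson trains and shift-invariant", {
  set.seed(6)
  vals <- vapply(1:200, function(i) {
    blk <- block_of(poisson_trains(10L, 30, t_end = 0.5), t_end = 0.5,
                    onset = 0.1, offset = 0.45)
    corrcoef(blk)$corrcoef
  }, numeric(1L))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 0.005)
  # uniform temporal shift of all trains leaves CorrCoef unchanged
  set.seed(7)
  trains <- poisson_trains(15L, 40, t_end = 0.3)
  b0 <- block_of(trains, t_end = 1, onset = 0.3, offset = 0.6)
  b0$trains <- lapply(trains, function(tt) tt + 0.3)
  b1 <- block_of(lapply(trains, function(tt) tt + 0.5), t_end = 1,
                 onset = 0.5, offset = 0.8)
  expect_equal(corrcoef(b0)$corrcoef, corrcoef(b1)$corrcoef,
               tolerance = 1e-12)
  # undefined with a single spiking trial
  sparse <- block_of(list(c(0.3), numeric(0L), numeric(0L)))
  expect_false(corrcoef(sparse)$defined)
})

test_that("TFRP recovers a planted sharp tuning bump at BF within one step", {
  p <- stim_protocol()  # full 129-tone grid
  arch <- default_archetypes()[["signal-like"]]
  for (seed in c(2L, 3L)) {
    latent <- recording_latent(p, seed)
    # sharp high-gain bump centered on tone #64
    latent$tone_bf_hz <- p$tone_frequencies_hz[64L]
    latent$tone_width_oct <- 0.15
    latent$tone_gain_hz <- 300
    conds <- protocol_conditions(p)
    tones <- conds[conds$class == "tone", , drop = FALSE]
    blocks <- lapply(seq_len(nrow(tones)), function(i)
      sample_trials(make_rate_template(tones$condition_id[i], arch, p,
                                       latent),
                    8L, 0.1, 0.001, seed = derive_seed(seed, "t", i)))
    names(blocks) <- tones$condition_id
    tf <- compute_tfrp(blocks, p)
    expect_true(tf$significant)
    bf_index <- which(p$tone_frequencies_hz == tf$bf_hz)
    expect_lte(abs(bf_index - 64L), 1L)
    expect_gt(tf$bandwidth_octaves, 0)
    expect_gt(tf$response_duration_ms, 0)
  }
})

test_that("doubling the tone gain does not shrink the tuning bandwidth", {
  p <- stim_protocol()
  arch <- default_archetypes()[["signal-like"]]
  conds <- protocol_conditions(p)
  tones <- conds[conds$class == "tone", , drop = FALSE]
  bw <- vapply(c(150, 300), function(gain) {
    latent <- recording_latent(p, 4L)
    latent$tone_bf_hz <- p$tone_frequencies_hz[64L]
    latent$tone_width_oct <- 0.3
    latent$tone_gain_hz <- gain
    blocks <- lapply(seq_len(nrow(tones)), function(i)
      sample_trials(make_rate_template(tones$condition_id[i], arch, p,
                                       latent),
                    8L, 0.1, 0.001, seed = derive_seed(4L, "bw", i)))
    names(blocks) <- tones$condition_id
    compute_tfrp(blocks, p)$bandwidth_octaves
  }, numeric(1L))
  expect_gte(bw[2L], bw[1L])
})

test_that("TFRP smoothing keeps true local means and flat input stays flat", {
  M <- matrix(5, 20, 10)
  expect_equal(noisecat:::box_smooth_2d(M, 2L), M)
  # impulse: total mass preserved only up to edge renormalization,
  # interior smoothing is an exact 25-cell mean
  I <- matrix(0, 20, 10); I[10, 5] <- 25
  S <- noisecat:::box_smooth_2d(I, 2L)
  expect_equal(S[10, 5], 1)
  expect_equal(S[8, 3], 1)
  expect_equal(S[7, 5], 0)
})

test_that("connected-component labelling separates disjoint regions", {
  m <- matrix(FALSE, 6, 6)
  m[1:2, 1:2] <- TRUE
  m[5:6, 5:6] <- TRUE
  m[1, 6] <- TRUE
  lab <- noisecat:::label_components(m)
  expect_equal(max(lab), 3L)
  expect_equal(length(unique(lab[m])), 3L)
  expect_true(all(lab[!m] == 0L))
  expect_equal(lab[1, 1], lab[2, 2])
})
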