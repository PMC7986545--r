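test_that("cosine distance matches hand-computed values and edge policy", {
  expect_equal(cosine_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 0), c(1, 1)), 1 - 1 / sqrt(2))
  expect_equal(cosine_distance(c(0, 0), c(1, 1)), 1)
  expect_true(is.na(cosine_distance(c(0, 0), c(0, 0))))
  expect_error(cosine_distance(1:3, 1:4), "length mismatch")
})

test_that("extraction index reproduces the worked example and its bounds", {
  # P_v=(1,0), P_n=(0,1), P_snr=(2,1)
  dn <- 1 - 1 / sqrt(5); dv <- 1 - 2 / sqrt(5)
  expect_equal(extraction_index(c(2, 1), c(1, 0), c(0, 1)),
               (dn - dv) / (dn + dv))
  expect_equal(round(extraction_index(c(2, 1), c(1, 0), c(0, 1)), 3),
               0.679)
  v <- c(3, 1, 0, 2); n <- c(0, 1, 4, 1)
  expect_equal(extraction_index(v, v, n), 1)
  expect_equal(extraction_index(n, v, n), -1)
  expect_true(is.na(extraction_index(v, v, v)))
  expect_error(extraction_index(1:4, 1:3, 1:3), "length")
})

test_that("EI is antisymmetric, scale invariant, and monotone in the signal mixture", {
  set.seed(123)
  for (i in 1:300) {
    ps <- runif(8); pv <- runif(8); pn <- runif(8)
    ei <- extraction_index(ps, pv, pn)
    expect_equal(extraction_index(ps, pn, pv), -ei)
    expect_equal(extraction_index(3.7 * ps, pv, 0.2 * pn), ei)
  }
  set.seed(5)
  for (i in 1:20) {
    pv <- runif(10); pn <- runif(10)
    lam <- seq(0, 1, by = 0.1)
    eis <- vapply(lam, function(l)
      extraction_index((1 - l) * pn + l * pv, pv, pn), numeric(1L))
    expect_true(all(diff(eis) > 0))
    expect_equal(eis[1L], -1)
    expect_equal(eis[length(eis)], 1)
  }
})

test_that("EI profiles of planted archetypes land in their sign regions", {
  p <- quick_protocol(5L)
  # idealized endpoints: pure signal coupling (no jitter, high rate) and
  # pure masker coupling
  pure <- list(
    "signal-like" = category_archetype("signal-like", c(1, 1, 1),
                                       c(0, 0, 0), 2, 200, 0, 0),
    "masker-like" = category_archetype("masker-like", c(0, 0, 0),
                                       c(1, 1, 1), 2, 200, 0, 0))
  arch <- default_archetypes()
  arch[names(pure)] <- pure
  cfg <- generator_config(p, n_per_category = c("signal-like" = 3L,
                                                "masker-like" = 3L),
                          archetypes = arch, seed = 12L)
  d <- make_dataset(cfg)
  for (r in d$recordings) {
    prof <- ei_profile(r, p)
    if (r$planted_category$stationary == "signal-like")
      expect_true(all(prof$ei > 0.5))
    else
      expect_true(all(prof$ei < 0))
  }
  # the defaults keep the sign structure, if not the idealized magnitude
  d2 <- make_dataset(generator_config(p, n_per_category = c(
    "signal-like" = 3L, "masker-like" = 3L), seed = 12L))
  for (r in d2$recordings) {
    prof <- ei_profile(r, p)
    if (r$planted_category$stationary == "signal-like")
      expect_true(all(prof$ei > 0.1))
    else
      expect_true(all(prof$ei < 0))
  }
})

test_that("a silent recording has an entirely undefined EI profile", {
  p <- quick_protocol(5L)
  cfg <- generator_config(p, n_per_category = c(insensitive = 1L),
                          seed = 2L)
  cfg$archetypes <- lapply(cfg$archetypes, function(a) {
    a$baseline_rate_hz <- 0; a$response_gain_hz <- 0; a
  })
  d <- make_dataset(cfg)
  r <- d$recordings[[1L]]
  expect_true(all(is.na(ei_profile(r, p)$ei)))
  st <- surrogate_thresholds(r, p, 10L, seed = 1L)
  expect_true(all(is.na(st$threshold)))
})

test_that("surrogate thresholds are deterministic given the seed", {
  d <- tiny_dataset()
  r <- d$recordings[[1L]]
  s1 <- surrogate_thresholds(r, d$protocol, 20L, seed = 5L)
  s2 <- surrogate_thresholds(r, d$protocol, 20L, seed = 5L)
  expect_identical(s1$threshold, s2$threshold)
  expect_error(surrogate_thresholds(r, d$protocol, 1L), "n_surrogates")
})

test_that("strongly modulated recordings pass the EI significance filter", {
  p <- quick_protocol(5L)
  cfg <- generator_config(p, n_per_category = c("signal-like" = 4L),
                          seed = 8L)
  d <- make_dataset(cfg)
  for (r in d$recordings) {
    f <- recording_selection_features(r, p, n_surrogates = 100L,
                                      seed = derive_seed(8L, r$recording_id))
    expect_true(f$any_significant)
    expect_true(f$six_defined)
  }
})

test_that("criterion (a) selection is a superset of criterion (b)", {
  d <- tiny_dataset()
  sel_b <- select_recordings(d, "b", n_surrogates = 25L, seed = 3L)
  sel_a <- select_recordings(d, "a", n_surrogates = 25L, seed = 3L,
                             features = sel_b$features)
  expect_true(all(sel_b$selected %in% sel_a$selected))
  expect_equal(sel_a$counts$n[sel_a$counts$stage == "total"],
               length(d$recordings))
  # stage counts are nonincreasing from the criterion stage onward
  cb <- sel_b$counts
  tail_counts <- cb$n[match(c("criterion_b", "six_ei_defined",
                              "ei_above_surrogate", "selected"), cb$stage)]
  expect_true(all(diff(tail_counts) <= 0))
})
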