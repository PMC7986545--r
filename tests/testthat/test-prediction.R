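# synthetic descriptor table: classes differ only in `informative` groups
synth_table <- function(n_per_class, informative = names(descriptor_groups()),
                        sep = 3, seed = 1L) {
  set.seed(seed)
  cats <- category_levels()
  n <- n_per_class * length(cats)
  tab <- as.data.frame(matrix(rnorm(n * 12L), n, 12L,
                              dimnames = list(NULL, descriptor_names())))
  labels <- rep(cats, each = n_per_class)
  shift <- matrix(rnorm(length(cats) * 12L, sd = sep), length(cats), 12L)
  cols <- unlist(descriptor_groups()[informative], use.names = FALSE)
  for (k in seq_along(cats)) {
    rows <- labels == cats[k]
    tab[rows, cols] <- sweep(tab[rows, cols, drop = FALSE], 2L,
                             shift[k, match(cols, descriptor_names())],
                             `+`)
  }
  tab <- cbind(recording_id = sprintf("rec%04d", seq_len(n)), tab,
               stringsAsFactors = FALSE)
  list(table = tab, labels = labels)
}

test_that("masker descriptors match the no-adaptation Poisson oracle", {
  p <- quick_protocol(5L)
  set.seed(21)
  tr <- sort(runif(15, 0.21, 0.49))
  blocks <- list()
  for (v in 1:4)
    blocks[[sprintf("voc%d_clean", v)]] <-
      block_of(rep(list(tr), 20L), t_end = 0.6,
               cid = sprintf("voc%d_clean", v))
  blocks[["noise_stat"]] <- trial_block(
    "noise_stat", poisson_trains(500L, 30, t_end = 0.864), 0, 0.864,
    0.2, 0.764)
  rec <- recording("rx", "CN", blocks)
  fake_tfrp <- structure(list(bf_firing_rate_hz = 120,
                              bandwidth_octaves = 1.2,
                              response_duration_ms = 25,
                              significant = TRUE), class = "tfrp_result")
  dsc <- extract_descriptors(rec, "stationary", p, tfrp = fake_tfrp)
  expect_length(dsc, 12L)
  expect_lt(abs(dsc[["mask_frm_ratio"]] - 1), 0.08)
  expect_lt(abs(dsc[["mask_rate"]] - 30), 3 * sqrt(30 / (0.564 * 500)))
  expect_lt(abs(dsc[["mask_initial_spikes"]] - 30 * 0.05),
            3 * 0.05 * sqrt(30 / (0.05 * 500)))
  expect_equal(dsc[["sig_corrcoef"]], 1)
  expect_equal(dsc[["tfrp_bf_rate"]], 120)
})

test_that("masker adaptation lowers FRm300/FRm200 and the final spike count", {
  d <- tiny_dataset()
  r <- Find(function(r) r$planted_category$stationary == "masker-like",
            d$recordings)
  dsc <- extract_descriptors(r, "stationary", d$protocol)
  expect_lt(dsc[["mask_frm_ratio"]], 1)
  expect_lt(dsc[["mask_final_spikes"]], dsc[["mask_initial_spikes"]])
})

test_that("silent recordings give zero rates and flagged ratios", {
  p <- quick_protocol(5L)
  blocks <- list()
  for (v in 1:4)
    blocks[[sprintf("voc%d_clean", v)]] <-
      block_of(rep(list(numeric(0L)), 20L), t_end = 0.6,
               cid = sprintf("voc%d_clean", v))
  blocks[["noise_stat"]] <- trial_block(
    "noise_stat", rep(list(numeric(0L)), 20L), 0, 0.864, 0.2, 0.764)
  rec <- recording("rs", "CN", blocks)
  fake_tfrp <- structure(list(bf_firing_rate_hz = 0, bandwidth_octaves = 0,
                              response_duration_ms = 0,
                              significant = FALSE), class = "tfrp_result")
  dsc <- extract_descriptors(rec, "stationary", p, tfrp = fake_tfrp)
  expect_equal(unname(dsc[["sig_rate"]]), 0)
  expect_equal(unname(dsc[["mask_rate"]]), 0)
  expect_true(is.na(dsc[["mask_frm_ratio"]]))
  expect_true(is.na(dsc[["s2m_fr200"]]))
})

test_that("imputation fills flagged values and excludes heavily flagged rows", {
  st <- synth_table(4L, seed = 3L)
  tab <- st$table
  tab$mask_frm_ratio[1:3] <- NA
  tab[2L, descriptor_names()[1:5]] <- NA  # 6 NAs total in row 2
  imp <- impute_descriptors(tab)
  expect_equal(imp$excluded, tab$recording_id[2L])
  expect_false(anyNA(imp$table[, descriptor_names()]))
  med <- median(tab$mask_frm_ratio, na.rm = TRUE)
  expect_equal(imp$table$mask_frm_ratio[1L], med)
})

test_that("LDA separates well-separated descriptor clusters almost perfectly", {
  st <- synth_table(30L, sep = 4, seed = 5L)
  rep1 <- train_eval_lda(st$table, st$labels, seed = 2L)
  expect_gte(rep1$cv_accuracy_percent, 95)
  expect_equal(sum(!is.na(rep1$confusion_percent[1L, ])) > 0, TRUE)
  expect_equal(unname(rowSums(rep1$confusion_percent,
                              na.rm = TRUE))[1:5], rep(100, 5L))
  # fold determinism
  rep2 <- train_eval_lda(st$table, st$labels, seed = 2L)
  expect_identical(rep1$predictions, rep2$predictions)
})

test_that("the cost matrix discourages predicting the insensitive category", {
  st <- synth_table(40L, sep = 0.8, seed = 7L)  # heavily overlapping
  flat_cost <- matrix(1, 5, 5, dimnames = dimnames(default_cost_matrix()))
  diag(flat_cost) <- 0
  r_flat <- train_eval_lda(st$table, st$labels, cost_matrix = flat_cost,
                           seed = 4L)
  r_cost <- train_eval_lda(st$table, st$labels, seed = 4L)
  expect_lte(sum(r_cost$predictions == "insensitive"),
             sum(r_flat$predictions == "insensitive"))
})

test_that("equal-cost decisions agree with a reference LDA implementation", {
  st <- synth_table(25L, sep = 2, seed = 8L)
  X <- as.matrix(st$table[, descriptor_names()])
  X <- scale(X)
  fit <- noisecat:::fit_lda(X, st$labels, ridge = 1e-9)
  mine <- noisecat:::lda_predict(fit, X)$prediction
  ref <- MASS::lda(X, grouping = st$labels)
  ref_pred <- as.character(predict(ref, X)$class)
  expect_gt(mean(mine == ref_pred), 0.98)
})

test_that("the 15 combinations enumerate every nonempty group subset once", {
  combos <- combo_enumeration()
  expect_length(combos, 15L)
  keys <- vapply(combos, function(cc) paste(sort(cc), collapse = "+"),
                 character(1L))
  expect_false(anyDuplicated(keys) > 0L)
  expect_setequal(combos[["1"]], names(descriptor_groups()))
  expect_equal(combos[["8"]], "tfrp")
  expect_equal(combos[["12"]], "signal")
  expect_equal(combos[["14"]], "masker")
  expect_equal(combos[["15"]], "signal_to_masker")
})

test_that("only the informative descriptor group carries class information", {
  st <- synth_table(30L, informative = "signal", sep = 4, seed = 10L)
  sw <- combo_sweep(st$table, st$labels, seed = 3L)
  acc <- vapply(sw, `[[`, numeric(1L), "cv_accuracy_percent")
  expect_gte(acc[["12"]], acc[["8"]] + 20)   # signal-only >> TFRP-only
  expect_lt(acc[["8"]], 35)                   # ablated: chance band
  expect_gte(acc[["1"]], 90)
})

test_that("generalization to an i.i.d. test cohort tracks CV accuracy", {
  st_all <- synth_table(60L, sep = 3, seed = 12L)
  idx <- rep(c(TRUE, FALSE), length.out = nrow(st_all$table))
  tr_tab <- st_all$table[idx, ]; te_tab <- st_all$table[!idx, ]
  g <- generalize_lda(tr_tab, st_all$labels[idx], te_tab,
                      st_all$labels[!idx])
  cv <- train_eval_lda(tr_tab, st_all$labels[idx], seed = 2L)
  expect_lt(abs(g$cv_accuracy_percent - cv$cv_accuracy_percent), 10)
  expect_error(generalize_lda(tr_tab, st_all$labels[idx], tr_tab,
                              st_all$labels[idx]), "overlap")
  expect_error(generalize_lda(tr_tab, st_all$labels[idx], te_tab[0, ],
                              character(0L)), "empty test")
})

test_that("stratification errors when a class is too small", {
  st <- synth_table(3L, seed = 13L)
  expect_error(train_eval_lda(st$table, st$labels, n_folds = 5L),
               "fewer than")
})
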