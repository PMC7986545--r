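# The 12 response descriptors per noise type and the cost-weighted linear
# discriminant classification of category membership (5-fold CV, the 15
# descriptor-group combinations, and reliable -> rest generalization).

#' @rdname descriptor_groups
#' @export
descriptor_names <- function() {
  c("tfrp_bf_rate", "tfrp_bandwidth", "tfrp_duration",
    "sig_rate", "sig_corrcoef",
    "mask_rate", "mask_corrcoef", "mask_frm_ratio",
    "mask_initial_spikes", "mask_final_spikes",
    "s2m_fr200", "s2m_fr300")
}

#' Descriptor groups
#'
#' The 12 descriptors come in four groups: `tfrp` (BF firing rate, tuning
#' bandwidth, response duration), `signal` (clean-vocalization firing rate
#' and CorrCoef), `masker` (masker firing rate, CorrCoef, the short-term
#' adaptation ratio FRm300/FRm200, and the spike counts of the first and
#' last 50 ms of the masker analysis period), and `signal_to_masker` (the
#' signal rate over FRm200 and over FRm300).
#'
#' @return Named list mapping group name to descriptor column names.
#' @export
descriptor_groups <- function() {
  n <- descriptor_names()
  list(tfrp = n[1:3], signal = n[4:5], masker = n[6:10],
       signal_to_masker = n[11:12])
}

#' Extract the 12 classifier descriptors of a recording
#'
#' Signal descriptors are averaged over the four clean vocalizations.
#' Masker descriptors come from the given noise's masker-alone block:
#' FRm200 is the rate over the first 200 ms of the masker, FRm300 the rate
#' over the window where the signal would have occurred; ratios with a zero
#' denominator are NA (flagged, imputed downstream by
#' [impute_descriptors()]).
#'
#' @param rec a [recording()].
#' @param noise_type masker type.
#' @param protocol the [stim_protocol()].
#' @param tfrp optional precomputed [compute_tfrp()] result.
#' @return Named numeric vector of length 12.
#' @export
extract_descriptors <- function(rec, noise_type, protocol, tfrp = NULL) {
  if (is.null(tfrp)) tfrp <- compute_tfrp(rec, protocol)
  nv <- length(protocol$vocalization_ids)
  sig_rates <- numeric(nv); sig_cc <- numeric(nv)
  for (v in seq_len(nv)) {
    blk <- rec$blocks[[sprintf("voc%d_clean", v)]]
    sig_rates[v] <- evoked_rate(blk)
    sig_cc[v] <- corrcoef(blk, protocol$corrcoef_kernel_s)$corrcoef
  }
  nb <- rec$blocks[[sprintf("noise_%s", noise_code(noise_type))]]
  if (is.null(nb)) stop(sprintf("missing noise-alone block for %s",
                                noise_type))
  on <- nb$onset_s
  frm200 <- mean(trial_rates(nb, c(on, on + protocol$masker_initial_window_s)))
  s0 <- on + protocol$signal_onset_in_masker_s
  frm300 <- mean(trial_rates(nb, c(s0, s0 +
                                     protocol$signal_window_in_masker_s)))
  per_end <- on + protocol$masker_analysis_period_s
  ew <- protocol$edge_window_s
  init50 <- mean(trial_rates(nb, c(on, on + ew))) * ew
  fin50 <- mean(trial_rates(nb, c(per_end - ew, per_end))) * ew
  sig_rate <- mean(sig_rates)
  ratio <- function(num, den) if (is.na(den) || den == 0) NA_real_
                              else num / den
  out <- c(tfrp$bf_firing_rate_hz, tfrp$bandwidth_octaves,
           tfrp$response_duration_ms,
           sig_rate, mean(sig_cc, na.rm = TRUE),
           evoked_rate(nb), corrcoef(nb, protocol$corrcoef_kernel_s)$corrcoef,
           ratio(frm300, frm200), init50, fin50,
           ratio(sig_rate, frm200), ratio(sig_rate, frm300))
  names(out) <- descriptor_names()
  out[is.nan(out)] <- NA_real_
  out
}

#' Build the per-noise descriptor table of a dataset
#'
#' @param dataset a [spike_dataset()].
#' @param noise_type masker type.
#' @param tfrps optional named list of precomputed TFRPs keyed by
#'   recording id.
#' @param ids restrict to these recording ids.
#' @return data.frame: `recording_id` plus the 12 descriptor columns.
#' @export
descriptor_table <- function(dataset, noise_type, tfrps = NULL,
                             ids = NULL) {
  recs <- dataset$recordings
  if (!is.null(ids)) recs <- recs[ids]
  rows <- lapply(recs, function(r)
    extract_descriptors(r, noise_type, dataset$protocol,
                        tfrp = tfrps[[r$recording_id]]))
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(recording_id = vapply(recs, `[[`, character(1L),
                                     "recording_id"),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Impute flagged (NA) descriptors
#'
#' NA entries (zero-denominator ratios, undefined CorrCoef) are replaced by
#' the column median of the defined values; recordings with more than
#' `max_imputed` imputed descriptors are excluded.
#'
#' @param table a [descriptor_table()].
#' @param max_imputed exclusion threshold (default 3).
#' @return List with `table` (imputed, kept rows), `excluded`
#'   (recording ids), `n_imputed` per kept row.
#' @export
impute_descriptors <- function(table, max_imputed = 3L) {
  cols <- descriptor_names()
  X <- table[, cols, drop = FALSE]
  n_imp <- rowSums(is.na(X))
  for (cn in cols) {
    nas <- is.na(X[[cn]])
    if (any(nas)) {
      med <- stats::median(X[[cn]], na.rm = TRUE)
      X[[cn]][nas] <- if (is.na(med)) 0 else med
    }
  }
  keep <- n_imp <= max_imputed
  out <- table
  out[, cols] <- X
  list(table = out[keep, , drop = FALSE],
       excluded = table$recording_id[!keep], n_imputed = n_imp[keep])
}

#' Misclassification cost matrix
#'
#' Cost 0 on the diagonal, 2 for predicting `insensitive` when the truth
#' is any other category (that category dominates the cohort), 1 elsewhere.
#'
#' @return 5 x 5 matrix, rows = true category, columns = predicted.
#' @export
default_cost_matrix <- function() {
  cats <- category_levels()
  C <- matrix(1, 5L, 5L, dimnames = list(cats, cats))
  diag(C) <- 0
  C[setdiff(cats, "insensitive"), "insensitive"] <- 2
  C
}

# -- linear discriminant with shared, ridge-conditioned covariance -------

fit_lda <- function(X, y, ridge = 1e-6) {
  X <- as.matrix(X)
  cls <- sort(unique(y))
  K <- length(cls); p <- ncol(X)
  mu <- matrix(0, K, p, dimnames = list(cls, colnames(X)))
  S <- matrix(0, p, p)
  for (k in seq_len(K)) {
    Xi <- X[y == cls[k], , drop = FALSE]
    mu[k, ] <- colMeans(Xi)
    if (nrow(Xi) > 1L)
      S <- S + crossprod(sweep(Xi, 2L, mu[k, ]))
  }
  S <- S / max(1L, nrow(X) - K)
  S <- S + diag(ridge * sum(diag(S)) / p + 1e-12, p)
  Sinv <- solve(S)
  prior <- as.numeric(table(factor(y, cls))) / length(y)
  list(classes = cls, mu = mu, Sinv = Sinv, prior = prior)
}

lda_posterior <- function(fit, X) {
  X <- as.matrix(X)
  A <- fit$mu %*% fit$Sinv                      # K x p
  d <- X %*% t(A) - matrix(0.5 * rowSums(A * fit$mu), nrow(X),
                           length(fit$classes), byrow = TRUE)
  d <- sweep(d, 2L, log(fit$prior), `+`)
  d <- d - apply(d, 1L, max)
  e <- exp(d)
  p <- e / rowSums(e)
  colnames(p) <- fit$classes
  p
}

lda_predict <- function(fit, X, cost_matrix = NULL) {
  post <- lda_posterior(fit, X)
  if (is.null(cost_matrix)) {
    pred <- fit$classes[max.col(post, ties.method = "first")]
  } else {
    C <- cost_matrix[fit$classes, , drop = FALSE]
    expected <- post %*% C                       # n x K_pred
    pred <- colnames(C)[apply(expected, 1L, which.min)]
  }
  list(prediction = pred, posterior = post)
}

make_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    if (length(idx) < n_folds)
      stop(sprintf(paste0("class '%s' has %d samples, fewer than %d ",
                          "folds; stratification impossible"),
                   cl, length(idx), n_folds))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(mu = mu, sd = sdv)
}

standardize_apply <- function(X, st) {
  scale(as.matrix(X), center = st$mu, scale = st$sd)
}

confusion_percent <- function(truth, pred) {
  cats <- category_levels()
  counts <- table(factor(truth, cats), factor(pred, cats))
  counts <- unclass(counts)
  rs <- rowSums(counts)
  100 * counts / ifelse(rs == 0, NA_real_, rs)
}

#' Cross-validated cost-weighted LDA over a descriptor combination
#'
#' Stratified `n_folds`-fold cross-validation. On each training fold the
#' selected descriptors are standardized (the test fold reuses the training
#' moments), a linear discriminant with shared ridge-conditioned
#' within-class covariance and empirical priors is fitted, and test samples
#' are assigned the category minimizing the expected cost under
#' `cost_matrix`. Accuracy is percent correct pooled over folds.
#'
#' @param table an (imputed) [descriptor_table()].
#' @param labels category per row of `table`.
#' @param combination character subset of `names(descriptor_groups())`.
#' @param cost_matrix see [default_cost_matrix()]; NULL = plain
#'   maximum-posterior decision.
#' @param n_folds folds (default 5).
#' @param seed fold-assignment seed.
#' @param folds optional precomputed fold vector (overrides `seed`), used
#'   to share identical folds across combinations.
#' @param ridge covariance ridge factor.
#' @return An object of class `classifier_report`: `combination`,
#'   `cv_accuracy_percent`, `confusion_percent` (rows = true, sum to 100),
#'   `n`, `predictions`.
#' @export
train_eval_lda <- function(table, labels, combination = names(descriptor_groups()),
                           cost_matrix = default_cost_matrix(),
                           n_folds = 5L, seed = 1L, folds = NULL,
                           ridge = 1e-6) {
  stopifnot(length(combination) >= 1L)
  cols <- unlist(descriptor_groups()[combination], use.names = FALSE)
  X <- as.matrix(table[, cols, drop = FALSE])
  y <- as.character(labels)
  stopifnot(nrow(X) == length(y))
  if (is.null(folds)) folds <- make_folds(y, n_folds, seed)
  pred <- character(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < length(unique(y)))
      stop("a class is absent from a training fold; change the seed")
    st <- standardize_fit(X[tr, , drop = FALSE])
    fit <- fit_lda(standardize_apply(X[tr, , drop = FALSE], st), y[tr],
                   ridge)
    pred[!tr] <- lda_predict(fit, standardize_apply(X[!tr, , drop = FALSE],
                                                    st),
                             cost_matrix)$prediction
  }
  structure(list(combination = combination,
                 cv_accuracy_percent = 100 * mean(pred == y),
                 confusion_percent = confusion_percent(y, pred),
                 n = length(y), predictions = pred),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("LDA [%s]: accuracy %.2f%% (n = %d)\n",
              paste(x$combination, collapse = "+"),
              x$cv_accuracy_percent, x$n))
  invisible(x)
}

#' The 15 descriptor-group combinations
#'
#' All nonempty subsets of the four groups, enumerated with TFRP-containing
#' combinations first (1 = all four, 8 = TFRP alone, 12 = signal alone,
#' 14 = masker alone, 15 = signal-to-masker alone).
#'
#' @return List of 15 character vectors, names `"1"`..`"15"`.
#' @export
combo_enumeration <- function() {
  g <- names(descriptor_groups())
  combos <- list()
  for (t in c(TRUE, FALSE)) for (s in c(TRUE, FALSE))
    for (m in c(TRUE, FALSE)) for (r in c(TRUE, FALSE)) {
      sel <- g[c(t, s, m, r)]
      if (length(sel)) combos[[length(combos) + 1L]] <- sel
    }
  names(combos) <- as.character(seq_along(combos))
  combos
}

#' Accuracy sweep over the 15 descriptor combinations
#'
#' Runs [train_eval_lda()] once per combination with identical folds.
#'
#' @inheritParams train_eval_lda
#' @return List of 15 `classifier_report`s keyed by combination id.
#' @export
combo_sweep <- function(table, labels, cost_matrix = default_cost_matrix(),
                        n_folds = 5L, seed = 1L, ridge = 1e-6) {
  folds <- make_folds(as.character(labels), n_folds, seed)
  lapply(combo_enumeration(), function(combo)
    train_eval_lda(table, labels, combo, cost_matrix, n_folds,
                   folds = folds, ridge = ridge))
}

#' Train on reliable recordings, test on the rest
#'
#' Fits one cost-weighted LDA on the training table (standardized on the
#' training data) and evaluates it on a disjoint test table; no
#' cross-validation.
#'
#' @param train_table,train_labels the reliable cohort.
#' @param test_table,test_labels the held-out cohort (disjoint recording
#'   ids, nonempty).
#' @inheritParams train_eval_lda
#' @return A `classifier_report` (accuracy on the test set).
#' @export
generalize_lda <- function(train_table, train_labels, test_table,
                           test_labels,
                           combination = names(descriptor_groups()),
                           cost_matrix = default_cost_matrix(),
                           ridge = 1e-6) {
  if (nrow(test_table) == 0L) stop("empty test set")
  if (length(intersect(train_table$recording_id,
                       test_table$recording_id)))
    stop("train and test recording sets overlap")
  cols <- unlist(descriptor_groups()[combination], use.names = FALSE)
  Xtr <- as.matrix(train_table[, cols, drop = FALSE])
  Xte <- as.matrix(test_table[, cols, drop = FALSE])
  st <- standardize_fit(Xtr)
  fit <- fit_lda(standardize_apply(Xtr, st), as.character(train_labels),
                 ridge)
  pred <- lda_predict(fit, standardize_apply(Xte, st),
                      cost_matrix)$prediction
  y <- as.character(test_labels)
  structure(list(combination = combination,
                 cv_accuracy_percent = 100 * mean(pred == y),
                 confusion_percent = confusion_percent(y, pred),
                 n = length(y), predictions = pred,
                 n_train = nrow(Xtr), n_test = nrow(Xte)),
            class = "classifier_report")
}
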