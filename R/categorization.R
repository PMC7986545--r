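# K-means categorization of 3-value EI profiles (one noise type at a
# time), the MSE elbow diagnostic, the deterministic mapping of the five
# clusters to named categories, and bootstrap category-stability testing.

#' Extract the per-noise EI profile matrix
#'
#' @param features list of [recording_selection_features()] (or of
#'   `ei_profile` objects).
#' @param noise_type which noise's 3-value profiles to extract.
#' @return Numeric matrix (recordings x SNR levels), rownames = ids.
#' @export
profile_matrix <- function(features, noise_type) {
  rows <- lapply(features, function(f) {
    prof <- if (inherits(f, "ei_profile")) f else f$profile
    prof$ei[noise_type, ]
  })
  X <- do.call(rbind, rows)
  ids <- vapply(seq_along(features), function(i) {
    f <- features[[i]]
    if (!is.null(f$recording_id)) f$recording_id
    else if (!is.null(names(features)[i]) && nzchar(names(features)[i]))
      names(features)[i]
    else sprintf("profile%04d", i)
  }, character(1L))
  rownames(X) <- ids
  X
}

kpp_init <- function(X, k) {
  n <- nrow(X)
  centers <- numeric(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((X - X[rep(centers[1L], n), , drop = FALSE])^2)
  for (j in seq_len(k - 1L)) {
    centers[j + 1L] <- if (all(d2 == 0)) sample.int(n, 1L)
    else sample.int(n, 1L, prob = d2)
    d2 <- pmin(d2, rowSums((X - X[rep(centers[j + 1L], n),
                                  , drop = FALSE])^2))
  }
  X[centers, , drop = FALSE]
}

#' K-means clustering of EI profiles
#'
#' Lloyd iterations under Euclidean distance, k-means++-style seeded
#' initialization, best of `n_restarts` by the clustering MSE
#' `(1/N) sum_i ||centroid(i) - profile_i||^2`. Deterministic given `seed`.
#'
#' @param profiles numeric matrix (recordings x 3 EI values), no NA.
#' @param k number of clusters.
#' @param n_restarts random restarts (default 50).
#' @param seed integer seed.
#' @return An object of class `ei_clustering`: `k`, `centroids`,
#'   `assignments` (named integer vector), `mse`, `sizes`,
#'   `label_map` (NULL until [label_clusters()]).
#' @export
kmeans_profiles <- function(profiles, k, n_restarts = 50L, seed = 1L) {
  X <- as.matrix(profiles)
  if (anyNA(X)) stop("profiles contain undefined EI values")
  if (nrow(X) < k) stop("fewer profiles than clusters")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- tryCatch(suppressWarnings(
      stats::kmeans(X, centers = kpp_init(X, k), iter.max = 200L,
                    algorithm = "Lloyd")), error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed on all restarts")
  res <- list(k = k, centroids = unname(best$centers),
              assignments = stats::setNames(best$cluster, rownames(X)),
              mse = best$tot.withinss / nrow(X),
              sizes = as.integer(best$size), label_map = NULL)
  colnames(res$centroids) <- colnames(profiles)
  class(res) <- "ei_clustering"
  res
}

#' @export
print.ei_clustering <- function(x, ...) {
  cat(sprintf("EI-profile k-means: k = %d, N = %d, MSE = %.4f\n",
              x$k, length(x$assignments), x$mse))
  cents <- round(x$centroids, 3)
  rownames(cents) <- if (!is.null(x$label_map)) x$label_map
                     else sprintf("cluster_%d", seq_len(x$k))
  print(cents)
  invisible(x)
}

#' MSE elbow curve over a range of k
#'
#' @param profiles as in [kmeans_profiles()].
#' @param k_range candidate cluster counts (default 1:10).
#' @param n_restarts,seed per-k clustering settings (sub-seed derived
#'   per k).
#' @return data.frame with `k` and `mse`; warns if the curve is not
#'   nonincreasing (insufficient restarts).
#' @export
elbow_curve <- function(profiles, k_range = 1:10, n_restarts = 50L,
                        seed = 1L) {
  k_range <- k_range[k_range <= nrow(profiles)]
  mse <- vapply(k_range, function(k)
    kmeans_profiles(profiles, k, n_restarts,
                    derive_seed(seed, "elbow", k))$mse, numeric(1L))
  if (any(diff(mse) > 1e-12))
    warning("elbow curve not nonincreasing; consider more restarts")
  data.frame(k = k_range, mse = mse)
}

#' Name the five clusters from their centroids
#'
#' Deterministic rule on the centroid features `m` (mean EI over SNRs) and
#' `r` (EI at the highest SNR minus EI at the lowest): masker-like is the
#' lowest-`m` centroid that is negative at all SNRs (else simply the lowest
#' `m`); balanced is the largest SNR range `r` above the median of the
#' remaining; signal-like the highest remaining `m`; insensitive the
#' smallest remaining `|m|`; signal-dominated is the remainder. Ties break
#' by descending `m`, then cluster index.
#'
#' @param centroids k x 3 centroid matrix, columns ordered from the
#'   highest to the lowest SNR.
#' @param named require the five category names (k must be 5); with
#'   `named = FALSE` generic `cluster_i` labels are returned for any k.
#' @return Character vector: label of each cluster (by row of `centroids`).
#' @export
label_clusters <- function(centroids, named = TRUE) {
  k <- nrow(centroids)
  if (!named) return(sprintf("cluster_%d", seq_len(k)))
  if (k != 5L) stop("named category labels require k = 5")
  m <- rowMeans(centroids)
  r <- centroids[, 1L] - centroids[, ncol(centroids)]
  labels <- character(5L)
  remaining <- seq_len(5L)
  pick <- function(cand, score, decreasing) {
    o <- order(if (decreasing) -score else score, -m[cand], cand)
    cand[o[1L]]
  }
  all_neg <- remaining[apply(centroids < 0, 1L, all)]
  cand <- if (length(all_neg)) all_neg else remaining
  i <- pick(cand, m[cand], decreasing = FALSE)
  labels[i] <- "masker-like"; remaining <- setdiff(remaining, i)
  rr <- r[remaining]
  cand <- remaining[rr > stats::median(rr)]
  if (!length(cand)) cand <- remaining
  i <- pick(cand, r[cand], decreasing = TRUE)
  labels[i] <- "balanced"; remaining <- setdiff(remaining, i)
  i <- pick(remaining, m[remaining], decreasing = TRUE)
  labels[i] <- "signal-like"; remaining <- setdiff(remaining, i)
  i <- pick(remaining, abs(m[remaining]), decreasing = FALSE)
  labels[i] <- "insensitive"; remaining <- setdiff(remaining, i)
  labels[remaining] <- "signal-dominated"
  labels
}

#' Assign profiles to existing centroids
#'
#' @param X profile matrix (rows = recordings).
#' @param centroids k x 3 centroid matrix.
#' @param label_map optional cluster labels (from [label_clusters()]).
#' @return data.frame with `recording_id`, `cluster`, `category`,
#'   `centroid_distance` (Euclidean).
#' @export
assign_to_centroids <- function(X, centroids, label_map = NULL) {
  X <- as.matrix(X)
  d <- outer(seq_len(nrow(X)), seq_len(nrow(centroids)),
             Vectorize(function(i, j) sqrt(sum((X[i, ] - centroids[j, ])^2))))
  cl <- apply(d, 1L, which.min)
  data.frame(
    recording_id = rownames(X) %||% sprintf("profile%04d", seq_len(nrow(X))),
    cluster = cl,
    category = if (is.null(label_map)) sprintf("cluster_%d", cl)
               else label_map[cl],
    centroid_distance = d[cbind(seq_len(nrow(X)), cl)],
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bootstrap stability of one recording's category
#'
#' Per replicate, the trials of every condition entering the EI (clean
#' vocalizations, noise alone, masked vocalizations of the given noise
#' type) are independently resampled with replacement keeping the trial
#' count; the PSTHs and the 3-value EI profile are recomputed and the
#' profile reallocated to the nearest original centroid. A replicate with
#' any undefined EI lands in an `"undefined"` sentinel outcome counted
#' against stability. Deterministic given `seed`.
#'
#' @param rec a [recording()].
#' @param protocol the [stim_protocol()].
#' @param noise_type which noise's categorization to test.
#' @param centroids original 5 x 3 centroid matrix.
#' @param label_map cluster labels (from [label_clusters()]).
#' @param n_boot replicates (default 100).
#' @param seed integer seed.
#' @param reliable_threshold minimal modal count for reliability
#'   (default 95).
#' @param bin_s EI PSTH bin.
#' @return An object of class `category_assignment`: `recording_id`,
#'   `noise_type`, `category` (from the recording's own profile),
#'   `centroid_distance`, `mode_category`, `bootstrap_mode_count`,
#'   `reliable`, `boot_categories` (replicate labels).
#' @export
bootstrap_stability <- function(rec, protocol, noise_type, centroids,
                                label_map, n_boot = 100L, seed = 1L,
                                reliable_threshold = 95L,
                                bin_s = protocol$psth_bin_s) {
  set.seed(seed)
  snrs <- protocol$snr_levels_db
  nv <- length(protocol$vocalization_ids)
  ntr <- protocol$n_trials_voc
  # per-condition trial count matrices on the EI windows
  CV <- vector("list", nv); CN <- vector("list", nv)
  CS <- vector("list", nv)
  for (v in seq_len(nv)) {
    w <- ei_windows(protocol, v, rec$blocks)
    clean <- rec$blocks[[sprintf("voc%d_clean", v)]]
    CV[[v]] <- trial_bin_counts(clean, bin_s,
                                c(w$clean_start, w$clean_start + w$dur))
    nb <- rec$blocks[[sprintf("noise_%s", noise_code(noise_type))]]
    m0 <- nb$onset_s + w$masker_rel_start
    CN[[v]] <- trial_bin_counts(nb, bin_s, c(m0, m0 + w$dur))
    CS[[v]] <- lapply(seq_along(snrs), function(si) {
      blk <- rec$blocks[[sprintf("voc%d_%s_%s", v, noise_code(noise_type),
                                 snr_label(snrs[si]))]]
      s0 <- blk$onset_s + w$masker_rel_start
      trial_bin_counts(blk, bin_s, c(s0, s0 + w$dur))
    })
  }
  resample_w <- function() t(stats::rmultinom(n_boot, ntr,
                                              rep(1 / ntr, ntr)))
  # bootstrap pooled PSTHs: rows = replicates
  PV <- lapply(CV, function(C) (resample_w() %*% C) / (ntr * bin_s))
  PN <- lapply(CN, function(C) (resample_w() %*% C) / (ntr * bin_s))
  PS <- lapply(CS, function(Cs) lapply(Cs, function(C)
    (resample_w() %*% C) / (ntr * bin_s)))
  cats <- character(n_boot)
  for (b in seq_len(n_boot)) {
    prof <- numeric(length(snrs))
    for (si in seq_along(snrs)) {
      eis <- rep(NA_real_, nv)
      for (v in seq_len(nv)) {
        dn <- cosine_distance(PN[[v]][b, ], PS[[v]][[si]][b, ])
        dv <- cosine_distance(PV[[v]][b, ], PS[[v]][[si]][b, ])
        if (!is.na(dn) && !is.na(dv) && dn + dv > 0)
          eis[v] <- (dn - dv) / (dn + dv)
      }
      prof[si] <- if (all(is.na(eis))) NA_real_ else mean(eis, na.rm = TRUE)
    }
    cats[b] <- if (anyNA(prof)) "undefined"
    else label_map[which.min(colSums((t(centroids) - prof)^2))]
  }
  tabb <- sort(table(cats), decreasing = TRUE)
  own <- ei_profile(rec, protocol, bin_s)$ei[noise_type, ]
  own_cat <- if (anyNA(own)) "undefined"
  else label_map[which.min(colSums((t(centroids) - own)^2))]
  own_dist <- if (anyNA(own)) NA_real_
  else sqrt(min(colSums((t(centroids) - own)^2)))
  structure(list(recording_id = rec$recording_id, noise_type = noise_type,
                 category = own_cat, centroid_distance = own_dist,
                 mode_category = names(tabb)[1L],
                 bootstrap_mode_count = as.integer(tabb[1L]),
                 reliable = as.integer(tabb[1L]) >= reliable_threshold,
                 boot_categories = cats),
            class = "category_assignment")
}

#' @export
print.category_assignment <- function(x, ...) {
  cat(sprintf("%s [%s]: %s (mode %s %d/100%s)\n", x$recording_id,
              x$noise_type, x$category, x$mode_category,
              x$bootstrap_mode_count,
              if (x$reliable) ", reliable" else ""))
  invisible(x)
}
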