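# PSTHs, firing rates, response significance, trial-to-trial reliability,
# and pure-tone TFRP quantification.

#' Peristimulus time histogram
#'
#' Repetition-averaged binned firing rate: bin value = total spikes in the
#' bin across trials / (n_trials * bin_s), in spikes/s.
#'
#' @param block a [trial_block()].
#' @param bin_s bin width (s).
#' @param window `c(start, end)` relative to trial start; must lie within
#'   the trial. Defaults to `c(onset_s, offset_s)`.
#' @return An object of class `psth`: list with `values` (spikes/s),
#'   `bin_s`, `window`, `n_trials`.
#' @export
compute_psth <- function(block, bin_s, window = NULL) {
  if (is.null(window)) window <- c(block$onset_s, block$offset_s)
  check_window(block, window)
  n_bins <- floor((window[2L] - window[1L]) / bin_s + 1e-9)
  counts <- pooled_bin_counts(block$trains, bin_s, window[1L], n_bins)
  structure(list(values = counts / (length(block$trains) * bin_s),
                 bin_s = bin_s, window = window,
                 n_trials = length(block$trains)),
            class = "psth")
}

check_window <- function(block, window) {
  if (length(window) != 2L || window[2L] <= window[1L])
    stop("window must be c(start, end) with end > start")
  if (window[1L] < block$t_start - 1e-9 || window[2L] > block$t_end + 1e-9)
    stop(sprintf("window [%g, %g] outside trial bounds [%g, %g] of block %s",
                 window[1L], window[2L], block$t_start, block$t_end,
                 block$condition_id))
  invisible(window)
}

pooled_bin_counts <- function(trains, bin_s, start, n_bins) {
  t <- unlist(trains, use.names = FALSE)
  if (!length(t)) return(numeric(n_bins))
  idx <- floor((t - start) / bin_s) + 1
  idx <- idx[idx >= 1 & idx <= n_bins]
  tabulate(idx, nbins = n_bins)
}

# per-trial count matrix (n_trials x n_bins)
trial_bin_counts <- function(block, bin_s, window) {
  check_window(block, window)
  n_bins <- floor((window[2L] - window[1L]) / bin_s + 1e-9)
  t(vapply(block$trains, function(tt)
    pooled_bin_counts(list(tt), bin_s, window[1L], n_bins),
    numeric(n_bins)))
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("PSTH: %d bins of %.0f ms over [%.3f, %.3f] s, peak %.1f sp/s\n",
              length(x$values), 1000 * x$bin_s, x$window[1L], x$window[2L],
              max(x$values)))
  invisible(x)
}

# per-trial spike rates in a window
trial_rates <- function(block, window) {
  check_window(block, window)
  vapply(block$trains, function(tt)
    sum(tt >= window[1L] & tt < window[2L]), numeric(1L)) /
    (window[2L] - window[1L])
}

#' Evoked and spontaneous firing rates
#'
#' Evoked: spikes in `[onset, offset]` divided by the stimulus duration,
#' averaged over trials. Spontaneous: rate in the `window_s` seconds
#' preceding stimulus onset.
#'
#' @param block a [trial_block()].
#' @param window_s spontaneous window length (s), default 0.2.
#' @return Rate in spikes/s.
#' @export
evoked_rate <- function(block) {
  mean(trial_rates(block, c(block$onset_s, block$offset_s)))
}

#' @rdname evoked_rate
#' @export
spontaneous_rate <- function(block, window_s = 0.2) {
  if (block$onset_s - window_s < block$t_start - 1e-9)
    stop(sprintf("block %s: no %.0f-ms pre-onset spontaneous window",
                 block$condition_id, 1000 * window_s))
  mean(trial_rates(block, c(block$onset_s - window_s, block$onset_s)))
}

#' Evoked-versus-spontaneous response significance
#'
#' Two-sided paired test of per-trial evoked rates against per-trial
#' spontaneous rates: Wilcoxon signed-rank (normal approximation), with a
#' sign-test fallback when fewer than 6 nonzero differences are available.
#' All-zero differences give p = 1.
#'
#' @param block a [trial_block()].
#' @param alpha significance level (default 0.05).
#' @param spont_window_s spontaneous window (s).
#' @return List with `significant` (logical) and `p_value`.
#' @export
response_significant <- function(block, alpha = 0.05,
                                 spont_window_s = 0.2) {
  if (length(block$trains) < 2L) stop("need >= 2 trials")
  ev <- trial_rates(block, c(block$onset_s, block$offset_s))
  sp <- trial_rates(block, c(block$onset_s - spont_window_s,
                             block$onset_s))
  d <- ev - sp
  nz <- sum(d != 0)
  p <- if (nz == 0L) 1
  else if (nz < 6L)
    stats::binom.test(sum(d > 0), nz, 0.5)$p.value
  else
    suppressWarnings(stats::wilcox.test(ev, sp, paired = TRUE,
                                        exact = FALSE)$p.value)
  list(significant = p < alpha, p_value = p)
}

#' Trial-to-trial temporal reliability (CorrCoef)
#'
#' Each trial is binned at 1 ms over the evoked window and convolved with a
#' Gaussian kernel (SD `kernel_s`); CorrCoef is the mean Pearson
#' correlation over all unordered trial pairs of the smoothed traces, so
#' identical trains score 1. Pairs where either trace has zero variance are
#' excluded; with no valid pair the index is undefined.
#'
#' @param block a [trial_block()].
#' @param kernel_s Gaussian SD (s), default 0.010.
#' @param window analysis window, default `c(onset_s, offset_s)`.
#' @return List with `corrcoef` (NA when undefined), `defined`,
#'   `n_trials`, `n_pairs`, `kernel_s`.
#' @export
corrcoef <- function(block, kernel_s = 0.010, window = NULL) {
  if (length(block$trains) < 2L) stop("need >= 2 trials")
  if (is.null(window)) window <- c(block$onset_s, block$offset_s)
  x <- trial_bin_counts(block, 0.001, window)
  xs <- gaussian_smooth_rows(x, kernel_s / 0.001)
  v <- apply(xs, 1L, var)
  keep <- which(v > 0)
  if (length(keep) < 2L)
    return(list(corrcoef = NA_real_, defined = FALSE,
                n_trials = nrow(x), n_pairs = 0L, kernel_s = kernel_s))
  cc <- stats::cor(t(xs[keep, , drop = FALSE]))
  pair <- cc[upper.tri(cc)]
  list(corrcoef = mean(pair), defined = TRUE, n_trials = nrow(x),
       n_pairs = length(pair), kernel_s = kernel_s)
}

gaussian_smooth_rows <- function(x, sigma_bins) {
  half <- max(1L, ceiling(4 * sigma_bins))
  k <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  k <- k / sum(k)
  n <- ncol(x)
  t(apply(x, 1L, function(r) {
    y <- stats::convolve(r, k, type = "open")
    y[(half + 1L):(half + n)]
  }))
}

# -- TFRP ----------------------------------------------------------------

#' Time-frequency response profile of the pure-tone block
#'
#' Per tone frequency, a 1-ms-bin PSTH over the 100 ms following tone
#' onset; the resulting 100 x 129 rate matrix is smoothed with a uniform
#' 5 x 5 window (edge cells use the available sub-window, so values remain
#' true local means). Baseline statistics come from the 50-ms pre-onset
#' window pooled across frequencies and smoothed identically (moments taken
#' over full-window cells; at map edges, where the renormalized window
#' averages fewer cells, the threshold is widened by `sqrt(25/n_window)` to
#' keep the false-positive rate uniform). A response is significant when
#' any matrix cell exceeds baseline mean + 6 SD; the
#' largest 4-connected supra-threshold region gives the tuning bandwidth
#' (octave span) and response duration (time extent, ms). The best
#' frequency (BF) is the frequency of the global matrix maximum.
#'
#' @param rec a [recording()] (or a named list of tone [trial_block()]s).
#' @param protocol the [stim_protocol()].
#' @return An object of class `tfrp_result` with `matrix` (time x
#'   frequency, smoothed spikes/s), `bf_hz`, `bf_firing_rate_hz`,
#'   `significant`, `bandwidth_octaves`, `response_duration_ms`,
#'   `baseline_mean`, `baseline_sd`.
#' @export
compute_tfrp <- function(rec, protocol) {
  blocks <- if (inherits(rec, "recording")) rec$blocks else rec
  fr <- protocol$tone_frequencies_hz
  nf <- length(fr)
  ids <- sprintf("tone_%03d", seq_len(nf))
  missing <- setdiff(ids, names(blocks))
  if (length(missing))
    stop(sprintf("missing tone conditions: %s%s",
                 paste(utils::head(missing, 5L), collapse = ", "),
                 if (length(missing) > 5L) ", ..." else ""))
  n_time <- 100L; n_base <- 50L
  M <- matrix(0, n_time, nf)
  B <- matrix(0, n_base, nf)
  for (j in seq_len(nf)) {
    b <- blocks[[ids[j]]]
    nt <- length(b$trains)
    M[, j] <- pooled_bin_counts(b$trains, 0.001, b$onset_s, n_time) /
      (nt * 0.001)
    B[, j] <- pooled_bin_counts(b$trains, 0.001, b$onset_s - 0.05,
                                n_base) / (nt * 0.001)
  }
  Ms <- box_smooth_2d(M, 2L)
  Bs <- box_smooth_2d(B, 2L)
  # baseline moments from full 5x5-window cells; edge cells of the map are
  # means over fewer cells, so their sampling SD is larger by
  # sqrt(25 / n_window) and the 6-SD contour is scaled accordingly
  interior <- Bs[3:(nrow(Bs) - 2L), 3:(ncol(Bs) - 2L)]
  bmean <- mean(interior); bsd <- sd(interior)
  win <- function(n) pmin(seq_len(n) + 2L, n) - pmax(seq_len(n) - 2L, 1L) + 1L
  n_window <- outer(win(n_time), win(nf))
  thr <- bmean + 6 * bsd * sqrt(25 / n_window)
  imax <- arrayInd(which.max(Ms), dim(Ms))
  mask <- Ms > thr
  significant <- FALSE
  bandwidth <- 0; duration <- 0
  if (any(mask)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0])
    # a single hot 1-ms bin smears into at most one 5x5 window of
    # supra-threshold cells; a genuine response contour must extend
    # beyond one window's footprint
    significant <- max(sizes) > 25L
    if (significant) {
      main <- which(lab == which.max(sizes), arr.ind = TRUE)
      bandwidth <- log2(fr[max(main[, 2L])] / fr[min(main[, 2L])])
      duration <- diff(range(main[, 1L])) + 1
    }
  }
  structure(list(matrix = Ms, bf_hz = fr[imax[2L]],
                 bf_firing_rate_hz = Ms[imax], significant = significant,
                 bandwidth_octaves = bandwidth,
                 response_duration_ms = duration,
                 baseline_mean = bmean, baseline_sd = bsd),
            class = "tfrp_result")
}

# uniform (2*half+1)^2 box smoother with renormalized partial windows
box_smooth_2d <- function(M, half) {
  M1 <- box_smooth_rows(M, half)
  t(box_smooth_rows(t(M1), half))
}

box_smooth_rows <- function(M, half) {
  n <- nrow(M)
  cs <- rbind(0, apply(M, 2L, cumsum))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

# 4-connected component labelling of a logical matrix (frontier growing)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    frontier <- start
    lab[frontier] <- cur
    while (length(frontier)) {
      i <- (frontier - 1L) %% nr + 1L
      nb <- c(frontier[i > 1L] - 1L, frontier[i < nr] + 1L,
              frontier[frontier > nr] - nr,
              frontier[frontier <= nr * (nc - 1L)] + nr)
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

#' @export
print.tfrp_result <- function(x, ...) {
  cat(sprintf(paste0("TFRP: BF %.0f Hz at %.1f sp/s; %s (bandwidth %.2f",
                     " oct, duration %g ms)\n"),
              x$bf_hz, x$bf_firing_rate_hz,
              if (x$significant) "significant" else "not significant",
              x$bandwidth_octaves, x$response_duration_ms),
      ...)
  invisible(x)
}
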