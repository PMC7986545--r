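# Category switching between the two masking noises: joint count matrix,
# per-category / per-structure switch percentages, and Shannon mutual
# information.

#' Tidy a set of category assignments
#'
#' @param assignments list of [bootstrap_stability()] results, or a
#'   data.frame already holding `recording_id`, `category` and optionally
#'   `reliable`, `structure`.
#' @return data.frame with one row per recording.
#' @export
assignments_df <- function(assignments) {
  if (is.data.frame(assignments)) return(assignments)
  out <- do.call(rbind, lapply(assignments, function(a)
    data.frame(recording_id = a$recording_id,
               noise_type = a$noise_type %||% NA_character_,
               category = a$category,
               reliable = a$reliable %||% NA,
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Category-switching matrix between the two noises
#'
#' Joint count table over the 5 x 5 category pairs: rows = category in
#' stationary noise, columns = category in chorus noise. Recordings present
#' in only one noise's assignment set are excluded. With
#' `filter = "reliable"` only recordings reliable in both noises are
#' counted.
#'
#' @param assign_stationary,assign_chorus assignments per noise (anything
#'   [assignments_df()] accepts); categories must be [category_levels()]
#'   entries (an `"undefined"` sentinel is dropped).
#' @param filter `"all"` or `"reliable"`.
#' @param structures optional named vector mapping recording id to
#'   structure label (used by [switch_percentages()]).
#' @return An object of class `switching_matrix`: `counts` (5 x 5 integer),
#'   `row_percent`, `n_total`, `joined` (the paired data.frame).
#' @export
switching_matrix <- function(assign_stationary, assign_chorus,
                             filter = c("all", "reliable"),
                             structures = NULL) {
  filter <- match.arg(filter)
  a <- assignments_df(assign_stationary)
  b <- assignments_df(assign_chorus)
  j <- merge(a[, intersect(names(a), c("recording_id", "category",
                                       "reliable"))],
             b[, intersect(names(b), c("recording_id", "category",
                                       "reliable"))],
             by = "recording_id", suffixes = c("_stationary", "_chorus"))
  j <- j[j$category_stationary %in% category_levels() &
           j$category_chorus %in% category_levels(), , drop = FALSE]
  if (filter == "reliable")
    j <- j[!is.na(j$reliable_stationary) & j$reliable_stationary &
             !is.na(j$reliable_chorus) & j$reliable_chorus, , drop = FALSE]
  if (!is.null(structures))
    j$structure <- unname(structures[j$recording_id])
  counts <- table(factor(j$category_stationary, category_levels()),
                  factor(j$category_chorus, category_levels()))
  counts <- unclass(counts)
  rs <- rowSums(counts)
  rp <- 100 * counts / ifelse(rs == 0, NA_real_, rs)
  structure(list(counts = counts, row_percent = rp,
                 n_total = sum(counts), joined = j),
            class = "switching_matrix")
}

#' @export
print.switching_matrix <- function(x, ...) {
  cat(sprintf("Switching matrix (stationary rows -> chorus cols), n = %d\n",
              x$n_total))
  print(x$counts)
  invisible(x)
}

#' Mutual information of a switching matrix
#'
#' Plug-in Shannon estimate in bits,
#' `MI = sum p(x,y) log2(p(x,y) / (p(x) p(y)))` over nonzero cells, with no
#' bias correction. A perfectly diagonal equal-count 5-category matrix
#' gives log2(5) = 2.32 bits; independent rows and columns give 0.
#'
#' @param m a [switching_matrix()] or a plain count matrix.
#' @return MI in bits (NA for an empty matrix).
#' @export
mutual_information <- function(m) {
  counts <- if (inherits(m, "switching_matrix")) m$counts else as.matrix(m)
  n <- sum(counts)
  if (n < 1) return(NA_real_)
  p <- counts / n
  px <- rowSums(p); py <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  sum(p[nz] * log2(p[nz] / (px[nz[, 1L]] * py[nz[, 2L]])))
}

#' Percentage of recordings changing category between noises
#'
#' Per category (of the stationary-noise assignment):
#' `100 * (1 - diagonal / row total)`. Per structure: the same fraction
#' computed on that structure's recordings (requires the matrix to have
#' been built with `structures`). Empty groups give NA.
#'
#' @param m a [switching_matrix()].
#' @return List with `by_category` and `by_structure` (named percentage
#'   vectors) and `overall`.
#' @export
switch_percentages <- function(m) {
  stopifnot(inherits(m, "switching_matrix"))
  rs <- rowSums(m$counts)
  by_cat <- 100 * (1 - diag(m$counts) / ifelse(rs == 0, NA_real_, rs))
  names(by_cat) <- rownames(m$counts)
  by_struct <- NULL
  j <- m$joined
  if (!is.null(j$structure) && nrow(j)) {
    sw <- j$category_stationary != j$category_chorus
    by_struct <- vapply(structure_levels(), function(s) {
      sel <- j$structure == s
      if (!any(sel)) NA_real_ else 100 * mean(sw[sel])
    }, numeric(1L))
  }
  overall <- if (m$n_total == 0) NA_real_
  else 100 * (1 - sum(diag(m$counts)) / m$n_total)
  list(by_category = by_cat, by_structure = by_struct, overall = overall)
}
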