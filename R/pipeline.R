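# End-to-end orchestration: simulate -> metrics/selection -> EI ->
# clustering/bootstrap -> switching/MI -> descriptors/classification,
# with per-stage sub-seeds derived from one global seed.

#' Pipeline configuration
#'
#' @param generator a [generator_config()] (ignored when `dataset` given).
#' @param dataset optional pre-built [spike_dataset()].
#' @param n_surrogates Poisson-surrogate replicates per recording.
#' @param n_boot bootstrap replicates per recording and noise (0 disables
#'   the bootstrap; reliable-only outputs are then absent).
#' @param k number of clusters (5 is canonical).
#' @param n_restarts k-means restarts.
#' @param reliable_threshold minimal bootstrap modal count for
#'   reliability (default 95).
#' @param criterion selection criterion, `"b"` (voc AND TFRP significant)
#'   or `"a"` (OR).
#' @param alpha evoked-response significance level.
#' @param n_folds classifier cross-validation folds.
#' @param do_classify run the descriptor/LDA stage.
#' @param combos `"all"` for the full 15-combination sweep or a character
#'   vector of combination ids (e.g. `c("1", "8")`).
#' @param seed global seed; every stage derives its own stream from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            dataset = NULL, n_surrogates = 100L,
                            n_boot = 100L, k = 5L, n_restarts = 50L,
                            reliable_threshold = 95L,
                            criterion = c("b", "a"), alpha = 0.05,
                            n_folds = 5L, do_classify = TRUE,
                            combos = "all", seed = 1L) {
  criterion <- match.arg(criterion)
  stopifnot(n_surrogates >= 2L, n_boot >= 0L, k >= 1L, n_restarts >= 1L,
            n_folds >= 2L)
  cfg <- list(generator = generator, dataset = dataset,
              n_surrogates = as.integer(n_surrogates),
              n_boot = as.integer(n_boot), k = as.integer(k),
              n_restarts = as.integer(n_restarts),
              reliable_threshold = as.integer(reliable_threshold),
              criterion = criterion, alpha = alpha,
              n_folds = as.integer(n_folds), do_classify = do_classify,
              combos = combos, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate (or take the provided dataset); (2) selection
#' features (response significance, TFRP, EI profiles, surrogate
#' thresholds) and recording selection; (3) per-noise k-means
#' categorization with named labels; (4) bootstrap category stability;
#' (5) switching matrices, switch percentages and mutual information (all
#' recordings and, when the bootstrap ran, reliable-only); (6) descriptor
#' extraction and the LDA combination sweep per noise plus the
#' reliable-to-rest generalization. Reruns with the same config are
#' identical.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `noisecat_report` (see its print method).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  dataset <- config$dataset
  if (is.null(dataset)) {
    gen <- config$generator
    gen$seed <- derive_seed(seed, "simulate")
    dataset <- make_dataset(gen)
  }
  protocol <- dataset$protocol
  if (!length(dataset$recordings)) stop("pipeline: empty dataset")

  sel <- select_recordings(dataset, config$criterion, config$alpha,
                           config$n_surrogates, derive_seed(seed, "ei"))
  selected <- sel$selected
  nts <- protocol$noise_types
  clusterings <- list(); assignments <- list()
  boots <- list()
  for (nt in nts) {
    X <- profile_matrix(sel$features[selected], nt)
    if (nrow(X) < config$k) {
      clusterings[[nt]] <- NULL
      next
    }
    cl <- kmeans_profiles(X, config$k, config$n_restarts,
                          derive_seed(seed, "kmeans", nt))
    cl$label_map <- tryCatch(label_clusters(cl$centroids),
                             error = function(e)
                               label_clusters(cl$centroids, named = FALSE))
    clusterings[[nt]] <- cl
    asg <- assign_to_centroids(X, cl$centroids, cl$label_map)
    asg$noise_type <- nt
    asg$reliable <- NA
    asg$bootstrap_mode_count <- NA_integer_
    if (config$n_boot > 0L) {
      bt <- lapply(selected, function(rid)
        bootstrap_stability(dataset$recordings[[rid]], protocol, nt,
                            cl$centroids, cl$label_map, config$n_boot,
                            derive_seed(seed, "boot", nt, rid),
                            config$reliable_threshold))
      names(bt) <- selected
      boots[[nt]] <- bt
      asg$bootstrap_mode_count <- vapply(bt, `[[`, integer(1L),
                                         "bootstrap_mode_count")[
                                           asg$recording_id]
      asg$reliable <- vapply(bt, `[[`, logical(1L),
                             "reliable")[asg$recording_id]
    }
    assignments[[nt]] <- asg
  }

  structures <- vapply(dataset$recordings, `[[`, character(1L),
                       "structure")
  switching <- NULL
  if (all(c("stationary", "chorus") %in% names(assignments))) {
    sw_all <- switching_matrix(assignments$stationary, assignments$chorus,
                               "all", structures)
    switching <- list(
      all = list(matrix = sw_all, mi_bits = mutual_information(sw_all),
                 percentages = switch_percentages(sw_all)))
    if (config$n_boot > 0L) {
      sw_rel <- switching_matrix(assignments$stationary,
                                 assignments$chorus, "reliable",
                                 structures)
      switching$reliable <- list(matrix = sw_rel,
                                 mi_bits = mutual_information(sw_rel),
                                 percentages = switch_percentages(sw_rel))
    }
  }

  classification <- NULL
  if (config$do_classify && length(assignments)) {
    tfrps <- lapply(sel$features, `[[`, "tfrp")
    classification <- list()
    for (nt in names(assignments)) {
      asg <- assignments[[nt]]
      tab <- descriptor_table(dataset, nt, tfrps, asg$recording_id)
      imp <- impute_descriptors(tab)
      keep <- match(imp$table$recording_id, asg$recording_id)
      labels <- asg$category[keep]
      ok_classes <- length(unique(labels)) >= 2L &&
        min(table(labels)) >= config$n_folds
      res <- list()
      if (ok_classes) {
        cv_seed <- derive_seed(seed, "cv", nt)
        res$sweep <- if (identical(config$combos, "all"))
          combo_sweep(imp$table, labels, default_cost_matrix(),
                      config$n_folds, cv_seed)
        else
          lapply(combo_enumeration()[config$combos], function(combo)
            train_eval_lda(imp$table, labels, combo,
                           default_cost_matrix(), config$n_folds,
                           cv_seed))
        rel <- !is.na(imp$table$recording_id) &
          imp$table$recording_id %in%
            asg$recording_id[which(asg$reliable)]
        if (config$n_boot > 0L && sum(rel) >= 10L && sum(!rel) >= 5L &&
            length(unique(labels[rel])) == length(unique(labels))) {
          res$generalization <- tryCatch(
            generalize_lda(imp$table[rel, ], labels[rel],
                           imp$table[!rel, ], labels[!rel]),
            error = function(e) NULL)
        }
      }
      res$excluded <- imp$excluded
      classification[[nt]] <- res
    }
  }

  report <- list(config = config, dataset = dataset, selection = sel,
                 clusterings = clusterings, assignments = assignments,
                 bootstrap = boots, switching = switching,
                 classification = classification,
                 category_by_structure = category_structure_table(
                   assignments, structures),
                 planted_recovery = planted_recovery(dataset, assignments))
  class(report) <- "noisecat_report"
  report
}

category_structure_table <- function(assignments, structures) {
  if (!length(assignments)) return(NULL)
  out <- list()
  for (nt in names(assignments)) {
    a <- assignments[[nt]]
    tab <- table(factor(structures[a$recording_id], structure_levels()),
                 factor(a$category, category_levels()))
    out[[nt]] <- unclass(tab)
  }
  out
}

planted_recovery <- function(dataset, assignments) {
  if (!length(assignments)) return(NULL)
  out <- list()
  for (nt in names(assignments)) {
    a <- assignments[[nt]]
    planted <- vapply(a$recording_id, function(rid)
      planted_or_na(dataset$recordings[[rid]], nt), character(1L))
    ok <- !is.na(planted)
    out[[nt]] <- if (!any(ok)) NA_real_
                 else mean(a$category[ok] == planted[ok])
  }
  out
}

#' @export
print.noisecat_report <- function(x, ...) {
  cat("noisecat pipeline report\n")
  cat(sprintf("  recordings: %d; selected: %d\n",
              length(x$dataset$recordings),
              length(x$selection$selected)))
  for (nt in names(x$clusterings)) {
    cl <- x$clusterings[[nt]]
    if (is.null(cl)) next
    cat(sprintf("  %s: k = %d, MSE = %.4f\n", nt, cl$k, cl$mse))
  }
  if (!is.null(x$switching)) {
    cat(sprintf("  MI (all recordings): %.3f bits\n",
                x$switching$all$mi_bits))
    if (!is.null(x$switching$reliable))
      cat(sprintf("  MI (reliable only): %.3f bits\n",
                  x$switching$reliable$mi_bits))
  }
  if (!is.null(x$planted_recovery)) {
    for (nt in names(x$planted_recovery))
      if (!is.na(x$planted_recovery[[nt]]))
        cat(sprintf("  planted-category recovery (%s): %.1f%%\n", nt,
                    100 * x$planted_recovery[[nt]]))
  }
  if (!is.null(x$classification)) {
    for (nt in names(x$classification)) {
      sw <- x$classification[[nt]]$sweep
      if (!is.null(sw))
        cat(sprintf("  LDA accuracy, all descriptors (%s): %.2f%%\n", nt,
                    sw[["1"]]$cv_accuracy_percent))
    }
  }
  invisible(x)
}

#' Write the report's tabular outputs
#'
#' Emits `selection.csv`, `ei.csv`, `categories.csv`, `switching.csv`,
#' `mi.json`, `classifier_report.json` and a run `manifest.json` under
#' `dir`.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(report$selection$counts, file.path(dir, "selection.csv"),
            row.names = FALSE)
  ei_rows <- list()
  for (f in report$selection$features) {
    thr <- f$thresholds
    for (nt in rownames(f$profile$ei)) for (sl in colnames(f$profile$ei)) {
      ei_rows[[length(ei_rows) + 1L]] <- data.frame(
        recording_id = f$recording_id, noise_type = nt, snr = sl,
        ei = f$profile$ei[nt, sl], threshold = thr[nt, sl],
        significant = isTRUE(f$profile$ei[nt, sl] > thr[nt, sl]))
    }
  }
  write.csv(do.call(rbind, ei_rows), file.path(dir, "ei.csv"),
            row.names = FALSE)
  if (length(report$assignments))
    write.csv(do.call(rbind, report$assignments),
              file.path(dir, "categories.csv"), row.names = FALSE)
  if (!is.null(report$switching)) {
    write.csv(as.data.frame(report$switching$all$matrix$counts),
              file.path(dir, "switching.csv"), row.names = TRUE)
    mi <- list(all = report$switching$all$mi_bits)
    if (!is.null(report$switching$reliable))
      mi$reliable <- report$switching$reliable$mi_bits
    jsonlite::write_json(mi, file.path(dir, "mi.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$classification)) {
    out <- lapply(report$classification, function(cl) {
      if (is.null(cl$sweep)) return(NULL)
      lapply(cl$sweep, function(r)
        list(combination = r$combination,
             accuracy_percent = r$cv_accuracy_percent))
    })
    jsonlite::write_json(out, file.path(dir, "classifier_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(seed = report$config$seed,
                   n_recordings = length(report$dataset$recordings),
                   n_selected = length(report$selection$selected),
                   k = report$config$k,
                   n_surrogates = report$config$n_surrogates,
                   n_boot = report$config$n_boot)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
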