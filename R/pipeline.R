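#' Configuration of the full methodological-permutation experiment
#'
#' The experiment crosses spatial smoothing (on/off), the number of
#' memory-recall repetitions used for training (1-5), and the feature
#' mask (whole GM, the 8 PTSD-neurocircuitry ROIs, GM minus those ROIs,
#' and 10 random ROI sets).
#'
#' @param smoothing Character subset of `c("on", "off")`.
#' @param k_runs_values Integer subset of 1..5.
#' @param masks Character subset of `c("gm", "ptsd_rois", "gm_minus_rois",
#'   "random_rois")`.
#' @param svm,cv,group_stats,smoothing_cfg Component configurations.
#' @param n_random_sets Random ROI sets for the `random_rois` cell.
#' @param seed Global seed; all per-component seeds derive from it.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(smoothing = c("off", "on"),
                              k_runs_values = 1:5,
                              masks = c("gm", "ptsd_rois", "gm_minus_rois",
                                        "random_rois"),
                              svm = svm_config(), cv = cv_config(),
                              group_stats = group_stats_config(),
                              smoothing_cfg = smoothing_config(),
                              n_random_sets = 10, seed = 1) {
  smoothing <- match.arg(smoothing, c("off", "on"), several.ok = TRUE)
  masks <- match.arg(masks, c("gm", "ptsd_rois", "gm_minus_rois",
                              "random_rois"), several.ok = TRUE)
  stopifnot(length(k_runs_values) >= 1, all(k_runs_values %in% 1:5))
  structure(list(smoothing = smoothing, k_runs_values = k_runs_values,
                 masks = masks, svm = svm, cv = cv,
                 group_stats = group_stats, smoothing_cfg = smoothing_cfg,
                 n_random_sets = n_random_sets, seed = seed),
            class = "experiment_config")
}

# Build the four mask variants for one subject.
subject_mask_variants <- function(subject, cfg) {
  grid <- subject$grid
  gm <- subject$gm_mask
  rois <- suppressWarnings(ptsd_roi_set(grid, gm))
  rand <- random_roi_sets(grid, gm, n_sets = cfg$n_random_sets,
                          seed = as.integer(derive_seeds(cfg$seed, 1, 3L)))
  list(gm = gm,
       ptsd_rois = if (mask_size(mask_union(rois))) mask_union(rois) else NULL,
       gm_minus_rois = mask_complement(gm, rois),
       random_sets = rand,
       roi_set = rois)
}

#' Run the full permutation grid for one subject
#'
#' Preprocesses the subject once per smoothing arm, then computes the
#' cross-validated decoding result for every (smoothing, k_runs, mask)
#' cell. The `random_rois` cell reports the median accuracy over the
#' random sets; per-cell failures are recorded in the table and do not
#' abort the run.
#'
#' @param subject A raw `subject_dataset`.
#' @param cfg An [experiment_config()].
#' @param subject_id Identifier recorded in the results table.
#' @return List with `results` (long-format data frame: subject,
#'   smoothing, k_runs, mask, accuracy, sensitivity, specificity,
#'   n_features, seed, error) and `weight_maps` (named list of median
#'   weight maps for the non-random cells).
#' @export
run_subject <- function(subject, cfg = experiment_config(), subject_id = 1) {
  rows <- list(); wmaps <- list()
  for (sm in cfg$smoothing) {
    pp <- preprocess_subject(subject,
                             smoothing = if (sm == "on") cfg$smoothing_cfg
                                         else FALSE)
    mv <- subject_mask_variants(pp, cfg)
    for (k in cfg$k_runs_values) for (mk in cfg$masks) {
      cell <- tryCatch({
        if (mk == "random_rois") {
          acc <- random_roi_accuracy(pp, mv$random_sets, k_runs = k,
                                     svm = cfg$svm, cv = cfg$cv)
          list(accuracy = as.numeric(acc), sensitivity = NA_real_,
               specificity = NA_real_,
               n_features = mask_size(mask_union(mv$random_sets[[1]])))
        } else {
          mask <- mv[[mk]]
          if (is.null(mask) || !mask_size(mask))
            stop("mask '", mk, "' empty on this grid")
          fit <- run_cv(build_features(pp, mask, k), svm = cfg$svm,
                        cv = cfg$cv)
          wmaps[[sprintf("sm-%s_k-%d_mask-%s", sm, k, mk)]] <- fit$weights
          list(accuracy = fit$accuracy, sensitivity = fit$sensitivity,
               specificity = fit$specificity, n_features = fit$n_features)
        }
      }, error = function(e) list(accuracy = NA_real_,
                                  sensitivity = NA_real_,
                                  specificity = NA_real_,
                                  n_features = NA_integer_,
                                  error = conditionMessage(e)))
      rows[[length(rows) + 1]] <- data.frame(
        subject = subject_id, smoothing = sm, k_runs = k, mask = mk,
        accuracy = cell$accuracy, sensitivity = cell$sensitivity,
        specificity = cell$specificity, n_features = cell$n_features,
        seed = cfg$seed, error = cell$error %||% NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  list(results = do.call(rbind, rows), weight_maps = wmaps)
}

#' Run the permutation experiment over a cohort
#'
#' @param cohort List of `(subject, truth)` pairs from
#'   [generate_cohort()], or a list of `subject_dataset`s.
#' @param cfg An [experiment_config()].
#' @return List with the combined `results` table and per-subject
#'   `weight_maps`.
#' @export
run_cohort <- function(cohort, cfg = experiment_config()) {
  res <- list(); maps <- list()
  for (i in seq_along(cohort)) {
    subj <- if (!is.null(cohort[[i]]$subject)) cohort[[i]]$subject
            else cohort[[i]]
    out <- run_subject(subj, cfg, subject_id = i)
    res[[i]] <- out$results
    maps[[i]] <- out$weight_maps
  }
  list(results = do.call(rbind, res), weight_maps = maps)
}

#' Paired comparison of two experiment cells across subjects
#'
#' Tests whether cross-validated accuracy differs between two cells of
#' the permutation grid (e.g. whole-GM vs PTSD-ROI masks) with a paired
#' test across subjects.
#'
#' @param results Long-format results table from [run_cohort()].
#' @param cell_a,cell_b Named lists selecting a cell, e.g.
#'   `list(smoothing = "off", k_runs = 3, mask = "gm")`.
#' @param test `"paired_t"` (default) or `"wilcoxon"`.
#' @return List with `statistic`, `p_value`, `mean_a`, `mean_b`, `n`.
#' @export
compare_cells <- function(results, cell_a, cell_b,
                          test = c("paired_t", "wilcoxon")) {
  test <- match.arg(test)
  pick <- function(cell) {
    sel <- rep(TRUE, nrow(results))
    for (nm in names(cell)) sel <- sel & results[[nm]] == cell[[nm]]
    sub <- results[sel, c("subject", "accuracy")]
    if (any(duplicated(sub$subject))) stop("cell selects multiple rows per subject")
    sub[order(sub$subject), ]
  }
  a <- pick(cell_a); b <- pick(cell_b)
  if (!identical(a$subject, b$subject)) stop("mismatched subject sets")
  d <- a$accuracy - b$accuracy
  if (all(d == 0)) return(list(statistic = 0, p_value = 1,
                               mean_a = mean(a$accuracy),
                               mean_b = mean(b$accuracy), n = nrow(a)))
  ht <- if (test == "paired_t") stats::t.test(a$accuracy, b$accuracy,
                                              paired = TRUE)
        else suppressWarnings(stats::wilcox.test(a$accuracy, b$accuracy,
                                                 paired = TRUE,
                                                 exact = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       mean_a = mean(a$accuracy), mean_b = mean(b$accuracy), n = nrow(a))
}
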