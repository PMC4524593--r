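#' Fisher r-to-z transform
#'
#' `z = arctanh(r)`, variance-stabilizing and normalizing for correlation
#' coefficients. Inputs with `|r| >= 1` are out of domain and raise an
#' error; see [map_similarity()] for the capped variant used on maps.
#'
#' @param r Correlation coefficient(s) in (-1, 1).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("fisher_z is defined for |r| < 1")
  atanh(r)
}

# cap used when |r| hits 1 exactly: atanh(1 - 1e-16) order of magnitude
Z_CAP <- 18.7

#' Spatial similarity of two weight maps
#'
#' Fisher-z-transformed Pearson correlation between two weight vectors on
#' a common mask. Perfect correlations (|r| = 1, e.g. a map against
#' itself) are reported as the documented sentinel +/-18.7 rather than
#' +/-Inf so similarity tables stay numeric.
#'
#' @param map_a,map_b Numeric vectors of equal length >= 3 with nonzero
#'   variance.
#' @return Fisher-z similarity.
#' @export
map_similarity <- function(map_a, map_b) {
  stopifnot(length(map_a) == length(map_b), length(map_a) >= 3)
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0)
    stop("degenerate map: zero variance")
  r <- stats::cor(map_a, map_b)
  if (abs(r) >= 1) return(sign(r) * Z_CAP)
  atanh(r)
}

#' Cross-model weight-map similarity matrix
#'
#' Trains the k-run model for each `k` (first `k` repetitions of each
#' condition) on a common mask and computes the Fisher-z spatial
#' correlation between every pair of median weight maps.
#'
#' @param subject A preprocessed `subject_dataset` with at least
#'   `max(k_values)` repetitions per condition.
#' @param mask Feature mask (default: the subject's GM mask, the
#'   convention for whole-brain weight maps).
#' @param k_values Training-set sizes to compare (default 1:5).
#' @param svm,cv Configurations as in [run_cv()].
#' @return Object of class `similarity_matrix`: symmetric k x k matrix of
#'   Fisher-z values with NA diagonal; attribute `weight_maps` holds the
#'   per-k median weight maps and attribute `accuracies` the per-k median
#'   CV accuracies (the models are fitted anyway, so both come for free).
#' @export
cross_model_similarity <- function(subject, mask = NULL, k_values = 1:5,
                                   svm = svm_config(), cv = cv_config()) {
  if (is.null(mask)) mask <- subject$gm_mask
  fits <- lapply(k_values, function(k)
    run_cv(build_features(subject, mask, k), svm = svm, cv = cv))
  maps <- lapply(fits, `[[`, "weights")
  n <- length(k_values)
  S <- matrix(NA_real_, n, n,
              dimnames = list(paste0("k", k_values), paste0("k", k_values)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    S[i, j] <- S[j, i] <- map_similarity(maps[[i]], maps[[j]])
  structure(S, class = c("similarity_matrix", "matrix"),
            k_values = k_values, weight_maps = maps,
            accuracies = vapply(fits, `[[`, numeric(1), "accuracy"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix (Fisher-z spatial correlations):\n")
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  print(round(m, 3))
  invisible(x)
}

#' Median similarity of one model with all others
#'
#' For model `k`, the median of row k's off-diagonal Fisher-z entries —
#' how reproducible that model's weight map is across all alternative
#' training-set sizes.
#'
#' @param matrix A `similarity_matrix` (or plain symmetric matrix with NA
#'   diagonal).
#' @param k Row index (position within the matrix's `k_values`).
#' @return Median Fisher-z similarity.
#' @export
median_cross_model_similarity <- function(matrix, k) {
  stopifnot(k >= 1, k <= nrow(matrix))
  stats::median(matrix[k, -k], na.rm = TRUE)
}

#' Compare model reproducibility across subjects
#'
#' Paired comparison of the per-subject median cross-model similarities
#' ([median_cross_model_similarity()]) between training-set sizes `k_a`
#' and `k_b`. Wilcoxon signed-rank by default (robust at cohort scale of
#' ~16); a paired t-test is available.
#'
#' @param cohort_matrices List of per-subject `similarity_matrix` objects.
#' @param k_a,k_b Model row indices to compare.
#' @param test `"wilcoxon"` (default) or `"paired_t"`.
#' @return List with `statistic`, `p_value`, `median_a`, `median_b` and
#'   the per-subject values.
#' @export
compare_model_similarity_across_subjects <- function(cohort_matrices, k_a, k_b,
                                                     test = c("wilcoxon",
                                                              "paired_t")) {
  test <- match.arg(test)
  stopifnot(length(cohort_matrices) >= 5)
  a <- vapply(cohort_matrices, median_cross_model_similarity, numeric(1), k = k_a)
  b <- vapply(cohort_matrices, median_cross_model_similarity, numeric(1), k = k_b)
  d <- a - b
  if (all(d == 0)) {
    stat <- 0; p <- 1
  } else if (test == "wilcoxon") {
    # signed-rank statistic recentred so its sign tracks the direction
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = FALSE, correct = FALSE))
    nz <- sum(d != 0)
    stat <- unname(ht$statistic) - nz * (nz + 1) / 4
    p <- ht$p.value
  } else {
    ht <- stats::t.test(a, b, paired = TRUE)
    stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  list(statistic = stat, p_value = p,
       median_a = stats::median(a), median_b = stats::median(b),
       per_subject_a = a, per_subject_b = b, test = test)
}

#' Write per-subject similarity matrices and a cohort summary
#'
#' @param cohort_matrices List of `similarity_matrix` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the cohort summary data frame (per-model median
#'   similarity averaged across subjects).
#' @export
write_similarity_tables <- function(cohort_matrices, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort_matrices)) {
    utils::write.table(round(unclass(cohort_matrices[[i]]), 6),
                       file.path(dir, sprintf("similarity_sub-%02d.tsv", i)),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  kk <- seq_len(nrow(cohort_matrices[[1]]))
  med <- sapply(kk, function(k)
    mean(vapply(cohort_matrices, median_cross_model_similarity,
                numeric(1), k = k)))
  summary <- data.frame(k = kk, mean_median_similarity = med)
  utils::write.table(summary, file.path(dir, "similarity_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summary)
}
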