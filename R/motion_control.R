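#' Framewise displacement
#'
#' Per-TR head motion summarized as the sum over the 6 rigid-body
#' parameters of the absolute temporal difference,
#' `FD_t = sum_j |R_tj - R_(t-1)j|`, with `FD_1 = 0` (no predecessor).
#' Parameters enter in their native units (mm and degrees); no lever-arm
#' conversion is applied.
#'
#' @param motion T x 6 motion-parameter matrix.
#' @return Nonnegative numeric vector of length T.
#' @export
framewise_displacement <- function(motion) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6, nrow(motion) >= 2)
  c(0, rowSums(abs(diff(motion))))
}

#' High/low-motion labels from a median split
#'
#' TRs with FD above the median are labelled `"high"`, below `"low"`;
#' ties at the exact median go to `"low"` (documented rule, so the split
#' is deterministic). When labelling a multi-run timeseries, concatenate
#' the FD across runs before calling (the split is over the pooled
#' distribution).
#'
#' @param fd Per-TR framewise displacement values (length >= 2).
#' @return Factor with levels `c("high", "low")`.
#' @export
median_split_labels <- function(fd) {
  stopifnot(length(fd) >= 2)
  if (max(fd) == min(fd)) stop("degenerate split: all FD values equal")
  med <- stats::median(fd)
  factor(ifelse(fd > med, "high", "low"), levels = c("high", "low"))
}

#' Motion-control classifier
#'
#' Rebuilds the condition classifier's exact feature matrix (same mask,
#' same runs, same preprocessing, same CV machinery) but replaces the
#' trauma/neutral labels with high/low-motion labels from a median split
#' of the framewise displacement concatenated across the included runs.
#' Decoding accuracy near chance here shows that condition decoding is
#' not driven by motion artifact.
#'
#' @param subject A preprocessed `subject_dataset`.
#' @param gm_mask Feature mask (default: the subject's GM mask).
#' @param k_runs Repetitions per condition included (default 3, matching
#'   the reference condition model).
#' @param svm,cv Configurations as in [run_cv()].
#' @param labels_override Internal: replacement label factor (used to
#'   verify that this code path is identical to condition decoding).
#' @return An `mvpa_cv` fit with positive class `"high"`.
#' @export
motion_control_cv <- function(subject, gm_mask = NULL, k_runs = 3,
                              svm = svm_config(), cv = cv_config(),
                              labels_override = NULL) {
  if (is.null(gm_mask)) gm_mask <- subject$gm_mask
  feats <- build_features(subject, gm_mask, k_runs)
  if (is.null(labels_override)) {
    reps <- vapply(subject$runs, `[[`, 1L, "repetition")
    keep <- which(reps <= k_runs)
    fd <- unlist(lapply(keep, function(i)
      framewise_displacement(subject$runs[[i]]$motion)))
    feats$labels <- median_split_labels(fd)
  } else {
    feats$labels <- labels_override
  }
  pos <- levels(feats$labels)[1]
  run_cv(feats, svm = svm_config(svm$C, svm$gamma, positive_class = pos),
         cv = cv)
}
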