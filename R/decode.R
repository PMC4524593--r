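#' SVM configuration for TR-level decoding
#'
#' Radial-basis-function kernel with `C = 100` by default, matching the
#' common choice for decoding single fMRI volumes. `gamma = NULL` uses the
#' feature-count rule `1/P`.
#'
#' @param C Soft-margin cost (default 100).
#' @param gamma RBF width, or `NULL` for `1/P`.
#' @param positive_class Label treated as the positive class for the
#'   decision function, sensitivity and weight-map sign (default
#'   `"trauma"`).
#' @return Object of class `svm_config`.
#' @export
svm_config <- function(C = 100, gamma = NULL, positive_class = "trauma") {
  stopifnot(C > 0, is.null(gamma) || gamma > 0)
  structure(list(C = C, gamma = gamma, positive_class = positive_class),
            class = "svm_config")
}

#' Cross-validation configuration
#'
#' @param n_folds Number of folds (default 10).
#' @param seed Seed for the random TR partition.
#' @param contiguous Assign contiguous blocks of rows to folds instead of
#'   a random TR partition (sensitivity-analysis mode; the random
#'   partition ignores temporal autocorrelation, as is standard for this
#'   design).
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10, seed = 1, contiguous = FALSE) {
  stopifnot(n_folds >= 2)
  structure(list(n_folds = as.integer(n_folds), seed = seed,
                 contiguous = contiguous), class = "cv_config")
}

#' Random fold assignment partitioning rows
#'
#' Assigns each row to exactly one of `n_folds` folds with fold sizes
#' differing by at most one; the assignment is a uniformly random
#' partition, deterministic for a given seed.
#'
#' @param n_rows Number of rows.
#' @param cfg A [cv_config()].
#' @return Integer vector of fold ids (1..n_folds) of length `n_rows`.
#' @examples
#' table(cv_split(860, cv_config(10, seed = 1)))  # ten folds of 86
#' @export
cv_split <- function(n_rows, cfg) {
  stopifnot(n_rows >= cfg$n_folds)
  base <- rep(seq_len(cfg$n_folds), length.out = n_rows)
  if (cfg$contiguous) return(sort(base))
  with_preserved_seed(cfg$seed, sample(base))
}

#' Build the TR-by-voxel feature matrix for a subject
#'
#' Rows are all TRs of the first `k_runs` repetitions of each condition,
#' in the subject's temporal run order; columns are the voxels of `mask`.
#' Features are z-scored per voxel over the included rows (the statistics
#' of the full included timeseries; set `zscore = "train"` downstream via
#' [run_cv()]'s `leakage_safe` option for a train-fold-only variant).
#' Zero-variance columns are set to zero rather than producing NaN.
#'
#' @param subject A (preprocessed) `subject_dataset`.
#' @param mask Feature mask.
#' @param k_runs Number of repetitions per condition to include.
#' @param zscore `"all"` (default) or `"none"`.
#' @return Object of class `feature_matrix`: list with `x` (N x P),
#'   `labels` (factor), `run_id`, `repetition`, `voxel_lin` (linear voxel
#'   indices mapping columns back to the grid), `grid`.
#' @export
build_features <- function(subject, mask, k_runs = 3, zscore = "all") {
  reps <- vapply(subject$runs, `[[`, 1L, "repetition")
  stopifnot(k_runs >= 1, k_runs <= max(reps))
  if (!any(mask)) stop("feature mask is empty")
  keep <- which(reps <= k_runs)
  lin <- which(mask)
  xs <- list(); labs <- character(0); rid <- integer(0); rp <- integer(0)
  for (i in keep) {
    run <- subject$runs[[i]]
    d <- dim(run$data)
    xs[[length(xs) + 1]] <-
      t(matrix(run$data, prod(d[1:3]), d[4])[lin, , drop = FALSE])
    labs <- c(labs, rep(run$condition, d[4]))
    rid <- c(rid, rep(i, d[4]))
    rp <- c(rp, rep(run$repetition, d[4]))
  }
  x <- do.call(rbind, xs)
  if (identical(zscore, "all")) {
    mu <- colMeans(x)
    sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))
    zero <- sdv <= 0
    sdv[zero] <- 1
    x <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    x[, zero] <- 0
  }
  lv <- sort(unique(labs), decreasing = TRUE)  # trauma before neutral
  structure(list(x = x, labels = factor(labs, levels = lv),
                 run_id = rid, repetition = rp, voxel_lin = lin,
                 grid = subject$grid),
            class = "feature_matrix")
}

# Fit the RBF SVM and extract the per-voxel weight vector as the
# support-vector-coefficient-weighted sum of support vectors (the linear
# pre-image of the dual solution). The sign convention is normalized so
# that positive decision values correspond to `positive_class`.
train_and_weights <- function(x, y, cfg) {
  y <- droplevels(y)
  if (nlevels(y) < 2) stop("degenerate fold: single-class training set")
  gamma <- cfg$gamma %||% (1 / ncol(x))
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    cost = cfg$C, gamma = gamma, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  # libsvm's positive class is the first encountered in the data
  first_class <- levels(y)[fit$labels[1]]
  if (!identical(first_class, cfg$positive_class)) w <- -w
  list(model = fit, weights = w)
}

#' Cross-validated decoding of a feature matrix
#'
#' Iterates the folds of a random TR partition, training the RBF-kernel
#' SVM on the held-in folds and testing on the held-out fold. Accuracy is
#' the median fold accuracy; sensitivity (proportion of positive-class
#' rows correctly classified) and specificity are pooled over the
#' held-out predictions of all folds; the feature-weight map is each
#' voxel's median weight across folds.
#'
#' @param features A [build_features()] result.
#' @param svm A [svm_config()].
#' @param cv A [cv_config()].
#' @param keep_model Also fit a model on all rows, enabling
#'   [predict.mvpa_cv()] (default FALSE).
#' @param leakage_safe Re-z-score each training fold with its own
#'   statistics (and apply them to the test fold) instead of relying on
#'   the full-timeseries z-scoring of the feature matrix.
#' @return Object of class `mvpa_cv`.
#' @export
run_cv <- function(features, svm = svm_config(), cv = cv_config(),
                   keep_model = FALSE, leakage_safe = FALSE) {
  stopifnot(inherits(features, "feature_matrix"))
  x <- features$x; y <- features$labels
  if (nlevels(y) != 2) stop("need exactly two classes")
  pos <- svm$positive_class
  if (!pos %in% levels(y)) pos <- levels(y)[1]
  fold <- cv_split(nrow(x), cv)
  k <- cv$n_folds
  fold_acc <- numeric(k)
  W <- matrix(NA_real_, k, ncol(x))
  pred <- factor(rep(levels(y)[1], nrow(x)), levels = levels(y))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    if (leakage_safe) {
      mu <- colMeans(xtr)
      sdv <- sqrt(colMeans(sweep(xtr, 2, mu)^2)); sdv[sdv <= 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    }
    fw <- tryCatch(train_and_weights(xtr, y[tr],
                                     svm_config(svm$C, svm$gamma, pos)),
                   error = function(e)
                     stop("fold ", f, ": ", conditionMessage(e)))
    p <- stats::predict(fw$model, xte)
    pred[te] <- as.character(p)
    fold_acc[f] <- mean(p == y[te])
    W[f, ] <- fw$weights
  }
  wmap <- apply(W, 2, stats::median)
  is_pos <- y == pos
  res <- structure(list(
    fold_accuracy = fold_acc,
    accuracy = stats::median(fold_acc),
    sensitivity = mean(pred[is_pos] == y[is_pos]),
    specificity = mean(pred[!is_pos] == y[!is_pos]),
    weights = wmap,
    fold_weights = W,
    predictions = pred,
    labels = y,
    positive_class = pos,
    n_features = ncol(x),
    voxel_lin = features$voxel_lin,
    grid = features$grid,
    svm = svm, cv = cv,
    model = NULL), class = "mvpa_cv")
  if (keep_model)
    res$model <- train_and_weights(x, y, svm_config(svm$C, svm$gamma, pos))
  res
}

#' Decode a subject: preprocess, mask, cross-validate
#'
#' The package's central fitting function: takes a raw or preprocessed
#' subject, preprocesses if needed, builds the TR-by-voxel feature matrix
#' over `mask` from the first `k_runs` repetitions of each condition, and
#' runs cross-validated RBF-SVM classification.
#'
#' @param subject A `subject_dataset`.
#' @param mask Feature mask (default: the subject's GM mask).
#' @param k_runs Repetitions per condition used for training (default 3).
#' @param smoothing A [smoothing_config()] or `FALSE` (default), applied
#'   only when the subject is not yet preprocessed.
#' @param svm A [svm_config()].
#' @param cv A [cv_config()].
#' @param keep_model Keep a full-data model for [predict.mvpa_cv()]
#'   (default TRUE).
#' @param ... Passed to [run_cv()].
#' @return An `mvpa_cv` object; see [print.mvpa_cv()], [coef.mvpa_cv()].
#' @examples
#' \donttest{
#' sd <- generate_subject(sim_config(grid_dims = c(12, 12, 12),
#'                                   n_signal_voxels = 100,
#'                                   trs_per_run = 30, seed = 2))
#' fit <- mvpa_decode(sd$subject, k_runs = 2, keep_model = FALSE)
#' fit
#' }
#' @export
mvpa_decode <- function(subject, mask = NULL, k_runs = 3, smoothing = FALSE,
                        svm = svm_config(), cv = cv_config(),
                        keep_model = TRUE, ...) {
  if (!isTRUE(attr(subject, "preprocessed")))
    subject <- preprocess_subject(subject, smoothing = smoothing)
  if (is.null(mask)) mask <- subject$gm_mask
  run_cv(build_features(subject, mask, k_runs), svm = svm, cv = cv,
         keep_model = keep_model, ...)
}

#' @export
print.mvpa_cv <- function(x, ...) {
  cat(sprintf("mvpa_cv: %d-fold CV, %d features, positive class '%s'\n",
              length(x$fold_accuracy), x$n_features, x$positive_class))
  cat(sprintf("  accuracy (median fold): %.3f\n", x$accuracy))
  cat(sprintf("  sensitivity %.3f / specificity %.3f (pooled)\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
summary.mvpa_cv <- function(object, ...) {
  structure(list(fit = object,
                 fold_range = range(object$fold_accuracy),
                 weight_quartiles = stats::quantile(object$weights,
                                                    c(.25, .5, .75))),
            class = "summary.mvpa_cv")
}

#' @export
print.summary.mvpa_cv <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  fold accuracy range: [%.3f, %.3f]\n",
              x$fold_range[1], x$fold_range[2]))
  cat("  weight quartiles:\n")
  print(signif(x$weight_quartiles, 3))
  invisible(x)
}

#' Extract the median feature-weight map
#'
#' The per-voxel median across folds of the SVM weight vector. For an RBF
#' kernel these are not primal weights: they are the linear pre-image of
#' the dual solution (the support-vector-coefficient-weighted sum of
#' support vectors), the quantity conventionally reported as the "feature
#' weight map" of a nonlinear SVM; interpret with that caveat.
#'
#' @param object An `mvpa_cv` fit.
#' @param as_volume Return a 3-D array on the fit's grid (NA outside the
#'   mask) instead of a vector.
#' @param ... Unused.
#' @return Numeric vector of length `n_features`, or a 3-D array.
#' @export
coef.mvpa_cv <- function(object, as_volume = FALSE, ...) {
  if (!as_volume) return(object$weights)
  vol <- array(NA_real_, object$grid$dims)
  vol[object$voxel_lin] <- object$weights
  vol
}

#' Classify new feature rows
#'
#' Requires the fit to have been run with `keep_model = TRUE` (a model
#' trained on all rows is then available).
#'
#' @param object An `mvpa_cv` fit.
#' @param newdata N x P matrix on the same features (same mask, same
#'   scaling) or a `feature_matrix`.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.mvpa_cv <- function(object, newdata, ...) {
  if (is.null(object$model))
    stop("fit was run with keep_model = FALSE; refit with keep_model = TRUE")
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$x
  stats::predict(object$model$model, newdata)
}

#' Held-out residuals of the cross-validated classifier
#'
#' Misclassification indicators (0 = correct, 1 = error) for every row
#' under its held-out fold prediction.
#'
#' @param object An `mvpa_cv` fit.
#' @param ... Unused.
#' @return Numeric 0/1 vector.
#' @export
residuals.mvpa_cv <- function(object, ...) {
  as.numeric(object$predictions != object$labels)
}

#' Plot fold accuracies of a cross-validated fit
#'
#' @param x An `mvpa_cv` fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.mvpa_cv <- function(x, ...) {
  graphics::barplot(x$fold_accuracy, names.arg = seq_along(x$fold_accuracy),
                    xlab = "fold", ylab = "accuracy", ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}

#' Median decoding accuracy over random ROI sets
#'
#' Runs the cross-validated classifier once per random ROI set (features
#' restricted to the union of that set's spheres) and returns the median
#' of the per-set median accuracies.
#'
#' @param subject A preprocessed `subject_dataset`.
#' @param random_sets List of `mask_set`s from [random_roi_sets()].
#' @param k_runs Repetitions per condition (default 3).
#' @param svm,cv Configurations as in [run_cv()].
#' @return Median accuracy, with attribute `per_set` (all per-set
#'   accuracies).
#' @export
random_roi_accuracy <- function(subject, random_sets, k_runs = 3,
                                svm = svm_config(), cv = cv_config()) {
  stopifnot(length(random_sets) >= 1)
  acc <- vapply(random_sets, function(s) {
    run_cv(build_features(subject, mask_union(s), k_runs),
           svm = svm, cv = cv)$accuracy
  }, numeric(1))
  structure(stats::median(acc), per_set = acc)
}
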