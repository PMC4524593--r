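test_that("cv_split partitions rows into near-equal random folds, deterministically", {
  f <- cv_split(860, cv_config(10, seed = 1))
  expect_length(f, 860)
  expect_true(all(table(f) == 86))
  expect_identical(f, cv_split(860, cv_config(10, seed = 1)))
  expect_false(identical(f, cv_split(860, cv_config(10, seed = 2))))
  f2 <- cv_split(103, cv_config(10, seed = 3))
  expect_true(all(table(f2) %in% c(10, 11)))
  expect_equal(sum(table(f2)), 103)
  f3 <- cv_split(100, cv_config(10, seed = 4))
  expect_true(all(table(f3) == 10))
  # contiguous mode yields ordered blocks
  fc <- cv_split(20, cv_config(4, contiguous = TRUE))
  expect_true(all(diff(fc) >= 0))
})

test_that("feature matrices have the right shape, z-scoring and metadata", {
  sub <- cached_subject()
  gm <- sub$pp$gm_mask
  fe <- build_features(sub$pp, gm, k_runs = 3)
  expect_equal(nrow(fe$x), 3 * 2 * 90)
  expect_equal(ncol(fe$x), mask_size(gm))
  expect_true(all(is.finite(fe$x)))
  expect_lt(max(abs(colMeans(fe$x))), 1e-10)
  expect_lt(max(abs(sqrt(colMeans(fe$x^2)) - 1)), 1e-10)
  expect_equal(levels(fe$labels), c("trauma", "neutral"))
  expect_equal(as.vector(table(fe$labels)), c(270, 270))
  expect_true(all(fe$repetition <= 3))
  fe1 <- build_features(sub$pp, gm, k_runs = 1)
  expect_equal(nrow(fe1$x), 180)
  expect_error(build_features(sub$pp, empty_mask(sub$pp$grid), 3),
               "empty")
})

test_that("the SVM separates separable classes and weights flip with labels", {
  set.seed(6)
  x <- matrix(rnorm(80 * 12), 80, 12)
  y <- factor(rep(c("trauma", "neutral"), each = 40),
              levels = c("trauma", "neutral"))
  x[y == "trauma", 1] <- x[y == "trauma", 1] + 10
  fw <- boldmvpa:::train_and_weights(x, y, svm_config())
  expect_true(all(predict(fw$model, x) == y))
  expect_length(fw$weights, 12)
  y_flip <- factor(ifelse(y == "trauma", "neutral", "trauma"),
                   levels = c("trauma", "neutral"))
  fw_flip <- boldmvpa:::train_and_weights(x, y_flip, svm_config())
  expect_equal(fw_flip$weights, -fw$weights, tolerance = 1e-6)
  expect_error(boldmvpa:::train_and_weights(x, factor(rep("a", 80)),
                                            svm_config()),
               "single-class")
})

test_that("label permutation yields chance-level accuracy on real-structure features", {
  sub <- cached_subject()
  fe <- build_features(sub$pp, sub$pp$gm_mask, k_runs = 1)
  set.seed(99)
  accs <- replicate(50, {
    fe_p <- fe
    fe_p$labels <- sample(fe$labels)
    run_cv(fe_p, cv = cv_config(10, seed = 1))$accuracy
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 2 * se + 0.02)
})

test_that("run_cv reports coherent rates and symmetric class swaps", {
  sub <- cached_subject()
  fe <- build_features(sub$pp, sub$pp$gm_mask, k_runs = 2)
  fit <- run_cv(fe, cv = cv_config(10, seed = 7))
  expect_s3_class(fit, "mvpa_cv")
  expect_true(all(fit$fold_accuracy >= 0 & fit$fold_accuracy <= 1))
  expect_gte(fit$accuracy, min(fit$fold_accuracy))
  expect_lte(fit$accuracy, max(fit$fold_accuracy))
  expect_true(fit$sensitivity >= 0 && fit$sensitivity <= 1)
  expect_true(fit$specificity >= 0 && fit$specificity <= 1)
  expect_length(fit$weights, fit$n_features)
  # swapping the positive class swaps sensitivity and specificity exactly
  fit2 <- run_cv(fe, svm = svm_config(positive_class = "neutral"),
                 cv = cv_config(10, seed = 7))
  expect_equal(fit2$sensitivity, fit$specificity)
  expect_equal(fit2$specificity, fit$sensitivity)
  expect_equal(fit2$fold_accuracy, fit$fold_accuracy)
  # and the weight map flips sign
  expect_equal(fit2$weights, -fit$weights, tolerance = 1e-8)
})

test_that("strongly separated features decode almost perfectly", {
  set.seed(8)
  n <- 120; p <- 30
  x <- matrix(rnorm(n * p), n, p)
  labs <- factor(rep(c("trauma", "neutral"), each = n / 2),
                 levels = c("trauma", "neutral"))
  x[labs == "trauma", 1:5] <- x[labs == "trauma", 1:5] + 4
  fe <- structure(list(x = scale(x), labels = labs,
                       run_id = rep(1:4, each = 30),
                       repetition = rep(1, n), voxel_lin = seq_len(p),
                       grid = voxel_grid(c(5, 5, 5))),
                  class = "feature_matrix")
  fit <- run_cv(fe, cv = cv_config(10, seed = 1))
  expect_gt(fit$accuracy, 0.95)
})

test_that("a fold whose training half loses one class aborts with the fold index", {
  set.seed(9)
  x <- matrix(rnorm(12 * 4), 12, 4)
  labs <- factor(c(rep("trauma", 11), "neutral"),
                 levels = c("trauma", "neutral"))
  fe <- structure(list(x = x, labels = labs, run_id = rep(1, 12),
                       repetition = rep(1, 12), voxel_lin = 1:4,
                       grid = voxel_grid(c(2, 2, 1))),
                  class = "feature_matrix")
  expect_error(run_cv(fe, cv = cv_config(2, seed = 1)), "fold")
})

test_that("mvpa_cv methods print, summarise, coerce and predict", {
  sub <- cached_subject()
  fit <- mvpa_decode(sub$pp, k_runs = 1, keep_model = TRUE,
                     cv = cv_config(10, seed = 2))
  expect_output(print(fit), "accuracy")
  expect_output(print(summary(fit)), "fold accuracy range")
  w <- coef(fit)
  expect_length(w, fit$n_features)
  vol <- coef(fit, as_volume = TRUE)
  expect_equal(dim(vol), sub$pp$grid$dims)
  expect_equal(vol[fit$voxel_lin], w)
  expect_true(all(is.na(vol[-fit$voxel_lin])))
  fe <- build_features(sub$pp, sub$pp$gm_mask, 1)
  pr <- predict(fit, fe$x[1:5, , drop = FALSE])
  expect_s3_class(pr, "factor")
  expect_length(pr, 5)
  res <- residuals(fit)
  expect_true(all(res %in% c(0, 1)))
  expect_equal(mean(res == 0), mean(fit$predictions == fit$labels))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  # keep_model = FALSE refuses to predict
  fit0 <- run_cv(fe, cv = cv_config(10, seed = 2))
  expect_error(predict(fit0, fe$x[1:2, ]), "keep_model")
})

test_that("random-ROI decoding returns the median over sets with a full record", {
  sub <- cached_subject()
  sets <- random_roi_sets(sub$pp$grid, sub$pp$gm_mask, n_sets = 3,
                          n_rois = 4, seed = 11)
  acc <- random_roi_accuracy(sub$pp, sets, k_runs = 1,
                             cv = cv_config(10, seed = 3))
  per <- attr(acc, "per_set")
  expect_length(per, 3)
  expect_equal(as.numeric(acc), median(per))
  same <- random_roi_accuracy(sub$pp, sets[c(1, 1, 1)], k_runs = 1,
                              cv = cv_config(10, seed = 3))
  expect_equal(as.numeric(same), attr(same, "per_set")[1])
})

test_that("decoding accuracy does not degrade with more stationary training runs", {
  # seeded replicate check of the repetition-count trend at desk scale
  accs <- sapply(1:2, function(s) {
    sd <- generate_subject(small_cfg(seed = 500 + s))
    pp <- preprocess_subject(sd$subject)
    c(run_cv(build_features(pp, pp$gm_mask, 1))$accuracy,
      run_cv(build_features(pp, pp$gm_mask, 3))$accuracy)
  })
  expect_gt(mean(accs[2, ]), mean(accs[1, ]) - 0.05)
})
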