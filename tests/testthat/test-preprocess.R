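test_that("Volterra expansion builds the 24-term block with zero-padded lags", {
  set.seed(1)
  R <- matrix(rnorm(20 * 6), 20, 6)
  V <- volterra_expand(R)
  expect_equal(ncol(V), 24)
  expect_equal(V[, 1:6], R, ignore_attr = TRUE)
  expect_equal(V[, 7:12], R^2, ignore_attr = TRUE)
  expect_equal(V[1, 13:24], rep(0, 12), ignore_attr = TRUE)
  expect_equal(V[2:20, 13:18], R[1:19, ], ignore_attr = TRUE)
  # hand-computed single-column case R = (1, 2)
  R2 <- cbind(matrix(0, 2, 5), c(1, 2))
  V2 <- volterra_expand(R2)
  expect_equal(unname(V2[, 12]), c(1, 4))   # R^2
  expect_equal(unname(V2[, 18]), c(0, 1))   # lag, zero-padded
  expect_equal(unname(V2[, 24]), c(0, 1))   # lag squared
  # all-zero motion gives an all-zero block
  expect_true(all(volterra_expand(matrix(0, 5, 6)) == 0))
  expect_error(volterra_expand(matrix(0, 5, 5)), "6 columns")
  expect_error(volterra_expand(matrix(0, 1, 6)), "2 TRs")
})

test_that("nuisance regression residuals are orthogonal to every regressor", {
  run <- noise_run(T = 40, seed = 2)
  mask <- as_mask(array(TRUE, run$grid$dims), run$grid)
  nuis <- cbind(volterra_expand(run$motion), trend = seq_len(40))
  out <- regress_nuisance(run, nuis, mask)
  X <- cbind(1, nuis)
  Y <- matrix(out$data, prod(run$grid$dims), 40)[1:200, , drop = FALSE]
  dots <- abs(Y %*% X)
  expect_lt(max(dots), 1e-6 * sqrt(sum(run$data^2)))
})

test_that("a voxel equal to a regressor residualizes to zero; orthogonal data lose only the mean", {
  run <- noise_run(T = 30, seed = 3)
  g <- run$grid
  mask <- as_mask(array(TRUE, g$dims), g)
  reg <- sin(seq_len(30))
  run$data[1, 1, 1, ] <- 5 * reg
  out <- regress_nuisance(run, cbind(reg = reg), mask)
  expect_equal(max(abs(out$data[1, 1, 1, ])), 0, tolerance = 1e-10)
  # data orthogonal to the regressor: centred input returned
  run2 <- noise_run(T = 30, seed = 4)
  v <- rnorm(30); v <- v - mean(v)
  reg2 <- rep(c(1, -1), 15)
  v <- v - reg2 * sum(v * reg2) / sum(reg2^2)
  run2$data[2, 2, 2, ] <- 100 + v
  out2 <- regress_nuisance(run2, cbind(reg2), mask)
  expect_equal(out2$data[2, 2, 2, ], v, tolerance = 1e-8)
})

test_that("rank-deficient nuisance designs are rejected, duplicates dropped", {
  run <- noise_run(T = 20, seed = 5)
  mask <- as_mask(array(TRUE, run$grid$dims), run$grid)
  tt <- seq_len(20)
  # exact duplicate columns are fine (dropped)
  expect_silent(regress_nuisance(run, cbind(tt, tt), mask))
  # a column collinear with existing ones (not an exact duplicate) errors
  expect_error(regress_nuisance(run, cbind(tt, 2 * tt), mask),
               "rank deficient")
})

test_that("FWHM estimator: white noise ~ voxel scale, presmoothed ~ kernel, constant = Inf", {
  run <- noise_run(T = 12, dims = c(20, 20, 20), seed = 6)
  mask <- as_mask(array(TRUE, run$grid$dims), run$grid)
  est_white <- estimate_fwhm(run, mask)
  expect_lt(abs(est_white - 3) / 3, 0.2)
  sm <- run
  sm$data <- boldmvpa:::gaussian_smooth(run$data, 6, 3)
  est_sm <- estimate_fwhm(sm, mask)
  expect_gt(est_sm, 5); expect_lt(est_sm, 7)
  flat <- run
  flat$data <- array(rep(rnorm(12), each = prod(run$grid$dims)),
                     dim = dim(run$data))
  expect_equal(estimate_fwhm(flat, mask), Inf)
})

test_that("smooth_to_fwhm reaches an 8 mm target and preserves volume means", {
  run <- noise_run(T = 10, dims = c(20, 20, 20), seed = 7)
  mask <- as_mask(array(TRUE, run$grid$dims), run$grid)
  cfg <- smoothing_config(target_fwhm_mm = 8, tolerance_mm = 0.5)
  out <- smooth_to_fwhm(run, cfg, mask)
  est <- estimate_fwhm(out, mask)
  expect_lt(abs(est - 8), 0.5 + 1e-9)
  m_in <- apply(run$data, 4, mean)
  m_out <- apply(out$data, 4, mean)
  expect_lt(max(abs(m_out - m_in) / abs(m_in)), 0.01)
  # already at target: no-op within tolerance
  again <- smooth_to_fwhm(out, cfg, mask)
  expect_equal(again$data, out$data)
})

test_that("smoothing a too-smooth input warns and leaves data unchanged", {
  run <- noise_run(T = 8, dims = c(20, 20, 20), seed = 8)
  run$data <- boldmvpa:::gaussian_smooth(run$data, 10, 3)
  mask <- as_mask(array(TRUE, run$grid$dims), run$grid)
  expect_warning(out <- smooth_to_fwhm(run, smoothing_config(target_fwhm_mm = 8),
                                       mask), "smoother")
  expect_identical(out$data, run$data)
})

test_that("percent signal change matches the formula and zeroes near-zero voxels", {
  g <- voxel_grid(c(4, 4, 4))
  arr <- array(1000, dim = c(4, 4, 4, 2))
  arr[1, 1, 1, ] <- c(90, 110)
  arr[2, 1, 1, ] <- c(0.001, -0.001)    # near-zero mean voxel
  run <- bold_run(arr, g, 2, "neutral", 1, matrix(0, 2, 6))
  mask <- as_mask(array(TRUE, g$dims), g)
  out <- to_psc(run, mask)
  expect_equal(out$data[1, 1, 1, ], c(-10, 10))
  expect_equal(out$data[2, 1, 1, ], c(0, 0))
  expect_equal(attr(out, "n_zeroed"), 1)
  # constant voxels give zeros, and all in-mask temporal means vanish
  expect_true(all(abs(out$data[3, , , ]) < 1e-12))
  tm <- apply(out$data, 1:3, mean)
  expect_lt(max(abs(tm)), 1e-10)
})

test_that("detrending removes polynomial trends exactly and is idempotent", {
  g <- voxel_grid(c(4, 4, 4))
  T <- 25
  tt <- seq_len(T)
  arr <- array(rnorm(64 * T), dim = c(4, 4, 4, T))
  arr[1, 1, 1, ] <- 3 + 0.5 * tt            # linear ramp
  run <- bold_run(arr + 1000, g, 2, "neutral", 1, matrix(0, T, 6))
  mask <- as_mask(array(TRUE, g$dims), g)
  out1 <- detrend(run, 1, mask)
  expect_lt(max(abs(out1$data[1, 1, 1, ])), 1e-9)
  # polyorder 0 is exact mean-centring
  out0 <- detrend(run, 0, mask)
  manual <- run$data[2, 2, 2, ] - mean(run$data[2, 2, 2, ])
  expect_equal(out0$data[2, 2, 2, ], manual, tolerance = 1e-10)
  # idempotence
  out2 <- detrend(detrend(run, 2, mask), 2, mask)
  expect_equal(out2$data, detrend(run, 2, mask)$data, tolerance = 1e-8)
  # residuals orthogonal to the polynomial basis
  X <- cbind(1, poly(seq(-1, 1, length.out = T), 2))
  Y <- matrix(detrend(run, 2, mask)$data, 64, T)
  expect_lt(max(abs(Y %*% X)), 1e-6)
})

test_that("the preprocessing entry point runs end to end and centres runs", {
  sub <- cached_subject()
  run <- sub$pp$runs[[1]]
  d <- dim(run$data)
  brain <- sub$pp$gm_mask | sub$pp$wm_mask | sub$pp$csf_mask
  flat <- matrix(run$data, prod(d[1:3]), d[4])
  expect_lt(max(abs(rowMeans(flat[which(brain), ]))), 1e-8)
  expect_true(all(is.finite(run$data)))
  expect_true(isTRUE(attr(sub$pp, "preprocessed")))
})
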