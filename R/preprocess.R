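#' Volterra expansion of rigid-body motion parameters
#'
#' Expands the 6 motion parameters R into the 24-column nuisance block
#' `[R, R^2, R lagged one TR, R^2 lagged one TR]`. The lagged terms at
#' t = 1 are zero-padded (the first TR has no predecessor), which keeps
#' volume-label alignment simple: no TR is dropped.
#'
#' @param motion T x 6 matrix of motion parameters (translations in mm,
#'   rotations in degrees).
#' @return T x 24 matrix with labelled columns.
#' @examples
#' volterra_expand(cbind(matrix(0, 3, 5), c(1, 2, 3)))[, c(6, 12, 18, 24)]
#' @export
volterra_expand <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have exactly 6 columns")
  if (nrow(motion) < 2) stop("need at least 2 TRs for lagged terms")
  lag1 <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, motion^2, lag1, lag1^2)
  base <- colnames(motion) %||% paste0("R", 1:6)
  colnames(out) <- c(base, paste0(base, "_sq"),
                     paste0(base, "_lag"), paste0(base, "_lag_sq"))
  out
}

#' Assemble the per-run nuisance regressor matrix
#'
#' Combines the 24 Volterra motion terms with the mean raw signal in the
#' WM and CSF compartments, and optionally polynomial trend terms. The
#' compartment means are computed from the run as-is, so this must be
#' called before the data are residualized.
#'
#' @param run A `bold_run`.
#' @param wm_mask,csf_mask Tissue masks on the run's grid.
#' @param polyorder Polynomial trend order to include, or `NULL` (default)
#'   to leave drift removal to the later detrend step.
#' @return T x K labelled matrix.
#' @export
build_nuisance <- function(run, wm_mask, csf_mask, polyorder = NULL) {
  if (!any(wm_mask) || !any(csf_mask))
    stop("WM and CSF masks must be non-empty to form compartment regressors")
  d <- dim(run$data)
  flat <- matrix(run$data, prod(d[1:3]), d[4])
  nuis <- cbind(volterra_expand(run$motion),
                wm_mean = colMeans(flat[which(wm_mask), , drop = FALSE]),
                csf_mean = colMeans(flat[which(csf_mask), , drop = FALSE]))
  if (!is.null(polyorder) && polyorder >= 1) {
    tt <- seq(-1, 1, length.out = d[4])
    tr <- sapply(seq_len(polyorder), function(p) tt^p)
    colnames(tr) <- paste0("poly", seq_len(polyorder))
    nuis <- cbind(nuis, tr)
  }
  nuis
}

#' Residualize voxel timeseries against nuisance regressors
#'
#' Least-squares projection of every in-mask voxel timeseries onto the
#' nuisance columns plus an intercept; the residuals are returned in place
#' of the data and are orthogonal to every regressor. Exact duplicate and
#' constant-zero columns are dropped before fitting; a design that is
#' still rank deficient is an error.
#'
#' @param run A `bold_run`.
#' @param nuisance T x K regressor matrix (e.g. from [build_nuisance()]).
#' @param mask Voxels to residualize; others are left untouched.
#' @return The run with residualized data.
#' @export
regress_nuisance <- function(run, nuisance, mask) {
  d <- dim(run$data)
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != d[4])
    stop("nuisance rows (", nrow(nuisance), ") != run TR count (", d[4], ")")
  keep <- apply(nuisance, 2, function(col) any(col != 0))
  nuisance <- nuisance[, keep, drop = FALSE]
  if (ncol(nuisance)) nuisance <- nuisance[, !duplicated(t(nuisance)),
                                           drop = FALSE]
  X <- cbind(intercept = 1, nuisance)
  if (ncol(X) >= d[4])
    stop("run too short: ", d[4], " TRs cannot support ", ncol(X),
         " nuisance regressors")
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("nuisance design is rank deficient after duplicate removal")
  lin <- which(mask)
  flat <- matrix(run$data, prod(d[1:3]), d[4])
  Y <- t(flat[lin, , drop = FALSE])
  flat[lin, ] <- t(qr.resid(qrx, Y))
  run$data <- array(flat, d)
  run
}

#' Estimate global spatial smoothness (FWHM)
#'
#' Estimates the effective Gaussian FWHM of the spatial autocorrelation
#' from the ratio of neighbouring-voxel difference variance to total
#' variance, computed on temporally differenced data (successive-volume
#' differences suppress task structure and drift so only the noise
#' smoothness is measured), then averaged over the three axes. For an
#' uncorrelated (white) field the estimate is ~1.18 voxel widths; a field
#' smoothed with a Gaussian kernel returns approximately that kernel's
#' FWHM.
#'
#' @param run A `bold_run` (needs at least 2 TRs).
#' @param mask Voxels over which smoothness is estimated.
#' @return FWHM estimate in mm; `Inf` when the field has no spatial
#'   variance (e.g. a spatially constant image).
#' @export
estimate_fwhm <- function(run, mask) {
  d <- dim(run$data)
  if (d[4] < 2) stop("need at least 2 TRs to difference temporally")
  if (!any(mask)) stop("mask is empty")
  dif <- run$data[, , , -1, drop = FALSE] - run$data[, , , -d[4], drop = FALSE]
  nt <- d[4] - 1
  m3 <- array(mask, dim = d[1:3])
  v <- run$grid$voxel_size_mm
  tot_num <- 0; tot_den <- 0
  ratios <- numeric(3)
  for (ax in 1:3) {
    hi <- lo <- rep(list(quote(expr = )), 4)
    hi[[ax]] <- 2:d[ax]; lo[[ax]] <- 1:(d[ax] - 1)
    mhi <- mlo <- rep(list(quote(expr = )), 3)
    mhi[[ax]] <- 2:d[ax]; mlo[[ax]] <- 1:(d[ax] - 1)
    pair_ok <- do.call(`[`, c(list(m3), mhi, list(drop = FALSE))) &
               do.call(`[`, c(list(m3), mlo, list(drop = FALSE)))
    if (!any(pair_ok)) { ratios[ax] <- NA; next }
    delta <- do.call(`[`, c(list(dif), hi, list(drop = FALSE))) -
             do.call(`[`, c(list(dif), lo, list(drop = FALSE)))
    sel <- as.vector(pair_ok)
    dsel <- matrix(delta, ncol = nt)[sel, , drop = FALSE]
    ratios[ax] <- mean(dsel^2)
  }
  xin <- matrix(dif, ncol = nt)[as.vector(m3), , drop = FALSE]
  s2 <- mean(sweep(xin, 2, colMeans(xin))^2)
  if (s2 <= 0) return(Inf)
  ratios <- ratios / s2
  ratios[!is.na(ratios) & ratios <= 0] <- NA
  fwhm_ax <- sqrt(8 * log(2)) * v / sqrt(2 * ratios)
  if (all(is.na(fwhm_ax))) return(Inf)
  mean(fwhm_ax, na.rm = TRUE)
}

# Separable Gaussian smoothing of a 3-D or 4-D array with a
# boundary-renormalized (row-stochastic) truncated kernel, so constant
# fields and per-volume means are preserved.
gaussian_smooth <- function(arr, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm <= 0) return(arr)
  sd_vox <- fwhm_mm / (sqrt(8 * log(2)) * voxel_size_mm)
  h <- max(1L, ceiling(3 * sd_vox))
  d <- dim(arr)
  for (ax in 1:3) {
    n <- d[ax]
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) ifelse(abs(i - j) <= h,
                                     exp(-(i - j)^2 / (2 * sd_vox^2)), 0))
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(seq_along(d), ax))
    ap <- aperm(arr, perm)
    dp <- dim(ap)
    ap <- K %*% matrix(ap, n)
    arr <- aperm(array(ap, dp), order(perm))
  }
  arr
}

#' Smoothing target configuration
#'
#' @param enabled Whether smoothing is applied.
#' @param target_fwhm_mm Desired final smoothness (default 8 mm).
#' @param max_iterations Cap on incremental smoothing passes (default 10).
#' @param tolerance_mm Acceptable distance from the target (default 0.5).
#' @return Object of class `smoothing_config`.
#' @export
smoothing_config <- function(enabled = TRUE, target_fwhm_mm = 8,
                             max_iterations = 10, tolerance_mm = 0.5) {
  stopifnot(target_fwhm_mm > 0, max_iterations >= 1, tolerance_mm > 0)
  structure(list(enabled = enabled, target_fwhm_mm = target_fwhm_mm,
                 max_iterations = max_iterations, tolerance_mm = tolerance_mm),
            class = "smoothing_config")
}

#' Iteratively smooth a run to a target FWHM
#'
#' Estimates the current smoothness ([estimate_fwhm()]) and applies
#' incremental Gaussian smoothing whose width is chosen by Gaussian
#' quadrature (`sqrt(target^2 - current^2)`, damped to avoid overshoot),
#' repeating until the estimate is within `tolerance_mm` of the target or
#' `max_iterations` is reached (with a warning). Data already at or above
#' the target are returned unchanged with a warning; the routine never
#' smooths beyond `target + tolerance`.
#'
#' @param run A `bold_run`.
#' @param cfg A [smoothing_config()] with `enabled = TRUE`.
#' @param mask Mask over which smoothness is estimated.
#' @return The smoothed run, with attribute `fwhm_achieved`.
#' @export
smooth_to_fwhm <- function(run, cfg, mask) {
  stopifnot(inherits(cfg, "smoothing_config"), cfg$enabled)
  target <- cfg$target_fwhm_mm
  if (target <= run$grid$voxel_size_mm)
    stop("target FWHM must exceed the voxel size")
  cur <- estimate_fwhm(run, mask)
  if (cur >= target - cfg$tolerance_mm) {
    if (cur > target + cfg$tolerance_mm)
      warning(sprintf("data already smoother (%.2f mm) than target %.2f mm; no-op",
                      cur, target))
    attr(run, "fwhm_achieved") <- cur
    return(run)
  }
  for (it in seq_len(cfg$max_iterations)) {
    add <- 0.9 * sqrt(max(target^2 - cur^2, 0))
    if (add < 0.1 * run$grid$voxel_size_mm) break
    run$data <- gaussian_smooth(run$data, add, run$grid$voxel_size_mm)
    cur <- estimate_fwhm(run, mask)
    if (abs(cur - target) <= cfg$tolerance_mm) break
  }
  if (abs(cur - target) > cfg$tolerance_mm)
    warning(sprintf("smoothing stopped at %.2f mm (target %.2f mm)", cur, target))
  attr(run, "fwhm_achieved") <- cur
  run
}

#' Rescale voxel timeseries to percent signal change
#'
#' Per in-mask voxel, `100 * (x_t - mean(x)) / m`, where the scaling
#' denominator `m` is the voxel's temporal mean (or a supplied baseline
#' mean when the data have already been centred by earlier steps). Voxels
#' whose denominator is within `threshold_frac` of zero relative to the
#' run's global in-mask mean are set to zero and counted in the
#' `n_zeroed` attribute rather than producing unstable values.
#'
#' @param run A `bold_run`.
#' @param mask Voxels to rescale; out-of-mask voxels are zeroed.
#' @param baseline Optional per-voxel baseline means (vector over in-mask
#'   voxels, in mask-index order) taken from the raw data.
#' @param threshold_frac Near-zero-mean threshold as a fraction of the
#'   global in-mask mean (default 0.01).
#' @return The rescaled run; every voxel's output temporal mean is ~0.
#' @export
to_psc <- function(run, mask, baseline = NULL, threshold_frac = 0.01) {
  d <- dim(run$data)
  lin <- which(mask)
  flat <- matrix(run$data, prod(d[1:3]), d[4])
  x <- flat[lin, , drop = FALSE]
  m <- if (is.null(baseline)) rowMeans(x) else baseline
  stopifnot(length(m) == length(lin))
  global_mean <- mean(abs(m))
  bad <- abs(m) < threshold_frac * global_mean
  out <- 100 * (x - rowMeans(x)) / ifelse(bad, 1, m)
  out[bad, ] <- 0
  flat[] <- 0
  flat[lin, ] <- out
  run$data <- array(flat, d)
  attr(run, "n_zeroed") <- sum(bad)
  run
}

#' Remove a polynomial trend from every voxel timeseries
#'
#' Per-voxel residual from an ordinary least-squares polynomial fit of
#' order `polyorder` in time (`polyorder = 0` is exact mean-centring).
#'
#' @param run A `bold_run`.
#' @param polyorder Polynomial order (>= 0, < T).
#' @param mask Voxels to detrend.
#' @return The detrended run.
#' @export
detrend <- function(run, polyorder = 2, mask) {
  d <- dim(run$data)
  stopifnot(polyorder >= 0, d[4] > polyorder)
  tt <- seq(-1, 1, length.out = d[4])
  X <- matrix(1, d[4], 1)
  if (polyorder >= 1)
    X <- cbind(X, stats::poly(tt, degree = polyorder, raw = FALSE))
  qrx <- qr(X)
  lin <- which(mask)
  flat <- matrix(run$data, prod(d[1:3]), d[4])
  flat[lin, ] <- t(qr.resid(qrx, t(flat[lin, , drop = FALSE])))
  run$data <- array(flat, d)
  run
}

#' Full per-run preprocessing pipeline
#'
#' Single entry point enforcing the default order: nuisance regression
#' (24 Volterra motion terms + WM/CSF means) -> optional smoothing to the
#' target FWHM -> polynomial detrending -> percent-signal-change scaling
#' against the raw-data baseline. Placing PSC last makes the output
#' directly usable as "% signal change" features; the smoothing arm is the
#' only difference between the smoothed and unsmoothed permutations.
#'
#' @param run A raw `bold_run`.
#' @param wm_mask,csf_mask,brain_mask Tissue/analysis masks on the run's
#'   grid (`brain_mask` defaults to the whole grid).
#' @param smoothing A [smoothing_config()] or `FALSE` for the unsmoothed
#'   arm.
#' @param polyorder Detrending order (default 2).
#' @param nuisance_polyorder Polynomial terms included directly in the
#'   nuisance model, or `NULL` (default) to rely on the detrend step.
#' @return The preprocessed run.
#' @export
preprocess_run <- function(run, wm_mask, csf_mask, brain_mask = NULL,
                           smoothing = FALSE, polyorder = 2,
                           nuisance_polyorder = NULL) {
  if (is.null(brain_mask))
    brain_mask <- as_mask(array(TRUE, run$grid$dims), run$grid)
  d <- dim(run$data)
  lin <- which(brain_mask)
  baseline <- rowMeans(matrix(run$data, prod(d[1:3]), d[4])[lin, , drop = FALSE])
  nuis <- build_nuisance(run, wm_mask, csf_mask, polyorder = nuisance_polyorder)
  run <- regress_nuisance(run, nuis, brain_mask)
  if (inherits(smoothing, "smoothing_config") && smoothing$enabled)
    run <- smooth_to_fwhm(run, smoothing, brain_mask)
  run <- detrend(run, polyorder, brain_mask)
  run <- to_psc(run, brain_mask, baseline = baseline)
  run
}

#' Preprocess every run of a subject
#'
#' Applies [preprocess_run()] to each run using the subject's tissue
#' masks; the analysis mask is the union of GM, WM and CSF.
#'
#' @param subject A `subject_dataset`.
#' @param smoothing A [smoothing_config()] or `FALSE`.
#' @param ... Passed to [preprocess_run()].
#' @return The subject with preprocessed runs and attribute
#'   `preprocessed = TRUE`.
#' @export
preprocess_subject <- function(subject, smoothing = FALSE, ...) {
  brain <- as_mask(subject$gm_mask | subject$wm_mask | subject$csf_mask,
                   subject$grid)
  subject$runs <- lapply(subject$runs, preprocess_run,
                         wm_mask = subject$wm_mask,
                         csf_mask = subject$csf_mask,
                         brain_mask = brain, smoothing = smoothing, ...)
  attr(subject, "preprocessed") <- TRUE
  subject
}
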