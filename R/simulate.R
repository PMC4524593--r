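#' Configuration for the synthetic BOLD generator
#'
#' Defines the simulated study: per condition (trauma / neutral memory
#' recall) a number of ~3-minute task-only runs at TR = 2 s on an isotropic
#' 3 mm grid, with a spatially clustered condition-discriminative signal,
#' AR(1) temporal noise, slow polynomial drift, random-walk head motion,
#' shared white-matter/CSF nuisance signals, and optional non-stationarity
#' of the signal pattern across repetitions.
#'
#' All amplitudes are expressed in units of the voxelwise noise SD, which
#' is itself 1% of the baseline BOLD level (baseline 1000 arbitrary units,
#' so percent signal change is well defined).
#'
#' @param n_runs_per_condition Runs per condition (default 5).
#' @param trs_per_run Volumes per run (default 90, i.e. 3 min at TR 2 s).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param effect_size Mean condition separation per signal voxel, in noise
#'   SD units (default 1.5).
#' @param n_signal_voxels Number of grey-matter voxels carrying signal
#'   (default 2500, about two thirds of the default grid's grey matter --
#'   a brain-wide distributed state difference; TR-level decoding strength
#'   scales with the signal fraction of the feature set).
#' @param signal_fwhm_mm Spatial scale of the signal clusters: signal
#'   support is drawn as spheres of this radius around random GM centres
#'   (default 6).
#' @param ar1_coef Lag-1 autocorrelation of the temporal noise, in `[0,1)`
#'   (default 0.3).
#' @param drift_amplitude SD of the random linear/quadratic drift
#'   coefficients, in noise SD units (default 2).
#' @param motion_step_sd Per-TR SD of the motion random-walk increments
#'   (mm or degrees; default 0.05).
#' @param nonstationarity Fraction of the signal support resampled between
#'   successive repetitions, in `[0,1]` (default 0).
#' @param severity_coupling Cohort-level scaling of the signal amplitude
#'   within the designated coupling ROI by standardized symptom severity
#'   (default 0; see [generate_cohort()]).
#' @param seed Integer seed; identical configs give bit-identical data.
#' @param grid_dims Grid size in voxels (default `c(24, 24, 24)`, a
#'   desk-scale brain; real-size grids pass through the same interfaces).
#' @param voxel_size_mm Isotropic voxel size (default 3).
#' @param baseline Baseline BOLD level in arbitrary units (default 1000).
#' @param envelope_period_s Period of the blocked task-modulation envelope
#'   carried by the signal pattern within trauma runs (default 8 s, the
#'   timescale of narrative events).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_runs_per_condition = 5, trs_per_run = 90,
                       tr_seconds = 2, effect_size = 1.5,
                       n_signal_voxels = 2500, signal_fwhm_mm = 6,
                       ar1_coef = 0.3, drift_amplitude = 2,
                       motion_step_sd = 0.05, nonstationarity = 0,
                       severity_coupling = 0, seed = 1,
                       grid_dims = c(24, 24, 24), voxel_size_mm = 3,
                       baseline = 1000, envelope_period_s = 8) {
  stopifnot(n_runs_per_condition >= 1, trs_per_run >= 2, tr_seconds > 0,
            effect_size >= 0, n_signal_voxels >= 1, signal_fwhm_mm >= 0,
            ar1_coef >= 0, ar1_coef < 1, drift_amplitude >= 0,
            motion_step_sd >= 0, nonstationarity >= 0, nonstationarity <= 1,
            baseline > 0, envelope_period_s > 0)
  structure(list(
    n_runs_per_condition = as.integer(n_runs_per_condition),
    trs_per_run = as.integer(trs_per_run), tr_seconds = tr_seconds,
    effect_size = effect_size, n_signal_voxels = as.integer(n_signal_voxels),
    signal_fwhm_mm = signal_fwhm_mm, ar1_coef = ar1_coef,
    drift_amplitude = drift_amplitude, motion_step_sd = motion_step_sd,
    nonstationarity = nonstationarity, severity_coupling = severity_coupling,
    seed = as.integer(seed), grid_dims = as.integer(grid_dims),
    voxel_size_mm = voxel_size_mm, baseline = baseline,
    envelope_period_s = envelope_period_s
  ), class = "sim_config")
}

#' Concentric ellipsoidal tissue compartments on a grid
#'
#' A central ellipsoidal "brain" occupying ~90% of the grid half-width,
#' partitioned by normalized radius into a CSF core (ventricles), a WM
#' shell, and an outer GM shell. The three compartments are pairwise
#' disjoint by construction.
#'
#' @param grid A [voxel_grid()].
#' @return List with logical masks `gm`, `wm`, `csf` and `brain` (their
#'   union).
#' @export
tissue_masks <- function(grid) {
  d <- grid$dims
  ctr <- (d + 1) / 2
  radii <- 0.92 * (d - 1) / 2
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  rho <- sqrt(((idx[, 1] - ctr[1]) / radii[1])^2 +
              ((idx[, 2] - ctr[2]) / radii[2])^2 +
              ((idx[, 3] - ctr[3]) / radii[3])^2)
  list(gm = as_mask(rho > 0.62 & rho <= 1, grid),
       wm = as_mask(rho > 0.30 & rho <= 0.62, grid),
       csf = as_mask(rho <= 0.30, grid),
       brain = as_mask(rho <= 1, grid))
}

#' Random-walk head-motion parameters
#'
#' Six independent cumulative-sum random walks (3 translations in mm,
#' 3 rotations in degrees), reflected at +/- 2 units so excursions stay
#' within a realistic range. Deterministic given a seed.
#'
#' @param T Number of TRs.
#' @param step_sd Per-step SD of the increments (default 0.05).
#' @param seed Integer seed, or NULL to use the ambient RNG stream.
#' @return T x 6 numeric matrix with columns
#'   `trans_x/y/z`, `rot_x/y/z`.
#' @export
generate_motion <- function(T, step_sd = 0.05, seed = NULL) {
  stopifnot(T >= 1, step_sd >= 0)
  with_preserved_seed(seed, {
    steps <- matrix(stats::rnorm(T * 6, sd = step_sd), T, 6)
    walk <- apply(steps, 2, cumsum)
    if (T == 1) walk <- matrix(walk, 1, 6)
    bound <- 2
    # reflect into [-bound, bound]
    walk <- abs((walk + bound) %% (4 * bound) - 2 * bound) - bound
    colnames(walk) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
    walk
  })
}

# Sample a spatially clustered signal support of exactly n voxels from GM:
# spheres of radius `fwhm` mm around random GM centres, one sign per
# cluster. Returns data.frame(idx = linear voxel index, amp = signed unit
# amplitude).
sample_signal_support <- function(grid, gm_lin, n, fwhm) {
  avail <- gm_lin
  chosen <- integer(0)
  amp <- numeric(0)
  guard <- 0
  while (length(chosen) < n) {
    guard <- guard + 1
    if (guard > 10 * n) stop("could not place signal support inside GM")
    ctr_lin <- avail[sample.int(length(avail), 1)]
    ctr_idx <- arrayInd(ctr_lin, grid$dims)
    sph <- sphere_mask(grid_index_to_mm(grid, as.integer(ctr_idx)),
                       max(fwhm, grid$voxel_size_mm), grid)
    new <- setdiff(intersect(which(sph), avail), chosen)
    if (!length(new)) next
    new <- new[seq_len(min(length(new), n - length(chosen)))]
    sgn <- sample(c(-1, 1), 1)
    chosen <- c(chosen, new)
    amp <- c(amp, rep(sgn, length(new)))
  }
  data.frame(idx = chosen, amp = amp)
}

# Resample a fraction q of the support between successive repetitions.
# Redrawn voxels move to fresh GM locations outside the previous support,
# so q = 1 yields disjoint successive supports.
resample_support <- function(support, grid, gm_lin, q) {
  n <- nrow(support)
  n_new <- round(q * n)
  if (n_new == 0) return(support)
  drop_i <- sample.int(n, n_new)
  keep <- support[-drop_i, , drop = FALSE]
  # prefer fresh GM locations; when the support is dense enough to
  # exhaust them, top up from the just-dropped locations
  fresh <- setdiff(gm_lin, support$idx)
  if (length(fresh) >= n_new) {
    add <- fresh[sample.int(length(fresh), n_new)]
  } else {
    dropped <- support$idx[drop_i]
    extra <- dropped[sample.int(length(dropped), n_new - length(fresh))]
    add <- c(fresh, extra)
  }
  rbind(keep, data.frame(idx = add,
                         amp = sample(c(-1, 1), n_new, replace = TRUE)))
}

# AR(1) series/matrix with stationary SD 1.
ar1_noise <- function(T, ncol, phi) {
  innov <- matrix(stats::rnorm(T * ncol), T, ncol)
  if (phi > 0) {
    innov <- innov * sqrt(1 - phi^2)
    innov <- apply(innov, 2, function(e)
      as.numeric(stats::filter(e, phi, method = "recursive")))
    if (T == 1) innov <- matrix(innov, 1, ncol)
  }
  innov
}

#' Generate one synthetic subject with ground truth
#'
#' Produces `2 * n_runs_per_condition` task-only runs (the 30 s rest
#' periods of the original design carry no classification data and are not
#' simulated). Trauma runs carry an additive, spatially clustered signal
#' pattern whose amplitude per voxel is `effect_size` noise-SD units,
#' modulated in time by a blocked +/-1 envelope with random phase so the
#' pattern survives per-run mean removal in preprocessing; neutral runs
#' carry no pattern. All brain voxels receive AR(1) noise plus polynomial
#' drift; WM and CSF compartments carry shared nuisance signals that also
#' bleed weakly into GM; motion is a bounded random walk. With
#' `nonstationarity = q`, a fraction `q` of the signal support is re-drawn
#' between successive repetitions.
#'
#' @param config A [sim_config()].
#' @param covariates Optional single-row data frame with columns
#'   `severity`, `age`, `depression`, `substance_use` (filled with
#'   plausible defaults when omitted).
#' @param coupling_amplitude Extra signed amplitude (noise SD units) added
#'   to the designated coupling ROI voxels; used by [generate_cohort()].
#' @return List with elements `subject` (class `subject_dataset`: `runs`,
#'   `gm_mask`, `wm_mask`, `csf_mask`, `covariates`, `grid`, `tr_seconds`)
#'   and `truth` (class `ground_truth`: `signal_mask` union over
#'   repetitions, `pattern` list of per-repetition data frames
#'   `(idx, amp)` in noise SD units, `coupling_roi`, `severity_value`).
#' @examples
#' sd <- generate_subject(sim_config(grid_dims = c(12, 12, 12),
#'                                   n_signal_voxels = 100,
#'                                   trs_per_run = 20, seed = 1))
#' length(sd$subject$runs)
#' @export
generate_subject <- function(config, covariates = NULL,
                             coupling_amplitude = 0) {
  stopifnot(inherits(config, "sim_config"))
  grid <- voxel_grid(config$grid_dims, config$voxel_size_mm)
  tis <- tissue_masks(grid)
  gm_lin <- which(tis$gm)
  if (config$n_signal_voxels > length(gm_lin))
    stop("n_signal_voxels exceeds the GM voxel count (",
         length(gm_lin), ")")
  if (is.null(covariates))
    covariates <- data.frame(severity = 62, age = 34,
                             depression = 0L, substance_use = 0L)

  with_preserved_seed(config$seed, {
    n_rep <- config$n_runs_per_condition
    T <- config$trs_per_run
    brain_lin <- which(tis$brain)
    gm_pos <- match(gm_lin, brain_lin)
    wm_pos <- match(which(tis$wm), brain_lin)
    csf_pos <- match(which(tis$csf), brain_lin)
    V <- length(brain_lin)

    # per-repetition signal support (possibly drifting)
    support <- vector("list", n_rep)
    support[[1]] <- sample_signal_support(grid, gm_lin,
                                          config$n_signal_voxels,
                                          config$signal_fwhm_mm)
    if (n_rep > 1) for (k in 2:n_rep)
      support[[k]] <- resample_support(support[[k - 1]], grid, gm_lin,
                                       config$nonstationarity)

    # coupling ROI: sphere at the left amygdalohippocampal coordinate,
    # snapped into GM if the printed coordinate misses this grid
    coup <- sphere_mask(c(-20, -8, -16), 6, grid) & tis$gm
    if (!any(coup)) {
      gm_idx <- mask_which(tis$gm)
      mm <- grid_index_to_mm(grid, gm_idx)
      d2 <- (mm[, 1] + 20)^2 + (mm[, 2] + 8)^2 + (mm[, 3] + 16)^2
      coup <- sphere_mask(mm[which.min(d2), ], 6, grid) & tis$gm
    }
    coup <- as_mask(coup, grid)
    coup_lin <- which(coup)

    # with a designated coupling amplitude the ROI voxels carry exactly
    # that signed amplitude (base + coupling * standardized severity, set
    # by generate_cohort), replacing any overlapping random support
    pattern <- lapply(support, function(s) {
      p <- data.frame(idx = s$idx, amp = s$amp * config$effect_size)
      if (coupling_amplitude != 0) {
        p <- rbind(p[!(p$idx %in% coup_lin), , drop = FALSE],
                   data.frame(idx = coup_lin,
                              amp = rep(coupling_amplitude, length(coup_lin))))
      }
      p
    })

    period_trs <- max(2, round(config$envelope_period_s / config$tr_seconds))

    make_run <- function(condition, repetition) {
      pct <- ar1_noise(T, V, config$ar1_coef)
      # slow drift: random linear + quadratic per voxel (orthogonalized
      # Legendre-style basis on [-1, 1])
      if (config$drift_amplitude > 0) {
        tt <- seq(-1, 1, length.out = T)
        basis <- cbind(tt, tt^2 - mean(tt^2))
        coefs <- matrix(stats::rnorm(2 * V, sd = config$drift_amplitude), 2, V)
        pct <- pct + basis %*% coefs
      }
      # shared nuisance signals. The WM/CSF signals are temporally smooth
      # and bleed into GM; the preprocessing nuisance model carries WM and
      # CSF mean regressors precisely to remove such components. The
      # global component is temporally white so that it carries no
      # run-identifying temporal structure (a smooth un-modelled global
      # signal would let TR-wise cross-validation fingerprint runs).
      g_sig <- ar1_noise(T, 1, 0)
      wm_sig <- ar1_noise(T, 1, 0.5)
      csf_sig <- ar1_noise(T, 1, 0.5)
      pct <- pct + g_sig %*% matrix(0.3, 1, V)
      pct[, wm_pos] <- pct[, wm_pos] + as.vector(wm_sig)
      pct[, csf_pos] <- pct[, csf_pos] + as.vector(csf_sig)
      pct[, gm_pos] <- pct[, gm_pos] +
        0.2 * (as.vector(wm_sig) + as.vector(csf_sig))
      if (condition == "trauma") {
        pat <- pattern[[repetition]]
        # blocked engagement envelope: "on" for a duty-cycle fraction of
        # each period, random phase per run, centred at zero so the
        # pattern survives per-run mean removal; the asymmetry (short
        # strong peaks vs long shallow troughs) gives the decision
        # function a consistent direction along the pattern. Amplitude is
        # scaled so the mean absolute per-voxel deviation between
        # conditions equals the configured effect size.
        duty <- 0.35
        phase <- sample.int(period_trs, 1)
        on <- ((seq_len(T) + phase - 1) %% period_trs) < duty * period_trs
        env <- (as.numeric(on) - duty) / (2 * duty * (1 - duty))
        pos <- match(pat$idx, brain_lin)
        pct[, pos] <- pct[, pos] + outer(env, pat$amp)
      }
      arr <- array(0, dim = c(grid$dims, T))
      flat <- matrix(0, prod(grid$dims), T)
      flat[brain_lin, ] <- t(config$baseline * (1 + pct / 100))
      arr[] <- flat
      motion <- generate_motion(T, config$motion_step_sd, seed = NULL)
      bold_run(arr, grid, config$tr_seconds, condition, repetition, motion)
    }

    runs <- list()
    for (cond in c("neutral", "trauma"))
      for (k in seq_len(n_rep))
        runs[[length(runs) + 1]] <- make_run(cond, k)

    signal_union <- empty_mask(grid)
    for (p in pattern) signal_union[p$idx] <- TRUE
    attr(signal_union, "grid") <- grid

    subject <- structure(list(runs = runs, gm_mask = tis$gm,
                              wm_mask = tis$wm, csf_mask = tis$csf,
                              covariates = covariates, grid = grid,
                              tr_seconds = config$tr_seconds),
                         class = "subject_dataset")
    truth <- structure(list(signal_mask = signal_union, pattern = pattern,
                            coupling_roi = coup,
                            severity_value = covariates$severity[1]),
                       class = "ground_truth")
    list(subject = subject, truth = truth)
  })
}

#' Construct a single BOLD run
#'
#' @param data 4-D numeric array `(x, y, z, T)` on `grid`; must be finite.
#' @param grid A [voxel_grid()].
#' @param tr_seconds Repetition time.
#' @param condition Condition label (e.g. `"trauma"` or `"neutral"`).
#' @param repetition Repetition index (1-based).
#' @param motion T x 6 motion-parameter matrix.
#' @return Object of class `bold_run`.
#' @export
bold_run <- function(data, grid, tr_seconds, condition, repetition, motion) {
  stopifnot(length(dim(data)) == 4, all(dim(data)[1:3] == grid$dims),
            dim(data)[4] >= 1, all(is.finite(data)),
            is.matrix(motion), ncol(motion) == 6,
            nrow(motion) == dim(data)[4])
  structure(list(data = data, grid = grid, tr_seconds = tr_seconds,
                 condition = condition, repetition = as.integer(repetition),
                 motion = motion),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold_run: %s rep %d, %d TRs (TR=%gs) on %dx%dx%d grid\n",
              x$condition, x$repetition, d[4], x$tr_seconds, d[1], d[2], d[3]))
  invisible(x)
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("subject_dataset: %d runs (%s), GM %d / WM %d / CSF %d voxels\n",
              length(x$runs),
              paste(sort(unique(vapply(x$runs, `[[`, "", "condition"))),
                    collapse = " vs "),
              mask_size(x$gm_mask), mask_size(x$wm_mask),
              mask_size(x$csf_mask)))
  invisible(x)
}

#' Generate a synthetic cohort with severity-coupled signal
#'
#' Draws per-subject covariates emulating a PTSD symptom-provocation
#' sample (severity on a PCL-like 17-85 scale, mean ~62, SD ~13; age
#' ~N(34, 11); depression comorbidity 44%; substance-use comorbidity 25%)
#' and generates each subject with a seed derived from `config$seed`.
#' Within the designated coupling ROI the trauma-condition signal
#' amplitude is `effect_size + severity_coupling * z(severity)` noise-SD
#' units, so group-level regressions of weight maps on severity have a
#' known target.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param config A [sim_config()]; `config$seed` seeds the whole cohort.
#' @return List of per-subject lists `(subject, truth)`, with attribute
#'   `severity` (the cohort severity vector).
#' @export
generate_cohort <- function(n_subjects, config) {
  stopifnot(n_subjects >= 2, inherits(config, "sim_config"))
  with_preserved_seed(config$seed, {
    sev <- pmin(85, pmax(17, round(stats::rnorm(n_subjects, 62, 13))))
    age <- pmin(65, pmax(18, round(stats::rnorm(n_subjects, 34, 11))))
    dep <- stats::rbinom(n_subjects, 1, 0.44)
    sub <- stats::rbinom(n_subjects, 1, 0.25)
    seeds <- derive_seeds(config$seed, n_subjects)
    z_sev <- as.numeric(scale(sev))
    out <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      cfg_i <- config
      cfg_i$seed <- as.integer(seeds[i])
      cov_i <- data.frame(severity = sev[i], age = age[i],
                          depression = dep[i], substance_use = sub[i])
      coup_amp <- if (config$severity_coupling != 0)
        config$effect_size + config$severity_coupling * z_sev[i] else 0
      out[[i]] <- generate_subject(cfg_i, covariates = cov_i,
                                   coupling_amplitude = coup_amp)
    }
    attr(out, "severity") <- sev
    out
  })
}

#' Inject a motion-coupled artifact into a subject's runs
#'
#' Adds `loading_v * FD_t` (framewise displacement, see
#' [framewise_displacement()]) to every brain voxel at each TR. The
#' loadings are spatially heterogeneous (uniform on `[0, scale]` by
#' default, drawn once per subject) because a spatially uniform artifact
#' would be absorbed by the WM/CSF mean regressors; heterogeneous motion
#' coupling is what survives nuisance regression in real data. Used as a
#' positive control for the motion-control classifier.
#'
#' @param subject A `subject_dataset`.
#' @param scale Maximum artifact amplitude per unit FD, in raw signal
#'   units.
#' @param loadings Optional per-brain-voxel loading vector (length = brain
#'   voxel count); defaults to `runif(n, 0, scale)`.
#' @return The modified `subject_dataset`.
#' @export
inject_motion_artifact <- function(subject, scale, loadings = NULL) {
  brain <- subject$gm_mask | subject$wm_mask | subject$csf_mask
  brain_lin <- which(brain)
  if (is.null(loadings))
    loadings <- stats::runif(length(brain_lin), 0, scale)
  stopifnot(length(loadings) == length(brain_lin))
  for (r in seq_along(subject$runs)) {
    run <- subject$runs[[r]]
    fd <- framewise_displacement(run$motion)
    d <- dim(run$data)
    flat <- matrix(run$data, prod(d[1:3]), d[4])
    flat[brain_lin, ] <- flat[brain_lin, ] + outer(loadings, fd)
    run$data <- array(flat, d)
    subject$runs[[r]] <- run
  }
  subject
}
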