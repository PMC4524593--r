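#' Group-level statistics configuration
#'
#' @param voxel_p_threshold Uncorrected voxelwise p threshold (default
#'   .01).
#' @param min_cluster_extent Minimum surviving cluster size in voxels
#'   (default 47; this is an input convention, not a recomputed constant —
#'   it depends on the data's smoothness and mask, see
#'   [estimate_cluster_extent()]).
#' @param connectivity Neighbourhood for cluster formation: 6 (faces), 18
#'   (+edges) or 26 (+corners; default, the common reporting convention).
#' @param n_null_sims Monte-Carlo simulations for the extent estimator.
#' @param seed Seed for the extent estimator.
#' @return Object of class `group_stats_config`.
#' @export
group_stats_config <- function(voxel_p_threshold = 0.01,
                               min_cluster_extent = 47,
                               connectivity = 26, n_null_sims = 1000,
                               seed = 1) {
  stopifnot(voxel_p_threshold > 0, voxel_p_threshold < 1,
            min_cluster_extent >= 1, connectivity %in% c(6, 18, 26))
  structure(list(voxel_p_threshold = voxel_p_threshold,
                 min_cluster_extent = as.integer(min_cluster_extent),
                 connectivity = as.integer(connectivity),
                 n_null_sims = as.integer(n_null_sims), seed = seed),
            class = "group_stats_config")
}

# Normalize weight maps input: a subjects x P matrix, or a list of equal-
# length vectors.
as_map_matrix <- function(weight_maps) {
  if (is.list(weight_maps)) weight_maps <- do.call(rbind, weight_maps)
  stopifnot(is.matrix(weight_maps))
  weight_maps
}

#' Voxelwise one-sample t-test map across subjects
#'
#' Per voxel, tests whether the cross-subject mean weight differs from
#' zero (two-sided). Voxels with zero cross-subject variance get the
#' sentinel p = 1 and are counted in the `n_degenerate` attribute.
#'
#' @param weight_maps Subjects x P matrix (or list of per-subject weight
#'   vectors) over a common mask.
#' @param mask The common mask (P = `mask_size(mask)`), used to reshape
#'   results onto the grid.
#' @return Object of class `group_map`: list with `stat` and `p` vectors,
#'   `mask`, `kind = "onesample_t"`, `df`.
#' @export
onesample_t_map <- function(weight_maps, mask) {
  W <- as_map_matrix(weight_maps)
  n <- nrow(W)
  stopifnot(n >= 3, ncol(W) == mask_size(mask))
  m <- colMeans(W)
  s <- sqrt(colSums(sweep(W, 2, m)^2) / (n - 1))
  degen <- s <= 0
  tval <- ifelse(degen, 0, m / (s / sqrt(n)))
  p <- ifelse(degen, 1, 2 * stats::pt(-abs(tval), df = n - 1))
  structure(list(stat = tval, p = p, mask = mask, kind = "onesample_t",
                 df = n - 1, n_degenerate = sum(degen)),
            class = "group_map")
}

# Huber IRLS robust regression cross-checked against MASS::rlm; MASS::rlm
# is the engine (psi.huber, k = 1.345), with p-values from the t
# distribution on n - p degrees of freedom.
robust_fit <- function(X, y) {
  fit <- MASS::rlm(X, y, psi = MASS::psi.huber, k = 1.345,
                   maxit = 50, acc = 1e-8)
  cf <- summary(fit)$coefficients
  list(coef = cf[, "Value"], se = cf[, "Std. Error"], t = cf[, "t value"])
}

#' Voxelwise robust regression of weight maps on symptom severity
#'
#' Per voxel, fits a robust linear model (Huber M-estimator, tuning
#' constant 1.345, iteratively reweighted least squares) of the subject
#' weights on severity, controlling for age and the binary depression and
#' substance-use comorbidity indicators. Reports the severity slope, its
#' t-type statistic and a two-sided p-value on n - p degrees of freedom.
#'
#' @param weight_maps Subjects x P matrix (or list of vectors).
#' @param severity Per-subject severity scores.
#' @param covariates Data frame with columns `age`, `depression`,
#'   `substance_use` (binary covariates entered as 0/1), or `NULL` for a
#'   severity-only model.
#' @param mask The common mask.
#' @return A `group_map` with `stat` (severity t), `p`, and `slope`.
#' @export
robust_regress_map <- function(weight_maps, severity, covariates = NULL,
                               mask) {
  W <- as_map_matrix(weight_maps)
  n <- nrow(W)
  stopifnot(length(severity) == n, ncol(W) == mask_size(mask))
  X <- cbind(intercept = 1, severity = severity)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == n)
    X <- cbind(X, age = covariates$age, depression = covariates$depression,
               substance_use = covariates$substance_use)
  }
  if (qr(X)$rank < ncol(X)) stop("degenerate covariates: collinear design")
  if (n < ncol(X) + 1) stop("need at least ", ncol(X) + 1, " subjects")
  P <- ncol(W)
  slope <- tval <- numeric(P)
  df <- n - ncol(X)
  for (v in seq_len(P)) {
    f <- robust_fit(X, W[, v])
    slope[v] <- f$coef["severity"]
    tval[v] <- f$t["severity"]
  }
  p <- 2 * stats::pt(-abs(tval), df = df)
  structure(list(stat = tval, p = p, slope = slope, mask = mask,
                 kind = "robust_severity", df = df),
            class = "group_map")
}

#' @export
print.group_map <- function(x, ...) {
  cat(sprintf("group_map (%s): %d voxels, df = %d\n",
              x$kind, length(x$stat), x$df))
  cat(sprintf("  p < .05 at %d voxels, p < .01 at %d\n",
              sum(x$p < .05), sum(x$p < .01)))
  if (!is.null(x$clusters))
    cat(sprintf("  %d surviving cluster(s), extent >= %d\n",
                nrow(x$clusters), attr(x$clusters, "min_extent")))
  invisible(x)
}

# Precomputed neighbour offsets for a connectivity scheme.
neighbour_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

# Label connected components of a logical 3-D array via breadth-first
# search over the chosen neighbourhood.
label_components <- function(vol, connectivity = 26) {
  d <- dim(vol)
  off <- neighbour_offsets(connectivity)
  labels <- array(0L, d)
  idx <- which(vol, arr.ind = TRUE)
  if (nrow(idx) == 0) return(labels)
  lin <- which(vol)
  inset <- array(FALSE, d); inset[lin] <- TRUE
  cur <- 0L
  for (s in seq_along(lin)) {
    if (labels[lin[s]] != 0L) next
    cur <- cur + 1L
    queue <- lin[s]
    labels[queue] <- cur
    while (length(queue)) {
      q <- arrayInd(queue, d)
      nxt <- integer(0)
      for (o in seq_len(nrow(off))) {
        nb <- sweep(q, 2, off[o, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
              nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        nb <- nb[ok, , drop = FALSE]
        nl <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
        new <- nl[inset[nl] & labels[nl] == 0L]
        if (length(new)) {
          labels[new] <- cur
          nxt <- c(nxt, new)
        }
      }
      queue <- unique(nxt)
    }
  }
  labels
}

#' Cluster-extent thresholding of a group map
#'
#' Forms connected components (configurable connectivity) of voxels with
#' `p < voxel_p_threshold` and removes components smaller than
#' `min_cluster_extent` voxels, the conventional cluster-level correction.
#'
#' @param map A `group_map`.
#' @param cfg A [group_stats_config()].
#' @return The map augmented with `cluster_labels` (3-D array, 0 outside
#'   surviving clusters) and a `clusters` data frame (id, size, peak
#'   statistic and peak voxel index).
#' @export
cluster_threshold <- function(map, cfg = group_stats_config()) {
  stopifnot(inherits(map, "group_map"))
  grid <- mask_grid(map$mask)
  supra <- array(FALSE, grid$dims)
  lin <- mask_indices(map$mask)
  supra[lin] <- map$p < cfg$voxel_p_threshold
  labels <- label_components(supra, cfg$connectivity)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= cfg$min_cluster_extent)
  out_labels <- array(0L, grid$dims)
  clusters <- data.frame(id = integer(0), size = integer(0),
                         peak_stat = numeric(0), peak_voxel = integer(0))
  stat_vol <- array(NA_real_, grid$dims)
  stat_vol[lin] <- map$stat
  for (new_id in seq_along(keep)) {
    members <- which(labels == keep[new_id])
    out_labels[members] <- new_id
    pk <- members[which.max(abs(stat_vol[members]))]
    clusters <- rbind(clusters,
                      data.frame(id = new_id, size = length(members),
                                 peak_stat = stat_vol[pk], peak_voxel = pk))
  }
  attr(clusters, "min_extent") <- cfg$min_cluster_extent
  map$cluster_labels <- out_labels
  map$clusters <- clusters
  map
}

#' Monte-Carlo cluster-extent threshold estimation
#'
#' Estimates the cluster size needed for a corrected p < `target_corrected_p`
#' by simulating smooth Gaussian null volumes: white noise on the grid is
#' smoothed to the stated FWHM, z-scored within the mask, thresholded
#' two-sided at `voxel_p`, and the maximum suprathreshold cluster size is
#' recorded per simulation; the returned extent is the
#' `(1 - target_corrected_p)` quantile of that null distribution plus one
#' (the smallest size whose null exceedance probability is below target).
#'
#' @param mask Analysis mask.
#' @param fwhm_mm Smoothness of the null field.
#' @param voxel_p Uncorrected voxelwise threshold.
#' @param target_corrected_p Desired corrected level (default .05).
#' @param n_null_sims Number of simulations (>= 100).
#' @param seed Integer seed (deterministic output).
#' @param connectivity Cluster-forming neighbourhood (default 26).
#' @return Integer extent threshold.
#' @export
estimate_cluster_extent <- function(mask, fwhm_mm, voxel_p = 0.01,
                                    target_corrected_p = 0.05,
                                    n_null_sims = 200, seed = 1,
                                    connectivity = 26) {
  stopifnot(n_null_sims >= 100)
  grid <- mask_grid(mask)
  lin <- mask_indices(mask)
  zthr <- stats::qnorm(1 - voxel_p / 2)
  with_preserved_seed(seed, {
    max_sizes <- vapply(seq_len(n_null_sims), function(i) {
      vol <- array(stats::rnorm(prod(grid$dims)), grid$dims)
      if (fwhm_mm > 0)
        vol <- gaussian_smooth(vol, fwhm_mm, grid$voxel_size_mm)
      z <- vol[lin]
      z <- (z - mean(z)) / stats::sd(z)
      supra <- array(FALSE, grid$dims)
      supra[lin] <- abs(z) > zthr
      labels <- label_components(supra, connectivity)
      if (!any(labels > 0)) return(0L)
      max(tabulate(labels[labels > 0]))
    }, integer(1))
    as.integer(stats::quantile(max_sizes, 1 - target_corrected_p,
                               type = 1)) + 1L
  })
}

#' ROI-level group tests on weight maps
#'
#' For each ROI: the cross-subject mean of the per-subject mean weight
#' within the ROI, its one-sample t-test against zero, and the robust-
#' regression severity slope with covariates.
#'
#' @param weight_maps Subjects x P matrix (or list) over `mask`.
#' @param roi_set A `mask_set`; ROI voxels outside `mask` are ignored.
#' @param severity Per-subject severity scores.
#' @param covariates Covariate data frame as in [robust_regress_map()].
#' @param mask The common feature mask the maps were computed on.
#' @return Data frame with one row per ROI: `roi`, `n_voxels`,
#'   `mean_weight`, `t`, `p_t`, `slope`, `p_slope`; degenerate ROIs
#'   (empty, or zero-variance weights) are flagged with NA statistics.
#' @export
roi_level_tests <- function(weight_maps, roi_set, severity,
                            covariates = NULL, mask) {
  W <- as_map_matrix(weight_maps)
  n <- nrow(W)
  lin <- mask_indices(mask)
  X <- cbind(intercept = 1, severity = severity)
  if (!is.null(covariates))
    X <- cbind(X, age = covariates$age, depression = covariates$depression,
               substance_use = covariates$substance_use)
  out <- lapply(names(roi_set), function(nm) {
    pos <- match(intersect(mask_indices(roi_set[[nm]]), lin), lin)
    if (!length(pos))
      return(data.frame(roi = nm, n_voxels = 0L, mean_weight = NA,
                        t = NA, p_t = NA, slope = NA, p_slope = NA))
    roi_mean <- rowMeans(W[, pos, drop = FALSE])
    if (stats::sd(roi_mean) == 0)
      return(data.frame(roi = nm, n_voxels = length(pos),
                        mean_weight = mean(roi_mean), t = NA, p_t = NA,
                        slope = NA, p_slope = NA))
    ht <- stats::t.test(roi_mean)
    f <- robust_fit(X, roi_mean)
    df <- n - ncol(X)
    data.frame(roi = nm, n_voxels = length(pos),
               mean_weight = mean(roi_mean),
               t = unname(ht$statistic), p_t = ht$p.value,
               slope = unname(f$coef["severity"]),
               p_slope = 2 * stats::pt(-abs(f$t["severity"]), df = df))
  })
  do.call(rbind, out)
}
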