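mask_of <- function(dims, n) {
  g <- voxel_grid(dims)
  m <- empty_mask(g); m[seq_len(n)] <- TRUE; attr(m, "grid") <- g
  m
}

test_that("one-sample t maps: sign, sentinel and null calibration", {
  set.seed(1)
  n <- 16; P <- 2000
  W <- matrix(rnorm(n * P), n, P)
  W[, 1] <- 5          # zero cross-subject variance, nonzero mean
  W[, 2] <- W[, 2] + 3 # strong positive mean
  m <- mask_of(c(15, 15, 10), P)
  gm <- onesample_t_map(W, m)
  expect_equal(gm$p[1], 1)                # sentinel path
  expect_equal(gm$n_degenerate, 1)
  expect_gt(gm$stat[2], 0)
  expect_lt(gm$p[2], 1e-4)
  expect_equal(sign(gm$stat[-1]), sign(colMeans(W[, -1])))
  # exact null calibration of the remaining voxels
  rej <- mean(gm$p[-(1:2)] < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / (P - 2)))
  # cross-check a voxel against t.test
  tt <- t.test(W[, 10])
  expect_equal(gm$stat[10], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(gm$p[10], tt$p.value, tolerance = 1e-10)
})

test_that("robust severity regression recovers slopes and respects invariances", {
  set.seed(2)
  n <- 16; P <- 150; beta <- 2
  sev <- rnorm(n, 62, 13); z <- as.numeric(scale(sev))
  cov <- data.frame(age = rnorm(n, 34, 11), depression = rbinom(n, 1, 0.44),
                    substance_use = rbinom(n, 1, 0.25))
  W <- beta * z %o% rep(1, P) + matrix(rnorm(n * P, sd = 0.2), n, P)
  m <- mask_of(c(10, 10, 10), P)
  gm <- suppressWarnings(robust_regress_map(W, sev, cov, m))
  # slope is per unit severity; convert to per-z units for comparison
  slope_z <- gm$slope * sd(sev)
  expect_lt(abs(mean(slope_z) - beta) / beta, 0.1)
  expect_true(all(gm$p[abs(slope_z - beta) < 0.5] < 0.01))
  # shifting severity by a constant leaves the slope unchanged
  gm_shift <- suppressWarnings(robust_regress_map(W, sev + 100, cov, m))
  expect_equal(gm_shift$slope, gm$slope, tolerance = 1e-6)
  # agrees with MASS::rlm run directly
  f <- MASS::rlm(cbind(1, sev, cov$age, cov$depression, cov$substance_use),
                 W[, 1], psi = MASS::psi.huber, k = 1.345, maxit = 50,
                 acc = 1e-8)
  expect_equal(gm$slope[1], unname(coef(f)[2]), tolerance = 1e-8)
  # collinear designs are rejected
  bad <- cov
  bad$substance_use <- bad$depression
  expect_error(robust_regress_map(W, sev, bad, m), "collinear")
})

test_that("cluster thresholding keeps only components reaching the extent", {
  g <- voxel_grid(c(12, 12, 12))
  mask <- as_mask(array(TRUE, g$dims), g)
  p <- rep(0.5, prod(g$dims))
  blob <- function(ctr, n) {
    sph <- which(sphere_mask(grid_index_to_mm(g, ctr), 9, g))
    sph[seq_len(n)]
  }
  big <- blob(c(4, 4, 4), 50)
  small <- blob(c(9, 9, 9), 40)
  p[big] <- 0.001; p[small] <- 0.001
  gm <- structure(list(stat = rnorm(prod(g$dims)) + 5, p = p, mask = mask,
                       kind = "onesample_t", df = 15), class = "group_map")
  out <- cluster_threshold(gm, group_stats_config(voxel_p_threshold = 0.01,
                                                  min_cluster_extent = 47))
  expect_equal(nrow(out$clusters), 1)
  expect_equal(out$clusters$size, 50)
  expect_setequal(which(out$cluster_labels > 0), big)
  # a 40-voxel blob alone fails the 47-voxel extent
  p2 <- rep(0.5, prod(g$dims)); p2[small] <- 0.001
  gm2 <- gm; gm2$p <- p2
  out2 <- cluster_threshold(gm2, group_stats_config())
  expect_equal(nrow(out2$clusters), 0)
  # empty suprathreshold set
  gm3 <- gm; gm3$p <- rep(0.9, prod(g$dims))
  out3 <- cluster_threshold(gm3, group_stats_config())
  expect_equal(nrow(out3$clusters), 0)
  expect_true(all(out3$cluster_labels == 0))
})

# Recursive flood-fill oracle for connected-component labelling.
flood_oracle <- function(vol, connectivity) {
  d <- dim(vol)
  off <- boldmvpa:::neighbour_offsets(connectivity)
  lab <- array(0L, d); cur <- 0L
  for (start in which(vol)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (lab[v] != 0L) next
      lab[v] <- cur
      vi <- arrayInd(v, d)
      for (o in seq_len(nrow(off))) {
        nb <- vi + off[o, ]
        if (any(nb < 1) || any(nb > d)) next
        nl <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
        if (vol[nl] && lab[nl] == 0L) stack <- c(stack, nl)
      }
    }
  }
  lab
}

test_that("component labelling agrees with a flood-fill oracle on random volumes", {
  set.seed(3)
  for (conn in c(6, 18, 26)) for (rep in 1:4) {
    vol <- array(runif(8^3) < 0.25, c(8, 8, 8))
    mine <- boldmvpa:::label_components(vol, conn)
    orac <- flood_oracle(vol, conn)
    # same partition up to label renaming: compare component size multisets
    # and co-membership on a sample of voxel pairs
    expect_equal(sort(tabulate(mine[mine > 0])),
                 sort(tabulate(orac[orac > 0])))
    on_vox <- which(vol)
    if (length(on_vox) >= 2) {
      pairs <- cbind(sample(on_vox, 200, TRUE), sample(on_vox, 200, TRUE))
      expect_equal(mine[pairs[, 1]] == mine[pairs[, 2]],
                   orac[pairs[, 1]] == orac[pairs[, 2]])
    }
  }
})

test_that("Monte-Carlo extent estimates are deterministic and monotone", {
  g <- voxel_grid(c(10, 10, 10))
  mask <- as_mask(array(TRUE, g$dims), g)
  e_white <- estimate_cluster_extent(mask, 0, voxel_p = 0.01,
                                     n_null_sims = 100, seed = 9)
  e_white2 <- estimate_cluster_extent(mask, 0, voxel_p = 0.01,
                                      n_null_sims = 100, seed = 9)
  expect_identical(e_white, e_white2)
  expect_lte(e_white, 6)   # white noise: only a few contiguous voxels
  e_smooth <- estimate_cluster_extent(mask, 6, voxel_p = 0.01,
                                      n_null_sims = 100, seed = 9)
  expect_gt(e_smooth, e_white)
  e_strict <- estimate_cluster_extent(mask, 6, voxel_p = 0.001,
                                      n_null_sims = 100, seed = 9)
  expect_lte(e_strict, e_smooth)
})

test_that("ROI-level tests report means, tests and degeneracies per region", {
  set.seed(10)
  g <- voxel_grid(c(12, 12, 12))
  mask <- as_mask(array(TRUE, g$dims), g)
  specs <- data.frame(name = c("hot", "cold", "far"),
                      x = c(0, 9, 400), y = c(0, 9, 0), z = c(0, 9, 0),
                      radius = 6)
  rs <- suppressWarnings(mask_set(specs, g))
  n <- 16
  sev <- rnorm(n, 62, 13)
  W <- matrix(rnorm(n * mask_size(mask), sd = 0.5), n, mask_size(mask))
  hot_cols <- match(mask_indices(rs$hot), mask_indices(mask))
  W[, hot_cols] <- W[, hot_cols] + 2
  tb <- roi_level_tests(W, rs, sev, covariates = NULL, mask = mask)
  expect_equal(nrow(tb), 3)
  expect_equal(tb$n_voxels[tb$roi == "far"], 0)
  expect_true(is.na(tb$t[tb$roi == "far"]))
  expect_lt(tb$p_t[tb$roi == "hot"], 0.001)
  expect_gt(tb$p_t[tb$roi == "cold"], tb$p_t[tb$roi == "hot"])
  # ROI mean invariant to voxel order within the ROI
  expect_equal(tb$mean_weight[tb$roi == "hot"], mean(W[, hot_cols]))
  # all-zero maps are degenerate-flagged
  tb0 <- roi_level_tests(matrix(0, n, mask_size(mask)), rs, sev,
                         covariates = NULL, mask = mask)
  expect_true(all(is.na(tb0$t[tb0$n_voxels > 0])))
  expect_equal(tb0$mean_weight[tb0$roi == "hot"], 0)
})
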