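#' Spherical voxel mask around a world coordinate
#'
#' The centre is snapped to the nearest voxel centre, and every voxel whose
#' centre-to-centre Euclidean distance to that voxel is less than or equal
#' to `radius_mm` is included (inclusive boundary). On a 3 mm isotropic
#' grid a 6 mm radius therefore yields 33 voxels; a strict inequality
#' would drop the 6 face voxels at exactly 6 mm and give 27.
#'
#' @param center_mm Length-3 world coordinate (mm) of the sphere centre.
#' @param radius_mm Sphere radius in mm (> 0 for a sphere; 0 selects the
#'   single voxel containing the centre).
#' @param grid A [voxel_grid()].
#' @return Logical mask array. Empty (all-FALSE) when the snapped centre
#'   lies so far outside the grid that no voxel is within reach; callers
#'   that require a non-empty mask should check [mask_size()].
#' @examples
#' g <- voxel_grid(c(24, 24, 24))
#' mask_size(sphere_mask(c(0, 0, 0), 6, g))  # 33
#' @export
sphere_mask <- function(center_mm, radius_mm, grid) {
  stopifnot(radius_mm >= 0)
  ctr_idx <- grid_mm_to_index(grid, center_mm)
  r_vox <- radius_mm / grid$voxel_size_mm
  # enumerate the integer offset cube once; exact squared-distance test
  span <- floor(r_vox + 1e-9)
  off <- seq.int(-span, span)
  m <- empty_mask(grid)
  r2 <- r_vox^2 + 1e-9
  for (dz in off) for (dy in off) for (dx in off) {
    if (dx * dx + dy * dy + dz * dz <= r2) {
      i <- ctr_idx[1] + dx; j <- ctr_idx[2] + dy; k <- ctr_idx[3] + dz
      if (i >= 1 && i <= grid$dims[1] && j >= 1 && j <= grid$dims[2] &&
          k >= 1 && k <= grid$dims[3]) m[i, j, k] <- TRUE
    }
  }
  m
}

#' Meta-analytic PTSD-neurocircuitry ROI coordinates
#'
#' Centres of mass (MNI mm) of the eight regions recurrently implicated in
#' PTSD neurocircuitry models and symptom-provocation meta-analyses:
#' the left amygdalohippocampal junction, left and right hippocampus,
#' perigenual and dorsal anterior cingulate, retrosplenial cortex,
#' posterior cingulate, and precuneus.
#'
#' @param radius_mm Sphere radius for each ROI (default 6).
#' @return Data frame with columns `name`, `x`, `y`, `z`, `radius`.
#' @export
ptsd_roi_table <- function(radius_mm = 6) {
  data.frame(
    name = c("L_amygdalohippocampal", "L_hippocampus", "R_hippocampus",
             "perigenual_ACC", "dorsal_ACC", "retrosplenial",
             "posterior_cingulate", "precuneus"),
    x = c(-20, -32, 28, -10, 3, 0, 2, -1),
    y = c(-8, -20, -12, 24, 26, -53, -50, -56),
    z = c(-16, -8, -24, 22, 21, 8, 22, 35),
    radius = radius_mm,
    stringsAsFactors = FALSE
  )
}

#' Construct a named set of ROI masks
#'
#' @param specs Data frame with columns `name`, `x`, `y`, `z`, `radius`
#'   (mm), one row per spherical ROI.
#' @param grid A [voxel_grid()].
#' @param gm_mask Optional grey-matter mask; each sphere is intersected
#'   with it when supplied.
#' @param set_name Label for the set.
#' @param provenance Free-text provenance note stored with the set.
#' @return An object of class `mask_set`: a named list of masks with
#'   attributes `name`, `provenance`, `voxel_counts` and `flagged` (names
#'   of ROIs left empty after grid clipping / GM intersection; they are
#'   retained so set geometry stays comparable across grids).
#' @export
mask_set <- function(specs, grid, gm_mask = NULL, set_name = "roi_set",
                     provenance = "fixed coordinates") {
  stopifnot(all(c("name", "x", "y", "z", "radius") %in% names(specs)))
  rois <- vector("list", nrow(specs))
  names(rois) <- specs$name
  for (i in seq_len(nrow(specs))) {
    m <- sphere_mask(c(specs$x[i], specs$y[i], specs$z[i]), specs$radius[i], grid)
    if (!is.null(gm_mask)) m <- as_mask(m & gm_mask, grid)
    rois[[i]] <- m
  }
  counts <- vapply(rois, mask_size, integer(1))
  flagged <- names(counts)[counts == 0L]
  if (length(flagged))
    warning(sprintf("ROI(s) empty after clipping/GM intersection: %s",
                    paste(flagged, collapse = ", ")))
  structure(rois, class = "mask_set", name = set_name,
            provenance = provenance, voxel_counts = counts, flagged = flagged)
}

#' @export
print.mask_set <- function(x, ...) {
  cnt <- attr(x, "voxel_counts")
  cat(sprintf("mask_set '%s' (%d ROIs, %d voxels in union; %s)\n",
              attr(x, "name"), length(x), mask_size(mask_union(x)),
              attr(x, "provenance")))
  for (nm in names(x)) cat(sprintf("  %-24s %d voxels\n", nm, cnt[[nm]]))
  invisible(x)
}

#' Union of all ROIs in a mask set
#' @param roi_set A `mask_set`.
#' @return A single logical mask (overlaps de-duplicated).
#' @export
mask_union <- function(roi_set) {
  stopifnot(length(roi_set) >= 1)
  g <- mask_grid(roi_set[[1]])
  u <- Reduce(`|`, roi_set)
  as_mask(u, g)
}

#' The eight PTSD-neurocircuitry spherical ROIs
#'
#' Places a 6 mm sphere at each meta-analytic centre of mass from
#' [ptsd_roi_table()] and intersects each with the grey-matter mask.
#' ROIs whose coordinates fall outside a small grid (or outside GM) are
#' retained empty and flagged, so downstream bookkeeping never loses a
#' region silently.
#'
#' @param grid A [voxel_grid()] whose world coordinates are MNI-style mm.
#' @param gm_mask Grey-matter mask on `grid`.
#' @param radius_mm Sphere radius (default 6).
#' @return A `mask_set` of 8 named ROIs.
#' @export
ptsd_roi_set <- function(grid, gm_mask, radius_mm = 6) {
  mask_set(ptsd_roi_table(radius_mm), grid, gm_mask,
           set_name = "ptsd_rois", provenance = "meta-analytic MNI coordinates")
}

#' Randomly placed spherical ROI sets within grey matter
#'
#' Draws ROI centres uniformly from the grey-matter voxels and intersects
#' each sphere with the GM mask; spheres may overlap (unions are
#' de-duplicated when counting features). Deterministic for a given seed.
#'
#' @param grid A [voxel_grid()].
#' @param gm_mask Grey-matter mask on `grid`.
#' @param n_sets Number of independent sets (default 10).
#' @param n_rois Spheres per set (default 8).
#' @param radius_mm Sphere radius (default 6).
#' @param seed Integer seed.
#' @return List of `mask_set` objects of length `n_sets`.
#' @export
random_roi_sets <- function(grid, gm_mask, n_sets = 10, n_rois = 8,
                            radius_mm = 6, seed = 1) {
  stopifnot(n_sets >= 1, n_rois >= 1)
  gm_idx <- mask_which(gm_mask)
  if (nrow(gm_idx) < n_rois)
    stop("gm_mask too small to host ", n_rois, " ROI centres")
  with_preserved_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      ctr <- gm_idx[sample.int(nrow(gm_idx), n_rois), , drop = FALSE]
      specs <- data.frame(
        name = sprintf("random_%02d", seq_len(n_rois)),
        x = grid_index_to_mm(grid, ctr)[, 1],
        y = grid_index_to_mm(grid, ctr)[, 2],
        z = grid_index_to_mm(grid, ctr)[, 3],
        radius = radius_mm
      )
      mask_set(specs, grid, gm_mask, set_name = sprintf("random_set_%02d", s),
               provenance = sprintf("random centres, seed %d, set %d", seed, s))
    })
  })
}

#' Grey matter minus a set of ROIs
#'
#' @param gm_mask Grey-matter mask.
#' @param roi_set A `mask_set` on the same grid.
#' @return Mask of GM voxels outside the union of the ROIs. Together with
#'   the union it partitions GM exactly.
#' @export
mask_complement <- function(gm_mask, roi_set) {
  g <- mask_grid(gm_mask)
  if (length(roi_set) == 0) return(as_mask(gm_mask, g))
  as_mask(gm_mask & !mask_union(roi_set), g)
}

#' Group grey-matter mask by subject-count consensus
#'
#' Retains voxels present in at least `min_fraction` of the subjects'
#' individual GM masks (default: at least half).
#'
#' @param gm_masks List of GM masks on a common grid.
#' @param min_fraction Minimum fraction of subjects (default 0.5).
#' @return Consensus GM mask.
#' @export
group_gm_mask <- function(gm_masks, min_fraction = 0.5) {
  stopifnot(length(gm_masks) >= 1)
  g <- mask_grid(gm_masks[[1]])
  counts <- Reduce(`+`, lapply(gm_masks, function(m) m * 1L))
  as_mask(counts >= min_fraction * length(gm_masks), g)
}

#' Read spherical ROI specifications from TSV
#'
#' Expects a header with columns `name`, `x`, `y`, `z` and optionally
#' `radius` (defaulting to 6 mm).
#'
#' @param path TSV file path.
#' @param default_radius_mm Radius used when the file has no radius column.
#' @return Data frame suitable for [mask_set()].
#' @export
read_roi_specs <- function(path, default_radius_mm = 6) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "x", "y", "z") %in% names(tb)))
  if (is.null(tb$radius)) tb$radius <- default_radius_mm
  tb
}

#' Per-ROI voxel-count report
#'
#' @param roi_set A `mask_set`.
#' @return Data frame with columns `roi`, `n_voxels` plus a union row.
#' @export
mask_set_report <- function(roi_set) {
  cnt <- attr(roi_set, "voxel_counts")
  rbind(data.frame(roi = names(cnt), n_voxels = as.integer(cnt)),
        data.frame(roi = ".union", n_voxels = mask_size(mask_union(roi_set))))
}
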