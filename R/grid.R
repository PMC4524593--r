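#' Define a regular isotropic voxel grid
#'
#' A voxel grid ties integer voxel indices to millimetre (MNI-style world)
#' coordinates. Voxel `(1,1,1)` sits at `origin_mm`; voxel `(i,j,k)` sits at
#' `origin_mm + (c(i,j,k) - 1) * voxel_size_mm`. By default the origin is
#' chosen so that the grid is centred on the world origin, which keeps
#' typical subcortical coordinates inside small desk-scale grids.
#'
#' @param dims Integer vector of length 3, voxels along x, y, z.
#' @param voxel_size_mm Isotropic voxel edge length in mm (default 3).
#' @param origin_mm World coordinate (mm) of voxel `(1,1,1)`. Defaults to
#'   `-(dims - 1) / 2 * voxel_size_mm`, centring the grid on `(0,0,0)`.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(24, 24, 24))
#' grid_index_to_mm(g, c(1, 1, 1))
#' @export
voxel_grid <- function(dims, voxel_size_mm = 3, origin_mm = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1),
            length(voxel_size_mm) == 1, voxel_size_mm > 0)
  if (is.null(origin_mm)) origin_mm <- -(dims - 1) / 2 * voxel_size_mm
  stopifnot(length(origin_mm) == 3)
  structure(list(dims = dims, voxel_size_mm = as.numeric(voxel_size_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, %.3g mm isotropic\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size_mm))
  cat(sprintf("  origin (mm): %s\n", paste(signif(x$origin_mm, 4), collapse = ", ")))
  invisible(x)
}

#' Map voxel indices to world coordinates
#'
#' @param grid A [voxel_grid()].
#' @param idx Integer vector of length 3 or an n x 3 matrix of 1-based
#'   voxel indices.
#' @return Numeric vector or n x 3 matrix of mm coordinates.
#' @export
grid_index_to_mm <- function(grid, idx) {
  if (is.null(dim(idx))) {
    grid$origin_mm + (as.numeric(idx) - 1) * grid$voxel_size_mm
  } else {
    sweep((idx - 1) * grid$voxel_size_mm, 2, grid$origin_mm, "+")
  }
}

#' Map world coordinates to the nearest voxel index
#'
#' Coordinates are snapped to the nearest voxel centre; indices may fall
#' outside `1..dims` when the point lies off the grid (callers decide
#' whether that is an error).
#'
#' @inheritParams grid_index_to_mm
#' @param mm Numeric vector of length 3 or an n x 3 matrix of coordinates.
#' @return Integer vector or matrix of 1-based voxel indices.
#' @export
grid_mm_to_index <- function(grid, mm) {
  if (is.null(dim(mm))) {
    as.integer(round((as.numeric(mm) - grid$origin_mm) / grid$voxel_size_mm)) + 1L
  } else {
    round(sweep(mm, 2, grid$origin_mm, "-") / grid$voxel_size_mm) + 1L
  }
}

#' Create an empty (all-FALSE) mask on a grid
#'
#' Masks are logical 3-D arrays carrying their grid as an attribute, so
#' set operations (`&`, `|`, `!`) work elementwise.
#'
#' @param grid A [voxel_grid()].
#' @return Logical array of dimension `grid$dims` with attribute `grid`.
#' @export
empty_mask <- function(grid) {
  m <- array(FALSE, dim = grid$dims)
  attr(m, "grid") <- grid
  m
}

#' Coerce logical data to a mask on a grid
#'
#' @param x Logical array or vector of length `prod(grid$dims)`.
#' @param grid A [voxel_grid()].
#' @return Logical mask array carrying the grid attribute.
#' @export
as_mask <- function(x, grid) {
  m <- array(as.logical(x), dim = grid$dims)
  attr(m, "grid") <- grid
  m
}

mask_grid <- function(mask) {
  g <- attr(mask, "grid")
  if (is.null(g)) stop("mask carries no voxel_grid attribute")
  g
}

#' Number of voxels in a mask
#' @param mask Logical mask array.
#' @return Integer count of TRUE voxels.
#' @export
mask_size <- function(mask) sum(mask)

#' Linear indices of the voxels in a mask
#' @param mask Logical mask array.
#' @return Integer vector of linear array indices.
#' @export
mask_indices <- function(mask) which(mask)

#' Voxel index triplets of a mask
#' @param mask Logical mask array.
#' @return n x 3 integer matrix of (i, j, k) indices.
#' @export
mask_which <- function(mask) which(mask, arr.ind = TRUE)
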