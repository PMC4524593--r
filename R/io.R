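# On-disk layout: one 4-D NIfTI-1 file per run plus a 6-column
# whitespace-delimited motion table per run, NIfTI masks, a covariates TSV
# and a manifest TSV tying run files to condition and repetition.

grid_affine <- function(grid) {
  aff <- diag(c(rep(grid$voxel_size_mm, 3), 1))
  aff[1:3, 4] <- grid$origin_mm
  aff
}

write_nifti_on_grid <- function(arr, grid, path) {
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- rep(grid$voxel_size_mm, 3)
  RNifti::sform(im) <- structure(grid_affine(grid), code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

grid_from_nifti <- function(im) {
  aff <- RNifti::xform(im, useQuaternionFirst = FALSE)
  voxel <- sqrt(sum(aff[1:3, 1]^2))
  voxel_grid(dim(im)[1:3], voxel_size_mm = voxel, origin_mm = aff[1:3, 4])
}

#' Write a subject dataset to a directory
#'
#' Writes each run as a 4-D NIfTI-1 file with its motion parameters as a
#' 6-column whitespace-delimited text file (one row per TR), the three
#' tissue masks as NIfTI label volumes, the covariates as a TSV with
#' header `subject, severity, age, depression, substance_use`, and a
#' `manifest.tsv` listing run files with condition and repetition.
#'
#' @param subject A `subject_dataset`.
#' @param dir Output directory (created if needed).
#' @param subject_id Identifier used in file names and the covariate row.
#' @return Invisibly, the manifest data frame.
#' @export
write_subject <- function(subject, dir, subject_id = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(subject$runs)) {
    run <- subject$runs[[i]]
    stem <- sprintf("sub-%02d_cond-%s_rep-%d", subject_id,
                    run$condition, run$repetition)
    write_nifti_on_grid(run$data, run$grid,
                        file.path(dir, paste0(stem, "_bold.nii")))
    utils::write.table(run$motion,
                       file.path(dir, paste0(stem, "_motion.txt")),
                       row.names = FALSE, col.names = FALSE)
    rows[[i]] <- data.frame(file = paste0(stem, "_bold.nii"),
                            motion_file = paste0(stem, "_motion.txt"),
                            condition = run$condition,
                            repetition = run$repetition,
                            tr_seconds = run$tr_seconds)
  }
  for (tm in c("gm", "wm", "csf"))
    write_nifti_on_grid(subject[[paste0(tm, "_mask")]] * 1L, subject$grid,
                        file.path(dir, sprintf("sub-%02d_mask-%s.nii",
                                               subject_id, tm)))
  cov <- cbind(subject = subject_id, subject$covariates)
  utils::write.table(cov, file.path(dir, "covariates.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a subject dataset from a directory written by [write_subject()]
#'
#' @param dir Directory containing `manifest.tsv`, run/mask NIfTI files,
#'   motion tables and `covariates.tsv`.
#' @param subject_id Identifier used in the mask file names.
#' @return A `subject_dataset`.
#' @export
read_subject <- function(dir, subject_id = 1) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  runs <- lapply(seq_len(nrow(manifest)), function(i) {
    im <- RNifti::readNifti(file.path(dir, manifest$file[i]))
    grid <- grid_from_nifti(im)
    motion <- as.matrix(utils::read.table(
      file.path(dir, manifest$motion_file[i])))
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    bold_run(array(as.numeric(im), dim(im)), grid,
             manifest$tr_seconds[i], manifest$condition[i],
             manifest$repetition[i], motion)
  })
  grid <- runs[[1]]$grid
  read_mask <- function(tm) {
    im <- RNifti::readNifti(file.path(dir, sprintf("sub-%02d_mask-%s.nii",
                                                   subject_id, tm)))
    as_mask(array(as.numeric(im) > 0, dim(im)[1:3]), grid)
  }
  cov <- utils::read.delim(file.path(dir, "covariates.tsv"))
  structure(list(runs = runs, gm_mask = read_mask("gm"),
                 wm_mask = read_mask("wm"), csf_mask = read_mask("csf"),
                 covariates = cov[cov$subject == subject_id,
                                  c("severity", "age", "depression",
                                    "substance_use"), drop = FALSE],
                 grid = grid, tr_seconds = runs[[1]]$tr_seconds),
            class = "subject_dataset")
}

#' Write a weight map as a NIfTI volume
#'
#' @param weights Weight vector over `mask` (mask-index order).
#' @param mask The feature mask.
#' @param path Output NIfTI path.
#' @return Invisibly, the path.
#' @export
write_weight_map <- function(weights, mask, path) {
  grid <- mask_grid(mask)
  vol <- array(0, grid$dims)
  vol[mask_indices(mask)] <- weights
  write_nifti_on_grid(vol, grid, path)
}

#' Write a decoding results table as TSV
#'
#' @param results Results data frame (e.g. from [run_cohort()]).
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_results_table <- function(results, path) {
  utils::write.table(results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
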