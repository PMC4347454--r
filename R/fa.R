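#' Load a stack of pre-aligned FA volumes into a modality matrix
#'
#' Reads one NIfTI volume per subject, checks that every volume shares the
#' mask's grid, and extracts the within-mask voxels in the mask's linear
#' (column-major array) order — the order documented for back-projection.
#'
#' @param image_paths character vector of NIfTI file paths, one per subject.
#' @param mask a NIfTI path or logical/0-1 array; must select >= 1 voxel.
#' @param subjects optional subject IDs (defaults to file base names).
#' @return a [modality_matrix()] tagged `"fa"`, with a `mask_index`
#'   attribute mapping columns back to voxel linear indices.
#' @export
load_fa_stack <- function(image_paths, mask, subjects = NULL) {
  if (is.character(mask)) mask <- RNifti::readNifti(mask)
  mask_arr <- as.array(mask) != 0
  idx <- which(mask_arr)
  assert_that(length(idx) > 0, "mask selects no voxels")
  if (is.null(subjects)) {
    subjects <- sub("\\.nii(\\.gz)?$", "", basename(image_paths))
  }
  rows <- lapply(image_paths, function(p) {
    vol <- as.array(RNifti::readNifti(p))
    assert_that(identical(dim(vol), dim(mask_arr)),
                sprintf("volume grid of '%s' does not match the mask", p))
    vol[idx]
  })
  out <- modality_matrix(do.call(rbind, rows), subjects = subjects,
                         variables = sprintf("vox%06d", idx), modality = "fa")
  attr(out, "mask_index") <- idx
  attr(out, "mask_dim") <- dim(mask_arr)
  out
}

#' Write a modality matrix as per-subject NIfTI volumes plus a mask
#'
#' Inverse of [load_fa_stack()] on a synthetic 3-D grid: voxels are placed
#' at the mask's linear indices; off-mask voxels are zero.
#'
#' @param X subjects-by-voxels matrix.
#' @param dir output directory (created if needed).
#' @param grid_dim 3-vector of grid dimensions; product must be >= ncol(X).
#' @param mask_index voxel linear indices; default packs voxels from index 1.
#' @return list of image paths and the mask path.
#' @export
write_fa_stack <- function(X, dir, grid_dim = NULL, mask_index = NULL) {
  X <- as.matrix(X)
  if (is.null(mask_index)) mask_index <- attr(X, "mask_index")
  if (is.null(grid_dim)) grid_dim <- attr(X, "mask_dim")
  if (is.null(grid_dim)) {
    side <- ceiling(ncol(X)^(1 / 3))
    grid_dim <- c(side, side, ceiling(ncol(X) / side^2))
  }
  if (is.null(mask_index)) mask_index <- seq_len(ncol(X))
  assert_that(prod(grid_dim) >= max(mask_index), "grid too small for the mask")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mask <- array(0, grid_dim)
  mask[mask_index] <- 1
  mask_path <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(mask), mask_path)
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(X)))
  paths <- vapply(seq_len(nrow(X)), function(i) {
    vol <- array(0, grid_dim)
    vol[mask_index] <- X[i, ]
    p <- file.path(dir, paste0(ids[i], ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(vol), p)
    p
  }, character(1))
  list(images = paths, mask = mask_path)
}

#' Remove acquisition-site effects by voxelwise regression
#'
#' Per voxel, ordinary least squares of FA on an intercept plus site dummy
#' variables; the returned matrix holds the residuals plus each voxel's
#' grand mean, so per-site voxel means are equalized while grand means are
#' preserved.
#'
#' @param X1 subjects-by-voxels FA matrix.
#' @param site per-subject site labels; >= 2 sites with >= 2 subjects each
#'   unless `allow_single_site = TRUE` (then a single site is a no-op).
#' @param allow_single_site skip correction when only one site is present.
#' @return corrected [modality_matrix()].
#' @export
regress_out_site <- function(X1, site, allow_single_site = FALSE) {
  X <- mm_values(as.matrix(X1))
  site <- factor(site)
  assert_that(length(site) == nrow(X), "one site label per subject")
  if (nlevels(site) < 2L) {
    assert_that(allow_single_site,
                "a single site cannot be corrected; set allow_single_site = TRUE for a no-op")
    return(X1)
  }
  assert_that(min(table(site)) >= 2L, "every site needs >= 2 subjects")
  # reference level = first lexicographically (factor default); the fitted
  # subspace, hence the residuals, is invariant to this choice
  Dm <- stats::model.matrix(~site)
  qd <- qr(Dm)
  fitted <- qr.fitted(qd, X)
  out <- X - fitted + rep(colMeans(X), each = nrow(X))
  modality_matrix(out, subjects = rownames(X1), variables = colnames(X1),
                  modality = attr(X1, "modality"))
}

#' Post-hoc site-by-diagnosis check on component loadings
#'
#' Tabulates per-site diagnosis group means of a loading column, flags
#' whether the group-mean direction is the same at every site, and reports
#' the site-by-diagnosis interaction F-test p-value.
#'
#' @param loadings numeric loading vector aligned to the covariates.
#' @param site,diagnosis per-subject labels.
#' @return list with the `means` table (site x diagnosis), the
#'   `consistent_direction` flag, and `interaction_p`.
#' @export
check_site_by_diagnosis <- function(loadings, site, diagnosis) {
  site <- factor(site); dx <- factor(diagnosis)
  assert_that(nlevels(dx) == 2L, "diagnosis must have two levels")
  means <- tapply(loadings, list(site, dx), mean)
  diffs <- means[, 1L] - means[, 2L]
  consistent <- all(diffs > 0) || all(diffs < 0)
  full <- lm(loadings ~ site * dx)
  add <- lm(loadings ~ site + dx)
  ip <- anova(add, full)[["Pr(>F)"]][2L]
  list(means = means, consistent_direction = consistent, interaction_p = ip)
}
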