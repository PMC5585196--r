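#' Read an ROI definition table
#'
#' An ROI table lists the regions whose average BOLD signals form the nodes of
#' the connectome: one row per region with its integer label, name, hemisphere
#' and MNI-millimetre barycenter. Row order is the canonical feature-indexing
#' order used by every downstream stage, so two feature vectors are comparable
#' only if they were built under the same table.
#'
#' Hemisphere assignment is taken from the `hemisphere` column (populated from
#' the `_L`/`_R` name suffixes in the packaged table); the sign of the
#' barycenter x-coordinate is used only as a consistency check, and a warning
#' is raised for any row where name-derived hemisphere and x-sign disagree.
#'
#' @param path Path to a tab-separated file with columns
#'   `roi_id`, `name`, `hemisphere`, `x`, `y`, `z`. Defaults to the packaged
#'   90-region AAL table (standard AAL-90 names and hemispheres; the
#'   barycenters are synthetic representative coordinates, see
#'   `vignette("inphconn-methods")`).
#' @return A tibble of class `roi_table` with one row per ROI in canonical
#'   order.
#' @examples
#' rois <- read_roi_table()
#' table(rois$hemisphere)
#' @export
read_roi_table <- function(path = system.file("extdata",
                                              "aal90_rois_synthetic_barycenters.tsv",
                                              package = "inphconn")) {
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  roi_table(raw)
}

#' Construct and validate an ROI table
#'
#' @param df Data frame with columns `roi_id`, `name`, `hemisphere`, `x`,
#'   `y`, `z`.
#' @return A validated `roi_table` tibble.
#' @export
roi_table <- function(df) {
  needed <- c("roi_id", "name", "hemisphere", "x", "y", "z")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("ROI table is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "inphconn_invalid_input")
  }
  tab <- as_tibble(df[needed])
  if (anyDuplicated(tab$roi_id)) {
    abort("ROI ids must be unique", class = "inphconn_invalid_input")
  }
  if (!all(tab$hemisphere %in% c("L", "R"))) {
    abort("hemisphere must be 'L' or 'R' for every ROI",
          class = "inphconn_invalid_input")
  }
  # x-sign consistency check: left of midline is negative x in MNI space
  expected_sign <- ifelse(tab$hemisphere == "L", -1, 1)
  mismatch <- sign(tab$x) != 0 & sign(tab$x) != expected_sign
  if (any(mismatch)) {
    warn(paste0("barycenter x-sign disagrees with hemisphere label for: ",
                paste(tab$name[mismatch], collapse = ", ")),
         class = "inphconn_hemisphere_mismatch")
  }
  class(tab) <- c("roi_table", class(tab))
  tab
}

#' Enumerate canonical ROI-pair edges
#'
#' Lists every unordered ROI pair exactly once, in row-major upper-triangle
#' order (i ascending, then j ascending, 1-based indices into the ROI table).
#' This ordering defines feature-vector indexing for the whole pipeline: for
#' 90 regions it yields the 4,005 connectivity features the classifiers
#' consume.
#'
#' @param n_rois Number of ROIs (>= 2).
#' @return A tibble with columns `edge`, `i`, `j` and `n_rois * (n_rois - 1) / 2`
#'   rows.
#' @examples
#' nrow(enumerate_edges(90)) # 4005
#' @export
enumerate_edges <- function(n_rois) {
  if (!is.numeric(n_rois) || length(n_rois) != 1 || is.na(n_rois) ||
      n_rois < 2 || n_rois != round(n_rois)) {
    abort("n_rois must be a single integer >= 2",
          class = "inphconn_invalid_input")
  }
  n_rois <- as.integer(n_rois)
  i <- rep.int(seq_len(n_rois - 1L), times = (n_rois - 1L):1L)
  j <- unlist(lapply(seq_len(n_rois - 1L), function(a) (a + 1L):n_rois),
              use.names = FALSE)
  tibble(edge = seq_along(i), i = i, j = j)
}

#' Classify edges as inter- or intra-hemispheric
#'
#' An edge is interhemispheric when its two ROIs carry different hemisphere
#' labels; otherwise it is intrahemispheric. For the 90-region table with 45
#' regions per side this partitions the 4,005 edges into 2,025 inter and
#' 1,980 intra edges.
#'
#' @param edges Data frame with columns `i`, `j` (indices into `rois`), e.g.
#'   from [enumerate_edges()].
#' @param rois An ROI table.
#' @return The input tibble with an added `class` column, `"inter"` or
#'   `"intra"`.
#' @export
edge_class <- function(edges, rois) {
  if (!all(c("i", "j") %in% names(edges))) {
    abort("edges must have columns i and j", class = "inphconn_invalid_input")
  }
  idx <- c(edges$i, edges$j)
  if (any(idx < 1 | idx > nrow(rois))) {
    abort("edge indices out of range for the ROI table",
          class = "inphconn_invalid_input")
  }
  hemi <- rois$hemisphere
  out <- as_tibble(edges)
  out$class <- ifelse(hemi[out$i] != hemi[out$j], "inter", "intra")
  out
}

#' Construct a label volume
#'
#' A label volume is a 3-D integer grid (0 = background, k > 0 = the
#' `roi_id` of the region owning the voxel) plus a voxel-to-MNI-mm affine,
#' following the NIfTI convention.
#'
#' @param grid 3-D integer array of ROI labels.
#' @param affine 4x4 voxel-to-world transform.
#' @return A `label_volume` object.
#' @export
label_volume <- function(grid, affine = diag(4)) {
  if (length(dim(grid)) != 3) {
    abort("label grid must be a 3-D array", class = "inphconn_invalid_input")
  }
  structure(list(grid = grid, affine = affine), class = "label_volume")
}

#' Construct a binary mask
#'
#' @param grid 3-D array of 0/1 values.
#' @param affine 4x4 voxel-to-world transform.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(grid, affine = diag(4)) {
  if (length(dim(grid)) != 3) {
    abort("mask grid must be a 3-D array", class = "inphconn_invalid_input")
  }
  if (!all(grid %in% c(0, 1))) {
    abort("mask grid must contain only 0 and 1",
          class = "inphconn_invalid_input")
  }
  structure(list(grid = grid, affine = affine), class = "binary_mask")
}

#' Read a NIfTI label volume or binary mask
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param as `"labels"` or `"mask"`.
#' @return A [label_volume()] or [binary_mask()].
#' @export
read_label_volume <- function(path, as = c("labels", "mask")) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  grid <- array(as.vector(img), dim = dim(img))
  affine <- structure(RNifti::xform(img), class = "matrix")
  if (as == "labels") {
    label_volume(round(grid), affine = affine)
  } else {
    binary_mask(1 * (grid > 0.5), affine = affine)
  }
}

#' Write a label volume or mask to NIfTI
#'
#' @param vol A [label_volume()] or [binary_mask()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$grid)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Remove ventricle-template voxels from an atlas
#'
#' In hydrocephalus the enlarged ventricles invade atlas regions defined on
#' healthy anatomy, so ROI averages would mix parenchymal BOLD signal with
#' CSF. This step zeroes every atlas voxel falling inside a binary ventricle
#' template, producing a modified atlas applied identically to every subject.
#'
#' A warning is raised for any ROI losing more than half of its voxels, and
#' an error for any ROI emptied entirely.
#'
#' @param labels A [label_volume()].
#' @param ventricle A [binary_mask()] with the same grid shape and affine.
#' @return A modified [label_volume()].
#' @export
modify_rois <- function(labels, ventricle) {
  if (!identical(dim(labels$grid), dim(ventricle$grid)) ||
      !isTRUE(all.equal(unclass(labels$affine), unclass(ventricle$affine),
                        check.attributes = FALSE, tolerance = 1e-6))) {
    abort("label volume and ventricle mask must share grid shape and affine",
          class = "inphconn_incompatible_geometry")
  }
  before <- tabulate_labels(labels$grid)
  out <- labels$grid
  out[ventricle$grid == 1] <- 0L
  after <- tabulate_labels(out)
  lost_all <- setdiff(names(before), names(after))
  if (length(lost_all) > 0) {
    abort(paste0("ventricle mask empties ROI(s): ",
                 paste(lost_all, collapse = ", ")),
          class = "inphconn_degenerate_roi")
  }
  frac <- after[names(before)] / before
  heavy <- names(before)[frac < 0.5]
  if (length(heavy) > 0) {
    warn(paste0("ROI(s) losing >50% of voxels to the ventricle template: ",
                paste(heavy, collapse = ", ")),
         class = "inphconn_roi_shrinkage")
  }
  label_volume(out, affine = labels$affine)
}

tabulate_labels <- function(grid) {
  v <- grid[grid != 0]
  tab <- table(v)
  stats::setNames(as.integer(tab), names(tab))
}

#' Average a voxel time series within each ROI
#'
#' Extracts the per-region BOLD signal: for every ROI, the unweighted mean
#' over its labelled voxels at each time point. Output column order follows
#' the ROI table.
#'
#' @param volume_series 4-D array (x, y, z, time).
#' @param labels A [label_volume()] whose spatial dimensions match.
#' @param rois An ROI table; every `roi_id` must have at least one voxel.
#' @return A numeric matrix, time points x ROIs, columns named by ROI name.
#' @export
roi_average <- function(volume_series, labels, rois) {
  d <- dim(volume_series)
  if (length(d) != 4 || !identical(d[1:3], dim(labels$grid))) {
    abort("volume_series spatial dimensions must match the label volume",
          class = "inphconn_invalid_input")
  }
  n_t <- d[4]
  flat <- matrix(volume_series, nrow = prod(d[1:3]), ncol = n_t)
  lab <- as.vector(labels$grid)
  out <- matrix(NA_real_, nrow = n_t, ncol = nrow(rois),
                dimnames = list(NULL, rois$name))
  for (k in seq_len(nrow(rois))) {
    vox <- which(lab == rois$roi_id[k])
    if (length(vox) == 0) {
      abort(paste0("ROI '", rois$name[k], "' (id ", rois$roi_id[k],
                   ") has no voxels in the label volume"),
            class = "inphconn_degenerate_roi")
    }
    out[, k] <- colMeans(flat[vox, , drop = FALSE])
  }
  out
}
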