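#' ROI-to-ROI Pearson correlation matrix
#'
#' Sample Pearson correlation of the BOLD time course between every pair of
#' ROIs. Each ROI series must have nonzero variance.
#'
#' @param roi_series Time x ROI numeric matrix with at least 3 time points.
#' @return Symmetric correlation matrix over the column order of the input.
#' @export
fc_matrix <- function(roi_series) {
  x <- as.matrix(roi_series)
  if (nrow(x) < 3) {
    abort("need at least 3 time points", class = "inphconn_invalid_input")
  }
  v <- apply(x, 2, stats::var)
  if (any(v <= 0 | !is.finite(v))) {
    bad <- colnames(x)[v <= 0 | !is.finite(v)]
    if (is.null(bad)) bad <- which(v <= 0 | !is.finite(v))
    abort(paste0("zero-variance ROI series: ", paste(bad, collapse = ", ")),
          class = "inphconn_degenerate_series")
  }
  cor(x)
}

#' Fisher z-transform of a correlation coefficient
#'
#' `atanh(r)` after clamping `r` into `[-1 + 1e-7, 1 - 1e-7]` so that values
#' at the boundary stay finite (about +/- 8.05); clamping is reported as an
#' informational condition. Values beyond `|r| = 1` by more than rounding
#' slack (1e-9) are rejected.
#'
#' @param r Numeric vector of correlations.
#' @return `atanh` of the clamped values.
#' @examples
#' fisher_z(c(0, 0.5, -0.5))
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-9, na.rm = TRUE)) {
    abort("correlation magnitude exceeds 1 beyond rounding slack",
          class = "inphconn_invalid_input")
  }
  eps <- 1e-7
  clamped <- pmin(pmax(r, -1 + eps), 1 - eps)
  if (any(clamped != r, na.rm = TRUE)) {
    inform(sprintf("%d correlation(s) clamped away from |r| = 1 before atanh",
                   sum(clamped != r, na.rm = TRUE)),
           class = "inphconn_fisher_clamp")
  }
  atanh(clamped)
}

# Stable hash of the ROI ordering so feature vectors built under different
# tables cannot be mixed silently.
roi_table_hash <- function(rois) {
  key <- paste(rois$roi_id, rois$name, rois$hemisphere, collapse = ";")
  h <- 48271
  for (b in utf8ToInt(key)) {
    h <- (h * 69621 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Vectorize an FC matrix into a canonical feature vector
#'
#' Fisher-z values of the upper triangle laid out in [enumerate_edges()]
#' order, carrying a hash of the ROI table so vectors from different
#' orderings cannot be combined.
#'
#' @param fc Correlation matrix from [fc_matrix()].
#' @param rois ROI table whose row count matches `fc`.
#' @return Numeric vector of length `n (n - 1) / 2` with attribute
#'   `roi_table_hash`.
#' @export
vectorize <- function(fc, rois) {
  if (!is.matrix(fc) || nrow(fc) != ncol(fc) || nrow(fc) != nrow(rois)) {
    abort("fc must be square and match the ROI table",
          class = "inphconn_invalid_input")
  }
  edges <- enumerate_edges(nrow(rois))
  z <- fisher_z(fc[cbind(edges$i, edges$j)])
  structure(z, roi_table_hash = roi_table_hash(rois))
}

#' Reassemble a feature vector into a symmetric matrix
#'
#' Inverse of [vectorize()] on the upper triangle (diagonal set to `NA`).
#'
#' @param z Feature vector in canonical edge order.
#' @param n_rois Number of ROIs.
#' @return Symmetric matrix of Fisher-z values.
#' @export
devectorize <- function(z, n_rois) {
  edges <- enumerate_edges(n_rois)
  if (length(z) != nrow(edges)) {
    abort("feature vector length disagrees with n_rois",
          class = "inphconn_invalid_input")
  }
  m <- matrix(NA_real_, n_rois, n_rois)
  m[cbind(edges$i, edges$j)] <- z
  m[cbind(edges$j, edges$i)] <- z
  m
}

#' Connectivity features for a whole cohort
#'
#' Computes the Fisher-z connectivity feature vector of every subject and
#' stacks them into a subjects x edges matrix alongside the metadata.
#'
#' @param cohort An `fc_cohort`, normally after [denoise_cohort()].
#' @return An object of class `fc_features`: list with `x` (subjects x edges
#'   matrix), `meta` (subject metadata tibble), `edges` (edge table with
#'   hemisphere class), `rois`, and `roi_table_hash`.
#' @export
cohort_features <- function(cohort) {
  rois <- attr(cohort, "rois")
  edges <- edge_class(enumerate_edges(nrow(rois)), rois)
  x <- t(vapply(cohort$series,
                function(s) as.numeric(vectorize(fc_matrix(s), rois)),
                numeric(nrow(edges))))
  rownames(x) <- cohort$subject_id
  meta <- as_tibble(cohort[, c("subject_id", "group", "gs_gait",
                               "gs_cognition", "gs_urinary")])
  structure(list(x = x, meta = meta, edges = edges, rois = rois,
                 roi_table_hash = roi_table_hash(rois)),
            class = "fc_features")
}

#' @export
print.fc_features <- function(x, ...) {
  cat(sprintf("<fc_features> %d subjects x %d edges (ROI hash %s)\n",
              nrow(x$x), ncol(x$x), x$roi_table_hash))
  invisible(x)
}

#' Tidy connectivity features into a long tibble
#'
#' @param x An `fc_features` object.
#' @param ... Unused.
#' @return A tibble with one row per subject-edge combination: subject
#'   metadata, edge ROI names, hemisphere class, and Fisher-z value.
#' @method tidy fc_features
#' @export
tidy.fc_features <- function(x, ...) {
  edges <- x$edges
  long <- tidyr::expand_grid(subject_id = x$meta$subject_id,
                             edge = edges$edge)
  long$z <- as.vector(t(x$x))
  long <- left_join(long, x$meta, by = "subject_id")
  long <- left_join(long,
                    mutate(edges,
                           name_i = x$rois$name[edges$i],
                           name_j = x$rois$name[edges$j]),
                    by = "edge")
  as_tibble(long)
}
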