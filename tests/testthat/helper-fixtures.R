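# Small deterministic fixtures shared across test files.

# Tiny ROI table with n_pairs homologous L/R pairs, AAL-style ordering
# (L then R for each base region).
toy_rois <- function(n_pairs = 3) {
  base <- sprintf("Region%02d", seq_len(n_pairs))
  roi_table(data.frame(
    roi_id = seq_len(2 * n_pairs),
    name = as.vector(rbind(paste0(base, "_L"), paste0(base, "_R"))),
    hemisphere = rep(c("L", "R"), n_pairs),
    x = rep(c(-30, 30), n_pairs),
    y = rep(seq_len(n_pairs) * 10, each = 2),
    z = 0))
}

# fc_features object built directly from a feature matrix, bypassing the
# simulator, for classifier unit tests.
toy_features <- function(x, group, gs_gait = NULL, rois = NULL) {
  n_edges <- ncol(x)
  # smallest even n_rois whose edge count is >= n_edges
  n_rois <- 2
  while (n_rois * (n_rois - 1) / 2 < n_edges) n_rois <- n_rois + 2
  if (is.null(rois)) rois <- toy_rois(n_rois / 2)
  edges <- edge_class(enumerate_edges(n_rois), rois)[seq_len(n_edges), ]
  if (is.null(gs_gait)) gs_gait <- ifelse(group == "iNPH", 2L, 0L)
  meta <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(nrow(x))),
    group = group, gs_gait = as.integer(gs_gait),
    gs_cognition = as.integer(gs_gait), gs_urinary = as.integer(gs_gait))
  structure(list(x = x, meta = meta, edges = edges, rois = rois,
                 roi_table_hash = "toy"),
            class = "fc_features")
}

# Small simulated cohort for end-to-end paths (10 ROIs keeps tests fast).
toy_cohort <- function(seed = 11, n_rois = 10, kappa = 0.8) {
  simulate_cohort(default_cohort_specs(),
                  sim_config(n_rois = n_rois, kappa = kappa, seed = seed))
}
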