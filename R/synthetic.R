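#' Simulation configuration for synthetic resting-state cohorts
#'
#' Defines the statistical structure of the synthetic BOLD cohorts: series
#' geometry (90 regions, 116 retained volumes at TR = 3 s, matching a 7-min
#' acquisition with the first four volumes discarded), the latent correlation
#' structure (within-hemisphere community correlation `rho_intra`, homotopic
#' left-right correlation `rho_homo` attenuated multiplicatively with disease
#' severity through `kappa`), temporal AR(1) smoothness, and additive shared
#' confound channels (six motion parameters plus white-matter and CSF
#' signals) that induce pseudo-correlation removable by nuisance regression.
#'
#' @param n_rois Number of regions (must be even for homologous L/R pairing).
#' @param n_volumes Retained time points per subject.
#' @param tr_seconds Repetition time in seconds.
#' @param rho_intra Baseline correlation inside a within-hemisphere community.
#' @param rho_homo Homotopic (left-right mirror pair) correlation in healthy
#'   subjects.
#' @param kappa Severity attenuation coefficient in \[0, 1\]: homotopic
#'   correlation for a patient is `rho_homo * (1 - kappa * GSmax / 4)` where
#'   GSmax is the maximum of the three symptom grades (0-4).
#' @param confound_loading Named numeric vector of mixing weights for the 8
#'   confound channels (`motion1`..`motion6`, `wm`, `csf`) into the observed
#'   ROI signals.
#' @param ar1_coef Temporal AR(1) coefficient of the latent BOLD series.
#' @param noise_sd Marginal standard deviation of the latent series.
#' @param n_communities Number of within-hemisphere communities the regions
#'   of each hemisphere are split into (contiguous blocks in table order).
#' @param seed Master seed; per-subject streams are derived from it and the
#'   subject id, so cohort composition changes do not reshuffle draws.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_rois = 90L,
                       n_volumes = 116L,
                       tr_seconds = 3,
                       rho_intra = 0.3,
                       rho_homo = 0.6,
                       kappa = 0.8,
                       confound_loading = c(motion1 = 0.1, motion2 = 0.1,
                                            motion3 = 0.1, motion4 = 0.1,
                                            motion5 = 0.1, motion6 = 0.1,
                                            wm = 0.4, csf = 0.4),
                       ar1_coef = 0.3,
                       noise_sd = 1,
                       n_communities = 5L,
                       seed = 1L) {
  if (rho_intra < 0 || rho_intra >= 1 || rho_homo < 0 || rho_homo >= 1) {
    abort("rho_intra and rho_homo must lie in [0, 1)",
          class = "inphconn_invalid_config")
  }
  if (kappa < 0 || kappa > 1) {
    abort("kappa must lie in [0, 1]", class = "inphconn_invalid_config")
  }
  if (n_volumes < 20) {
    abort("n_volumes must be >= 20", class = "inphconn_invalid_config")
  }
  if (n_rois %% 2 != 0) {
    abort("n_rois must be even (homologous L/R pairs)",
          class = "inphconn_invalid_config")
  }
  if (length(confound_loading) != 8) {
    abort("confound_loading must have 8 entries (6 motion + wm + csf)",
          class = "inphconn_invalid_config")
  }
  if (abs(ar1_coef) >= 1) {
    abort("ar1_coef must lie in (-1, 1)", class = "inphconn_invalid_config")
  }
  structure(list(n_rois = as.integer(n_rois),
                 n_volumes = as.integer(n_volumes),
                 tr_seconds = tr_seconds,
                 rho_intra = rho_intra, rho_homo = rho_homo, kappa = kappa,
                 confound_loading = confound_loading,
                 ar1_coef = ar1_coef, noise_sd = noise_sd,
                 n_communities = as.integer(n_communities),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Subject specifications for a synthetic cohort
#'
#' @param subject_id Character ids, unique.
#' @param group `"HC"` or `"iNPH"`.
#' @param gs_gait,gs_cognition,gs_urinary Symptom grades 0 (normal) to 4
#'   (severe); healthy controls must be 0 (their grade is assumed normal).
#' @param mmse Optional Mini-Mental State Examination score (0-30).
#' @return A tibble of class `subject_spec`.
#' @export
subject_spec <- function(subject_id, group,
                         gs_gait = 0L, gs_cognition = 0L, gs_urinary = 0L,
                         mmse = NA_integer_) {
  tab <- tibble(subject_id = as.character(subject_id),
                group = as.character(group),
                gs_gait = as.integer(gs_gait),
                gs_cognition = as.integer(gs_cognition),
                gs_urinary = as.integer(gs_urinary),
                mmse = as.integer(mmse))
  validate_subject_spec(tab)
}

validate_subject_spec <- function(tab) {
  if (!all(tab$group %in% c("HC", "iNPH"))) {
    abort("group must be 'HC' or 'iNPH'", class = "inphconn_invalid_input")
  }
  sev <- as.matrix(tab[, c("gs_gait", "gs_cognition", "gs_urinary")])
  if (any(sev < 0 | sev > 4)) {
    abort("severity grades must lie in 0..4", class = "inphconn_invalid_input")
  }
  hc <- tab$group == "HC"
  if (any(sev[hc, ] != 0)) {
    abort("healthy controls must have all severity grades 0",
          class = "inphconn_invalid_input")
  }
  class(tab) <- unique(c("subject_spec", class(tab)))
  tab
}

#' Default 22-subject cohort specification
#'
#' Eleven patients carrying the published per-patient grading-scale profile
#' (gait, cognition, urinary) and MMSE scores, plus eleven healthy controls
#' with all grades fixed at 0.
#'
#' @return A `subject_spec` tibble with 22 rows.
#' @export
default_cohort_specs <- function() {
  inph <- tibble(
    subject_id = sprintf("iNPH%02d", 1:11),
    group = "iNPH",
    gs_gait      = c(3L, 2L, 2L, 3L, 3L, 2L, 2L, 1L, 1L, 2L, 2L),
    gs_cognition = c(3L, 1L, 2L, 3L, 2L, 2L, 2L, 2L, 1L, 2L, 3L),
    gs_urinary   = c(0L, 1L, 0L, 3L, 2L, 2L, 0L, 0L, 0L, 4L, 2L),
    mmse         = c(17L, 25L, 22L, 16L, 19L, 28L, 25L, 29L, 25L, 25L, 20L))
  hc <- tibble(subject_id = sprintf("HC%02d", 1:11), group = "HC",
               gs_gait = 0L, gs_cognition = 0L, gs_urinary = 0L,
               mmse = NA_integer_)
  validate_subject_spec(bind_rows(inph, hc))
}

#' Published clinical scores of the patient group
#'
#' Per-patient MMSE, Frontal Assessment Battery (FAB) and grading-scale
#' values for the eleven patients, as a tidy tibble. These are inputs for
#' worked examples and summary checks, not simulation output.
#'
#' @return A tibble with columns `subject_id`, `mmse`, `fab`, `gs_gait`,
#'   `gs_cognition`, `gs_urinary`.
#' @export
inph_clinical_table <- function() {
  tibble(
    subject_id = sprintf("iNPH%02d", 1:11),
    mmse = c(17L, 25L, 22L, 16L, 19L, 28L, 25L, 29L, 25L, 25L, 20L),
    fab  = c(10L, 11L, 10L, 9L, 6L, 13L, 6L, 13L, 17L, 16L, 12L),
    gs_gait      = c(3L, 2L, 2L, 3L, 3L, 2L, 2L, 1L, 1L, 2L, 2L),
    gs_cognition = c(3L, 1L, 2L, 3L, 2L, 2L, 2L, 2L, 1L, 2L, 3L),
    gs_urinary   = c(0L, 1L, 0L, 3L, 2L, 2L, 0L, 0L, 0L, 4L, 2L))
}

# Homotopic (mirror) pairs: match by base name when _L/_R suffixes are
# present, otherwise pair the k-th left region with the k-th right region.
homotopic_pairs <- function(rois) {
  base <- sub("_(L|R)$", "", rois$name)
  suffixed <- grepl("_(L|R)$", rois$name)
  if (all(suffixed)) {
    left <- which(rois$hemisphere == "L")
    right_all <- which(rois$hemisphere == "R")
    ord <- match(base[left], base[right_all])
    if (anyNA(ord)) {
      abort("unpaired left region(s) in ROI table",
            class = "inphconn_invalid_input")
    }
    cbind(left, right_all[ord])
  } else {
    left <- which(rois$hemisphere == "L")
    right <- which(rois$hemisphere == "R")
    if (length(left) != length(right)) {
      abort("hemispheres must have equal region counts for pairing",
            class = "inphconn_invalid_input")
    }
    cbind(left, right)
  }
}

community_assignment <- function(rois, n_communities) {
  comm <- integer(nrow(rois))
  for (h in c("L", "R")) {
    idx <- which(rois$hemisphere == h)
    comm[idx] <- as.integer(cut(seq_along(idx), breaks = n_communities,
                                labels = FALSE))
  }
  comm
}

#' Target correlation matrix for one subject
#'
#' Builds the latent correlation structure the simulator draws from:
#' unit diagonal; homotopic entries `rho_homo * (1 - kappa * GSmax / 4)`
#' where GSmax is the subject's maximum symptom grade; `rho_intra` between
#' regions sharing a hemisphere and community; zero elsewhere. The matrix is
#' then repaired to the nearest positive-definite matrix by eigenvalue
#' clipping at 1e-6 followed by re-normalisation to unit diagonal; whether a
#' repair occurred is recorded in the attributes.
#'
#' @param spec One-row `subject_spec`.
#' @param config A [sim_config()].
#' @param rois ROI table consistent with `config$n_rois`.
#' @return Correlation matrix with attributes `pre_repair` (the unclipped
#'   matrix) and `repaired` (logical).
#' @export
build_target_correlation <- function(spec, config, rois) {
  if (nrow(rois) != config$n_rois) {
    abort("ROI table size disagrees with config$n_rois",
          class = "inphconn_invalid_config")
  }
  n <- config$n_rois
  gsmax <- max(spec$gs_gait, spec$gs_cognition, spec$gs_urinary)
  sigma <- diag(n)
  comm <- community_assignment(rois, config$n_communities)
  same_comm <- outer(comm, comm, "==") &
    outer(rois$hemisphere, rois$hemisphere, "==")
  sigma[same_comm] <- config$rho_intra
  hp <- homotopic_pairs(rois)
  rho_h <- config$rho_homo * (1 - config$kappa * gsmax / 4)
  sigma[hp] <- rho_h
  sigma[hp[, c(2, 1)]] <- rho_h
  diag(sigma) <- 1
  repaired <- nearest_pd(sigma)
  structure(repaired$mat, pre_repair = sigma, repaired = repaired$clipped)
}

# Eigenvalue clipping at 1e-6 then re-normalisation to unit diagonal.
nearest_pd <- function(sigma, floor_ev = 1e-6) {
  ev <- eigen(sigma, symmetric = TRUE)
  clipped <- any(ev$values < floor_ev)
  if (clipped) {
    vals <- pmax(ev$values, floor_ev)
    m <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    diag(m) <- 1
    list(mat = (m + t(m)) / 2, clipped = TRUE)
  } else {
    list(mat = sigma, clipped = FALSE)
  }
}

# Deterministic 31-bit hash of a string (multiplicative congruential mix)
# for per-subject stream derivation.
string_seed <- function(s, master) {
  h <- 48271
  for (b in utf8ToInt(s)) {
    h <- (h * 69621 + b) %% 2147483647
  }
  as.integer((h + as.numeric(master) * 7919) %% 2147483647)
}

ar1_series <- function(n, phi, innov) {
  # innov: n x k matrix of N(0, Sigma) draws; output has stationary cov Sigma
  x <- matrix(0, nrow = n, ncol = ncol(innov))
  x[1, ] <- innov[1, ]
  s <- sqrt(1 - phi^2)
  for (t in 2:n) x[t, ] <- phi * x[t - 1, ] + s * innov[t, ]
  x
}

#' Simulate one subject's ROI series and confound table
#'
#' Draws a latent multivariate series with the subject's target correlation
#' and AR(1) temporal structure, then contaminates it with shared confound
#' channels: six independent AR(1) motion parameters, and white-matter and
#' CSF channels sharing a common latent with the contamination term, so that
#' raw pairwise correlations are inflated toward positive values and the
#' inflation is removable by confound regression. Deterministic given
#' `(config$seed, spec$subject_id)`.
#'
#' @param spec One-row `subject_spec`.
#' @param config A [sim_config()].
#' @param rois ROI table.
#' @return List with `series` (time x ROI matrix), `confounds` (time x 8
#'   matrix), and `target` (the target correlation used).
#' @export
simulate_subject <- function(spec, config, rois) {
  target <- build_target_correlation(spec, config, rois)
  n_t <- config$n_volumes
  n <- config$n_rois
  seed <- string_seed(spec$subject_id, config$seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  L <- chol(target)
  z <- matrix(rnorm(n_t * n), nrow = n_t) %*% L
  latent <- config$noise_sd * ar1_series(n_t, config$ar1_coef, z)

  motion <- ar1_series(n_t, 0.5, matrix(rnorm(n_t * 6), nrow = n_t))
  g <- ar1_series(n_t, 0.5, matrix(rnorm(n_t), nrow = n_t))[, 1]
  wm <- g + 0.3 * rnorm(n_t)
  csf <- g + 0.3 * rnorm(n_t)
  confounds <- cbind(motion, wm, csf)
  colnames(confounds) <- c(paste0("motion", 1:6), "wm", "csf")

  # Per-ROI contamination gains are heterogeneous (unit mean, unit spread,
  # occasionally negative) so the raw correlation distribution is both
  # shifted positive and widely spread, and confound regression shrinks
  # its mean and its standard deviation.
  roi_gain <- matrix(rnorm(n * 8, mean = 1, sd = 1), nrow = n) *
    matrix(config$confound_loading, nrow = n, ncol = 8, byrow = TRUE)
  series <- latent + confounds %*% t(roi_gain)
  colnames(series) <- rois$name
  list(series = series, confounds = confounds, target = target)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a cohort of subjects
#'
#' @param specs A `subject_spec` tibble (>= 2 subjects, unique ids).
#' @param config A [sim_config()].
#' @param rois ROI table; defaults to the packaged 90-region table truncated
#'   or validated against `config$n_rois`.
#' @return A tibble of class `fc_cohort` with one row per subject, metadata
#'   columns, and list-columns `series` and `confounds`; the ROI table,
#'   config and provenance are carried in attributes.
#' @examples
#' cfg <- sim_config(n_rois = 10, seed = 7)
#' coh <- simulate_cohort(default_cohort_specs(), cfg)
#' coh
#' @export
simulate_cohort <- function(specs, config = sim_config(),
                            rois = default_rois(config)) {
  if (nrow(specs) < 2) {
    abort("need at least 2 subjects", class = "inphconn_invalid_input")
  }
  if (anyDuplicated(specs$subject_id)) {
    abort("duplicate subject_id", class = "inphconn_invalid_input")
  }
  specs <- validate_subject_spec(as_tibble(specs))
  sims <- lapply(seq_len(nrow(specs)), function(k) {
    simulate_subject(specs[k, ], config, rois)
  })
  out <- specs
  out$series <- lapply(sims, `[[`, "series")
  out$confounds <- lapply(sims, `[[`, "confounds")
  attr(out, "rois") <- rois
  attr(out, "config") <- config
  attr(out, "provenance") <- list(
    seed = config$seed,
    repaired = map_lgl(sims, function(s) isTRUE(attr(s$target, "repaired"))),
    denoised = FALSE)
  class(out) <- unique(c("fc_cohort", class(out)))
  out
}

#' Default ROI table for a simulation config
#'
#' The packaged 90-region table when `n_rois` is 90; otherwise a reduced
#' synthetic table with `n_rois / 2` homologous pairs drawn from the packaged
#' names.
#'
#' @param config A [sim_config()].
#' @return An ROI table with `config$n_rois` rows.
#' @export
default_rois <- function(config = sim_config()) {
  full <- read_roi_table()
  if (config$n_rois == 90L) return(full)
  half <- config$n_rois / 2
  keep <- sort(c(seq_len(half) * 2 - 1, seq_len(half) * 2))
  tab <- full[keep, ]
  tab$roi_id <- seq_len(nrow(tab))
  roi_table(tab)
}

#' Toy voxel-level fixture for the atlas path
#'
#' Builds a small label volume placing every ROI on at least two voxels, a
#' ventricle mask overlapping known ROIs, and a 4-D voxel series constructed
#' so that [roi_average()] recovers a designated per-ROI series exactly
#' (voxel pairs are `s + delta` and `s - delta`).
#'
#' @param rois ROI table.
#' @param roi_series Time x ROI matrix the voxel averages must reproduce.
#' @param grid_dim 3-vector of grid dimensions, at most 24 each.
#' @param n_masked Number of leading ROIs the ventricle mask overlaps (one
#'   voxel each).
#' @return List with `labels`, `mask`, `series4d`, and `overlap` (tibble of
#'   masked voxel counts per ROI).
#' @export
voxel_fixture <- function(rois, roi_series, grid_dim = c(12L, 12L, 12L),
                          n_masked = 3L) {
  if (any(grid_dim > 24)) {
    abort("fixture grids are capped at 24 voxels per side",
          class = "inphconn_invalid_config")
  }
  n <- nrow(rois)
  if (prod(grid_dim) < 2 * n) {
    abort("grid too small to place two voxels per ROI",
          class = "inphconn_invalid_config")
  }
  n_t <- nrow(roi_series)
  grid <- array(0L, dim = grid_dim)
  vox1 <- seq_len(n) * 2 - 1
  vox2 <- seq_len(n) * 2
  grid[vox1] <- rois$roi_id
  grid[vox2] <- rois$roi_id
  series4d <- array(0, dim = c(grid_dim, n_t))
  flat <- matrix(series4d, nrow = prod(grid_dim), ncol = n_t)
  delta <- 0.5
  for (k in seq_len(n)) {
    flat[vox1[k], ] <- roi_series[, k] + delta
    flat[vox2[k], ] <- roi_series[, k] - delta
  }
  series4d <- array(flat, dim = c(grid_dim, n_t))
  mask <- array(0L, dim = grid_dim)
  masked <- utils::head(vox2, n_masked)
  mask[masked] <- 1L
  overlap <- tibble(roi_id = rois$roi_id[seq_len(n_masked)],
                    masked_voxels = 1L)
  list(labels = label_volume(grid),
       mask = binary_mask(mask),
       series4d = series4d,
       overlap = overlap)
}

#' @export
print.fc_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<fc_cohort> %d subjects (%d iNPH / %d HC), %d ROIs x %d volumes, TR %gs%s\n",
              nrow(x), sum(x$group == "iNPH"), sum(x$group == "HC"),
              cfg$n_rois, cfg$n_volumes, cfg$tr_seconds,
              if (isTRUE(attr(x, "provenance")$denoised)) ", denoised" else ""))
  NextMethod()
}
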