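test_that("target correlation encodes severity-attenuated homotopic coupling", {
  rois <- toy_rois(5)
  cfg <- sim_config(n_rois = 10, rho_homo = 0.6, rho_intra = 0.3,
                    kappa = 0.5, n_communities = 2)
  hp <- inphconn:::homotopic_pairs(rois)

  hc <- subject_spec("h1", "HC")
  m_hc <- build_target_correlation(hc, cfg, rois)
  expect_equal(unname(attr(m_hc, "pre_repair")[hp]), rep(0.6, 5))

  # plug-in arithmetic: kappa = 0.5, GSmax = 2, rho_homo = 0.6 -> 0.45
  p2 <- subject_spec("p2", "iNPH", gs_gait = 2, gs_cognition = 1)
  m_p2 <- build_target_correlation(p2, cfg, rois)
  expect_equal(unname(attr(m_p2, "pre_repair")[hp]), rep(0.45, 5))

  # full attenuation: kappa = 1, GSmax = 4 -> 0 before repair
  cfg1 <- sim_config(n_rois = 10, kappa = 1)
  p4 <- subject_spec("p4", "iNPH", gs_urinary = 4)
  expect_equal(unname(attr(build_target_correlation(p4, cfg1, rois),
                           "pre_repair")[hp]), rep(0, 5))

  # symmetry, unit diagonal, positive definiteness after repair
  for (m in list(m_hc, m_p2)) {
    expect_equal(m, t(m), tolerance = 1e-12)
    expect_equal(unname(diag(m)), rep(1, 10))
    expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)
  }

  # homotopic targets never increase with kappa
  prev <- Inf
  for (kap in c(0, 0.25, 0.5, 0.75, 1)) {
    cfgk <- sim_config(n_rois = 10, kappa = kap)
    mk <- attr(build_target_correlation(p2, cfgk, rois), "pre_repair")
    expect_true(all(mk[hp] <= prev + 1e-12))
    prev <- mk[hp]
  }

  expect_error(sim_config(rho_homo = 1.2), class = "inphconn_invalid_config")
  expect_error(sim_config(kappa = -0.1), class = "inphconn_invalid_config")
  expect_error(sim_config(n_volumes = 10), class = "inphconn_invalid_config")
})

test_that("subject simulation is deterministic and recovers its target correlation", {
  rois <- toy_rois(5)
  spec <- subject_spec("s1", "iNPH", gs_gait = 3)
  cfg <- sim_config(n_rois = 10, seed = 9)
  a <- simulate_subject(spec, cfg, rois)
  b <- simulate_subject(spec, cfg, rois)
  expect_identical(a$series, b$series)
  expect_identical(a$confounds, b$confounds)

  # long-run sample correlation approaches the target (confounds off)
  cfg_long <- sim_config(n_rois = 10, n_volumes = 20000,
                         confound_loading = rep(0, 8), seed = 5)
  long <- simulate_subject(spec, cfg_long, rois)
  expect_lt(max(abs(cor(long$series) - long$target)), 0.03)

  # shared confounds inflate raw correlations relative to the clean draw
  cfg_on <- sim_config(n_rois = 10, seed = 13)
  cfg_off <- sim_config(n_rois = 10, seed = 13, confound_loading = rep(0, 8))
  on <- simulate_subject(spec, cfg_on, rois)
  off <- simulate_subject(spec, cfg_off, rois)
  mean_offdiag <- function(s) { r <- cor(s); mean(r[upper.tri(r)]) }
  expect_gt(mean_offdiag(on$series), mean_offdiag(off$series))
})

test_that("cohort simulation validates specs and carries the published severity profile", {
  coh <- toy_cohort(seed = 2)
  expect_equal(nrow(coh), 22)
  expect_equal(sum(coh$group == "iNPH"), 11)
  expect_equal(sum(coh$group == "HC"), 11)
  expect_equal(mean(coh$gs_gait[coh$group == "iNPH"]), 23 / 11)

  expect_error(simulate_cohort(default_cohort_specs()[0, ], sim_config(n_rois = 10)),
               class = "inphconn_invalid_input")
  dup <- default_cohort_specs(); dup$subject_id[2] <- dup$subject_id[1]
  expect_error(simulate_cohort(dup, sim_config(n_rois = 10)),
               class = "inphconn_invalid_input")
  hc_bad <- default_cohort_specs(); hc_bad$gs_gait[hc_bad$group == "HC"][1] <- 2L
  expect_error(simulate_cohort(hc_bad, sim_config(n_rois = 10)),
               class = "inphconn_invalid_input")
})

test_that("voxel fixture reproduces its designated ROI series exactly", {
  rois <- toy_rois(5)
  series <- matrix(rnorm(12 * 10), 12, 10)
  fx <- voxel_fixture(rois, series, grid_dim = c(6, 6, 6), n_masked = 3)
  expect_true(all(rois$roi_id %in% fx$labels$grid))
  got <- roi_average(fx$series4d, fx$labels, rois)
  expect_equal(unname(got), unname(series), tolerance = 1e-10)
  # mask overlap matches the construction table
  for (r in seq_len(nrow(fx$overlap))) {
    id <- fx$overlap$roi_id[r]
    expect_equal(sum(fx$mask$grid == 1 & fx$labels$grid == id),
                 fx$overlap$masked_voxels[r])
  }
  expect_error(voxel_fixture(read_roi_table(), series, grid_dim = c(3, 3, 3)),
               class = "inphconn_invalid_config")
})

test_that("severity signal is recoverable from homotopic edges across replicates", {
  # patients with GSmax >= 2 vs controls on mean homotopic Fisher-z,
  # confound regression applied first
  rois <- default_rois(sim_config(n_rois = 30))
  hp <- inphconn:::homotopic_pairs(rois)
  edges <- enumerate_edges(30)
  hp_edge <- match(paste(hp[, 1], hp[, 2]), paste(edges$i, edges$j))
  rejections <- 0L
  n_rep <- 100
  for (s in seq_len(n_rep)) {
    coh <- simulate_cohort(default_cohort_specs(),
                           sim_config(n_rois = 30, kappa = 0.8,
                                      rho_homo = 0.6, seed = 3000 + s))
    reg <- regress_cohort(coh)
    feats <- cohort_features(reg)
    score <- rowMeans(feats$x[, hp_edge, drop = FALSE])
    gsmax <- pmax(coh$gs_gait, coh$gs_cognition, coh$gs_urinary)
    p <- stats::t.test(score[coh$group == "iNPH" & gsmax >= 2],
                       score[coh$group == "HC"])$p.value
    rejections <- rejections + (p < 0.05)
  }
  expect_gte(rejections / n_rep, 0.8)
})

test_that("a null cohort yields no spuriously significant classification", {
  # kappa = 0: labels carry no edge information. Leave-one-out accuracy is
  # pessimistically biased below chance in this regime (feature selection
  # inside the fold), so the guarantee the generator must provide is
  # one-sided: accuracy does not systematically exceed the significance
  # bound for chance performance.
  bound <- qbinom(0.95, 22, 0.5) # one-sided 95% null bound on correct counts
  exceed <- 0L
  n_rep <- 15
  for (s in seq_len(n_rep)) {
    coh <- simulate_cohort(default_cohort_specs(),
                           sim_config(n_rois = 30, kappa = 0, seed = 4000 + s))
    feats <- cohort_features(suppressMessages(denoise_cohort(coh)))
    cv <- suppressMessages(loocv(feats, "diagnosis"))
    exceed <- exceed + (cv$k > bound)
  }
  # under the null, exceedances are at most ~5% of replicates; allow the
  # exact binomial 99% upper bound for 15 trials at p = 0.05
  expect_lte(exceed, qbinom(0.99, n_rep, 0.05) + 1)
})
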