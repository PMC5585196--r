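test_that("t-test filter matches stats::t.test feature by feature", {
  set.seed(12)
  x <- matrix(rnorm(20 * 40), 20, 40)
  x[1:10, 1:5] <- x[1:10, 1:5] + 2 # make some features differ
  g <- rep(c("iNPH", "HC"), each = 10)
  sel <- ttest_filter(x, g, alpha = 0.05)
  p <- attr(sel, "p_values")

  oracle <- vapply(seq_len(ncol(x)), function(j) {
    t.test(x[g == "HC", j], x[g == "iNPH", j], var.equal = TRUE)$p.value
  }, numeric(1))
  expect_equal(unname(p), oracle, tolerance = 1e-12)
  expect_equal(as.integer(sel), which(oracle < 0.05))
  expect_true(all(1:5 %in% sel))

  # alpha monotonicity: stricter threshold selects a subset
  expect_true(all(ttest_filter(x, g, 0.01) %in% sel))

  # zero-variance feature is excluded with a note
  x0 <- x; x0[, 7] <- 3
  expect_message(sel0 <- ttest_filter(x0, g, 0.05),
                 class = "inphconn_filter_degenerate")
  expect_false(7 %in% sel0)

  expect_error(ttest_filter(x, rep("a", 20)), class = "inphconn_invalid_input")
  expect_error(ttest_filter(x, c("a", rep("b", 19))),
               class = "inphconn_invalid_input")
})

test_that("scaling parameters come from the training rows only", {
  set.seed(2)
  train <- matrix(rnorm(10 * 6, mean = 5, sd = 3), 10, 6)
  test <- matrix(rnorm(2 * 6), 2, 6)
  sc <- scale_features(train)
  expect_lt(max(abs(colMeans(sc$scaled))), 1e-12)
  expect_equal(apply(sc$scaled, 2, sd), rep(1, 6),
               ignore_attr = TRUE, tolerance = 1e-12)

  # held-out rows are transformed with the training parameters
  both <- scale_features(train, rbind(train, test))
  expect_equal(both$scaled[1:10, ], sc$scaled, tolerance = 1e-12)
  expect_equal(unname(both$scaled[11:12, ]),
               unname(sweep(sweep(test, 2, sc$center), 2, sc$scale, "/")),
               tolerance = 1e-12)

  # an extreme held-out row must not move the parameters
  sc2 <- scale_features(train, rbind(train, test * 1e6))
  expect_equal(sc2$center, sc$center)
  expect_equal(sc2$scale, sc$scale)

  # constant training column floors to zero
  train_c <- train; train_c[, 3] <- 1
  expect_message(scc <- scale_features(train_c), class = "inphconn_scale_floor")
  expect_true(all(scc$scaled[, 3] == 0))
})

test_that("linear SVM matches a grid-search oracle on a 1-D problem", {
  # three points: class A at -1, class B at +1 and +1.2; inverse-count class
  # weights give A cost 1 and B cost 1/2
  x <- matrix(c(-1, 1, 1.2), ncol = 1)
  y <- factor(c("A", "B", "B"))
  fit <- fit_linear_svm(x, y, classifier_config())

  objective <- function(w, b) {
    f <- w * x[, 1] + b
    ysgn <- ifelse(y == "A", 1, -1) # positive class is levels(y)[1]
    cw <- ifelse(y == "A", 1, 0.5)
    0.5 * w^2 + sum(cw * pmax(0, 1 - ysgn * f))
  }
  # coarse grid, then refine around the optimum
  grid <- expand.grid(w = seq(-3, 3, by = 0.01), b = seq(-3, 3, by = 0.01))
  vals <- mapply(objective, grid$w, grid$b)
  best <- grid[which.min(vals), ]
  fine <- expand.grid(w = seq(best$w - 0.02, best$w + 0.02, by = 1e-4),
                      b = seq(best$b - 0.02, best$b + 0.02, by = 1e-4))
  fvals <- mapply(objective, fine$w, fine$b)
  opt <- fine[which.min(fvals), ]

  expect_equal(unname(fit$w), opt$w, tolerance = 0.02)
  expect_equal(fit$b, opt$b, tolerance = 0.02)
  # the fitted solution achieves (near-)optimal objective value
  expect_lt(objective(unname(fit$w), fit$b), min(fvals) + 1e-4)

  # orientation: decision value positive for class A's side
  expect_gt(decision_values(fit, matrix(-1)), 0)
  expect_lt(decision_values(fit, matrix(1)), 0)
  expect_equal(as.character(predict(fit, matrix(c(-2, 2), ncol = 1))),
               c("A", "B"))
})

test_that("decision orientation is independent of training row order", {
  set.seed(6)
  x <- matrix(rnorm(12 * 3), 12, 3)
  x[1:6, 1] <- x[1:6, 1] + 3
  y <- factor(rep(c("HC", "iNPH"), each = 6))
  fit_ab <- fit_linear_svm(x, y, classifier_config())
  perm <- c(7:12, 1:6) # iNPH rows first
  fit_ba <- fit_linear_svm(x[perm, ], y[perm], classifier_config())
  # libsvm solves to a working-set tolerance, so only near-equality holds
  expect_equal(fit_ab$w, fit_ba$w, tolerance = 1e-2)
  expect_equal(fit_ab$b, fit_ba$b, tolerance = 1e-2)
  expect_equal(predict(fit_ab, x), predict(fit_ba, x))
})

test_that("inverse-count class weights recover the minority class", {
  # 2 vs 10 with overlap: unweighted SVM is pulled toward the majority
  set.seed(31)
  x <- rbind(matrix(rnorm(2 * 2, mean = 1.2, sd = 0.5), 2, 2),
             matrix(rnorm(10 * 2, mean = -1.2, sd = 0.5), 10, 2))
  y <- factor(c("pos", "pos", rep("neg", 10)), levels = c("pos", "neg"))
  fw <- fit_linear_svm(x, y, classifier_config(class_weight_mode = "inverse_count"))
  fu <- fit_linear_svm(x, y, classifier_config(class_weight_mode = "none"))
  # weighted margin sits farther from the minority class: its decision
  # values on minority points are at least as large
  expect_gte(min(decision_values(fw, x[1:2, , drop = FALSE])),
             min(decision_values(fu, x[1:2, , drop = FALSE])) - 1e-8)
})

test_that("one-against-all reduces to the binary machine for two classes", {
  set.seed(9)
  x <- matrix(rnorm(16 * 4), 16, 4)
  x[1:8, 1] <- x[1:8, 1] + 2
  yv <- rep(c(0L, 2L), each = 8)
  ova <- inphconn:::fit_one_vs_all(x, yv, classifier_config())
  expect_equal(ova$classes, c(0L, 2L))
  pred <- predict(ova, x)

  bin <- fit_linear_svm(x, factor(ifelse(yv == 0L, "pos", "rest"),
                                  levels = c("pos", "rest")),
                        classifier_config())
  pred_bin <- ifelse(as.character(predict(bin, x)) == "pos", 0L, 2L)
  expect_equal(pred, pred_bin)

  # exact decision-value ties resolve to the lowest class
  fake <- structure(list(
    machines = list(structure(list(w = c(0, 0, 0, 0), b = 0.5),
                              class = "linear_svm"),
                    structure(list(w = c(0, 0, 0, 0), b = 0.5),
                              class = "linear_svm")),
    classes = c(1L, 3L)), class = "one_vs_all_svm")
  expect_equal(predict(fake, x[1:3, ]), rep(1L, 3))
})

test_that("binomial test equals tail enumeration and reproduces printed values", {
  # full enumeration oracle for every (k, n <= 30) at several chance levels
  for (p0 in c(0.2, 0.5, 1 / 3)) {
    for (n in c(5, 11, 22, 30)) {
      for (k in 0:n) {
        probs <- dbinom(0:n, n, p0)
        oracle <- min(1, 2 * min(sum(probs[0:n <= k]),
                                 sum(probs[0:n >= k])))
        expect_equal(binomial_test(k, n, p0), oracle, tolerance = 1e-12)
      }
    }
  }

  # printed in-study values
  expect_equal(floor(binomial_test(14, 22, 0.5) * 100) / 100, 0.28)
  expect_lt(binomial_test(18, 22, 0.5), 0.01)
  expect_equal(binomial_test(11, 22, 0.5), 1)

  expect_error(binomial_test(5, 4), class = "inphconn_invalid_input")
  expect_error(binomial_test(-1, 4), class = "inphconn_invalid_input")
  expect_error(binomial_test(2, 4, 0), class = "inphconn_invalid_input")
})

test_that("percent truncation follows the floor convention", {
  expect_equal(percent_trunc(14, 22), 63L)
  expect_equal(percent_trunc(18, 22), 81L)
  expect_equal(percent_trunc(22, 22), 100L)
  expect_equal(percent_trunc(7, 11), 63L)
  expect_equal(percent_trunc(0, 22), 0L)
})

test_that("leave-one-out runs one fold per subject without leakage", {
  coh <- toy_cohort(seed = 17, n_rois = 12)
  feats <- cohort_features(suppressMessages(denoise_cohort(coh)))
  cv <- suppressMessages(loocv(feats, "diagnosis"))
  expect_equal(nrow(cv$folds), 22)
  expect_equal(cv$folds$subject_id, coh$subject_id)
  expect_equal(cv$k, sum(cv$folds$correct))
  expect_equal(cv$accuracy, cv$k / 22)
  expect_equal(cv$p, binomial_test(cv$k, 22, 0.5))

  # leakage guard: corrupting the held-out subject's features must not
  # change which edges that fold selects
  k_probe <- 3
  feats_c <- feats
  feats_c$x[k_probe, ] <- feats_c$x[k_probe, ] + 50
  cv_c <- suppressMessages(loocv(feats_c, "diagnosis"))
  expect_identical(cv_c$folds$selected[[k_probe]],
                   cv$folds$selected[[k_probe]])

  # pooled scope uses one selection everywhere, and it sees all subjects
  cvp <- suppressMessages(loocv(
    feats, "diagnosis", classifier_config(selection_scope = "pooled")))
  expect_true(all(vapply(cvp$folds$selected,
                         identical, logical(1), cvp$pooled_selection)))
  cvp_c <- suppressMessages(loocv(
    feats_c, "diagnosis", classifier_config(selection_scope = "pooled")))
  expect_false(identical(cvp_c$pooled_selection, cvp$pooled_selection))

  # glance/tidy contracts
  g <- glance(cv)
  expect_equal(g$k, cv$k)
  expect_equal(g$percent, percent_trunc(cv$k, 22))
  expect_equal(nrow(tidy(cv)), 22)
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})

test_that("severity tasks filter on diagnosis and report patient-restricted accuracy", {
  coh <- toy_cohort(seed = 23, n_rois = 12)
  feats <- cohort_features(suppressMessages(denoise_cohort(coh)))
  cv <- suppressMessages(loocv(feats, "gs_gait"))
  expect_equal(cv$n, 22)
  expect_equal(cv$chance, 1 / length(unique(c(coh$gs_gait))))
  expect_equal(cv$restricted$n, 11)
  expect_equal(cv$restricted$k,
               sum(cv$folds$correct[cv$folds$group == "iNPH"]))

  # the per-fold selected sets equal the diagnosis-contrast selection,
  # not any severity-based contrast
  cvd <- suppressMessages(loocv(feats, "diagnosis"))
  expect_identical(cv$folds$selected, cvd$folds$selected)

  expect_error(loocv(feats, "mmse"))
  expect_error(classifier_config(cost = 0), class = "inphconn_invalid_config")
  expect_error(classifier_config(filter_alpha = 1),
               class = "inphconn_invalid_config")
})
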