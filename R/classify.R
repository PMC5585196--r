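#' Classifier configuration
#'
#' @param cost Soft-margin cost factor (default 1).
#' @param filter_alpha Two-sided p-value threshold of the t-test feature
#'   filter (default 0.05).
#' @param selection_scope `"per_fold"` (filter recomputed inside every
#'   cross-validation fold on the training subjects only; leakage-safe
#'   default) or `"pooled"` (filter computed once on all subjects before
#'   cross-validation, reproducing the described original procedure).
#' @param class_weight_mode `"inverse_count"` scales each class's
#'   misclassification cost by 1 / (number of training subjects with that
#'   label), removing the bias from unbalanced label counts; `"none"` leaves
#'   costs equal.
#' @param chance_level Chance probability for the binomial significance test;
#'   `NULL` means 0.5 for diagnosis and 1 / (number of observed label values)
#'   for severity tasks.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(cost = 1,
                              filter_alpha = 0.05,
                              selection_scope = c("per_fold", "pooled"),
                              class_weight_mode = c("inverse_count", "none"),
                              chance_level = NULL) {
  if (cost <= 0) abort("cost must be positive", class = "inphconn_invalid_config")
  if (filter_alpha <= 0 || filter_alpha >= 1) {
    abort("filter_alpha must lie in (0, 1)", class = "inphconn_invalid_config")
  }
  structure(list(cost = cost,
                 filter_alpha = filter_alpha,
                 selection_scope = match.arg(selection_scope),
                 class_weight_mode = match.arg(class_weight_mode),
                 chance_level = chance_level),
            class = "classifier_config")
}

#' Two-sample t-test feature filter
#'
#' Pooled-variance two-sample t-test per feature between the two diagnostic
#' groups; features with two-sided p below `alpha` are retained. The
#' grouping variable is always the diagnosis (patient vs control), including
#' when the downstream labels are severity grades. Features with zero
#' variance in both groups are excluded with an informational note.
#'
#' @param x Subjects x features numeric matrix.
#' @param groups Vector with exactly two distinct values, >= 2 subjects each.
#' @param alpha Two-sided p threshold.
#' @return Integer vector of selected feature indices, with attribute
#'   `p_values` (per-feature two-sided p).
#' @export
ttest_filter <- function(x, groups, alpha = 0.05) {
  g <- as.factor(groups)
  if (nlevels(g) != 2) {
    abort("exactly two groups required", class = "inphconn_invalid_input")
  }
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  if (n1 < 2 || n2 < 2) {
    abort("each group needs at least 2 subjects",
          class = "inphconn_invalid_input")
  }
  x1 <- x[g == levels(g)[1], , drop = FALSE]
  x2 <- x[g == levels(g)[2], , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(x2, 2, m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  df <- n1 + n2 - 2
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se == 0
  if (any(degenerate)) {
    inform(sprintf("%d zero-variance feature(s) excluded from the t-filter",
                   sum(degenerate)), class = "inphconn_filter_degenerate")
    p[degenerate] <- 1
  }
  structure(which(p < alpha), p_values = p)
}

#' Scale features to zero mean and unit variance on the training set
#'
#' Centre/scale parameters are computed on the training rows only and then
#' applied to both the training rows and any held-out rows, so the held-out
#' subject never influences the scaling. Columns whose training standard
#' deviation falls below 1e-12 are mapped to zero with an informational note.
#'
#' @param train Training subjects x features matrix.
#' @param apply_to Matrix to transform with the training parameters
#'   (default: the training matrix itself).
#' @return List with `scaled` (transformed `apply_to`), `center`, `scale`,
#'   and `constant` (logical, floored columns).
#' @export
scale_features <- function(train, apply_to = train) {
  if (nrow(train) < 1) {
    abort("training set must be nonempty", class = "inphconn_invalid_input")
  }
  ctr <- colMeans(train)
  s <- sqrt(colSums(sweep(train, 2, ctr)^2) / max(1, nrow(train) - 1))
  constant <- s < 1e-12
  if (any(constant)) {
    inform(sprintf("%d constant feature(s) floored to zero during scaling",
                   sum(constant)), class = "inphconn_scale_floor")
  }
  s_eff <- ifelse(constant, 1, s)
  out <- sweep(sweep(apply_to, 2, ctr), 2, s_eff, "/")
  out[, constant] <- 0
  list(scaled = out, center = ctr, scale = s_eff, constant = constant)
}

#' Fit a class-weighted linear support-vector machine
#'
#' Soft-margin linear C-classification with per-class misclassification cost
#' `cost * (1 / n_class)` (the inverse-count class weighting that offsets
#' unbalanced label counts). The primal weight vector `w` and bias `b` are
#' recovered from the support-vector expansion so downstream weight analysis
#' can read them; the decision function is `f(x) = w . x + b`, positive for
#' the first factor level.
#'
#' @param x Training subjects x features matrix (already filtered/scaled).
#' @param y Factor of training labels with at least two classes present.
#' @param config A [classifier_config()].
#' @return An object of class `linear_svm` with elements `w`, `b`,
#'   `levels` (the positive class is `levels[1]`), and the underlying fit.
#' @export
fit_linear_svm <- function(x, y, config = classifier_config()) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) {
    abort("training labels must contain at least two classes",
          class = "inphconn_invalid_input")
  }
  cw <- if (config$class_weight_mode == "inverse_count") {
    tab <- table(y); stats::setNames(as.numeric(1 / tab), names(tab))
  } else {
    stats::setNames(rep(1, nlevels(y)), levels(y))
  }
  fit <- e1071::svm(x = x, y = y, type = "C-classification",
                    kernel = "linear", cost = config$cost,
                    class.weights = cw, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm orients the decision function toward the class of the first
  # training row (fit$labels[1]); normalise so positive means levels(y)[1]
  if (fit$labels[1] != 1L) {
    w <- -w
    b <- -b
  }
  structure(list(w = w, b = b, levels = levels(y), fit = fit),
            class = "linear_svm")
}

#' Decision values of a linear SVM
#'
#' @param object A `linear_svm`.
#' @param x Matrix of feature rows.
#' @return Numeric vector `x %*% w + b`, positive for the first class level.
#' @export
decision_values <- function(object, x) {
  drop(x %*% object$w + object$b)
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  f <- decision_values(object, newdata)
  factor(ifelse(f >= 0, object$levels[1], object$levels[2]),
         levels = object$levels)
}

# One-against-all ensemble: one binary machine per label value present in
# the training data; prediction is the argmax of decision values, ties
# resolved toward the lowest label.
fit_one_vs_all <- function(x, y_values, config) {
  classes <- sort(unique(y_values))
  machines <- lapply(classes, function(cl) {
    y_bin <- factor(ifelse(y_values == cl, "pos", "rest"),
                    levels = c("pos", "rest"))
    fit_linear_svm(x, y_bin, config)
  })
  structure(list(machines = machines, classes = classes),
            class = "one_vs_all_svm")
}

#' @export
predict.one_vs_all_svm <- function(object, newdata, ...) {
  dv <- vapply(object$machines, decision_values, numeric(nrow(newdata)),
               x = newdata)
  dv <- matrix(dv, nrow = nrow(newdata))
  # max.col with ties.method = "first" picks the lowest label on exact ties
  # because classes are sorted ascending
  object$classes[max.col(dv, ties.method = "first")]
}

#' Exact two-sided binomial test for classification accuracy
#'
#' `p = min(1, 2 * min(P(X <= k), P(X >= k)))` under Binomial(n, p0): the
#' doubled smaller exact tail.
#'
#' @param k Number of correct predictions.
#' @param n Number of cross-validation tests.
#' @param p0 Chance probability.
#' @return The two-sided exact p-value.
#' @examples
#' binomial_test(14, 22, 0.5) # 0.286..., prints as 0.28
#' binomial_test(18, 22, 0.5) # below 0.01
#' @export
binomial_test <- function(k, n, p0 = 0.5) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      k < 0 || n < 1 || k > n || k != round(k) || n != round(n)) {
    abort("k and n must be integers with 0 <= k <= n",
          class = "inphconn_invalid_input")
  }
  if (p0 <= 0 || p0 >= 1) {
    abort("p0 must lie in (0, 1)", class = "inphconn_invalid_input")
  }
  lower <- pbinom(k, n, p0)
  upper <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Leave-one-out cross-validated classification
#'
#' Each subject in turn is held out; the t-test filter (always on the
#' diagnostic contrast) and the feature scaling are fit on the remaining
#' subjects (scope `"per_fold"`) or the filter is computed once on the full
#' cohort (scope `"pooled"`); a class-weighted linear SVM is trained and the
#' held-out subject predicted. Diagnosis is a single binary machine;
#' severity grades use a one-against-all ensemble over the label values
#' present in the training fold, predicting the class with the largest
#' decision value (ties to the lowest grade). For severity tasks the
#' accuracy restricted to the patient test rounds is also reported.
#'
#' Folds in which removing the held-out subject empties a training class are
#' flagged degenerate and logged; a prediction is still produced from the
#' remaining classes.
#'
#' @param features An `fc_features` object from [cohort_features()].
#' @param task One of `"diagnosis"`, `"gs_gait"`, `"gs_cognition"`,
#'   `"gs_urinary"`.
#' @param config A [classifier_config()].
#' @return An object of class `fc_cv`; see [tidy.fc_cv()] and
#'   [glance.fc_cv()].
#' @export
loocv <- function(features, task = c("diagnosis", "gs_gait", "gs_cognition",
                                     "gs_urinary"),
                  config = classifier_config()) {
  task <- match.arg(task)
  x <- features$x
  meta <- features$meta
  n <- nrow(x)
  if (n < 3) abort("need at least 3 subjects", class = "inphconn_invalid_input")
  diag_groups <- meta$group
  if (length(unique(diag_groups)) != 2) {
    abort("both diagnostic groups must be present",
          class = "inphconn_invalid_input")
  }
  labels <- if (task == "diagnosis") diag_groups else meta[[task]]

  pooled_sel <- NULL
  if (config$selection_scope == "pooled") {
    pooled_sel <- as.integer(ttest_filter(x, diag_groups, config$filter_alpha))
  }

  folds <- vector("list", n)
  for (k in seq_len(n)) {
    train <- setdiff(seq_len(n), k)
    sel <- if (is.null(pooled_sel)) {
      as.integer(ttest_filter(x[train, , drop = FALSE], diag_groups[train],
                              config$filter_alpha))
    } else pooled_sel
    degenerate <- FALSE
    if (length(sel) == 0) {
      # nothing survives the filter: predict the majority training label
      tab <- table(labels[train])
      pred <- names(tab)[which.max(tab)]
      degenerate <- TRUE
      inform(sprintf("fold %d: empty feature selection; majority prediction", k),
             class = "inphconn_degenerate_fold")
    } else {
      sc <- scale_features(x[train, sel, drop = FALSE],
                           x[c(train, k), sel, drop = FALSE])
      xtr <- sc$scaled[seq_along(train), , drop = FALSE]
      xte <- sc$scaled[length(train) + 1, , drop = FALSE]
      if (task == "diagnosis") {
        fit <- fit_linear_svm(xtr, factor(labels[train]), config)
        pred <- as.character(predict(fit, xte))
      } else {
        if (!all(unique(labels) %in% labels[train])) {
          degenerate <- TRUE
          inform(sprintf(
            "fold %d: label value(s) %s absent from training; predicting from remaining classes",
            k, paste(setdiff(unique(labels), labels[train]), collapse = ",")),
            class = "inphconn_degenerate_fold")
        }
        fit <- fit_one_vs_all(xtr, labels[train], config)
        pred <- as.character(predict(fit, xte))
      }
    }
    folds[[k]] <- tibble(subject_id = meta$subject_id[k],
                         group = meta$group[k],
                         true = as.character(labels[k]),
                         predicted = pred,
                         correct = pred == as.character(labels[k]),
                         n_selected = length(sel),
                         selected = list(sel),
                         degenerate = degenerate)
  }
  folds <- bind_rows(folds)

  accuracy <- mean(folds$correct)
  chance <- if (!is.null(config$chance_level)) config$chance_level
            else if (task == "diagnosis") 0.5 else 1 / length(unique(labels))
  p_all <- binomial_test(sum(folds$correct), n, chance)

  restricted <- NULL
  if (task != "diagnosis") {
    sub <- folds[folds$group == "iNPH", ]
    restricted <- list(accuracy = mean(sub$correct),
                       k = sum(sub$correct), n = nrow(sub),
                       p = binomial_test(sum(sub$correct), nrow(sub), chance))
  }

  structure(list(folds = folds, task = task, accuracy = accuracy,
                 k = sum(folds$correct), n = n, chance = chance, p = p_all,
                 restricted = restricted, config = config,
                 pooled_selection = pooled_sel,
                 roi_table_hash = features$roi_table_hash),
            class = "fc_cv")
}

#' Truncate a fraction to an integer percent
#'
#' The reporting convention used throughout: `floor(100 * k / n)`, so 14/22
#' prints as 63% and 18/22 as 81%.
#'
#' @param k Numerator, `n` denominator.
#' @param n Denominator.
#' @return Integer percent.
#' @export
percent_trunc <- function(k, n) as.integer(floor(100 * k / n))

#' @export
print.fc_cv <- function(x, ...) {
  cat(sprintf("<fc_cv> task %s, scope %s: %d/%d correct (%d%%), exact binomial p = %.4g (chance %.3g)\n",
              x$task, x$config$selection_scope, x$k, x$n,
              percent_trunc(x$k, x$n), x$p, x$chance))
  if (!is.null(x$restricted)) {
    cat(sprintf("  patient-restricted: %d/%d correct (%d%%), p = %.4g\n",
                x$restricted$k, x$restricted$n,
                percent_trunc(x$restricted$k, x$restricted$n),
                x$restricted$p))
  }
  invisible(x)
}

#' Tidy per-fold cross-validation records
#'
#' @param x An `fc_cv` object.
#' @param ... Unused.
#' @return A tibble with one row per fold.
#' @method tidy fc_cv
#' @export
tidy.fc_cv <- function(x, ...) x$folds

#' One-row cross-validation summary
#'
#' @param x An `fc_cv` object.
#' @param ... Unused.
#' @return Tibble with accuracy, counts, chance level, binomial p, and the
#'   patient-restricted versions when applicable.
#' @method glance fc_cv
#' @export
glance.fc_cv <- function(x, ...) {
  tibble(task = x$task,
         scope = x$config$selection_scope,
         n = x$n, k = x$k,
         accuracy = x$accuracy,
         percent = percent_trunc(x$k, x$n),
         chance = x$chance,
         p_value = x$p,
         restricted_n = if (is.null(x$restricted)) NA_integer_ else x$restricted$n,
         restricted_k = if (is.null(x$restricted)) NA_integer_ else x$restricted$k,
         restricted_accuracy = if (is.null(x$restricted)) NA_real_ else x$restricted$accuracy,
         restricted_p = if (is.null(x$restricted)) NA_real_ else x$restricted$p)
}

#' Plot cross-validated accuracy with its exact binomial interval
#'
#' @param object An `fc_cv` object.
#' @param ... Unused.
#' @return A ggplot object: accuracy bar with Clopper-Pearson 95% interval
#'   and the chance level as a dashed line.
#' @method autoplot fc_cv
#' @export
autoplot.fc_cv <- function(object, ...) {
  ci <- stats::binom.test(object$k, object$n)$conf.int
  df <- tibble(task = object$task, accuracy = object$accuracy,
               lo = ci[1], hi = ci[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$task, y = .data$accuracy)) +
    ggplot2::geom_col(width = 0.5, fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.15) +
    ggplot2::geom_hline(yintercept = object$chance, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(y = "LOOCV accuracy", x = NULL) +
    ggplot2::theme_minimal()
}
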