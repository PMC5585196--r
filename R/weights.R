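#' Extract per-edge weight magnitudes from trained linear machines
#'
#' For a binary machine, the absolute primal weight per selected edge; for a
#' one-against-all ensemble, the sum of absolute weights across the class
#' machines, edge by edge. Unselected edges receive weight 0 and are
#' excluded from ranking.
#'
#' @param model A `linear_svm` or `one_vs_all_svm`.
#' @param selected Integer indices (into the full edge enumeration) of the
#'   features the model was trained on, in training column order.
#' @param n_edges Total number of edges in the enumeration.
#' @return Numeric vector of length `n_edges` of weight magnitudes, with
#'   attribute `selected`.
#' @export
extract_weights <- function(model, selected, n_edges) {
  mag <- if (inherits(model, "linear_svm")) {
    abs(model$w)
  } else if (inherits(model, "one_vs_all_svm")) {
    Reduce(`+`, lapply(model$machines, function(m) abs(m$w)))
  } else {
    abort("weights can only be read from linear models",
          class = "inphconn_unsupported_model")
  }
  if (length(mag) != length(selected)) {
    abort("selected index set disagrees with model dimensionality",
          class = "inphconn_invalid_input")
  }
  out <- numeric(n_edges)
  out[selected] <- mag
  structure(out, selected = selected)
}

#' Cumulative weight fraction of the top-k edges
#'
#' @param report An `fc_weights` report.
#' @param k Number of leading edges (>= 1, at most the number of selected
#'   edges).
#' @return List with `edges` (the top-k rows of the ranking) and `fraction`
#'   (their summed weight over the total weight of all selected edges).
#' @export
top_k_fraction <- function(report, k) {
  ranked <- report$ranking
  if (k <= 0) abort("k must be positive", class = "inphconn_invalid_input")
  if (k > nrow(ranked)) {
    abort("k exceeds the number of ranked edges",
          class = "inphconn_invalid_input")
  }
  top <- ranked[seq_len(k), ]
  list(edges = top, fraction = sum(top$weight) / sum(ranked$weight))
}

#' Hemisphere-partition sums of SVM weights
#'
#' Splits the selected-edge weight mass into interhemispheric and
#' intrahemispheric sums and reports the interhemispheric share of the
#' selected edges (by count).
#'
#' @param report An `fc_weights` report.
#' @return One-row tibble with `inter_sum`, `intra_sum`,
#'   `inter_fraction_selected`.
#' @export
partition_sums <- function(report) {
  ranked <- report$ranking
  tibble(inter_sum = sum(ranked$weight[ranked$class == "inter"]),
         intra_sum = sum(ranked$weight[ranked$class == "intra"]),
         inter_fraction_selected = mean(ranked$class == "inter"))
}

#' Wilcoxon rank-sum comparison of two weight samples
#'
#' Rank-sum statistic with midranks for ties. The p-value is exact (by
#' enumeration of orderings) when the combined sample size is at most 20 and
#' there are no ties, and otherwise uses the normal approximation with tie
#' and continuity corrections; the method used is recorded.
#'
#' @param x,y Nonempty numeric samples (e.g. inter- vs intrahemispheric
#'   weight magnitudes).
#' @return One-row tibble with `statistic` (rank sum of `x`), `p_value`,
#'   `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be nonempty", class = "inphconn_invalid_input")
  }
  ranks <- rank(c(x, y))
  statistic <- sum(ranks[seq_along(x)])
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 20
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided"))
  tibble(statistic = statistic, p_value = wt$p.value,
         method = if (exact) "exact" else "normal_approximation")
}

#' Interpretation weights of the connectome classifier
#'
#' Retrains the classifier on the full cohort using the pooled-scope t-test
#' selection (the single weight table the study design calls for), reads out
#' the per-edge weight magnitudes, ranks them (descending, ties broken by
#' canonical edge index), and attaches the hemisphere-partition summary and
#' the Wilcoxon rank-sum comparison of inter- vs intrahemispheric weights.
#'
#' @param features An `fc_features` object.
#' @param task `"diagnosis"` or a severity grade column.
#' @param config A [classifier_config()]; the filter is always applied at
#'   `config$filter_alpha` on the diagnostic contrast.
#' @return An object of class `fc_weights` with elements `ranking` (tibble
#'   `rank`, `edge`, `name_i`, `name_j`, `class`, `weight`), `task`,
#'   `partition` (from [partition_sums()]), and `wilcoxon`.
#' @export
weight_report <- function(features, task = c("diagnosis", "gs_gait",
                                             "gs_cognition", "gs_urinary"),
                          config = classifier_config()) {
  task <- match.arg(task)
  x <- features$x
  meta <- features$meta
  sel <- as.integer(ttest_filter(x, meta$group, config$filter_alpha))
  if (length(sel) == 0) {
    abort("no edges survive the t-test filter; no weights to report",
          class = "inphconn_invalid_input")
  }
  sc <- scale_features(x[, sel, drop = FALSE])
  labels <- if (task == "diagnosis") meta$group else meta[[task]]
  model <- if (task == "diagnosis") {
    fit_linear_svm(sc$scaled, factor(labels), config)
  } else {
    fit_one_vs_all(sc$scaled, labels, config)
  }
  w <- extract_weights(model, sel, ncol(x))
  edges <- features$edges
  ranking <- edges[sel, ]
  ranking$weight <- w[sel]
  ranking$name_i <- features$rois$name[ranking$i]
  ranking$name_j <- features$rois$name[ranking$j]
  ranking <- ranking[order(-ranking$weight, ranking$edge), ]
  ranking$rank <- seq_len(nrow(ranking))
  ranking <- ranking[, c("rank", "edge", "i", "j", "name_i", "name_j",
                         "class", "weight")]
  out <- structure(list(ranking = as_tibble(ranking), task = task,
                        config = config, model = model, selected = sel,
                        roi_table_hash = features$roi_table_hash),
                   class = "fc_weights")
  out$partition <- partition_sums(out)
  w_inter <- ranking$weight[ranking$class == "inter"]
  w_intra <- ranking$weight[ranking$class == "intra"]
  out$wilcoxon <- if (length(w_inter) > 0 && length(w_intra) > 0) {
    wilcoxon_rank_sum(w_inter, w_intra)
  } else {
    # all selected edges fall in one hemisphere class (possible on very
    # small ROI sets): the comparison is undefined
    tibble(statistic = NA_real_, p_value = NA_real_, method = "undefined")
  }
  out
}

#' @export
print.fc_weights <- function(x, ...) {
  cat(sprintf("<fc_weights> task %s: %d selected edges; inter sum %.4g, intra sum %.4g (inter share of edges %.1f%%)\n",
              x$task, nrow(x$ranking), x$partition$inter_sum,
              x$partition$intra_sum,
              100 * x$partition$inter_fraction_selected))
  print(head(x$ranking, 10))
  invisible(x)
}

#' Tidy the ranked weight table
#'
#' @param x An `fc_weights` object.
#' @param ... Unused.
#' @return The ranking tibble (`rank`, edge names, hemisphere class,
#'   weight).
#' @method tidy fc_weights
#' @export
tidy.fc_weights <- function(x, ...) x$ranking

#' One-row weight-report summary
#'
#' @param x An `fc_weights` object.
#' @param ... Unused.
#' @return Tibble with the partition sums, interhemispheric share, top-20
#'   cumulative weight fraction (top-30 for severity tasks), and the
#'   Wilcoxon comparison.
#' @method glance fc_weights
#' @export
glance.fc_weights <- function(x, ...) {
  k <- if (x$task == "diagnosis") 20L else 30L
  k <- min(k, nrow(x$ranking))
  tibble(task = x$task,
         n_selected = nrow(x$ranking),
         inter_sum = x$partition$inter_sum,
         intra_sum = x$partition$intra_sum,
         inter_fraction_selected = x$partition$inter_fraction_selected,
         top_k = k,
         top_k_fraction = top_k_fraction(x, k)$fraction,
         wilcoxon_statistic = x$wilcoxon$statistic,
         wilcoxon_p = x$wilcoxon$p_value)
}

#' Plot the top-k connectome weights
#'
#' @param object An `fc_weights` object.
#' @param k Number of edges to show (default 20).
#' @param ... Unused.
#' @return A ggplot bar chart of weight magnitudes, coloured by hemisphere
#'   class.
#' @method autoplot fc_weights
#' @export
autoplot.fc_weights <- function(object, k = 20, ...) {
  top <- top_k_fraction(object, min(k, nrow(object$ranking)))$edges
  top$pair <- factor(paste(top$name_i, top$name_j, sep = " - "),
                     levels = rev(paste(top$name_i, top$name_j, sep = " - ")))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$pair, y = .data$weight,
                                    fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "|SVM weight|", fill = "edge class") +
    ggplot2::theme_minimal()
}
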