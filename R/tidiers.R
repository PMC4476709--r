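#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained signature model at the component level
#'
#' One row per retained principal component: its LASSO coefficient,
#' whether it survived selection, and the OLS refit coefficient.
#'
#' @param x a `trained_model`.
#' @param ... unused.
#' @return A tibble with `component`, `lasso_coef`, `selected`, `ols_coef`.
#' @export
tidy.trained_model <- function(x, ...) {
  ols <- rep(NA_real_, x$n_components)
  ols[x$selected] <- x$component_coefs
  tibble::tibble(
    component = seq_len(x$n_components),
    lasso_coef = x$lasso_coefs,
    selected = seq_len(x$n_components) %in% x$selected,
    ols_coef = ols
  )
}

#' @rdname tidy.trained_model
#' @export
glance.trained_model <- function(x, ...) {
  tibble::tibble(
    n_obs = x$train_n,
    n_components = x$n_components,
    n_selected = length(x$selected),
    lambda = x$lambda,
    intercept = x$weight_map$intercept,
    n_nonzero_voxels = sum(x$weight_map$weights != 0)
  )
}

#' Tidy cross-validation results
#'
#' @param x a `cv_result` from [loso_cross_validate()].
#' @param ... unused.
#' @return `tidy()`: the per-subject metric tibble; `glance()`: one-row
#'   summary with mean/SE of within-subject r and RMSE and pooled metrics.
#' @export
tidy.cv_result <- function(x, ...) x$by_subject

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    n_folds = dplyr::n_distinct(x$predictions$fold),
    mean_r = x$mean_r, se_r = x$se_r,
    mean_rmse = x$mean_rmse, se_rmse = x$se_rmse,
    pooled_r = x$pooled_r, pooled_rmse = x$pooled_rmse
  )
}

#' Tidy a classification result
#'
#' @param x a `classification_result`.
#' @param ... unused.
#' @return One-row tibble with accuracy, sensitivity, specificity, SE, n,
#'   threshold and p-value.
#' @export
tidy.classification_result <- function(x, ...) {
  tibble::tibble(
    test = x$test, accuracy = x$accuracy, sensitivity = x$sensitivity,
    specificity = x$specificity, se = x$se, n = x$n,
    threshold = x$threshold, p_value = x$p_value
  )
}

#' Tidy a cluster solution
#'
#' @param x a `cluster_solution`.
#' @param ... unused.
#' @return `tidy()`: tibble of region-to-cluster assignments; `glance()`:
#'   one-row summary.
#' @export
tidy.cluster_solution <- function(x, ...) {
  tibble::tibble(
    region = seq_along(x$assignment),
    cluster = as.integer(x$assignment)
  )
}

#' @rdname tidy.cluster_solution
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble::tibble(
    n_regions = length(x$assignment), n_clusters = x$n_clusters,
    cut_fraction = x$cut_fraction, cut_height = x$cut_height,
    max_height = max(x$tree$height), normalization = x$normalization
  )
}

#' Plot cross-validated predictions against observed ratings
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return A ggplot: per-level mean predicted rating with SE ribbons.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- dplyr::summarise(
    dplyr::group_by(object$predictions, .data$rating),
    mean_pred = mean(.data$predicted),
    se = stats::sd(.data$predicted) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rating, y = .data$mean_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_pred - .data$se, ymax = .data$mean_pred + .data$se
    )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "observed rating", y = "predicted rating",
      title = "Cross-validated signature predictions")
}

#' Plot a benchmark grid
#'
#' @param object a `benchmark_grid`.
#' @param ... unused.
#' @return A ggplot comparing patterns across the classification columns.
#' @export
autoplot.benchmark_grid <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$grid, "pattern", "emotion_high_vs_low",
      "pain_high_vs_low", "emotion_vs_pain"),
    -"pattern",
    names_to = "comparison", values_to = "accuracy"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$pattern, y = .data$accuracy, fill = .data$comparison
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::labs(y = "balanced accuracy (%)", x = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the subnetwork dendrogram cut
#'
#' @param object a `cluster_solution`.
#' @param ... unused.
#' @return A ggplot of merge heights with the cut level marked.
#' @export
autoplot.cluster_solution <- function(object, ...) {
  df <- tibble::tibble(
    merge = seq_along(object$tree$height),
    height = object$tree$height
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$merge, y = .data$height)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$cut_height, colour = "red",
      linetype = "dashed") +
    ggplot2::labs(x = "merge", y = "Ward merge height",
      title = sprintf("%d clusters at %.0f%% of max height",
        object$n_clusters, 100 * object$cut_fraction))
}
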