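#' Pattern response of images to a signature
#'
#' The canonical expression measure is the dot product of each vectorized
#' activation image with the signature weights plus the signature's
#' intercept, yielding one scalar per image in the units the signature was
#' trained on. Scale-free alternatives (Pearson or Spearman spatial
#' correlation between image and weights, which ignore the intercept) are
#' available for comparing responses across maps with different scales.
#'
#' @param images a [beta_image_set()], a voxel matrix, or a single image
#'   vector.
#' @param map a [weight_map()] sharing the image mask.
#' @param method `"dot"`, `"pearson"`, or `"spearman"`.
#' @param pattern_name label recorded with each response.
#' @return For a `beta_image_set`, a tibble of the set's metadata plus
#'   `pattern`, `response`, `method`; for matrix/vector input, a numeric
#'   vector (scalar).
#' @export
pattern_response <- function(images, map,
                             method = c("dot", "pearson", "spearman"),
                             pattern_name = "pattern") {
  method <- match.arg(method)
  stopifnot(inherits(map, "weight_map"))
  if (inherits(images, "beta_image_set")) {
    check_same_mask(images$mask, map$mask, "images and weight map")
    X <- images$data
    meta <- images$meta
  } else {
    X <- if (is.matrix(images)) images else matrix(images, nrow = 1)
    if (ncol(X) != length(map$weights)) {
      stop("image length does not match weight map", call. = FALSE)
    }
    meta <- NULL
  }
  resp <- switch(method,
    dot = as.numeric(X %*% map$weights + map$intercept),
    pearson = apply(X, 1L, function(r) stats::cor(r, map$weights)),
    spearman = apply(X, 1L, function(r) {
      stats::cor(r, map$weights, method = "spearman")
    })
  )
  if (is.null(meta)) return(resp)
  dplyr::bind_cols(meta, tibble::tibble(
    pattern = pattern_name, response = resp, method = method
  ))
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Compare the spatial topography of two maps
#'
#' Pearson, Spearman, point-biserial (for a binary mask as the second map),
#' or a robust ranked statistic: both maps are rank-transformed within the
#' scope, standardized, and related by an iteratively reweighted robust
#' regression (Huber M-estimate); the symmetrized slope is reported, clamped
#' to \[-1, 1\]. Rank-based statistics are invariant to strictly increasing
#' monotone transforms of either map.
#'
#' @param a a [weight_map()].
#' @param b a [weight_map()] or, for point-biserial, a [brain_mask()] /
#'   binary vector on the same space.
#' @param statistic `"pearson"`, `"spearman"`, `"ranked_robust"`, or
#'   `"pointbiserial"`.
#' @param scope optional [brain_mask()] restricting the comparison to an
#'   ROI (must be within the shared mask).
#' @return One-row tibble: `pattern_a`, `pattern_b`, `statistic`, `value`,
#'   `n_voxels`, `scope`, `defined`.
#' @export
compare_maps <- function(a, b,
                         statistic = c("pearson", "spearman",
                           "ranked_robust", "pointbiserial"),
                         scope = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(a, "weight_map"))
  va <- a$weights
  if (inherits(b, "weight_map")) {
    check_same_mask(a$mask, b$mask, "maps")
    vb <- b$weights
    name_b <- "B"
  } else if (inherits(b, "brain_mask")) {
    if (!same_grid(a$mask, b)) stop("mask grids differ", call. = FALSE)
    vb <- as.numeric(vectorize(b$inclusion, a$mask))
    name_b <- "mask"
  } else {
    vb <- as.numeric(b)
    stopifnot(length(vb) == length(va))
    name_b <- "vector"
  }
  scope_name <- "whole-mask"
  if (!is.null(scope)) {
    stopifnot(inherits(scope, "brain_mask"))
    keep <- vectorize(scope$inclusion, a$mask) > 0
    va <- va[keep]
    vb <- vb[keep]
    scope_name <- "roi"
  }
  defined <- stats::sd(va) > 0 && stats::sd(vb) > 0
  value <- NA_real_
  if (defined) {
    value <- switch(statistic,
      pearson = stats::cor(va, vb),
      pointbiserial = stats::cor(va, vb),
      spearman = stats::cor(va, vb, method = "spearman"),
      ranked_robust = {
        ra <- standardize(rank(va))
        rb <- standardize(rank(vb))
        f1 <- MASS::rlm(rb ~ ra, maxit = 50)
        f2 <- MASS::rlm(ra ~ rb, maxit = 50)
        s <- sign(f1$coefficients[2]) *
          sqrt(abs(f1$coefficients[2] * f2$coefficients[2]))
        unname(pmin(1, pmax(-1, s)))
      }
    )
  }
  tibble::tibble(
    pattern_a = "A", pattern_b = name_b, statistic = statistic,
    value = value, n_voxels = length(va), scope = scope_name,
    defined = defined
  )
}

#' Average activation within a region of interest
#'
#' The mean in-ROI voxel value per observation: equivalent to a dot-product
#' response with a uniform weight map scaled by 1/|ROI| and zero intercept.
#'
#' @param images a [beta_image_set()].
#' @param roi a [brain_mask()] within the image mask.
#' @param roi_name label recorded with each response.
#' @return Tibble of metadata plus `pattern`, `response`, `method = "roi_mean"`.
#' @export
roi_response <- function(images, roi, roi_name = "roi") {
  stopifnot(inherits(images, "beta_image_set"), inherits(roi, "brain_mask"))
  if (!same_grid(images$mask, roi)) stop("ROI grid differs", call. = FALSE)
  keep <- vectorize(roi$inclusion, images$mask) > 0
  if (!any(keep)) stop("ROI is empty within the mask", call. = FALSE)
  resp <- rowMeans(images$data[, keep, drop = FALSE])
  dplyr::bind_cols(images$meta, tibble::tibble(
    pattern = roi_name, response = resp, method = "roi_mean"
  ))
}

#' Calibrate arbitrary-scale responses to rating units
#'
#' Fits a univariate linear model `rating ~ response` on a training table
#' and predicts ratings for a test table, so RMSE-type benchmarks of ROI
#' means (or any score without intrinsic rating units) are computed on a
#' fair scale. The calibration is estimated on the training split only.
#'
#' @param train,test tibbles with `response` and (for `train`) `rating`.
#' @return `test` with a `predicted` column.
#' @export
calibrate_responses <- function(train, test) {
  fit <- stats::lm(rating ~ response, data = train)
  test$predicted <- as.numeric(stats::predict(fit, newdata = test))
  test
}

#' Event-locked pattern response time courses
#'
#' Applies a signature to every volume of a 4-D timeseries and extracts
#' peristimulus segments following each event onset, averaged by condition.
#'
#' @param series 4-D array (x, y, z, time) on the map's grid, or the list
#'   returned by [simulate_timeseries()].
#' @param map a [weight_map()].
#' @param events data frame with `onset` (s) and a condition column
#'   (`rating` by default).
#' @param window peristimulus window length in seconds (truncated with a
#'   warning when it runs past the series).
#' @param tr repetition time in seconds.
#' @param condition name of the condition column.
#' @return Tibble: `condition`, `time` (s after onset), `response` (mean
#'   across events), `n_events`.
#' @export
timeseries_response <- function(series, map, events = NULL, window = 20,
                                tr = 2, condition = "rating") {
  if (is.list(series) && !is.null(series$series)) {
    if (is.null(events)) events <- series$events
    tr <- series$tr
    series <- series$series
  }
  stopifnot(inherits(map, "weight_map"), length(dim(series)) == 4L)
  if (!all(dim(series)[1:3] == map$mask$grid_shape)) {
    stop("series grid does not match map", call. = FALSE)
  }
  nt <- dim(series)[4]
  flat <- matrix(series, ncol = nt)
  inc <- as.vector(map$mask$inclusion)
  pr <- as.numeric(crossprod(flat[inc, , drop = FALSE], map$weights)) +
    map$intercept
  events <- tibble::as_tibble(events)
  n_steps <- floor(window / tr)
  segs <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    start <- floor(events$onset[i] / tr) + 1L
    idx <- start + 0:n_steps
    if (max(idx) > nt) {
      warning("peristimulus window truncated at end of series", call. = FALSE)
      idx <- idx[idx <= nt]
    }
    tibble::tibble(
      event = i, condition = events[[condition]][i],
      time = (idx - start) * tr, response = pr[idx]
    )
  })
  dplyr::summarise(
    dplyr::group_by(segs, .data$condition, .data$time),
    n_events = dplyr::n(), response = mean(.data$response), .groups = "drop"
  )
}

#' Item analysis of trial-level pattern responses
#'
#' Averages trial responses and ratings within item (photo) across
#' subjects, and correlates the item-mean response with the item-mean
#' rating (two-sided t-test on `n_items - 2` degrees of freedom).
#'
#' @param trial_responses tibble with `item`, `subject_id`, `response`, and
#'   `rating` (or supply `ratings` separately with `item` + `rating`).
#' @param ratings optional item-level rating table.
#' @return A list: `items` tibble (item, mean_response, mean_rating,
#'   n_subjects, flagged for items with < 2 subjects), `r`, `statistic`,
#'   `df`, `p_value`.
#' @export
item_analysis <- function(trial_responses, ratings = NULL) {
  tr <- tibble::as_tibble(trial_responses)
  stopifnot(all(c("item", "response") %in% names(tr)))
  if (!is.null(ratings)) {
    ratings <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(ratings), .data$item),
      mean_rating = mean(.data$rating), .groups = "drop"
    )
  }
  items <- dplyr::summarise(
    dplyr::group_by(tr, .data$item),
    mean_response = mean(.data$response),
    mean_rating = if ("rating" %in% names(tr)) mean(.data$rating) else NA_real_,
    n_subjects = if ("subject_id" %in% names(tr)) {
      dplyr::n_distinct(.data$subject_id)
    } else {
      dplyr::n()
    },
    .groups = "drop"
  )
  if (!is.null(ratings)) {
    items <- dplyr::left_join(dplyr::select(items, -"mean_rating"),
      ratings,
      by = "item"
    )
  }
  items$flagged <- items$n_subjects < 2L
  if (nrow(items) < 3L) stop("need at least 3 items", call. = FALSE)
  r <- stats::cor(items$mean_response, items$mean_rating)
  df <- nrow(items) - 2L
  tstat <- r * sqrt(df / (1 - r^2))
  list(
    items = items, r = r, statistic = tstat, df = df,
    p_value = 2 * stats::pt(-abs(tstat), df)
  )
}
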