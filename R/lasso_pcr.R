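#' Fit a LASSO-PCR signature model
#'
#' The whole-brain training pipeline: voxel features are mean-centered,
#' reduced by principal components analysis, the component scores enter an
#' L1-regularized least-squares fit (LASSO), the components with non-zero
#' coefficients are refit by ordinary least squares so their estimates are
#' not shrunken, and the refit coefficients are back-projected through the
#' component loadings to a voxel [weight_map()] plus intercept. Voxel-space
#' predictions `X %*% w + b` equal the component-space predictions exactly
#' (up to numerical tolerance).
#'
#' Features are centered but not variance-scaled before PCA: voxel units are
#' homogeneous, and scaling would reweight low-variance voxels.
#'
#' @param train a [beta_image_set()] (or numeric matrix with `mask`
#'   supplied).
#' @param ratings numeric outcome per observation; defaults to the set's
#'   `rating` metadata.
#' @param n_components components retained by PCA; default and upper bound
#'   `n_obs - 1`. Values above the bound are truncated.
#' @param penalty `"cv"` for an inner 5-fold cross-validated penalty path on
#'   the component scores, or a fixed non-negative numeric lambda (glmnet
#'   scale: `1/(2n) RSS + lambda * L1`).
#' @param seed seed for the inner cross-validation folds.
#' @param mask mask to attach when `train` is a bare matrix.
#' @return A `trained_model` with fields `weight_map`, `n_components`,
#'   `selected` (component indices kept by the LASSO), `loadings`
#'   (diagnostic, selected components only), `lambda`, and training
#'   metadata.
#' @export
fit_lasso_pcr <- function(train, ratings = NULL, n_components = NULL,
                          penalty = "cv", seed = 1L, mask = NULL) {
  if (inherits(train, "beta_image_set")) {
    X <- train$data
    if (is.null(ratings)) ratings <- train$meta$rating
    mask <- train$mask
  } else {
    X <- as.matrix(train)
    if (is.null(mask)) {
      stop("supply `mask` when training from a bare matrix", call. = FALSE)
    }
  }
  y <- as.numeric(ratings)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (length(y) != n) stop("ratings length must match observations", call. = FALSE)
  if (stats::sd(y) == 0) {
    warning("constant outcome; intercept-only model", call. = FALSE)
    return(structure(
      list(
        weight_map = weight_map(numeric(ncol(X)), mask, intercept = y[1],
          provenance = "intercept-only (constant outcome)"),
        n_components = 0L, selected = integer(0),
        loadings = matrix(0, ncol(X), 0), component_coefs = numeric(0),
        component_intercept = y[1], lasso_coefs = numeric(0),
        pca_center = colMeans(X), rotation = matrix(0, ncol(X), 0),
        lambda = NA_real_, algorithm = "lasso_pcr", seed = seed, train_n = n
      ),
      class = "trained_model"
    ))
  }
  k_max <- n - 1L
  k <- if (is.null(n_components)) k_max else min(as.integer(n_components), k_max)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  pca <- stats::prcomp(Xc, center = FALSE, scale. = FALSE, rank. = k)
  keep <- which(pca$sdev[seq_len(ncol(pca$x))] > 1e-10)
  Z <- pca$x[, keep, drop = FALSE]
  V <- pca$rotation[, keep, drop = FALSE]
  # glmnet requires >= 2 predictors; pad single-component fits with a zero
  # column (its coefficient stays 0) and drop it again below
  padded <- ncol(Z) == 1L
  Zg <- if (padded) cbind(Z, 0) else Z
  lam <- select_penalty(Zg, y, penalty, seed)
  fit <- glmnet::glmnet(Zg, y,
    alpha = 1, lambda = lam, standardize = FALSE, intercept = TRUE,
    thresh = 1e-12
  )
  beta <- as.numeric(fit$beta)[seq_len(ncol(Z))]
  selected <- which(abs(beta) > 0)
  if (length(selected) == 0L) {
    warning("all LASSO coefficients shrunk to zero; intercept-only model",
      call. = FALSE
    )
    coefs <- numeric(0)
    b0 <- mean(y)
  } else {
    ols <- stats::lm.fit(cbind(1, Z[, selected, drop = FALSE]), y)
    b0 <- ols$coefficients[1]
    coefs <- ols$coefficients[-1]
    coefs[is.na(coefs)] <- 0
  }
  w <- if (length(selected)) {
    as.numeric(V[, selected, drop = FALSE] %*% coefs)
  } else {
    numeric(ncol(X))
  }
  intercept <- as.numeric(b0 - sum(mu * w))
  structure(
    list(
      weight_map = weight_map(w, mask, intercept = intercept,
        provenance = sprintf(
          "LASSO-PCR: %d obs, %d comps, %d selected, lambda %.4g",
          n, length(keep), length(selected), lam
        )
      ),
      n_components = length(keep),
      selected = selected,
      loadings = V[, selected, drop = FALSE],
      component_coefs = coefs,
      component_intercept = as.numeric(b0),
      lasso_coefs = beta,
      pca_center = mu,
      rotation = V,
      lambda = lam,
      algorithm = "lasso_pcr",
      seed = seed,
      train_n = n
    ),
    class = "trained_model"
  )
}

select_penalty <- function(Z, y, penalty, seed) {
  if (is.numeric(penalty)) return(as.numeric(penalty))
  if (!identical(penalty, "cv")) {
    stop("`penalty` must be \"cv\" or a numeric lambda", call. = FALSE)
  }
  nfolds <- max(3L, min(5L, nrow(Z)))
  with_seed(seed, {
    cv <- glmnet::cv.glmnet(Z, y,
      alpha = 1, nfolds = nfolds, standardize = FALSE, intercept = TRUE
    )
    cv$lambda.min
  })
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model> LASSO-PCR: %d training obs, %d components, %d selected\n",
    x$train_n, x$n_components, length(x$selected)
  ))
  print(x$weight_map)
  invisible(x)
}

#' Predict ratings from a trained signature model
#'
#' @param object a `trained_model`.
#' @param newdata a [beta_image_set()] or observations x voxels matrix.
#' @param ... unused.
#' @return Numeric vector of predicted ratings.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "beta_image_set")) newdata$data else as.matrix(newdata)
  as.numeric(X %*% object$weight_map$weights + object$weight_map$intercept)
}

component_predict <- function(model, X) {
  Xc <- sweep(as.matrix(X), 2L, model$pca_center)
  Z <- Xc %*% model$rotation
  if (length(model$selected)) {
    as.numeric(model$component_intercept +
      Z[, model$selected, drop = FALSE] %*% model$component_coefs)
  } else {
    rep(model$component_intercept, nrow(Z))
  }
}

#' Split subjects into stratified training and test sets
#'
#' Subjects are ranked by their average rating and divided into strata from
#' which test subjects are drawn, so the two groups have closely matched
#' mean ratings; with 30 or more subjects the group means of
#' subject-average ratings are required to differ by less than `tol` rating
#' units (the draw is repeated, bounded, until they do). The split is at
#' subject granularity; training size is `round(fraction * n_subjects)`.
#'
#' @param set a [beta_image_set()].
#' @param fraction fraction of subjects assigned to training.
#' @param seed integer seed.
#' @param tol maximum allowed difference in group mean rating (checked when
#'   `n >= 30`).
#' @param max_retries resampling attempts before erroring.
#' @return List with `train` and `test` [beta_image_set()]s (split tags set).
#' @export
stratified_split <- function(set, fraction = 2 / 3, seed = 1L, tol = 0.1,
                             max_retries = 50L) {
  stopifnot(inherits(set, "beta_image_set"))
  subj <- dplyr::summarise(
    dplyr::group_by(set$meta, .data$subject_id),
    mean_rating = mean(.data$rating), .groups = "drop"
  )
  n <- nrow(subj)
  if (n < 3L) stop("need at least 3 subjects to split", call. = FALSE)
  n_train <- round(fraction * n)
  n_test <- n - n_train
  if (n_train < 1L || n_test < 1L) {
    stop("fraction leaves an empty split", call. = FALSE)
  }
  ord <- order(subj$mean_rating, subj$subject_id)
  sizes <- diff(round(seq(0, n, length.out = n_test + 1)))
  strata <- split(ord, rep(seq_len(n_test), times = sizes))
  ok <- FALSE
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      test_idx <- vapply(strata, function(s) s[sample.int(length(s), 1L)],
        numeric(1)
      )
      test_ids <- subj$subject_id[test_idx]
      mtest <- mean(subj$mean_rating[test_idx])
      mtrain <- mean(subj$mean_rating[-test_idx])
      if (n < 30L || abs(mtest - mtrain) < tol) {
        ok <- TRUE
        break
      }
    }
  })
  if (!ok) {
    stop("could not stratify split within tolerance after max retries",
      call. = FALSE
    )
  }
  is_test <- set$meta$subject_id %in% test_ids
  train <- subset_images(set, !is_test)
  test <- subset_images(set, is_test)
  train$meta$split <- "train"
  test$meta$split <- "test"
  list(train = train, test = test)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the model is fit on all other subjects' images and
#' evaluated on the held-out subject, so predictions never use the
#' predicted subject's data.
#'
#' @param set a [beta_image_set()].
#' @param ratings outcome; defaults to `rating` metadata.
#' @param n_components,penalty,seed passed to [fit_lasso_pcr()].
#' @return A `cv_result` with `predictions` (tibble: subject, fold, rating,
#'   predicted), `by_subject` (per-subject Pearson r and RMSE; r is `NA` and
#'   flagged for single-observation or constant-rating subjects), and pooled
#'   summary fields.
#' @export
loso_cross_validate <- function(set, ratings = NULL, n_components = NULL,
                                penalty = "cv", seed = 1L) {
  stopifnot(inherits(set, "beta_image_set"))
  if (is.null(ratings)) ratings <- set$meta$rating
  subjects <- sort(unique(set$meta$subject_id))
  if (length(subjects) < 3L) stop("need at least 3 subjects", call. = FALSE)
  preds <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    hold <- set$meta$subject_id == s
    model <- fit_lasso_pcr(subset_images(set, !hold), ratings[!hold],
      n_components = n_components, penalty = penalty, seed = seed
    )
    preds[[i]] <- tibble::tibble(
      subject_id = s, fold = i,
      rating = ratings[hold],
      predicted = predict(model, set$data[hold, , drop = FALSE])
    )
  }
  predictions <- dplyr::bind_rows(preds)
  by_subject <- prediction_metrics(
    predictions$predicted, predictions$rating, predictions$subject_id
  )
  structure(
    list(
      predictions = predictions,
      by_subject = by_subject$by_group,
      mean_r = by_subject$mean_r,
      se_r = by_subject$se_r,
      mean_rmse = by_subject$mean_rmse,
      se_rmse = by_subject$se_rmse,
      pooled_r = by_subject$pooled_r,
      pooled_rmse = by_subject$pooled_rmse
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d folds; within-subject r = %.3f +/- %.3f, RMSE = %.3f +/- %.3f\n",
    dplyr::n_distinct(x$predictions$fold), x$mean_r, x$se_r,
    x$mean_rmse, x$se_rmse
  ))
  invisible(x)
}

#' Train and cross-validate a within-subject signature
#'
#' Fits a LASSO-PCR model to a single subject's trial-level images with
#' k-fold cross-validation over trials: every trial is predicted exactly
#' once by a model that did not see it. The final map is refit on all
#' trials. Group-level weight consistency across subjects can then be
#' assessed with a one-sample t-test per voxel ([weight_consistency_map()]).
#'
#' @param trials a [beta_image_set()] holding one subject's trials.
#' @param ratings outcome; defaults to `rating` metadata.
#' @param k_folds folds over trials.
#' @param n_components,penalty,seed passed to [fit_lasso_pcr()].
#' @return A list: `model` (trained on all trials), `cv_r` (cross-validated
#'   trial-level Pearson r; `NA` and flagged for constant ratings),
#'   `predictions` tibble.
#' @export
fit_within_subject <- function(trials, ratings = NULL, k_folds = 5L,
                               n_components = NULL, penalty = "cv",
                               seed = 1L) {
  stopifnot(inherits(trials, "beta_image_set"))
  if (is.null(ratings)) ratings <- trials$meta$rating
  n <- nrow(trials$data)
  if (n < k_folds) stop("need at least k_folds trials", call. = FALSE)
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  pred <- numeric(n)
  for (f in seq_len(k_folds)) {
    hold <- folds == f
    m <- fit_lasso_pcr(subset_images(trials, !hold), ratings[!hold],
      n_components = n_components, penalty = penalty, seed = seed
    )
    pred[hold] <- predict(m, trials$data[hold, , drop = FALSE])
  }
  cv_r <- if (stats::sd(ratings) == 0 || stats::sd(pred) == 0) {
    NA_real_
  } else {
    stats::cor(pred, ratings)
  }
  model <- fit_lasso_pcr(trials, ratings,
    n_components = n_components, penalty = penalty, seed = seed
  )
  list(
    model = model,
    cv_r = cv_r,
    r_defined = !is.na(cv_r),
    predictions = tibble::tibble(
      trial = seq_len(n), fold = folds, rating = ratings, predicted = pred
    )
  )
}

#' Voxelwise one-sample t-test across subject weight maps
#'
#' Tests, at every voxel, whether per-subject signature weights are
#' consistently different from zero across subjects.
#'
#' @param maps list of [weight_map()]s on a shared mask (one per subject).
#' @return Tibble with per-voxel `mean_weight`, `t`, `p`.
#' @export
weight_consistency_map <- function(maps) {
  stopifnot(length(maps) >= 2L)
  W <- do.call(rbind, lapply(maps, function(m) m$weights))
  n <- nrow(W)
  mw <- colMeans(W)
  sw <- apply(W, 2L, stats::sd)
  tt <- ifelse(sw > 0, mw / (sw / sqrt(n)), 0)
  tibble::tibble(
    voxel = seq_len(ncol(W)),
    mean_weight = mw,
    t = tt,
    p = 2 * stats::pt(-abs(tt), df = n - 1)
  )
}

#' Retrain a signature excluding a voxel region
#'
#' Runs the identical LASSO-PCR pipeline on the voxels remaining after
#' removing `exclusion` (e.g., the occipital lobe, to test dependence on
#' visual cortex); the returned map carries zeros in the excluded voxels so
#' it still lives on the original mask.
#'
#' @param set a [beta_image_set()].
#' @param exclusion a [brain_mask()] on the same grid; its `TRUE` voxels are
#'   removed.
#' @param ... passed to [fit_lasso_pcr()].
#' @return A `trained_model` on the full mask with zeroed excluded voxels.
#' @export
retrain_excluding <- function(set, exclusion, ...) {
  stopifnot(inherits(set, "beta_image_set"), inherits(exclusion, "brain_mask"))
  if (!same_grid(set$mask, exclusion)) {
    stop("exclusion mask is not on the image grid", call. = FALSE)
  }
  keep <- !vectorize(exclusion$inclusion, set$mask)
  if (!any(keep)) stop("exclusion removes every voxel", call. = FALSE)
  submask <- brain_mask(
    set$mask$inclusion & !exclusion$inclusion, affine = set$mask$affine
  )
  subset_data <- set$data[, keep, drop = FALSE]
  model <- fit_lasso_pcr(subset_data, set$meta$rating, mask = submask, ...)
  w_full <- numeric(set$mask$n_voxels)
  w_full[keep] <- model$weight_map$weights
  model$weight_map <- weight_map(w_full, set$mask,
    intercept = model$weight_map$intercept,
    provenance = paste0(model$weight_map$provenance, "; voxels excluded")
  )
  model$excluded_voxels <- sum(!keep)
  model
}
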