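make_subject_set <- function(n_subjects, seed = 1) {
  # minimal one-image-per-subject set for split tests
  set.seed(seed)
  mask <- brain_mask(array(TRUE, dim = c(2, 2, 2)))
  beta_image_set(
    matrix(rnorm(n_subjects * 8), n_subjects),
    tibble::tibble(
      subject_id = sprintf("s%03d", seq_len(n_subjects)),
      condition = "m", rating = round(runif(n_subjects, 1, 5), 2)
    ),
    mask
  )
}

test_that("stratified split reproduces the 2/3 design and balances ratings", {
  set182 <- make_subject_set(182)
  sp <- stratified_split(set182, fraction = 2 / 3, seed = 3)
  expect_equal(dplyr::n_distinct(sp$train$meta$subject_id), 121)
  expect_equal(dplyr::n_distinct(sp$test$meta$subject_id), 61)
  expect_length(
    intersect(sp$train$meta$subject_id, sp$test$meta$subject_id), 0
  )
  m_tr <- mean(tapply(sp$train$meta$rating, sp$train$meta$subject_id, mean))
  m_te <- mean(tapply(sp$test$meta$rating, sp$test$meta$subject_id, mean))
  expect_lt(abs(m_tr - m_te), 0.1)

  sp3 <- stratified_split(make_subject_set(3), fraction = 2 / 3, seed = 1)
  expect_equal(dplyr::n_distinct(sp3$train$meta$subject_id), 2)
  expect_equal(dplyr::n_distinct(sp3$test$meta$subject_id), 1)

  spa <- stratified_split(set182, seed = 7)
  spb <- stratified_split(set182, seed = 7)
  expect_identical(spa$test$meta$subject_id, spb$test$meta$subject_id)
  expect_error(stratified_split(make_subject_set(2)), "at least 3")
})

test_that("noiseless single-direction outcomes are fit exactly", {
  set.seed(5)
  mask <- brain_mask(array(TRUE, dim = c(4, 4, 2)))
  dir_v <- rnorm(32)
  scores <- rnorm(20)
  X <- outer(scores, dir_v)
  y <- 2 + 3 * scores
  m <- fit_lasso_pcr(X, y, penalty = 1e-8, mask = mask)
  expect_lt(max(abs(predict(m, X) - y)), 1e-8)
})

test_that("the L1 stage matches a coordinate-descent oracle on its scores", {
  set.seed(6)
  mask <- brain_mask(array(TRUE, dim = c(2, 2, 2)))
  X <- matrix(rnorm(6 * 8), 6, 8)
  y <- rnorm(6)
  lam <- 0.07
  m <- fit_lasso_pcr(X, y, n_components = 3, penalty = lam, mask = mask)
  # recompute the component scores independently and solve by brute force
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  Zpkg <- Xc %*% m$rotation
  # the package's scores are the top-3 principal scores (up to sign)
  expect_lt(max(abs(abs(Xc %*% sv$v[, 1:3]) - abs(Zpkg))), 1e-8)
  o <- oracle_lasso_cd(Zpkg, y, lam)
  expect_lt(max(abs(m$lasso_coefs - o$beta)), 1e-6)
})

test_that("the penalty-free limit equals closed-form PCR", {
  set.seed(7)
  mask <- brain_mask(array(TRUE, dim = c(5, 1, 1)))
  X <- matrix(rnorm(10 * 5), 10, 5)
  y <- rnorm(10)
  k <- 4
  m <- fit_lasso_pcr(X, y, n_components = k, penalty = 1e-12, mask = mask)
  o <- oracle_pcr(X, y, k)
  expect_lt(max(abs(predict(m, X) - o$predict(X))), 1e-6)
  expect_lt(max(abs(m$weight_map$weights - o$weights)), 1e-6)
  expect_lt(abs(m$weight_map$intercept - o$intercept), 1e-6)
})

test_that("voxel-space predictions equal component-space predictions", {
  set.seed(8)
  mask <- brain_mask(array(TRUE, dim = c(4, 4, 3)))
  for (rep in 1:5) {
    X <- matrix(rnorm(15 * 48), 15, 48)
    y <- rnorm(15)
    m <- fit_lasso_pcr(X, y, penalty = 0.05, mask = mask)
    expect_lt(
      max(abs(predict(m, X) - affectsig:::component_predict(m, X))), 1e-6
    )
  }
})

test_that("all-zero selection falls back to an intercept-only model", {
  set.seed(9)
  mask <- brain_mask(array(TRUE, dim = c(3, 3, 2)))
  X <- matrix(rnorm(10 * 18), 10, 18)
  y <- rnorm(10)
  expect_warning(
    m <- fit_lasso_pcr(X, y, penalty = 1e6, mask = mask),
    "intercept-only"
  )
  expect_true(all(m$weight_map$weights == 0))
  expect_equal(predict(m, X), rep(mean(y), 10))
})

test_that("leave-one-subject-out folds are subject-disjoint and leak-free", {
  sim <- quick_sim(n_subjects = 8, seed = 41, grid_shape = c(6, 6, 4),
    n_true_regions = 2, region_size = 15)
  cv <- loso_cross_validate(sim$images, penalty = 0.2, seed = 1)
  subjects <- unique(sim$images$meta$subject_id)
  expect_equal(dplyr::n_distinct(cv$predictions$fold), length(subjects))
  expect_equal(
    sort(unique(cv$predictions$subject_id)), sort(subjects)
  )
  each <- table(unique(cv$predictions[c("subject_id", "fold")])$subject_id)
  expect_true(all(each == 1))

  # a subject's own ratings never reach the model that predicts them:
  # perturbing them leaves that subject's fold predictions unchanged
  perturbed_r <- sim$images$meta$rating
  rows <- sim$images$meta$subject_id == subjects[1]
  perturbed_r[rows] <- 6 - perturbed_r[rows]
  cv2 <- loso_cross_validate(sim$images, ratings = perturbed_r,
    penalty = 0.2, seed = 1)
  own <- cv$predictions$subject_id == subjects[1]
  expect_equal(cv2$predictions$predicted[own], cv$predictions$predicted[own])
  # while folds that train on this subject do change
  expect_false(isTRUE(all.equal(
    cv2$predictions$predicted[!own], cv$predictions$predicted[!own]
  )))
})

test_that("high-SNR simulations give strong held-out subject correlations", {
  sim <- quick_sim(n_subjects = 15, seed = 42, effect_size = 1, noise_sd = 1,
    level_presence = rep(1, 5))
  cv <- loso_cross_validate(sim$images, penalty = "cv", seed = 2)
  expect_gt(cv$mean_r, 0.8)
})

test_that("LOSO results do not depend on subject ordering", {
  sim <- quick_sim(n_subjects = 6, seed = 43, grid_shape = c(6, 6, 4),
    n_true_regions = 2, region_size = 15)
  cv1 <- loso_cross_validate(sim$images, penalty = 0.2, seed = 1)
  perm <- rev(seq_len(nrow(sim$images$data)))
  shuffled <- subset_images(sim$images, perm)
  cv2 <- loso_cross_validate(shuffled, penalty = 0.2, seed = 1)
  a <- dplyr::arrange(cv1$by_subject, group)
  b <- dplyr::arrange(cv2$by_subject, group)
  expect_equal(a$r, b$r, tolerance = 1e-8)
})

test_that("within-subject models predict each trial exactly once", {
  cfg <- sim_config(grid_shape = c(6, 6, 4), n_subjects = 1, effect_size = 1.2,
    noise_sd = 1, n_true_regions = 2, region_size = 15, seed = 51)
  truth <- make_ground_truth_pattern(cfg)
  trials <- simulate_trial_dataset(cfg, truth, n_trials = 30)
  fw <- fit_within_subject(trials$images, k_folds = 5, penalty = 0.3, seed = 1)
  expect_equal(nrow(fw$predictions), 30)
  expect_equal(sort(unique(fw$predictions$trial)), 1:30)
  expect_true(all(table(fw$predictions$fold) == 6))
  # high-SNR single subject decodes its own trials well
  expect_gt(fw$cv_r, 0.7)
})

test_that("zero-signal within-subject correlations show no optimistic bias", {
  # pooled k-fold prediction correlations carry a small conservative
  # (negative) bias under the null: intercept-only fold models predict the
  # training-fold mean rating, which anti-correlates with the held-out
  # fold's ratings. The check is therefore one-sided: the null must never
  # look like positive decoding signal.
  rs <- vapply(1:100, function(i) {
    cfg <- sim_config(grid_shape = c(5, 5, 3), n_subjects = 1, effect_size = 0,
      noise_sd = 1, n_true_regions = 0, smooth_fwhm = 0, seed = 100 + i)
    trials <- simulate_trial_dataset(cfg, n_trials = 20)
    fit_within_subject(trials$images, k_folds = 5, penalty = 0.3, seed = 1)$cv_r
  }, numeric(1))
  m <- mean(rs, na.rm = TRUE)
  expect_lt(m, 0.05)
  expect_gt(m, -0.15)
})

test_that("constant ratings flag an undefined within-subject correlation", {
  set.seed(52)
  mask <- brain_mask(array(TRUE, dim = c(4, 4, 2)))
  trials <- beta_image_set(
    matrix(rnorm(10 * 32), 10),
    tibble::tibble(subject_id = "s1", condition = "3", trial = 1:10, rating = 3),
    mask,
    rating_granularity = "trial"
  )
  fw <- suppressWarnings(fit_within_subject(trials, k_folds = 5, penalty = 0.3))
  expect_true(is.na(fw$cv_r))
  expect_false(fw$r_defined)
})

test_that("retraining with exclusions zeroes excluded voxels", {
  cfg <- sim_config(grid_shape = c(8, 8, 6), n_subjects = 8, effect_size = 0.8,
    subject_sd = 0, noise_sd = 0, n_true_regions = 2, region_size = 20,
    level_presence = rep(1, 5), seed = 61)
  truth <- make_ground_truth_pattern(cfg)
  sim <- simulate_dataset(cfg, truth)

  # excluding only zero-signal voxels leaves noiseless predictions unchanged
  excl_null <- brain_mask(devectorize(
    as.numeric(truth$weights == 0), truth$mask
  ) > 0)
  m_full <- fit_lasso_pcr(sim$images, penalty = 1e-6)
  m_red <- retrain_excluding(sim$images, excl_null, penalty = 1e-6)
  expect_true(all(m_red$weight_map$weights[truth$weights == 0] == 0))
  expect_equal(
    predict(m_red, sim$images), predict(m_full, sim$images),
    tolerance = 1e-6
  )

  # excluding the signal region destroys held-out decoding
  cfg_n <- sim_config(grid_shape = c(8, 8, 6), n_subjects = 14,
    effect_size = 0.8, noise_sd = 1, n_true_regions = 2, region_size = 20,
    level_presence = rep(1, 5), seed = 62)
  sim_n <- simulate_dataset(cfg_n, truth)
  sp <- stratified_split(sim_n$images, seed = 1)
  excl_sig <- brain_mask(devectorize(
    as.numeric(truth$weights != 0), truth$mask
  ) > 0)
  m_les <- retrain_excluding(sp$train, excl_sig, penalty = "cv")
  pr <- pattern_response(sp$test, m_les$weight_map)
  pair <- dplyr::inner_join(
    pr[pr$rating == 5, c("subject_id", "response")],
    pr[pr$rating == 1, c("subject_id", "response")],
    by = "subject_id", suffix = c("_h", "_l")
  )
  fc <- forced_choice(pair$response_h, pair$response_l)
  expect_lt(fc$accuracy, 0.9)

  off <- brain_mask(array(TRUE, dim = c(3, 3, 3)))
  expect_error(retrain_excluding(sim$images, off), "grid")
  all_vox <- brain_mask(array(TRUE, dim = c(8, 8, 6)))
  expect_error(retrain_excluding(sim$images, all_vox), "every voxel")
})
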