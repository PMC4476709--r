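# Build a thresholded map with n_regions disjoint 2x2x1 square regions on a
# flat grid, plus the matching region set.
make_region_fixture <- function(n_regions, weights_per_region = NULL,
                                seed = 1) {
  set.seed(seed)
  shp <- c(3 * n_regions, 2, 1)
  mask <- brain_mask(array(TRUE, dim = shp))
  g <- array(FALSE, dim = shp)
  w <- array(0, dim = shp)
  for (r in seq_len(n_regions)) {
    cols <- (3 * (r - 1) + 1):(3 * (r - 1) + 2)
    g[cols, 1:2, 1] <- TRUE
    # default weights keep a clearly non-zero regional sum so that a shared
    # amplitude actually expresses in the local dot product
    w[cols, 1:2, 1] <- if (is.null(weights_per_region)) {
      rnorm(4, mean = 2, sd = 0.5)
    } else {
      weights_per_region[[r]]
    }
  }
  tmap <- structure(
    list(weights = vectorize(w, mask), surviving = vectorize(g, mask) > 0,
      rule = list(type = "p", alpha = .001), k = 1, connectivity = 6,
      mask = mask, intercept = 0.5, n_surviving = sum(g)),
    class = "thresholded_map"
  )
  list(tmap = tmap, regions = extract_regions(tmap, connectivity = 6),
    mask = mask)
}

make_trial_set <- function(fix, n_subjects, n_trials, group_of_region,
                           noise = 0.1, seed = 2) {
  # trials where regions in the same group share a latent amplitude
  set.seed(seed)
  n_groups <- max(group_of_region)
  rows <- list()
  meta <- list()
  for (s in seq_len(n_subjects)) {
    for (t in seq_len(n_trials)) {
      x <- numeric(fix$mask$n_voxels)
      amps <- rnorm(n_groups)
      for (r in seq_len(nrow(fix$regions$regions))) {
        vox <- which(fix$regions$assignment == r)
        x[vox] <- amps[group_of_region[r]] + rnorm(length(vox), 0, noise)
      }
      rows[[length(rows) + 1]] <- x
      meta[[length(meta) + 1]] <- tibble::tibble(
        subject_id = sprintf("s%02d", s), condition = "t", trial = t,
        rating = sample(1:5, 1)
      )
    }
  }
  beta_image_set(do.call(rbind, rows), dplyr::bind_rows(meta), fix$mask,
    rating_granularity = "trial")
}

test_that("regional responses partition the whole-map dot product", {
  fix <- make_region_fixture(3, seed = 3)
  trials <- make_trial_set(fix, n_subjects = 2, n_trials = 5,
    group_of_region = 1:3)
  rrm <- region_trial_responses(trials, fix$regions)
  whole <- pattern_response(trials, as_weight_map(fix$tmap))
  expect_equal(
    rowSums(rrm$responses), whole$response - fix$tmap$intercept,
    tolerance = 1e-10
  )

  # zero-weight region gives an all-zero column
  fix0 <- make_region_fixture(2,
    weights_per_region = list(rep(0, 4), c(1, 2, -1, 0.5)))
  tr0 <- make_trial_set(fix0, 1, 4, group_of_region = 1:2)
  rr0 <- region_trial_responses(tr0, fix0$regions)
  zero_col <- which(vapply(seq_len(2), function(j) {
    all(rr0$responses[, j] == 0)
  }, logical(1)))
  expect_length(zero_col, 1)

  # two-region hand example
  fix2 <- make_region_fixture(2,
    weights_per_region = list(c(1, 1, 1, 1), c(2, 0, 0, 0)))
  x <- numeric(fix2$mask$n_voxels)
  x[which(fix2$regions$assignment == 1)] <- c(1, 2, 3, 4)
  x[which(fix2$regions$assignment == 2)] <- c(5, 0, 0, 0)
  one <- beta_image_set(matrix(x, 1), tibble::tibble(
    subject_id = "s", condition = "t", rating = 1
  ), fix2$mask, rating_granularity = "trial")
  rr2 <- region_trial_responses(one, fix2$regions)
  w1 <- fix2$tmap$weights[which(fix2$regions$assignment == 1)]
  w2 <- fix2$tmap$weights[which(fix2$regions$assignment == 2)]
  expect_equal(sort(as.numeric(rr2$responses)), sort(c(
    sum(w1 * c(1, 2, 3, 4)), sum(w2 * c(5, 0, 0, 0))
  )))
})

test_that("rank normalization ranks within subject and is monotone-invariant", {
  fix <- make_region_fixture(2, seed = 4)
  resp <- rbind(
    c(0.3, 1), c(0.1, 2), c(0.2, 3), # subject A
    c(5, -1), c(7, -2) # subject B
  )
  rrm <- structure(
    list(responses = resp, subject_id = c("a", "a", "a", "b", "b"),
      trial_meta = NULL, normalization = "raw"),
    class = "region_response_matrix"
  )
  rn <- rank_normalize(rrm)
  expect_equal(rn$normalization, "rank")
  # ranks (3,1,2) for subject A's first region, then z-scored
  zr <- (c(3, 1, 2) - 2) / sd(c(3, 1, 2))
  expect_equal(rn$responses[1:3, 1], zr)

  # monotone transform changes nothing
  rrm_t <- rrm
  rrm_t$responses <- exp(rrm$responses / 2)
  expect_equal(rank_normalize(rrm_t)$responses, rn$responses)

  # ties share average ranks
  rrm_tie <- rrm
  rrm_tie$responses[1:3, 1] <- c(0.1, 0.1, 0.9)
  rt <- rank_normalize(rrm_tie)
  expect_equal(rt$responses[1, 1], rt$responses[2, 1])

  rrm_one <- structure(
    list(responses = resp[1:1, , drop = FALSE], subject_id = "a",
      trial_meta = NULL, normalization = "raw"),
    class = "region_response_matrix"
  )
  expect_error(rank_normalize(rrm_one), "at least 2 trials")
})

test_that("Ward clustering matches the naive agglomerative oracle", {
  set.seed(5)
  for (i in 1:5) {
    X <- matrix(rnorm(12 * sample(4:8, 1)), nrow = 12)
    rrm <- structure(
      list(responses = X, subject_id = rep("a", 12), trial_meta = NULL,
        normalization = "raw"),
      class = "region_response_matrix"
    )
    sol <- cluster_regions(rrm, cut_fraction = 0.5)
    ow <- oracle_ward(t(X))
    expect_equal(sort(sol$tree$height), sort(ow$heights), tolerance = 1e-8)
    cut_oracle <- oracle_ward_cut(t(X), 0.5 * max(ow$heights))
    expect_equal(adjusted_rand(sol$assignment, cut_oracle), 1)
  }
})

test_that("merge heights are nondecreasing and order does not matter", {
  set.seed(6)
  X <- matrix(rnorm(20 * 6), 20, 6)
  rrm <- structure(
    list(responses = X, subject_id = rep("a", 20), trial_meta = NULL,
      normalization = "raw"),
    class = "region_response_matrix"
  )
  sol <- cluster_regions(rrm)
  expect_true(all(diff(sol$tree$height) >= -1e-12))
  perm <- c(4, 2, 6, 1, 3, 5)
  rrm2 <- rrm
  rrm2$responses <- X[, perm]
  sol2 <- cluster_regions(rrm2)
  # same partition after undoing the permutation of region columns
  expect_equal(adjusted_rand(sol$assignment[perm], sol2$assignment), 1)
})

test_that("well-separated groups and simulated subnetworks are recovered", {
  # two separated column groups form two clusters over a wide cut range
  set.seed(7)
  g1 <- matrix(rnorm(30 * 3, mean = 0), 30)
  g2 <- matrix(rnorm(30 * 3, mean = 8), 30)
  rrm <- structure(
    list(responses = cbind(g1, g2), subject_id = rep("a", 30),
      trial_meta = NULL, normalization = "raw"),
    class = "region_response_matrix"
  )
  for (f in c(0.3, 0.5, 0.7)) {
    expect_equal(cluster_regions(rrm, cut_fraction = f)$n_clusters, 2)
  }

  # three co-expression subnetworks over six regions, via the full path
  fix <- make_region_fixture(6, seed = 8)
  groups <- c(1, 1, 2, 2, 3, 3)
  trials <- make_trial_set(fix, n_subjects = 8, n_trials = 20,
    group_of_region = groups, noise = 0.2)
  rrm_full <- rank_normalize(region_trial_responses(trials, fix$regions))
  sol <- cluster_regions(rrm_full, cut_fraction = 0.31)
  expect_gt(adjusted_rand(sol$assignment, groups), 0.9)
})

test_that("virtual lesions split responses additively", {
  fix <- make_region_fixture(4, seed = 9)
  groups <- c(1, 1, 2, 2)
  trials <- make_trial_set(fix, 3, 6, group_of_region = groups)
  rrm <- rank_normalize(region_trial_responses(trials, fix$regions))
  sol <- cluster_regions(rrm, cut_fraction = 0.31)
  full <- pattern_response(trials, as_weight_map(fix$tmap))$response
  for (k in seq_len(sol$n_clusters)) {
    rem <- pattern_response(trials,
      virtual_lesion(fix$tmap, fix$regions, sol, k, "remove"))$response
    only <- pattern_response(trials,
      virtual_lesion(fix$tmap, fix$regions, sol, k, "only"))$response
    expect_lt(max(abs(rem + only - full)), 1e-10)
  }
  expect_error(virtual_lesion(fix$tmap, fix$regions, sol, 99), "unknown")
})

test_that("lesioning a zero-weight cluster changes nothing", {
  fix <- make_region_fixture(2,
    weights_per_region = list(rep(0, 4), c(1, -1, 2, 0.5)), seed = 10)
  trials <- make_trial_set(fix, 3, 6, group_of_region = 1:2)
  rrm <- region_trial_responses(trials, fix$regions)
  sol <- structure(
    list(tree = NULL, cut_fraction = 0.31, cut_height = 0,
      assignment = fix$regions$regions$sign * 0 + seq_len(2), n_clusters = 2,
      normalization = "raw"),
    class = "cluster_solution"
  )
  zero_cluster <- which(vapply(1:2, function(k) {
    all(fix$tmap$weights[affectsig:::cluster_voxels(fix$regions, sol, k)] == 0)
  }, logical(1)))
  full <- pattern_response(trials, as_weight_map(fix$tmap))$response
  lesioned <- pattern_response(trials,
    virtual_lesion(fix$tmap, fix$regions, sol, zero_cluster, "remove"))$response
  expect_equal(lesioned, full, tolerance = 1e-12)
})

test_that("lesioning the sole signal cluster drops accuracy to chance", {
  cfg <- sim_config(grid_shape = c(8, 8, 6), n_subjects = 16,
    effect_size = 0.9, noise_sd = 0.8, n_true_regions = 1, region_size = 25,
    level_presence = rep(1, 5), seed = 11)
  truth <- make_ground_truth_pattern(cfg)
  sim <- simulate_dataset(cfg, truth)
  sp <- stratified_split(sim$images, seed = 1)
  model <- fit_lasso_pcr(sp$train, penalty = "cv", seed = 1)
  boot <- bootstrap_weights(sp$train, B = 30, seed = 1)
  tmap <- threshold_map(boot, model$weight_map, rule = "p:0.001", k = 5)
  expect_gt(tmap$n_surviving, 0)
  regions <- extract_regions(tmap)
  sol <- structure(
    list(tree = NULL, cut_fraction = 0.31, cut_height = 0,
      assignment = rep(1L, nrow(regions$regions)), n_clusters = 1,
      normalization = "raw"),
    class = "cluster_solution"
  )
  eval_fc <- function(map) {
    pr <- pattern_response(sp$test, map)
    pair <- dplyr::inner_join(
      pr[pr$rating == 5, c("subject_id", "response")],
      pr[pr$rating == 1, c("subject_id", "response")],
      by = "subject_id", suffix = c("_h", "_l")
    )
    forced_choice(pair$response_h, pair$response_l)$accuracy
  }
  expect_gt(eval_fc(as_weight_map(tmap)), 0.85)
  lesion_acc <- eval_fc(virtual_lesion(tmap, regions, sol, 1, "remove"))
  expect_lt(lesion_acc, 0.8)
})
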