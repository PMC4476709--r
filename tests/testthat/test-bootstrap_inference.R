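fake_boot_result <- function(p, mask, z = NULL) {
  # hand-built bootstrap summary for thresholding tests
  structure(
    list(
      voxel_stats = tibble::tibble(
        voxel = seq_along(p), mean = 0, sd = 1,
        z = if (is.null(z)) stats::qnorm(p / 2) else z, p = p,
        degenerate = FALSE
      ),
      B = 1000L, unit = "subject", model = NULL, mask = mask, samples = NULL
    ),
    class = "bootstrap_result"
  )
}

test_that("bootstrap z equals mean/SD of the stored resample matrix", {
  sim <- quick_sim(n_subjects = 6, seed = 71, grid_shape = c(5, 5, 3),
    n_true_regions = 1, region_size = 12)
  boot <- bootstrap_weights(sim$images, B = 25, seed = 3, penalty = 0.3,
    keep_samples = TRUE)
  mw <- colMeans(boot$samples)
  sdw <- apply(boot$samples, 2, stats::sd)
  ok <- sdw > 0
  expect_lt(max(abs(boot$voxel_stats$z[ok] - mw[ok] / sdw[ok])), 1e-10)
  expect_equal(boot$B, 25)
  expect_error(bootstrap_weights(sim$images, B = 1), "at least 2")
})

test_that("clone-subject resamples give the degenerate near-zero-p sentinel", {
  mask <- brain_mask(array(TRUE, dim = c(4, 4, 2)))
  set.seed(72)
  dir_v <- rnorm(32)
  scores <- rep(c(-1, 0, 1), 3)
  X <- outer(scores, dir_v)
  meta <- tibble::tibble(
    subject_id = rep(c("a", "b", "c"), each = 3),
    condition = rep(c("1", "2", "3"), 3),
    rating = rep(1:3, 3)
  )
  set <- beta_image_set(X, meta, mask)
  # all subjects identical: every resample refits the same deterministic model
  boot <- bootstrap_weights(set, B = 10, seed = 1, penalty = 1e-8)
  nz <- abs(boot$voxel_stats$mean) > 1e-8
  expect_true(any(nz))
  expect_true(all(boot$voxel_stats$degenerate[nz]))
  expect_true(all(boot$voxel_stats$p[nz] == 1 / 11))
  expect_true(all(boot$voxel_stats$p[!nz] == 1))
  expect_true(all(boot$voxel_stats$z[!nz] == 0))
})

test_that("null data give z values centered near zero", {
  sim <- quick_sim(n_subjects = 6, seed = 73, effect_size = 0, noise_sd = 1,
    n_true_regions = 0, grid_shape = c(5, 5, 3), smooth_fwhm = 0)
  boot <- bootstrap_weights(sim$images, B = 40, seed = 2, penalty = 0.3)
  expect_lt(abs(mean(boot$voxel_stats$z)), 0.2)
})

test_that("subject-level resampling keeps subject blocks intact", {
  ids <- rep(c("a", "b", "c", "d"), times = c(3, 2, 4, 1))
  set.seed(5)
  for (i in 1:25) {
    rows <- affectsig:::resample_rows(ids, "subject")
    drawn <- ids[rows]
    # each drawn subject appears as complete copies of its block
    counts <- table(drawn) / table(ids)[names(table(drawn))]
    expect_true(all(counts == round(counts)))
    expect_equal(length(rows) >= 4, TRUE)
  }
  rows_r <- affectsig:::resample_rows(ids, "row")
  expect_length(rows_r, length(ids))
})

test_that("thresholding applies the p rule, BH-FDR, and the extent rule", {
  mask10 <- brain_mask(array(TRUE, dim = c(10, 1, 1)))
  wm <- weight_map(rep(1, 10), mask10)

  # all p = 1 leaves nothing
  empty <- threshold_map(fake_boot_result(rep(1, 10), mask10), wm,
    rule = "p:0.001", k = 1)
  expect_equal(empty$n_surviving, 0)

  # BH step-up keeps exactly the 3 smallest on the canonical vector
  p <- c(.001, .004, .012, .03, .2, .5, .7, .8, .9, .95)
  tm <- threshold_map(fake_boot_result(p, mask10), wm, rule = "fdr:0.05", k = 1)
  expect_identical(which(tm$surviving), 1:3)
  expect_identical(tm$surviving, oracle_bh(p, 0.05))

  # extent rule: a 12-voxel blob survives k=10, a 7-voxel blob does not
  mask3d <- brain_mask(array(TRUE, dim = c(10, 5, 2)))
  grid <- array(1, dim = c(10, 5, 2))
  blob1 <- expand.grid(i = 1:3, j = 1:2, k = 1:2) # 12 voxels
  blob2 <- expand.grid(i = 7:10, j = 4:5, k = 1)[1:7, ] # 7 voxels
  pg <- array(1, dim = c(10, 5, 2))
  for (r in seq_len(nrow(blob1))) pg[blob1$i[r], blob1$j[r], blob1$k[r]] <- 1e-5
  for (r in seq_len(nrow(blob2))) pg[blob2$i[r], blob2$j[r], blob2$k[r]] <- 1e-5
  wm3 <- weight_map(rep(1, 100), mask3d)
  tm3 <- threshold_map(fake_boot_result(vectorize(pg, mask3d), mask3d), wm3,
    rule = "p:0.001", k = 10)
  expect_equal(tm3$n_surviving, 12)
  surv <- devectorize(as.numeric(tm3$surviving), mask3d)
  expect_true(all(surv[1:3, 1:2, 1:2] == 1))

  expect_error(
    threshold_map(fake_boot_result(p, mask10), wm, rule = "bonferroni:0.05"),
    "rule"
  )
})

test_that("BH-FDR survivors match the step-up definition on random vectors", {
  mask <- function(n) brain_mask(array(TRUE, dim = c(n, 1, 1)))
  set.seed(74)
  for (i in 1:20) {
    n <- sample(5:100, 1)
    p <- runif(n)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    m <- mask(n)
    tm <- threshold_map(fake_boot_result(p, m), weight_map(rep(1, n), m),
      rule = sprintf("fdr:%f", q), k = 1)
    expect_identical(tm$surviving, oracle_bh(p, q))
  }
})

test_that("stricter thresholds never enlarge the surviving set", {
  set.seed(75)
  m <- brain_mask(array(TRUE, dim = c(6, 6, 4)))
  p <- runif(144)^2
  wm <- weight_map(rnorm(144), m)
  fb <- fake_boot_result(p, m)
  sizes <- vapply(c(0.05, 0.01, 0.005, 0.001), function(a) {
    threshold_map(fb, wm, rule = sprintf("p:%f", a), k = 1)$n_surviving
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("connected components follow the declared connectivity", {
  g <- array(FALSE, dim = c(3, 3, 1))
  g[1, 1, 1] <- TRUE
  g[2, 2, 1] <- TRUE # diagonal neighbour
  g[3, 3, 1] <- TRUE
  l26 <- label_components(g, 26)
  l6 <- label_components(g, 6)
  expect_equal(max(l26), 1)
  expect_equal(max(l6), 3)
})

test_that("regions are extracted in a stable size-then-position order", {
  m <- brain_mask(array(TRUE, dim = c(10, 4, 1)))
  # blob A: 6 voxels (3 x 2 corner); blob B: 2 voxels far along the grid
  g <- array(FALSE, dim = c(10, 4, 1))
  g[1:3, 1:2, 1] <- TRUE
  g[8:9, 4, 1] <- TRUE
  surv <- vectorize(g, m) > 0
  w <- numeric(40)
  w[surv] <- ifelse(seq_len(40)[surv] < 30, 1, -1)
  tmap <- structure(
    list(weights = w, surviving = surv, rule = list(type = "p", alpha = .001),
      k = 1, connectivity = 26, mask = m, intercept = 0,
      n_surviving = sum(surv)),
    class = "thresholded_map"
  )
  rs <- extract_regions(tmap)
  expect_equal(nrow(rs$regions), 2)
  expect_equal(rs$regions$size, c(6, 2))
  expect_equal(rs$regions$sign, c(1, -1))
  rs2 <- extract_regions(tmap)
  expect_identical(rs$assignment, rs2$assignment)

  none <- structure(
    list(weights = numeric(40), surviving = rep(FALSE, 40),
      rule = list(type = "p", alpha = .001), k = 1, connectivity = 26,
      mask = m, intercept = 0, n_surviving = 0),
    class = "thresholded_map"
  )
  expect_equal(nrow(extract_regions(none)$regions), 0)
})
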