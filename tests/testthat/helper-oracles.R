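# Independent reference implementations used to cross-check the package's
# core numerics. These deliberately share no code with the implementation.

# LASSO by plain cyclic coordinate descent on the objective
#   (1/(2n)) * ||y - b0 - X b||^2 + lambda * ||b||_1
oracle_lasso_cd <- function(X, y, lambda, tol = 1e-12, max_iter = 10000L) {
  n <- nrow(X)
  p <- ncol(X)
  b <- numeric(p)
  b0 <- mean(y)
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (it in seq_len(max_iter)) {
    b_old <- c(b0, b)
    r <- y - b0 - X %*% b
    for (j in seq_len(p)) {
      r <- r + X[, j] * b[j]
      rho <- sum(X[, j] * r) / n
      denom <- sum(X[, j]^2) / n
      b[j] <- if (denom > 0) soft(rho, lambda) / denom else 0
      r <- r - X[, j] * b[j]
    }
    b0 <- b0 + mean(r)
    r <- y - b0 - X %*% b
    if (max(abs(c(b0, b) - b_old)) < tol) break
  }
  list(intercept = b0, beta = b)
}

# Principal components regression by the normal equations: project centered
# X onto its top-k right singular vectors and solve OLS in score space.
oracle_pcr <- function(X, y, k) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  V <- sv$v[, seq_len(k), drop = FALSE]
  Z <- Xc %*% V
  A <- cbind(1, Z)
  coefs <- solve(t(A) %*% A, t(A) %*% y)
  w <- V %*% coefs[-1]
  list(
    weights = as.numeric(w),
    intercept = as.numeric(coefs[1] - sum(mu * w)),
    predict = function(Xn) as.numeric(Xn %*% w + coefs[1] - sum(mu * w))
  )
}

# Benjamini-Hochberg step-up from the definition: reject H_(1..k*) where
# k* = max { i : p_(i) <= i q / m }.
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= seq_len(m) * q / m)
  keep <- logical(m)
  if (length(below)) keep[ord[seq_len(max(below))]] <- TRUE
  keep
}

# Naive O(n^3) Ward agglomeration from the merge-cost definition
#   delta(A, B) = |A||B|/(|A|+|B|) * ||centroid(A) - centroid(B)||^2
# with merge heights sqrt(2 * delta), matching the Euclidean/ward convention.
oracle_ward <- function(X) {
  n <- nrow(X)
  clusters <- lapply(seq_len(n), identity)
  centroids <- X
  sizes <- rep(1, n)
  active <- rep(TRUE, n + n - 1)
  centroids <- rbind(centroids, matrix(NA, n - 1, ncol(X)))
  sizes <- c(sizes, rep(NA, n - 1))
  members <- c(lapply(seq_len(n), identity), vector("list", n - 1))
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  ids <- seq_len(n)
  for (step in seq_len(n - 1)) {
    best <- c(Inf, NA, NA)
    act <- which(active[seq_len(n + step - 1)])
    for (a in seq_along(act)) {
      for (b in seq_len(a - 1L)) {
        i <- act[a]
        j <- act[b]
        d2 <- sum((centroids[i, ] - centroids[j, ])^2)
        delta <- sizes[i] * sizes[j] / (sizes[i] + sizes[j]) * d2
        if (delta < best[1]) best <- c(delta, j, i)
      }
    }
    i <- best[2]
    j <- best[3]
    new <- n + step
    active[c(i, j)] <- FALSE
    active[new] <- TRUE
    members[[new]] <- c(members[[i]], members[[j]])
    sizes[new] <- sizes[i] + sizes[j]
    centroids[new, ] <- (sizes[i] * centroids[i, ] + sizes[j] * centroids[j, ]) /
      sizes[new]
    merges[step, ] <- c(i, j)
    heights[step] <- sqrt(2 * best[1])
  }
  list(heights = heights, members = members[(n + 1):(2 * n - 1)])
}

# cutree-style assignment from the oracle tree at a height h: clusters are
# the maximal merges with height <= h
oracle_ward_cut <- function(X, h) {
  n <- nrow(X)
  ow <- oracle_ward(X)
  assign <- seq_len(n)
  for (step in seq_len(n - 1)) {
    if (ow$heights[step] <= h) {
      mem <- ow$members[[step]]
      assign[mem] <- min(assign[mem])
    }
  }
  as.integer(factor(assign))
}

# Adjusted Rand index between two partitions
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Independent brute-force single-interval classifier: scans every midpoint
# threshold, recomputes rates and signal-detection bias directly.
oracle_single_interval <- function(responses, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  s <- sort(unique(responses))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
    s[length(s)] + 1)
  clamp <- function(r, n) min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  rows <- t(vapply(cand, function(t) {
    pred <- responses > t
    tpr <- sum(pred & labels) / n_pos
    fpr <- sum(pred & !labels) / n_neg
    bias <- -(qnorm(clamp(tpr, n_pos)) + qnorm(clamp(fpr, n_neg))) / 2
    c(t = t, bias = abs(bias), b = (tpr + 1 - fpr) / 2)
  }, numeric(3)))
  rows <- rows[order(rows[, "bias"], -rows[, "b"], rows[, "t"]), , drop = FALSE]
  list(threshold = rows[1, "t"], balanced_accuracy = rows[1, "b"])
}

# Small simulated dataset shared across tests
quick_sim <- function(n_subjects = 12, seed = 11, effect_size = 0.6,
                      noise_sd = 1, modality = "emotion",
                      grid_shape = c(10, 10, 8), n_true_regions = 3,
                      region_size = 30, ...) {
  cfg <- sim_config(
    grid_shape = grid_shape, n_subjects = n_subjects,
    effect_size = effect_size, noise_sd = noise_sd,
    n_true_regions = n_true_regions, region_size = region_size,
    modality = modality, seed = seed, ...
  )
  c(simulate_dataset(cfg), list(config = cfg))
}
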