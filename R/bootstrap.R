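#' Bootstrap distribution of signature voxel weights
#'
#' Resamples the training data with replacement `B` times, refits the
#' LASSO-PCR pipeline on each resample, and summarizes the per-voxel weight
#' distribution as `z = mean / SD` with a two-tailed p-value from the
#' normal reference. The default resampling unit is the subject, which
#' keeps each subject's within-subject rows intact in every resample; pure
#' row resampling is available. Each resample is refit with the penalty
#' fixed from the full-data fit (deterministic and cheap); pass
#' `penalty = "cv"` to re-select the penalty inside every resample.
#'
#' Degenerate voxels with zero bootstrap SD get `z = 0, p = 1` when the
#' mean is also zero; a zero-SD voxel with non-zero mean is flagged and
#' assigned the near-zero sentinel `p = 1/(B + 1)`.
#'
#' @param train a [beta_image_set()].
#' @param ratings outcome; defaults to `rating` metadata.
#' @param B number of bootstrap resamples (>= 2).
#' @param unit `"subject"` or `"row"`.
#' @param seed integer seed.
#' @param n_components passed to [fit_lasso_pcr()].
#' @param penalty `NULL` (fix the full-fit penalty), a numeric lambda, or
#'   `"cv"`.
#' @param keep_samples retain the B x voxels resample weight matrix.
#' @return A `bootstrap_result`: tibble `voxel_stats` (mean, sd, z, p,
#'   degenerate), `B`, `unit`, the full-data `model`, and optionally
#'   `samples`.
#' @export
bootstrap_weights <- function(train, ratings = NULL, B = 5000L,
                              unit = c("subject", "row"), seed = 1L,
                              n_components = NULL, penalty = NULL,
                              keep_samples = FALSE) {
  unit <- match.arg(unit)
  stopifnot(inherits(train, "beta_image_set"))
  if (B < 2L) stop("B must be at least 2", call. = FALSE)
  if (is.null(ratings)) ratings <- train$meta$rating
  full <- fit_lasso_pcr(train, ratings,
    n_components = n_components,
    penalty = if (is.null(penalty) || identical(penalty, "cv")) "cv" else penalty,
    seed = seed
  )
  lam_fixed <- if (identical(penalty, "cv")) NULL else full$lambda
  subjects <- unique(train$meta$subject_id)
  if (unit == "subject" && length(subjects) < 2L) {
    stop("need at least 2 subjects for subject-level resampling", call. = FALSE)
  }
  nv <- ncol(train$data)
  # Welford accumulation: exact zero variance when resampled fits coincide
  mw <- numeric(nv)
  m2 <- numeric(nv)
  samples <- if (keep_samples) matrix(NA_real_, B, nv) else NULL
  with_seed(seed + 1L, {
    for (b in seq_len(B)) {
      rows <- resample_rows(train$meta$subject_id, unit)
      m <- tryCatch(
        suppressWarnings(fit_lasso_pcr(
          train$data[rows, , drop = FALSE], ratings[rows],
          n_components = n_components,
          penalty = if (is.null(lam_fixed)) "cv" else lam_fixed,
          seed = seed, mask = train$mask
        )),
        error = function(e) NULL
      )
      w <- if (is.null(m)) numeric(nv) else m$weight_map$weights
      d <- w - mw
      mw <- mw + d / b
      m2 <- m2 + d * (w - mw)
      if (keep_samples) samples[b, ] <- w
    }
  })
  sdw <- sqrt(pmax(0, m2 / (B - 1)))
  z <- numeric(nv)
  p <- rep(1, nv)
  degenerate <- sdw == 0 & mw != 0
  ok <- sdw > 0
  z[ok] <- mw[ok] / sdw[ok]
  p[ok] <- 2 * stats::pnorm(-abs(z[ok]))
  z[degenerate] <- sign(mw[degenerate]) * Inf
  p[degenerate] <- 1 / (B + 1)
  structure(
    list(
      voxel_stats = tibble::tibble(
        voxel = seq_len(nv), mean = mw, sd = sdw, z = z, p = p,
        degenerate = degenerate
      ),
      B = B, unit = unit, model = full, mask = train$mask, samples = samples
    ),
    class = "bootstrap_result"
  )
}

# one bootstrap draw of row indices; subject-level draws keep each drawn
# subject's rows as an intact block
resample_rows <- function(subject_ids, unit) {
  if (unit == "subject") {
    subjects <- unique(subject_ids)
    picked <- sample(subjects, length(subjects), replace = TRUE)
    unlist(lapply(picked, function(s) which(subject_ids == s)))
  } else {
    sample.int(length(subject_ids), replace = TRUE)
  }
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> B = %d (%s resampling), %d voxels, %d with |z| > 3\n",
    x$B, x$unit, nrow(x$voxel_stats), sum(abs(x$voxel_stats$z) > 3)
  ))
  invisible(x)
}

parse_threshold_rule <- function(rule) {
  if (is.list(rule)) return(rule)
  parts <- strsplit(rule, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("p", "fdr")) {
    stop("threshold rule must be \"p:<alpha>\" or \"fdr:<q>\"", call. = FALSE)
  }
  list(type = parts[1], alpha = as.numeric(parts[2]))
}

#' Threshold a weight map by bootstrap p-values and cluster extent
#'
#' Voxels passing the p-rule keep their original signed weights; connected
#' components smaller than `k` voxels are then removed. The FDR rule is
#' Benjamini-Hochberg applied over the in-mask voxels.
#'
#' @param result a [bootstrap_weights()] result.
#' @param weights the [weight_map()] to threshold (typically the full-data
#'   model's map); must share the result's mask.
#' @param rule `"p:<alpha>"` (uncorrected) or `"fdr:<q>"`.
#' @param k minimum surviving cluster extent, in voxels.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return A `thresholded_map` with zeroed non-survivors, the surviving
#'   voxel set, and the rule metadata.
#' @export
threshold_map <- function(result, weights, rule = "p:0.001", k = 10L,
                          connectivity = 26L) {
  stopifnot(inherits(result, "bootstrap_result"), inherits(weights, "weight_map"))
  check_same_mask(result$mask, weights$mask, "bootstrap result and weight map")
  rule <- parse_threshold_rule(rule)
  p <- result$voxel_stats$p
  pass <- switch(rule$type,
    p = p < rule$alpha,
    fdr = stats::p.adjust(p, method = "BH") <= rule$alpha
  )
  grid <- devectorize(as.numeric(pass), weights$mask) > 0
  labels <- label_components(grid, connectivity)
  lab_v <- labels[weights$mask$inclusion]
  if (any(pass)) {
    sizes <- table(lab_v[lab_v > 0])
    small <- as.integer(names(sizes)[sizes < k])
    pass <- pass & !(lab_v %in% small)
  }
  w <- weights$weights
  w[!pass] <- 0
  structure(
    list(
      weights = w, surviving = pass, rule = rule, k = k,
      connectivity = connectivity, mask = weights$mask,
      intercept = weights$intercept, n_surviving = sum(pass)
    ),
    class = "thresholded_map"
  )
}

#' @export
print.thresholded_map <- function(x, ...) {
  cat(sprintf(
    "<thresholded_map> %s %g, extent k = %d: %d voxel(s) survive\n",
    x$rule$type, x$rule$alpha, x$k, x$n_surviving
  ))
  invisible(x)
}

#' Convert a thresholded map to a weight map
#'
#' @param x a `thresholded_map`.
#' @return A [weight_map()] with zeros outside the surviving set.
#' @export
as_weight_map <- function(x) {
  stopifnot(inherits(x, "thresholded_map"))
  weight_map(x$weights, x$mask, intercept = x$intercept,
    provenance = sprintf("thresholded (%s %g, k=%d)", x$rule$type,
      x$rule$alpha, x$k)
  )
}

#' Label connected components in a 3-D logical array
#'
#' Breadth-first flood fill under 6- (faces) or 26- (faces, edges, corners)
#' connectivity.
#'
#' @param grid logical 3-D array.
#' @param connectivity 6 or 26.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(grid, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  d <- dim(grid)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) {
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  }
  labels <- array(0L, dim = d)
  coords <- which(grid, arr.ind = TRUE)
  if (!nrow(coords)) return(labels)
  current <- 0L
  for (i in seq_len(nrow(coords))) {
    v <- coords[i, ]
    if (labels[v[1], v[2], v[3]] != 0L) next
    current <- current + 1L
    queue <- matrix(v, nrow = 1)
    labels[v[1], v[2], v[3]] <- current
    while (nrow(queue)) {
      head <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      nb <- sweep(offs, 2, head, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) next
      idx <- cbind(nb[, 1], nb[, 2], nb[, 3])
      new <- grid[idx] & labels[idx] == 0L
      if (any(new)) {
        idx_new <- idx[new, , drop = FALSE]
        labels[idx_new] <- current
        queue <- rbind(queue, idx_new)
      }
    }
  }
  labels
}

#' Extract contiguous regions from a thresholded map
#'
#' Connected components of the surviving voxel set, deterministically
#' ordered by decreasing size with ties broken by the smallest voxel index.
#'
#' @param tmap a [threshold_map()] result.
#' @param connectivity 6 or 26; defaults to the map's.
#' @return A `region_set`: `assignment` (per in-mask voxel, 0 = none),
#'   `regions` tibble (region, size, sign of summed weight), and the mask.
#'   Empty maps give zero regions, not an error.
#' @export
extract_regions <- function(tmap, connectivity = NULL) {
  stopifnot(inherits(tmap, "thresholded_map"))
  if (is.null(connectivity)) connectivity <- tmap$connectivity
  grid <- devectorize(as.numeric(tmap$surviving), tmap$mask) > 0
  labels <- label_components(grid, connectivity)
  lab_v <- labels[tmap$mask$inclusion]
  ids <- setdiff(sort(unique(lab_v)), 0L)
  if (!length(ids)) {
    return(structure(
      list(
        assignment = lab_v,
        regions = tibble::tibble(region = integer(), size = integer(),
          sign = numeric(), sum_weight = numeric()),
        mask = tmap$mask, source = tmap
      ),
      class = "region_set"
    ))
  }
  info <- purrr::map_dfr(ids, function(id) {
    vox <- which(lab_v == id)
    tibble::tibble(
      old = id, size = length(vox), first_voxel = min(vox),
      sum_weight = sum(tmap$weights[vox])
    )
  })
  info <- dplyr::arrange(info, dplyr::desc(.data$size), .data$first_voxel)
  remap <- integer(max(ids))
  remap[info$old] <- seq_len(nrow(info))
  assignment <- ifelse(lab_v > 0, remap[pmax(lab_v, 1L)], 0L)
  structure(
    list(
      assignment = as.integer(assignment),
      regions = tibble::tibble(
        region = seq_len(nrow(info)), size = info$size,
        sign = sign(info$sum_weight), sum_weight = info$sum_weight
      ),
      mask = tmap$mask, source = tmap
    ),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d region(s)\n", nrow(x$regions)))
  invisible(x)
}
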