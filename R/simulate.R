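#' Simulation configuration
#'
#' Describes a synthetic multi-subject beta-image experiment: an ordinal
#' affect rating task (levels 1-5) or a thermal pain task (low/medium/high),
#' a spatially structured ground-truth pattern, per-subject amplitude
#' variation, and spatially smoothed Gaussian noise. Signal for subject `s`
#' at level `r` is `r * (effect_size + delta_s) * truth + noise` with
#' `delta_s ~ N(0, subject_sd)`.
#'
#' Defaults mirror the emotion study design: 5 rating levels with realistic
#' per-level usage probabilities (not every participant uses the extreme
#' ratings; in particular only ~80% ever report the top level), and pain
#' sessions with 28 subjects over three intensity levels.
#'
#' @param grid_shape integer triple; the synthetic brain grid.
#' @param n_subjects number of subjects.
#' @param levels rating levels (numeric scores; pain uses 1:3 labelled
#'   low/medium/high).
#' @param level_presence per-level probability that a subject produces an
#'   image at that level (emulates unused extreme ratings).
#' @param effect_size signal amplitude per rating unit.
#' @param subject_sd SD of between-subject amplitude deviations.
#' @param noise_sd voxelwise SD of the smoothed Gaussian noise field.
#' @param smooth_fwhm FWHM (voxels) of the Gaussian smoothing applied to the
#'   noise field.
#' @param n_true_regions,region_size number and target voxel size of the
#'   contiguous signed blobs making up the ground-truth pattern.
#' @param modality `"emotion"` or `"pain"`.
#' @param seed integer seed; fully determines all generated output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid_shape = c(16L, 16L, 12L),
                       n_subjects = 182L,
                       levels = if (modality == "pain") 1:3 else 1:5,
                       level_presence = if (modality == "pain") {
                         rep(1, 3)
                       } else {
                         c(0.98, 0.88, 0.98, 0.88, 0.80)
                       },
                       effect_size = 0.5,
                       subject_sd = 0.1,
                       noise_sd = 1,
                       smooth_fwhm = 3,
                       n_true_regions = 9L,
                       region_size = 60L,
                       modality = c("emotion", "pain"),
                       seed = 1L) {
  modality <- match.arg(modality)
  stopifnot(
    length(grid_shape) == 3L, all(grid_shape >= 1),
    n_subjects >= 1, length(levels) >= 1,
    length(level_presence) == length(levels),
    effect_size >= 0, subject_sd >= 0, noise_sd >= 0, smooth_fwhm >= 0,
    n_true_regions >= 0, region_size >= 1
  )
  structure(
    list(
      grid_shape = as.integer(grid_shape), n_subjects = as.integer(n_subjects),
      levels = levels, level_presence = level_presence,
      effect_size = effect_size, subject_sd = subject_sd, noise_sd = noise_sd,
      smooth_fwhm = smooth_fwhm, n_true_regions = as.integer(n_true_regions),
      region_size = as.integer(region_size), modality = modality,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

gaussian_kernel_1d <- function(fwhm) {
  if (fwhm <= 0) return(1)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

conv_axis <- function(arr, kernel, axis, circular = FALSE) {
  if (length(kernel) == 1L) return(arr)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  n <- dim(x)[1]
  m <- matrix(x, nrow = n)
  r <- (length(kernel) - 1L) / 2L
  idx <- outer(seq_len(n), seq(-r, r), `+`)
  if (circular) {
    idx <- ((idx - 1L) %% n) + 1L
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(kernel)) {
      out <- out + kernel[j] * m[idx[, j], , drop = FALSE]
    }
  } else {
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(kernel)) {
      ok <- idx[, j] >= 1L & idx[, j] <= n
      out[ok, ] <- out[ok, ] + kernel[j] * m[idx[ok, j], , drop = FALSE]
    }
  }
  aperm(array(out, dim = dim(x)), order(perm))
}

#' Smooth a 3-D array with a separable Gaussian kernel
#'
#' @param arr 3-D numeric array.
#' @param fwhm kernel full-width at half maximum, in voxels.
#' @param circular wrap-around convolution (keeps the variance of a smoothed
#'   white-noise field spatially uniform); zero-padding otherwise.
#' @return Smoothed array of the same shape.
#' @export
smooth_gaussian <- function(arr, fwhm, circular = FALSE) {
  k <- gaussian_kernel_1d(fwhm)
  for (ax in 1:3) arr <- conv_axis(arr, k, ax, circular = circular)
  arr
}

#' Simulate a smoothed Gaussian noise field with unit-calibrated variance
#'
#' White Gaussian noise smoothed by a circular separable Gaussian kernel and
#' rescaled so each voxel's marginal SD equals `sd`.
#'
#' @param grid_shape integer triple.
#' @param sd target voxelwise SD.
#' @param fwhm smoothing FWHM in voxels.
#' @return 3-D array.
#' @export
noise_field <- function(grid_shape, sd = 1, fwhm = 3) {
  w <- array(stats::rnorm(prod(grid_shape)), dim = grid_shape)
  if (fwhm > 0) {
    k <- gaussian_kernel_1d(fwhm)
    w <- smooth_gaussian(w, fwhm, circular = TRUE)
    # circular convolution scales white-noise variance by the power of the
    # kernel folded onto each (finite) axis
    power <- vapply(grid_shape, function(n) {
      keff <- tapply(k, ((seq_along(k) - 1L) %% n), sum)
      sum(keff^2)
    }, numeric(1))
    w <- w / sqrt(prod(power))
  }
  w * sd
}

#' Build a ground-truth signature pattern of contiguous signed blobs
#'
#' Places `n_true_regions` contiguous regions of roughly `region_size`
#' voxels each (grown by randomized flood fill, smoothed, thresholded at
#' half maximum), with alternating signs, mimicking a distributed mesoscale
#' pattern spanning several systems. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param mask optional [brain_mask()]; defaults to the full grid.
#' @return A [weight_map()] with zero intercept.
#' @export
make_ground_truth_pattern <- function(config, mask = NULL) {
  stopifnot(inherits(config, "sim_config"))
  shp <- config$grid_shape
  if (is.null(mask)) mask <- brain_mask(array(TRUE, dim = shp))
  if (config$n_true_regions * config$region_size > prod(shp)) {
    stop("requested regions exceed grid capacity", call. = FALSE)
  }
  acc <- array(0, dim = shp)
  with_seed(config$seed, {
    occupied <- array(FALSE, dim = shp)
    for (b in seq_len(config$n_true_regions)) {
      # prefer a 2-voxel separation margin so distinct systems stay distinct
      # after smoothing; relax it when the grid is too tight
      blob <- NULL
      for (margin in 2:0) {
        blocked <- if (margin > 0) dilate3d(occupied, margin) else occupied
        blob <- tryCatch(grow_blob(shp, config$region_size, blocked),
          error = function(e) NULL
        )
        if (!is.null(blob)) break
      }
      if (is.null(blob)) {
        stop("could not place a blob of the requested size", call. = FALSE)
      }
      occupied <- occupied | blob
      sm <- smooth_gaussian(array(as.numeric(blob), dim = shp), 2)
      # threshold at the size-matched quantile so the final blob keeps about
      # the requested voxel count
      thr <- sort(sm[sm > 0], decreasing = TRUE)[
        min(config$region_size, sum(sm > 0))
      ]
      keep <- sm >= thr
      sgn <- if (b %% 2 == 1) 1 else -1
      acc <- acc + sgn * sm * keep
    }
  })
  w <- vectorize(acc, mask)
  if (any(w != 0)) w <- w / stats::sd(w[w != 0])
  weight_map(w, mask, intercept = 0,
    provenance = sprintf("synthetic ground truth (seed %d)", config$seed)
  )
}

dilate3d <- function(mask, r = 1L) {
  out <- mask
  for (step in seq_len(r)) {
    d <- dim(out)
    grown <- out
    grown[-1, , ] <- grown[-1, , ] | out[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | out[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | out[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | out[, -1, ]
    grown[, , -1] <- grown[, , -1] | out[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | out[, , -1]
    out <- grown
  }
  out
}

grow_blob <- function(shp, size, occupied, max_tries = 50L) {
  margin <- 2L
  for (try in seq_len(max_tries)) {
    start <- vapply(1:3, function(a) {
      lo <- min(margin + 1L, shp[a])
      hi <- max(lo, shp[a] - margin)
      sample(lo:hi, 1L)
    }, integer(1))
    if (occupied[start[1], start[2], start[3]]) next
    blob <- array(FALSE, dim = shp)
    blob[start[1], start[2], start[3]] <- TRUE
    frontier <- matrix(start, nrow = 1)
    count <- 1L
    steps <- rbind(
      c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)
    )
    while (count < size && nrow(frontier) > 0) {
      i <- sample.int(nrow(frontier), 1L)
      v <- frontier[i, ]
      nb <- sweep(steps, 2, v, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= shp[1] & nb[, 2] >= 1 & nb[, 2] <= shp[2] &
        nb[, 3] >= 1 & nb[, 3] <= shp[3]
      nb <- nb[ok, , drop = FALSE]
      added <- FALSE
      if (nrow(nb)) {
        free <- !blob[nb] & !occupied[nb]
        nb <- nb[free, , drop = FALSE]
        if (nrow(nb)) {
          j <- sample.int(nrow(nb), 1L)
          blob[nb[j, 1], nb[j, 2], nb[j, 3]] <- TRUE
          frontier <- rbind(frontier, nb[j, , drop = FALSE])
          count <- count + 1L
          added <- TRUE
        }
      }
      if (!added) frontier <- frontier[-i, , drop = FALSE]
    }
    if (count >= size * 0.9) return(blob)
  }
  stop("could not place a blob of the requested size", call. = FALSE)
}

#' Simulate a multi-subject beta-image dataset with known ground truth
#'
#' Generates one condition-level image per subject and present rating level:
#' `r * (effect_size + delta_s) * truth + noise`, where `delta_s` is the
#' subject's amplitude deviation and the noise field is smoothed Gaussian
#' noise. Whether a subject produces a given level is Bernoulli with the
#' config's `level_presence`, emulating participants who never use extreme
#' ratings; every subject keeps at least two levels.
#'
#' @param config a [sim_config()].
#' @param truth a [weight_map()] ground-truth pattern; defaults to
#'   [make_ground_truth_pattern()] of the config.
#' @return A list with `images` ([beta_image_set()]), `ratings` (tibble),
#'   and `ground_truth` (list with the truth map, per-subject amplitude
#'   multipliers, and per-observation rating assignments).
#' @export
simulate_dataset <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- make_ground_truth_pattern(config)
  mask <- truth$mask
  shp <- config$grid_shape
  stopifnot(all(mask$grid_shape == shp))
  labels <- if (config$modality == "pain") {
    c("low", "medium", "high")[config$levels]
  } else {
    as.character(config$levels)
  }
  with_seed(config$seed + 1L, {
    delta <- stats::rnorm(config$n_subjects, 0, config$subject_sd)
    rows <- list()
    meta <- list()
    for (s in seq_len(config$n_subjects)) {
      present <- stats::runif(length(config$levels)) < config$level_presence
      if (sum(present) < 2L) {
        present[order(config$level_presence, decreasing = TRUE)[1:2]] <- TRUE
      }
      for (li in which(present)) {
        r <- config$levels[li]
        signal <- r * (config$effect_size + delta[s]) * truth$weights
        noise <- vectorize(
          noise_field(shp, config$noise_sd, config$smooth_fwhm), mask
        )
        rows[[length(rows) + 1L]] <- signal + noise
        meta[[length(meta) + 1L]] <- tibble::tibble(
          subject_id = sprintf("s%03d", s), condition = labels[li],
          rating = r, modality = config$modality
        )
      }
    }
    images <- beta_image_set(do.call(rbind, rows), dplyr::bind_rows(meta), mask)
  })
  ratings <- dplyr::select(
    images$meta, "subject_id", "condition", "rating", "modality"
  )
  list(
    images = images,
    ratings = ratings,
    ground_truth = list(
      truth = truth,
      subject_amplitude = config$effect_size + delta,
      assignments = ratings,
      config = config
    )
  )
}

#' Simulate trial-level images for within-subject analyses
#'
#' Like [simulate_dataset()] but generates `n_trials` individual trials per
#' subject (ratings drawn uniformly from the config's levels), the
#' granularity needed for within-subject models and subnetwork clustering.
#'
#' @param config a [sim_config()].
#' @param truth ground-truth [weight_map()]; defaults to
#'   [make_ground_truth_pattern()].
#' @param n_trials trials per subject.
#' @return A list with `images` (trial-granularity [beta_image_set()]) and
#'   `ratings`.
#' @export
simulate_trial_dataset <- function(config, truth = NULL, n_trials = 30L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- make_ground_truth_pattern(config)
  mask <- truth$mask
  shp <- config$grid_shape
  with_seed(config$seed + 3L, {
    delta <- stats::rnorm(config$n_subjects, 0, config$subject_sd)
    rows <- list()
    meta <- list()
    for (s in seq_len(config$n_subjects)) {
      ratings <- sample(config$levels, n_trials, replace = TRUE)
      for (t in seq_len(n_trials)) {
        signal <- ratings[t] * (config$effect_size + delta[s]) * truth$weights
        noise <- vectorize(
          noise_field(shp, config$noise_sd, config$smooth_fwhm), mask
        )
        rows[[length(rows) + 1L]] <- signal + noise
        meta[[length(meta) + 1L]] <- tibble::tibble(
          subject_id = sprintf("s%03d", s), condition = as.character(ratings[t]),
          trial = t, rating = ratings[t], modality = config$modality
        )
      }
    }
    images <- beta_image_set(do.call(rbind, rows), dplyr::bind_rows(meta),
      mask,
      rating_granularity = "trial"
    )
  })
  list(images = images, ratings = images$meta)
}

#' Canonical double-gamma hemodynamic response function
#'
#' @param t time in seconds (vector).
#' @param peak,undershoot gamma shape peaks in seconds (canonical 6 and 16).
#' @param ratio undershoot amplitude relative to the peak (canonical 1/6).
#' @return HRF values, peak normalized to 1.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  a1 <- peak
  a2 <- undershoot
  h <- stats::dgamma(t, shape = a1, rate = 1) -
    ratio * stats::dgamma(t, shape = a2, rate = 1)
  h / max(stats::dgamma(seq(0, 30, by = 0.01), shape = a1, rate = 1))
}

#' Simulate a 4-D timeseries from event onsets
#'
#' Each voxel's signal is the event boxcar (scaled by the event's rating and
#' `effect_size` and the voxel's ground-truth weight) convolved with the
#' canonical double-gamma HRF, plus white noise. Overlapping events add.
#'
#' @param config a [sim_config()].
#' @param truth ground-truth [weight_map()].
#' @param events data frame with `onset`, `duration` (seconds) and `rating`.
#' @param tr repetition time in seconds.
#' @param n_volumes number of volumes; defaults to cover all events plus
#'   24 s.
#' @return A list with `series` (4-D array), `events`, `tr`, `mask`.
#' @export
simulate_timeseries <- function(config, truth, events, tr = 2,
                                n_volumes = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "weight_map"))
  events <- tibble::as_tibble(events)
  if (nrow(events)) {
    stopifnot(all(c("onset", "duration", "rating") %in% names(events)))
  }
  if (is.null(n_volumes)) {
    last <- if (nrow(events)) max(events$onset + events$duration) else 0
    n_volumes <- ceiling((last + 24) / tr)
  }
  if (nrow(events) && any(events$onset + events$duration > n_volumes * tr)) {
    stop("events extend beyond the scan duration", call. = FALSE)
  }
  dt <- 0.1
  nt <- ceiling(n_volumes * tr / dt)
  stick <- numeric(nt)
  for (i in seq_len(nrow(events))) {
    on <- floor(events$onset[i] / dt) + 1L
    off <- min(nt, ceiling((events$onset[i] + events$duration[i]) / dt))
    stick[on:off] <- stick[on:off] + events$rating[i]
  }
  hrf <- hrf_double_gamma(seq(0, 30, by = dt))
  conv <- stats::convolve(stick, rev(hrf), type = "open")[seq_len(nt)] * dt
  vol_t <- (seq_len(n_volumes) - 1) * tr
  amp <- conv[pmin(nt, floor(vol_t / dt) + 1L)] * config$effect_size
  shp <- config$grid_shape
  series <- array(0, dim = c(shp, n_volumes))
  tw <- devectorize(truth$weights, truth$mask)
  with_seed(config$seed + 2L, {
    for (v in seq_len(n_volumes)) {
      series[, , , v] <- amp[v] * tw +
        if (config$noise_sd > 0) {
          noise_field(shp, config$noise_sd, config$smooth_fwhm)
        } else {
          0
        }
    }
  })
  list(series = series, events = events, tr = tr, mask = truth$mask)
}
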