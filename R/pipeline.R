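default_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "train", "bootstrap", "evaluate", "cluster",
      "lesion"),
    simulate = list(grid_shape = c(12L, 12L, 10L), n_subjects = 30L,
      effect_size = 0.6, noise_sd = 1, n_true_regions = 4L,
      region_size = 40L),
    pain = list(n_subjects = 12L),
    train = list(fraction = 2 / 3, penalty = "cv", n_components = NULL),
    bootstrap = list(B = 60L, unit = "subject", threshold = "p:0.01",
      extent = 5L),
    cluster = list(cut_fraction = 0.31)
  )
}

validate_config <- function(config) {
  if (!is.null(config$images)) {
    for (field in c("mask", "ratings")) {
      if (is.null(config[[field]])) {
        stop(sprintf("config$%s is required when config$images is set", field),
          call. = FALSE
        )
      }
    }
    for (field in c("images", "mask", "ratings")) {
      if (!file.exists(config[[field]])) {
        stop(sprintf("config$%s: file '%s' does not exist", field,
          config[[field]]), call. = FALSE)
      }
    }
  }
  if (!is.null(config$train$fraction) &&
    (config$train$fraction <= 0 || config$train$fraction >= 1)) {
    stop("config$train$fraction must be in (0, 1)", call. = FALSE)
  }
  invisible(config)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

file_digest <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full signature-development pipeline from a configuration
#'
#' Executes the configured stages in order — simulate (or load) the
#' datasets, stratified split and LASSO-PCR training, bootstrap
#' thresholding, benchmark evaluation, subnetwork clustering, and virtual
#' lesions — writing each stage's artifacts (NIfTI maps, CSV tables) and a
#' JSON run manifest (command, full parameter set, seeds, file digests,
#' package version, timestamp) into `out_dir`. No stage mutates its
#' inputs; reruns with the same config and seed reproduce all CSV outputs
#' byte-identically.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Keys mirror the module parameters (`simulate`, `pain`, `train`,
#'   `bootstrap`, `cluster`, `stages`, `seed`). Supplying `images`,
#'   `ratings` and `mask` paths replaces the simulate stage with real data.
#' @param out_dir output directory.
#' @return The manifest list, invisibly; artifacts are on disk.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("affectsig_run_")) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file '%s' does not exist", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  input_files <- unlist(config[c("images", "ratings", "mask")])
  config <- merge_config(default_config(), config)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  artifacts <- character()
  log_msg <- function(...) message(sprintf(...))
  results <- list()

  if ("simulate" %in% config$stages && is.null(config$images)) {
    log_msg("stage simulate: emotion + pain datasets")
    emo_cfg <- do.call(sim_config, c(config$simulate,
      list(modality = "emotion", seed = seed)))
    emo <- simulate_dataset(emo_cfg)
    pain_cfg <- do.call(sim_config, c(
      config$simulate[setdiff(
        names(config$simulate),
        c("n_subjects", "levels", "level_presence")
      )],
      config$pain, list(modality = "pain", seed = seed + 1000L)
    ))
    pain <- simulate_dataset(pain_cfg, truth = NULL)
    utils::write.csv(emo$ratings, file.path(out_dir, "emotion_ratings.csv"),
      row.names = FALSE
    )
    utils::write.csv(pain$ratings, file.path(out_dir, "pain_ratings.csv"),
      row.names = FALSE
    )
    artifacts <- c(artifacts, file.path(out_dir,
      c("emotion_ratings.csv", "pain_ratings.csv")))
    results$emotion <- emo
    results$pain <- pain
  } else if (!is.null(config$images)) {
    log_msg("stage load: reading image table")
    mask <- read_mask(config$mask)
    tbl <- read_response_table(config$images, required = "subject_id")
    results$emotion <- list(
      images = read_image_set(tbl, mask),
      ratings = read_response_table(config$ratings,
        required = c("subject_id", "rating"))
    )
  }

  if ("train" %in% config$stages) {
    log_msg("stage train: stratified split + LASSO-PCR")
    split <- stratified_split(results$emotion$images,
      fraction = config$train$fraction, seed = seed
    )
    model <- fit_lasso_pcr(split$train,
      n_components = config$train$n_components,
      penalty = config$train$penalty, seed = seed
    )
    write_weight_map(model$weight_map, file.path(out_dir, "signature.nii.gz"))
    preds <- tibble::tibble(
      subject_id = split$test$meta$subject_id,
      rating = split$test$meta$rating,
      predicted = predict(model, split$test)
    )
    utils::write.csv(preds, file.path(out_dir, "test_predictions.csv"),
      row.names = FALSE
    )
    artifacts <- c(artifacts, file.path(out_dir,
      c("signature.nii.gz", "signature.json", "test_predictions.csv")))
    results$split <- split
    results$model <- model
  }

  if ("bootstrap" %in% config$stages) {
    log_msg("stage bootstrap: B = %d", config$bootstrap$B)
    boot <- bootstrap_weights(results$split$train,
      B = config$bootstrap$B, unit = config$bootstrap$unit, seed = seed
    )
    tmap <- threshold_map(boot, results$model$weight_map,
      rule = config$bootstrap$threshold, k = config$bootstrap$extent
    )
    write_weight_map(as_weight_map(tmap),
      file.path(out_dir, "signature_thresholded.nii.gz"))
    utils::write.csv(boot$voxel_stats, file.path(out_dir, "bootstrap_stats.csv"),
      row.names = FALSE
    )
    artifacts <- c(artifacts, file.path(out_dir,
      c("signature_thresholded.nii.gz", "bootstrap_stats.csv")))
    results$bootstrap <- boot
    results$thresholded <- tmap
  }

  if ("evaluate" %in% config$stages) {
    log_msg("stage evaluate: benchmark grid")
    grid <- run_benchmark(
      list(signature = results$model$weight_map),
      results$split$test,
      if (!is.null(results$pain)) results$pain$images
    )
    utils::write.csv(grid$grid, file.path(out_dir, "benchmark_grid.csv"),
      row.names = FALSE
    )
    artifacts <- c(artifacts, file.path(out_dir, "benchmark_grid.csv"))
    results$benchmark <- grid
  }

  if ("cluster" %in% config$stages && !is.null(results$thresholded) &&
    results$thresholded$n_surviving > 0) {
    log_msg("stage cluster: subnetworks")
    regions <- extract_regions(results$thresholded)
    if (nrow(regions$regions) >= 2L) {
      rrm <- rank_normalize(
        region_trial_responses(results$split$test, regions)
      )
      sol <- cluster_regions(rrm, cut_fraction = config$cluster$cut_fraction)
      out <- tibble::tibble(
        region = seq_along(sol$assignment),
        size = regions$regions$size,
        cluster = sol$assignment
      )
      utils::write.csv(out, file.path(out_dir, "clusters.csv"),
        row.names = FALSE
      )
      merges <- data.frame(sol$tree$merge, height = sol$tree$height)
      names(merges) <- c("left", "right", "height")
      utils::write.csv(merges, file.path(out_dir, "linkage.csv"),
        row.names = FALSE
      )
      artifacts <- c(artifacts, file.path(out_dir,
        c("clusters.csv", "linkage.csv")))
      results$regions <- regions
      results$clusters <- sol

      if ("lesion" %in% config$stages) {
        log_msg("stage lesion: virtual lesions over %d cluster(s)",
          sol$n_clusters)
        lgrid <- virtual_lesion_grid(results$thresholded, regions, sol,
          results$split$test,
          if (!is.null(results$pain)) results$pain$images
        )
        utils::write.csv(lgrid$grid, file.path(out_dir, "virtual_lesions.csv"),
          row.names = FALSE
        )
        artifacts <- c(artifacts, file.path(out_dir, "virtual_lesions.csv"))
        results$lesions <- lgrid
      }
    }
  }

  manifest <- list(
    command = "run_pipeline",
    parameters = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("affectsig")),
    timestamp = format(Sys.time(), tz = "UTC"),
    input_digests = file_digest(input_files %||% character()),
    artifacts = file_digest(artifacts)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(results, list(manifest = manifest, out_dir = out_dir)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
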