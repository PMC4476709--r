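pattern_scores <- function(images, pattern) {
  if (inherits(pattern, "weight_map")) {
    pattern_response(images, pattern, method = "dot")
  } else if (inherits(pattern, "brain_mask")) {
    # binary parcel treated as a pattern: point-biserial spatial correlation
    wm <- weight_map(
      as.numeric(vectorize(pattern$inclusion, images$mask)), images$mask
    )
    pattern_response(images, wm, method = "pearson")
  } else if (is.list(pattern) && identical(pattern$type, "roi")) {
    roi_response(images, pattern$mask)
  } else {
    stop("pattern type not recognized (weight_map, brain_mask, or roi spec)",
      call. = FALSE
    )
  }
}

#' Mark a binary mask as an ROI benchmark entry
#'
#' ROI entries are scored by mean in-ROI activation; bare [brain_mask()]
#' entries are scored as binary patterns via point-biserial spatial
#' correlation.
#'
#' @param mask a [brain_mask()].
#' @return A tagged list for [run_benchmark()].
#' @export
as_roi <- function(mask) {
  stopifnot(inherits(mask, "brain_mask"))
  list(type = "roi", mask = mask)
}

subject_level_pair <- function(scores, level_high, level_low) {
  wide <- dplyr::summarise(
    dplyr::group_by(scores, .data$subject_id, .data$rating),
    response = mean(.data$response), .groups = "drop"
  )
  hi <- wide[wide$rating == level_high, c("subject_id", "response")]
  lo <- wide[wide$rating == level_low, c("subject_id", "response")]
  both <- dplyr::inner_join(hi, lo, by = "subject_id",
    suffix = c("_high", "_low")
  )
  both
}

cell_high_low <- function(scores, level_high, level_low, design) {
  pair <- subject_level_pair(scores, level_high, level_low)
  if (!nrow(pair)) return(NULL)
  if (design == "forced_choice") {
    forced_choice(pair$response_high, pair$response_low)
  } else {
    single_interval(
      c(pair$response_high, pair$response_low),
      c(rep(TRUE, nrow(pair)), rep(FALSE, nrow(pair)))
    )
  }
}

cell_cross_modality <- function(scores_emotion, scores_pain, level_emotion,
                                level_pain, design) {
  em <- scores_emotion[scores_emotion$rating == level_emotion, ]
  pa <- scores_pain[scores_pain$rating == level_pain, ]
  if (!nrow(em) || !nrow(pa)) return(NULL)
  single_interval(
    c(em$response, pa$response),
    c(rep(TRUE, nrow(em)), rep(FALSE, nrow(pa)))
  )
}

level_correlation <- function(scores) {
  pm <- prediction_metrics(scores$response, scores$rating, scores$subject_id)
  c(mean = pm$mean_r, se = pm$se_r)
}

#' Run the sensitivity/specificity benchmark grid
#'
#' For each supplied pattern (signature weight map, binary network mask, or
#' ROI entry from [as_roi()]), computes the standard comparison columns on
#' the emotion and pain test sets: high-vs-low emotion classification
#' (top rating vs bottom rating; subjects lacking either level are
#' excluded), high-vs-low pain, emotion-vs-pain discrimination (top emotion
#' level vs high pain), and per-subject response-rating Pearson
#' correlations in each modality. Classification cells use single-interval
#' balanced accuracy with the bias-minimizing threshold by default
#' (`design = "forced_choice"` switches the within-modality cells).
#' Accuracies are signed: values above 50% mean the higher-intensity (or
#' emotion) condition scored greater. Each cell is tested against chance,
#' and against the first pattern in the list (the reference) with McNemar's
#' test on shared units.
#'
#' @param patterns named list of [weight_map()], [brain_mask()] (scored
#'   point-biserially), or [as_roi()] entries; the first is the reference.
#' @param emotion_set test [beta_image_set()] with ratings.
#' @param pain_set optional pain-modality test set (levels 1-3 =
#'   low/medium/high).
#' @param design `"single_interval"` or `"forced_choice"` for the
#'   within-modality cells.
#' @return A `benchmark_grid`: `grid` tibble (one row per pattern) and
#'   `cells` (named list of `classification_result`s for full traceability).
#' @export
run_benchmark <- function(patterns, emotion_set, pain_set = NULL,
                          design = c("single_interval", "forced_choice")) {
  design <- match.arg(design)
  stopifnot(length(patterns) >= 1L, !is.null(names(patterns)))
  emo_levels <- range(emotion_set$meta$rating, na.rm = TRUE)
  cells <- list()
  rows <- list()
  ref <- list()
  for (nm in names(patterns)) {
    p <- patterns[[nm]]
    es <- pattern_scores(emotion_set, p)
    ps <- if (!is.null(pain_set)) pattern_scores(pain_set, p) else NULL
    emo_cell <- cell_high_low(es, emo_levels[2], emo_levels[1], design)
    pain_cell <- if (!is.null(ps)) {
      pl <- range(ps$rating, na.rm = TRUE)
      cell_high_low(ps, pl[2], pl[1], design)
    }
    cross_cell <- if (!is.null(ps)) {
      cell_cross_modality(es, ps, emo_levels[2], max(ps$rating), "single_interval")
    }
    emo_cor <- level_correlation(es)
    pain_cor <- if (!is.null(ps)) level_correlation(ps) else c(mean = NA, se = NA)
    if (nm == names(patterns)[1]) {
      ref <- list(emotion = emo_cell, cross = cross_cell)
    }
    vs_ref_p <- NA_real_
    if (nm != names(patterns)[1] && !is.null(emo_cell) && !is.null(ref$emotion)) {
      vs_ref_p <- compare_accuracies(ref$emotion, emo_cell, "dependent")$p_value
    }
    cells[[nm]] <- list(emotion = emo_cell, pain = pain_cell, cross = cross_cell)
    rows[[nm]] <- tibble::tibble(
      pattern = nm,
      type = if (inherits(p, "weight_map")) {
        "map"
      } else if (inherits(p, "brain_mask")) {
        "network"
      } else {
        "roi"
      },
      emotion_high_vs_low = pct(cell_field(emo_cell, "accuracy")),
      emotion_high_vs_low_se = pct(cell_field(emo_cell, "se")),
      emotion_high_vs_low_p = cell_field(emo_cell, "p_value"),
      emotion_n = cell_field(emo_cell, "n"),
      pain_high_vs_low = pct(cell_field(pain_cell, "accuracy")),
      pain_high_vs_low_se = pct(cell_field(pain_cell, "se")),
      emotion_vs_pain = pct(cell_field(cross_cell, "accuracy")),
      emotion_vs_pain_se = pct(cell_field(cross_cell, "se")),
      emotion_correlation = unname(emo_cor["mean"]),
      emotion_correlation_se = unname(emo_cor["se"]),
      pain_correlation = unname(pain_cor["mean"]),
      pain_correlation_se = unname(pain_cor["se"]),
      vs_reference_p = vs_ref_p
    )
  }
  structure(
    list(grid = dplyr::bind_rows(rows), cells = cells, design = design),
    class = "benchmark_grid"
  )
}

pct <- function(x) if (is.null(x) || is.na(x)) NA_real_ else 100 * x

cell_field <- function(cell, field) {
  if (is.null(cell)) NA_real_ else cell[[field]]
}

#' @export
print.benchmark_grid <- function(x, ...) {
  cat(sprintf("<benchmark_grid> (%s classification)\n", x$design))
  print(dplyr::select(
    x$grid, "pattern", "type", "emotion_high_vs_low", "pain_high_vs_low",
    "emotion_vs_pain", "emotion_correlation", "pain_correlation"
  ))
  invisible(x)
}
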