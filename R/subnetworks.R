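#' Trial-level local pattern responses per region
#'
#' For each extracted region, the dot product of the parent signature's
#' weights restricted to that region with each trial image (no intercept).
#' Summing the columns of the resulting matrix recovers the whole-map
#' dot-product response minus the intercept.
#'
#' @param trials a [beta_image_set()] of trial-level images.
#' @param regions a [extract_regions()] result on the same mask.
#' @param parent a [weight_map()] whose weights define the local patterns;
#'   defaults to the thresholded map the regions came from.
#' @return A `region_response_matrix`: `responses` (trials x regions),
#'   `subject_id`, `trial_meta`, `normalization = "raw"`.
#' @export
region_trial_responses <- function(trials, regions, parent = NULL) {
  stopifnot(inherits(trials, "beta_image_set"), inherits(regions, "region_set"))
  check_same_mask(trials$mask, regions$mask, "trials and regions")
  w <- if (is.null(parent)) regions$source$weights else parent$weights
  stopifnot(length(w) == trials$mask$n_voxels)
  n_regions <- nrow(regions$regions)
  if (!n_regions) stop("region set is empty", call. = FALSE)
  resp <- sapply(seq_len(n_regions), function(rid) {
    vox <- which(regions$assignment == rid)
    if (!length(vox)) stop("empty region", call. = FALSE)
    as.numeric(trials$data[, vox, drop = FALSE] %*% w[vox])
  })
  resp <- matrix(resp, nrow = nrow(trials$data))
  colnames(resp) <- paste0("R", seq_len(n_regions))
  structure(
    list(
      responses = resp, subject_id = trials$meta$subject_id,
      trial_meta = trials$meta, normalization = "raw"
    ),
    class = "region_response_matrix"
  )
}

#' @export
print.region_response_matrix <- function(x, ...) {
  cat(sprintf(
    "<region_response_matrix> %d trials x %d regions (%s)\n",
    nrow(x$responses), ncol(x$responses), x$normalization
  ))
  invisible(x)
}

#' Rank-normalize region responses within subject
#'
#' Each region's trial responses are rank-ordered within subject (ties get
#' average ranks) and the ranks are then z-scored within subject, giving a
#' robust, monotone-invariant co-expression substrate for clustering that
#' is insensitive to between-subject differences in response scale and
#' hemodynamics.
#'
#' @param x a [region_trial_responses()] result; each subject needs at
#'   least 2 trials.
#' @return The matrix with `normalization = "rank"`.
#' @export
rank_normalize <- function(x) {
  stopifnot(inherits(x, "region_response_matrix"))
  out <- x$responses
  for (s in unique(x$subject_id)) {
    rows <- which(x$subject_id == s)
    if (length(rows) < 2L) {
      stop("each subject needs at least 2 trials to rank-normalize",
        call. = FALSE
      )
    }
    for (j in seq_len(ncol(out))) {
      r <- rank(x$responses[rows, j], ties.method = "average")
      out[rows, j] <- standardize(r)
    }
  }
  x$responses <- out
  x$normalization <- "rank"
  x
}

#' Cluster signature regions into subnetworks
#'
#' Ward minimum-variance agglomerative clustering (on Euclidean distances
#' between region columns of the subject-concatenated trial x region
#' matrix), cut at a fixed fraction of the maximum merge height. Merge
#' heights are nondecreasing and the solution is invariant to region input
#' order.
#'
#' @param x a [region_response_matrix()] (rank-normalize first for the
#'   robust variant).
#' @param cut_fraction tree cut height as a fraction of the maximum merge
#'   height (default 0.31).
#' @return A `cluster_solution`: `tree` (hclust), `cut_fraction`,
#'   `cut_height`, `assignment` (region -> cluster), `n_clusters`.
#' @export
cluster_regions <- function(x, cut_fraction = 0.31) {
  stopifnot(inherits(x, "region_response_matrix"))
  if (ncol(x$responses) < 2L) stop("need at least 2 regions", call. = FALSE)
  d <- stats::dist(t(x$responses), method = "euclidean")
  tree <- stats::hclust(d, method = "ward.D2")
  h <- cut_fraction * max(tree$height)
  assignment <- stats::cutree(tree, h = h)
  structure(
    list(
      tree = tree, cut_fraction = cut_fraction, cut_height = h,
      assignment = assignment, n_clusters = max(assignment),
      normalization = x$normalization
    ),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf(
    "<cluster_solution> %d region(s) -> %d cluster(s) (cut %.0f%% of max height)\n",
    length(x$assignment), x$n_clusters, 100 * x$cut_fraction
  ))
  invisible(x)
}

cluster_voxels <- function(regions, solution, cluster) {
  rid <- which(solution$assignment == cluster)
  if (!length(rid)) stop("unknown cluster id", call. = FALSE)
  which(regions$assignment %in% rid)
}

#' Virtual-lesion and single-cluster maps
#'
#' Builds derived signature maps from a thresholded map and a subnetwork
#' assignment: `"remove"` zeroes the cluster's voxels (testing the
#' cluster's necessity), `"only"` keeps just them (testing sufficiency).
#' The intercept is retained unchanged in both modes, so the `remove` and
#' `only` dot-product responses sum to the full thresholded-map response
#' with the intercept counted once.
#'
#' @param tmap a [threshold_map()] result.
#' @param regions the [extract_regions()] of `tmap`.
#' @param solution a [cluster_regions()] solution over those regions.
#' @param cluster cluster id.
#' @param mode `"remove"` or `"only"`.
#' @return A [weight_map()].
#' @export
virtual_lesion <- function(tmap, regions, solution, cluster,
                           mode = c("remove", "only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tmap, "thresholded_map"), inherits(regions, "region_set"))
  vox <- cluster_voxels(regions, solution, cluster)
  w <- tmap$weights
  if (mode == "remove") {
    w[vox] <- 0
  } else {
    keep <- rep(FALSE, length(w))
    keep[vox] <- TRUE
    w[!keep] <- 0
  }
  weight_map(w, tmap$mask,
    intercept = if (mode == "remove") tmap$intercept else 0,
    provenance = sprintf("virtual lesion: cluster %d %sd", cluster, mode)
  )
}

#' Evaluate every cluster's necessity and sufficiency
#'
#' Runs the benchmark grid on the full thresholded map and on each
#' cluster's `"only"` (single cluster) and `"remove"` (virtual lesion)
#' derivative.
#'
#' @param tmap,regions,solution as in [virtual_lesion()].
#' @param emotion_set,pain_set test [beta_image_set()]s.
#' @param ... passed to [run_benchmark()].
#' @return A [run_benchmark()] grid with one row per derived map.
#' @export
virtual_lesion_grid <- function(tmap, regions, solution, emotion_set,
                                pain_set = NULL, ...) {
  full <- as_weight_map(tmap)
  patterns <- list(full = full)
  for (k in seq_len(solution$n_clusters)) {
    patterns[[sprintf("only_c%d", k)]] <-
      virtual_lesion(tmap, regions, solution, k, "only")
    patterns[[sprintf("remove_c%d", k)]] <-
      virtual_lesion(tmap, regions, solution, k, "remove")
  }
  run_benchmark(patterns, emotion_set, pain_set, ...)
}
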