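#' Sets of condition-level beta images
#'
#' A `beta_image_set` holds an observations x voxels matrix of vectorized
#' condition-level images ("beta maps") together with per-observation
#' metadata (subject, condition label, numeric rating where applicable,
#' modality, split tag) and the shared [brain_mask()].
#'
#' @param data numeric matrix, observations in rows, in-mask voxels in
#'   columns (mask vectorization order).
#' @param meta data frame with one row per observation; must contain
#'   `subject_id` and `condition`; a numeric `rating` column and `modality`
#'   (`"emotion"` or `"pain"`) and `split` (`"train"`, `"test"`, `"none"`)
#'   are added with defaults when absent. Extra columns pass through.
#' @param mask the shared [brain_mask()].
#' @param rating_granularity `"rating"` (one condition-level image per
#'   subject x rating, checked unique) or `"trial"`.
#' @return A `beta_image_set`.
#' @export
beta_image_set <- function(data, meta, mask,
                           rating_granularity = c("rating", "trial")) {
  rating_granularity <- match.arg(rating_granularity)
  stopifnot(inherits(mask, "brain_mask"))
  data <- as.matrix(data)
  meta <- tibble::as_tibble(meta)
  if (nrow(meta) != nrow(data)) {
    stop("metadata rows must match image rows", call. = FALSE)
  }
  if (ncol(data) != mask$n_voxels) {
    stop("data columns must equal mask voxel count", call. = FALSE)
  }
  req <- setdiff(c("subject_id", "condition"), names(meta))
  if (length(req)) {
    stop("metadata missing required columns: ", paste(req, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"rating" %in% names(meta)) {
    meta$rating <- suppressWarnings(as.numeric(meta$condition))
  }
  if (!"modality" %in% names(meta)) meta$modality <- "emotion"
  if (!"split" %in% names(meta)) meta$split <- "none"
  bad <- which(!apply(data, 1L, function(r) all(is.finite(r))))
  if (length(bad)) {
    stop(sprintf(
      "non-finite values inside the mask in %d observation(s) (first: row %d)",
      length(bad), bad[1]
    ), call. = FALSE)
  }
  if (rating_granularity == "rating") {
    key <- paste(meta$subject_id, meta$condition, meta$modality)
    if (anyDuplicated(key)) {
      stop("duplicate (subject, condition) pairs at rating-level granularity",
        call. = FALSE
      )
    }
  }
  structure(
    list(data = data, meta = meta, mask = mask,
         rating_granularity = rating_granularity),
    class = "beta_image_set"
  )
}

#' @export
print.beta_image_set <- function(x, ...) {
  cat(sprintf(
    "<beta_image_set> %d observations x %d voxels, %d subject(s), modality: %s\n",
    nrow(x$data), ncol(x$data), dplyr::n_distinct(x$meta$subject_id),
    paste(unique(x$meta$modality), collapse = "/")
  ))
  invisible(x)
}

#' @export
dim.beta_image_set <- function(x) dim(x$data)

#' Subset a beta image set by observation
#'
#' @param set a [beta_image_set()].
#' @param idx logical or integer index over observations.
#' @return A `beta_image_set` with the selected rows.
#' @export
subset_images <- function(set, idx) {
  stopifnot(inherits(set, "beta_image_set"))
  beta_image_set(set$data[idx, , drop = FALSE], set$meta[idx, , drop = FALSE],
    set$mask,
    rating_granularity = set$rating_granularity
  )
}

#' Read beta images from NIfTI files into a masked matrix
#'
#' Each file is checked against the mask's grid shape and affine; mismatches
#' must be fixed explicitly with [resample_grid()] first. NaN/Inf inside the
#' mask is an error naming the file and the number of voxels affected.
#'
#' @param image_table data frame with a `path` column plus the metadata
#'   columns of [beta_image_set()] (at least `subject_id`, `condition`).
#' @param mask shared [brain_mask()].
#' @param rating_granularity see [beta_image_set()].
#' @return A [beta_image_set()].
#' @export
read_image_set <- function(image_table, mask,
                           rating_granularity = c("rating", "trial")) {
  image_table <- tibble::as_tibble(image_table)
  if (!"path" %in% names(image_table)) {
    stop("`image_table` must have a `path` column", call. = FALSE)
  }
  if (!nrow(image_table)) stop("no images listed", call. = FALSE)
  rows <- lapply(seq_len(nrow(image_table)), function(i) {
    p <- image_table$path[i]
    img <- RNifti::readNifti(p)
    arr <- as.array(img)
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
    if (length(dim(arr)) != 3L || !all(dim(arr) == mask$grid_shape)) {
      stop(sprintf(
        "grid mismatch for '%s': image %s vs mask %s", p,
        paste(dim(arr), collapse = "x"),
        paste(mask$grid_shape, collapse = "x")
      ), call. = FALSE)
    }
    aff <- unclass(RNifti::xform(img))
    if (max(abs(aff - mask$affine)) > 1e-3) {
      stop(sprintf("affine mismatch for '%s'", p), call. = FALSE)
    }
    v <- vectorize(arr, mask)
    nbad <- sum(!is.finite(v))
    if (nbad > 0) {
      stop(sprintf(
        "'%s' has %d non-finite voxel(s) inside the mask", p, nbad
      ), call. = FALSE)
    }
    v
  })
  beta_image_set(do.call(rbind, rows),
    image_table[setdiff(names(image_table), "path")],
    mask,
    rating_granularity = rating_granularity
  )
}

#' Write a beta image set as one NIfTI file per observation
#'
#' @param set a [beta_image_set()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return tibble mapping observations to written paths.
#' @export
write_image_set <- function(set, dir, prefix = "beta") {
  stopifnot(inherits(set, "beta_image_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(set$data))
  for (i in seq_len(nrow(set$data))) {
    paths[i] <- file.path(dir, sprintf("%s_%04d.nii.gz", prefix, i))
    arr <- devectorize(set$data[i, ], set$mask)
    img <- RNifti::asNifti(arr)
    RNifti::qform(img) <- structure(set$mask$affine, code = 2L)
    RNifti::writeNifti(img, paths[i])
  }
  dplyr::bind_cols(set$meta, tibble::tibble(path = paths))
}
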