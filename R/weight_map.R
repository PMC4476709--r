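#' Signature weight maps
#'
#' A `weight_map` is a voxel weight vector plus a scalar intercept on a mask
#' grid. Applied to an activation image by dot product it yields a scalar
#' pattern response in the units the map was trained on (rating units, for a
#' map trained on affect ratings).
#'
#' @param weights numeric vector of length `mask$n_voxels`.
#' @param mask a [brain_mask()].
#' @param intercept finite scalar added to dot-product responses.
#' @param provenance free-text description of how the map was trained.
#' @return A `weight_map`.
#' @export
weight_map <- function(weights, mask, intercept = 0, provenance = "") {
  stopifnot(inherits(mask, "brain_mask"))
  weights <- as.numeric(weights)
  if (length(weights) != mask$n_voxels) {
    stop("weights length must equal mask voxel count", call. = FALSE)
  }
  if (!is.finite(intercept)) stop("intercept must be finite", call. = FALSE)
  structure(
    list(weights = weights, intercept = as.numeric(intercept), mask = mask,
         provenance = provenance),
    class = "weight_map"
  )
}

#' @export
print.weight_map <- function(x, ...) {
  cat(sprintf(
    "<weight_map> %d voxels (%d non-zero), intercept %.4g\n",
    length(x$weights), sum(x$weights != 0), x$intercept
  ))
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Write a weight map to NIfTI with a JSON sidecar
#'
#' Out-of-mask voxels are written as zero. NIfTI has no slot for the
#' intercept, so it goes in `<path>.json` alongside the provenance string;
#' [read_weight_map()] restores both.
#'
#' @param map a [weight_map()].
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_weight_map <- function(map, path) {
  stopifnot(inherits(map, "weight_map"))
  arr <- devectorize(map$weights, map$mask)
  img <- RNifti::asNifti(arr)
  RNifti::qform(img) <- structure(map$mask$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(
    list(intercept = map$intercept, provenance = map$provenance),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a weight map written by [write_weight_map()]
#'
#' @param path NIfTI path; `<path>.json` sidecar read when present
#'   (intercept 0 otherwise).
#' @param mask mask restricting the map; defaults to all non-zero voxels of
#'   the stored image.
#' @return A [weight_map()].
#' @export
read_weight_map <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  aff <- unclass(RNifti::xform(img))
  if (is.null(mask)) {
    mask <- brain_mask(array(TRUE, dim = dim(arr)), affine = aff)
  } else if (!all(dim(arr) == mask$grid_shape)) {
    stop("stored map grid does not match mask", call. = FALSE)
  }
  side <- sidecar_path(path)
  intercept <- 0
  provenance <- ""
  if (file.exists(side)) {
    js <- jsonlite::read_json(side)
    if (!is.null(js$intercept)) intercept <- as.numeric(js$intercept)
    if (!is.null(js$provenance)) provenance <- as.character(js$provenance)
  }
  weight_map(vectorize(arr, mask), mask, intercept = intercept,
    provenance = provenance
  )
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}
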