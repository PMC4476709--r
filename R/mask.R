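#' Brain masks
#'
#' A `brain_mask` fixes the voxel space every other object in the package
#' lives on: a 3-D inclusion grid, its shape, a 4x4 voxel-to-world affine
#' (mm), and a deterministic linear ordering of the included voxels.
#' Vectorization follows R's native column-major layout (first axis fastest)
#' over the `TRUE` cells, so two loads of the same mask always agree on the
#' ordering.
#'
#' @param inclusion logical 3-D array (or numeric, non-zero = included).
#' @param affine 4x4 voxel-to-world transform in mm. Defaults to an identity
#'   spacing of 1 mm with a 0-based voxel origin.
#' @return An object of class `brain_mask` with fields `inclusion`,
#'   `grid_shape`, `affine`, `n_voxels`.
#' @examples
#' m <- brain_mask(array(TRUE, dim = c(4, 4, 4)))
#' m$n_voxels
#' @export
brain_mask <- function(inclusion, affine = NULL) {
  if (length(dim(inclusion)) != 3L) {
    stop("`inclusion` must be a 3-D array", call. = FALSE)
  }
  inc <- array(as.logical(inclusion) & !is.na(inclusion), dim = dim(inclusion))
  if (is.null(affine)) {
    affine <- diag(4)
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine[1:3, 1:3])) < .Machine$double.eps) {
    stop("`affine` must be an invertible 4x4 matrix", call. = FALSE)
  }
  structure(
    list(
      inclusion = inc,
      grid_shape = dim(inc),
      affine = affine,
      n_voxels = sum(inc)
    ),
    class = "brain_mask"
  )
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf(
    "<brain_mask> grid %s, %d in-mask voxels\n",
    paste(x$grid_shape, collapse = "x"), x$n_voxels
  ))
  invisible(x)
}

#' Read a binary mask from a NIfTI file
#'
#' Non-zero voxels are included. The affine is taken from the image header.
#'
#' @param path path to a NIfTI-1 file.
#' @return A [brain_mask()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  brain_mask(arr != 0, affine = unclass(RNifti::xform(img)))
}

#' Write a mask to a NIfTI file
#'
#' @param mask a [brain_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "brain_mask"))
  img <- RNifti::asNifti(array(as.numeric(mask$inclusion), dim = mask$grid_shape))
  RNifti::qform(img) <- structure(mask$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Vectorize and devectorize masked images
#'
#' `vectorize()` extracts the in-mask voxels of a 3-D grid as a vector in the
#' mask's fixed ordering; `devectorize()` writes such a vector back into a
#' full grid, filling out-of-mask voxels with `fill`.
#'
#' @param grid a 3-D array on the mask's grid.
#' @param mask a [brain_mask()].
#' @param v a numeric vector of length `mask$n_voxels`.
#' @param fill value for out-of-mask voxels.
#' @return `vectorize()`: a numeric vector; `devectorize()`: a 3-D array.
#' @export
vectorize <- function(grid, mask) {
  stopifnot(inherits(mask, "brain_mask"))
  if (!all(dim(grid) == mask$grid_shape)) {
    stop("grid shape does not match mask", call. = FALSE)
  }
  as.numeric(grid[mask$inclusion])
}

#' @rdname vectorize
#' @export
devectorize <- function(v, mask, fill = 0) {
  stopifnot(inherits(mask, "brain_mask"))
  if (length(v) != mask$n_voxels) {
    stop("vector length does not match mask voxel count", call. = FALSE)
  }
  out <- array(fill, dim = mask$grid_shape)
  out[mask$inclusion] <- v
  out
}

#' Voxel coordinates of in-mask voxels
#'
#' @param mask a [brain_mask()].
#' @return integer matrix (n_voxels x 3) of 0-based voxel indices, in the
#'   mask's vectorization order.
#' @export
mask_coordinates <- function(mask) {
  stopifnot(inherits(mask, "brain_mask"))
  which(mask$inclusion, arr.ind = TRUE) - 1L
}

same_grid <- function(a, b, tol = 1e-4) {
  all(a$grid_shape == b$grid_shape) && max(abs(a$affine - b$affine)) < tol
}

check_same_mask <- function(a, b, what = "objects") {
  if (!same_grid(a, b) || !identical(a$inclusion, b$inclusion)) {
    stop(sprintf("%s are not defined on the same mask", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Resample a mask or image grid to a target mask's grid
#'
#' Masks (and other label grids) are resampled by nearest-neighbour lookup;
#' continuous maps by trilinear interpolation. Both operate through the
#' affines: each target voxel centre is mapped to world space and then into
#' the source voxel grid.
#'
#' @param grid 3-D array to resample.
#' @param from [brain_mask()] (or any object with `affine` and `grid_shape`)
#'   describing the source grid.
#' @param to target [brain_mask()].
#' @param method `"nearest"` or `"trilinear"`.
#' @return 3-D array on `to`'s grid.
#' @export
resample_grid <- function(grid, from, to, method = c("nearest", "trilinear")) {
  method <- match.arg(method)
  shp <- to$grid_shape
  idx <- as.matrix(expand.grid(
    i = seq_len(shp[1]) - 1L, j = seq_len(shp[2]) - 1L, k = seq_len(shp[3]) - 1L
  ))
  world <- cbind(idx, 1) %*% t(to$affine)
  src <- world %*% t(solve(from$affine))
  src <- src[, 1:3, drop = FALSE]
  out <- numeric(nrow(src))
  d <- dim(grid)
  if (method == "nearest") {
    p <- round(src) + 1
    ok <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    out[ok] <- grid[cbind(p[ok, 1], p[ok, 2], p[ok, 3])]
  } else {
    f <- floor(src)
    w <- src - f
    for (dx in 0:1) {
      for (dy in 0:1) {
        for (dz in 0:1) {
          p <- f + rep(c(dx, dy, dz), each = nrow(f)) + 1
          wt <- (dx * w[, 1] + (1 - dx) * (1 - w[, 1])) *
            (dy * w[, 2] + (1 - dy) * (1 - w[, 2])) *
            (dz * w[, 3] + (1 - dz) * (1 - w[, 3]))
          ok <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
            p[, 3] >= 1 & p[, 3] <= d[3]
          val <- numeric(nrow(p))
          val[ok] <- grid[cbind(p[ok, 1], p[ok, 2], p[ok, 3])]
          out <- out + wt * val
        }
      }
    }
  }
  array(out, dim = shp)
}
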