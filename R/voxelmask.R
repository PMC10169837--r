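## Volumetric binary masks with isotropic voxels. World convention (used
## everywhere in the package): voxel indices are 0-based with the corner of
## voxel (0,0,0) at `origin`, so world = origin + index * voxel_size and a
## point p falls in voxel floor((p - origin) / voxel_size). Geometric tests
## (ball removal, phantom shapes) use voxel centers.

#' Construct a voxel mask
#'
#' @param grid 3-D logical array.
#' @param voxel_size isotropic voxel edge length, um.
#' @param origin world coordinate (um) of the corner of voxel (0,0,0).
#' @return object of class `voxel_mask`.
#' @export
voxel_mask <- function(grid, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(is.array(grid), length(dim(grid)) == 3, is.logical(grid),
            length(voxel_size) == 1, voxel_size > 0, length(origin) == 3)
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<voxel_mask> %dx%dx%d voxels, %.6g um/voxel, %d foreground (%.4g mm^3)\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$grid),
              mask_volume(x) * 1e-9))
  invisible(x)
}

#' Foreground volume of a mask
#'
#' @param mask a `voxel_mask`.
#' @return volume in um^3 (voxel count times voxel volume).
#' @export
mask_volume <- function(mask) sum(mask$grid) * mask$voxel_size^3

#' Convert between world coordinates and voxel indices
#'
#' `world_to_voxel` maps points (um) to 0-based voxel indices;
#' `voxel_centers_axes` returns the per-axis voxel-center coordinates.
#'
#' @param mask a `voxel_mask`.
#' @param points numeric matrix (n x 3) of world positions, um.
#' @return integer matrix (n x 3) of 0-based voxel indices.
#' @export
world_to_voxel <- function(mask, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  idx <- floor(sweep(points, 2, mask$origin) / mask$voxel_size)
  storage.mode(idx) <- "integer"
  idx
}

voxel_centers_axes <- function(mask) {
  d <- dim(mask$grid)
  lapply(1:3, function(a) {
    mask$origin[a] + (seq_len(d[a]) - 0.5) * mask$voxel_size
  })
}

#' Test whether world points fall inside the mask foreground
#'
#' @param mask a `voxel_mask`.
#' @param points numeric matrix (n x 3), um.
#' @return logical vector; `FALSE` for points outside the grid.
#' @export
points_in_mask <- function(mask, points) {
  idx <- world_to_voxel(mask, points)
  d <- dim(mask$grid)
  ok <- idx[, 1] >= 0 & idx[, 1] < d[1] &
        idx[, 2] >= 0 & idx[, 2] < d[2] &
        idx[, 3] >= 0 & idx[, 3] < d[3]
  out <- logical(nrow(idx))
  if (any(ok)) {
    lin <- 1 + idx[ok, 1] + d[1] * (idx[ok, 2] + d[2] * idx[ok, 3])
    out[ok] <- mask$grid[lin]
  }
  out
}

#' Euclidean distance transform of a mask
#'
#' Distance (um) from each foreground voxel to the nearest background
#' voxel, exact in the voxel-center metric. Background voxels get 0.
#' Voxels of a foreground region touching the array boundary measure
#' distance to background inside the array only; masks produced by the
#' phantom are padded so this never matters.
#'
#' @param mask a `voxel_mask`.
#' @return numeric 3-D array of distances, um.
#' @export
distance_transform <- function(mask) {
  d2 <- edt_squared_cpp(as.logical(mask$grid), dim(mask$grid))
  array(sqrt(d2) * mask$voxel_size, dim = dim(mask$grid))
}
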