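# Resampling between grids (the stand-in for offline co-registration): the
# target grid's voxel centres are mapped through the inverse of the given
# rigid transform into the source volume and interpolated there.

# Trilinear interpolation of `arr` at continuous 1-based voxel indices
# (n x 3). Out-of-field points get `fill`.
interp_trilinear <- function(arr, idx, fill = 0) {
  d <- dim(arr)
  i0 <- floor(idx)
  f <- idx - i0
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
            idx[, 2] >= 1 & idx[, 2] <= d[2] &
            idx[, 3] >= 1 & idx[, 3] <= d[3]
  # clamp corner indices so edge voxels interpolate against themselves
  cl <- function(v, n) pmin(pmax(v, 1), n)
  x0 <- cl(i0[, 1], d[1]); x1 <- cl(i0[, 1] + 1, d[1])
  y0 <- cl(i0[, 2], d[2]); y1 <- cl(i0[, 2] + 1, d[2])
  z0 <- cl(i0[, 3], d[3]); z1 <- cl(i0[, 3] + 1, d[3])
  at <- function(ix, iy, iz) arr[cbind(ix, iy, iz)]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  v <-
    at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x1, y0, z0) * fx       * (1 - fy) * (1 - fz) +
    at(x0, y1, z0) * (1 - fx) * fy       * (1 - fz) +
    at(x1, y1, z0) * fx       * fy       * (1 - fz) +
    at(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    at(x1, y0, z1) * fx       * (1 - fy) * fz +
    at(x0, y1, z1) * (1 - fx) * fy       * fz +
    at(x1, y1, z1) * fx       * fy       * fz
  v[!inside] <- fill
  v
}

interp_nearest <- function(arr, idx, fill = 0) {
  d <- dim(arr)
  i <- round(idx)
  inside <- i[, 1] >= 1 & i[, 1] <= d[1] &
            i[, 2] >= 1 & i[, 2] <= d[2] &
            i[, 3] >= 1 & i[, 3] <= d[3]
  v <- rep(fill, nrow(i))
  v[inside] <- arr[i[inside, , drop = FALSE]]
  v
}

# All voxel-centre world coordinates of a grid, as an (prod(dim) x 3) matrix
# in R's column-major array order.
grid_points <- function(geom) {
  g <- as_grid_geometry(geom)
  xs <- axis_coords(g, 1); ys <- axis_coords(g, 2); zs <- axis_coords(g, 3)
  cbind(rep(xs, times = g$dim[2] * g$dim[3]),
        rep(rep(ys, each = g$dim[1]), times = g$dim[3]),
        rep(zs, each = g$dim[1] * g$dim[2]))
}

#' Resample a volume onto a target grid under a rigid transform
#'
#' The transform maps source-space anatomy to target space (e.g. the session
#' repositioning); each target voxel centre is pulled back through its
#' inverse and the source volume is interpolated there. With the identity
#' transform and an identical grid the input is returned bit-exactly.
#'
#' @param src Source `na_volume`.
#' @param target_grid Target geometry ([grid_geometry()] or a volume).
#' @param transform A [rigid_transform()]; default identity.
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @param fill Value for target voxels outside the source field of view.
#' @return An `na_volume` on the target grid.
#' @export
resample_to_grid <- function(src, target_grid,
                             transform = rigid_transform(),
                             interpolation = c("trilinear", "nearest"),
                             fill = 0) {
  stopifnot(inherits(src, "na_volume"))
  interpolation <- match.arg(interpolation)
  g <- as_grid_geometry(target_grid)
  sg <- as_grid_geometry(src)
  identity_tf <- all(transform$translation == 0) &&
    all(transform$rotation_deg == 0) && is.null(transform$rotation_matrix)
  if (identity_tf && identical(g$dim, sg$dim) &&
      isTRUE(all.equal(g$spacing, sg$spacing)) &&
      isTRUE(all.equal(g$origin, sg$origin))) {
    return(src)
  }
  pts <- grid_points(g)
  src_pts <- if (identity_tf) pts else apply_transform(invert_transform(transform), pts)
  idx <- world_to_voxel(src, src_pts)
  vals <- switch(interpolation,
                 trilinear = interp_trilinear(src$data, idx, fill = fill),
                 nearest = interp_nearest(src$data, idx, fill = fill))
  volume(array(vals, dim = g$dim), spacing = g$spacing, origin = g$origin)
}
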