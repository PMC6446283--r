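# Volume data model: axis-aligned 3D grids with voxel spacing and a world
# origin (mm, centre of voxel index (1,1,1) in R's 1-based convention; the
# NIfTI header stores the equivalent 0-based mapping). Sufficient for the
# synthetic cohort; oblique acquisitions are declared unsupported.

#' Construct a 3D volume
#'
#' @param data 3D numeric (or integer, for label volumes) array.
#' @param spacing Voxel spacing per axis (mm), length 3, all > 0.
#' @param origin World coordinates (mm) of the centre of the first voxel,
#'   length 3. Default `c(0, 0, 0)`.
#' @return An object of class `na_volume`.
#' @export
volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop_invalid("data must be a 3D array")
  }
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_invalid("spacing must be 3 positive numbers (mm)")
  }
  if (length(origin) != 3 || any(!is.finite(origin))) {
    stop_invalid("origin must be 3 finite numbers (mm)")
  }
  if (any(!is.finite(data))) stop_invalid("volume intensities must be finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "na_volume")
}

#' @export
print.na_volume <- function(x, ...) {
  cat(sprintf("<na_volume> %s voxels @ %s mm, origin (%s) mm, range [%g, %g]\n",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Describe a grid geometry without allocating data
#'
#' @param dim Integer grid dimensions, length 3.
#' @param spacing Voxel spacing (mm), length 3.
#' @param origin World coordinates (mm) of the first voxel centre.
#' @return A `grid_geometry` list.
#' @export
grid_geometry <- function(dim, spacing, origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1))
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3, all(spacing > 0), length(origin) == 3)
  structure(list(dim = dim, spacing = spacing, origin = origin),
            class = "grid_geometry")
}

#' @rdname grid_geometry
#' @param x A volume or grid geometry.
#' @export
as_grid_geometry <- function(x) {
  if (inherits(x, "grid_geometry")) return(x)
  if (inherits(x, "na_volume")) {
    return(grid_geometry(dim(x$data), x$spacing, x$origin))
  }
  stop_invalid("cannot interpret object as a grid geometry")
}

#' Map world coordinates (mm) to continuous voxel indices
#'
#' Voxel-centre addressing: the centre of voxel `(1,1,1)` maps to the volume
#' origin. `world_to_voxel` and `voxel_to_world` are mutual inverses.
#'
#' @param vol A volume or grid geometry.
#' @param points Numeric matrix (n x 3) or length-3 vector of world mm.
#' @return An n x 3 matrix of continuous (1-based) voxel indices.
#' @export
world_to_voxel <- function(vol, points) {
  g <- as_grid_geometry(vol)
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  sweep(sweep(pts, 2, g$origin, "-"), 2, g$spacing, "/") + 1
}

#' @rdname world_to_voxel
#' @param index n x 3 matrix or length-3 vector of continuous voxel indices.
#' @export
voxel_to_world <- function(vol, index) {
  g <- as_grid_geometry(vol)
  idx <- if (is.matrix(index)) index else matrix(index, ncol = 3)
  sweep(sweep(idx - 1, 2, g$spacing, "*"), 2, g$origin, "+")
}

# World coordinates of all voxel centres along one axis.
axis_coords <- function(g, axis) {
  g$origin[axis] + (seq_len(g$dim[axis]) - 1) * g$spacing[axis]
}

# World centre of the volume (midpoint of the voxel-centre bounding box);
# used as the default rotation centre of rigid transforms.
volume_center <- function(vol) {
  g <- as_grid_geometry(vol)
  g$origin + (g$dim - 1) * g$spacing / 2
}

#' Read / write axis-aligned NIfTI-1 volumes
#'
#' Thin wrappers around RNifti keeping the `na_volume` convention (spacing in
#' mm, origin = world position of the first voxel centre). Only axis-aligned
#' orientations with positive spacing are supported; anything oblique raises
#' an error rather than silently reinterpreting the grid.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_nifti` returns an `na_volume`; `write_nifti` returns `path`
#'   invisibly.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop_invalid("malformed NIfTI file '",
                                                   path, "': ", conditionMessage(e)))
  if (length(dim(img)) != 3) stop_invalid("expected a 3D NIfTI volume")
  arr <- array(as.numeric(img), dim = dim(img))
  m <- RNifti::xform(img)
  rot <- m[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot))))) {
    stop_invalid("unsupported orientation: NIfTI volume is not axis-aligned")
  }
  if (any(diag(rot) <= 0)) {
    stop_invalid("unsupported orientation: negative/zero axis scaling")
  }
  volume(arr, spacing = diag(rot), origin = m[1:3, 4])
}

#' @rdname read_nifti
#' @param vol An `na_volume`.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "na_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
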