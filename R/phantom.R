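# Digital head phantom: geometric primitives rasterised on a fine anatomical
# grid (1 mm default), with an external cylindrical reference tube. The
# geometry is simulator plumbing — sized so that the default landmarks sit
# deep inside region cores — not an anatomical atlas.

#' Phantom configuration
#'
#' Defines the anatomical grid, the sodium grid spacing, and the geometric
#' primitives of the digital head phantom. Primitives are painted in list
#' order (later primitives override earlier ones where they overlap);
#' internal structures are clipped to the head ellipsoid, the reference tube
#' is required to lie outside it.
#'
#' Default geometry (world mm, head centred at the origin): head/GM ellipsoid
#' radii (60, 72, 54); WM core ellipsoid (42, 54, 38); bilateral caudate-head
#' spheres r = 10 at (+/-27, 8, 0); midline pons sphere r = 11 at
#' (0, -30, -28); bilateral cerebellum spheres r = 11 at (+/-21, -36, -24);
#' bilateral ventricle (CSF) ellipsoids (9, 14, 8) at (+/-10, 28, 4);
#' reference cylinder (z axis) r = 12, half-length 30 at (82, 0, -10).
#'
#' @param anat_spacing_mm Anatomical grid spacing (mm). Default 1.
#' @param sodium_spacing_mm Sodium grid spacing (mm); must be coarser than the
#'   anatomical spacing. Default 3.6.
#' @param primitives List of primitives from [ellipsoid_primitive()] /
#'   [sphere_primitive()] / [cylinder_primitive()]; `NULL` for the default
#'   head phantom.
#' @param margin_mm Air margin added around the primitives when deriving the
#'   grid extent. Default 8 (covers the PSF support plus repositioning).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(anat_spacing_mm = 1, sodium_spacing_mm = 3.6,
                           primitives = NULL, margin_mm = 8) {
  check_scalar(anat_spacing_mm, "anat_spacing_mm", positive = TRUE)
  check_scalar(sodium_spacing_mm, "sodium_spacing_mm", positive = TRUE)
  if (sodium_spacing_mm <= anat_spacing_mm) {
    stop_invalid("sodium grid must be coarser than the anatomical grid")
  }
  if (is.null(primitives)) primitives <- default_primitives()
  if (length(primitives) == 0) stop_invalid("primitive list must not be empty")
  labs <- vapply(primitives, function(p) p$label, 0L)
  if (anyDuplicated(labs)) stop_invalid("primitive labels must be unique")
  if (any(labs <= 0)) stop_invalid("labels must be positive (0 = background)")
  # grid extent from primitive bounding boxes + margin; the lower corner is
  # aligned so both grids place a voxel centre exactly at world 0 per axis,
  # making left/right sampling mirror-symmetric about the midline
  bb <- sapply(primitives, primitive_bbox)   # 6 x n: xmin..zmin, xmax..zmax
  align <- alignment_step(anat_spacing_mm, sodium_spacing_mm)
  lo <- floor((apply(bb[1:3, , drop = FALSE], 1, min) - margin_mm) / align) *
    align
  hi <- apply(bb[4:6, , drop = FALSE], 1, max) + margin_mm
  dim_anat <- as.integer(floor((hi - lo) / anat_spacing_mm)) + 1L
  anat <- grid_geometry(dim_anat, rep(anat_spacing_mm, 3), lo)
  dim_na <- as.integer(floor((hi - lo) / sodium_spacing_mm)) + 1L
  sodium <- grid_geometry(dim_na, rep(sodium_spacing_mm, 3), lo)
  structure(list(anat_grid = anat, sodium_grid = sodium,
                 primitives = primitives,
                 anat_spacing_mm = anat_spacing_mm,
                 sodium_spacing_mm = sodium_spacing_mm),
            class = "phantom_config")
}

#' Phantom primitives
#'
#' @param name Region instance name, e.g. `"HCN_left"`.
#' @param region Compartment name it maps to (must exist in the compartment
#'   library), e.g. `"HCN"`.
#' @param side `"left"`, `"right"` or `"midline"`.
#' @param center Length-3 world centre (mm).
#' @param radii Length-3 semi-axes (mm) for ellipsoids.
#' @param label Unique positive integer label.
#' @param clip_to_head Intersect with the first primitive (the head)?
#' @return A primitive list usable in [phantom_config()].
#' @export
ellipsoid_primitive <- function(name, region, side, center, radii, label,
                                clip_to_head = TRUE) {
  stopifnot(length(center) == 3, length(radii) == 3, all(radii > 0))
  list(name = name, region = region, side = side, type = "ellipsoid",
       center = as.numeric(center), radii = as.numeric(radii),
       label = as.integer(label), clip_to_head = clip_to_head)
}

#' @rdname ellipsoid_primitive
#' @param radius Sphere/cylinder radius (mm).
#' @export
sphere_primitive <- function(name, region, side, center, radius, label,
                             clip_to_head = TRUE) {
  ellipsoid_primitive(name, region, side, center, rep(radius, 3), label,
                      clip_to_head = clip_to_head)
}

#' @rdname ellipsoid_primitive
#' @param half_length Cylinder half-length along its axis (mm).
#' @param axis Cylinder axis (1, 2 or 3).
#' @export
cylinder_primitive <- function(name, region, side, center, radius, half_length,
                               label, axis = 3, clip_to_head = FALSE) {
  stopifnot(length(center) == 3, radius > 0, half_length > 0, axis %in% 1:3)
  list(name = name, region = region, side = side, type = "cylinder",
       center = as.numeric(center), radius = radius, half_length = half_length,
       axis = as.integer(axis), label = as.integer(label),
       clip_to_head = clip_to_head)
}

default_primitives <- function() {
  list(
    ellipsoid_primitive("GM", "GM", "midline", c(0, 0, 0), c(60, 72, 54), 1L,
                        clip_to_head = FALSE),
    ellipsoid_primitive("WM", "WM", "midline", c(0, 0, 0), c(42, 54, 38), 2L),
    sphere_primitive("HCN_left",  "HCN", "left",  c(-27, 8, 0), 10, 3L),
    sphere_primitive("HCN_right", "HCN", "right", c(27, 8, 0), 10, 4L),
    sphere_primitive("pons", "pons", "midline", c(0, -30, -28), 11, 5L),
    sphere_primitive("cerebellum_left",  "cerebellum", "left",
                     c(-21, -36, -24), 11, 6L),
    sphere_primitive("cerebellum_right", "cerebellum", "right",
                     c(21, -36, -24), 11, 7L),
    ellipsoid_primitive("CSF_left",  "CSF", "left",  c(-10, 28, 4),
                        c(10, 15, 9), 8L),
    ellipsoid_primitive("CSF_right", "CSF", "right", c(10, 28, 4),
                        c(10, 15, 9), 9L),
    cylinder_primitive("reference", "reference", "midline", c(82, 0, -10),
                       radius = 12, half_length = 30, label = 10L)
  )
}

# Smallest step that is an integer multiple of both grid spacings (so a
# world point at a multiple of it is a voxel centre on both grids).
alignment_step <- function(anat, sodium) {
  for (k in 1:1000) {
    a <- k * sodium
    if (abs(a / anat - round(a / anat)) < 1e-9) return(a)
  }
  sodium
}

primitive_bbox <- function(p) {
  if (p$type == "ellipsoid") {
    c(p$center - p$radii, p$center + p$radii)
  } else {
    ext <- rep(p$radius, 3); ext[p$axis] <- p$half_length
    c(p$center - ext, p$center + ext)
  }
}

# Logical mask of one primitive on a grid geometry, built from separable
# per-axis coordinate vectors (no n x 3 point matrix needed).
primitive_mask <- function(p, g) {
  xs <- axis_coords(g, 1); ys <- axis_coords(g, 2); zs <- axis_coords(g, 3)
  if (p$type == "ellipsoid") {
    qx <- ((xs - p$center[1]) / p$radii[1])^2
    qy <- ((ys - p$center[2]) / p$radii[2])^2
    qz <- ((zs - p$center[3]) / p$radii[3])^2
    outer(outer(qx, qy, "+"), qz, "+") <= 1
  } else {
    ax <- p$axis; pl <- setdiff(1:3, ax)
    co <- list(xs, ys, zs)
    q1 <- (co[[pl[1]]] - p$center[pl[1]])^2
    q2 <- (co[[pl[2]]] - p$center[pl[2]])^2
    qa <- abs(co[[ax]] - p$center[ax]) <= p$half_length
    inplane <- outer(q1, q2, "+") <= p$radius^2
    # reorder the separable pieces into (x, y, z) array order
    dims <- g$dim
    arr <- array(FALSE, dims)
    if (ax == 3) {
      arr[] <- outer(as.vector(inplane), qa, "&")
    } else if (ax == 1) {
      arr[] <- aperm(array(outer(as.vector(inplane), qa, "&"),
                           c(dims[2], dims[3], dims[1])), c(3, 1, 2))
    } else {
      arr[] <- aperm(array(outer(as.vector(inplane), qa, "&"),
                           c(dims[1], dims[3], dims[2])), c(1, 3, 2))
    }
    arr
  }
}

#' Rasterise the phantom into an anatomical label volume
#'
#' Paints every primitive in order (later primitives take precedence);
#' internal structures are intersected with the head (first primitive). The
#' reference tube must be disjoint from the head and every configured region
#' must be non-empty.
#'
#' @param config A [phantom_config()].
#' @return An `na_volume` of integer labels (0 = background) with the
#'   primitive table attached as attribute `"regions"`.
#' @export
build_label_volume <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  g <- config$anat_grid
  lab <- array(0L, g$dim)
  head_mask <- NULL
  for (i in seq_along(config$primitives)) {
    p <- config$primitives[[i]]
    m <- primitive_mask(p, g)
    if (i == 1) head_mask <- m
    if (p$clip_to_head) {
      if (is.null(head_mask)) stop_invalid("no head primitive to clip against")
      m <- m & head_mask
    }
    if (p$region == "reference" && any(m & head_mask)) {
      stop_invalid("reference tube overlaps the head")
    }
    if (!any(m)) stop_invalid("primitive '", p$name, "' rasterises to zero voxels")
    lab[m] <- p$label
  }
  for (p in config$primitives) {
    if (!any(lab == p$label)) {
      stop_invalid("region '", p$name, "' fully overpainted by later primitives")
    }
  }
  out <- volume(lab, spacing = g$spacing, origin = g$origin)
  attr(out, "regions") <- primitive_table(config)
  out
}

# Primitive metadata table (name, region, side, label) of a phantom config.
primitive_table <- function(config) {
  data.frame(
    name = vapply(config$primitives, `[[`, "", "name"),
    region = vapply(config$primitives, `[[`, "", "region"),
    side = vapply(config$primitives, `[[`, "", "side"),
    label = vapply(config$primitives, `[[`, 0L, "label"),
    stringsAsFactors = FALSE)
}

# Separable Gaussian blur (zero-padded) with sigma in mm per axis. For
# sparse inputs (label indicators) only the support's bounding box, padded by
# the kernel radius, is convolved.
gaussian_blur <- function(arr, sigma_mm, spacing) {
  d <- dim(arr)
  rr <- vapply(1:3, function(ax) {
    max(1L, as.integer(ceiling(3 * sigma_mm / spacing[ax])))
  }, 0L)
  nz <- which(arr != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) return(arr * 0)
  lo <- pmax(apply(nz, 2, min) - rr, 1L)
  hi <- pmin(apply(nz, 2, max) + rr, d)
  sub <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  for (ax in 1:3) {
    s_vox <- sigma_mm / spacing[ax]
    if (s_vox <= 0) next
    w <- exp(-0.5 * ((-rr[ax]:rr[ax]) / s_vox)^2)
    w <- w / sum(w)
    sub <- shift_convolve(sub, w, rr[ax], ax)
  }
  out <- array(0, d)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  out
}

shift_convolve <- function(arr, w, r, axis) {
  d <- dim(arr)
  n <- d[axis]
  acc <- array(0, d)
  idx_full <- lapply(d, seq_len)
  for (j in -r:r) {
    src <- idx_full; dst <- idx_full
    if (j >= 0) {
      dst[[axis]] <- seq_len(n - j) + j
      src[[axis]] <- seq_len(n - j)
    } else {
      dst[[axis]] <- seq_len(n + j)
      src[[axis]] <- seq_len(n + j) - j
    }
    piece <- acc[dst[[1]], dst[[2]], dst[[3]], drop = FALSE] +
      w[j + r + 1] * arr[src[[1]], src[[2]], src[[3]], drop = FALSE]
    acc[dst[[1]], dst[[2]], dst[[3]]] <- piece
  }
  acc
}
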