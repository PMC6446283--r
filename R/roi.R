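# ROI protocol: fixed-area circular ROIs (default 0.508 cm^2) replicated on
# three consecutive slices at named anatomic landmarks, placed per reader
# with in-plane jitter, extracted on the sodium grid. ROI geometry is defined
# in world millimetres and re-rasterised on whichever grid it is applied to
# (the grids differ: 1 mm anatomical vs 3.6 mm sodium).

#' Circular landmark ROI specification
#'
#' @param region Region name (e.g. `"GM"`, `"HCN"`, `"reference"`).
#' @param side `"left"`, `"right"` or `"midline"` (midline is reserved for
#'   the pons and the reference tube).
#' @param center Length-3 world centre (mm).
#' @param area_cm2 In-plane disc area (cm^2), > 0. Default 0.508
#'   (radius about 4.02 mm).
#' @param n_slices Number of consecutive slices, >= 1. Default 3.
#' @param axis Slice axis (1, 2 or 3). Default 3.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(region, side = "midline", center, area_cm2 = 0.508,
                     n_slices = 3, axis = 3) {
  stopifnot(is.character(region), length(center) == 3)
  if (!side %in% c("left", "right", "midline")) {
    stop_invalid("side must be left, right or midline")
  }
  if (side == "midline" && !region %in% c("pons", "reference")) {
    stop_invalid("side = midline is reserved for pons and reference (got '",
                 region, "')")
  }
  check_scalar(area_cm2, "area_cm2", positive = TRUE)
  stopifnot(n_slices >= 1, axis %in% 1:3)
  structure(list(region = region, side = side, center = as.numeric(center),
                 area_cm2 = area_cm2, n_slices = as.integer(n_slices),
                 axis = as.integer(axis)),
            class = "roi_spec")
}

#' In-plane radius of an ROI (mm)
#' @param spec A [roi_spec()].
#' @return Radius `sqrt(area / pi)` in mm.
#' @export
roi_radius_mm <- function(spec) sqrt(spec$area_cm2 * 100 / pi)

#' Rasterise a circular ROI on a grid
#'
#' The in-plane disc (radius `sqrt(area/pi)`) is replicated on `n_slices`
#' consecutive slices centred on the landmark slice (shifted inward at the
#' volume edge); a voxel belongs to the ROI iff its centre lies within the
#' disc radius of the ROI centre.
#'
#' @param spec A [roi_spec()].
#' @param grid A volume or [grid_geometry()].
#' @return A logical `na_volume` mask with attribute `"n_voxels"`.
#' @export
roi_mask <- function(spec, grid) {
  stopifnot(inherits(spec, "roi_spec"))
  g <- as_grid_geometry(grid)
  ax <- spec$axis; pl <- setdiff(1:3, ax)
  r <- roi_radius_mm(spec)
  lo <- voxel_to_world(g, c(1, 1, 1))
  hi <- voxel_to_world(g, g$dim)
  # the disc (and the slice stack) must fit inside the voxel-centre field
  if (any(spec$center[pl] - r < lo[pl] - 1e-9) ||
      any(spec$center[pl] + r > hi[pl] + 1e-9) ||
      spec$center[ax] < lo[ax] || spec$center[ax] > hi[ax]) {
    stop_invalid("ROI '", spec$region, "/", spec$side,
                 "' extends outside the field of view")
  }
  if (spec$n_slices > g$dim[ax]) {
    stop_invalid("ROI '", spec$region, "' requests more slices than the volume has")
  }
  k <- round(world_to_voxel(g, spec$center)[1, ax])
  k0 <- k - (spec$n_slices - 1) %/% 2
  k0 <- min(max(k0, 1), g$dim[ax] - spec$n_slices + 1)
  slices <- seq(k0, k0 + spec$n_slices - 1)
  co <- lapply(1:3, function(a) axis_coords(g, a))
  d1 <- (co[[pl[1]]] - spec$center[pl[1]])^2
  d2 <- (co[[pl[2]]] - spec$center[pl[2]])^2
  disc <- outer(d1, d2, "+") <= r^2
  mask <- array(FALSE, g$dim)
  idx <- lapply(g$dim, seq_len)
  idx[[ax]] <- slices
  if (ax == 3) {
    mask[idx[[1]], idx[[2]], idx[[3]]] <- disc
  } else if (ax == 1) {
    mask[idx[[1]], idx[[2]], idx[[3]]] <- aperm(
      array(disc, c(dim(disc), length(slices))), c(3, 1, 2))
  } else {
    mask[idx[[1]], idx[[2]], idx[[3]]] <- aperm(
      array(disc, c(dim(disc), length(slices))), c(1, 3, 2))
  }
  out <- volume(mask * 1L, spacing = g$spacing, origin = g$origin)
  out$data <- array(as.logical(out$data), g$dim)
  attr(out, "n_voxels") <- sum(mask)
  out
}

#' Mean signal over an ROI mask
#'
#' @param vol An `na_volume`.
#' @param mask Logical mask volume from [roi_mask()] (same grid).
#' @return Arithmetic mean of the masked voxels.
#' @export
extract_mean <- function(vol, mask) {
  stopifnot(inherits(vol, "na_volume"), inherits(mask, "na_volume"))
  if (!identical(dim(vol$data), dim(mask$data))) {
    stop_invalid("volume and mask are on different grids")
  }
  m <- as.logical(mask$data)
  if (!any(m)) stop_invalid("empty ROI mask")
  mean(vol$data[m])
}

#' Reader-dependent ROI placement
#'
#' Displaces the ROI centre in-plane by independent Normal(0, jitter_sd)
#' draws, emulating manual placement by a reader. The displacement is
#' deterministic for a given (seed, key, reader) triple.
#'
#' @param spec A [roi_spec()].
#' @param reader Reader identifier (e.g. `"R1"`).
#' @param jitter_sd In-plane placement SD (mm), >= 0.
#' @param seed Integer master seed.
#' @param key Context string making the draw unique per (subject, visit);
#'   default uses region/side only.
#' @return The displaced `roi_spec`.
#' @export
reader_place <- function(spec, reader, jitter_sd, seed,
                         key = paste(spec$region, spec$side, sep = "/")) {
  stopifnot(inherits(spec, "roi_spec"))
  check_scalar(jitter_sd, "jitter_sd", nonneg = TRUE)
  if (jitter_sd == 0) return(spec)
  pl <- setdiff(1:3, spec$axis)
  dxy <- with_seed(derive_seed(seed, paste0("jitter/", reader, "/", key)),
                   rnorm(2, 0, jitter_sd))
  center <- spec$center
  center[pl] <- center[pl] + dxy
  out <- spec
  out$center <- center
  out
}

#' Default landmark table
#'
#' The nine predetermined brain landmarks (bilateral GM, WM, caudate head,
#' cerebellum; midline pons) plus bilateral CSF (ventricles) and the
#' reference tube, in the default phantom's world coordinates.
#'
#' @return A data.frame with columns region, side, x_mm, y_mm, z_mm.
#' @export
default_landmarks <- function() {
  read_landmarks(system.file("extdata", "default_landmarks.csv",
                             package = "natsc", mustWork = TRUE))
}

#' Read / write a landmark table CSV
#'
#' Columns: region, side, x_mm, y_mm, z_mm. Round-trips losslessly.
#'
#' @param path CSV path.
#' @return `read_landmarks`: the validated data.frame.
#' @export
read_landmarks <- function(path) {
  lm <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "side", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(lm))
  if (length(miss)) {
    stop_invalid("landmark table missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- !lm$side %in% c("left", "right", "midline")
  if (any(bad)) {
    stop_invalid("invalid side value(s): ", paste(unique(lm$side[bad]), collapse = ", "))
  }
  lm
}

#' @rdname read_landmarks
#' @param landmarks Landmark data.frame.
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.csv(landmarks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Measure all ROIs across a cohort
#'
#' For every session and reader: places each landmark ROI (with reader
#' jitter), maps its centre through the session's known rigid transform,
#' rasterises it on the session's sodium grid, extracts the mean signal, and
#' converts it to concentration by [quantify_tsc()] against the session's own
#' reference-tube ROI mean. The reference ROI is placed (and jittered) per
#' reader from the `"reference"` landmark row, which must be present.
#'
#' @param cohort A `sodium_cohort` from [simulate_cohort()].
#' @param landmarks Landmark table (see [default_landmarks()]).
#' @param readers Character vector of reader ids. Default `c("R1","R2")`.
#' @param jitter_sd In-plane reader placement SD (mm). Default 1.
#' @param seed Integer seed for the jitter draws; default the cohort seed.
#' @param area_cm2,n_slices ROI geometry. Defaults 0.508 cm^2 on 3 slices.
#' @param ref_weights Passed to [quantify_tsc()].
#' @return A data.frame with one row per
#'   (subject, visit, reader, region, side): columns subject, visit, reader,
#'   region, side, mean_signal, concentration, n_voxels.
#' @export
measure_all <- function(cohort, landmarks = default_landmarks(),
                        readers = c("R1", "R2"), jitter_sd = 1,
                        seed = NULL, area_cm2 = 0.508, n_slices = 3,
                        ref_weights = c("reference", "tissue")) {
  stopifnot(inherits(cohort, "sodium_cohort"))
  ref_weights <- match.arg(ref_weights)
  if (is.null(seed)) seed <- cohort$seed
  if (!any(landmarks$region == "reference")) {
    stop_invalid("landmark table has no 'reference' row: cannot calibrate ",
                 "without the reference tube")
  }
  lib <- cohort$lib
  unknown <- setdiff(unique(landmarks$region),
                     c(names(lib$entries), "reference"))
  if (length(unknown)) {
    stop_invalid("landmark region(s) not in compartment library: ",
                 paste(unknown, collapse = ", "))
  }
  acq <- cohort$acq
  rows <- list()
  for (sess in cohort$sessions) {
    spec <- sess$spec
    img <- sess$image
    for (rd in readers) {
      specs <- lapply(seq_len(nrow(landmarks)), function(i) {
        l <- landmarks[i, ]
        s <- roi_spec(l$region, l$side, c(l$x_mm, l$y_mm, l$z_mm),
                      area_cm2 = area_cm2, n_slices = n_slices)
        reader_place(s, rd, jitter_sd, seed,
                     key = paste(spec$subject, spec$visit, l$region, l$side,
                                 sep = "/"))
      })
      # track the session's repositioning: the anatomy at world point p
      # appears at transform(p) in the session image
      place <- function(s) {
        s$center <- as.numeric(apply_transform(spec$transform, s$center))
        s
      }
      specs <- lapply(specs, place)
      is_ref <- landmarks$region == "reference"
      ref_mean <- mean(vapply(which(is_ref), function(i) {
        extract_mean(img, roi_mask(specs[[i]], img))
      }, 0.0))
      if (!is.finite(ref_mean) || ref_mean <= 0) {
        stop_invalid("reference-tube signal is not positive in session ",
                     spec$subject, "/", spec$visit)
      }
      for (i in which(!is_ref)) {
        s <- specs[[i]]
        msk <- roi_mask(s, img)
        m <- extract_mean(img, msk)
        conc <- quantify_tsc(m, ref_mean, lib$reference$concentration,
                             tiss = lib$entries[[s$region]]$relax,
                             ref = lib$reference$relax, acq = acq,
                             ref_weights = ref_weights)
        rows[[length(rows) + 1]] <- data.frame(
          subject = spec$subject, visit = spec$visit, reader = rd,
          region = s$region, side = s$side, mean_signal = m,
          concentration = conc, n_voxels = attr(msk, "n_voxels"),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Read / write a measurement table CSV
#'
#' @param path CSV path.
#' @return `read_measurements`: the validated data.frame.
#' @export
read_measurements <- function(path) {
  mt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "visit", "reader", "region", "side",
            "mean_signal", "concentration", "n_voxels")
  miss <- setdiff(need, names(mt))
  if (length(miss)) {
    stop_invalid("measurement table missing column(s): ",
                 paste(miss, collapse = ", "))
  }
  mt
}

#' @rdname read_measurements
#' @param measurements Measurement data.frame.
#' @export
write_measurements <- function(measurements, path) {
  df <- measurements
  for (cn in c("mean_signal", "concentration")) {
    df[[cn]] <- format(df[[cn]], digits = 17, scientific = FALSE, trim = TRUE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
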