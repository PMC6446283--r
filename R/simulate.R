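# Forward signal synthesis and cohort simulation.
#
# Noiseless voxel signal on the anatomical grid is
#   gain * concentration(label) * saturation_factor(TR, T1) * te_decay(TE, relax);
# the session's rigid repositioning is applied and the image is degraded to
# the sodium grid through an isotropic Gaussian PSF (FWHM = one sodium voxel)
# followed by sampling at the sodium voxel centres. Because an isotropic
# Gaussian commutes with rigid motion, the blur is computed once per phantom
# (per-label indicator volumes) and each session only re-samples it — exactly
# equivalent to displacing first and blurring afterwards.

#' Session specification
#'
#' One scan session: a global gain multiplier (scanner calibration drift),
#' rigid repositioning, and the Rician noise level.
#'
#' @param subject Subject identifier (e.g. `"S01"`).
#' @param visit Visit label: `"V1"`, `"V2"` (same day) or `"V3"` (8 days).
#' @param gain Global multiplicative gain, > 0.
#' @param transform A [rigid_transform()] describing head repositioning.
#' @param noise_sigma Rician noise sigma (signal units), >= 0.
#' @param seed Integer seed for the session's noise draw.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(subject, visit, gain = 1,
                         transform = rigid_transform(),
                         noise_sigma = 0, seed = 0L) {
  stopifnot(is.character(subject), visit %in% c("V1", "V2", "V3"))
  check_scalar(gain, "gain", positive = TRUE)
  check_scalar(noise_sigma, "noise_sigma", nonneg = TRUE)
  structure(list(subject = subject, visit = visit, gain = gain,
                 transform = transform, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "session_spec")
}

#' Precompute PSF-blurred label indicators
#'
#' Blurs each label's indicator volume with the isotropic Gaussian PSF
#' (FWHM = one sodium voxel). The result is reused across all sessions of a
#' cohort, since rigid motion commutes with the isotropic blur.
#'
#' @param labels Label `na_volume` from [build_label_volume()].
#' @param config The [phantom_config()].
#' @return A `phantom_cache` list with the blurred indicator arrays.
#' @export
phantom_cache <- function(labels, config) {
  stopifnot(inherits(labels, "na_volume"), inherits(config, "phantom_config"))
  fwhm <- config$sodium_spacing_mm
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  regions <- attr(labels, "regions")
  blurred <- lapply(regions$label, function(l) {
    gaussian_blur((labels$data == l) * 1.0, sigma, labels$spacing)
  })
  names(blurred) <- regions$name
  structure(list(labels = labels, regions = regions, blurred = blurred,
                 sigma_mm = sigma, config = config),
            class = "phantom_cache")
}

# Noiseless signal value of one region instance (label) given its
# concentration and relaxation constants.
label_signal <- function(conc, relax, acq, gain = 1) {
  gain * conc * saturation_factor(acq$tr_ms, relax$t1_ms) *
    te_decay(acq$te_ms, relax)
}

#' Synthesize a sodium-grid image for one session
#'
#' @param labels Label volume from [build_label_volume()] (used to build the
#'   PSF cache when `cache` is not supplied).
#' @param lib A `compartment_library` ([default_compartments()]).
#' @param acq An [acquisition_spec()].
#' @param session A [session_spec()]. Noise is NOT added here; see
#'   [add_rician_noise()].
#' @param config The [phantom_config()] (for the sodium grid geometry).
#' @param cache Optional [phantom_cache()] to reuse across sessions.
#' @param concentrations Optional named numeric vector of per-region-instance
#'   concentrations (names = primitive names, e.g. `"HCN_left"`); defaults to
#'   the library's region concentrations (reference tube gets the reference
#'   concentration).
#' @return A noiseless sodium-grid `na_volume`.
#' @export
synthesize_sodium_image <- function(labels, lib, acq, session, config,
                                    cache = NULL, concentrations = NULL) {
  stopifnot(inherits(lib, "compartment_library"),
            inherits(acq, "acquisition_spec"),
            inherits(session, "session_spec"))
  if (is.null(cache)) cache <- phantom_cache(labels, config)
  regions <- cache$regions
  unknown <- setdiff(regions$region, c(names(lib$entries), "reference"))
  if (length(unknown)) {
    stop_invalid("label(s) without compartment entry: ",
                 paste(unknown, collapse = ", "))
  }
  g <- config$sodium_grid
  pts <- grid_points(g)
  tf <- session$transform
  identity_tf <- all(tf$translation == 0) && all(tf$rotation_deg == 0) &&
    is.null(tf$rotation_matrix)
  src_pts <- if (identity_tf) pts else apply_transform(invert_transform(tf), pts)
  idx <- world_to_voxel(cache$labels, src_pts)
  sig <- numeric(nrow(pts))
  for (i in seq_len(nrow(regions))) {
    rn <- regions$name[i]
    region <- regions$region[i]
    conc <- if (!is.null(concentrations) && rn %in% names(concentrations)) {
      concentrations[[rn]]
    } else if (region == "reference") {
      lib$reference$concentration
    } else {
      lib$entries[[region]]$concentration
    }
    relax <- if (region == "reference") lib$reference$relax
             else lib$entries[[region]]$relax
    v <- label_signal(conc, relax, acq, gain = session$gain)
    sig <- sig + v * interp_trilinear(cache$blurred[[rn]], idx, fill = 0)
  }
  volume(array(sig, dim = g$dim), spacing = g$spacing, origin = g$origin)
}

#' Add Rician noise to a magnitude image
#'
#' Each voxel `v` is replaced by `|v + n1 + i n2|` with independent
#' `n1, n2 ~ Normal(0, sigma)` — the noise model of magnitude-reconstructed
#' MRI (Rayleigh in air, near-Gaussian at high SNR). `sigma = 0` returns the
#' input unchanged.
#'
#' @param vol An `na_volume`.
#' @param sigma Noise sigma in signal units, >= 0.
#' @param seed Integer seed; the draw is reproducible.
#' @return An `na_volume` of the same geometry.
#' @export
add_rician_noise <- function(vol, sigma, seed) {
  stopifnot(inherits(vol, "na_volume"))
  check_scalar(sigma, "sigma", nonneg = TRUE)
  if (sigma == 0) return(vol)
  n <- length(vol$data)
  noisy <- with_seed(seed, {
    n1 <- rnorm(n, 0, sigma)
    n2 <- rnorm(n, 0, sigma)
    sqrt((as.vector(vol$data) + n1)^2 + n2^2)
  })
  volume(array(noisy, dim = dim(vol$data)), vol$spacing, vol$origin)
}

#' Simulate a synthetic test-retest cohort
#'
#' Emulates the study design: `n_subjects` subjects, visits V1/V2 acquired
#' back-to-back on one day and V3 after an 8-day interval. A subject's
#' region concentrations are drawn once (Normal around the library means with
#' the between-subject SDs) and shared by all three visits; visits differ
#' only by session effects — gain drift, rigid repositioning, fresh Rician
#' noise. Everything derives deterministically from the master seed via
#' per-context sub-seeds, so cohorts are extensible without reshuffling.
#'
#' @param n_subjects Number of subjects, >= 1. Default 12.
#' @param seed Master integer seed.
#' @param config A [phantom_config()] (default phantom when `NULL`).
#' @param lib Compartment library; default [default_compartments()].
#' @param acq Acquisition; default [acquisition_spec()].
#' @param visits Visit labels to simulate. Default `c("V1","V2","V3")`.
#' @param between_subject_sd `NULL` to use the library SDs, or a single
#'   number / named vector (by region) overriding them.
#' @param gain_drift Half-width of the uniform gain drift. Default 0.02.
#' @param reposition_mm Half-width of uniform per-axis translations (mm).
#'   Default 2.
#' @param reposition_deg Half-width of uniform per-axis rotations (deg).
#'   Default 2.
#' @param noise_sigma Rician noise sigma (signal units). Default 2 (about
#'   SNR 20 in brain tissue with the default constants).
#' @param laterality_offset Optional named numeric vector: concentration
#'   added to the LEFT side of the named region(s), e.g. `c(HCN = 4)`.
#' @param cache Optional [phantom_cache()] to reuse.
#' @param images If `FALSE`, draw truths and session parameters but skip
#'   image synthesis (for parameter-level Monte-Carlo checks).
#' @return A `sodium_cohort` list: `sessions` (list of
#'   `list(spec, image)`), `truth` (data.frame subject/region/side/
#'   true_conc), plus the config, library, acquisition and cache used.
#' @export
simulate_cohort <- function(n_subjects = 12, seed = 1, config = NULL,
                            lib = default_compartments(),
                            acq = acquisition_spec(),
                            visits = c("V1", "V2", "V3"),
                            between_subject_sd = NULL,
                            gain_drift = 0.02,
                            reposition_mm = 2, reposition_deg = 2,
                            noise_sigma = 2,
                            laterality_offset = NULL,
                            cache = NULL, images = TRUE) {
  stopifnot(n_subjects >= 1, all(visits %in% c("V1", "V2", "V3")))
  check_scalar(gain_drift, "gain_drift", nonneg = TRUE)
  check_scalar(reposition_mm, "reposition_mm", nonneg = TRUE)
  check_scalar(reposition_deg, "reposition_deg", nonneg = TRUE)
  check_scalar(noise_sigma, "noise_sigma", nonneg = TRUE)
  if (is.null(config)) config <- phantom_config()
  if (is.null(cache)) {
    cache <- if (images) phantom_cache(build_label_volume(config), config)
             else list(labels = NULL, regions = primitive_table(config),
                       blurred = NULL, config = config)
  }
  regions <- cache$regions
  tissue_regions <- unique(regions$region[regions$region != "reference"])
  sd_of <- function(region) {
    if (is.null(between_subject_sd)) return(lib$entries[[region]]$sd)
    if (length(between_subject_sd) == 1 && is.null(names(between_subject_sd))) {
      return(as.numeric(between_subject_sd))
    }
    if (region %in% names(between_subject_sd)) {
      return(as.numeric(between_subject_sd[[region]]))
    }
    lib$entries[[region]]$sd
  }
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  center <- volume_center(config$sodium_grid)

  truth_rows <- list()
  sessions <- list()
  for (s in subjects) {
    subj_conc <- with_seed(derive_seed(seed, paste0("truth/", s)), {
      vapply(tissue_regions, function(rg) {
        max(rnorm(1, lib$entries[[rg]]$concentration, sd_of(rg)), 1e-3)
      }, 0.0)
    })
    # per region INSTANCE (primitive) concentration, with optional left offset
    inst_conc <- vapply(seq_len(nrow(regions)), function(i) {
      rg <- regions$region[i]
      if (rg == "reference") return(lib$reference$concentration)
      v <- subj_conc[[rg]]
      if (!is.null(laterality_offset) && rg %in% names(laterality_offset) &&
          regions$side[i] == "left") {
        v <- v + laterality_offset[[rg]]
      }
      v
    }, 0.0)
    names(inst_conc) <- regions$name
    for (i in seq_len(nrow(regions))) {
      if (regions$region[i] == "reference") next
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        subject = s, region = regions$region[i], side = regions$side[i],
        true_conc = inst_conc[[i]], stringsAsFactors = FALSE)
    }
    for (v in visits) {
      key <- paste0(s, "/", v)
      sess <- with_seed(derive_seed(seed, paste0("session/", key)), {
        session_spec(
          subject = s, visit = v,
          gain = 1 + runif(1, -gain_drift, gain_drift),
          transform = rigid_transform(
            translation = runif(3, -reposition_mm, reposition_mm),
            rotation_deg = runif(3, -reposition_deg, reposition_deg),
            center = center),
          noise_sigma = noise_sigma,
          seed = derive_seed(seed, paste0("noise/", key)))
      })
      img <- NULL
      if (images) {
        img <- synthesize_sodium_image(cache$labels, lib, acq, sess, config,
                                       cache = cache,
                                       concentrations = inst_conc)
        img <- add_rician_noise(img, sess$noise_sigma, sess$seed)
      }
      sessions[[key]] <- list(spec = sess, image = img,
                              concentrations = inst_conc)
    }
  }
  structure(list(sessions = sessions,
                 truth = do.call(rbind, truth_rows),
                 config = config, lib = lib, acq = acq, cache = cache,
                 seed = seed),
            class = "sodium_cohort")
}

#' @export
print.sodium_cohort <- function(x, ...) {
  subj <- unique(vapply(x$sessions, function(s) s$spec$subject, ""))
  vis <- unique(vapply(x$sessions, function(s) s$spec$visit, ""))
  cat(sprintf("<sodium_cohort> %d subjects x %d visits (%d sessions), seed %d\n",
              length(subj), length(vis), length(x$sessions), x$seed))
  invisible(x)
}
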