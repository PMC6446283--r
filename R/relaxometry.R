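# Relaxometry core: the relaxation-corrected, reference-phantom-calibrated
# conversion of sodium image signal to tissue sodium concentration (TSC).
#
# Sodium in tissue relaxes biexponentially (fast/slow transverse components
# with weights alfa/beta, a consequence of quadrupolar interactions); CSF and
# other free-fluid compartments are effectively monoexponential (alfa = 0).
# Quantification references the tissue signal against an external tube of
# known NaCl concentration imaged in the same field of view, correcting both
# compartments for T1 saturation at the sequence TR and for T2 decay at TE.

#' Relaxation parameters of one compartment
#'
#' Bundles the longitudinal relaxation time and the biexponential transverse
#' relaxation model (fast/slow times with their weights) of a tissue class or
#' of the reference phantom.
#'
#' @param t1_ms Longitudinal relaxation time T1 (ms), > 0.
#' @param t2_fast_ms Fast transverse component T2f (ms), > 0.
#' @param t2_slow_ms Slow transverse component T2s (ms), >= `t2_fast_ms`.
#' @param weight_fast Weight of the fast component ("alfa"), in `[0, 1]`.
#' @param weight_slow Weight of the slow component ("beta");
#'   `weight_fast + weight_slow` must equal 1 (tolerance 1e-9).
#' @return An object of class `relaxation_spec`.
#' @examples
#' brain <- relaxation_spec(t1_ms = 29, t2_fast_ms = 4, t2_slow_ms = 29,
#'                          weight_fast = 0.6, weight_slow = 0.4)
#' @export
relaxation_spec <- function(t1_ms, t2_fast_ms, t2_slow_ms,
                            weight_fast, weight_slow) {
  check_scalar(t1_ms, "t1_ms", positive = TRUE)
  check_scalar(t2_fast_ms, "t2_fast_ms", positive = TRUE)
  check_scalar(t2_slow_ms, "t2_slow_ms", positive = TRUE)
  check_scalar(weight_fast, "weight_fast", nonneg = TRUE)
  check_scalar(weight_slow, "weight_slow", nonneg = TRUE)
  if (t2_fast_ms > t2_slow_ms) {
    stop_invalid("t2_fast_ms must be <= t2_slow_ms")
  }
  if (abs(weight_fast + weight_slow - 1) > 1e-9) {
    stop_invalid("weight_fast + weight_slow must equal 1 (got ",
                 weight_fast + weight_slow, ")")
  }
  structure(list(t1_ms = t1_ms, t2_fast_ms = t2_fast_ms,
                 t2_slow_ms = t2_slow_ms, weight_fast = weight_fast,
                 weight_slow = weight_slow),
            class = "relaxation_spec")
}

#' @export
print.relaxation_spec <- function(x, ...) {
  cat(sprintf(
    "<relaxation_spec> T1 = %g ms; T2 = %g/%g ms (fast/slow); weights %g/%g\n",
    x$t1_ms, x$t2_fast_ms, x$t2_slow_ms, x$weight_fast, x$weight_slow))
  invisible(x)
}

#' Acquisition parameters of the sodium sequence
#'
#' @param tr_ms Repetition time (ms), > 0. Default 120.
#' @param te_ms Echo time (ms), >= 0. Default 0.2.
#' @param voxel_mm Isotropic voxel edge of the sodium grid (mm). Default 3.6.
#' @param flip_deg Flip angle (degrees); informational only, it does not enter
#'   the quantification formula.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(tr_ms = 120, te_ms = 0.2, voxel_mm = 3.6,
                             flip_deg = 87) {
  check_scalar(tr_ms, "tr_ms", positive = TRUE)
  check_scalar(te_ms, "te_ms", nonneg = TRUE)
  check_scalar(voxel_mm, "voxel_mm", positive = TRUE)
  check_scalar(flip_deg, "flip_deg")
  structure(list(tr_ms = tr_ms, te_ms = te_ms, voxel_mm = voxel_mm,
                 flip_deg = flip_deg),
            class = "acquisition_spec")
}

#' T1 saturation factor
#'
#' Fractional longitudinal recovery at repetition time TR:
#' `1 - exp(-TR/T1)`, strictly in (0, 1) and increasing in TR.
#'
#' @param tr_ms Repetition time (ms), > 0.
#' @param t1_ms Longitudinal relaxation time (ms), > 0.
#' @return Dimensionless scalar in (0, 1).
#' @export
saturation_factor <- function(tr_ms, t1_ms) {
  check_scalar(tr_ms, "tr_ms", positive = TRUE)
  check_scalar(t1_ms, "t1_ms", positive = TRUE)
  1 - exp(-tr_ms / t1_ms)
}

#' Biexponential transverse decay at the echo time
#'
#' `alfa * exp(-TE/T2f) + beta * exp(-TE/T2s)`, in (0, 1] and non-increasing
#' in TE; equals 1 at TE = 0.
#'
#' @param te_ms Echo time (ms), >= 0.
#' @param relax A [relaxation_spec()].
#' @return Dimensionless scalar in (0, 1].
#' @export
te_decay <- function(te_ms, relax) {
  check_scalar(te_ms, "te_ms", nonneg = TRUE)
  stopifnot(inherits(relax, "relaxation_spec"))
  relax$weight_fast * exp(-te_ms / relax$t2_fast_ms) +
    relax$weight_slow * exp(-te_ms / relax$t2_slow_ms)
}

#' Relaxation correction factor of the quantification equation
#'
#' The product of the T1-saturation ratio and the TE-decay ratio between the
#' reference compartment and the tissue compartment:
#' \deqn{\frac{1 - e^{-TR/T_1^{ref}}}{1 - e^{-TR/T_1^{tiss}}} \times
#'       \frac{\alpha_r e^{-TE/T_{2f}^{ref}} + \beta_r e^{-TE/T_{2s}^{ref}}}
#'            {\alpha_t e^{-TE/T_{2f}^{tiss}} + \beta_t e^{-TE/T_{2s}^{tiss}}}}
#'
#' By default (`ref_weights = "reference"`) each compartment's decay uses its
#' own fast/slow weights; for every brain-tissue compartment this coincides
#' with sharing a single alfa/beta pair because the shipped reference weights
#' equal the brain weights (0.6/0.4). `ref_weights = "tissue"` forces the
#' tissue compartment's weights onto the reference decay (the single-pair
#' reading of the formula), which differs only when quantifying
#' monoexponential compartments such as CSF.
#'
#' @param tiss [relaxation_spec()] of the tissue compartment.
#' @param ref [relaxation_spec()] of the reference phantom.
#' @param acq [acquisition_spec()].
#' @param ref_weights `"reference"` (default) or `"tissue"`; see Details.
#' @return Dimensionless scalar; equals 1 when `tiss` and `ref` are identical.
#' @export
correction_factor <- function(tiss, ref, acq, ref_weights = c("reference", "tissue")) {
  stopifnot(inherits(tiss, "relaxation_spec"), inherits(ref, "relaxation_spec"),
            inherits(acq, "acquisition_spec"))
  ref_weights <- match.arg(ref_weights)
  ref_eff <- if (ref_weights == "tissue") {
    relaxation_spec(ref$t1_ms, ref$t2_fast_ms, ref$t2_slow_ms,
                    tiss$weight_fast, tiss$weight_slow)
  } else ref
  (saturation_factor(acq$tr_ms, ref$t1_ms) /
     saturation_factor(acq$tr_ms, tiss$t1_ms)) *
    (te_decay(acq$te_ms, ref_eff) / te_decay(acq$te_ms, tiss))
}

#' Convert a sodium signal ratio to tissue sodium concentration
#'
#' The calibration equation: the tissue-to-reference signal ratio times the
#' known reference concentration times the relaxation [correction_factor()].
#' Output is in mmol/kg wet weight (the reference concentration in mmol/L is
#' treated as numerically interchangeable for calibration purposes).
#'
#' @param s_tiss Mean tissue ROI signal, >= 0 (vectorised).
#' @param s_ref Mean reference-tube ROI signal, > 0.
#' @param ref_conc Reference NaCl concentration (mmol/L).
#' @param tiss,ref [relaxation_spec()]s of tissue and reference.
#' @param acq [acquisition_spec()].
#' @param ref_weights Passed to [correction_factor()].
#' @return Concentration(s) in mmol/kg wet weight.
#' @examples
#' acq <- acquisition_spec()
#' lib <- default_compartments()
#' quantify_tsc(s_tiss = 40, s_ref = 100, ref_conc = lib$reference$concentration,
#'              tiss = lib$entries$WM$relax, ref = lib$reference$relax, acq = acq)
#' @export
quantify_tsc <- function(s_tiss, s_ref, ref_conc, tiss, ref, acq,
                         ref_weights = c("reference", "tissue")) {
  if (!is.numeric(s_ref) || length(s_ref) != 1 || !is.finite(s_ref) || s_ref <= 0) {
    stop_invalid("s_ref must be a positive scalar (reference signal); got ",
                 paste(s_ref, collapse = ","))
  }
  if (!is.numeric(s_tiss) || any(!is.finite(s_tiss)) || any(s_tiss < 0)) {
    stop_invalid("s_tiss must be finite and non-negative")
  }
  check_scalar(ref_conc, "ref_conc", positive = TRUE)
  (s_tiss / s_ref) * ref_conc *
    correction_factor(tiss, ref, acq, ref_weights = ref_weights)
}

#' Default compartment library
#'
#' The compartment constants used throughout: reference phantom T2 fast/slow
#' 7.15/33.7 ms with weights 0.6/0.4 and an assumed T1 of 35 ms (typical for
#' an aqueous NaCl phantom at 3 T; an assumption, not a measured value);
#' brain tissue T2 4/29 ms, weights 0.6/0.4, T1 29 ms; CSF monoexponential
#' T2 55 ms, T1 58.1 ms. Region ground-truth concentrations (mmol/kg wet
#' weight) and between-subject SDs are the healthy-cohort means the synthetic
#' generator emulates: GM 51.5 +/- 4.5, WM 40.9 +/- 3.8, HCN 60.9 +/- 8.1,
#' pons 39.8 +/- 5.3, cerebellum 40.1 +/- 4.9, CSF 102.1 +/- 21.6. The
#' reference tube holds 0.6 % NaCl = 102.67 mmol/L (6 g/L / 58.44 g/mol).
#'
#' Loaded from the shipped YAML config (`inst/extdata/default_config.yaml`);
#' see [load_compartments()].
#'
#' @return A `compartment_library`: list with `entries` (named list of
#'   `list(relax, concentration, sd)` per region) and `reference`
#'   (`list(relax, concentration)`).
#' @export
default_compartments <- function() {
  load_compartments(system.file("extdata", "default_config.yaml",
                                package = "natsc", mustWork = TRUE))
}

#' Load a compartment library from a YAML config
#'
#' The config nests constants by region name; each region carries `t1_ms`,
#' `t2_fast_ms`, `t2_slow_ms`, `weight_fast`, `weight_slow`, `concentration`
#' and optionally `sd` (between-subject SD used by the cohort simulator). A
#' `reference` block is mandatory. An `acquisition` block (tr_ms, te_ms,
#' voxel_mm, flip_deg) is returned alongside when present.
#'
#' @param path Path to the YAML file.
#' @return A `compartment_library` (see [default_compartments()]); if the file
#'   has an `acquisition` block it is attached as attribute `"acquisition"`.
#' @export
load_compartments <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$regions) || is.null(cfg$reference)) {
    stop_invalid("config must contain 'regions' and 'reference' blocks")
  }
  as_spec <- function(b, where) {
    need <- c("t1_ms", "t2_fast_ms", "t2_slow_ms", "weight_fast", "weight_slow")
    miss <- setdiff(need, names(b))
    if (length(miss)) {
      stop_invalid("config block '", where, "' missing field(s): ",
                   paste(miss, collapse = ", "))
    }
    relaxation_spec(b$t1_ms, b$t2_fast_ms, b$t2_slow_ms,
                    b$weight_fast, b$weight_slow)
  }
  entries <- lapply(names(cfg$regions), function(rn) {
    b <- cfg$regions[[rn]]
    check_scalar(b$concentration, paste0(rn, "$concentration"), positive = TRUE)
    list(relax = as_spec(b, rn),
         concentration = b$concentration,
         sd = if (is.null(b$sd)) 0 else b$sd)
  })
  names(entries) <- names(cfg$regions)
  if (anyDuplicated(names(entries))) stop_invalid("duplicate region names in config")
  required <- c("GM", "WM", "HCN", "pons", "cerebellum", "CSF")
  miss <- setdiff(required, names(entries))
  if (length(miss)) {
    stop_invalid("config must define region(s): ", paste(miss, collapse = ", "))
  }
  check_scalar(cfg$reference$concentration, "reference$concentration",
               positive = TRUE)
  lib <- structure(
    list(entries = entries,
         reference = list(relax = as_spec(cfg$reference, "reference"),
                          concentration = cfg$reference$concentration)),
    class = "compartment_library")
  if (!is.null(cfg$acquisition)) {
    a <- cfg$acquisition
    attr(lib, "acquisition") <- acquisition_spec(
      tr_ms = a$tr_ms, te_ms = a$te_ms,
      voxel_mm = if (is.null(a$voxel_mm)) 3.6 else a$voxel_mm,
      flip_deg = if (is.null(a$flip_deg)) 87 else a$flip_deg)
  }
  lib
}

#' @export
print.compartment_library <- function(x, ...) {
  cat("<compartment_library>", length(x$entries), "regions +",
      sprintf("reference (%.2f mmol/L)\n", x$reference$concentration))
  for (rn in names(x$entries)) {
    e <- x$entries[[rn]]
    cat(sprintf("  %-10s %6.1f mmol/kg WW (SD %4.1f); T1 %5.1f, T2 %g/%g, w %g/%g\n",
                rn, e$concentration, e$sd, e$relax$t1_ms, e$relax$t2_fast_ms,
                e$relax$t2_slow_ms, e$relax$weight_fast, e$relax$weight_slow))
  }
  invisible(x)
}
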