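# Shared fixtures, built once per test run (the PSF cache of the default
# phantom is the expensive piece; every cohort in the suite reuses it).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

default_cfg <- function() fixture("cfg", phantom_config())

default_cache <- function() fixture("cache", {
  cfg <- default_cfg()
  phantom_cache(build_label_volume(cfg), cfg)
})

default_lib <- function() fixture("lib", default_compartments())

# Noiseless cohort: no noise, no repositioning, no gain drift; subject truths
# still vary between subjects (the recovery oracle is the truth table).
noiseless_cohort <- function() fixture("noiseless", {
  simulate_cohort(n_subjects = 3, seed = 11, cache = default_cache(),
                  noise_sigma = 0, reposition_mm = 0, reposition_deg = 0,
                  gain_drift = 0)
})

# Fully degenerate cohort: additionally zero between-subject variability,
# so every session of every subject is identical.
degenerate_cohort <- function() fixture("degenerate", {
  simulate_cohort(n_subjects = 3, seed = 5, cache = default_cache(),
                  noise_sigma = 0, reposition_mm = 0, reposition_deg = 0,
                  gain_drift = 0, between_subject_sd = 0)
})

degenerate_measurements <- function() fixture("degenerate_meas", {
  measure_all(degenerate_cohort(), jitter_sd = 0)
})

# Default-conditions cohort at reduced size (noise, drift, repositioning and
# reader jitter all at the generator defaults).
noisy_cohort <- function() fixture("noisy", {
  simulate_cohort(n_subjects = 4, seed = 23, cache = default_cache())
})

noisy_measurements <- function() fixture("noisy_meas", {
  measure_all(noisy_cohort())
})

# Join measurements to the cohort truth table by (subject, region, side).
# Midline-truth regions (a single primitive measured bilaterally, e.g. the
# GM shell) match either measured side.
join_truth <- function(measurements, cohort) {
  tr <- cohort$truth
  mid <- tr[tr$side == "midline", ]
  if (nrow(mid) > 0) {
    tr <- rbind(tr,
                transform(mid, side = "left"),
                transform(mid, side = "right"))
  }
  merge(measurements, tr, by = c("subject", "region", "side"))
}

random_relax <- function() {
  t2 <- sort(runif(2, 1, 60))
  a <- runif(1)
  relaxation_spec(t1_ms = runif(1, 10, 80), t2_fast_ms = t2[1],
                  t2_slow_ms = t2[2], weight_fast = a, weight_slow = 1 - a)
}
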