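# Test-retest statistics: repeatability (V1 vs V2, same day) and
# reproducibility (V1 vs V3, 8-day interval) correlations, paired visit
# comparisons against baseline, laterality, inter-individual fluctuation,
# inter-reader agreement and normality.
#
# Paired comparisons use subject-paired sign-flip permutation tests (exact
# enumeration for n <= 14, otherwise seeded Monte-Carlo) with |mean
# difference| as the statistic — distribution-free, exact, and well defined
# for degenerate inputs (identical data gives p = 1, a constant shift gives
# the extreme-orthant p of 2 / 2^n).

#' Squared Pearson correlation
#'
#' @param x,y Paired numeric vectors, length >= 3, each with nonzero variance.
#' @return r^2 in `[0, 1]`; invariant to affine rescaling of either argument.
#' @export
pearson_r2 <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  if (length(x) < 3) stop_invalid("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_invalid("undefined correlation: zero variance")
  }
  stats::cor(x, y)^2
}

#' Maximum percentage difference
#'
#' The inter-individual fluctuation statistic: `100 * (max - min) / max`,
#' scale-invariant and in `[0, 100)` for positive inputs.
#'
#' @param values Numeric vector, length >= 2, all > 0.
#' @return Percentage in `[0, 100)`.
#' @examples
#' max_pct_diff(c(65.4, 42.4))  # ~35.2
#' @export
max_pct_diff <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2) stop_invalid("need at least 2 values")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop_invalid("values must be positive and finite")
  }
  100 * (max(values) - min(values)) / max(values)
}

# cache of exact sign-flip matrices, keyed by n
.sign_cache <- new.env(parent = emptyenv())

sign_matrix <- function(n) {
  key <- as.character(n)
  if (!exists(key, envir = .sign_cache)) {
    assign(key, as.matrix(expand.grid(rep(list(c(-1, 1)), n))),
           envir = .sign_cache)
  }
  get(key, envir = .sign_cache)
}

# Sign-flip permutation p-value for paired differences d, two-sided, with
# |mean| as the statistic. Exact enumeration when 2^n <= 2^max_exact.
signflip_test <- function(d, n_perm = 1e4, seed = 1, max_exact = 14) {
  d <- as.numeric(d)
  n <- length(d)
  if (n < 3) stop_invalid("need at least 3 paired differences")
  obs <- abs(mean(d))
  tol <- 1e-12 * max(1, max(abs(d)))
  if (n <= max_exact) {
    perms <- abs(sign_matrix(n) %*% d) / n
    p <- mean(perms >= obs - tol)
  } else {
    perms <- with_seed(seed, {
      replicate(n_perm, abs(mean(d * sample(c(-1, 1), n, replace = TRUE))))
    })
    # add-one: the observed labelling is itself a valid permutation
    p <- (1 + sum(perms >= obs - tol)) / (n_perm + 1)
  }
  min(p, 1)
}

#' Paired visit comparison against baseline
#'
#' Tests whether a region's concentration differs between baseline V1 and a
#' follow-up visit, pairing by subject (readers and sides averaged first).
#' Implemented as an exact subject-paired sign-flip permutation test.
#'
#' @param measurements Measurement data.frame (see [measure_all()]), or `NULL`
#'   when `x`/`y` are given directly.
#' @param pair Character length-2, e.g. `c("V1","V2")` (repeatability) or
#'   `c("V1","V3")` (reproducibility).
#' @param region Region to test; `NULL` pools all regions as (subject,
#'   region) pairs.
#' @param x,y Alternative direct interface: paired per-subject values.
#' @param n_perm,seed Monte-Carlo settings when n > 14 pairs.
#' @return Two-sided p-value in `[0, 1]` (1 for identical data). Unpaired
#'   subjects are dropped with a warning.
#' @export
paired_visit_test <- function(measurements = NULL, pair = c("V1", "V2"),
                              region = NULL, x = NULL, y = NULL,
                              n_perm = 1e4, seed = 1) {
  if (is.null(x)) {
    stopifnot(is.data.frame(measurements), length(pair) == 2)
    agg <- subject_visit_values(measurements, region)
    w <- stats::reshape(agg, idvar = c("subject", "region"), timevar = "visit",
                        direction = "wide")
    v1 <- w[[paste0("value.", pair[1])]]
    v2 <- w[[paste0("value.", pair[2])]]
    if (is.null(v1) || is.null(v2)) {
      stop_invalid("visit ", paste(setdiff(pair, unique(agg$visit)), collapse = ","),
                   " absent from measurements")
    }
    keep <- stats::complete.cases(v1, v2)
    if (any(!keep)) warning(sum(!keep), " unpaired subject(s) dropped")
    x <- v1[keep]; y <- v2[keep]
  }
  signflip_test(y - x, n_perm = n_perm, seed = seed)
}

# Average concentration per (subject, visit, region) across readers and
# sides; optionally restricted to one region (or pooling all).
subject_visit_values <- function(measurements, region = NULL) {
  m <- measurements
  if (!is.null(region)) m <- m[m$region == region, , drop = FALSE]
  if (nrow(m) == 0) stop_invalid("no measurements", if (!is.null(region))
    paste0(" for region '", region, "'"))
  out <- stats::aggregate(concentration ~ subject + region + visit, data = m,
                          FUN = mean)
  names(out)[names(out) == "concentration"] <- "value"
  out
}

#' Joint max-|t| permutation test of all visits against baseline
#'
#' Family-wise contrast-vs-baseline test in the spirit of a repeated-measures
#' comparison with a control: the statistic is the maximum over follow-up
#' visits of |t| for the paired difference against V1; the null distribution
#' comes from permuting visit labels within subject.
#'
#' @param measurements Measurement data.frame.
#' @param region Region (or `NULL` to pool regions).
#' @param baseline Baseline visit. Default `"V1"`.
#' @param n_perm Number of within-subject label permutations. Default 2000.
#' @param seed RNG seed.
#' @return List with the family-wise `p` and the observed per-visit `t`.
#' @export
visit_maxt_test <- function(measurements, region = NULL, baseline = "V1",
                            n_perm = 2000, seed = 1) {
  agg <- subject_visit_values(measurements, region)
  visits <- sort(unique(agg$visit))
  if (!baseline %in% visits || length(visits) < 2) {
    stop_invalid("need the baseline visit plus at least one follow-up")
  }
  w <- stats::reshape(agg, idvar = c("subject", "region"), timevar = "visit",
                      direction = "wide")
  vals <- as.matrix(w[, paste0("value.", visits), drop = FALSE])
  keep <- stats::complete.cases(vals)
  vals <- vals[keep, , drop = FALSE]
  if (nrow(vals) < 3) stop_invalid("need at least 3 complete subjects")
  b <- which(visits == baseline)
  tstat <- function(m) {
    d <- m[, -b, drop = FALSE] - m[, b]
    apply(d, 2, function(di) {
      s <- stats::sd(di)
      if (s < 1e-12 * max(1, max(abs(m)))) 0 else
        abs(mean(di)) / (s / sqrt(length(di)))
    })
  }
  t_obs <- tstat(vals)
  perms <- with_seed(seed, {
    replicate(n_perm, {
      shuffled <- t(apply(vals, 1, sample))
      max(tstat(shuffled))
    })
  })
  p <- (1 + sum(perms >= max(t_obs) - 1e-12)) / (n_perm + 1)
  list(p = min(p, 1), t = t_obs, visits = visits[-b])
}

#' Left-right laterality test
#'
#' Paired (by subject) two-sided sign-flip permutation test on left minus
#' right concentrations of a bilateral region.
#'
#' @param left,right Paired per-subject values.
#' @param region Optional label carried into the result.
#' @param n_perm,seed Monte-Carlo settings when n > 14.
#' @return List with `left_mean`, `right_mean`, `p` (and `region`).
#' @export
laterality_test <- function(left, right, region = NULL, n_perm = 1e4, seed = 1) {
  stopifnot(is.numeric(left), is.numeric(right))
  if (length(left) != length(right)) stop_invalid("left/right must be paired")
  if (length(left) < 3) stop_invalid("need at least 3 subjects")
  list(region = region, left_mean = mean(left), right_mean = mean(right),
       p = signflip_test(left - right, n_perm = n_perm, seed = seed))
}

#' Spearman rank correlation between readers
#'
#' @param reader1,reader2 Paired value vectors, length >= 3; ties are handled
#'   by midranks.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(reader1, reader2) {
  stopifnot(is.numeric(reader1), is.numeric(reader2))
  if (length(reader1) != length(reader2)) stop_invalid("inputs must be paired")
  if (length(reader1) < 3) stop_invalid("need at least 3 pairs")
  if (stats::sd(reader1) == 0 || stats::sd(reader2) == 0) {
    stop_invalid("undefined correlation: constant input")
  }
  stats::cor(reader1, reader2, method = "spearman")
}

#' Bland-Altman limits of agreement on the reader ratio
#'
#' Ratios `r_i = a_i / b_i`; returns their mean and mean +/- 1.96 SD, the
#' agreement display used for inter-reader comparison.
#'
#' @param a,b Paired positive value vectors (reader 1, reader 2).
#' @return List with `mean_ratio`, `lower`, `upper`, and the `ratios`.
#' @export
bland_altman_ratio <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) stop_invalid("inputs must be paired")
  if (length(a) < 2) stop_invalid("need at least 2 pairs")
  if (any(a <= 0) || any(b <= 0)) stop_invalid("values must be positive")
  r <- a / b
  m <- mean(r)
  s <- stats::sd(r)
  list(mean_ratio = m, lower = m - 1.96 * s, upper = m + 1.96 * s, ratios = r)
}

# Lilliefors statistic: KS distance of the standardised sample against the
# standard normal.
lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  u <- stats::pnorm(z)
  max(seq_len(n) / n - u, u - (seq_len(n) - 1) / n)
}

#' Normality test with estimated parameters
#'
#' One-sample Kolmogorov-Smirnov test against a normal with the sample mean
#' and SD. Because the parameters are estimated, the naive KS null is wrong;
#' the null distribution is simulated (Lilliefors-style Monte-Carlo).
#'
#' @param values Numeric vector, length >= 5, non-constant.
#' @param n_sim Null simulations. Default 2000.
#' @param seed RNG seed for the null draws.
#' @return p-value in (0, 1].
#' @export
ks_normality <- function(values, n_sim = 2000, seed = 1) {
  stopifnot(is.numeric(values))
  n <- length(values)
  if (n < 5) stop_invalid("need at least 5 values")
  if (stats::sd(values) == 0) stop_invalid("constant data: normality undefined")
  d_obs <- lilliefors_stat(values)
  d_null <- with_seed(seed, {
    replicate(n_sim, lilliefors_stat(stats::rnorm(n)))
  })
  (1 + sum(d_null >= d_obs)) / (n_sim + 1)
}
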