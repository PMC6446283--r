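# Cohort-level summary: the repeatability/reproducibility table (per-region
# visit means +/- SD with paired p-values), pooled correlations, fluctuation
# statistics, laterality, inter-reader agreement, Bland-Altman limits and
# normality. Readers (and sides) are averaged within (subject, visit, region)
# before any across-subject statistic.

#' Summarize a measurement table into a repeatability report
#'
#' @param measurements Measurement data.frame from [measure_all()] (or read
#'   via [read_measurements()]); needs at least two visits.
#' @param baseline Baseline visit. Default `"V1"`.
#' @param n_perm,seed Permutation/Monte-Carlo settings for the tests.
#' @return An object of class `repeatability_report`: a list with elements
#'   `table2` (per-region visit-pair comparisons), `overall` (pooled r^2 per
#'   pair), `family` (max-|t| family-wise p per region), `fluctuation`
#'   (per-region min/max and max percentage difference), `laterality`,
#'   `inter_reader` (Spearman rho per region), `bland_altman` and
#'   `normality`. Fields that are undefined on degenerate input (e.g. rank
#'   correlations of constant data) are `NA` rather than errors.
#' @export
summarize_cohort <- function(measurements, baseline = "V1",
                             n_perm = 1e4, seed = 1) {
  m <- measurements
  stopifnot(is.data.frame(m), nrow(m) > 0)
  visits <- sort(unique(m$visit))
  if (length(visits) < 2) stop_invalid("need at least two visits")
  followups <- setdiff(visits, baseline)
  pairs <- lapply(followups, function(v) c(baseline, v))
  regions <- unique(m$region)
  agg <- subject_visit_values(m)   # (subject, region, visit) -> value
  wide <- stats::reshape(agg, idvar = c("subject", "region"),
                         timevar = "visit", direction = "wide")
  val <- function(v) wide[[paste0("value.", v)]]
  na_or <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  # --- Table-2-shaped per-region comparisons (plus a pooled "Mean" row) ---
  t2 <- list()
  for (pr in pairs) {
    for (rg in c(regions, "Mean")) {
      sel <- if (rg == "Mean") rep(TRUE, nrow(wide)) else wide$region == rg
      a <- val(pr[1])[sel]; b <- val(pr[2])[sel]
      keep <- stats::complete.cases(a, b)
      a <- a[keep]; b <- b[keep]
      if (rg == "Mean") {
        # display pools all (subject, region) values, but the paired test
        # unit is the subject (regions of one subject share session effects)
        subj <- wide$subject[sel][keep]
        d <- tapply(b - a, subj, mean)
      } else {
        d <- b - a
      }
      t2[[length(t2) + 1]] <- data.frame(
        region = rg, pair = paste(pr, collapse = "-"),
        mean_a = mean(a), sd_a = stats::sd(a),
        mean_b = mean(b), sd_b = stats::sd(b),
        p = na_or(signflip_test(as.numeric(d), n_perm = n_perm, seed = seed)),
        n = length(a), stringsAsFactors = FALSE)
    }
  }
  table2 <- do.call(rbind, t2)

  # --- pooled correlation per visit pair (all subject x region values) ---
  overall <- do.call(rbind, lapply(pairs, function(pr) {
    a <- val(pr[1]); b <- val(pr[2])
    keep <- stats::complete.cases(a, b)
    data.frame(pair = paste(pr, collapse = "-"),
               r2 = na_or(pearson_r2(a[keep], b[keep])),
               n = sum(keep), stringsAsFactors = FALSE)
  }))

  # --- family-wise max-|t| p per region (all follow-ups vs baseline) ---
  family <- do.call(rbind, lapply(regions, function(rg) {
    p <- na_or(visit_maxt_test(m, region = rg, baseline = baseline,
                               seed = seed)$p)
    data.frame(region = rg, p_family = p, stringsAsFactors = FALSE)
  }))

  # --- inter-individual fluctuation per region ---
  fluct <- do.call(rbind, lapply(regions, function(rg) {
    v <- agg$value[agg$region == rg]
    data.frame(region = rg, min = min(v), max = max(v),
               max_pct_diff = na_or(max_pct_diff(v)),
               stringsAsFactors = FALSE)
  }))

  # --- laterality for bilateral regions (visits and readers averaged) ---
  bilat <- intersect(regions, unique(m$region[m$side %in% c("left", "right")]))
  lat <- do.call(rbind, lapply(bilat, function(rg) {
    sub <- m[m$region == rg & m$side %in% c("left", "right"), , drop = FALSE]
    per <- stats::aggregate(concentration ~ subject + side, data = sub, FUN = mean)
    w <- stats::reshape(per, idvar = "subject", timevar = "side",
                        direction = "wide")
    l <- w$concentration.left; r <- w$concentration.right
    keep <- stats::complete.cases(l, r)
    res <- tryCatch(laterality_test(l[keep], r[keep], region = rg,
                                    n_perm = n_perm, seed = seed),
                    error = function(e) list(left_mean = NA_real_,
                                             right_mean = NA_real_,
                                             p = NA_real_))
    data.frame(region = rg, left_mean = res$left_mean,
               right_mean = res$right_mean, p = res$p,
               stringsAsFactors = FALSE)
  }))

  # --- inter-reader agreement ---
  readers <- sort(unique(m$reader))
  inter_reader <- NULL
  ba <- NULL
  if (length(readers) >= 2) {
    r1 <- readers[1]; r2 <- readers[2]
    key <- c("subject", "visit", "region", "side")
    a <- m[m$reader == r1, c(key, "concentration")]
    b <- m[m$reader == r2, c(key, "concentration")]
    mg <- merge(a, b, by = key, suffixes = c(".1", ".2"))
    inter_reader <- do.call(rbind, lapply(regions, function(rg) {
      s <- mg[mg$region == rg, ]
      data.frame(region = rg,
                 rho = na_or(spearman_rho(s$concentration.1, s$concentration.2)),
                 n = nrow(s), stringsAsFactors = FALSE)
    }))
    ba <- tryCatch(bland_altman_ratio(mg$concentration.1, mg$concentration.2),
                   error = function(e) NULL)
  }

  # --- normality per region on (subject, visit) values ---
  normality <- do.call(rbind, lapply(regions, function(rg) {
    v <- agg$value[agg$region == rg]
    data.frame(region = rg,
               p = if (length(v) >= 5) na_or(ks_normality(v, seed = seed))
                   else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))

  structure(list(table2 = table2, overall = overall, family = family,
                 fluctuation = fluct, laterality = lat,
                 inter_reader = inter_reader, bland_altman = ba,
                 normality = normality, baseline = baseline),
            class = "repeatability_report")
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat("Repeatability / reproducibility of sodium concentrations\n")
  cat("(values mmol/kg wet weight; readers and sides averaged per subject)\n\n")
  t2 <- x$table2
  for (pr in unique(t2$pair)) {
    cat(sprintf("  %s:\n", pr))
    s <- t2[t2$pair == pr, ]
    for (i in seq_len(nrow(s))) {
      cat(sprintf("    %-10s %5.1f +/- %4.1f  vs  %5.1f +/- %4.1f   p = %s\n",
                  s$region[i], s$mean_a[i], s$sd_a[i], s$mean_b[i], s$sd_b[i],
                  formatC(s$p[i], digits = 2, format = "fg")))
    }
  }
  cat("\n  pooled r^2:",
      paste(sprintf("%s %.3f", x$overall$pair, x$overall$r2), collapse = ", "),
      "\n")
  if (!is.null(x$bland_altman)) {
    cat(sprintf("  Bland-Altman reader ratio: %.3f [%.3f, %.3f]\n",
                x$bland_altman$mean_ratio, x$bland_altman$lower,
                x$bland_altman$upper))
  }
  invisible(x)
}

#' Write a repeatability report as CSV files
#'
#' Writes `table2.csv` (the visit-pair comparison table), plus
#' `overall.csv`, `family.csv`, `fluctuation.csv`, `laterality.csv`,
#' `inter_reader.csv`, `normality.csv` and `summary.csv` (a flat
#' key,value file of every scalar statistic, full precision).
#'
#' @param report A `repeatability_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "repeatability_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      num <- vapply(df, is.numeric, TRUE)
      df[num] <- lapply(df[num], function(v)
        format(v, digits = 17, scientific = FALSE, trim = TRUE))
      utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                       quote = FALSE)
    }
  }
  wr(report$table2, "table2.csv")
  wr(report$overall, "overall.csv")
  wr(report$family, "family.csv")
  wr(report$fluctuation, "fluctuation.csv")
  wr(report$laterality, "laterality.csv")
  wr(report$inter_reader, "inter_reader.csv")
  wr(report$normality, "normality.csv")
  flat <- report_flat(report)
  utils::write.csv(flat, file.path(dir, "summary.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

# Flatten every scalar statistic of a report into key,value rows.
report_flat <- function(report) {
  rows <- list()
  add <- function(key, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      key = key, value = format(value, digits = 17, scientific = FALSE,
                                trim = TRUE),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(report$overall))) {
    add(paste0("r2.", report$overall$pair[i]), report$overall$r2[i])
  }
  for (i in seq_len(nrow(report$fluctuation))) {
    add(paste0("max_pct_diff.", report$fluctuation$region[i]),
        report$fluctuation$max_pct_diff[i])
  }
  if (!is.null(report$laterality)) {
    for (i in seq_len(nrow(report$laterality))) {
      add(paste0("laterality_p.", report$laterality$region[i]),
          report$laterality$p[i])
    }
  }
  if (!is.null(report$inter_reader)) {
    for (i in seq_len(nrow(report$inter_reader))) {
      add(paste0("spearman_rho.", report$inter_reader$region[i]),
          report$inter_reader$rho[i])
    }
  }
  if (!is.null(report$bland_altman)) {
    add("bland_altman.mean_ratio", report$bland_altman$mean_ratio)
    add("bland_altman.lower", report$bland_altman$lower)
    add("bland_altman.upper", report$bland_altman$upper)
  }
  for (i in seq_len(nrow(report$normality))) {
    add(paste0("ks_p.", report$normality$region[i]), report$normality$p[i])
  }
  do.call(rbind, rows)
}
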