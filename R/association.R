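## Binned-association statistics: mutation rate per methylation bin, slope
## comparisons between cohorts, replication-timing stratification,
## per-sample slopes, candidate-site fractions, windowed correlations and
## the one-sample t-test used for hotspot methylation.

#' Binned mutation rate versus methylation
#'
#' Bins CpGs by methylation fraction (width `bin_width` over `[0,1]`, the
#' topmost bin closed) and computes the mutation rate per megabase of CpG
#' dinucleotide sequence in each bin: `events / (CpG count x 2 bp) x 1e6`.
#' A linear (Pearson) regression of rate on bin midpoint gives slope,
#' intercept, r-squared and two-sided p-value.
#'
#' @param table A `cpg_table`.
#' @param bin_width Methylation bin width (default 0.1).
#' @param measure `"events"` (default: pooled mutation events) or
#'   `"sites"` (count of mutated CpGs).
#' @return A `binned_assoc` list: `bins` (`mid`, `n_cpg`, `events`,
#'   `rate`), `slope`, `intercept`, `r_squared`, `p_value`, `n_sites`.
#' @export
binned_rate <- function(table, bin_width = 0.1, measure = "events") {
  tab <- as.data.table(table)
  stopifnot(nrow(tab) > 0)
  measure <- match.arg(measure, c("events", "sites"))
  edges <- seq(0, 1, by = bin_width)
  nb <- length(edges) - 1L
  tab2 <- tab[!is.na(M)]
  idx <- pmin(pmax(floor(tab2$M / bin_width), 0L) + 1L, nb)
  ev <- if (measure == "events") tab2$events else as.integer(tab2$mutated)
  bins <- data.table(bin = seq_len(nb),
                     mid = edges[-length(edges)] + bin_width / 2)
  agg <- data.table(bin = idx, ev = ev)[, .(n_cpg = .N, events = sum(ev)),
                                        by = bin]
  bins <- agg[bins, on = "bin"]
  bins[is.na(n_cpg), `:=`(n_cpg = 0L, events = 0L)]
  bins[, rate := ifelse(n_cpg > 0, events / (n_cpg * 2) * 1e6, NA_real_)]
  data.table::setorder(bins, bin)
  use <- bins[n_cpg > 0]
  if (nrow(use) < 3) stopf("binned_rate: fewer than 3 non-empty bins")
  fit <- lm(rate ~ mid, data = use)
  sm <- summary(fit)
  structure(list(bins = bins[, .(mid, n_cpg, events, rate)],
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 bin_width = bin_width, measure = measure,
                 n_sites = nrow(tab2)),
            class = "binned_assoc")
}

#' @export
print.binned_assoc <- function(x, ...) {
  cat(sprintf(
    "Binned mutation-methylation association (%s, %d CpGs)\n",
    x$measure, x$n_sites))
  cat(sprintf("  slope %.4g  intercept %.4g  r^2 %.3f  p %.3g\n",
              x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' Compare binned-association slopes against a reference cohort
#'
#' Stacks the binned (midpoint, rate) points of several cohorts and fits
#' one linear model with a group-by-midpoint interaction, the reference
#' cohort as baseline. The interaction coefficients are the slope
#' differences versus the reference, with t-test p-values.
#'
#' @param assocs Named list of `binned_assoc` objects on identical bins.
#' @param reference Name of the reference cohort.
#' @return A `slope_comparison`: `data.table` with `group`, `slope`,
#'   `slope_diff` (vs reference; 0 for the reference itself), `p_value`
#'   (`NA` for the reference).
#' @export
compare_slopes <- function(assocs, reference) {
  stopifnot(is.list(assocs), !is.null(names(assocs)))
  if (!reference %in% names(assocs)) {
    stopf("reference '%s' not among groups", reference)
  }
  mids <- lapply(assocs, function(a) a$bins$mid)
  if (!all(vapply(mids, identical, TRUE, y = mids[[1]]))) {
    stopf("binned associations do not share bin edges")
  }
  stacked <- data.table::rbindlist(lapply(names(assocs), function(g) {
    b <- assocs[[g]]$bins[n_cpg > 0]
    data.table(group = g, mid = b$mid, rate = b$rate)
  }))
  stacked[, group := stats::relevel(factor(group), ref = reference)]
  fit <- lm(rate ~ mid * group, data = stacked)
  sm <- summary(fit)$coefficients
  groups <- levels(stacked$group)
  out <- data.table(group = groups, slope = NA_real_,
                    slope_diff = 0, p_value = NA_real_)
  ref_slope <- sm["mid", 1]
  for (g in groups) {
    term <- paste0("mid:group", g)
    if (g == reference) {
      out[group == g, slope := ref_slope]
    } else if (term %in% rownames(sm)) {
      out[group == g, `:=`(slope = ref_slope + sm[term, 1],
                           slope_diff = sm[term, 1],
                           p_value = sm[term, 4])]
    }
  }
  data.table::setattr(out, "reference", reference)
  data.table::setattr(out, "model", fit)
  data.table::setattr(out, "class", c("slope_comparison", class(out)))
  out[]
}

#' Stratify the CpG table by replication timing and bin each stratum
#'
#' Splits sites into genome-wide timing strata (tertiles by default, on
#' the distribution of per-site timing values; higher timing = earlier
#' replication, so the highest stratum is `"early"`), then computes the
#' binned association independently per stratum. The result can be fed to
#' [compare_slopes()] with `reference = "early"`.
#'
#' @param table A `cpg_table` with `R` present on all sites.
#' @param n_strata Number of strata (default 3: late / mid / early).
#' @param bin_width Methylation bin width (default 0.1).
#' @param measure Passed to [binned_rate()].
#' @return Named list of `binned_assoc`, ordered late -> early.
#' @export
stratify_by_timing <- function(table, n_strata = 3, bin_width = 0.1,
                               measure = "events") {
  tab <- as.data.table(table)[!is.na(R)]
  stopifnot(nrow(tab) > 0)
  qs <- quantile(tab$R, probs = seq_len(n_strata - 1) / n_strata,
                 names = FALSE)
  if (length(unique(tab$R)) < n_strata) {
    stopf("degenerate timing distribution: cannot form %d strata", n_strata)
  }
  if (anyDuplicated(qs)) {
    warnf("ties span a stratum boundary; boundary assignment is deterministic")
    qs <- unique(qs)
  }
  n_eff <- length(qs) + 1L
  labels <- if (n_eff == 3) c("late", "mid", "early") else
    paste0("stratum", seq_len(n_eff))
  idx <- findInterval(tab$R, qs, left.open = TRUE) + 1L
  ## ties at a boundary fall deterministically in the lower stratum
  out <- lapply(seq_len(n_eff), function(i) {
    binned_rate(tab[idx == i], bin_width = bin_width, measure = measure)
  })
  names(out) <- labels
  out
}

#' Per-sample association slopes and their link to mutation burden
#'
#' Computes, for each sample, the binned-association slope using that
#' sample's own mutation events, then the Pearson correlation (across
#' samples) of slope with total mutation count.
#'
#' @param table A `cpg_table` carrying the `sample_hits` attribute.
#' @param samples Samples to include (default: all with hits).
#' @param bin_width Methylation bin width.
#' @return List: `slopes` (`data.table` of `sample_id`, `slope`, `total`),
#'   `r_squared`, `p_value` (`NA` with a flag when slope variance is zero),
#'   `excluded` (samples with zero events).
#' @export
per_sample_slopes <- function(table, samples = NULL, bin_width = 0.1) {
  hits <- attr(table, "sample_hits")
  if (is.null(hits)) stopf("table lacks per-sample hit information")
  samples <- samples %||% sort(unique(hits$sample_id))
  if (length(samples) < 2) stopf("need at least 2 samples")
  tab <- as.data.table(table)
  excluded <- character()
  rows <- lapply(samples, function(s) {
    h <- hits[sample_id == s, .(chrom, pos, n)]
    if (!nrow(h) || sum(h$n) == 0) {
      excluded <<- c(excluded, s)
      return(NULL)
    }
    t2 <- h[tab, on = c("chrom", "pos")]
    t2[is.na(n), n := 0L]
    t2[, `:=`(events = n, mutated = n >= 1L)]
    a <- binned_rate(t2, bin_width = bin_width, measure = "events")
    data.table(sample_id = s, slope = a$slope, total = sum(h$n))
  })
  if (length(excluded)) {
    warnf("per_sample_slopes: excluded %d sample(s) with zero events",
          length(excluded))
  }
  slopes <- data.table::rbindlist(rows)
  if (nrow(slopes) < 2) stopf("fewer than 2 samples with events")
  if (sd(slopes$slope) == 0 || sd(slopes$total) == 0) {
    return(list(slopes = slopes[], r_squared = NA_real_, p_value = NA_real_,
                zero_variance = TRUE, excluded = excluded))
  }
  ct <- cor.test(slopes$slope, slopes$total)
  list(slopes = slopes[], r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, zero_variance = FALSE, excluded = excluded)
}

#' Per-sample mutated fraction of low- vs high-methylation candidate sites
#'
#' Candidate sites are CpGs with a given forward-strand trinucleotide
#' context (default `TCG`). For each sample, the percentage of
#' low-methylation (`M < low`) and high-methylation (`M > high`)
#' candidates at which that sample carries a C>T at the C is computed,
#' and the high-vs-low contrast is tested by both paired and unpaired
#' t-tests.
#'
#' @param table A `cpg_table` with `sample_hits` and contexts.
#' @param context Forward-strand 3-mer defining candidates (default
#'   `"TCG"`).
#' @param low,high Methylation cut-offs (defaults 0.25 / 0.75).
#' @param samples Samples to include (default: all with hits).
#' @param mutations Optional `mutation_table` used to restrict hits to
#'   C>T at the C; if omitted, any recorded hit at the site counts.
#' @return List: `fractions` (`sample_id`, `low_pct`, `high_pct`),
#'   `paired` and `unpaired` htest results (or `NA` with
#'   `zero_difference` flag), counts of candidate sites per stratum.
#' @export
candidate_fraction <- function(table, context = "TCG", low = 0.25,
                               high = 0.75, samples = NULL,
                               mutations = NULL) {
  tab <- as.data.table(table)
  ctx <- context
  cand <- tab[context == ctx]
  low_sites <- cand[M < low]
  high_sites <- cand[M > high]
  if (!nrow(low_sites) || !nrow(high_sites)) {
    stopf("empty candidate stratum (low: %d sites, high: %d sites)",
          nrow(low_sites), nrow(high_sites))
  }
  hits <- attr(table, "sample_hits")
  if (is.null(hits)) stopf("table lacks per-sample hit information")
  if (!is.null(mutations)) {
    mut <- as.data.table(mutations)[ref == "C" & alt == "T"]
    hits <- mut[, .(n = .N), by = .(chrom, pos, sample_id)]
  }
  samples <- samples %||% sort(unique(hits$sample_id))
  pct <- function(sites, s) {
    h <- hits[sample_id == s]
    hit <- sites[h, on = c("chrom", "pos"), nomatch = NULL]
    100 * nrow(hit) / nrow(sites)
  }
  fr <- data.table::rbindlist(lapply(samples, function(s) {
    data.table(sample_id = s, low_pct = pct(low_sites, s),
               high_pct = pct(high_sites, s))
  }))
  d <- fr$high_pct - fr$low_pct
  zero_diff <- length(d) < 2 || sd(d) == 0
  paired <- if (!zero_diff) t.test(fr$high_pct, fr$low_pct, paired = TRUE)
  unpaired <- if (length(d) >= 2 &&
                  (sd(fr$high_pct) > 0 || sd(fr$low_pct) > 0))
    t.test(fr$high_pct, fr$low_pct, paired = FALSE)
  list(fractions = fr[], paired = paired, unpaired = unpaired,
       zero_difference = zero_diff,
       n_low_sites = nrow(low_sites), n_high_sites = nrow(high_sites))
}

#' One-sample t-test of methylation values against a hotspot value
#'
#' Two-sided test of `values` against the constant `mu`. With zero
#' variance the p-value is defined by convention: 1 when the common value
#' equals `mu`, 0 otherwise, with `degenerate = TRUE`.
#'
#' @param values Numeric vector (e.g. methylation at all CpGs in a gene's
#'   coding exons), length >= 2.
#' @param mu Reference value (e.g. methylation at the hotspot codon).
#' @return List: `t`, `p_value`, `mean`, `n`, `degenerate`.
#' @export
one_sample_ttest <- function(values, mu) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 2)
  if (sd(values) == 0) {
    eq <- isTRUE(all.equal(mean(values), mu))
    return(list(t = if (eq) 0 else sign(mean(values) - mu) * Inf,
                p_value = if (eq) 1 else 0,
                mean = mean(values), n = length(values), degenerate = TRUE))
  }
  ht <- t.test(values, mu = mu)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       mean = mean(values), n = length(values), degenerate = FALSE)
}

#' Pearson correlation of a windowed signal with replication timing
#'
#' @param signal `data.table`/data.frame with columns `chrom`, `start`,
#'   `value` (per-window means, e.g. excision-repair read density).
#' @param timing A `timing_track`.
#' @return List: `r`, `r_squared`, `p_value`, `n_windows`.
#' @export
windowed_signal_correlation <- function(signal, timing) {
  sg <- as.data.table(signal)
  tm <- as.data.table(timing)[!is.na(timing), .(chrom, start, timing)]
  m <- merge(sg, tm, by = c("chrom", "start"))
  m <- m[complete.cases(m[, .(value, timing)])]
  if (nrow(m) < 3) stopf("fewer than 3 shared windows")
  ct <- cor.test(m$value, m$timing)
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, n_windows = nrow(m))
}
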