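## Build a cpg_table-like data.table directly.
site_table <- function(M, events, R = 50, context = "ACG",
                       sample_hits = NULL) {
  dt <- data.table::data.table(
    chrom = "chr1", pos = seq_along(M) * 10L, M = M, R = R,
    context = context, mutated = events >= 1L, events = as.integer(events))
  if (!is.null(sample_hits)) {
    data.table::setattr(dt, "sample_hits", sample_hits)
  }
  data.table::setattr(dt, "class", c("cpg_table", class(dt)))
  dt[]
}

test_that("binned rates follow the per-megabase arithmetic", {
  ## 100 CpGs with 6 events in one bin: 6 / (200 bp / 1e6) = 30000 per Mb
  M <- c(rep(0.05, 100), rep(0.55, 50), rep(0.95, 80))
  events <- c(rep(0L, 94), rep(1L, 6), rep(0L, 50), rep(0L, 80))
  a <- binned_rate(site_table(M, events))
  expect_equal(a$bins[mid == 0.05, n_cpg], 100L)
  expect_equal(a$bins[mid == 0.05, rate], 30000)
  expect_equal(a$bins[mid == 0.55, rate], 0)
  ## conservation across bins
  expect_equal(sum(a$bins$events), sum(events))
})

test_that("rates exactly linear in midpoints fit with r-squared 1", {
  mids <- seq(0.05, 0.95, by = 0.1)
  ## place one CpG in each bin and give it events so rate = 1000 * mid:
  ## rate for 1 CpG with k events = k * 5e5, so use many CpGs instead
  M <- rep(mids, each = 100)
  events <- integer(length(M))
  a0 <- binned_rate(site_table(M, events + rep(seq_len(10), each = 100)))
  expect_equal(unname(a0$r_squared), 1, tolerance = 1e-10)
  expect_gt(a0$slope, 0)
})

test_that("fits are refused with fewer than three occupied bins", {
  expect_error(binned_rate(site_table(rep(c(0.1, 0.9), 5), rep(0L, 10))),
               "fewer than 3")
})

test_that("mutated-site counting is available as an alternative measure", {
  M <- rep(c(0.05, 0.55, 0.95), each = 10)
  events <- rep(c(0L, 2L, 5L), each = 10)   # multi-hit sites
  ev <- binned_rate(site_table(M, events), measure = "events")
  st <- binned_rate(site_table(M, events), measure = "sites")
  expect_equal(ev$bins[.N, events], 50L)   # topmost bin, multi-hit events
  expect_equal(st$bins[.N, events], 10L)   # same bin, mutated sites
})

test_that("slope differences recover noiseless constructions exactly", {
  mids <- seq(0.05, 0.95, by = 0.1)
  a <- make_assoc(mids, 100 * mids + 7)
  b <- make_assoc(mids, 300 * mids + 7)
  cmp <- compare_slopes(list(g1 = a, g2 = b), reference = "g1")
  expect_equal(cmp[group == "g1", slope_diff], 0)
  expect_equal(cmp[group == "g2", slope_diff], 200, tolerance = 1e-8)
  ## identical groups: difference 0, p = 1 (needs non-degenerate residuals)
  set.seed(1)
  noisy <- 100 * mids + rnorm(10)
  cmp0 <- compare_slopes(list(g1 = make_assoc(mids, noisy),
                              g2 = make_assoc(mids, noisy)),
                         reference = "g1")
  expect_equal(cmp0[group == "g2", slope_diff], 0, tolerance = 1e-10)
  expect_equal(cmp0[group == "g2", p_value], 1, tolerance = 1e-8)
})

test_that("reference swaps re-express differences without changing fits", {
  mids <- seq(0.05, 0.95, by = 0.1)
  set.seed(2)
  assocs <- list(g1 = make_assoc(mids, 100 * mids + rnorm(10)),
                 g2 = make_assoc(mids, 250 * mids + rnorm(10)),
                 g3 = make_assoc(mids, 400 * mids + rnorm(10)))
  c1 <- compare_slopes(assocs, "g1")
  c2 <- compare_slopes(assocs, "g2")
  ## per-group slopes agree under either parameterization
  expect_equal(c1[order(group), slope], c2[order(group), slope],
               tolerance = 1e-8)
  expect_equal(c2[group == "g1", slope_diff],
               -c1[group == "g2", slope_diff], tolerance = 1e-8)
  expect_error(compare_slopes(assocs, "nope"), "not among")
})

test_that("timing stratification recovers planted per-stratum slopes", {
  set.seed(3)
  n <- 30000
  R <- rep(c(10, 50, 90), each = n / 3)
  M <- runif(n)
  ## later-replicating (lower R) strata get steeper methylation slopes
  p <- (0.002 + 0.004 * (R == 10) + 0.002 * (R == 50)) * (0.5 + M)
  events <- rbinom(n, 1L, p)
  tab <- site_table(M, events, R = R)
  strata <- stratify_by_timing(tab)
  expect_named(strata, c("late", "mid", "early"))
  cmp <- compare_slopes(strata, reference = "early")
  expect_gt(cmp[group == "late", slope_diff], 0)
  expect_gt(cmp[group == "mid", slope_diff], 0)
  ## degenerate timing is refused
  expect_error(stratify_by_timing(site_table(runif(100), rep(0L, 100),
                                             R = 50)),
               "degenerate")
})

test_that("per-sample slopes scale linearly and track total burden", {
  M <- rep(seq(0.05, 0.95, by = 0.1), each = 200)
  base_events <- as.integer(round(rep(seq(1, 19, by = 2), each = 200) / 4))
  mk_hits <- function(mult) {
    data.table::data.table(chrom = "chr1",
                           pos = seq_along(M) * 10L,
                           n = base_events * mult)[n > 0]
  }
  hits <- data.table::rbindlist(list(
    data.table::copy(mk_hits(1L))[, sample_id := "s1"],
    data.table::copy(mk_hits(2L))[, sample_id := "s2"],
    data.table::copy(mk_hits(3L))[, sample_id := "s3"]))
  tab <- site_table(M, base_events * 6L, sample_hits = hits)
  res <- per_sample_slopes(tab)
  sl <- res$slopes[order(sample_id)]
  ## doubling every bin's events doubles the slope
  expect_equal(sl[sample_id == "s2", slope] / sl[sample_id == "s1", slope],
               2, tolerance = 1e-8)
  ## slopes {x,2x,3x} vs totals {y,2y,3y} are collinear
  expect_equal(res$r_squared, 1, tolerance = 1e-8)
  ## zero-event samples are excluded with a warning
  hits0 <- data.table::rbindlist(list(
    hits, data.table::data.table(chrom = "chr1", pos = 10L, n = 0L,
                                 sample_id = "s4")))
  tab0 <- site_table(M, base_events * 6L, sample_hits = hits0)
  expect_warning(res0 <- per_sample_slopes(tab0), "zero events")
  expect_equal(res0$excluded, "s4")
})

test_that("candidate fractions count per-sample hits in TCG strata", {
  ## 10 low- and 10 high-methylation TCG candidates
  M <- c(rep(0.1, 10), rep(0.9, 10))
  hits <- data.table::data.table(
    chrom = "chr1", pos = c(10L, 20L, 110L, 120L, 130L),
    sample_id = c("s1", "s1", "s1", "s1", "s1"), n = 1L)
  tab <- site_table(M, integer(20), context = "TCG", sample_hits = hits)
  res <- candidate_fraction(tab, samples = "s1")
  expect_equal(res$fractions$low_pct, 20)    # 2 of 10
  expect_equal(res$fractions$high_pct, 30)   # 3 of 10
  ## empty stratum errors
  tab_hi <- site_table(rep(0.9, 10), integer(10), context = "TCG",
                       sample_hits = hits)
  expect_error(candidate_fraction(tab_hi, samples = "s1"), "empty candidate")
})

test_that("a planted high-vs-low offset is detected by the paired test", {
  ## high% - low% offset of +5 points across 8 samples, sd 1
  set.seed(4)
  n_samp <- 8
  low <- rnorm(n_samp, 10, 1)
  high <- low + 5 + rnorm(n_samp, 0, 1)
  ## verify via an independent t computation before using the wrapper
  d <- high - low
  t_manual <- mean(d) / (sd(d) / sqrt(n_samp))
  p_manual <- 2 * pt(-abs(t_manual), n_samp - 1)
  expect_lt(p_manual, 0.01)
  ht <- t.test(high, low, paired = TRUE)
  expect_equal(unname(ht$statistic), t_manual, tolerance = 1e-12)
  expect_equal(ht$p.value, p_manual, tolerance = 1e-12)
})

test_that("one-sample t-tests handle symmetric and degenerate input", {
  expect_equal(one_sample_ttest(c(0.5, 0.5, 0.5), 0.5)$p_value, 1)
  expect_equal(one_sample_ttest(c(0.1, 0.2, 0.3), 0.2)$t, 0)
  r <- one_sample_ttest(c(0.5, 0.5), 0.9)
  expect_true(r$degenerate)
  expect_equal(r$p_value, 0)
  ## analytic check: N(0.5, 0.1^2), n = 100 against mu = 0.97 is many
  ## standard errors away
  set.seed(5)
  v <- rnorm(100, 0.5, 0.1)
  r2 <- one_sample_ttest(v, 0.97)
  expect_lt(r2$p_value, 1e-10)
})

test_that("windowed correlations capture identity, sign and independence", {
  tm <- timing_rows("chr1", seq(0, 99) * 1000L, seq(1, 100) * 1000L,
                    sin(seq_len(100)) * 20 + 50)
  sig <- data.frame(chrom = "chr1", start = seq(0, 99) * 1000L,
                    value = tm$timing)
  r1 <- windowed_signal_correlation(sig, tm)
  expect_equal(r1$r_squared, 1)
  sig$value <- -tm$timing
  r2 <- windowed_signal_correlation(sig, tm)
  expect_equal(r2$r_squared, 1)
  expect_equal(r2$r, -1)
  set.seed(6)
  sig$value <- rnorm(100)
  r3 <- windowed_signal_correlation(sig, tm)
  expect_lt(r3$r_squared, 0.1)
  expect_error(windowed_signal_correlation(sig[1:2, ], tm), "fewer than 3")
})
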