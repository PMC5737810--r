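test_that("the toy CDS yields exactly its one planted stop-gain site", {
  sites <- enumerate_stop_gain_tcg("ATGACTCGAAAATAA", gene = "toy")
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$codon_index, 3L)
  expect_equal(sites$ref_codon, "CGA")
  expect_equal(sites$mut_codon, "TGA")
  expect_equal(sites$strand, "coding")
  ## brute force over all substitutions confirms uniqueness
  orc <- oracle_stop_gain("ATGACTCGAAAATAA")
  expect_equal(sites$cds_pos, orc$cds_pos)
  expect_equal(sites$strand, orc$strand)
})

test_that("a CAG codon in TCA context yields no candidate", {
  sites <- enumerate_stop_gain_tcg("ATGACTCAGTAA")
  expect_equal(nrow(sites), 0L)
  expect_equal(nrow(oracle_stop_gain("ATGACTCAGTAA")), 0L)
  ## and a CDS with no TCG context at all is empty
  expect_equal(nrow(enumerate_stop_gain_tcg("ATGAAATTTAAA")), 0L)
})

test_that("flanking bases resolve edge contexts on both strands", {
  ## CGA as the first codon: the 5' T comes from the flank
  with_flank <- enumerate_stop_gain_tcg("CGAAAATAA", flank5 = "T")
  expect_equal(with_flank$codon_index, 1L)
  expect_warning(
    without <- enumerate_stop_gain_tcg("CGAAAATAA", flank5 = "N"),
    "ambiguous")
  expect_equal(nrow(without), 0L)
})

test_that("enumeration matches the all-substitutions oracle on random CDSs", {
  set.seed(21)
  for (i in seq_len(100)) {
    cds <- random_cds(sample(4:15, 1))
    got <- suppressWarnings(
      enumerate_stop_gain_tcg(cds, flank5 = "A", flank3 = "A"))
    orc <- oracle_stop_gain(cds, flank5 = "A", flank3 = "A")
    expect_equal(got$cds_pos, orc$cds_pos, info = cds)
    expect_equal(got$strand, orc$strand, info = cds)
  }
})

test_that("planted gene hotspots are annotated with their CpG methylation", {
  sim <- small_sim()
  for (g in names(sim$genes)) {
    cs <- cds_sequence(sim$genome, sim$genes[[g]])
    sites <- enumerate_stop_gain_tcg(cs$cds, cs$flank5, cs$flank3, gene = g)
    expect_gte(nrow(sites), 1L)
    rk <- rank_hotspot_methylation(sites, sim$genes[[g]], sim$methylation)
    expect_false(any(rk$sites$missing))
    ## the annotated value is the track value at the mapped forward C
    m <- sim$methylation[chrom == sim$genes[[g]]$chrom]
    expect_equal(rk$sites$methylation,
                 m[match(rk$sites$cpg_pos, pos), methylation])
    ## t-test against the gene background is defined whenever the gene
    ## has at least two CpGs with methylation in its coding exons
    if (length(rk$background) >= 2) {
      expect_true(all(vapply(rk$tests, function(t) !is.null(t), TRUE)))
      expect_true(all(vapply(rk$tests, function(t) t$p_value >= 0, TRUE)))
    }
  }
  ## a site absent from the track is flagged missing
  empty_track <- meth_rows("chr1", integer(), numeric())
  cs1 <- cds_sequence(sim$genome, sim$genes$TSG1)
  s1 <- enumerate_stop_gain_tcg(cs1$cds, cs1$flank5, cs1$flank3, "TSG1")
  rk1 <- rank_hotspot_methylation(s1, sim$genes$TSG1, empty_track)
  expect_true(all(rk1$sites$missing))
})

test_that("Fisher p-values match full hypergeometric enumeration", {
  ## the fully unbalanced 10/10 table
  tab <- matrix(c(10L, 0L, 0L, 10L), 2, byrow = TRUE)
  p <- fisher.test(tab)$p.value
  expect_equal(p, 2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(p, oracle_fisher_p(tab), tolerance = 1e-12)
  ## perfect symmetry
  expect_equal(fisher.test(matrix(5L, 2, 2))$p.value, 1)
  ## random tables up to n = 200
  set.seed(22)
  for (i in seq_len(200)) {
    cells <- as.integer(rmultinom(1, sample(4:200, 1), runif(4, 0.05, 1)))
    tb <- matrix(cells, 2, 2)
    expect_equal(fisher.test(tb)$p.value, oracle_fisher_p(tb),
                 tolerance = 1e-9, info = paste(cells, collapse = ","))
  }
})

test_that("strand asymmetry builds the side-by-strand table correctly", {
  org <- list(chrom = "chr1", pos = 10000L, name = "ori")
  ## 10 plus-pyrimidine 5' and 10 minus-pyrimidine 3'
  muts <- mut_rows("chr1",
                   c(9000L + 1:10, 11000L + 1:10),
                   ref = c(rep("C", 10), rep("G", 10)),
                   alt = c(rep("T", 10), rep("A", 10)),
                   sample_id = "s")
  res <- strand_asymmetry(muts, org, flank = 5000, context_class = NULL)
  expect_equal(unclass(res$table),
               matrix(c(10L, 0L, 0L, 10L), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-10)
  ## balanced counts give p = 1
  muts2 <- mut_rows("chr1", 9000L + 1:20,
                    ref = rep(c("C", "G"), 10), alt = rep(c("T", "A"), 10),
                    sample_id = "s")
  res2 <- strand_asymmetry(muts2, org, flank = 5000, context_class = NULL)
  expect_equal(res2$p_value, 1)
  ## reversing the 5'/3' labels transposes the table, p unchanged
  org_flip <- list(chrom = "chr1", pos = 10000L)
  muts_flip <- data.table::copy(muts)[, pos := 20000L - pos]
  data.table::setattr(muts_flip, "class", class(muts))
  res3 <- strand_asymmetry(muts_flip, org_flip, flank = 5000,
                           context_class = NULL)
  expect_equal(res3$table["5prime", ], res$table["3prime", ])
  expect_equal(res3$p_value, res$p_value)
  expect_error(strand_asymmetry(muts, list(chrom = "chr2", pos = 1L),
                                flank = 100, context_class = NULL),
               "no matching")
})

test_that("context classes are matched on the correct strand", {
  ## genome with T C G at 0-based 3..5 (plus) and its reverse complement
  ## C G A at 10..12 carrying the minus-strand TCG
  genome <- make_genome(chr1 = "AAATCGAAAACGAAAA")
  org <- list(chrom = "chr1", pos = 8L)
  muts <- mut_rows("chr1", c(4L, 11L), ref = c("C", "G"),
                   alt = c("T", "A"), sample_id = "s")
  res <- strand_asymmetry(muts, org, flank = 8, context_class = "T[C>T]G",
                          genome = genome)
  expect_equal(res$n, 2L)
  expect_equal(unname(res$table["5prime", "plus"]), 1L)
  expect_equal(unname(res$table["3prime", "minus"]), 1L)
  ## a malformed class is rejected
  expect_error(strand_asymmetry(muts, org, context_class = "TCG",
                                genome = genome),
               "malformed")
})

test_that("a planted 9:1 strand bias is detected at 50 mutations per side", {
  set.seed(23)
  org <- list(chrom = "chr1", pos = 50000L)
  pos <- c(org$pos - sample(25000L, 50), org$pos + sample(25000L, 50))
  muts <- mut_rows("chr1", pos, "C", "T", "s")
  planted <- plant_asymmetry(muts, org, ratio = 0.9, flank = 25000,
                             seed = 24)
  res <- strand_asymmetry(planted, org, flank = 25000,
                          context_class = NULL)
  expect_lt(res$p_value, 0.05)
})

test_that("hotspot contingency reproduces exact enumeration", {
  ## 4 mutant POLE-like vs 46 wild-type MSS-like samples
  group <- c(rep("POLE", 4), rep("MSS", 46))
  mutated <- c(rep(TRUE, 4), rep(FALSE, 46))
  res <- hotspot_contingency(group, mutated)
  expect_equal(res$p_value,
               oracle_fisher_p(matrix(c(0L, 46L, 4L, 0L), 2,
                                      byrow = TRUE)),
               tolerance = 1e-12)
  ## identical proportions give p = 1
  res2 <- hotspot_contingency(rep(c("a", "b"), each = 10),
                              rep(c(TRUE, FALSE), 10))
  expect_equal(res2$p_value, 1)
  ## single-sample groups are uninformative off the margin
  res3 <- hotspot_contingency(c("a", "b"), c(TRUE, FALSE))
  expect_equal(res3$p_value, 1)
  expect_error(hotspot_contingency(rep("a", 5), rep(TRUE, 5)),
               "two non-empty")
})
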