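test_that("methylation reading merges CpG strands and drops non-CpG records", {
  genome <- make_genome(chr1 = "TTACGTTTCGTTACGT")
  ## CpGs at 0-based C positions 3, 8, 13
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t3\t4\t0.8",   # C record of CpG 3
               "chr1\t4\t5\t0.2",   # G record of the same CpG: ignored
               "chr1\t9\t10\t0.5",  # G-only record of CpG 8: fallback
               "chr1\t5\t6\t0.9"),  # not at a CpG: dropped
             path)
  track <- suppressMessages(
    read_methylation(path, genome, chroms = "chr1"))
  expect_equal(track$pos, c(3L, 8L))
  expect_equal(track$methylation, c(0.8, 0.5))
  expect_equal(attr(track, "n_dropped_non_cpg"), 1L)
  expect_equal(attr(track, "n_g_fallback"), 1L)
})

test_that("methylation validation rejects bad values and malformed lines", {
  genome <- make_genome(chr1 = "TTACGTTT")
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t3\t4\t1.7", path)
  expect_error(read_methylation(path, genome, chroms = "chr1"),
               "outside \\[0,1\\]")
  writeLines(c("chr1\t3\t4\t0.5", "chr1\tnot_a_number\t5\t0.2"), path)
  expect_error(read_methylation(path, genome, chroms = "chr1"), "line 2")
})

test_that("methylation tracks round-trip through bedGraph", {
  sim <- small_sim()
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_methylation(sim$methylation, path)
  back <- suppressMessages(
    read_methylation(path, sim$genome, chroms = names(sim$genome)))
  expect_equal(back$chrom, sim$methylation$chrom)
  expect_equal(back$pos, sim$methylation$pos)
  expect_equal(back$methylation, sim$methylation$methylation,
               tolerance = 1e-12)
})

test_that("every simulated methylation record sits on a genomic CpG", {
  sim <- small_sim()
  ctx <- sim$methylation$context
  expect_true(all(substr(ctx, 2, 3) == "CG"))
  ## independent scan of the sequence itself
  scan <- find_cpg_sites(sim$genome)
  expect_true(all(paste(sim$methylation$chrom, sim$methylation$pos) %in%
                    paste(scan$chrom, scan$pos)))
})

test_that("timing windows average within and then across tracks", {
  dir <- withr::local_tempdir()
  pa <- file.path(dir, "a.bedGraph"); pb <- file.path(dir, "b.bedGraph")
  writeLines(c("chr1\t0\t1000000\t40", "chr1\t1000000\t2000000\t10"), pa)
  writeLines(c("chr1\t0\t1000000\t60", "chr1\t1000000\t2000000\t20",
               "chr1\t2000000\t2500000\t60"), pb)
  tt <- read_timing(c(pa, pb), seqlengths = c(chr1 = 2.5e6))
  expect_equal(tt$timing, c(50, 15, 60))
  expect_equal(tt$n_tracks, c(2L, 2L, 1L))
  expect_true(tt$short[3])   # 0.5 Mb end window kept and flagged
  ## single track is the identity
  t1 <- read_timing(pa, seqlengths = c(chr1 = 2e6))
  expect_equal(t1$timing, c(40, 10))
  ## permutation invariance in track order
  rev_tt <- read_timing(c(pb, pa), seqlengths = c(chr1 = 2.5e6))
  expect_equal(rev_tt$timing, tt$timing)
})

test_that("three tracks with window values 10, 20, 60 average to 30", {
  dir <- withr::local_tempdir()
  paths <- file.path(dir, paste0("t", 1:3, ".bedGraph"))
  for (i in seq_along(paths)) {
    writeLines(sprintf("chr1\t0\t1000000\t%d", c(10L, 20L, 60L)[i]),
               paths[i])
  }
  tt <- read_timing(paths, seqlengths = c(chr1 = 1e6))
  expect_equal(tt$timing, mean(c(10, 20, 60)))
})

test_that("wig-format timing tracks are accepted", {
  path <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=1 step=1000000 span=1000000",
               "40", "10"), path)
  tt <- read_timing(path, seqlengths = c(chr1 = 2e6))
  expect_equal(tt$timing, c(40, 10))
})

test_that("timing with no usable values errors", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chrX\t0\t1000000\t40", path)   # excluded by autosome filter
  expect_error(read_timing(path), "no usable")
})

test_that("mutation reading filters PASS and non-SNVs as specified", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tsample\tfilter",
               "chr1\t101\tC\tT\tS1\tPASS",
               "chr1\t201\tG\tA\tS1\tPASS",
               "chr1\t301\tC\tA\tS2\tPASS",
               "chr1\t401\tC\tT\tS2\tLowQual",
               "chr1\t501\tT\tG\tS2\tLowEVS"), path)
  kept <- read_mutations(path, pass_only = TRUE)
  expect_equal(nrow(kept), 3L)
  expect_equal(kept$pos, c(100L, 200L, 300L))   # converted to 0-based
  all5 <- read_mutations(path, pass_only = FALSE)
  expect_equal(nrow(all5), 5L)
  ## indel skipped with warning
  writeLines(c("chrom\tpos\tref\talt\tsample\tfilter",
               "chr1\t101\tAC\tA\tS1\tPASS",
               "chr1\t201\tC\tT\tS1\tPASS"), path)
  expect_warning(snv <- read_mutations(path), "non-SNV")
  expect_equal(nrow(snv), 1L)
  ## missing sample column is an error
  writeLines(c("chrom\tpos\tref\talt", "chr1\t101\tC\tT"), path)
  expect_error(read_mutations(path), "sample")
})

test_that("VCF input is parsed with 1-based conversion and filters", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tC\tT\t.\tPASS\t.",
               "chr1\t200\t.\tG\tA\t.\tLowQual\t."), path)
  muts <- suppressMessages(read_mutations(path, sample_id = "S9"))
  expect_equal(nrow(muts), 1L)
  expect_equal(muts$pos, 99L)
  expect_equal(muts$sample_id, "S9")
})

test_that("mutation tables round-trip through the TSV writer", {
  muts <- mut_rows("chr1", c(10L, 20L), c("C", "G"), c("T", "A"),
                   c("S1", "S2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mutations(muts, path)
  back <- read_mutations(path)
  expect_equal(back$pos, muts$pos)
  expect_equal(back$ref, muts$ref)
  expect_equal(back$sample_id, muts$sample_id)
})

test_that("gene models round-trip through BED12 and reassemble their CDS", {
  sim <- small_sim()
  path <- withr::local_tempfile(fileext = ".bed")
  write_gene_models(sim$genes, path)
  back <- read_gene_models(path)
  expect_setequal(names(back), names(sim$genes))
  for (g in names(back)) {
    expect_equal(back[[g]]$strand, sim$genes[[g]]$strand)
    expect_equal(back[[g]]$exons, sim$genes[[g]]$exons)
  }
  ## the minus-strand two-exon gene reassembles the planted CDS exactly
  cs <- cds_sequence(sim$genome, sim$genes$TSG2)
  expect_equal(cs$cds, "ATGGCTTCGACTCGATGGAAACCCTAA")
  expect_equal(length(cs$genomic_pos), nchar(cs$cds))
  ## CDS length divisible by 3 is enforced
  expect_error(gene_model("bad", "chr1", "+",
                          data.frame(start = 0L, end = 4L)),
               "divisible by 3")
})
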