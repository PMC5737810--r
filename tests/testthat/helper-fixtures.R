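## Shared small fixtures, built once per test run.

make_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

## A small simulated study used across modules: 2 chromosomes of 200 kb,
## ~8000 CpGs, 5 kb timing windows.
small_config <- function(seed = 42) {
  simulation_config(seed = seed, genome_length = 2e5, n_chrom = 2L,
                    window_size = 5e3, timing_period = 5e4,
                    origins = data.table::data.table(
                      chrom = "chr1", pos = 1e5, name = "ori1"))
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_genome(small_config())
    cache
  }
})

## Mutation table literal helper (1-based file convention is handled by
## the readers; this builds the in-memory 0-based representation).
mut_rows <- function(chrom, pos, ref, alt, sample_id, filter = "PASS") {
  dt <- data.table::data.table(chrom = chrom, pos = as.integer(pos),
                               ref = ref, alt = alt, sample_id = sample_id,
                               filter_status = filter)
  data.table::setattr(dt, "class", c("mutation_table", class(dt)))
  dt[]
}

## Methylation track literal helper (positions must be the C of a CpG in
## the companion genome when one is used).
meth_rows <- function(chrom, pos, methylation, context = NULL) {
  dt <- data.table::data.table(chrom = chrom, pos = as.integer(pos),
                               methylation = methylation)
  if (!is.null(context)) dt[, context := context]
  data.table::setkeyv(dt, c("chrom", "pos"))
  data.table::setattr(dt, "class", c("methylation_track", class(dt)))
  dt[]
}

## Timing track literal helper.
timing_rows <- function(chrom, start, end, timing) {
  dt <- data.table::data.table(chrom = chrom, start = start, end = end,
                               timing = timing, n_tracks = 1L,
                               short = FALSE)
  data.table::setkeyv(dt, c("chrom", "start"))
  data.table::setattr(dt, "window_size", unique(end - start)[1])
  data.table::setattr(dt, "class", c("timing_track", class(dt)))
  dt[]
}
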