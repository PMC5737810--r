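## Fully synthetic inputs with the statistical structure the analysis
## assumes: a small genome with a controlled CpG density, bimodal CpG
## methylation, a smooth replication-timing signal, per-sample mutations
## drawn from the logistic mutation-probability model, planted
## strand-asymmetric mutation classes around declared origins, and toy
## CDSs with known stop-gain TCG sites.

#' Default planted genes
#'
#' Two toy tumour-suppressor-like CDSs with known stop-gain TCG sites:
#' `TSG1` (plus strand, single exon) carries exactly one coding-strand
#' site (codon 3, CGA->TGA); `TSG2` (minus strand, two exons) carries one
#' site at codon 5.
#'
#' @return List of gene specifications (`gene`, `strand`, `cds`,
#'   `offset`, `n_exons`).
#' @export
default_gene_specs <- function() {
  list(
    list(gene = "TSG1", strand = "+", cds = "ATGACTCGAAAATAA",
         offset = 1000L, n_exons = 1L),
    list(gene = "TSG2", strand = "-",
         cds = "ATGGCTTCGACTCGATGGAAACCCTAA",
         offset = 3000L, n_exons = 2L))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate a
#' desk-scale colorectal-like study: a strongly bimodal methylation
#' landscape (most CpGs highly methylated, a hypomethylated minority), a
#' smooth replication-timing wave on a 20-80 scale (higher = earlier), and
#' the logistic mutation law with coefficients
#' `b = (-8, 3, -1, 0.01, 0.005)`.
#'
#' @param seed Random seed (mandatory).
#' @param genome_length Length of each chromosome in bp.
#' @param n_chrom Number of chromosomes (named `chr1..`).
#' @param cpg_density Planted CpGs per bp (default 0.02).
#' @param meth_mix Two-component Beta mixture for methylation fractions:
#'   list with `weight` (mixing weights, sum 1), `shape1`, `shape2`.
#' @param timing_range Range of the replication-timing signal.
#' @param timing_period Wavelength in bp of the per-chromosome sinusoid.
#' @param window_size Timing window width in bp (scaled down from the
#'   megabase windows used on real genomes so that desk-scale chromosomes
#'   still span many windows).
#' @param coefficients Named or positional numeric `b0..b4` of the
#'   generating logistic model.
#' @param n_samples Number of tumour samples.
#' @param sample_multiplier Per-sample multiplier on the mutation
#'   probability (scalar or length `n_samples`).
#' @param meth_timing_cor Optional confounding knob in `[-1,1]`: shifts
#'   the odds of drawing the highly-methylated component with standardized
#'   timing (0 = methylation independent of timing).
#' @param origins Planted replication origins: `data.table`/list rows with
#'   `chrom`, `pos`, `name`.
#' @param asym_ratio Probability that a mutation 5' of an origin has its
#'   pyrimidine on the plus strand (mirrored 3'); used by
#'   [plant_asymmetry()].
#' @param genes Planted CDS specifications (see [default_gene_specs()]).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              genome_length = 1e6,
                              n_chrom = 2L,
                              cpg_density = 0.02,
                              meth_mix = list(weight = c(0.2, 0.8),
                                              shape1 = c(1.5, 12),
                                              shape2 = c(15, 2)),
                              timing_range = c(20, 80),
                              timing_period = 2.5e5,
                              window_size = 1e4,
                              coefficients = c(b0 = -8, b1 = 3, b2 = -1,
                                               b3 = 0.01, b4 = 0.005),
                              n_samples = 10L,
                              sample_multiplier = 1,
                              meth_timing_cor = 0,
                              origins = data.table(chrom = "chr1",
                                                   pos = 5e5, name = "ori1"),
                              asym_ratio = 0.9,
                              genes = default_gene_specs()) {
  if (missing(seed)) stopf("simulation_config: a seed is mandatory")
  stopifnot(cpg_density > 0, genome_length > 100, n_chrom >= 1)
  if (cpg_density > 0.25) {
    stopf("cpg_density %.3g too high to place non-overlapping CpGs",
          cpg_density)
  }
  stopifnot(abs(sum(meth_mix$weight) - 1) < 1e-8,
            all(meth_mix$weight >= 0),
            length(meth_mix$shape1) == length(meth_mix$weight),
            length(meth_mix$shape2) == length(meth_mix$weight))
  b <- as.numeric(coefficients)
  stopifnot(length(b) == 5, all(is.finite(b)))
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 n_chrom = as.integer(n_chrom), cpg_density = cpg_density,
                 meth_mix = meth_mix, timing_range = timing_range,
                 timing_period = timing_period, window_size = window_size,
                 coefficients = setNames(b, paste0("b", 0:4)),
                 n_samples = as.integer(n_samples),
                 sample_multiplier = sample_multiplier,
                 meth_timing_cor = meth_timing_cor,
                 origins = as.data.table(origins),
                 asym_ratio = asym_ratio, genes = genes),
            class = "simulation_config")
}

## Smooth per-chromosome timing signal (higher = earlier), at position x.
timing_signal <- function(x, chrom_index, config) {
  rg <- config$timing_range
  mid <- mean(rg); amp <- diff(rg) / 2
  phase <- (chrom_index - 1) * pi / 3
  mid + amp * sin(2 * pi * x / config$timing_period + phase)
}

## Draw methylation fractions from the configured Beta mixture; the
## optional confounding knob shifts the component odds with timing.
draw_methylation <- function(n, timing, config) {
  mix <- config$meth_mix
  k <- length(mix$weight)
  if (k == 2 && config$meth_timing_cor != 0 && sd(timing) > 0) {
    z <- scale(timing)[, 1]
    p_high <- plogis(qlogis(mix$weight[2]) + 2 * config$meth_timing_cor * z)
    comp <- rbinom(n, 1, p_high) + 1L
  } else {
    comp <- sample.int(k, n, replace = TRUE, prob = mix$weight)
  }
  rbeta(n, mix$shape1[comp], mix$shape2[comp])
}

#' Simulate a genome with companion methylation and timing tracks
#'
#' Builds, per chromosome, a CpG-free background sequence, plants
#' `cpg_density * genome_length` CpG dinucleotides at random non-adjacent
#' positions, and overwrites reserved intervals with the configured toy
#' CDSs. All CpGs in the final sequence (planted plus those inside the
#' genes) receive a methylation fraction from the bimodal Beta mixture;
#' the timing track is the smooth configured signal averaged per window.
#' Deterministic given `config$seed`.
#'
#' @param config A `simulation_config`.
#' @return List: `genome` (`DNAStringSet`), `methylation`
#'   (`methylation_track` with a `context` column), `timing`
#'   (`timing_track`), `genes` (list of `gene_model`), `config`.
#' @export
simulate_genome <- function(config) {
  set.seed(seed_stream(config$seed, 1L))
  len <- as.integer(config$genome_length)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  seqs <- character(config$n_chrom)
  gene_models <- list()
  for (ci in seq_len(config$n_chrom)) {
    b <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    ## remove background CpGs: any G following a C becomes A (one pass
    ## suffices: no new G is introduced)
    cg <- which(b[-len] == "C" & b[-1] == "G")
    if (length(cg)) b[cg + 1L] <- "A"
    reserved <- rep(FALSE, len)
    if (ci == 1L) {
      ## plant genes on chr1
      for (gs in config$genes) {
        gseq <- if (gs$strand == "-") revcomp(gs$cds) else gs$cds
        glen <- nchar(gseq)
        if (gs$n_exons == 1L) {
          span <- glen
          b[(gs$offset + 1):(gs$offset + glen)] <- strsplit(gseq, "")[[1]]
          exons <- data.table(start = gs$offset, end = gs$offset + glen)
        } else {
          k <- (glen %/% 2)
          intron <- strsplit("TTATTATTAT", "")[[1]]
          part1 <- substr(gseq, 1, k); part2 <- substr(gseq, k + 1, glen)
          span <- glen + 10L
          b[(gs$offset + 1):(gs$offset + k)] <- strsplit(part1, "")[[1]]
          b[(gs$offset + k + 1):(gs$offset + k + 10)] <- intron
          b[(gs$offset + k + 11):(gs$offset + span)] <-
            strsplit(part2, "")[[1]]
          exons <- data.table(start = c(gs$offset, gs$offset + k + 10L),
                              end = c(gs$offset + k, gs$offset + span))
        }
        reserved[max(1, gs$offset - 1):min(len, gs$offset + span + 2)] <- TRUE
        gene_models[[gs$gene]] <- gene_model(gs$gene, chroms[ci],
                                             gs$strand, exons)
      }
    }
    ## plant CpGs outside reserved intervals, non-adjacent
    n_cpg <- round(config$cpg_density * len)
    cand <- which(!reserved[1:(len - 1L)] & !reserved[2:len])
    cand <- cand[cand > 1 & cand < len - 1]
    picks <- sort(sample(cand, min(length(cand), ceiling(n_cpg * 1.15))))
    keep <- c(TRUE, diff(picks) >= 2L)
    ## also drop picks that would extend a previously planted CpG
    picks <- picks[keep][seq_len(min(n_cpg, sum(keep)))]
    b[picks] <- "C"; b[picks + 1L] <- "G"
    ## planting may create "CCG" runs where b[pick-1] == "C"; those are
    ## legitimate CpGs and are picked up by the genome-wide scan below
    seqs[ci] <- paste(b, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(setNames(seqs, chroms))
  ## timing windows
  seqlengths <- setNames(rep(len, config$n_chrom), chroms)
  windows <- tile_windows(seqlengths, config$window_size)
  windows[, timing := timing_signal((start + end) / 2,
                                    match(chrom, chroms), config)]
  windows[, n_tracks := 1L]
  data.table::setkeyv(windows, c("chrom", "start"))
  data.table::setattr(windows, "window_size", config$window_size)
  data.table::setattr(windows, "class", c("timing_track", class(windows)))
  ## methylation for every CpG in the final genome
  cpgs <- find_cpg_sites(genome)
  site_timing <- timing_signal(cpgs$pos, match(cpgs$chrom, chroms), config)
  meth <- data.table(chrom = cpgs$chrom, pos = cpgs$pos,
                     methylation = draw_methylation(nrow(cpgs),
                                                    site_timing, config),
                     coverage = 30L)
  meth[, context := trinuc_context(genome, chrom, pos)]
  data.table::setkeyv(meth, c("chrom", "pos"))
  data.table::setattr(meth, "class", c("methylation_track", class(meth)))
  list(genome = genome, methylation = meth[], timing = windows[],
       genes = gene_models, config = config)
}

#' Simulate per-CpG covariates without a sequence
#'
#' Generates `n` CpG sites with bimodal methylation, a smooth windowed
#' replication-timing signal and a random (uniform 5' base) trinucleotide
#' context -- the covariate structure the logistic model consumes --
#' without materialising a genome. Used for large parameter-recovery
#' experiments.
#'
#' @param n Number of CpG sites.
#' @param config A `simulation_config`.
#' @param spacing Distance in bp between consecutive sites (default 50).
#' @return `data.table`: `chrom`, `pos`, `M`, `R`, `context`.
#' @export
simulate_cpg_sites <- function(n, config, spacing = 50L) {
  set.seed(seed_stream(config$seed, 2L))
  pos <- seq_len(n) * spacing
  wstart <- floor(pos / config$window_size) * config$window_size
  R <- timing_signal(wstart + config$window_size / 2, 1L, config)
  M <- draw_methylation(n, R, config)
  context <- paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), "CG")
  data.table(chrom = "chr1", pos = as.integer(pos), M = M, R = R,
             context = context)
}

## Linear predictor of the generating model on (M, R).
logistic_lp <- function(M, R, b) {
  b[1] + b[2] * M + b[3] * M^2 + b[4] * R + b[5] * (M * R)
}

#' Draw per-sample mutations from the logistic mutation law
#'
#' Every CpG is mutated independently in each sample with probability
#' `inverse-logit(b0 + b1*M + b2*M^2 + b3*R + b4*M*R)` (times the
#' sample's multiplier), as C>T at the C or G>A at the G with equal
#' probability.
#'
#' @param sites `data.table` with columns `chrom`, `pos`, `M`, `R` (e.g.
#'   from [simulate_cpg_sites()] or a joined genome simulation).
#' @param coefficients Numeric `b0..b4`.
#' @param n_samples Number of samples (`0` gives an empty table).
#' @param seed Random seed.
#' @param sample_multiplier Scalar or per-sample multiplier on the
#'   mutation probability.
#' @return A `mutation_table` with samples `S1..Sn` and `PASS` filters.
#' @export
simulate_mutations <- function(sites, coefficients, n_samples, seed,
                               sample_multiplier = 1) {
  b <- as.numeric(coefficients)
  stopifnot(length(b) == 5, all(is.finite(b)))
  sites <- as.data.table(sites)
  p <- plogis(logistic_lp(sites$M, sites$R, b))
  mult <- rep_len(sample_multiplier, max(n_samples, 1L))
  if (any(p * max(mult) >= 1)) {
    stopf("mutation probability reaches 1; coefficients implausible")
  }
  set.seed(seed_stream(seed, 3L))
  out <- data.table::rbindlist(lapply(seq_len(n_samples), function(s) {
    hit <- which(rbinom(nrow(sites), 1L, p * mult[s]) == 1L)
    if (!length(hit)) return(NULL)
    on_c <- rbinom(length(hit), 1L, 0.5) == 1L
    data.table(chrom = sites$chrom[hit],
               pos = sites$pos[hit] + ifelse(on_c, 0L, 1L),
               ref = ifelse(on_c, "C", "G"),
               alt = ifelse(on_c, "T", "A"),
               sample_id = sprintf("S%02d", s),
               filter_status = "PASS")
  }))
  if (is.null(out) || !nrow(out)) {
    out <- data.table(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      sample_id = character(), filter_status = character())
  }
  data.table::setattr(out, "class", c("mutation_table", class(out)))
  out[]
}

#' Draw signature-style mutations at a fixed trinucleotide context
#'
#' Adds per-sample mutations at forward-strand occurrences of a given
#' trinucleotide (default `TCT`, mutated `C>A` -- the hallmark channel of
#' the POLE-exonuclease signature). POLE-mutant genomes are dominated by
#' such non-CpG mutations, so planting them gives simulated POLE-like
#' samples a spectrum that actually correlates with signature 10.
#'
#' @param genome `DNAStringSet`.
#' @param n_per_sample Mutations to draw per sample.
#' @param sample_ids Character vector of samples.
#' @param seed Random seed.
#' @param context Forward-strand 3-mer (default `"TCT"`).
#' @param ref,alt Substitution applied at the middle base.
#' @return A `mutation_table`.
#' @export
simulate_signature_mutations <- function(genome, n_per_sample, sample_ids,
                                         seed, context = "TCT",
                                         ref = "C", alt = "A") {
  hits <- Biostrings::vmatchPattern(context, genome)
  sites <- data.table::rbindlist(lapply(names(genome), function(ch) {
    data.table(chrom = ch, pos = BiocGenerics::start(hits[[ch]]))  # middle
  }))
  if (!nrow(sites)) stopf("context %s absent from genome", context)
  set.seed(seed_stream(seed, 6L))
  out <- data.table::rbindlist(lapply(sample_ids, function(s) {
    pick <- sites[sample(.N, min(n_per_sample, .N))]
    data.table(chrom = pick$chrom, pos = pick$pos, ref = ref, alt = alt,
               sample_id = s, filter_status = "PASS")
  }))
  data.table::setattr(out, "class", c("mutation_table", class(out)))
  out[]
}

#' Draw a site-level binary outcome from the logistic mutation law
#'
#' One Bernoulli outcome per CpG directly from the model probability --
#' the generating law the regression is meant to recover (a pooled
#' any-of-S-samples outcome would follow a different link).
#'
#' @param sites `data.table` with `M` and `R`.
#' @param coefficients Numeric `b0..b4`.
#' @param seed Random seed.
#' @return A `cpg_table`-compatible `data.table` with `mutated` and
#'   `events` set.
#' @export
simulate_outcomes <- function(sites, coefficients, seed) {
  b <- as.numeric(coefficients)
  sites <- data.table::copy(as.data.table(sites))
  p <- plogis(logistic_lp(sites$M, sites$R, b))
  if (any(p >= 1)) stopf("mutation probability reaches 1")
  set.seed(seed_stream(seed, 4L))
  sites[, events := rbinom(.N, 1L, p)]
  sites[, mutated := events >= 1L]
  data.table::setattr(sites, "class", c("cpg_table", class(sites)))
  sites[]
}

#' Plant strand asymmetry around an origin
#'
#' Reassigns the pyrimidine-strand label of mutations within `flank` bp of
#' an origin: 5' of the origin the mutated pyrimidine lies on the plus
#' strand with probability `ratio`, 3' of it with probability
#' `1 - ratio`. Only the strand label (ref/alt complementation) changes;
#' positions and counts are conserved.
#'
#' @param mutations A `mutation_table`.
#' @param origin List/row with `chrom`, `pos`.
#' @param ratio Plus-strand probability 5' of the origin, in `(0, 1]`.
#' @param flank Flank in bp (default 25000).
#' @param seed Random seed.
#' @return A modified copy of `mutations`.
#' @export
plant_asymmetry <- function(mutations, origin, ratio, flank = 25000, seed) {
  stopifnot(ratio > 0, ratio <= 1)
  org <- as.list(origin)
  mut <- data.table::copy(as.data.table(mutations))
  idx <- which(mut$chrom == org$chrom & abs(mut$pos - org$pos) <= flank)
  if (!length(idx)) stopf("no mutations within the flank")
  set.seed(seed_stream(seed, 5L))
  p_plus <- ifelse(mut$pos[idx] < org$pos, ratio, 1 - ratio)
  want_plus <- rbinom(length(idx), 1L, p_plus) == 1L
  is_plus <- mut$ref[idx] %in% c("C", "T")
  flip <- idx[want_plus != is_plus]
  if (length(flip)) {
    mut[flip, `:=`(ref = comp_base(ref), alt = comp_base(alt))]
  }
  data.table::setattr(mut, "class", class(mutations))
  mut[]
}

#' Write a simulation to the on-disk formats the readers consume
#'
#' @param sim Output of [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @param mutations Optional `mutation_table` to write alongside.
#' @return Named list of the file paths written.
#' @export
write_simulation <- function(sim, dir, mutations = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    methylation = file.path(dir, "methylation.bedGraph"),
    timing = file.path(dir, "timing.bedGraph"),
    genes = file.path(dir, "genes.bed"))
  Biostrings::writeXStringSet(sim$genome, paths$genome)
  write_methylation(sim$methylation, paths$methylation)
  write_timing(sim$timing, paths$timing)
  write_gene_models(sim$genes, paths$genes)
  if (!is.null(mutations)) {
    paths$mutations <- file.path(dir, "mutations.tsv")
    write_mutations(mutations, paths$mutations)
  }
  paths
}
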