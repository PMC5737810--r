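## Truncating-candidate enumeration at TCG trinucleotides in coding
## sequence, hotspot methylation ranking, replication-origin strand
## asymmetry, and hotspot contingency tests.

#' Enumerate C>T stop-gain candidates at TCG trinucleotides
#'
#' Scans an in-frame coding sequence on both strands for positions where a
#' single C>T substitution (i) lies in a 5'-TCG-3' context on the mutated
#' strand and (ii) converts a non-stop codon into an immediate stop codon
#' (TAA/TAG/TGA). A template-strand C>T appears on the coding strand as
#' G>A in a CGA context.
#'
#' @param cds Coding-strand sequence, 5' to 3', length divisible by 3.
#' @param flank5,flank3 Single bases immediately flanking the CDS on the
#'   coding strand (default `"N"`: edge contexts unresolvable and skipped).
#' @param gene Gene name carried into the output.
#' @return `data.table`: `gene`, `codon_index` (1-based), `cds_pos`
#'   (1-based position of the mutated base in the CDS), `strand`
#'   (`"coding"`/`"template"`), `ref_codon`, `mut_codon`, sorted by codon.
#' @export
enumerate_stop_gain_tcg <- function(cds, flank5 = "N", flank3 = "N",
                                    gene = "") {
  cds <- toupper(cds)
  b <- strsplit(cds, "")[[1]]
  L <- length(b)
  if (L %% 3L != 0L) stopf("CDS length %d not divisible by 3", L)
  up <- c(toupper(flank5), b[-L])
  down <- c(b[-1], toupper(flank3))
  ## coding strand: T C G with C>T
  cod <- which(b == "C" & up == "T" & down == "G")
  ## template strand: coding-strand C G A with the G mutated (G>A)
  tmp <- which(b == "G" & up == "C" & down == "A")
  ## candidates whose context cannot be resolved because of an N
  n_ambig <- sum(b == "C" & down == "G" & up == "N") +
    sum(b == "C" & up == "T" & down == "N") +
    sum(b == "G" & up == "C" & down == "N") +
    sum(b == "G" & down == "A" & up == "N")
  if (n_ambig > 0) {
    warnf("enumerate_stop_gain_tcg: %d site(s) with ambiguous context skipped",
          n_ambig)
  }
  scan_one <- function(i, alt, strand) {
    ci <- (i - 1L) %/% 3L + 1L
    off <- (i - 1L) %% 3L + 1L
    ref_codon <- substr(cds, 3L * ci - 2L, 3L * ci)
    mut_codon <- ref_codon
    substr(mut_codon, off, off) <- alt
    if (!(ref_codon %in% STOP_CODONS) && mut_codon %in% STOP_CODONS) {
      data.table(gene = gene, codon_index = ci, cds_pos = i,
                 strand = strand, ref_codon = ref_codon,
                 mut_codon = mut_codon)
    }
  }
  rows <- c(lapply(cod, scan_one, alt = "T", strand = "coding"),
            lapply(tmp, scan_one, alt = "A", strand = "template"))
  out <- data.table::rbindlist(rows)
  if (!nrow(out)) {
    return(data.table(gene = character(), codon_index = integer(),
                      cds_pos = integer(), strand = character(),
                      ref_codon = character(), mut_codon = character()))
  }
  data.table::setorder(out, codon_index, cds_pos)
  out[]
}

## Map a 1-based CDS position to its 0-based genomic coordinate.
cds_to_genomic <- function(model, cds_pos) {
  ex <- model$exons
  gpos <- unlist(lapply(seq_len(nrow(ex)), function(i) {
    seq.int(ex$start[i], ex$end[i] - 1L)
  }))
  if (model$strand == "-") gpos <- rev(gpos)
  gpos[cds_pos]
}

#' Annotate stop-gain candidates with CpG methylation and rank vs background
#'
#' Maps each candidate to the forward-strand C of its CpG, looks up its
#' methylation, and tests the methylation of all CpGs inside the gene's
#' coding exons against each candidate's value with a one-sample t-test
#' (see [one_sample_ttest()]).
#'
#' @param sites Output of [enumerate_stop_gain_tcg()] for one gene.
#' @param model The gene's `gene_model`.
#' @param methylation A `methylation_track`.
#' @return List: `sites` (with `genomic_pos`, `cpg_pos`, `methylation`,
#'   `missing`), `background` (methylation of all CpGs in coding exons),
#'   `tests` (one per annotated site: `t`, `p_value`, ...).
#' @export
rank_hotspot_methylation <- function(sites, model, methylation) {
  sites <- data.table::copy(as.data.table(sites))
  meth <- as.data.table(methylation)
  g <- cds_to_genomic(model, sites$cds_pos)
  ## forward-strand base at the mutated position is C exactly when the
  ## mutated strand and the gene strand agree
  is_fwd_c <- (sites$strand == "coding") == (model$strand == "+")
  cpg_pos <- ifelse(is_fwd_c, g, g - 1L)
  sites[, `:=`(genomic_pos = g, cpg_pos = cpg_pos)]
  mm <- meth[chrom == model$chrom, .(pos, methylation)]
  sites[, methylation := mm[match(sites$cpg_pos, mm$pos), methylation]]
  sites[, missing := is.na(methylation)]
  ex <- model$exons
  bg <- meth[chrom == model$chrom &
               pos %in% unlist(lapply(seq_len(nrow(ex)), function(i) {
                 seq.int(ex$start[i], ex$end[i] - 1L)
               })), methylation]
  tests <- lapply(seq_len(nrow(sites)), function(i) {
    if (sites$missing[i] || length(bg) < 2) return(NULL)
    one_sample_ttest(bg, mu = sites$methylation[i])
  })
  list(sites = sites[], background = bg, tests = tests)
}

## Parse "T[C>T]G" into its components.
parse_context_class <- function(context_class) {
  m <- regmatches(context_class,
                  regexec("^([ACGT])\\[([CT])>([ACGT])\\]([ACGT])$",
                          context_class))[[1]]
  if (length(m) != 5) stopf("malformed context class '%s'", context_class)
  list(up = m[2], from = m[3], to = m[4], down = m[5])
}

#' Mutation strand asymmetry around a replication origin
#'
#' Classifies mutations of a pyrimidine-strand context class (e.g.
#' `T[C>T]G`) falling within `flank` bp of an origin by (5' vs 3' of the
#' origin) x (genomic strand carrying the mutated pyrimidine), and tests
#' the 2x2 table with a two-sided Fisher exact test. Leading/lagging
#' strand roles flip across an origin, so replicase-specific mutagenesis
#' shows up as opposite strand preference on the two sides.
#'
#' @param mutations A `mutation_table`.
#' @param origin List or one-row data.frame with `chrom`, `pos` (0-based)
#'   and optionally `name`.
#' @param flank Flank size in bp on each side (default 25000).
#' @param context_class Pyrimidine-strand class like `"T[C>T]G"`, or
#'   `NULL` to classify every substitution by its pyrimidine strand only.
#' @param genome `DNAStringSet` for context matching; required unless
#'   `context_class` is `NULL`.
#' @return An `asymmetry_result`: `origin`, `flank`, `context_class`,
#'   `table` (2x2: side x strand), `p_value`, `odds_ratio`.
#' @export
strand_asymmetry <- function(mutations, origin, flank = 25000,
                             context_class = "T[C>T]G", genome = NULL) {
  stopifnot(flank > 0)
  org <- as.list(origin)
  mut <- as.data.table(mutations)[
    chrom == org$chrom & abs(pos - org$pos) <= flank & pos != org$pos]
  if (!is.null(context_class)) {
    cc <- parse_context_class(context_class)
    if (is.null(genome)) stopf("context matching requires a genome")
    up <- genome_base(genome, mut$chrom, mut$pos - 1L)
    down <- genome_base(genome, mut$chrom, mut$pos + 1L)
    plus <- mut$ref == cc$from & mut$alt == cc$to &
      up == cc$up & down == cc$down
    minus <- mut$ref == comp_base(cc$from) & mut$alt == comp_base(cc$to) &
      up == comp_base(cc$down) & down == comp_base(cc$up)
  } else {
    plus <- mut$ref %in% c("C", "T")
    minus <- !plus
  }
  keep <- plus | minus
  mut <- mut[keep]
  if (!nrow(mut)) stopf("no matching mutations within the flank")
  side <- ifelse(mut$pos < org$pos, "5prime", "3prime")
  strand <- ifelse(plus[keep], "plus", "minus")
  tab <- table(factor(side, levels = c("5prime", "3prime")),
               factor(strand, levels = c("plus", "minus")))
  ft <- fisher.test(tab)
  structure(list(origin = org$name %||% sprintf("%s:%d", org$chrom, org$pos),
                 flank = flank, context_class = context_class,
                 table = unclass(tab), p_value = ft$p.value,
                 odds_ratio = unname(ft$estimate), n = nrow(mut)),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf("Strand asymmetry at %s (+/- %d bp, class %s)\n",
              x$origin, x$flank, x$context_class %||% "any"))
  print(x$table)
  cat(sprintf("  Fisher exact p = %.3g (odds ratio %.3g, n = %d)\n",
              x$p_value, x$odds_ratio, x$n))
  invisible(x)
}

#' Hotspot mutation contingency between two sample groups
#'
#' 2x2 table of sample group versus hotspot mutation status, tested with a
#' two-sided Fisher exact test (e.g. POLE-mutant vs MSS samples, mutant vs
#' wild-type at a hotspot codon).
#'
#' @param group Character/factor of group labels per sample (exactly two
#'   distinct values, each non-empty).
#' @param site_mutated Logical per sample.
#' @return List: `table`, `p_value`, `odds_ratio`.
#' @export
hotspot_contingency <- function(group, site_mutated) {
  stopifnot(length(group) == length(site_mutated))
  g <- factor(group)
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    stopf("need exactly two non-empty sample groups")
  }
  tab <- table(g, factor(site_mutated, levels = c(TRUE, FALSE),
                         labels = c("mutant", "wild-type")))
  ft <- fisher.test(tab)
  list(table = unclass(tab), p_value = ft$p.value,
       odds_ratio = unname(ft$estimate))
}
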