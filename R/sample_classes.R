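## 96-channel trinucleotide mutation spectra and MSS / MSI / POLE-mutant
## sample classification. POLE-mutant status requires both a somatic POLE
## exonuclease-domain mutation (amino acids 268-471) and a Pearson
## correlation above 0.85 between the sample's spectrum and mutational
## signature 10; MSI-H annotation takes effect only when the POLE criteria
## fail.

POLE_EXO_RANGE <- c(268L, 471L)
SIG10_CORRELATION_THRESHOLD <- 0.85

#' The 96 trinucleotide substitution channels
#'
#' Conventional ordering: six pyrimidine-strand substitution classes
#' (C>A, C>G, C>T, T>A, T>C, T>G), each crossed with the 16 flanking
#' contexts in alphabetical order, e.g. `A[C>A]A`, `A[C>A]C`, ...
#'
#' @return Character vector of length 96.
#' @export
spectrum_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(u, d) {
      paste0(u, "[", s, "]", d)
    })))
  }))
}

## Fold one mutation (ref, alt, forward-strand 3-mer context centred on the
## mutated base) onto its pyrimidine-strand channel; NA if not resolvable.
fold_channel <- function(ref, alt, context) {
  pyr <- ref %in% c("C", "T")
  ref2 <- ifelse(pyr, ref, comp_base(ref))
  alt2 <- ifelse(pyr, alt, comp_base(alt))
  up <- ifelse(pyr, substr(context, 1, 1), comp_base(substr(context, 3, 3)))
  down <- ifelse(pyr, substr(context, 3, 3), comp_base(substr(context, 1, 1)))
  ch <- paste0(up, "[", ref2, ">", alt2, "]", down)
  ch[grepl("N", ch)] <- NA_character_
  ch
}

#' Count mutation channels into a 96-spectrum
#'
#' @param channels Character vector of channel labels (as produced by
#'   [spectrum_channels()]).
#' @return A `spectrum96`: named numeric vector of counts.
#' @export
spectrum_from_channels <- function(channels) {
  all_ch <- spectrum_channels()
  bad <- !is.na(channels) & !channels %in% all_ch
  if (any(bad)) stopf("unknown channel(s): %s", channels[bad][1])
  counts <- table(factor(channels[!is.na(channels)], levels = all_ch))
  structure(as.numeric(counts), names = all_ch, class = "spectrum96")
}

#' Compute a sample's 96-channel trinucleotide spectrum
#'
#' Mutations with a purine reference base are folded to the pyrimidine
#' strand by reverse complement; mutations whose context contains `N` are
#' excluded with a warning. Counts are conserved otherwise.
#'
#' @param mutations A `mutation_table` (typically one sample's records).
#' @param genome `DNAStringSet` used to resolve the +/-1 bp context.
#' @return A `spectrum96` of counts.
#' @export
trinucleotide_spectrum <- function(mutations, genome) {
  mut <- as.data.table(mutations)
  ctx <- trinuc_context(genome, mut$chrom, mut$pos)
  ch <- fold_channel(mut$ref, mut$alt, ctx)
  if (anyNA(ch)) {
    warnf("trinucleotide_spectrum: excluded %d mutation(s) with N context",
          sum(is.na(ch)))
  }
  spectrum_from_channels(ch)
}

#' Normalize a spectrum to proportions
#'
#' @param spectrum A `spectrum96` (or plain numeric vector of length 96).
#' @return A `spectrum96` summing to 1 (all-zero input is returned as is).
#' @export
normalize_spectrum <- function(spectrum) {
  s <- sum(spectrum)
  out <- if (s > 0) spectrum / s else spectrum
  structure(as.numeric(out), names = names(spectrum), class = "spectrum96")
}

#' Load the packaged signature-10 reference spectrum
#'
#' The shipped vector (`inst/extdata/signature10_synthetic.tsv`) is a
#' synthetic stand-in constructed to carry the hallmark of mutational
#' signature 10 -- dominance of the `T[C>A]T` and `T[C>T]G` channels, as
#' seen in POLE-exonuclease-mutant tumours. Supply `path` to use a
#' different reference (e.g. a published signature matrix column).
#'
#' @param path Optional path to a two-column TSV (`channel`, `proportion`).
#' @return A normalized `spectrum96`.
#' @export
load_signature10 <- function(path = NULL) {
  path <- path %||% system.file("extdata", "signature10_synthetic.tsv",
                                package = "mutscape", mustWork = TRUE)
  dt <- data.table::fread(path, sep = "\t")
  stopifnot(all(c("channel", "proportion") %in% names(dt)))
  v <- setNames(dt$proportion, dt$channel)[spectrum_channels()]
  if (anyNA(v)) stopf("signature file is missing channels")
  normalize_spectrum(structure(as.numeric(v), names = spectrum_channels(),
                               class = "spectrum96"))
}

#' Classify one sample as MSS / MSI / POLE-mutant
#'
#' A sample is POLE-mutant iff it carries a somatic POLE mutation in the
#' exonuclease domain (amino acids 268-471) *and* its spectrum has Pearson
#' correlation strictly greater than 0.85 with signature 10. Samples
#' failing the POLE rule are labelled `MSI` when annotated MSI-H, `MSS`
#' when annotated microsatellite stable, and `unclassified` otherwise (or
#' when the correlation is undefined because a spectrum has zero variance).
#'
#' @param sample_id Sample name.
#' @param protein_mutations `data.table`/data.frame of the sample's somatic
#'   protein-level mutations with columns `gene` and `aa_pos`.
#' @param spectrum The sample's `spectrum96`.
#' @param signature10 Reference spectrum (default [load_signature10()]).
#' @param msi_status External annotation: `"MSI-H"`, `"MSS"`, or `NA`.
#' @return One-row `data.table`: `sample_id`, `msi_status`,
#'   `pole_exonuclease_mutation`, `sig10_correlation`, `label`, `reason`.
#' @export
classify_pole <- function(sample_id, protein_mutations, spectrum,
                          signature10 = load_signature10(),
                          msi_status = NA_character_) {
  pm <- as.data.table(protein_mutations)
  pole_mut <- nrow(pm) > 0 && pm[
    gene == "POLE" & aa_pos >= POLE_EXO_RANGE[1] & aa_pos <= POLE_EXO_RANGE[2],
    .N] > 0
  sp <- normalize_spectrum(spectrum)
  sg <- normalize_spectrum(signature10)
  undefined <- sd(sp) == 0 || sd(sg) == 0
  r <- if (undefined) NA_real_ else cor(as.numeric(sp), as.numeric(sg))
  reason <- NA_character_
  if (!undefined && pole_mut && r > SIG10_CORRELATION_THRESHOLD) {
    label <- "POLE-mutant"
  } else if (!is.na(msi_status) && msi_status == "MSI-H") {
    label <- "MSI"
  } else if (!is.na(msi_status) && msi_status == "MSS") {
    label <- "MSS"
  } else {
    label <- "unclassified"
    reason <- if (undefined) "zero-variance spectrum" else "no annotation"
  }
  data.table(sample_id = sample_id, msi_status = msi_status,
             pole_exonuclease_mutation = pole_mut,
             sig10_correlation = r, label = label, reason = reason)
}

#' Classify every sample of a cohort
#'
#' @param mutations A `mutation_table` covering all samples.
#' @param genome `DNAStringSet` for spectrum contexts.
#' @param protein_mutations Table with columns `sample_id`, `gene`,
#'   `aa_pos` (somatic protein-level calls).
#' @param msi_annotations Named character vector, sample -> annotation.
#' @param signature10 Reference spectrum (default [load_signature10()]).
#' @return `data.table` of per-sample labels (see [classify_pole()]).
#' @export
classify_samples <- function(mutations, genome, protein_mutations,
                             msi_annotations = character(),
                             signature10 = load_signature10()) {
  mut <- as.data.table(mutations)
  pm <- as.data.table(protein_mutations)
  samples <- sort(unique(mut$sample_id))
  data.table::rbindlist(lapply(samples, function(s) {
    classify_pole(
      sample_id = s,
      protein_mutations = pm[sample_id == s, .(gene, aa_pos)],
      spectrum = trinucleotide_spectrum(mut[sample_id == s], genome),
      signature10 = signature10,
      msi_status = if (s %in% names(msi_annotations))
        msi_annotations[[s]] else NA_character_)
  }))
}
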