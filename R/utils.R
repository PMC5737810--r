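## Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default autosome allow-list
#'
#' Chromosome names retained by default throughout the package. Regression
#' models and binned associations use autosomal data only, so sex
#' chromosomes, the mitochondrial genome and non-primary contigs are
#' excluded up front. Both UCSC-style (`chr1`) and bare (`1`) names are
#' accepted.
#'
#' @return Character vector of allowed chromosome names.
#' @export
autosome_names <- function() {
  c(paste0("chr", 1:22), as.character(1:22))
}

## Filter a data.table on an allow-list of chromosome names (NULL = keep all).
filter_chroms <- function(dt, chroms) {
  if (is.null(chroms)) return(dt)
  dt[chrom %in% chroms]
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_base <- function(x) unname(COMPLEMENT[x])

revcomp <- function(s) {
  vapply(strsplit(s, ""), function(b) {
    paste(rev(unname(COMPLEMENT[b])), collapse = "")
  }, character(1))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

## Translate a codon via the standard genetic code (Biostrings table).
codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  unname(aa)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Validate a single seed and derive a stream of sub-seeds below 2^31.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483647L
}

is_single_base <- function(x) x %in% c("A", "C", "G", "T")

## Function-specific RNG stream: the same user seed must give a different
## (decorrelated) stream in each generator stage, otherwise e.g. the
## Bernoulli outcome draw would reuse the very uniforms that produced the
## methylation covariates and induce a spurious association. Lehmer-style
## mixing keeps the result a valid 32-bit seed and fully deterministic.
seed_stream <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 48271 + 62089911 * salt) %% 2147483647)
}
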