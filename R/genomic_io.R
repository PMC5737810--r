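## Readers and writers for the external formats the pipeline consumes:
## reference FASTA, WGBS methylation bedGraph/BED, replication-timing
## bedGraph/WIG, somatic mutation tables (TSV or VCF) and BED12 gene models.
##
## Coordinate dialect: everything is 0-based half-open internally. BED-family
## input is taken as 0-based; VCF-like input (including the tab-delimited
## mutation table, whose `pos` column follows VCF convention) is 1-based and
## converted on read.

#' Read a reference genome from FASTA
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return A [Biostrings::DNAStringSet] with sequence names truncated to the
#'   first whitespace-delimited token.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Locate all CpG dinucleotides in a genome
#'
#' @param genome A `DNAStringSet`.
#' @param chroms Chromosome allow-list (default all sequences present).
#' @return `data.table` with columns `chrom` and `pos`, where `pos` is the
#'   0-based coordinate of the C of each forward-strand CpG.
#' @export
find_cpg_sites <- function(genome, chroms = NULL) {
  keep <- names(genome)
  if (!is.null(chroms)) keep <- intersect(keep, chroms)
  hits <- Biostrings::vmatchPattern("CG", genome[keep])
  out <- data.table::rbindlist(lapply(keep, function(ch) {
    data.table(chrom = ch, pos = BiocGenerics::start(hits[[ch]]) - 1L)
  }))
  data.table::setkeyv(out, c("chrom", "pos"))
  out[]
}

## Base at a 0-based position ("N" outside bounds).
genome_base <- function(genome, chrom, pos) {
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  ok <- !is.na(len) & pos >= 0L & pos < len
  out <- rep("N", length(pos))
  for (ch in unique(chrom[ok])) {
    sel <- ok & chrom == ch
    out[sel] <- as.character(Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(pos[sel] + 1L, pos[sel] + 1L)))
  }
  out
}

#' Trinucleotide context around positions
#'
#' @param genome A `DNAStringSet`.
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @return Character vector of 3-mers centred on `pos` (forward strand),
#'   padded with `N` at sequence bounds.
#' @export
trinuc_context <- function(genome, chrom, pos) {
  paste0(genome_base(genome, chrom, pos - 1L),
         genome_base(genome, chrom, pos),
         genome_base(genome, chrom, pos + 1L))
}

## ---------------------------------------------------------------------------
## Methylation

## Read a bedGraph/BED-like table with fread, reporting 1-based line numbers
## (header excluded) for malformed rows.
read_bedgraph_like <- function(path, value_name = "value") {
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE),
    error = function(e) stopf("cannot parse '%s': %s", path, conditionMessage(e))
  )
  ## tolerate a track/header line
  if (nrow(dt) && is.character(dt[[2]][1]) &&
      is.na(suppressWarnings(as.numeric(dt[[2]][1])))) {
    dt <- dt[-1]
  }
  if (ncol(dt) < 4L) stopf("'%s': expected >= 4 bedGraph columns", path)
  out <- dt[, 1:4]
  data.table::setnames(out, c("chrom", "start", "end", value_name))
  out[, chrom := as.character(chrom)]
  for (col in c("start", "end", value_name)) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]))
    if (length(bad)) {
      stopf("'%s' line %d: malformed field '%s'", path, bad[1], col)
    }
    data.table::set(out, j = col, value = v)
  }
  if (ncol(dt) >= 5L) {
    out[, coverage := suppressWarnings(as.numeric(dt[[5]]))]
  }
  out
}

## Import a WIG track as a (chrom, start, end, value) table (0-based).
read_wig_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "wig")
  data.table(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             value = as.numeric(gr$score))
}

#' Read a single-base CpG methylation track
#'
#' Reads a WGBS methylation bedGraph/BED (one row per cytosine, value =
#' fraction methylated in `[0,1]`, optional fifth column = read coverage)
#' and merges the two strands of each CpG: where the forward-strand cytosine
#' carries a value it is kept; where only the G-strand record exists its
#' value is used as a fallback (counted). Records not overlapping a genomic
#' CpG are dropped (counted).
#'
#' @param path bedGraph/BED file (0-based starts) or WIG file.
#' @param genome `DNAStringSet` of the companion genome.
#' @param min_coverage Minimum read coverage to retain a record (default 0:
#'   no filter).
#' @param chroms Chromosome allow-list; default [autosome_names()].
#' @return A `methylation_track`: `data.table` with columns `chrom`, `pos`
#'   (0-based C of the CpG), `methylation`, and `coverage` when present.
#'   Attributes `n_dropped_non_cpg` and `n_g_fallback` record the merge.
#' @export
read_methylation <- function(path, genome, min_coverage = 0,
                             chroms = autosome_names()) {
  if (grepl("\\.wig(\\.gz)?$", path, ignore.case = TRUE)) {
    dt <- read_wig_intervals(path)
  } else {
    dt <- read_bedgraph_like(path)
  }
  dt <- filter_chroms(dt, chroms)
  dt <- dt[chrom %in% names(genome)]
  if (!nrow(dt)) stopf("no methylation records on allowed chromosomes")
  if (dt[, any(value < 0 | value > 1)]) {
    stopf("methylation values outside [0,1]; first offending value %g",
          dt[value < 0 | value > 1][1, value])
  }
  dt[, pos := as.integer(start)]
  if (min_coverage > 0 && "coverage" %in% names(dt)) {
    dt <- dt[coverage >= min_coverage]
  }
  base0 <- genome_base(genome, dt$chrom, dt$pos)
  is_c <- base0 == "C" &
    genome_base(genome, dt$chrom, dt$pos + 1L) == "G"
  is_g <- base0 == "G" &
    genome_base(genome, dt$chrom, dt$pos - 1L) == "C"
  n_dropped <- sum(!is_c & !is_g)
  if (n_dropped > 0) {
    message(sprintf("read_methylation: dropped %d records not at a CpG",
                    n_dropped))
  }
  dt[, `:=`(cpg_pos = ifelse(is_c, pos, pos - 1L),
            is_c_record = is_c)]
  dt <- dt[is_c | is_g]
  ## forward-strand C record wins; G-strand record only as fallback
  data.table::setorder(dt, chrom, cpg_pos, -is_c_record)
  merged <- dt[, .SD[1], by = .(chrom, cpg_pos)]
  n_fallback <- merged[, sum(!is_c_record)]
  if (n_fallback > 0) {
    message(sprintf(
      "read_methylation: %d CpGs used the G-strand value (no C record)",
      n_fallback))
  }
  keep_cols <- c("chrom", "cpg_pos", "value",
                 if ("coverage" %in% names(merged)) "coverage")
  out <- merged[, keep_cols, with = FALSE]
  data.table::setnames(out, c("cpg_pos", "value"), c("pos", "methylation"))
  data.table::setkeyv(out, c("chrom", "pos"))
  data.table::setattr(out, "n_dropped_non_cpg", n_dropped)
  data.table::setattr(out, "n_g_fallback", n_fallback)
  data.table::setattr(out, "class",
                      c("methylation_track", class(out)))
  out[]
}

#' Write a methylation track as bedGraph
#'
#' @param track A `methylation_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(track, path) {
  out <- data.table(chrom = track$chrom, start = track$pos,
                    end = track$pos + 1L, value = track$methylation)
  if ("coverage" %in% names(track)) out[, coverage := track$coverage]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Replication timing

#' Read replication-timing tracks into megabase windows
#'
#' Divides the genome into fixed-width windows and computes, per window, the
#' mean across tracks of each track's within-window (overlap-weighted) mean.
#' Higher values mean earlier replication. Windows with no data in any track
#' are kept with `timing = NA`; windows truncated at chromosome ends are
#' flagged `short`.
#'
#' @param paths One or more bedGraph (0-based) or WIG files, one per
#'   cell type.
#' @param window_size Window width in bp (default 1e6).
#' @param seqlengths Named vector of chromosome lengths; taken from `genome`
#'   if supplied, otherwise from the maximum covered coordinate per
#'   chromosome.
#' @param genome Optional `DNAStringSet` supplying `seqlengths`.
#' @param chroms Chromosome allow-list; default [autosome_names()].
#' @return A `timing_track`: `data.table` with columns `chrom`, `start`,
#'   `end`, `timing`, `n_tracks` (tracks contributing) and `short`.
#' @export
read_timing <- function(paths, window_size = 1e6, seqlengths = NULL,
                        genome = NULL, chroms = autosome_names()) {
  stopifnot(length(paths) >= 1)
  tracks <- lapply(paths, function(p) {
    dt <- if (grepl("\\.wig(\\.gz)?$", p, ignore.case = TRUE)) {
      read_wig_intervals(p)
    } else {
      read_bedgraph_like(p)
    }
    filter_chroms(dt, chroms)
  })
  if (sum(vapply(tracks, nrow, 1L)) == 0L) {
    stopf("no usable replication-timing values on allowed chromosomes")
  }
  if (is.null(seqlengths)) {
    if (!is.null(genome)) {
      seqlengths <- setNames(Biostrings::width(genome), names(genome))
      if (!is.null(chroms)) {
        seqlengths <- seqlengths[names(seqlengths) %in% chroms]
      }
    } else {
      cov <- data.table::rbindlist(tracks)[, .(len = max(end)), by = chrom]
      seqlengths <- setNames(cov$len, cov$chrom)
    }
  }
  windows <- tile_windows(seqlengths, window_size)
  means <- lapply(seq_along(tracks), function(i) {
    window_means(tracks[[i]], windows)[, track := i]
  })
  means <- data.table::rbindlist(means)
  agg <- means[!is.na(value),
               .(timing = mean(value), n_tracks = .N),
               by = .(chrom, start)]
  out <- merge(windows, agg, by = c("chrom", "start"), all.x = TRUE)
  out[is.na(n_tracks), n_tracks := 0L]
  if (all(is.na(out$timing))) stopf("all timing windows empty")
  data.table::setkeyv(out, c("chrom", "start"))
  data.table::setattr(out, "window_size", window_size)
  data.table::setattr(out, "class", c("timing_track", class(out)))
  out[]
}

## Fixed-width windows over named chromosome lengths (0-based half-open).
tile_windows <- function(seqlengths, window_size) {
  out <- data.table::rbindlist(lapply(names(seqlengths), function(ch) {
    len <- as.numeric(seqlengths[[ch]])
    starts <- seq(0, len - 1, by = window_size)
    data.table(chrom = ch, start = starts,
               end = pmin(starts + window_size, len))
  }))
  out[, short := (end - start) < window_size]
  out
}

## Overlap-weighted per-window mean of one interval track.
window_means <- function(dt, windows) {
  if (!nrow(dt)) {
    return(data.table(chrom = windows$chrom, start = windows$start,
                      value = NA_real_))
  }
  w <- data.table::copy(windows)[, .(chrom, wstart = start, wend = end)]
  x <- dt[, .(chrom, start, end, value)]
  data.table::setkeyv(w, c("chrom", "wstart", "wend"))
  ov <- data.table::foverlaps(
    x[, .(chrom, wstart = start, wend = end, value)], w,
    by.x = c("chrom", "wstart", "wend"), type = "any", nomatch = NULL)
  ov[, overlap := pmin(i.wend, wend) - pmax(i.wstart, wstart)]
  m <- ov[overlap > 0,
          .(value = sum(value * overlap) / sum(overlap)),
          by = .(chrom, start = wstart)]
  merge(windows[, .(chrom, start)], m, by = c("chrom", "start"),
        all.x = TRUE)
}

#' Write a timing track as bedGraph
#'
#' @param track A `timing_track`.
#' @param path Output path.
#' @return `path`, invisibly. Windows without data are omitted.
#' @export
write_timing <- function(track, path) {
  out <- track[!is.na(timing), .(chrom, start, end, timing)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Somatic mutations

#' Read somatic single-base substitutions
#'
#' Accepts either a tab-delimited table with header columns
#' `chrom, pos, ref, alt, sample` (optional `filter`; `pos` 1-based, VCF
#' convention) or a VCF 4.x file. Indels and multi-nucleotide variants are
#' skipped with a warning; with `pass_only` only records whose filter status
#' is `PASS` are kept.
#'
#' @param path Input file.
#' @param pass_only Keep only `PASS` records (default `TRUE`).
#' @param sample_id Sample name to assign when the input (e.g. a VCF)
#'   carries none; defaults to the file base name.
#' @param chroms Chromosome allow-list (`NULL` = keep all).
#' @return A `mutation_table`: `data.table` with columns `chrom`, `pos`
#'   (0-based), `ref`, `alt`, `sample_id`, `filter_status`.
#' @export
read_mutations <- function(path, pass_only = TRUE, sample_id = NULL,
                           chroms = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^##fileformat=VCF", first)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.table(vcfR::getFIX(vcf))
    dt <- data.table(
      chrom = as.character(fix$CHROM),
      pos = as.integer(fix$POS) - 1L,
      ref = as.character(fix$REF),
      alt = as.character(fix$ALT),
      sample_id = sample_id %||% sub("\\.vcf(\\.gz)?$", "", basename(path)),
      filter_status = ifelse(is.na(fix$FILTER) | fix$FILTER == ".",
                             "PASS", as.character(fix$FILTER)))
  } else {
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
    data.table::setnames(dt, tolower(names(dt)))
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(dt))) {
      stopf("mutation table missing column(s): %s",
            paste(setdiff(need, names(dt)), collapse = ", "))
    }
    if (!"sample" %in% names(dt) && !"sample_id" %in% names(dt)) {
      stopf("mutation table has no 'sample' column")
    }
    if ("sample" %in% names(dt)) {
      data.table::setnames(dt, "sample", "sample_id")
    }
    if (!"filter" %in% names(dt) && !"filter_status" %in% names(dt)) {
      dt[, filter_status := "PASS"]
    } else if ("filter" %in% names(dt)) {
      data.table::setnames(dt, "filter", "filter_status")
    }
    dt <- dt[, .(chrom = as.character(chrom), pos = as.integer(pos) - 1L,
                 ref = toupper(as.character(ref)),
                 alt = toupper(as.character(alt)),
                 sample_id = as.character(sample_id),
                 filter_status = as.character(filter_status))]
  }
  dt <- filter_chroms(dt, chroms)
  snv <- is_single_base(dt$ref) & is_single_base(dt$alt) & dt$ref != dt$alt
  if (any(!snv)) {
    warnf("read_mutations: skipped %d non-SNV record(s)", sum(!snv))
    dt <- dt[snv]
  }
  n_before <- nrow(dt)
  if (pass_only) {
    dt <- dt[filter_status == "PASS"]
    if (nrow(dt) < n_before) {
      message(sprintf("read_mutations: excluded %d non-PASS record(s)",
                      n_before - nrow(dt)))
    }
  }
  data.table::setattr(dt, "class", c("mutation_table", class(dt)))
  dt[]
}

#' Write a mutation table (1-based TSV)
#'
#' @param muts A `mutation_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(muts, path) {
  out <- data.table(chrom = muts$chrom, pos = muts$pos + 1L,
                    ref = muts$ref, alt = muts$alt,
                    sample = muts$sample_id, filter = muts$filter_status)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Gene models

#' Construct a gene model
#'
#' @param gene Gene name.
#' @param chrom Chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.table`/data.frame of CDS exon intervals (`start`,
#'   `end`; 0-based half-open), in genomic order, non-overlapping, with
#'   total length divisible by 3.
#' @return A `gene_model` list.
#' @export
gene_model <- function(gene, chrom, strand, exons) {
  exons <- as.data.table(exons)[, .(start = as.integer(start),
                                    end = as.integer(end))]
  data.table::setorder(exons, start)
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stopf("gene %s: overlapping CDS exons", gene)
  }
  len <- exons[, sum(end - start)]
  if (len %% 3L != 0L) {
    stopf("gene %s: CDS length %d not divisible by 3", gene, len)
  }
  stopifnot(strand %in% c("+", "-"))
  structure(list(gene = gene, chrom = chrom, strand = strand,
                 exons = exons, cds_length = len),
            class = "gene_model")
}

#' Read gene models from BED12
#'
#' Blocks are interpreted as CDS exons (the convention used by the
#' simulator's output and by CDS-only BED12 exports).
#'
#' @param path BED12 file.
#' @return List of `gene_model` objects, named by gene.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  models <- lapply(seq_along(gr), function(i) {
    blocks <- gr$blocks[[i]]
    abs_start <- BiocGenerics::start(gr)[i] - 1L   # back to 0-based
    exons <- data.table(
      start = abs_start + BiocGenerics::start(blocks) - 1L,
      end = abs_start + BiocGenerics::end(blocks))
    gene_model(gene = gr$name[i],
               chrom = as.character(GenomeInfoDb::seqnames(gr))[i],
               strand = as.character(BiocGenerics::strand(gr))[i],
               exons = exons)
  })
  names(models) <- vapply(models, `[[`, "", "gene")
  models
}

#' Write gene models as BED12
#'
#' @param models List of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    ex <- m$exons
    data.table(chrom = m$chrom, start = ex$start[1], end = ex$end[nrow(ex)],
               name = m$gene, score = 0L, strand = m$strand,
               thickStart = ex$start[1], thickEnd = ex$end[nrow(ex)],
               rgb = "0,0,0", blockCount = nrow(ex),
               blockSizes = paste0(paste(ex$end - ex$start, collapse = ","), ","),
               blockStarts = paste0(paste(ex$start - ex$start[1],
                                          collapse = ","), ","))
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Extract the coding sequence of a gene model
#'
#' @param genome `DNAStringSet`.
#' @param model A `gene_model`.
#' @return List with `cds` (5'->3' coding-strand sequence), `flank5` and
#'   `flank3` (single bases immediately outside the CDS on the coding
#'   strand), and `genomic_pos` (integer vector mapping each CDS position,
#'   1-based in CDS order, to its 0-based genomic coordinate).
#' @export
cds_sequence <- function(genome, model) {
  ex <- model$exons
  gpos <- unlist(lapply(seq_len(nrow(ex)), function(i) {
    seq.int(ex$start[i], ex$end[i] - 1L)
  }))
  seqs <- as.character(Biostrings::extractAt(
    genome[[model$chrom]], IRanges::IRanges(ex$start + 1L, ex$end)))
  cds <- paste(seqs, collapse = "")
  left <- genome_base(genome, model$chrom, ex$start[1] - 1L)
  right <- genome_base(genome, model$chrom, ex$end[nrow(ex)])
  if (model$strand == "-") {
    cds <- revcomp(cds)
    gpos <- rev(gpos)
    fl5 <- comp_base(right); fl3 <- comp_base(left)
  } else {
    fl5 <- left; fl3 <- right
  }
  list(cds = cds, flank5 = fl5, flank3 = fl3, genomic_pos = gpos)
}
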