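## The genome-wide per-CpG annotation table: one row per CpG dinucleotide
## with methylation (M), replication timing (R), trinucleotide context and
## mutation status. Every downstream association and regression consumes it.

#' Default deamination-equivalent mutation classes
#'
#' A mutation is assigned to a CpG if it falls on either base of the
#' dinucleotide and matches the class rule: `"deamination"` keeps C>T at the
#' C plus the strand-symmetric G>A at the G (the 5mC deamination signature);
#' `"all"` keeps any single-base substitution at either base.
#'
#' @name mutation-classes
NULL

## Assign mutations to CpG sites under a class rule. Returns the matching
## records with the 0-based position of the CpG's C in `cpg_pos`.
match_mutations_to_cpgs <- function(mutations, cpg_pos_by_chrom,
                                    mutation_classes = "deamination") {
  mut <- as.data.table(mutations)
  keyed <- cpg_pos_by_chrom
  at_c <- keyed[mut, on = c("chrom", "pos"), which = TRUE]
  g <- data.table(chrom = mut$chrom, pos = mut$pos - 1L)
  at_g <- keyed[g, on = c("chrom", "pos"), which = TRUE]
  hit_c <- !is.na(at_c)
  hit_g <- !is.na(at_g)
  if (mutation_classes == "deamination") {
    hit_c <- hit_c & mut$ref == "C" & mut$alt == "T"
    hit_g <- hit_g & mut$ref == "G" & mut$alt == "A"
  } else if (mutation_classes != "all") {
    stopf("unknown mutation_classes '%s'", mutation_classes)
  }
  ## a position can only be the C or the G of a given CpG, prefer C-match
  cpg_pos <- rep(NA_integer_, nrow(mut))
  cpg_pos[hit_g] <- mut$pos[hit_g] - 1L
  cpg_pos[hit_c] <- mut$pos[hit_c]
  out <- data.table::copy(mut)[, cpg_pos := cpg_pos]
  out[!is.na(cpg_pos)]
}

#' Build the per-CpG annotation table
#'
#' Joins a methylation track, a replication-timing track and a cohort's
#' somatic mutations into one row per CpG with methylation data. A CpG is
#' `mutated` if at least one sample in the supplied cohort carries a
#' matching mutation on either base of the dinucleotide (the binary outcome
#' is therefore evaluated per cohort or subtype: subset `mutations` before
#' calling).
#'
#' @param methylation A `methylation_track` (defines the CpG set; CpGs
#'   without methylation data are not represented).
#' @param timing A `timing_track`, or `NULL` to leave `R` as `NA`.
#' @param mutations A `mutation_table` for the cohort under analysis.
#' @param genome Optional `DNAStringSet` used to derive trinucleotide
#'   contexts; if `NULL`, a `context` column already present on
#'   `methylation` is used (as produced by the simulator), else `NA`.
#' @param mutation_classes `"deamination"` (default: C>T at the C, G>A at
#'   the G) or `"all"` (any substitution at either base).
#' @param chroms Chromosome allow-list; default [autosome_names()].
#' @return A `cpg_table`: `data.table` with columns `chrom`, `pos`, `M`,
#'   `R`, `context`, `mutated`, `events`. Attribute `sample_hits` holds the
#'   per-sample event counts (`chrom`, `pos`, `sample_id`, `n`); attribute
#'   `mutation_classes` records the rule used.
#' @export
build_cpg_table <- function(methylation, timing, mutations, genome = NULL,
                            mutation_classes = "deamination",
                            chroms = autosome_names()) {
  meth <- filter_chroms(as.data.table(methylation), chroms)
  if (!nrow(meth)) stopf("no CpGs with methylation on allowed chromosomes")
  tab <- meth[, .(chrom, pos, M = methylation)]
  if (!is.null(genome)) {
    tab[, context := trinuc_context(genome, chrom, pos)]
  } else if ("context" %in% names(meth)) {
    tab[, context := meth$context]
  } else {
    tab[, context := NA_character_]
  }
  ## replication timing from the enclosing window
  if (!is.null(timing)) {
    wsize <- attr(timing, "window_size") %||%
      as.numeric(stats::median(timing$end - timing$start))
    tw <- as.data.table(timing)[, .(chrom, wstart = start, timing)]
    tab[, wstart := floor(pos / wsize) * wsize]
    tab <- tw[tab, on = c("chrom", "wstart")]
    tab[, `:=`(R = timing, timing = NULL, wstart = NULL)]
  } else {
    tab[, R := NA_real_]
  }
  data.table::setcolorder(tab, c("chrom", "pos", "M", "R", "context"))
  data.table::setkeyv(tab, c("chrom", "pos"))
  ## mutation assignment
  if (!is.null(mutations) && nrow(mutations)) {
    mut <- filter_chroms(as.data.table(mutations), chroms)
    matched <- match_mutations_to_cpgs(
      mut, tab[, .(chrom, pos)], mutation_classes)
    hits <- matched[, .(n = .N), by = .(chrom, pos = cpg_pos, sample_id)]
  } else {
    hits <- data.table(chrom = character(), pos = integer(),
                       sample_id = character(), n = integer())
  }
  ev <- hits[, .(events = sum(n)), by = .(chrom, pos)]
  tab <- ev[tab, on = c("chrom", "pos")]
  tab[is.na(events), events := 0L]
  tab[, mutated := events >= 1L]
  data.table::setcolorder(tab, c("chrom", "pos", "M", "R", "context",
                                 "mutated", "events"))
  data.table::setattr(tab, "sample_hits", hits)
  data.table::setattr(tab, "mutation_classes", mutation_classes)
  data.table::setattr(tab, "class", c("cpg_table", class(tab)))
  tab[]
}

#' Serialize / load a per-CpG table
#'
#' Tab-delimited with header `chrom, pos, M, R, context, mutated, events`.
#' The per-sample hit attribute is written alongside when present
#' (`<path>.samples`).
#'
#' @param table A `cpg_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpg_table <- function(table, path) {
  data.table::fwrite(
    table[, .(chrom, pos, M, R, context, mutated = as.integer(mutated),
              events)],
    path, sep = "\t")
  hits <- attr(table, "sample_hits")
  if (!is.null(hits) && nrow(hits)) {
    data.table::fwrite(hits, paste0(path, ".samples"), sep = "\t")
  }
  invisible(path)
}

#' @rdname write_cpg_table
#' @export
read_cpg_table <- function(path) {
  tab <- data.table::fread(path, sep = "\t")
  tab[, mutated := as.logical(mutated)]
  data.table::setkeyv(tab, c("chrom", "pos"))
  spath <- paste0(path, ".samples")
  if (file.exists(spath)) {
    data.table::setattr(tab, "sample_hits", data.table::fread(spath))
  }
  data.table::setattr(tab, "class", c("cpg_table", class(tab)))
  tab[]
}

#' Mutation and methylation profile around transcription start sites
#'
#' Pools mutations over a set of TSS anchors into nucleotide-resolution
#' counts by position relative to the TSS, together with binned counts and
#' the mean methylation profile. Positions at minus-strand anchors are
#' reflected so that the transcribed direction is always positive.
#'
#' @param mutations A `mutation_table`.
#' @param methylation A `methylation_track` (or `NULL` to skip the
#'   methylation profile).
#' @param tss_anchors `data.table`/data.frame with columns `chrom`, `pos`
#'   (0-based TSS) and `strand`.
#' @param flank Half-window size in bp.
#' @param bin Bin width in bp for the binned mutation profile (default 25).
#' @param seqlengths Optional named chromosome lengths; anchors whose
#'   window leaves the chromosome are skipped with a warning.
#' @return A `profile_track` list: `per_position` (`relpos`, `count`,
#'   `mean_methylation`), `binned` (`bin_start`, `bin_mid`, `count`), and
#'   the parameters used.
#' @export
tss_profile <- function(mutations, methylation, tss_anchors, flank,
                        bin = 25L, seqlengths = NULL) {
  anchors <- as.data.table(tss_anchors)
  stopifnot(nrow(anchors) > 0, flank > 0)
  if (!is.null(seqlengths)) {
    len <- seqlengths[anchors$chrom]
    ok <- anchors$pos - flank >= 0 & anchors$pos + flank < len & !is.na(len)
    if (any(!ok)) {
      warnf("tss_profile: skipped %d anchor(s) beyond chromosome bounds",
            sum(!ok))
      anchors <- anchors[ok]
    }
    if (!nrow(anchors)) stopf("no usable anchors")
  }
  rel_for <- function(dt) {
    ## relative positions of dt rows to every anchor, strand-reflected
    data.table::rbindlist(lapply(seq_len(nrow(anchors)), function(i) {
      a <- anchors[i]
      x <- dt[chrom == a$chrom & abs(pos - a$pos) <= flank]
      if (!nrow(x)) return(NULL)
      rel <- x$pos - a$pos
      if (a$strand == "-") rel <- -rel
      x[, .(relpos = rel, value = value)]
    }))
  }
  mut_rel <- rel_for(as.data.table(mutations)[, .(chrom, pos, value = 1)])
  grid <- data.table(relpos = seq(-flank, flank))
  counts <- if (nrow(mut_rel)) {
    mut_rel[, .(count = .N), by = relpos]
  } else data.table(relpos = integer(), count = integer())
  per_pos <- counts[grid, on = "relpos"]
  per_pos[is.na(count), count := 0L]
  if (!is.null(methylation)) {
    meth_rel <- rel_for(as.data.table(methylation)[
      , .(chrom, pos, value = methylation)])
    mm <- if (nrow(meth_rel)) {
      meth_rel[, .(mean_methylation = mean(value)), by = relpos]
    } else data.table(relpos = integer(), mean_methylation = numeric())
    per_pos <- mm[per_pos, on = "relpos"]
  } else {
    per_pos[, mean_methylation := NA_real_]
  }
  data.table::setorder(per_pos, relpos)
  data.table::setcolorder(per_pos, c("relpos", "count", "mean_methylation"))
  per_pos[, bin_start := floor((relpos + flank) / bin) * bin - flank]
  binned <- per_pos[, .(count = sum(count)), by = bin_start]
  binned[, bin_mid := bin_start + bin / 2]
  per_pos[, bin_start := NULL]
  structure(list(per_position = per_pos[],
                 binned = binned[, .(bin_start, bin_mid, count)],
                 flank = flank, bin = bin, n_anchors = nrow(anchors)),
            class = "profile_track")
}
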