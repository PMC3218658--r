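## Relating genome tag sites to gene models: transcript site ranks,
## sense/antisense classification, upstream distances, overlapping-gene
## confounds, mitochondrial partition.

## spliced sequence of one transcript (exons in transcript order,
## minus-strand exons reverse-complemented)
spliced_sequence <- function(exons_t, genome) {
  strand <- exons_t$strand[1L]
  ord <- order(exons_t$exon_rank)
  ex <- exons_t[ord]
  len <- nchar(genome[ex$contig])
  if (any(ex$start < 0L) || any(ex$end > len))
    stop_fmt("spliced_sequence(): exon coordinates outside contig %s", ex$contig[1L])
  parts <- substr0(genome[ex$contig], ex$start, ex$end)
  if (strand == "-") parts <- revcomp(parts)
  paste(parts, collapse = "")
}

#' Locate DpnII tag sites on spliced transcripts
#'
#' Finds every GATC occurrence on each spliced transcript sequence
#' whose 20-mer window fits, assigns 3'-terminus ranks (rank 1 =
#' downstream-most) and upstream distances (spliced length minus
#' 0-based site position), and populates the corresponding genomic
#' site when the 20-mer lies within a single exon (tags spanning an
#' exon junction have no contiguous genomic image and are reported as
#' genome-unmappable).
#'
#' @param models a [gene_model_set()].
#' @param genome named character vector (or `DNAStringSet`).
#' @return data.table of transcript tag sites: `transcript_id`,
#'   `locus_id`, `class`, `spliced_pos` (0-based GATC start),
#'   `rank_from_3prime`, `upstream_distance`, `tag`, `genome_mappable`,
#'   `contig`, `gatc_start`, `strand`. Transcripts with no site are
#'   absent (use the transcript table to flag them siteless).
#' @export
locate_transcript_sites <- function(models, genome) {
  if (methods::is(genome, "DNAStringSet")) genome <- setNames(as.character(genome), names(genome))
  out <- list()
  tx <- models$transcripts
  for (i in seq_len(nrow(tx))) {
    tid <- tx$transcript_id[i]
    ex <- models$exons[transcript_id == tid]
    if (!nrow(ex)) next
    sp <- spliced_sequence(ex, genome)
    L <- nchar(sp)
    pos <- gatc_starts0(sp)
    pos <- pos[pos + TAG_LENGTH <= L]
    if (!length(pos)) next
    pos <- sort(pos)
    tagseq <- substr0(sp, pos, pos + TAG_LENGTH)
    ## map spliced window to a single exon, if contained in one
    strand <- ex$strand[1L]
    exo <- ex[order(exon_rank)]
    elen <- exo$end - exo$start
    off0 <- cumsum(c(0L, head(elen, -1L)))   # spliced offset of each exon
    eidx <- findInterval(pos, off0)
    within <- (pos + TAG_LENGTH) <= (off0[eidx] + elen[eidx])
    rel <- pos - off0[eidx]
    gatc <- if (strand == "+") exo$start[eidx] + rel else exo$end[eidx] - rel - 4L
    ## minus-strand genomic site also needs its 16 nt genomic flank
    flank_ok <- if (strand == "+")
      gatc + TAG_LENGTH <= nchar(genome[exo$contig[eidx]]) else gatc >= 16L
    ok <- within & flank_ok
    out[[tid]] <- data.table(
      transcript_id = tid, locus_id = tx$locus_id[i], class = tx$class[i],
      spliced_pos = pos,
      rank_from_3prime = rev(seq_along(pos)),
      upstream_distance = L - pos,
      tag = tagseq, genome_mappable = ok,
      contig = fifelse(ok, exo$contig[eidx], NA_character_),
      gatc_start = fifelse(ok, as.integer(gatc), NA_integer_),
      strand = fifelse(ok, strand, NA_character_))
  }
  if (!length(out))
    return(data.table(transcript_id = character(0), locus_id = character(0),
                      class = character(0), spliced_pos = integer(0),
                      rank_from_3prime = integer(0), upstream_distance = integer(0),
                      tag = character(0), genome_mappable = logical(0),
                      contig = character(0), gatc_start = integer(0),
                      strand = character(0)))
  res <- rbindlist(out)
  setkey(res, transcript_id, rank_from_3prime)
  res[]
}

#' Strand-aware genomic distance from a site to the locus 3' end
#'
#' For a plus-strand locus the 3' end is its end coordinate (0-based
#' exclusive) and the distance is `end - gatc_start`; for a
#' minus-strand locus it is `gatc_start - start`. The site must lie
#' within the locus boundary.
#'
#' @param gatc_start 0-based GATC start coordinate(s).
#' @param locus_start,locus_end locus boundary (0-based half-open).
#' @param locus_strand `+` or `-`.
#' @return nonnegative integer distance(s).
#' @export
upstream_distance_genomic <- function(gatc_start, locus_start, locus_end,
                                      locus_strand) {
  if (any(gatc_start < locus_start | gatc_start >= locus_end))
    stop_fmt("upstream_distance_genomic(): site outside locus boundary")
  ifelse(locus_strand == "+", locus_end - gatc_start, gatc_start - locus_start)
}

#' Classify unique-mapping tags against gene models
#'
#' For every unique-mapping tag in the index, reports its relation to
#' the gene models: the locus it falls in (GATC start within the locus
#' boundary, introns included) or `NA` for intergenic sites;
#' orientation (`sense` when the site strand equals the locus strand,
#' `antisense` otherwise, `NA` for intergenic); whether it sits on the
#' 3' terminus (equals a rank-1 or rank-2 transcript site of the
#' locus, pooled over the locus's transcripts); the genomic upstream
#' distance from the locus 3' end; the overlapping-gene confound flag
#' (tag inside >= 2 antiparallel-overlapping loci, hence sense to one
#' and antisense to the other); and the mitochondrial flag. Tags inside
#' several loci get one row per (tag, locus) pair. Multi-mapping tags
#' are a contract violation: they cannot be unambiguously assigned and
#' must be excluded upstream.
#'
#' @param index a [build_index()] object.
#' @param models a [gene_model_set()].
#' @param tsites transcript tag sites from [locate_transcript_sites()].
#' @param tags optional character vector restricting the tags to
#'   classify (must all be unique-mapping).
#' @return data.table with one row per (tag, locus) pair (or per tag
#'   for intergenic tags): `tag`, `contig`, `gatc_start`, `strand`,
#'   `locus_id`, `orientation`, `on_3prime`, `upstream_dist`,
#'   `confound`, `mito`, `locus_classes`.
#' @export
classify_tags <- function(index, models, tsites, tags = NULL) {
  uni <- index$tags[class == "unique", tag]
  if (!is.null(tags)) {
    bad <- setdiff(tags, uni)
    if (length(bad))
      stop_fmt("classify_tags(): %d tag(s) are not unique-mapping (e.g. %s)",
               length(bad), bad[1L])
    uni <- tags
  }
  sites <- index$sites[tag %chin% uni]
  loci <- models$loci
  if (!nrow(sites)) {
    return(data.table(tag = character(0), contig = character(0),
                      gatc_start = integer(0), strand = character(0),
                      locus_id = character(0), orientation = character(0),
                      on_3prime = logical(0), upstream_dist = integer(0),
                      confound = logical(0), mito = logical(0),
                      locus_classes = character(0)))
  }
  ## site-in-locus containment via interval overlap
  sgr <- GenomicRanges::GRanges(sites$contig,
                                IRanges::IRanges(sites$gatc_start + 1L,
                                                 sites$gatc_start + 1L))
  lgr <- if (nrow(loci)) GenomicRanges::GRanges(loci$contig,
                                                IRanges::IRanges(loci$start + 1L, loci$end))
         else GenomicRanges::GRanges()
  hits <- GenomicRanges::findOverlaps(sgr, lgr, ignore.strand = TRUE)
  ann <- sites[S4Vectors::queryHits(hits)]
  hit_loci <- loci[S4Vectors::subjectHits(hits)]
  ann[, `:=`(locus_id = hit_loci$locus_id,
             locus_strand = hit_loci$strand,
             mito = hit_loci$mitochondrial)]
  ann[, orientation := fifelse(strand == locus_strand, "sense", "antisense")]
  ann[, upstream_dist := upstream_distance_genomic(gatc_start, hit_loci$start,
                                                   hit_loci$end, locus_strand)]
  ## 3'-terminus membership: rank <= 2 on any transcript of the locus
  term <- unique(tsites[genome_mappable == TRUE & rank_from_3prime <= 2L,
                        .(locus_id, contig, gatc_start, strand)])
  ann[, on_3prime := FALSE]
  if (nrow(term))
    ann[term, on_3prime := TRUE, on = c("locus_id", "contig", "gatc_start", "strand")]
  ann[orientation != "sense", on_3prime := FALSE]
  ## confound: tag within >= 2 antiparallel loci inducing both orientations
  ann[, confound := uniqueN(orientation) >= 2L, by = tag]
  ## transcript classes present at the locus (for NM-only style splits)
  cls <- models$transcripts[, .(locus_classes = paste(sort(unique(class)),
                                                      collapse = ",")), by = locus_id]
  ann <- cls[ann, on = "locus_id"]
  ## intergenic sites: no locus row
  inter <- sites[!tag %chin% ann$tag]
  if (nrow(inter)) {
    inter[, `:=`(locus_id = NA_character_, orientation = "intergenic",
                 on_3prime = FALSE, upstream_dist = NA_integer_,
                 confound = FALSE, mito = FALSE, locus_classes = NA_character_)]
    ann <- rbind(ann[, .(tag, contig, gatc_start, strand, locus_id, orientation,
                         on_3prime, upstream_dist, confound, mito, locus_classes)],
                 inter[, .(tag, contig, gatc_start, strand, locus_id, orientation,
                           on_3prime, upstream_dist, confound, mito, locus_classes)])
  } else {
    ann <- ann[, .(tag, contig, gatc_start, strand, locus_id, orientation,
                   on_3prime, upstream_dist, confound, mito, locus_classes)]
  }
  setkey(ann, tag)
  ann[]
}

#' Mitochondrial / nuclear partition of within-locus abundance
#'
#' Per library, sums TPM of within-locus tags (sense and antisense,
#' one (tag, locus) pair counted once per tag using its mitochondrial
#' status) into mitochondrial and nuclear totals and the fraction
#' mito/(mito + nuclear).
#'
#' @param atlas a `tag_atlas`.
#' @param annotation output of [classify_tags()].
#' @param multi_assign optional [assign_multi_single_locus()] table;
#'   when given, multi-mapping tags with a single within-locus site
#'   contribute to the partition as well (without it the abundance of
#'   loci whose 3'-terminal tag is duplicated elsewhere in the genome
#'   is invisible, biasing the fraction).
#' @return data.table per library: `mito_tpm`, `nuclear_tpm`,
#'   `mito_fraction` (0 when no within-locus abundance).
#' @export
partition_mitochondrial <- function(atlas, annotation, multi_assign = NULL) {
  within <- annotation[!is.na(locus_id), .(mito = any(mito)), by = tag]
  if (!is.null(multi_assign) && nrow(multi_assign))
    within <- unique(rbind(within, multi_assign[, .(mito = any(mito)), by = tag]))
  dt <- atlas$tpm[within, on = "tag", nomatch = NULL]
  res <- dt[, .(mito_tpm = sum(tpm[mito]), nuclear_tpm = sum(tpm[!mito])), by = library_id]
  res <- res[atlas$libraries[, .(library_id)], on = "library_id"]
  res[is.na(mito_tpm), `:=`(mito_tpm = 0, nuclear_tpm = 0)]
  res[, mito_fraction := fifelse(mito_tpm + nuclear_tpm > 0,
                                 mito_tpm / (mito_tpm + nuclear_tpm), 0)]
  res[]
}

#' Assign multi-mapping tags with a single within-locus site
#'
#' A tag that maps to several genomic locations cannot in general be
#' assigned to a locus, but when exactly one of its sites lies within
#' a gene boundary and all others are intergenic (the classic
#' pseudogene/assembly-duplication situation), it is reasonable to
#' attribute its abundance to that locus. Returns those assignments
#' for use as an optional augmentation of abundance partitions.
#'
#' @param index a [build_index()] object.
#' @param models a [gene_model_set()].
#' @return data.table `tag`, `locus_id`, `orientation`, `mito`.
#' @export
assign_multi_single_locus <- function(index, models) {
  empty <- data.table(tag = character(0), locus_id = character(0),
                      orientation = character(0), mito = logical(0))
  mt <- index$tags[class == "multi", tag]
  sites <- index$sites[tag %chin% mt]
  if (!nrow(sites) || !nrow(models$loci)) return(empty)
  sgr <- GenomicRanges::GRanges(sites$contig,
                                IRanges::IRanges(sites$gatc_start + 1L,
                                                 sites$gatc_start + 1L))
  lgr <- GenomicRanges::GRanges(models$loci$contig,
                                IRanges::IRanges(models$loci$start + 1L,
                                                 models$loci$end))
  hits <- GenomicRanges::findOverlaps(sgr, lgr, ignore.strand = TRUE)
  within <- sites[S4Vectors::queryHits(hits)]
  hl <- models$loci[S4Vectors::subjectHits(hits)]
  within[, `:=`(locus_id = hl$locus_id,
                orientation = fifelse(strand == hl$strand, "sense", "antisense"),
                mito = hl$mitochondrial)]
  one <- within[, .N, by = tag][N == 1L, tag]
  unique(within[tag %chin% one, .(tag, locus_id, orientation, mito)])
}
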