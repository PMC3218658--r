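## Gene model container and GFF3 serialization.
## Internal coordinates are 0-based half-open; GFF3 on disk is 1-based
## closed, converted only at the file boundary.

#' Construct a gene model set
#'
#' Loci, transcripts and exons of an annotation. A locus boundary is
#' the union span of all its transcripts (introns included).
#' Transcript classes follow RefSeq accession prefixes: NM (curated
#' protein-coding), NR (curated non-coding), XM (computationally
#' predicted model). A locus is protein-coding if any of its
#' transcripts is NM or XM.
#'
#' @param loci data.table: `locus_id`, `contig`, `strand`, `start`,
#'   `end` (0-based half-open), `mitochondrial` (logical).
#' @param transcripts data.table: `transcript_id`, `locus_id`, `class`.
#' @param exons data.table: `transcript_id`, `exon_rank` (1 = 5'-most),
#'   `contig`, `strand`, `start`, `end` (0-based half-open).
#' @return A `gene_model_set` list with keyed data.tables; transcript
#'   spliced lengths are derived from the exons.
#' @export
gene_model_set <- function(loci, transcripts, exons) {
  loci <- as.data.table(loci); transcripts <- as.data.table(transcripts)
  exons <- as.data.table(exons)
  stopifnot(all(transcripts$class %in% c("NM", "NR", "XM")))
  if (nrow(exons)) {
    ov <- exons[, {
      o <- order(start)
      any(start[o][-1] < end[o][-.N])
    }, by = transcript_id]
    if (any(ov$V1))
      stop_fmt("gene_model_set(): overlapping exons in transcript %s",
               ov[V1 == TRUE, transcript_id][1L])
  }
  sl <- exons[, .(spliced_length = sum(end - start)), by = transcript_id]
  transcripts <- sl[transcripts, on = "transcript_id"]
  transcripts[is.na(spliced_length), spliced_length := 0L]
  if ("protein_coding" %in% names(loci)) loci[, protein_coding := NULL]
  pc <- transcripts[, .(protein_coding = any(class %in% c("NM", "XM"))),
                    by = locus_id]
  loci <- pc[loci, on = "locus_id"]
  loci[is.na(protein_coding), protein_coding := FALSE]
  setkey(loci, locus_id); setkey(transcripts, transcript_id)
  setkey(exons, transcript_id, exon_rank)
  structure(list(loci = loci[], transcripts = transcripts[], exons = exons[]),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("<gene_model_set> %d loci (%d mitochondrial), %d transcripts, %d exons\n",
              nrow(x$loci), sum(x$loci$mitochondrial), nrow(x$transcripts),
              nrow(x$exons)))
  invisible(x)
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon features with ID/Parent attributes, the
#' transcript accession class in a `transcript_class` attribute, and
#' `organelle=mitochondrion` on mitochondrial gene features.
#' Coordinates are converted to 1-based closed intervals.
#'
#' @param models a [gene_model_set()].
#' @param path output GFF3 path.
#' @export
write_models_gff3 <- function(models, path) {
  rows <- list()
  if (nrow(models$loci)) {
    rows$gene <- with(models$loci, GenomicRanges::GRanges(
      contig, IRanges::IRanges(start + 1L, end), strand = strand,
      type = "gene", ID = locus_id, Parent = NA_character_,
      transcript_class = NA_character_,
      organelle = ifelse(mitochondrial, "mitochondrion", NA_character_)))
    tx <- models$transcripts[models$loci[, .(locus_id, contig, strand)],
                             on = "locus_id", nomatch = NULL]
    sp <- models$exons[, .(start = min(start), end = max(end)), by = transcript_id]
    tx <- sp[tx, on = "transcript_id"]
    rows$mrna <- with(tx, GenomicRanges::GRanges(
      contig, IRanges::IRanges(start + 1L, end), strand = strand,
      type = "mRNA", ID = transcript_id, Parent = locus_id,
      transcript_class = class, organelle = NA_character_))
    ex <- models$exons
    rows$exon <- with(ex, GenomicRanges::GRanges(
      contig, IRanges::IRanges(start + 1L, end), strand = strand,
      type = "exon", ID = NA_character_, Parent = transcript_id,
      transcript_class = NA_character_, organelle = NA_character_))
  }
  gr <- if (length(rows)) do.call(c, unname(rows)) else
    GenomicRanges::GRanges()
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Inverse of [write_models_gff3()]: expects gene/mRNA/exon features
#' with ID/Parent attributes; transcript class is taken from the
#' `transcript_class` attribute (default NM) and the mitochondrial flag
#' from `organelle=mitochondrion`.
#'
#' @param path GFF3 file.
#' @return A [gene_model_set()].
#' @export
read_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  first_parent <- function(p) vapply(p, function(v)
    if (length(v)) v[[1L]] else NA_character_, character(1))
  type <- as.character(md$type)
  dt <- data.table(
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    type = type,
    id = if ("ID" %in% names(md)) as.character(md$ID) else NA_character_,
    parent = if ("Parent" %in% names(md)) first_parent(md$Parent) else NA_character_,
    class = if ("transcript_class" %in% names(md))
      as.character(md$transcript_class) else NA_character_,
    organelle = if ("organelle" %in% names(md))
      as.character(md$organelle) else NA_character_)
  genes <- dt[type == "gene"]
  loci <- genes[, .(locus_id = id, contig, strand, start, end,
                    mitochondrial = !is.na(organelle) & organelle == "mitochondrion")]
  mrna <- dt[type == "mRNA"]
  transcripts <- mrna[, .(transcript_id = id, locus_id = parent,
                          class = fifelse(is.na(class), "NM", class))]
  ex <- dt[type == "exon"]
  if (nrow(ex)) {
    ex <- ex[, .(transcript_id = parent, contig, strand, start, end)]
    setorder(ex, transcript_id, start)
    ex[, exon_rank := if (strand[1L] == "+") seq_len(.N) else rev(seq_len(.N)),
       by = transcript_id]
  } else {
    ex <- data.table(transcript_id = character(0), contig = character(0),
                     strand = character(0), start = integer(0), end = integer(0),
                     exon_rank = integer(0))
  }
  gene_model_set(loci, transcripts,
                 ex[, .(transcript_id, exon_rank, contig, strand, start, end)])
}

#' Write a genome as FASTA
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param path output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
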