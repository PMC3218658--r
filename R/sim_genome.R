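## Synthetic genome + gene model generator with full ground truth.
##
## Emulates the draft-genome features the downstream analysis has to
## cope with: multi-exon gene models on both strands, antiparallel
## overlapping loci, multi-mapping 3'-terminal tags (duplicated sites),
## transcripts without a DpnII site, and a dedicated organelle contig
## of single-exon mitochondrial genes.

#' Specification of a simulated genome
#'
#' @param n_contigs number of nuclear contigs.
#' @param contig_length length (nt) of each nuclear contig (>= 200).
#' @param n_loci number of nuclear loci to place.
#' @param transcripts_per_locus integer range `c(min, max)`.
#' @param exons_per_transcript integer range `c(min, max)`.
#' @param overlap_fraction proportion of loci placed
#'   antiparallel-overlapping another locus (realized within +-1 locus).
#' @param duplicate_site_fraction proportion of loci whose 3'-terminal
#'   tag sequence is copied to a second, intergenic genomic location
#'   (multi-mapper generator).
#' @param siteless_fraction proportion of loci generated without any
#'   DpnII site (default 0.03, the typical share of gene models lacking
#'   a predicted recognition sequence).
#' @param mito_genes number of organelle-style single-exon loci on a
#'   dedicated `MT` contig; when >= 3, two of them are generated
#'   siteless (emulating the COX3/ND3 situation of transcripts with no
#'   DpnII site).
#' @param rng_seed integer seed; identical seeds give byte-identical
#'   genomes.
#' @return A validated list of class `sim_genome_spec`.
#' @export
sim_genome_spec <- function(n_contigs = 4L, contig_length = 50000L,
                            n_loci = 60L, transcripts_per_locus = c(1L, 3L),
                            exons_per_transcript = c(1L, 4L),
                            overlap_fraction = 0.1,
                            duplicate_site_fraction = 0.05,
                            siteless_fraction = 0.03,
                            mito_genes = 11L, rng_seed = NULL) {
  stopifnot(is_count(n_contigs), is_count(n_loci), is_count(mito_genes),
            is_count(contig_length), contig_length >= 200,
            length(transcripts_per_locus) == 2L, transcripts_per_locus[1] >= 1,
            length(exons_per_transcript) == 2L, exons_per_transcript[1] >= 1,
            is_prob(overlap_fraction), is_prob(duplicate_site_fraction),
            is_prob(siteless_fraction))
  structure(as.list(environment()), class = "sim_genome_spec")
}

## exon/intron geometry constants of the generator (nt)
.SIM <- list(exon_len = c(150L, 400L), last_exon_len = c(300L, 400L),
             intron_len = c(100L, 300L), gap_len = c(300L, 800L),
             margin = 300L, mito_gene_len = c(500L, 900L),
             mito_gap = c(120L, 200L),
             site_u1 = c(5L, 40L), site_step = c(45L, 90L))

#' Generate a synthetic genome with gene models and ground truth
#'
#' Places multi-exon loci on random contigs, scrubs naturally occurring
#' GATC tetramers from locus neighborhoods and then plants 2-3 DpnII
#' sites in the 3'-terminal exon of every non-siteless locus, so every
#' planted site and its 20-base sense/antisense tags are known exactly.
#' A fraction of loci is placed antiparallel-overlapping a host locus,
#' and a fraction of 3'-terminal tag sequences is copied to a second,
#' intergenic location to create multi-mapping tags.
#'
#' @param spec a [sim_genome_spec()].
#' @return list of class `sim_genome` with `genome` (named character
#'   vector), `models` (a [gene_model_set()]) and `truth` (lists of
#'   loci, transcripts, per-locus genomic tag sites with sense and
#'   antisense tag sequences, and duplicated-tag records).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "sim_genome_spec"))
  with_seed_if(spec$rng_seed, .generate_genome(spec))
}

.generate_genome <- function(spec) {
  g <- .SIM
  n_pairs <- round(spec$overlap_fraction * spec$n_loci / 2)
  n_primary <- spec$n_loci - n_pairs
  if (n_primary < n_pairs) { n_pairs <- floor(spec$n_loci / 2); n_primary <- spec$n_loci - n_pairs }

  contig_names <- if (spec$n_contigs > 0) sprintf("ctg%02d", seq_len(spec$n_contigs)) else character(0)

  ## ---- lay out primary loci ----
  loci <- list(); chains <- list()
  ci <- 1L
  cursor <- g$margin
  for (i in seq_len(n_primary)) {
    n_ex <- sample(spec$exons_per_transcript[1]:spec$exons_per_transcript[2], 1L)
    ex_len <- c(if (n_ex > 1) sample(g$exon_len[1]:g$exon_len[2], n_ex - 1L, TRUE),
                sample(g$last_exon_len[1]:g$last_exon_len[2], 1L))
    in_len <- if (n_ex > 1) sample(g$intron_len[1]:g$intron_len[2], n_ex - 1L, TRUE) else integer(0)
    span <- sum(ex_len) + sum(in_len)
    gap <- sample(g$gap_len[1]:g$gap_len[2], 1L)
    while (ci <= spec$n_contigs &&
           cursor + gap + span > spec$contig_length - g$margin) {
      ci <- ci + 1L; cursor <- g$margin
    }
    if (ci > spec$n_contigs)
      stop_fmt(paste0("generate_genome(): contig_length=%d x n_contigs=%d ",
                      "too short to host n_loci=%d (failed at locus %d)"),
               spec$contig_length, spec$n_contigs, spec$n_loci, i)
    s0 <- cursor + gap
    starts <- s0 + cumsum(c(0L, head(ex_len, -1L) + in_len))
    locus_id <- sprintf("LOC%04d", i)
    strand <- sample(c("+", "-"), 1L)
    chains[[locus_id]] <- data.table(contig = contig_names[ci], strand = strand,
                                     start = starts, end = starts + ex_len)
    loci[[locus_id]] <- data.table(locus_id = locus_id, contig = contig_names[ci],
                                   strand = strand, start = s0, end = s0 + span,
                                   mitochondrial = FALSE, host = NA_character_)
    cursor <- s0 + span
  }

  ## ---- antiparallel overlappers nested in hosts ----
  ## Overlappers stay clear of the host's 3'-terminal exon so the
  ## host's planted site ranks are not perturbed by overlapper GATCs.
  if (n_pairs > 0) {
    room <- vapply(names(loci), function(lid) {
      ch <- chains[[lid]]
      if (nrow(ch) < 2L) return(-1L)
      h <- loci[[lid]]
      if (h$strand == "+") (ch[which.max(start), start] - 20L) - (h$start + 20L)
      else (h$end - 20L) - (ch[which.min(start), end] + 20L)
    }, numeric(1))
    host_ids <- names(loci)[order(-room)]
    host_ids <- head(host_ids[room[host_ids] >= 240L], n_pairs)
    for (j in seq_along(host_ids)) {
      h <- loci[[host_ids[j]]]
      ch <- chains[[host_ids[j]]]
      lo <- if (h$strand == "+") h$start + 20L else ch[which.min(start), end] + 20L
      hi <- if (h$strand == "+") ch[which.max(start), start] - 20L else h$end - 20L
      olen <- max(180L, min(420L, (hi - lo) - 20L))
      avail <- (hi - lo) - olen
      if (avail < 0) next
      s0 <- lo + sample(0:avail, 1L)
      locus_id <- sprintf("LOC%04d", n_primary + j)
      strand <- if (h$strand == "+") "-" else "+"
      chains[[locus_id]] <- data.table(contig = h$contig, strand = strand,
                                       start = s0, end = s0 + olen)
      loci[[locus_id]] <- data.table(locus_id = locus_id, contig = h$contig,
                                     strand = strand, start = s0, end = s0 + olen,
                                     mitochondrial = FALSE, host = h$locus_id)
    }
  }

  ## ---- mitochondrial contig ----
  mito_len <- 0L
  if (spec$mito_genes > 0) {
    cur <- g$margin
    for (i in seq_len(spec$mito_genes)) {
      len <- sample(g$mito_gene_len[1]:g$mito_gene_len[2], 1L)
      gap <- sample(g$mito_gap[1]:g$mito_gap[2], 1L)
      s0 <- cur + gap
      locus_id <- sprintf("MTG%02d", i)
      chains[[locus_id]] <- data.table(contig = "MT", strand = "+",
                                       start = s0, end = s0 + len)
      loci[[locus_id]] <- data.table(locus_id = locus_id, contig = "MT",
                                     strand = "+", start = s0, end = s0 + len,
                                     mitochondrial = TRUE, host = NA_character_)
      cur <- s0 + len
    }
    mito_len <- cur + g$margin
  }

  loci_dt <- if (length(loci)) rbindlist(loci) else
    data.table(locus_id = character(0), contig = character(0), strand = character(0),
               start = integer(0), end = integer(0), mitochondrial = logical(0),
               host = character(0))

  ## ---- siteless loci ----
  nuc_ids <- loci_dt[mitochondrial == FALSE, locus_id]
  n_siteless <- round(spec$siteless_fraction * length(nuc_ids))
  siteless_ids <- if (n_siteless > 0) sample(nuc_ids, n_siteless) else character(0)
  if (spec$mito_genes >= 3)
    siteless_ids <- c(siteless_ids, sprintf("MTG%02d", c(3L, 5L)))
  loci_dt[, siteless := locus_id %in% siteless_ids]

  ## ---- raw sequence, scrub GATC around loci ----
  genome <- setNames(vapply(seq_len(spec$n_contigs),
                            function(i) random_dna(spec$contig_length),
                            character(1)), contig_names)
  if (spec$mito_genes > 0) genome <- c(genome, MT = random_dna(mito_len))
  for (ctg in names(genome)) {
    sp <- loci_dt[contig == ctg]
    if (!nrow(sp)) next
    pos <- gatc_starts0(genome[[ctg]])
    hit <- pos[data.table::inrange(pos, sp$start - 24L, sp$end + 24L)]
    if (length(hit)) {
      s <- strsplit(genome[[ctg]], "", fixed = TRUE)[[1L]]
      s[hit + 4L] <- "T"   # GATC -> GATT; cannot recreate a GATC
      genome[ctg] <- paste(s, collapse = "")
    }
  }

  ## ---- plant DpnII sites in the 3'-terminal exon ----
  ## Nested antiparallel loci share sequence with their host, so planted
  ## GATCs of different loci must not overwrite one another; aim for
  ## >= 24 nt separation (no shared tag windows), accept >= 4 nt.
  site_rows <- list()
  planted <- list()
  for (lid in loci_dt[siteless == FALSE, locus_id]) {
    ch <- chains[[lid]]
    strand <- ch$strand[1L]
    last <- if (strand == "+") ch[which.max(start)] else ch[which.min(start)]
    L <- last$end - last$start
    k <- if (loci_dt[locus_id == lid, mitochondrial] || L < 300L) 2L else sample(2:3, 1L)
    occupied <- planted[[last$contig]]
    for (try in 1:200) {
      u1 <- sample(g$site_u1[1]:g$site_u1[2], 1L)
      off <- (L - TAG_LENGTH - u1) - cumsum(c(0L, sample(g$site_step[1]:g$site_step[2],
                                                         k - 1L, TRUE)))
      if (any(off < 16L)) next
      gpos <- if (strand == "+") last$start + off else last$end - off - 4L
      min_sep <- if (length(occupied))
        min(vapply(gpos, function(p) min(abs(p - occupied)), numeric(1))) else Inf
      if (min_sep >= 24L || (try > 100 && min_sep >= 4L)) break
      if (try == 200)
        stop_fmt("generate_genome(): cannot place DpnII sites for %s without collision", lid)
    }
    planted[[last$contig]] <- c(occupied, gpos)
    site_rows[[lid]] <- data.table(locus_id = lid, site_rank = seq_len(k),
                                   contig = last$contig, gatc_start = gpos,
                                   strand = strand, last_exon_off = off)
  }
  sites <- if (length(site_rows)) rbindlist(site_rows) else
    data.table(locus_id = character(0), site_rank = integer(0), contig = character(0),
               gatc_start = integer(0), strand = character(0), last_exon_off = integer(0))
  for (ctg in unique(sites$contig)) {
    p <- sites[contig == ctg, gatc_start]
    s <- strsplit(genome[[ctg]], "", fixed = TRUE)[[1L]]
    s[rep(p, each = 4L) + 0:3 + 1L] <- rep(c("G", "A", "T", "C"), length(p))
    genome[ctg] <- paste(s, collapse = "")
  }

  ## sense/antisense 20-mers of every planted site
  if (nrow(sites)) {
    seqs <- genome[sites$contig]
    plus_win <- substr0(seqs, sites$gatc_start, sites$gatc_start + TAG_LENGTH)
    minus_win <- revcomp(substr0(seqs, sites$gatc_start - 16L, sites$gatc_start + 4L))
    sites[, tag_sense := fifelse(strand == "+", plus_win, minus_win)]
    sites[, tag_anti := fifelse(strand == "+", minus_win, plus_win)]
  } else {
    sites[, `:=`(tag_sense = character(0), tag_anti = character(0))]
  }

  ## ---- duplicate a fraction of 3'-terminal tags intergenically ----
  dup_rows <- list()
  n_dup <- round(spec$duplicate_site_fraction *
                   nrow(loci_dt[mitochondrial == FALSE & siteless == FALSE]))
  if (n_dup > 0) {
    cand <- loci_dt[mitochondrial == FALSE & siteless == FALSE, locus_id]
    dup_ids <- sample(cand, min(n_dup, length(cand)))
    ## free tail space after the last locus on each contig
    tails <- loci_dt[contig %chin% contig_names,
                     .(from = max(end) + 100L), by = contig]
    tails[, to := spec$contig_length - g$margin]
    for (d in seq_along(dup_ids)) {
      lid <- dup_ids[d]
      tg <- sites[locus_id == lid & site_rank == 1L, tag_sense]
      slot <- tails[to - from >= 60L][1L]
      if (is.na(slot$contig)) break
      p <- slot$from
      tails[contig == slot$contig, from := from + 60L]
      s <- strsplit(genome[[slot$contig]], "", fixed = TRUE)[[1L]]
      s[p + seq_len(TAG_LENGTH)] <- strsplit(tg, "", fixed = TRUE)[[1L]]
      genome[slot$contig] <- paste(s, collapse = "")
      dup_rows[[d]] <- data.table(locus_id = lid, tag = tg,
                                  contig = slot$contig, gatc_start = p)
    }
  }
  duplicates <- if (length(dup_rows)) rbindlist(dup_rows) else
    data.table(locus_id = character(0), tag = character(0),
               contig = character(0), gatc_start = integer(0))

  ## ---- transcripts: shared 3' end, variable 5' extent ----
  tx_rows <- list(); exon_rows <- list(); tsite_rows <- list()
  ti <- 0L
  for (lid in loci_dt$locus_id) {
    ch <- chains[[lid]]
    strand <- ch$strand[1L]
    is_mito <- loci_dt[locus_id == lid, mitochondrial]
    n_ex <- nrow(ch)
    tx_order <- if (strand == "+") order(ch$start) else order(-ch$start)
    chain <- ch[tx_order]   # transcript 5'->3' order
    n_tx <- if (is_mito || n_ex == 1L) 1L else
      sample(spec$transcripts_per_locus[1]:spec$transcripts_per_locus[2], 1L)
    firsts <- c(1L, if (n_tx > 1) sample(seq_len(n_ex), n_tx - 1L, TRUE))
    lsites <- site_rows[[lid]]
    for (j in seq_len(n_tx)) {
      ti <- ti + 1L
      tid <- sprintf("%s.t%d", lid, j)
      cls <- if (is_mito) "NM" else
        sample(c("NM", "XM", "NR"), 1L, prob = c(0.7, 0.2, 0.1))
      tx_rows[[ti]] <- data.table(transcript_id = tid, locus_id = lid, class = cls)
      ex <- chain[firsts[j]:n_ex]
      exon_rows[[ti]] <- data.table(transcript_id = tid,
                                    exon_rank = seq_len(nrow(ex)),
                                    contig = ex$contig, strand = strand,
                                    start = ex$start, end = ex$end)
      if (!is.null(lsites)) {
        sl <- sum(ex$end - ex$start)
        L_last <- ex[.N, end - start]
        tsite_rows[[length(tsite_rows) + 1L]] <-
          data.table(transcript_id = tid, locus_id = lid,
                     site_rank = lsites$site_rank,
                     spliced_pos = sl - L_last + lsites$last_exon_off,
                     spliced_length = sl)
      }
    }
  }
  transcripts <- if (ti > 0) rbindlist(tx_rows) else
    data.table(transcript_id = character(0), locus_id = character(0), class = character(0))
  exons <- if (ti > 0) rbindlist(exon_rows) else
    data.table(transcript_id = character(0), exon_rank = integer(0), contig = character(0),
               strand = character(0), start = integer(0), end = integer(0))
  tx_sites <- if (length(tsite_rows)) rbindlist(tsite_rows) else
    data.table(transcript_id = character(0), locus_id = character(0),
               site_rank = integer(0), spliced_pos = integer(0),
               spliced_length = integer(0))

  models <- gene_model_set(loci_dt[, .(locus_id, contig, strand, start, end, mitochondrial)],
                           transcripts, exons)
  truth <- list(loci = loci_dt[], sites = sites[], transcript_sites = tx_sites[],
                duplicates = duplicates[], spec = spec)
  structure(list(genome = genome, models = models, truth = truth),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d contigs (%s nt), %d loci, %d planted DpnII sites, %d duplicated tags\n",
              length(x$genome), format(sum(nchar(x$genome)), big.mark = ","),
              nrow(x$truth$loci), nrow(x$truth$sites), nrow(x$truth$duplicates)))
  invisible(x)
}
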