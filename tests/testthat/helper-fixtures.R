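# Shared fixtures, built in code and memoized for the test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small genome shared by many tests
tiny_genome <- function() cached("tiny_genome", {
  generate_genome(sim_genome_spec(n_contigs = 2L, contig_length = 25000L,
                                  n_loci = 14L, mito_genes = 5L,
                                  overlap_fraction = 0.15,
                                  duplicate_site_fraction = 0.1,
                                  rng_seed = 101L))
})

# full small pipeline: 6 libraries x 2e4 reads, 2 planted clusters
small_pipeline <- function() cached("small_pipeline", {
  sa <- generate_atlas(n_libraries = 6L, planted_clusters = 2L,
                       n_reads = 2e4, seed = 202L)
  atlas <- ingest_atlas(sa)
  index <- build_index(enumerate_virtual_tags(sa$genome$genome))
  tsites <- locate_transcript_sites(sa$genome$models, sa$genome$genome)
  annotation <- classify_tags(index, sa$genome$models, tsites)
  list(sim = sa, atlas = atlas, index = index, tsites = tsites,
       annotation = annotation, models = sa$genome$models)
})

# hand-built contig hosting the six-tag cascade fixture:
# a protein-coding locus with a planted site (genic unique tag), an
# intergenic site, a tag planted at two locations (multi-mapper), and
# two atlas-only tags (one non-mapping, one low-abundance failing the
# significance filter together with a second low-abundance tag)
cascade_fixture <- function() cached("cascade_fixture", {
  unit <- "ACCTAGGTTCAATTGGACCT"           # GATC-free filler, 20 nt
  seg <- function(n) paste(rep(unit, n), collapse = "")
  tag_genic <- "GATCTTGGAACCTTGGAACC"
  tag_inter <- "GATCCAATTGGCCAATTGGC"
  tag_multi <- "GATCAAGGTTCCAAGGTTCC"
  tag_nomap <- "GATCGGTTAACCGGTTAACC"
  tag_low1  <- "GATCTTCCGGAATTCCGGAA"
  tag_low2  <- "GATCAACCGGTTAACCGGTT"
  contig <- paste0(seg(3),  # 0..59
                   tag_genic,        # locus exon: GATC at 60
                   seg(2),           # 80..119
                   tag_inter,        # GATC at 120
                   seg(2),           # 140..179
                   tag_multi,        # GATC at 180
                   seg(2),           # 200..239
                   tag_multi,        # GATC at 240
                   seg(3))
  genome <- c(chrT = contig)
  models <- gene_model_set(
    loci = data.table::data.table(locus_id = "LOCX", contig = "chrT",
                                  strand = "+", start = 40L, end = 100L,
                                  mitochondrial = FALSE),
    transcripts = data.table::data.table(transcript_id = "LOCX.t1",
                                         locus_id = "LOCX", class = "NM"),
    exons = data.table::data.table(transcript_id = "LOCX.t1", exon_rank = 1L,
                                   contig = "chrT", strand = "+",
                                   start = 40L, end = 100L))
  mk <- function(id, tags, tpms) {
    tag_library(data.table::data.table(tag = tags, raw = pmax(1L, round(tpms)),
                                       tpm = tpms), library_id = id)
  }
  libs <- list(
    mk("lib1", c(tag_genic, tag_inter, tag_multi, tag_nomap, tag_low1),
       c(50, 10, 5, 2, 1.5)),
    mk("lib2", c(tag_genic, tag_low2), c(40, 1.0)))
  atlas <- build_atlas(libs)
  index <- build_index(enumerate_virtual_tags(genome))
  tsites <- locate_transcript_sites(models, genome)
  list(genome = genome, models = models, atlas = atlas, index = index,
       tsites = tsites,
       tags = list(genic = tag_genic, inter = tag_inter, multi = tag_multi,
                   nomap = tag_nomap, low1 = tag_low1, low2 = tag_low2))
})

random_tag <- function() {
  paste0("GATC", paste(sample(c("A", "C", "G", "T"), 16, TRUE), collapse = ""))
}

# study-scale bundle: 12 libraries x 1e5 reads, 3 planted clusters
acceptance_bundle <- function() cached("acceptance_bundle", {
  sa <- generate_atlas(n_libraries = 12L, planted_clusters = 3L,
                       n_reads = 1e5, seed = 420L)
  atlas <- ingest_atlas(sa)
  index <- build_index(enumerate_virtual_tags(sa$genome$genome))
  tsites <- locate_transcript_sites(sa$genome$models, sa$genome$genome)
  annotation <- classify_tags(index, sa$genome$models, tsites)
  list(sim = sa, atlas = atlas, index = index, tsites = tsites,
       annotation = annotation, models = sa$genome$models)
})

# erroneous-model fixture: gene models whose XM-only loci have their
# 3' boundary displaced 400 nt downstream, as a mis-annotated model
# would; distances computed against these models spike near 400 nt
extend_xm_models <- function(sim, by = 400L) {
  models <- sim$models
  loci <- data.table::copy(models$loci)
  cls <- models$transcripts[, .(only_xm = all(class == "XM")), by = locus_id]
  cand <- loci[cls[only_xm == TRUE], on = "locus_id", nomatch = NULL]
  cand <- cand[mitochondrial == FALSE]
  targets <- character(0)
  for (i in seq_len(nrow(cand))) {
    li <- cand[i]
    same <- loci[contig == li$contig & locus_id != li$locus_id]
    if (li$strand == "+") {
      clash <- same[start > li$end & start < li$end + by + 50L]
      if (nrow(clash) == 0L) {
        loci[locus_id == li$locus_id, end := end + by]
        targets <- c(targets, li$locus_id)
      }
    } else {
      clash <- same[end < li$start & end > li$start - by - 50L]
      if (nrow(clash) == 0L) {
        loci[locus_id == li$locus_id, start := start - by]
        targets <- c(targets, li$locus_id)
      }
    }
  }
  list(models = gene_model_set(loci, models$transcripts, models$exons),
       targets = targets)
}
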