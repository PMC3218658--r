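test_that("transcript site ranking follows the 3'-most convention (hand case)", {
  # single-exon transcript: ...GATC(+16nt)...GATC(+16nt)AAA-3'
  filler <- "ACCTAGGTTCAATTGGACCT"
  seq <- paste0(filler, "GATCTTGGAACCTTGGAACC", filler,
                "GATCCAATTGGCCAATTGGC", "AAA")
  g <- c(c1 = seq)
  models <- gene_model_set(
    loci = data.table::data.table(locus_id = "L1", contig = "c1", strand = "+",
                                  start = 0L, end = nchar(seq),
                                  mitochondrial = FALSE),
    transcripts = data.table::data.table(transcript_id = "L1.t1", locus_id = "L1",
                                         class = "NM"),
    exons = data.table::data.table(transcript_id = "L1.t1", exon_rank = 1L,
                                   contig = "c1", strand = "+", start = 0L,
                                   end = nchar(seq)))
  ts <- locate_transcript_sites(models, g)
  expect_equal(nrow(ts), 2L)
  expect_equal(ts[spliced_pos == 60L, rank_from_3prime], 1L)   # downstream-most
  expect_equal(ts[spliced_pos == 20L, rank_from_3prime], 2L)
  expect_equal(ts$upstream_distance, nchar(seq) - ts$spliced_pos)
  # a transcript with no GATC yields no sites
  models2 <- gene_model_set(
    loci = data.table::data.table(locus_id = "L2", contig = "c2", strand = "+",
                                  start = 0L, end = 40L, mitochondrial = FALSE),
    transcripts = data.table::data.table(transcript_id = "L2.t1", locus_id = "L2",
                                         class = "NM"),
    exons = data.table::data.table(transcript_id = "L2.t1", exon_rank = 1L,
                                   contig = "c2", strand = "+", start = 0L, end = 40L))
  expect_equal(nrow(locate_transcript_sites(models2, c(c2 = strrep("ACCT", 10)))), 0L)
})

test_that("planted primary sites are recovered with rank 1 on every transcript", {
  sg <- tiny_genome()
  ts <- locate_transcript_sites(sg$models, sg$genome)
  tr <- sg$truth$transcript_sites
  m <- merge(ts, tr, by = c("transcript_id", "spliced_pos"))
  expect_equal(nrow(m), nrow(tr))
  expect_equal(m$rank_from_3prime, m$site_rank)
  expect_true(all(m[site_rank == 1L, rank_from_3prime] == 1L))
})

test_that("rank ordering is invariant under exon re-segmentation", {
  filler <- "ACCTAGGTTCAATTGGACCT"
  seq <- paste0(filler, "GATCTTGGAACCTTGGAACC", filler, filler,
                "GATCCAATTGGCCAATTGGC", filler)
  g <- c(c1 = seq)
  base_loci <- data.table::data.table(locus_id = "L1", contig = "c1",
                                      strand = "+", start = 0L,
                                      end = nchar(seq), mitochondrial = FALSE)
  tx <- data.table::data.table(transcript_id = "L1.t1", locus_id = "L1", class = "NM")
  one <- gene_model_set(base_loci, tx,
    data.table::data.table(transcript_id = "L1.t1", exon_rank = 1L, contig = "c1",
                           strand = "+", start = 0L, end = nchar(seq)))
  # split into two abutting exons: same spliced sequence
  two <- gene_model_set(base_loci, tx,
    data.table::data.table(transcript_id = "L1.t1", exon_rank = 1:2, contig = "c1",
                           strand = "+", start = c(0L, 50L), end = c(50L, nchar(seq))))
  t1 <- locate_transcript_sites(one, g)
  t2 <- locate_transcript_sites(two, g)
  expect_equal(t2[, .(spliced_pos, rank_from_3prime, upstream_distance, tag)],
               t1[, .(spliced_pos, rank_from_3prime, upstream_distance, tag)])
})

test_that("genomic upstream distance is strand-aware arithmetic", {
  expect_equal(upstream_distance_genomic(900L, 0L, 1000L, "+"), 100L)
  expect_equal(upstream_distance_genomic(260L, 200L, 1000L, "-"), 60L)
  expect_equal(upstream_distance_genomic(999L, 0L, 1000L, "+"), 1L)
  expect_error(upstream_distance_genomic(1500L, 0L, 1000L, "+"), "outside")
})

test_that("tag classification assigns locus, orientation and 3'-terminus flags", {
  p <- small_pipeline()
  ann <- p$annotation
  truth_sites <- p$sim$genome$truth$sites
  loci <- p$sim$genome$truth$loci

  # planted rank-1 sense tags that map uniquely are sense + on 3' terminus
  own <- ann[truth_sites[site_rank == 1L], on = c(tag = "tag_sense", locus_id = "locus_id"),
             nomatch = NULL]
  expect_true(all(own$orientation == "sense"))
  expect_true(all(own$on_3prime))

  # rank-3 sites (where planted) are sense but not on the 3' terminus
  r3 <- truth_sites[site_rank == 3L]
  own3 <- ann[r3, on = c(tag = "tag_sense", locus_id = "locus_id"), nomatch = NULL]
  expect_gt(nrow(own3), 0L)
  expect_true(all(own3$orientation == "sense"))
  expect_false(any(own3$on_3prime))

  # antisense counterparts are antisense and never on the 3' terminus
  owna <- ann[truth_sites, on = c(tag = "tag_anti", locus_id = "locus_id"),
              nomatch = NULL]
  expect_true(all(owna$orientation == "antisense"))
  expect_false(any(owna$on_3prime))

  # intergenic sites carry no locus and no orientation
  inter <- ann[is.na(locus_id)]
  expect_gt(nrow(inter), 0L)
  expect_true(all(inter$orientation == "intergenic"))

  # tags inside antiparallel overlapping loci are confounded, with both
  # (locus, orientation) pairs reported
  ov <- loci[!is.na(host)]
  conf <- ann[confound == TRUE]
  expect_gt(nrow(conf), 0L)
  both <- conf[, .(n = data.table::uniqueN(orientation)), by = tag]
  expect_true(all(both$n == 2L))
  expect_true(all(conf$locus_id %in% c(ov$locus_id, ov$host)))

  # multi-mapping tags are refused
  multi <- p$index$tags[class == "multi", tag]
  if (length(multi))
    expect_error(classify_tags(p$index, p$models, p$tsites, tags = multi[1]),
                 "unique")
})

test_that("within-locus sense TPM partitions into on/not-on 3' terminus", {
  p <- small_pipeline()
  ls <- library_summary(p$atlas, p$annotation)
  expect_equal(ls$on3_tpm + ls$not_on3_tpm, ls$sense_tpm_nmnr)
  expect_true(all(unlist(ls[, -1]) >= 0))
})

test_that("mitochondrial partition recovers simulated fractions and edge cases", {
  p <- small_pipeline()
  pm <- partition_mitochondrial(p$atlas, p$annotation)
  spec_frac <- 0.114
  expect_true(all(abs(pm$mito_fraction - spec_frac) <
                    3 * sqrt(spec_frac * (1 - spec_frac) / 2e4) + 0.01))

  # all-mito library -> fraction 1; no-mito library -> fraction 0
  sg <- tiny_genome()
  all_mito <- simulate_library(sg, sim_library_spec(
    n_reads = 2000, mito_fraction = 1, adapter_rate = 0, n_rate = 0,
    error_rate = 0, rng_seed = 3L))
  no_mito <- simulate_library(sg, sim_library_spec(
    n_reads = 2000, mito_fraction = 0, adapter_rate = 0, n_rate = 0,
    error_rate = 0, rng_seed = 4L))
  at <- build_atlas(list(ingest_reads(all_mito$reads, library_id = "allmt")$library,
                         ingest_reads(no_mito$reads, library_id = "nomt")$library))
  idx <- build_index(enumerate_virtual_tags(sg$genome))
  ts <- locate_transcript_sites(sg$models, sg$genome)
  ann <- classify_tags(idx, sg$models, ts)
  pm2 <- partition_mitochondrial(at, ann)
  expect_equal(pm2[library_id == "allmt", mito_fraction], 1)
  expect_equal(pm2[library_id == "nomt", mito_fraction], 0)
})
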