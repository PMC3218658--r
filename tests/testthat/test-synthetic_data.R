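test_that("genome generation realizes the requested structure", {
  # empty case: no gene features, valid (empty) GFF3
  sg0 <- generate_genome(sim_genome_spec(n_loci = 0L, mito_genes = 0L,
                                         n_contigs = 1L, contig_length = 5000L,
                                         rng_seed = 1L))
  expect_equal(nrow(sg0$models$loci), 0L)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_models_gff3(sg0$models, path)
  back <- read_models_gff3(path)
  expect_equal(nrow(back$loci), 0L)

  # overlap target realized within +-1 locus
  sg <- generate_genome(sim_genome_spec(n_loci = 10L, overlap_fraction = 0.5,
                                        exons_per_transcript = c(2L, 4L),
                                        mito_genes = 0L, rng_seed = 3L))
  n_over <- 2L * sum(!is.na(sg$truth$loci$host))
  expect_lte(abs(n_over - 5L), 1L)
  # overlappers are antiparallel and overlap their host's span
  ov <- sg$truth$loci[!is.na(host)]
  hostrows <- sg$truth$loci[match(ov$host, locus_id)]
  expect_true(all(ov$strand != hostrows$strand))
  expect_true(all(ov$start < hostrows$end & ov$end > hostrows$start))

  # sizing error names the constraint
  expect_error(generate_genome(sim_genome_spec(n_contigs = 1L, contig_length = 2000L,
                                               n_loci = 20L, mito_genes = 0L,
                                               rng_seed = 4L)),
               "too short to host")
})

test_that("without duplication every 3'-most tag is genome-unique (brute force)", {
  sg <- generate_genome(sim_genome_spec(n_contigs = 1L, contig_length = 15000L,
                                        n_loci = 8L, duplicate_site_fraction = 0,
                                        mito_genes = 3L, rng_seed = 17L))
  scan <- brute_force_virtual_tags(sg$genome)
  counts <- table(scan$tag)
  r1 <- sg$truth$sites[site_rank == 1L, tag_sense]
  expect_true(all(counts[r1] == 1L))
})

test_that("siteless loci have no GATC on their transcripts", {
  sg <- tiny_genome()
  sl_ids <- sg$truth$loci[siteless == TRUE, locus_id]
  expect_gt(length(sl_ids), 0L)   # the organelle COX3/ND3-style pair at least
  ts <- locate_transcript_sites(sg$models, sg$genome)
  expect_equal(nrow(ts[locus_id %in% sl_ids]), 0L)
})

test_that("library simulation conserves truth and respects the read model", {
  sg <- tiny_genome()
  spec <- sim_library_spec(n_reads = 4000, rng_seed = 5L)
  sl <- simulate_library(sg, spec)
  # truth conservation: one record per emitted read
  expect_equal(nrow(sl$truth), 4000L)
  expect_equal(sl$truth$read, sl$reads)
  # reads are 20-base strings beginning GATC except artifacts/errors
  clean <- sl$truth[read_class == "tag"]
  expect_true(all(nchar(clean$read) == 20L))
  expect_true(all(startsWith(clean$tag_true, "GATC")))

  # no-noise libraries emit only genomic 20-mers
  sl0 <- simulate_library(sg, sim_library_spec(n_reads = 3000, error_rate = 0,
                                               adapter_rate = 0, n_rate = 0,
                                               rng_seed = 6L))
  idx <- build_index(enumerate_virtual_tags(sg$genome))
  expect_true(all(sl0$reads %in% idx$tags$tag))

  # unknown locus in the expression profile is a key error
  bad <- sim_library_spec(n_reads = 10,
                          expression_profile = c(NOPE = 1), rng_seed = 1L)
  expect_error(simulate_library(sg, bad), "unknown locus")
})

test_that("identical seeds give byte-identical outputs", {
  spec_g <- sim_genome_spec(n_contigs = 1L, contig_length = 15000L, n_loci = 6L,
                            mito_genes = 3L, rng_seed = 77L)
  g1 <- generate_genome(spec_g); g2 <- generate_genome(spec_g)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth$sites, g2$truth$sites)
  s1 <- simulate_library(g1, sim_library_spec(n_reads = 2000, rng_seed = 13L))
  s2 <- simulate_library(g2, sim_library_spec(n_reads = 2000, rng_seed = 13L))
  expect_identical(s1$reads, s2$reads)
  a1 <- generate_atlas(3L, 2L, n_reads = 500, genome_spec = spec_g, seed = 5L)
  a2 <- generate_atlas(3L, 2L, n_reads = 500, genome_spec = spec_g, seed = 5L)
  expect_identical(lapply(a1$libs, `[[`, "reads"), lapply(a2$libs, `[[`, "reads"))
})

test_that("simulator moments converge to spec values (binomial 3 sigma)", {
  sg <- tiny_genome()
  n <- 2e4
  spec <- sim_library_spec(n_reads = n, rng_seed = 55L)
  sl <- simulate_library(sg, spec)
  tr <- sl$truth[read_class != "adapter"]
  sig <- function(p) 3 * sqrt(p * (1 - p) / nrow(tr))
  # site-rank usage among nuclear sense reads
  sense <- tr[orientation == "sense" & !startsWith(locus_id, "MTG")]
  expect_lt(abs(mean(sense$site_rank == 1L) - spec$p_primary_site),
            3 * sqrt(.915 * .085 / nrow(sense)) + 1e-9)
  # antisense and mito routing
  nuc <- tr[!startsWith(locus_id, "MTG")]
  expect_lt(abs(mean(nuc$orientation == "antisense") - spec$antisense_rate), sig(0.103))
  expect_lt(abs(mean(startsWith(tr$locus_id, "MTG")) - spec$mito_fraction), sig(0.114))
  # adapter artifact count: binomial expectation within 3 sigma
  n_ad <- sum(sl$truth$read_class == "adapter")
  expect_lt(abs(n_ad - n * spec$adapter_rate), 3 * sqrt(n * spec$adapter_rate))
  # and every adapter read is removed at ingestion
  flt <- filter_artifacts(aggregate_raw_tags(sl$reads))
  expect_equal(flt$report$adapter_raw_count, n_ad)
})

test_that("atlas generation respects its contracts", {
  a0 <- generate_atlas(0L, 0L, seed = 1L,
                       genome_spec = sim_genome_spec(n_contigs = 1L,
                                                     contig_length = 12000L,
                                                     n_loci = 5L, mito_genes = 0L))
  expect_equal(length(a0$libs), 0L)
  expect_equal(nrow(ingest_atlas(a0)$libraries), 0L)
  expect_error(generate_atlas(2L, 3L, seed = 1L), "planted_clusters")
  expect_error(generate_atlas(4L, 2L, separation = -1, seed = 1L), "separation")

  # single planted cluster: pairwise distances small and homogeneous
  a1 <- generate_atlas(4L, 1L, n_reads = 4000, seed = 9L,
                       genome_spec = sim_genome_spec(n_contigs = 1L,
                                                     contig_length = 20000L,
                                                     n_loci = 10L, mito_genes = 0L))
  profs <- atlas_profiles(ingest_atlas(a1))
  tree <- cluster_profiles(profs)
  d <- as.matrix(attr(tree, "dist"))
  off <- d[upper.tri(d)]
  expect_lt(max(off) / min(off), 3)
})

test_that("genome FASTA and gene-model GFF3 serialization round trips", {
  sg <- tiny_genome()
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(sg$genome, fa)
  expect_identical(read_genome_fasta(fa), sg$genome)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_models_gff3(sg$models, gff)
  back <- read_models_gff3(gff)
  expect_equal(as.data.frame(back$loci[order(locus_id)]),
               as.data.frame(sg$models$loci[order(locus_id)]))
  expect_equal(as.data.frame(back$transcripts[order(transcript_id),
                 .(transcript_id, locus_id, class, spliced_length)]),
               as.data.frame(sg$models$transcripts[order(transcript_id),
                 .(transcript_id, locus_id, class, spliced_length)]))
  expect_equal(nrow(back$exons), nrow(sg$models$exons))
})
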