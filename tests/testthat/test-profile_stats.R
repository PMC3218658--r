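test_that("MEL behaves like a robust mean", {
  expect_equal(mel(c(1, 2, 3)), 2)
  expect_equal(mel(rep(7, 5)), 7)
  out <- mel(c(1, 2, 3, 1000))
  expect_gt(out, 2); expect_lt(out, mean(c(1, 2, 3, 1000)))
  expect_error(mel(numeric(0)), "empty")
})

test_that("MAD scale matches hand computation and is consistent for the sd", {
  expect_equal(mad_scale(1:5), 1.4826)
  expect_equal(mad_scale(rep(3, 10)), 0)
  expect_equal(mad_scale(1:5, robust_params(mad_consistency = 1)), 1)
  set.seed(4)
  x <- rnorm(20000, sd = 2.5)
  expect_lt(abs(mad_scale(x) - 2.5) / 2.5, 0.05)
  expect_error(mad_scale(numeric(0)), "empty")
})

test_that("MEL and MAD agree with independent direct implementations", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(3:60, 1)
    x <- rnorm(n, sample(-5:5, 1), runif(1, 0.5, 4))
    if (i %% 3 == 0) x <- c(x, runif(2, 50, 100))  # contaminated cases
    expect_lt(abs(mel(x) - direct_mel(x)), 1e-10)
    expect_lt(abs(mad_scale(x) - direct_mad(x)), 1e-10)
  }
})

test_that("the upstream-distance ECDF is a proper step function", {
  ann <- data.table::data.table(
    tag = paste0("t", 1:3), locus_id = "L", orientation = "sense",
    upstream_dist = c(10L, 20L, 30L))
  e <- ecdf_upstream_distance(ann, "sense")
  expect_equal(e[distance == 20, ecdf], 2 / 3)
  expect_true(all(diff(e$ecdf) >= 0))
  expect_equal(e$ecdf[nrow(e)], 1)

  zero <- data.table::data.table(tag = "t", locus_id = "L",
                                 orientation = "sense", upstream_dist = 0L)
  expect_equal(ecdf_upstream_distance(zero, "sense"),
               data.table::data.table(distance = 0L, ecdf = 1))
  expect_equal(nrow(ecdf_upstream_distance(ann[0], "antisense")), 0L)

  p <- small_pipeline()
  es <- ecdf_upstream_distance(p$annotation, "sense")
  expect_true(all(diff(es$ecdf) >= 0))
  expect_equal(es$ecdf[nrow(es)], 1)
})

test_that("distance histograms conserve the binned TPM", {
  ann <- data.table::data.table(tag = "t1", locus_id = "L", orientation = "sense",
                                upstream_dist = 50L, locus_classes = "NM")
  lib <- tag_library(data.table::data.table(tag = "t1", raw = 1L, tpm = 100),
                     library_id = "x")
  atlas <- build_atlas(list(lib))
  h <- distance_histogram(ann, atlas, "sense", bin_width = 100)
  expect_equal(h, data.table::data.table(bin_start = 0, bin_end = 100, weight = 100))
  expect_error(distance_histogram(ann, atlas, "sense", bin_width = 0), "bin_width")

  p <- small_pipeline()
  hs <- distance_histogram(p$annotation, p$atlas, "sense")
  within_nm <- unique(p$annotation[orientation == "sense" & !is.na(upstream_dist) &
                                     grepl("NM|NR|XM", locus_classes), tag])
  expect_equal(sum(hs$weight), p$atlas$tags[tag %in% within_nm, sum(total_tpm)])
})

test_that("weighted transcript length is the TPM-weighted mean, standardized", {
  # two transcripts, lengths {1000, 3000}, TPM {3, 1} -> weighted mean 1500
  w <- sum(c(3, 1) * c(1000, 3000)) / 4
  expect_equal(w, 1500)
  p <- small_pipeline()
  wl <- weighted_transcript_length(p$atlas, p$annotation, p$tsites, p$models)
  expect_equal(nrow(wl), nrow(p$atlas$libraries))
  expect_true(all(is.finite(wl$weighted_mean_length)))
  # standardization: a value equal to the reference MEL standardizes to 0
  melr <- attr(wl, "mel_ref"); madr <- attr(wl, "mad_ref")
  expect_equal((melr - melr) / madr, 0)
  expect_equal(wl$standardized, (wl$weighted_mean_length - melr) / madr)
})

test_that("profiles planted on short vs long transcripts standardize with opposite signs", {
  sg <- tiny_genome()
  tx <- sg$models$transcripts[class == "NM" & spliced_length > 0]
  tx <- tx[!locus_id %in% sg$truth$loci[siteless == TRUE, locus_id]]
  tx <- tx[!startsWith(locus_id, "MTG")]
  per_locus <- tx[, .(len = min(spliced_length)), by = locus_id][order(len)]
  short <- per_locus$locus_id[1:2]
  long <- per_locus$locus_id[(nrow(per_locus) - 1):nrow(per_locus)]
  mk <- function(id, loci, seed) {
    prof <- setNames(rep(1 / length(loci), length(loci)), loci)
    sl <- simulate_library(sg, sim_library_spec(
      n_reads = 5000, expression_profile = prof, mito_fraction = 0,
      antisense_rate = 0, error_rate = 0, adapter_rate = 0, n_rate = 0,
      rng_seed = seed))
    ingest_reads(sl$reads, library_id = id)$library
  }
  atlas <- build_atlas(list(mk("short_lib", short, 1L), mk("long_lib", long, 2L)))
  idx <- build_index(enumerate_virtual_tags(sg$genome))
  ts <- locate_transcript_sites(sg$models, sg$genome)
  ann <- classify_tags(idx, sg$models, ts)
  wl <- weighted_transcript_length(atlas, ann, ts, sg$models)
  expect_lt(wl[library_id == "short_lib", standardized], 0)
  expect_gt(wl[library_id == "long_lib", standardized], 0)
})

test_that("constitutive gene ranking follows the coefficient of variation", {
  m <- rbind(constL = c(10, 10, 10), varL = c(10, 20, 30), absL = c(5, 0, 9))
  colnames(m) <- paste0("l", 1:3)
  hk <- constitutive_genes(m)
  expect_equal(hk$locus_id, c("constL", "varL"))  # absL absent in one library
  expect_equal(hk[locus_id == "constL", cv], 0)
  expect_equal(constitutive_genes(rbind(x = c(10, 20)))$cv, sd(c(10, 20)) / 15)
  expect_equal(round(constitutive_genes(rbind(x = c(10, 20)))$cv, 4), 0.4714)

  # permutation invariance over libraries
  p <- small_pipeline()
  lm <- locus_sense_tpm(p$atlas, p$annotation)
  hk1 <- constitutive_genes(lm)
  hk2 <- constitutive_genes(lm[, rev(seq_len(ncol(lm))), drop = FALSE])
  expect_equal(hk1[, .(locus_id, cv)], hk2[, .(locus_id, cv)])
})

test_that("constitutive tags require presence in every library", {
  mk <- function(id, tags, tpms)
    tag_library(data.table::data.table(tag = tags, raw = 1L, tpm = tpms),
                library_id = id)
  atlas <- build_atlas(list(mk("l1", c("T1", "T2"), c(5, 5)),
                            mk("l2", c("T1"), 4)))
  classes <- data.table::data.table(tag = c("T1", "T2"),
                                    class = c("intergenic", "within"))
  ct <- constitutive_tags(atlas, classes)
  expect_equal(ct$tags$tag, "T1")
  expect_equal(ct$summary$class, "intergenic")

  # simulation: planted constitutive intergenic tags are recovered exactly
  p <- small_pipeline()
  mapping <- map_atlas(p$atlas, p$index)
  cls <- p$annotation[, .(class = ifelse(any(!is.na(locus_id)), "within_locus",
                                         "intergenic")), by = tag]
  cls <- rbind(cls, data.table::data.table(
    tag = setdiff(p$atlas$tags$tag, cls$tag), class = "non_mapping"))
  ct2 <- constitutive_tags(p$atlas, cls)
  n_lib <- nrow(p$atlas$libraries)
  expect_setequal(ct2$tags$tag, p$atlas$tags[n_libraries_present == n_lib, tag])
})

test_that("antisense and site-usage recovery statistics are coherent", {
  p <- small_pipeline()
  sh <- site_usage_shares(p$atlas, p$annotation, p$tsites)
  expect_equal(sh$primary_share + sh$secondary_share, 1)
  expect_lt(abs(sh$primary_share - 0.915), 0.02)
  a <- antisense_share(p$atlas, p$annotation, scope = "nuclear")
  expect_lt(abs(a - 0.103), 0.02)
  am <- antisense_share(p$atlas, p$annotation, scope = "mito")
  expect_lt(abs(am - 0.044), 0.02)
})
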