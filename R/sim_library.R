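## Simulated DGE tag libraries over a synthetic genome, with per-read
## ground truth.

#' Specification of a simulated tag library
#'
#' Defaults reflect the behaviour of polyA-anchored DpnII tag
#' libraries: 91.5% of tag abundance from the 3'-most (primary) DpnII
#' site and 8.5% from the next-to-3'-most (secondary) site; any
#' remaining probability mass is spread over upstream sites with
#' geometric decay `upstream_decay` (the upstream-usage law is a
#' generator choice, not an observed quantity). Antisense reads arise
#' at `antisense_rate` for nuclear loci (default 0.103, a typical
#' within-locus antisense abundance share) and at `mito_antisense_rate`
#' (default 0.044) for mitochondrial loci; antisense reads use their
#' own, more 3'-biased site-rank law (`antisense_p_primary`), matching
#' the tendency of antisense tags to sit closer to the 3' terminus.
#' `mito_fraction` (default 0.114, a typical mitochondrial share of
#' within-locus abundance) routes reads to the organelle loci.
#'
#' @param library_id library identifier.
#' @param n_reads number of reads to draw.
#' @param p_primary_site,p_secondary_site usage probabilities of site
#'   ranks 1 and 2; their sum must be <= 1.
#' @param antisense_rate,mito_antisense_rate probability that a
#'   nuclear/mitochondrial read is antisense.
#' @param antisense_p_primary rank-1 usage probability for antisense
#'   reads (remainder goes to rank 2).
#' @param error_rate per-base substitution probability.
#' @param adapter_rate probability that a read is the adapter artifact
#'   (GATC + adapter 16-mer).
#' @param n_rate probability that a read carries an indeterminate base.
#' @param mito_fraction proportion of reads drawn from mitochondrial
#'   loci.
#' @param upstream_decay geometric decay parameter of upstream
#'   (rank >= 3) site usage.
#' @param expression_profile optional named numeric vector mapping
#'   nuclear locus ids to relative abundances (must sum to 1); by
#'   default a log-normal profile is drawn under the library seed.
#' @param mito_expression_profile optional named numeric vector over
#'   mitochondrial locus ids (must sum to 1); by default log-normal.
#' @param metadata named list (tissue, class_path, stage, sex).
#' @param rng_seed integer seed; identical seeds give byte-identical
#'   libraries.
#' @return A validated list of class `sim_library_spec`.
#' @export
sim_library_spec <- function(library_id = "lib1", n_reads = 1e5,
                             p_primary_site = 0.915, p_secondary_site = 0.085,
                             antisense_rate = 0.103, mito_antisense_rate = 0.044,
                             antisense_p_primary = 0.98,
                             error_rate = 0.002, adapter_rate = 0.013,
                             n_rate = 0.005, mito_fraction = 0.114,
                             upstream_decay = 0.5, expression_profile = NULL,
                             mito_expression_profile = NULL,
                             metadata = list(), rng_seed = NULL) {
  stopifnot(is_count(n_reads),
            is_prob(p_primary_site), is_prob(p_secondary_site),
            is_prob(antisense_rate), is_prob(mito_antisense_rate),
            is_prob(antisense_p_primary), is_prob(error_rate),
            is_prob(adapter_rate), is_prob(n_rate), is_prob(mito_fraction),
            is_prob(upstream_decay))
  if (p_primary_site + p_secondary_site > 1 + 1e-12)
    stop_fmt("sim_library_spec(): p_primary_site + p_secondary_site must be <= 1")
  if (!is.null(expression_profile)) {
    stopifnot(is.numeric(expression_profile), !is.null(names(expression_profile)),
              all(expression_profile >= 0))
    if (abs(sum(expression_profile) - 1) > 1e-8)
      stop_fmt("sim_library_spec(): expression_profile must sum to 1")
  }
  structure(as.list(environment()), class = "sim_library_spec")
}

## draw a site rank given per-read uniforms and the spec's rank law
.draw_ranks <- function(n, p1, p2, decay) {
  u <- runif(n)
  r <- integer(n)
  r[u < p1] <- 1L
  r[u >= p1 & u < p1 + p2] <- 2L
  up <- which(r == 0L)
  if (length(up)) r[up] <- 3L + rgeom(length(up), prob = max(decay, 1e-6))
  r
}

#' Simulate one tag library from a synthetic genome
#'
#' Draws `n_reads` 20-base reads: adapter artifacts, reads with an
#' indeterminate base, and transcript tags chosen by locus (expression
#' profile, mitochondrial routing), site rank and orientation, with
#' independent per-base substitution errors. Every read has exactly one
#' ground-truth record.
#'
#' @param sim a `sim_genome` from [generate_genome()].
#' @param spec a [sim_library_spec()].
#' @return list of class `sim_library` with `reads` (character vector)
#'   and `truth` (one data.table row per read: read class, origin
#'   locus/transcript, site rank, orientation, error flag, true and
#'   emitted tag).
#' @export
simulate_library <- function(sim, spec) {
  stopifnot(inherits(sim, "sim_genome"), inherits(spec, "sim_library_spec"))
  with_seed_if(spec$rng_seed, .simulate_library(sim, spec))
}

.simulate_library <- function(sim, spec) {
  sites <- sim$truth$sites
  loci <- sim$truth$loci
  nuc <- loci[mitochondrial == FALSE & siteless == FALSE, locus_id]
  mito <- loci[mitochondrial == TRUE & siteless == FALSE, locus_id]
  if (!length(nuc) && !length(mito))
    stop_fmt("simulate_library(): genome has no transcript with a DpnII site")

  profile <- spec$expression_profile
  if (is.null(profile)) {
    profile <- exp(rnorm(length(nuc), 0, 1.2))
    profile <- setNames(profile / sum(profile), nuc)
  } else {
    unknown <- setdiff(names(profile), nuc)
    if (length(unknown))
      stop_fmt("simulate_library(): expression_profile references unknown locus %s",
               unknown[1L])
  }
  mito_profile <- spec$mito_expression_profile
  if (is.null(mito_profile) && length(mito)) {
    w <- exp(rnorm(length(mito), 0, 0.8))
    mito_profile <- setNames(w / sum(w), mito)
  } else if (!is.null(mito_profile)) {
    unknown <- setdiff(names(mito_profile), mito)
    if (length(unknown))
      stop_fmt("simulate_library(): mito_expression_profile references unknown locus %s",
               unknown[1L])
  }

  n <- as.integer(spec$n_reads)
  if (n == 0L)
    return(structure(list(reads = character(0),
                          truth = data.table(read_class = character(0))),
                     class = "sim_library", library_id = spec$library_id))

  cls <- sample(c("adapter", "nbase", "tag"), n, replace = TRUE,
                prob = c(spec$adapter_rate, spec$n_rate,
                         1 - spec$adapter_rate - spec$n_rate))
  truth <- data.table(read_id = seq_len(n), read_class = cls,
                      locus_id = NA_character_, transcript_id = NA_character_,
                      site_rank = NA_integer_, orientation = NA_character_,
                      tag_true = NA_character_)
  reads <- character(n)
  reads[cls == "adapter"] <- paste0(DPNII_SITE, DGE_ADAPTER)

  is_tag <- cls != "adapter"
  m <- sum(is_tag)
  if (m) {
    use_mito <- if (length(nuc) == 0L) rep(TRUE, m) else
      length(mito) > 0 & runif(m) < spec$mito_fraction
    lid <- character(m)
    if (any(!use_mito))
      lid[!use_mito] <- sample(names(profile), sum(!use_mito), TRUE, prob = profile)
    if (any(use_mito))
      lid[use_mito] <- sample(names(mito_profile), sum(use_mito), TRUE,
                              prob = mito_profile)
    anti <- runif(m) < fifelse(use_mito, spec$mito_antisense_rate,
                               spec$antisense_rate)
    rank <- integer(m)
    if (any(!anti))
      rank[!anti] <- .draw_ranks(sum(!anti), spec$p_primary_site,
                                 spec$p_secondary_site, spec$upstream_decay)
    if (any(anti))
      rank[anti] <- .draw_ranks(sum(anti), spec$antisense_p_primary,
                                1 - spec$antisense_p_primary, spec$upstream_decay)
    nsite <- sites[, .N, by = locus_id]
    rank <- pmin(rank, nsite$N[match(lid, nsite$locus_id)])
    ## transcript: uniform among the locus's transcripts
    txs <- sim$models$transcripts[, .(transcript_id, locus_id)]
    txl <- split(txs$transcript_id, txs$locus_id)
    tid <- vapply(txl[lid], function(v)
      if (length(v) == 1L) v else sample(v, 1L), character(1))
    key <- paste(lid, rank)
    sense_tags <- setNames(sites$tag_sense, paste(sites$locus_id, sites$site_rank))
    anti_tags <- setNames(sites$tag_anti, paste(sites$locus_id, sites$site_rank))
    tg <- fifelse(anti, anti_tags[key], sense_tags[key])

    truth[is_tag, `:=`(locus_id = lid, transcript_id = tid, site_rank = rank,
                       orientation = fifelse(anti, "antisense", "sense"),
                       tag_true = tg)]
    emitted <- tg
    ## independent per-base substitution errors
    if (spec$error_rate > 0) {
      nerr <- rbinom(m, TAG_LENGTH, spec$error_rate)
      for (i in which(nerr > 0L)) {
        s <- strsplit(emitted[i], "", fixed = TRUE)[[1L]]
        at <- sample.int(TAG_LENGTH, nerr[i])
        s[at] <- vapply(s[at], function(b) sample(DNA_BASES[DNA_BASES != b], 1L),
                        character(1))
        emitted[i] <- paste(s, collapse = "")
      }
    }
    reads[is_tag] <- emitted
  }
  ## indeterminate-base reads: one random position set to N
  nidx <- which(cls == "nbase")
  for (i in nidx) {
    s <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    s[sample.int(TAG_LENGTH, 1L)] <- "N"
    reads[i] <- paste(s, collapse = "")
  }
  truth[, read := reads]
  structure(list(reads = reads, truth = truth[]),
            class = "sim_library", library_id = spec$library_id,
            spec = spec)
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("<sim_library> %s: %d reads (%d tag, %d adapter, %d with N)\n",
              attr(x, "library_id"), length(x$reads),
              sum(x$truth$read_class == "tag"),
              sum(x$truth$read_class == "adapter"),
              sum(x$truth$read_class == "nbase")))
  invisible(x)
}

#' Generate a multi-library atlas with planted cluster structure
#'
#' Simulates `n_libraries` libraries over one synthetic genome.
#' Libraries are assigned cyclically to `planted_clusters` groups; each
#' group has its own expression profile in which a random quarter of
#' the loci is up-shifted by `separation` on the log scale, and
#' libraries within a group perturb the group profile by multiplicative
#' log-normal noise (sd 0.15). Larger `separation` means
#' better-separated groups in simplex geometry.
#'
#' @param n_libraries number of libraries.
#' @param planted_clusters number of groups (<= `n_libraries`).
#' @param separation positive log-scale effect size between groups.
#' @param n_reads reads per library.
#' @param genome_spec a [sim_genome_spec()]; its `rng_seed` is derived
#'   from `seed` when unset.
#' @param library_spec template [sim_library_spec()] supplying rates
#'   for every library.
#' @param seed integer master seed.
#' @return list of class `sim_atlas`: `genome` (the `sim_genome`),
#'   `libs` (list of `sim_library`), `metadata` (library table with
#'   planted cluster labels and ontology class paths).
#' @export
generate_atlas <- function(n_libraries, planted_clusters = 3L, separation = 2,
                           n_reads = 1e5, genome_spec = sim_genome_spec(),
                           library_spec = sim_library_spec(), seed = 1L) {
  stopifnot(is_count(n_libraries), is_count(planted_clusters))
  if (n_libraries > 0 && planted_clusters > n_libraries)
    stop_fmt("generate_atlas(): planted_clusters must be <= n_libraries")
  if (!is.null(separation) && separation <= 0)
    stop_fmt("generate_atlas(): separation must be > 0")
  if (is.null(genome_spec$rng_seed)) genome_spec$rng_seed <- seed
  sim <- generate_genome(genome_spec)
  if (n_libraries == 0L)
    return(structure(list(genome = sim, libs = list(),
                          metadata = data.table(library_id = character(0),
                                                cluster = integer(0))),
                     class = "sim_atlas"))
  nuc <- sim$truth$loci[mitochondrial == FALSE & siteless == FALSE, locus_id]
  class_names <- c("nervous tissue", "muscle", "gland", "connective tissue",
                   "alimentary canal", "urogenital")
  libs <- vector("list", n_libraries)
  meta <- vector("list", n_libraries)
  mito_loci <- sim$truth$loci[mitochondrial == TRUE & siteless == FALSE, locus_id]
  base_log <- with_seed_if(seed + 1L, rnorm(length(nuc), 0, 1.2))
  shifts <- with_seed_if(seed + 2L, {
    lapply(seq_len(planted_clusters), function(cl) {
      up <- sample(length(nuc), max(1L, round(length(nuc) / 4)))
      v <- numeric(length(nuc)); v[up] <- separation; v
    })
  })
  mito_base <- with_seed_if(seed + 3L, rnorm(length(mito_loci), 0, 0.8))
  mito_shifts <- with_seed_if(seed + 4L, {
    lapply(seq_len(planted_clusters), function(cl) {
      up <- sample(length(mito_loci), max(1L, round(length(mito_loci) / 3)))
      v <- numeric(length(mito_loci)); v[up] <- separation; v
    })
  })
  for (i in seq_len(n_libraries)) {
    cl <- ((i - 1L) %% planted_clusters) + 1L
    lg <- base_log + shifts[[cl]] +
      with_seed_if(seed + 100L + i, rnorm(length(nuc), 0, 0.15))
    prof <- setNames(exp(lg) / sum(exp(lg)), nuc)
    lspec <- library_spec
    lspec$library_id <- sprintf("SIM%03d", i)
    lspec$n_reads <- n_reads
    lspec$expression_profile <- prof
    if (length(mito_loci)) {
      mlg <- mito_base + mito_shifts[[cl]] +
        with_seed_if(seed + 500L + i, rnorm(length(mito_loci), 0, 0.15))
      lspec$mito_expression_profile <- setNames(exp(mlg) / sum(exp(mlg)), mito_loci)
    }
    lspec$rng_seed <- seed + 1000L + i
    lspec$metadata <- list(
      tissue = sprintf("%s %d", class_names[cl], i),
      class_path = sprintf("%s/region %d", class_names[cl], cl),
      stage = "juvenile", sex = c("female", "male")[(i %% 2L) + 1L])
    libs[[i]] <- simulate_library(sim, lspec)
    meta[[i]] <- data.table(library_id = lspec$library_id, cluster = cl,
                            tissue = lspec$metadata$tissue,
                            class_path = lspec$metadata$class_path)
  }
  structure(list(genome = sim, libs = libs, metadata = rbindlist(meta)),
            class = "sim_atlas")
}

#' Ingest all libraries of a simulated atlas
#'
#' Runs [ingest_reads()] on every simulated library and stacks the
#' results into a [build_atlas()] object.
#'
#' @param sim_atlas a [generate_atlas()] result.
#' @param adapter adapter sequence for artifact filtering.
#' @return A `tag_atlas`.
#' @export
ingest_atlas <- function(sim_atlas, adapter = DGE_ADAPTER) {
  libs <- lapply(sim_atlas$libs, function(sl) {
    spec <- attr(sl, "spec")
    ingest_reads(sl$reads, library_id = attr(sl, "library_id"),
                 metadata = spec$metadata, adapter = adapter)$library
  })
  build_atlas(libs)
}
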