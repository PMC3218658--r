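## Per-library summaries, distance distributions, abundance-weighted
## inferred transcript lengths, and constitutive (housekeeping)
## gene/tag detection.

## (tag, locus) pair table with per-library TPM for within-locus tags
.pair_tpm <- function(atlas, annotation) {
  pairs <- annotation[!is.na(locus_id)]
  atlas$tpm[pairs, on = "tag", nomatch = NULL, allow.cartesian = TRUE]
}

#' Per-library summary of within-locus tag abundance
#'
#' For each library: distinct loci with sense tags (GeneID count),
#' unique sense tag sequences and TPM within loci, the same for the
#' curated (NM/NR) subset split into on-3'-terminus versus
#' not-on-3'-terminus abundance, the antisense analogues, and the
#' mitochondrial fraction. The partition identity
#' `on3_tpm + not_on3_tpm = sense_tpm_nmnr` is exact by construction.
#'
#' @param atlas a `tag_atlas`.
#' @param annotation output of [classify_tags()] on the uniquely
#'   mapping tag set under analysis.
#' @return data.table, one row per library.
#' @export
library_summary <- function(atlas, annotation) {
  dt <- .pair_tpm(atlas, annotation)
  nmnr <- function(lc) !is.na(lc) & grepl("NM|NR", lc)
  s <- dt[orientation == "sense",
          .(n_gene_ids = uniqueN(locus_id), n_sense_tags = uniqueN(tag),
            sense_tpm = sum(tpm),
            sense_tpm_nmnr = sum(tpm[nmnr(locus_classes)]),
            on3_tpm = sum(tpm[nmnr(locus_classes) & on_3prime]),
            not_on3_tpm = sum(tpm[nmnr(locus_classes) & !on_3prime])),
          by = library_id]
  a <- dt[orientation == "antisense",
          .(n_antisense_gene_ids = uniqueN(locus_id),
            n_antisense_tags = uniqueN(tag), antisense_tpm = sum(tpm)),
          by = library_id]
  res <- merge(s, a, by = "library_id", all = TRUE)
  res <- res[atlas$libraries[, .(library_id)], on = "library_id"]
  for (cc in setdiff(names(res), "library_id"))
    set(res, which(is.na(res[[cc]])), cc, 0)
  mf <- partition_mitochondrial(atlas, annotation)
  res <- mf[, .(library_id, mito_fraction)][res, on = "library_id"]
  setcolorder(res, "library_id")
  res[]
}

#' ECDF of the upstream distance from the 3' terminus
#'
#' Empirical cumulative distribution of the genomic upstream distance
#' of within-locus tags of one orientation, computed over unique tag
#' sequences (unweighted). Returns the step-function table
#' (nondecreasing, right limit 1); empty input yields an empty table.
#'
#' @param annotation output of [classify_tags()].
#' @param orientation `"sense"` or `"antisense"`.
#' @return data.table `distance`, `ecdf`.
#' @export
ecdf_upstream_distance <- function(annotation, orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation)
  ori <- orientation
  d <- unique(annotation[orientation == ori & !is.na(upstream_dist),
                         .(tag, upstream_dist)])$upstream_dist
  if (!length(d)) return(data.table(distance = numeric(0), ecdf = numeric(0)))
  tab <- data.table(distance = sort(unique(d)))
  tab[, ecdf := cumsum(tabulate(match(sort(d), distance)))/length(d)]
  tab[]
}

#' Abundance-weighted histogram of upstream distances
#'
#' Bins the genomic upstream distance of within-locus tags of one
#' orientation, weighting each tag by its total TPM over libraries.
#' `model_classes` restricts to tags in loci carrying at least one
#' transcript of the given classes (e.g. `"NM"` for curated-only,
#' `c("NM", "XM")` to include computational models). Bin weights sum
#' to the total TPM of the binned tags.
#'
#' @param annotation output of [classify_tags()].
#' @param atlas a `tag_atlas` supplying the TPM weights.
#' @param orientation `"sense"` or `"antisense"`.
#' @param model_classes transcript classes the locus must carry.
#' @param bin_width positive bin width in nt (default 100).
#' @return data.table `bin_start`, `bin_end`, `weight`.
#' @export
distance_histogram <- function(annotation, atlas,
                               orientation = c("sense", "antisense"),
                               model_classes = c("NM", "NR", "XM"),
                               bin_width = 100) {
  orientation <- match.arg(orientation)
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop_fmt("distance_histogram(): bin_width must be > 0")
  ori <- orientation
  patt <- paste(model_classes, collapse = "|")
  dt <- annotation[orientation == ori & !is.na(upstream_dist) &
                     grepl(patt, locus_classes)]
  dt <- unique(dt[, .(tag, upstream_dist)])
  dt <- atlas$tags[, .(tag, total_tpm)][dt, on = "tag", nomatch = NULL]
  if (!nrow(dt))
    return(data.table(bin_start = numeric(0), bin_end = numeric(0),
                      weight = numeric(0)))
  dt[, bin := floor(upstream_dist / bin_width)]
  h <- dt[, .(weight = sum(total_tpm)), keyby = bin]
  h[, `:=`(bin_start = bin * bin_width, bin_end = (bin + 1) * bin_width)]
  h[, .(bin_start, bin_end, weight)]
}

#' Abundance-weighted inferred transcript length per library
#'
#' Restricts to sense, uniquely mapping tags that coincide with a
#' DpnII site of an NM transcript; each tag inherits the spliced
#' length of the transcript in which its site has the smallest rank
#' (ties broken by the longest transcript). The per-library weighted
#' mean length `sum(TPM_i * L_i)/sum(TPM_i)` is standardized against
#' the robust location (MEL) and scale (MAD) of the reference set of
#' all NM transcript lengths, so 0 means "typical transcript length"
#' and the unit is one MAD. Libraries with no qualifying tag get NA
#' (flagged, not zero).
#'
#' @param atlas a `tag_atlas`.
#' @param annotation output of [classify_tags()].
#' @param tsites transcript tag sites from [locate_transcript_sites()].
#' @param models a [gene_model_set()].
#' @param params a [robust_params()].
#' @return data.table per library: `weighted_mean_length`,
#'   `standardized`, `n_tags`, plus attributes `mel_ref`, `mad_ref`.
#' @export
weighted_transcript_length <- function(atlas, annotation, tsites, models,
                                       params = robust_params()) {
  nm_len <- models$transcripts[class == "NM", spliced_length]
  if (!length(nm_len))
    stop_fmt("weighted_transcript_length(): no NM transcripts in the models")
  mel_ref <- mel(nm_len, params)
  mad_ref <- mad_scale(nm_len, params)
  ## tag -> NM transcript length via its best-ranked NM site
  nm_sites <- tsites[class == "NM" & genome_mappable == TRUE]
  nm_sites <- models$transcripts[, .(transcript_id, spliced_length)][
    nm_sites, on = "transcript_id"]
  setorder(nm_sites, tag, rank_from_3prime, -spliced_length)
  tag_len <- nm_sites[, .SD[1L], by = tag][, .(tag, len = spliced_length)]
  sense <- unique(annotation[orientation == "sense", .(tag)])
  tag_len <- tag_len[sense, on = "tag", nomatch = NULL]
  dt <- atlas$tpm[tag_len, on = "tag", nomatch = NULL]
  res <- dt[tpm > 0, .(weighted_mean_length = sum(tpm * len) / sum(tpm),
                       n_tags = uniqueN(tag)), by = library_id]
  res <- res[atlas$libraries[, .(library_id)], on = "library_id"]
  res[is.na(n_tags), n_tags := 0L]
  res[, standardized := if (mad_ref > 0)
    (weighted_mean_length - mel_ref) / mad_ref else NA_real_]
  setattr(res, "mel_ref", mel_ref)
  setattr(res, "mad_ref", mad_ref)
  res[]
}

#' Rank constitutively expressed genes by coefficient of variation
#'
#' Takes a locus x library matrix of per-locus sense TPM sums, keeps
#' only loci with positive sums in every library (constitutive
#' expression), and orders them by ascending coefficient of variation
#' `cv = sd/mean` (sample sd, ties broken by locus id) — the lowest-CV
#' loci are the best housekeeping candidates.
#'
#' @param locus_tpm numeric matrix, rows = loci (rownames), columns =
#'   libraries.
#' @return data.table `locus_id`, per-library columns, `mean_tpm`,
#'   `sd_tpm`, `cv`, ordered by ascending `cv`.
#' @export
constitutive_genes <- function(locus_tpm) {
  stopifnot(is.matrix(locus_tpm), !is.null(rownames(locus_tpm)))
  keep <- rowSums(locus_tpm > 0) == ncol(locus_tpm)
  m <- locus_tpm[keep, , drop = FALSE]
  if (!nrow(m))
    return(data.table(locus_id = character(0), mean_tpm = numeric(0),
                      sd_tpm = numeric(0), cv = numeric(0)))
  dt <- data.table(locus_id = rownames(m),
                   mean_tpm = rowMeans(m),
                   sd_tpm = apply(m, 1L, sd))
  dt[, cv := sd_tpm / mean_tpm]
  setorder(dt, cv, locus_id)
  dt[]
}

#' Per-locus sense TPM matrix of an atlas
#'
#' Helper building the input of [constitutive_genes()]: sums TPM of
#' sense within-locus tags per locus and library, optionally
#' restricted to loci carrying curated (NM/NR) transcripts.
#'
#' @param atlas a `tag_atlas`.
#' @param annotation output of [classify_tags()].
#' @param curated_only keep only loci with an NM or NR transcript.
#' @return numeric matrix loci x libraries.
#' @export
locus_sense_tpm <- function(atlas, annotation, curated_only = TRUE) {
  dt <- .pair_tpm(atlas, annotation)[orientation == "sense"]
  if (curated_only) dt <- dt[grepl("NM|NR", locus_classes)]
  libs <- atlas$libraries$library_id
  agg <- dt[, .(sense_tpm = sum(tpm)), by = .(locus_id, library_id)]
  loci <- sort(unique(agg$locus_id))
  m <- matrix(0, length(loci), length(libs), dimnames = list(loci, libs))
  if (nrow(agg))
    m[cbind(match(agg$locus_id, loci), match(agg$library_id, libs))] <- agg$sense_tpm
  m
}

#' Constitutive tags per mapping class
#'
#' Lists tags with positive TPM in every library of the atlas,
#' partitioned by a class label (e.g. within-locus / intergenic /
#' non-mapping / single-mismatch-rescued / EST-matched), with
#' per-class counts and TPM totals.
#'
#' @param atlas a `tag_atlas`.
#' @param classes data.table `tag`, `class` labelling (a superset of)
#'   the atlas tags.
#' @return list with `tags` (data.table `tag`, `class`, `total_tpm`)
#'   and `summary` (per-class `n`, `total_tpm`).
#' @export
constitutive_tags <- function(atlas, classes) {
  n_lib <- nrow(atlas$libraries)
  const <- atlas$tags[n_libraries_present == n_lib]
  dt <- as.data.table(classes)[const[, .(tag, total_tpm)], on = "tag"]
  dt[is.na(class), class := "unclassified"]
  list(tags = dt[order(tag)],
       summary = dt[, .(n = .N, total_tpm = sum(total_tpm)), keyby = class])
}

#' Observed 3'-site usage shares
#'
#' Measures how observed sense abundance splits between the 3'-most
#' (rank 1) and next-to-3'-most (rank 2) DpnII sites. To keep the
#' estimate unbiased, only loci whose rank-1 and rank-2 tags are both
#' uniquely mapping (hence observable in the annotation) contribute;
#' confounded (overlapping-locus) tags are excluded.
#'
#' @param atlas a `tag_atlas`.
#' @param annotation output of [classify_tags()] over the index.
#' @param tsites transcript tag sites from [locate_transcript_sites()].
#' @return list: `primary_share`, `secondary_share` (of rank-1 +
#'   rank-2 abundance), `n_loci` used.
#' @export
site_usage_shares <- function(atlas, annotation, tsites) {
  ranked <- unique(tsites[genome_mappable == TRUE, .(locus_id, tag, rank_from_3prime)])
  ranked <- ranked[, .(rank = min(rank_from_3prime)), by = .(locus_id, tag)]
  sense <- annotation[orientation == "sense" & confound == FALSE, .(tag, locus_id)]
  rk <- ranked[sense, on = c("locus_id", "tag"), nomatch = NULL]
  ok <- rk[rank <= 2L, uniqueN(rank), by = locus_id][V1 == 2L, locus_id]
  x <- rk[locus_id %chin% ok & rank <= 2L]
  tp <- atlas$tpm[, .(tpm = sum(tpm)), by = tag]
  x <- tp[x, on = "tag", nomatch = NULL]
  tot <- sum(x$tpm)
  list(primary_share = if (tot > 0) sum(x$tpm[x$rank == 1L]) / tot else NA_real_,
       secondary_share = if (tot > 0) sum(x$tpm[x$rank == 2L]) / tot else NA_real_,
       n_loci = length(ok))
}

#' Antisense share of within-locus abundance
#'
#' Antisense TPM over sense + antisense TPM of within-locus
#' (tag, locus) pairs, by default excluding tags confounded by
#' antiparallel overlapping loci (which are sense and antisense at
#' once).
#'
#' @param atlas a `tag_atlas`.
#' @param annotation output of [classify_tags()].
#' @param exclude_confound drop confounded pairs (default TRUE).
#' @param scope `"all"` loci, `"nuclear"` only, or `"mito"` only.
#' @param multi_assign optional [assign_multi_single_locus()] table;
#'   restores the abundance of multi-mapping tags attributable to a
#'   single locus (e.g. 3'-terminal tags duplicated intergenically),
#'   which otherwise skews the sense/antisense balance of those loci.
#' @return the abundance share (scalar in [0, 1]).
#' @export
antisense_share <- function(atlas, annotation, exclude_confound = TRUE,
                            scope = c("all", "nuclear", "mito"),
                            multi_assign = NULL) {
  scope <- match.arg(scope)
  ann <- annotation[!is.na(locus_id), .(tag, locus_id, orientation, confound, mito)]
  if (!is.null(multi_assign) && nrow(multi_assign)) {
    extra <- multi_assign[, .(tag, locus_id, orientation, confound = FALSE, mito)]
    ann <- unique(rbind(ann, extra))
  }
  if (exclude_confound) ann <- ann[confound == FALSE]
  if (scope == "mito") ann <- ann[mito == TRUE]
  if (scope == "nuclear") ann <- ann[mito == FALSE]
  dt <- atlas$tpm[ann, on = "tag", nomatch = NULL, allow.cartesian = TRUE]
  tot <- dt[, sum(tpm)]
  if (tot == 0) return(NA_real_)
  dt[orientation == "antisense", sum(tpm)] / tot
}
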