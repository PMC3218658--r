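## The significance filter and the named tag subsets of the mapping /
## filtering cascade, with unique-sequence counts and TPM totals.

#' Significance filter parameters
#'
#' A tag passes when its abundance reaches `min_tpm` in at least one
#' library **or** it is present (TPM > 0) in at least `min_libraries`
#' libraries. Defaults are the classic 2 TPM / ten tissue constraint.
#'
#' @param min_tpm positive TPM threshold (default 2).
#' @param min_libraries minimum number of libraries for the presence
#'   clause (default 10).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(min_tpm = 2, min_libraries = 10L) {
  stopifnot(is.numeric(min_tpm), min_tpm > 0, is_count(min_libraries),
            min_libraries >= 1)
  structure(list(min_tpm = min_tpm, min_libraries = as.integer(min_libraries)),
            class = "filter_params")
}

#' Apply the significance filter to an atlas
#'
#' @param atlas a `tag_atlas` (normalized per library).
#' @param params a [filter_params()].
#' @return character vector of passing tag sequences (the filtered
#'   set), with attribute `clauses` giving per-clause counts.
#' @export
significance_filter <- function(atlas, params = filter_params()) {
  t <- atlas$tags
  by_tpm <- t$max_tpm >= params$min_tpm
  by_presence <- t$n_libraries_present >= params$min_libraries
  keep <- t$tag[by_tpm | by_presence]
  attr(keep, "clauses") <- c(by_tpm = sum(by_tpm), by_presence = sum(by_presence),
                             both = sum(by_tpm & by_presence))
  keep
}

CASCADE_SETS <- c("Os", "Os-G", "Os-F", "Os-fG", "Os-fgU", "Os-fgu-PC",
                  "Os-fNG", "Os-fng-SMM", "Os-fng-EST")

#' Build the tag mapping/filtering cascade report
#'
#' Computes every named subset of the observed tag universe with its
#' unique-sequence count and total TPM: `Os` (all completely defined
#' observed tags), `Os-G` (mapping to the genome), `Os-F`
#' (significance-filtered), `Os-fG` (filtered and mapping), `Os-fgU`
#' (filtered, uniquely mapping), `Os-fgu-PC` (uniquely mapping within
#' protein-coding loci), `Os-fNG` (filtered, non-mapping),
#' `Os-fng-SMM` (non-mapping but rescued by a single mismatch at tag
#' positions 5-20) and `Os-fng-EST` (non-mapping but perfectly
#' matching an EST). The set identities `Os-F = Os-fG (+) Os-fNG`
#' (disjoint union), `Os-fgU <= Os-fG <= Os-G` and
#' `Os-fgu-PC <= Os-fgU` hold by construction; SMM and EST are
#' non-exclusive overlays on `Os-fNG`.
#'
#' @param atlas a `tag_atlas`.
#' @param mapping per-tag mapping status from [map_atlas()]; its tag
#'   universe must cover the atlas.
#' @param annotation output of [classify_tags()] (needed for
#'   `Os-fgu-PC`; optional).
#' @param rescue output of [rescue_single_mismatch()] on the `Os-fNG`
#'   tags (optional).
#' @param est_matches output of [match_ests()] on the `Os-fNG` tags
#'   (optional).
#' @param params a [filter_params()].
#' @param models a [gene_model_set()] (needed for `Os-fgu-PC`).
#' @return A `filter_report` data.table: `set`, `n_unique`,
#'   `total_tpm`.
#' @export
build_cascade <- function(atlas, mapping, annotation = NULL, rescue = NULL,
                          est_matches = NULL, params = filter_params(),
                          models = NULL) {
  missing_tags <- setdiff(atlas$tags$tag, mapping$tag)
  if (length(missing_tags))
    stop_fmt("build_cascade(): mapping lacks %d atlas tag(s) (e.g. %s)",
             length(missing_tags), missing_tags[1L])
  tg <- mapping[atlas$tags, on = "tag"]
  os <- tg$tag
  os_g <- tg[status != "unmapped", tag]
  os_f <- significance_filter(atlas, params)
  os_fg <- intersect(os_f, os_g)
  os_fgu <- intersect(os_f, tg[status == "unique", tag])
  os_fng <- setdiff(os_f, os_g)
  os_fgu_pc <- character(0)
  if (!is.null(annotation) && !is.null(models)) {
    pc_loci <- models$loci[protein_coding == TRUE, locus_id]
    pc_tags <- unique(annotation[locus_id %chin% pc_loci, tag])
    os_fgu_pc <- intersect(os_fgu, pc_tags)
  }
  smm <- if (!is.null(rescue)) intersect(os_fng, rescue$rescued) else character(0)
  est <- if (!is.null(est_matches)) intersect(os_fng, unique(est_matches$tag)) else character(0)
  sets <- list("Os" = os, "Os-G" = os_g, "Os-F" = os_f, "Os-fG" = os_fg,
               "Os-fgU" = os_fgu, "Os-fgu-PC" = os_fgu_pc, "Os-fNG" = os_fng,
               "Os-fng-SMM" = smm, "Os-fng-EST" = est)
  tot <- setNames(tg$total_tpm, tg$tag)
  report <- rbindlist(lapply(names(sets), function(nm)
    data.table(set = nm, n_unique = length(sets[[nm]]),
               total_tpm = sum(tot[sets[[nm]]]))))
  setattr(report, "sets", sets)
  setattr(report, "class", c("filter_report", class(report)))
  report
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  print(as.data.table(x))
  invisible(x)
}

#' Run the whole cascade over a simulated or ingested dataset
#'
#' Orchestrates [map_atlas()], [classify_tags()],
#' [rescue_single_mismatch()] and [match_ests()] and feeds
#' [build_cascade()].
#'
#' @inheritParams build_cascade
#' @param index a [build_index()] object.
#' @param tsites transcript tag sites from [locate_transcript_sites()].
#' @param ests optional EST set for the EST overlay.
#' @return list with `report`, `mapping`, `annotation`, `rescue`,
#'   `est_matches`.
#' @export
run_cascade <- function(atlas, index, models, tsites, ests = NULL,
                        params = filter_params()) {
  mapping <- map_atlas(atlas, index)
  annotation <- classify_tags(index, models, tsites)
  os_f <- significance_filter(atlas, params)
  os_fng <- intersect(os_f, mapping[status == "unmapped", tag])
  ## only GATC-anchored tags are candidates for positional mismatch rescue
  rescue <- rescue_single_mismatch(os_fng[startsWith(os_fng, DPNII_SITE)], index)
  est_matches <- if (!is.null(ests)) match_ests(os_fng, ests) else NULL
  report <- build_cascade(atlas, mapping, annotation, rescue, est_matches,
                          params, models)
  list(report = report, mapping = mapping, annotation = annotation,
       rescue = rescue, est_matches = est_matches)
}

#' Write a filter report as TSV or JSON
#'
#' @param report a `filter_report`.
#' @param path output path; format chosen by extension (.json or .tsv).
#' @export
write_filter_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    x <- setNames(lapply(seq_len(nrow(report)), function(i)
      list(n_unique = report$n_unique[i], total_tpm = report$total_tpm[i])),
      report$set)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else fwrite(as.data.table(report), path, sep = "\t")
  invisible(path)
}
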