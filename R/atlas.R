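## Atlas container: unique tags x libraries, long-format TPM with
## per-tag derived summaries.

#' Build a tag atlas from a set of libraries
#'
#' Stacks normalized [tag_library()] objects into one long-format table
#' (`tag`, `library_id`, `raw`, `tpm`) plus per-tag derived fields:
#' number of libraries in which the tag is present (TPM > 0), maximum
#' TPM over libraries, and total TPM.
#'
#' @param libraries list of [tag_library()] objects (unique library ids).
#' @return A `tag_atlas`: list with `tpm` (long data.table), `tags`
#'   (per-tag summary), `libraries` (metadata data.table).
#' @export
build_atlas <- function(libraries) {
  if (length(libraries) == 0L) {
    return(structure(list(
      tpm = data.table(tag = character(0), library_id = character(0),
                       raw = integer(0), tpm = numeric(0)),
      tags = data.table(tag = character(0), n_libraries_present = integer(0),
                        max_tpm = numeric(0), total_tpm = numeric(0)),
      libraries = data.table(library_id = character(0))
    ), class = "tag_atlas"))
  }
  ids <- vapply(libraries, function(l) attr(l, "library_id"), character(1))
  if (anyDuplicated(ids)) stop_fmt("build_atlas(): duplicated library ids")
  long <- rbindlist(lapply(libraries, function(l) {
    data.table(tag = l$tag, library_id = attr(l, "library_id"),
               raw = l$raw, tpm = l$tpm)
  }))
  setkey(long, tag, library_id)
  tags <- long[, .(n_libraries_present = sum(tpm > 0),
                   max_tpm = max(tpm), total_tpm = sum(tpm)), by = tag]
  setkey(tags, tag)
  meta <- rbindlist(lapply(libraries, function(l) {
    md <- attr(l, "metadata")
    data.table(library_id = attr(l, "library_id"),
               tissue = if (!is.null(md$tissue)) md$tissue else NA_character_,
               class_path = if (!is.null(md$class_path)) md$class_path else NA_character_,
               stage = if (!is.null(md$stage)) md$stage else NA_character_,
               sex = if (!is.null(md$sex)) md$sex else NA_character_)
  }))
  structure(list(tpm = long, tags = tags, libraries = meta),
            class = "tag_atlas")
}

#' @export
print.tag_atlas <- function(x, ...) {
  cat(sprintf("<tag_atlas> %d unique tags x %d libraries, %.0f total TPM\n",
              nrow(x$tags), nrow(x$libraries), sum(x$tpm$tpm)))
  invisible(x)
}

#' Subset an atlas to a set of tags
#'
#' @param atlas a `tag_atlas`.
#' @param tags character vector of tag sequences to keep.
#' @return A `tag_atlas` restricted to `tags`.
#' @export
subset_atlas <- function(atlas, tags) {
  structure(list(tpm = atlas$tpm[tag %chin% tags],
                 tags = atlas$tags[tag %chin% tags],
                 libraries = atlas$libraries),
            class = "tag_atlas")
}

#' Tag x library TPM matrix
#'
#' Dense TPM matrix (rows = tags, columns = libraries) of an atlas,
#' mainly for clustering and per-tag arithmetic at desk scale.
#'
#' @param atlas a `tag_atlas`.
#' @return numeric matrix with dimnames.
#' @export
atlas_matrix <- function(atlas) {
  tags <- atlas$tags$tag
  libs <- atlas$libraries$library_id
  m <- matrix(0, nrow = length(tags), ncol = length(libs),
              dimnames = list(tags, libs))
  if (nrow(atlas$tpm))
    m[cbind(match(atlas$tpm$tag, tags), match(atlas$tpm$library_id, libs))] <-
      atlas$tpm$tpm
  m
}
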