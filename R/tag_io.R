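## Tag ingestion: aggregate raw reads, remove artifact tags, normalize to TPM.

#' Construct a tag library object
#'
#' A `tag_library` is a per-library table of unique tag sequences with
#' raw counts and TPM, plus library metadata (tissue name, ontology
#' class path, stage, sex).
#'
#' @param table a data.frame/data.table with columns `tag`, `raw` and
#'   optionally `tpm`.
#' @param library_id library identifier.
#' @param metadata named list of metadata fields.
#' @return A `tag_library` (a data.table with attributes).
#' @export
tag_library <- function(table, library_id = "lib1", metadata = list()) {
  dt <- as.data.table(table)
  stopifnot(all(c("tag", "raw") %in% names(dt)))
  if (anyDuplicated(dt$tag)) stop_fmt("tag_library(): duplicated tag sequences")
  if (nrow(dt) && any(dt$raw < 1)) stop_fmt("tag_library(): raw counts must be >= 1")
  setkey(dt, tag)
  setattr(dt, "library_id", library_id)
  setattr(dt, "metadata", metadata)
  setattr(dt, "class", c("tag_library", class(dt)))
  dt
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("<tag_library> %s: %d unique tags, %s raw tags, %.1f TPM total\n",
              attr(x, "library_id"), nrow(x), format(sum(x$raw), big.mark = ","),
              if ("tpm" %in% names(x)) sum(x$tpm) else NA_real_))
  invisible(x)
}

#' Aggregate raw reads into a unique-tag count table
#'
#' Collapses identical read sequences into one row per distinct
#' sequence with its occurrence count. Counts are conserved: the column
#' sum equals the number of input reads.
#'
#' @param reads character vector of read sequences over \{A,C,G,T,N\}.
#' @return data.table with columns `tag`, `raw`, keyed by `tag`.
#' @export
aggregate_raw_tags <- function(reads) {
  if (length(reads) == 0L)
    return(data.table(tag = character(0), raw = integer(0), key = "tag"))
  bad <- which(!nzchar(reads))
  if (length(bad))
    stop_fmt("aggregate_raw_tags(): zero-length read at record %d", bad[1L])
  dt <- data.table(tag = reads)[, .(raw = .N), by = tag]
  setkey(dt, tag)
  dt[]
}

#' Remove artifact tags from a raw tag table
#'
#' Drops tags that (in this order of accounting) are not exactly
#' `TAG_LENGTH` bases long, contain an indeterminate base (N), or
#' contain the adapter sequence as a substring. Adapter matching is
#' substring containment because the 16-base adapter is shorter than
#' the 20-base tag. The filter is total (never errors) and idempotent.
#'
#' @param raw_table data.table with columns `tag`, `raw`
#'   (from [aggregate_raw_tags()]).
#' @param adapter non-empty DNA string; default [DGE_ADAPTER].
#' @return list with `table` (clean data.table) and `report`, an
#'   `artifact_report` list whose removed/kept raw totals reconcile
#'   with the input total.
#' @export
filter_artifacts <- function(raw_table, adapter = DGE_ADAPTER) {
  stopifnot(is.character(adapter), length(adapter) == 1L, nzchar(adapter))
  dt <- as.data.table(raw_table)
  badlen <- nchar(dt$tag) != TAG_LENGTH
  hasn <- !badlen & grepl("N", dt$tag, fixed = TRUE)
  isad <- !badlen & !hasn & grepl(adapter, dt$tag, fixed = TRUE)
  clean <- dt[!(badlen | hasn | isad)]
  setkey(clean, tag)
  report <- structure(list(
    n_badlen_tags     = sum(badlen),
    badlen_raw_count  = sum(dt$raw[badlen]),
    n_n_tags          = sum(hasn),
    n_raw_count       = sum(dt$raw[hasn]),
    n_adapter_tags    = sum(isad),
    adapter_raw_count = sum(dt$raw[isad]),
    n_raw_total       = sum(dt$raw),
    n_clean_total     = sum(clean$raw)
  ), class = "artifact_report")
  list(table = clean[], report = report)
}

#' @export
print.artifact_report <- function(x, ...) {
  cat(sprintf(paste0("<artifact_report> raw %d -> clean %d ",
                     "(adapter: %d tags/%d raw; N: %d tags/%d raw; bad length: %d tags/%d raw)\n"),
              x$n_raw_total, x$n_clean_total, x$n_adapter_tags, x$adapter_raw_count,
              x$n_n_tags, x$n_raw_count, x$n_badlen_tags, x$badlen_raw_count))
  invisible(x)
}

#' Normalize a clean tag table to tags per million (TPM)
#'
#' `tpm_i = raw_i * 1e6 / sum(raw)`, rounded to `digits` decimal
#' places. Each library then sums to 1e6 TPM within the rounding
#' tolerance implied by the storage precision.
#'
#' @param clean_table data.table with columns `tag`, `raw`.
#' @param digits decimal places at which TPM values are stored
#'   (default 4).
#' @inheritParams tag_library
#' @return A [tag_library()].
#' @export
normalize_tpm <- function(clean_table, library_id = "lib1", metadata = list(),
                          digits = 4L) {
  dt <- as.data.table(clean_table)
  total <- sum(dt$raw)
  if (!nrow(dt) || total <= 0)
    stop_fmt("normalize_tpm(): empty clean table, nothing to normalize")
  dt <- copy(dt)
  dt[, tpm := round(raw * 1e6 / total, digits)]
  lib <- tag_library(dt, library_id = library_id, metadata = metadata)
  setattr(lib, "tpm_digits", as.integer(digits))
  lib
}

#' Ingest raw reads into a normalized tag library
#'
#' Convenience pipeline: [aggregate_raw_tags()] then
#' [filter_artifacts()] then [normalize_tpm()].
#'
#' @inheritParams aggregate_raw_tags
#' @inheritParams filter_artifacts
#' @inheritParams normalize_tpm
#' @return list with `library` (a [tag_library()]) and `report`.
#' @export
ingest_reads <- function(reads, library_id = "lib1", metadata = list(),
                         adapter = DGE_ADAPTER, digits = 4L) {
  flt <- filter_artifacts(aggregate_raw_tags(reads), adapter = adapter)
  list(library = normalize_tpm(flt$table, library_id = library_id,
                               metadata = metadata, digits = digits),
       report = flt$report)
}

#' Read raw reads from FASTQ or a two-column tag table
#'
#' @param path FASTQ file (qualities ignored) for `read_fastq_reads()`,
#'   or a headered TSV with columns `tag`, `raw` for
#'   `read_tag_counts()`.
#' @return character vector of reads, or a tag count data.table.
#' @export
read_fastq_reads <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' @rdname read_fastq_reads
#' @export
read_tag_counts <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "tag"))
  stopifnot(all(c("tag", "raw") %in% names(dt)))
  setkey(dt, tag)
  dt[]
}

#' Write / read a tag library as three-column TSV
#'
#' The on-disk format is the classic tag library file: unique sequence,
#' raw tag count, normalized count in TPM. A write/read round trip
#' reproduces the table exactly.
#'
#' @param lib a [tag_library()].
#' @param path output file.
#' @export
write_tag_library <- function(lib, path) {
  fwrite(as.data.table(lib)[, .(tag, raw, tpm)], path, sep = "\t")
  invisible(path)
}

#' @rdname write_tag_library
#' @param library_id,metadata metadata to attach on read.
#' @export
read_tag_library <- function(path, library_id = basename(path), metadata = list()) {
  dt <- fread(path, sep = "\t", colClasses = list(character = "tag"))
  tag_library(dt, library_id = library_id, metadata = metadata)
}

#' Write reads as FASTQ (dummy qualities)
#'
#' @param reads character vector of reads.
#' @param path output FASTQ path.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("read%06d", seq_along(reads))
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}
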