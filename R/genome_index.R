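## Virtual-tag genome index: every possible DpnII 20-mer on both strands.

#' Enumerate all virtual DpnII tags in a genome
#'
#' Scans every contig for GATC occurrences and emits, for each, the
#' 20-base tag on each strand where it fits: on the plus strand the tag
#' is the GATC plus the following 16 bases (requires
#' `gatc_start + 20 <= contig length`); on the minus strand it is the
#' reverse complement of the window `[gatc_start - 16, gatc_start + 4)`
#' (requires `gatc_start >= 16`). Because GATC is its own reverse
#' complement, every internal occurrence yields exactly one site per
#' strand. Windows containing N are skipped: only fully defined 20-mers
#' can match observed tags. Coordinates are 0-based.
#'
#' @param genome named character vector or `DNAStringSet` of contig
#'   sequences over \{A,C,G,T,N\}.
#' @return data.table of genome tag sites: `tag`, `contig`,
#'   `gatc_start` (0-based plus-strand coordinate of the GATC),
#'   `strand`.
#' @export
enumerate_virtual_tags <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    gen <- as.character(genome)
  } else gen <- genome
  stopifnot(is.character(gen), !is.null(names(gen)))
  out <- vector("list", 2L * length(gen))
  k <- 0L
  for (ctg in names(gen)) {
    seq <- gen[[ctg]]
    len <- nchar(seq)
    pos <- gatc_starts0(seq)
    plus <- pos[pos + TAG_LENGTH <= len]
    if (length(plus)) {
      tags <- substr0(seq, plus, plus + TAG_LENGTH)
      ok <- !grepl("N", tags, fixed = TRUE)
      k <- k + 1L
      out[[k]] <- data.table(tag = tags[ok], contig = ctg,
                             gatc_start = plus[ok], strand = "+")
    }
    minus <- pos[pos >= TAG_LENGTH - 4L]
    if (length(minus)) {
      win <- substr0(seq, minus - 16L, minus + 4L)
      ok <- !grepl("N", win, fixed = TRUE)
      if (any(ok)) {
        k <- k + 1L
        out[[k]] <- data.table(tag = revcomp(win[ok]), contig = ctg,
                               gatc_start = minus[ok], strand = "-")
      }
    }
  }
  sites <- rbindlist(out[seq_len(k)])
  if (!nrow(sites))
    sites <- data.table(tag = character(0), contig = character(0),
                        gatc_start = integer(0), strand = character(0))
  setkey(sites, tag)
  sites[]
}

#' Build a tag index from genome tag sites
#'
#' Groups sites by tag sequence and assigns each tag a multiplicity
#' class: `unique` (one genomic site) or `multi` (several).
#'
#' @param sites data.table from [enumerate_virtual_tags()].
#' @return A `tag_index`: list with `sites` (all sites, keyed by tag)
#'   and `tags` (per-tag `n_sites` and `class`).
#' @export
build_index <- function(sites) {
  sites <- as.data.table(sites)
  setkey(sites, tag)
  tags <- sites[, .(n_sites = .N), by = tag]
  tags[, class := ifelse(n_sites == 1L, "unique", "multi")]
  setkey(tags, tag)
  structure(list(sites = sites[], tags = tags[]), class = "tag_index")
}

#' @export
print.tag_index <- function(x, ...) {
  cat(sprintf("<tag_index> %d virtual tag sites, %d distinct tags (%d unique / %d multi)\n",
              nrow(x$sites), nrow(x$tags), sum(x$tags$class == "unique"),
              sum(x$tags$class == "multi")))
  invisible(x)
}

#' Map a tag library against a tag index
#'
#' Partitions the library's tags into mapped-unique, mapped-multi and
#' unmapped sets; the three sets partition the library and their TPM
#' totals sum to the library total.
#'
#' @param lib a normalized [tag_library()].
#' @param index a [build_index()] object.
#' @return A `mapping_partition`: the library table with added `status`
#'   (`unique`/`multi`/`unmapped`) and `n_sites` columns, plus a
#'   `totals` attribute of per-status TPM sums.
#' @export
map_library <- function(lib, index) {
  dt <- as.data.table(lib)[, .(tag, raw, tpm)]
  dt <- index$tags[dt, on = "tag"]
  dt[, status := fifelse(is.na(n_sites), "unmapped",
                         fifelse(n_sites == 1L, "unique", "multi"))]
  dt[is.na(n_sites), n_sites := 0L]
  dt[, class := NULL]
  setkey(dt, tag)
  totals <- dt[, .(tpm = sum(tpm), n = .N), by = status]
  setattr(dt, "totals", totals)
  setattr(dt, "library_id", attr(lib, "library_id"))
  setattr(dt, "class", c("mapping_partition", class(dt)))
  dt
}

#' Per-tag mapping status of a whole atlas
#'
#' @param atlas a `tag_atlas`.
#' @param index a [build_index()] object.
#' @return data.table `tag`, `status`, `n_sites` over the atlas tag
#'   universe.
#' @export
map_atlas <- function(atlas, index) {
  dt <- index$tags[atlas$tags[, .(tag)], on = "tag"]
  dt[, status := fifelse(is.na(n_sites), "unmapped",
                         fifelse(n_sites == 1L, "unique", "multi"))]
  dt[is.na(n_sites), n_sites := 0L]
  dt[, class := NULL]
  setkey(dt, tag)
  dt[]
}

## all 48 single-substitution neighbors at 1-based positions 5..20
mismatch_neighbors <- function(tag) {
  out <- character(48L)
  k <- 0L
  for (p in 5:20) {
    cur <- substr(tag, p, p)
    for (b in DNA_BASES[DNA_BASES != cur]) {
      k <- k + 1L
      x <- tag
      substr(x, p, p) <- b
      out[k] <- x
    }
  }
  out[seq_len(k)]
}

#' Rescue non-mapping tags by a single mismatch at positions 5-20
#'
#' A tag is rescued iff substituting exactly one base at 1-based tag
#' positions 5 to 20 (the GATC anchor occupies positions 1-4) yields a
#' tag present in the index; this is realized by enumerating all
#' 16 x 3 = 48 substitution neighbors per tag. Tags that already map
#' are rejected as a contract violation (they must be partitioned out
#' upstream).
#'
#' @param tags character vector of unmapped tag sequences beginning
#'   GATC.
#' @param index a [build_index()] object.
#' @return list with `rescued` (character vector) and `matches`
#'   (data.table `tag`, `neighbor`, `contig`, `gatc_start`, `strand` of
#'   every matched site).
#' @export
rescue_single_mismatch <- function(tags, index) {
  if (length(tags) == 0L)
    return(list(rescued = character(0),
                matches = data.table(tag = character(0), neighbor = character(0),
                                     contig = character(0), gatc_start = integer(0),
                                     strand = character(0))))
  if (!all(substr(tags, 1L, 4L) == DPNII_SITE))
    stop_fmt("rescue_single_mismatch(): tags must begin %s", DPNII_SITE)
  already <- tags[tags %chin% index$tags$tag]
  if (length(already))
    stop_fmt("rescue_single_mismatch(): %d tag(s) already map (e.g. %s); pass only unmapped tags",
             length(already), already[1L])
  nb <- data.table(tag = rep(tags, each = 48L),
                   neighbor = unlist(lapply(tags, mismatch_neighbors)))
  hits <- index$sites[nb, on = c(tag = "neighbor"), nomatch = NULL,
                      .(tag = i.tag, neighbor = x.tag, contig, gatc_start, strand)]
  setkey(hits, tag)
  list(rescued = unique(hits$tag), matches = hits[])
}

#' Match non-mapping tags against an EST set
#'
#' A tag matches iff it occurs as an exact substring of an EST or of
#' its reverse complement. Since every tag begins GATC, candidate
#' windows are the GATC-anchored 20-mers of each EST on both strands.
#'
#' @param tags character vector of tag sequences.
#' @param ests named character vector or `DNAStringSet` of EST
#'   sequences over \{A,C,G,T,N\}.
#' @return data.table `tag`, `est`, `strand` of matches (one row per
#'   matched EST/strand).
#' @export
match_ests <- function(tags, ests) {
  empty <- data.table(tag = character(0), est = character(0),
                      strand = character(0))
  if (methods::is(ests, "DNAStringSet")) ests <- as.character(ests)
  if (length(ests) == 0L || length(tags) == 0L) return(empty)
  stopifnot(is.character(ests), !is.null(names(ests)))
  out <- vector("list", 2L * length(ests))
  k <- 0L
  for (id in names(ests)) {
    for (str in c("+", "-")) {
      seq <- if (str == "+") ests[[id]] else revcomp(ests[[id]])
      pos <- gatc_starts0(seq)
      pos <- pos[pos + TAG_LENGTH <= nchar(seq)]
      if (!length(pos)) next
      win <- unique(substr0(seq, pos, pos + TAG_LENGTH))
      hit <- win[win %chin% tags]
      if (length(hit)) {
        k <- k + 1L
        out[[k]] <- data.table(tag = hit, est = id, strand = str)
      }
    }
  }
  if (k == 0L) return(empty)
  res <- rbindlist(out[seq_len(k)])
  setkey(res, tag)
  res[]
}

#' Serialize / load a tag index as sorted TSV
#'
#' Columns: tag, contig, start (1-based), strand.
#'
#' @param index a [build_index()] object.
#' @param path file path.
#' @export
write_index <- function(index, path) {
  out <- index$sites[, .(tag, contig, start = gatc_start + 1L, strand)]
  setorder(out, tag, contig, start, strand)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = list(character = c("tag", "contig", "strand")))
  build_index(dt[, .(tag, contig, gatc_start = start - 1L, strand)])
}
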