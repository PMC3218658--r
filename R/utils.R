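## Shared constants and small sequence helpers.

#' Tag geometry and adapter constants
#'
#' Every analysis tag is a 20-base sequence beginning with the DpnII
#' recognition site GATC (4 anchor bases + 16 transcript-derived bases).
#' `DGE_ADAPTER` is the library-construction adapter whose carry-through
#' reads are removed during ingestion.
#' @format Character/integer scalars.
#' @name tag-constants
NULL

#' @rdname tag-constants
#' @export
TAG_LENGTH <- 20L

#' @rdname tag-constants
#' @export
DPNII_SITE <- "GATC"

#' @rdname tag-constants
#' @export
DGE_ADAPTER <- "GTCGGACTGTAGAACT"

DNA_BASES <- c("A", "C", "G", "T")

## reverse complement of a character vector of DNA strings
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## uniform random DNA string(s)
random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

## evaluate `expr` under a fixed seed when `seed` is non-NULL, leaving the
## caller's RNG state untouched; otherwise use the ambient RNG stream
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

## 0-based GATC start positions within a DNA string
gatc_starts0 <- function(seq) {
  m <- gregexpr(DPNII_SITE, seq, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

## vectorized 0-based half-open substring
substr0 <- function(seq, from0, to0) {
  substring(seq, from0 + 1L, to0)
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == as.integer(x)

is_prob <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x <= 1
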