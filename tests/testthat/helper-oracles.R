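# Independent oracles used to cross-check the implementation.

# brute-force both-strand 20-mer scan: every window of the genome and
# of its reverse complement, kept iff it starts with GATC; a
# reverse-strand window at rc-coordinate s maps to the plus-strand
# GATC coordinate L - s - 4
brute_force_virtual_tags <- function(genome) {
  rows <- list()
  for (ctg in names(genome)) {
    seq <- genome[[ctg]]
    len <- nchar(seq)
    if (len < 20L) next
    starts <- 0:(len - 20L)
    win <- substring(seq, starts + 1L, starts + 20L)
    plus <- !grepl("N", win, fixed = TRUE) & startsWith(win, "GATC")
    rcseq <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]),
                   collapse = "")
    rwin <- substring(rcseq, starts + 1L, starts + 20L)
    minus <- !grepl("N", rwin, fixed = TRUE) & startsWith(rwin, "GATC")
    rows[[ctg]] <- rbind(
      if (any(plus)) data.frame(tag = win[plus], contig = ctg,
                                gatc_start = starts[plus], strand = "+"),
      if (any(minus)) data.frame(tag = rwin[minus], contig = ctg,
                                 gatc_start = len - starts[minus] - 4L,
                                 strand = "-"))
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tag = character(0), contig = character(0),
                      gatc_start = integer(0), strand = character(0))
  out[order(out$tag, out$contig, out$gatc_start, out$strand), , drop = FALSE]
}

# full Hamming scan: tag rescued iff some indexed tag differs from it
# at exactly one position and that position is in 5..20 (1-based)
brute_force_rescue <- function(tags, index_tags) {
  im <- do.call(rbind, strsplit(index_tags, ""))
  vapply(tags, function(tg) {
    tc <- strsplit(tg, "")[[1]]
    diffs <- im != matrix(tc, nrow(im), 20L, byrow = TRUE)
    nd <- rowSums(diffs)
    any(nd == 1L & apply(diffs, 1L, which.max) >= 5L)
  }, logical(1), USE.NAMES = FALSE)
}

# naive agglomerative complete linkage; returns sorted merge heights
brute_force_complete_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(groups) > 1L) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
      h <- max(d[groups[[i]], groups[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    groups[[bi]] <- c(groups[[bi]], groups[[bj]])
    groups[[bj]] <- NULL
  }
  sort(heights)
}

# literal transcription of the one-step Huber M-estimate and the MAD,
# written against the formulas rather than the package code
direct_mel <- function(x, bend = 1.28) {
  med <- sort(x)[ceiling(length(x) / 2)]
  if (length(x) %% 2 == 0) {
    s <- sort(x); med <- (s[length(x) / 2] + s[length(x) / 2 + 1]) / 2
  }
  madn <- direct_mad(x, 1.4826)
  if (madn == 0) return(med)
  u <- (x - med) / madn
  psi <- ifelse(u > bend, bend, ifelse(u < -bend, -bend, u))
  med + madn * sum(psi) / sum(abs(u) <= bend)
}

direct_mad <- function(x, constant = 1.4826) {
  s <- sort(x); n <- length(x)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  dev <- sort(abs(x - med))
  m2 <- if (n %% 2 == 1) dev[(n + 1) / 2] else (dev[n / 2] + dev[n / 2 + 1]) / 2
  constant * m2
}

adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  stop("mclust not available")
}
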