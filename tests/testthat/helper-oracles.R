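# Brute-force oracles, independent of the package's interval engine:
# base-painting for merges/venns and all-pairs scans for overlap flags.
# Coordinates here are 0-based half-open triples (chrom, start, end).

suppressPackageStartupMessages({
  library(GenomicRanges)
})

grFromDf <- function(df) {
  GRanges(df$chrom, IRanges(df$start + 1, df$end))
}

dfFromGr <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L, end = end(gr),
             stringsAsFactors = FALSE)
}

# paint covered bases on a boolean array, bridge gaps <= maxGap, extract runs
paintMerge <- function(df, maxGap = 0) {
  out <- lapply(split(df, df$chrom), function(d) {
    L <- max(d$end) + 1L
    covered <- logical(L)
    for (i in seq_len(nrow(d)))
      covered[(d$start[i] + 1):d$end[i]] <- TRUE
    if (maxGap > 0) {
      r <- rle(covered)
      pos <- cumsum(r$lengths)
      inner <- which(!r$values & r$lengths <= maxGap &
                       seq_along(r$values) > 1 &
                       seq_along(r$values) < length(r$values))
      for (i in inner) covered[(pos[i] - r$lengths[i] + 1):pos[i]] <- TRUE
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(chrom = d$chrom[1], start = starts[keep] - 1L,
               end = ends[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

overlaps1bp <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 & s1 < e2 & s2 < e1
}

# all-pairs membership of each locus (df rows) against a list of peak dfs
orMembership <- function(lociDf, setDfs) {
  m <- matrix(FALSE, nrow(lociDf), length(setDfs))
  for (j in seq_along(setDfs)) {
    s <- setDfs[[j]]
    for (i in seq_len(nrow(lociDf))) {
      m[i, j] <- any(overlaps1bp(lociDf$chrom[i], lociDf$start[i],
                                 lociDf$end[i], s$chrom, s$start, s$end))
    }
  }
  m
}

orVenn <- function(aDf, bDf, maxGap = 0) {
  loci <- paintMerge(rbind(aDf, bDf), maxGap)
  m <- orMembership(loci, list(aDf, bDf))
  c(a_only = sum(m[, 1] & !m[, 2]),
    shared = sum(m[, 1] & m[, 2]),
    b_only = sum(!m[, 1] & m[, 2]))
}

randIntervalDf <- function(n, chromLen = 1e4, chroms = "chr1",
                           maxWidth = 200) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- floor(runif(n, 0, chromLen - maxWidth))
  width <- pmax(1, floor(runif(n, 1, maxWidth)))
  data.frame(chrom = chrom, start = start, end = start + width,
             stringsAsFactors = FALSE)
}
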