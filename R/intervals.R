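## Interval geometry: merging, consensus construction, venn partitions and
## per-timepoint occupancy flags. Geometry is delegated to IRanges/
## GenomicRanges (reduce, overlapsAny); overlap everywhere means >= 1 bp.

#' Merge overlapping or nearby intervals
#'
#' Collapses a peak set so that no two output intervals lie within `maxGap`
#' bp of each other, preserving the union of covered bases. Book-ended
#' intervals (gap 0) are merged at the default `maxGap = 0`, matching common
#' merge-tool behavior and keeping consensus rows stable. Metadata columns
#' are dropped; unsorted input is sorted internally.
#'
#' @param peaks A [GenomicRanges::GRanges].
#' @param maxGap Non-negative gap (bp) across which intervals are still
#'   merged. Default 0.
#' @return A sorted, strand-less `GRanges` with no two intervals within
#'   `maxGap` of each other.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 11), c(10, 20)))
#' mergePeaks(gr)   # book-ended: one interval 1-20
#' @export
mergePeaks <- function(peaks, maxGap = 0) {
  stopifnot(is.numeric(maxGap), length(maxGap) == 1L, maxGap >= 0)
  gr <- .sortPeaks(granges(peaks))
  IRanges::reduce(gr, min.gapwidth = maxGap + 1, ignore.strand = TRUE)
}

#' Build consensus loci with per-set membership flags
#'
#' Merges the concatenation of all input sets into consensus loci and flags,
#' for every locus and every contributing set, whether at least one interval
#' of that set overlaps the locus by >= 1 bp. Every input interval falls in
#' exactly one consensus locus, and every locus carries at least one flag.
#'
#' @param sets A named list of [GenomicRanges::GRanges] (a bare `GRanges` is
#'   treated as a one-set list). Unnamed lists get `set1..setk` labels.
#' @param maxGap Merge gap forwarded to [mergePeaks()].
#' @return A [ConsensusPeaks][ConsensusPeaks-class] object.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 150))
#' membership(consensusPeaks(list(A = a, B = b)))
#' @export
consensusPeaks <- function(sets, maxGap = 0) {
  if (is(sets, "GRanges")) sets <- list(set1 = sets)
  if (!is.list(sets) || length(sets) == 0L)
    stop("at least one peak set is required")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_along(sets))
  ## concatenation across sets with disjoint seqlevels is intended here
  loci <- mergePeaks(suppressWarnings(
    do.call(c, unname(lapply(sets, granges)))), maxGap = maxGap)
  m <- vapply(sets,
              function(s) IRanges::overlapsAny(loci, s, ignore.strand = TRUE),
              logical(length(loci)))
  if (length(loci) <= 1L)  # vapply drops to vector for 0/1 loci
    m <- matrix(m, nrow = length(loci), ncol = length(sets),
                dimnames = list(NULL, names(sets)))
  se <- SummarizedExperiment(
    assays = list(membership = m),
    rowRanges = loci,
    colData = DataFrame(label = names(sets), row.names = names(sets)))
  new("ConsensusPeaks", se)
}

#' Two-set venn partition of consensus loci
#'
#' Partitions the consensus loci of two peak sets into A-only, shared and
#' B-only regions. Because counts are computed on merged consensus loci, the
#' shared count is symmetric: `vennPartition(a, b)` and `vennPartition(b, a)`
#' agree, and `a_only + shared` equals the number of consensus loci covered
#' by A.
#'
#' @param a,b Peak sets ([GenomicRanges::GRanges]).
#' @param labels Length-2 character labels for the two sets.
#' @param maxGap Merge gap for consensus construction.
#' @return A [VennPartition][VennPartition-class] object.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' vennCounts(vennPartition(a, a))   # one shared locus
#' @export
vennPartition <- function(a, b, labels = c("A", "B"), maxGap = 0) {
  stopifnot(length(labels) == 2L)
  cp <- consensusPeaks(stats::setNames(list(a, b), labels), maxGap = maxGap)
  m <- membership(cp)
  loci <- consensusLoci(cp)
  inA <- m[, 1]
  inB <- m[, 2]
  new("VennPartition",
      setLabels = as.character(labels),
      aOnly = sum(inA & !inB),
      shared = sum(inA & inB),
      bOnly = sum(!inA & inB),
      lociByClass = list(a_only = loci[inA & !inB],
                         shared = loci[inA & inB],
                         b_only = loci[!inA & inB]))
}

#' Per-timepoint occupancy flags on consensus loci
#'
#' For a consensus built from per-timepoint peak sets (or a superset), flags
#' each locus 1 at timepoint t iff it overlaps a peak called at t by
#' at least 1 bp. This is the presence-based open/closed call feeding the
#' accessibility-dynamics classifier.
#'
#' @param consensus A [ConsensusPeaks][ConsensusPeaks-class] or a `GRanges`
#'   of loci.
#' @param sets Ordered list of per-timepoint peak sets.
#' @param timepoints Optional numeric timepoints (hours); must match
#'   `length(sets)` and is used to name the columns `"0h", "4h", ...`.
#' @return Integer 0/1 matrix, loci x timepoints, rownames = [locusId()].
#' @examples
#' loci <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' occupancyFlags(loci, list(GenomicRanges::GRanges(),
#'                           GenomicRanges::GRanges("chr1",
#'                                                  IRanges::IRanges(50, 60))),
#'                timepoints = c(0, 4))
#' @export
occupancyFlags <- function(consensus, sets, timepoints = NULL) {
  loci <- if (is(consensus, "ConsensusPeaks")) consensusLoci(consensus)
          else consensus
  if (!is.list(sets)) sets <- list(sets)
  if (!is.null(timepoints) && length(timepoints) != length(sets))
    stop("timepoint count (", length(timepoints),
         ") does not match the number of peak sets (", length(sets), ")")
  m <- vapply(sets,
              function(s) as.integer(
                IRanges::overlapsAny(loci, s, ignore.strand = TRUE)),
              integer(length(loci)))
  if (length(loci) <= 1L)
    m <- matrix(m, nrow = length(loci), ncol = length(sets))
  cn <- if (!is.null(timepoints)) sprintf("%gh", timepoints)
        else if (!is.null(names(sets))) names(sets)
        else paste0("t", seq_along(sets))
  dimnames(m) <- list(locusId(loci), cn)
  m
}
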