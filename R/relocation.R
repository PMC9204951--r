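## Occupancy relocation between two timepoints: presence-based lost /
## retained / gained partition, fold-change binding dynamics, CAD-class
## composition of binding sites, and co-occupancy counts with histone marks.

#' Presence-based binding relocation between two timepoints
#'
#' On the consensus loci of the two binding sets, loci covered only at the
#' first timepoint are `lost`, loci covered at both are `retained`, and loci
#' only at the second are `gained`. By construction
#' `lost + retained` = loci covered at t0 and `retained + gained` = loci
#' covered at t1.
#'
#' @param set0,set1 Binding peak sets ([GenomicRanges::GRanges]) at the two
#'   timepoints.
#' @param labels Length-2 labels (default `c("t0", "t1")`).
#' @return A [VennPartition][VennPartition-class]; summarize with
#'   [relocationCounts()] or expand with [relocationTable()].
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201), c(100, 300)))
#' relocationCounts(bindingDynamics(a, a))
#' @export
bindingDynamics <- function(set0, set1, labels = c("t0", "t1")) {
  vennPartition(set0, set1, labels = labels)
}

#' @rdname bindingDynamics
#' @param x A `VennPartition` from [bindingDynamics()].
#' @return `relocationCounts` returns
#'   `c(lost, retained, gained, t0_total, t1_total)`.
#' @export
relocationCounts <- function(x) {
  stopifnot(is(x, "VennPartition"))
  v <- vennCounts(x)
  c(lost = unname(v["a_only"]), retained = unname(v["shared"]),
    gained = unname(v["b_only"]),
    t0_total = unname(v["a_only"] + v["shared"]),
    t1_total = unname(v["shared"] + v["b_only"]))
}

#' @rdname bindingDynamics
#' @return `relocationTable` returns a data.frame with one row per consensus
#'   locus (`locus`, `status`).
#' @export
relocationTable <- function(x) {
  stopifnot(is(x, "VennPartition"))
  cls <- lociByClass(x)
  status <- c("lost", "retained", "gained")
  do.call(rbind, lapply(seq_along(cls), function(i) {
    if (!length(cls[[i]]))
      return(data.frame(locus = character(0), status = character(0)))
    data.frame(locus = locusId(cls[[i]]), status = status[i],
               stringsAsFactors = FALSE)
  }))
}

#' Fold-change binding dynamics between two timepoints
#'
#' Per-locus signal comparison with \eqn{r = (s_1 + \epsilon)/(s_0 + \epsilon)}:
#' `up` if \eqn{r \ge fc}, `down` if \eqn{r \le 1/fc}, `permanent` otherwise
#' (interpreting the two-fold rule symmetrically on the ratio scale).
#'
#' @param s0,s1 Non-negative per-locus signals at the two timepoints
#'   (matching names when both are named).
#' @param fc Fold-change threshold (> 1, default 2).
#' @param eps Pseudocount (default 1).
#' @return Factor with levels `down`, `permanent`, `up`.
#' @examples
#' bindingDynamicsFC(c(8, 2, 4), c(2, 8, 6))
#' @export
bindingDynamicsFC <- function(s0, s1, fc = 2, eps = 1) {
  stopifnot(fc > 1, eps >= 0)
  if (length(s0) != length(s1))
    stop("the two timepoints cover different numbers of loci")
  if (!is.null(names(s0)) && !is.null(names(s1)) &&
      !identical(names(s0), names(s1)))
    stop("locus ids at the two timepoints do not match")
  if (any(s0 < 0) || any(s1 < 0)) stop("signals must be non-negative")
  r <- (s1 + eps) / (s0 + eps)
  lab <- ifelse(r >= fc, "up", ifelse(r <= 1 / fc, "down", "permanent"))
  stats::setNames(factor(lab, levels = c("down", "permanent", "up")),
                  names(s0))
}

#' Accessibility-class composition of a binding set
#'
#' Intersects a factor's binding peaks with labelled accessibility consensus
#' loci and reports the fraction of units in each dynamics class plus the
#' aggregate \emph{open-associated} fraction (PON + CO + POU). Two counting
#' units are available: `"consensus"` (default) counts each labelled
#' consensus locus hit by >= 1 binding peak once, with binding peaks that
#' hit no labelled locus counted under `NONE`; `"binding"` counts merged
#' binding peaks, each inheriting the label of the consensus locus it
#' overlaps most (majority bp overlap, ties broken by the fixed class order
#' CO1 < CO2 < CO3 < OC1 < OC2 < OC3 < POU < POD < PON).
#'
#' @param binding Binding peak set ([GenomicRanges::GRanges]).
#' @param cad A [CadResult][CadResult-class] whose loci coordinates are set.
#' @param unit `"consensus"` or `"binding"`.
#' @return A [BindingComposition][BindingComposition-class].
#' @export
cadComposition <- function(binding, cad, unit = c("consensus", "binding")) {
  unit <- match.arg(unit)
  loci <- cadLoci(cad)
  if (!length(loci))
    stop("cad carries no locus coordinates; classify with loci= set")
  lab <- cadLabels(cad)
  lev <- levels(lab)
  bind <- mergePeaks(binding)
  if (unit == "consensus") {
    hit <- IRanges::overlapsAny(loci, bind, ignore.strand = TRUE)
    units <- as.character(lab[hit])
    orphan <- sum(!IRanges::overlapsAny(bind, loci, ignore.strand = TRUE))
    units <- c(units, rep("NONE", orphan))
  } else {
    hits <- IRanges::findOverlaps(bind, loci, ignore.strand = TRUE)
    ow <- BiocGenerics::width(pintersect(bind[queryHits(hits)],
                                         loci[subjectHits(hits)]))
    units <- rep("NONE", length(bind))
    if (length(hits)) {
      tie <- match(as.character(lab)[subjectHits(hits)], .CAD_TIEBREAK)
      tie[is.na(tie)] <- length(.CAD_TIEBREAK) + 1L
      ord <- order(queryHits(hits), -ow, tie)
      first <- !duplicated(queryHits(hits)[ord])
      q <- queryHits(hits)[ord][first]
      units[q] <- as.character(lab)[subjectHits(hits)[ord][first]]
    }
  }
  counts <- table(factor(units, levels = lev))
  counts <- stats::setNames(as.integer(counts), lev)
  total <- sum(counts)
  frac <- if (total > 0) counts / total else counts * 0
  new("BindingComposition",
      counts = counts,
      fractions = frac,
      openAssociated = sum(frac[intersect(.OPEN_ASSOCIATED, lev)]),
      unit = unit)
}

#' Co-occupancy counts between a factor and chromatin marks
#'
#' Shared consensus-locus counts ([vennPartition()] `shared`) between one
#' factor's binding set and each of several mark sets, ranked by overlap.
#'
#' @param factor_ Factor binding set ([GenomicRanges::GRanges]).
#' @param marks Named list of mark peak sets.
#' @return data.frame (`mark`, `shared`, `rank`) sorted by decreasing
#'   shared count.
#' @export
cooccupancyCounts <- function(factor_, marks) {
  if (!is.list(marks) || is.null(names(marks)) || !length(marks))
    stop("marks must be a non-empty named list of peak sets")
  shared <- vapply(marks, function(m)
    unname(vennCounts(vennPartition(factor_, m))["shared"]), integer(1))
  out <- data.frame(mark = names(marks), shared = unname(shared),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$shared, out$mark), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
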