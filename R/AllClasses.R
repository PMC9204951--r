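## Central S4 containers. ConsensusPeaks rides on RangedSummarizedExperiment
## so the membership matrix, locus ranges and set metadata travel together.

.CAD_LEVELS <- c("CO1", "CO2", "CO3", "OC1", "OC2", "OC3",
                 "POU", "POD", "PON", "NONE", "OTHER")
## fixed tie-break order for binding -> CAD label transfer
.CAD_TIEBREAK <- c("CO1", "CO2", "CO3", "OC1", "OC2", "OC3",
                   "POU", "POD", "PON")
.OPEN_ASSOCIATED <- c("PON", "CO1", "CO2", "CO3", "POU")
.GEP_LEVELS <- c("Group1", "Group2", "Group3", "Unchanged")

#' Chromatin-accessibility-dynamics class labels
#'
#' The label vocabulary of the accessibility-dynamics classifier: loci that
#' change from closed to open in one of the inter-timepoint windows
#' (`CO1`..`CO3`), open to closed (`OC1`..`OC3`), permanently open with an
#' upward, downward or flat signal trend (`POU`, `POD`, `PON`), never open
#' (`NONE`), or following a non-monotone trajectory that matches no template
#' (`OTHER`). For `k` timepoints the transition classes run `CO1..CO(k-1)`
#' and `OC1..OC(k-1)`.
#'
#' @param k Number of timepoints (default 4, giving the canonical 11 labels).
#' @return Character vector of label names.
#' @examples
#' cadLevels()
#' @export
cadLevels <- function(k = 4) {
  stopifnot(k >= 2)
  c(paste0("CO", seq_len(k - 1)), paste0("OC", seq_len(k - 1)),
    "POU", "POD", "PON", "NONE", "OTHER")
}

#' Gene-expression-pattern group labels
#'
#' Trajectory groups for time-course expression: `Group1` (gradually
#' upregulated -- the fold-change threshold is first reached after the first
#' post-baseline timepoint), `Group2` (immediately upregulated), `Group3`
#' (downregulated at the final timepoint) and `Unchanged`.
#'
#' @return Character vector of the four group names.
#' @examples
#' gepLevels()
#' @export
gepLevels <- function() .GEP_LEVELS

#' ConsensusPeaks: merged loci with per-set membership flags
#'
#' A \linkS4class{RangedSummarizedExperiment} whose rows are the merged
#' consensus loci of one or more peak sets and whose single assay,
#' `"membership"`, is a logical locus-by-set matrix: `TRUE` where at least
#' one interval of the contributing set overlaps the locus by >= 1 bp.
#'
#' Build with [consensusPeaks()]; access with [consensusLoci()] and
#' [membership()].
#'
#' @aliases ConsensusPeaks-class
#' @exportClass ConsensusPeaks
setClass("ConsensusPeaks",
         contains = "RangedSummarizedExperiment")

setValidity("ConsensusPeaks", function(object) {
  if (!"membership" %in% SummarizedExperiment::assayNames(object))
    return("assay 'membership' is missing")
  m <- SummarizedExperiment::assay(object, "membership")
  if (!is.logical(m))
    return("assay 'membership' must be logical")
  if (nrow(m) > 0 && any(rowSums(m) == 0))
    return("every consensus locus must carry at least one membership flag")
  TRUE
})

#' VennPartition: two-set partition of consensus loci
#'
#' Counts of consensus loci covered only by set A, by both sets, and only by
#' set B, together with the loci themselves. Counts are computed on merged
#' consensus loci so that the shared count is symmetric in A and B.
#'
#' Build with [vennPartition()] or [bindingDynamics()]; access with
#' [vennCounts()], [relocationCounts()] and [lociByClass()].
#'
#' @aliases VennPartition-class
#' @exportClass VennPartition
setClass("VennPartition",
         representation(setLabels = "character",
                        aOnly = "integer",
                        shared = "integer",
                        bOnly = "integer",
                        lociByClass = "list"))

setValidity("VennPartition", function(object) {
  if (length(object@setLabels) != 2L) return("setLabels must have length 2")
  if (object@aOnly < 0L || object@shared < 0L || object@bOnly < 0L)
    return("region counts must be non-negative")
  cls <- c("a_only", "shared", "b_only")
  if (!identical(names(object@lociByClass), cls))
    return("lociByClass must be named a_only, shared, b_only")
  n <- vapply(object@lociByClass, length, integer(1))
  if (!identical(unname(n),
                 c(object@aOnly, object@shared, object@bOnly)))
    return("lociByClass lengths must match the region counts")
  TRUE
})

#' CadResult: per-locus accessibility-dynamics labels
#'
#' One label from [cadLevels()] per classified locus, optionally carrying the
#' locus coordinates. Build with [classifyCad()]; access with [cadLabels()]
#' and [cadCounts()].
#'
#' @aliases CadResult-class
#' @exportClass CadResult
setClass("CadResult",
         representation(ids = "character",
                        loci = "GRanges",
                        labels = "factor"))

setValidity("CadResult", function(object) {
  if (length(object@ids) != length(object@labels))
    return("ids and labels must have equal length")
  if (!all(levels(object@labels) %in% .CAD_LEVELS) &&
      !all(grepl("^(CO|OC)[0-9]+$|^(POU|POD|PON|NONE|OTHER)$",
                 levels(object@labels))))
    return("labels carry unknown levels")
  if (anyNA(object@labels))
    return("every locus must receive exactly one label")
  if (length(object@loci) != 0L &&
      length(object@loci) != length(object@labels))
    return("loci must be empty or parallel to labels")
  if (anyDuplicated(object@ids))
    return("locus ids must be unique")
  TRUE
})

#' CompositionTable: row-normalized class-composition fractions
#'
#' A fractions matrix whose nonempty rows sum to 1, plus the per-row
#' denominator (number of mapped genes, or loci, behind the fractions). Rows
#' with denominator 0 are flagged undefined and hold `NA` fractions rather
#' than propagating NaN.
#'
#' Build with [compositionForward()] / [compositionReverse()]; access with
#' [compositionFractions()] and [compositionDenominators()].
#'
#' @aliases CompositionTable-class
#' @exportClass CompositionTable
setClass("CompositionTable",
         representation(fractions = "matrix",
                        denominators = "integer"))

setValidity("CompositionTable", function(object) {
  if (nrow(object@fractions) != length(object@denominators))
    return("one denominator per row is required")
  rs <- rowSums(object@fractions)
  ok <- object@denominators == 0L | abs(rs - 1) < 1e-9
  if (!all(ok | is.na(ok)))
    return("nonempty rows must sum to 1 within 1e-9")
  if (any(object@denominators > 0L & apply(is.na(object@fractions), 1, any)))
    return("rows with a positive denominator must not contain NA")
  TRUE
})

#' BindingComposition: CAD-class composition of a binding set
#'
#' Per-class fractions (and counts) of the accessibility-dynamics labels
#' inherited by a factor's binding loci, plus the aggregate
#' \emph{open-associated} fraction PON + CO + POU. Build with
#' [cadComposition()].
#'
#' @aliases BindingComposition-class
#' @exportClass BindingComposition
setClass("BindingComposition",
         representation(counts = "integer",
                        fractions = "numeric",
                        openAssociated = "numeric",
                        unit = "character"))

setValidity("BindingComposition", function(object) {
  if (!identical(names(object@counts), names(object@fractions)))
    return("counts and fractions must share names")
  if (sum(object@counts) > 0 && abs(sum(object@fractions) - 1) > 1e-9)
    return("fractions (including the NONE bucket) must sum to 1")
  TRUE
})

## ---- generics -------------------------------------------------------------

#' @rdname ConsensusPeaks-class
#' @param x A `ConsensusPeaks` object.
#' @return `consensusLoci` returns the merged loci as a [GenomicRanges::GRanges].
#' @export
setGeneric("consensusLoci", function(x) standardGeneric("consensusLoci"))

#' @rdname ConsensusPeaks-class
#' @return `membership` returns the logical locus-by-set membership matrix.
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname VennPartition-class
#' @param x A `VennPartition` object.
#' @return `vennCounts` returns the named integer vector
#'   `c(a_only, shared, b_only)`.
#' @export
setGeneric("vennCounts", function(x) standardGeneric("vennCounts"))

#' @rdname VennPartition-class
#' @return `lociByClass` returns the named list of `GRanges` per region.
#' @export
setGeneric("lociByClass", function(x) standardGeneric("lociByClass"))

#' @rdname CadResult-class
#' @param x A `CadResult` object.
#' @return `cadLabels` returns the named factor of per-locus labels.
#' @export
setGeneric("cadLabels", function(x) standardGeneric("cadLabels"))

#' @rdname CadResult-class
#' @return `cadCounts` returns the integer count per label, including
#'   zero-count classes.
#' @export
setGeneric("cadCounts", function(x) standardGeneric("cadCounts"))

#' @rdname CadResult-class
#' @return `cadLoci` returns the locus coordinates (may be empty).
#' @export
setGeneric("cadLoci", function(x) standardGeneric("cadLoci"))

#' @rdname CompositionTable-class
#' @param x A `CompositionTable` object.
#' @return `compositionFractions` returns the fractions matrix.
#' @export
setGeneric("compositionFractions",
           function(x) standardGeneric("compositionFractions"))

#' @rdname CompositionTable-class
#' @return `compositionDenominators` returns the per-row denominators.
#' @export
setGeneric("compositionDenominators",
           function(x) standardGeneric("compositionDenominators"))

## ---- methods --------------------------------------------------------------

#' @rdname ConsensusPeaks-class
setMethod("consensusLoci", "ConsensusPeaks", function(x) {
  gr <- SummarizedExperiment::rowRanges(x)
  names(gr) <- locusId(gr)
  gr
})

#' @rdname ConsensusPeaks-class
setMethod("membership", "ConsensusPeaks", function(x) {
  m <- SummarizedExperiment::assay(x, "membership")
  rownames(m) <- locusId(SummarizedExperiment::rowRanges(x))
  m
})

setMethod("show", "ConsensusPeaks", function(object) {
  cat(sprintf("ConsensusPeaks with %d loci over %d peak set(s): %s\n",
              nrow(object), ncol(object),
              paste(colnames(object), collapse = ", ")))
})

#' @rdname VennPartition-class
setMethod("vennCounts", "VennPartition", function(x)
  c(a_only = x@aOnly, shared = x@shared, b_only = x@bOnly))

#' @rdname VennPartition-class
setMethod("lociByClass", "VennPartition", function(x) x@lociByClass)

setMethod("show", "VennPartition", function(object) {
  cat(sprintf("VennPartition [%s | %s]: %d only-%s, %d shared, %d only-%s\n",
              object@setLabels[1], object@setLabels[2],
              object@aOnly, object@setLabels[1],
              object@shared, object@bOnly, object@setLabels[2]))
})

#' @rdname CadResult-class
setMethod("cadLabels", "CadResult", function(x)
  stats::setNames(x@labels, x@ids))

#' @rdname CadResult-class
setMethod("cadCounts", "CadResult", function(x) {
  tab <- table(x@labels)
  stats::setNames(as.integer(tab), names(tab))
})

#' @rdname CadResult-class
setMethod("cadLoci", "CadResult", function(x) {
  gr <- x@loci
  if (length(gr)) names(gr) <- x@ids
  gr
})

setMethod("show", "CadResult", function(object) {
  cat(sprintf("CadResult for %d loci\n", length(object@labels)))
  print(cadCounts(object))
})

#' @rdname CompositionTable-class
setMethod("compositionFractions", "CompositionTable",
          function(x) x@fractions)

#' @rdname CompositionTable-class
setMethod("compositionDenominators", "CompositionTable", function(x)
  stats::setNames(x@denominators, rownames(x@fractions)))

setMethod("show", "CompositionTable", function(object) {
  cat(sprintf("CompositionTable: %d row(s) x %d class(es)\n",
              nrow(object@fractions), ncol(object@fractions)))
  print(cbind(round(object@fractions, 4), n = object@denominators))
})

setMethod("show", "BindingComposition", function(object) {
  cat(sprintf("BindingComposition over %d %s unit(s)\n",
              sum(object@counts), object@unit))
  print(round(object@fractions, 4))
  cat(sprintf("open-associated (PON+CO+POU): %.4f\n",
              object@openAssociated))
})

#' Accessors for BindingComposition
#'
#' @param x A [BindingComposition][BindingComposition-class] object.
#' @return `bindingFractions` the per-class fractions; `bindingCounts` the
#'   per-class unit counts; `openAssociated` the aggregate PON + CO + POU
#'   fraction.
#' @aliases bindingCounts openAssociated
#' @export
bindingFractions <- function(x) x@fractions

#' @rdname bindingFractions
#' @export
bindingCounts <- function(x) x@counts

#' @rdname bindingFractions
#' @export
openAssociated <- function(x) x@openAssociated
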