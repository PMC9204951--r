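## Chromatin-accessibility-dynamics (CAD) classification: template matching
## of binary open/closed trajectories over the timecourse, subdivision of
## permanently-open loci by signal fold change, and knockdown-vs-control
## differential accessibility calls.

## canonical monotone templates for k timepoints, keyed by the 0/1 string
.cadTemplates <- function(k) {
  stopifnot(k >= 2)
  tmpl <- character(0)
  for (j in seq_len(k - 1)) {
    tmpl[paste(c(rep(0L, j), rep(1L, k - j)), collapse = "")] <-
      paste0("CO", j)
    tmpl[paste(c(rep(1L, j), rep(0L, k - j)), collapse = "")] <-
      paste0("OC", j)
  }
  tmpl[strrep("0", k)] <- "NONE"
  tmpl[strrep("1", k)] <- "PO"
  tmpl
}

#' Binarize an accessibility signal at an open threshold
#'
#' `state = 1` iff `signal >= tau` (the threshold itself counts as open).
#' This is the signal-threshold alternative to presence-based
#' [occupancyFlags()].
#'
#' @param signal Non-negative numeric vector or matrix (loci x timepoints).
#' @param tau Positive open threshold, in the same (arbitrary normalized)
#'   units as `signal`.
#' @return Integer 0/1 object of the same shape.
#' @examples
#' binarizeSignal(c(0, 1, 5), tau = 1)
#' @export
binarizeSignal <- function(signal, tau) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0)
  if (any(signal < 0, na.rm = TRUE))
    stop("accessibility signal must be non-negative")
  out <- (signal >= tau) + 0L
  out
}

## core vectorized labeller; state/signal are matrices loci x timepoints
.classifyStates <- function(state, signal = NULL, fcPo = 2, eps = 1) {
  stopifnot(fcPo > 1, eps >= 0)
  k <- ncol(state)
  if (!all(state %in% c(0, 1)))
    stop("state must be binary")
  if (!is.null(signal)) {
    if (!identical(dim(signal), dim(state)))
      stop("signal and state dimensions must agree")
    if (any(signal < 0)) stop("accessibility signal must be non-negative")
  }
  tmpl <- .cadTemplates(k)
  keys <- do.call(paste0, as.data.frame(state))
  lab <- unname(tmpl[keys])
  lab[is.na(lab)] <- "OTHER"
  po <- which(lab == "PO")
  if (length(po)) {
    if (is.null(signal)) {
      lab[po] <- "PON"
    } else {
      r <- (signal[po, k] + eps) / (signal[po, 1] + eps)
      lab[po] <- ifelse(r >= fcPo, "POU", ifelse(r <= 1 / fcPo, "POD", "PON"))
    }
  }
  factor(lab, levels = cadLevels(k))
}

#' Classify a single accessibility trajectory
#'
#' Template matching over the binary open/closed trajectory: closed-then-open
#' with persistence maps to `CO1..CO(k-1)` by transition window, open-then-
#' closed to `OC1..OC(k-1)`, all-closed to `NONE`, and any non-monotone
#' pattern to `OTHER`. Permanently open trajectories are subdivided by the
#' last/first signal ratio \eqn{r = (s_{last} + \epsilon)/(s_{first} + \epsilon)}: `POU` if
#' \eqn{r \ge fcPo}, `POD` if \eqn{r \le 1/fcPo}, else `PON`. Without a signal vector
#' the trend is unknowable and permanently open loci fall back to `PON`.
#'
#' @param state Binary 0/1 vector over timepoints.
#' @param signal Optional non-negative signal vector of the same length.
#' @param fcPo Fold-change threshold for the permanently-open subdivision
#'   (default 2).
#' @param eps Pseudocount guarding the ratio against zero signal (default 1
#'   signal unit).
#' @return A length-1 factor with levels `cadLevels(length(state))`.
#' @examples
#' classifyTrajectory(c(0, 1, 1, 1))                       # CO1
#' classifyTrajectory(c(1, 1, 1, 1), c(4, 4, 4, 9))        # POU
#' @export
classifyTrajectory <- function(state, signal = NULL, fcPo = 2, eps = 1) {
  state <- matrix(as.integer(state), nrow = 1)
  if (!is.null(signal)) signal <- matrix(as.numeric(signal), nrow = 1)
  .classifyStates(state, signal, fcPo = fcPo, eps = eps)
}

#' Classify all loci of a timecourse into accessibility-dynamics classes
#'
#' Applies [classifyTrajectory()] to every row of a binary state matrix
#' (from [occupancyFlags()] or [binarizeSignal()]), producing an exhaustive
#' partition: each locus receives exactly one label and the per-class counts
#' (including zero-count classes) sum to the locus count.
#'
#' @param state Integer 0/1 matrix, loci x timepoints. Rownames (or `loci`)
#'   provide locus ids.
#' @param signal Optional signal matrix of the same shape, used to subdivide
#'   permanently-open loci; rows must be in the same order as `state`.
#' @param fcPo,eps See [classifyTrajectory()].
#' @param loci Optional [GenomicRanges::GRanges] parallel to the rows.
#' @return A [CadResult][CadResult-class] object.
#' @examples
#' st <- rbind(a = c(0, 1, 1, 1), b = c(1, 1, 0, 0), c = c(0, 0, 0, 0))
#' cadCounts(classifyCad(st))
#' @export
classifyCad <- function(state, signal = NULL, fcPo = 2, eps = 1,
                        loci = NULL) {
  if (is.null(dim(state))) state <- matrix(state, nrow = 1)
  if (nrow(state) == 0L) stop("at least one locus is required")
  labels <- .classifyStates(state, signal, fcPo = fcPo, eps = eps)
  ids <- rownames(state)
  if (is.null(ids)) {
    ids <- if (!is.null(loci)) locusId(loci)
           else sprintf("locus%06d", seq_len(nrow(state)))
  }
  new("CadResult",
      ids = ids,
      loci = if (is.null(loci)) GRanges() else granges(loci),
      labels = labels)
}

#' Knockdown-vs-control differential accessibility calls
#'
#' Compares per-locus accessibility between a control and a knockdown
#' condition at a single timepoint. With
#' \eqn{r = (kd + \epsilon)/(ctrl + \epsilon)}, a locus is called `ATD` (signal down) if
#' \eqn{r \le 1/fc}, `ATU` (signal up) if \eqn{r \ge fc}, and `ATP` (permanent)
#' otherwise.
#'
#' @param ctrl,kd Non-negative signal vectors over the same loci (matching
#'   names, when both are named).
#' @param fc Fold-change threshold (> 1, default 2).
#' @param eps Pseudocount (default 1).
#' @return Factor with levels `ATD`, `ATU`, `ATP`, named like `ctrl`.
#' @examples
#' diffAccessibility(c(l1 = 10, l2 = 2, l3 = 5), c(l1 = 2, l2 = 10, l3 = 5))
#' @export
diffAccessibility <- function(ctrl, kd, fc = 2, eps = 1) {
  stopifnot(fc > 1, eps >= 0)
  if (length(ctrl) != length(kd))
    stop("control and knockdown cover different numbers of loci")
  if (!is.null(names(ctrl)) && !is.null(names(kd)) &&
      !identical(names(ctrl), names(kd)))
    stop("control and knockdown locus ids do not match")
  if (any(ctrl < 0) || any(kd < 0))
    stop("accessibility signal must be non-negative")
  r <- (kd + eps) / (ctrl + eps)
  lab <- ifelse(r <= 1 / fc, "ATD", ifelse(r >= fc, "ATU", "ATP"))
  stats::setNames(factor(lab, levels = c("ATD", "ATU", "ATP")), names(ctrl))
}
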