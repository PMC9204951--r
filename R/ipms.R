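## Label-free IP-MS differential interactomics: missing-value filtering and
## imputation, row-wise two-sample t statistics with a fold-change gate,
## and interactome set algebra.

#' Filter, log-transform and impute an IP-MS intensity matrix
#'
#' Proteins observed in fewer than `minObs` replicates in every condition
#' are dropped; remaining intensities are log2-transformed and missing
#' entries are imputed from the left tail of each sample's observed
#' distribution: `"min_shift"` (default, deterministic) fills with the
#' sample minimum minus `shift` log2 units; `"min_prob"` draws from a
#' normal centred there (sd = `sdFrac` x the sample sd), reproducibly under
#' `seed`. Observed values are never altered.
#'
#' @param intensities Numeric matrix, proteins x samples, on the linear
#'   intensity scale; `NA` or 0 marks a missing value.
#' @param samples data.frame with columns `sample`, `condition`,
#'   `replicate`; `sample` must match `colnames(intensities)`.
#' @param minObs Minimum observations in at least one condition (default 2,
#'   i.e. 2-of-3 for triplicates).
#' @param method `"min_shift"` or `"min_prob"`.
#' @param shift Left shift of the imputation centre in log2 units
#'   (default 1).
#' @param sdFrac Width of the `min_prob` draw as a fraction of the sample sd
#'   (default 0.3).
#' @param seed Optional integer making `min_prob` reproducible.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"log2"`, `colData` from `samples`, and
#'   `metadata()$dropped` naming the filtered proteins.
#' @export
preprocessIntensities <- function(intensities, samples, minObs = 2,
                                  method = c("min_shift", "min_prob"),
                                  shift = 1, sdFrac = 0.3, seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(intensities), minObs >= 1, shift >= 0)
  req <- c("sample", "condition", "replicate")
  if (!all(req %in% names(samples)))
    stop("samples needs columns: ", paste(req, collapse = ", "))
  if (!setequal(samples$sample, colnames(intensities)))
    stop("samples$sample must match the intensity matrix columns")
  samples <- samples[match(colnames(intensities), samples$sample), ]
  if (length(unique(samples$condition)) < 2L)
    stop("at least two conditions are required")
  obs <- !is.na(intensities) & intensities > 0
  keep <- vapply(seq_len(nrow(intensities)), function(i) {
    any(tapply(obs[i, ], samples$condition, sum) >= minObs)
  }, logical(1))
  dropped <- rownames(intensities)[!keep]
  x <- intensities[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  log2x <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  log2x[obs] <- log2(x[obs])
  nMissing <- sum(!obs)
  if (nMissing > 0) {
    if (method == "min_prob" && !is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    globalMin <- min(log2x, na.rm = TRUE)
    globalSd <- stats::sd(log2x, na.rm = TRUE)
    for (j in seq_len(ncol(log2x))) {
      miss <- which(!obs[, j])
      if (!length(miss)) next
      colObs <- log2x[obs[, j], j]
      centre <- (if (length(colObs)) min(colObs) else globalMin) - shift
      if (method == "min_shift") {
        log2x[miss, j] <- centre
      } else {
        wsd <- sdFrac * (if (length(colObs) > 1) stats::sd(colObs)
                         else globalSd)
        log2x[miss, j] <- stats::rnorm(length(miss), centre, wsd)
      }
    }
  }
  se <- SummarizedExperiment(
    assays = list(log2 = log2x),
    colData = DataFrame(samples, row.names = samples$sample))
  metadata(se)$dropped <- dropped
  metadata(se)$imputation <- list(method = method, shift = shift,
                                  minObs = minObs)
  se
}

## row-wise two-sample t; pooled Student (default) or Welch.
.rowTTest <- function(case, ctrl, varEqual = TRUE) {
  n1 <- ncol(case); n0 <- ncol(ctrl)
  stopifnot(n1 >= 2, n0 >= 2)
  m1 <- unname(rowMeans(case)); m0 <- unname(rowMeans(ctrl))
  v1 <- unname(apply(case, 1, stats::var))
  v0 <- unname(apply(ctrl, 1, stats::var))
  d <- m1 - m0
  if (varEqual) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(d))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  t <- d / se
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se == 0
  if (any(degenerate)) {
    zeroDiff <- degenerate & d == 0
    t[zeroDiff] <- 0; p[zeroDiff] <- 1; df[zeroDiff] <- n1 + n0 - 2
    unequal <- degenerate & d != 0
    t[unequal] <- sign(d[unequal]) * Inf; p[unequal] <- 0
    df[unequal] <- n1 + n0 - 2
    degenerate <- unequal   # only the p -> 0 limit is flagged
  }
  list(log2fc = d, t = t, df = df, pvalue = p, degenerate = degenerate)
}

#' Call differential interactors with t-test and fold-change thresholds
#'
#' Per protein: `log2fc = mean(case) - mean(control)` and a two-sided
#' two-sample t-test on the log2 intensities (pooled Student's t by
#' default, per the study's statistics; Welch via `varEqual = FALSE`). A
#' protein is a significant interactor iff `p < alpha` \emph{and}
#' `log2fc >= log2(fc)` -- the fold-change gate is one-directional, toward
#' enrichment in the case pull-down. Zero-variance rows with equal means
#' get `p = 1` by convention; zero variance with unequal means is the
#' `p -> 0` limit and is flagged degenerate.
#'
#' @param x A [SummarizedExperiment::SummarizedExperiment] from
#'   [preprocessIntensities()] (assay `"log2"`), or a numeric log2 matrix
#'   with `samples` supplied.
#' @param case,control Condition labels to compare.
#' @param samples Sample sheet (only when `x` is a bare matrix).
#' @param alpha Significance threshold on the (adjusted) p-value
#'   (default 0.01).
#' @param fc Fold-change threshold (default 2, i.e. log2fc >= 1).
#' @param varEqual Pooled-variance Student's t (`TRUE`, default) or Welch.
#' @param adjust `"none"` (default; raw p-values, as in the thresholding
#'   scheme) or `"BH"`.
#' @return A [S4Vectors::DataFrame] with one row per protein: `log2fc`,
#'   `t`, `df`, `pvalue`, (`padj`,) `significant`, `degenerate`.
#' @examples
#' case <- matrix(c(10, 10.2, 9.8), 1); ctrl <- matrix(c(8, 8.2, 7.8), 1)
#' x <- cbind(case, ctrl); rownames(x) <- "p1"
#' colnames(x) <- c("c1", "c2", "c3", "g1", "g2", "g3")
#' sheet <- data.frame(sample = colnames(x),
#'                     condition = rep(c("IP", "ctrl"), each = 3),
#'                     replicate = rep(1:3, 2))
#' testInteractors(x, "IP", "ctrl", samples = sheet)
#' @export
testInteractors <- function(x, case, control, samples = NULL, alpha = 0.01,
                            fc = 2, varEqual = TRUE,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(alpha > 0, alpha <= 1, fc > 1)
  if (is(x, "SummarizedExperiment")) {
    samples <- as.data.frame(colData(x))
    mat <- assay(x, "log2")
  } else {
    if (is.null(samples)) stop("samples is required for a bare matrix")
    mat <- x
  }
  cond <- samples$condition[match(colnames(mat), samples$sample)]
  if (!case %in% cond || !control %in% cond)
    stop("case/control condition not present in the sample sheet")
  res <- .rowTTest(mat[, cond == case, drop = FALSE],
                   mat[, cond == control, drop = FALSE],
                   varEqual = varEqual)
  out <- DataFrame(log2fc = res$log2fc, t = res$t, df = res$df,
                   pvalue = res$pvalue, row.names = rownames(mat))
  pUse <- res$pvalue
  if (adjust == "BH") {
    out$padj <- stats::p.adjust(res$pvalue, method = "BH")
    pUse <- out$padj
  }
  out$significant <- pUse < alpha & res$log2fc >= log2(fc)
  out$degenerate <- res$degenerate
  out
}

#' @rdname testInteractors
#' @param calls A `DataFrame` returned by `testInteractors`.
#' @return `interactors` returns the character vector of significant
#'   proteins.
#' @export
interactors <- function(calls) rownames(calls)[calls$significant]

#' Exact venn region counts over interactor sets
#'
#' Counts every one of the `2^k - 1` membership regions of `k` interactor
#' sets. Region names join the member set names with `&`; counts sum to the
#' size of the union and are invariant to input order.
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return Named integer vector over all non-empty membership regions.
#' @examples
#' interactomeVenn(list(A = c("p1", "p2"), B = c("p2", "p3")))
#' @export
interactomeVenn <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L)
    stop("at least two interactor sets are required")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  un <- unique(unlist(sets, use.names = FALSE))
  m <- vapply(sets, function(s) un %in% s, logical(length(un)))
  if (length(un) <= 1L)
    m <- matrix(m, nrow = length(un), dimnames = list(NULL, names(sets)))
  k <- length(sets)
  regions <- integer(0)
  for (size in seq_len(k)) {
    combos <- utils::combn(k, size, simplify = FALSE)
    for (cmb in combos) {
      inside <- rowSums(m[, cmb, drop = FALSE]) == length(cmb) &
        rowSums(m[, -cmb, drop = FALSE]) == 0
      ## canonical region key: member names in sorted order, so the counts
      ## are invariant to the input ordering of the sets
      key <- paste(sort(names(sets)[cmb], method = "radix"),
                   collapse = "&")
      regions[key] <- sum(inside)
    }
  }
  regions[sort(names(regions), method = "radix")]
}

#' Shared interactors between two baits
#'
#' Plain set intersection of two interactor sets (e.g. the proteins called
#' for two different baits at the same timepoint).
#'
#' @param a,b Character vectors of protein identifiers.
#' @return Character vector of proteins present in both.
#' @export
sharedInteractors <- function(a, b) intersect(unique(a), unique(b))
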