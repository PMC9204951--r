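## Expression-trajectory grouping and CAD <-> GEP integration through
## TSS +/- window peak-to-gene assignment.

#' Classify TPM trajectories into expression-pattern groups
#'
#' Rule-based grouping of a time-course expression trajectory with
#' pseudocounted ratios to baseline, \eqn{r_t = (tpm_t + c)/(tpm_0 + c)}:
#' `Group3` (down) iff \eqn{r_{last} \le 1/fc}; otherwise `Group2` (immediately up)
#' iff the ratio at the first post-baseline timepoint reaches `fc`;
#' otherwise `Group1` (gradually up) iff any later ratio reaches `fc`;
#' otherwise `Unchanged`.
#'
#' @param tpm Non-negative matrix (genes x timepoints) or a single
#'   trajectory vector. Units: TPM.
#' @param fc Fold-change threshold (> 1, default 1.5).
#' @param pseudo Pseudocount `c` (default 1 TPM).
#' @return Factor with levels [gepLevels()], named by `rownames(tpm)`.
#' @examples
#' classifyGep(rbind(g1 = c(10, 12, 14, 20),    # gradual -> Group1
#'                   g2 = c(10, 20, 30, 40),    # immediate -> Group2
#'                   g3 = c(30, 20, 15, 10),    # down -> Group3
#'                   g4 = c(10, 10, 10, 10)))   # Unchanged
#' @export
classifyGep <- function(tpm, fc = 1.5, pseudo = 1) {
  stopifnot(fc > 1, pseudo >= 0)
  if (is.null(dim(tpm))) tpm <- matrix(tpm, nrow = 1)
  if (ncol(tpm) < 2L) stop("at least two timepoints are required")
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  k <- ncol(tpm)
  r <- (tpm + pseudo) / (tpm[, 1] + pseudo)
  rmax <- do.call(pmax, as.data.frame(r[, -1, drop = FALSE]))
  lab <- ifelse(r[, k] <= 1 / fc, "Group3",
         ifelse(r[, 2] >= fc, "Group2",
         ifelse(rmax >= fc, "Group1", "Unchanged")))
  stats::setNames(factor(lab, levels = gepLevels()), rownames(tpm))
}

#' Read a TSS annotation table
#'
#' Accepts either a 4-column TSV (`gene_id`, `chrom`, `tss`, `strand`; a
#' header row is detected and skipped) with `tss` as the 0-based TSS
#' position, or BED6, where the TSS of a `-`-strand gene is the record's 3'
#' coordinate (`end - 1`), so the assignment window is always centered on
#' the true TSS.
#'
#' @param path File path.
#' @param format `"auto"`, `"tsv"` or `"bed"`.
#' @return A width-1 [GenomicRanges::GRanges] (1-based TSS position) with a
#'   `gene_id` metadata column and strand set.
#' @export
readTss <- function(path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("TSS file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "tsv"
  if (format == "bed") {
    gr <- readPeaks(path, format = "bed")
    if (!"name" %in% names(mcols(gr)))
      stop("BED TSS annotation needs a name column (gene id)")
    neg <- as.character(strand(gr)) == "-"
    tss1 <- ifelse(neg, BiocGenerics::end(gr), BiocGenerics::start(gr))
    out <- GRanges(seqnames(gr), IRanges(tss1, width = 1),
                   strand = strand(gr))
    mcols(out)$gene_id <- mcols(gr)$name
  } else {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4L) stop("TSS TSV needs 4 columns: gene_id chrom tss strand")
    if (is.na(suppressWarnings(as.numeric(df[1, 3]))))
      df <- df[-1, , drop = FALSE]   # header row
    tss0 <- as.numeric(df[[3]])
    if (anyNA(tss0) || any(tss0 < 0)) stop("invalid TSS coordinate in ", path)
    st <- as.character(df[[4]])
    if (!all(st %in% c("+", "-"))) stop("invalid strand in ", path)
    out <- GRanges(as.character(df[[2]]), IRanges(tss0 + 1, width = 1),
                   strand = st)
    mcols(out)$gene_id <- as.character(df[[1]])
  }
  if (anyDuplicated(mcols(out)$gene_id))
    stop("duplicated gene ids in TSS annotation")
  out
}

#' Assign peaks to genes through TSS windows
#'
#' A peak maps to a gene iff it overlaps the window `[tss - window,
#' tss + window]` (0-based inclusive, i.e. half-open
#' `[tss - window, tss + window + 1)`) by >= 1 bp. A peak may map to
#' several genes and a gene may collect several peaks; peaks hitting no
#' window are recorded as unmapped. TSS chromosomes absent from the peak
#' set simply contribute no mappings.
#'
#' @param peaks Peak set ([GenomicRanges::GRanges]).
#' @param tss TSS annotation from [readTss()] (width-1 `GRanges` with
#'   `gene_id`).
#' @param window Half-width of the assignment window in bp (default 10000).
#' @return A list of class `PeakGeneMap`: `edges` (data.frame `peak`,
#'   `gene`), `peakToGene` / `geneToPeak` (named lists), `unmapped`
#'   (character peak ids), `window`.
#' @examples
#' pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(29901, 30100))
#' ts <- GenomicRanges::GRanges("chr1", IRanges::IRanges(30001, width = 1),
#'                              strand = "+", gene_id = "g1")
#' mapPeaksToGenes(pk, ts)$edges
#' @export
mapPeaksToGenes <- function(peaks, tss, window = 10000) {
  stopifnot(window >= 0)
  if (!"gene_id" %in% names(mcols(tss)))
    stop("tss must carry a gene_id metadata column")
  ids <- locusId(peaks)
  win <- GRanges(seqnames(tss),
                 IRanges(pmax(BiocGenerics::start(tss) - window, 1),
                         BiocGenerics::start(tss) + window))
  hits <- IRanges::findOverlaps(granges(peaks), win, ignore.strand = TRUE)
  edges <- data.frame(peak = ids[queryHits(hits)],
                      gene = mcols(tss)$gene_id[subjectHits(hits)],
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  structure(list(
    edges = edges,
    peakToGene = split(edges$gene, factor(edges$peak, levels = unique(edges$peak))),
    geneToPeak = split(edges$peak, factor(edges$gene, levels = unique(edges$gene))),
    unmapped = setdiff(ids, edges$peak),
    window = window), class = "PeakGeneMap")
}

#' @export
print.PeakGeneMap <- function(x, ...) {
  cat(sprintf("PeakGeneMap: %d peak-gene edge(s), %d unmapped peak(s), window %d bp\n",
              nrow(x$edges), length(x$unmapped), as.integer(x$window)))
  invisible(x)
}

## shared worker: fractions of `colLabels` within each row's gene set
.rowFractions <- function(rows, cols, rowGenes, geneLabel) {
  frac <- matrix(NA_real_, nrow = length(rows), ncol = length(cols),
                 dimnames = list(rows, cols))
  denom <- integer(length(rows))
  for (i in seq_along(rows)) {
    genes <- rowGenes[[i]]
    denom[i] <- length(genes)
    if (length(genes)) {
      tab <- table(factor(geneLabel[genes], levels = cols))
      frac[i, ] <- as.numeric(tab) / length(genes)
    }
  }
  new("CompositionTable", fractions = frac, denominators = denom)
}

#' Expression-group composition of each accessibility class
#'
#' For every accessibility-dynamics class, collects the genes reached from
#' its peaks through the TSS-window map, intersects them with the
#' differentially expressed genes (the three dynamic groups; set
#' `denominator = "all"` to add `Unchanged` as a fourth slice), and reports
#' the per-group fractions with the gene denominator. Classes with no
#' mapped (DE) genes are flagged undefined (denominator 0, `NA` fractions).
#'
#' @param cad A [CadResult][CadResult-class]; its locus ids must match the
#'   peak ids of `map`.
#' @param gep Named factor of gene groups from [classifyGep()].
#' @param map A `PeakGeneMap` from [mapPeaksToGenes()].
#' @param denominator `"de"` (default: Group1-3 only) or `"all"`.
#' @return A [CompositionTable][CompositionTable-class], rows = CAD classes,
#'   columns = expression groups.
#' @export
compositionForward <- function(cad, gep, map,
                               denominator = c("de", "all")) {
  denominator <- match.arg(denominator)
  cols <- if (denominator == "de") gepLevels()[1:3] else gepLevels()
  lab <- cadLabels(cad)
  rows <- levels(lab)
  byClass <- split(names(lab), lab)
  rowGenes <- lapply(rows, function(cl) {
    pk <- byClass[[cl]]
    genes <- unique(map$edges$gene[map$edges$peak %in% pk])
    genes <- genes[genes %in% names(gep)]
    genes[as.character(gep[genes]) %in% cols]
  })
  .rowFractions(rows, cols, rowGenes, gep)
}

#' Accessibility-class composition of each expression group
#'
#' The mirror of [compositionForward()]: rows are expression groups, columns
#' accessibility classes. A gene contributes to every class that has at
#' least one peak mapped to it -- once per class in `"multi"` mode (default)
#' or `1/n_classes` in `"fractional"` mode; rows are normalized to sum to 1
#' either way.
#'
#' @param gep Named factor of gene groups from [classifyGep()].
#' @param cad A [CadResult][CadResult-class].
#' @param map A `PeakGeneMap` from [mapPeaksToGenes()].
#' @param mode `"multi"` or `"fractional"` counting for multi-class genes.
#' @param rows Which expression groups form the rows (default the three
#'   dynamic groups).
#' @return A [CompositionTable][CompositionTable-class]; denominators count
#'   the mapped genes per group.
#' @export
compositionReverse <- function(gep, cad, map,
                               mode = c("multi", "fractional"),
                               rows = gepLevels()[1:3]) {
  mode <- match.arg(mode)
  lab <- cadLabels(cad)
  cols <- levels(lab)
  geneClasses <- lapply(map$geneToPeak, function(pk)
    unique(as.character(lab[pk])))
  frac <- matrix(NA_real_, nrow = length(rows), ncol = length(cols),
                 dimnames = list(rows, cols))
  denom <- integer(length(rows))
  for (i in seq_along(rows)) {
    genes <- names(gep)[as.character(gep) == rows[i]]
    genes <- intersect(genes, names(geneClasses))
    denom[i] <- length(genes)
    if (!length(genes)) next
    w <- numeric(length(cols))
    names(w) <- cols
    for (g in genes) {
      cls <- geneClasses[[g]]
      add <- if (mode == "multi") 1 else 1 / length(cls)
      w[cls] <- w[cls] + add
    }
    frac[i, ] <- w / sum(w)
  }
  new("CompositionTable", fractions = frac, denominators = denom)
}
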