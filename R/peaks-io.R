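## BED / narrowPeak reading and writing. Intentionally a small strict parser:
## the contract requires line-numbered parse errors, track/browser/# skipping
## and a byte-identical BED3 round-trip, with transparent gzip input.

#' Locus identifiers in `chrom:start-end` form
#'
#' Identifiers use the on-disk 0-based half-open coordinates, so they match
#' the rows of signal matrices keyed the same way.
#'
#' @param gr A [GenomicRanges::GRanges].
#' @return Character vector, one id per range.
#' @examples
#' locusId(GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200)))
#' @export
locusId <- function(gr) {
  sprintf("%s:%d-%d", as.character(seqnames(gr)),
          BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr))
}

#' @rdname locusId
#' @param ids Character ids in `chrom:start-end` form (0-based half-open).
#' @return `lociFromIds` returns the corresponding `GRanges`.
#' @export
lociFromIds <- function(ids) {
  m <- regmatches(ids, regexec("^(.*):([0-9]+)-([0-9]+)$", ids))
  bad <- which(lengths(m) != 4L)
  if (length(bad))
    stop("not a locus id (chrom:start-end): ", ids[bad[1]])
  chrom <- vapply(m, `[`, character(1), 2)
  start0 <- as.numeric(vapply(m, `[`, character(1), 3))
  end0 <- as.numeric(vapply(m, `[`, character(1), 4))
  GRanges(chrom, IRanges(start0 + 1, end0))
}

## lexicographic (C-locale) chromosome order, ties by (start, end)
.sortPeaks <- function(gr) {
  lev <- sort(unique(as.character(seqnames(gr))), method = "radix")
  GenomeInfoDb::seqlevels(gr) <- lev
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}

#' Read a BED or narrowPeak file into a sorted peak set
#'
#' Reads BED3/BED6 or ENCODE narrowPeak (10 columns) into a
#' [GenomicRanges::GRanges] with 0-based half-open file coordinates converted
#' to the usual 1-based closed GRanges convention. Lines starting with
#' `track`, `browser` or `#` are skipped; gzip-compressed input is accepted
#' transparently. The result is sorted lexicographically by chromosome name,
#' then by (start, end).
#'
#' @param path File path (plain or `.gz`).
#' @param format `"auto"` (by extension), `"bed"` or `"narrowPeak"`.
#' @return A sorted `GRanges`; BED name/score and narrowPeak statistics land
#'   in `mcols()`.
#' @seealso [writePeaks()], [mergePeaks()]
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200", "chr1\t50\t80"), f)
#' readPeaks(f)
#' @export
readPeaks <- function(path, format = c("auto", "bed", "narrowPeak")) {
  format <- match.arg(format)
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("peak file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.narrowpeak(\\.gz)?$", path, ignore.case = TRUE))
      "narrowPeak" else "bed"
  }
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- nzchar(lines) & !grepl("^(track|browser|#)", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (format == "narrowPeak") {
    bad <- which(nf != 10L)
    if (length(bad))
      stop(sprintf("parse error at line %d of %s: narrowPeak needs 10 columns, found %d",
                   lineNo[bad[1]], path, nf[bad[1]]))
  } else if (any(nf < 3L)) {
    bad <- which(nf < 3L)
    stop(sprintf("parse error at line %d of %s: fewer than 3 tab-separated columns",
                 lineNo[bad[1]], path))
  }
  col <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, character(1))
  chrom <- col(1)
  start0 <- suppressWarnings(as.numeric(col(2)))
  end0 <- suppressWarnings(as.numeric(col(3)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: non-numeric coordinate",
                 lineNo[bad[1]], path))
  bad <- which(start0 < 0)
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: negative start coordinate",
                 lineNo[bad[1]], path))
  bad <- which(end0 <= start0)
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: end <= start",
                 lineNo[bad[1]], path))
  if (any(!nzchar(chrom)))
    stop(sprintf("parse error at line %d of %s: empty chromosome name",
                 lineNo[which(!nzchar(chrom))[1]], path))
  gr <- GRanges(chrom, IRanges(start0 + 1, end0))
  nmax <- max(nf)
  if (nmax >= 4L) {
    nm <- col(4)
    if (any(!is.na(nm))) mcols(gr)$name <- nm
  }
  if (nmax >= 5L) {
    sc <- suppressWarnings(as.numeric(col(5)))
    if (any(!is.na(sc))) mcols(gr)$score <- sc
  }
  if (nmax >= 6L) {
    st <- col(6)
    st[!st %in% c("+", "-")] <- "*"
    strand(gr) <- st
  }
  if (format == "narrowPeak") {
    mcols(gr)$signalValue <- suppressWarnings(as.numeric(col(7)))
    mcols(gr)$pValue <- suppressWarnings(as.numeric(col(8)))
    mcols(gr)$qValue <- suppressWarnings(as.numeric(col(9)))
    mcols(gr)$peak <- suppressWarnings(as.integer(col(10)))
  }
  .sortPeaks(gr)
}

#' Write a peak set as BED
#'
#' Emits tab-separated BED in sorted order with 0-based half-open
#' coordinates and no header. With `name`/`score` metadata (or explicit
#' strand) present, BED6-compatible columns are written; otherwise BED3.
#' `writePeaks(readPeaks(f), f2)` reproduces a canonical sorted BED3 file
#' byte for byte.
#'
#' @param peaks A [GenomicRanges::GRanges].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writePeaks <- function(peaks, path) {
  gr <- .sortPeaks(peaks)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  hasName <- "name" %in% names(mcols(gr))
  hasScore <- "score" %in% names(mcols(gr))
  hasStrand <- any(as.character(strand(gr)) != "*")
  cols <- list(as.character(seqnames(gr)),
               formatC(BiocGenerics::start(gr) - 1L, format = "d"),
               formatC(BiocGenerics::end(gr), format = "d"))
  if (hasName || hasScore || hasStrand) {
    nm <- if (hasName) as.character(mcols(gr)$name) else rep(".", length(gr))
    nm[is.na(nm)] <- "."
    sc <- if (hasScore) as.character(mcols(gr)$score) else rep("0", length(gr))
    sc[is.na(sc)] <- "0"
    st <- as.character(strand(gr))
    st[st == "*"] <- "."
    cols <- c(cols, list(nm, sc, st))
  }
  out <- do.call(paste, c(cols, sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(out)) writeLines(out, con, sep = "\n")
  invisible(path)
}
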