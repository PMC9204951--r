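test_that("classifyGep applies the trajectory rules", {
  tpm <- rbind(flat = c(10, 10, 10, 10),
               gradual = c(10, 12, 14, 20),
               down = c(30, 20, 15, 10),
               immediate = c(10, 20, 30, 40))
  got <- classifyGep(tpm)
  expect_identical(as.character(got),
                   c("Unchanged", "Group1", "Group3", "Group2"))
  ## the down rule wins over the up rules; a single trajectory works too
  expect_identical(as.character(classifyGep(c(30, 60, 40, 10))), "Group3")
})

test_that("readTss handles TSV (with header) and minus-strand BED6", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\ttss\tstrand",
               "g1\tchr1\t30000\t+",
               "g2\tchr2\t500\t-"), f)
  tss <- readTss(f)
  expect_identical(S4Vectors::mcols(tss)$gene_id, c("g1", "g2"))
  expect_identical(BiocGenerics::start(tss), c(30001L, 501L))

  fb <- tempfile(fileext = ".bed")
  ## minus-strand gene body 1000-2000: TSS is the 3' end, 0-based 1999
  writeLines(c("chr1\t1000\t2000\tgneg\t0\t-",
               "chr1\t5000\t6000\tgpos\t0\t+"), fb)
  tssb <- readTss(fb)
  neg <- tssb[S4Vectors::mcols(tssb)$gene_id == "gneg"]
  pos <- tssb[S4Vectors::mcols(tssb)$gene_id == "gpos"]
  expect_identical(BiocGenerics::start(neg), 2000L)  # 1-based of 0-based 1999
  expect_identical(BiocGenerics::start(pos), 5001L)
})

test_that("TSS windows are inclusive with a half-open peak boundary", {
  tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(30001, width = 1),
                                strand = "+")
  S4Vectors::mcols(tss)$gene_id <- "g1"
  inPeak <- GenomicRanges::GRanges("chr1", IRanges::IRanges(29901, 30100))
  expect_identical(mapPeaksToGenes(inPeak, tss)$edges$gene, "g1")
  ## peak covering 0-based bases ...19999 misses a window starting at 20000
  outPeak <- GenomicRanges::GRanges("chr1", IRanges::IRanges(19501, 20000))
  m <- mapPeaksToGenes(outPeak, tss)
  expect_identical(nrow(m$edges), 0L)
  expect_identical(m$unmapped, locusId(outPeak))
  ## the base at exactly tss - window maps
  edgePeak <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20001, 20001))
  expect_identical(mapPeaksToGenes(edgePeak, tss)$edges$gene, "g1")
})

test_that("one peak maps to all genes whose windows it touches", {
  tss <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(10001, 15001), width = 1),
                                strand = "+")
  S4Vectors::mcols(tss)$gene_id <- c("g1", "g2")
  peak <- GenomicRanges::GRanges("chr1", IRanges::IRanges(12001, 12200))
  m <- mapPeaksToGenes(peak, tss)
  expect_setequal(m$edges$gene, c("g1", "g2"))
  ## mapping symmetry between the two directions
  expect_true(all(vapply(seq_len(nrow(m$edges)), function(i)
    m$edges$peak[i] %in% m$geneToPeak[[m$edges$gene[i]]] &&
      m$edges$gene[i] %in% m$peakToGene[[m$edges$peak[i]]], logical(1))))
})

test_that("enlarging the window never removes a peak-gene edge", {
  set.seed(23)
  peaks <- grFromDf(randIntervalDf(50, chromLen = 2e5, maxWidth = 800))
  tss <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(sort(sample(2e5, 30)),
                                                 width = 1),
                                strand = "+")
  S4Vectors::mcols(tss)$gene_id <- sprintf("g%02d", 1:30)
  prev <- NULL
  for (w in c(1000, 5000, 10000, 20000)) {
    edges <- mapPeaksToGenes(peaks, tss, window = w)$edges
    key <- paste(edges$peak, edges$gene)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

toyIntegration <- function() {
  ## three loci with classes CO1, CO1, OC1; genes g1:G1 g2:G1 g3:G3 g4:Unch
  loci <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(1, 50001, 100001),
                                                  width = 200))
  st <- rbind(c(0, 1, 1, 1), c(0, 1, 1, 1), c(1, 0, 0, 0))
  rownames(st) <- locusId(loci)
  cad <- classifyCad(st, loci = loci)
  tss <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(101, 151, 50101, 100101),
                                                 width = 1),
                                strand = "+")
  S4Vectors::mcols(tss)$gene_id <- c("g1", "g2", "g3", "g4")
  gep <- factor(c(g1 = "Group1", g2 = "Group1", g3 = "Group3",
                  g4 = "Unchanged"), levels = gepLevels())
  map <- mapPeaksToGenes(cadLoci(cad), tss, window = 10000)
  list(cad = cad, gep = gep, map = map)
}

test_that("compositionForward reports hand-enumerated fractions", {
  toy <- toyIntegration()
  ct <- compositionForward(toy$cad, toy$gep, toy$map)
  fr <- compositionFractions(ct)
  dn <- compositionDenominators(ct)
  ## CO1 reaches g1,g2 (Group1) and g3 (Group1? no: g3 is Group3, near locus 2)
  expect_equal(unname(fr["CO1", ]), c(2 / 3, 0, 1 / 3))
  expect_identical(unname(dn["CO1"]), 3L)
  ## OC1 reaches only g4 (Unchanged), excluded from the DE denominator
  expect_identical(unname(dn["OC1"]), 0L)
  expect_true(all(is.na(fr["OC1", ])))
  ## with denominator = "all" the OC1 row is defined and all Unchanged
  ctAll <- compositionForward(toy$cad, toy$gep, toy$map,
                              denominator = "all")
  expect_equal(unname(compositionFractions(ctAll)["OC1", ]), c(0, 0, 0, 1))
  ## nonempty rows sum to 1
  rs <- rowSums(fr)
  expect_true(all(abs(rs[dn > 0] - 1) < 1e-9))
})

test_that("compositionReverse matches exhaustive enumeration", {
  toy <- toyIntegration()
  ct <- compositionReverse(toy$gep, toy$cad, toy$map)
  fr <- compositionFractions(ct)
  expect_equal(unname(fr["Group1", "CO1"]), 1)  # g1,g2 only near CO1 loci
  expect_equal(unname(fr["Group3", "CO1"]), 1)  # g3 near the second CO1 locus
  expect_identical(unname(compositionDenominators(ct)["Group1"]), 2L)

  ## randomized instance against a brute-force loop, both counting modes
  set.seed(5)
  loci <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(seq(1, by = 30000,
                                                      length.out = 12),
                                                  width = 500))
  st <- cbind(rbinom(12, 1, 0.5), rbinom(12, 1, 0.5),
              rbinom(12, 1, 0.5), rbinom(12, 1, 0.5))
  rownames(st) <- locusId(loci)
  cad <- classifyCad(st, matrix(rlnorm(48, 2, 1), 12, 4), loci = loci)
  tss <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(sample(36e4, 20), width = 1),
                                strand = "+")
  S4Vectors::mcols(tss)$gene_id <- sprintf("g%02d", 1:20)
  gep <- stats::setNames(factor(sample(gepLevels(), 20, replace = TRUE),
                                levels = gepLevels()),
                         S4Vectors::mcols(tss)$gene_id)
  map <- mapPeaksToGenes(cadLoci(cad), tss)
  for (mode in c("multi", "fractional")) {
    ct <- compositionReverse(gep, cad, map, mode = mode)
    fr <- compositionFractions(ct)
    lab <- cadLabels(cad)
    for (g1 in gepLevels()[1:3]) {
      genes <- intersect(names(gep)[gep == g1], names(map$geneToPeak))
      w <- stats::setNames(numeric(length(levels(lab))), levels(lab))
      for (g in genes) {
        cls <- unique(as.character(lab[map$geneToPeak[[g]]]))
        w[cls] <- w[cls] + if (mode == "multi") 1 else 1 / length(cls)
      }
      if (length(genes))
        expect_equal(unname(fr[g1, ]), unname(w / sum(w)))
      else expect_true(all(is.na(fr[g1, ])))
    }
  }
})
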