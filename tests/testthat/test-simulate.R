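smallParams <- function(seed = 1, ...) {
  simParams(seed = seed, nLoci = 300, nGenes = 150,
            ipms = list(nProteins = 120, nTrue = 12, nShared = 3), ...)
}

test_that("identical parameters give byte-identical outputs", {
  d1 <- tempfile(); d2 <- tempfile()
  simulateAll(smallParams(seed = 4), outdir = d1)
  simulateAll(smallParams(seed = 4), outdir = d2)
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readBin(f1[i], "raw", file.size(f1[i])),
                     readBin(f2[i], "raw", file.size(f2[i])),
                     info = basename(f1[i]))
  ## a different seed changes the data
  d3 <- tempfile()
  simulateAll(smallParams(seed = 5), outdir = d3)
  sig1 <- readLines(file.path(d1, "atac_signal.tsv"))
  sig3 <- readLines(file.path(d3, "atac_signal.tsv"))
  expect_false(identical(sig1, sig3))
})

test_that("annotation places non-overlapping loci and respects coupling", {
  p <- smallParams(seed = 8, coupling = 1)
  ann <- simulateAnnotation(p)
  expect_identical(length(ann$loci), 300L)
  expect_identical(length(unique(names(ann$loci))), 300L)
  red <- IRanges::reduce(ann$loci)
  expect_identical(length(red), length(ann$loci))   # no overlaps
  ## coupling 1: every gene within 10 kb of >= 1 locus
  win <- GenomicRanges::resize(ann$tss, width = 20001, fix = "center")
  expect_true(all(IRanges::overlapsAny(win, ann$loci)))

  ## coupling 0: near-locus rate matches the uniform expectation within 3 SE
  p0 <- simParams(seed = 8, nLoci = 300, nGenes = 4000, coupling = 0)
  ann0 <- simulateAnnotation(p0)
  win0 <- GenomicRanges::resize(ann0$tss, width = 20001, fix = "center")
  hitRate <- mean(IRanges::overlapsAny(win0, ann0$loci))
  covered <- sum(BiocGenerics::width(IRanges::reduce(
    GenomicRanges::resize(ann0$loci, width = BiocGenerics::width(ann0$loci) +
                            20000, fix = "center"))))
  pExp <- covered / sum(p0$chromSizes)
  se3 <- 3 * sqrt(pExp * (1 - pExp) / 4000)
  expect_lt(abs(hitRate - pExp), se3 + 0.01)
})

test_that("noise-free simulation is recovered perfectly by the classifiers", {
  p <- smallParams(seed = 6, pFlip = 0, sigmaSignal = 0, gepNoise = 0)
  ann <- simulateAnnotation(p)
  atac <- simulateAtac(ann, p)
  res <- classifyCad(atac$states, atac$signal)
  expect_identical(as.character(cadLabels(res)), as.character(atac$truth))
  ## the same recovery through presence flags on the emitted peak sets
  open <- rowSums(atac$states) > 0
  cp <- consensusPeaks(atac$peakSets)
  flags <- occupancyFlags(cp, atac$peakSets,
                          timepoints = p$timepoints)
  expect_identical(sort(rownames(flags)), sort(names(ann$loci)[open]))
  sig <- atac$signal[rownames(flags), ]
  res2 <- classifyCad(flags, sig)
  expect_identical(as.character(cadLabels(res2)),
                   as.character(atac$truth)[match(rownames(flags),
                                                  names(ann$loci))])
  ## expression recovery
  expr <- simulateExpression(ann, p)
  expect_identical(as.character(classifyGep(expr$tpm)),
                   as.character(expr$truth))
})

test_that("degenerate class proportions produce the planted pattern", {
  p <- simParams(seed = 2, nLoci = 50, nGenes = 10, pFlip = 0,
                 classProportions = c(CO1 = 1))
  ann <- simulateAnnotation(p)
  atac <- simulateAtac(ann, p)
  expect_identical(length(atac$peakSets[["0h"]]), 0L)
  expect_identical(length(atac$peakSets[["4h"]]), 50L)
  expect_identical(length(atac$peakSets[["12h"]]), 50L)
})

test_that("chip relocation follows the planted occupancy model", {
  ## deterministic extreme: background 0, full binding probabilities
  p <- smallParams(seed = 9, pBindClosing = 1, pBindOpening = 1,
                   pBackground = 0, markOverlap = c(m1 = 1))
  ann <- simulateAnnotation(p)
  chip <- simulateChip(ann, p)
  cls <- as.character(S4Vectors::mcols(ann$loci)$class)
  expect_identical(length(chip$t0), sum(cls %in% c("OC1", "OC2", "OC3", "POD")))
  expect_identical(length(chip$t1), sum(cls %in% c("CO1", "CO2", "CO3", "POU")))
  ## closing and opening classes are disjoint loci -> nothing retained
  rc <- relocationCounts(bindingDynamics(chip$t0, chip$t1))
  expect_identical(rc[["retained"]], 0L)
  ## a mark with overlap probability 1 and background 0 equals the factor set
  expect_identical(locusId(chip$marks$m1), locusId(chip$t1))
  co <- cooccupancyCounts(chip$t1, chip$marks)
  expect_identical(co$shared[1], length(mergePeaks(chip$t1)))

  ## planted relocation rate: gained/(gained+retained) near its expectation
  p2 <- simParams(seed = 10, nLoci = 2000, nGenes = 10)
  ann2 <- simulateAnnotation(p2)
  chip2 <- simulateChip(ann2, p2)
  rc2 <- relocationCounts(bindingDynamics(chip2$t0, chip2$t1))
  gainedFrac <- rc2[["gained"]] / (rc2[["gained"]] + rc2[["retained"]])
  cls2 <- as.character(S4Vectors::mcols(ann2$loci)$class)
  pT1 <- ifelse(cls2 %in% c("CO1", "CO2", "CO3", "POU"),
                p2$pBindOpening, p2$pBackground)
  pT0 <- ifelse(cls2 %in% c("OC1", "OC2", "OC3", "POD"),
                p2$pBindClosing, p2$pBackground)
  expGained <- sum(pT1 * (1 - pT0)) / sum(pT1)
  se3 <- 3 * sqrt(expGained * (1 - expGained) / sum(pT1))
  expect_lt(abs(gainedFrac - expGained), se3 + 0.01)
})

test_that("ipms simulation plants recoverable interactors", {
  p <- smallParams(seed = 12)
  p$ipms$sigma <- 0.01
  p$ipms$missingRate <- 0
  sim <- simulateIpms(p)
  for (b in p$ipms$baits) {
    se <- preprocessIntensities(sim[[b]]$intensities, sim[[b]]$samples)
    calls <- testInteractors(se, "IP", "ctrl")
    expect_setequal(interactors(calls), sim[[b]]$truth)
  }
  ## the planted cross-bait overlap is exactly recovered
  expect_identical(length(sim$shared), 3L)
  got <- sharedInteractors(sim[[p$ipms$baits[1]]]$truth,
                           sim[[p$ipms$baits[2]]]$truth)
  expect_setequal(got, sim$shared)
})

test_that("simulation truth files are consistent with the emitted data", {
  d <- tempfile()
  sim <- simulateAll(smallParams(seed = 20, pFlip = 0, sigmaSignal = 0),
                     outdir = d)
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(unname(truth$cad), as.character(sim$atac$truth))
  ## re-derive labels from the emitted files at zero noise
  sigDf <- read.delim(file.path(d, "atac_signal.tsv"), check.names = FALSE)
  sig <- as.matrix(sigDf[, -1]); rownames(sig) <- sigDf[[1]]
  states <- binarizeSignal(sig, tau = 5)
  res <- classifyCad(states, sig)
  expect_identical(as.character(cadLabels(res)), unname(truth$cad))
})
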