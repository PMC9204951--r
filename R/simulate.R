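## Seeded synthetic-data generator. Emulates the statistical structure of a
## 4-timepoint accessibility timecourse with nine trajectory archetypes,
## expression trajectories coupled to nearby accessibility classes, factor
## occupancy redistributing from closing to opening loci, and 3-replicate
## log-normal IP-MS intensities with planted interactors. Every stage draws
## from its own named substream derived from the master seed, so stages can
## be regenerated independently and identically.

.STAGE_OFFSETS <- c(annotation = 101L, atac = 202L, expression = 303L,
                    chip = 404L, ipms = 505L)

.stageSeed <- function(params, stage) {
  off <- .STAGE_OFFSETS[[stage]]
  as.integer((as.numeric(params$seed) * 1009 + off) %% 2147483647)
}

.UP_CLASSES <- c("CO1", "CO2", "CO3", "POU")
.DOWN_CLASSES <- c("OC1", "OC2", "OC3", "POD")

#' Parameters of the synthetic-data generator
#'
#' One validated parameter list drives every simulation stage. The defaults
#' describe the emulated study design: four timepoints (0/4/8/12 h), 5,000
#' accessibility loci of 200-1,000 bp on a 50 Mb pseudo-chromosome with
#' class proportions echoing the study's relative class sizes (the first
#' closed-to-open wave much larger than the rest), log-normal open/closed
#' signals, 2,000 genes whose expression groups couple to nearby
#' accessibility classes, factor occupancy moving from closing loci at 0 h
#' to opening loci at 8 h, and two-bait 3v3 log-normal IP-MS with 50
#' planted interactors per bait, three of them shared between baits.
#'
#' @param seed Master seed; each stage derives its own substream from it.
#' @param chromSizes Named vector of pseudo-chromosome lengths (bp).
#' @param nLoci,locusWidth Number of non-overlapping loci and their width
#'   range (bp).
#' @param classProportions Named proportions over the nine trajectory
#'   classes (must sum to 1).
#' @param timepoints Strictly increasing hours (>= 2).
#' @param muOpen,muClosed,sigmaSignal Log-scale means of the open/closed
#'   signal and the log-normal noise sd.
#' @param poTrend Last/first signal ratio planted in POU (and 1/ratio in
#'   POD) loci.
#' @param pFlip Per-flag open/closed flip probability (observation noise on
#'   the binary states).
#' @param tau Open threshold used when binarizing signals.
#' @param nGenes,coupling,gepProportions Gene count, probability that a
#'   gene's TSS (and its expression group) follows a nearby locus class,
#'   and the background group proportions.
#' @param gepNoise,gepScaleSd Multiplicative log-normal noise on TPM values
#'   and the sd of the per-gene log expression scale.
#' @param pBindClosing,pBindOpening,pBackground Occupancy probabilities of
#'   the factor at t0 (closing classes), t1 (opening classes) and
#'   elsewhere.
#' @param markOverlap Named per-mark probabilities of occupying a
#'   factor-bound locus at t1 (background elsewhere).
#' @param ipms List: `nProteins`, `nTrue`, `nShared`, `log2fc`, `sigma`,
#'   `missingRate`, `nReplicates`, `baseMean`, `baseSd`, `baits`.
#' @return A validated list of class `SimParams`.
#' @examples
#' p <- simParams(seed = 7, nLoci = 100, nGenes = 50)
#' @export
simParams <- function(seed = 1,
                      chromSizes = c(chrS = 5e7),
                      nLoci = 5000,
                      locusWidth = c(200, 1000),
                      classProportions = c(CO1 = 0.28, CO2 = 0.06,
                                           CO3 = 0.02, OC1 = 0.05,
                                           OC2 = 0.05, OC3 = 0.05,
                                           POU = 0.13, POD = 0.18,
                                           PON = 0.18),
                      timepoints = c(0, 4, 8, 12),
                      muOpen = log(50), muClosed = log(2),
                      sigmaSignal = 0.3, poTrend = 4,
                      pFlip = 0.02, tau = 5,
                      nGenes = 2000, coupling = 0.8,
                      gepProportions = c(Group1 = 0.2, Group2 = 0.15,
                                         Group3 = 0.15, Unchanged = 0.5),
                      gepNoise = 0.1, gepScaleSd = 0.5,
                      pBindClosing = 0.8, pBindOpening = 0.8,
                      pBackground = 0.05,
                      markOverlap = c(H3K27ac = 0.85, H3K4me1 = 0.5,
                                      H3K27me3 = 0.05),
                      ipms = list()) {
  ipmsDefaults <- list(nProteins = 1000, nTrue = 50, nShared = 3,
                       log2fc = 2, sigma = 0.3, missingRate = 0.1,
                       nReplicates = 3, baseMean = 25, baseSd = 2,
                       baits = c("JUN", "SS18"))
  ipms <- utils::modifyList(ipmsDefaults, ipms)
  p <- list(seed = seed, chromSizes = chromSizes, nLoci = nLoci,
            locusWidth = locusWidth, classProportions = classProportions,
            timepoints = timepoints, muOpen = muOpen, muClosed = muClosed,
            sigmaSignal = sigmaSignal, poTrend = poTrend, pFlip = pFlip,
            tau = tau, nGenes = nGenes, coupling = coupling,
            gepProportions = gepProportions, gepNoise = gepNoise,
            gepScaleSd = gepScaleSd, pBindClosing = pBindClosing,
            pBindOpening = pBindOpening, pBackground = pBackground,
            markOverlap = markOverlap, ipms = ipms)
  k <- length(p$timepoints)
  stopifnot(k >= 2, all(diff(p$timepoints) > 0),
            all(p$chromSizes > 0), p$nLoci >= 1,
            length(p$locusWidth) == 2, p$locusWidth[1] >= 1,
            p$locusWidth[2] >= p$locusWidth[1])
  if (abs(sum(p$classProportions) - 1) > 1e-6)
    stop("classProportions must sum to 1")
  need <- c(paste0("CO", seq_len(k - 1)), paste0("OC", seq_len(k - 1)),
            "POU", "POD", "PON")
  if (!all(names(p$classProportions) %in% need))
    stop("classProportions names must be among: ",
         paste(need, collapse = ", "))
  probs <- c(p$pFlip, p$coupling, p$pBindClosing, p$pBindOpening,
             p$pBackground, p$markOverlap, p$ipms$missingRate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  stopifnot(p$sigmaSignal >= 0, p$gepNoise >= 0, p$poTrend > 1,
            p$tau > 0, abs(sum(p$gepProportions) - 1) < 1e-6,
            identical(names(p$gepProportions), gepLevels()))
  with(p$ipms, stopifnot(nTrue <= nProteins, nShared <= nTrue,
                         nReplicates >= 2, sigma >= 0,
                         length(baits) >= 1))
  structure(p, class = "SimParams")
}

#' Simulate the genome annotation: loci and TSS table
#'
#' Places `nLoci` non-overlapping loci pseudo-uniformly (one per equal-width
#' slot, jittered within the slot), assigns each its planted
#' accessibility-dynamics class, and places each gene's TSS within 10 kb of
#' a randomly chosen locus with probability `coupling`, uniformly
#' otherwise. Fully reproducible under the master seed.
#'
#' @param params A [simParams()] object.
#' @return List: `loci` ([GenomicRanges::GRanges] with planted `class`),
#'   `tss` (width-1 `GRanges` with `gene_id` and the coupled locus index,
#'   `NA` for uncoupled genes).
#' @export
simulateAnnotation <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  set.seed(.stageSeed(params, "annotation"))
  sizes <- params$chromSizes
  nPer <- round(params$nLoci * sizes / sum(sizes))
  nPer[length(nPer)] <- params$nLoci - sum(nPer[-length(nPer)])
  lociList <- vector("list", length(sizes))
  for (ci in seq_along(sizes)) {
    n <- nPer[ci]
    if (n == 0) { lociList[[ci]] <- GRanges(); next }
    slot <- floor(sizes[ci] / n)
    if (slot <= params$locusWidth[2] + 1)
      stop("nLoci too large for the genome: slots of ", slot,
           " bp cannot hold loci up to ", params$locusWidth[2], " bp")
    w <- round(runif(n, params$locusWidth[1], params$locusWidth[2]))
    off <- floor(runif(n, 0, slot - w))
    start0 <- (seq_len(n) - 1) * slot + off
    lociList[[ci]] <- GRanges(names(sizes)[ci],
                              IRanges(start0 + 1, width = w))
  }
  loci <- do.call(c, lociList)
  mcols(loci)$class <- factor(
    sample(names(params$classProportions), length(loci), replace = TRUE,
           prob = params$classProportions),
    levels = cadLevels(length(params$timepoints)))
  names(loci) <- locusId(loci)

  nG <- params$nGenes
  coupled <- runif(nG) < params$coupling
  lociIdx <- sample.int(length(loci), nG, replace = TRUE)
  tss0 <- numeric(nG)
  chrom <- character(nG)
  for (g in seq_len(nG)) {
    if (coupled[g]) {
      i <- lociIdx[g]
      lo <- max(0, BiocGenerics::start(loci)[i] - 1 - 9000)
      hi <- BiocGenerics::end(loci)[i] + 9000
      chrom[g] <- as.character(seqnames(loci)[i])
      tss0[g] <- floor(runif(1, lo, min(hi, sizes[[chrom[g]]] - 1) + 1))
    } else {
      chrom[g] <- sample(names(sizes), 1, prob = sizes)
      tss0[g] <- floor(runif(1, 0, sizes[[chrom[g]]]))
    }
  }
  tss <- GRanges(chrom, IRanges(tss0 + 1, width = 1),
                 strand = sample(c("+", "-"), nG, replace = TRUE))
  mcols(tss)$gene_id <- sprintf("gene%05d", seq_len(nG))
  mcols(tss)$coupledLocus <- ifelse(coupled, lociIdx, NA_integer_)
  list(loci = loci, tss = tss)
}

## class -> binary template matrix (classes x timepoints)
.classTemplates <- function(classes, k) {
  tmpl <- .cadTemplates(k)
  keyOf <- stats::setNames(names(tmpl), tmpl)
  keyOf[c("POU", "POD", "PON")] <- strrep("1", k)
  keyOf["OTHER"] <- NA
  t(vapply(classes, function(cl) {
    as.integer(strsplit(keyOf[[cl]], "")[[1]])
  }, integer(k)))
}

#' Simulate the accessibility timecourse from planted classes
#'
#' Each locus's binary trajectory is its class template with per-flag flip
#' probability `pFlip`; its signal at timepoint t is log-normal around the
#' open or closed level given the (possibly flipped) state, with a planted
#' monotone trend of total ratio `poTrend` for POU loci (inverse for POD).
#' A locus appears in the timepoint-t peak set iff its state at t is open.
#'
#' @param annotation Output of [simulateAnnotation()].
#' @param params A [simParams()] object.
#' @return List: `states` and `signal` (loci x timepoints matrices,
#'   rownames = locus ids), `peakSets` (named list of per-timepoint
#'   `GRanges`), `truth` (planted class factor).
#' @export
simulateAtac <- function(annotation, params) {
  stopifnot(inherits(params, "SimParams"))
  set.seed(.stageSeed(params, "atac"))
  loci <- annotation$loci
  classes <- as.character(mcols(loci)$class)
  n <- length(loci)
  k <- length(params$timepoints)
  state <- .classTemplates(classes, k)
  flip <- matrix(runif(n * k) < params$pFlip, n, k)
  state <- (state + flip) %% 2L
  trend <- matrix(0, n, k)
  ramp <- seq(0, log(params$poTrend), length.out = k)
  nUp <- sum(classes == "POU"); nDn <- sum(classes == "POD")
  if (nUp) trend[classes == "POU", ] <- matrix(ramp, nUp, k, byrow = TRUE)
  if (nDn) trend[classes == "POD", ] <- matrix(-ramp, nDn, k, byrow = TRUE)
  mu <- ifelse(state == 1, params$muOpen + trend, params$muClosed)
  signal <- exp(mu + matrix(rnorm(n * k, 0, params$sigmaSignal), n, k))
  cn <- sprintf("%gh", params$timepoints)
  dimnames(state) <- dimnames(signal) <- list(names(loci), cn)
  peakSets <- lapply(seq_len(k), function(t) granges(loci[state[, t] == 1]))
  names(peakSets) <- cn
  list(states = state, signal = signal, peakSets = peakSets,
       truth = mcols(loci)$class)
}

## genes' planted expression groups given proximity to classed loci
.planGeneGroups <- function(annotation, params) {
  tss <- annotation$tss
  loci <- annotation$loci
  nG <- length(tss)
  near <- rep(NA_integer_, nG)
  ci <- mcols(tss)$coupledLocus
  near[!is.na(ci)] <- ci[!is.na(ci)]
  ## uncoupled genes may still land near a locus by chance
  win <- GRanges(seqnames(tss),
                 IRanges(pmax(BiocGenerics::start(tss) - 10000, 1),
                         BiocGenerics::start(tss) + 10000))
  hits <- IRanges::findOverlaps(win, loci, ignore.strand = TRUE)
  first <- !duplicated(queryHits(hits))
  idx <- queryHits(hits)[first]
  repl <- subjectHits(hits)[first]
  fill <- is.na(near[idx])
  near[idx[fill]] <- repl[fill]
  nearClass <- rep(NA_character_, nG)
  nearClass[!is.na(near)] <- as.character(mcols(loci)$class)[near[!is.na(near)]]
  follow <- runif(nG) < params$coupling
  grp <- character(nG)
  up <- !is.na(nearClass) & nearClass %in% .UP_CLASSES & follow
  dn <- !is.na(nearClass) & nearClass %in% .DOWN_CLASSES & follow
  grp[up] <- sample(c("Group1", "Group2"), sum(up), replace = TRUE)
  grp[dn] <- "Group3"
  rest <- !nzchar(grp)
  grp[rest] <- sample(names(params$gepProportions), sum(rest),
                      replace = TRUE, prob = params$gepProportions)
  factor(grp, levels = gepLevels())
}

#' Simulate the expression timecourse coupled to accessibility classes
#'
#' Genes near closed-to-open or POU loci are drawn into the upregulated
#' groups with probability `coupling` (near open-to-closed or POD loci,
#' into the downregulated group); all other genes follow the background
#' group proportions. TPM trajectories are the group templates scaled per
#' gene and perturbed with multiplicative log-normal noise.
#'
#' @param annotation Output of [simulateAnnotation()].
#' @param params A [simParams()] object.
#' @return List: `tpm` (genes x timepoints matrix), `truth` (planted group
#'   factor, named by gene).
#' @export
simulateExpression <- function(annotation, params) {
  stopifnot(inherits(params, "SimParams"))
  set.seed(.stageSeed(params, "expression"))
  k <- length(params$timepoints)
  tpl <- rbind(Group1 = c(10, 12, 18, 30)[seq_len(min(4, k))],
               Group2 = c(10, 25, 30, 35)[seq_len(min(4, k))],
               Group3 = c(30, 18, 12, 8)[seq_len(min(4, k))],
               Unchanged = c(10, 10.5, 10, 10.5)[seq_len(min(4, k))])
  if (k > 4)  # extend flatly past the canonical four timepoints
    tpl <- cbind(tpl, matrix(tpl[, 4], nrow(tpl), k - 4))
  grp <- .planGeneGroups(annotation, params)
  nG <- length(grp)
  scale <- exp(rnorm(nG, 0, params$gepScaleSd))
  noise <- matrix(exp(rnorm(nG * k, 0, params$gepNoise)), nG, k)
  tpm <- tpl[as.character(grp), , drop = FALSE] * scale * noise
  dimnames(tpm) <- list(mcols(annotation$tss)$gene_id,
                        sprintf("%gh", params$timepoints))
  names(grp) <- rownames(tpm)
  list(tpm = tpm, truth = grp)
}

#' Simulate factor occupancy relocation (and optional marks)
#'
#' The factor occupies a locus at t0 with probability `pBindClosing` if the
#' locus class is closing (OC or POD) and `pBackground` otherwise; at t1
#' with `pBindOpening` if the class is opening (CO or POU), `pBackground`
#' otherwise. Each mark occupies factor-bound t1 loci with its
#' `markOverlap` probability and other loci at background, so the planted
#' co-occupancy ranking follows the `markOverlap` order.
#'
#' @param annotation Output of [simulateAnnotation()].
#' @param params A [simParams()] object.
#' @return List: `t0`, `t1` (factor peak sets), `marks` (named list of mark
#'   peak sets), `boundT0`, `boundT1` (planted logical vectors).
#' @export
simulateChip <- function(annotation, params) {
  stopifnot(inherits(params, "SimParams"))
  set.seed(.stageSeed(params, "chip"))
  loci <- annotation$loci
  classes <- as.character(mcols(loci)$class)
  n <- length(loci)
  closing <- classes %in% .DOWN_CLASSES
  opening <- classes %in% .UP_CLASSES
  boundT0 <- runif(n) < ifelse(closing, params$pBindClosing,
                               params$pBackground)
  boundT1 <- runif(n) < ifelse(opening, params$pBindOpening,
                               params$pBackground)
  marks <- lapply(params$markOverlap, function(p) {
    bound <- runif(n) < ifelse(boundT1, p, params$pBackground)
    granges(loci[bound])
  })
  list(t0 = granges(loci[boundT0]), t1 = granges(loci[boundT1]),
       marks = marks, boundT0 = boundT0, boundT1 = boundT1)
}

#' Simulate label-free IP-MS intensity matrices with planted interactors
#'
#' For each bait, protein log2 intensities are normal around a per-protein
#' base level; planted interactors gain `log2fc` in the IP condition.
#' Entries go missing completely at random at `missingRate`, and matrices
#' are emitted on the linear intensity scale. Bait true-interactor sets
#' overlap in exactly `nShared` proteins.
#'
#' @param params A [simParams()] object.
#' @return Named list per bait: `intensities` (proteins x samples, linear
#'   scale), `samples` (sample sheet), `truth` (planted interactor ids);
#'   plus `shared` (the planted cross-bait overlap).
#' @export
simulateIpms <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  set.seed(.stageSeed(params, "ipms"))
  ip <- params$ipms
  prot <- sprintf("prot%05d", seq_len(ip$nProteins))
  baits <- ip$baits
  trueSets <- vector("list", length(baits))
  names(trueSets) <- baits
  trueSets[[1]] <- sample(prot, ip$nTrue)
  if (length(baits) > 1) {
    sharedSet <- sample(trueSets[[1]], ip$nShared)
    for (b in seq_along(baits)[-1]) {
      pool <- setdiff(prot, trueSets[[1]])
      trueSets[[b]] <- c(sharedSet,
                         sample(pool, ip$nTrue - ip$nShared))
    }
  } else {
    sharedSet <- character(0)
  }
  out <- list()
  for (b in baits) {
    nr <- ip$nReplicates
    cols <- c(sprintf("%s_IP_%d", b, seq_len(nr)),
              sprintf("%s_ctrl_%d", b, seq_len(nr)))
    base <- rnorm(ip$nProteins, ip$baseMean, ip$baseSd)
    log2x <- matrix(rnorm(ip$nProteins * 2 * nr, 0, ip$sigma),
                    ip$nProteins, 2 * nr) + base
    log2x[prot %in% trueSets[[b]], seq_len(nr)] <-
      log2x[prot %in% trueSets[[b]], seq_len(nr)] + ip$log2fc
    x <- 2^log2x
    x[matrix(runif(length(x)) < ip$missingRate, nrow(x))] <- NA
    dimnames(x) <- list(prot, cols)
    out[[b]] <- list(
      intensities = x,
      samples = data.frame(sample = cols,
                           condition = rep(c("IP", "ctrl"), each = nr),
                           replicate = rep(seq_len(nr), 2),
                           stringsAsFactors = FALSE),
      truth = sort(trueSets[[b]]))
  }
  out$shared <- sort(sharedSet)
  out
}

#' Run every simulation stage, optionally writing all pipeline inputs
#'
#' Chains [simulateAnnotation()], [simulateAtac()], [simulateExpression()],
#' [simulateChip()] and [simulateIpms()] under one master seed. With
#' `outdir` set, writes the files a real analysis would start from:
#' per-timepoint peak BEDs, the signal and TPM matrices (TSV), the TSS
#' table, factor/mark BEDs, per-bait intensity matrices and sample sheets,
#' and the planted ground truth as JSON. Identical parameters (including
#' the seed) give byte-identical files.
#'
#' @param params A [simParams()] object.
#' @param outdir Optional output directory.
#' @return Invisible list with all stage outputs (`annotation`, `atac`,
#'   `expression`, `chip`, `ipms`) and, when written, `files`.
#' @export
simulateAll <- function(params, outdir = NULL) {
  stopifnot(inherits(params, "SimParams"))
  ann <- simulateAnnotation(params)
  atac <- simulateAtac(ann, params)
  expr <- simulateExpression(ann, params)
  chip <- simulateChip(ann, params)
  ipms <- simulateIpms(params)
  out <- list(annotation = ann, atac = atac, expression = expr,
              chip = chip, ipms = ipms)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    wp <- function(gr, name) {
      f <- file.path(outdir, name); writePeaks(gr, f); f
    }
    for (t in names(atac$peakSets))
      files[paste0("atac_", t)] <- wp(atac$peakSets[[t]],
                                      sprintf("atac_%s.bed", t))
    sig <- data.frame(locus = rownames(atac$signal), atac$signal,
                      check.names = FALSE)
    f <- file.path(outdir, "atac_signal.tsv")
    write.table(sig, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["signal"] <- f
    tssDf <- data.frame(gene_id = mcols(ann$tss)$gene_id,
                        chrom = as.character(seqnames(ann$tss)),
                        tss = BiocGenerics::start(ann$tss) - 1L,
                        strand = as.character(strand(ann$tss)))
    f <- file.path(outdir, "tss.tsv")
    write.table(tssDf, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["tss"] <- f
    tpmDf <- data.frame(gene_id = rownames(expr$tpm), expr$tpm,
                        check.names = FALSE)
    f <- file.path(outdir, "expression_tpm.tsv")
    write.table(tpmDf, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["tpm"] <- f
    files["chip_t0"] <- wp(chip$t0, "chip_factor_0h.bed")
    files["chip_t1"] <- wp(chip$t1, "chip_factor_8h.bed")
    for (m in names(chip$marks))
      files[paste0("mark_", m)] <- wp(chip$marks[[m]],
                                      sprintf("chip_mark_%s.bed", m))
    for (b in params$ipms$baits) {
      xdf <- data.frame(protein = rownames(ipms[[b]]$intensities),
                        ipms[[b]]$intensities, check.names = FALSE)
      f <- file.path(outdir, sprintf("ipms_%s_intensities.tsv", b))
      write.table(xdf, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files[paste0("ipms_", b)] <- f
      f <- file.path(outdir, sprintf("ipms_%s_samples.tsv", b))
      write.table(ipms[[b]]$samples, f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files[paste0("ipms_samples_", b)] <- f
    }
    truth <- list(
      cad = stats::setNames(as.character(atac$truth),
                            names(ann$loci)),
      gep = stats::setNames(as.character(expr$truth),
                            names(expr$truth)),
      boundT0 = names(ann$loci)[chip$boundT0],
      boundT1 = names(ann$loci)[chip$boundT1],
      interactors = lapply(params$ipms$baits,
                           function(b) ipms[[b]]$truth),
      sharedInteractors = ipms$shared)
    names(truth$interactors) <- params$ipms$baits
    f <- file.path(outdir, "truth.json")
    jsonlite::write_json(truth, f, auto_unbox = FALSE, pretty = TRUE)
    files["truth"] <- f
    out$files <- files
  }
  invisible(out)
}
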