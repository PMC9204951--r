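## End-to-end pipeline: configuration, stage orchestration, fixed-name
## artifacts under a run directory, and a machine-readable report with
## internal-consistency checks. Deterministic by seed: the report carries a
## hash of the scientific configuration but no paths or timings, so a rerun
## with the same config reproduces report.json byte for byte.

#' Pipeline configuration
#'
#' Validates and assembles everything [runPipeline()] needs: either
#' `simulate = TRUE` with generator parameters, or paths to real inputs.
#' Thresholds are checked up front so a bad configuration fails before any
#' stage runs.
#'
#' @param outdir Run directory for the fixed-name artifacts.
#' @param seed Master seed (simulation and any stochastic step).
#' @param simulate Generate inputs with [simulateAll()] (default) instead
#'   of reading files.
#' @param sim Named list of [simParams()] overrides.
#' @param inputs For `simulate = FALSE`: named list of paths --
#'   `atacPeaks` (character vector, one BED per timepoint), `signal`,
#'   `tss`, `expression`, `chipT0`, `chipT1`, optionally `marks` (named
#'   vector of BEDs) and `ipms` (named list per bait:
#'   `list(intensities =, samples =)`).
#' @param timepoints Hours of the accessibility timecourse.
#' @param tau Open threshold for signal binarization (`stateMode =
#'   "signal"`).
#' @param fcPo Permanently-open subdivision fold change.
#' @param gepFc Expression-group fold change.
#' @param window TSS assignment window half-width (bp).
#' @param alpha,ipmsFc IP-MS significance and fold-change thresholds.
#' @param stateMode `"presence"` (peak called at t) or `"signal"`
#'   (binarize the signal matrix at `tau`).
#' @param denominator Composition denominator mode (see
#'   [compositionForward()]).
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outdir, seed = 1, simulate = TRUE,
                           sim = list(), inputs = list(),
                           timepoints = c(0, 4, 8, 12), tau = 5,
                           fcPo = 2, gepFc = 1.5, window = 10000,
                           alpha = 0.01, ipmsFc = 2,
                           stateMode = c("presence", "signal"),
                           denominator = c("de", "all")) {
  stateMode <- match.arg(stateMode)
  denominator <- match.arg(denominator)
  stopifnot(length(timepoints) >= 2, all(diff(timepoints) > 0),
            tau > 0, fcPo > 1, gepFc > 1, window >= 0,
            alpha > 0, alpha <= 1, ipmsFc > 1)
  cfg <- list(outdir = outdir, seed = seed, simulate = simulate,
              sim = sim, inputs = inputs, timepoints = timepoints,
              tau = tau, fcPo = fcPo, gepFc = gepFc, window = window,
              alpha = alpha, ipmsFc = ipmsFc, stateMode = stateMode,
              denominator = denominator)
  class(cfg) <- "PipelineConfig"
  cfg
}

## hash over the scientific parameters only (no paths), via canonical JSON
.configHash <- function(cfg) {
  sci <- cfg[c("seed", "simulate", "sim", "timepoints", "tau", "fcPo",
               "gepFc", "window", "alpha", "ipmsFc", "stateMode",
               "denominator")]
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(sci, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

.checkInputsExist <- function(cfg) {
  need <- c("atacPeaks", "signal", "tss", "expression", "chipT0", "chipT1")
  flat <- c(unlist(cfg$inputs[need]),
            unlist(cfg$inputs$marks),
            unlist(lapply(cfg$inputs$ipms, unlist)))
  missing <- setdiff(need, names(cfg$inputs))
  if (length(missing))
    stop("pipeline input(s) not configured: ",
         paste(missing, collapse = ", "))
  if (length(cfg$inputs$atacPeaks) != length(cfg$timepoints))
    stop("stage classify-cad: need one peak file per timepoint")
  absent <- flat[!file.exists(flat)]
  if (length(absent))
    stop("pipeline input file(s) missing: ",
         paste(absent, collapse = ", "))
}

#' Consistency checks over a pipeline report
#'
#' Re-evaluates the report's internal identities from its own numbers: the
#' relocation venn identities (`lost + retained = t0 total`,
#' `retained + gained = t1 total`), row-normalization of every nonempty
#' composition row, the binding-composition sum, and (when present) that
#' interactome venn region counts add up to the union size.
#'
#' @param report A report list from [runPipeline()].
#' @return data.frame (`check`, `pass`).
#' @export
reportChecks <- function(report) {
  checks <- list()
  rc <- report$relocation$counts
  checks[["relocation_t0_identity"]] <-
    rc[["lost"]] + rc[["retained"]] == rc[["t0_total"]]
  checks[["relocation_t1_identity"]] <-
    rc[["retained"]] + rc[["gained"]] == rc[["t1_total"]]
  rowOk <- function(tab) {
    sums <- vapply(tab$fractions, function(r) sum(unlist(r)), numeric(1))
    dn <- unlist(tab$denominators)
    all(dn == 0 | (!is.na(sums) & abs(sums - 1) < 1e-9))
  }
  checks[["composition_forward_rows"]] <-
    rowOk(report$composition$forward)
  checks[["composition_reverse_rows"]] <-
    rowOk(report$composition$reverse)
  bc <- report$relocation$cadComposition
  checks[["binding_composition_sum"]] <-
    sum(unlist(bc$counts)) == 0 ||
    abs(sum(unlist(bc$fractions)) - 1) < 1e-9
  if (!is.null(report$ipms$venn)) {
    checks[["interactome_venn_sum"]] <-
      sum(unlist(report$ipms$venn$regions)) ==
      report$ipms$venn$unionSize
  }
  data.frame(check = names(checks),
             pass = unlist(checks, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Write a pipeline report as JSON
#'
#' @param report Report list from [runPipeline()].
#' @param path Output path (conventionally `report.json`).
#' @return Invisibly, `path`.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

.compositionAsList <- function(ct) {
  fr <- compositionFractions(ct)
  list(fractions = apply(fr, 1, function(r) as.list(r), simplify = FALSE),
       denominators = as.list(compositionDenominators(ct)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> classify-cad -> integrate-expression ->
#' relocation -> ipms -> report, writing each stage's artifact under the
#' run directory with fixed names (`cad_labels.tsv`, `cad_counts.json`,
#' `composition_forward.tsv`, `composition_reverse.tsv`, `relocation.tsv`,
#' `cooccupancy.tsv`, `interactors.tsv`, `venn.json`, `report.json`).
#' Missing inputs fail fast, naming the stage and path, before any stage
#' runs. Internal identities (venn sums, composition row sums) are checked
#' and recorded in the report; with `strict = TRUE` (default) a failing
#' identity is an error after the report is written.
#'
#' @param config A [pipelineConfig()] object.
#' @param strict Error on a failing internal identity.
#' @return The report, invisibly (also written to
#'   `file.path(outdir, "report.json")`).
#' @export
runPipeline <- function(config, strict = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tp <- config$timepoints
  k <- length(tp)

  if (config$simulate) {
    params <- do.call(simParams,
                      c(list(seed = config$seed, timepoints = tp),
                        config$sim))
    message("stage simulate: seed ", config$seed)
    sim <- simulateAll(params, outdir = file.path(outdir, "sim"))
    peakSets <- sim$atac$peakSets
    signal <- sim$atac$signal
    tss <- sim$annotation$tss
    tpm <- sim$expression$tpm
    chipT0 <- sim$chip$t0
    chipT1 <- sim$chip$t1
    marks <- sim$chip$marks
    ipmsIn <- lapply(params$ipms$baits, function(b) sim$ipms[[b]])
    names(ipmsIn) <- params$ipms$baits
  } else {
    .checkInputsExist(config)
    peakSets <- lapply(config$inputs$atacPeaks, readPeaks)
    names(peakSets) <- sprintf("%gh", tp)
    sigDf <- read.delim(config$inputs$signal, check.names = FALSE)
    signal <- as.matrix(sigDf[, -1, drop = FALSE])
    rownames(signal) <- sigDf[[1]]
    tss <- readTss(config$inputs$tss)
    tpmDf <- read.delim(config$inputs$expression, check.names = FALSE)
    tpm <- as.matrix(tpmDf[, -1, drop = FALSE])
    rownames(tpm) <- tpmDf[[1]]
    chipT0 <- readPeaks(config$inputs$chipT0)
    chipT1 <- readPeaks(config$inputs$chipT1)
    marks <- lapply(config$inputs$marks, readPeaks)
    ipmsIn <- lapply(config$inputs$ipms, function(x) {
      xdf <- read.delim(x$intensities, check.names = FALSE)
      m <- as.matrix(xdf[, -1, drop = FALSE])
      rownames(m) <- xdf[[1]]
      list(intensities = m, samples = read.delim(x$samples))
    })
  }

  ## ---- classify-cad -------------------------------------------------------
  message("stage classify-cad (", config$stateMode, " mode)")
  if (config$stateMode == "presence") {
    cp <- consensusPeaks(peakSets)
    flags <- occupancyFlags(cp, peakSets, timepoints = tp)
    sigAligned <- NULL
    if (!is.null(signal)) {
      hit <- match(rownames(flags), rownames(signal))
      if (!anyNA(hit)) {
        sigAligned <- signal[hit, , drop = FALSE]
      } else {
        message("  signal matrix does not cover the consensus loci; ",
                "permanently open loci fall back to PON")
      }
    }
    cad <- classifyCad(flags, sigAligned, fcPo = config$fcPo,
                       loci = consensusLoci(cp))
  } else {
    flags <- binarizeSignal(signal, config$tau)
    cad <- classifyCad(flags, signal, fcPo = config$fcPo,
                       loci = lociFromIds(rownames(signal)))
  }
  lab <- cadLabels(cad)
  write.table(data.frame(locus = names(lab), label = as.character(lab)),
              file.path(outdir, "cad_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(cadCounts(cad)),
                       file.path(outdir, "cad_counts.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  ## ---- integrate-expression ----------------------------------------------
  message("stage integrate-expression")
  gep <- classifyGep(tpm, fc = config$gepFc)
  map <- mapPeaksToGenes(cadLoci(cad), tss, window = config$window)
  fwd <- compositionForward(cad, gep, map,
                            denominator = config$denominator)
  rev_ <- compositionReverse(gep, cad, map)
  writeComp <- function(ct, path) {
    df <- data.frame(class = rownames(compositionFractions(ct)),
                     compositionFractions(ct),
                     n = compositionDenominators(ct),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeComp(fwd, file.path(outdir, "composition_forward.tsv"))
  writeComp(rev_, file.path(outdir, "composition_reverse.tsv"))

  ## ---- relocation ---------------------------------------------------------
  message("stage relocation")
  vp <- bindingDynamics(chipT0, chipT1, labels = c("0h", "8h"))
  write.table(relocationTable(vp), file.path(outdir, "relocation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  bindComp <- cadComposition(chipT1, cad)
  cooc <- NULL
  if (length(marks)) {
    cooc <- cooccupancyCounts(chipT1, marks)
    write.table(cooc, file.path(outdir, "cooccupancy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  ## ---- ipms ---------------------------------------------------------------
  ipmsReport <- NULL
  if (length(ipmsIn)) {
    message("stage ipms")
    calls <- lapply(names(ipmsIn), function(b) {
      se <- preprocessIntensities(ipmsIn[[b]]$intensities,
                                  ipmsIn[[b]]$samples)
      cl <- testInteractors(se, "IP", "ctrl", alpha = config$alpha,
                            fc = config$ipmsFc)
      data.frame(bait = b, protein = rownames(cl),
                 as.data.frame(cl), row.names = NULL)
    })
    callsDf <- do.call(rbind, calls)
    write.table(callsDf, file.path(outdir, "interactors.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sets <- lapply(split(callsDf, callsDf$bait),
                   function(d) d$protein[d$significant])
    ipmsReport <- list(
      nSignificant = lapply(sets, length),
      interactors = lapply(sets, sort))
    if (length(sets) >= 2) {
      vn <- interactomeVenn(sets)
      ipmsReport$venn <- list(regions = as.list(vn),
                              unionSize = length(unique(unlist(sets))))
      ipmsReport$shared <- sharedInteractors(sets[[1]], sets[[2]])
      jsonlite::write_json(ipmsReport$venn,
                           file.path(outdir, "venn.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
  }

  ## ---- report -------------------------------------------------------------
  message("stage report")
  report <- list(
    provenance = list(package = "chromdyn",
                      version = as.character(packageVersion("chromdyn")),
                      seed = config$seed,
                      configHash = .configHash(config)),
    cad = list(counts = as.list(cadCounts(cad)),
               nLoci = length(lab)),
    composition = list(forward = .compositionAsList(fwd),
                       reverse = .compositionAsList(rev_)),
    relocation = list(
      counts = as.list(relocationCounts(vp)),
      cadComposition = list(
        counts = as.list(bindingCounts(bindComp)),
        fractions = as.list(bindingFractions(bindComp)),
        openAssociated = openAssociated(bindComp))),
    cooccupancy = if (!is.null(cooc))
      lapply(seq_len(nrow(cooc)), function(i) as.list(cooc[i, ])),
    ipms = ipmsReport)
  report$checks <- reportChecks(report)
  writeReport(report, file.path(outdir, "report.json"))
  failed <- report$checks$check[!report$checks$pass]
  if (strict && length(failed))
    stop("internal identity check failed: ",
         paste(failed, collapse = ", "))
  invisible(report)
}
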