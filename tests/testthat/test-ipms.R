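makeSheet <- function(nr = 3) {
  data.frame(sample = c(sprintf("IP_%d", 1:nr), sprintf("ctrl_%d", 1:nr)),
             condition = rep(c("IP", "ctrl"), each = nr),
             replicate = rep(1:nr, 2), stringsAsFactors = FALSE)
}

test_that("preprocess filters by min observations and keeps observed values", {
  sheet <- makeSheet()
  x <- matrix(2^rnorm(5 * 6, 20), 5, 6,
              dimnames = list(sprintf("p%d", 1:5), sheet$sample))
  ## p5 observed once per condition -> dropped; p4 2-of-3 in IP -> kept
  x["p5", c("IP_2", "IP_3", "ctrl_1", "ctrl_3")] <- NA
  x["p4", c("IP_3", "ctrl_1", "ctrl_2", "ctrl_3")] <- NA
  se <- preprocessIntensities(x, sheet)
  expect_identical(S4Vectors::metadata(se)$dropped, "p5")
  got <- SummarizedExperiment::assay(se, "log2")
  obs <- !is.na(x[rownames(got), ])
  expect_equal(got[obs], log2(x[rownames(got), ][obs]))
  expect_false(anyNA(got))
  ## min_shift imputes at the column minimum minus the shift
  j <- "ctrl_1"
  colMin <- min(log2(x[rownames(got), j]), na.rm = TRUE)
  expect_equal(unname(got["p4", j]), colMin - 1)
})

test_that("complete matrices pass through imputation unchanged", {
  sheet <- makeSheet()
  x <- matrix(2^rnorm(12, 20), 2, 6,
              dimnames = list(c("a", "b"), sheet$sample))
  se <- preprocessIntensities(x, sheet)
  expect_equal(SummarizedExperiment::assay(se, "log2"), log2(x))
})

test_that("min_prob imputation is reproducible under a seed", {
  sheet <- makeSheet()
  x <- matrix(2^rnorm(40 * 6, 20, 2), 40, 6,
              dimnames = list(sprintf("p%d", 1:40), sheet$sample))
  x[matrix(runif(length(x)) < 0.15, nrow(x))] <- NA
  keeps <- rowSums(!is.na(x[, 1:3])) >= 2 | rowSums(!is.na(x[, 4:6])) >= 2
  a <- SummarizedExperiment::assay(
    preprocessIntensities(x, sheet, method = "min_prob", seed = 9), "log2")
  b <- SummarizedExperiment::assay(
    preprocessIntensities(x, sheet, method = "min_prob", seed = 9), "log2")
  expect_identical(a, b)
  obs <- !is.na(x[rownames(a), ])
  expect_equal(a[obs], log2(x[rownames(a), ][obs]))
})

test_that("the worked example is significant and matches t.test", {
  case <- c(10.0, 10.2, 9.8)
  ctrl <- c(8.0, 8.2, 7.8)
  x <- matrix(c(case, ctrl), 1, dimnames = list("p1", makeSheet()$sample))
  out <- testInteractors(x, "IP", "ctrl", samples = makeSheet())
  expect_equal(out$log2fc, 2)
  expect_equal(out$df, 4)
  oracle <- stats::t.test(case, ctrl, var.equal = TRUE)
  expect_equal(out$pvalue, oracle$p.value)
  expect_lt(out$pvalue, 0.01)
  expect_true(out$significant)
  ## Welch variant agrees with its own oracle
  outW <- testInteractors(x, "IP", "ctrl", samples = makeSheet(),
                          varEqual = FALSE)
  oracleW <- stats::t.test(case, ctrl)
  expect_equal(outW$pvalue, oracleW$p.value)
})

test_that("row-wise p-values equal per-row t.test on random matrices", {
  set.seed(77)
  sheet <- makeSheet()
  x <- matrix(rnorm(50 * 6, 22, 1), 50, 6,
              dimnames = list(sprintf("p%02d", 1:50), sheet$sample))
  for (ve in c(TRUE, FALSE)) {
    out <- testInteractors(x, "IP", "ctrl", samples = sheet, varEqual = ve)
    oracle <- apply(x, 1, function(r)
      stats::t.test(r[1:3], r[4:6], var.equal = ve)$p.value)
    expect_equal(out$pvalue, unname(oracle))
  }
})

test_that("the fold-change gate and degenerate conventions hold", {
  sheet <- makeSheet()
  ## strong p but log2fc below log2(2) -> not significant
  x <- matrix(c(10.8, 10.81, 10.79, 10.0, 10.01, 9.99), 1,
              dimnames = list("p1", sheet$sample))
  out <- testInteractors(x, "IP", "ctrl", samples = sheet)
  expect_lt(out$pvalue, 1e-4)
  expect_false(out$significant)
  ## equal constant vectors: p = 1 by convention
  xe <- matrix(rep(5, 6), 1, dimnames = list("p1", sheet$sample))
  oute <- testInteractors(xe, "IP", "ctrl", samples = sheet)
  expect_equal(oute$pvalue, 1)
  expect_false(oute$degenerate)
  ## zero variance, unequal means: p -> 0 limit, flagged degenerate
  xd <- matrix(c(8, 8, 8, 5, 5, 5), 1, dimnames = list("p1", sheet$sample))
  outd <- testInteractors(xd, "IP", "ctrl", samples = sheet)
  expect_equal(outd$pvalue, 0)
  expect_true(outd$degenerate)
  expect_true(outd$significant)
})

test_that("interactome venn counts every region and is order-invariant", {
  sets <- list(A = c("p1", "p2", "p3"), B = c("p2", "p3", "p4"),
               C = c("p3", "p4", "p5"))
  vn <- interactomeVenn(sets)
  expect_identical(sum(vn), 5L)                # union size
  expect_identical(unname(vn["A&B&C"]), 1L)    # p3
  expect_identical(unname(vn["B&C"]), 1L)      # p4
  vn2 <- interactomeVenn(sets[c(3, 1, 2)])
  expect_identical(unname(vn2["A&B&C"]), unname(vn["A&B&C"]))
  expect_identical(sum(vn2), sum(vn))
  ## identical and disjoint edge cases
  same <- interactomeVenn(list(X = c("a", "b"), Y = c("a", "b")))
  expect_identical(unname(same["X&Y"]), 2L)
  expect_identical(sum(same), 2L)
  disj <- interactomeVenn(list(X = "a", Y = "b"))
  expect_identical(unname(disj[c("X", "Y", "X&Y")]), c(1L, 1L, 0L))

  ## random instances against a membership-vector oracle
  set.seed(2)
  for (i in 1:10) {
    ss <- lapply(1:3, function(j)
      sample(sprintf("p%02d", 1:20), sample(3:12, 1)))
    names(ss) <- c("S1", "S2", "S3")
    vn <- interactomeVenn(ss)
    un <- unique(unlist(ss))
    key <- vapply(un, function(p) paste(
      names(ss)[vapply(ss, function(s) p %in% s, logical(1))],
      collapse = "&"), character(1))
    oracle <- table(key)
    for (region in names(vn)) {
      expected <- if (region %in% names(oracle))
        as.integer(oracle[[region]]) else 0L
      expect_identical(unname(vn[region]), expected)
    }
    expect_identical(sum(vn), length(un))
  }
})

test_that("sharedInteractors is plain intersection", {
  expect_identical(sharedInteractors(c("a", "b"), c("c")), character(0))
  expect_identical(sharedInteractors(c("a", "b"), c("a", "b", "c")),
                   c("a", "b"))
})
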