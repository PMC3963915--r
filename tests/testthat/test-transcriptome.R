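test_that("quantile normalization matches the order-statistic construction", {
  toy <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantileNormalize(toy)
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5), tolerance = 1e-12)
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5), tolerance = 1e-12)

  # identical columns are already exchangeable
  same <- cbind(x = c(5, 1, 3), y = c(5, 1, 3))
  expect_equal(quantileNormalize(same), same, tolerance = 1e-12)

  set.seed(61)
  m <- matrix(rnorm(600), 100, 6)
  out <- quantileNormalize(m)
  sorted <- apply(out, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  # idempotent
  expect_equal(quantileNormalize(out), out, tolerance = 1e-12)
  # permutation-equivariant over samples
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(quantileNormalize(m[, perm]), out[, perm], tolerance = 1e-12)
  expect_error(quantileNormalize(cbind(c(1, NA), c(2, 3))), "missing")
})

test_that("welchT matches stats::t.test on random instances to 1e-12", {
  set.seed(62)
  for (i in 1:300) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    got <- welchT(a, b)
    ref <- t.test(a, b)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("welchT degenerates gracefully", {
  g <- c(1, 2, 3)
  got <- welchT(g, g)
  expect_identical(got$t, 0)
  expect_identical(got$p, 1)
  expect_error(welchT(1, c(1, 2)), "at least 2")
  expect_warning(res <- welchT(c(1, 1), c(2, 2)), "zero-variance")
  expect_identical(res$p, 1)
})

test_that("the vectorized row-wise Welch agrees with the scalar version", {
  set.seed(63)
  A <- matrix(rnorm(50 * 7), 50, 7)
  B <- matrix(rnorm(50 * 9, 0.3), 50, 9)
  rw <- cordMediate:::rowWelch(A, B)
  for (i in c(1, 17, 50)) {
    sc <- welchT(A[i, ], B[i, ])
    expect_equal(rw$t[i], sc$t, tolerance = 1e-12)
    expect_equal(rw$p[i], sc$p, tolerance = 1e-12)
  }
})

test_that("replicate collapsing averages intensities and ANDs flags", {
  mat <- rbind(p1 = c(4, 8), p2 = c(6, 10), p3 = c(1, 2))
  colnames(mat) <- c("s1", "s2")
  se <- makeSE(mat, transcript = c("tA", "tA", "tB"),
               gene = c("GA", "GA", "GB"))
  SummarizedExperiment::assay(se, "spot_uniform")["p2", "s2"] <- FALSE
  col <- collapseReplicates(se)
  expect_identical(sort(rownames(col)), c("tA", "tB"))
  expect_equal(SummarizedExperiment::assay(col, "log2")["tA", ],
               c(s1 = 5, s2 = 9))
  # singleton group unchanged
  expect_equal(SummarizedExperiment::assay(col, "log2")["tB", ],
               c(s1 = 1, s2 = 2))
  # conservative flags: one unreliable replicate poisons the group
  expect_false(SummarizedExperiment::assay(col, "spot_uniform")["tA", "s2"])
  expect_true(SummarizedExperiment::assay(col, "spot_uniform")["tA", "s1"])
})

test_that("reliability filtering requires all five flags in every subset sample", {
  set.seed(64)
  mat <- matrix(rnorm(40), 10, 4,
                dimnames = list(sprintf("f%02d", 1:10), sprintf("s%d", 1:4)))
  se <- makeSE(mat)
  expect_equal(reliableFeatures(se), rownames(mat), ignore_attr = TRUE)
  SummarizedExperiment::assay(se, "above_noise")["f03", "s2"] <- FALSE
  expect_false("f03" %in% reliableFeatures(se))
  expect_true("f03" %in% reliableFeatures(se, c("s1", "s3", "s4")))

  # random flags versus brute-force enumeration on a small instance
  flagNames <- c("above_noise", "below_saturation", "not_population_outlier",
                 "spot_uniform", "background_not_outlier")
  se2 <- makeSE(mat)
  for (f in flagNames)
    SummarizedExperiment::assay(se2, f)[] <- matrix(runif(40) > 0.1, 10, 4)
  subset <- c("s1", "s2", "s4")
  expected <- rownames(mat)[vapply(seq_len(10), function(i) {
    all(vapply(flagNames, function(f)
      all(SummarizedExperiment::assay(se2, f)[i, subset]), logical(1)))
  }, logical(1))]
  expect_identical(reliableFeatures(se2, subset), expected,
                   ignore_attr = TRUE)
  filt <- reliabilityFilter(se2, subset)
  expect_identical(rownames(filt), expected)
  expect_identical(S4Vectors::metadata(filt)$reliability$nIn, 10L)
})

test_that("the expression TSV dialect round-trips and reports schema errors", {
  cfg <- simConfig(nSubjects = 12, seed = 65, nNullGenes = 98)
  sim <- generateCohort(cfg)
  se <- generateExpression(sim$cohort, sim$truth, cfg)
  expect_identical(dim(se), c(nrow(se), 12L))
  dir <- tempfile()
  paths <- writeExpressionMatrix(se, dir)
  back <- readExpressionMatrix(paths["intensity"], paths["flags"],
                               paths["annotation"])
  expect_equal(SummarizedExperiment::assay(back, "log2"),
               SummarizedExperiment::assay(se, "log2"), tolerance = 1e-8)
  expect_identical(SummarizedExperiment::assay(back, "spot_uniform"),
                   SummarizedExperiment::assay(se, "spot_uniform"))
  expect_identical(
    as.data.frame(SummarizedExperiment::rowData(back)),
    as.data.frame(SummarizedExperiment::rowData(se)[, c("probe_id",
      "transcript", "gene_symbol", "panels")]))

  # drop one flag column: the error must name it
  fl <- read.delim(paths["flags"])
  fl$spot_uniform <- NULL
  broken <- tempfile(fileext = ".tsv")
  write.table(fl, broken, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readExpressionMatrix(paths["intensity"], broken,
                                    paths["annotation"]),
               "spot_uniform")
})

screenFixture <- function(mat, nAsHigh = 15, nAsLow = 15, nBwLow = 12,
                          nBwHigh = 12) {
  ns <- ncol(mat)
  asLab <- factor(rep("median", ns), levels = c("low", "median", "high"))
  bwLab <- factor(rep("mid", ns), levels = c("low", "mid", "high"))
  asLab[seq_len(nAsHigh)] <- "high"
  asLab[nAsHigh + seq_len(nAsLow)] <- "low"
  off <- nAsHigh + nAsLow
  bwLab[off + seq_len(nBwLow)] <- "low"
  bwLab[off + nBwLow + seq_len(nBwHigh)] <- "high"
  list(asLab = asLab, bwLab = bwLab, sex = rep("girls", ns))
}

test_that("the quadrant screen recovers a strongly planted mediator in quadrant 1", {
  set.seed(66)
  ns <- 70
  mat <- matrix(rnorm(100 * ns, 8, 0.5), 100, ns,
                dimnames = list(sprintf("g%03d", 1:100),
                                sprintf("s%03d", 1:ns)))
  fx <- screenFixture(mat)
  # plant: up in high-As, up in low-BW
  mat[1, fx$asLab == "high"] <- mat[1, fx$asLab == "high"] + 1.5
  mat[1, fx$bwLab == "low"] <- mat[1, fx$bwLab == "low"] + 1.5
  se <- makeSE(mat)
  scr <- quadrantScreen(se, fx$asLab, fx$bwLab, "girls", sex = fx$sex)
  tab <- screenTable(scr)
  row <- tab[tab$feature == "g001", ]
  expect_identical(row$quadrant, 1L)
  expect_true(row$candidate)
  expect_lt(row$p_as, 0.05)
  expect_lt(row$p_bw, 0.05)
  expect_true(all(is.finite(tab$mlog10_p_as)))
})

test_that("negating the expression matrix swaps quadrants 1 and 3", {
  set.seed(67)
  ns <- 60
  mat <- matrix(rnorm(50 * ns), 50, ns,
                dimnames = list(sprintf("g%03d", 1:50),
                                sprintf("s%03d", 1:ns)))
  fx <- screenFixture(mat)
  a <- screenTable(quadrantScreen(makeSE(mat), fx$asLab, fx$bwLab, "girls",
                                  sex = fx$sex))
  b <- screenTable(quadrantScreen(makeSE(-mat), fx$asLab, fx$bwLab, "girls",
                                  sex = fx$sex))
  map <- c(`1` = 3L, `2` = 4L, `3` = 1L, `4` = 2L)
  expect_identical(unname(map[as.character(a$quadrant)]), b$quadrant)
  expect_equal(a$p_as, b$p_as, tolerance = 1e-12)
  expect_equal(a$d_as, -b$d_as, tolerance = 1e-12)
})

test_that("the screen is invariant to probe and sample order", {
  set.seed(68)
  ns <- 60
  mat <- matrix(rnorm(40 * ns), 40, ns,
                dimnames = list(sprintf("g%03d", 1:40),
                                sprintf("s%03d", 1:ns)))
  fx <- screenFixture(mat)
  a <- screenTable(quadrantScreen(makeSE(mat), fx$asLab, fx$bwLab, "girls",
                                  sex = fx$sex))
  rperm <- sample(40)
  cperm <- sample(ns)
  b <- screenTable(quadrantScreen(makeSE(mat[rperm, cperm]),
                                  fx$asLab[cperm], fx$bwLab[cperm], "girls",
                                  sex = fx$sex[cperm]))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the screen errors when stratification empties a contrast group", {
  set.seed(69)
  mat <- matrix(rnorm(10 * 20), 10, 20)
  fx <- screenFixture(mat, nAsHigh = 4, nAsLow = 4, nBwLow = 4, nBwHigh = 4)
  sexBoys <- rep("boys", 20)
  expect_error(quadrantScreen(makeSE(mat), fx$asLab, fx$bwLab, "girls",
                              sex = sexBoys),
               "fewer than 2")
})
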