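# Shared fixture builders for the test suite. All fixtures are generated in
# code; nothing is read from disk except explicit round-trip tests.

# A minimal expression SummarizedExperiment with all-passing flags.
makeSE <- function(mat, transcript = rownames(mat),
                   gene = transcript,
                   panels = "embryonal_growth") {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("P%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("S%03d", seq_len(ncol(mat)))
  flagNames <- c("above_noise", "below_saturation", "not_population_outlier",
                 "spot_uniform", "background_not_outlier")
  flags <- lapply(flagNames, function(f)
    matrix(TRUE, nrow(mat), ncol(mat), dimnames = dimnames(mat)))
  names(flags) <- flagNames
  rd <- S4Vectors::DataFrame(probe_id = rownames(mat),
                             transcript = transcript,
                             gene_symbol = gene,
                             panels = rep_len(panels, nrow(mat)),
                             row.names = rownames(mat))
  SummarizedExperiment::SummarizedExperiment(
    assays = c(list(log2 = mat), flags), rowData = rd)
}

# A noise-free configuration in which birth weight is a deterministic
# function of gestational age and sex only.
zeroNoiseConfig <- function(n = 60, seed = 1) {
  simConfig(nSubjects = n, seed = seed,
            residualBwSd = 0, expressionNoiseSd = 0, qpcrNoiseSd = 0,
            betaAsPerIqr = 0, betaAsHighGroup = 0,
            betaSmoking = 0, betaParity0 = 0, betaParity1 = 0,
            mediatorLog2FCHighAs = 0,
            mediatorBwEffectGirls = 0, mediatorBwEffectBoys = 0)
}

# Textbook Welch formulas written out independently of the package.
oracleWelch <- function(a, b) {
  m1 <- sum(a) / length(a); m2 <- sum(b) / length(b)
  v1 <- sum((a - m1)^2) / (length(a) - 1)
  v2 <- sum((b - m2)^2) / (length(b) - 1)
  s1 <- v1 / length(a); s2 <- v2 / length(b)
  t <- (m1 - m2) / sqrt(s1 + s2)
  df <- (s1 + s2)^2 / (s1^2 / (length(a) - 1) + s2^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
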