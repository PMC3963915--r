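# Microarray preprocessing and the sex-stratified dual-contrast quadrant
# screen. Expression lives in a SummarizedExperiment with a log2 assay and
# five logical reliability-flag assays mirroring feature-extraction QC:
# intensity above the feature noise level, below saturation, not a population
# outlier, spot uniform, background not an outlier.

FLAG_ASSAYS <- c("above_noise", "below_saturation", "not_population_outlier",
                 "spot_uniform", "background_not_outlier")

#' Read an expression matrix with reliability flags and annotation
#'
#' Assembles a [SummarizedExperiment::SummarizedExperiment] from three
#' tab-separated files: a wide intensity table (`probe_id` plus one numeric
#' column per sample, log2 scale), a long flags table (`probe_id`,
#' `sample_id` and the five 0/1 reliability flag columns), and an annotation
#' table (`probe_id`, `transcript`, `gene_symbol`, `panels` with
#' comma-separated panel names). Duplicate keys, unmatched keys, missing flag
#' columns and non-numeric intensities are explicit errors.
#'
#' @param intensityFile,flagsFile,annotationFile file paths.
#' @return a SummarizedExperiment with assays `log2` and the five flag
#'   assays.
#' @seealso [writeExpressionMatrix()]
#' @export
readExpressionMatrix <- function(intensityFile, flagsFile, annotationFile) {
  int <- utils::read.delim(intensityFile, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(int)[1] != "probe_id") stop("intensity table must start with probe_id")
  if (anyDuplicated(int$probe_id))
    stop("duplicate probe_id in intensity table")
  probes <- int$probe_id
  mat <- as.matrix(int[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric intensity values")
  rownames(mat) <- probes
  samples <- colnames(mat)

  fl <- utils::read.delim(flagsFile, stringsAsFactors = FALSE)
  need <- c("probe_id", "sample_id", FLAG_ASSAYS)
  missing <- setdiff(need, names(fl))
  if (length(missing))
    stop("flags table is missing column(s): ", paste(missing, collapse = ", "))
  key <- paste(fl$probe_id, fl$sample_id)
  if (anyDuplicated(key)) stop("duplicate (probe, sample) cells in flags table")
  unmatched <- unique(c(setdiff(fl$probe_id, probes),
                        setdiff(fl$sample_id, samples)))
  if (length(unmatched))
    stop("flags table keys not present in intensity table: ",
         paste(utils::head(unmatched, 5), collapse = ", "))
  if (nrow(fl) != length(probes) * length(samples))
    stop("flags table does not cover every (probe, sample) cell")
  ri <- match(fl$probe_id, probes)
  ci <- match(fl$sample_id, samples)
  flags <- lapply(FLAG_ASSAYS, function(f) {
    m <- matrix(NA, length(probes), length(samples),
                dimnames = dimnames(mat))
    m[cbind(ri, ci)] <- as.logical(fl[[f]])
    m
  })
  names(flags) <- FLAG_ASSAYS

  ann <- utils::read.delim(annotationFile, stringsAsFactors = FALSE)
  need <- c("probe_id", "transcript", "gene_symbol", "panels")
  missing <- setdiff(need, names(ann))
  if (length(missing))
    stop("annotation table is missing column(s): ",
         paste(missing, collapse = ", "))
  idx <- match(probes, ann$probe_id)
  if (anyNA(idx))
    stop("annotation missing for probe(s): ",
         paste(utils::head(probes[is.na(idx)], 5), collapse = ", "))
  rd <- S4Vectors::DataFrame(ann[idx, need], row.names = probes)

  SummarizedExperiment::SummarizedExperiment(
    assays = c(list(log2 = mat), flags), rowData = rd)
}

#' Write an expression SummarizedExperiment to TSV files
#'
#' Inverse of [readExpressionMatrix()]: writes `<prefix>_intensity.tsv`
#' (wide), `<prefix>_flags.tsv` (long) and `<prefix>_annotation.tsv` into
#' `dir`.
#'
#' @param se SummarizedExperiment with a `log2` assay and the five flag
#'   assays.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named character vector of the three paths, invisibly.
#' @export
writeExpressionMatrix <- function(se, dir, prefix = "expression") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- SummarizedExperiment::assay(se, "log2")
  paths <- c(
    intensity = file.path(dir, paste0(prefix, "_intensity.tsv")),
    flags = file.path(dir, paste0(prefix, "_flags.tsv")),
    annotation = file.path(dir, paste0(prefix, "_annotation.tsv")))
  utils::write.table(
    data.frame(probe_id = rownames(mat), mat, check.names = FALSE),
    paths["intensity"], sep = "\t", quote = FALSE, row.names = FALSE)
  grid <- expand.grid(probe_id = rownames(mat), sample_id = colnames(mat),
                      stringsAsFactors = FALSE)
  for (f in FLAG_ASSAYS)
    grid[[f]] <- as.integer(SummarizedExperiment::assay(se, f)[
      cbind(match(grid$probe_id, rownames(mat)),
            match(grid$sample_id, colnames(mat)))])
  utils::write.table(grid, paths["flags"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  utils::write.table(
    rd[, c("probe_id", "transcript", "gene_symbol", "panels")],
    paths["annotation"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Quantile normalization of log2 intensities
#'
#' Forces every sample's intensity distribution onto the common reference
#' distribution of cross-sample order-statistic means (delegated to
#' `limma::normalizeQuantiles`; ties within a sample receive the mean of the
#' reference quantiles at their tied ranks). Idempotent, and equivariant
#' under sample permutation. Missing values must be handled beforehand.
#'
#' @param x numeric matrix (features by samples) or a SummarizedExperiment,
#'   whose `log2` assay is then normalized in place.
#' @return object of the same type as `x`.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantileNormalize <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "log2") <-
      quantileNormalize(SummarizedExperiment::assay(x, "log2"))
    return(x)
  }
  m <- as.matrix(x)
  if (anyNA(m)) stop("missing values must be handled before normalization")
  if (ncol(m) < 2L) stop("need at least 2 samples")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Collapse replicate probes to one value per sequence
#'
#' Averages log2 intensities over the replicate probes of each transcript
#' sequence and combines reliability flags conservatively: a collapsed
#' feature is reliable in a sample only if every replicate probe is.
#'
#' @param se SummarizedExperiment with rowData column `transcript`.
#' @return SummarizedExperiment keyed by transcript, carrying `transcript`
#'   and `gene_symbol` (and `panels` when present) in its rowData.
#' @export
collapseReplicates <- function(se) {
  rd <- SummarizedExperiment::rowData(se)
  if (!"transcript" %in% names(rd)) stop("rowData lacks a transcript column")
  groups <- as.character(rd$transcript)
  if (anyNA(groups) || any(!nzchar(groups)))
    stop("replicate group with missing transcript key")
  mat <- SummarizedExperiment::assay(se, "log2")
  counts <- as.vector(table(groups)[sort(unique(groups))])
  mean_ <- rowsum(mat, groups) / counts
  flags <- lapply(FLAG_ASSAYS, function(f) {
    fails <- rowsum(1 - SummarizedExperiment::assay(se, f) * 1, groups)
    fails == 0
  })
  names(flags) <- FLAG_ASSAYS
  keys <- rownames(mean_)
  first <- match(keys, groups)
  keep <- intersect(c("transcript", "gene_symbol", "panels"), names(rd))
  gsym <- tapply(as.character(rd$gene_symbol), groups, function(v)
    length(unique(v)))
  if (any(gsym > 1))
    stop("conflicting gene symbols within a replicate group")
  newRd <- S4Vectors::DataFrame(as.data.frame(rd[first, keep, drop = FALSE]),
                                row.names = keys)
  SummarizedExperiment::SummarizedExperiment(
    assays = c(list(log2 = mean_), flags), rowData = newRd,
    colData = SummarizedExperiment::colData(se))
}

#' Reliable features over a sample subset
#'
#' A feature is reliable when all five quality flags pass in every sample of
#' the subset; features failing any flag in any considered sample are
#' excluded from statistical analysis.
#'
#' @param se SummarizedExperiment with the five flag assays.
#' @param samples sample names (or indices) defining the subset; defaults to
#'   all samples.
#' @return `reliableFeatures`: character vector of reliable feature ids, with
#'   attributes `nIn` and `nOut`. `reliabilityFilter`: the SummarizedExperiment
#'   subset to those features, with the in/out counts in its `metadata()`
#'   under `reliability`.
#' @export
reliableFeatures <- function(se, samples = colnames(se)) {
  if (!length(samples)) stop("sample subset is empty")
  ok <- rep(TRUE, nrow(se))
  for (f in FLAG_ASSAYS) {
    fl <- SummarizedExperiment::assay(se, f)[, samples, drop = FALSE]
    ok <- ok & rowSums(!fl) == 0
  }
  structure(rownames(se)[ok], nIn = nrow(se), nOut = sum(ok))
}

#' @rdname reliableFeatures
#' @export
reliabilityFilter <- function(se, samples = colnames(se)) {
  ids <- reliableFeatures(se, samples)
  out <- se[ids, ]
  S4Vectors::metadata(out)$reliability <-
    list(nIn = attr(ids, "nIn"), nOut = attr(ids, "nOut"),
         nSamples = length(samples))
  out
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided t-test with the Welch statistic and Satterthwaite degrees of
#' freedom. When both groups have zero variance the test degenerates: equal
#' means give t = 0, p = 1; a zero-variance contrast with unequal means is
#' reported with p = 1 and a warning rather than NaN, so screening over
#' thousands of genes never produces non-finite p-values.
#'
#' @param groupA,groupB numeric vectors, at least 2 values each.
#' @return list with `t`, `df`, `p` and `diff` (mean of A minus mean of B).
#' @examples
#' welchT(c(1, 2, 3), c(2, 3, 4))
#' @export
welchT <- function(groupA, groupB) {
  n1 <- length(groupA); n2 <- length(groupB)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  m1 <- mean(groupA); m2 <- mean(groupB)
  v1 <- stats::var(groupA); v2 <- stats::var(groupB)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (m1 != m2) warning("zero-variance contrast with unequal means; p set to 1")
    return(list(t = 0, df = NA_real_, p = 1, diff = m1 - m2))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df), diff = m1 - m2)
}

# Vectorized Welch test over matrix rows (same formulas as welchT).
rowWelch <- function(A, B) {
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (n1 - 1)
  v2 <- rowSums((B - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * pt(-abs(tstat), df), 1)
  nzv <- sum(se2 == 0)
  if (nzv > 0)
    warning(nzv, " zero-variance feature(s); p set to 1")
  list(t = tstat, df = df, p = p, diff = m1 - m2)
}

#' Sex-stratified dual-contrast quadrant screen
#'
#' For every reliable panel gene within one sex stratum, computes two Welch
#' contrasts: high-versus-low arsenic exposure and low-versus-high
#' gestational-age-adjusted birth weight. The two mean log2 differences place
#' each gene in a quadrant: quadrant 1 (both positive) holds transcripts up
#' with exposure and up with growth restriction, quadrant 3 (both negative)
#' the mirror image; these concordant quadrants flag potential mediators.
#' Candidates are concordant-quadrant genes with both p-values below `alpha`.
#' No multiple-testing correction is applied to the primary calls (the screen
#' is a targeted panel analysis); BH q-values are attached for information.
#'
#' @param se SummarizedExperiment of collapsed, normalized log2 expression
#'   with flag assays and rowData columns `gene_symbol` and `panels`.
#' @param asLabels factor per sample with levels low/median/high (see
#'   [classifyExposure()]).
#' @param bwLabels factor per sample with levels low/mid/high (see
#'   [fitGAAdjustment()]); the contrast is low minus high.
#' @param stratum sex stratum to screen ("girls" or "boys").
#' @param sex per-sample sex; defaults to `colData(se)$sex`.
#' @param panel panel name to subset on, or NULL for all features.
#' @param alpha significance cut-off for the candidate flag (default 0.05).
#' @return a [QuadrantScreen-class].
#' @export
quadrantScreen <- function(se, asLabels, bwLabels, stratum,
                           sex = SummarizedExperiment::colData(se)$sex,
                           panel = "embryonal_growth", alpha = 0.05) {
  ns <- ncol(se)
  stopifnot(length(asLabels) == ns, length(bwLabels) == ns,
            length(sex) == ns)
  inStratum <- as.character(sex) == stratum
  gAsHigh <- which(inStratum & asLabels == "high")
  gAsLow <- which(inStratum & asLabels == "low")
  gBwLow <- which(inStratum & bwLabels == "low")
  gBwHigh <- which(inStratum & bwLabels == "high")
  sizes <- c(as_high = length(gAsHigh), as_low = length(gAsLow),
             bw_low = length(gBwLow), bw_high = length(gBwHigh))
  if (any(sizes < 2L))
    stop("a contrast group has fewer than 2 samples after stratification: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))

  if (!is.null(panel)) {
    panels <- SummarizedExperiment::rowData(se)$panels
    if (is.null(panels)) stop("rowData lacks a panels column")
    se <- se[grepl(panel, panels, fixed = TRUE), ]
    if (!nrow(se)) stop("no features annotated to panel ", panel)
  }
  union <- sort(unique(c(gAsHigh, gAsLow, gBwLow, gBwHigh)))
  ids <- sort(reliableFeatures(se, colnames(se)[union]))
  se <- se[ids, ]
  mat <- SummarizedExperiment::assay(se, "log2")

  asW <- rowWelch(mat[, gAsHigh, drop = FALSE], mat[, gAsLow, drop = FALSE])
  bwW <- rowWelch(mat[, gBwLow, drop = FALSE], mat[, gBwHigh, drop = FALSE])

  quadrant <- rep(NA_integer_, nrow(mat))
  quadrant[asW$diff > 0 & bwW$diff > 0] <- 1L
  quadrant[asW$diff < 0 & bwW$diff > 0] <- 2L
  quadrant[asW$diff < 0 & bwW$diff < 0] <- 3L
  quadrant[asW$diff > 0 & bwW$diff < 0] <- 4L

  tiny <- .Machine$double.xmin
  tab <- data.frame(
    feature = rownames(mat),
    gene = as.character(SummarizedExperiment::rowData(se)$gene_symbol),
    d_as = asW$diff, p_as = asW$p,
    d_bw = bwW$diff, p_bw = bwW$p,
    quadrant = quadrant,
    candidate = !is.na(quadrant) & quadrant %in% c(1L, 3L) &
      asW$p < alpha & bwW$p < alpha,
    labelled = asW$p < alpha | bwW$p < alpha,
    q_as = p.adjust(asW$p, "BH"),
    q_bw = p.adjust(bwW$p, "BH"),
    mlog10_p_as = -log10(pmax(asW$p, tiny)),
    mlog10_p_bw = -log10(pmax(bwW$p, tiny)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  new("QuadrantScreen", stratum = stratum,
      panel = if (is.null(panel)) "all" else panel,
      table = tab, groupSizes = sizes)
}

#' @describeIn quadrantScreen the full per-gene statistics table.
#' @param object a [QuadrantScreen-class].
#' @export
setMethod("screenTable", "QuadrantScreen", function(object) object@table)

#' @describeIn quadrantScreen rows of candidate mediator genes (concordant
#'   quadrant, both contrasts significant).
#' @export
setMethod("candidates", "QuadrantScreen", function(object)
  object@table[object@table$candidate, , drop = FALSE])

setMethod("show", "QuadrantScreen", function(object) {
  cat(sprintf("QuadrantScreen: %s stratum, panel '%s', %d features\n",
              object@stratum, object@panel, nrow(object@table)))
  cat(sprintf("  groups: As high/low %d/%d, BW low/high %d/%d\n",
              object@groupSizes["as_high"], object@groupSizes["as_low"],
              object@groupSizes["bw_low"], object@groupSizes["bw_high"]))
  cand <- candidates(object)
  cat("  candidates (quadrant 1/3, both p < 0.05):",
      if (nrow(cand)) paste(unique(cand$gene), collapse = ", ") else "none",
      "\n")
  invisible(object)
})
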