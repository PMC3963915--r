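# qPCR confirmation: reference-gene stability (geNorm M), multi-reference
# relative quantification, and array/qPCR platform concordance.
# A Cq table is a long data.frame: sample_id, target_id, cq, efficiency
# (fold per cycle; 2.0 for perfect doubling).

# Internal: log2 relative quantities per target across samples,
# efficiency-corrected: log2 q = -Cq * log2(E), as a targets x samples matrix.
cqToLog2Quantity <- function(cq) {
  need <- c("sample_id", "target_id", "cq", "efficiency")
  stopifnot(all(need %in% names(cq)))
  key <- paste(cq$target_id, cq$sample_id)
  if (anyDuplicated(key)) stop("duplicate (target, sample) Cq entries")
  targets <- sort(unique(cq$target_id))
  samples <- sort(unique(cq$sample_id))
  m <- matrix(NA_real_, length(targets), length(samples),
              dimnames = list(targets, samples))
  m[cbind(match(cq$target_id, targets), match(cq$sample_id, samples))] <-
    -cq$cq * log2(cq$efficiency)
  m
}

#' geNorm expression-stability measure M for reference genes
#'
#' For each candidate reference gene j, M is the mean over the other
#' reference genes k of the standard deviation across samples of the log2
#' ratio of their efficiency-corrected relative quantities. Perfectly
#' co-regulated (parallel) references give M = 0; lower M means more stable.
#' Sample-wide Cq shifts (loading differences) cancel in the ratios and do
#' not affect M. The full geNorm procedure iteratively drops the least
#' stable gene; [genormRanking()] exposes that ranking (the pairwise
#' variation V cut-off of 0.15 is advisory and not enforced).
#'
#' @param cq Cq table (see above).
#' @param referenceGenes at least 2 target ids to evaluate.
#' @return named numeric vector of M values.
#' @export
genormStability <- function(cq, referenceGenes) {
  if (length(referenceGenes) < 2L) stop("need at least 2 reference genes")
  q <- cqToLog2Quantity(cq)
  missing <- setdiff(referenceGenes, rownames(q))
  if (length(missing))
    stop("reference gene(s) absent from Cq table: ",
         paste(missing, collapse = ", "))
  q <- q[referenceGenes, , drop = FALSE]
  if (anyNA(q)) stop("every sample must have all reference genes measured")
  if (ncol(q) < 3L) stop("need at least 3 samples")
  vapply(referenceGenes, function(j) {
    others <- setdiff(referenceGenes, j)
    mean(vapply(others, function(k) sd(q[j, ] - q[k, ]), numeric(1)))
  }, numeric(1))
}

#' @describeIn genormStability stepwise geNorm ranking: repeatedly removes
#'   the gene with the highest M until two remain; returns genes in removal
#'   order (least stable first) followed by the final stable pair.
#' @export
genormRanking <- function(cq, referenceGenes) {
  remaining <- referenceGenes
  removed <- character()
  while (length(remaining) > 2L) {
    m <- genormStability(cq, remaining)
    worst <- names(m)[which.max(m)]
    removed <- c(removed, worst)
    remaining <- setdiff(remaining, worst)
  }
  c(removed, remaining)
}

#' Relative quantification against multiple reference genes
#'
#' Computes, per target and sample, the efficiency-corrected relative
#' quantity `E^(Cq_ref - Cq_sample)` versus a designated reference sample,
#' normalizes it by the geometric mean of the reference genes' relative
#' quantities, and returns the result as a log2 fold change. The reference
#' sample scores exactly 0 for every target, and adding a constant to all Cq
#' values of a sample (a loading difference) leaves the output unchanged.
#'
#' @param cq Cq table.
#' @param referenceGenes reference gene target ids.
#' @param referenceSample sample id serving as the fold-change anchor;
#'   defaults to the lexicographically first sample.
#' @return data.frame with columns `sample_id`, `target_id`, `log2_fc`.
#' @export
relativeQuantify <- function(cq, referenceGenes, referenceSample = NULL) {
  q <- cqToLog2Quantity(cq)
  if (is.null(referenceSample)) referenceSample <- colnames(q)[1]
  if (!referenceSample %in% colnames(q))
    stop("reference sample not present: ", referenceSample)
  absent <- setdiff(referenceGenes, rownames(q))
  if (length(absent))
    stop("missing reference gene(s): ", paste(absent, collapse = ", "))
  refQ <- q[referenceGenes, , drop = FALSE]
  if (anyNA(refQ))
    stop("missing reference gene measurement for some sample")
  # log2 fold change vs reference sample, before normalization
  rel <- q - q[, referenceSample]
  normFactor <- colMeans(refQ) - mean(refQ[, referenceSample])
  out <- sweep(rel, 2, normFactor)
  grid <- expand.grid(target_id = rownames(out), sample_id = colnames(out),
                      stringsAsFactors = FALSE)
  data.frame(sample_id = grid$sample_id, target_id = grid$target_id,
             log2_fc = out[cbind(match(grid$target_id, rownames(out)),
                                 match(grid$sample_id, colnames(out)))],
             stringsAsFactors = FALSE)
}

#' Concordance between array and qPCR log2 fold changes
#'
#' Pearson correlation between paired array and qPCR log2 fold changes on a
#' matched sample subset, plus (when exposure groups are given) the Welch
#' high-versus-low contrast computed on each platform so differential calls
#' can be compared across technologies.
#'
#' @param arrayFC,qpcrFC numeric vectors of log2 fold changes, matched by
#'   position (or by name when both are named).
#' @param groups optional factor/character with two levels (e.g. high/low
#'   arsenic) aligned to the samples.
#' @return list with `r`, `p`, `n`, and when groups are given
#'   `arrayContrast` and `qpcrContrast` (each a [welchT()] result).
#' @export
platformConcordance <- function(arrayFC, qpcrFC, groups = NULL) {
  if (!is.null(names(arrayFC)) && !is.null(names(qpcrFC))) {
    shared <- intersect(names(arrayFC), names(qpcrFC))
    arrayFC <- arrayFC[shared]
    qpcrFC <- qpcrFC[shared]
    if (!is.null(groups) && !is.null(names(groups))) groups <- groups[shared]
  }
  ok <- !is.na(arrayFC) & !is.na(qpcrFC)
  arrayFC <- arrayFC[ok]
  qpcrFC <- qpcrFC[ok]
  if (length(arrayFC) < 3L) stop("fewer than 3 matched pairs")
  ct <- suppressWarnings(cor.test(arrayFC, qpcrFC, method = "pearson"))
  out <- list(r = unname(ct$estimate), p = ct$p.value, n = length(arrayFC))
  if (!is.null(groups)) {
    groups <- groups[ok]
    lev <- unique(as.character(groups[!is.na(groups)]))
    if (length(lev) != 2L) stop("groups must have exactly 2 levels")
    out$arrayContrast <- welchT(arrayFC[groups == lev[1]],
                                arrayFC[groups == lev[2]])
    out$qpcrContrast <- welchT(qpcrFC[groups == lev[1]],
                               qpcrFC[groups == lev[2]])
  }
  out
}
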