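# Plain-text serialization of the tabular containers. Column names and units
# are part of the interface: arsenic in ug/L, weights in grams, gestational
# age in completed weeks.

#' Write and read a cohort table
#'
#' CSV round-trip of the cohort data.frame produced by [generateCohort()]
#' (factor columns `sex`, `parity`, `education` are restored with their
#' canonical level order).
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return `readCohort` returns the cohort data.frame.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("sex" %in% names(x))
    x$sex <- factor(x$sex, levels = c("girls", "boys"))
  if ("parity" %in% names(x))
    x$parity <- factor(x$parity, levels = c("0", "1", "2+"))
  if ("education" %in% names(x))
    x$education <- factor(x$education, levels = c("low", "middle", "high"))
  x
}

#' Write and read sex-specific growth curves
#'
#' CSV round-trip of the (sex, week, p10_g) reference table used by
#' [classifySGA()].
#'
#' @param curves data.frame with columns `sex`, `week`, `p10_g`.
#' @param path file path.
#' @return `readGrowthCurves` returns the curves data.frame.
#' @export
writeGrowthCurves <- function(curves, path) {
  stopifnot(all(c("sex", "week", "p10_g") %in% names(curves)))
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGrowthCurves
#' @export
readGrowthCurves <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
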