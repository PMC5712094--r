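#' Reads-per-million normalization
#'
#' Normalized expression = (actual miRNA count / total clean reads) x 1e6.
#'
#' @param count non-negative read count(s).
#' @param total_clean clean-read total of the library (> 0).
#' @return RPM value(s).
#' @examples
#' normalize_rpm(10, 1e6)  # 10 RPM
#' @export
normalize_rpm <- function(count, total_clean) {
  if (any(total_clean <= 0)) stopf("total_clean must be > 0")
  if (any(count < 0)) stopf("counts must be non-negative")
  count / total_clean * 1e6
}

#' Log2 fold-change of normalized expression
#'
#' fold_change = log2(treatment RPM / control RPM). Antisymmetric in its
#' arguments. When both sides are zero the fold-change is undefined and NA
#' is returned; zero on one side only yields +/-Inf here — [run_de()]
#' instead applies a one-read pseudocount to the zero side before
#' normalization and flags the row.
#'
#' @param rpm_treatment,rpm_control normalized expression values (>= 0).
#' @return log2 ratio (NA when both inputs are zero).
#' @export
log2_fold_change <- function(rpm_treatment, rpm_control) {
  if (any(rpm_treatment < 0) || any(rpm_control < 0))
    stopf("RPM values must be non-negative")
  ifelse(rpm_treatment == 0 & rpm_control == 0, NA_real_,
         log2(rpm_treatment / rpm_control))
}

#' Two-sided count-proportion test between two pooled libraries
#'
#' Exact binomial test of the treatment count against the proportion of
#' sequencing effort in the treatment library, i.e. an Audic-Claverie-style
#' test for unreplicated pooled count data: under the null the treatment
#' count given the combined count k = count_t + count_c is
#' Binomial(k, total_t / (total_t + total_c)). Symmetric in the two
#' libraries; returns 1 when both counts are zero.
#'
#' @param count_t,count_c pooled miRNA counts in treatment and control.
#' @param total_t,total_c clean-read totals of the two libraries.
#' @return two-sided p-value in [0, 1].
#' @export
de_test <- function(count_t, total_t, count_c, total_c) {
  if (total_t <= 0 || total_c <= 0) stopf("library totals must be > 0")
  k <- count_t + count_c
  if (k == 0) return(1)
  p0 <- total_t / (total_t + total_c)
  stats::binom.test(count_t, k, p = p0, alternative = "two.sided")$p.value
}

#' Significance class and regulation call
#'
#' Thresholds as used throughout the package:
#' highly significant when |fold_change| > 1 and p < 0.01; significant when
#' |fold_change| > 1 and 0.01 <= p <= 0.05; otherwise not significant.
#' Regulation is called from the unlogged ratio: up when ratio > 2, down
#' when ratio < 1/2, otherwise unchanged (boundaries are strict).
#'
#' @param fold_change log2 fold-change.
#' @param p_value p-value from [de_test()].
#' @param ratio treatment/control ratio of normalized expression.
#' @return a list with `class` (one of "highly_significant",
#'   "significant", "not_significant") and `regulation` (one of "up",
#'   "down", "unchanged").
#' @export
classify_de <- function(fold_change, p_value, ratio) {
  cls <- ifelse(!is.na(fold_change) & abs(fold_change) > 1 & p_value < 0.01,
                "highly_significant",
         ifelse(!is.na(fold_change) & abs(fold_change) > 1 &
                  p_value >= 0.01 & p_value <= 0.05,
                "significant", "not_significant"))
  reg <- ifelse(!is.na(ratio) & ratio > 2, "up",
         ifelse(!is.na(ratio) & ratio < 0.5, "down", "unchanged"))
  list(class = cls, regulation = reg)
}

#' Differential expression over a count matrix
#'
#' Replicate counts are summed per condition (pooled) before normalization;
#' the pooled control and treatment libraries then run through
#' normalize -> fold-change -> test -> classify per miRNA. Rows with zero
#' counts in both conditions are excluded (listed in the `excluded`
#' attribute); a zero on one side only receives a one-read pseudocount
#' before normalization and is flagged.
#'
#' @param counts integer matrix, rows = miRNA ids, columns = libraries.
#' @param totals named clean-read totals per library (>= column sums).
#' @param condition factor/character per library, two levels; the level
#'   named by `treatment` is the treatment.
#' @param treatment name of the treatment level (default "T").
#' @return a data.frame sorted by decreasing |fold_change| with columns:
#'   id, per-library RPM, pooled rpm_control / rpm_treatment, fold_change,
#'   p_value, ratio, class, regulation, pseudocounted.
#' @export
run_de <- function(counts, totals, condition, treatment = "T") {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (is.null(names(totals))) names(totals) <- colnames(counts)
  totals <- totals[colnames(counts)]
  if (any(is.na(totals)) || any(totals <= 0))
    stopf("every library needs a positive clean-read total")
  if (any(counts < 0)) stopf("negative counts")
  condition <- as.character(condition)
  if (length(condition) != ncol(counts)) stopf("condition length mismatch")
  lev <- unique(condition)
  if (length(lev) != 2L) stopf("exactly two conditions required")
  if (!treatment %in% lev) stopf("treatment level '%s' not found", treatment)
  control <- setdiff(lev, treatment)

  t_cols <- condition == treatment
  c_cols <- condition == control
  count_t <- rowSums(counts[, t_cols, drop = FALSE])
  count_c <- rowSums(counts[, c_cols, drop = FALSE])
  total_t <- sum(totals[t_cols])
  total_c <- sum(totals[c_cols])

  excluded <- rownames(counts)[count_t == 0 & count_c == 0]
  keep <- count_t > 0 | count_c > 0
  count_t <- count_t[keep]; count_c <- count_c[keep]
  ids <- rownames(counts)[keep]

  pseudo <- count_t == 0 | count_c == 0
  adj_t <- ifelse(count_t == 0, 1, count_t)
  adj_c <- ifelse(count_c == 0, 1, count_c)
  rpm_t <- normalize_rpm(adj_t, total_t)
  rpm_c <- normalize_rpm(adj_c, total_c)
  fc <- log2_fold_change(rpm_t, rpm_c)
  ratio <- rpm_t / rpm_c
  pv <- mapply(de_test, count_t, MoreArgs = list(total_t = total_t,
               total_c = total_c), count_c = count_c)
  cl <- classify_de(fc, pv, ratio)

  per_lib <- sweep(counts[keep, , drop = FALSE], 2, as.numeric(totals),
                   "/") * 1e6
  colnames(per_lib) <- paste0("rpm_", colnames(counts))
  res <- data.frame(id = ids, per_lib,
                    rpm_control = rpm_c, rpm_treatment = rpm_t,
                    fold_change = fc, p_value = pv, ratio = ratio,
                    class = cl$class, regulation = cl$regulation,
                    pseudocounted = pseudo, stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  res <- res[order(-abs(res$fold_change), res$id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  attr(res, "pooling") <- "summed replicate counts per condition"
  attr(res, "test") <- "two-sided exact binomial (Audic-Claverie style)"
  res
}
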