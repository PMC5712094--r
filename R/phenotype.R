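#' Total chlorophyll content from two-wavelength absorbance
#'
#' Chlorophyll a and b absorb maximally at 645 nm and 663 nm; total
#' chlorophyll (mg/g fresh weight, for the standard 80% acetone extraction
#' and path length) is the linear combination
#' C_T = C_a + C_b = 20.29 * A645 + 8.05 * A663.
#'
#' @param a645,a663 non-negative absorbance readings (unitless), vectorized.
#' @return total chlorophyll in mg/g fresh weight.
#' @examples
#' chlorophyll_total(0.150, 0.320)
#' @export
chlorophyll_total <- function(a645, a663) {
  if (any(!is.finite(a645)) || any(!is.finite(a663)))
    stopf("absorbances must be finite")
  if (any(a645 < 0) || any(a663 < 0))
    stopf("absorbances must be non-negative")
  20.29 * a645 + 8.05 * a663
}

#' Relative expression by the delta-delta-Ct method
#'
#' Computes 2^(-ddCt) per sample with dCt = Ct_target - Ct_reference and
#' ddCt = dCt_sample - dCt_calibrator. Technical replicates are averaged on
#' the Ct scale (arithmetic mean) before exponentiation; amplification
#' efficiency is fixed at 2 (no efficiency correction). Typical references
#' in this package's study design are miR5059 for miRNAs and beta-actin for
#' target genes.
#'
#' @param ct data.frame with columns `sample`, `ct_target`, `ct_reference`
#'   (one row per technical replicate; replicates share a `sample` id).
#' @param calibrator sample id used as calibrator (relative expression 1).
#' @return data.frame with columns `sample`, `dct`, `ddct`,
#'   `rel_expression`, ordered by first appearance.
#' @export
relative_expression <- function(ct, calibrator) {
  need <- c("sample", "ct_target", "ct_reference")
  if (!all(need %in% names(ct)))
    stopf("ct table needs columns: %s", paste(need, collapse = ", "))
  if (any(is.na(ct$ct_reference)))
    stopf("missing reference Ct for sample '%s'",
          ct$sample[which(is.na(ct$ct_reference))[1]])
  if (any(is.na(ct$ct_target)))
    stopf("missing target Ct for sample '%s'",
          ct$sample[which(is.na(ct$ct_target))[1]])
  bad <- ct$ct_target <= 0 | ct$ct_target >= 45 |
    ct$ct_reference <= 0 | ct$ct_reference >= 45
  if (any(bad)) stopf("Ct values must lie in (0, 45)")
  if (!calibrator %in% ct$sample) stopf("calibrator '%s' absent", calibrator)
  ord <- unique(ct$sample)
  mt <- tapply(ct$ct_target, ct$sample, mean)[ord]
  mr <- tapply(ct$ct_reference, ct$sample, mean)[ord]
  dct <- mt - mr
  ddct <- dct - dct[[calibrator]]
  data.frame(sample = ord, dct = as.numeric(dct), ddct = as.numeric(ddct),
             rel_expression = 2^(-as.numeric(ddct)),
             stringsAsFactors = FALSE)
}
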