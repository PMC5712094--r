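#' Fold an RNA sequence under the stacked-pair energy model
#'
#' Computes the optimal pseudoknot-free secondary structure by dynamic
#' programming. The energy model is deliberately self-contained: a base pair
#' contributes energy only when stacked directly inside an adjacent enclosing
#' pair (-2 for G:C, -1 for A:U and G:U), isolated and loop-closing pairs
#' contribute 0, and hairpin loops must hold at least 3 unpaired bases. The
#' resulting score (<= 0, "MFE" in model units) is used consistently across
#' hairpin evaluation and target-duplex scoring, so thresholds stated
#' elsewhere in the package are internally comparable.
#'
#' @param x a single sequence (A/C/G/U/T); typical precursor windows are
#'   40-400 nt but any length up to 2000 nt is accepted.
#' @param allow_gu logical; accept G:U wobble pairs (default TRUE).
#' @return a list with `structure` (dot-bracket string), `mfe` (model
#'   energy, <= 0) and `partner` (1-based pairing partner per position,
#'   0 when unpaired).
#' @examples
#' fold_hairpin("GGGGAAAACCCC")
#' @export
fold_hairpin <- function(x, allow_gu = TRUE) {
  if (length(x) != 1L || !is.character(x)) stopf("x must be a single string")
  codes <- encode_seq(x)
  res <- .fold_mfe_cpp(codes, allow_gu)
  list(structure = res$structure, mfe = res$mfe, partner = res$partner)
}
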