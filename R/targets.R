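#' Score a miRNA:target duplex position by position
#'
#' The target site is given 5'->3' on the transcript and paired antiparallel,
#' so miRNA position i (1-based from the miRNA 5' end, the indexing used by
#' all rule arithmetic) faces site position L-i+1. Each position is classed
#' as Watson-Crick pair, G:U wobble, or mismatch, and scored 0 / 0.5 / 1.
#' Duplex and perfect-complement "MFE" values use the same stacked-pair
#' model as [fold_hairpin()]: a paired position stacked on a paired
#' neighbour contributes -2 (G:C) or -1 (A:U, G:U).
#'
#' Only ungapped, equal-length duplexes are scored; bulged alignments are
#' out of scope because the positional rules are defined on a fixed 1..L
#' index.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param site target site sequence, 5'->3' on the transcript, same length.
#' @return an object of class `duplex_alignment`: per-position `state`
#'   ("WC", "GU", "mm"), `score`, total score, `mfe_duplex`,
#'   `mfe_perfect`, `mfe_ratio`.
#' @export
score_duplex <- function(mirna, site) {
  m <- norm_seq(mirna)
  s <- norm_seq(site)
  L <- nchar(m)
  if (L != nchar(s)) stopf("miRNA and site lengths differ (%d vs %d); gapped duplexes are not supported", L, nchar(s))
  mb <- strsplit(m, "")[[1]]
  sb <- rev(strsplit(s, "")[[1]])  # base faced by miRNA position i
  bad <- which(!(mb %in% BASES) | !(sb %in% BASES))
  if (length(bad)) stopf("non-ACGU/T base in duplex at position %d", bad[1])
  code <- match(mb, BASES) + match(sb, BASES)  # A=1 C=2 G=3 T=4
  wc <- code == 5L
  gu <- code == 7L
  state <- ifelse(wc, "WC", ifelse(gu, "GU", "mm"))
  score <- ifelse(wc, 0, ifelse(gu, 0.5, 1))
  paired <- wc | gu
  stack <- ifelse(wc & mb %in% c("G", "C"), -2, -1)
  contrib <- c(0, ifelse(paired[-1] & paired[-L], stack[-1], 0))
  mfe_duplex <- sum(contrib)
  perfect <- sum(ifelse(mb[-1] %in% c("G", "C"), -2, -1))
  mfe_perfect <- if (L >= 2) perfect else 0
  ratio <- if (mfe_perfect < 0) mfe_duplex / mfe_perfect else NA_real_
  structure(list(mirna = m, site = s, state = state, score = score,
                 total_score = sum(score), mfe_duplex = mfe_duplex,
                 mfe_perfect = mfe_perfect, mfe_ratio = ratio),
            class = "duplex_alignment")
}

#' Apply the six plant miRNA target-prediction rules
#'
#' Rules, evaluated on a scored duplex with positions counted 1..L from the
#' miRNA 5' end:
#' \describe{
#'   \item{a}{no more than two adjacent mismatches (longest run of
#'     mismatch-state positions <= 2);}
#'   \item{b}{total mismatch score <= 4 (G:U wobble counts 0.5);}
#'   \item{c}{mismatch score over positions 1-12 <= 2.5;}
#'   \item{d}{no mismatch-state position at 10 or 11;}
#'   \item{e}{no two adjacent mismatch-state positions within 2-12;}
#'   \item{f}{duplex MFE at least 75% of the perfect-complement MFE
#'     (`mfe_ratio >= 0.75`; fails closed when the perfect MFE is 0).}
#' }
#' G:U wobble contributes to the summed scores of rules b and c but is not a
#' mismatch state for the positional rules a, d, e.
#'
#' @param duplex a `duplex_alignment` from [score_duplex()].
#' @param mfe_fraction required duplex/perfect MFE fraction (default 0.75).
#' @return an object of class `rule_verdict`: logical `a`..`f`, `pass`
#'   (their conjunction), and `mfe_ratio`.
#' @export
apply_rules <- function(duplex, mfe_fraction = 0.75) {
  stopifnot(inherits(duplex, "duplex_alignment"))
  L <- length(duplex$state)
  mm <- duplex$state == "mm"
  runs <- rle(mm)
  rule_a <- !any(runs$values & runs$lengths > 2)
  rule_b <- duplex$total_score <= 4
  hi <- seq_len(min(12L, L))
  rule_c <- sum(duplex$score[hi]) <= 2.5
  rule_d <- if (L >= 11) !(mm[10] || mm[11]) else TRUE
  idx <- 2:min(11L, L - 1L)
  rule_e <- !any(mm[idx] & mm[idx + 1] & (idx + 1) <= 12)
  rule_f <- !is.na(duplex$mfe_ratio) && duplex$mfe_ratio >= mfe_fraction
  v <- c(a = rule_a, b = rule_b, c = rule_c, d = rule_d, e = rule_e,
         f = rule_f)
  structure(list(rules = v, pass = all(v), mfe_ratio = duplex$mfe_ratio),
            class = "rule_verdict")
}

#' Scan transcripts for miRNA target sites
#'
#' Slides a window of miRNA length over every transcript, scores each
#' ungapped antiparallel duplex, applies the six rules, and returns the
#' passing sites sorted by (miRNA id, transcript id, position). The scan is
#' fully deterministic.
#'
#' @param mirnas named character vector, miRNA id -> mature sequence.
#' @param transcripts named character vector, transcript id -> sequence.
#' @param verbose also return every rejected window with its rule flags.
#' @param mfe_fraction passed to [apply_rules()].
#' @return a data.frame of hits with columns `mirna`, `transcript`,
#'   `start` (0-based), `score`, `mfe_ratio`, and logical columns
#'   `rule_a`..`rule_f`; with `verbose = TRUE`, a list with elements
#'   `hits` and `rejected`.
#' @export
scan_transcriptome <- function(mirnas, transcripts, verbose = FALSE,
                               mfe_fraction = 0.75) {
  if (length(mirnas) && is.null(names(mirnas)))
    stopf("mirnas must be named")
  if (length(transcripts) && is.null(names(transcripts)))
    stopf("transcripts must be named")
  empty <- data.frame(mirna = character(), transcript = character(),
                      start = integer(), score = numeric(),
                      mfe_ratio = numeric(), rule_a = logical(),
                      rule_b = logical(), rule_c = logical(),
                      rule_d = logical(), rule_e = logical(),
                      rule_f = logical(), stringsAsFactors = FALSE)
  if (!length(transcripts)) {
    warning("empty transcript set; no sites scanned")
    return(if (verbose) list(hits = empty, rejected = empty) else empty)
  }
  out <- vector("list", length(mirnas) * length(transcripts))
  rej <- if (verbose) vector("list", length(out)) else NULL
  k <- 0L
  for (mi in seq_along(mirnas)) {
    mseq <- norm_seq(mirnas[[mi]])
    mb <- strsplit(mseq, "")[[1]]
    L <- length(mb)
    mcode <- match(mb, BASES)
    gc_m <- mb %in% c("G", "C")
    perfect <- if (L >= 2) sum(ifelse(gc_m[-1], -2, -1)) else 0
    for (ti in seq_along(transcripts)) {
      tseq <- norm_seq(transcripts[[ti]])
      tcode <- match(strsplit(tseq, "")[[1]], BASES)
      n <- length(tcode)
      W <- n - L + 1L
      if (W < 1L) next
      # code[i, w] = miRNA base i + transcript base at (w + L - i)
      scorem <- matrix(0, nrow = L, ncol = W)
      mmm <- matrix(FALSE, nrow = L, ncol = W)
      pairedm <- matrix(FALSE, nrow = L, ncol = W)
      stackm <- matrix(0, nrow = L, ncol = W)
      for (i in seq_len(L)) {
        tv <- tcode[(L - i) + seq_len(W)]
        sm <- mcode[i] + tv
        wc <- !is.na(sm) & sm == 5L
        gu <- !is.na(sm) & sm == 7L
        mmm[i, ] <- !(wc | gu)
        pairedm[i, ] <- wc | gu
        scorem[i, ] <- ifelse(wc, 0, ifelse(gu, 0.5, 1))
        stackm[i, ] <- ifelse(wc & gc_m[i], -2, -1)
      }
      total <- colSums(scorem)
      csum <- colSums(scorem[seq_len(min(12L, L)), , drop = FALSE])
      # rule a: any run of >= 3 consecutive mismatch positions
      if (L >= 3) {
        tri <- mmm[1:(L - 2), , drop = FALSE] & mmm[2:(L - 1), , drop = FALSE] &
          mmm[3:L, , drop = FALSE]
        a_ok <- !apply(tri, 2, any)
      } else a_ok <- rep(TRUE, W)
      d_ok <- if (L >= 11) !(mmm[10, ] | mmm[11, ]) else rep(TRUE, W)
      ii <- 2:min(11L, L - 1L)
      adj <- mmm[ii, , drop = FALSE] & mmm[ii + 1, , drop = FALSE] &
        matrix((ii + 1) <= 12, nrow = length(ii), ncol = W)
      e_ok <- !apply(adj, 2, any)
      both <- pairedm[-1, , drop = FALSE] & pairedm[-L, , drop = FALSE]
      mfe_d <- colSums(stackm[-1, , drop = FALSE] * both)
      ratio <- if (perfect < 0) mfe_d / perfect else rep(NA_real_, W)
      f_ok <- !is.na(ratio) & ratio >= mfe_fraction
      b_ok <- total <= 4
      c_ok <- csum <= 2.5
      pass <- a_ok & b_ok & c_ok & d_ok & e_ok & f_ok
      mk <- function(sel) data.frame(
        mirna = names(mirnas)[mi], transcript = names(transcripts)[ti],
        start = which(sel) - 1L, score = total[sel],
        mfe_ratio = ratio[sel], rule_a = a_ok[sel], rule_b = b_ok[sel],
        rule_c = c_ok[sel], rule_d = d_ok[sel], rule_e = e_ok[sel],
        rule_f = f_ok[sel], stringsAsFactors = FALSE)
      k <- k + 1L
      if (any(pass)) out[[k]] <- mk(pass)
      if (verbose && any(!pass)) rej[[k]] <- mk(!pass)
    }
  }
  hits <- if (k && length(Filter(Negate(is.null), out)))
    do.call(rbind, Filter(Negate(is.null), out)) else empty
  hits <- hits[order(hits$mirna, hits$transcript, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  if (verbose) {
    rejected <- if (length(Filter(Negate(is.null), rej)))
      do.call(rbind, Filter(Negate(is.null), rej)) else empty
    rejected <- rejected[order(rejected$mirna, rejected$transcript,
                               rejected$start), , drop = FALSE]
    rownames(rejected) <- NULL
    list(hits = hits, rejected = rejected)
  } else hits
}
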