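#' Derive miRNA family names from mature ids
#'
#' Strips the species prefix and member suffix: `ppe-miR395d` and
#' `miR395e-5p` both give `miR395`.
#'
#' @param ids character vector of mature miRNA ids.
#' @return character vector of family names.
#' @export
mirna_family <- function(ids) {
  core <- sub("^[A-Za-z]{2,4}-", "", ids)
  fam <- sub("^((mi|MI)[Rr][A-Za-z]*?[0-9]+).*$", "\\1", core)
  fam
}

#' Match unique tags against a mature-miRNA database
#'
#' A tag matches a database entry iff the lengths are equal and the Hamming
#' distance is at most `max_mm` (default 2); alignments are full-length and
#' ungapped. Each matching tag is assigned to exactly one miRNA: the entry
#' with the fewest mismatches, ties broken by lexicographically smallest
#' id (ties are recorded in the `ties` attribute). Per-miRNA counts are
#' the sums of the counts of all tags assigned to that miRNA.
#'
#' @param tags tag table from [clean_reads()] (`sequence` + count columns).
#' @param mirna_db named character vector id -> mature sequence (18-26 nt).
#' @param max_mm maximum mismatches (default 2).
#' @return list with `hits` (data.frame: sequence, mirna, family,
#'   mismatches), `counts` (matrix miRNA x library) and attribute-style
#'   element `ties` (data.frame of logged ambiguous assignments).
#' @export
match_known <- function(tags, mirna_db, max_mm = 2L) {
  if (anyDuplicated(names(mirna_db)))
    stopf("duplicate miRNA ids in database")
  db <- norm_seq(mirna_db)
  dblen <- nchar(db)
  if (any(dblen < 18 | dblen > 26))
    stopf("database sequences must be 18-26 nt")
  libs <- setdiff(names(tags), "sequence")
  # order db so that the first best hit found is the lexicographically
  # smallest id among equal-mismatch candidates
  ord <- order(names(db))
  db <- db[ord]
  dblen <- dblen[ord]

  seqs <- tags$sequence
  n <- length(seqs)
  best_id <- rep(NA_character_, n)
  best_mm <- rep(NA_integer_, n)
  tie_with <- vector("list", n)
  for (w in unique(dblen)) {
    ti <- which(nchar(seqs) == w)
    if (!length(ti)) next
    tm <- matrix(unlist(strsplit(seqs[ti], "")), nrow = w)
    for (j in which(dblen == w)) {
      dj <- strsplit(db[[j]], "")[[1]]
      mm <- colSums(tm != dj)
      upd <- mm <= max_mm & (is.na(best_mm[ti]) | mm < best_mm[ti])
      tie <- !is.na(best_mm[ti]) & mm <= max_mm & mm == best_mm[ti]
      for (k in which(tie)) {
        tie_with[[ti[k]]] <- c(tie_with[[ti[k]]], names(db)[j])
      }
      best_id[ti[upd]] <- names(db)[j]
      best_mm[ti[upd]] <- mm[upd]
    }
  }
  hit <- !is.na(best_id)
  hits <- data.frame(sequence = seqs[hit], mirna = best_id[hit],
                     family = mirna_family(best_id[hit]),
                     mismatches = best_mm[hit], stringsAsFactors = FALSE)
  ties <- data.frame(
    sequence = seqs[hit & vapply(tie_with, length, 0L) > 0],
    assigned = best_id[hit & vapply(tie_with, length, 0L) > 0],
    also = vapply(tie_with[hit & vapply(tie_with, length, 0L) > 0],
                  paste, "", collapse = ","),
    stringsAsFactors = FALSE)

  ids <- sort(unique(hits$mirna))
  counts <- matrix(0L, nrow = length(ids), ncol = length(libs),
                   dimnames = list(ids, libs))
  if (nrow(hits)) {
    for (lib in libs) {
      v <- tapply(tags[[lib]][hit], best_id[hit], sum)
      counts[names(v), lib] <- as.integer(v)
    }
  }
  list(hits = hits, counts = counts, ties = ties)
}

#' Extract candidate precursor windows from unannotated tag loci
#'
#' Clusters mapped tag loci (per chromosome and strand, merging loci within
#' `merge_dist` nt) and extends each cluster by `flank` nt on both sides,
#' clipping at chromosome ends (clipped windows are flagged).
#'
#' @param hits GRanges of exact-match tag loci (e.g. the `hits` element of
#'   [classify_tags()], subset to unannotated tags), with a `tag_index`
#'   column.
#' @param genome named character vector of chromosome sequences.
#' @param flank extension on each side (>= 50, default 150).
#' @param merge_dist cluster-merge distance in nt (default 30).
#' @return GRanges of candidate windows with metadata `n_tags` and
#'   `clipped`.
#' @export
extract_candidate_loci <- function(hits, genome, flank = 150L,
                                   merge_dist = 30L) {
  if (flank < 50) stopf("flank must be >= 50")
  if (!length(hits)) return(GenomicRanges::GRanges(n_tags = integer(0),
                                                   clipped = logical(0)))
  red <- GenomicRanges::reduce(hits, min.gapwidth = merge_dist + 1L,
                               with.revmap = TRUE, ignore.strand = FALSE)
  n_tags <- S4Vectors::elementNROWS(red$revmap)
  win <- red
  GenomicRanges::start(win) <- pmax(1L, GenomicRanges::start(red) - flank)
  lens <- setNames(nchar(genome), names(genome))
  maxend <- lens[as.character(GenomicRanges::seqnames(red))]
  GenomicRanges::end(win) <- pmin(as.integer(maxend),
                                  GenomicRanges::end(red) + flank)
  clipped <- GenomicRanges::start(red) - flank < 1L |
    GenomicRanges::end(red) + flank > maxend
  win$revmap <- NULL
  win$n_tags <- n_tags
  win$clipped <- as.logical(clipped)
  win
}

#' Default hairpin acceptance criteria
#'
#' @param score_max maximum (most positive) folding score accepted, in
#'   model units of the stacked-pair energy. The default -45 is calibrated
#'   as the ~1st percentile of the dinucleotide-shuffle null distribution
#'   for precursor-sized (60-120 nt) sequences under this model; genuine
#'   hairpin precursors score well below it, shuffles and random sequences
#'   of that size above it.
#' @param min_paired minimum mature bases paired to the opposite arm
#'   (default 16).
#' @param len_range accepted precursor length range (default 60-300 nt).
#' @return named list of criteria.
#' @export
hairpin_criteria <- function(score_max = -45, min_paired = 16L,
                             len_range = c(60L, 300L)) {
  list(score_max = score_max, min_paired = as.integer(min_paired),
       len_range = as.integer(len_range))
}

#' Evaluate a folded precursor candidate
#'
#' Folds the window with [fold_hairpin()] and checks: the mature interval
#' lies wholly in one arm (all its pairing partners on one side, none
#' inside the mature itself — i.e. it does not cross the terminal loop);
#' at least `min_paired` mature bases pair to the opposite arm; the
#' folding score is at or below `score_max`; and the precursor length is
#' within `len_range`. Rejection with per-criterion flags is the normal
#' path, not an error.
#'
#' @param sequence precursor window sequence.
#' @param mature_start 1-based start of the mature miRNA in the window.
#' @param mature_len mature length in nt.
#' @param criteria list from [hairpin_criteria()].
#' @return list with `accepted`, `flags` (named logicals `one_arm`,
#'   `no_loop_crossing`, `paired`, `score`, `length`), `mfe`, `structure`,
#'   `n_paired`, and `star` (1-based interval of the pairing image, NA
#'   when unpaired).
#' @export
evaluate_hairpin <- function(sequence, mature_start, mature_len,
                             criteria = hairpin_criteria()) {
  n <- nchar(sequence)
  mature_start <- as.integer(mature_start)
  mature_len <- as.integer(mature_len)
  if (mature_start < 1 || mature_start + mature_len - 1L > n)
    stopf("mature interval outside the window")
  fold <- fold_hairpin(sequence)
  pt <- fold$partner
  mat <- seq(mature_start, mature_start + mature_len - 1L)
  partners <- pt[mat]
  outside <- partners[partners > 0 & !(partners %in% mat)]
  n_paired <- length(outside)
  self_paired <- any(partners %in% mat & partners > 0)
  one_side <- length(outside) == 0 ||
    all(outside > max(mat)) || all(outside < min(mat))
  flags <- c(
    one_arm = one_side && !self_paired,
    no_loop_crossing = !self_paired && one_side,
    paired = n_paired >= criteria$min_paired,
    score = fold$mfe <= criteria$score_max,
    length = n >= criteria$len_range[1] && n <= criteria$len_range[2])
  star <- if (n_paired > 0) range(outside) else c(NA_integer_, NA_integer_)
  list(accepted = all(flags), flags = flags, mfe = fold$mfe,
       structure = fold$structure, n_paired = n_paired, star = star)
}

#' Discover novel miRNA candidates from unannotated tags
#'
#' Takes the unannotated, genome-mapped tags left after classification and
#' known-miRNA matching (known matching has precedence: a tag already
#' matched to the database never supports a novel candidate), clusters
#' their loci into candidate windows, folds each window and evaluates the
#' hairpin with the most abundant tag of the window as the mature. Accepted
#' candidates are named `novel-<chrom>-<start>`.
#'
#' @details
#' For each cluster window the most abundant supporting tag is taken as the
#' putative mature; a folding subwindow of mature +/- `flank` nt (clipped
#' to the cluster window) is folded, and the precursor is then trimmed to
#' the pairing span enclosing mature and star plus a 10 nt pad before the
#' final evaluation — so the length criterion applies to the hairpin
#' proper, not to the raw search window. Clusters with fewer than
#' `min_support` supporting reads are not folded (dispersed low-coverage
#' intergenic reads otherwise dominate the candidate list).
#'
#' @param tags tag table from [clean_reads()].
#' @param classification result of [classify_tags()] on the same tags.
#' @param known_sequences character vector of tag sequences already matched
#'   to known miRNAs (excluded from novel support).
#' @param genome named character vector of chromosome sequences.
#' @param flank,merge_dist window construction, see
#'   [extract_candidate_loci()].
#' @param criteria acceptance criteria from [hairpin_criteria()].
#' @param min_support minimum supporting reads for a cluster (default 5).
#' @return list with `candidates` (data.frame of all evaluated windows
#'   with flags), `counts` (matrix accepted-candidate x library) and
#'   `windows` (the candidate GRanges).
#' @export
discover_novel <- function(tags, classification, known_sequences = character(),
                           genome, flank = 150L, merge_dist = 30L,
                           criteria = hairpin_criteria(), min_support = 5L) {
  libs <- setdiff(names(tags), "sequence")
  unann <- which(classification$assignment$class == "unannotated" &
                   !(tags$sequence %in% known_sequences))
  hits <- classification$hits
  hits <- hits[hits$tag_index %in% unann]
  win <- extract_candidate_loci(hits, genome, flank = flank,
                                merge_dist = merge_dist)
  empty_counts <- matrix(0L, 0, length(libs),
                         dimnames = list(NULL, libs))
  if (!length(win)) {
    return(list(candidates = data.frame(), counts = empty_counts,
                windows = win))
  }
  tag_total <- rowSums(as.matrix(tags[libs]))
  ovall <- GenomicRanges::findOverlaps(hits, win, type = "within")
  by_win <- split(S4Vectors::queryHits(ovall), S4Vectors::subjectHits(ovall))
  rows <- list()
  counts <- list()
  kept_win <- integer(0)
  for (k in seq_along(win)) {
    wk <- win[k]
    hi <- by_win[[as.character(k)]]
    if (is.null(hi)) next
    ov <- hits[hi]
    ov <- ov[as.character(GenomicRanges::strand(ov)) ==
               as.character(GenomicRanges::strand(wk))]
    if (!length(ov)) next
    sup <- unique(ov$tag_index)
    support <- sum(tag_total[sup])
    if (support < min_support) next
    # most abundant supporting tag defines the mature
    top <- which.max(tag_total[ov$tag_index])
    ts <- GenomicRanges::start(ov)[top]
    te <- GenomicRanges::end(ov)[top]
    chrom <- as.character(GenomicRanges::seqnames(wk))
    minus <- as.character(GenomicRanges::strand(wk)) == "-"
    # folding subwindow centred on the mature tag
    fs <- max(GenomicRanges::start(wk), ts - flank)
    fe <- min(GenomicRanges::end(wk), te + flank)
    sub_fwd <- substr(genome[[chrom]], fs, fe)
    wseq <- if (minus) revcomp(sub_fwd) else sub_fwd
    m_start <- if (minus) fe - te + 1L else ts - fs + 1L
    m_len <- te - ts + 1L
    fold <- fold_hairpin(wseq)
    mat <- seq(m_start, m_start + m_len - 1L)
    partners <- fold$partner[mat]
    outside <- partners[partners > 0 & !(partners %in% mat)]
    if (length(outside)) {
      lo <- max(1L, min(c(mat, outside)) - 10L)
      hi2 <- min(nchar(wseq), max(c(mat, outside)) + 10L)
    } else {
      lo <- max(1L, m_start - 10L)
      hi2 <- min(nchar(wseq), m_start + m_len + 9L)
    }
    pseq <- substr(wseq, lo, hi2)
    ev <- evaluate_hairpin(pseq, m_start - lo + 1L, m_len, criteria)
    cnt <- colSums(as.matrix(tags[sup, libs, drop = FALSE]))
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("novel-%s-%d", chrom, ts),
      chrom = chrom,
      start = GenomicRanges::start(wk), end = GenomicRanges::end(wk),
      strand = as.character(GenomicRanges::strand(wk)),
      mature = tags$sequence[ov$tag_index[top]],
      precursor = pseq,
      mfe = ev$mfe, n_paired = ev$n_paired,
      accepted = ev$accepted, t(ev$flags),
      support = support,
      structure = ev$structure, stringsAsFactors = FALSE)
    counts[[length(rows)]] <- cnt
    kept_win <- c(kept_win, k)
  }
  if (!length(rows)) {
    return(list(candidates = data.frame(), counts = empty_counts,
                windows = win[0]))
  }
  cand <- do.call(rbind, rows)
  rownames(cand) <- NULL
  cand$id <- sprintf("%s%s", cand$id, ifelse(cand$strand == "-", "r", ""))
  # the same mature tag can support two windows (its antisense match lies
  # on the star arm); keep the best-scoring accepted candidate per mature
  cand$duplicate <- FALSE
  acc0 <- which(cand$accepted)
  if (length(acc0) > 1) {
    o <- acc0[order(cand$mfe[acc0], -cand$support[acc0])]
    d <- o[duplicated(cand$mature[o])]
    cand$duplicate[d] <- TRUE
    cand$accepted[d] <- FALSE
  }
  acc <- which(cand$accepted)
  cm <- matrix(0L, nrow = length(acc), ncol = length(libs),
               dimnames = list(cand$id[acc], libs))
  for (j in seq_along(acc)) cm[j, ] <- as.integer(counts[[acc[j]]])
  list(candidates = cand, counts = cm, windows = win[kept_win])
}

#' Assemble the known + novel count matrix
#'
#' @param known_counts matrix from [match_known()].
#' @param novel_counts matrix from [discover_novel()] (may have 0 rows).
#' @param totals named per-library clean-read totals.
#' @return list with `counts` (rbind of both, same column order) and
#'   `totals`; totals must be at least the column sums.
#' @export
build_count_matrix <- function(known_counts, novel_counts, totals) {
  if (!is.null(novel_counts) && nrow(novel_counts)) {
    novel_counts <- novel_counts[, colnames(known_counts), drop = FALSE]
    counts <- rbind(known_counts, novel_counts)
  } else counts <- known_counts
  totals <- totals[colnames(counts)]
  if (any(colSums(counts) > totals))
    stopf("library totals smaller than column sums")
  list(counts = counts, totals = totals)
}
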