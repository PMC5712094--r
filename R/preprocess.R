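#' Default quality-control thresholds
#'
#' @param min_len,max_len retained insert length bounds (nt).
#' @param low_quality_frac,low_quality_phred discard a read when more than
#'   `low_quality_frac` of its bases fall below Phred `low_quality_phred`.
#' @param polya_frac,polya_run post-trim insert is poly-A when its A
#'   fraction reaches `polya_frac` or it contains an A-run of `polya_run`.
#' @param adapter_prefix length of the adapter prefix used for the exact
#'   search; `adapter_min_overlap` is the minimum read-suffix overlap
#'   (<= 1 mismatch) accepted as adapter evidence when no exact match.
#' @param adapter_min_overlap see above.
#' @return a named list of thresholds.
#' @export
qc_config <- function(min_len = 18L, max_len = 30L,
                      low_quality_frac = 0.1, low_quality_phred = 20L,
                      polya_frac = 0.8, polya_run = 10L,
                      adapter_prefix = 12L, adapter_min_overlap = 8L) {
  list(min_len = as.integer(min_len), max_len = as.integer(max_len),
       low_quality_frac = low_quality_frac,
       low_quality_phred = as.integer(low_quality_phred),
       polya_frac = polya_frac, polya_run = as.integer(polya_run),
       adapter_prefix = as.integer(adapter_prefix),
       adapter_min_overlap = as.integer(adapter_min_overlap))
}

# QC removal categories in precedence order (first match wins); the
# reported table needs disjoint categories, so an order is imposed:
# N-containing, then low quality, then adapter-only (insert null), then
# no-adapter-evidence (removed adapter), then poly-A, then length bounds.
QC_CATEGORIES <- c("n_containing", "low_quality", "insert_null",
                   "removed_adapter", "poly_a", "too_short", "too_long")

# classify + trim one library; returns insert per read and category
.clean_one <- function(reads, adapter, cfg) {
  n <- nrow(reads)
  seqs <- norm_seq(reads$seq)
  category <- rep("clean", n)

  has_n <- grepl("N", seqs, fixed = TRUE)
  category[has_n] <- "n_containing"

  # fraction of bases below the Phred threshold (Phred+33)
  thr_char <- rawToChar(as.raw(33L + cfg$low_quality_phred - 1L))
  low_pat <- sprintf("[^!-%s]", thr_char)  # keeps chars below threshold
  n_low <- nchar(reads$qual) - nchar(gsub(sprintf("[!-%s]", thr_char), "",
                                          reads$qual))
  frac_low <- n_low / nchar(reads$qual)
  lowq <- category == "clean" & frac_low > cfg$low_quality_frac
  category[lowq] <- "low_quality"

  # adapter search: exact prefix match anywhere, else read-suffix overlap
  pref <- substr(adapter, 1, min(nchar(adapter), cfg$adapter_prefix))
  pos <- rep(-1L, n)
  todo <- category == "clean"
  hit <- regexpr(pref, seqs[todo], fixed = TRUE)
  pos[todo] <- as.integer(hit)
  # suffix overlap >= adapter_min_overlap with <= 1 mismatch
  need <- todo & pos == -1L
  if (any(need)) {
    idx <- which(need)
    len <- nchar(seqs[idx])
    found <- rep(FALSE, length(idx))
    fpos <- rep(-1L, length(idx))
    kmax <- min(nchar(adapter), max(len) - 1L)
    ks <- if (kmax >= cfg$adapter_min_overlap)
      seq(kmax, cfg$adapter_min_overlap) else integer(0)
    for (k in ks) {
      open <- !found & len > k
      if (!any(open)) next
      suf <- substr(seqs[idx[open]], len[open] - k + 1L, len[open])
      ak <- substr(adapter, 1, k)
      mm <- mapply(function(a, b) {
        sum(utf8ToInt(a) != utf8ToInt(b))
      }, suf, rep(ak, length(suf)), USE.NAMES = FALSE)
      ok <- mm <= 1L
      found[which(open)[ok]] <- TRUE
      fpos[which(open)[ok]] <- len[which(open)[ok]] - k + 1L
    }
    pos[idx] <- fpos
  }
  insert <- seqs
  adap <- todo & pos > 0L
  insert[adap] <- substr(seqs[adap], 1, pos[adap] - 1L)
  category[todo & pos == 1L] <- "insert_null"
  # no adapter evidence: discard long reads (failed ligation); reads already
  # within the retained length range are treated as pre-trimmed inserts,
  # which makes cleaning idempotent on clean tags
  noad <- todo & pos == -1L
  category[noad & nchar(seqs) > cfg$max_len] <- "removed_adapter"

  todo <- category == "clean"
  ilen <- nchar(insert)
  n_a <- nchar(insert) - nchar(gsub("A", "", insert, fixed = TRUE))
  polya <- todo & ilen > 0 &
    (n_a / pmax(ilen, 1L) >= cfg$polya_frac |
       grepl(strrep("A", cfg$polya_run), insert, fixed = TRUE))
  category[polya] <- "poly_a"
  todo <- category == "clean"
  category[todo & ilen < cfg$min_len] <- "too_short"
  category[todo & ilen > cfg$max_len] <- "too_long"

  list(insert = insert, category = category)
}

#' Clean raw reads into unique 18-30 nt tags with a QC report
#'
#' Trims the 3' adapter, removes contaminant reads in a fixed precedence
#' order (N-containing, low quality, adapter-only/insert-null, no adapter
#' evidence, poly-A, too short, too long), and collapses the surviving
#' inserts into unique tags with per-library counts. The QC report
#' reconciles exactly: clean + all removal categories = raw count per
#' library, with percentages against the raw count.
#'
#' @param reads a data.frame (`id`, `seq`, `qual`) for one library, or a
#'   named list of such data.frames (one per library).
#' @param adapter 3' adapter sequence.
#' @param config thresholds from [qc_config()].
#' @return list with `tags` (data.frame: `sequence`, one count column per
#'   library), `qc` (per-library category counts and percentages) and
#'   `categories` (per-read category assignments, one vector per library).
#' @export
clean_reads <- function(reads, adapter, config = qc_config()) {
  if (is.data.frame(reads)) reads <- list(lib1 = reads)
  if (is.null(names(reads))) stopf("library list must be named")
  adapter <- norm_seq(adapter)
  if (!nzchar(adapter)) stopf("adapter must be non-empty")

  per_lib <- lapply(reads, .clean_one, adapter = adapter, cfg = config)
  libs <- names(reads)

  tag_tabs <- lapply(libs, function(lib) {
    r <- per_lib[[lib]]
    keep <- r$category == "clean"
    if (!any(keep)) {
      return(data.table::data.table(sequence = character(),
                                    count = integer(), library = lib))
    }
    dt <- data.table::data.table(sequence = r$insert[keep])
    dt <- dt[, list(count = .N), by = "sequence"]
    dt$library <- lib
    dt
  })
  all_tags <- data.table::rbindlist(tag_tabs)
  if (nrow(all_tags)) {
    wide <- data.table::dcast(all_tags, sequence ~ library,
                              value.var = "count", fill = 0L)
    miss <- setdiff(libs, names(wide))
    for (m in miss) wide[[m]] <- 0L
    data.table::setcolorder(wide, c("sequence", libs))
    data.table::setorder(wide, sequence)
    tags <- as.data.frame(wide)
  } else {
    tags <- data.frame(sequence = character(), stringsAsFactors = FALSE)
    for (lib in libs) tags[[lib]] <- integer()
  }

  qc <- do.call(rbind, lapply(libs, function(lib) {
    cat_ <- per_lib[[lib]]$category
    raw <- length(cat_)
    cnt <- c(clean = sum(cat_ == "clean"),
             vapply(QC_CATEGORIES, function(k) sum(cat_ == k), 0L))
    pct <- if (raw > 0) 100 * cnt / raw else cnt * 0
    out <- data.frame(library = lib, raw = raw, t(cnt),
                      stringsAsFactors = FALSE, check.names = FALSE)
    names(pct) <- paste0(names(cnt), "_pct")
    cbind(out, t(pct))
  }))
  rownames(qc) <- NULL
  list(tags = tags,
       qc = qc,
       categories = lapply(per_lib, `[[`, "category"))
}

#' Write collapsed tags as FASTA
#'
#' Headers follow the conventional collapsed-read form
#' `>tag{serial}_x{count}` with the count summed over libraries.
#'
#' @param tags tag table from [clean_reads()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_collapsed_tags <- function(tags, path) {
  libs <- setdiff(names(tags), "sequence")
  total <- rowSums(as.matrix(tags[libs]))
  write_fasta(setNames(tags$sequence,
                       sprintf("tag%d_x%d", seq_len(nrow(tags)), total)),
              path)
}

#' Length distribution of unique tags and total reads
#'
#' @param tags tag table from [clean_reads()] (`sequence` + count columns).
#' @param range length range reported (default 18:30).
#' @return data.frame with one row per length and, per library, the
#'   count-weighted total-read fraction (`<lib>_reads`) and unweighted
#'   unique-tag fraction (`<lib>_unique`); each column sums to 1.
#' @export
length_distribution <- function(tags, range = 18:30) {
  if (!nrow(tags)) stopf("empty tag set")
  libs <- setdiff(names(tags), "sequence")
  len <- nchar(tags$sequence)
  out <- data.frame(length = range)
  for (lib in libs) {
    cnt <- tags[[lib]]
    tot <- vapply(range, function(L) sum(cnt[len == L]), 0)
    uni <- vapply(range, function(L) sum(len == L & cnt > 0), 0)
    out[[paste0(lib, "_reads")]] <- if (sum(tot) > 0) tot / sum(tot) else tot
    out[[paste0(lib, "_unique")]] <- if (sum(uni) > 0) uni / sum(uni) else uni
  }
  out
}

# exact-match positions of tags in the genome, both strands;
# returns a GRanges with a tag_index metadata column
.map_tags <- function(sequences, genome) {
  chroms <- names(genome)
  res <- list()
  widths <- nchar(sequences)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(sequences[idx]))
    for (ch in chroms) {
      subj <- Biostrings::DNAString(genome[[ch]])
      si <- Biostrings::startIndex(Biostrings::matchPDict(pd, subj))
      nh <- lengths(si)
      if (sum(nh)) {
        res[[length(res) + 1L]] <- GenomicRanges::GRanges(
          ch, IRanges::IRanges(unlist(si, use.names = FALSE), width = w),
          strand = "+", tag_index = rep(idx, nh))
      }
      sir <- Biostrings::startIndex(
        Biostrings::matchPDict(pd, Biostrings::reverseComplement(subj)))
      nhr <- lengths(sir)
      if (sum(nhr)) {
        glen <- length(subj)
        # position on the forward strand for a revcomp match
        rstart <- unlist(sir, use.names = FALSE)
        fstart <- glen - (rstart + w - 1L) + 1L
        res[[length(res) + 1L]] <- GenomicRanges::GRanges(
          ch, IRanges::IRanges(fstart, width = w), strand = "-",
          tag_index = rep(idx, nhr))
      }
    }
  }
  if (!length(res)) {
    return(GenomicRanges::GRanges(tag_index = integer(0)))
  }
  do.call(c, res)
}

# annotation class precedence for tag assignment
CLASS_PRECEDENCE <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "scRNA",
                      "repeat", "exon", "intron")

#' Classify unique tags by genomic annotation
#'
#' Maps each tag to the genome (exact full-length match, both strands) and
#' assigns one class by precedence: miRNA (miRNA_primary_transcript loci),
#' then rRNA, tRNA, snRNA, snoRNA, scRNA, then repeat, exon, intron; a
#' multi-mapping tag takes the highest-precedence class over all its loci.
#' Mapped tags overlapping no feature, and unmapped tags, are
#' `unannotated`.
#'
#' @param tags tag table from [clean_reads()].
#' @param genome named character vector of chromosome sequences.
#' @param annotation GRanges with a `type` metadata column
#'   (miRNA_primary_transcript, rRNA, tRNA, snRNA, snoRNA, scRNA,
#'   repeat_region, exon, intron).
#' @return list with `assignment` (per-tag class + mapping count),
#'   `breakdown` (per-class totals for reads and unique tags) and `hits`
#'   (GRanges of all exact-match loci with `tag_index`).
#' @export
classify_tags <- function(tags, genome, annotation) {
  bad <- setdiff(as.character(GenomicRanges::seqnames(annotation)),
                 names(genome))
  if (length(bad)) {
    stopf("annotation references unknown chromosome: %s",
          paste(unique(bad), collapse = ","))
  }
  libs <- setdiff(names(tags), "sequence")
  hits <- .map_tags(tags$sequence, genome)

  type <- as.character(annotation$type)
  type[type == "miRNA_primary_transcript"] <- "miRNA"
  type[type == "repeat_region"] <- "repeat"

  cls <- rep("unannotated", nrow(tags))
  if (length(hits)) {
    ov <- GenomicRanges::findOverlaps(hits, annotation,
                                      ignore.strand = TRUE)
    if (length(ov)) {
      dt <- data.table::data.table(
        tag = hits$tag_index[S4Vectors::queryHits(ov)],
        rank = match(type[S4Vectors::subjectHits(ov)], CLASS_PRECEDENCE))
      dt <- dt[!is.na(dt$rank)]
      if (nrow(dt)) {
        best <- dt[, list(rank = min(rank)), by = "tag"]
        cls[best$tag] <- CLASS_PRECEDENCE[best$rank]
      }
    }
    mapped <- unique(hits$tag_index)
  } else mapped <- integer(0)

  n_loci <- integer(nrow(tags))
  if (length(hits)) {
    tab <- table(hits$tag_index)
    n_loci[as.integer(names(tab))] <- as.integer(tab)
  }
  assignment <- data.frame(sequence = tags$sequence, class = cls,
                           n_loci = n_loci, stringsAsFactors = FALSE)

  total_counts <- rowSums(as.matrix(tags[libs]))
  classes <- c(CLASS_PRECEDENCE, "unannotated")
  breakdown <- data.frame(
    class = classes,
    reads = vapply(classes, function(k) sum(total_counts[cls == k]), 0),
    unique = vapply(classes, function(k) sum(cls == k), 0),
    stringsAsFactors = FALSE)
  rownames(breakdown) <- NULL
  list(assignment = assignment, breakdown = breakdown, hits = hits)
}
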