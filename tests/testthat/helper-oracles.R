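# Independent oracles used by the property and acceptance tests. These are
# deliberately naive re-implementations (loops, enumeration) kept separate
# from the package code paths they check.

# --- exhaustive secondary-structure enumeration -----------------------------
# Enumerates every pseudoknot-free structure (min loop 3) over WC + G:U
# pairs and scores each complete structure with the stacked-pair rule
# (-2 per G:C pair stacked directly inside an adjacent pair, -1 for
# A:U / G:U). Returns the minimum energy. Independent of the DP.
oracle_fold_mfe <- function(seq, allow_gu = TRUE) {
  s <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  n <- length(s)
  pairable <- function(a, b) {
    p <- paste0(sort(c(a, b)), collapse = "")
    p %in% c("AT", "CG") || (allow_gu && p == "GT")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < 4) return(list(integer(0)))
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- rec(i + 1, j)                       # i unpaired
    for (k in (i + 4):j) {
      if (!pairable(s[i], s[k])) next
      left <- rec(i + 1, k - 1)
      right <- if (k + 1 <= j) rec(k + 1, j) else list(integer(0))
      for (L in left) for (R in right) {
        out[[length(out) + 1L]] <- c(i, k, L, R)
      }
    }
    memo[[key]] <- out
    out
  }
  structs <- rec(1, n)
  energy <- function(pairs) {
    if (!length(pairs)) return(0)
    partner <- integer(n)
    a <- pairs[seq(1, length(pairs), 2)]
    b <- pairs[seq(2, length(pairs), 2)]
    partner[a] <- b
    partner[b] <- a
    e <- 0
    for (k in seq_along(a)) {
      i <- a[k]; j <- b[k]
      if (i > 1 && j < n && partner[i - 1] == j + 1) {
        e <- e + if (paste0(sort(c(s[i], s[j])), collapse = "") == "CG") -2 else -1
      }
    }
    e
  }
  min(vapply(structs, energy, 0))
}

# --- brute-force duplex scorer + rule checker -------------------------------
# Direct loop-based restatement of the six rules; its own pairing tables.
oracle_check_rules <- function(mirna, site, mfe_fraction = 0.75) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- strsplit(chartr("U", "T", toupper(mirna)), "")[[1]]
  sb <- rev(strsplit(chartr("U", "T", toupper(site)), "")[[1]])
  L <- length(m)
  state <- character(L)
  for (i in seq_len(L)) {
    if (comp[[m[i]]] == sb[i]) state[i] <- "WC"
    else if ((m[i] == "G" && sb[i] == "T") ||
             (m[i] == "T" && sb[i] == "G")) state[i] <- "GU"
    else state[i] <- "mm"
  }
  score <- ifelse(state == "WC", 0, ifelse(state == "GU", 0.5, 1))
  # stacked-pair energies, written as an explicit loop
  pairenergy <- function(i) {
    if (state[i] == "WC" && m[i] %in% c("G", "C")) -2 else -1
  }
  dup <- 0; per <- 0
  for (i in 2:L) {
    if (state[i] != "mm" && state[i - 1] != "mm") dup <- dup + pairenergy(i)
    per <- per + if (m[i] %in% c("G", "C")) -2 else -1
  }
  ratio <- if (per < 0) dup / per else NA_real_
  # a: <= two adjacent mismatches (no run of 3+)
  run <- 0; maxrun <- 0
  for (i in seq_len(L)) {
    run <- if (state[i] == "mm") run + 1 else 0
    maxrun <- max(maxrun, run)
  }
  a <- maxrun <= 2
  # b: <= 4 mismatch score total
  b <- sum(score) <= 4
  # c: <= 2.5 over positions 1-12
  c_ <- sum(score[1:min(12, L)]) <= 2.5
  # d: no mismatches at 10-11
  d <- !(state[10] == "mm" || state[11] == "mm")
  # e: no adjacent mismatches within positions 2-12
  e <- TRUE
  for (i in 2:11) {
    if (i + 1 <= 12 && state[i] == "mm" && state[i + 1] == "mm") e <- FALSE
  }
  f <- !is.na(ratio) && ratio >= mfe_fraction
  c(a = a, b = b, c = c_, d = d, e = e, f = f)
}

# --- brute-force Hamming matcher --------------------------------------------
oracle_match <- function(sequences, db, max_mm = 2) {
  ids <- sort(names(db))
  db <- db[ids]
  db_split <- strsplit(unname(db), "")
  out_id <- rep(NA_character_, length(sequences))
  out_mm <- rep(NA_integer_, length(sequences))
  for (t in seq_along(sequences)) {
    tb <- strsplit(sequences[t], "")[[1]]
    best <- NA_integer_
    bid <- NA_character_
    for (j in seq_along(db)) {
      eb <- db_split[[j]]
      if (length(eb) != length(tb)) next
      mm <- sum(tb != eb)
      if (mm <= max_mm && (is.na(best) || mm < best)) {
        best <- mm
        bid <- ids[j]
      }
    }
    out_id[t] <- bid
    out_mm[t] <- best
  }
  data.frame(sequence = sequences, mirna = out_id, mismatches = out_mm,
             stringsAsFactors = FALSE)
}

# --- exhaustive per-position interval classifier ----------------------------
# Scans every annotation row for overlap with a tag locus; precedence
# identical to the documented order but resolved by explicit looping.
oracle_classify_locus <- function(start, end, ann_df) {
  prec <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "scRNA",
            "repeat", "exon", "intron")
  found <- character(0)
  for (r in seq_len(nrow(ann_df))) {
    if (start <= ann_df$end[r] && end >= ann_df$start[r]) {
      ty <- ann_df$type[r]
      if (ty == "miRNA_primary_transcript") ty <- "miRNA"
      if (ty == "repeat_region") ty <- "repeat"
      found <- c(found, ty)
    }
  }
  hit <- prec[prec %in% found]
  if (length(hit)) hit[1] else "unannotated"
}

# random duplex generator: revcomp of the miRNA with k random edits that
# create mismatches or G:U wobbles at random positions
random_duplex_site <- function(mirna, n_mm, n_gu) {
  m <- strsplit(mirna, "")[[1]]
  L <- length(m)
  sb <- strsplit(revcomp(mirna), "")[[1]]
  pos <- sample(L, min(L, n_mm + n_gu))
  mmp <- pos[seq_len(n_mm)]
  gup <- setdiff(pos, mmp)
  for (i in mmp) sb[L - i + 1] <- m[i]  # same base never pairs
  for (i in gup) {
    # force G:U where the miRNA base allows it, else a mismatch
    sb[L - i + 1] <- if (m[i] == "G") "T" else if (m[i] == "T") "G"
                     else m[i]
  }
  paste(sb, collapse = "")
}
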