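#' Generate a synthetic small-RNA reference bundle
#'
#' Builds a toy genome with embedded miRNA precursor hairpins (a "known"
#' set whose matures go into the mature-miRNA database, and a "novel" set
#' left unannotated for the discovery stage to find), annotated ncRNA /
#' repeat / exon / intron loci, and a transcript set carrying planted
#' miRNA target sites with controlled rule violations. Every mature
#' sequence occurs verbatim in its precursor arm, precursor loci never
#' overlap ncRNA loci, and every violation-free planted target site
#' passes the package's own rule checker (verified at construction).
#'
#' The genome is sized to `genome_factor` times the total embedded feature
#' length (default 10x), with feature order and spacer lengths randomized
#' under `seed`; a fixed seed gives bit-identical output.
#'
#' @param n_known,n_novel numbers of database-known and novel precursors.
#' @param n_per_ncrna_class loci per ncRNA class (rRNA, tRNA, snRNA,
#'   snoRNA, scRNA).
#' @param n_repeat,n_exon,n_intron further annotated locus counts.
#' @param n_transcripts transcripts in the target-scan set.
#' @param genome_factor genome length as a multiple of embedded feature
#'   length (must leave at least 20 nt between features).
#' @param chrom_length optional explicit chromosome length; an error names
#'   the deficit when it cannot hold the requested features.
#' @param seed integer RNG seed.
#' @return an object of class `srna_reference`.
#' @export
synthetic_reference <- function(n_known = 12, n_novel = 8,
                                n_per_ncrna_class = 3, n_repeat = 4,
                                n_exon = 6, n_intron = 6,
                                n_transcripts = 20, genome_factor = 10,
                                chrom_length = NULL, seed = 1) {
  set.seed(seed)
  n_mir <- n_known + n_novel
  stopifnot(n_known >= 1, n_novel >= 0)

  # --- mature miRNAs and hairpin precursors ------------------------------
  mat_len <- sample(c(20L, 21L, 22L, 24L), n_mir, replace = TRUE,
                    prob = c(0.10, 0.65, 0.15, 0.10))
  matures <- vapply(mat_len, function(L) random_seq(1, L), "")
  fam <- 150 + ceiling(seq_len(n_known) / 2)
  letter <- rep(c("a", "b"), length.out = n_known)
  known_ids <- sprintf("ppa-miR%d%s", fam, letter)
  novel_ids <- sprintf("novel-m%02d", seq_len(n_novel))
  ids <- c(known_ids, novel_ids)

  build_precursor <- function(mature) {
    f1 <- random_seq(1, 10)
    ext <- random_seq(1, 15)
    loop <- random_seq(1, 11, gc = 0.25)  # AU-rich loop folds less
    f2 <- random_seq(1, 10)
    seq <- paste0(f1, mature, ext, loop, revcomp(ext), revcomp(mature), f2)
    list(seq = seq, mature_start = 11L, mature_len = nchar(mature))
  }
  precs <- lapply(matures, build_precursor)

  # --- other annotated features ------------------------------------------
  nc_classes <- rep(c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA"),
                    each = n_per_ncrna_class)
  other <- data.frame(
    type = c(nc_classes, rep("repeat_region", n_repeat),
             rep("exon", n_exon), rep("intron", n_intron)),
    len = c(sample(80:200, length(nc_classes), replace = TRUE),
            sample(100:300, n_repeat, replace = TRUE),
            sample(100:250, n_exon, replace = TRUE),
            sample(80:250, n_intron, replace = TRUE)),
    stringsAsFactors = FALSE)
  other$seq <- vapply(other$len, function(L) random_seq(1, L), "")
  other$id <- sprintf("%s_%03d", tolower(sub("_region", "", other$type)),
                      seq_len(nrow(other)))

  # --- assemble the chromosome -------------------------------------------
  feat <- data.frame(
    id = c(ids, other$id),
    type = c(rep("miRNA_primary_transcript", n_mir), other$type),
    seq = c(vapply(precs, `[[`, "", "seq"), other$seq),
    stringsAsFactors = FALSE)
  feat$len <- nchar(feat$seq)
  feat <- feat[sample(nrow(feat)), , drop = FALSE]
  total_feat <- sum(feat$len)
  min_gap <- 20L
  needed <- total_feat + (nrow(feat) + 1L) * min_gap
  glen <- if (is.null(chrom_length)) genome_factor * total_feat
          else as.integer(chrom_length)
  if (glen < needed) {
    stopf("chromosome length %d cannot hold %d nt of features plus minimum gaps (need >= %d, deficit %d nt)",
          glen, total_feat, needed, needed - glen)
  }
  free <- glen - total_feat - (nrow(feat) + 1L) * min_gap
  gw <- as.vector(rmultinom(1, free, rep(1, nrow(feat) + 1L))) + min_gap
  strand <- sample(c("+", "-"), nrow(feat), replace = TRUE)
  pieces <- character(2L * nrow(feat) + 1L)
  starts <- integer(nrow(feat))
  pos <- 0L
  for (k in seq_len(nrow(feat))) {
    pieces[2L * k - 1L] <- random_seq(1, gw[k])
    pos <- pos + gw[k]
    starts[k] <- pos + 1L
    emb <- if (strand[k] == "-") revcomp(feat$seq[k]) else feat$seq[k]
    pieces[2L * k] <- emb
    pos <- pos + feat$len[k]
  }
  pieces[2L * nrow(feat) + 1L] <- random_seq(1, gw[nrow(feat) + 1L])
  genome <- setNames(paste(pieces, collapse = ""), "chr1")
  feat$start <- starts
  feat$end <- starts + feat$len - 1L
  feat$strand <- strand

  ann <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(feat$start, feat$end),
    strand = feat$strand, type = feat$type, ID = feat$id)
  idx <- match(ids, feat$id)
  precursors <- data.frame(
    id = ids, known = c(rep(TRUE, n_known), rep(FALSE, n_novel)),
    chrom = "chr1", start = feat$start[idx], end = feat$end[idx],
    strand = feat$strand[idx],
    mature_start = vapply(precs, `[[`, 1L, "mature_start"),
    mature_len = mat_len,
    seq = vapply(precs, `[[`, "", "seq"),
    mature = matures, stringsAsFactors = FALSE)
  # novel precursors stay out of the annotation: they are what discovery
  # is supposed to find from unannotated tags
  ann <- ann[!(ann$ID %in% novel_ids)]

  # --- transcripts with planted target sites -----------------------------
  tx_len <- sample(300:600, n_transcripts, replace = TRUE)
  transcripts <- setNames(vapply(tx_len, function(L) random_seq(1, L), ""),
                          sprintf("tx%02d", seq_len(n_transcripts)))
  sites <- list()
  n_pass <- min(n_known, 8L, n_transcripts)
  for (i in seq_len(n_pass)) {
    pl <- plant_target_site(transcripts[[i]], matures[i], "none")
    transcripts[[i]] <- pl$sequence
    sites[[length(sites) + 1L]] <- data.frame(
      transcript = names(transcripts)[i], mirna = ids[i],
      violation = "none", start = pl$site$start,
      failed_rules = pl$site$failed_rules, stringsAsFactors = FALSE)
  }
  viol <- c("a", "b", "c", "d", "e", "f")
  for (k in seq_along(viol)) {
    ti <- n_pass + k
    if (ti > n_transcripts) break
    mi <- ((k - 1L) %% n_known) + 1L
    pl <- plant_target_site(transcripts[[ti]], matures[mi], viol[k])
    transcripts[[ti]] <- pl$sequence
    sites[[length(sites) + 1L]] <- data.frame(
      transcript = names(transcripts)[ti], mirna = ids[mi],
      violation = viol[k], start = pl$site$start,
      failed_rules = pl$site$failed_rules, stringsAsFactors = FALSE)
  }
  target_sites <- do.call(rbind, sites)

  structure(list(
    genome = genome, annotation = ann,
    mirna_db = setNames(matures[seq_len(n_known)], known_ids),
    precursors = precursors, transcripts = transcripts,
    target_sites = target_sites,
    params = list(n_known = n_known, n_novel = n_novel, seed = seed,
                  genome_length = glen)),
    class = "srna_reference")
}

#' Plant a miRNA target site into a transcript
#'
#' Embeds the reverse complement of the miRNA, optionally edited so that
#' the site violates exactly one of the six target-prediction rules while
#' satisfying the others where arithmetically possible (a violation that
#' unavoidably degrades the duplex MFE may also trip rule f; the intended
#' rule is always among the failures, which are recorded). Mismatches are
#' created by copying the miRNA base into the facing site position, which
#' can never form a Watson-Crick or G:U pair.
#'
#' @param transcript transcript sequence to edit.
#' @param mirna mature miRNA sequence (20-24 nt).
#' @param violation "none" or a single rule id "a".."f".
#' @param pos optional 0-based site start; random interior position if NULL.
#' @return list with `sequence` (edited transcript) and `site` (a list:
#'   `start` 0-based, `site_seq`, `violation`, `failed_rules`).
#' @export
plant_target_site <- function(transcript, mirna, violation = "none",
                              pos = NULL) {
  mirna <- norm_seq(mirna)
  L <- nchar(mirna)
  if (L < 20 || L > 24) stopf("miRNA length must be 20-24 nt, got %d", L)
  violation <- match.arg(violation, c("none", letters[1:6]))
  mb <- strsplit(mirna, "")[[1]]

  edit_site <- function(mm_pos) {
    sb <- strsplit(revcomp(mirna), "")[[1]]
    for (i in mm_pos) sb[L - i + 1L] <- mb[i]  # same base never pairs
    paste(sb, collapse = "")
  }
  check <- function(site) apply_rules(score_duplex(mirna, site))

  site <- NULL
  if (violation == "none") {
    site <- edit_site(integer(0))
    v <- check(site)
    if (!v$pass) stopf("internal: perfect site failed rules")
  } else if (violation == "a") {
    site <- edit_site(c(13L, 14L, 15L))
  } else if (violation == "b") {
    site <- edit_site(c(1L, 13L, 15L, 17L, 19L))
  } else if (violation == "c") {
    site <- edit_site(c(3L, 5L, 7L))
  } else if (violation == "d") {
    site <- edit_site(10L)
  } else if (violation == "e") {
    site <- edit_site(c(5L, 6L))
  } else if (violation == "f") {
    cand <- list(c(14L), c(14L, 17L), c(14L, min(17L, L - 1L), L - 1L),
                 c(5L, 14L, 17L, min(L - 1L, 20L)),
                 c(3L, 6L, 14L, 17L), c(3L, 6L, 15L, 18L))
    cand <- lapply(cand, function(p) unique(pmin(p, L - 1L)))
    cand <- Filter(function(p) all(diff(sort(p)) >= 2) &&
                     !any(p %in% c(10L, 11L)), cand)
    for (p in cand) {
      s <- edit_site(p)
      v <- check(s)
      if (!v$rules[["f"]] && all(v$rules[letters[1:5]])) { site <- s; break }
    }
    if (is.null(site)) {
      stopf("cannot construct a single-rule violation of rule f for this miRNA (duplex too AU-poor to drop below the MFE fraction within 4 mismatches)")
    }
  }
  verdict <- check(site)
  if (violation != "none" && verdict$rules[[violation]]) {
    stopf("planted site does not violate rule %s", violation)
  }
  failed <- names(verdict$rules)[!verdict$rules]
  tn <- nchar(transcript)
  if (tn < L + 2) stopf("transcript too short to hold a site")
  if (is.null(pos)) {
    lo <- min(50L, max(0L, tn - L - 1L))
    hi <- max(lo, tn - L - min(50L, tn - L))
    pos <- if (hi > lo) sample(lo:hi, 1L) else lo
  }
  if (pos < 0 || pos + L > tn) stopf("site position out of range")
  sequence <- paste0(substr(transcript, 1, pos), site,
                     substr(transcript, pos + L + 1, tn))
  list(sequence = sequence,
       site = list(start = as.integer(pos), site_seq = site,
                   violation = violation,
                   failed_rules = paste(failed, collapse = ",")))
}

#' Describe a two-condition simulation design
#'
#' Holds the library layout (three control CK and three treatment T
#' replicates by default), sequencing depth, per-miRNA baseline expression
#' weights, planted treatment/control expression ratios, contaminant
#' fractions per QC category, adapter, and seed.
#'
#' @param n_replicates replicates per condition (default 3: CK1-3 / T1-3).
#' @param depth expected reads per library.
#' @param expression_profile optional named weights per miRNA id; drawn
#'   log-normally at simulation time when NULL.
#' @param planted_ratios named treatment/control expression ratios; ids
#'   must exist in the expression profile.
#' @param contamination named fractions for categories `removed_adapter`,
#'   `insert_null`, `n_containing`, `too_short`, `poly_a`, `too_long`,
#'   `low_quality`; each in \[0,1\], summing to < 1. Defaults approximate a
#'   typical small-RNA run (dominant too-short fraction, sub-percent
#'   adapter-only and low-quality reads).
#' @param class_fractions composition of the genomic (non-contaminant)
#'   reads over origin classes; must sum to 1.
#' @param adapter 3' adapter ligated to every genuine insert (default: the
#'   standard Illumina small-RNA 3' adapter).
#' @param read_length raw read length in nt.
#' @param seed integer seed; fixed seed gives byte-identical FASTQ.
#' @return an object of class `simulation_design`.
#' @export
simulation_design <- function(n_replicates = 3, depth = 200000,
                              expression_profile = NULL,
                              planted_ratios = numeric(0),
                              contamination = c(
                                removed_adapter = 0.001, insert_null = 0.015,
                                n_containing = 0.002, too_short = 0.18,
                                poly_a = 0.0005, too_long = 0.06,
                                low_quality = 0.001),
                              class_fractions = c(
                                miRNA = 0.55, rRNA = 0.12, tRNA = 0.08,
                                snRNA = 0.03, snoRNA = 0.03, scRNA = 0.01,
                                "repeat" = 0.04, exon = 0.05, intron = 0.03,
                                intergenic = 0.06),
                              adapter = "TGGAATTCTCGGGTGCCAAGG",
                              read_length = 50, seed = 1) {
  if (depth <= 0) stopf("depth must be > 0")
  if (!nzchar(adapter)) stopf("adapter must be non-empty")
  need <- c("removed_adapter", "insert_null", "n_containing", "too_short",
            "poly_a", "too_long", "low_quality")
  miss <- setdiff(need, names(contamination))
  if (length(miss)) stopf("contamination missing: %s", paste(miss, collapse = ","))
  contamination <- contamination[need]
  if (any(contamination < 0) || any(contamination > 1) ||
      sum(contamination) >= 1) {
    stopf("contamination fractions must each lie in [0,1] and sum to < 1")
  }
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stopf("class_fractions must sum to 1")
  if (length(planted_ratios)) {
    if (is.null(names(planted_ratios))) stopf("planted_ratios must be named")
    if (any(planted_ratios <= 0)) stopf("planted ratios must be > 0")
    if (!is.null(expression_profile) &&
        !all(names(planted_ratios) %in% names(expression_profile))) {
      stopf("planted_ratios keys missing from expression_profile")
    }
  }
  structure(list(n_replicates = as.integer(n_replicates),
                 depth = as.integer(depth),
                 expression_profile = expression_profile,
                 planted_ratios = planted_ratios,
                 contamination = contamination,
                 class_fractions = class_fractions,
                 adapter = norm_seq(adapter),
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "simulation_design")
}

# insert-length distribution over 18-30 nt for non-miRNA reads:
# dominant 21 nt mode with ~2x the mass of the secondary 24 nt mode
LENGTH_WEIGHTS <- c(`18` = 0.05, `19` = 0.06, `20` = 0.08, `21` = 0.30,
                    `22` = 0.08, `23` = 0.07, `24` = 0.15, `25` = 0.05,
                    `26` = 0.04, `27` = 0.035, `28` = 0.03, `29` = 0.025,
                    `30` = 0.03)

# expected per-origin intensities for one library (fraction of depth);
# treatment libraries scale miRNA intensities by the planted ratios, so the
# expected treatment/control count ratio of a planted miRNA is exactly the
# planted ratio (library size floats slightly instead)
.origin_intensity <- function(ref, design, weights, treated) {
  contam <- design$contamination
  g <- 1 - sum(contam)
  cf <- design$class_fractions
  w <- weights / sum(weights)
  r <- rep(1, length(w))
  names(r) <- names(w)
  if (treated && length(design$planted_ratios)) {
    r[names(design$planted_ratios)] <- design$planted_ratios
  }
  mir <- g * cf[["miRNA"]] * w * r
  other <- g * cf[setdiff(names(cf), "miRNA")]
  c(contam, mir, setNames(as.numeric(other), setdiff(names(cf), "miRNA")))
}

#' Simulate per-library true counts per origin
#'
#' Counts per origin (miRNA id, ncRNA/repeat/exon/intron class, intergenic,
#' or contaminant category) are drawn independently Poisson with expected
#' value depth x intensity — equivalently, multinomial sampling conditioned
#' on the realized library size. Treatment libraries multiply planted
#' miRNAs' intensities by their ratios, so expected count ratios equal the
#' planted ratios exactly.
#'
#' @param ref an `srna_reference`.
#' @param design a `simulation_design`.
#' @return list with `counts` (data.frame origin x library), `weights`,
#'   `truth` (per-miRNA ratio/regulation table) and `warnings`.
#' @export
simulate_counts <- function(ref, design) {
  stopifnot(inherits(ref, "srna_reference"),
            inherits(design, "simulation_design"))
  ids <- ref$precursors$id
  weights <- design$expression_profile
  if (is.null(weights)) {
    weights <- setNames(rlnorm(length(ids), meanlog = 3, sdlog = 1.2), ids)
    # planted miRNAs get median-abundance baselines: a planted fold-change
    # on a composition-dominating miRNA would shift the library total and
    # confound the RPM normalization it is meant to test
    pl <- intersect(names(design$planted_ratios), ids)
    if (length(pl)) weights[pl] <- stats::median(weights)
  }
  if (!all(ids %in% names(weights))) stopf("expression profile missing ids")
  weights <- weights[ids]
  if (length(design$planted_ratios) &&
      !all(names(design$planted_ratios) %in% ids)) {
    stopf("planted_ratios name unknown miRNAs")
  }
  libs <- c(sprintf("CK%d", seq_len(design$n_replicates)),
            sprintf("T%d", seq_len(design$n_replicates)))
  treated <- grepl("^T", libs)
  cols <- lapply(seq_along(libs), function(k) {
    intens <- .origin_intensity(ref, design, weights, treated[k])
    rpois(length(intens), design$depth * intens)
  })
  intens0 <- .origin_intensity(ref, design, weights, FALSE)
  counts <- as.data.frame(cols, col.names = libs)
  rownames(counts) <- names(intens0)

  r <- setNames(rep(1, length(ids)), ids)
  if (length(design$planted_ratios))
    r[names(design$planted_ratios)] <- design$planted_ratios
  reg <- ifelse(r > 2, "up", ifelse(r < 0.5, "down", "unchanged"))
  exp_ck <- design$depth * intens0[ids] * design$n_replicates
  truth <- data.frame(id = ids, weight = as.numeric(weights),
                      ratio = as.numeric(r), regulation = reg,
                      expected_pooled_control = as.numeric(exp_ck),
                      stringsAsFactors = FALSE)
  warn <- character(0)
  low <- names(design$planted_ratios)[
    design$depth * intens0[names(design$planted_ratios)] < 1]
  if (length(low)) {
    warn <- sprintf("planted miRNA %s has expected per-library count < 1",
                    low)
  }
  list(counts = counts, weights = weights, truth = truth, warnings = warn)
}

# uniformly sample n intergenic (feature-free) positions able to hold 'len'
.sample_intergenic <- function(ref, n, lens) {
  glen <- nchar(ref$genome)
  feats <- GenomicRanges::reduce(ref$annotation, ignore.strand = TRUE)
  nov <- ref$precursors[!ref$precursors$known, , drop = FALSE]
  if (nrow(nov)) {
    feats <- GenomicRanges::reduce(c(feats, GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(nov$start, nov$end))), ignore.strand = TRUE)
  }
  gaps <- IRanges::gaps(IRanges::ranges(feats), start = 1, end = glen)
  gw <- IRanges::width(gaps)
  ok <- gw >= max(lens) + 1L
  gaps <- gaps[ok]; gw <- gw[ok]
  gi <- sample.int(length(gaps), n, replace = TRUE, prob = gw)
  off <- floor(runif(n) * (gw[gi] - lens)) + 1L
  IRanges::start(gaps)[gi] + off - 1L
}

#' Simulate two-condition small-RNA FASTQ libraries with ground truth
#'
#' Builds reads as insert + 3' adapter (+ a fixed downstream filler),
#' truncated to the read length, with contaminant classes injected at the
#' design fractions and miRNA reads sampled under the planted expression
#' ratios. Clean reads carry Phred+33 quality I (Q40) everywhere;
#' low-quality contaminants have >= 20% of bases below Q10. Each read id
#' records its true origin, and a per-library origin count table is
#' returned as ground truth. Fixed seed gives byte-identical FASTQ output.
#'
#' @param ref an `srna_reference`.
#' @param design a `simulation_design`.
#' @param outdir optional directory; when given, `CK1..T{n}.fastq.gz` and
#'   `ground_truth.tsv` are written there.
#' @return list with `reads` (per-library data.frames id/seq/qual),
#'   `truth` (origin counts, per-miRNA truth, warnings) and `files`.
#' @export
simulate_libraries <- function(ref, design, outdir = NULL) {
  set.seed(design$seed)
  sim <- simulate_counts(ref, design)
  libs <- colnames(sim$counts)
  adapter <- design$adapter
  rl <- design$read_length
  filler <- paste(rep("CGTATGCCGTCTTCTGCTTG", 4), collapse = "")
  q_hi <- strrep("I", rl)

  mature_seq <- setNames(ref$precursors$mature, ref$precursors$id)
  class_loci <- list()
  for (cl in c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA")) {
    class_loci[[cl]] <- ref$annotation[ref$annotation$type == cl]
  }
  class_loci[["repeat"]] <- ref$annotation[ref$annotation$type == "repeat_region"]
  class_loci[["exon"]] <- ref$annotation[ref$annotation$type == "exon"]
  class_loci[["intron"]] <- ref$annotation[ref$annotation$type == "intron"]

  lens_pool <- as.integer(names(LENGTH_WEIGHTS))

  frag_from_loci <- function(gr, n) {
    if (!length(gr) || n == 0) return(character(n))
    li <- sample.int(length(gr), n, replace = TRUE)
    lw <- GenomicRanges::width(gr)[li]
    fl <- pmin(sample(lens_pool, n, replace = TRUE, prob = LENGTH_WEIGHTS), lw)
    off <- floor(runif(n) * (lw - fl + 1L))
    s <- GenomicRanges::start(gr)[li] + off
    frag <- substring(ref$genome, s, s + fl - 1L)
    neg <- as.character(GenomicRanges::strand(gr))[li] == "-"
    frag[neg] <- revcomp(frag[neg])
    frag
  }

  reads <- list()
  origin_counts <- list()
  for (lib in libs) {
    cnt <- setNames(sim$counts[[lib]], rownames(sim$counts))
    inserts <- character(0)
    origins <- character(0)
    add <- function(seqs, label) {
      inserts <<- c(inserts, seqs)
      origins <<- c(origins, rep(label, length(seqs)))
    }
    for (id in names(mature_seq)) {
      if (cnt[[id]] > 0) add(rep(mature_seq[[id]], cnt[[id]]), id)
    }
    for (cl in names(class_loci)) {
      if (cnt[[cl]] > 0) add(frag_from_loci(class_loci[[cl]], cnt[[cl]]), cl)
    }
    if (cnt[["intergenic"]] > 0) {
      n <- cnt[["intergenic"]]
      fl <- sample(lens_pool, n, replace = TRUE, prob = LENGTH_WEIGHTS)
      s <- .sample_intergenic(ref, n, fl)
      add(substring(ref$genome, s, s + fl - 1L), "intergenic")
    }

    full <- function(ins) substr(paste0(ins, adapter, filler), 1, rl)
    seqs <- full(inserts)
    quals <- rep(q_hi, length(seqs))

    # contaminants
    ct <- function(k) cnt[[k]]
    if (ct("removed_adapter") > 0) {
      s <- random_seq(ct("removed_adapter"), rl)
      seqs <- c(seqs, s); quals <- c(quals, rep(q_hi, length(s)))
      origins <- c(origins, rep("removed_adapter", length(s)))
    }
    if (ct("insert_null") > 0) {
      s <- rep(substr(paste0(adapter, filler), 1, rl), ct("insert_null"))
      seqs <- c(seqs, s); quals <- c(quals, rep(q_hi, length(s)))
      origins <- c(origins, rep("insert_null", length(s)))
    }
    if (ct("n_containing") > 0) {
      n <- ct("n_containing")
      ins <- random_seq(n, 21)
      p <- sample(1:21, n, replace = TRUE)
      substr(ins, p, p) <- "N"
      s <- full(ins)
      q <- q_hi
      seqs <- c(seqs, s); quals <- c(quals, rep(q, n))
      origins <- c(origins, rep("n_containing", n))
    }
    if (ct("too_short") > 0) {
      n <- ct("too_short")
      ins <- random_seq(n, sample(10:17, n, replace = TRUE))
      s <- full(ins)
      seqs <- c(seqs, s); quals <- c(quals, rep(q_hi, n))
      origins <- c(origins, rep("too_short", n))
    }
    if (ct("poly_a") > 0) {
      n <- ct("poly_a")
      ins <- strrep("A", sample(20:28, n, replace = TRUE))
      s <- full(ins)
      seqs <- c(seqs, s); quals <- c(quals, rep(q_hi, n))
      origins <- c(origins, rep("poly_a", n))
    }
    if (ct("too_long") > 0) {
      n <- ct("too_long")
      ins <- random_seq(n, sample(31:40, n, replace = TRUE))
      s <- full(ins)
      seqs <- c(seqs, s); quals <- c(quals, rep(q_hi, n))
      origins <- c(origins, rep("too_long", n))
    }
    if (ct("low_quality") > 0) {
      n <- ct("low_quality")
      ins <- random_seq(n, 21)
      s <- full(ins)
      # 30% of positions at Q2 ('#'), comfortably over the 20%-below-Q10 bar
      q <- vapply(seq_len(n), function(i) {
        qq <- rep("I", rl)
        qq[sample.int(rl, ceiling(0.3 * rl))] <- "#"
        paste(qq, collapse = "")
      }, "")
      seqs <- c(seqs, s); quals <- c(quals, q)
      origins <- c(origins, rep("low_quality", n))
    }

    ord <- sample.int(length(seqs))
    df <- data.frame(
      id = sprintf("%s.%07d %s", lib, seq_along(ord), origins[ord]),
      seq = seqs[ord], qual = quals[ord], stringsAsFactors = FALSE)
    reads[[lib]] <- df
    origin_counts[[lib]] <- cnt
  }

  oc <- as.data.frame(origin_counts)
  oc <- cbind(origin = rownames(sim$counts), oc)
  rownames(oc) <- NULL
  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- setNames(file.path(outdir, paste0(libs, ".fastq.gz")), libs)
    for (lib in libs) write_fastq_gz(reads[[lib]], files[[lib]])
    write_tsv(oc, file.path(outdir, "ground_truth.tsv"))
    write_tsv(sim$truth, file.path(outdir, "mirna_truth.tsv"))
  }
  list(reads = reads,
       truth = list(origin_counts = oc, mirna = sim$truth,
                    weights = sim$weights, warnings = sim$warnings),
       files = files)
}

#' Write a synthetic reference bundle to disk
#'
#' Emits `genome.fa`, `annotation.gff3` (feature types
#' miRNA_primary_transcript, rRNA, tRNA, snRNA, snoRNA, scRNA,
#' repeat_region, exon, intron; 1-based closed coordinates),
#' `mature.fa` (miRBase-like `>id` headers), `transcripts.fa`,
#' `precursors.tsv` and `target_sites.tsv`.
#'
#' @param ref an `srna_reference`.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(genome = file.path(dir, "genome.fa"),
         annotation = file.path(dir, "annotation.gff3"),
         mature = file.path(dir, "mature.fa"),
         transcripts = file.path(dir, "transcripts.fa"),
         precursors = file.path(dir, "precursors.tsv"),
         target_sites = file.path(dir, "target_sites.tsv"))
  write_fasta(ref$genome, p[["genome"]])
  rtracklayer::export.gff3(ref$annotation, p[["annotation"]])
  write_fasta(ref$mirna_db, p[["mature"]])
  write_fasta(ref$transcripts, p[["transcripts"]])
  write_tsv(ref$precursors, p[["precursors"]])
  write_tsv(ref$target_sites, p[["target_sites"]])
  invisible(p)
}
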