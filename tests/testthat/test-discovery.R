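test_that("mirna_family strips species prefixes and member suffixes", {
  expect_equal(mirna_family(c("ppe-miR395d", "ppe-miR395e")),
               c("miR395", "miR395"))
  expect_equal(mirna_family("ath-miR398a-5p"), "miR398")
  expect_equal(mirna_family("miR159"), "miR159")
})

test_that("match_known applies the two-mismatch bound and tie-breaking", {
  db <- c(mirA = "ACGTACGTACGTACGTACGTA",
          mirB = "ACGTACGTACGTACGTACGAA",  # 1 mm from mirA
          mirC = "TTTTTTTTTTTTTTTTTTTTT")
  tags <- data.frame(sequence = c(
    db[["mirA"]],                          # identical -> mirA, 0 mm
    "ACGTACGTACGTACGTACCCA",               # 2 mm from mirA, 3 from mirB
    "AAAAACGTACGTACGTACGTA",               # 3+ mm from everything
    "ACGTACGTACGTACGTACGCA"),              # 1 mm from both A and B -> tie
    L1 = c(4L, 2L, 1L, 1L))
  res <- match_known(tags, db)
  h <- res$hits
  expect_equal(h$mirna[h$sequence == db[["mirA"]]], "mirA")
  expect_equal(h$mismatches[h$sequence == db[["mirA"]]], 0L)
  expect_equal(h$mirna[h$sequence == "ACGTACGTACGTACGTACCCA"], "mirA")
  expect_false("AAAAACGTACGTACGTACGTA" %in% h$sequence)
  # equidistant tag -> lexicographically smallest id, tie logged
  expect_equal(h$mirna[h$sequence == "ACGTACGTACGTACGTACGCA"], "mirA")
  expect_true("ACGTACGTACGTACGTACGCA" %in% res$ties$sequence)
  # counts aggregate per miRNA
  expect_equal(unname(res$counts["mirA", "L1"]), 4L + 2L + 1L)
  expect_error(match_known(tags, c(a = "ACGTACGTACGTACGTACGTA",
                                   a = "ACGTACGTACGTACGTACGTT")),
               "duplicate")
  expect_error(match_known(tags, c(x = "ACGT")), "18-26")
})

test_that("match_known equals the brute-force Hamming scan", {
  set.seed(81)
  db <- setNames(uvbsrna:::random_seq(40, sample(20:24, 40, replace = TRUE)),
                 sprintf("m%03d", sample(999, 40)))
  # tags: mutated db entries plus random sequences
  tags <- c(
    vapply(sample(db, 60, replace = TRUE), function(s) {
      b <- strsplit(s, "")[[1]]
      k <- sample(0:4, 1)
      for (p in sample(length(b), k)) b[p] <- sample(c("A","C","G","T"), 1)
      paste(b, collapse = "")
    }, ""),
    uvbsrna:::random_seq(20, sample(20:24, 20, replace = TRUE)))
  tags <- unique(tags)
  tab <- data.frame(sequence = tags, L1 = 1L)
  res <- match_known(tab, db)
  want <- oracle_match(tags, db)
  got <- merge(data.frame(sequence = tags, stringsAsFactors = FALSE),
               res$hits[c("sequence", "mirna", "mismatches")],
               by = "sequence", all.x = TRUE)
  cmp <- merge(got, want, by = "sequence", suffixes = c("_got", "_want"))
  expect_equal(cmp$mirna_got, cmp$mirna_want)
  expect_equal(cmp$mismatches_got, cmp$mismatches_want)
})

test_that("extract_candidate_loci clusters, flanks, clips and splits strands", {
  g <- setNames(paste(rep("ACGT", 500), collapse = ""), "chr1")
  gr <- function(s, e, str, idx) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(s, e), strand = str, tag_index = idx)
  # single tag: window = tag +/- flank
  w <- extract_candidate_loci(gr(1000, 1020, "+", 1L), g, flank = 150)
  expect_equal(GenomicRanges::start(w), 850)
  expect_equal(GenomicRanges::end(w), 1170)
  expect_false(w$clipped)
  # two tags 10 nt apart merge; 50 nt apart do not
  h2 <- c(gr(1000, 1020, "+", 1L), gr(1030, 1050, "+", 2L))
  expect_equal(length(extract_candidate_loci(h2, g)), 1)
  h3 <- c(gr(1000, 1020, "+", 1L), gr(1100, 1120, "+", 2L))
  expect_equal(length(extract_candidate_loci(h3, g)), 2)
  # same locus on both strands -> one window per strand
  h4 <- c(gr(1000, 1020, "+", 1L), gr(1000, 1020, "-", 1L))
  w4 <- extract_candidate_loci(h4, g)
  expect_equal(length(w4), 2)
  expect_setequal(as.character(GenomicRanges::strand(w4)), c("+", "-"))
  # clipping at the chromosome start
  w5 <- extract_candidate_loci(gr(30, 50, "+", 1L), g)
  expect_equal(GenomicRanges::start(w5), 1)
  expect_true(w5$clipped)
  expect_error(extract_candidate_loci(gr(1, 20, "+", 1L), g, flank = 10),
               ">= 50")
})

test_that("evaluate_hairpin accepts an ideal hairpin and flags defects", {
  set.seed(82)
  # perfect inverted repeat: 36 bp stem, 8 nt loop, mature in the 5' arm
  arm <- uvbsrna:::random_seq(1, 36)
  loop <- "ATATATAT"
  hp <- paste0(arm, loop, revcomp(arm))
  ev <- evaluate_hairpin(hp, mature_start = 3, mature_len = 21)
  expect_true(ev$accepted)
  expect_true(all(ev$flags))
  expect_equal(ev$n_paired, 21)
  # star interval is the pairing image of the mature
  expect_true(ev$star[1] > 36 + 8)

  # mature straddling the loop -> loop-crossing flag
  ev2 <- evaluate_hairpin(hp, mature_start = 30, mature_len = 21)
  expect_false(ev2$accepted)
  expect_false(ev2$flags[["no_loop_crossing"]])

  # an unfoldable window fails the pairing and score criteria
  ev3 <- evaluate_hairpin(strrep("A", 80), 10, 21)
  expect_false(ev3$accepted)
  expect_false(ev3$flags[["paired"]])
  expect_false(ev3$flags[["score"]])

  # length bounds
  ev4 <- evaluate_hairpin(substr(hp, 1, 50), 3, 21)
  expect_false(ev4$flags[["length"]])
  expect_error(evaluate_hairpin(hp, 100, 21), "outside")
})

test_that("dinucleotide-shuffled precursors are rejected on the score threshold", {
  ref <- synthetic_reference(n_known = 2, n_novel = 1, n_transcripts = 2,
                             seed = 83)
  prec <- ref$precursors$seq[1]
  set.seed(83)
  rejected <- 0L
  for (i in 1:100) {
    s <- shuffle_dinucleotide(prec)
    if (fold_hairpin(s)$mfe > hairpin_criteria()$score_max) {
      rejected <- rejected + 1L
    }
  }
  expect_gte(rejected, 90)
  # the un-shuffled precursor itself passes the threshold comfortably
  expect_lte(fold_hairpin(prec)$mfe, hairpin_criteria()$score_max)
})

test_that("shuffle_dinucleotide preserves dinucleotide composition", {
  set.seed(84)
  dinucs <- function(x) {
    b <- strsplit(x, "")[[1]]
    sort(paste0(b[-length(b)], b[-1]))
  }
  for (i in 1:10) {
    s <- uvbsrna:::random_seq(1, 60)
    sh <- shuffle_dinucleotide(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dinucs(sh), dinucs(s))
  }
})

test_that("planted precursors are discovered and no tag is counted twice", {
  ref <- synthetic_reference(n_known = 6, n_novel = 4, seed = 85)
  des <- simulation_design(n_replicates = 2, depth = 15000, seed = 85)
  sim <- simulate_libraries(ref, des)
  cl <- clean_reads(sim$reads, des$adapter)
  cls <- classify_tags(cl$tags, ref$genome, ref$annotation)
  mk <- match_known(cl$tags, ref$mirna_db)
  nov <- discover_novel(cl$tags, cls, mk$hits$sequence, ref$genome)
  acc <- nov$candidates[nov$candidates$accepted, , drop = FALSE]
  # every planted novel precursor whose mature tag survived QC is recovered
  novp <- ref$precursors[!ref$precursors$known, ]
  surviving <- novp$mature %in% cl$tags$sequence
  for (i in which(surviving)) {
    expect_true(any(acc$chrom == novp$chrom[i] &
                      acc$start <= novp$end[i] & acc$end >= novp$start[i]),
                info = novp$id[i])
  }
  # known-matched tag sequences never support a novel candidate
  expect_false(any(acc$mature %in% mk$hits$sequence))
  # accepted candidates are unique per mature tag
  expect_false(any(duplicated(acc$mature)))
})
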