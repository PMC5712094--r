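ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

mk_read <- function(insert, adapter = ADAPTER, rl = 50, qchar = "I") {
  seq <- substr(paste0(insert, adapter, strrep("C", rl)), 1, rl)
  list(seq = seq, qual = strrep(qchar, nchar(seq)))
}

mk_lib <- function(inserts, ...) {
  r <- lapply(inserts, mk_read, ...)
  data.frame(id = sprintf("r%03d", seq_along(r)),
             seq = vapply(r, `[[`, "", "seq"),
             qual = vapply(r, `[[`, "", "qual"), stringsAsFactors = FALSE)
}

test_that("clean_reads retains canonical reads and bins contaminants", {
  set.seed(61)
  good22 <- uvbsrna:::random_seq(1, 22)
  short16 <- uvbsrna:::random_seq(1, 16)
  long33 <- uvbsrna:::random_seq(1, 33)
  polya <- strrep("A", 24)
  reads <- mk_lib(c(good22, short16, long33, polya, ""))
  # append an N-containing read, a low-quality read, and a no-adapter read
  nread <- mk_read("ACGTNACGTACGTACGTACGTA")
  lq <- mk_read(good22)
  lq$qual <- paste0(strrep("#", 20), strrep("I", 30))  # 40% below Q20
  noad <- list(seq = uvbsrna:::random_seq(1, 50), qual = strrep("I", 50))
  reads <- rbind(reads, data.frame(
    id = c("rn", "rq", "ra"),
    seq = c(nread$seq, lq$seq, noad$seq),
    qual = c(nread$qual, lq$qual, noad$qual)))
  res <- clean_reads(list(L1 = reads), ADAPTER)
  cats <- res$categories$L1
  expect_equal(cats, c("clean", "too_short", "too_long", "poly_a",
                       "insert_null", "n_containing", "low_quality",
                       "removed_adapter"))
  expect_equal(res$tags$sequence, good22)
  expect_equal(res$tags$L1, 1L)
  # reconciliation: clean + removals = raw, exactly
  qc <- res$qc
  cat_cols <- c("clean", uvbsrna:::QC_CATEGORIES)
  expect_equal(sum(qc[1, cat_cols]), qc$raw[1])
})

test_that("cleaning is idempotent on clean tags", {
  set.seed(62)
  tags <- uvbsrna:::random_seq(20, sample(18:30, 20, replace = TRUE))
  tags <- tags[!grepl("AAAAAAAAAA", tags)]
  lib <- data.frame(id = sprintf("t%d", seq_along(tags)), seq = tags,
                    qual = strrep("I", nchar(tags)))
  res <- clean_reads(list(L1 = lib), ADAPTER)
  expect_true(all(res$categories$L1 == "clean"))
  expect_equal(sort(res$tags$sequence), sort(tags))
})

test_that("read_fastq round-trips and rejects malformed records", {
  dir <- withr::local_tempdir()
  reads <- mk_lib(c("ACGTACGTACGTACGTACGTA", "TTTTACGTACGTACGTACGTAC"))
  fq <- file.path(dir, "x.fastq.gz")
  write_fastq_gz(reads, fq)
  back <- read_fastq(fq)
  expect_equal(back$seq, reads$seq)
  expect_equal(back$qual, reads$qual)

  bad <- file.path(dir, "bad.fastq")
  writeLines(c("@r1", "ACGT", "+", "II"), bad)  # qual length mismatch
  expect_error(read_fastq(bad), "record 1")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), bad)
  expect_error(read_fastq(bad), "truncated")
})

test_that("length_distribution computes weighted and unweighted fractions", {
  tags <- data.frame(sequence = c(strrep("A", 21), strrep("C", 24)),
                     L1 = c(3L, 1L))
  ld <- length_distribution(tags)
  expect_equal(ld$L1_reads[ld$length == 21], 0.75)
  expect_equal(ld$L1_reads[ld$length == 24], 0.25)
  expect_equal(ld$L1_unique[ld$length == 21], 0.5)
  expect_equal(sum(ld$L1_reads), 1)
  expect_equal(sum(ld$L1_unique), 1)

  one <- data.frame(sequence = strrep("G", 21), L1 = 5L)
  ld1 <- length_distribution(one)
  expect_equal(ld1$L1_reads[ld1$length == 21], 1)
  expect_error(length_distribution(tags[0, ]), "empty")
})

test_that("classify_tags follows the precedence order and finds loci", {
  set.seed(63)
  # hand-built genome: rRNA at 101-200, repeat at 301-400 overlapping an
  # exon at 351-450
  g <- uvbsrna:::random_seq(1, 600)
  ann <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(101, 301, 351), c(200, 400, 450)),
    strand = "+", type = c("rRNA", "repeat_region", "exon"),
    ID = c("r1", "rep1", "e1"))
  tag_r <- substr(g, 120, 140)   # inside rRNA
  tag_mix <- substr(g, 390, 410) # overlaps repeat + exon -> repeat
  tag_un <- substr(g, 500, 520)  # unannotated locus
  tag_no <- strrep("ACGT", 6)    # not in genome (with high probability)
  tags <- data.frame(sequence = c(tag_r, tag_mix, tag_un, tag_no),
                     L1 = c(2L, 1L, 1L, 1L))
  res <- classify_tags(tags, c(chr1 = g), ann)
  expect_equal(res$assignment$class,
               c("rRNA", "repeat", "unannotated", "unannotated"))
  expect_equal(sum(res$breakdown$reads), sum(tags$L1))
  expect_equal(sum(res$breakdown$unique), nrow(tags))
  expect_error(classify_tags(tags, c(chrX = g), ann), "unknown chromosome")
})

test_that("classify_tags agrees with the exhaustive interval oracle", {
  set.seed(64)
  ref <- synthetic_reference(n_known = 4, n_novel = 2,
                             n_per_ncrna_class = 2, n_transcripts = 2,
                             seed = 64)
  # tags drawn from random feature loci plus random sequence
  ann <- ref$annotation
  ann_df <- data.frame(start = GenomicRanges::start(ann),
                       end = GenomicRanges::end(ann),
                       type = ann$type, stringsAsFactors = FALSE)
  picks <- sample(length(ann), 30, replace = TRUE)
  starts <- GenomicRanges::start(ann)[picks] +
    sample(0:40, 30, replace = TRUE)
  seqs <- unique(c(substring(ref$genome, starts, starts + 20),
                   uvbsrna:::random_seq(5, 21)))
  tags <- data.frame(sequence = seqs, L1 = 1L)
  res <- classify_tags(tags, ref$genome, ann)
  hits <- res$hits
  for (i in seq_len(nrow(tags))) {
    loci <- hits[hits$tag_index == i]
    if (!length(loci)) {
      expect_equal(res$assignment$class[i], "unannotated")
    } else {
      want <- vapply(seq_along(loci), function(k) {
        oracle_classify_locus(GenomicRanges::start(loci)[k],
                              GenomicRanges::end(loci)[k], ann_df)
      }, "")
      prec <- c(uvbsrna:::CLASS_PRECEDENCE, "unannotated")
      best <- prec[min(match(want, prec))]
      expect_equal(res$assignment$class[i], best, info = seqs[i])
    }
  }
})
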