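test_that("synthetic_reference satisfies its structural invariants", {
  ref <- synthetic_reference(n_known = 10, n_novel = 5, seed = 71)
  p <- ref$precursors
  expect_equal(nrow(p), 15)
  # every mature occurs verbatim in its precursor arm
  expect_true(all(mapply(grepl, p$mature, p$seq, MoreArgs = list(fixed = TRUE))))
  expect_true(all(substr(p$seq, p$mature_start,
                         p$mature_start + p$mature_len - 1) == p$mature))
  # precursor loci never overlap ncRNA loci
  nc <- ref$annotation[ref$annotation$type %in%
                         c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA")]
  pr <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start, p$end))
  expect_equal(length(GenomicRanges::findOverlaps(pr, nc)), 0)
  # novel precursors are absent from both annotation and database
  expect_false(any(p$id[!p$known] %in% ref$annotation$ID))
  expect_false(any(p$id[!p$known] %in% names(ref$mirna_db)))
  # every violation-free planted site passes the module's own checker
  ts <- ref$target_sites
  expect_true(all(ts$failed_rules[ts$violation == "none"] == ""))
  for (i in which(ts$violation != "none")) {
    expect_true(grepl(ts$violation[i], ts$failed_rules[i]))
  }
})

test_that("reference generation is deterministic and sizing errors are explicit", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_reference(synthetic_reference(n_known = 5, n_novel = 3, seed = 72),
                  dir1)
  write_reference(synthetic_reference(n_known = 5, n_novel = 3, seed = 72),
                  dir2)
  for (f in list.files(dir1)) {
    expect_equal(unname(tools::md5sum(file.path(dir1, f))),
                 unname(tools::md5sum(file.path(dir2, f))), info = f)
  }
  expect_error(synthetic_reference(n_known = 20, chrom_length = 1000,
                                   seed = 1),
               "deficit")
})

test_that("simulated libraries are byte-identical for a fixed seed", {
  ref <- synthetic_reference(n_known = 4, n_novel = 2, seed = 73)
  des <- simulation_design(n_replicates = 1, depth = 3000, seed = 73)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_libraries(ref, des, outdir = d1)
  simulate_libraries(ref, des, outdir = d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("ground-truth origin labels reconcile with library contents", {
  ref <- synthetic_reference(n_known = 4, n_novel = 2, seed = 74)
  des <- simulation_design(n_replicates = 2, depth = 5000, seed = 74)
  sim <- simulate_libraries(ref, des)
  oc <- sim$truth$origin_counts
  for (lib in names(sim$reads)) {
    expect_equal(sum(oc[[lib]]), nrow(sim$reads[[lib]]))
    origins <- sub("^\\S+\\s+", "", sim$reads[[lib]]$id)
    tab <- table(origins)
    for (o in names(tab)) {
      expect_equal(unname(tab[[o]]), oc[[lib]][oc$origin == o], info = o)
    }
  }
})

test_that("zero contamination yields only genomic origins; zero ncRNA loci propagate", {
  ref <- synthetic_reference(n_known = 4, n_novel = 2,
                             n_per_ncrna_class = 0, seed = 75)
  contam0 <- setNames(rep(0, 7), c("removed_adapter", "insert_null",
                                   "n_containing", "too_short", "poly_a",
                                   "too_long", "low_quality"))
  cf <- c(miRNA = 0.7, rRNA = 0, tRNA = 0, snRNA = 0, snoRNA = 0,
          scRNA = 0, "repeat" = 0.1, exon = 0.1, intron = 0.05,
          intergenic = 0.05)
  des <- simulation_design(n_replicates = 1, depth = 4000,
                           contamination = contam0, class_fractions = cf,
                           seed = 75)
  sim <- simulate_libraries(ref, des)
  origins <- sub("^\\S+\\s+", "", sim$reads$CK1$id)
  expect_false(any(origins %in% c("removed_adapter", "insert_null",
                                  "n_containing", "too_short", "poly_a",
                                  "too_long", "low_quality")))
  cl <- clean_reads(sim$reads, des$adapter)
  res <- classify_tags(cl$tags, ref$genome, ref$annotation)
  bd <- res$breakdown
  expect_equal(sum(bd$reads[bd$class %in% c("rRNA", "tRNA", "snRNA",
                                            "snoRNA", "scRNA")]), 0)
})

test_that("a planted 4x ratio is recovered within 3 binomial standard errors", {
  ref <- synthetic_reference(n_known = 10, n_novel = 0, n_transcripts = 2,
                             seed = 76)
  mirX <- names(ref$mirna_db)[1]
  # mean over >= 10 seeds of the empirical pooled-count ratio
  ratios <- vapply(1:10, function(seed) {
    des <- simulation_design(n_replicates = 2, depth = 50000,
                             planted_ratios = setNames(4, mirX),
                             seed = seed)
    set.seed(seed)
    sim <- simulate_counts(ref, des)
    ct <- sum(sim$counts[mirX, grepl("^T", names(sim$counts))])
    cc <- sum(sim$counts[mirX, grepl("^CK", names(sim$counts))])
    ct / cc
  }, 0)
  mean_ratio <- mean(ratios)
  # binomial/Poisson sampling error of the mean pooled ratio at these depths
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean_ratio - 4), 3 * se + 1e-9)
})

test_that("planted target-site violations are flagged exactly as intended", {
  set.seed(77)
  for (i in 1:10) {
    m <- uvbsrna:::random_seq(1, sample(c(20, 21, 22, 24), 1))
    tx <- uvbsrna:::random_seq(1, 300)
    pl0 <- plant_target_site(tx, m, "none")
    expect_equal(pl0$site$failed_rules, "")
    expect_equal(substr(pl0$sequence, pl0$site$start + 1,
                        pl0$site$start + nchar(m)), revcomp(m))
    for (v in letters[1:6]) {
      pl <- plant_target_site(tx, m, v)
      failed <- strsplit(pl$site$failed_rules, ",")[[1]]
      expect_true(v %in% failed, info = paste(v, m))
      # a single mid-duplex mismatch can only trip rule d
      if (v == "d") expect_equal(failed, v)
    }
  }
  expect_error(plant_target_site(strrep("A", 300), "ACGT", "none"),
               "20-24")
})

test_that("simulation_design validates its invariants", {
  expect_error(simulation_design(depth = 0), "depth")
  expect_error(simulation_design(adapter = ""), "adapter")
  bad <- c(removed_adapter = 0.5, insert_null = 0.5, n_containing = 0.1,
           too_short = 0, poly_a = 0, too_long = 0, low_quality = 0)
  expect_error(simulation_design(contamination = bad), "sum")
  expect_error(simulation_design(planted_ratios = c(mirX = -1)), "> 0")
  expect_error(
    simulation_design(planted_ratios = c(nope = 2),
                      expression_profile = c(mirA = 1)), "missing")
  # low-depth planted miRNA produces a warning record, not an error
  ref <- synthetic_reference(n_known = 3, n_novel = 0, n_transcripts = 2,
                             seed = 78)
  prof <- setNames(c(1, 1e-5, 1), ref$precursors$id)
  des <- simulation_design(n_replicates = 1, depth = 1000,
                           expression_profile = prof,
                           planted_ratios = setNames(4, ref$precursors$id[2]),
                           seed = 78)
  set.seed(78)
  sim <- simulate_counts(ref, des)
  expect_true(length(sim$warnings) > 0)
})
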