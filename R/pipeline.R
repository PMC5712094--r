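#' Build a pipeline configuration
#'
#' A single nested configuration drives the whole chain
#' simulate -> clean -> classify -> discover -> targets -> DE -> report.
#' Exactly one input mode is active: the default simulation block, or
#' `input` paths to existing files (FASTQ libraries plus reference bundle).
#' All defaults are recorded in the run report for provenance.
#'
#' @param simulation list: `n_known`, `n_novel`, `n_replicates`, `depth`,
#'   `planted` (named ratio vector, or NULL for the default plant of five
#'   up-regulated miRNAs at ratios 4,4,4,6,8).
#' @param input optional list with `fastq` (named vector of FASTQ paths),
#'   `genome`, `annotation`, `mature`, `transcripts` paths; disables the
#'   simulation block.
#' @param qc list: `adapter` plus overrides for [qc_config()].
#' @param discovery list: `max_mm`, `flank`, `merge_dist`, plus overrides
#'   for [hairpin_criteria()].
#' @param targets list: `mfe_fraction`.
#' @param de list: `treatment` condition label.
#' @param seed integer seed for every random stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = list(), input = NULL,
                            qc = list(), discovery = list(),
                            targets = list(), de = list(), seed = 1L) {
  sim_def <- list(n_known = 30L, n_novel = 20L, n_replicates = 3L,
                  depth = 200000L, planted = NULL,
                  contamination = NULL)
  qc_def <- list(adapter = "TGGAATTCTCGGGTGCCAAGG")
  disc_def <- list(max_mm = 2L, flank = 150L, merge_dist = 30L,
                   score_max = -45, min_paired = 16L,
                   len_range = c(60L, 300L), min_support = 5L)
  tgt_def <- list(mfe_fraction = 0.75)
  de_def <- list(treatment = "T")
  merge <- function(def, user) {
    def[names(user)] <- user
    def
  }
  if (!is.null(input) && length(simulation)) {
    stopf("exactly one of simulation block or input paths must be used")
  }
  structure(list(simulation = if (is.null(input)) merge(sim_def, simulation),
                 input = input,
                 qc = merge(qc_def, qc),
                 discovery = merge(disc_def, discovery),
                 targets = merge(tgt_def, targets),
                 de = merge(de_def, de),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with top-level keys matching the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("simulation", "input", "qc", "discovery",
                                  "targets", "de", "seed"))]
  if (!is.null(args$simulation$planted))
    args$simulation$planted <- unlist(args$simulation$planted)
  do.call(pipeline_config, args)
}

#' Run the full small-RNA analysis pipeline
#'
#' Executes the stages in fixed order, writes every summary table under
#' `outdir`, and returns the run report. A rerun with an identical
#' configuration and seed reproduces byte-identical outputs. Any stage
#' error aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return a `run_report` list: `qc`, `length_distribution`,
#'   `class_breakdown`, `known`, `novel`, `counts`, `de`, `target_hits`,
#'   `truth` (when simulated), `confusion` (truth evaluation), `params`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  seed <- config$seed
  run_id <- sprintf("seed%d", seed)

  truth <- NULL; ref <- NULL; reads <- NULL
  if (!is.null(config$input)) {
    inp <- config$input
    ref <- stage("load-reference", list(
      genome = read_fasta(inp$genome),
      annotation = rtracklayer::import(inp$annotation),
      mirna_db = read_fasta(inp$mature),
      transcripts = if (!is.null(inp$transcripts))
        read_fasta(inp$transcripts) else character(0)))
    reads <- stage("load-fastq",
                   lapply(inp$fastq, read_fastq))
    if (is.null(names(reads)))
      names(reads) <- sub("\\.fastq(\\.gz)?$", "", basename(unlist(inp$fastq)))
  } else {
    sim <- config$simulation
    ref <- stage("simulate-reference", synthetic_reference(
      n_known = sim$n_known, n_novel = sim$n_novel, seed = seed))
    planted <- sim$planted
    if (is.null(planted)) {
      planted <- setNames(c(4, 4, 4, 6, 8),
                          names(ref$mirna_db)[seq_len(min(5, sim$n_known))])
    }
    des_args <- list(n_replicates = sim$n_replicates, depth = sim$depth,
                     planted_ratios = planted,
                     adapter = config$qc$adapter, seed = seed)
    if (!is.null(sim$contamination))
      des_args$contamination <- unlist(sim$contamination)
    design <- stage("simulation-design", do.call(simulation_design, des_args))
    simlib <- stage("simulate-libraries",
                    simulate_libraries(ref, design,
                                       outdir = file.path(outdir, "fastq")))
    stage("write-reference", write_reference(ref, file.path(outdir, "ref")))
    reads <- simlib$reads
    truth <- simlib$truth
    truth$run_id <- run_id
  }

  qc_over <- config$qc[setdiff(names(config$qc), "adapter")]
  cfg <- do.call(qc_config, qc_over)
  cleaned <- stage("clean", clean_reads(reads, config$qc$adapter, cfg))
  ld <- stage("length-distribution", length_distribution(cleaned$tags))
  classification <- stage("classify",
                          classify_tags(cleaned$tags, ref$genome,
                                        ref$annotation))
  known <- stage("match-known",
                 match_known(cleaned$tags, ref$mirna_db,
                             max_mm = config$discovery$max_mm))
  crit <- hairpin_criteria(score_max = config$discovery$score_max,
                           min_paired = config$discovery$min_paired,
                           len_range = config$discovery$len_range)
  novel <- stage("discover-novel",
                 discover_novel(cleaned$tags, classification,
                                known$hits$sequence, ref$genome,
                                flank = config$discovery$flank,
                                merge_dist = config$discovery$merge_dist,
                                criteria = crit,
                                min_support = config$discovery$min_support))
  libs <- setdiff(names(cleaned$tags), "sequence")
  totals <- setNames(cleaned$qc$clean[match(libs, cleaned$qc$library)], libs)
  cm <- stage("count-matrix",
              build_count_matrix(known$counts, novel$counts, totals))
  condition <- sub("[0-9]+$", "", colnames(cm$counts))
  de <- stage("differential-expression",
              run_de(cm$counts, cm$totals, condition,
                     treatment = config$de$treatment))
  mirnas <- c(ref$mirna_db,
              if (nrow(novel$candidates) && any(novel$candidates$accepted))
                setNames(novel$candidates$mature[novel$candidates$accepted],
                         novel$candidates$id[novel$candidates$accepted]))
  hits <- stage("target-scan", if (length(ref$transcripts)) {
    scan_transcriptome(mirnas, ref$transcripts,
                       mfe_fraction = config$targets$mfe_fraction)
  } else data.frame())

  report <- list(qc = cleaned$qc, length_distribution = ld,
                 class_breakdown = classification$breakdown,
                 known = known, novel = novel,
                 counts = cm, de = de, target_hits = hits,
                 categories = cleaned$categories,
                 reads = if (is.null(config$input)) reads,
                 reference = ref, truth = truth,
                 run_id = run_id,
                 params = config)
  if (!is.null(truth)) {
    report$confusion <- stage("evaluate-truth",
                              evaluate_against_truth(report, truth))
  }

  stage("write-report", {
    write_tsv(cleaned$qc, file.path(outdir, "qc.tsv"))
    write_collapsed_tags(cleaned$tags, file.path(outdir, "tags.fa"))
    write_tsv(ld, file.path(outdir, "length_distribution.tsv"))
    write_tsv(classification$breakdown,
              file.path(outdir, "class_breakdown.tsv"))
    write_tsv(known$hits, file.path(outdir, "known_hits.tsv"))
    if (nrow(novel$candidates)) {
      write_tsv(novel$candidates[setdiff(names(novel$candidates),
                                         "structure")],
                file.path(outdir, "novel_candidates.tsv"))
      acc <- novel$candidates[novel$candidates$accepted, , drop = FALSE]
      if (nrow(acc)) {
        write_fasta(setNames(acc$mature, acc$id),
                    file.path(outdir, "novel_mature.fa"))
        write_fasta(setNames(acc$precursor, acc$id),
                    file.path(outdir, "novel_precursors.fa"))
        writeLines(sprintf(">%s\n%s", acc$id, acc$structure),
                   file.path(outdir, "novel_structures.txt"))
        gr <- GenomicRanges::GRanges(
          acc$chrom, IRanges::IRanges(acc$start, acc$end),
          strand = acc$strand, type = "miRNA_primary_transcript",
          ID = acc$id)
        rtracklayer::export.gff3(gr, file.path(outdir, "novel_candidates.gff3"))
      }
    }
    cdf <- data.frame(id = rownames(cm$counts), cm$counts,
                      stringsAsFactors = FALSE, check.names = FALSE)
    write_tsv(cdf, file.path(outdir, "counts.tsv"))
    write_tsv(de, file.path(outdir, "de.tsv"))
    if (nrow(hits)) write_tsv(hits, file.path(outdir, "target_hits.tsv"))
    prov <- list(run_id = run_id, seed = seed,
                 package_version = as.character(utils::packageVersion("uvbsrna")),
                 qc = config$qc, discovery = config$discovery,
                 targets = config$targets, de = config$de,
                 de_test = attr(de, "test"), pooling = attr(de, "pooling"))
    yaml::write_yaml(prov, file.path(outdir, "provenance.yaml"))
    if (!is.null(report$confusion)) {
      yaml::write_yaml(report$confusion,
                       file.path(outdir, "truth_evaluation.yaml"))
    }
  })
  invisible(report)
}

#' Compare a run report against simulation ground truth
#'
#' Per-stage recovery metrics: QC category accuracy per contaminant class
#' (fraction of reads of that true origin assigned to exactly that
#' category), known-miRNA detection, accepted-novel recovery of planted
#' precursors, and the direction accuracy of DE calls against planted
#' ratios.
#'
#' @param report a run report from [run_pipeline()].
#' @param truth the `truth` element of the same run.
#' @return list of metrics; errors on empty truth or a run-id mismatch.
#' @export
evaluate_against_truth <- function(report, truth) {
  if (is.null(truth) || is.null(truth$mirna) || !nrow(truth$mirna))
    stopf("empty ground truth")
  if (!is.null(truth$run_id) && !is.null(report$run_id) &&
      !identical(truth$run_id, report$run_id))
    stopf("run id mismatch between report and truth")

  # QC category accuracy from the origin labels embedded in read ids
  qc_acc <- NULL
  if (!is.null(report$reads)) {
    acc <- list()
    for (lib in names(report$reads)) {
      origin <- sub("^\\S+\\s+", "", report$reads[[lib]]$id)
      assigned <- report$categories[[lib]]
      for (k in QC_CATEGORIES) {
        sel <- origin == k
        if (any(sel)) {
          acc[[k]] <- c(acc[[k]], mean(assigned[sel] == k))
        }
      }
      sel <- !(origin %in% QC_CATEGORIES)
      acc[["clean"]] <- c(acc[["clean"]], mean(assigned[sel] == "clean"))
    }
    qc_acc <- vapply(acc, mean, 0)
  }

  known_ids <- names(report$reference$mirna_db)
  detected <- rownames(report$counts$counts)
  known_recovery <- mean(vapply(known_ids, function(id) {
    id %in% detected && sum(report$counts$counts[id, ]) > 0
  }, TRUE))

  novel_recovery <- NA_real_
  prec <- report$reference$precursors
  nov <- prec[!prec$known, , drop = FALSE]
  if (nrow(nov)) {
    accw <- report$novel$candidates
    accw <- accw[accw$accepted, , drop = FALSE]
    hit <- vapply(seq_len(nrow(nov)), function(i) {
      any(accw$chrom == nov$chrom[i] & accw$start <= nov$end[i] &
            accw$end >= nov$start[i])
    }, TRUE)
    novel_recovery <- mean(hit)
  }

  tm <- truth$mirna
  de <- report$de
  call_of <- function(id) {
    r <- de$regulation[de$id == id]
    if (length(r)) r[1] else "absent"
  }
  planted <- tm[tm$regulation != "unchanged", , drop = FALSE]
  de_sensitivity <- NA_real_
  de_false_direction <- NA_real_
  if (nrow(planted)) {
    calls <- vapply(planted$id, call_of, "")
    de_sensitivity <- mean(calls == planted$regulation)
    flip <- (planted$regulation == "up" & calls == "down") |
      (planted$regulation == "down" & calls == "up")
    de_false_direction <- mean(flip)
  }
  null_mir <- tm[tm$regulation == "unchanged", , drop = FALSE]
  de_null_call_rate <- if (nrow(null_mir)) {
    calls <- vapply(null_mir$id, call_of, "")
    mean(calls %in% c("up", "down"))
  } else NA_real_

  list(qc_category_accuracy = qc_acc,
       known_recovery = known_recovery,
       novel_recovery = novel_recovery,
       de_direction_sensitivity = de_sensitivity,
       de_false_direction_rate = de_false_direction,
       de_null_call_rate = de_null_call_rate)
}
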