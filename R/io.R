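#' Read a (possibly gzipped) FASTQ file
#'
#' Minimal strict FASTQ reader for small-RNA libraries. Malformed records
#' (truncated file, missing '+' separator, sequence/quality length
#' mismatch) raise an error naming the offending record index.
#'
#' @param path FASTQ or FASTQ.gz file.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4 != 0) {
    stopf("malformed FASTQ '%s': truncated record %d", path, n %/% 4 + 1)
  }
  idx <- seq(1, n, by = 4)
  ids <- lines[idx]
  seqs <- lines[idx + 1]
  plus <- lines[idx + 2]
  quals <- lines[idx + 3]
  bad <- which(substr(ids, 1, 1) != "@" | substr(plus, 1, 1) != "+")
  if (length(bad)) stopf("malformed FASTQ '%s': bad record %d", path, bad[1])
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stopf("malformed FASTQ '%s': sequence/quality length mismatch in record %d",
          path, bad[1])
  }
  data.frame(id = sub("^@", "", ids), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

#' Write reads to a gzipped FASTQ file
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path output path (written gzip-compressed).
#' @return `path`, invisibly.
#' @export
write_fastq_gz <- function(reads, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
             con)
  invisible(path)
}

# write a named character vector as FASTA
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
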