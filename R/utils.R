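#' @useDynLib uvbsrna, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats rbinom rmultinom rlnorm rpois runif binom.test setNames
#' @importFrom utils write.table read.table head tail
NULL

BASES <- c("A", "C", "G", "T")

#' Normalize a nucleotide string to the internal DNA alphabet
#'
#' Uppercases and converts U to T. All sequence handling in the package is
#' done on the DNA alphabet; folding and duplex scoring treat T as U.
#'
#' @param x character vector of sequences.
#' @return character vector over A/C/G/T/N.
#' @export
norm_seq <- function(x) {
  chartr("acgtunU", "ACGTTNT", x)
}

#' Reverse complement
#'
#' @param x character vector of A/C/G/T/N sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  if (length(x) > 10) {
    return(as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x))))
  }
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

# integer base codes used by the C++ folding engine: A=0, C=1, G=2, T/U=3
encode_seq <- function(x) {
  s <- strsplit(norm_seq(x), "")[[1]]
  codes <- match(s, BASES) - 1L
  if (anyNA(codes)) {
    stop("invalid base at position ", which(is.na(codes))[1], ": '",
         s[which(is.na(codes))[1]], "'")
  }
  codes
}

# sample random sequences as character strings; len is scalar or per-seq
random_seq <- function(n, len, gc = 0.5) {
  if (n == 0) return(character(0))
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  len <- rep_len(len, n)
  L <- max(len)
  chars <- sample(BASES, n * L, replace = TRUE, prob = p)
  full <- do.call(paste0, as.data.frame(matrix(chars, nrow = n),
                                        stringsAsFactors = FALSE))
  substr(full, 1L, len)
}

#' Dinucleotide shuffle
#'
#' Shuffles a sequence while preserving its dinucleotide composition
#' (Altschul-Erickson style: a random Eulerian arrangement of the
#' dinucleotide multigraph, obtained by shuffled-edge walks with restart).
#' Used to build null sequences for hairpin-score calibration.
#'
#' @param x a single sequence string.
#' @return a shuffled sequence of identical length and dinucleotide counts.
#' @export
shuffle_dinucleotide <- function(x) {
  s <- strsplit(norm_seq(x), "")[[1]]
  n <- length(s)
  if (n < 3) return(x)
  # edge lists per source base, shuffled; walk until all edges are used,
  # retrying whenever the walk strands early (rejection sampling)
  for (attempt in 1:200) {
    edges <- split(s[-1], s[-n])
    edges <- lapply(edges, sample)
    used <- lapply(edges, function(e) 0L)
    out <- character(n)
    out[1] <- s[1]
    cur <- s[1]
    ok <- TRUE
    for (i in 2:n) {
      k <- used[[cur]] + 1L
      if (k > length(edges[[cur]])) { ok <- FALSE; break }
      used[[cur]] <- k
      nxt <- edges[[cur]][k]
      out[i] <- nxt
      cur <- nxt
    }
    if (ok && all(vapply(names(edges), function(b) used[[b]] == length(edges[[b]]), TRUE))) {
      return(paste(out, collapse = ""))
    }
  }
  # fall back: plain shuffle (extremely unlikely for natural sequences)
  paste(sample(s), collapse = "")
}

# stack energy of a pair type under the package energy model
stack_energy <- function(b1, b2) {
  gc <- (b1 == "G" & b2 == "C") | (b1 == "C" & b2 == "G")
  ifelse(gc, -2, -1)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
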