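#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character())
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

## canonical form without input validation -- the hot path; callers must
## guarantee pure-ACGT input
canonical_nocheck <- function(x) {
  rc <- stringi::stri_reverse(chartr("ACGT", "TGCA", x))
  ifelse(x <= rc, x, rc)
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' k-mer and its reverse complement (C collation: A < C < G < T), which
#' makes all downstream structures strand-free.
#'
#' @param x character vector of k-mers over `{A,C,G,T}`.
#' @return character vector of canonical k-mers.
#' @export
canonical_kmer <- function(x) {
  if (!length(x)) return(character())
  if (any(grepl("[^ACGT]", x))) {
    stop("k-mers must contain only A, C, G, T")
  }
  canonical_nocheck(x)
}

## all k-length windows of one sequence, skipping windows that contain
## any non-ACGT character (ambiguity codes cannot index the graph)
kmer_windows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  starts <- seq_len(n - k + 1L)
  w <- substring(seq, starts, starts + k - 1L)
  if (grepl("[^ACGT]", seq)) w <- w[!grepl("[^ACGT]", w)] else w
}

as_seq_vector <- function(seqs) {
  if (is.data.frame(seqs)) seqs$seq else as.character(seqs)
}

#' Enumerate canonical k-mers with occurrence counts
#'
#' Slides a window of length `k` over every input sequence, canonicalizes
#' each window, and tallies occurrences. A window counts once toward its
#' canonical form regardless of the strand it was read from, so a
#' palindromic k-mer is counted once per window, not twice. Windows that
#' contain `N` (or any non-ACGT character) are skipped. k-mers observed
#' fewer than `c` times are removed.
#'
#' @param seqs character vector of sequences, or a [seq_records()] frame.
#' @param k k-mer length (>= 2).
#' @param c coverage cutoff: minimum total count for a k-mer to be kept.
#' @return an object of class `kmer_set`: a list with elements `k`,
#'   `counts` (named integer vector, names sorted canonical k-mers) and
#'   `n` (number of distinct k-mers).
#' @export
enumerate_kmers <- function(seqs, k, c = 1L) {
  k <- as.integer(k)
  stopifnot(k >= 2L, c >= 1L)
  seqs <- as_seq_vector(seqs)
  counts <- kmer_count_cpp(seqs, k)
  counts <- counts[counts >= c]
  structure(list(k = k, counts = counts, n = length(counts)),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat("kmer_set: ", x$n, " canonical ", x$k, "-mers\n", sep = "")
  invisible(x)
}

#' Extend a k-mer set by one letter
#'
#' Given the set of canonical k'-mers of `seqs`, returns the canonical
#' (k'+1)-mers of `seqs` whose k'-prefix, read in either orientation,
#' survives in `kset`. Iterating this from small k' up to the target k
#' reproduces direct enumeration when no coverage cutoff is applied,
#' while never materialising more candidate k-mers than the survivors
#' can extend to.
#'
#' @param kset a `kmer_set` at length k', built from the same `seqs`.
#' @param seqs the sequences `kset` was built from.
#' @param c coverage cutoff applied to the extended set.
#' @return a `kmer_set` at length k'+1.
#' @export
extend_kmers <- function(kset, seqs, c = 1L) {
  stopifnot(inherits(kset, "kmer_set"))
  k1 <- kset$k + 1L
  if (kset$n == 0L) {
    return(structure(list(k = k1, counts = integer(0), n = 0L),
                     class = "kmer_set"))
  }
  counts <- kmer_extend_cpp(as_seq_vector(seqs), k1, names(kset$counts))
  counts <- counts[counts >= c]
  structure(list(k = k1, counts = counts, n = length(counts)),
            class = "kmer_set")
}
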