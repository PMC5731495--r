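## Random-sequence generators and independent brute-force oracles used
## across the suite. The oracles deliberately use different machinery
## than the package (Biostrings reverse complement, table() counting,
## igraph components) so that agreement is informative.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_seq_set <- function(n, lo, hi) {
  vapply(sample(lo:hi, n, replace = TRUE), rand_dna, character(1))
}

## Biostrings-based reverse complement (independent of the package's own)
bio_rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## naive sliding-window + canonicalization k-mer counter
oracle_kmers <- function(seqs, k, c = 1L) {
  wins <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    st <- seq_len(n - k + 1L)
    w <- substring(s, st, st + k - 1L)
    w[!grepl("[^ACGT]", w)]
  }), use.names = FALSE)
  if (!length(wins)) return(integer(0))
  rc <- bio_rc(wins)
  can <- ifelse(wins <= rc, wins, rc)
  tab <- table(can)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts <- counts[counts >= c]
  counts[order(names(counts), method = "radix")]
}

## oriented k-mer adjacency straight from the uncompacted graph
## definition: an edge for every observed (k+1)-mer, in both of its
## orientations. Returns a character vector of "cu ou cv ov" keys.
oracle_raw_edges <- function(seqs, k) {
  k1 <- names(oracle_kmers(seqs, k + 1L))
  if (!length(k1)) return(character())
  both <- unique(c(k1, bio_rc(k1)))
  U <- substr(both, 1L, k)
  V <- substr(both, 2L, k + 1L)
  cu_rc <- bio_rc(U); cv_rc <- bio_rc(V)
  cu <- ifelse(U <= cu_rc, U, cu_rc)
  cv <- ifelse(V <= cv_rc, V, cv_rc)
  unique(paste(cu, ifelse(U == cu, "+", "-"), cv, ifelse(V == cv, "+", "-")))
}

## degree of a compacted node on one side, recomputed from the raw
## k-mer adjacency: the right side of a node is the outgoing side of its
## last k-mer read forward, the left side the outgoing side of the
## reverse complement of its first k-mer.
oracle_node_degree <- function(raw_edges, node_seq, k, side) {
  n <- nchar(node_seq)
  term <- if (side == "right") {
    substr(node_seq, n - k + 1L, n)
  } else {
    bio_rc(substr(node_seq, 1L, k))
  }
  rc <- bio_rc(term)
  can <- if (term <= rc) term else rc
  ori <- if (term == can) "+" else "-"
  from <- paste(can, ori)
  sum(startsWith(raw_edges, paste0(from, " ")) &
        nchar(raw_edges) > nchar(from))
}

## independent re-simulation of the greedy long-node coverage rule
oracle_greedy <- function(long_node_sets, keep_nodeless = FALSE) {
  covered <- character(0)
  retained <- logical(length(long_node_sets))
  for (i in seq_along(long_node_sets)) {
    ln <- as.character(long_node_sets[[i]])
    if (!length(ln)) {
      retained[i] <- keep_nodeless
    } else if (!all(ln %in% covered)) {
      retained[i] <- TRUE
      covered <- union(covered, ln)
    }
  }
  retained
}

## brute-force pairwise-sharing connected components (igraph)
oracle_components <- function(long_node_sets) {
  n <- length(long_node_sets)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (length(intersect(long_node_sets[[i]], long_node_sets[[j]]))) {
          g <- igraph::add_edges(g, c(i, j))
        }
      }
    }
  }
  igraph::components(g)$membership
}

## brute-force N50: the largest observed length L such that sequences of
## length >= L together hold at least half of all bases
oracle_n50 <- function(lens) {
  tot <- sum(as.numeric(lens))
  for (L in sort(unique(lens), decreasing = TRUE)) {
    if (sum(as.numeric(lens[lens >= L])) >= tot / 2) return(L)
  }
  NA_integer_
}

## spell the sequence of an oriented node path with k-1 overlaps
spell_path <- function(graph, path) {
  parts <- vapply(seq_len(nrow(path)), function(i) {
    s <- graph$nodes$seq[path$node[i]]
    if (path$orient[i] == "+") s else bio_rc(s)
  }, character(1))
  out <- parts[1]
  k <- graph$k
  for (i in seq_len(nrow(path))[-1]) {
    out <- paste0(out, substring(parts[i], k, nchar(parts[i])))
  }
  out
}

write_temp_fasta <- function(seqs, ids = sprintf("s%03d", seq_along(seqs))) {
  path <- tempfile(fileext = ".fasta")
  write_fasta(seq_records(ids, seqs), path)
  path
}
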