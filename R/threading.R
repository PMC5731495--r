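#' Thread a transcript through the compacted graph
#'
#' Walks the transcript's consecutive k-mers through the graph and
#' records the ordered list of (node, orientation) steps it visits,
#' merging consecutive k-mers that sit at contiguous offsets of the same
#' oriented node into a single step. A node revisited later in the walk
#' (a repeat traversal) counts as a separate step.
#'
#' @param graph a `dbg_graph` built from a transcript set that includes
#'   `rec` (so that all of its k-mers are present).
#' @param rec a single-record [seq_records()] row, or a list with `id`
#'   and `seq`.
#' @return an object of class `transcript_path`: list with `id`, `seq`,
#'   `path` (data frame `node`, `orient`, `enter`, `exit` giving the
#'   node-forward offsets of the first and last k-mer of the step),
#'   `extended_seq` (equal to `seq` until [extend_ends()] is applied),
#'   `node_count` (number of path steps) and `avg_len`
#'   (`nchar(extended_seq) / node_count`). The path is empty when the
#'   transcript is shorter than k.
#' @export
thread_transcript <- function(graph, rec) {
  id <- if (is.data.frame(rec)) rec$id[1] else rec$id
  seq <- if (is.data.frame(rec)) rec$seq[1] else rec$seq
  k <- graph$k
  nb <- nchar(seq)
  empty_path <- data.frame(node = integer(0), orient = character(0),
                           enter = integer(0), exit = integer(0),
                           stringsAsFactors = FALSE)
  if (nb < k) {
    return(structure(list(id = id, seq = seq, path = empty_path,
                          extended_seq = seq, node_count = 0L,
                          avg_len = NA_real_),
                     class = "transcript_path"))
  }
  starts <- seq_len(nb - k + 1L)
  wins <- substring(seq, starts, starts + k - 1L)
  if (grepl("[^ACGT]", seq)) {
    bad <- which(grepl("[^ACGT]", wins))
    if (length(bad) == length(wins)) {
      return(structure(list(id = id, seq = seq, path = empty_path,
                            extended_seq = seq, node_count = 0L,
                            avg_len = NA_real_),
                       class = "transcript_path"))
    }
    if (length(bad)) {
      stop("transcript '", id, "' has an ambiguous k-mer at position ",
           bad[1], "; it cannot be threaded")
    }
  }
  can <- canonical_nocheck(wins)
  r <- match(can, graph$index_kmers)
  if (anyNA(r)) {
    stop("k-mer of transcript '", id, "' at position ", which(is.na(r))[1],
         " is absent from the graph (graph/transcript mismatch)")
  }
  nid <- graph$index_node[r]
  off <- graph$index_off[r]
  nfw <- graph$index_fwd[r]
  worient <- wins == can
  nor <- worient == nfw                    # TRUE: node traversed forward
  m <- length(r)
  if (m == 1L) {
    brk <- TRUE
  } else {
    step <- ifelse(nor[-m], 1L, -1L)
    brk <- c(TRUE, nid[-1L] != nid[-m] | nor[-1L] != nor[-m] |
               off[-1L] != off[-m] + step)
  }
  sidx <- which(brk)
  eidx <- c(sidx[-1L] - 1L, m)
  path <- data.frame(
    node = nid[sidx],
    orient = ifelse(nor[sidx], "+", "-"),
    enter = off[sidx],
    exit = off[eidx],
    stringsAsFactors = FALSE
  )
  structure(list(id = id, seq = seq, path = path, extended_seq = seq,
                 node_count = nrow(path),
                 avg_len = nb / nrow(path)),
            class = "transcript_path")
}

#' @export
print.transcript_path <- function(x, ...) {
  cat("transcript_path '", x$id, "': ", nchar(x$extended_seq), " bp over ",
      x$node_count, " node(s)\n", sep = "")
  invisible(x)
}

#' Unambiguously extend a transcript within its terminal nodes
#'
#' The leftover bases of the first and last node of the path -- the bases
#' of those unitigs that the transcript itself does not reach -- form an
#' unambiguous extension of the transcript and are prepended/appended.
#' The extension never crosses a node boundary. The operation is a pure
#' function of the record and its path, hence idempotent.
#'
#' @param graph a `dbg_graph`.
#' @param tp a `transcript_path` with a non-empty path.
#' @return `tp` with `extended_seq` and `avg_len` updated.
#' @export
extend_ends <- function(graph, tp) {
  if (!nrow(tp$path)) return(tp)
  k <- graph$k
  first <- tp$path[1L, ]
  last <- tp$path[nrow(tp$path), ]
  s1 <- graph$nodes$seq[first$node]
  sl <- graph$nodes$seq[last$node]
  prefix <- if (first$orient == "+") {
    substr(s1, 1L, first$enter - 1L)
  } else {
    revcomp(substr(s1, first$enter + k, nchar(s1)))
  }
  suffix <- if (last$orient == "+") {
    substr(sl, last$exit + k, nchar(sl))
  } else {
    revcomp(substr(sl, 1L, last$exit - 1L))
  }
  if (!length(prefix)) prefix <- ""
  if (!length(suffix)) suffix <- ""
  tp$extended_seq <- paste0(prefix, tp$seq, suffix)
  tp$avg_len <- nchar(tp$extended_seq) / tp$node_count
  tp
}

#' Filter transcripts by average node length of their path
#'
#' Retains a transcript only when its (extended) length divided by the
#' number of nodes in its path is strictly above the cutoff `c1`. Paths
#' crowded with many short nodes are the signature of noisy, chimeric or
#' poorly assembled transcripts.
#'
#' @param tps list of `transcript_path` objects with `node_count >= 1`.
#' @param c1 average length cutoff (default 25).
#' @return the retained subset, order preserved.
#' @export
filter_by_avg_len <- function(tps, c1 = 25) {
  keep <- vapply(tps, function(tp) {
    tp$node_count >= 1L && nchar(tp$extended_seq) / tp$node_count > c1
  }, logical(1))
  tps[keep]
}
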