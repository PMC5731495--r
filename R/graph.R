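## Oriented-vertex encoding for canonical k-mers
## k-mer i forward (spelling the canonical string) -> 2i-1, reverse -> 2i.
enc_fwd <- function(i) 2L * i - 1L
flip_enc <- function(e) bitwXor(e - 1L, 1L) + 1L
vert_of <- function(e) (e + 1L) %/% 2L
is_fwd <- function(e) e %% 2L == 1L

#' Build a compacted bidirected de Bruijn graph from transcripts
#'
#' Vertices are the canonical k-mers of the input transcripts; two
#' oriented k-mers are joined by an edge when the (k-1)-suffix of the
#' first equals the (k-1)-prefix of the second and the implied (k+1)-mer
#' is itself observed in the transcripts. Every maximal non-branching
#' linear path is then collapsed into a single node whose string is the
#' concatenation of its constituent k-mers overlapping by k-1 letters.
#' A node and its reverse complement are one and the same node; walks
#' through the graph carry an orientation instead.
#'
#' Self-loops, hairpin edges (a k-mer followed by its own reverse
#' complement) and palindromic k-mers terminate unitigs: they are never
#' merged, the standard safe compaction rule.
#'
#' @param transcripts a [seq_records()] frame or character vector with at
#'   least one sequence of length >= `params$k`.
#' @param params a [merge_params()] list; `params$c` is applied uniformly
#'   to the k-mer and (k+1)-mer sets.
#' @return an object of class `dbg_graph`: list with `k`, `nodes` (data
#'   frame `id`, `seq`, `kmer_count`, ids assigned in sorted order of the
#'   canonical node string), `edges` (data frame `from`, `from_or`, `to`,
#'   `to_or`, one row per bidirected edge, mirror image not duplicated)
#'   and a k-mer index mapping every canonical k-mer to its unique
#'   (node, offset, orientation).
#' @export
build_graph <- function(transcripts, params = merge_params()) {
  k <- as.integer(params$k)
  stopifnot(k >= 2L)
  seqs <- as_seq_vector(transcripts)
  kset <- enumerate_kmers(seqs, k, c = params$c)
  if (kset$n == 0L) {
    stop("no transcript reaches the k-mer length k=", k,
         "; cannot build a graph")
  }
  k1set <- enumerate_kmers(seqs, k + 1L, c = params$c)
  kmers <- names(kset$counts)              # sorted canonical k-mers
  n <- length(kmers)
  rc_kmers <- revcomp(kmers)
  pal <- kmers == rc_kmers                 # possible only for even k

  ## --- k-mer level oriented edges from observed (k+1)-mers ------------
  ef <- integer(0); et <- integer(0)
  if (k1set$n > 0L) {
    w <- names(k1set$counts)
    wrc <- revcomp(w)
    allw <- c(w, wrc[wrc != w])            # both orientations, palindromes once
    U <- substr(allw, 1L, k)
    V <- substr(allw, 2L, k + 1L)
    cu <- canonical_nocheck(U)
    cv <- canonical_nocheck(V)
    iu <- match(cu, kmers)
    iv <- match(cv, kmers)
    ok <- !is.na(iu) & !is.na(iv)          # ends removed by the cutoff c
    eu <- ifelse(U[ok] == cu[ok], enc_fwd(iu[ok]), enc_fwd(iu[ok]) + 1L)
    ev <- ifelse(V[ok] == cv[ok], enc_fwd(iv[ok]), enc_fwd(iv[ok]) + 1L)
    dup <- duplicated(paste(eu, ev))
    ef <- eu[!dup]; et <- ev[!dup]
  }

  ## --- unitig construction -------------------------------------------
  two_n <- 2L * n
  outdeg <- tabulate(ef, nbins = two_n)
  succ <- integer(two_n)
  one <- which(outdeg[ef] == 1L)
  succ[ef[one]] <- et[one]

  xs <- vert_of(seq_len(two_n))
  mergeable <- outdeg == 1L & succ > 0L
  sy <- integer(two_n)
  sy[mergeable] <- vert_of(succ[mergeable])
  mergeable <- mergeable & sy != xs
  mergeable[mergeable] <- outdeg[flip_enc(succ[which(mergeable)])] == 1L
  mergeable[pal[xs]] <- FALSE
  mergeable <- mergeable & !pal[pmax(sy, 1L)]

  visited <- logical(n)
  buf <- integer(n)
  node_seq_raw <- character(0)
  nn <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    ## walk left from (i, forward) to the start of the unitig
    e <- enc_fwd(i)
    steps <- 0L
    repeat {
      pe <- flip_enc(e)
      if (!mergeable[pe]) break
      prev <- flip_enc(succ[pe])
      pv <- vert_of(prev)
      if (pv == i || visited[pv]) break    # circular unitig guard
      e <- prev
      steps <- steps + 1L
      if (steps > n) break
    }
    ## walk right collecting the chain
    m <- 1L
    buf[1L] <- e
    visited[vert_of(e)] <- TRUE
    cur <- e
    repeat {
      if (!mergeable[cur]) break
      nxt <- succ[cur]
      if (visited[vert_of(nxt)]) break
      m <- m + 1L
      buf[m] <- nxt
      visited[vert_of(nxt)] <- TRUE
      cur <- nxt
    }
    chain <- buf[seq_len(m)]
    vs <- vert_of(chain)
    fw <- is_fwd(chain)
    os <- ifelse(fw, kmers[vs], rc_kmers[vs])
    s <- if (m == 1L) os else paste0(os[1L], paste(substr(os[-1L], k, k),
                                                   collapse = ""))
    nn <- nn + 1L
    node_seq_raw[nn] <- s
  }

  ## canonical node representative; ids by sorted canonical node string
  node_rc <- revcomp(node_seq_raw)
  node_can <- ifelse(node_seq_raw <= node_rc, node_seq_raw, node_rc)
  ord <- order(node_can, method = "radix")
  node_can <- node_can[ord]
  nodes <- data.frame(
    id = seq_len(nn),
    seq = node_can,
    kmer_count = nchar(node_can) - k + 1L,
    stringsAsFactors = FALSE
  )

  ## --- index: canonical k-mer -> (node, offset, strand) ---------------
  per <- nodes$kmer_count
  idx_node <- rep.int(nodes$id, per)
  starts <- unlist(lapply(per, seq_len), use.names = FALSE)
  idx_off <- starts
  big <- rep.int(nodes$seq, per)
  wkm <- substr(big, starts, starts + k - 1L)
  ckm <- canonical_nocheck(wkm)
  idx_fwd <- wkm == ckm                    # node-forward spells the canonical
  ## a palindromic node cannot occur (hairpins are never merged), so the
  ## index is one-to-one
  o2 <- match(ckm, kmers)
  index_node <- integer(n); index_off <- integer(n); index_fwd <- logical(n)
  index_node[o2] <- idx_node
  index_off[o2] <- idx_off
  index_fwd[o2] <- idx_fwd

  ## --- node-level edges ----------------------------------------------
  edges <- data.frame(from = integer(0), from_or = character(0),
                      to = integer(0), to_or = character(0),
                      stringsAsFactors = FALSE)
  if (length(ef)) {
    vf <- vert_of(ef); vt <- vert_of(et)
    n1 <- index_node[vf]; n2 <- index_node[vt]
    o1 <- index_off[vf]; o2f <- index_off[vt]
    d1 <- is_fwd(ef) == index_fwd[vf]      # TRUE: node traversed forward
    d2 <- is_fwd(et) == index_fwd[vt]
    internal <- n1 == n2 & d1 == d2 &
      ifelse(d1, o2f == o1 + 1L, o2f == o1 - 1L)
    keep <- !internal
    a <- n1[keep]; da <- d1[keep]; b <- n2[keep]; db <- d2[keep]
    ## canonical representative of the edge vs its mirror
    key_f <- paste(a, da, b, db)
    key_m <- paste(b, !db, a, !da)
    swap <- key_m < key_f
    a2 <- ifelse(swap, b, a); da2 <- ifelse(swap, !db, da)
    b2 <- ifelse(swap, a, b); db2 <- ifelse(swap, !da, db)
    key <- paste(a2, da2, b2, db2)
    keep2 <- !duplicated(key)
    edges <- data.frame(
      from = a2[keep2],
      from_or = ifelse(da2[keep2], "+", "-"),
      to = b2[keep2],
      to_or = ifelse(db2[keep2], "+", "-"),
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$from, edges$from_or, edges$to, edges$to_or,
                         method = "radix"), , drop = FALSE]
    rownames(edges) <- NULL
  }

  structure(list(
    k = k,
    nodes = nodes,
    edges = edges,
    index_kmers = kmers,
    index_node = index_node,
    index_off = index_off,
    index_fwd = index_fwd
  ), class = "dbg_graph")
}

#' @export
print.dbg_graph <- function(x, ...) {
  cat("dbg_graph: k=", x$k, ", ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges, ", length(x$index_kmers),
      " canonical k-mers\n", sep = "")
  invisible(x)
}

#' Degree of a node on one side
#'
#' The right side of a node is the end its forward orientation leaves
#' from; the left side is the end its reverse orientation leaves from.
#'
#' @param graph a `dbg_graph`.
#' @param node_id node identifier.
#' @param side `"left"` or `"right"`.
#' @return number of distinct bidirected edges attached at that side.
#' @export
node_degree <- function(graph, node_id, side = c("left", "right")) {
  side <- match.arg(side)
  if (!node_id %in% graph$nodes$id) stop("unknown node id: ", node_id)
  e <- graph$edges
  if (!nrow(e)) return(0L)
  ## an edge (a, da) -> (b, db) leaves a at (da == "+" ? right : left)
  ## and enters b at (db == "+" ? left : right)
  at_from <- e$from == node_id &
    (e$from_or == (if (side == "right") "+" else "-"))
  at_to <- e$to == node_id &
    (e$to_or == (if (side == "left") "+" else "-"))
  sum(at_from | at_to)
}

#' Export the compacted graph as GFA1
#'
#' Writes S-lines carrying the node strings and L-lines carrying the
#' bidirected edges with k-1 base overlaps, for inspection in standard
#' assembly-graph viewers.
#'
#' @param graph a `dbg_graph`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gfa <- function(graph, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  writeLines(sprintf("S\t%d\t%s", graph$nodes$id, graph$nodes$seq), con)
  if (nrow(graph$edges)) {
    writeLines(sprintf("L\t%d\t%s\t%d\t%s\t%dM",
                       graph$edges$from, graph$edges$from_or,
                       graph$edges$to, graph$edges$to_or,
                       graph$k - 1L), con)
  }
  invisible(path)
}
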