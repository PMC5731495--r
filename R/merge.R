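#' Parameters of the merging algorithm
#'
#' @param k k-mer length used to build the de Bruijn graph (default 25).
#' @param c k-mer coverage cutoff. Coverage filtering belongs to the
#'   upstream per-library assemblies; during merging it defaults to 1
#'   (no filtering), and when raised it is applied uniformly to the
#'   k-mer and (k+1)-mer sets.
#' @param c1 average length cutoff: a transcript is retained only when
#'   its extended length divided by its path node count is above `c1`
#'   (default 25).
#' @param c2 node length cutoff: a node is "long" when its string is
#'   longer than `c2` bases (default 50). Long nodes are the unit of
#'   redundancy removal and locus grouping.
#' @return a list of class `merge_params`.
#' @export
merge_params <- function(k = 25L, c = 1L, c1 = 25, c2 = 50L) {
  k <- as.integer(k); c <- as.integer(c); c2 <- as.integer(c2)
  stopifnot(k >= 2L, c >= 1L, c1 >= 0, c2 >= 1L)
  structure(list(k = k, c = c, c1 = c1, c2 = c2), class = "merge_params")
}

#' Long nodes visited by a transcript
#'
#' @param graph a `dbg_graph`.
#' @param tp a `transcript_path` threaded on `graph`.
#' @param c2 node length cutoff; a node qualifies when its string length
#'   is strictly above `c2`.
#' @return integer vector of distinct long-node ids on the path.
#' @export
long_nodes <- function(graph, tp, c2 = 50L) {
  ids <- unique(tp$path$node)
  ids[nchar(graph$nodes$seq[ids]) > c2]
}

#' Rank transcripts for greedy selection
#'
#' Transcripts formed from more graph nodes tend to be longer and better
#' assembled, so ranking is by path node count, descending. Ties are
#' broken deterministically: extended length descending, then record id
#' ascending, then sequence.
#'
#' @param tps list of `transcript_path` objects.
#' @return the list reordered by rank.
#' @export
rank_transcripts <- function(tps) {
  if (!length(tps)) return(tps)
  nc <- vapply(tps, `[[`, integer(1), "node_count")
  len <- vapply(tps, function(tp) nchar(tp$extended_seq), integer(1))
  ids <- vapply(tps, `[[`, character(1), "id")
  seqs <- vapply(tps, `[[`, character(1), "extended_seq")
  tps[order(-nc, -len, ids, seqs, method = "radix")]
}

#' Greedy removal of redundant transcripts
#'
#' One pass down the ranking: a transcript is retained iff it contains at
#' least one long node not yet covered by the transcripts retained before
#' it; on retention its long nodes join the covered set. Exact duplicates
#' and transcripts whose long nodes are a subset of better-ranked
#' survivors are thereby removed.
#'
#' @param ranked list of `transcript_path` in rank order (see
#'   [rank_transcripts()]).
#' @param long_node_map list of long-node id vectors, parallel to
#'   `ranked` (see [long_nodes()]).
#' @param keep_nodeless retain transcripts that traverse no long node at
#'   all (as future singleton loci) instead of dropping them (default).
#' @return an object of class `ranked_selection`: list with `order` (the
#'   ranked transcripts), `long_node_map`, `retained` (logical vector)
#'   and `covered_long_nodes` (sorted ids).
#' @export
remove_redundant <- function(ranked, long_node_map, keep_nodeless = FALSE) {
  stopifnot(length(ranked) == length(long_node_map))
  covered <- integer(0)
  covered_env <- new.env(hash = TRUE, parent = emptyenv())
  retained <- logical(length(ranked))
  for (i in seq_along(ranked)) {
    ln <- long_node_map[[i]]
    if (!length(ln)) {
      retained[i] <- keep_nodeless
      next
    }
    new <- ln[!vapply(as.character(ln), exists, logical(1),
                      envir = covered_env, inherits = FALSE)]
    if (length(new)) {
      retained[i] <- TRUE
      for (v in as.character(new)) assign(v, TRUE, envir = covered_env)
      covered <- c(covered, new)
    }
  }
  structure(list(order = ranked, long_node_map = long_node_map,
                 retained = retained,
                 covered_long_nodes = sort(covered)),
            class = "ranked_selection")
}

#' @export
print.ranked_selection <- function(x, ...) {
  cat("ranked_selection: ", sum(x$retained), " of ", length(x$retained),
      " transcripts retained, ", length(x$covered_long_nodes),
      " long nodes covered\n", sep = "")
  invisible(x)
}

#' Group retained transcripts into loci
#'
#' Two retained transcripts belong to the same locus when they share at
#' least one long node; the condition is applied transitively, so loci
#' are the connected components of the sharing graph. Retained
#' transcripts without long nodes form singleton loci. Loci are numbered
#' by the rank of their best member, members by rank.
#'
#' @param selection a `ranked_selection`.
#' @param long_node_map optional override of the map stored in
#'   `selection`.
#' @return list of loci, each a list with `id`, `members` (indices into
#'   `selection$order`) and `long_nodes`.
#' @export
group_loci <- function(selection, long_node_map = NULL) {
  lnm <- if (is.null(long_node_map)) selection$long_node_map else long_node_map
  idx <- which(selection$retained)
  if (!length(idx)) return(list())
  ## union-find over retained transcripts, united through shared nodes
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nodes <- unlist(lnm[idx], use.names = FALSE)
  owner <- rep.int(seq_along(idx), lengths(lnm[idx]))
  if (length(nodes)) {
    for (grp in split(owner, nodes)) {
      if (length(grp) > 1L) {
        r0 <- find(grp[1L])
        for (j in grp[-1L]) {
          rj <- find(j)
          if (rj != r0) parent[rj] <- r0
        }
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  comp <- split(seq_along(idx), roots)
  ## order loci by best (lowest) member rank
  best <- vapply(comp, function(v) min(idx[v]), integer(1))
  comp <- comp[order(best)]
  lapply(seq_along(comp), function(li) {
    members <- sort(idx[comp[[li]]])
    list(id = li, members = members,
         long_nodes = sort(unique(unlist(lnm[members], use.names = FALSE))))
  })
}

#' Summary statistics of a merged transcriptome
#'
#' N50 is the smallest length L such that retained transcripts of length
#' at least L together contain at least half of all retained bases.
#'
#' @param selection a `ranked_selection`.
#' @param loci list of loci from [group_loci()].
#' @return list with `transcripts`, `loci`, `n50`, `total_bases`.
#' @export
summary_stats <- function(selection, loci) {
  lens <- vapply(selection$order[selection$retained],
                 function(tp) nchar(tp$extended_seq), integer(1))
  list(
    transcripts = length(lens),
    loci = length(loci),
    n50 = n50(lens),
    total_bases = sum(lens)
  )
}

#' N50 of a set of lengths
#'
#' @param lens integer vector of sequence lengths.
#' @return the N50 value, or `NA` for an empty set.
#' @export
n50 <- function(lens) {
  if (!length(lens)) return(NA_integer_)
  s <- sort(lens, decreasing = TRUE)
  cs <- cumsum(as.numeric(s))
  s[which(cs >= cs[length(cs)] / 2)[1]]
}

#' Merge per-library transcriptome assemblies
#'
#' The full pipeline: read all transcript FASTA files, build the
#' compacted de Bruijn graph over them, thread each transcript, extend
#' its ends within terminal nodes, drop transcripts whose average node
#' length is not above `c1`, rank by path node count, greedily remove
#' transcripts whose long nodes (length above `c2`) are already covered,
#' group survivors into loci, and emit them as
#' `Locus_<L>_Transcript_<T>` records.
#'
#' Transcripts shorter than `k` cannot thread and are dropped with a
#' warning.
#'
#' @param fasta_paths character vector of per-library transcript FASTA
#'   files (a [seq_records()] frame is also accepted).
#' @param params a [merge_params()] list.
#' @param keep_nodeless retain transcripts without long nodes as
#'   singleton loci.
#' @return list of class `merge_result`: `records` (a [seq_records()]
#'   frame of the merged transcriptome), `report` (see
#'   [summary_stats()]), `table` (per-transcript data frame: id,
#'   node_count, long-node count, retained flag, locus id), plus the
#'   `graph`, `selection` and `loci` for inspection.
#' @export
merge_assemblies <- function(fasta_paths, params = merge_params(),
                             keep_nodeless = FALSE) {
  recs <- if (is.data.frame(fasta_paths)) {
    fasta_paths
  } else {
    if (!length(fasta_paths)) stop("at least one input file is required")
    do.call(rbind, lapply(fasta_paths, function(p) {
      r <- read_fasta(p)
      class(r) <- "data.frame"
      r
    }))
  }
  too_short <- nchar(recs$seq) < params$k
  if (any(too_short)) {
    warning(sum(too_short), " transcript(s) shorter than k=", params$k,
            " dropped")
    recs <- recs[!too_short, , drop = FALSE]
  }
  if (!nrow(recs)) stop("no transcript reaches the k-mer length")

  graph <- build_graph(recs, params)
  tps <- lapply(seq_len(nrow(recs)), function(i) {
    extend_ends(graph, thread_transcript(graph, recs[i, , drop = FALSE]))
  })
  tps <- tps[vapply(tps, function(tp) tp$node_count > 0L, logical(1))]
  tps <- filter_by_avg_len(tps, params$c1)
  ranked <- rank_transcripts(tps)
  lnm <- lapply(ranked, long_nodes, graph = graph, c2 = params$c2)
  selection <- remove_redundant(ranked, lnm, keep_nodeless = keep_nodeless)
  loci <- group_loci(selection)
  report <- summary_stats(selection, loci)

  ## output records: loci by best member rank, members by rank
  out_id <- character(0); out_seq <- character(0)
  locus_of <- integer(length(ranked))
  for (lc in loci) {
    for (t in seq_along(lc$members)) {
      i <- lc$members[t]
      locus_of[i] <- lc$id
      out_id <- c(out_id, sprintf("Locus_%d_Transcript_%d", lc$id, t))
      out_seq <- c(out_seq, ranked[[i]]$extended_seq)
    }
  }
  if (!length(out_id)) {
    warning("no transcript was retained; the merged transcriptome is empty")
    records <- seq_records(character(0), character(0))
  } else {
    records <- seq_records(out_id, out_seq)
  }
  tab <- data.frame(
    id = vapply(ranked, `[[`, character(1), "id"),
    node_count = vapply(ranked, `[[`, integer(1), "node_count"),
    long_nodes = lengths(lnm),
    retained = selection$retained,
    locus = ifelse(selection$retained, locus_of, NA_integer_),
    stringsAsFactors = FALSE
  )
  structure(list(records = records, report = report, table = tab,
                 graph = graph, selection = selection, loci = loci),
            class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  cat("merge_result: ", x$report$transcripts, " transcripts in ",
      x$report$loci, " loci; N50 = ", x$report$n50, ", ",
      x$report$total_bases, " bases\n", sep = "")
  invisible(x)
}

#' Write the tab-separated merge report
#'
#' @param report the `report` element of a `merge_result`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  df <- data.frame(transcripts = report$transcripts, loci = report$loci,
                   n50 = report$n50, total_bases = report$total_bases)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
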