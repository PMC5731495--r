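mk_tp <- function(id, len, nodes, path_nodes = seq_len(nodes)) {
  nodes <- as.integer(nodes)
  structure(list(id = id, seq = strrep("A", len),
                 path = data.frame(node = path_nodes, orient = "+",
                                   enter = 1L, exit = 1L),
                 extended_seq = strrep("A", len), node_count = nodes,
                 avg_len = len / nodes),
            class = "transcript_path")
}

test_that("long-node selection is strict in the length cutoff", {
  set.seed(51)
  g <- build_graph(seq_records("t", rand_dna(51)), merge_params(k = 25))
  expect_equal(nchar(g$nodes$seq), 51L)
  tp <- thread_transcript(g, list(id = "t", seq = g$nodes$seq))
  expect_equal(long_nodes(g, tp, c2 = 50), g$nodes$id)   # 51 > 50
  expect_length(long_nodes(g, tp, c2 = 51), 0L)          # 51 not > 51
  expect_equal(long_nodes(g, tp, c2 = 0), g$nodes$id)
})

test_that("ranking prefers node count, then length, then id", {
  tps <- list(mk_tp("a", 100, 3), mk_tp("b", 400, 5), mk_tp("c", 50, 1))
  r <- rank_transcripts(tps)
  expect_equal(vapply(r, `[[`, character(1), "id"), c("b", "a", "c"))
  tps <- list(mk_tp("x", 100, 2), mk_tp("y", 200, 2))
  expect_equal(vapply(rank_transcripts(tps), `[[`, character(1), "id"),
               c("y", "x"))
  ## permutation invariance
  set.seed(52)
  tps <- lapply(1:40, function(i) {
    mk_tp(sprintf("t%02d", i), sample(50:500, 1), sample(1:8, 1))
  })
  r1 <- rank_transcripts(tps)
  r2 <- rank_transcripts(sample(tps))
  expect_identical(r1, r2)
})

test_that("greedy redundancy removal follows the coverage rule", {
  ## identical duplicates collapse to one
  tps <- list(mk_tp("a", 100, 2), mk_tp("b", 100, 2))
  lnm <- list(c(1L, 2L), c(1L, 2L))
  sel <- remove_redundant(tps, lnm)
  expect_equal(sel$retained, c(TRUE, FALSE))
  ## a strict subset of an already-retained set is removed
  sel <- remove_redundant(list(mk_tp("a", 100, 3), mk_tp("b", 60, 2)),
                          list(c(1L, 2L, 3L), c(2L, 3L)))
  expect_equal(sel$retained, c(TRUE, FALSE))
  ## a transcript contributing one uncovered long node is retained
  sel <- remove_redundant(list(mk_tp("a", 100, 3), mk_tp("b", 60, 2)),
                          list(c(1L, 2L), c(2L, 4L)))
  expect_equal(sel$retained, c(TRUE, TRUE))
  expect_equal(sel$covered_long_nodes, c(1L, 2L, 4L))
  ## nodeless transcripts are dropped unless kept explicitly
  sel <- remove_redundant(list(mk_tp("a", 100, 1)), list(integer(0)))
  expect_false(sel$retained)
  sel <- remove_redundant(list(mk_tp("a", 100, 1)), list(integer(0)),
                          keep_nodeless = TRUE)
  expect_true(sel$retained)
})

test_that("greedy selection matches an independent re-simulation", {
  set.seed(53)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    tps <- lapply(seq_len(n), function(i) {
      mk_tp(sprintf("t%02d", i), sample(50:500, 1), sample(1:8, 1))
    })
    lnm <- lapply(seq_len(n), function(i) {
      sample.int(15, sample(0:4, 1))
    })
    ranked <- rank_transcripts(tps)
    ## reuse node sets under the ranked order
    ids <- vapply(ranked, `[[`, character(1), "id")
    lnm_ranked <- lnm[match(ids, sprintf("t%02d", seq_len(n)))]
    sel <- remove_redundant(ranked, lnm_ranked)
    expect_identical(sel$retained, oracle_greedy(lnm_ranked))
    ## invariant: no retained transcript fully covered by earlier retained
    cov <- character(0)
    for (i in seq_len(n)) {
      ln <- as.character(lnm_ranked[[i]])
      if (sel$retained[i]) {
        expect_true(length(ln) > 0 && !all(ln %in% cov))
        cov <- union(cov, ln)
      }
    }
  }
})

test_that("locus grouping is transitive sharing", {
  tps <- list(mk_tp("A", 100, 2), mk_tp("B", 90, 2), mk_tp("C", 80, 2))
  lnm <- list(c(1L), c(1L, 2L), c(2L))  # A-B share 1, B-C share 2
  sel <- remove_redundant(tps, lnm)
  loci <- group_loci(sel)
  expect_equal(length(loci), 1L)
  expect_setequal(loci[[1]]$members, which(sel$retained))
  ## no sharing: one locus each
  sel2 <- remove_redundant(tps, list(1L, 2L, 3L))
  loci2 <- group_loci(sel2)
  expect_equal(length(loci2), 3L)
})

test_that("loci equal brute-force connected components", {
  skip_if_not_installed("igraph")
  set.seed(54)
  for (rep in 1:20) {
    n <- sample(3:25, 1)
    tps <- lapply(seq_len(n), function(i) mk_tp(sprintf("t%02d", i), 100, 1))
    lnm <- lapply(seq_len(n), function(i) sample.int(12, sample(1:3, 1)))
    sel <- structure(list(order = tps, long_node_map = lnm,
                          retained = rep(TRUE, n),
                          covered_long_nodes = sort(unique(unlist(lnm)))),
                     class = "ranked_selection")
    loci <- group_loci(sel)
    memb <- integer(n)
    for (lc in loci) memb[lc$members] <- lc$id
    want <- oracle_components(lnm)
    ## same partition up to labels
    expect_equal(length(unique(memb)), length(unique(want)))
    expect_true(all(tapply(want, memb, function(v) length(unique(v))) == 1))
    ## partition property
    expect_equal(sort(unlist(lapply(loci, `[[`, "members"))), seq_len(n))
  }
})

test_that("N50 and summary statistics", {
  expect_equal(n50(100L), 100L)
  expect_equal(n50(c(2L, 2L, 2L)), 2L)
  expect_true(is.na(n50(integer(0))))
  set.seed(55)
  for (rep in 1:30) {
    lens <- sample(50:2000, sample(1:60, 1), replace = TRUE)
    expect_equal(n50(lens), oracle_n50(lens))
  }
})

test_that("merging a single transcript returns it unchanged", {
  set.seed(56)
  s <- rand_dna(400)
  f <- write_temp_fasta(s, "tx1")
  res <- merge_assemblies(f, merge_params())
  expect_equal(res$records$id, "Locus_1_Transcript_1")
  expect_equal(res$records$seq, s)
  expect_equal(res$report$transcripts, 1L)
  expect_equal(res$report$loci, 1L)
  expect_equal(res$report$n50, 400L)
})

test_that("merging a file with itself equals merging it once", {
  set.seed(57)
  f <- write_temp_fasta(vapply(rep(300, 5), rand_dna, character(1)))
  out1 <- tempfile(fileext = ".fasta")
  out2 <- tempfile(fileext = ".fasta")
  write_fasta(merge_assemblies(f, merge_params())$records, out1)
  write_fasta(merge_assemblies(c(f, f), merge_params())$records, out2)
  expect_identical(readLines(out1), readLines(out2))
})

test_that("short transcripts are dropped with a warning", {
  set.seed(58)
  f <- write_temp_fasta(c(rand_dna(100), "ACGTACGT"))
  expect_warning(res <- merge_assemblies(f, merge_params(k = 25)),
                 "shorter than k")
  expect_equal(res$report$transcripts, 1L)
})

test_that("increasing c1 weakly decreases the retained count", {
  spec <- fixture_spec(seed = 59, n_true = 15, length_range = c(150L, 400L),
                       shared_pairs = 4L, shared_len = 80L)
  truth <- make_true_set(spec)
  libs <- make_library_assemblies(truth, spec)
  prev <- Inf
  for (c1 in c(0, 25, 60, 120)) {
    res <- merge_assemblies(libs$files, merge_params(c1 = c1))
    expect_lte(res$report$transcripts, prev)
    prev <- res$report$transcripts
  }
})

test_that("the per-transcript table is consistent with the selection", {
  spec <- fixture_spec(seed = 60, n_true = 10)
  truth <- make_true_set(spec)
  libs <- make_library_assemblies(truth, spec)
  res <- merge_assemblies(libs$files, merge_params())
  tab <- res$table
  expect_equal(sum(tab$retained), res$report$transcripts)
  expect_true(all(!is.na(tab$locus[tab$retained])))
  expect_true(all(is.na(tab$locus[!tab$retained])))
  expect_equal(nrow(res$records), res$report$transcripts)
})
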