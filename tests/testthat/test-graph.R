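test_that("a single non-branching transcript collapses to one node", {
  g <- build_graph(seq_records("t1", "ACGGT"), merge_params(k = 3))
  expect_equal(nrow(g$nodes), 1L)
  expect_true(g$nodes$seq %in% c("ACGGT", "ACCGT"))
  expect_equal(g$nodes$kmer_count, 3L)
  expect_equal(nrow(g$edges), 0L)
  expect_equal(node_degree(g, 1, "left"), 0L)
  expect_equal(node_degree(g, 1, "right"), 0L)
})

test_that("convergent transcripts force a branch", {
  g <- build_graph(seq_records(c("t1", "t2"), c("AAACG", "CAACG")),
                   merge_params(k = 3))
  expect_gte(nrow(g$nodes), 2L)
  ## the shared suffix node has in-degree 2 on its entry side
  degs <- vapply(g$nodes$id, function(i) {
    node_degree(g, i, "left") + node_degree(g, i, "right")
  }, integer(1))
  expect_true(any(degs >= 2))
  expect_error(node_degree(g, 999L, "left"), "unknown node")
})

test_that("graph construction fails cleanly on hopeless input", {
  expect_error(build_graph(seq_records("x", "ACG"), merge_params(k = 25)),
               "no transcript reaches")
})

test_that("k-mer and spelling conservation hold on random inputs", {
  set.seed(31)
  for (rep in 1:8) {
    seqs <- rand_seq_set(sample(5:30, 1), 40, 250)
    k <- sample(c(5L, 15L, 25L), 1)
    g <- build_graph(seqs, merge_params(k = k))
    input_kmers <- oracle_kmers(seqs, k)
    expect_equal(sum(g$nodes$kmer_count), length(input_kmers))
    respelled <- oracle_kmers(g$nodes$seq, k)
    expect_identical(names(respelled), names(input_kmers))
    expect_true(all(respelled == 1L))
  }
})

test_that("compaction is maximal: no mergeable degree-1/degree-1 pair", {
  set.seed(32)
  for (rep in 1:8) {
    seqs <- rand_seq_set(sample(5:25, 1), 40, 200)
    k <- sample(c(5L, 15L), 1)
    g <- build_graph(seqs, merge_params(k = k))
    if (!nrow(g$edges)) next
    for (i in seq_len(nrow(g$edges))) {
      e <- g$edges[i, ]
      if (e$from == e$to) next  # self-loops and hairpins stay unmerged
      from_side <- if (e$from_or == "+") "right" else "left"
      to_side <- if (e$to_or == "+") "left" else "right"
      expect_false(node_degree(g, e$from, from_side) == 1L &&
                     node_degree(g, e$to, to_side) == 1L,
                   info = sprintf("rep %d edge %d is mergeable", rep, i))
    }
  }
})

test_that("the graph is invariant under reverse-complementing the input", {
  set.seed(33)
  seqs <- rand_seq_set(20, 40, 200)
  g1 <- build_graph(seqs, merge_params(k = 15))
  g2 <- build_graph(revcomp(seqs), merge_params(k = 15))
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$edges, g2$edges)
})

test_that("the graph is deterministic across record orderings", {
  set.seed(34)
  seqs <- rand_seq_set(20, 40, 200)
  g1 <- build_graph(seqs, merge_params(k = 9))
  g2 <- build_graph(sample(seqs), merge_params(k = 9))
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$edges, g2$edges)
})

test_that("node degrees agree with the uncompacted adjacency oracle", {
  set.seed(35)
  for (rep in 1:6) {
    seqs <- rand_seq_set(sample(4:12, 1), 20, 80)
    k <- 5L
    g <- build_graph(seqs, merge_params(k = k))
    raw <- oracle_raw_edges(seqs, k)
    for (i in g$nodes$id) {
      for (side in c("left", "right")) {
        want <- oracle_node_degree(raw, g$nodes$seq[i], k, side)
        expect_equal(node_degree(g, i, side), want,
                     info = sprintf("rep %d node %d side %s", rep, i, side))
      }
    }
  }
})

test_that("edges respect the (k+1)-mer validation rule", {
  ## AAACG and AACGT overlap by a 3-mer suffix/prefix but the joining
  ## 4-mer AACG only appears where it is actually spelled
  g <- build_graph(seq_records(c("a", "b"), c("TTTAAC", "AACGGG")),
                   merge_params(k = 3))
  ## every stored edge corresponds to an observed (k+1)-mer
  k1 <- names(oracle_kmers(c("TTTAAC", "AACGGG"), 4))
  if (nrow(g$edges)) {
    for (i in seq_len(nrow(g$edges))) {
      e <- g$edges[i, ]
      sf <- g$nodes$seq[e$from]
      st <- g$nodes$seq[e$to]
      a <- if (e$from_or == "+") sf else bio_rc(sf)
      b <- if (e$to_or == "+") st else bio_rc(st)
      jk <- paste0(substring(a, nchar(a) - g$k + 1L), substring(b, g$k, g$k))
      rc <- bio_rc(jk)
      expect_true(min(jk, rc) %in% k1)
    }
  }
})

test_that("GFA export writes one S line per node and L lines per edge", {
  g <- build_graph(seq_records(c("t1", "t2"), c("AAACG", "CAACG")),
                   merge_params(k = 3))
  f <- tempfile(fileext = ".gfa")
  write_gfa(g, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "S\t")), nrow(g$nodes))
  expect_equal(sum(startsWith(lines, "L\t")), nrow(g$edges))
  expect_true(all(grepl("2M$", lines[startsWith(lines, "L\t")])))
})
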