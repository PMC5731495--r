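# txcombine

Merge many small per-library *de novo* transcriptome assemblies into one
large, low-redundancy transcriptome.

## The problem

Joint *de novo* assembly of a large RNA-Seq data set (many conditions,
stages, replicates) is prohibitively memory-intensive for the most
accurate assemblers. A practical divide-and-conquer alternative is to
split the data into libraries, assemble each library independently with
any existing assembler, and then **merge** the per-library transcript
sets. The merge is the hard part: the same transcript shows up in many
libraries, often truncated or fragmented, and naively concatenating the
assemblies produces a hugely redundant transcriptome. `txcombine`
implements the merging step for anyone running such a workflow.

## The algorithm

Given the predicted transcripts of all libraries and a k-mer length *k*
(default 25):

1. **Graph.** Build a bidirected de Bruijn graph whose vertices are the
   canonical k-mers of the transcripts; two k-mers are connected when
   they overlap by k−1 bases *and* the implied (k+1)-mer is itself
   observed. Maximal non-branching paths are compacted into single
   nodes (unitigs). A node and its reverse complement are one node.
2. **Threading and extension.** Each transcript corresponds to an
   oriented node path. Leftover bases of its first and last node are an
   unambiguous extension and are added to the transcript.
3. **Filter.** A transcript is kept only if
   (extended length) / (path node count) > *c₁* (default 25) — paths
   crowded with short nodes indicate noisy assembly.
4. **Greedy selection.** Transcripts are ranked by path node count
   (descending). Walking down the ranking, a transcript is retained only
   if it contains a *long node* (node string longer than *c₂*, default
   50) not yet covered by the transcripts retained before it. Exact
   duplicates and sub-fragments vanish here.
5. **Loci.** Retained transcripts sharing at least one long node are
   grouped — transitively — into loci, and emitted as
   `Locus_<L>_Transcript_<T>` FASTA records with summary statistics
   (count, loci, N50, total bases).

A Phred quality read trimmer (cut at the first base with quality < 15)
is included for preparing reads upstream, plus a seeded synthetic
fixture generator used throughout the test suite.

## Worked example

```r
library(txcombine)

spec  <- fixture_spec(seed = 42, n_true = 6, n_libraries = 3)
truth <- make_true_set(spec)                      # 6 planted transcripts
libs  <- make_library_assemblies(truth, spec)     # 3 noisy library FASTAs

res <- merge_assemblies(libs$files, merge_params())
res
#> merge_result: 6 transcripts in 6 loci; N50 = 1397, 6755 bases
head(res$table)
#>             id node_count long_nodes retained locus
#> 1 true_0003_L2          1          1     TRUE     1
#> 2 true_0003_L3          1          1    FALSE    NA
#> 3 true_0005_L1          1          1     TRUE     2
#> 4 true_0005_L2          1          1    FALSE    NA
#> 5 true_0005_L3          1          1    FALSE    NA
#> 6 true_0004_L1          1          1     TRUE     3
```

The 6 planted transcripts were scattered over 3 libraries as 12 partly
truncated copies; the merge returns exactly 6 transcripts (one per
locus), each the full-length original — truncated copies were extended
back to their complete unitig and then removed as redundant
(`retained = FALSE` rows, whose long node was already covered by the
higher-ranked copy). `write_fasta(res$records, "merged.fasta")` saves
the result.

The same pipeline from a shell:

```sh
txcombine merge -k 25 --c1 25 --c2 50 lib*.fasta -o merged.fasta --report merged.tsv
txcombine trim --quality 15 reads.fq.gz -o trimmed.fq.gz
```

(`txcombine` is installed under `exec/` in the package library; or call
`txcombine::txcombine_main(c("merge", ...))` directly.)

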