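---
title: "Merging per-library transcriptome assemblies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging per-library transcriptome assemblies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txcombine)
```

## Why merge assemblies at all

The most accurate *de novo* transcriptome assemblers are
memory-intensive: assembling one large RNA-Seq data set jointly can
require hundreds of gigabytes. The divide-and-conquer workaround —
assemble each library independently, then combine the per-library
transcript sets — moves the hard part into the *merge*: the same gene is
typically assembled in several libraries, in different states of
completeness and on arbitrary strands, so a naive union is both enormous
and redundant. `txcombine` merges such per-library transcript sets into
a non-redundant transcriptome by reasoning about a de Bruijn graph of
the transcripts themselves (not the reads), which is small enough to be
cheap even when the underlying read set is not.

## The graph model

For a k-mer length $k$, every k-mer of every input transcript is a
vertex, stored *canonically*: a k-mer and its reverse complement are the
same vertex, represented by the lexicographically smaller string. Two
oriented k-mers $s_1\cdots s_k$ and $s_2\cdots s_{k+1}$ are joined by an
edge only when the $(k{+}1)$-mer $s_1\cdots s_{k+1}$ is itself observed
in the transcripts — overlap alone is not evidence of adjacency. Every
maximal non-branching path is compacted into a single node (a unitig)
spelling the concatenation of its k-mers with $k-1$ overlaps. The graph
is bidirected: nodes are strand-free, and any walk through them carries
an orientation per node.

Three safety rules terminate unitigs where a merge would be ambiguous or
self-referential: self-loops, hairpins (a k-mer followed by its own
reverse complement), and palindromic k-mers (possible only for even
$k$) are never merged. A useful consequence is that no node string can
be its own reverse complement, so every canonical k-mer occupies exactly
one (node, offset, orientation) slot — the index that threading relies
on.

With a coverage cutoff $c$, k-mers (and $(k{+}1)$-mers) observed fewer
than $c$ times are removed. Coverage filtering belongs to the upstream
per-library assemblies, so $c$ defaults to 1 (off) during merging; when
raised it is applied uniformly to both the vertex and the edge evidence,
since an edge attested only by discarded $(k{+}1)$-mers would otherwise
survive its own evidence.

## From transcripts to a transcriptome

**Threading.** Each transcript maps to the ordered list of (node,
orientation) steps visited by its consecutive k-mers; consecutive k-mers
at contiguous offsets of the same oriented node merge into one step, and
a repeat traversal of the same node counts again — the path, not the
node set, is what the downstream ratio measures.

**End extension.** The terminal nodes of the path may spell bases beyond
the transcript's entry and exit offsets. Those bases are an unambiguous
continuation of the transcript (they sit on the same unitig) and are
prepended/appended. Extension never crosses a node boundary: past the
terminal node a junction begins and continuation would be a guess, even
when the out-degree there is 1 (the neighbouring node's bases are not
part of this transcript's own unambiguous context). Extension is a pure
function of the record and its path, hence idempotent.

**Average-length filter ($c_1$, default 25).** A transcript is retained
only when its *extended* length divided by its path node count is
strictly above $c_1$. Fragmented, noisy or chimeric transcripts thread
through many short nodes and fail this ratio. The extended length is
used because extension precedes selection in the pipeline: the filter
judges the transcript as it would be emitted. The comparison is strict —
a ratio exactly equal to $c_1$ is removed — and the boundary is tested
explicitly.

**Ranking and greedy selection ($c_2$, default 50).** Transcripts are
ranked by path node count, descending; node count correlates with length
but penalizes transcripts that are long merely because they span
repetitive or translocated junk. Ties break by extended length
(descending), then record id, then sequence, making the ranking a pure
function of the record set. A *long node* is a node whose string is
strictly longer than $c_2$ bases; short nodes are too promiscuous (they
are shared by unrelated transcripts at random) to serve as evidence of
identity. Walking down the ranking, a transcript is retained iff it
contains at least one long node not yet covered, and its long nodes then
join the covered set. Coverage grows only on retention: if a discarded
transcript could shadow nodes, sequence visible only in it would vanish
from the output without any retained representative. Transcripts with no
long nodes at all are removed by default (`keep_nodeless = TRUE` keeps
them as singleton loci, for short-transcript use cases).

**Loci.** Retained transcripts sharing at least one long node are
grouped transitively — loci are the connected components of the sharing
relation, computed by a union–find keyed by long node (linear in the
number of transcript–node incidences). Output records are named
`Locus_<L>_Transcript_<T>` with loci numbered by their best member's
rank.

**Statistics.** The report gives the retained count, locus count, total
bases, and N50 — the largest length $L$ such that retained transcripts
of length $\ge L$ together contain at least half of all retained bases
(computed as the first crossing of the descending cumulative sum).

## Parameters at a glance

| parameter | default | unit | meaning |
|---|---|---|---|
| `k` | 25 | bases | k-mer length of the graph; also the minimum transcript length that can thread |
| `c` | 1 | count | k-mer coverage cutoff; leave at 1 when merging (filtering belongs upstream) |
| `c1` | 25 | bases/node | minimum average node length of a path (strict) |
| `c2` | 50 | bases | minimum node string length for a *long* node (strict) |
| `threshold` | 15 | Phred | read trimming: cut at the first base below this quality |

The defaults are the tested operating point for transcripts from typical
short-read assemblers; `k` must stay below the shortest transcript you
want to keep. For `k ≤ 31` k-mers are handled as 2-bit-packed 64-bit
integers (numeric order equals lexicographic order, so canonical
semantics are unchanged); longer `k` transparently falls back to a
string-keyed path.

## Read trimming

`trim_reads()` cuts each read to the prefix strictly before the first
position with quality below the threshold (default 15) — the hard-clip
rule commonly used to prepare reads for assembly. Phred+33 is assumed,
with a `phred64` option. Reads trimmed to length zero are dropped by
default because they break downstream tools; `keep_empty` and `min_len`
adjust this. Whether very short trimmed reads should also be discarded
is use-case dependent, so `min_len` defaults to 0 rather than guessing.

## The synthetic fixture generator

`fixture_spec()` / `make_true_set()` / `make_library_assemblies()`
emulate the input the merge receives: a planted "truth" of random
transcripts (default 50 transcripts of 300–1500 bp, a typical mRNA
range) scattered over libraries (default 3) such that each transcript
has one full-length primary copy in its home library, appears in each
other library with probability `duplicate_rate` (0.5), and non-primary
copies are end-truncated with probability `truncation_rate` (0.5, up to
25% per end) and optionally mutated (`snp_rate`, default 0;
substitution-only so the k-mer sharing structure stays analyzable).
`shared_pairs`/`shared_len` embed a common block in transcript pairs to
plant locus structure. `make_reads()` adds uniform-coverage reads with
planted low-quality tails for the trimmer. All generators are pure
functions of their inputs and a seed, and a JSON manifest records the
ground truth for recovery scoring.

What the generator does *not* emulate: expression levels, splice
isoforms, indels, chimeras, or assembler-specific artifacts. Passing
tests therefore demonstrate the combinatorial correctness of the merge
(redundancy collapses, planted sequence is recovered, loci equal
transitive sharing) — not that any particular upstream assembler's
errors are repaired.

## Numerical and degenerate-input choices

* Lexicographic comparisons and sorts use C (byte) collation throughout,
  so results are locale- and platform-independent; node ids are assigned
  by sorted canonical node string, making the graph, the FASTA output
  and the reports byte-identical across runs and input orderings.
* A k-mer equal to its own reverse complement counts once per window,
  not twice.
* Windows containing `N` are skipped entirely; a transcript whose every
  window contains `N` has no path and is dropped with a warning, as are
  transcripts shorter than `k`.
* An empty retained set is a warning plus an empty FASTA, not an error.
* Sequences shorter than `k` contribute no k-mers; building a graph from
  such input alone is an error with a clear message.

## Problem sizes used by the test suite

The suite validates every stage against independent brute-force oracles
(a naive sliding-window counter with a different reverse-complement
engine, an uncompacted adjacency list for degrees, a greedy
re-simulation, igraph connected components, a cumulative-sum N50): 100
random transcript sets of 20–200 sequences × 30–500 bp at
k ∈ {5, 15, 25} for enumeration and iterative extension, 25 random
graphs for compaction, and end-to-end merges of 50 planted transcripts
across 3 libraries. The full suite runs in about three minutes on one
CPU.

## Known limitations

* The merge assumes its inputs are assembled transcripts, not reads; it
  performs no error correction, tip clipping or bubble popping — the
  upstream assemblers already did that, and applying such simplification
  here would destroy real isoform structure.
* Redundancy is judged solely through long-node coverage: two retained
  transcripts may still overlap by stretches shorter than `c2`.
* Expression-based selection, ORF assessment and reference-based
  validation are deliberately out of scope.
* With `c > 1` at merge time, edges and vertices are filtered jointly;
  raising `c` here is exposed but untested territory and best left at 1.
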