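#' Specification for a synthetic assembly fixture
#'
#' Describes a planted "true" transcript set and how its copies are
#' scattered across independently assembled libraries: some copies are
#' truncated at the ends (mimicking incomplete per-library assemblies),
#' some are duplicated into other libraries (mimicking transcripts
#' expressed in several conditions), and copies may carry substitution
#' noise. Substitution-only noise keeps the k-mer sharing structure of
#' the planted set analyzable.
#'
#' @param seed integer seed; every generator below is a pure function of
#'   its inputs and this seed.
#' @param n_true number of planted transcripts.
#' @param length_range integer vector `c(min, max)` of transcript
#'   lengths; the minimum must stay at or above the k used downstream.
#' @param n_libraries number of per-library files to scatter copies into.
#' @param truncation_rate fraction of the non-primary copies truncated at
#'   their ends (the primary copy of each transcript stays full length).
#' @param duplicate_rate probability that a transcript also appears in
#'   each non-home library.
#' @param snp_rate per-base substitution probability on non-primary
#'   copies.
#' @param shared_pairs number of transcript pairs forced to share a
#'   common sequence block, to plant locus structure.
#' @param shared_len length of the shared block (choose it above the
#'   node length cutoff c2 so the pair shares a long node).
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_true = 50L,
                         length_range = c(300L, 1500L), n_libraries = 3L,
                         truncation_rate = 0.5, duplicate_rate = 0.5,
                         snp_rate = 0, shared_pairs = 0L,
                         shared_len = 120L) {
  stopifnot(n_true >= 0L, n_libraries >= 1L,
            truncation_rate >= 0, truncation_rate <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            snp_rate >= 0, snp_rate <= 1,
            length_range[1] <= length_range[2],
            2L * shared_pairs <= max(n_true, 1L))
  structure(list(seed = as.integer(seed), n_true = as.integer(n_true),
                 length_range = as.integer(length_range),
                 n_libraries = as.integer(n_libraries),
                 truncation_rate = truncation_rate,
                 duplicate_rate = duplicate_rate, snp_rate = snp_rate,
                 shared_pairs = as.integer(shared_pairs),
                 shared_len = as.integer(shared_len)),
            class = "fixture_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate the planted "true" transcript set
#'
#' @param spec a [fixture_spec()].
#' @return a [seq_records()] frame of `spec$n_true` random transcripts;
#'   for each of the first `spec$shared_pairs` consecutive pairs a common
#'   block of `spec$shared_len` bases is embedded in both members.
#' @export
make_true_set <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_true
    if (n == 0L) return(seq_records(character(0), character(0)))
    lens <- sample(seq(spec$length_range[1], spec$length_range[2]), n,
                   replace = TRUE)
    seqs <- vapply(lens, random_dna, character(1))
    if (spec$shared_pairs > 0L) {
      for (p in seq_len(spec$shared_pairs)) {
        i <- 2L * p - 1L; j <- 2L * p
        block <- random_dna(spec$shared_len)
        for (t in c(i, j)) {
          pos <- sample.int(nchar(seqs[t]) - spec$shared_len + 1L, 1L)
          substr(seqs[t], pos, pos + spec$shared_len - 1L) <- block
        }
      }
    }
    seq_records(sprintf("true_%04d", seq_len(n)), seqs)
  })
}

#' Scatter noisy copies of the true set into per-library FASTA files
#'
#' Each transcript is assigned a home library (round robin) where its
#' primary, full-length copy lives; it additionally appears in each
#' other library with probability `duplicate_rate`. Non-primary copies
#' are truncated with probability `truncation_rate` (up to 25% off each
#' end) and mutated at `snp_rate` per base.
#'
#' @param truth a [seq_records()] frame from [make_true_set()].
#' @param spec a [fixture_spec()].
#' @param dir directory to write `lib<i>.fasta` files and
#'   `manifest.json` into.
#' @return list with `files` (library FASTA paths), `manifest` (path to
#'   the ground-truth JSON) and `copies` (data frame of copy
#'   provenance: copy id, source transcript, library, truncated,
#'   mutated).
#' @export
make_library_assemblies <- function(truth, spec, dir = tempfile("fixture")) {
  stopifnot(nrow(truth) > 0L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed + 1L, {
    L <- spec$n_libraries
    home <- rep_len(seq_len(L), nrow(truth))
    rows <- list()
    for (t in seq_len(nrow(truth))) {
      libs <- home[t]
      if (L > 1L) {
        extra <- setdiff(seq_len(L), home[t])
        extra <- extra[stats::runif(length(extra)) < spec$duplicate_rate]
        libs <- c(libs, extra)
      }
      for (lib in libs) {
        s <- truth$seq[t]
        primary <- lib == home[t]
        truncated <- FALSE; mutated <- FALSE
        if (!primary && stats::runif(1) < spec$truncation_rate) {
          n <- nchar(s)
          cut_l <- sample.int(max(1L, floor(n * 0.25)), 1L) - 1L
          cut_r <- sample.int(max(1L, floor(n * 0.25)), 1L) - 1L
          s <- substr(s, 1L + cut_l, n - cut_r)
          truncated <- cut_l + cut_r > 0L
        }
        if (!primary && spec$snp_rate > 0) {
          ch <- strsplit(s, "", fixed = TRUE)[[1]]
          hit <- which(stats::runif(length(ch)) < spec$snp_rate)
          if (length(hit)) {
            for (p in hit) {
              ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
            }
            s <- paste(ch, collapse = "")
            mutated <- TRUE
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_L%d", truth$id[t], lib),
          source = truth$id[t], library = lib, seq = s,
          truncated = truncated, mutated = mutated,
          stringsAsFactors = FALSE
        )
      }
    }
    copies <- do.call(rbind, rows)
    files <- character(L)
    for (lib in seq_len(L)) {
      sub <- copies[copies$library == lib, , drop = FALSE]
      files[lib] <- file.path(dir, sprintf("lib%02d.fasta", lib))
      write_fasta(seq_records(sub$id, sub$seq), files[lib])
    }
    manifest <- file.path(dir, "manifest.json")
    jsonlite::write_json(
      list(truth = data.frame(id = truth$id, length = nchar(truth$seq),
                              seq = truth$seq, stringsAsFactors = FALSE),
           copies = copies[, c("id", "source", "library", "truncated",
                               "mutated")],
           spec = unclass(spec)),
      manifest, auto_unbox = TRUE, digits = NA
    )
    list(files = files, manifest = manifest, copies = copies)
  })
}

#' Simulate uniform-coverage reads with synthetic qualities
#'
#' Reads are drawn uniformly along each transcript, on either strand.
#' Qualities are high (40) throughout, except that a fraction of reads
#' carries a planted low-quality tail (scores below 15) starting at a
#' random position -- the structure the quality trimmer is meant to cut.
#'
#' @param truth a [seq_records()] frame; every sequence must be at least
#'   `read_len` long.
#' @param read_len read length in bases.
#' @param depth mean per-base coverage; `depth = 0` yields no reads.
#' @param seed integer seed.
#' @param bad_tail_rate fraction of reads given a low-quality tail.
#' @return a [seq_records()] frame with a `qual` list-column.
#' @export
make_reads <- function(truth, read_len, depth, seed = 1L,
                       bad_tail_rate = 0.3) {
  stopifnot(all(nchar(truth$seq) >= read_len))
  with_seed(seed, {
    ids <- character(0); seqs <- character(0); quals <- list()
    for (t in seq_len(nrow(truth))) {
      n <- nchar(truth$seq[t])
      n_reads <- round(depth * n / read_len)
      if (n_reads < 1L) next
      starts <- sample.int(n - read_len + 1L, n_reads, replace = TRUE)
      for (r in seq_len(n_reads)) {
        s <- substr(truth$seq[t], starts[r], starts[r] + read_len - 1L)
        if (stats::runif(1) < 0.5) s <- revcomp(s)
        q <- rep(40L, read_len)
        if (stats::runif(1) < bad_tail_rate) {
          p <- sample.int(read_len, 1L)
          q[p:read_len] <- sample(2:14, read_len - p + 1L, replace = TRUE)
        }
        ids <- c(ids, sprintf("read_%s_%06d", truth$id[t], r))
        seqs <- c(seqs, s)
        quals[[length(quals) + 1L]] <- q
      }
    }
    if (!length(ids)) {
      out <- seq_records(character(0), character(0))
      out$qual <- list()
      return(out)
    }
    seq_records(ids, seqs, qual = quals)
  })
}
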