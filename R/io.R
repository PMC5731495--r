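#' Construct a set of sequence records
#'
#' Sequence records are the common currency of the package: a plain
#' `data.frame` with columns `id`, `seq` and (optionally) a list-column
#' `qual` of integer Phred scores, one vector per record.
#'
#' @param id character vector of record identifiers.
#' @param seq character vector of DNA sequences over `{A,C,G,T,N}`.
#' @param qual optional list of integer vectors, one per record, each the
#'   same length as the corresponding sequence.
#' @return a `data.frame` with class `seq_records`.
#' @export
seq_records <- function(id, seq, qual = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  seq <- chartr("U", "T", seq)
  if (length(id) != length(seq)) {
    stop("'id' and 'seq' must have the same length")
  }
  if (any(!nzchar(id))) {
    stop("record identifiers must be non-empty")
  }
  df <- data.frame(id = id, seq = seq, stringsAsFactors = FALSE)
  if (!is.null(qual)) {
    if (length(qual) != nrow(df)) {
      stop("'qual' must supply one vector per record")
    }
    bad <- which(lengths(qual) != nchar(seq))
    if (length(bad)) {
      stop("quality length differs from sequence length for record '",
           id[bad[1]], "'")
    }
    df$qual <- lapply(qual, as.integer)
  }
  class(df) <- c("seq_records", "data.frame")
  df
}

#' Read a FASTA file
#'
#' Sequences are uppercased and `U` is mapped to `T` so that downstream
#' k-mer machinery only ever sees DNA. The record id is the first
#' whitespace-delimited token of the header. Files ending in `.gz` are
#' decompressed transparently.
#'
#' @param path path to a FASTA file (optionally gzip-compressed).
#' @return a [seq_records()] data frame in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  empty <- which(!nzchar(seqs))
  if (length(empty)) {
    stop("empty sequence for record '", ids[empty[1]], "' in ", path)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate record id '", ids[duplicated(ids)][1], "' in ", path)
  }
  seq_records(ids, seqs)
}

#' Write records to a FASTA file
#'
#' @param records a [seq_records()] data frame with non-empty sequences.
#' @param path output path; `.gz` triggers gzip compression.
#' @param width line width for wrapping sequence lines.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(width >= 1L)
  if (any(!nzchar(records$seq))) stop("refusing to write empty sequences")
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(
    set, path, width = as.integer(width), format = "fasta",
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path path to a FASTQ file (optionally gzip-compressed).
#' @param encoding Phred encoding of the quality line, `"phred33"`
#'   (modern default) or `"phred64"`.
#' @return a [seq_records()] data frame with a `qual` list-column.
#' @export
read_fastq <- function(path, encoding = c("phred33", "phred64")) {
  encoding <- match.arg(encoding)
  offset <- if (encoding == "phred33") 33L else 64L
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ in '", path, "': ", length(lines),
         " lines is not a multiple of 4")
  }
  n <- length(lines) %/% 4L
  heads <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(substr(heads, 1L, 1L) != "@")) {
    stop("malformed FASTQ header in '", path, "'")
  }
  ids <- sub("\\s.*$", "", substring(heads, 2L))
  if (any(nchar(quals) != nchar(seqs))) {
    bad <- which(nchar(quals) != nchar(seqs))[1]
    stop("quality/sequence length mismatch for record '", ids[bad], "'")
  }
  qual <- lapply(quals, function(q) utf8ToInt(q) - offset)
  seq_records(ids, seqs, qual = qual)
}

#' Write records to a FASTQ file
#'
#' @inheritParams write_fasta
#' @param encoding Phred encoding for the quality line.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(records, path, encoding = c("phred33", "phred64")) {
  encoding <- match.arg(encoding)
  offset <- if (encoding == "phred33") 33L else 64L
  if (is.null(records$qual)) stop("records carry no quality scores")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  qlines <- vapply(records$qual, function(q) {
    if (!length(q)) "" else intToUtf8(q + offset)
  }, character(1))
  out <- character(4L * nrow(records))
  out[seq(1L, by = 4L, length.out = nrow(records))] <- paste0("@", records$id)
  out[seq(2L, by = 4L, length.out = nrow(records))] <- records$seq
  out[seq(3L, by = 4L, length.out = nrow(records))] <- "+"
  out[seq(4L, by = 4L, length.out = nrow(records))] <- qlines
  writeLines(out, con)
  invisible(path)
}

#' Trim reads at the first low-quality base
#'
#' Each read is cut back to the prefix strictly before the first position
#' whose quality score falls below `threshold`; reads with no such
#' position are returned unchanged. This is the standard hard-clip rule
#' used to prepare reads for de novo assembly.
#'
#' @param records a [seq_records()] data frame with a `qual` column.
#' @param threshold minimum acceptable Phred score (default 15).
#' @param min_len drop trimmed reads shorter than this many bases.
#'   The default 0 keeps everything except empty reads (see `keep_empty`).
#' @param keep_empty keep reads trimmed to length zero (default drops
#'   them, since zero-length records break downstream tools).
#' @return a [seq_records()] data frame of trimmed reads.
#' @export
trim_reads <- function(records, threshold = 15L, min_len = 0L,
                       keep_empty = FALSE) {
  if (is.null(records$qual)) stop("records carry no quality scores")
  keep_n <- vapply(records$qual, function(q) {
    low <- which(q < threshold)
    if (length(low)) low[1] - 1L else length(q)
  }, integer(1))
  seqs <- substr(records$seq, 1L, keep_n)
  qual <- mapply(function(q, n) q[seq_len(n)], records$qual, keep_n,
                 SIMPLIFY = FALSE)
  out <- data.frame(id = records$id, seq = seqs, stringsAsFactors = FALSE)
  out$qual <- unname(qual)
  keep <- keep_n >= max(min_len, if (keep_empty) 0L else 1L)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("seq_records", "data.frame")
  out
}
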