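# Sequence primitives, transcriptome container and FASTA/TSV I/O.
#
# Conventions used throughout the package:
#   * all coordinates are 0-based, half-open [start, end); report writers
#     additionally print 1-based inclusive coordinates for human reading;
#   * sequences are DNA alphabet {A,C,G,T,N}; U is mapped to T and case is
#     folded to upper on every input path;
#   * N in a transcriptome is treated conservatively in off-target
#     screening (mismatch against every base); candidate oligos may not
#     contain N.

#' Normalize a nucleotide sequence
#'
#' Upper-cases, maps U to T and validates the alphabet `{A,C,G,T,N}`.
#'
#' @param seq single character string.
#' @param what label used in error messages.
#' @return normalized string.
#' @keywords internal
normalize_seq <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    ob_stop(sprintf("%s must be a single character string", what))
  s <- chartr("u", "T", toupper(seq))
  s <- chartr("U", "T", s)
  bad <- regexpr("[^ACGTN]", s)[1L]
  if (bad > 0L)
    ob_stop(sprintf("%s contains non-nucleotide character '%s' at position %d",
                    what, substr(s, bad, bad), bad))
  s
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick reverse complement over `{A,C,G,T,N}`; `N` maps to `N`.
#' The empty string is its own reverse complement and the operation is an
#' involution.
#'
#' @param seq nucleotide string (U accepted, mapped to T).
#' @return reverse-complemented string.
#' @examples
#' reverse_complement("TCCGATGGTAGTGGGT")
#' @export
reverse_complement <- function(seq) {
  s <- normalize_seq(seq)
  if (nchar(s) == 0L) return("")
  comp <- chartr("ACGTN", "TGCAN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Hamming distance between equal-length strings
#'
#' Number of positions at which the two strings differ, by byte
#' comparison: `N` therefore mismatches every base except `N` itself.
#'
#' @param a,b strings of equal length.
#' @return integer count of mismatching positions.
#' @export
hamming_distance <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L || length(b) != 1L)
    ob_stop("hamming_distance expects two single strings")
  if (nchar(a) != nchar(b))
    ob_stop(sprintf("unequal lengths: %d vs %d", nchar(a), nchar(b)))
  if (nchar(a) == 0L) return(0L)
  sum(charToRaw(a) != charToRaw(b))
}

#' Transcript record
#'
#' A single transcript: identifier, normalized sequence and an optional
#' biotype label (e.g. `"miRNA"`, `"YRNA"`, `"protein_coding"`).
#'
#' @param id non-empty identifier.
#' @param seq non-empty nucleotide string.
#' @param biotype optional biotype string.
#' @return object of class `transcript_record`.
#' @export
transcript_record <- function(id, seq, biotype = NA_character_) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    ob_stop("transcript id must be a non-empty string")
  s <- normalize_seq(seq, what = sprintf("sequence of '%s'", id))
  if (!nzchar(s)) ob_stop(sprintf("transcript '%s' has an empty sequence", id))
  structure(list(id = id, seq = s, biotype = as.character(biotype)),
            class = "transcript_record")
}

#' Transcriptome container
#'
#' Ordered collection of transcripts; the search space for off-target
#' screening. Construct from a named character vector of sequences.
#'
#' @param seqs named character vector (names are transcript ids).
#' @param biotypes optional named character vector mapping ids to biotypes.
#' @return object of class `transcriptome`.
#' @export
transcriptome <- function(seqs, biotypes = NULL) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids))
    ob_stop("all sequences must carry a non-empty id (names of `seqs`)")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    ob_stop(sprintf("duplicate transcript ids: %s", paste(dup, collapse = ", ")))
  norm <- vapply(seq_along(seqs), function(i)
    normalize_seq(seqs[[i]], what = sprintf("sequence of '%s'", ids[i])),
    character(1))
  if (any(!nzchar(norm)))
    ob_stop(sprintf("empty sequence for: %s",
                    paste(ids[!nzchar(norm)], collapse = ", ")))
  names(norm) <- ids
  bt <- rep(NA_character_, length(ids))
  names(bt) <- ids
  if (!is.null(biotypes)) {
    keep <- intersect(names(biotypes), ids)
    bt[keep] <- as.character(biotypes[keep])
  }
  structure(list(ids = ids, seqs = norm, biotypes = bt),
            class = "transcriptome")
}

#' @export
length.transcriptome <- function(x) length(x$ids)

#' Fetch one transcript record by id or index
#' @param tx transcriptome.
#' @param id transcript id (or integer index).
#' @return `transcript_record`.
#' @export
tx_get <- function(tx, id) {
  stopifnot(inherits(tx, "transcriptome"))
  if (is.numeric(id)) id <- tx$ids[[id]]
  if (!id %in% tx$ids) ob_stop(sprintf("transcript '%s' not found", id))
  transcript_record(id, tx$seqs[[id]], tx$biotypes[[id]])
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("transcriptome: %d transcripts, total %d nt\n",
              length(x$ids), sum(nchar(x$seqs))))
  n <- min(5L, length(x$ids))
  for (i in seq_len(n))
    cat(sprintf("  %s (%d nt, biotype %s)\n", x$ids[i], nchar(x$seqs[i]),
                x$biotypes[i]))
  if (length(x$ids) > n) cat(sprintf("  ... and %d more\n", length(x$ids) - n))
  invisible(x)
}

#' Genomic-style interval on a transcript
#'
#' 0-based, half-open `[start, end)` on the sense strand of one transcript.
#' Blocking oligos always bind antisense to the sense transcript.
#'
#' @param transcript_id transcript identifier.
#' @param start,end 0-based half-open bounds, `0 <= start < end`.
#' @return object of class `ob_interval`.
#' @export
interval <- function(transcript_id, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    ob_stop(sprintf("invalid interval [%s, %s): need 0 <= start < end",
                    start, end))
  structure(list(transcript_id = transcript_id, start = start, end = end,
                 strand_of_oligo = "antisense"),
            class = "ob_interval")
}

interval_length <- function(iv) iv$end - iv$start

#' Read a transcriptome from FASTA
#'
#' Wrapped or unwrapped FASTA; the header token before the first
#' whitespace is the transcript id. U is normalized to T and case folded
#' to upper. Duplicate ids and empty sequences are errors.
#'
#' @param path FASTA file.
#' @param biotypes optional named character vector or path to a 2-column
#'   TSV `transcript_id<TAB>biotype` (optional header).
#' @return `transcriptome`.
#' @export
read_fasta <- function(path, biotypes = NULL) {
  if (!file.exists(path)) ob_stop(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (is.character(biotypes) && length(biotypes) == 1L && file.exists(biotypes))
    biotypes <- read_biotypes(biotypes)
  if (length(set) == 0L)
    return(transcriptome(stats::setNames(character(0), character(0))))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  names(seqs) <- ids
  transcriptome(seqs, biotypes = biotypes)
}

#' Write a transcriptome to FASTA
#'
#' @param tx transcriptome.
#' @param path output file.
#' @param width line-wrap width (default 60).
#' @export
write_fasta <- function(tx, path, width = 60L) {
  stopifnot(inherits(tx, "transcriptome"))
  set <- Biostrings::DNAStringSet(tx$seqs)
  names(set) <- tx$ids
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Read a biotype map from a 2-column TSV
#'
#' Columns: transcript_id, biotype; an optional header line (recognized by
#' the literal tokens `transcript_id`/`biotype`) is skipped.
#'
#' @param path TSV file.
#' @return named character vector id -> biotype.
#' @export
read_biotypes <- function(path) {
  if (!file.exists(path)) ob_stop(sprintf("biotype TSV not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    ob_stop(sprintf("biotype TSV line without two tab-separated fields: '%s'",
                    lines[which(lengths(fields) < 2L)[1L]]))
  first <- tolower(fields[[1L]])
  if (first[1L] %in% c("transcript_id", "id") || first[2L] == "biotype")
    fields <- fields[-1L]
  ids <- vapply(fields, `[`, character(1), 1L)
  bt <- vapply(fields, `[`, character(1), 2L)
  stats::setNames(bt, ids)
}

# ---- exact k-mer lookup ----------------------------------------------------

#' Build an exact k-mer index over a transcriptome
#'
#' Optional acceleration structure for exact k-mer lookup; results are
#' identical with or without the index.
#'
#' @param tx transcriptome.
#' @param k k-mer length.
#' @return object of class `kmer_index`.
#' @export
build_kmer_index <- function(tx, k) {
  stopifnot(inherits(tx, "transcriptome"))
  k <- as.integer(k)
  ob_assert(k >= 1L, "k must be >= 1")
  env <- new.env(parent = emptyenv(), hash = TRUE)
  for (id in tx$ids) {
    s <- tx$seqs[[id]]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    for (i in seq_along(kmers)) {
      key <- kmers[i]
      hit <- c(id = id, start = starts[i] - 1L)
      env[[key]] <- c(env[[key]], list(hit))
    }
  }
  structure(list(k = k, env = env), class = "kmer_index")
}

#' Exact k-mer lookup in a transcriptome
#'
#' All (overlapping) exact occurrences of `kmer` on the sense strand.
#'
#' @param tx transcriptome.
#' @param kmer query k-mer.
#' @param index optional `kmer_index` built with matching `k`.
#' @return data.frame with columns transcript_id, start, end (0-based
#'   half-open), sorted by (transcript_id, start).
#' @export
tx_find_kmer <- function(tx, kmer, index = NULL) {
  stopifnot(inherits(tx, "transcriptome"))
  kmer <- normalize_seq(kmer, "kmer")
  k <- nchar(kmer)
  if (!is.null(index)) {
    stopifnot(inherits(index, "kmer_index"))
    if (index$k != k) ob_stop("index k does not match query length")
    hits <- index$env[[kmer]]
    if (is.null(hits))
      return(data.frame(transcript_id = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE))
    df <- data.frame(
      transcript_id = vapply(hits, `[[`, character(1), "id"),
      start = as.integer(vapply(hits, `[[`, character(1), "start")),
      stringsAsFactors = FALSE)
  } else {
    out_id <- character(0); out_start <- integer(0)
    for (id in tx$ids) {
      s <- tx$seqs[[id]]
      L <- nchar(s)
      if (L < k) next
      starts <- seq_len(L - k + 1L)
      hit <- substring(s, starts, starts + k - 1L) == kmer
      if (any(hit)) {
        out_id <- c(out_id, rep(id, sum(hit)))
        out_start <- c(out_start, starts[hit] - 1L)
      }
    }
    df <- data.frame(transcript_id = out_id, start = out_start,
                     stringsAsFactors = FALSE)
  }
  df$end <- df$start + k
  df[order(df$transcript_id, df$start), , drop = FALSE]
}
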