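# Internal adenosine-rich RT-priming sites and the design window 5' of
# them in which blocking candidates are tiled.
#
# "Adenosine-rich" is formalized as: any window of length >= min_run with
# A-fraction >= min_a_fraction, lying wholly outside the terminal
# tail_exclusion zone. Reported sites are the connected components of the
# union coverage of all qualifying windows, trimmed to A at both ends; a
# component whose merged A-fraction falls below the threshold (possible
# when overlapping qualifying windows bridge through a non-A patch) is
# shrunk to its longest contained qualifying window (leftmost on ties)
# rather than dropped, so a genuine A-run is never lost. This definition
# is mirrored brute-force by the test oracle.

polya_site <- function(transcript_id, start, end, a_fraction) {
  structure(list(interval = interval(transcript_id, start, end),
                 a_fraction = a_fraction,
                 run_length = end - start),
            class = "polya_site")
}

#' @export
print.polya_site <- function(x, ...) {
  iv <- x$interval
  cat(sprintf("polya_site %s:[%d,%d) (1-based %d-%d), %d nt, A-fraction %.3f\n",
              iv$transcript_id, iv$start, iv$end, iv$start + 1L, iv$end,
              x$run_length, x$a_fraction))
  invisible(x)
}

#' Find internal adenosine-rich RT-priming sites
#'
#' Locates maximal internal A-rich stretches that oligo-dT primers can
#' misprime on (the origin of artifactual 3' end reads from transcripts
#' such as mitochondrial rRNA or MALAT1). Terminal poly(A) tails are
#' excluded by ignoring the final `tail_exclusion` nucleotides.
#'
#' @param transcript `transcript_record` (or a transcriptome plus `id`
#'   via [tx_get()]).
#' @param min_run minimum qualifying window length (nt), default 8.
#' @param min_a_fraction minimum A fraction within a window, default 0.8.
#' @param tail_exclusion terminal zone excluded from search (nt),
#'   default 30.
#' @return list of `polya_site`, non-overlapping, sorted by start.
#' @export
find_internal_polya <- function(transcript, min_run = 8L,
                                min_a_fraction = 0.8,
                                tail_exclusion = 30L) {
  stopifnot(inherits(transcript, "transcript_record"))
  min_run <- as.integer(min_run)
  tail_exclusion <- as.integer(tail_exclusion)
  if (min_run < 4L)
    ob_config_stop("min_run < 4 gives a degenerate poly(A) definition")
  if (min_a_fraction <= 0 || min_a_fraction > 1)
    ob_config_stop("min_a_fraction must be in (0, 1]")
  s <- transcript$seq
  L <- nchar(s)
  if (L <= min_run)
    ob_stop(sprintf("transcript '%s' (%d nt) is not longer than min_run (%d)",
                    transcript$id, L, min_run))
  limit <- L - tail_exclusion          # windows must end at or before this
  if (limit < min_run) return(list())
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  isA <- chars == "A"
  prefix <- c(0L, cumsum(isA))
  cover <- logical(limit)
  # union coverage of qualifying windows, one O(limit) pass per length
  for (len in min_run:limit) {
    n_starts <- limit - len + 1L
    if (n_starts < 1L) break
    starts <- seq_len(n_starts)
    acount <- prefix[starts + len] - prefix[starts]
    ok <- starts[acount + 1e-9 >= min_a_fraction * len]
    if (!length(ok)) next
    tab_on <- tabulate(ok, nbins = limit + 1L)
    tab_off <- tabulate(ok + len, nbins = limit + 1L)
    covered <- cumsum(tab_on - tab_off) > 0L
    cover <- cover | covered[seq_len(limit)]
  }
  if (!any(cover)) return(list())
  r <- rle(cover)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  comp <- cbind(starts[r$values], ends[r$values])   # 1-based inclusive
  afrac <- function(a, b) (prefix[b + 1L] - prefix[a]) / (b - a + 1L)
  sites <- list()
  for (i in seq_len(nrow(comp))) {
    a <- comp[i, 1L]; b <- comp[i, 2L]
    while (a <= b && !isA[a]) a <- a + 1L
    while (b >= a && !isA[b]) b <- b - 1L
    if (a > b) next
    if (afrac(a, b) + 1e-9 < min_a_fraction) {
      if (b - a + 1L < min_run) next
      # bridged component: shrink to the longest qualifying window inside
      found <- FALSE
      for (len in (b - a + 1L):min_run) {
        for (s0 in a:(b - len + 1L)) {
          if (afrac(s0, s0 + len - 1L) + 1e-9 >= min_a_fraction) {
            a <- s0; b <- s0 + len - 1L; found <- TRUE; break
          }
        }
        if (found) break
      }
      if (!found) next
      while (a <= b && !isA[a]) a <- a + 1L
      while (b >= a && !isA[b]) b <- b - 1L
    }
    sites[[length(sites) + 1L]] <-
      polya_site(transcript$id, a - 1L, b, afrac(a, b))
  }
  sites
}

#' Design window 5' of a priming site
#'
#' The blocking oligo must sit between the oligo-dT primer and the
#' fragment body, i.e. in the direction reverse transcriptase travels:
#' the `width` sense-strand bases immediately 5' of the A-run,
#' `[max(0, site_start - width), site_start)`, truncated at the
#' transcript start.
#'
#' @param site `polya_site`.
#' @param transcript `transcript_record` containing the site.
#' @param width window width in nt (default 50, the usual design region).
#' @return object of class `design_window`.
#' @export
design_window <- function(site, transcript, width = 50L) {
  stopifnot(inherits(site, "polya_site"), inherits(transcript, "transcript_record"))
  width <- as.integer(width)
  ob_assert(width >= 1L, "width must be >= 1")
  iv <- site$interval
  if (iv$transcript_id != transcript$id)
    ob_stop(sprintf("site is on '%s', not on '%s'", iv$transcript_id,
                    transcript$id))
  L <- nchar(transcript$seq)
  if (iv$end > L) ob_stop("site does not lie within the transcript")
  if (iv$start == 0L)
    ob_stop("no design space 5' of priming site")
  ws <- max(0L, iv$start - width)
  structure(list(
    interval = interval(transcript$id, ws, iv$start),
    seq = substr(transcript$seq, ws + 1L, iv$start),
    source_site = site,
    mode = "polya",
    anchor = "priming_site"
  ), class = "design_window")
}

#' Design window for a short RNA fragment
#'
#' Short-fragment mode: the whole fragment is the design window and the
#' anchor records which end the selector prefers on melting-temperature
#' ties (blockers for short fragments are placed against the 3' end,
#' where reverse transcription starts).
#'
#' @param fragment_seq the fragment sequence.
#' @param anchor currently only `"three_prime_end"`.
#' @param k intended oligo length; the fragment must be at least this long.
#' @return object of class `design_window`.
#' @export
fragment_window <- function(fragment_seq, anchor = "three_prime_end", k) {
  anchor <- match.arg(anchor, "three_prime_end")
  s <- normalize_seq(fragment_seq, "fragment")
  k <- as.integer(k)
  if (nchar(s) < k)
    ob_stop(sprintf("fragment (%d nt) is shorter than k = %d", nchar(s), k))
  structure(list(
    interval = interval("fragment", 0L, nchar(s)),
    seq = s,
    source_site = NULL,
    mode = "fragment",
    anchor = anchor
  ), class = "design_window")
}

#' @export
print.design_window <- function(x, ...) {
  iv <- x$interval
  cat(sprintf("design_window (%s) %s:[%d,%d) (1-based %d-%d), %d nt\n",
              x$mode, iv$transcript_id, iv$start, iv$end, iv$start + 1L,
              iv$end, interval_length(iv)))
  invisible(x)
}

#' Export priming sites as BED-like TSV
#'
#' Columns: transcript_id, start, end (0-based half-open), name,
#' a_fraction, plus 1-based inclusive start/end for human reading.
#'
#' @param sites list of `polya_site`.
#' @param path output TSV path.
#' @export
write_sites_tsv <- function(sites, path) {
  df <- do.call(rbind, lapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    data.frame(transcript_id = s$interval$transcript_id,
               start = s$interval$start, end = s$interval$end,
               name = sprintf("polyA_site_%d", i),
               a_fraction = s$a_fraction,
               start_1based = s$interval$start + 1L,
               end_1based = s$interval$end,
               stringsAsFactors = FALSE)
  }))
  if (is.null(df))
    df <- data.frame(transcript_id = character(0), start = integer(0),
                     end = integer(0), name = character(0),
                     a_fraction = numeric(0), start_1based = integer(0),
                     end_1based = integer(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
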