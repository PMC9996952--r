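# Candidate tiling, off-target screening and blocker selection.

.chemistries <- c("DNA", "LNA", "OME", "MOE")
.pattern_presets <- c("full_dna", "full_lna", "alternating_lna",
                      "full_ome", "alternating_ome",
                      "full_moe", "alternating_moe")

#' Per-position chemistry pattern of an oligo
#'
#' Either a preset name (`full_lna`, `alternating_lna`, `full_ome`,
#' `full_moe`, `alternating_ome`, `alternating_moe`, `full_dna`) or an
#' explicit per-position vector over `DNA`/`LNA`/`OME`/`MOE`.
#' Alternating presets start modified at the first (5') position.
#'
#' @param pattern preset name or character vector of chemistries.
#' @param length oligo length (required for presets).
#' @return character vector of chemistries, one per position.
#' @export
modification_pattern <- function(pattern, length) {
  if (length(pattern) == 1L && pattern %in% .pattern_presets) {
    length <- as.integer(length)
    ob_assert(length >= 1L, "pattern length must be >= 1")
    chem <- toupper(sub("^(full|alternating)_", "", pattern))
    if (chem == "DNA") return(rep("DNA", length))
    if (startsWith(pattern, "full_")) return(rep(chem, length))
    out <- rep("DNA", length)
    out[seq(1L, length, by = 2L)] <- chem   # position 0 (5') is modified
    return(out)
  }
  pattern <- toupper(as.character(pattern))
  if (!all(pattern %in% .chemistries))
    ob_stop(sprintf("unknown chemistry: %s; use %s or a preset (%s)",
                    paste(setdiff(pattern, .chemistries), collapse = ", "),
                    paste(.chemistries, collapse = "/"),
                    paste(.pattern_presets, collapse = ", ")))
  if (!missing(length) && length(pattern) != length)
    ob_stop("explicit pattern length must equal oligo length")
  pattern
}

#' Antisense oligo candidate
#'
#' An antisense DNA-alphabet k-mer with its sense-strand footprint,
#' modification pattern, and (once computed) melting temperature and
#' off-target hits.
#'
#' @param seq antisense sequence (12-30 nt, no N).
#' @param target_site [interval()] of the sense-strand footprint.
#' @param pattern preset name or chemistry vector.
#' @return object of class `oligo_candidate`.
#' @export
oligo_candidate <- function(seq, target_site, pattern = "full_lna") {
  s <- normalize_seq(seq, "oligo")
  k <- nchar(s)
  if (k < 12L || k > 30L)
    ob_stop(sprintf("oligo length %d outside the supported 12-30 nt range", k))
  if (grepl("N", s, fixed = TRUE))
    ob_stop("candidate oligos may not contain N")
  stopifnot(inherits(target_site, "ob_interval"))
  if (interval_length(target_site) != k)
    ob_stop("target_site length must equal oligo length")
  structure(list(seq = s, target_site = target_site,
                 pattern = modification_pattern(pattern, k),
                 tm_c = NA_real_, offtargets = NULL,
                 rank_metadata = list()),
            class = "oligo_candidate")
}

#' @export
print.oligo_candidate <- function(x, ...) {
  iv <- x$target_site
  cat(sprintf("oligo_candidate %s (%d nt) vs %s:[%d,%d); Tm %s C; offtargets %s\n",
              x$seq, nchar(x$seq), iv$transcript_id, iv$start, iv$end,
              ifelse(is.na(x$tm_c), "?", sprintf("%.1f", x$tm_c)),
              ifelse(is.null(x$offtargets), "?", nrow(x$offtargets))))
  invisible(x)
}

#' Tile antisense candidates across a design window
#'
#' One candidate per start offset: a window of length L yields exactly
#' `L - k + 1` candidates, each the reverse complement of the sense
#' k-mer, ordered 5' to 3' along the sense window. Windows containing N
#' drop the affected offsets with a warning.
#'
#' @param window `design_window`.
#' @param k oligo length.
#' @param pattern modification pattern applied to every candidate.
#' @return list of `oligo_candidate`.
#' @export
tile_candidates <- function(window, k, pattern = "full_lna") {
  stopifnot(inherits(window, "design_window"))
  k <- as.integer(k)
  L <- nchar(window$seq)
  if (L < k)
    ob_stop(sprintf("window (%d nt) is shorter than k = %d", L, k))
  offs <- 0:(L - k)
  sense <- substring(window$seq, offs + 1L, offs + k)
  has_n <- grepl("N", sense, fixed = TRUE)
  if (any(has_n)) {
    warning(sprintf("%d candidate offsets dropped (window contains N)",
                    sum(has_n)))
    offs <- offs[!has_n]; sense <- sense[!has_n]
  }
  lapply(seq_along(offs), function(i) {
    site <- interval(window$interval$transcript_id,
                     window$interval$start + offs[i],
                     window$interval$start + offs[i] + k)
    cand <- oligo_candidate(reverse_complement(sense[i]), site, pattern)
    cand$rank_metadata$window_offset <- offs[i]
    cand$rank_metadata$anchor <- window$anchor
    cand
  })
}

#' Exhaustive mismatch-tolerant off-target screen
#'
#' Every sense-strand window of every transcript whose Hamming distance
#' to the candidate's sense target k-mer is at most `max_mismatches`,
#' minus the intended site. The scan is exhaustive (compiled full scan;
#' no heuristic misses). Only the sense strand is searched: the oligo
#' hybridizes the RNA. Transcripts shorter than the oligo are skipped
#' with a logged notice.
#'
#' @param candidate `oligo_candidate`.
#' @param transcriptome `transcriptome` search space.
#' @param max_mismatches maximum Hamming distance (default 3).
#' @param exclude interval of the intended site to exclude; defaults to
#'   the candidate's own `target_site`.
#' @return data.frame(transcript_id, start, end, mismatches), 0-based
#'   half-open, sorted by (transcript_id, start).
#' @export
screen_offtargets <- function(candidate, transcriptome, max_mismatches = 3L,
                              exclude = candidate$target_site) {
  stopifnot(inherits(candidate, "oligo_candidate"),
            inherits(transcriptome, "transcriptome"))
  max_mismatches <- as.integer(max_mismatches)
  ob_assert(max_mismatches >= 0L, "max_mismatches must be >= 0")
  sense <- reverse_complement(candidate$seq)
  k <- nchar(sense)
  short <- nchar(transcriptome$seqs) < k
  if (any(short))
    message(sprintf("skipping %d transcript(s) shorter than the oligo (%d nt)",
                    sum(short), k))
  raw <- .scan_hamming_cpp(unname(transcriptome$seqs), sense, max_mismatches)
  hits <- data.frame(
    transcript_id = transcriptome$ids[raw$subject],
    start = raw$start,
    end = raw$start + k,
    mismatches = raw$mismatches,
    stringsAsFactors = FALSE)
  if (!is.null(exclude)) {
    stopifnot(inherits(exclude, "ob_interval"))
    self <- hits$transcript_id == exclude$transcript_id &
      hits$start == exclude$start & hits$end == exclude$end
    hits <- hits[!self, , drop = FALSE]
  }
  hits <- hits[order(hits$transcript_id, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

count_offtargets_by_mm <- function(offtargets, max_mm = 3L) {
  vapply(0:max_mm, function(m) sum(offtargets$mismatches == m), integer(1))
}

#' Select the final blocking oligo
#'
#' Two-stage rule: (1) retain candidates with zero off-targets; if that
#' empties the pool, fall back to the minimal-off-target-count set
#' (flagged); (2) among the retained, pick the maximum-Tm candidate.
#' Ties break by smaller off-target count, then by position closest to
#' the priming-site/3' anchor, then leftmost. The result is invariant
#' under permutation of the candidate list.
#'
#' @param candidates list of `oligo_candidate`, each with `tm_c` and
#'   `offtargets` filled in (see [design_pipeline()]).
#' @param max_mismatches mismatch cap used for reporting (default 3).
#' @return list with elements `selected` (`oligo_candidate`), `report`
#'   (data.frame of all candidates) and `fallback` (logical).
#' @export
select_oligo <- function(candidates, max_mismatches = 3L) {
  if (!length(candidates)) ob_stop("empty candidate list")
  ok <- vapply(candidates, function(cand)
    inherits(cand, "oligo_candidate") && !is.na(cand$tm_c) &&
      is.data.frame(cand$offtargets), logical(1))
  if (!all(ok))
    ob_stop("all candidates must be screened and Tm-scored before selection")
  n_off <- vapply(candidates, function(cand) nrow(cand$offtargets), integer(1))
  tm <- vapply(candidates, `[[`, numeric(1), "tm_c")
  starts <- vapply(candidates, function(cand) cand$target_site$start, integer(1))
  ends <- vapply(candidates, function(cand) cand$target_site$end, integer(1))
  anchor_end <- max(ends)
  dist_anchor <- anchor_end - ends
  retained <- n_off == 0L
  fallback <- !any(retained)
  if (fallback) retained <- n_off == min(n_off)
  ord <- order(!retained, -tm, n_off, dist_anchor, starts)
  best <- ord[1L]
  mm_counts <- t(vapply(candidates, function(cand)
    count_offtargets_by_mm(cand$offtargets, max_mismatches),
    integer(max_mismatches + 1L)))
  colnames(mm_counts) <- sprintf("n_offtargets_mm%d", 0:max_mismatches)
  report <- data.frame(
    candidate_seq = vapply(candidates, `[[`, character(1), "seq"),
    target_transcript = vapply(candidates, function(cand)
      cand$target_site$transcript_id, character(1)),
    start = starts, end = ends,
    start_1based = starts + 1L, end_1based = ends,
    tm_c = round(tm, 2), mm_counts,
    n_offtargets = n_off,
    retained = retained,
    selected = seq_along(candidates) == best,
    stringsAsFactors = FALSE)
  sel <- candidates[[best]]
  sel$rank_metadata$fallback <- fallback
  list(selected = sel, report = report, fallback = fallback)
}

default_design_config <- function() {
  list(mode = "polya", k = 16L, max_mismatches = 3L, pattern = "full_lna",
       width = 50L, min_run = 8L, min_a_fraction = 0.8, tail_exclusion = 30L,
       target_id = NULL, conditions = thermo_conditions())
}

#' End-to-end blocking-oligo design
#'
#' Composition of the design steps. In `polya` mode, internal A-rich
#' priming sites of the target transcript are located, a design window is
#' derived 5' of each site, candidates are tiled, screened against the
#' whole transcriptome, Tm-scored and selected -- one blocker per site
#' (a transcript with two internal priming sites yields two oligos). In
#' `fragment` mode the supplied short fragment is the design window and
#' the 3' end is the anchor.
#'
#' @param target_spec in `polya` mode a transcript id present in the
#'   transcriptome; in `fragment` mode a raw fragment sequence or a
#'   transcript id (the whole transcript is then the fragment).
#' @param transcriptome `transcriptome` search space for off-targets.
#' @param config list overriding any of: mode ("polya"/"fragment"), k,
#'   max_mismatches, pattern, width, min_run, min_a_fraction,
#'   tail_exclusion, target_id (fragment provenance for self-exclusion),
#'   conditions.
#' @return object of class `design_report`: list with `mode`, `target`,
#'   `sites`, `selections` (list of per-site [select_oligo()] results),
#'   `candidates` (combined data.frame), `config`, `provenance`.
#' @export
design_pipeline <- function(target_spec, transcriptome, config = list()) {
  stopifnot(inherits(transcriptome, "transcriptome"))
  cfg <- utils::modifyList(default_design_config(), config)
  cfg$mode <- match.arg(cfg$mode, c("polya", "fragment"))
  windows <- list()
  sites <- list()
  target_label <- target_spec
  if (cfg$mode == "fragment") {
    if (target_spec %in% transcriptome$ids) {
      frag <- transcriptome$seqs[[target_spec]]
      if (is.null(cfg$target_id)) cfg$target_id <- target_spec
    } else {
      frag <- normalize_seq(target_spec, "fragment")
      target_label <- "fragment"
    }
    windows <- list(fragment_window(frag, k = cfg$k))
  } else {
    rec <- tx_get(transcriptome, target_spec)
    sites <- find_internal_polya(rec, min_run = cfg$min_run,
                                 min_a_fraction = cfg$min_a_fraction,
                                 tail_exclusion = cfg$tail_exclusion)
    if (!length(sites)) {
      warning(sprintf("no internal poly(A) site found in '%s'; empty report",
                      target_spec))
    }
    windows <- lapply(sites, design_window, transcript = rec,
                      width = cfg$width)
  }
  selections <- list()
  cand_rows <- list()
  for (w in seq_along(windows)) {
    cands <- tile_candidates(windows[[w]], k = cfg$k, pattern = cfg$pattern)
    cands <- lapply(cands, function(cand) {
      excl <- cand$target_site
      if (cfg$mode == "fragment") {
        # raw fragments live on a pseudo-transcript; exclude the exact
        # sense site on the provenance transcript when known
        excl <- NULL
        if (!is.null(cfg$target_id) && cfg$target_id %in% transcriptome$ids) {
          sense <- reverse_complement(cand$seq)
          pos <- tx_find_kmer(transcriptome, sense)
          pos <- pos[pos$transcript_id == cfg$target_id, , drop = FALSE]
          if (nrow(pos) == 1L)
            excl <- interval(cfg$target_id, pos$start[1L], pos$end[1L])
        }
      }
      cand$offtargets <- screen_offtargets(
        cand, transcriptome, max_mismatches = cfg$max_mismatches,
        exclude = excl)
      if (any(cand$pattern %in% c("OME", "MOE"))) {
        cand$tm_c <- as.numeric(tm_estimate(cand, cfg$conditions))
        cand$rank_metadata$tm_is_estimate <- TRUE
      } else {
        cand$tm_c <- melting_temperature(cand, cfg$conditions)
      }
      cand
    })
    sel <- select_oligo(cands, max_mismatches = cfg$max_mismatches)
    sel$report$site_index <- w
    selections[[w]] <- sel
    cand_rows[[w]] <- sel$report
  }
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame()
  structure(list(mode = cfg$mode, target = target_label, sites = sites,
                 selections = selections, candidates = candidates,
                 config = cfg,
                 provenance = list(
                   package = "oligoblock",
                   version = as.character(utils::packageVersion("oligoblock")),
                   parameter_tables = c("nn_dna_santalucia1998 v1.0",
                                        "nn_lna_increments_mctigue2004 v1.0"))),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("design_report (%s mode) for %s: %d site(s), %d candidate row(s)\n",
              x$mode, x$target, length(x$selections),
              nrow(x$candidates)))
  for (i in seq_along(x$selections)) {
    sel <- x$selections[[i]]
    cat(sprintf("  site %d -> %s (Tm %.1f C, %d off-target(s)%s)\n", i,
                sel$selected$seq, sel$selected$tm_c,
                nrow(sel$selected$offtargets),
                if (sel$fallback) ", fallback retention" else ""))
  }
  invisible(x)
}

#' Write a design report as TSV plus a JSON twin
#'
#' The TSV holds the candidate table (one row per candidate, columns
#' candidate_seq, target_transcript, start, end, 1-based twins, tm_c,
#' n_offtargets_mm0..3, retained, selected, site_index). The JSON twin
#' carries full provenance: config, thermodynamic conditions and
#' parameter-table versions.
#'
#' @param report `design_report`.
#' @param tsv_path output TSV path.
#' @param json_path output JSON path (default: TSV path with .json).
#' @export
write_design_report <- function(report, tsv_path,
                                json_path = sub("\\.tsv$", ".json", tsv_path)) {
  stopifnot(inherits(report, "design_report"))
  utils::write.table(report$candidates, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- report$config
  cfg$conditions <- unclass(cfg$conditions)
  payload <- list(
    mode = report$mode, target = report$target,
    selected = lapply(report$selections, function(sel) list(
      seq = sel$selected$seq,
      transcript = sel$selected$target_site$transcript_id,
      start = sel$selected$target_site$start,
      end = sel$selected$target_site$end,
      tm_c = sel$selected$tm_c,
      n_offtargets = nrow(sel$selected$offtargets),
      fallback = sel$fallback)),
    config = cfg, provenance = report$provenance)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(tsv_path, json_path))
}
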