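# Seeded synthetic-data generators with ground-truth manifests. Every
# generator is a pure function of (parameters, seed); each returns the
# data plus a manifest that fully determines regeneration and records
# the planted structure for round-trip tests.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Remove spontaneous adenosine-rich windows from a background sequence so
# planted sites are the only ones a finder can report. Uses the same
# formal window definition as find_internal_polya (min_run 8, A-fraction
# 0.8, no tail exclusion so transcript ends are clean too); the middle of
# each offending stretch is mutated to C until none remains.
scrub_polya <- function(seq, min_run = 8L, min_a_fraction = 0.8) {
  repeat {
    rec <- transcript_record("tmp", seq)
    sites <- find_internal_polya(rec, min_run = min_run,
                                 min_a_fraction = min_a_fraction,
                                 tail_exclusion = 0L)
    if (!length(sites)) return(seq)
    iv <- sites[[1L]]$interval
    span <- (iv$start + 1L):iv$end                      # 1-based positions
    a_pos <- span[substring(seq, span, span) == "A"]    # mutate the middle A:
    mid <- a_pos[(length(a_pos) + 1L) %/% 2L]           # degenerate runs keep
    substr(seq, mid, mid) <- "C"                        # their non-A bases
  }
}

mutate_kmer <- function(kmer, n_mismatches) {
  if (n_mismatches == 0L) return(kmer)
  chars <- strsplit(kmer, "", fixed = TRUE)[[1L]]
  pos <- sample(seq_along(chars), n_mismatches)
  for (p in pos)
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Synthetic transcriptome with planted priming sites and decoys
#'
#' Generates uniform-random background transcripts (scrubbed of
#' spontaneous A-rich windows so the planted truth is unambiguous),
#' plants `n_polya_sites` pure-A runs into the first transcript (each
#' isolated by a 5-nt C spacer and leaving `window_width` nt of design
#' space 5' of it), and plants decoy near-matches of the design-window
#' k-mer directly 5' of site 1 into subsequent transcripts with exactly
#' the requested number of substitutions.
#'
#' @param n_transcripts number of transcripts (>= 1 + number of decoys).
#' @param length_range integer range of transcript lengths.
#' @param n_polya_sites A-runs planted into transcript 1.
#' @param polya_run_length length of each planted A-run (nt).
#' @param n_decoys number of decoy transcripts carrying near-matches.
#' @param decoy_mismatches integer vector (recycled over decoys) of
#'   substitution counts, >= 0.
#' @param seed integer seed.
#' @param k length of the decoy source k-mer (default 16).
#' @param window_width design-window width the geometry must allow.
#' @param tail_exclusion terminal zone kept free of planted sites.
#' @return list(transcriptome, manifest); the manifest records planted
#'   sites, decoys, the decoy source k-mer, seed and parameters.
#' @export
synth_transcriptome <- function(n_transcripts = 20L,
                                length_range = c(500L, 2000L),
                                n_polya_sites = 2L,
                                polya_run_length = 12L,
                                n_decoys = 0L,
                                decoy_mismatches = integer(0),
                                seed = 1L,
                                k = 16L,
                                window_width = 50L,
                                tail_exclusion = 30L) {
  if (n_decoys > 0L && !length(decoy_mismatches))
    ob_stop("decoy_mismatches required when n_decoys > 0")
  if (length(decoy_mismatches) && any(decoy_mismatches < 0L))
    ob_stop("decoy_mismatches must be >= 0")
  if (n_transcripts < 1L + n_decoys)
    ob_stop("need at least 1 + n_decoys transcripts")
  n_transcripts <- as.integer(n_transcripts)
  length_range <- as.integer(length_range)
  n_polya_sites <- as.integer(n_polya_sites)
  polya_run_length <- as.integer(polya_run_length)
  n_decoys <- as.integer(n_decoys)
  k <- as.integer(k)
  window_width <- as.integer(window_width)
  tail_exclusion <- as.integer(tail_exclusion)
  spacer <- 5L
  slot <- polya_run_length + window_width + 2L * spacer
  need <- tail_exclusion + n_polya_sites * slot + 10L
  if (length_range[1L] < need)
    ob_stop(sprintf(
      "infeasible geometry: transcripts of >= %d nt cannot hold %d site(s) + windows (need >= %d nt)",
      length_range[1L], n_polya_sites, need))
  set.seed(as.integer(seed))
  lens <- sample(length_range[1L]:length_range[2L], n_transcripts,
                 replace = TRUE)
  ids <- sprintf("tx_%03d", seq_len(n_transcripts))
  seqs <- vapply(lens, function(L) scrub_polya(random_dna(L)), character(1))
  names(seqs) <- ids

  # plant A-runs into transcript 1, evenly spaced with seeded jitter
  L1 <- lens[1L]
  sites <- list()
  if (n_polya_sites > 0L) {
    usable <- L1 - tail_exclusion - need + tail_exclusion # leftover slack
    for (i in seq_len(n_polya_sites)) {
      base0 <- window_width + spacer + (i - 1L) * slot      # 0-based start
      jitter <- if (i == n_polya_sites) 0L else sample(0:5, 1L)
      s0 <- base0 + jitter
      e0 <- s0 + polya_run_length
      seq1 <- seqs[[1L]]
      substr(seq1, s0 - spacer + 1L, s0) <- strrep("C", spacer)
      substr(seq1, s0 + 1L, e0) <- strrep("A", polya_run_length)
      substr(seq1, e0 + 1L, e0 + spacer) <- strrep("C", spacer)
      seqs[[1L]] <- seq1
      sites[[i]] <- list(transcript_id = ids[1L], start = s0, end = e0)
    }
  }

  # decoy source: the k-mer immediately 5' of planted site 1
  decoy_kmer <- NULL
  decoys <- list()
  if (n_decoys > 0L) {
    if (!length(sites))
      ob_stop("decoys require at least one planted poly(A) site")
    s0 <- sites[[1L]]$start
    decoy_kmer <- substr(seqs[[1L]], s0 - k + 1L, s0)
    mms <- rep_len(as.integer(decoy_mismatches), n_decoys)
    for (j in seq_len(n_decoys)) {
      tx_i <- 1L + j
      variant <- mutate_kmer(decoy_kmer, mms[j])
      Lj <- lens[tx_i]
      pos0 <- (Lj - k) %/% 2L                       # 0-based plant position
      sj <- seqs[[tx_i]]
      substr(sj, pos0 + 1L, pos0 + k) <- variant
      seqs[[tx_i]] <- sj
      decoys[[j]] <- list(transcript_id = ids[tx_i], start = pos0,
                          end = pos0 + k, mismatches = mms[j],
                          seq = variant)
    }
  }

  manifest <- list(
    generator = "synth_transcriptome",
    seed = as.integer(seed),
    params = list(n_transcripts = n_transcripts, length_range = length_range,
                  n_polya_sites = n_polya_sites,
                  polya_run_length = polya_run_length, n_decoys = n_decoys,
                  decoy_mismatches = as.integer(decoy_mismatches), k = k,
                  window_width = window_width,
                  tail_exclusion = tail_exclusion),
    target_transcript = ids[1L],
    polya_sites = sites,
    decoy_source_kmer = decoy_kmer,
    decoys = decoys)
  list(transcriptome = transcriptome(seqs), manifest = manifest)
}

lognormal_fractions <- function(n, sigma) {
  a <- stats::rlnorm(n, meanlog = 0, sdlog = sigma)
  a / sum(a)
}

#' Synthetic gene x sample count table with a dominant gene
#'
#' Long-tailed (log-normal) background abundances with one designated
#' gene consuming a fixed fraction of all reads (a single abundant
#' unwanted transcript over a long-tailed background); counts drawn
#' multinomially at `depth` per sample.
#'
#' @param n_genes number of genes.
#' @param depth reads per sample.
#' @param dominant_gene_fraction share of reads for the dominant gene,
#'   `0 <= f < 1`; at 0 the gene is drawn from the background like any
#'   other.
#' @param lognormal_sigma sd of the log-normal background (default 1.5).
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @return list(table = `count_table`, manifest).
#' @export
synth_count_table <- function(n_genes = 1000L, depth = 2e6,
                              dominant_gene_fraction = 0.2,
                              lognormal_sigma = 1.5, n_samples = 1L,
                              seed = 1L) {
  if (dominant_gene_fraction < 0 || dominant_gene_fraction >= 1)
    ob_stop("dominant_gene_fraction must satisfy 0 <= f < 1")
  set.seed(as.integer(seed))
  ids <- sprintf("gene_%04d", seq_len(n_genes))
  dominant <- ids[1L]
  if (dominant_gene_fraction > 0) {
    bg <- lognormal_fractions(n_genes - 1L, lognormal_sigma)
    p <- c(dominant_gene_fraction, (1 - dominant_gene_fraction) * bg)
  } else {
    p <- lognormal_fractions(n_genes, lognormal_sigma)
  }
  counts <- stats::rmultinom(n_samples, size = depth, prob = p)
  tab <- count_table(counts, gene_ids = ids,
                     sample_ids = sprintf("S%d", seq_len(n_samples)))
  manifest <- list(generator = "synth_count_table", seed = as.integer(seed),
                   params = list(n_genes = n_genes, depth = depth,
                                 dominant_gene_fraction = dominant_gene_fraction,
                                 lognormal_sigma = lognormal_sigma,
                                 n_samples = n_samples),
                   dominant_gene = dominant, fractions = stats::setNames(p, ids))
  list(table = tab, manifest = manifest)
}

#' Synthetic control/treated library pair under partial depletion
#'
#' Emulates matched standard vs blocking library preparations: control
#' replicates are drawn with the target at fraction `f0`; treated
#' replicates with the target at [effective_target_fraction()]`(f0,
#' efficiency)` and the freed depth reallocated to the background. An
#' optional planted off-target gene is additionally suppressed by a
#' stated factor in the treated libraries.
#'
#' Defaults emulate a plasma small-RNA experiment: libraries downsampled
#' to 13 million reads, ~600 detected miRNA-scale features, the blocked
#' fragment at 29.74% of reads (platelet-free plasma before blocking),
#' and 4 matched replicate pairs (2 samples x 2 technical replicates).
#'
#' @param base_config list overriding n_genes, depth, f0,
#'   lognormal_sigma.
#' @param efficiency depletion efficiency d in `[0, 1]`.
#' @param n_replicates matched replicate pairs (default 4).
#' @param seed integer seed.
#' @param offtarget_gene optional gene id (e.g. `"gene_0042"`) to
#'   suppress in treated libraries.
#' @param offtarget_suppression suppression factor (>= 1) for the
#'   planted off-target.
#' @return list(control, treated, manifest); `manifest$implied_fold` is
#'   the expected CPM fold reduction `(1 - f0 d) / (1 - d)`.
#' @export
synth_depletion_pair <- function(base_config = list(), efficiency,
                                 n_replicates = 4L, seed = 1L,
                                 offtarget_gene = NULL,
                                 offtarget_suppression = 1) {
  cfg <- utils::modifyList(list(n_genes = 600L, depth = 13e6, f0 = 0.2974,
                                lognormal_sigma = 1.5), base_config)
  if (efficiency < 0 || efficiency > 1)
    ob_stop("efficiency must be in [0, 1]")
  if (offtarget_suppression < 1)
    ob_stop("offtarget_suppression must be >= 1")
  set.seed(as.integer(seed))
  ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  target <- ids[1L]
  bg <- lognormal_fractions(cfg$n_genes - 1L, cfg$lognormal_sigma)
  p_control <- c(cfg$f0, (1 - cfg$f0) * bg)
  eff <- effective_target_fraction(cfg$f0, efficiency)
  p_treated <- c(eff, (1 - eff) * bg)
  if (!is.null(offtarget_gene)) {
    io <- match(offtarget_gene, ids)
    if (is.na(io) || io == 1L)
      ob_stop("offtarget_gene must name a background gene")
    p_treated[io] <- p_treated[io] / offtarget_suppression
    p_treated <- p_treated / sum(p_treated)
  }
  control <- stats::rmultinom(n_replicates, size = cfg$depth, prob = p_control)
  treated <- stats::rmultinom(n_replicates, size = cfg$depth, prob = p_treated)
  reps <- sprintf("R%d", seq_len(n_replicates))
  manifest <- list(generator = "synth_depletion_pair", seed = as.integer(seed),
                   params = c(cfg, list(efficiency = efficiency,
                                        n_replicates = n_replicates,
                                        offtarget_gene = offtarget_gene,
                                        offtarget_suppression = offtarget_suppression)),
                   target_gene = target,
                   implied_fold = if (efficiency < 1)
                     (1 - cfg$f0 * efficiency) / (1 - efficiency) else Inf)
  list(control = count_table(control, ids, paste0("ctrl_", reps)),
       treated = count_table(treated, ids, paste0("lna_", reps)),
       manifest = manifest)
}

#' Synthetic two-group count data with planted fold changes
#'
#' Log-normal baseline abundances; a fraction of genes carries a planted
#' symmetric log2 fold change (up or down in group B). Directions are
#' assigned by a greedy mass-balancing partition so that the total
#' probability mass is (nearly) conserved: without balancing, the
#' renormalization of group B shifts every non-differential gene by a
#' common compositional factor, turning exact nulls into true (if small)
#' differences. The residual imbalance after greedy assignment is
#' negligible (|log2 shift| well below counting noise).
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group.
#' @param frac_de fraction of genes with a planted effect.
#' @param log2fc planted absolute log2 fold change.
#' @param depth reads per sample.
#' @param seed integer seed.
#' @return list(groupA, groupB, manifest); `manifest$de_genes` is a
#'   data.frame(gene, direction, log2fc).
#' @export
synth_two_group_counts <- function(n_genes = 800L, n_per_group = 4L,
                                   frac_de = 0.1, log2fc = 2, depth = 2e6,
                                   seed = 1L) {
  if (frac_de < 0 || frac_de > 1) ob_stop("frac_de must be in [0, 1]")
  set.seed(as.integer(seed))
  ids <- sprintf("gene_%04d", seq_len(n_genes))
  base <- lognormal_fractions(n_genes, 1.5)
  n_de <- round(frac_de * n_genes)
  de_idx <- if (n_de > 0L) sample(n_genes, n_de) else integer(0)
  # greedy mass-balancing: assigning gene g "up" adds base_g (2^fc - 1)
  # mass, "down" removes base_g (1 - 2^-fc); walk genes by decreasing
  # mass, always moving the running imbalance toward zero
  up <- integer(0); down <- integer(0)
  delta <- 0
  for (g in de_idx[order(base[de_idx], decreasing = TRUE)]) {
    d_up <- base[g] * (2^log2fc - 1)
    d_down <- base[g] * (1 - 2^-log2fc)
    if (abs(delta + d_up) < abs(delta - d_down)) {
      up <- c(up, g); delta <- delta + d_up
    } else {
      down <- c(down, g); delta <- delta - d_down
    }
  }
  pB <- base
  pB[up] <- pB[up] * 2^log2fc
  pB[down] <- pB[down] / 2^log2fc
  pB <- pB / sum(pB)
  A <- stats::rmultinom(n_per_group, size = depth, prob = base)
  B <- stats::rmultinom(n_per_group, size = depth, prob = pB)
  manifest <- list(generator = "synth_two_group_counts",
                   seed = as.integer(seed),
                   params = list(n_genes = n_genes, n_per_group = n_per_group,
                                 frac_de = frac_de, log2fc = log2fc,
                                 depth = depth),
                   de_genes = data.frame(
                     gene = ids[c(up, down)],
                     direction = rep(c("up", "down"), c(length(up), length(down))),
                     log2fc = rep(c(log2fc, -log2fc), c(length(up), length(down))),
                     stringsAsFactors = FALSE))
  list(groupA = count_table(A, ids, sprintf("A%d", seq_len(n_per_group))),
       groupB = count_table(B, ids, sprintf("B%d", seq_len(n_per_group))),
       manifest = manifest)
}

#' Write a truth manifest as JSON
#'
#' @param manifest manifest list from any generator.
#' @param path output JSON path.
#' @export
write_truth_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}
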