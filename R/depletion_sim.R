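# Depletion-benefit simulator: detected genes as a function of
# sequencing depth, initial unwanted-transcript fraction and depletion
# efficiency.
#
# Reallocation convention: depleted target reads are replaced by
# background reads at fixed total depth (re-normalized categorical
# distribution). The gain in detected genes with efficiency is only
# possible because freed depth flows to the background. Sampling is
# multinomial from the fraction vector; a hypergeometric variant from a
# finite table is exposed in the metrics module as subsample_counts().

#' Count table (genes x samples)
#'
#' Validated non-negative integer matrix with unique gene ids as row
#' names and sample ids as column names.
#'
#' @param counts numeric matrix (coerced to integer).
#' @param gene_ids,sample_ids optional dimension names (default: taken
#'   from `counts` dimnames).
#' @return integer matrix of class `count_table`.
#' @export
count_table <- function(counts, gene_ids = rownames(counts),
                        sample_ids = colnames(counts)) {
  m <- as.matrix(counts)
  if (is.null(gene_ids)) ob_stop("count table needs gene ids (row names)")
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%d", seq_len(ncol(m)))
  if (anyDuplicated(gene_ids))
    ob_stop("gene ids must be unique")
  if (any(is.na(m)) || any(m < 0))
    ob_stop("counts must be non-negative and complete")
  if (any(abs(m - round(m)) > 1e-8))
    ob_stop("counts must be integers")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(gene_ids, sample_ids)
  class(m) <- c("count_table", class(m))
  m
}

#' Read a gene x sample count table from TSV
#'
#' First column gene id, remaining columns integer counts per sample;
#' header row required.
#'
#' @param path TSV file.
#' @return `count_table`.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) ob_stop(sprintf("count TSV not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) ob_stop("count TSV needs a gene-id column plus counts")
  m <- as.matrix(df[, -1L, drop = FALSE])
  count_table(m, gene_ids = as.character(df[[1L]]), sample_ids = colnames(df)[-1L])
}

#' Write a count table to TSV
#' @param table `count_table`.
#' @param path output path.
#' @param id_col name of the gene-id column (default "gene_id").
#' @export
write_counts <- function(table, path, id_col = "gene_id") {
  df <- data.frame(rownames(table), unclass(table), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Background sampling distribution with the target removed
#'
#' Removes the unwanted gene from one sample's counts and renormalizes
#' the remaining genes to fractions summing to one. This distribution
#' guides the depletion simulation.
#'
#' @param table `count_table`.
#' @param sample sample id or column index.
#' @param target_gene gene id to remove.
#' @return object of class `background_distribution` with `gene_ids`,
#'   `fractions` (named, sums to 1), `target_gene`, `source_sample`.
#' @export
background_distribution <- function(table, sample, target_gene) {
  stopifnot(inherits(table, "count_table"))
  if (is.character(sample) && !sample %in% colnames(table))
    ob_stop(sprintf("sample '%s' not found", sample))
  col <- unclass(table)[, sample]
  if (!target_gene %in% rownames(table))
    ob_stop(sprintf("target gene '%s' not found", target_gene))
  bg <- col[setdiff(rownames(table), target_gene)]
  tot <- sum(as.numeric(bg))
  if (tot <= 0) ob_stop("background (non-target) counts are all zero")
  structure(list(gene_ids = names(bg),
                 fractions = bg / tot,
                 target_gene = target_gene,
                 source_sample = if (is.character(sample)) sample else
                   colnames(table)[sample]),
            class = "background_distribution")
}

#' Target fraction after partial depletion
#'
#' Removing a fraction `d` of the target's molecules and re-normalizing
#' at fixed total depth leaves the target with share
#' `f0 (1 - d) / (f0 (1 - d) + (1 - f0)) = f0 (1 - d) / (1 - f0 d)`.
#'
#' @param f0 initial target fraction(s), `0 <= f0 < 1`.
#' @param d depletion efficiency(ies), `0 <= d <= 1`.
#' @return effective target fraction (vectorized).
#' @export
effective_target_fraction <- function(f0, d) {
  if (any(f0 < 0 | f0 >= 1)) ob_stop("f0 must satisfy 0 <= f0 < 1")
  if (any(d < 0 | d > 1)) ob_stop("d must satisfy 0 <= d <= 1")
  f0 * (1 - d) / (f0 * (1 - d) + (1 - f0))
}

#' Configuration for the depletion simulation grid
#'
#' Defaults mirror the published simulation design: depths 0.5, 1, 2, 4
#' and 8 million counts; initial target fraction 0 to 0.9 by 0.1;
#' depletion efficiency 0 to 1 by 0.02; a gene is detected at >= 10
#' counts.
#'
#' @param depths total counts per simulated library.
#' @param initial_fractions initial target fractions f0.
#' @param efficiencies depletion efficiencies d.
#' @param detection_threshold detected-gene count threshold (>= 1).
#' @param n_reps replicates per grid cell (default 10; the Monte-Carlo
#'   error is reported as a per-cell sd).
#' @param seed integer seed; the full grid is reproducible from it.
#' @return object of class `depletion_sim_config`.
#' @export
depletion_sim_config <- function(depths = c(0.5e6, 1e6, 2e6, 4e6, 8e6),
                                 initial_fractions = seq(0, 0.9, by = 0.1),
                                 efficiencies = seq(0, 1, by = 0.02),
                                 detection_threshold = 10L,
                                 n_reps = 10L, seed = 1L) {
  if (any(depths <= 0)) ob_stop("depths must be positive")
  if (any(initial_fractions < 0 | initial_fractions >= 1))
    ob_stop("initial fractions must satisfy 0 <= f0 < 1")
  if (any(efficiencies < 0 | efficiencies > 1))
    ob_stop("efficiencies must satisfy 0 <= d <= 1")
  detection_threshold <- as.integer(detection_threshold)
  if (detection_threshold < 1L) ob_stop("detection_threshold must be >= 1")
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) ob_stop("n_reps must be >= 1")
  structure(list(depths = as.numeric(depths),
                 initial_fractions = as.numeric(initial_fractions),
                 efficiencies = as.numeric(efficiencies),
                 detection_threshold = detection_threshold,
                 n_reps = n_reps, seed = as.integer(seed)),
            class = "depletion_sim_config")
}

# Deterministic 31-bit sub-seed per (depth, f0, rep) cell. Efficiency is
# deliberately excluded so draws along the efficiency axis share random
# numbers: at f0 = 0 all efficiencies give bit-identical libraries, and
# efficiency curves are smoothed by common random numbers.
cell_seed <- function(seed, i_depth, i_f0, rep) {
  as.integer((as.double(seed) * 48271 + i_depth * 1000003 +
                i_f0 * 10007 + rep * 389) %% 2147483647)
}

#' Simulate depletion over a (depth x f0 x efficiency) grid
#'
#' For each grid cell, `depth` reads are drawn from the categorical
#' distribution that gives the target `effective_target_fraction(f0, d)`
#' and each background gene `(1 - eff) * fraction`. The number of genes
#' (target included) at or above the detection threshold is recorded per
#' replicate.
#'
#' @param bg `background_distribution`.
#' @param config `depletion_sim_config`.
#' @return object of class `depletion_sim_result`: data.frame with
#'   columns depth, f0, d, rep, detected_genes, target_counts; the
#'   config is attached as attribute `config`.
#' @export
simulate_depletion <- function(bg, config = depletion_sim_config()) {
  stopifnot(inherits(bg, "background_distribution"),
            inherits(config, "depletion_sim_config"))
  p_bg <- as.numeric(bg$fractions)
  thr <- config$detection_threshold
  n_cells <- length(config$depths) * length(config$initial_fractions) *
    config$n_reps * length(config$efficiencies)
  depth_v <- f0_v <- d_v <- rep_v <- det_v <- tgt_v <- vector("numeric", n_cells)
  row <- 0L
  for (i in seq_along(config$depths)) {
    N <- config$depths[i]
    for (j in seq_along(config$initial_fractions)) {
      f0 <- config$initial_fractions[j]
      for (r in seq_len(config$n_reps)) {
        cs <- cell_seed(config$seed, i, j, r)
        for (d in config$efficiencies) {
          eff <- effective_target_fraction(f0, d)
          set.seed(cs)
          draw <- stats::rmultinom(1L, size = N, prob = c(eff, (1 - eff) * p_bg))
          row <- row + 1L
          depth_v[row] <- N; f0_v[row] <- f0; d_v[row] <- d; rep_v[row] <- r
          det_v[row] <- sum(draw >= thr)
          tgt_v[row] <- draw[1L]
        }
      }
    }
  }
  res <- data.frame(depth = depth_v, f0 = f0_v, d = d_v, rep = rep_v,
                    detected_genes = as.integer(det_v),
                    target_counts = as.integer(tgt_v))
  attr(res, "config") <- config
  attr(res, "target_gene") <- bg$target_gene
  class(res) <- c("depletion_sim_result", class(res))
  res
}

#' Summarize the detected-gene surface
#'
#' Mean and sd of detected genes per (depth, f0) as a function of the
#' depletion efficiency.
#'
#' @param result `depletion_sim_result`.
#' @param path optional TSV output path.
#' @return data.frame(depth, f0, d, mean_detected, sd_detected,
#'   mean_target_counts, n_reps) of class `detected_gene_surface`.
#' @export
detected_gene_surface <- function(result, path = NULL) {
  stopifnot(inherits(result, "depletion_sim_result"))
  if (!nrow(result)) ob_stop("empty simulation result")
  key <- interaction(result$depth, result$f0, result$d, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(result)), key), function(idx) {
    data.frame(depth = result$depth[idx[1L]], f0 = result$f0[idx[1L]],
               d = result$d[idx[1L]],
               mean_detected = mean(result$detected_genes[idx]),
               sd_detected = stats::sd(result$detected_genes[idx]),
               mean_target_counts = mean(result$target_counts[idx]),
               n_reps = length(idx))
  }))
  agg <- agg[order(agg$depth, agg$f0, agg$d), , drop = FALSE]
  rownames(agg) <- NULL
  if (!is.null(path))
    utils::write.table(agg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  class(agg) <- c("detected_gene_surface", class(agg))
  agg
}

#' Plot a detected-gene surface
#'
#' One line per initial fraction f0, detected genes against depletion
#' efficiency, faceted by sequencing depth in a base-graphics panel grid.
#'
#' @param x `detected_gene_surface`.
#' @param ... passed to matplot.
#' @importFrom graphics matplot legend par
#' @export
plot.detected_gene_surface <- function(x, ...) {
  depths <- unique(x$depth)
  old <- graphics::par(mfrow = c(1, length(depths)))
  on.exit(graphics::par(old))
  for (N in depths) {
    sub <- x[x$depth == N, ]
    wide <- tapply(sub$mean_detected, list(sub$d, sub$f0), mean)
    graphics::matplot(as.numeric(rownames(wide)), wide, type = "l", lty = 1,
                      xlab = "depletion efficiency d",
                      ylab = "mean detected genes",
                      main = sprintf("depth %g", N), ...)
  }
  invisible(x)
}
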