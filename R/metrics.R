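# Depletion-efficiency and library-complexity metrics: CPM, exact
# hypergeometric subsampling, fold reduction, biotype fractions,
# detection counts, differential expression, concordance between
# subsamples and standardized-residual off-target flagging.

#' Counts per million
#'
#' `counts * 1e6 / column sum`; every column of the result sums to 1e6.
#'
#' @param table `count_table` (or plain counts matrix).
#' @return numeric matrix of CPM values.
#' @export
cpm <- function(table) {
  m <- unclass(as.matrix(table))
  storage.mode(m) <- "double"
  cs <- colSums(m)
  if (any(cs == 0)) {
    bad <- colnames(m)[cs == 0]
    if (is.null(bad)) bad <- which(cs == 0)
    ob_stop(sprintf("zero-sum column(s): %s", paste(bad, collapse = ", ")))
  }
  sweep(m, 2L, cs, "/") * 1e6
}

# log2 CPM with a 0.5-count offset (sparse plasma tables contain zeros);
# the +1 on the library size keeps fractions below 1.
log2_cpm <- function(table) {
  m <- unclass(as.matrix(table))
  storage.mode(m) <- "double"
  cs <- colSums(m)
  if (any(cs == 0)) ob_stop("zero-sum column in log2_cpm input")
  log2(sweep(m + 0.5, 2L, cs + 1, "/") * 1e6)
}

# exact multivariate hypergeometric draw via sequential conditionals
rmvhyper_seq <- function(x, depth) {
  out <- integer(length(x))
  rem_k <- depth
  rem_n <- sum(as.numeric(x))
  for (i in seq_along(x)) {
    if (rem_k == 0L) break
    xi <- x[i]
    draw <- stats::rhyper(1L, xi, rem_n - xi, rem_k)
    out[i] <- draw
    rem_k <- rem_k - draw
    rem_n <- rem_n - xi
  }
  out
}

#' Subsample a count table without replacement
#'
#' Per column, draws exactly `depth` reads without replacement from that
#' column's reads (multivariate hypergeometric, computed by exact
#' sequential conditional sampling). Subsampling at full depth is the
#' identity; depth 0 gives an all-zero column.
#'
#' @param table `count_table`.
#' @param depth target depth, `0 <= depth <=` every column total.
#' @param seed optional integer seed.
#' @return `count_table` with identical dimensions.
#' @export
subsample_counts <- function(table, depth, seed = NULL) {
  stopifnot(inherits(table, "count_table"))
  depth <- round(as.numeric(depth))
  if (depth < 0) ob_stop("depth must be >= 0")
  m <- unclass(table)
  tot <- colSums(m)
  if (any(tot < depth)) {
    bad <- colnames(m)[tot < depth]
    ob_stop(sprintf("depth %g exceeds the total of sample(s): %s", depth,
                    paste(bad, collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- vapply(seq_len(ncol(m)), function(j) rmvhyper_seq(m[, j], depth),
                integer(nrow(m)))
  count_table(out, gene_ids = rownames(m), sample_ids = colnames(m))
}

#' Fold reduction of a blocked target
#'
#' Mean control CPM over replicates divided by mean treated CPM; the
#' headline depletion-efficiency metric. When either side is zero, CPM
#' is recomputed with a +0.5-count continuity correction on both sides
#' and the result carries `attr(, "corrected") == TRUE`.
#'
#' @param control,treated `count_table`s containing `gene`.
#' @param gene target gene id.
#' @return positive scalar (possibly with attribute `corrected`).
#' @export
fold_reduction <- function(control, treated, gene) {
  for (tb in list(control, treated))
    if (!gene %in% rownames(tb))
      ob_stop(sprintf("gene '%s' absent from a count table", gene))
  mc <- mean(cpm(control)[gene, ])
  mt <- mean(cpm(treated)[gene, ])
  corrected <- FALSE
  if (mc == 0 || mt == 0) {
    corrected <- TRUE
    cc <- function(tb) {
      m <- unclass(as.matrix(tb)) + 0.5
      sweep(m, 2L, colSums(m), "/") * 1e6
    }
    mc <- mean(cc(control)[gene, ])
    mt <- mean(cc(treated)[gene, ])
  }
  structure(mc / mt, corrected = corrected)
}

#' Per-biotype read fractions
#'
#' Fraction of each column's reads per biotype; genes without a biotype
#' annotation are pooled as `"other"`.
#'
#' @param table `count_table`.
#' @param biotype_map named character vector gene id -> biotype (or path
#'   to the 2-column TSV accepted by [read_biotypes()]).
#' @return matrix biotypes x samples of fractions in `[0, 1]`, columns
#'   summing to 1.
#' @export
biotype_fractions <- function(table, biotype_map) {
  stopifnot(inherits(table, "count_table"))
  if (is.character(biotype_map) && length(biotype_map) == 1L &&
      file.exists(biotype_map))
    biotype_map <- read_biotypes(biotype_map)
  if (!length(intersect(names(biotype_map), rownames(table))))
    ob_stop("biotype map covers no gene of the table")
  m <- unclass(table)
  cs <- colSums(m)
  if (any(cs == 0))
    ob_stop(sprintf("zero-sum column(s): %s",
                    paste(colnames(m)[cs == 0], collapse = ", ")))
  bt <- biotype_map[rownames(m)]
  bt[is.na(bt)] <- "other"
  agg <- rowsum(m, group = bt)
  sweep(agg, 2L, cs, "/")
}

#' Detected genes per sample
#'
#' A gene is detected in a sample if it has at least `min_count` counts.
#'
#' @param table `count_table`.
#' @param min_count detection threshold (default 10).
#' @return named integer vector, one entry per sample.
#' @export
detected_genes <- function(table, min_count = 10L) {
  stopifnot(inherits(table, "count_table"))
  out <- colSums(unclass(table) >= min_count)
  stats::setNames(as.integer(out), names(out))
}

#' Detected feature sets per sample (CPM threshold)
#'
#' A feature is detected in a sample when its CPM is strictly greater
#' than `min_cpm` (default 0.5, the usual miRNA detection rule).
#'
#' @param table `count_table`.
#' @param min_cpm strict CPM threshold.
#' @return named list of character vectors of detected gene ids.
#' @export
detect_features <- function(table, min_cpm = 0.5) {
  stopifnot(inherits(table, "count_table"))
  x <- cpm(table)
  stats::setNames(lapply(seq_len(ncol(x)), function(j)
    rownames(x)[x[, j] > min_cpm]), colnames(x))
}

# default pluggable DE engine: row-wise Welch t-test on log2 CPM
de_engine_ttest <- function(logA, logB) {
  nA <- ncol(logA); nB <- ncol(logB)
  mA <- rowMeans(logA); mB <- rowMeans(logB)
  vA <- rowSums((logA - mA)^2) / (nA - 1L)
  vB <- rowSums((logB - mB)^2) / (nB - 1L)
  se2 <- vA / nA + vB / nB
  tstat <- (mB - mA) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1L) + (vB / nB)^2 / (nB - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  p[zero & mA == mB] <- 1
  p[zero & mA != mB] <- 0
  list(effect = mB - mA, p = p)
}

#' Two-group differential expression test
#'
#' Genes below `min_rpm` summed reads-per-million over all samples are
#' filtered out (they carry no p-value). The default engine is a
#' two-sample unequal-variance t-test on log2 CPM (+0.5-count offset)
#' with Benjamini-Hochberg adjustment; a voom-style fit can be plugged
#' in via `engine` (a function of the two log-CPM matrices returning
#' `list(effect, p)`).
#'
#' @param groupA,groupB `count_table`s with identical genes, >= 2
#'   samples each.
#' @param min_rpm RPM filter threshold (default 10).
#' @param alpha significance level for the `significant` flag
#'   (default 0.05, on BH-adjusted p).
#' @param engine pluggable test engine.
#' @return data.frame of class `de_result` with columns gene, log2fc,
#'   p, padj, filtered, significant.
#' @export
de_test <- function(groupA, groupB, min_rpm = 10, alpha = 0.05,
                    engine = de_engine_ttest) {
  stopifnot(inherits(groupA, "count_table"), inherits(groupB, "count_table"))
  if (ncol(groupA) < 2L || ncol(groupB) < 2L)
    ob_stop("each group needs at least 2 samples")
  if (!identical(rownames(groupA), rownames(groupB)))
    ob_stop("both groups must share the same genes in the same order")
  combined <- cbind(unclass(groupA), unclass(groupB))
  rpm_sum <- rowSums(cpm(count_table(combined, rownames(groupA))))
  filtered <- rpm_sum < min_rpm
  logA <- log2_cpm(groupA)
  logB <- log2_cpm(groupB)
  fit <- engine(logA[!filtered, , drop = FALSE],
                logB[!filtered, , drop = FALSE])
  p <- rep(NA_real_, nrow(groupA))
  eff <- rep(NA_real_, nrow(groupA))
  p[!filtered] <- fit$p
  eff[!filtered] <- fit$effect
  padj <- rep(NA_real_, nrow(groupA))
  padj[!filtered] <- stats::p.adjust(fit$p, method = "BH")
  res <- data.frame(gene = rownames(groupA), log2fc = eff, p = p,
                    padj = padj, filtered = filtered,
                    significant = !filtered & !is.na(padj) & padj < alpha,
                    stringsAsFactors = FALSE)
  attr(res, "alpha") <- alpha
  attr(res, "min_rpm") <- min_rpm
  class(res) <- c("de_result", class(res))
  res
}

#' Concordance of DE calls between repeated subsamples
#'
#' Draws `n_subsamples` independent seeded subsamples of every column at
#' `depth`, runs [de_test()] on each, and summarizes the overlap of the
#' significant sets over all subsample pairs as a Jaccard percentage
#' (100 * |A n B| / |A u B|; two identical sets -- including two empty
#' sets -- score 100). Raw per-pair overlap counts are returned so
#' alternative denominators can be computed.
#'
#' @param groupA,groupB `count_table`s as in [de_test()].
#' @param depth subsampling depth (must be feasible for every column).
#' @param n_subsamples number of independent subsamples (default 4).
#' @param alpha,min_rpm passed to [de_test()].
#' @param seed integer seed; subsample s uses a seed derived from it.
#' @param engine passed to [de_test()].
#' @return object of class `concordance_result`: list with `sets`
#'   (significant gene sets), `pairs` (data.frame i, j, overlap, union,
#'   jaccard) and `concordance` (mean Jaccard %).
#' @export
de_concordance <- function(groupA, groupB, depth, n_subsamples = 4L,
                           alpha = 0.05, min_rpm = 10, seed = 1L,
                           engine = de_engine_ttest) {
  n_subsamples <- as.integer(n_subsamples)
  ob_assert(n_subsamples >= 2L, "need at least 2 subsamples")
  sets <- vector("list", n_subsamples)
  for (s in seq_len(n_subsamples)) {
    sub_seed <- as.integer((as.double(seed) * 131 + s * 9973) %% 2147483647)
    subA <- subsample_counts(groupA, depth, seed = sub_seed)
    subB <- subsample_counts(groupB, depth, seed = sub_seed + 1L)
    de <- de_test(subA, subB, min_rpm = min_rpm, alpha = alpha,
                  engine = engine)
    sets[[s]] <- de$gene[de$significant]
  }
  idx <- utils::combn(n_subsamples, 2L)
  pairs <- data.frame(t(idx))
  colnames(pairs) <- c("i", "j")
  pairs$overlap <- pairs$union <- integer(nrow(pairs))
  pairs$jaccard <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- sets[[pairs$i[r]]]; b <- sets[[pairs$j[r]]]
    ov <- length(intersect(a, b)); un <- length(union(a, b))
    pairs$overlap[r] <- ov; pairs$union[r] <- un
    pairs$jaccard[r] <- if (un == 0L) 100 else 100 * ov / un
  }
  structure(list(sets = sets, pairs = pairs,
                 concordance = mean(pairs$jaccard), depth = depth),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance at depth %g over %d subsamples: %.1f%%\n",
              x$depth, length(x$sets), x$concordance))
  invisible(x)
}

#' Flag putative off-target genes by standardized residuals
#'
#' For each matched replicate pair (column j of `control` vs column j of
#' `treated`), fits a least-squares line of treated on control log2 CPM
#' over the detected features and standardizes residuals by their
#' standard deviation. Genes with `|standardized residual| >
#' threshold_sd` *in the same direction* in ALL replicate pairs are
#' flagged and annotated with that direction (consistently lower or
#' higher in treated).
#'
#' The fit is restricted to features with at least `min_count` counts in
#' every library of both tables: undetected features have counting noise
#' far above the global residual standard deviation, which would make a
#' global-SD rule meaningless (see the methods vignette).
#'
#' @param control,treated `count_table`s with identical genes and a
#'   matched column layout (>= 1 replicate pair).
#' @param threshold_sd flagging threshold (default 2).
#' @param min_count detection filter applied before the fit (default 10,
#'   the package-wide detected-gene rule).
#' @return data.frame(gene, direction, min_abs_residual) of flagged
#'   genes (possibly empty).
#' @export
flag_offtarget_outliers <- function(control, treated, threshold_sd = 2,
                                    min_count = 10L) {
  stopifnot(inherits(control, "count_table"), inherits(treated, "count_table"))
  if (!identical(rownames(control), rownames(treated)))
    ob_stop("control and treated must share the same genes")
  if (ncol(control) != ncol(treated) || ncol(control) < 1L)
    ob_stop("need >= 1 matched replicate pair with equal column counts")
  keep <- rowSums(cbind(unclass(control), unclass(treated)) >= min_count) ==
    ncol(control) + ncol(treated)
  if (sum(keep) < 3L)
    ob_stop("fewer than 3 detected features; cannot fit a residual line")
  lc <- log2_cpm(control)[keep, , drop = FALSE]
  lt <- log2_cpm(treated)[keep, , drop = FALSE]
  z <- matrix(NA_real_, nrow(lc), ncol(lc), dimnames = dimnames(lc))
  for (j in seq_len(ncol(lc))) {
    x <- lc[, j]; y <- lt[, j]
    b <- stats::cov(x, y) / stats::var(x)
    a <- mean(y) - b * mean(x)
    r <- y - (a + b * x)
    s <- stats::sd(r)
    z[, j] <- if (s == 0) 0 else r / s   # identical libraries: no outliers
  }
  hit <- rowSums(z > threshold_sd) == ncol(z) |
    rowSums(z < -threshold_sd) == ncol(z)
  if (!any(hit))
    return(data.frame(gene = character(0), direction = character(0),
                      min_abs_residual = numeric(0), stringsAsFactors = FALSE))
  zz <- z[hit, , drop = FALSE]
  data.frame(gene = rownames(zz),
             direction = ifelse(rowMeans(zz) < 0, "lower", "higher"),
             min_abs_residual = apply(abs(zz), 1L, min),
             stringsAsFactors = FALSE)
}
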