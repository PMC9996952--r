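# Independent brute-force oracles. These deliberately re-derive results
# by the most literal method available (explicit loops, full window
# enumeration, hand summation from the shipped parameter files) and are
# kept free of the package's own computational shortcuts.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- 0L
  for (i in seq_along(ca)) if (ca[i] != cb[i]) n <- n + 1L
  n
}

# every window of every transcript, explicit Hamming count
oracle_scan <- function(tx, sense_kmer, max_mm) {
  k <- nchar(sense_kmer)
  pc <- strsplit(sense_kmer, "")[[1]]
  out <- list()
  for (id in tx$ids) {
    s <- tx$seqs[[id]]
    L <- nchar(s)
    if (L < k) next
    sc <- strsplit(s, "")[[1]]
    for (i in 0:(L - k)) {
      mm <- sum(sc[(i + 1):(i + k)] != pc)
      if (mm <= max_mm)
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = id, start = i, end = i + k, mismatches = mm,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# enumerate every (start, len >= min_run) window ending before the tail
# zone, keep qualifying ones, take union coverage, split into components,
# trim non-A ends, drop components whose A-fraction falls below threshold
oracle_polya <- function(seq, min_run = 8L, min_a = 0.8,
                         tail_exclusion = 30L) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  limit <- L - tail_exclusion
  isA <- chars == "A"
  cover <- rep(FALSE, max(limit, 0L))
  if (limit >= min_run) {
    for (s in 1:(limit - min_run + 1L)) {
      for (len in min_run:(limit - s + 1L)) {
        w <- isA[s:(s + len - 1L)]
        if (sum(w) / len + 1e-9 >= min_a)
          cover[s:(s + len - 1L)] <- TRUE
      }
    }
  }
  frac <- function(a, b) sum(isA[a:b]) / (b - a + 1L)
  sites <- list()
  i <- 1L
  while (i <= length(cover)) {
    if (!cover[i]) { i <- i + 1L; next }
    j <- i
    while (j + 1L <= length(cover) && cover[j + 1L]) j <- j + 1L
    a <- i; b <- j
    while (a <= b && !isA[a]) a <- a + 1L
    while (b >= a && !isA[b]) b <- b - 1L
    ok <- a <= b
    if (ok && frac(a, b) + 1e-9 < min_a) {
      # bridged component: longest qualifying window inside, leftmost tie
      ok <- FALSE
      if (b - a + 1L >= min_run) for (len in (b - a + 1L):min_run) {
        for (s0 in a:(b - len + 1L)) {
          if (frac(s0, s0 + len - 1L) + 1e-9 >= min_a) {
            a <- s0; b <- s0 + len - 1L; ok <- TRUE; break
          }
        }
        if (ok) break
      }
      if (ok) {
        while (a <= b && !isA[a]) a <- a + 1L
        while (b >= a && !isA[b]) b <- b - 1L
      }
    }
    if (ok) sites[[length(sites) + 1L]] <- c(start = a - 1L, end = b)
    i <- j + 1L
  }
  sites
}

# hand summation of the two-state nearest-neighbor model straight from
# the shipped parameter files (independent of the package's Tm code path)
oracle_tm_dna <- function(seq, conc = 0.25e-6, na = 0.05) {
  path <- system.file("extdata", "thermo", "nn_dna_santalucia1998.tsv",
                      package = "oligoblock")
  tab <- read.delim(path, comment.char = "#")
  rownames(tab) <- tab$dimer
  k <- nchar(seq)
  dH <- 0; dS <- 0
  for (i in 1:(k - 1)) {
    d <- substr(seq, i, i + 1)
    dH <- dH + tab[d, "dH_kcal"]
    dS <- dS + tab[d, "dS_eu"]
  }
  for (e in c(substr(seq, 1, 1), substr(seq, k, k))) {
    key <- if (e %in% c("A", "T")) "init_AT" else "init_GC"
    dH <- dH + tab[key, "dH_kcal"]
    dS <- dS + tab[key, "dS_eu"]
  }
  dS <- dS + 0.368 * (k - 1) * log(na)
  dH * 1000 / (dS + 1.9872 * log(conc / 4)) - 273.15
}

make_tx <- function(seqs) transcriptome(seqs)
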