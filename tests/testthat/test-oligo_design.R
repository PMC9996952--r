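test_that("modification patterns expand correctly", {
  expect_identical(modification_pattern("full_lna", 4), rep("LNA", 4))
  expect_identical(modification_pattern("alternating_lna", 5),
                   c("LNA", "DNA", "LNA", "DNA", "LNA"))  # 5' starts modified
  expect_identical(modification_pattern("alternating_moe", 4),
                   c("MOE", "DNA", "MOE", "DNA"))
  expect_identical(modification_pattern("full_dna", 3), rep("DNA", 3))
  expect_error(modification_pattern("full_xxx", 4), class = "ob_input_error")
})

test_that("tiling produces exactly L - k + 1 antisense candidates in order", {
  set.seed(41)
  w <- fragment_window(random_seq(32), k = 16)
  cands <- tile_candidates(w, 16)
  expect_length(cands, 17L)
  w2 <- fragment_window(random_seq(50), k = 18)
  expect_length(tile_candidates(w2, 18), 33L)
  # candidates are the reverse complements of the sense k-mers, 5'->3'
  for (i in c(1L, 9L, 17L)) {
    sense <- substr(w$seq, i, i + 15)
    expect_identical(cands[[i]]$seq, reverse_complement(sense))
    expect_identical(cands[[i]]$target_site$start, i - 1L)
  }
  # cardinality property over random (L, k)
  for (rep in 1:20) {
    k <- sample(12:24, 1)
    L <- k + sample(0:40, 1)
    wr <- fragment_window(random_seq(L), k = k)
    expect_length(tile_candidates(wr, k), L - k + 1L)
  }
  expect_error(tile_candidates(fragment_window(random_seq(16), k = 16), 18),
               class = "ob_input_error")
})

test_that("off-target screening excludes the intended site and finds planted decoys", {
  set.seed(42)
  target <- random_seq(400)
  tx <- make_tx(c(target = target))
  i0 <- 101L
  sense <- substr(target, i0 + 1, i0 + 16)
  cand <- oligo_candidate(reverse_complement(sense),
                          interval("target", i0, i0 + 16))
  expect_identical(nrow(screen_offtargets(cand, tx, 3)), 0L)

  g <- synth_transcriptome(n_transcripts = 6, length_range = c(400, 800),
                           n_polya_sites = 1, n_decoys = 3,
                           decoy_mismatches = c(0, 2, 4), seed = 6)
  man <- g$manifest
  s0 <- man$polya_sites[[1]]$start
  cand2 <- oligo_candidate(reverse_complement(man$decoy_source_kmer),
                           interval(man$target_transcript, s0 - 16L, s0))
  hits <- screen_offtargets(cand2, g$transcriptome, 3)
  expect_identical(nrow(hits), 2L)                       # 4-mm decoy invisible
  expect_setequal(hits$mismatches, c(0L, 2L))
  two <- hits[hits$mismatches == 2L, ]
  truth2 <- Filter(function(d) d$mismatches == 2L, man$decoys)[[1]]
  expect_identical(two$transcript_id, truth2$transcript_id)
  expect_identical(two$start, truth2$start)
})

test_that("screening is bit-identical to the brute-force Hamming oracle", {
  set.seed(43)
  for (f in 1:10) {
    tx <- make_tx(setNames(vapply(1:8, function(i)
      random_seq(sample(150:400, 1)), ""), sprintf("s%d", 1:8)))
    for (c_i in 1:2) {
      tid <- sample(tx$ids, 1)
      p <- sample(nchar(tx$seqs[[tid]]) - 15L, 1)
      sense <- substr(tx$seqs[[tid]], p, p + 15L)
      cand <- oligo_candidate(reverse_complement(sense),
                              interval(tid, p - 1L, p + 15L))
      mm <- sample(0:4, 1)
      got <- screen_offtargets(cand, tx, mm)
      want <- oracle_scan(tx, sense, mm)
      self <- want$transcript_id == tid & want$start == p - 1L
      want <- want[!self, , drop = FALSE]
      rownames(want) <- NULL
      expect_identical(got, want)
    }
  }
})

test_that("Tm equals a hand summation from the shipped parameter table", {
  # unmodified 8-mer, default conditions
  expect_equal(melting_temperature("ACGTTAGC"), oracle_tm_dna("ACGTTAGC"),
               tolerance = 1e-10)
  expect_equal(melting_temperature("GGGCGCCC"), oracle_tm_dna("GGGCGCCC"),
               tolerance = 1e-10)
})

test_that("Tm responds monotonically to chemistry, concentration and salt", {
  set.seed(44)
  s <- "ACCCACTACCATCGGA"
  expect_gt(melting_temperature(s, pattern = "full_lna"),
            melting_temperature(s))
  # concentration and monovalent-salt grids, strictly increasing
  tm_conc <- vapply(c(0.05, 0.25, 1, 4) * 1e-6, function(ct)
    melting_temperature(s, thermo_conditions(oligo_concentration = ct)),
    numeric(1))
  expect_true(all(diff(tm_conc) > 0))
  tm_salt <- vapply(c(0.01, 0.05, 0.1, 0.5, 1), function(na)
    melting_temperature(s, thermo_conditions(monovalent_salt = na)),
    numeric(1))
  expect_true(all(diff(tm_salt) > 0))
  # full-LNA >= alternating-LNA >= DNA for random 16-mers
  for (i in 1:100) {
    r <- random_seq(16)
    t_dna <- melting_temperature(r)
    t_alt <- melting_temperature(r, pattern = "alternating_lna")
    t_full <- melting_temperature(r, pattern = "full_lna")
    expect_gt(t_alt, t_dna)
    expect_gt(t_full, t_alt)
  }
})

test_that("chemistries without a thermodynamic model are refused with guidance", {
  err <- expect_error(
    melting_temperature("ACCCACTACCATCGGA", pattern = "full_ome"),
    class = "ob_input_error")
  expect_match(conditionMessage(err), "tm_estimate")
  est <- tm_estimate("ACCCACTACCATCGGA", pattern = "full_ome")
  expect_true(isTRUE(attr(est, "estimate")))
  expect_equal(as.numeric(est),
               melting_temperature("ACCCACTACCATCGGA") + 16 * 0.7)
})

test_that("selection retains zero-off-target candidates and maximizes Tm", {
  mk <- function(seq, start, tm, n_off) {
    cand <- oligo_candidate(seq, interval("t", start, start + nchar(seq)))
    cand$tm_c <- tm
    cand$offtargets <- data.frame(
      transcript_id = rep("x", n_off),
      start = seq_len(n_off) * 10L - 10L, end = seq_len(n_off) * 10L + 6L,
      mismatches = rep(1L, n_off))[seq_len(n_off), , drop = FALSE]
    cand
  }
  set.seed(45)
  seqs <- vapply(1:3, function(i) random_seq(16), "")
  # single candidate: selected regardless of off-targets, fallback flagged
  one <- select_oligo(list(mk(seqs[1], 0, 70, 2)))
  expect_identical(one$selected$seq, seqs[1])
  expect_true(one$fallback)
  # plain argmax over clean candidates
  clean <- list(mk(seqs[1], 0, 70, 0), mk(seqs[2], 4, 85, 0),
                mk(seqs[3], 8, 80, 0))
  expect_identical(select_oligo(clean)$selected$tm_c, 85)
  # the only off-target-free candidate wins despite 3rd-highest Tm
  mixed <- list(mk(seqs[1], 0, 90, 1), mk(seqs[2], 4, 88, 2),
                mk(seqs[3], 8, 80, 0))
  sel <- select_oligo(mixed)
  expect_identical(sel$selected$tm_c, 80)
  expect_false(sel$fallback)
  # permutation invariance
  for (perm in 1:5) {
    shuffled <- sample(mixed)
    expect_identical(select_oligo(shuffled)$selected$seq, sel$selected$seq)
  }
  expect_error(select_oligo(list()), class = "ob_input_error")
})

test_that("design_pipeline composes the steps in both modes", {
  set.seed(46)
  g <- synth_transcriptome(n_transcripts = 6, length_range = c(400, 800),
                           n_polya_sites = 2, seed = 16)
  tx <- g$transcriptome

  # fragment mode: 32-nt fragment, k = 16 -> 17 candidate rows, 1 selection
  rep_f <- design_pipeline(random_seq(32), tx, list(mode = "fragment", k = 16))
  expect_identical(nrow(rep_f$candidates), 17L)
  expect_length(rep_f$selections, 1L)

  # polyA mode: two planted sites -> two selected oligos
  rep_p <- design_pipeline(g$manifest$target_transcript, tx,
                           list(mode = "polya", k = 16))
  expect_length(rep_p$selections, 2L)
  expect_identical(unique(rep_p$candidates$site_index), c(1L, 2L))
  for (sel in rep_p$selections)
    expect_identical(nchar(sel$selected$seq), 16L)

  # transcript without sites: empty report plus a warning
  tx0 <- make_tx(c(flat = strrep("ACGC", 100)))
  expect_warning(rep0 <- design_pipeline("flat", tx0, list(mode = "polya")),
                 regexp = "no internal poly")
  expect_identical(nrow(rep0$candidates), 0L)

  # report writer: TSV columns + JSON twin
  tsv <- tempfile(fileext = ".tsv")
  write_design_report(rep_p, tsv)
  df <- read.delim(tsv)
  expect_true(all(c("candidate_seq", "target_transcript", "start", "end",
                    "tm_c", "n_offtargets_mm0", "n_offtargets_mm3",
                    "retained", "selected") %in% colnames(df)))
  js <- jsonlite::read_json(sub("\\.tsv$", ".json", tsv),
                            simplifyVector = TRUE)
  expect_length(js$selected$seq, 2L)
  expect_equal(js$config$k, 16)
})
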