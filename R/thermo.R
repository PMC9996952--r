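# Two-state nearest-neighbor melting-temperature model.
#
# Duplex formation enthalpy/entropy is summed over dinucleotide stacks
# (unified DNA/DNA parameter set) plus per-position LNA perturbation
# increments, with duplex-initiation terms, an oligo-concentration term
# and a monovalent-salt entropy correction. Parameter tables ship as
# versioned, citation-carrying TSV files under inst/extdata/thermo.
#
# Selection decisions in this package depend only on the *ranking* of Tm
# across candidates from one window, which is robust to the condition
# choice; absolute values for fully LNA-substituted oligos are
# under-estimates (see the table header and the methods vignette).

.thermo_cache <- new.env(parent = emptyenv())

load_nn_table <- function(name) {
  if (!is.null(.thermo_cache[[name]])) return(.thermo_cache[[name]])
  path <- system.file("extdata", "thermo", paste0(name, ".tsv"),
                      package = "oligoblock")
  if (!nzchar(path)) ob_stop(sprintf("thermodynamic table '%s' not found", name))
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  rownames(tab) <- tab$dimer
  .thermo_cache[[name]] <- tab
  tab
}

#' Hybridization conditions for melting-temperature prediction
#'
#' Defaults: 0.25 uM oligo (the working concentration of the blocking
#' oligo in the RT reaction), 50 mM monovalent salt, no divalent salt.
#' Divalent cations are folded into an effective monovalent concentration
#' with the von Ahsen approximation (120 * sqrt(mM Mg) mM equivalents).
#'
#' @param oligo_concentration molar oligo concentration (> 0).
#' @param monovalent_salt molar monovalent cation concentration (> 0).
#' @param divalent_salt molar divalent cation concentration (>= 0).
#' @return object of class `thermo_conditions`.
#' @export
thermo_conditions <- function(oligo_concentration = 0.25e-6,
                              monovalent_salt = 0.05,
                              divalent_salt = 0) {
  if (!is.numeric(oligo_concentration) || oligo_concentration <= 0)
    ob_stop("oligo_concentration must be > 0 (molar)")
  if (!is.numeric(monovalent_salt) || monovalent_salt <= 0)
    ob_stop("monovalent_salt must be > 0 (molar)")
  if (!is.numeric(divalent_salt) || divalent_salt < 0)
    ob_stop("divalent_salt must be >= 0 (molar)")
  structure(list(oligo_concentration = oligo_concentration,
                 monovalent_salt = monovalent_salt,
                 divalent_salt = divalent_salt),
            class = "thermo_conditions")
}

#' Nearest-neighbor melting temperature of a (possibly LNA-modified) oligo
#'
#' Two-state duplex Tm in degrees Celsius against the perfectly
#' complementary DNA strand. Accepts an [oligo_candidate] (uses its
#' sequence and modification pattern) or a plain sequence plus `pattern`.
#' Chemistries `OME`/`MOE` carry no shipped thermodynamic tables and
#' raise an error pointing to [tm_estimate()].
#'
#' @param x `oligo_candidate` or a character sequence.
#' @param conditions `thermo_conditions`.
#' @param pattern modification pattern (preset name or per-position
#'   vector); only used when `x` is a character sequence. Default
#'   `"full_dna"` (unmodified backbone).
#' @return Tm in degrees Celsius.
#' @examples
#' melting_temperature("ACCCACTACCATCGGA", pattern = "full_lna")
#' @export
melting_temperature <- function(x, conditions = thermo_conditions(),
                                pattern = "full_dna") {
  if (inherits(x, "oligo_candidate")) {
    seq <- x$seq
    pat <- x$pattern
  } else {
    seq <- normalize_seq(x, "oligo")
    pat <- modification_pattern(pattern, nchar(seq))
  }
  stopifnot(inherits(conditions, "thermo_conditions"))
  k <- nchar(seq)
  if (k < 2L) ob_stop("oligo must be at least 2 nt for a stack model")
  if (grepl("N", seq, fixed = TRUE))
    ob_stop("candidate oligos may not contain N")
  if (length(pat) != k) ob_stop("pattern length must equal oligo length")
  if (any(pat %in% c("OME", "MOE")))
    ob_stop(paste("no thermodynamic model is shipped for 2'-O-methyl/",
                  "2'-MOE chemistries; use tm_estimate() for a flagged",
                  "heuristic estimate"))
  dna <- load_nn_table("nn_dna_santalucia1998")
  dimers <- substring(seq, seq_len(k - 1L), seq_len(k - 1L) + 1L)
  dH <- sum(dna[dimers, "dH_kcal"])
  dS <- sum(dna[dimers, "dS_eu"])
  for (endbase in c(substr(seq, 1L, 1L), substr(seq, k, k))) {
    key <- if (endbase %in% c("A", "T")) "init_AT" else "init_GC"
    dH <- dH + dna[key, "dH_kcal"]
    dS <- dS + dna[key, "dS_eu"]
  }
  lna_pos <- which(pat == "LNA")
  lna_pos <- lna_pos[lna_pos < k]          # 3'-terminal LNA: no increment
  if (length(lna_pos)) {
    lna <- load_nn_table("nn_lna_increments_mctigue2004")
    inc_dimers <- dimers[lna_pos]
    dH <- dH + sum(lna[inc_dimers, "ddH_kcal"])
    dS <- dS + sum(lna[inc_dimers, "ddS_eu"])
  }
  na_eq <- conditions$monovalent_salt +
    120 * sqrt(conditions$divalent_salt * 1000) / 1000
  dS_corr <- dS + 0.368 * (k - 1L) * log(na_eq)
  R <- 1.9872      # cal/(mol K)
  tm_k <- dH * 1000 / (dS_corr + R * log(conditions$oligo_concentration / 4))
  tm_k - 273.15
}

#' Heuristic Tm estimate for chemistries without a thermodynamic model
#'
#' For 2'-O-methyl (`OME`) and 2'-methoxy-ethoxy (`MOE`) patterns no
#' nearest-neighbor tables are shipped; this returns the DNA-backbone Tm
#' plus a documented per-modification heuristic offset (+0.7 C per OME,
#' +1.0 C per MOE position). The result carries `attr(, "estimate") ==
#' TRUE` and is reported as an estimate wherever it appears.
#'
#' @inheritParams melting_temperature
#' @return Tm estimate in degrees Celsius with attribute `estimate`.
#' @export
tm_estimate <- function(x, conditions = thermo_conditions(),
                        pattern = "full_ome") {
  if (inherits(x, "oligo_candidate")) {
    seq <- x$seq; pat <- x$pattern
  } else {
    seq <- normalize_seq(x, "oligo")
    pat <- modification_pattern(pattern, nchar(seq))
  }
  base <- melting_temperature(seq, conditions, pattern = "full_dna")
  offset <- sum(pat == "OME") * 0.7 + sum(pat == "MOE") * 1.0 +
    sum(pat == "LNA") * 0    # LNA positions have a real model; use it
  if (any(pat == "LNA")) {
    dna_lna <- ifelse(pat == "LNA", "LNA", "DNA")
    base <- melting_temperature(seq, conditions, pattern = dna_lna)
  }
  structure(base + offset, estimate = TRUE)
}
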