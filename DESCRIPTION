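Package: oligoblock
Title: Design and Evaluation of Blocking Oligonucleotides for Targeted
    Depletion in RNA-Seq Libraries
Version: 0.1.0
Authors@R:
    person("oligoblock", "developers", email = "oligoblock@example.org",
           role = c("aut", "cre"))
Description: Tools to design high-affinity antisense blocking
    oligonucleotides (e.g. LNA-modified) that prevent reverse
    transcription and PCR amplification of unwanted abundant RNA
    fragments in sequencing libraries, and to evaluate the benefit of
    such depletion. Includes detection of internal adenosine-rich
    reverse-transcription priming sites, candidate tiling across design
    windows, exhaustive mismatch-tolerant off-target screening against a
    transcriptome, nearest-neighbor melting-temperature scoring with
    locked-nucleic-acid increments, a seeded count-matrix depletion
    simulator (detected genes as a function of depth, initial target
    fraction and depletion efficiency), depletion-efficiency and
    library-complexity metrics (CPM, hypergeometric subsampling, fold
    reduction, biotype fractions, detection counts, differential
    expression concordance, standardized-residual off-target flagging),
    and seeded synthetic-data generators with ground-truth manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
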