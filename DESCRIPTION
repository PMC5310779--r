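Package: rgetools
Title: Genetic Parameters and Clade Statistics for Reductive Genome Evolution in Endosymbionts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes and compares the genetic parameters used to study reductive
    genome evolution in intracellular endosymbionts that have lost DNA-repair genes:
    a sliding-window k-mer repeat-sequence density, GC content of intact genes and
    degraded remnants, pairwise nucleotide distances from an outgroup ortholog
    (p, JC69, K80 and pairwise-ML HKY), and Nei-Gojobori (1986) dN/dS. Provides the
    clade-level comparative layer (per-gene clade summaries, round-robin paired
    t-test matrices, degraded/intact clade-ratio analysis with exact Mann-Whitney
    tests, and cross-parameter regressions) together with a sequence-evolution
    simulator (HKY with per-clade GC equilibria and rate multipliers, selection as
    acceptance thinning, and pseudogenization with deletion accumulation) that
    generates two-clade gene-by-symbiont panels with ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
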