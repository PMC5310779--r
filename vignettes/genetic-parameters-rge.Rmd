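---
title: "Measuring the genomic footprint of DNA-repair-gene loss: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the genomic footprint of DNA-repair-gene loss: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgetools)
```

## The scientific question

Intracellular endosymbionts of deep-sea vesicomyid clams are undergoing
reductive genome evolution (RGE): their genomes shrink by pseudogenization and
deletion. One proposed driver is the loss of DNA-repair genes. Losing
nucleotide excision repair (*uvrA/B/C/D*, *mfd*) and the mismatch glycosylase
*mutY* is expected to leave three measurable footprints on the remaining
genomic genes:

1. **higher substitution rates**, visible as larger genetic distances from an
   outgroup ortholog;
2. **lower GC content**, because unrepaired G·A mismatches resolve toward A/T;
3. **higher short-repeat density**, because base composition sets the
   equilibrium frequency of chance k-mer repeats — the substrate of
   RecA-independent illegitimate recombination and hence of further deletion.

The symbiont panel this package is built around has two rRNA-defined clades:
clade I (5 taxa, missing *uvrB*, *uvrC*, *mutY*, *recA*) and clade II (7 taxa,
mostly repair-complete), plus the thioautotrophic symbiont of *Bathymodiolus
septemdierum* (`Bsep_S`) as the outgroup. `rgetools` implements the three
parameters, the clade-level comparisons, and a sequence-evolution simulator
that generates such panels with known ground truth, so that every statistical
claim can be exercised end to end without access to the deposited sequences.

## The three genetic parameters

### Repeat-sequence density

For a window of $W$ bases (default 200) the statistic counts k-mer start
positions (default $k = 5$) whose k-mer occurs at at least one *other* start
position in the same window. Counting is occurrence-wise, not pair-wise: three
copies of the same 5-mer contribute 3, not $\binom{3}{2}$. Windows slide by
$s = 10$ bases and only full windows are used; the per-gene scalar is the mean
across windows (optionally after a centered moving average, disabled by
default because no span is universally right; edge windows are truncated to
the available values). Gaps and `N` are stripped before windowing so that
alignment punctuation in degraded remnants cannot masquerade as sequence.

Two conventions were considered: *anywhere-in-window* repeats (the default)
and *tandem-only* (an identical copy at offset exactly $k$; available via
`tandem_only = TRUE`). The anywhere convention is the one consistent with the
published per-k calibration series for the shortest gene in the panel (~188
repeated positions for 3-mers in 200 bp is only reachable when any re-use in
the window counts), and the tandem variant is kept for sensitivity analysis.

Why composition controls this statistic: for iid bases with match probability
$q = \sum_b p_b^2$, the expected count is approximately
$m\,(1 - (1 - q^k)^{m-1})$ with $m = W - k + 1$. Because $q$ grows as
composition skews away from 50% GC, AT-rich sequences carry more chance
repeats. `expected_repeat_count()` exposes both this closed form and a
Monte-Carlo estimate; the approximation ignores overlap dependence between
k-mers and therefore sits a few counts above the simulated mean, well inside
the window-to-window spread.

### GC content

`gc_content()` is $(G + C)/(A + C + G + T)$ with gaps and `N` excluded from
numerator and denominator, reported both as a fraction and as percent.
Exclusion (rather than counting toward the denominator) avoids remnant-length
artifacts when degraded regions are measured on their aligned extent.

### Genetic distance

Distances are pairwise against the outgroup ortholog, after pairwise deletion
of columns containing gaps or `N` (degraded remnants have gene-specific
deletion patterns, so complete deletion would discard most of the signal):

* `p`: raw mismatch fraction;
* `JC69`: $t = -\tfrac34 \ln(1 - \tfrac43 p)$;
* `K80` (default): $t = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$ from
  transition and transversion proportions, with a delta-method standard
  error and a transition/transversion ratio estimate;
* `HKY`: numerical maximization of the pairwise likelihood over $(t, \kappa)$
  with empirical base frequencies, via spectral decomposition of the
  reversible rate matrix; the standard error comes from the observed
  information.

Saturated pairs (non-positive log arguments) are reported as `Inf` with a
`saturated` flag rather than silently dropped. K80 is the default because the
panel's real divergences (~0.6–1 substitutions/site) make the
transition/transversion distinction matter while remaining closed-form and
fast; the HKY fit is available when composition asymmetry should be absorbed
by the model.

### dN/dS

`ng86_dn_ds()` implements the Nei–Gojobori (1986) counting method:
synonymous site fractions per codon from the standard genetic code (changes
to stop codons count as non-synonymous), averaged over the two sequences;
differences in multi-hit codons averaged over all mutational pathways with
equal weight, excluding pathways that pass through a stop codon (if every
ordering is blocked, all orderings are used); Jukes–Cantor correction applied
to $p_N$ and $p_S$ separately. Codons containing a gap, `N` or stop in either
sequence are excluded pairwise. $d_S = 0$ yields `ratio = NA` with a flag;
a saturated $d_S = \infty$ yields the limiting ratio 0 plus a
`ds_saturated` flag.

**Which pairs to compare.** Counting methods saturate quickly on synonymous
sites: against an outgroup at ~0.6–0.8 substitutions/site overall, synonymous
divergence approaches the 3/4 ceiling and $d_S$ diverges. Per-clade dN/dS
summaries are therefore computed from *within-clade* intact pairs
(`clade_dnds()`), which are roughly an order of magnitude less diverged and
keep $d_S$ in the well-behaved range; the per-cell vs-outgroup table
(`dnds_table()`) remains available for inspection. Users should expect the
NG86 estimate to sit below the generating non-synonymous acceptance
probability when transitions are favored ($\kappa > 1$) — the equal-rate
assumption undercounts synonymous opportunity — which is the usual,
documented behavior of this method family.

## The comparative layer

* `clade_summary()`: NA-aware per-gene, per-clade means and SDs, outgroup
  excluded.
* `round_robin_paired()` / `pair_matrix()`: every unordered symbiont pair is
  compared by a two-sided paired t-test across the shared genes of a gene
  set, dropping genes missing in either member. The published presentation
  pairs two gene sets in one matrix — all genes (including remnants) in the
  lower-left half, the universally intact genes in the upper-right half — and
  `pair_matrix()` reproduces that layout with per-symbiont across-gene
  averages. Degenerate difference vectors are defined rather than fatal:
  zero variance with nonzero mean gives $p = 0$, zero variance with zero
  mean gives $p = 1$, both flagged.
* `ratio_analysis()`: per-gene clade-I/clade-II ratios of a parameter,
  compared between the degraded gene group (*uvrB*, *uvrC*, *mutY*) and the
  intact group with a two-sided exact Mann–Whitney U test. For genes in the
  intact group only cells with status `intact` enter the clade means, so a
  gene degraded in a minority of taxa (e.g. *uvrD* in two clade II symbionts)
  is averaged over its intact copies.
* `parameter_regression()`: ordinary least squares pooling every
  (gene, symbiont) cell as one point. This mirrors the published dot
  definition and is therefore deliberately phylogenetically naive; the
  points are not independent and the p-values should be read accordingly.
* `two_sample_test()`: Welch (default), Student, one-way ANOVA, and
  Mann–Whitney with the exact null when $n_1 + n_2 \le 12$ without ties and
  the tie-corrected normal approximation otherwise. Fully tied data give
  $p = 1$ with a degenerate flag.

No multiple-testing correction is applied anywhere: the round-robin matrices
report raw p-values against a uniform 0.05 threshold, as in the original
analysis, and any correction is left to the reader.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` evolves each gene's root sequence down a fixed rooted
tree under HKY with GC-symmetric equilibrium frequencies
($\pi_A = \pi_T$, $\pi_G = \pi_C$), scaled so branch lengths are expected
neutral substitutions per site. Selection is an acceptance probability
$\omega$ on non-synonymous events (exact at the event level; proposals
creating internal stops are always rejected while a gene is under
selection). Pseudogenization on a designated branch switches the gene to
$\omega = 1$ and starts a deletion process — Poisson events with geometric
lengths — on that branch and all its descendants, so remnant deletion
profiles diversify downstream of the loss event, and homology is tracked
through deletions so the emitted alignments are exact.

Default study conditions (all overridable through `simulation_config()`):

| setting | default | rationale |
|---|---|---|
| panel | 5 clade I + 7 clade II tips + outgroup | the real panel's shape |
| tree depth | outgroup stem 0.9, ingroup stem 0.5, clade stems 0.3, tips 0.1 (sibling pair 0.04/0.06) | realized K80 outgroup distances ~0.6–0.8 subs/site, the observed scale |
| rate multiplier | clade I ×1.5 | repair loss elevates the substitution rate |
| GC equilibrium | clade I 0.32, clade II/ancestral 0.38 | observed gene GC of the two clades |
| $\kappa$ | 4 | typical bacterial transition bias |
| genes | 10, 231 bp (`groES`) to 3426 bp (`mfd`) | the examined panel's lengths |
| per-gene $\omega$ | 0.16–0.44 | near the published per-gene dN/dS scale |
| pseudogenization | *uvrB*, *uvrC*, *mutY* on the clade-I stem; *uvrD* on the `Ifos_S`/`Apha_S` tips; *mutY* on the `Rma` tip | the documented loss events |
| deletion process | 0.035 events/site per unit branch, mean length 20 bp | remnants end near 55–65% of intact length, as observed |

Known departures from real data, hence limits on what green tests show:

* Root sequences are iid codons at the target composition with stop codons
  rejected; the rejection biases realized root GC upward by about +0.014
  (stops are AT-rich), identically for all genes, so clade contrasts are
  unaffected. There is no codon-usage structure, no amino-acid composition
  realism, and no site-to-site rate variation.
* Composition differences between clades arise only through incomplete HKY
  relaxation toward the clade equilibrium over finite branches; real clades
  have had longer to equilibrate, so simulated GC gaps (~2–3 points) are
  smaller than the observed ~5 points. Directional contrasts are preserved;
  absolute gaps are conservative.
* Deletions only — no insertions, no rearrangements, no recombination — and
  pseudogenization is a clean switch, not a gradual erosion.
* All taxa in a clade share one rate multiplier; real lineages vary.

## Numerical choices

* Neutral branches use the exact finite-time transition matrix from a
  symmetric eigen-decomposition of the reversible rate matrix; selected
  branches use uniformized event sampling (constant majorizing rate, thinned
  jumps), which is exact and costs $O(1)$ per proposed event.
* The HKY-ML optimizer works on $(\log t, \log\kappa)$ with Nelder–Mead,
  relative tolerance $10^{-10}$, initialized from the JC distance; pairwise
  base frequencies get a half-count guard against absent bases.
* Parameter tables serialize with `%.17g`, so TSV round trips are bit-exact.
* Test problem sizes: the suite exercises 100 kb pairs for distance recovery,
  10 kb genes for $\omega$ recovery, exhaustive enumeration over all 4096
  binary 12-mers for the repeat counter, and 20-seed pipeline replicates for
  mechanism recovery; these sizes keep each check well-powered while the full
  suite completes in minutes.

## Reproducibility

Every dataset is a pure function of its `simulation_config()` (including the
seed); `run_pipeline()` stamps each output file with the seed and a config
hash, and rerunning a config reproduces every table byte-for-byte.

```{r example, eval = FALSE}
run <- run_pipeline(list(seed = 1))
run                      # clade means, ratio analysis, regression
run$pair_matrices$gc     # round-robin paired-t matrix, both halves
run$dnds_clades          # within-clade NG86 dN/dS per gene and clade
```
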