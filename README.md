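# rgetools

Genetic parameters and clade statistics for reductive genome evolution in
endosymbionts.

## What this is for

Intracellular symbionts of deep-sea vesicomyid clams are losing DNA-repair
genes (nucleotide excision repair: *uvrA/B/C/D*, *mfd*; the glycosylase
*mutY*) while their genomes shrink. The loss is expected to leave three
measurable footprints on the surviving genomic genes, and this package
measures and compares all three on a gene-by-symbiont panel:

* **genetic distance** from an outgroup ortholog (p, JC69, K80 with
  t = −½ ln(1−2P−Q) − ¼ ln(1−2Q), or pairwise-ML HKY) — a substitution-rate
  proxy;
* **GC content** of intact ORFs and degraded remnant regions;
* **repeat-sequence density** — repeated k-mer occurrences (default 5-mers)
  in sliding 200 bp windows with 10 bp shift, averaged per gene — the
  substrate of RecA-independent deletion;

plus **NG86 dN/dS** (pathway-averaged Nei–Gojobori with Jukes–Cantor
correction) for selection-pressure summaries, and the comparative layer used
to contrast the repair-deficient clade I (5 taxa) with the mostly
repair-complete clade II (7 taxa): per-gene clade summaries, round-robin
paired t-test matrices over all-genes / intact-genes sets, degraded/intact
clade-ratio analysis with exact Mann–Whitney tests, and cross-parameter OLS
regressions.

A sequence-evolution simulator (`simulate_dataset()`) generates such
two-clade panels under HKY with per-clade GC equilibria and rate
multipliers, selection as non-synonymous acceptance thinning, and
pseudogenization with an accumulating deletion process — with exact
truth-tracked alignments — so the whole analysis is testable end to end
without the deposited sequences. It is aimed at researchers studying
reductive genome evolution who want a transparent, scriptable
re-implementation of this analysis style for their own panels (real via
FASTA/TSV inputs, or simulated).

## Worked example

```r
library(rgetools)
run <- run_pipeline(list(seed = 1))
run
#> rge_run (seed 1 )
#>   distance       clade means: I=0.782, II=0.628
#>   gc             clade means: I=35.830, II=39.006
#>   repeat_density clade means: I=45.429, II=42.274
#>   dN/dS          clade means: I=0.182, II=0.170 (within-clade pairs)
#>   ratio I/II distance    degraded 1.866+/-0.068 intact 1.033+/-0.062 (MWU p=0.0167)
#>   ratio I/II gc          degraded 0.890+/-0.055 intact 0.929+/-0.044 (MWU p=0.667)
#>   ratio I/II repeat_density degraded 1.081+/-0.056 intact 1.078+/-0.055 (MWU p=1)
#>   repeat ~ GC regression: slope -1.237, R -0.649, p 1.05e-15 (n=120)
```

Reading this: clade I (repair-deficient) genes sit farther from the outgroup
(0.78 vs 0.63 substitutions/site), are more AT-rich (35.8% vs 39.0% GC) and
carry more 5-mer repeats per 200 bp window (45.4 vs 42.3). The degraded
genes (*uvrB*, *uvrC*, *mutY*) diverge ~1.9× faster in clade I than clade II
versus ~1.03× for intact genes (exact Mann–Whitney p = 0.017), and repeat
density falls significantly with GC content across all gene × symbiont
points — the composition-driven mechanism linking *mutY* loss to repeat
accumulation. The per-seed ratio contrasts for GC and repeat density are
noisier (non-significant at this seed); their directions are recovered in
≥ 18/20 seeds by the acceptance suite.

Individual pieces are usable on their own:

```r
count_window_repeats("AAAAA", k = 2)                   # 4
gc_content("ATGC-N")$gc_fraction                       # 0.5, 2 bases excluded
nucleotide_distance(pairwise_alignment(a, b), "k80")   # t, kappa_hat, se_t
ng86_dn_ds(pairwise_alignment(cds_a, cds_b))           # dN, dS, ratio
```

Real panels enter through `input = list(fasta=, meta=, aln_dir=)` in the run
config: a FASTA of per-gene sequences with `symbiont|gene` headers, a TSV
assigning clade and intact/degraded/absent status, and one alignment FASTA
per gene including the outgroup. A thin command-line wrapper lives at
`inst/scripts/rge.R` (`Rscript rge.R run --seed 1 --out report/`).

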