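# estrocon

Cross-species conservation analysis of estrogen-responsive genes.

## The problem

Estrogens drive transcriptional programs implicated in reproductive-system
cancers, but which target genes are *robustly* estrogen-responsive — across
species, platforms and model systems — is hard to establish from any single
experiment.  One productive design: expose a whole organism (zebrafish) to
17β-estradiol (E2) with and without the pure anti-estrogen ICI 182,780
(fulvestrant), call a gene estrogen-responsive only if E2 deregulates it
*and* ICI co-treatment suppresses or normalizes that change, then map the
responsive genes to human homologs, intersect with estrogen-responsive gene
lists from human cancer cell lines (MCF7, T47D, Ishikawa), and ask whether
the conserved core is enriched for direct estrogen-receptor (ER) regulation
— ER binding sites within 100 kb, estrogen-response-element (ERE) motifs in
20 kb flanks.

`estrocon` implements that entire analysis as a tested R package: two-channel
array ingestion and LOWESS normalization, Significance Analysis of
Microarrays (SAM) in multiclass and two-class forms with a permutation FDR,
the anti-estrogen rescue criterion, homolog mapping and set-overlap
statistics, degenerate-consensus motif scanning, windowed binding-site
enrichment with a randomization null, a generic Fisher gene-set enrichment,
and a seeded synthetic-data generator that emulates every input so the whole
chain is testable without downloads.

## The statistics at the core

* **SAM**: per-gene d = r / (s + s0); two-class r is the mean difference with
  pooled SE s, multiclass r is the F-like between-class numerator
  √((Σn_k/Πn_k)·Σ n_k(x̄_k−x̄)²).  The fudge factor s0 minimizes the
  coefficient of variation of window-wise MADs of d.  FDR comes from label
  permutations (exhaustive when feasible) via the delta-slab rule:
  FDR(δ) = π₀·median(false calls)/calls; a gene's q-value is the minimum FDR
  at which it is called.  Genes with q < 0.08 pass.
* **Rescue criterion**: keep a candidate iff |mean(E2) − mean(control)| ≥
  log2(2) in the candidate's direction and mean(E2+ICI) lies on the control
  side of mean(E2); label `normalized` if the residual shift is ≤ 0.25 of
  the E2 shift, else `partial`.
* **Overlap significance**: one-sided binomial P(X ≥ k), X ~ Bin(|a|, |b|/N)
  against the full homolog universe, plus the exact hypergeometric tail.
* **ERE scanning**: exact IUPAC matching of the palindromic consensus
  GGTCAnnnTGACC (self-reverse-complementary: one report per position);
  flank enrichment via Binomial(total hits, region fraction).
* **Site enrichment**: sites within a window of each gene; observed total
  over the conserved set versus 1000 redraws of equally many genes from the
  background (p_empirical = (1+#{null ≥ obs})/(n_rand+1)), with an analytic
  binomial expectation reported alongside.

## Worked example

The `analysis/` scripts run the full chain on the default synthetic study
(2000 probes, 4 control + 3 E2 + 3 E2+ICI arrays, 100 planted responsive
genes at 2–128 fold, a 2 × 1 Mb genome with 600 human-side loci and 500
binding sites planted at 3× density near conserved genes):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_conservation.R
Rscript analysis/04_regulome.R
Rscript analysis/05_run_all.R
```

The end-to-end run prints:

```
probes: 2000; prefilter: 93; responsive: 92 (39 up / 53 down)
mapped to human: 34 (37.0%); conserved: 12 (35% of mapped)
sites/gene: 10.58 conserved vs 2.59 non-conserved; p_empirical = 0.000999
ERE flank enrichment p = 0.525 (ratio 1.01)
planted recovery: responsive 0.91, conserved 1.00
```

Reading: of 2000 probes, the multiclass SAM prefilter at q < 0.08 keeps 93;
92 survive the two-class contrast and the rescue criterion (91% of the 100
planted genes — the misses are at the 2-fold detection floor).  37% map to
human homologs (generator target 43.5%, small-sample noise), 12 of the 34
mapped genes are conserved in at least one cell-line list, and those 12
carry 10.58 binding sites per gene versus 2.59 for non-conserved homologs —
the planted 3× enrichment, detected at the randomization-null resolution
limit (p = 1/1001).  The ERE flank test is null (ratio 1.01), the expected
negative control: motif presence does not track responsiveness.

Equivalent single call in R:

```r
library(estrocon)
report <- run_pipeline(default_config(seed = 20260927, outdir = "results/run_all"))
```

## Layout

```
R/                  package code: arrayio, sam, response, homology,
                    regulome, enrich, synthdata, pipeline
analysis/           numbered narrative drivers (01 simulate ... 05 run-all)
scripts/acceptance.R  headline-quantity recomputation (see above)
tests/testthat/     unit, property and acceptance tests
vignettes/methods.Rmd  the models, assumptions, parameters and limitations
```
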