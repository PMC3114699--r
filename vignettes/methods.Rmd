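---
title: "Identifying conserved estrogen-responsive genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying conserved estrogen-responsive genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estrocon)
```

## The analysis

`estrocon` implements a comparative-transcriptomics workflow for estrogen
signalling.  The design it analyzes is a three-arm exposure experiment read
out on two-channel microarrays: vehicle controls, 17β-estradiol (E2), and
E2 plus the pure anti-estrogen ICI 182,780 (fulvestrant), which binds
estrogen-receptor monomers and blocks receptor dimerization.  The working
definition of an *estrogen-responsive* gene is therefore pharmacological,
not merely statistical: the gene must be deregulated by E2 **and** that
deregulation must be suppressed or normalized when ICI is co-administered.
Downstream, responsive genes are mapped to human homologs, intersected with
estrogen-responsive gene lists from human cancer cell lines (MCF7, T47D,
Ishikawa style), and the conserved core is interrogated for
estrogen-response-element (ERE) motifs and estrogen-receptor (ER) binding
sites in its regulatory neighbourhoods.

Every stage is a package function; the `analysis/` scripts are thin
narrative drivers, and `run_pipeline()` executes the whole chain from one
configuration with one master seed.

## Normalization and filtering

Spot-level input is GenePix-style: per-channel foreground and background
medians plus a quality flag.  Net intensity is foreground minus local
background; a spot with a nonpositive flag or a nonpositive net in either
channel is missing, because its log-ratio is undefined.  No more elaborate
background model is attempted.

Within each array we compute M = log2(Cy5/Cy3) and
A = ½·log2(Cy5·Cy3) per spot and remove the intensity-dependent dye trend
with a LOWESS fit of M on A (degree-1 local regression, tricube weights,
3 robustness iterations, span 0.3).  The span default follows common
two-channel practice; only the method, not its parameters, is prescribed
by the study design, so the span is exposed as `thresholds$span`.

Probes missing in more than `max_missing = 6` of the 10 arrays are
excluded.  Replicate probes per gene are **not** averaged before testing:
each probe passes through SAM on its own, and collapse to gene level (most
significant probe represents the gene) happens only at reporting.
Averaging replicate probes before a variance-shrunken statistic mixes
within- and between-probe variance and can manufacture or destroy
significance; keeping probes separate is the conservative choice.

## SAM: moderated statistics with a permutation null

The testing engine is Significance Analysis of Microarrays in its
Tusher-style form.  For gene *i*,

d_i = r_i / (s_i + s0),

where in the two-class design r_i is the difference of class means and
s_i the pooled standard error; in the multiclass design

r_i = √( (Σ n_k / Π n_k) · Σ_k n_k (x̄_ik − x̄_i)² ),
s_i = √( Σ_k 1/n_k · pooled within-class variance ),

an F-like between-class numerator with the same shrinkage.  The fudge
factor s0 is chosen on the 0, 5, …, 100 percentile grid of the s_i to
minimize the coefficient of variation of window-wise median absolute
deviations of d — flattening the dependence of the spread of d on s so
that low-variance genes cannot dominate.  Missing entries are ignored per
gene; a gene needs at least two non-missing values per class, else its
statistic is undefined and reported `NA`.  The degenerate 0/0 case
(constant gene, no shrinkage) is defined as d = 0.

Significance comes from label permutations: all distinct assignments when
there are few enough (at most 1e5; e.g. all 20 for a 3-vs-3 contrast, all
4200 for the 4+3+3 design at 100 requested permutations the sampler falls
back to seeded random shuffles), otherwise `n_perm` seeded shuffles.  For
each delta on a grid the sorted observed statistics are compared to the
permutation-averaged order statistics; genes outside the slab of
half-width delta beyond the asymmetric cutpoints are *called*.  The FDR at
delta is

FDR(δ) = π₀ · median over permutations of false calls / calls,

with π₀ = min(1, 2 · fraction of observed d inside the permutation-null
interquartile range).  A gene's q-value is the minimum FDR over deltas at
which it is called, then made monotone in |d| rank.  The delta grid mixes
rank-based (quantiles of the observed slab gaps) and linear spacing; a
purely rank-based grid leaves the region where strong effects separate
from the null almost unresolved and can inflate q-values there by a factor
of two.  Undefined permutation statistics (a shuffle can empty a class for
a gene with missing values) sit at the null centre, 0.

### Two-stage selection

The study design prefilters with multiclass SAM over all three classes at
q < 0.08 ("boosting power" by using every arm), then tests the E2 vs
control contrast at q < 0.08.  One subtlety is load-bearing: the two-class
statistic and its permutation null are computed **on the whole array**,
and the selection is intersected with the prefilter survivors afterwards.
Running the permutation machinery on the prefiltered subset alone is
statistically broken — the subset is signal-rich, the permuted order
statistics are contaminated by the planted effects, and genuinely strong
genes can sit inside the slab at every delta and receive q = 1.  We
verified exactly this failure on synthetic data before adopting the
full-array form.

## The rescue criterion

A two-class candidate with per-class means (control, E2, E2+ICI) is kept
as estrogen-responsive when

* the E2 shift from control points in the candidate's direction and has
  magnitude ≥ log2(`min_fold`), default 2; and
* the E2+ICI mean lies on the control side of the E2 mean (up:
  mean(E2) > mean(E2+ICI); down: reversed).

Kept genes are labelled `normalized` when the residual E2+ICI shift from
control is at most τ = 0.25 of the E2 shift, else `partial`.  The
normalized/partial boundary is descriptive in the underlying design (two
heatmap sub-families), so τ is a package convention, configurable, chosen
to sit well between the generator's rescue factors (0.1 and 0.6, below).
Suppression is tested on class means only; an optional stricter route
would re-run two-class SAM on E2 vs E2+ICI, but the default mirrors the
descriptive criterion.  Up/down counts are reported as computed — the
pipeline never fixes totals by hand.

## Homology and conservation

The homology map is a two-column source→target table.  After collapse
(a source maps to at most one target, lexicographically first for
determinism; duplicate targets deduplicated) all set operations live on
the target namespace, since intersections are only well-defined on one
namespace.  The mapping rate is |mapped inputs| / |inputs|.

Overlap of the mapped responsive set with a cell-line list is tested
one-sided against the full homolog universe (every human homolog of any
gene on the array — the "8056-style" background) under two nulls: the
binomial P(X ≥ k), X ~ Bin(|a|, |b|/N), which is the test the study
design names, and the exact hypergeometric tail of the 2×2 table.  Both
are reported; they agree closely in the sparse regime and the
hypergeometric is exact.  `percent_overlap` uses the first-listed
(zebrafish-derived) set as denominator, matching the fish-vs-cell-line
percentages; for cell-line pairs both candidate denominators are
recoverable from the reported sizes, since the original percentage
conventions are not fully specified.

## Regulatory-region analysis

**Coordinates** are 0-based half-open (BED convention) throughout;
browser-style 1-based input is converted at the BED reader boundary.

**Motif scanning.**  The ERE consensus GGTCAnnnTGACC is degenerate IUPAC
and is its own reverse complement, so every match is present on both
strands at the same position; each position is reported once with strand
`+`.  Non-palindromic patterns are scanned on both strands.  Matching is
exact (no mismatch tolerance, no PWM): the consensus *is* the object of
interest.  Scanning uses `Biostrings::matchPattern(fixed = FALSE)`; the
test suite holds it to exact agreement with an independent
overlapping-match regular-expression oracle.

**Flank enrichment.**  For each gene the scanned region is the union of a
20 kb 5' flank, the gene body, and a 20 kb 3' flank, clipped to the
chromosome (flank width scales with the synthetic genome, below).  With n
hits genome-wide and merged regions covering fraction w of the genome,
the in-region count is tested against Binomial(n, w), one-sided.  On both
the real-scale design and calibrated synthetic data this test is null —
EREs are not concentrated near estrogen-responsive genes — and the
package's test suite reproduces that negative pattern rather than a
positive one.

**Binding-site assignment.**  A site counts for a gene when its interval
overlaps [start − window, end + window), window 100 kb at human scale.
Windows are anchored on gene bodies, not TSSs (the neighbourhood notion
here is gene-centric; a TSS-anchored variant would need strand-resolved
promoter logic the input does not guarantee).  Windows of neighbouring
genes are *not* merged: a site near two genes counts for both, which is
what "sites per gene" arithmetic requires.  Per-gene rates are truncated
(not rounded) to two decimals — 210 sites over 336 genes prints 0.62 —
matching the reporting convention of the analysis this reproduces.

**Site enrichment.**  The observed total over the target (conserved) genes
is compared to an empirical null: `n_rand = 1000` draws of the same number
of genes from the full locus collection, recounting each time;
p_empirical = (1 + #{null ≥ observed}) / (n_rand + 1), resolution
1/(n_rand + 1).  The null mean is reported as `expected`, alongside an
analytic binomial expectation in which each of the site→gene assignments
observed over the whole background falls on a target with probability
|targets|/|background| — the randomization and analytic expectations agree
under uniform placement, and both are printed because the derivation of a
single "expected" count is otherwise underdetermined.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
under which everything else is validated.

* **Expression** (`gen_expression`): 2000 genes, the 4 control + 3 E2 +
  3 E2+ICI design, i.i.d. Normal(0, σ = 0.5) log2 ratios for nulls.
  Planted genes shift the E2 class by ±log2(f) with f log-uniform on
  [2, 128] — the observed span of transcript-abundance changes; the
  distribution across that span is unstated, and log-uniform spreads
  effect sizes evenly on the scale the statistic sees.  The E2+ICI class
  moves r of the way from control to E2: r = 0.1 for `normalized`,
  r = 0.6 for `partial` rescue — clearly inside/outside τ = 0.25.
* **Spot tables** (`gen_spot_tables`): per-spot mean intensities
  A ~ U(8, 14), a planted linear dye bias (0.2 log2 units per log2
  intensity), constant background, ~1% flagged spots.  Reading these back
  through the normalizer recovers the true ratios up to smoother residual
  (median absolute error well under 0.1 in tests).
* **Genome and loci** (`gen_genome_and_loci`): i.i.d. bases at GC 0.41,
  2 chromosomes × 1 Mb, 600 gene loci.  Because a 10-fixed-base consensus
  occurs spontaneously only ~once per Mb, motifs are *planted*: uniformly
  genome-wide (10 per 100 kb by default) and, when asked, at a per-flank
  rate near designated genes.  Plants never overlap, so the truth record
  is exactly recoverable by the scanner.
* **Regulome and sets** (`gen_regulome_and_sets`): homology with mapping
  rate 0.435 (the observed zebrafish→human rate) and a 10% many-to-one
  fraction; 500 binding sites placed uniformly except `enrich_factor = 3`
  higher density inside conserved-gene windows; four cell-line lists sized
  at 18% of the universe, built so that every planted conserved gene is in
  at least one list and the conserved fraction of the mapped responsive
  set is 0.29 in expectation.
* **Conserved candidates**: planted conserved genes are drawn from planted
  responsive genes with fold ≥ 4 (`robust_min_fold`).  Genes detectable
  across species, platforms and laboratories are by nature the robustly
  responding core, not genes at the 2-fold detection floor; a generator
  that declared borderline genes "conserved" would conflate conservation
  recovery with detection power at the floor, which the SAM-level
  calibration tests already characterize separately.
* **Geometry scaling**: the synthetic genome is ~1/1500 of a human genome
  per chromosome, so neighbourhood geometry scales: flanks and windows
  default to 5 kb in the synthetic configuration while the real-scale
  defaults (20 kb / 100 kb) remain in `thresholds`.

What the generator does **not** emulate: spatial array artifacts,
print-tip effects, dye-swap designs, correlated gene-gene noise, repeat
structure or isochores in the genome, and realistic binding-site width
distributions.  Passing tests therefore demonstrate the statistical
machinery under the stated noise model, not robustness to every artifact
of real arrays.

## Numerical choices and degenerate inputs

* Seeds: one master seed; each stage derives `seed + k` offsets, all well
  below 2³¹.  Same configuration ⇒ byte-identical report JSON.
* Ties in |d| are broken by stable ordering of the input gene list; q
  monotonization uses a running maximum down the |d| ranking.
* `tune_s0` returns 0 with a warning for a constant scatter vector; fewer
  than 10 usable genes also yield 0.
* Empty inputs: an empty gene list maps with rate 0 and a
  `rate_defined = FALSE` flag rather than NaN; zero motif hits genome-wide
  make the enrichment test undefined and raise a typed error.
* Truncation vs rounding matters only for printed per-gene rates and is
  truncation by definition (0.625 → 0.62).

## Problem sizes used by the test suite

The suite validates at sizes chosen to make each property sharp: exhaustive
permutation agreement on 50 genes × 6 samples (all 20 assignments); null
calibration and planted recall on the full 2000 × (4+3+3) design over 10
seeds; motif-scanner equality with the regex oracle on 100 × 10 kb
sequences; flank-enrichment null calibration over 50 genomes of 300 kb;
randomization-null convergence over 10 independent site placements;
overlap-test exactness over a sweep of tables with universes up to 200 and
500 null draws; and two full end-to-end runs for determinism.  These sizes
are the package's own validation choices — large enough for the binomial
and normal-theory bounds used in the assertions, small enough to keep the
suite quick on one CPU.

## Known limitations

* The multiclass F-like statistic is one-sided by construction; direction
  comes from the two-class stage, so a gene up in E2 but down in E2+ICI
  relative to control is classified by its E2 direction only.
* The permutation FDR inherits SAM's known conservativeness when a large
  fraction of genes carry very strong effects (the permuted statistics of
  those genes contaminate the null's tail).  The full-array two-stage
  scheme keeps that fraction realistic (~5%), where the effect is small.
* The binomial overlap test treats list membership as independent draws;
  the hypergeometric is exact and is reported alongside for every overlap.
* With windows of neighbouring genes overlapping, per-gene site counts are
  not independent across genes; the randomization null accounts for this
  by resampling genes, not sites, which is exactly why it is preferred to
  the binomial for the headline p-value.
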