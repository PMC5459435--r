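---
title: "Windowed 5hmC analysis of pooled hMeDIP-seq libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed 5hmC analysis of pooled hMeDIP-seq libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmedipr)
```

## The analysis problem

Hydroxymethylated-DNA immunoprecipitation sequencing (hMeDIP-seq) enriches
DNA fragments carrying 5-hydroxymethylcytosine (5hmC), so aligned-read
pileups are proportional to regional hydroxymethylation. A common design in
human epigenotoxicology pools many individuals into one library per
condition — for example one pooled sperm library from exposed donors and
one from controls — which leaves the analyst with exactly two libraries
and no replicates. `hmedipr` implements the complete downstream analysis
for this design:

1. **Windowed quantification.** The genome is tiled into fixed-width
   windows (default 100 bp). A read increments every window it overlaps by
   at least one base, and counts are converted to RPKM,
   $\mathrm{RPKM}_w = c_w / (\ell_w/10^3 \cdot N/10^6)$, with $\ell_w$ the
   window length and $N$ the number of mapped reads. A window is *covered*
   when any part of it is hit by at least one read.
2. **Immunoprecipitation QC.** Coverage saturation (correlation of window
   counts between random read subsets, extrapolated to a doubled library)
   and a CpG enrichment score (CpG density inside read-covered bases over
   genome-wide CpG density; 1 means no enrichment).
3. **Context profiles.** Covered fractions per chromosome and per gene
   part, CpG-density strata, CpG-island and promoter capture, repeat-class
   coverage, and strand-aware metagene profiles around transcription start
   sites.
4. **Differential windows (DhMRs).** A conditional negative-binomial exact
   test per window between the two libraries, with hyper/hypo
   classification.
5. **Annotation and gene-set statistics.** Primary-feature assignment,
   gene mapping, imprinted-promoter flags, and hypergeometric gene-set
   enrichment with Benjamini–Hochberg FDR control.

All interval algebra uses Bioconductor `GRanges` (1-based, closed)
internally; BED files are converted at the boundary by `rtracklayer`, so
on-disk coordinates follow each format's native convention.

## The exact test for two pooled libraries

With a single library per condition, window counts $a$ (control) and $b$
(case) are modeled as negative binomial with common dispersion $\varphi$
(variance $\mu + \varphi\mu^2$; $\varphi = 0$ is Poisson). Counts are
first placed on a common scale by dividing by geometric-mean-centered size
factors and rounding. Conditional on the adjusted total $t = a' + b'$, the
null distribution of $a'$ does not depend on the unknown mean: it is
$\mathrm{Binomial}(t, \tfrac12)$ for $\varphi = 0$ and the symmetric
negative-binomial conditional

$$
P(a' \mid t) \propto \binom{a' + r - 1}{a'}\binom{t - a' + r - 1}{t - a'},
\qquad r = 1/\varphi,
$$

for $\varphi > 0$. The two-sided p-value sums all outcome probabilities
not exceeding that of the observed split (the minimum-likelihood
convention). The test suite verifies this against `binom.test()` in the
Poisson limit and against edgeR's small-p exact test for positive
dispersion (agreement to $10^{-15}$); edgeR is used only as an
independent oracle, never as the implementation.

Because two pooled libraries cannot inform a dispersion estimate,
$\varphi$ is an explicit parameter of `dhmr_params()` (default 0.1, a
conservative value for pooled human data; 0 selects the Poisson test).
Windows at or below the raw p-value threshold (default 0.005) with
unequal adjusted counts are reported; tied windows have no direction and
are never called. A BH-FDR column is attached for transparency but does
not drive calling, and adjacent significant windows are not merged by
default, so DhMR counts are window-level counts.

The test operates on integer counts with size-factor adjustment, never on
RPKM: exact tests are only defined for counts, so RPKM values are
reported alongside each DhMR but are not themselves tested.

## What the simulator emulates — and what it does not

`simulation_config()` describes a desk-scale two-library study whose
defaults are fixed study conditions, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `chrom_sizes` | 2 × 500 kb | 10,000 windows of 100 bp |
| `read_length` | 51 bp | matches the pooled sperm libraries the package targets |
| `library_size_ratio` | 1.2297 | exposed/control total-read ratio of those libraries (44,263,854 / 35,995,280) |
| `depth_per_window` | 10 | expected reads per window per library |
| `dispersion` | 0.05 | NB dispersion of window counts |
| `n_hyper`, `n_hypo` | 50, 10 | planted differential windows |
| `fold_change` | 4 | planted effect size |
| `cgi_cpg_per_100bp` | 10 | CpG density inside islands (800 bp, grid-aligned) |
| `background_cpg_per_100bp` | 1 | Poisson background CpG density |
| `repeat_fraction` | LINE .10, SINE .08, LTR .04, DNA .03 | disjoint labeled repeats |

The original study does not state a dispersion, per-window depth or
effect size, so these defaults are declared choices: dispersion 0.05 and
depth 10–20 give count magnitudes where the exact test is neither trivial
nor hopeless, and fold 4 is a strong but realistic enrichment change.
Reads are placed by drawing a per-window count and then uniform start
positions inside the window, so reads overhang window edges and exercise
overlap counting; about half of 51-bp reads also touch the next 100-bp
window. Gene sets are sampled with controlled overlaps (the bivalent set
is exactly the H3K4me3 ∩ H3K27me3 intersection) so set-algebra reporting
is exercised.

Deliberately **not** emulated: sequence content (no FASTA/FASTQ, no
mapping error), fragment-length effects, GC or CpG-dependent
immunoprecipitation efficiency, and any spatial autocorrelation of 5hmC
beyond the planted windows. Two consequences matter when reading test
results. First, because background depth is homogeneous, window counts
carry little reproducible between-window variance, so saturation
correlations on simulated data are low (~0.2–0.4) even at full depth —
on real data, where biological heterogeneity dominates, the same
statistic approaches 1. Second, CpG sites are placed independently of
read placement, so the CpG enrichment score is ~1 by construction;
the score is validated on constructed cases where the true density ratio
is known exactly.

```{r quick-run}
report <- run_pipeline(pipeline_config(
  sim = simulation_config(seed = 42, depth_per_window = 20,
                          dispersion = 0.05),
  dhmr = dhmr_params(dispersion = 0.05)))
report
```

## Statistical behaviour on planted signals

Two properties of the caller are worth stating precisely, because both
are verified by the test suite and both follow from the model rather
than from implementation detail.

*Type-I error.* Under a null simulation (no planted windows, Poisson
counts, matched test), the fraction of windows called at p ≤ 0.005 stays
at or below 0.005: discrete exact tests are conservative at these counts.

*Power.* Sensitivity for a 4-fold planted window at depth 20 with
dispersion 0.05 and a matched-dispersion test is roughly 50% at
p ≤ 0.005, with two causes. The conditional test must absorb
negative-binomial noise on both counts — even without any overlap
effects, Monte-Carlo power for NB(30) vs NB(120) pairs is about 80%,
identically for this implementation and edgeR. On top of that, overlap
counting mixes each planted window's reads with spill-in from its
background neighbours (~50% of a neighbour's 51-bp reads cross the
boundary), diluting the effective fold from 4 toward 3. Recovered
windows carry the correct hyper/hypo label essentially always; what is
lost to noise is detection, not direction. Analysts who need higher
sensitivity at fixed depth should widen windows or merge adjacent calls
rather than lower the dispersion below what the data plausibly support —
an understated dispersion buys sensitivity at the price of false
positives.

## Numerical and design choices

* **Window classes.** CpG-density strata use integer bounds per 100-bp
  window: low = 0, moderate = 1–5 inclusive, high = ≥ 6, which partitions
  all windows exhaustively; bounds scale with non-default widths. CpG
  sites are counted by the C position of the forward-strand CG, so each
  palindromic CpG counts once.
* **Capture vs. base ratios.** Element capture (CpG islands, promoters,
  repeats) uses the any-part rule (≥ 1 bp overlap with a covered window);
  chromosome and gene-part statistics are base-resolution ratios over the
  union of each part type, so bases shared by overlapping genes count
  once. Both flavours are exposed because they answer different
  questions.
* **Promoters and TTS.** Promoter = 2 kb immediately upstream of the TSS,
  strand-aware, clipped at chromosome bounds; TTS region = 1 kb
  downstream of the transcription end. Both widths are parameters.
* **Primary-feature precedence.** promoter > 5′UTR > exon > 3′UTR > TTS >
  intron > intergenic. A precedence is required because a 100-bp window
  can straddle features of different genes; promoters rank first because
  they are the interpretive focus of promoter-centric 5hmC analyses.
* **Metagene profile.** Six 500-bp bins spanning TSS −2.5 kb to +0.5 kb,
  oriented 5′→3′ in transcription direction; bin values are
  base-weighted means of window RPKM, bins clipped entirely outside the
  chromosome are NA and drop out of set means.
* **Saturation estimate.** The headline number doubles each random read
  half by bootstrap resampling before the final correlation
  (an estimate for a library of the full input size on both sides); the
  half-vs-half "truncated" correlation is reported alongside.
* **CpG enrichment.** With CpG sites given as coordinates (the package's
  input format), the observed/expected formulation reduces algebraically
  to the same density ratio as the relH-style score, so a single score is
  reported. A sequence-composition-based variant would need the genome
  FASTA, which the pipeline deliberately does not require.
* **Degenerate inputs.** Zero-read libraries make RPKM and the QC scores
  undefined and raise errors rather than returning NaN; both-zero count
  pairs give p = 1; empty targets make coverage ratios an error while
  empty element lists report not-applicable.

## Problem sizes used by the test and acceptance runs

The default desk-scale genome (10,000 windows, ~100,000 reads per
library) runs the full pipeline in a few seconds. The test suite's
calibration checks use 20 replicate null simulations of 10,000 windows;
recovery checks aggregate five simulated studies; oracle-equivalence
checks run 1,000 randomized small instances per operation; the
hypergeometric test is compared against exhaustive enumeration for every
parameter combination up to a universe of 25. These sizes keep each
property estimate's Monte-Carlo error well below the asserted margins.

## Known limitations

* No replicate-aware inference: the package is built for the two-pooled-
  libraries design; with replicates, edgeR/DESeq2 GLMs are the right tool
  and this package's exact test is deliberately out of that scope.
* The dispersion is an assumption, not an estimate; results should be
  read as conditional on it.
* Window-level calling does not model spatial correlation; merged regions
  are available (`merge = TRUE`) but p-values are not recomputed for
  merged spans.
* Multi-transcript gene models must be collapsed to one model per gene
  before input; the simulator produces single-transcript genes by
  construction.
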