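# hmedipr

Genome-wide 5-hydroxymethylcytosine (5hmC) analysis for **pooled
hMeDIP-seq** designs: two libraries, one per condition, no replicates.
The package is aimed at epigenomics analysts who receive aligned reads
from hydroxymethylated-DNA immunoprecipitation sequencing — for example
pooled human sperm from an exposed and an unexposed donor group — and
need the full downstream chain: windowed quantification, enrichment QC,
context-stratified coverage statistics, differential region calling,
genomic annotation, and gene-set enrichment.

## What it computes

* **Window grid and RPKM.** The genome is tiled into 100-bp windows
  (configurable). A read increments every window it overlaps by ≥ 1 bp;
  counts become RPKM = count / (window kb × library millions). A window
  is *covered* when ≥ 1 read touches any part of it.
* **QC.** Coverage saturation (window-count correlation between random
  read subsets, extrapolated to a doubled library) and a CpG enrichment
  score (CpG density inside read-covered bases over genome-wide density;
  \>1 indicates successful enrichment).
* **Coverage profiles.** Covered fraction per chromosome and per gene
  part (promoter, 5′UTR, exon, intron, 3′UTR, TTS), CpG-density strata
  (low 0 / moderate 1–5 / high ≥ 6 CpG per 100 bp), CpG-island and
  promoter capture with mean RPKM, repeat-class coverage, and six-bin
  strand-aware metagene profiles over TSS −2.5 kb … +0.5 kb.
* **DhMRs.** Differentially hydroxymethylated 100-bp windows between the
  two libraries, tested with a conditional negative-binomial exact test:
  counts are scaled by geometric-mean-centered size factors and, given
  the adjusted total *t*, the null split is Binomial(*t*, ½) at
  dispersion φ = 0 or the symmetric NB conditional (a beta-binomial with
  shape 1/φ) at φ > 0; the two-sided p sums all outcomes no likelier
  than the observed one. Windows with p ≤ 0.005 (default) are classified
  hyper (case above control after normalization) or hypo.
* **Annotation and gene sets.** Primary genomic feature per DhMR
  (promoter > 5′UTR > exon > 3′UTR > TTS > intron > intergenic),
  DhMR-to-gene mapping with hyper/hypo/union counts, imprinted-promoter
  flags with parent-of-origin labels, repeat-class attribution, and
  hypergeometric overlap enrichment with Benjamini–Hochberg FDR.

A deterministic simulator (`build_toy_genome()`, `plant_dhmr_signals()`,
`simulate_reads()`, `write_fixtures()`) generates a complete toy study —
genome annotation, CpG landscape, repeats, gene sets, and two read
libraries with planted hyper/hypo windows under an NB count model — so
the entire pipeline is testable without any external data.

## Worked example

```r
library(hmedipr)

report <- run_pipeline(pipeline_config(
  sim  = simulation_config(seed = 42, depth_per_window = 20,
                           dispersion = 0.05),
  dhmr = dhmr_params(dispersion = 0.05)))
report
#> <hmedip_report>
#>   windows: 10000; reads: 199859 control / 249907 exposed
#>   genome covered: 100.0% control / 100.0% exposed
#>   QC: saturation 0.279/0.458, CpG enrichment 1.000/1.000
#>   DhMRs: 48 (39 hyper, 9 hypo) of 10000 tested windows
#>   affected genes: 10 (6 hyper, 4 hypo)
#>   planted-signal recall: 53.3% (direction accuracy 100.0%)

head(report$dhmr$table[, c("chrom", "start", "end", "count_control",
                           "count_case", "p_value", "direction")], 4)
#>   chrom start   end count_control count_case      p_value direction
#> 1  chr1 43901 44000            28        138 0.0003329302     hyper
#> 2  chr1 44001 44100            25        101 0.0029668025     hyper
#> 3  chr1 65801 65900            22        104 0.0009426107     hyper
#> 4  chr1 89001 89100           129         47 0.0009076217      hypo
```

Reading the output: this simulated study plants 50 hyper and 10 hypo
4-fold windows in a 1-Mb toy genome at 20 reads per window. The caller
finds 48 significant windows, every recovered window carries the correct
direction, and recall is ~53% — the expected sensitivity of a
matched-dispersion exact test at this depth and fold (see the methods
vignette for the power analysis). Saturation is low on simulated data
because background depth is homogeneous; on real data the same statistic
approaches 1. The per-window table is BED-compatible in its first three
columns; `run_pipeline(...(out_dir = ...))` writes every block
(QC, coverage, DhMRs, annotation, enrichment) as TSV.

Individual stages are ordinary functions (`make_windows()`,
`count_reads()`, `to_rpkm()`, `covered_windows()`,
`saturation_analysis()`, `cpg_enrichment_score()`, `call_dhmrs()`,
`assign_primary_feature()`, `dhmrs_to_genes()`, `overlap_report()`, …)
and accept BED/GFF3/TSV inputs via `read_fixture_bundle()` or
`rtracklayer`. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R` and YAML configs load with
`pipeline_config_from_yaml()`.

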