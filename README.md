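# clonephene

Tumors evolve under treatment: genetically distinct subclones expand,
collapse, and sweep through bottlenecks, and the survivors carry
phenotypes — mesenchymal shifts, receptor-tyrosine-kinase signaling,
immune avoidance — that can themselves be drug targets. `clonephene` is an
R toolkit for reconstructing that evolution from serially sampled bulk and
single-cell data and for connecting it to actionable phenotypes. It is
aimed at computational cancer-genomics analysts working with longitudinal
patient samples (pleural effusions, ascites, biopsies) profiled by WGS/WES,
scRNA-Seq, and drug-response assays.

The pipeline covers, end to end:

* **Purity correction** — gene-level absolute copy (`2^(n+1)` from log2
  ratios), centering of the 2-copy peak, and a multiplier search that
  stretches the profile until the most genes fall within 0.1 of the
  integer states 1, 3, 4; purity = 1/multiplier, and VAFs are rescaled
  accordingly.
* **Subclone reconstruction** — somatic (germline VAF < 0.001),
  copy-neutral mutations clustered by cross-timepoint presence
  (VAF ≥ 0.05), per-cluster consensus VAFs by kernel density estimation,
  cancer cell fractions CCF = 2×VAF (4× for pseudo-tetraploid genomes) or
  from CNA mixing `(mean − base)/(altered − base)`, exhaustive enumeration
  of subclone trees under the sum rule (children's CCFs ≤ parent's), and
  merging of per-timepoint trees into longitudinal histories under the
  evolutionary consistency rule.
* **Mutational signatures** — 96-channel pyrimidine-centered
  trinucleotide spectra, greedy forward-selection deconvolution against a
  signature catalog, APOBEC (TCW-motif) fractions, and a log-space pooled
  two-proportion test for between-subclone enrichment.
* **Single-cell CNA inference** — 101-gene windowed expression averaging
  against a normal-cell reference, survivor/disappearing region dynamics,
  per-cell subclone assignment, and expressed-SNV validation (≥10×
  coverage, max VAF > 0.2).
* **Phenotype screening** — ssGSEA enrichment scores per cell, t-test /
  one-way ANOVA screens over thousands of gene sets with rank plots of
  −log10 p, expressing-cell fraction tests.
* **Drug synergy** — fibroblast-background subtraction, DMSO
  normalization, 4PL IC50 fits (with honest "unmet" reporting), and Bliss
  independence `E = a + b − a·b` with a t-test on the observed excess.
* **Synthetic patients** — generators for variants, copy profiles,
  spectra, single cells, and dose-response plates with known ground truth,
  so the whole pipeline is testable without controlled-access data.

## A worked example

Simulate a four-timepoint patient with a truncal cluster, a parental
subclone, a dying branch, and a bottleneck subclone that sweeps to
CCF 1.0, then recover its history:

```r
library(clonephene)

cfg <- sim_config(
  clusters = data.frame(cluster = c("TR", "A", "B", "C"),
                        parent  = c("root", "TR", "A", "A"),
                        n_mut   = 200),
  ccf = rbind(TR = c(1, 1, 1, 1), A = c(0, .85, 1, 1),
              B = c(0, .35, 0, 0), C = c(0, 0, .5, 1)),
  purity = rep(1, 4))

sim <- simulate_variants(cfg, seed = 42)
vt  <- filter_copy_neutral(filter_somatic(sim$variants), "diploid")
cc  <- cluster_ccfs(cluster_by_presence(vt), "diploid")
round(cc$ccf, 2)
#>      t1   t2   t3   t4
#> C1 0.00 0.00 0.48 1.00
#> C2 0.00 0.84 1.00 1.00
#> C3 0.96 1.00 0.97 0.95
#> C4 0.00 0.34 0.00 0.00

histories <- merge_timepoints(timepoint_structures(cc$ccf))
length(histories)
#> [1] 1
histories[[1]]$trees[[4]]$parent
#>     C1     C2     C3
#>   "C2"   "C3" "root"
```

The recovered CCF matrix tracks the simulated truth (C3 is the truncal
cluster at CCF ≈ 1 throughout; C4 is the dying branch, present only at
t2; C1 is the bottleneck rising from CCF 0.5 to 1.0), and exactly one
longitudinal history is consistent across all four timepoints — the true
one, with the bottleneck C1 nested inside C2 under the truncal C3.

A CNA-based CCF, the relation behind the tree arithmetic:

```r
ccf_from_cna(mean_copy = 2.5, base_copy = 2, altered_copy = 3)
#> [1] 0.5
```

A region averaging 2.5 copies, where carriers have 3 and non-carriers 2,
is carried by 50% of cancer cells.

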