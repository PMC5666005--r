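---
title: "Reconstructing tumor clonal evolution and its phenotypes with clonephene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing tumor clonal evolution and its phenotypes with clonephene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonephene)
```

`clonephene` reconstructs the subclonal evolution of a tumor sampled
repeatedly over years of treatment, characterizes the mutational processes
and expression phenotypes of the subclones, and quantifies drug-combination
synergy against cells carrying those phenotypes. This vignette explains the
models behind each stage, the parameters that matter, and the choices made
where the methods left room.

## From read counts to cancer cell fractions

A somatic mutation present in a fraction of tumor cells shows up in bulk
sequencing as a variant allele frequency (VAF): the fraction of reads at
the locus carrying the mutant allele. For a heterozygous mutation at a
copy-neutral locus in a diploid genome, a mutation carried by a fraction
`CCF` of cancer cells in a sample of purity `p` has expected VAF

```
E[VAF] = p * CCF / 2
```

(with 4 in place of 2 for a genome-doubled, pseudo-tetraploid tumor). The
pipeline inverts this relation in three steps.

**Purity from copy-number peaks.** A pure aneuploid tumor has gene-level
absolute-copy peaks at the integers; normal contamination shrinks every
peak toward 2. Gene-level log2 ratios are converted to absolute copy as
`2^(n+1)`, the dominant peak is centered at exactly 2 (Gaussian KDE,
Silverman bandwidth, 0.01 grid over [0, 8]), and the profile is stretched
around the 2-axis as `c' = 2 + m (c - 2)` over a multiplier grid
`m = 1.00, 1.01, ..., 5.00`. The multiplier that places the most genes
within 0.1 of the states 1, 3 and 4 is kept, and purity is `1/m`. The grid
and the peak-finding bandwidth are choices of this package: the grid bounds
detectable purity at 0.2 and its 0.01 step bounds the resolution error near
purity 1 at under 1%; ties resolve to the smallest multiplier so the
correction is never larger than the data demand. Raw VAFs are multiplied
by `m`, capped at 1 (the cap is a choice; over-correction past 1 has no
biological reading). A profile with essentially no genes away from 2
copies is refused rather than guessed at: without aneuploid peaks the
multiplier is unidentifiable.

**Presence clustering and consensus VAFs.** Somatic mutations (germline
VAF strictly below 0.001) at copy-neutral loci (absolute copy 1.5-2.5, or
3.6-4.4 in the tetraploid mode, bounds inclusive) are grouped by the
pattern of timepoints in which they are present, presence meaning adjusted
VAF at least 0.05. Each cluster's per-timepoint consensus VAF is the mode
of a Gaussian KDE (Silverman bandwidth, 0.005 grid on [0, 1]); a secondary
local maximum reaching half the main peak's density is flagged, since a
bimodal cluster hints at sub-clusters, but is not split automatically --
the split rule would be arbitrary and the flag keeps the analyst in the
loop. Clusters are ranked by size; those under `min_cluster_size`
(default 20) are reported but kept out of tree building, where their noisy
CCFs would multiply spurious structures. CCF is then `min(1, 2 * VAF)`
(or `4 *`). When a cluster's KDE consensus is unreliable -- a subclone at
very low CCF, or one better measured by a clonal copy-number gain -- a
per-cluster override can supply the CCF directly, e.g. from the mixing
relation `(mean_copy - base) / (altered - base)` (a region averaging 2.5
copies where carriers have 3 means half the cells carry it).

**Trees under the sum rule.** Subclones nest: the cells carrying a child
cluster are a subset of those carrying its parent, so at every timepoint
the CCFs of a node's children cannot sum past the node's own CCF. All
parent assignments (each cluster under the root, CCF 1, or under another
cluster) satisfying this within a tolerance are enumerated exhaustively
(bounded at 12 clusters; beyond that, pre-merge clusters). The tolerance
defaults to 0.05 CCF: at 60x depth a cluster of ~200 mutations carries a
consensus-VAF standard error near 0.01-0.02, and CCF doubles it. All
sum-rule comparisons carry an extra 1e-9 slack because consensus VAFs live
on a 0.005 grid and CCF doubling regularly produces exact boundary ties
that raw floating-point comparison would break arbitrarily. Trees are
reported sorted by total sum-rule residual, then by depth (shallower
first); this ranking is a reporting convention, not a claim about which
tree is real.

**Merging timepoints.** Ancestry is a permanent fact of a lineage: once
cluster B arises inside cluster A's cells, every later cell with B also
has A. A combination of per-timepoint trees is therefore kept only if
(i) every pair of clusters present in two trees stands in the same
ancestor/descendant/unrelated relation in both, and (ii) a cluster's
ancestor is present wherever the cluster is. The surviving combinations
are the consistent longitudinal histories; when none survives, the
per-pair conflicts are reported instead.

## Mutational signatures

Each SNV is classified into one of 96 channels by its substitution and
flanking bases, reverse-complementing purine-centered triplets so both
strand representations of a mutation share a channel. Spectra (channel
proportions) are deconvolved against a signature catalog by greedy forward
selection: starting from zero weights, the single signature whose weight
update most reduces the squared reconstruction error is updated, under
non-negativity and total weight at most 1, until the error improvement
drops below `1e-3`; final weights under `0.06` are zeroed without
renormalizing and the unassigned remainder is reported as unknown/other.
Both constants follow the published defaults of the standard greedy
deconvolution approach. A consequence worth knowing: a modest contribution
from a nearly flat profile improves the fit by less than the stopping
threshold and is absorbed into unknown/other; concentrated profiles (like
the APOBEC-type ones) do not suffer this. The 0.03 grouping used in
figure-style summaries is display-level and not applied to the weights.

APOBEC-associated mutations are operationalized as C>T or C>G changes at
the TCW motif (W = A or T), the canonical APOBEC3 target; the motif set is
an argument, since "APOBEC-associated" has no single fixed definition.
Between-group enrichment uses a pooled two-proportion z test without
continuity correction (so z^2 equals the 1-df chi-square statistic), with
the p-value computed in log space so that contrasts this strong remain
reportable far below double underflow.

Because the real 30-signature catalog is distributed by its curators and
not re-shipped here, the package generates a synthetic catalog of the same
shape (`simulate_catalog()`): two profiles concentrate on the APOBEC TCW
channels, one is flat (the near-uniform spectrum characteristic of
homologous-recombination deficiency), and the rest are sparse fixed random
profiles. Any catalog with 96 rows and unit column sums drops in.

## Single-cell CNAs and subclone assignment

Cells are first filtered on the standard quality bounds: at least 1700
genes detected and at least 150,000 mapped reads ("fewer than" excludes
strictly below the bound, so boundary cells pass). A cell's relative-copy
track is the per-gene `log2(TPM + 1)` deviation from the mean of normal
reference cells, clipped to +/-3, averaged over a 101-gene moving window
within each chromosome, then median-centered per cell. The window width is
the method's defining constant; clipping and median centering follow the
established expression-based CNA inference recipe. Median centering makes
the track exactly invariant to global per-cell scaling, so library-size
differences cannot masquerade as CNAs. Only genes with a full window are
kept -- shrinking windows at chromosome ends would mix noise levels across
the track.

A region whose bulk copy sits strictly between the baseline and altered
states before treatment and then moves toward the altered state by at
least `delta` (default 0.3 copies) marks the surviving subclone; movement
back to baseline marks a disappearing one. Cells are scored per region by
their mean track signal -- using only windows lying entirely inside the
region, because windows straddling the region edge mix carrier and
neutral genes and dilute the signal (regions narrower than a window fall
back to window centers). The present/absent threshold is the midpoint of
a two-component Gaussian fit to the pre-treatment cells' region scores,
with a dead zone of 0.25 x the component separation scored as ambiguous;
a cell's label is the majority vote over informative regions, ties giving
ambiguous. Expressed-SNV validation requires at least 10x coverage in a
cell to call it, calls mutant on any alternate read, and ignores SNVs
whose VAF never exceeds 0.2 in any cell.

Cells without CNAs at all -- mesothelial, fibroblast and immune cells in
an effusion -- are triaged by track flatness before any subclone work:
each cell's windowed track variance is compared with a permutation null
made by shuffling that cell's own gene-level deviations (which preserves
per-gene noise but destroys regional structure), and a cell that does not
exceed the null's 95th percentile shows no evidence of copy alteration
and is flagged normal. The quantile is a calibration choice of this
package: the null is exact per cell, so the flag's false-cancer rate is
the chosen tail mass.

## Pathway screening

ssGSEA scores each cell against each gene set from expression ranks
alone: genes are sorted by decreasing expression (ties broken by stable
gene order -- the score depends on it, so the order is documented
behavior), in-set genes advance a running sum by their rank weight to the
power `tau = 0.25` normalized over in-set genes, out-of-set genes advance
a uniform complement, and the enrichment score integrates the difference.
Scores are therefore invariant under any strictly increasing per-cell
transform of expression. Raw scores are used for testing (the optional
min-max normalization is display-only). Sets overlapping the measured
genes by fewer than 5 genes are skipped and recorded.

Screens compare scores between two groups by two-tailed Student's t-test,
or across more groups by one-way ANOVA. P-values are deliberately not
adjusted for multiple comparisons; instead every set receives a rank
(most significant = highest rank) and the lowest-5% band is flagged,
matching the rank-plot convention. Expressing-cell fractions (expression
strictly above 0) are compared with the same pooled z test as the
signature enrichment. Fold-change heatmaps share a single pseudo-count --
the minimum nonzero value over the gene list -- so zero baselines stay
finite without per-gene distortion.

## Drug response and Bliss synergy

Plates carry a cancer + fibroblast condition and a fibroblast-only
background. Cancer-only viability at dose d is
`100 * (CF_d - mean(F_d)) / (mean(CF_vehicle) - mean(F_vehicle))`.
Dose-response curves are four-parameter logistics fit by
Levenberg-Marquardt least squares, initialized from data quantiles and
bounded (top 50-150%, bottom -10-60%, hill slope in (0, 10]); the IC50 is
reported "unmet" when the fit fails, the curve never crosses 50% in the
tested range, or the fitted IC50 exceeds the top tested dose --
extrapolated potency is not reported. Bliss independence is computed on
inhibition fractions `i = 1 - viability/100`, where `E = a + b - a*b` is
an actual independence model (viability-space "Bliss" is not); the
observed combination replicates are compared against `E` by a two-sided
one-sample t-test, treating the single-agent means as fixed; a two-sample
variant (`two_sample = TRUE`) instead compares against per-replicate
expectations and propagates single-agent uncertainty. The signed excess
(observed minus expected inhibition) is positive for synergy.

## The synthetic-data generator

Every stage is exercised against `simulate_*` generators whose defaults
encode the study conditions: 60x mean depth (Poisson), binomial read
sampling, per-timepoint purity entering VAFs as `p * CCF / f`, germline
SNPs at VAF 0.5 regardless of purity, bulk copy mixing
`p * copy + (1 - p) * 2` with 0.05-SD gene-level noise, log-normal
single-cell expression (gene means log2 ~ N(4, 1.5), per-cell SD 0.8)
with CNA blocks scaling TPM by `copy/2`, uniform dropout (default 0.2,
the plausible rate for the moderately expressed genes retained for CNA
inference on a full-length single-cell platform), and 4PL plates with
additive fibroblast background and Gaussian replicate noise. One seed per
generator call makes each stage independently reproducible.

Test problem sizes are chosen at desk scale: purity recovery uses 20
profiles of 5000 genes; tree recovery a four-timepoint patient with four
clusters of 200 mutations; signature recovery 10,000 drawn mutations;
the cell-assignment study 200 tumor cells with two 150-gene 1.5x CNA
blocks per subclone (subclones in this setting typically carry several
co-occurring CNAs, and a single 150-gene block at 1.5x sits near the
information floor of a 101-gene window under dropout); the screening
study 500 decoy sets against one planted one-SD shift.

What passing these tests does and does not show: the generator draws
independent reads and cells, has no sequencing batch structure, no
expression-level-dependent dropout, no doublets, and its signature
catalog is synthetic. Recovery under these conditions demonstrates the
estimators are implemented correctly and calibrated at realistic noise,
not that real tumors meet the models' assumptions.

## Known limitations

Presence clustering cannot separate subclones sharing a presence pattern
unless their VAF modes differ enough for the bimodality flag; continuous
mixture deconvolution is out of scope. Exhaustive tree enumeration is
exponential and bounded at 12 clusters. The greedy signature fit can
park small flat-profile contributions in unknown/other, as noted. The
two-component region split assumes both carrier and non-carrier cells
exist pre-treatment -- a region fully clonal before treatment is not
informative for assignment and should be labelled uninformative.

## A worked end-to-end example

```{r example, eval = FALSE}
cfg <- sim_config(
  clusters = data.frame(cluster = c("TR", "A", "B", "C"),
                        parent = c("root", "TR", "A", "A"),
                        n_mut = 200),
  ccf = rbind(TR = c(1, 1, 1, 1), A = c(0, .85, 1, 1),
              B = c(0, .35, 0, 0), C = c(0, 0, .5, 1)),
  purity = rep(1, 4))
sim <- simulate_variants(cfg, seed = 42)
vt <- filter_copy_neutral(filter_somatic(sim$variants), "diploid")
cc <- cluster_ccfs(cluster_by_presence(vt), "diploid")
histories <- merge_timepoints(timepoint_structures(cc$ccf))
length(histories)  # 1: the true history, uniquely
```
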