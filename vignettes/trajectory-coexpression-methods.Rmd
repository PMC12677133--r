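---
title: "Methods: ranking coexpressed genes along a diffusion-pseudotime lineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking coexpressed genes along a diffusion-pseudotime lineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajrank)
```

# The problem

Olfactory sensory neurons (OSNs) mature along a well-defined lineage —
globose basal cells (GBC) to immediate neuronal precursors (INP) to
immature (iOSN) and mature OSNs (mOSN). Accessory proteins such as the
receptor-transporting protein Rtp1 are induced along this axis and are
required for odorant receptors (ORs) to reach the cell surface. Genes that
are *coregulated* with such a reference gene across maturation are natural
candidates for the same pathway. `trajrank` ranks every gene in a
single-cell RNA-seq dataset by how closely its expression trajectory along
a continuous maturation axis tracks a chosen reference gene, and annotates
the candidates with onset timing, cell-type enrichment, and external
regulatory-network and differential-expression evidence.

# The procedure

## QC, normalization, gene exclusion

Cells are scored by total counts and mitochondrial fraction (symbol prefix
`mt-` by default) and filtered at `max_mito = 0.2` and `min_counts = 500`.
These two thresholds are stated defaults, not derived quantities: common
droplet-data practice, always echoed in the run log so the effective QC of
any run is auditable. Counts are then depth-normalized to 10,000 per cell
and log-transformed (`log(1 + x)`), the standard variance-stabilizing
sequence for UMI data; "log counts" throughout this package means log1p of
the depth-normalized values, which is the usual single-cell convention.

Two kinds of gene exclusion are distinguished. Mitochondrial and `Malat`
transcripts are removed *globally* — they carry technical rather than
developmental signal. OR genes (patterns `Olfr` and `Or` + digit, with a
whitelist escape, since no exhaustive list is bundled) are excluded *only
from the embedding*: the one-receptor-per-neuron mosaic would otherwise
shred the maturation manifold, but their trajectories remain interesting
and stay available downstream. Symbol matching is case-sensitive, with an
optional uppercase normalization in the GMT reader for mixing human and
mouse conventions.

## Embedding and pseudotime

Highly variable genes are chosen by binned normalized dispersion
(variance/mean, z-scored within 20 mean-expression bins; constant genes can
never be selected). PCA (40 components, genes centered and unit-scaled) is
followed by a k-nearest-neighbor graph (k = 10, Euclidean, union
symmetrization) with an adaptive Gaussian kernel whose per-cell bandwidth
is the distance to the ceiling(k/2)-th neighbor.

The diffusion operator is built with anisotropic density normalization
(exponent 1): the kernel is divided by the degree on both sides, then row
normalized. Its leading eigenpairs are obtained through the symmetric
conjugate operator with a deterministic block orthogonal iteration
(analytic start basis, Rayleigh–Ritz extraction, tolerance 1e-12): results
are bit-reproducible without touching the RNG, and on small problems agree
with a dense eigensolver to 1e-8, which the test suite checks. The
stationary eigenvector is dropped and 15 diffusion components kept.

Pseudotime is the Euclidean distance from a root cell in the diffusion
space scaled by `lambda / (1 - lambda)` per component (the accumulated
transition operator), rescaled to [0, 1]. The root is the cell of the
progenitor (GBC) cluster maximizing mean marker expression (ties resolve
to the smallest barcode); without markers, the cluster cell extremal in
the first diffusion component. Branch detection is deliberately absent:
the lineage analyzed here is a single linear maturation axis.

## Binned trajectories and the four count forms

Pseudotime is cut into 50 equal-width bins (0-based ids; the last bin is
right-closed). Equal-width was chosen over equal-count as the default so
that bins have a fixed pseudotime meaning; equal-count binning can be
emulated by transforming pseudotime ranks upstream. Each gene's trajectory
is the per-bin mean of its expression. Bins with fewer than `min_cells_bin
= 3` members are filled by linear interpolation between the nearest
well-populated bins (constant extension at the ends) and flagged — keeping
every trajectory the same length is what makes RMSE values comparable
across genes, which is why interpolation was preferred over dropping bins.

Four representations ("count forms") of each trajectory are ranked:

* `NORM` — depth-normalized counts,
* `LOG` — log1p of those,
* `NORM_MAX`, `LOG_MAX` — the same divided by the gene's maximum over bins.

Max-scaling is applied to the *binned trajectory* (one row maximum per
gene), not to per-cell values: each form must yield a single trajectory
per gene so that one RMSE per gene per form exists. The max-scaled forms
compare trajectory *shape* regardless of expression magnitude; the
unscaled forms retain magnitude. Genes with all-zero trajectories cannot
be max-scaled; they are flagged and excluded from the max-scaled forms
only.

## RMSE ranking and integration

For gene g and reference r with binned trajectories $x_g, x_r$ over B
bins, under each count form:

$$\mathrm{RMSE}_g = \sqrt{\tfrac{1}{B}\sum_{b=1}^{B} (x_{g,b} - x_{r,b})^2}$$

The reference scores exactly 0 and rank 1 in every form, on any input —
the structural anchor the test suite asserts. Ranks are ascending with
lexicographic tie-breaks.

The four rankings are integrated without favoring any normalization: a
gene's `topk_hits` counts the forms (0–4) in which it is within the top k
(default 50), and `mean_rank` is the arithmetic mean of its four ranks.
Final ordering is descending `topk_hits`, then ascending `mean_rank`, then
symbol. This concrete integration rule is this package's design choice
(several reasonable aggregations exist); both sub-orderings are exposed as
columns so users can re-rank. Genes missing from the max-scaled forms are
averaged over the forms they have and flagged. An optional antiregulation
screen reports RMSE against the vertically flipped max-scaled reference
(`1 - x̂_r`) in a separate column — the simplest reading of "antiregulated"
consistent with max-scaled trajectories.

Pan-neuronal genes — broadly neuronal rather than olfactory-specific, e.g.
the top neuron-enriched genes of an olfactory-bulb dataset computed with
`enrichment_scores()` — are flagged and removed from the candidate
ordering but kept in the table with their RMSE values intact.

## Onset timing, enrichment, and external evidence

Onset is scored by the trapezoidal area under the max-scaled trajectory
(`LOG_MAX` by default; configurable since either max form is defensible),
normalized by the midpoint span: a constantly-on gene scores 1, a gene
switching on midway about 0.5, so larger AUC means earlier onset. Genes
are split into early/mid/late onset terciles (boundaries at the 1/3 and
2/3 AUC quantiles; the tercile split and the boundary-to-earlier-class
rule are package choices, as no canonical thresholds exist).

Cell-type enrichment per gene is `log2((mean_target + eps)/(mean_rest +
eps))` with `eps = 1e-9` (avoids infinities while preserving order) plus a
two-sided Wilcoxon rank-sum p-value and BH FDR; the "top enriched" list is
the top `n_top` by fold change among FDR < 0.05 genes. Over-representation
of a selection in gene sets uses the one-sided hypergeometric upper tail
with BH correction across sets; gene sets come from user-supplied GMT
files (no annotation downloads, no term semantics). Pearson correlation
between AUC and an external DE table's logFC quantifies the
onset-vs-stress-enrichment relationship.

Network evidence consumes a regulatory edge list (e.g. an ARACNE
mutual-information network): self-loops dropped, duplicate pairs collapsed
to the maximum weight, and each candidate scored by the number of distinct
curated ER-stress transcription factors (Atf5, Atf6, Ddit3, Ebf1–4,
Nfe2l2, Xbp1) adjacent to it. Edges count in both orientations by default
because mutual information is symmetric; a directed mode exists. DE
overlays only *annotate* (flag + logFC); the evidence layer never reorders
or removes candidates, because no principled composite weighting formula
exists for these heterogeneous sources — flags and counts are exposed and
the weighting is left to the analyst.

# The simulator

`simulate_lineage()` generates the study conditions every recovery claim
in the test suite is measured under: 3,000 cells and 2,000 genes by
default, latent time t ~ Uniform(0,1), stages cut at 0.25/0.5/0.75
(GBC/INP/iOSN/mOSN), and counts NB(mean = L_c · mu_g(t_c), dispersion phi
= 0.3) with log-normal library-size factors (sdlog 0.3). Gene programs are
sigmoid-on/off (`A/(1 + e^{∓s(t - t_0)}) + baseline`), Gaussian pulses, or
constants, with parameters recorded per gene so oracles are closed-form.
The negative binomial is the standard UMI count model; dispersion is
shared across genes for simplicity (per-gene override available).

Planted structure:

* the reference gene (named `Rtp1`) is sigmoid-on at t0 = 0.35, slope 12,
  amplitude 4 — an early-onset maturation program;
* 25 *coregulated* genes share its (t0, slope) within small jitter (SD
  0.015 on onset, 5% on slope) and amplitudes within ~15% log-jitter —
  coexpression is about shape, but the unscaled forms also see magnitude,
  so realistic coregulation keeps amplitudes in the reference's
  neighborhood;
* 30 pan-neuronal genes: maturation-onset programs with broadly varying
  timing (t0 in 0.2–0.55), the kind of genes a bulb dataset flags;
* 100 OR-like genes (`Olfr...`): zero outside the mature stage, and each
  mature cell expresses exactly one of them at high amplitude (the chosen
  receptor's draw is floored at 5 counts so the mutual-exclusivity
  invariant is exact);
* 10 mitochondrial genes at housekeeping levels, with 3% damaged cells
  whose mitochondrial means are inflated far past the QC threshold;
* 5 GBC marker genes (sigmoid-off at t0 = 0.15) anchoring root selection.

The `shuffled` planted mode is the negative control: the same 25 flagged
genes are re-drawn from dynamics far from the reference's onset window
(sigmoid-off and late pulses). A literal random re-assignment of templates
would leave each flagged gene a few-percent chance of resembling the
reference by coincidence, making "the control recovers nothing" a coin
flip rather than a property; redrawing away from the reference makes the
control deterministic in spirit and still destroys exactly what the
positive condition plants.

What the simulator does *not* emulate: empirical depth/dropout profiles of
real droplet chemistry, batch effects, doublets, ambient RNA, or branching
lineages. Passing recovery tests therefore demonstrates that the method
does what it claims under its own assumptions (smooth programs on a 1-D
manifold, NB noise), not that any particular biological dataset will rank
a given gene highly.

# Validation and problem sizes

The test suite checks, among ~340 assertions: exact RMSE closed forms and
scale/symmetry properties; PCA against a dense covariance
eigendecomposition; kNN lists against exhaustive distance sorts; diffusion
eigenpairs against a dense eigensolver (1e-8, fixtures ≤ 100 cells); bin
means against brute-force group-by; the hypergeometric ORA p against
exhaustive draw enumeration; BH against a brute-force step-up; rank-sum
p against all 70 permutations of a 4-vs-4 fixture; and NB moments of the
simulator against their closed forms.

End-to-end, on three seeds of the default simulator: ≥ 80% of planted
coregulated genes appear in the integrated top-50 (typically 23–24 of 25)
while the shuffled control recovers 0; Spearman correlation between
computed pseudotime and true latent time exceeds 0.9 (typically > 0.99);
AUC anti-correlates with true onset time (Spearman ≤ −0.9); and
bulb-derived pan-neuronal exclusion empties the top-50 of planted
pan-neuronal genes. `scripts/acceptance.R` recomputes all of these from
scratch at the default problem size (3,000 × 2,000, three simulation
seeds plus three shuffled controls — a few minutes of compute, chosen so
the full validation is cheap to rerun).

# Numerical and degenerate-input choices

* Eigen-iteration: fixed analytic start (`sin` ramp), spectral shift +1 so
  the largest algebraic eigenvalues dominate, Ritz re-sort every 5 steps;
  a warning (not silent acceptance) if the iteration cap is hit.
* Cells with zero totals get `mito_frac = 0` and a flag; depth
  normalization refuses zero-total cells by barcode name.
* Duplicate barcodes or symbols, negative counts, disconnected graphs
  (component sizes named), empty root clusters (available clusters named),
  and all-cells-removed QC all fail fast with actionable messages.
* Degenerate bandwidth (duplicate points) falls back to the smallest
  positive neighbor distance.
* All-equal AUCs put every gene in one onset class rather than splitting
  arbitrarily.

# Limitations

RMSE to a single reference is sensitive to the reference's own noise at
low expression; the four-form integration mitigates but does not remove
this. The integration rule (top-k hits, then mean rank) is one reasonable
choice among several — both ingredients are exported. Absolute RMSE values
depend on bin count, bin scheme, and empty-bin policy, so cross-study
comparisons of raw RMSE numbers are not meaningful; ranks are the stable
output. The pipeline assumes one linear trajectory; branching data needs
upstream subsetting to a single path.
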