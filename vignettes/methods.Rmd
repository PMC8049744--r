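---
title: "Models, assumptions and design decisions in hydrareg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, assumptions and design decisions in hydrareg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`hydrareg` implements the statistical pipeline for asking when head
and foot regeneration programs diverge after bisection: differential
testing of RNA-seq and ATAC-seq counts, the regeneration context
effect, TCF-dependence classification, motif deviation scores, IDR
peak consensus with QC, enrichment statistics, and a four-criteria
candidate-TF screen. Because the real sequencing data are not
reproducible at desk scale, everything is validated against a
synthetic generator with planted ground truth. This vignette records
the models, the tunable parameters, and every place where the design
was genuinely open and we had to choose.

# The count model and differential testing

Both assays are modelled as negative-binomial counts,
$X_{gj} \sim \mathrm{NB}(\mu_{gj}, \phi_g)$ with
$\log \mu_{gj} = \log(\text{effective library size}_j) + x_j^\top
\beta_g$. We use the group-means parameterisation: one coefficient per
structure × timepoint × treatment cell, so every reported quantity is
a contrast of cell means. Fitting and testing are delegated to edgeR's
quasi-likelihood pipeline (`estimateDisp` with prior df 10,
`glmQLFit`, `glmQLFTest`): the study names that model family
explicitly, and re-deriving an NB-QL fitter would duplicate a mature,
heavily validated implementation. Our own code owns everything around
it — filtering, TMM factors, contrast construction, BH adjustment —
and the contract we test is *calibration* (null p-values uniform,
KS < 0.03 at 2,000 features) and *recovery* (sensitivity ≥ 0.8 at
empirical FDR ≤ 0.05 for planted |log2FC| ≥ 2 with 3 replicates), not
numerical identity with any specific tool version.

Key thresholds (all study-stated, all defaults in `run_config()`):

| parameter | default | meaning |
|---|---|---|
| RNA filter | ≥ 2 CPM in ≥ 3 samples | low-expression filter |
| ATAC filter | ≥ 10 CPM in ≥ 3 samples | low-accessibility filter |
| RNA FDR | 1e-3 | significance for transcripts |
| ATAC FDR | 1e-4 | significance for peaks |
| IDR cut | 0.1 | reproducible-peak threshold |
| min pairs | 3 | pairwise comparisons needed for consensus |
| peak width | 250 bp | fixed width for motif recounting |
| SC cutoff | 1e-6 | adjusted p for single-cell enrichment |

The CPM boundary is *inclusive* (a peak with exactly 10 CPM in exactly
3 samples is kept); the stated rule ("at least ... in at least ...")
reads naturally as ≥, and we record that reading here.

TMM normalisation is our own implementation of the trimmed mean of
M-values (30% two-sided M trim, 5% A trim, precision weighting,
geometric-mean centring); tests verify it against both a hand-computed
toy and `edgeR::calcNormFactors` to 1e-8. TMM matters in the synthetic
world for exactly its textbook reason: when 10–20% of the library is
planted upward at 3 hpa, raw CPM carries a composition bias of several
tenths of a log2 unit which TMM's trimming removes.

**Context effect.** `delta = log2FC_H(t vs 0) − log2FC_F(t vs 0)`,
positive = head-specific, tested by the QL F-test on the
difference-of-differences contrast `(H_t − H_0) − (F_t − F_0)`. The
published legend describes the subtraction in words that contradict
its own sign convention ("positive = head-enriched"); we follow the
sign convention. Because both log2FCs come from the same fit, `delta`
equals their difference exactly (asserted to 1e-12 in tests).

**Design without batch terms.** Whether the original analysis included
replicate batch factors is not stated; we default to the pure
structure:timepoint:treatment cell-means design. Replicates in the
generator are exchangeable, so a batch term would only spend df.

**TCF classes.** "Not significantly upregulated" under iCRT14 uses the
same FDR ≤ 1e-3 cutoff as every other transcript-level call; the
source implies but never states this, and using a single cutoff keeps
the three-way classification mutually exclusive by construction.

**Wilcoxon.** The single-cell head/foot enrichment uses the two-sided
rank-sum test: exact enumeration when min(n) ≤ 25 and there are no
ties, otherwise mid-ranks with tie-corrected variance and continuity
correction. Exactness is validated against full label enumeration for
n ≤ 8.

# IDR and peak consensus

Scores are reduced to ranks, pushed through the shifted empirical CDF
`u = rank/(n+1)` (the shift avoids infinite pseudo-values), and mapped
to pseudo-values `z = G⁻¹(u)` where `G` is the *current mixture
marginal* — recomputed every EM iteration. This self-consistent
transform is essential: with a fixed `qnorm(u)` transform, the noise
component's "standard normal" assumption is violated whenever a
reproducible component exists, and the mixing proportion cannot be
recovered (we measured ~0.27 for a true 0.5). With the self-consistent
transform, recovery at 5,000 peaks is within ±0.02.

Numerical choices: 5 EM grid starts, convergence |Δ log-likelihood| <
1e-6 or 500 iterations; reproducible-component floors mu ≥ 0.5 and
rho ≥ 0.2. The floors resolve a genuine degeneracy — on fully
irreproducible input the two components can collapse onto each other,
after which the posterior (and hence IDR) is meaningless and can drift
toward "everything reproducible". A fit that *lands on* the floors is
reported as fully irreproducible (`pi_noise = 1`, all local IDR 1).
The cost is that genuinely weak reproducible components (mu < 0.5 on
the pseudo-value scale) are conservatively discarded; at the study's
signal strengths fitted mu is ≈ 1.2.

Peak identity across replicates uses ≥ 50% reciprocal overlap against
merged reference regions, ties broken by larger overlap then lower
start coordinate; consensus coordinates are the union over matched
member peaks. The upstream pipeline the study delegated this to does
not document its parameters, so these are recorded package decisions.
A group's consensus requires IDR ≤ 0.1 in ≥ 3 pairwise comparisons;
with exactly 3 replicates that means all 3 pairs, reading the stated
rule literally. IDR ranks peaks by the narrowPeak signal-value column
(column 7); the original score column is unstated.

Pseudo-replicates split each peak's pooled read weight
Binomial(w, 1/2). The split score correlation — and therefore the
usefulness of the self-consistency/rescue ratios — comes entirely from
the spread of peak weights: binomial noise is ~√w while real peak
strengths span orders of magnitude. The QC stage therefore draws
weights log-uniform over ~2⁴–2¹².

TSS enrichment: per-gene profiles over ±1 kb are averaged, normalised
by the mean of the two outermost 100-bp flanks, smoothed with a 21-bp
running mean, and scored as the maximum within ±50 bp of the TSS. The
generator plants a Gaussian accessibility bump (sd 50 bp) whose centre
is `enrichment ×` the flank rate, so the score is directly
interpretable as fold enrichment.

# Motif deviations

For motif *i* and sample *j*,
`raw_ij = (X_ij − E_ij)/E_ij` with
`E_ij = (Σ counts in motif peaks / grand total) × sample total`.
Background iterations replace each peak with one of its k = 50 nearest
neighbours in standardised (GC, log relative depth) space; z-scores
centre and scale `raw` by the 50 background deviations. Constants
(k = 50 neighbours, 50 iterations) are the cited tool's defaults.

Two implementation decisions worth recording:

* the depth feature is `log1p(relative depth × 10⁶)` rather than raw
  log counts, so z-scores are exactly invariant to a common scaling of
  all samples (a property we assert);
* background sampling is *balanced*: each peak cycles through a
  shuffled permutation of its k neighbours across iterations, so the
  substitute multiset is essentially seed-independent and z-scores
  from different seeds correlate > 0.99 at 50 iterations. Naive
  with-replacement sampling gives ~0.96–0.97.

Per-motif significance at a timepoint is a two-sided Welch t-test of
replicate z-scores at t vs 0 hpa, BH-adjusted across motifs. Motif
redundancy clustering uses average-linkage on 1 − similarity, where
similarity is the best Pearson correlation over ungapped alignments
(≥ 4 columns) in both orientations; the cluster representative is the
member with the largest range of mean z across design groups — i.e.
the motif showing the greatest accessibility change.

PWM scanning scores log2-odds against the background with pseudocount
0.008 per cell; `N` bases contribute 0; a hit requires ≥ 80% of the
maximum achievable score (the external tool the study used leaves its
threshold undocumented). Motifs whose maximum achievable score is ≤ 0
(uninformative PWMs) produce no hits at any threshold.

# Enrichment and the screen

Hypergeometric and Fisher tails are exact log-gamma summations,
validated against brute-force enumeration for every universe N ≤ 12.
Peak-to-gene assignment: body overlap first (ties → lower gene start),
else nearest TSS within 20 kb (a package decision — the study never
defines "near"; the distance is a config/CLI flag). The concordance
universe is the set of peaks surviving the ATAC CPM filter. "Putative
promoter" for screen presence flags means the promoter peak of a gene
(the synthetic world designates one per gene); in a sequence-level
application it would be 1 kb upstream to 500 bp downstream of the gene
start. Screen criterion 3 uses FDR ≤ 0.05 ("significantly enriched" is
stated without a number). The motif→TF plausibility map is an input
table, never inferred.

# The synthetic world

`generate_experiment()` draws per-feature baselines
(log2 mean ~ Uniform(2, 10)) and dispersions (log-normal, median 0.05,
log-sd 0.5 — typical bulk biological CVs), library sizes
(Normal, mean 3e6, CV 0.15, floored at 20%), and then NB counts with
planted log2FC programs:

* a generic injury program at 3 hpa, symmetric across structures and
  arms (effects ~ Normal(2, 0.5)), plus a smaller apoptosis-like set;
* head-/foot-specific programs at 8 and 12 hpa
  (effects ~ Normal(2.5, 0.5)) applied only in the matching structure;
* under iCRT14, the context effect is scaled by 0 at 8 hpa and 0.5 at
  12 hpa (divergence abolished, then partially recovered), and 30% of
  the injury program persists into 8/12 hpa (wound-response
  prolongation). The relative magnitude of generic vs
  structure-specific effects is not stated anywhere; both are exposed
  as parameters rather than fixed as a ratio.

The toy genome is a single chromosome of per-gene 5-kb loci: one
promoter peak straddling each gene start, one distal peak inside the
locus, and leftover "orphan" peaks > 20 kb from any gene. ATAC peaks
inherit the log2FC of their linked gene, which is what makes the
peak–gene concordance and the screen recoverable end-to-end. The
planted injury motif occupies every injury-gene promoter peak plus a
5% background; decoys are placed independently at 10%.

One root seed spawns one child stream per stage (child-seed draw, RNA
baselines, ATAC baselines, library sizes, effect realisation, RNA
counts, ATAC counts, motif placements/GC), so output is bit-identical
for a fixed `(config, seed)` and every generator restores the caller's
RNG state.

**What the generator does not emulate** — and hence what a green test
does not establish: no read-level artefacts (GC-dependent
amplification, Tn5 insertion bias, fragment-length structure,
duplication), no gene-length effects, no correlated features
(co-regulation beyond the planted programs), no batch structure, no
mitochondrial/duplicate contamination, and motif "hits" in the
synthetic screen are planted placements rather than sequence scans
(the scanner itself is tested separately on constructed sequences).
Calibration and recovery results transfer to real data only insofar as
the NB model with independent features is adequate.

# Known limitations

* The IDR degeneracy guard discards weakly-separated reproducible
  components wholesale rather than propagating uncertainty.
* Deviation z-scores assume every motif annotates ≥ 1 peak and every
  sample has non-zero counts; both are hard errors, not warnings.
* `consensus_peaks` skips a replicate pair entirely when fewer than 50
  shared regions exist (the IDR fit would be meaningless), which can
  reduce the attainable pass count for sparse groups.
* The pipeline holds all matrices in memory; it is sized for
  thousands-of-features desk experiments, not genome-scale atlases.
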