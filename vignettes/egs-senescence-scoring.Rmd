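---
title: "Ensemble-of-gene-sets senescence scoring: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-of-gene-sets senescence scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Senescent fibroblasts do not express a single, universal transcriptional
program. Individual SASP (senescence-associated secretory phenotype) genes —
IGFBP7, SERPINE2, IL6, MMP1/3, TIMP1 and many others — are highly expressed
only in *subpopulations* of senescent cells, and the composition of those
subpopulations shifts between early and mature replicative senescence and
between tissues. A single-signature score (a module score over one SASP gene
list) averages over this heterogeneity and dilutes subpopulation-specific
signal. `egscore` implements an ensemble alternative: one up/down gene-set
pair per *driver gene* — a SASP or senescence gene of interest whose high
expressers form a subpopulation — and a per-cell score that lets whichever
pair best explains a cell dominate.

## The model

**Reference standardization.** All expression is log-normalized,
$x_{gc} = \ln(1 + 10^4\, n_{gc} / N_c)$, and z-scored against per-gene
mean/SD computed over the *control* population (proliferating low-passage
cells) and frozen at ensemble-build time. Every later use of the ensemble —
including on other tissues — standardizes with these stored statistics, so
scores are always "distance from the proliferating reference". SD uses the
$n-1$ denominator; genes with zero reference SD get $z \equiv 0$ and are
unusable as drivers.

**Ensemble construction.** For each driver gene $g$ and senescent group
(e.g. PDL_46np, PDL_50np): cells with $z_g > 1.5$ are the subpopulation;
if at least 50 such cells exist, a two-sided Wilcoxon rank-sum comparison
against the control cells (log2 fold change on de-logged means,
$|\mathrm{log2FC}| \ge 0.25$, Bonferroni-adjusted $p \le 0.05$) yields the
pair's upregulated and downregulated gene lists. The driver gene itself is
excluded from its own pair's candidates: its cells were *selected* on that
gene, so its apparent upregulation is tautological, and keeping it would
make even a signal-free dataset produce a "significant" pair for every
driver. One auxiliary *lowSASP*
pair per group is built from cells whose detected fraction of SASP genes
falls in the bottom quartile of the group and that have no SASP gene above
the $z$ cutoff — capturing senescence without the SASP.

**Scoring.** The score of cell $c$ under pair $k$ is
$s_{kc} = \overline{z}_{\mathrm{up}(k),c} - \overline{z}_{\mathrm{down}(k),c}$.
The per-cell ensemble score is the *signed absolute extremum* over pairs:
the element of largest absolute value, sign preserved. An exact tie in
absolute value between a positive and a negative pair score resolves to the
positive one — the senescence-positive reading — a case the aggregation
rule itself leaves open; the tie is measure-zero in practice and the choice
is pinned by a test.

**Classification.** A Gaussian is fitted (moment estimates) to the control
and senescent score distributions; the decision threshold minimizes the
expected count of false positives plus false negatives,
$n_{\mathrm{ctrl}}(1-\Phi_{\mathrm{ctrl}}(t)) + n_{\mathrm{sen}}\Phi_{\mathrm{sen}}(t)$,
over a 2001-point grid spanning $[\mu_c - 3\sigma_c,\ \mu_s + 3\sigma_s]$.
Count weighting is the default because it reads "sum of false positives and
false negatives" literally; equal-prior weighting is available
(`threshold_weighting = "equal"`) since the two coincide for balanced
designs. The grid is used rather than the analytic quadratic root because
the quadratic degenerates at equal variances; an oracle test checks the
grid against the analytic density crossing in the non-degenerate cases, and
ties are broken toward the larger threshold. The final threshold is clamped
to $[\mu_{\mathrm{ctrl}}, \mu_{\mathrm{sen}}]$, making explicit the
contract that a decision boundary below the control mean or above the
senescent mean is never useful. Cells are senescent iff their score
*strictly exceeds* the threshold.

**Tissue transfer.** A cell-line-derived ensemble is not applied blindly to
tissue. It ranks tissue cells (with the stored reference statistics), and
only the extremes are trusted: the $n$ lowest-scoring p21⁻/p16⁻ cells and
the $n$ highest-scoring p21⁺ or p16⁺ cells (presence = nonzero raw CDKN1A /
CDKN2A count). Tissue-specific markers are re-derived between these strata
(Wilcoxon DE, keeping genes detected in at least 90% of one stratum), a
tissue-internal z-score set score is computed, and $(n, \mathrm{logfc})$
are optimized over a grid to maximize the separation of the two strata.
The final threshold is the midpoint of the two stratum means.

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `z_high` | 1.5 | z-score cutoff defining high expressers (strict) |
| `min_cells` | 50 | minimum subpopulation size for a pair |
| `logfc_threshold` | 0.25 | log2 fold change gate before testing |
| `adj_p_max` | 0.05 | Bonferroni-adjusted p cutoff |
| `scale_factor` | 10,000 | counts-per-cell normalization target |
| `n_confident` | 100 | cells per confident stratum |
| `k_folds` | 3 | cross-validation folds |
| `coverage_min` | 0.3 | minimum fraction of a pair's genes present to score it |
| `lowsasp_quantile` | 0.25 | detection-fraction quantile for lowSASP candidates |
| `n_bins`, `n_ctrl_per_gene` | 24, 100 | bin-matched control sampling (module/proliferation scores) |

The DE significance gate (Bonferroni at 0.05) goes beyond the named test
and fold-change threshold; it adopts the surrounding single-cell DE
convention and is configurable. Two details follow that tool's conventions
deliberately: the log2 fold change uses de-logged means with pseudocount
$10^{-9}$ (so oracle tests can pin it exactly), and the Bonferroni factor
is the number of *all* candidate genes, not just those passing the
fold-change gate — the gate preselects genes correlated with the test
statistic, so correcting only over tested genes would leave the
family-wise error inflated, which a null-simulation test demonstrates.

## Decisions taken where the procedure was open

- **Proliferation score.** The score is built from S-phase and G2/M gene
  signatures with expression-bin-matched control genes (24 equal-frequency
  bins, 100 sampled controls per signature gene, seeded), and the scalar
  per-cell score is `max(S, G2M)`; a cell is proliferative iff the score is
  strictly positive. Whether the published procedure used the max, the sum,
  or phase assignment is not stated; the max convention is this package's
  documented choice and matches the "nonzero score = proliferative"
  criterion. Bin pools and signature genes are iterated in canonical sorted
  order so the score is invariant to gene ordering.
- **lowSASP cell definition.** "Undetected or low" SASP expression is
  operationalized as: detection fraction in the bottom group quartile AND
  no SASP gene with $z >$ `z_high`. Both knobs are configurable. The
  arrest gating genes CDKN1A (p21), CDKN2A (p16) and TP53 do not count as
  SASP factors for this rule — SASP-silent senescent cells are typically
  still p21-positive, and counting p21 would exclude exactly the cells the
  lowSASP sets exist to capture.
- **p21/p16 positivity** is presence/absence of raw counts, not a z
  cutoff — gating-marker semantics consistent with treating nonzero
  proliferation scores as "proliferative".
- **Missing genes at transfer** are dropped per pair (an empty side
  contributes zero; a pair below 30% gene coverage is excluded), rather
  than imputed. Imputation would manufacture reference-distributed
  pseudo-expression for genes the tissue panel never measured.
- **Separation objective for transfer optimization.** "Most distinct
  distributions" is quantified as the pooled-SD standardized mean
  difference $(\mu_h - \mu_l)/\sqrt{(\sigma_h^2 + \sigma_l^2)/2}$. This is
  the largest open call in the package: any scale-free divergence would be
  defensible, and the choice is isolated in `optimize_transfer()`. Grid
  defaults $n \in \{50, 100, 150, 200\}$,
  $\mathrm{logfc} \in \{0.25, 0.5, 1\}$ bracket the reference settings.
- **Top-percent selection size** uses round-half-up, pinned by the
  11,889-cell cohort whose top 1% is 119 cells.
- **Cross-validation** folds are stratified by group label under a fixed
  seed; extremes accuracy applies the fold-fitted threshold to the
  `n_confident` lowest- and highest-scoring held-out cells.

## The synthetic generator

`sim_config()` / `simulate_dataset()` produce counts with the structure the
analysis assumes, plus full ground truth. Counts are negative binomial
(`size = 1/nb_dispersion`) around per-gene baselines (log-normal across
genes) scaled by log-normal library sizes. Planted structure, all in
log-normalized units:

- **Driver subpopulations**: within each senescent group, one
  subpopulation per driver (mostly disjoint block assignment at
  `subpop_frac`, plus a small independent `overlap_rate` so cells can
  express two drivers' programs, as co-expression in real senescent cells
  motivates); the driver and its 20 up-program genes shift by
  `+effect_lognorm`, its 20 down-program genes by `-effect_lognorm`.
- **A shared senescence core program** (15 up / 15 down) in every
  senescent cell, planted at a weaker effect (`core_effect_lognorm = 0.8`)
  than the driver programs — the common arrest-associated program on top
  of which SASP heterogeneity sits. Keeping it weaker than the focal
  driver programs is what preserves subpopulation identifiability (the
  pair matching a cell's planted driver should win the extremum); it is
  also what tissue-marker derivation should recover.
- **SASP-silent senescence**: a fraction of each senescent group with all
  SASP genes suppressed, the population the lowSASP sets exist for.
- **Cell-cycle structure**: each cycling cell is assigned a phase
  (S-active, G2M-active, or both), so the proliferating reference is
  heterogeneous in cycle genes — as real cycling populations are — while
  arrested cells silence them; controls cycle, senescent cells are fully
  arrested by default. Cycle genes get sparse-detection baselines
  (MKI67-like) and the panel carries 20 genes per phase by default, so the
  cycle program is a realistic few percent of each library rather than a
  compositional artifact.
- **p21/p16** as zero-inflated presence: forced nonzero in 80% / 30% of
  senescent cells, 15% / 5% of controls, because the classifier gates on
  presence, not magnitude.

Default study conditions: three groups of 900 cells (control PDL_25p,
early PDL_46np, mature PDL_50np), 1200 genes, 8 drivers,
`effect_lognorm = 1.5`, dispersion 0.1, library sizes
$\mathrm{logN}(\ln 10^4, 0.25)$. The group sizes keep per-driver
subpopulations (~90 cells) above the 50-cell rule even inside
cross-validation training folds (two-thirds of the data); 8 drivers at 10%
each plus a 10% silent fraction leave a rump of unexplained senescent
cells, which is what makes the lowSASP mechanism testable. Effects of 1.5
log-units (≈ 4.5-fold) with dispersion 0.1 put driver detection
($z > 1.5$) around 95% per cell — strong but within the range of real
replicative-senescence markers. The `wi38-like` fixture reuses the
published five-group design (900/573/657/1179/991 cells) as dimensions
only; the `tissue-like` fixture (1700 mostly quiescent normal + 300
senescent cells) emulates a tissue cohort where normals are also arrested,
so transfer separation must come from the programs and p21 gating rather
than the cell cycle. Its senescent cells carry the shared core program,
p21/p16 enrichment and arrest but *not* the cell-line driver
subpopulations — mirroring the empirical observation that cell-line SASP
co-expression patterns transfer only partially to tissue, and making the
planted core program the ground truth that tissue-marker derivation
should recover.

**What the generator does not emulate** — and therefore what passing tests
do not establish about real data: batch effects and ambient RNA, doublets,
gene–gene correlation beyond the planted programs, compositional
renormalization (a cell's planted up-shifts do not shrink other genes'
shares), continuous senescence trajectories (classes are discrete), and
annotation noise in the group labels. Recovery results on this generator
are best read as *internal correctness* of the pipeline under its own
assumptions, not as benchmarks of biological sensitivity.

## Numerical choices

- Wilcoxon rank-sum: exact permutation distribution (dynamic programming
  over doubled midranks, so ties are exact) when both groups have ≤ 10
  cells; otherwise the normal approximation with midranks, tie correction
  and continuity correction. Two-sided p is the symmetric tail probability,
  which coincides with the doubled-tail convention because the midrank
  permutation distribution is symmetric.
- Reference SDs clamp tiny negative variances (floating-point two-pass) to
  zero; zero-SD genes score $z = 0$ everywhere rather than propagating
  infinities.
- All stochastic steps (fold assignment, bin-matched control sampling,
  simulation) run under locally scoped seeds that restore the caller's RNG
  state; a pipeline-level seed fans out to per-stage child seeds so stages
  can be rerun independently.
- Degenerate inputs are contract errors, not silent repairs: fewer than two
  control cells, overlapping DE groups, empty score vectors, reversed class
  means in the threshold fit, and strata smaller than `n` in confident
  selection all raise errors naming the violated condition.

## Problem sizes and limitations

The test suite and the acceptance script run the full pipeline on the
default 2700-cell / 1200-gene conditions (cross-validation rebuilds the
ensemble three times) and the 4300-cell `wi38-like` and 2000-cell
`tissue-like` fixtures — sizes chosen so a complete run exercises every
stage at realistic single-cell scale while remaining convenient on one
CPU. Known limitations: the 62-pair count of the original cell-line
analysis is data-dependent and not a reproducible target (the synthetic
conditions yield their own pair count); the separation objective for
transfer optimization is a package choice, not a published formula; and
with `n_drivers * subpop_frac` near 1 the "no subpopulation" rump shrinks,
which weakens the lowSASP pair — the default leaves 10% headroom.
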