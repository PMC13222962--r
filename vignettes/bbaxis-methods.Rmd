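---
title: "Models and methods behind bbaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bbaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`bbaxis` chains seven analysis stages — resting-state regional metrics,
group contrasts, imaging-transcriptomic and receptor associations,
cell-type specificity, gene-program discovery, interaction-network
modules, and mediation — behind a synthetic-data layer that plants known
ground truth in every input. This vignette explains the statistical models,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic data do and do not establish about real data.

## Regional metrics

**ALFF.** For a demeaned series \(x_t\) of length \(n\) sampled every
`tr` seconds, the periodogram amplitude at bin \(k\) is
\(2 |X_k| / n\) (so a pure sinusoid of amplitude \(A\) contributes
\(A\) at its bin), and ALFF is the mean amplitude over bins whose frequency
lies in the band (default 0.01–0.08 Hz, the canonical low-frequency window;
the band must sit inside \((0, 1/(2\,\mathrm{tr})]\)). Only demeaning is
applied — no detrending — because the upstream toolboxes this emulates
leave that to preprocessing. ALFF is invariant to additive constants and
exactly linear in signal amplitude.

**ReHo.** Kendall's coefficient of concordance over a parcel and its
neighbors, with tie correction:
\(W = 12 S / (m^2 (n^3 - n) - m T)\), where \(S\) is the squared deviation
of per-timepoint rank sums and \(T\) the usual tie term. On lattice
parcellations the neighborhood is all parcels within 1.8 lattice spacings
(26-connectivity); on irregular parcellations the same distance rule
applies with a user-set radius. \(W\) is undefined (returned as `NA` with a
warning) when every series is constant; it is invariant under any common
monotone transform because it sees only ranks.

**Group contrasts.** Each parcel gets a linear model
`value ~ group + covariates`; the group t statistic is thresholded
two-sided at a forming p (default 0.001), supra-threshold parcels are
clustered on the neighbor graph separately by sign, and each cluster's
family-wise p is the proportion of group-label permutations whose largest
cluster (either sign) is at least as large. Permutation of the label —
rather than random-field theory — was chosen because it is assumption-light
and exactly testable; the output records the method. Covariates enter the
per-parcel model directly (equivalent to Frisch–Waugh residualization, with
simpler bookkeeping). A rank-deficient design is an error naming the
collinear columns. Extent-based max-cluster inference is valid but
conservative at small parcel counts: cluster sizes are small integers, so
the achievable p grid is coarse and the realized null rejection rate sits
well below the nominal 5% (about 1–2% in the packaged simulations). We kept
extent rather than mass because extent is the conventional statistic for
cluster-level correction.

## Imaging transcriptomics

Per-gene Spearman correlations (average ranks for ties) link a contrast map
to regional expression profiles; constant profiles are reported as missing
with a reason code rather than silently dropped. Significance uses
**variogram-matched surrogate maps**: the map's binned empirical
semivariogram (10 equal-count distance bins) is fitted with a
Gaussian-kernel-plus-nugget model
\(\gamma(h) = c_0 + c_1 (1 - e^{-h^2 / 2L^2})\) by a grid search over
\(L\) with non-negative linear coefficients; Gaussian fields drawn from the
fitted covariance are rank-remapped onto the original value multiset, so
every surrogate preserves the values exactly and the autocorrelation
approximately. A plain value-permutation fallback exists and is flagged in
metadata. A volumetric (distance-based) null was required because
subcortical parcels have no spherical coordinates for a spin test.

One honest caveat: at around 100 parcels, the per-surrogate binned
variogram is itself a noisy statistic — even an independent redraw from the
*true* generating covariance differs from the target by more than 15% in
most bins. Surrogate quality is therefore assessed (and tested) at the
ensemble level: the across-surrogate mean variogram tracks the target
within 15% on at least 80% of bins, and for white-noise maps the surrogate
correlation null is indistinguishable from the permutation null.

Empirical p-values use the add-one estimator
\(p = (1 + \#\{|\rho_{surr}| \ge |\rho_{obs}|\}) / (n_{surr} + 1)\), so
they are never zero and are monotone in \(|\rho_{obs}|\). The **dual
threshold** demands both \(p_{perm} < 0.05\) and a parametric Spearman p
(t approximation) at or below \(0.05 / n_{genes}\). The Bonferroni arm is
applied to the parametric p because the empirical floor
\(1/(n_{surr}+1)\) cannot clear a genome-wide cutoff (at 10,000 surrogates
the floor is ~1e-4 versus a cutoff near 5e-6) — the only reading under
which the dual threshold is satisfiable. The ALFF/ReHo intersection is a
plain set intersection, reported in lexicographic order; matching
correlation signs across the two metrics is not required.

## Receptor association

Per-subject difference maps (subject minus control mean) are correlated
with each receptor density map; \(\rho\) is clamped to
\(\pm(1 - 10^{-12})\) before the Fisher transform \(z = \mathrm{arctanh}\,
\rho\) so a perfect match stays finite. The group statistic is the mean
\(z\) across subjects — invariant to subject order — tested two-sided
against the same statistic recomputed on spatial surrogates of the receptor
map, then Benjamini–Hochberg corrected across all receptor maps in the run
(one modality per family, mirroring per-panel reporting). The spatial null
was preferred over a one-sample t-test on \(z\) because subjects share the
map's spatial structure, violating independence across parcels.

## Cell-type specificity

Counts are normalized to counts-per-10,000 and log1p-transformed. Three
per-gene, per-group metrics follow: the Welch t of the group against all
other cells (`det`), the fold enrichment of group mean over rest mean
(`ges`), and the expression proportion (`ep`). Each is rescaled per gene to
[0, 1] by rank-based min–max over groups and ESμ is their mean — but three
sparsity gates zero a gene's score in a group unless its expression
proportion exceeds the uniform share \(1/\#groups\), its Welch t clears a
one-sided 5% gate, and its fold enrichment exceeds 1.1. Without the gates,
rank rescaling would hand every noise gene a full-range score in whichever
group it randomly topped; with them, an exactly uniform gene scores zero
everywhere and a single-group gene scores one in that group. Group sets for
enrichment default to ESμ > 0, with the cutoff exposed.

**Hypergeometric enrichment** is the upper tail \(P[X \ge k]\) for overlap
\(k\) between a query of size \(n\) and a group set of size \(K\) in a
universe of size \(N\), BH-corrected across groups; the universe should be
the detected-gene intersection so never-observed genes cannot inflate
enrichment. The same routine backs region enrichment, program enrichment,
and module enrichment (the latter removing overlaps below 3 genes after
testing).

**pSI.** The specificity statistic for gene \(g\) in tissue \(t\) is its
log expression minus the mean log expression over the remaining tissues.
Its p-value is the upper normal tail with mean and SD estimated robustly
(median/MAD) from a pooled null built by shuffling tissue labels within
every gene (default 100 shuffles). The robust-parametric tail is the
deliberate choice here: a purely empirical pooled p has a floor of one over
the pool size and is contaminated by genuinely specific genes' own permuted
extremes, so the tightest threshold (1e-4) would be unreachable at a few
hundred genes. The parametric tail is exactly calibrated when log
expression is normal (the synthetic generators' regime) and approximately
otherwise; tissue sets are nested across thresholds by construction.

## Gene programs

NMF minimizes Frobenius reconstruction error with Lee–Seung multiplicative
updates (`eps = 1e-10` guards, tol = 1e-5 relative change, max 500
iterations by default), best of `n_restarts` random initializations, gauge
fixed by unit-L2 columns of W. The objective trace is non-increasing up to
floating-point rounding. Multiplicative updates converge slowly near an
exact factorization — recovering a planted exact rank-2 product to 1e-6
relative error takes on the order of 10,000 iterations — which is why the
iteration cap is exposed.

**Rank selection** runs `n_restarts` fits per candidate rank, each on a
random 70% subsample of genes, assigns cells to their dominant program, and
builds a consensus matrix. Two diagnostics follow: the cophenetic
correlation between consensus distances and their average-linkage
hierarchical cophenetic distances, and the mean silhouette of the k-cluster
consensus partition. The chosen rank maximizes their mean. Gene subsampling
is essential: with a deterministic optimizer on clean low-rank data, the
overfit-rank optimum is essentially unique, so plain-restart consensus
stays perfectly stable *above* the true rank and a "steepest cophenetic
drop" rule degenerates. Under subsampling, both merging below the true rank
and splitting above it depend on which genes were drawn, so stability peaks
exactly at the planted rank (16/16 in development replicates, and ≥80%
required by the packaged tests).

Top-weight genes per program are ordered by weight with lexicographic tie
breaks for determinism (the conventional annotation budget is the top 200;
the synthetic-scale tests use twice the planted program size). Per-cell
program activity is the program's H entry divided by the cell's total
activity; cell types are compared by two-sided Wilcoxon rank-sum tests with
BH correction, excluding types with fewer than 3 cells. Activity (not mean
expression of top genes) is the default score; the alternative is a
one-liner on the returned decomposition.

## Network modules

Edge lists in the STRING dialect are filtered at combined score ≥ 0.4
(medium confidence), with 0–1000 integer scores auto-rescaled, self-loops
dropped, and duplicate undirected edges collapsed to their maximum score.
Module detection follows the MCODE recipe with its published defaults
(degree cutoff 2, node score cutoff 0.2, k-core 2, haircut on, fluff off):
node weight = k number × density of the highest k-core of the closed
neighborhood; greedy expansion from the highest-weight unassigned seed,
admitting neighbors within `(1 - node_score_cutoff)` of the seed weight;
modules lacking a 2-core are discarded and haircut prunes singly-connected
members. Edge weights filter but do not enter density, matching MCODE
semantics. All ties break lexicographically by node name, so output is
deterministic and relabeling-equivariant.

## Mediation

For exposure X, mediator M, outcome Y (optionally with covariates), OLS
gives `a` (X→M), `b` (M→Y | X), `c'` (direct), and total `c`; ACME = a·b
and the identity ACME + ADE = total holds exactly in-sample. Inference is a
nonparametric case-resampling bootstrap (percentile CI, default 5,000
draws; p = 2·min(frac ≤ 0, frac ≥ 0)); the percentile CI reproduces the
asymmetric intervals typical of resampling. If both structural noises are
zero, M is an exact linear function of X and `b` is unidentifiable — the
fit stops with a collinearity error rather than returning an arbitrary
split.

The four-model comparison runs the four conventional role assignments of
(bone density, regional activity, cognition) and flags models whose ACME CI
excludes zero. A caution on identifiability: in a linear-Gaussian system
generated under model 1 (X→M→Y), the reversed orderings of models 2 and 4
have nonzero population ACMEs (the relevant partial covariances do not
vanish), so with enough data they are flagged too; only model 3's mediator
path is identically zero when the direct path is small. The summary
therefore also reports the *best-supported* model — the flagged model with
the largest |ACME|/bootstrap-SE — which recovers the generating ordering in
the packaged simulations. Cross-sectional mediation cannot by itself
establish causal direction; the comparison ranks prespecified models, no
more.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of their arguments including the seed.
Spatial structure everywhere is a Gaussian kernel over parcel distances
with length scale `autocorr_length`, default 10 distance units — one
lattice spacing, a realistic smoothness for parcel-level maps and the
regime in which the surrogate-null machinery is demonstrably calibrated
(3–8% rejection at p < 0.05) while planted ρ = 0.6 genes remain detectable
(sensitivity ≥ 0.9). Group effects enter as amplitude scaling of the
in-band signal component (with per-subject amplitude SD 0.15), which makes
ALFF the sensitive statistic by construction. Linked genes are built on the
normal-score scale using the bivariate-normal identity
\(\rho_s = (6/\pi) \arcsin(r/2)\) so the target is a *Spearman*
correlation; `noise_sd` scales the orthogonal smooth component and zero
collapses a linked gene onto an exact monotone transform of the map.
Counts are Poisson (negative binomial optional) around a low-rank rate
model: per-region marker genes, background factors each concentrated in one
cell type (so planted programs are genuinely well-separated), and one
planted program active in one cell type of one region. `background =
"shared"` makes background activities label-independent, giving a clean
exchangeable null for type-I checks. Mediation cohorts follow
M = aX + ε₁, Y = c′X + bM + ε₂ exactly, with independent nuisance
covariates.

What passing tests therefore establish: the estimators are correctly
implemented (oracle agreement to 1e-10 or better), calibrated under their
declared nulls, and able to recover planted structure at realistic
desk-scale sizes. What they do not establish: robustness to fMRI
preprocessing artifacts, donor-level expression heterogeneity, batch
effects, non-Gaussian spatial fields, or model misspecification in the
mediation stage — none of which the generators emulate.

## Problem sizes in the packaged checks

The test suite and `scripts/acceptance.R` use: 100 parcels / 500 genes /
1,000 surrogates for null calibration (the headline analyses use 10,000
surrogates; 1,000 keeps the empirical floor at 1e-3 which is ample for a
0.05 arm); 300–500 null contrast simulations at 64 parcels with 199
permutations; 8–10 replicates of the rank-4 program recovery at 150 genes ×
180 cells; 100 replicates of n = 2,000 cohorts for ACME bias; and the exact
K5/K4 module traces. These sizes were chosen so each property is measured
with enough replication to be stable across seeds.
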