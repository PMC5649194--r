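---
title: "Models and methods behind wallmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wallmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wallmech)
```

wallmech re-implements, as a tested and reusable pipeline, an integrative
analysis of the *Saccharomyces cerevisiae* cell wall: single-cell AFM
nanomechanics (indentation and single-molecule force spectroscopy),
scalar cell-surface assays, microarray differential expression, and a
sparse-PLS integration of the gene and phenotype blocks. This vignette
explains the models, the tunable parameters and their defaults, the
numerical choices, what the synthetic-data generators emulate, and what
the tests do and do not establish about real data.

## Indentation mechanics: conical Hertz model

A sharp AFM tip pressing on a soft cell is modelled as a rigid cone on an
elastic half-space (Sneddon's solution):

$$F = \frac{2\,E\,\tan\alpha}{\pi\,(1-\nu^2)}\;\delta^2$$

with indentation depth $\delta$ (nm), Young's modulus $E$ (kPa), cone
half-angle $\alpha = 0.31$ rad and Poisson ratio $\nu = 0.5$
(incompressible). Units are pN/nm/kPa throughout
($1\,\mathrm{kPa} = 10^{-3}\,\mathrm{pN/nm^2}$); at $E = 483$ kPa and
$\delta = 50$ nm the model force is about 330 pN, the right scale for a
0.5 nN maximal-load map.

`fit_hertz()` estimates $E$ from a baseline-corrected approach trace over
the first 50 nm of indentation (`max_indentation_nm`, the depth used for
elasticity mapping of yeast). Because the contact point of a soft,
noisy curve is the weakest link of any indentation fit, it is treated as
a free nuisance parameter: for a fixed contact point the modulus is a
closed-form least-squares slope in $\delta^2$, so the fit reduces to a
one-dimensional profile optimisation of the contact point inside a
window (`contact_window_nm`, default 30 nm) around the initial
detector estimate. The window must comfortably exceed the detector's
systematic lateness — a $3\sigma$ threshold detector fires only once the
force has risen above the noise, roughly 15 nm past contact at 10 pN
noise and ~500 kPa — which is why the default is generous; a 10 nm
window leaves a ~35% upward bias in the modal modulus under those
conditions.

Per-cell stiffness is summarised by `modal_modulus()`: the fitted moduli
of one force-volume map (32 × 32 = 1,024 curves) are binned
(Freedman–Diaconis), a single Gaussian is fitted to the bin counts by
least squares, and the fitted mean is reported as the most probable
(modal) modulus with the fitted $\sigma$ as spread. The Gaussian is
started both from the sample moments and from the histogram argmax and
the better residual wins; the argmax start keeps the fit anchored on the
dominant peak when the map mixes two populations (e.g. cell body vs
bud-scar-adjacent sites). If the Gaussian fit fails outright, the
histogram argmax is reported with `sigma = NA`, ties broken toward the
lower modulus.

## Single-molecule force spectroscopy: FJC and WLC

Retract curves acquired with a lectin-functionalised tip show unbinding
fingerprints as the tip stretches mannan chains. Two standard polymer
models are implemented in the force–extension plane:

* **Freely-jointed chain** (single events): extension under force
  $x(F) = L_c\left[\coth(F l_k / k_B T) - k_B T / (F l_k)\right]$,
  with contour length $L_c$ and Kuhn length $l_k$. The model is given as
  $x(F)$; segments are sampled on the extension axis, so `fjc_force()`
  inverts it numerically by bisection to a relative tolerance of
  $10^{-6}$.
* **Worm-like chain** (multiple events): interpolated Marko–Siggia force
  $F(x) = (k_B T/l_p)\left[\tfrac14 (1 - x/L_c)^{-2} + x/L_c -
  \tfrac14\right]$ with persistence length $l_p$.

$k_B T$ is always derived from the temperature (298 K by default,
`thermal_context()`), never hard-coded; at room temperature it is
4.11 pN·nm. Curves with exactly one specific event are routed to the
FJC model and curves with two or more to the WLC model
(`classify_curve()`), matching how single and multiple unbinding
patterns are conventionally analysed.

`fit_polymer()` is a box-constrained least-squares fit of
$(L_c, \text{stiffness length})$ with $L_c$ constrained to (max observed
extension, 10 × max extension] and the stiffness length to [0.01, 10] nm.
The profile in $L_c$ has shallow local minima, so the optimiser starts
from a deterministic ladder of contour lengths (max extension / 0.95,
0.8, 0.6) plus three RNG-perturbed restarts, with parameter scaling
(`parscale`) to handle the ~200-fold difference in magnitude between
$L_c$ and $l_p$; the lowest residual wins and ties break toward the
smaller $L_c$. Fitted stiffness lengths below 0.1 nm are sub-physical
(below one monomer) and are flagged (`subphysical`), not clamped,
because published fits do report such values and clamping would hide
them.

## Event detection

`detect_adhesion_events()` works on baseline-corrected retract traces.
The noise scale $\sigma$ is the MAD of the far-field (outer 30% of the
separation range). An event *seeds* where the force stays below
$-3\sigma$ for at least `min_points = 5` consecutive samples, then
*extends* by hysteresis until two consecutive samples return above
$-1\sigma$, and finally *splits* at sudden force releases larger than
$\max(3\sigma_{\text{thr}}, 6\sigma)$ between consecutive samples (a
rupture jump, well above the $\sqrt2\sigma$ scale of single-sample noise
differences). Each event reports the unsigned rupture force (deepest
force) and the rupture distance (separation where the force returns to
baseline). Events rupturing closer than 5 nm to the surface are flagged
nonspecific — the standard convention separating tip–surface snap-off
from tether extension.

These defaults were calibrated on the generator's noise model: the
seed-run length of 5 keeps the false-positive rate on noise-only curves
at ~0.05% (a 3-sample minimum admits ~0.8% through baseline-extrapolation
wander, enough to bias the adhesion frequency by almost a full
percentage point), and the hysteresis extension prevents noisy
oscillation around the $-3\sigma$ threshold from fragmenting one tether
into several short events, which otherwise truncates fit segments and
destroys the identifiability of $L_c$. All thresholds are arguments.

`adhesion_frequency()` is simply the percentage of curves with at least
one specific event; `contour_length_distribution()` summarises converged
polymer fits as a histogram with mean ± SD.

## Scalar assays

`hydrophobicity_index()` implements the microbial-adhesion-to-solvents
(octane) index. The bounded convention $100\,(A_0 - A_F)/A_0$ is the
default: it lies in [0, 100] and matches the scale of reported values;
the literal reading with $A_F$ in the denominator is unbounded as
$A_F \to 0$ and is provided only behind `convention = "literal"` for
comparison. Which denominator the source assay used cannot be resolved
from its printed formula; the bounded form is the standard one.
`glucan_ratio()` and `mannosyl_units()` (contour length / 0.5 nm per
mannosyl unit) are straightforward arithmetic on the phenotype table,
and `validate_phenotype_table()` enforces the table's invariants
(percentages in range, wall-composition sum within 90–110%).

## Transcriptome preprocessing and differential expression

`preprocess_expression()` follows the one-colour chain: log2 transform;
within-array centring on the weighted global median (weight-0 spots
excluded); quantile normalization across arrays — per strain by default,
with `scope = "all_arrays"` as an override, since cross-strain
comparisons go through gene-level summaries; and per-gene median over
replicate spots. Weight-0 spots are imputed with the per-array median
*only* so that quantile normalization sees complete columns; they are
excluded again from the per-gene summaries, because letting an imputed
value into a two-spot median halves the apparent fold change of strong
genes and inflates their variance.

`moderated_ttest()` shrinks per-gene variances toward a prior:
$\tilde s^2_g = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, with the moderated
statistic referred to $t_{d_0 + d_g}$. When not supplied, $(d_0, s_0^2)$
are estimated by the method of moments on log sample variances: with
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, $d_0$ solves
$\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d_g/2)$ (trigamma inverted by
root-finding on a log grid) and
$s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$. Setting $d_0 = 0$
recovers the ordinary pooled t-test exactly, and the estimates agree
with limma's `squeezeVar` on heteroscedastic data (checked in the test
suite, where limma serves as an independent oracle, not as the
implementation). `bh_adjust()` delegates to `stats::p.adjust` and is
checked against a hand-written step-up in the tests. `de_filter()`
applies the study's cuts (fold change ≥ 2 and p < 0.01, both
configurable), and `common_set()` computes the full Venn partition
across strains. `hypergeometric_enrichment()` is the upper-tail
hypergeometric test for flat, user-supplied category tables; the
annotation universe size is a required argument because no annotation
database is bundled or queried.

## Two-block integration: sparse PLS

`spls_fit()` implements sPLS in regression mode. For each component,
with $M = X^\top Y$ on the standardized blocks, the loading pair
$(u, v)$ is found by alternating soft-thresholded power iterations —
keep the `keepX` (resp. `keepY`) largest-magnitude entries, shrink the
rest to zero, renormalise — to a $10^{-9}$ tolerance, then $X$ and $Y$
are deflated on the score $t = Xu$ with regression coefficients. With
sparsity disabled the first component equals the leading singular pair
of $X^\top Y$ (asserted to $10^{-8}$ against `svd()`), scores are
mutually orthogonal, and the whole fit is deterministic: loadings are
oriented so each component's largest $|u|$ entry is positive, and there
is no RNG anywhere in the fit.

Defaults: `ncomp = 2`, `keepX = 50` genes per component, `keepY` = all
phenotypes — the component count and sparsity of the original analysis
are not stated, so these are package defaults chosen to select on the
order of a hundred genes over two components; all are arguments.
Standardization (`center_unit_scale()`) divides by the population
(1/n) standard deviation; the convention only rescales $X^\top Y$ and
does not change correlations, selections or singular-vector directions.

`correlation_circle()` reports each variable's correlation with the
first two scores; variables outside radius 0.5 are well represented and
can be read off against each other by angular proximity.
`similarity_map()` builds the clustered-image-map similarity
$\mathrm{sim}(j, i) = \sum_h r_h(\text{pheno}_j)\, r_h(\text{gene}_i)$
over retained components (genes restricted to those the model
selected), clusters rows and columns by complete-linkage hierarchical
clustering of Euclidean distances on similarity profiles, and cuts the
trees into `k_pheno = 4` and `k_gene = 6` groups, the grouping used for
the study's heat map. Complete linkage on Euclidean distances is
deterministic and standard for image maps; tree cutting inherits
`stats::cutree`'s lower-index-first labelling.

The integration runs on replicate-level profiles (5 strains × 3
replicates = 15 rows) rather than strain means, keeping $n$ above the
component count; `run_pipeline()` exposes both the expression matrix and
the phenotype table if a strain-mean variant is wanted.

## Synthetic data: what is emulated, and what is not

The generators (`gen_force_volume()`, `gen_retract_curves()`,
`gen_expression()`, `gen_linked_phenotypes()`) produce every input the
pipeline consumes, with machine-readable truth records, and are strictly
seeded: identical configuration gives byte-identical artifacts. Strain
presets (`force_sim_preset()`) are populated from the bundled reference
phenotype table (`strain_presets()`): per-curve moduli
$\mathcal N(483, 61^2)$ kPa for BY4743 and so on, event probabilities
from the per-strain adhesion frequencies, contour lengths from the
per-strain distributions. The single-molecule stage uses 3 pN force
noise (soft-cantilever thermal noise) while force-volume maps use 10 pN
(higher loading rates); contact sits at 120 nm on a 1 nm grid, rupture
forces are drawn $\mathcal N(60, 5^2)$ pN — the single lectin–mannose
unbinding scale — and retract traces extend to 400 nm, the longest
rupture distances observed. Strictly positive quantities are drawn from
normals truncated at zero by redraw. Retract forces are negative below
baseline (AFM convention), magnitudes reported unsigned.

Planted expression effects are drawn uniformly in
$[1, 3]$ on the log2 scale for strain-specific genes — at or above the
two-fold filter threshold — and in $[2, 3]$ for the 71-gene cross-strain
core, mirroring the qualitative character of the real common set
(absent gene families and auxotrophic markers with 10–20-fold
differences). An effect pinned exactly at the threshold would be missed
half the time by symmetry, so threshold-level effects are the floor,
not the typical case.

Not emulated: instrument artifacts (hydrodynamic drag, piezo
hysteresis, drift), multi-Gaussian modulus maps from wall heterogeneity,
bud-scar geometry, dye bias, probe-sequence effects, and any real GO
annotation. Passing recovery tests therefore demonstrates that the
estimators are unbiased and correctly calibrated *under the stated noise
model* — they do not certify performance on raw instrument files, which
the package deliberately does not parse (plain-text bundles only).

## Problem sizes and determinism

The test suite runs the study-scale checks directly: 1,024-curve maps
for the modal-modulus recoveries, 500 retract curves for the
contour-length recovery, 1,000 curves for the adhesion frequency, 2,000
genes for DE calibration and recovery — sizes chosen to match the
study's printed designs while keeping a full run in minutes.
`run_pipeline()` defaults to the full design (32 × 32 maps, 1,000
retract curves, 6,000 genes per strain) and scales down through its
configuration for examples and smoke tests. Every stochastic step takes
its stream from an explicit seed; the only RNG consumer outside the
generators is the polymer fitter's restart perturbations, which
`run_pipeline()` and the acceptance script seed explicitly.

## Known limitations

* The Hertz stage assumes a conical tip and 50 nm indentation;
  spherical/pyramidal geometry and substrate (bottom-effect) corrections
  are out of scope.
* The FJC model here has two parameters ($L_c$, $l_k$); a segment
  elasticity term is sometimes added in the literature but is not part
  of the implemented force law.
* Event detection assumes a flat baseline after linear correction;
  strong nonlinear drift would need dedicated correction first.
* The enrichment stage treats annotation as a flat table; no GO DAG
  semantics, and p-values depend on the user-supplied universe size.
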