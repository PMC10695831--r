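---
title: "Methods: models, parameters and design choices in asymfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in asymfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymfold)
```

`asymfold` is an analysis toolkit for studying how lipid charge asymmetry
between the two leaflets of a bilayer modulates the folding of bacterial
outer membrane proteins (OMPs). This vignette documents the models behind
each module, the tunable parameters and their defaults, what the
synthetic-data generators emulate (and what they deliberately do not),
and the design decisions taken where the underlying methodology left
choices open.

## Designing and validating charge-asymmetric liposomes

Asymmetric liposomes are made by methyl-β-cyclodextrin (MβCD)-mediated
exchange of donor lipid into the outer leaflet of acceptor liposomes.
`plan_exchange()` implements the exchange stoichiometry

$$C_d = a \, C_a \, \frac{\mathrm{asym}}{1-\mathrm{asym}}, \qquad
  C_m = n \, C_d + \frac{C_d \, K}{n},$$

where $a$ is the fraction of acceptor lipid accessible to exchange
(default 0.5 for large unilamellar vesicles), $\mathrm{asym}$ the target
outer-leaflet donor fraction, $n = 4$ the CD–lipid complex stoichiometry
and $K$ an empirically derived donor constant (292 for PC/PG/PS
donation, 150 for PE). Two quirks are worth stating plainly:

* $K$ is quoted with irregular units in the source protocols yet enters
  the formula linearly. The formula is therefore evaluated exactly as
  printed, in whatever concentration unit the caller supplies, and no
  unit conversion is attempted.
* The 70% CD–lipid saturation level at which $K$ was calibrated is
  stored as plan metadata only. It was absorbed into $K$ empirically and
  there is no published formula through which it could enter the
  arithmetic independently.

Validation couples a symmetric-liposome ζ-potential calibration to the
accessible fraction. For an outside-only single-round exchange, the
whole-liposome donor fraction $f$ implies an outer-leaflet fraction
$f/a$; `classify_on_asymmetry_line()` compares a measured ζ against the
calibration evaluated at $f$ (symmetric hypothesis) and at $f/a$
(asymmetric hypothesis). The margin (default 10%) is interpreted as a
*relative* band on each predicted ζ magnitude, mirroring the shaded band
drawn around theoretical asymmetry lines; an absolute-mV band would make
the test incoherent across compositions whose ζ differ several-fold.
The calibration is supplied as a table of (fraction, ζ) points with
monotone piecewise-linear interpolation; extrapolation is refused rather
than guessed. Measured asymmetries are grouped to the nearest 10%
(±3 percentage points) by `bin_asymmetry()`; samples farther from any
bin centre are excluded (`NA`).

## The ζ-potential ensemble predictor

`train_zeta_ensemble()` models liposome ζ-potential from eight features:
monovalent and divalent salt concentration (M), pH, hydrodynamic radius
(nm), temperature (°C), mean lipid headgroup charge (e per lipid), mean
lipid melting temperature over non-cholesterol lipids (°C) and
cholesterol mole fraction. Hyper-parameters follow the published
configuration: learning rate 0.05, maximum depth 6, subsample per tree
and per node 0.85, minimum child weight 2.5, early stopping with
patience 25 on a random 25% validation split, 50 ensemble members all
required to reach a validation MAE below 5 mV, and a 4-fold
cross-validation for reporting. Choices the published configuration
leaves open, and how they are resolved here:

* **Weight direction.** Measurement standard deviations are mapped to
  sample weights on [0.375, 0.625]; the published range does not state
  the direction. Smallest sd → 0.625 and largest → 0.375
  (inverse-error weighting, the standard convention); missing sds get
  the midpoint 0.5.
* **Member diversity.** Each member draws its own validation split and
  row subsamples from seed `base_seed + index`; members failing the
  5 mV cutoff are retrained with fresh seeds up to `10 × ensemble_size`
  total attempts.
* **CV scope.** The 4-fold CV is a report, not a model-selection loop:
  final members train on all data minus their own early-stop split.
* **Ablation cost.** Leave-one-feature-out ablation refits the 4-fold
  CV with single members per fold rather than full 50-member ensembles.
  The ablation question — does removing a feature worsen held-out MAE —
  is answered by the CV route at a fortieth of the cost.

The generator `gen_zeta_table()` plants a known linear effect structure
(default: charge-dominant at 30 mV per elementary charge, so a fully
charged PG-like composition sits near −30 mV) with either homoscedastic
noise or per-row heteroscedastic sds drawn from 0.5–1.5 mV. It emulates
the statistical shape of a compiled literature table — feature ranges,
noise scale, reported measurement errors — but not the physics of the
electric double layer; a tree ensemble that recovers the planted effect
demonstrates the training machinery, not electrokinetic theory.

## Curve-level analysis

**Folding kinetics.** Traces are fitted to
$F(t) = F_0 + A\,(1 - e^{-k t})$, or to a two-phase sum with $k_1 > k_2$,
by Levenberg–Marquardt least squares from multi-start guesses
($k_0 \in \{1, 10, 100\}/t_\max$). The published criterion for adopting a
second phase — "high residual error" in one-phase fits — is quantified
here as: the two-phase fit must reduce RMSE by at least 20% *and* the two
rates must separate at least 3-fold. Both thresholds err on the side of
parsimony; a clean single-exponential trace with realistic noise never
triggers them. Traces below 75% completion are returned with
`accepted = FALSE` and the rate flagged unusable. Completion uses the
fitted fractional approach to the asymptote when no independent folding
yield is supplied; an externally measured folded fraction, when
available, takes precedence, since the fitted asymptote cannot
distinguish slow folding from low yield.

**Urea titrations.** Folded fraction versus urea is fitted to a
four-parameter logistic and summarized by the half-amplitude midpoint
$P_m$ with a standard deviation from the fit covariance. A logistic is
used rather than a thermodynamic linear-extrapolation model because
membrane-inserted OMPs resist complete unfolding even in 8 M urea, so
equilibrium free energies are not recoverable and only an apparent
midpoint is meaningful. Fits whose amplitude falls below 0.2 are refused
outright — reported midpoints from near-flat curves would be noise.

**Laurdan melting midpoints.** The gel–fluid transition temperature is
the extremum of the numerical first differential of generalized
polarization, GP = (I₄₄₀ − I₄₉₀)/(I₄₄₀ + I₄₉₀), versus temperature,
refined by a quadratic through the extremum and its neighbours. A curve
counts as having no transition when its median-centred derivative never
exceeds five times a noise floor estimated robustly (MAD of second
differences); this rejects both linear drifts and pure noise without any
free threshold parameter.

**Absorbance deconvolution.** Raw spectra are decomposed over reference
spectra (unlabelled liposomes, fluorophore alone) by non-negative least
squares minimizing the summed squared reconstruction error over the
measured range. Non-negativity is imposed because the scales are
physical concentrations, even though the source description does not
state it; nearly collinear references are flagged rather than silently
inverted.

## Permutation inference

`permutation_test()` uses the statistic mean(a) − mean(b) and assumes
exchangeability only under the null. All $\binom{n_a+n_b}{n_a}$ distinct
group reassignments are enumerated exactly when there are at most 10⁶
(far above every replicate count in practice); otherwise distinct
assignments are sampled without replacement by drawing combination ranks
and unranking them, with the observed labelling always included. The
p-value counts assignments *at least as extreme as* the observed one,
including the observed labelling itself. Strict "larger than" counting
would yield p = 0 for fully separated groups — impossible for a valid
permutation test — whereas inclusive counting gives the familiar
small-sample floors: 2/70 ≈ 0.029 two-sided for two groups of four.
Two-sided is the default; both one-sided directions are exposed. Urea
stability comparisons use the classical two-tailed paired t-test.

## Membrane-depth enrichment and the positive patch

Structures aligned in the membrane frame (z along the normal, origin at
the membrane centre, extracellular side positive) are pooled into 1 Å
slabs by Cα position, half-open $[i, i+1)$. Per-slab, per-amino-acid
enrichment is

$$E(s, r) = \log_2 \frac{c_{sr} + pc}{n_s q_r + pc}, \qquad
  q_r = \frac{b_r + pc}{B + 20\,pc},$$

the log₂ ratio of the observed count to the count expected under the
background composition, with a 0.5 pseudocount. The background is either
the whole-protein composition or the soluble regions only; in
soluble-only mode transmembrane residues are excluded from both slabs
and background — the mode in which the positive patch emerges, because
the hydrophobic-biased transmembrane composition otherwise skews the
statistics. Two deliberate statistical choices:

* **Regularizing the expectation, not both frequencies.** The common
  alternative — pseudocounting both the slab and background *frequency*
  vectors — assigns zero-count cells in sparsely populated slabs a
  spuriously *positive* enrichment of $\log_2\!\big((B+20pc)/(n_s+20pc)\big)$,
  flagging residues as enriched exactly where they are absent. The
  observed-versus-expected form keeps such cells on the depletion side,
  makes a uniform-composition profile exactly zero, and scores a doubled
  frequency as ≈ +1 log₂ unit.
* **Significance thresholds.** The 2σ/3σ thresholds are computed
  separately for enrichment and depletion as the standard deviations of
  the positive and negative enrichment values, over cells within 50 Å of
  the membrane centre (so sparse far-field slabs do not dominate), and
  only when a side has at least 10 cells (a σ from a handful of values
  is meaningless). Empty slabs are NA, never zero.

`detect_positive_patch()` pools Lys + Arg counts per slab on the
extracellular side and reports the maximal contiguous run exceeding
2σ, located relative to the outer-leaflet plane. A patch call requires
at least 2 contiguous slabs by default: at a 2σ threshold, isolated
single-slab excursions arise by chance in roughly half of null cohorts,
while the band of interest spans ~4 slabs. Contiguity is judged over
*populated* slabs, since unpopulated slabs carry no evidence either way.

**Sequence mode.** For topology-annotated sequences without coordinates,
`calibrate_distance()` learns the monotone mapping from residue count
(sequence distance from the membrane boundary) to median |z| over loop
residues of calibration structures, with isotonic regression enforcing
monotonicity and offsets observed fewer than 10 times flagged
low-confidence. `sequence_enrichment()` then places loop/turn residues
at their calibrated pseudo-depths — extracellular loops positive,
periplasmic turns negative, soluble stretches inheriting the sign of
their membrane-flanking neighbour — and reruns the identical slab
machinery. Because every residue at offset $k$ maps to one depth, the
effective resolution is one residue count (~3 Å) per populated slab;
patch calls on sequence-derived profiles therefore use `min_slabs = 1`.

## Lipid–protein contacts and occupancy

A residue and a lipid molecule are in contact in a frame when any bead
pair lies within 0.55 nm, counted once per residue–molecule pair per
frame (which keeps the subsequent normalization interpretable as
contacts per lipid per frame). Counts are normalized by the absolute
lipid count per species and the frame number; mole-fraction
normalization differs only by a constant per system and absolute counts
are the less ambiguous convention. Periodic distances use the
orthorhombic minimum-image convention; triclinic boxes are rejected
with a clear error rather than mis-measured. Site occupancy follows the
dual-cutoff hysteresis scheme of residence-time analysis: a molecule
binds when its minimum distance to the site drops to 0.475 nm and
unbinds only past 0.8 nm, suppressing rapid rebinding artifacts;
occupancy is the fraction of frames with at least one bound lipid of
the species.

## The synthetic-data generators

Every input class has a generator with a machine-readable ground truth,
so each analysis stage is tested by parameter recovery rather than
against fixtures. Preset truths are anchored to the headline measured
quantities of the study system: DMPC folding at $k_{obs} = 5\times10^{-4}$ s⁻¹
and DMPG at 44-fold faster (satisfying the observed "more than 40-fold"
contrast); urea midpoints of 4.5 M (DMPG) and 2.3 M (DMPC); laurdan
melting midpoints of 24 °C (DMPC) and 23 °C (DMPG). The two-phase
kinetics preset ($k_1 = 10^{-2}$, $k_2 = 5\times10^{-4}$ s⁻¹, equal
amplitudes) is an invented but representative biphasic system. Noise
defaults: 1% of amplitude for kinetic traces, 0.03 absolute for
titration fractions, 0.002 GP units for laurdan curves.

`gen_membrane_cohort()` builds idealized β-barrels: even numbers of
transmembrane strands crossing ±15 Å (a typical hydrophobic
half-thickness) with hydrophobic-biased composition, extracellular loops
of 6–14 residues arcing at ~3 Å per residue with 1 Å vertical jitter,
short periplasmic turns, uniform loop/turn composition except inside the
planted band where the Lys/Arg probability is multiplied by the excess
factor. The default cohort size of 75 matches a realistic
clustered experimental-structure cohort. Matched sequence records are
derived from the same chains so the two analysis modes share one ground
truth. `gen_trajectory()` plants binder lipids following a two-state
Markov (telegraph) process with stationary bound fraction $f$ and mean
bound dwell of 3 frames; bound positions lie within the short cutoff of
the site, unbound positions and all background lipids stay beyond the
long cutoff, so the realized bound fraction is exactly recoverable from
occupancy analysis.

What the generators do *not* emulate — and hence what passing tests do
not show — includes: real electric-double-layer physics behind ζ
(features are statistically, not physically, coupled), instrument
artifacts (drift, inner-filter effects, photobleaching), real β-barrel
geometry (shear, tilt, loop secondary structure), lipid diffusion and
membrane undulations, and the composition biases of real OMP databases.
Parameter recovery on these generators validates the estimators and
their error handling, not biological conclusions.

## Problem sizes and numerical conventions

The test and acceptance workloads are sized for interactive use: 315-row
ζ tables (the compiled-table scale), 50-member ensembles, 400-point
kinetic traces, 17-point titrations, 81-point laurdan curves, cohorts of
75 barrels and 20-cohort recovery sweeps, and trajectories of a few
thousand frames. Nonlinear fits report failure only after all
multi-start guesses fail; ties in the asymmetry classifier (both or
neither hypothesis within its band, including the degenerate
zero-fraction case where the two predictions coincide) return
"indeterminate" rather than forcing a label; and all generators are
bit-reproducible under a fixed seed.

## Known limitations

* The exchange plan records, but cannot re-derive, the saturation level;
  plans for donors outside the four calibrated headgroup classes require
  a user-supplied $K$.
* The enrichment σ thresholds are global per profile; residue-type
  stratified thresholds might behave differently for alphabets with very
  uneven abundance.
* The sequence-mode depth axis inherits the calibration cohort's loop
  geometry; sequences from proteins with much longer or shorter loops
  than the calibration set are extrapolated linearly beyond the last
  observed offset.
* The contact module reads a plain frame-table format; binary MD
  trajectory formats should be converted upstream or adapted through
  `as_trajectory()`.
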