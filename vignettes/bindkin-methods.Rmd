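---
title: "Models and numerical methods in bindkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in bindkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindkin)
```

bindkin implements the computational layer of a protein--ligand binding
study around human glutathione transferase P1-1 (hGSTP1-1) and
curcumin-analogue inhibitors: end-point binding-free-energy estimation
from molecular-dynamics interaction energies, steady-state inhibition
kinetics, and trajectory geometry analysis, together with seeded
synthetic-data generators that stand in for the raw simulations and
assays. This vignette documents the models, their assumptions, the
tunable parameters, and the numerical decisions, in that order.

## End-point binding free energies (LIE and LRA)

The linear interaction energy (LIE) estimator approximates the binding
free energy of a ligand L to a solvated protein site P from four mean
interaction energies sampled along equilibrium simulations of the bound
and the free (aqueous, W) states:

$$\Delta G_{\mathrm{bind}} =
  \alpha\left(\langle V_{\mathrm{vdW}}^{L-P}\rangle -
              \langle V_{\mathrm{vdW}}^{L-W}\rangle\right) +
  \beta \left(\langle V_{\mathrm{ele}}^{L-P}\rangle -
              \langle V_{\mathrm{ele}}^{L-W}\rangle\right)$$

The linear response approximation (LRA) adds a preorganization term
$\beta\,\langle V_{\mathrm{ele}}^{L-P}\rangle_0$, the ligand--protein
electrostatic energy sampled with all ligand partial charges set to
zero. A negative value means the binding-site dipoles are already
oriented favourably toward the uncharged ligand shape.

Assumptions worth keeping in mind: electrostatics respond linearly to
charging (the LRA premise), the van der Waals term scales linearly with
a transferable coefficient, and the sampled means are converged --- the
estimator sees only first moments, so all sampling error enters through
the standard error of the mean.

**Coefficients.** `lie_coefficients()` defaults to $\alpha = 0.5$,
$\beta = 1.043$, the Paulsen--Ornstein refinement appropriate for
polar, buried binding sites; the original Åqvist $\beta = 0.16$ is a
legitimate alternative for less polar sites and can be selected
explicitly, but is never applied silently, because the two conventions
differ by a factor of six in the electrostatic weight.

**Replicates.** `aggregate_replicates()` summarises independent
production runs as mean and sample standard deviation ($n-1$
denominator) of the per-replicate $\Delta G$ values. We deliberately do
not propagate per-component standard deviations through the estimator:
components sampled from the same run are correlated, and the spread of
independent replicate estimates is the honest dispersion measure.

**Experimental reference.** `ki_to_free_energy()` converts an
inhibition constant via $\Delta G = RT\ln(K_i/c^\circ)$ with
$c^\circ = 1\,$M. The default temperature is 310.15 K with
$R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$: this is the unique
choice that reproduces the published experimental free energies bundled
in `gstp1_inhibition_constants()` at their printed precision, even
though the assays themselves ran at 25 °C; both values are plain
arguments. Three entries of that reference table do not survive the
round trip: one $K_i$ row is inconsistent by 0.36 kcal/mol (flagged
`consistent = FALSE`), and two $K_i'$ entries sit one unit in the last
printed digit away from the conversion --- no single temperature
reconciles them with the remaining rows, so they are flagged
`prime_consistent = FALSE` rather than silently absorbed.

## Inhibition kinetics

All three inhibition types are special cases of one general-modifier
rate law in which the inhibitor binds the free enzyme E (constant
$K_i$) and the enzyme--substrate complex ES (constant $K_i'$), and the
ternary ESI complex retains a fraction $b$ of the catalytic rate:

$$v = \frac{V_{\max}\,S\,(1 + b I/K_i')}
           {K_m (1 + I/K_i) + S (1 + I/K_i')}$$

$b = 0$ gives linear mixed inhibition, $b = 0$ with $K_i = K_i'$ pure
non-competitive inhibition, and $b > 0$ partial (hyperbolic) mixed
inhibition. The published study names these cases without printing the
law; this general-modifier form is the standard parameterisation that
reduces to every named case, which is why the package adopts it.

**The replot chain.** `lineweaver_burk()` fits $1/v$ on $1/S$ by
unweighted ordinary least squares within each inhibitor level ---
deliberately mirroring how such plots are drawn in practice, so that
the diagnostics match the figures practitioners actually inspect. Under
the law above the primary slope and intercept are

$$\mathrm{slope}(I) = \frac{K_m}{V_{\max}}\,
    \frac{1 + I/K_i}{1 + bI/K_i'}, \qquad
  \mathrm{int}(I) = \frac{1}{V_{\max}}\,
    \frac{1 + I/K_i'}{1 + bI/K_i'}$$

both linear in $I$ exactly when $b = 0$ and hyperbolic otherwise ---
the "parabolic" secondary replot that signals partial inhibition.

**Curvature decision.** The published account calls the secondary
replot parabolic without stating a criterion, so the package makes one
explicit: a nested-model F-test of quadratic versus linear at
$\alpha = 0.05$ (configurable), applied to both the slope and the
intercept replots. Noiseless linear data leave a floating-point-zero
linear residual, which is classified as linear directly rather than
through the 0/0 F-ratio. Fewer than four inhibitor levels leave no
residual degrees of freedom and return "inconclusive" rather than an
error. Automatic model selection in `inhibition_fit()` keys on the
slope replot only --- the canonical signature of hyperbolic inhibition
--- since driving selection from either replot would double the false
positive rate under noise. The test's power depends on the design: inhibitor levels should
bracket $K_i'$, because far above it the hyperbola saturates and the
curvature information vanishes. That is how such assays are designed in
practice (the partial-mixed reference design uses 0--7 uM around
$K_i' = 1.45$ uM), and the classifier tests follow that design.

**Tertiary replot.** For $I > 0$, both reciprocal increments are
exactly linear in $1/I$:

$$\frac{1}{\Delta\mathrm{slope}} =
   \frac{V_{\max}/K_m}{1/K_i - b/K_i'}\left(\frac{1}{I} +
   \frac{b}{K_i'}\right), \qquad
  \frac{1}{\Delta\mathrm{int}} =
   \frac{V_{\max}K_i'}{1-b}\,\frac{1}{I} + \frac{V_{\max}\,b}{1-b}$$

With $V_{\max}$ and $K_m$ from the uninhibited primary fit, the two
fitted lines invert in closed form: $b = c_i/(V_{\max}+c_i)$ from the
intercept-line intercept $c_i$, then $K_i'$ from its slope, then $K_i$
from the slope-line slope. At $b = 0$ this reduces to the familiar
linear-mixed expressions. A sign change in the increments across $I$
indicates the data do not follow the assumed law and is reported as an
error rather than averaged over.

**Global fit.** `inhibition_fit()` reports parameters from a direct
weighted nonlinear least-squares fit of the rate law on $(S, I, v)$
(Levenberg--Marquardt), using the replot estimates only as starting
values: reciprocal transforms distort the error structure, so the
replots serve as diagnostics and initialisation while the direct fit
provides the estimates and standard errors. Default weights are
$1/v^2$, matching the multiplicative error of initial-velocity assays;
uniform weights are available. The optimiser first runs at very tight
tolerances (needed to recover noiseless parameters to more than six
significant digits) and falls back to default tolerances if the
zero-residual optimum makes the post-fit model construction report a
singular gradient.

**Dose--response.** `ic50_fit()` fits the four-parameter logistic on
$\log_{10}$ concentration, with the asymptotes free by default or
pinned via `constrain = c(100, 0)`. Zero concentrations cannot sit on
the log axis; they are dropped with a warning and should define the
100 % normalisation upstream (`percent_viability()`,
`percent_inhibition()`). The fit uses the raw Levenberg--Marquardt
interface: noiseless curves that never approach one asymptote have a
near-singular 4PL Jacobian at the optimum, which the `nls`-object
interface refuses even though the optimisation itself is
well-behaved. For pure non-competitive inhibition the remaining
activity is $1/(1+I/K_i)$ at every substrate concentration, so the
fitted IC50 equals $K_i$ independently of $S$ --- a property the tests
exploit as an internal consistency check between the two modules.

## Trajectory geometry

**Superposition.** `kabsch_superpose()` implements the closed-form SVD
solution with reflection correction (the rotation determinant is always
+1). Collinear or undersized atom sets are rejected. The test suite
cross-checks it against a rotation-search oracle (random quaternions
plus Nelder--Mead refinement, no SVD anywhere) and against an
established reference implementation.

**RMSD and RMSF.** `rmsd_series()` follows the two-selection protocol:
superpose each frame on a fit selection, then measure RMSD over a
measure selection without refitting --- e.g. ligand RMSD after an
active-site backbone fit. The active-site backbone is defined as
backbone N/CA/C/O of residues with any atom within 10 Å of the ligand
in the reference frame (`select_atoms(within_of = ...)`); the cutoff is
an argument because no published enumeration of the set exists.
`rmsf()` measures per-atom fluctuation about the mean position after
frame-wise fitting; ligand RMSF can be computed after a protein fit or
after a ligand self-fit, since conventions differ, by passing the
corresponding `fit_selection`.

**Interaction detection.** `detect_interactions()` re-implements the
published PLIP geometric rules: hydrogen bonds (donor--acceptor
$\le 4.1$ Å, donor angle $\ge 100^\circ$), hydrophobic carbon--carbon
contacts ($\le 4.0$ Å), $\pi$-stacking (centroid $\le 5.5$ Å, plane
angle within 30° of parallel or perpendicular, offset $\le 2.0$ Å) and
$\pi$-cation contacts ($\le 6.0$ Å). All cutoffs are arguments of
`interaction_criteria()`. Supporting perception is deliberately
minimal and geometric: bonds by the additive covalent-radius rule
($d \le r_i + r_j + 0.4$ Å, stable under thermal jitter), donors as
N/O with an inferred bonded hydrogen, acceptors as all N/O, apolar
carbons as C with no bonded N/O, cations as lysine/arginine side-chain
nitrogens, and aromatic rings as planar 5-/6-membered C/N cycles found
by depth-first search on the bond graph. When a structure carries no
hydrogens at all, every N/O is treated as a potential donor and the
angle criterion is waived --- a documented downgrade, since snapshot
PDB files frequently lack hydrogens. `occurrence()` reports, per
interaction key, the percentage of frames containing at least one
matching event, pooled over all frames scanned, with the mean distance
alongside.

## Synthetic data: what it emulates, and what it does not

`gen_energy_series()` draws stationary AR(1) series with exact target
means, emulating the one property of MD energy traces that matters for
mean estimation: slow decorrelation. The effective sample size
$n(1-\rho)/(1+\rho)$ (`effective_sample_size()`) governs every
convergence tolerance in the tests. Defaults --- four replicates,
per-frame $\sigma$ of order 1.5 kcal/mol, $\rho = 0.8$ --- are chosen
to resemble well-equilibrated production runs at a desk-scale frame
count of 2000 per replicate.

`gen_kinetic_data()` draws velocities from the rate law on log-spaced
substrate grids spanning the standard assay ranges (CDNB 14--1000 uM,
GSH 37.5--3750 uM) with inhibitor levels in 0--50 uM, multiplicative
Gaussian noise at 2 % CV, and triplicates --- the error model of
triplicate initial-velocity measurements.

`gen_toy_trajectory()` jitters a hard-coded ~60-atom synthetic complex
(`toy_complex()`: a zig-zag peptide-like fragment with one aromatic
ring, an ammonium nitrogen and a hydroxyl probe acceptor, plus a
phenol-like ligand) with iid isotropic Gaussian noise. The first frame
is the unjittered template --- the reference configuration --- so the
expected RMSD of later frames is exactly $\sigma\sqrt{3}$ and the
expected RMSF converges to the same value. The serine probe acceptor is
placed in hydrogen-bond geometry in an independent Bernoulli($p$)
subset of frames, giving the occurrence statistics an exact ground
truth. Every generator is a pure function of its spec, seed included.

What the generators do **not** emulate: force-field physics,
correlated collective motions, conformational transitions, solvent
structure, or heteroscedastic assay drift. Passing recovery tests on
these synthetics therefore demonstrates the correctness of the
estimators and their statistical calibration --- not that real
trajectories or assays satisfy the generating assumptions.

## Numerical choices and degenerate inputs

* Velocities $\le 0$ are rejected before reciprocal transforms;
  inhibitor groups with fewer than three substrate levels are skipped
  with a warning; a missing $I = 0$ group is an error.
* Replot-based starting values fall back to secondary-line ratios and
  then to crude medians when the tertiary mapping is not computable;
  the global fit restarts once from neutral values before reporting a
  convergence error.
* All-identical velocities, all-identical responses, fewer than five
  dose levels, empty atom selections, single-frame RMSF, and sub-3-atom
  or collinear superpositions are rejected with specific errors.
* Energies are kcal/mol and concentrations uM throughout the kinetics
  CSV dialect; Ki values enter `ki_to_free_energy()` in molar units.
  No unit auto-detection is attempted.
* PDB round trips are exact to the format's three printed decimals;
  residue numbers pass through verbatim with no renumbering.

Test problem sizes are chosen for tight statistical bounds at
interactive runtimes: 2000-frame trajectories (binomial occurrence SE
0.8 %, RMSF within 5 %), 100-seed recovery studies for the kinetics
calibration, and 50 random instances for the superposition oracle.

## Known limitations

* The replot classifier inherits the power limitations of the F-test:
  designs whose inhibitor levels saturate the ESI hyperbola cannot
  distinguish partial from linear inhibition, whatever the software
  does.
* Interaction perception has no aromaticity model beyond planarity and
  no formal-charge model beyond side-chain naming; exotic ligands need
  explicit criteria or selections.
* Water-bridged, halogen-bond and salt-bridge interactions are not
  detected.
* The two-substrate (GSH + CDNB) bi-bi mechanism is not modelled; each
  substrate is analysed with the other held at its assay concentration,
  as in the underlying experiments.
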