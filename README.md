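# bindkin

Binding free energies, inhibition kinetics and trajectory geometry for
protein–ligand studies, built around the analysis of curcumin-analogue
inhibitors of human glutathione transferase P1-1 (hGSTP1-1).

hGSTP1-1 is a detoxification enzyme overexpressed in many tumours,
where it contributes to drug resistance; small-molecule inhibitors of
its glutathione/CDNB conjugation activity are of direct pharmacological
interest. Characterising such inhibitors requires three kinds of
computation that this package provides as one tested toolchain:

1. **End-point binding free energies.** The linear interaction energy
   (LIE) estimator
   `ΔG = α(⟨V_vdW⟩_bound − ⟨V_vdW⟩_free) + β(⟨V_ele⟩_bound − ⟨V_ele⟩_free)`
   and its linear-response (LRA) extension, which adds the
   preorganized-electrostatics term `β⟨V_ele⟩₀` sampled with ligand
   charges zeroed. Defaults α = 0.5, β = 1.043; replicate aggregation
   as mean ± sample SD; plus the experimental reference conversion
   `ΔG = RT ln(Ki/c°)`.
2. **Inhibition kinetics.** The general-modifier rate law
   `v = Vmax·S·(1 + b·I/Ki′) / (Km(1 + I/Ki) + S(1 + I/Ki′))`
   covering pure non-competitive (`Ki = Ki′`, `b = 0`), linear mixed
   (`b = 0`) and partial (hyperbolic) mixed inhibition (`b > 0`); the
   Lineweaver–Burk primary/secondary/tertiary replot chain with an
   explicit F-test curvature criterion; direct nonlinear global fitting
   of `Vmax, Km, Ki, Ki′, b`; four-parameter-logistic IC50 fits; and
   assay-unit helpers (ε = 9600 L·mol⁻¹·cm⁻¹ at 340 nm).
3. **Trajectory geometry.** Kabsch superposition, two-selection
   RMSD series and per-atom RMSF, and PLIP-style geometric detection of
   hydrogen bonds, hydrophobic contacts, π-stacking and π-cation
   interactions with per-frame occurrence (occupancy) statistics, on
   multi-model PDB trajectories.

A fourth module generates synthetic inputs with exact ground truth
(AR(1) interaction-energy series, rate-law velocity tables, jittered
toy-complex trajectories), so every estimator is tested against known
answers. See `vignette source in vignettes/bindkin-methods.Rmd` for the
models, assumptions and numerical decisions.

## Worked example

Binding free energies for the strongest inhibitor, DM96, from the
bundled reference interaction-energy components:

```r
library(bindkin)
row <- subset(gstp1_energy_means(), ligand == "DM96")
cmp <- energy_components(row$vdw_bound, row$vdw_free,
                         row$ele_bound, row$ele_free,
                         row$ele_bound_uncharged)
lie_free_energy(cmp)
#> Binding free energy [LIE]: -7.84 kcal/mol
lra_free_energy(cmp)
#> Binding free energy [LRA]: -8.13 kcal/mol
ki_to_free_energy(3.67e-6)   # its measured Ki, 3.67 uM
#> Binding free energy [experimental (RT ln Ki)]: -7.71 kcal/mol
```

The LIE estimate (−7.84) and the experimental value from the inhibition
constant (−7.71) agree to about 0.1 kcal/mol; LRA adds the favourable
preorganization term (−0.28 kcal/mol, scaled by β).

Recovering inhibition constants from a synthetic triplicate assay with
2 % multiplicative noise, generated from the linear-mixed truth
`Ki = 3.67`, `Ki′ = 4.97` μM:

```r
truth <- kinetic_parameters(Vmax = 100, Km = 100, Ki = 3.67,
                            Ki_prime = 4.97)
d <- gen_kinetic_data(kinetic_generator_spec(truth, cv = 0.02,
                                             replicates = 3, seed = 42))
summary(inhibition_fit(d))
#> Inhibition fit: linear_mixed model, n = 126
#>          estimate std_error
#> Vmax      100.515   0.74038
#> Km        100.011   1.35548
#> Ki          3.615   0.04349
#> Ki_prime    4.942   0.05941
#> Secondary replots: slope linear, intercept nonlinear
```

The model is selected automatically from the secondary slope replot
(linear ⇒ not hyperbolic), and both constants are recovered within
about 1.5 % of the generating truth.

Hydrogen-bond occupancy on a synthetic trajectory whose probe bond is
formed with probability 0.85 per frame:

```r
tr <- gen_toy_trajectory(trajectory_generator_spec(sigma = 0.1,
                                                   p_hbond = 0.85,
                                                   frames = 300,
                                                   seed = 1))
occurrence(interaction_events(tr), n_frames(tr))
#>          type residue resno occurrence mean_distance n_frames_present
#> 1 hydrophobic     PHE     5      100.0          3.84              300
#> 2    pi_stack     PHE     5      100.0          3.80              300
#> 3   pi_cation     LYS     6      100.0          4.50              300
#> 4       hbond     SER     7       85.7          2.90              257
```

A command-line front-end over the same functions lives at
`inst/cli/bindkin` (subcommands `lie`, `lra`, `ki2dg`, `kinfit`,
`ic50`, `rmsd`, `rmsf`, `interactions`, `simulate`).

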