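# placentaflux

Kinetic simulation of tracer phenylalanine transfer across the ex vivo
dually perfused human placental cotyledon, for placental physiologists and
modellers who want to ask *what limits amino acid delivery to the fetus* —
flow, membrane transport, or intracellular metabolism.

The placenta is represented as three well-mixed compartments — maternal
intervillous space (m), syncytiotrophoblast (s), fetal capillary (f) —
coupled by carrier kinetics and flow:

- MVM and BM **exchanger** (antiporter, trans-stimulated):
  `J_ex = V_ex (A_I R_II − A_II R_I) / (K_ex (Tot_I + Tot_II)/2 + Tot_I Tot_II)`
- BM **facilitated transporter**:
  `J_fa = V_fa (A_s/(K_fa + Tot_s) − A_f/(K_fa + Tot_f))`
- **flow** `F (A_in − A)`, **metabolism** `k_metab A_s` (protein
  incorporation), **paracellular diffusion** `V_dif (A_m − A_f)`

with `d[A]_i/dt` given by the signed sum of these fluxes over `v_i`.
Endogenous amino acids enter as two constant generic pools (substrates of
facilitated+exchange carriers, and of exchangers only), so carrier fluxes
are trans-stimulated by the millimolar intracellular amino acid content
while the tracer itself stays in the linear regime.

On top of the core model the package provides the stepwise maternal/fetal
flow protocol of the dual perfusion experiment (3 × 3 flow design plus
baseline and wash), steady-state analysis, deterministic calibration of the
unpublished maximal rates against uptake/transfer observables, five-fold
parameter sensitivity analysis, two-way flow ANOVA and model-versus-data
regression, the radiotracer mass-balance arithmetic (quench correction,
free/protein partition, tissue concentration, basal-membrane gradient), and
a synthetic perfusion-dataset generator with known ground truth.

## Worked example

```r
library(placentaflux)

traj <- simulatePerfusion()     # default 225-min protocol, full model
traj
#> Perfusion trajectory: 225 min, variant 'transport+metabolism', 40 samples
#>   cumulative uptake 4.594e-09 mol, transfer 7.624e-10 mol, metabolised 3.101e-09 mol
#>   mass-balance residual 5e-15 (relative)

accountFromTrajectory(traj)
#> Tracer account (nmol per cotyledon):
#>   uptake 4.59, transferred 0.762 (17%), retained 3.83
#>   recovered 0.731 free + 3.1 protein = 3.83 (100% of retained)
#>   trophoblast free tracer 116 nmol/l
```

The cotyledon takes up ~4.6 nmol of tracer over the experiment and passes
less than a fifth of it to the fetal circuit; the rest is incorporated into
protein or remains free in the tissue.  Because the simulator conserves
tracer exactly (residual 5e-15), its accounting chain recovers 100% of the
retained tracer — the benchmark against which incomplete experimental
recoveries are judged.  (The free tissue tracer reads 116 nmol/l here
because the 15-min wash clears part of it; at the end of the tracer
infusion it stands at 163 nmol/l.)

```r
g <- predictGrid()              # quasi-steady uptake/transfer per condition
round(data.frame(F_m_ml = g$F_m*1e3, F_f_ml = g$F_f*1e3,
                 uptake_pmol_min = g$uptake*1e12,
                 transfer_pmol_min = g$transfer*1e12), 3)
#>   F_m_ml F_f_ml uptake_pmol_min transfer_pmol_min
#> 1     10      3          17.930             2.204
#> 2     10      6          17.930             3.051
#> 3     10      9          17.930             3.509
#> 4     14      3          22.129             3.000
#> 5     14      6          22.129             3.980
#> 6     14      9          22.129             4.474
#> 7     18      3          25.438             3.676
#> 8     18      6          25.438             4.749
#> 9     18      9          25.438             5.260
```

Uptake rises ~40% from the lowest to the highest maternal flow and is
identical across fetal flows — tracer delivery to the MVM exchanger is
rate-limiting.  Run `predictGrid(mode = "physiological")` to see that
dependence collapse when maternal amino acids are at physiological levels,
or `predictGrid(variant = modelVariant("diffusion"))` for the
fetal-flow-dominated pattern a pure diffusion pathway would give.

Synthetic experiments with known truth:

```r
ds <- generatePerfusionDataset(nPlacentas = 5, noiseCv = 0.1, seed = 1)
datasetSummary(ds)              # per-condition means ± SE
flowAnova(ds, "uptake")         # two-way ANOVA on the flow design
```

See the vignette (`vignettes/placental-transfer-model.Rmd`) for the model's
assumptions, the calibration of the default parameters, and known
limitations.

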