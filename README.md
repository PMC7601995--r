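# nanoqnar

Atomistic nanodescriptors and kNN read-across modelling of metal-oxide
nanoparticle cytotoxicity.

## What this package is for

Predicting how toxic a metal-oxide (Me<sub>x</sub>O<sub>y</sub>)
nanoparticle is to cells — its % cell viability in ATP or LDH assays — is
a central problem in nanosafety and safe-by-design nanomaterial
development. `nanoqnar` implements a full quantitative
nanostructure–activity relationship (QNAR) workflow for this problem,
aimed at computational toxicologists and nanoinformatics practitioners:

1. **Nanoparticle construction.** Starting from a bulk crystal structure
   (CIF), a supercell is replicated, a spherical particle is carved,
   electroneutrality is restored by removing outermost excess ions, and
   the cluster is relaxed by Polak–Ribière conjugate-gradient
   minimisation. Energetics are Buckingham pair potentials,
   *E(r) = A e^(−r/ρ) − C/r⁶*, plus Coulomb interactions under the
   damped, energy-shifted Wolf summation, with the Wolf parameters
   calibrated against a direct-sum Madelung reference.
2. **62 atomistic nanodescriptors.** The relaxed particle is split into a
   1 nm surface *shell* and an interior *core*, and statistics are
   computed over atom scopes (all/metal/oxygen) × regions
   (whole/core/shell): composition (9), mean potential energy (9), mean
   coordination number within *R = 1.2 (R_M + R_O)* (9), lattice-energy
   aggregates (5), size (3) and force-vector statistics (27) including
   the surface-normal force component
   *V = (x f_x + y f_y + z f_z)/d* about the centre of mass.
3. **Read-across model.** A modelling table of 77 independent variables
   (15 experimental/molecular + 62 atomistic) is cleaned with a 20%
   shared-value redundancy filter, Z-score normalised on the training
   split, split 70/30, reduced by correlation-based feature selection
   (CFS merit with best-first search), and fitted with a k-nearest-
   neighbour regressor (Euclidean distance, 0/1 for nominal features,
   unweighted mean of 3 neighbours). Validation follows the OECD-style
   suite: Tropsha external statistics (R²_pred, R²_cvext, through-origin
   k, k′, R₀², R₀′²), Y-randomisation, and an applicability domain
   APD = ⟨d⟩ + 0.5 σ on training distances.
4. **Batch prediction service.** JSON/CSV request tuples with the seven
   deployed descriptors (`id, coreSize, hydroSize, ecEv, assay,
   exposureDose, des306, des606`) are validated, normalised with the
   stored training statistics and answered with the full response record:
   four nearest neighbours with distances, normalised inputs, the kNN
   prediction and the APD reliability flag.

Everything is testable offline: toy rock-salt crystals, a synthetic force
field and planted-signal modelling tables are generated in code.

## Worked example

Train the pipeline on the bundled synthetic screening study (24 oxide
materials × log-spaced dose series × both assays) and serve a prediction
request:

```r
library(nanoqnar)

tab <- make_service_table(seed = 5)     # 288 experiment records
fit <- qnar_train(tab, split_seed = 5)
print(fit)
#> QNAR read-across bundle (nanoqnar-bundle-1)
#> Selected features: ecEv, exposureDose, des606
#> Training rows: 202 ; neighbours: 3
#> APD threshold: 1.7106 (Z = 0.5)
#> Tropsha validation: R2_pred=0.8116 R2_cvext=0.8115
#> k=1.0164 k'=0.8969 R0^2=0.7552 R0'^2=0.7845
#> -> predictive (all criteria pass)
```

The report says the held-out test set is predicted with R² = 0.81, the
through-origin regression slopes in both directions are within the
0.85–1.15 acceptance band, and all external-validation criteria pass.
Feature selection kept the conduction-band energy, the exposure dose and
the surface-normal force descriptor. Now a prediction request:

```r
req <- parse_requests('[{"id":"CuO","coreSize":25,"hydroSize":45,
  "ecEv":-5.17,"assay":"ATP","exposureDose":3.2,
  "des306":3.579,"des606":-0.243}]')
rec <- predict_batch(fit, req)
rec[, c("id","assay","apdPrediction","nn1ID","nn1Distance",
        "knnprediction","viabilityPercent")]
#>    id assay apdPrediction nn1ID nn1Distance knnprediction viabilityPercent
#> 1 CuO   ATP      reliable   HfO       0.322          1.72             92.7
```

The record reports the nearest training neighbour and its Euclidean
distance in normalised feature space, the prediction on the normalised
endpoint scale (`knnprediction`), the same number denormalised to % cell
viability (`viabilityPercent`), and the applicability-domain verdict:
this query lies inside the model's reliability domain.

Building a particle and its descriptors from a crystal structure:

```r
m <- make_material_set(1)[[1]]          # toy rock-salt oxide + force field
res <- build_and_describe(m$cell, m$ff, m$radii, radius = 8,
                          shell_depth = 4, tol = list(maxit = 40))
length(res$descriptors)                 # 62
res$descriptors["cn_mean_metal_shell"]  # "des306"-style surface CN
```

A thin command-line front end (`inst/cli/nanoqnar`) wraps the same
functions as `build`, `describe`, `train`, `predict`, `validate` and
`fixtures` subcommands.

## Real data

The package ships no measured dataset. To model real oxides, supply a
curated modelling table (e.g. a NanoPharos-style CSV export) via
`modeling_table()`, bulk structures as CIF files, force-field parameter
files in the documented plain-text format (`read_forcefield()`), and
ionic radii via `radii_table()`. Quantum-chemical inputs (E_V, E_C, E_g,
electronegativities, formation enthalpies) are external inputs by design.
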