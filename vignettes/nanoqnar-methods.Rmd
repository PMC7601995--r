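---
title: "Atomistic nanodescriptors and kNN read-across for metal-oxide nanoparticle cytotoxicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atomistic nanodescriptors and kNN read-across for metal-oxide nanoparticle cytotoxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoqnar)
```

## Scope and overview

`nanoqnar` implements a complete nanoinformatics chain for predicting the
cytotoxicity (% cell viability) of metal-oxide (Me~x~O~y~) nanoparticles:

1. **Particle construction** — a bulk crystal unit cell is replicated into a
   supercell, a sphere is carved out, electroneutrality is restored and the
   cluster is relaxed by conjugate-gradient energy minimisation under a
   Buckingham + Coulomb force field with Wolf-summed electrostatics.
2. **Nanodescriptors** — the relaxed particle is partitioned into a surface
   *shell* and an interior *core* and 62 atomistic descriptors are computed
   over the grid of atom scopes (all / metal / oxygen) and regions (whole /
   core / shell).
3. **Read-across modelling** — a modelling table of 77 independent
   variables (15 experimental/molecular + 62 atomistic) is filtered,
   Z-score normalised, split 70%/30%, reduced by correlation-based feature
   selection and fitted with a k-nearest-neighbour regressor; the model is
   validated with Tropsha's external statistics, Y-randomisation and a
   distance-based applicability domain, and exposed through a JSON/CSV
   batch-prediction interface.

This vignette records the model assumptions, the tunable parameters, the
numerical choices, and what the synthetic fixtures do and do not emulate.

## Particle construction

### Replication, carving, neutralisation

`replicate_cell()` translates the unit-cell sites over the lattice grid;
`carve_sphere()` keeps the atoms within a radius of a centre. The **carve
centre** defaults to the geometric centre of the supercell's coordinate
extents; it is configurable (e.g. to a lattice site) because the centre
choice changes the surface termination of the carved particle, and no
single convention is canonical.

Carving a charged sublattice imbalance is unavoidable, so `neutralize()`
removes ions of the over-represented charge sign until the total formal
charge is exactly zero. The removal rule is deterministic: outermost atoms
first (largest distance from the carve centre), ties broken by species
symbol and then input order. Removing surface ions (rather than random or
innermost ones) mimics the physical intuition that excess surface ions are
the least bound, and keeps the interior stoichiometric.

### Energetics

Short-range repulsion/dispersion is the Buckingham pair potential

$$E_B(r) = A\,e^{-r/\rho} - C/r^6, \qquad r \le r_\mathrm{cut},$$

truncated to exactly zero beyond the per-pair cutoff. Electrostatics use
the damped, energy-shifted Wolf summation: for $r_{ij} \le R_c$

$$E_{ij} = k_e\, q_i q_j \left[\frac{\operatorname{erfc}(\alpha
r_{ij})}{r_{ij}} - \frac{\operatorname{erfc}(\alpha R_c)}{R_c}\right],
\qquad
E_i^\mathrm{self} = -k_e \left[\frac{\operatorname{erfc}(\alpha R_c)}{2
R_c} + \frac{\alpha}{\sqrt{\pi}}\right] q_i^2,$$

with $k_e = 14.399645$ eV Å. Every pair term is split 50/50 between the
two partners so per-atom energies (needed for the core/shell descriptor
averages) sum exactly to the total. The particle is treated as an isolated
finite cluster: for pair potentials this is equivalent to a large periodic
box with no self-interaction, and it removes any box-size parameter.

**Wolf calibration.** `calibrate_wolf()` selects $(\alpha, R_c)$ on a grid
(default $\alpha \in \{0.10, 0.12, \dots, 0.50\}$ Å⁻¹, $R_c \in \{6, 7,
\dots, 14\}$ Å) by matching the Wolf electrostatic energy per unit cell of
the *infinite* crystal — each atom of one cell summed against its periodic
images within the cutoff — to an independent reference: the unscreened
direct Coulomb sum over growing cubic clusters ($2^3$, $4^3$, $6^3$ cells)
extrapolated linearly in $1/n$, which removes the leading surface term.
The matched quantity is therefore the Madelung energy per cell. On the
rock-salt fixture the optimum residual is below $10^{-3}$ relative, and
the calibrated energy agrees with the analytic Madelung constant
($M = 1.747565$) to about 0.5%. Matching in the periodic environment
rather than on a free-standing small cluster is essential: a finite
$2\times2\times2$ open cluster carries an irreducible several-percent
surface deficit relative to the bulk energy, which no damping parameter
can cancel.

### Minimisation

`minimize_energy()` is a Polak–Ribière nonlinear conjugate-gradient
minimiser with a backtracking Armijo line search (first trial step capped
at 0.1 Å of maximum displacement, sufficient-decrease constant $10^{-4}$,
halving on rejection, automatic steepest-descent restart when the search
direction loses descent). The $\beta$ coefficient is clipped at zero
(PR+), the standard safeguard against stagnation. Termination criteria,
all configurable through `tol`:

| control  | default | meaning |
|----------|---------|---------|
| `energy` | 1e-8    | relative energy change per accepted step |
| `force`  | 1e-4 eV/Å | maximum force component |
| `maxit`  | 1e5     | iteration cap |

Energy is non-increasing across accepted steps by construction, a property
asserted by the test suite, and analytic forces are validated against
central finite differences to better than $10^{-5}$ relative error. Two
divergence guards abort with diagnostics: inter-atomic fusion (any pair
below 0.5 Å is treated as infinite energy and never accepted) and
runaway energies.

## The 62-descriptor schema

`assign_regions()` tags an atom *shell* when its distance from the carve
centre is at least `nominal_radius - shell_depth`, else *core*. The
default shell depth is 10 Å (1 nm), the conventional surface-layer depth
for oxide nanoparticles; a depth at or above the radius degrades
gracefully to an all-shell particle with a warning.

The descriptor vector (`compute_descriptors()`, names in
`descriptor_names()`) is organised in six blocks over the $3 \times 3$
grid of scopes {all, metal, oxygen} × regions {whole, core, shell}:

| block | count | statistic |
|-------|-------|-----------|
| composition | 9 | atom count per scope × region |
| potential energy | 9 | mean per-atom energy (eV) |
| topology | 9 | mean coordination number |
| lattice energy | 5 | total E, per-atom E, core total, shell total, shell/total ratio |
| size | 3 | diameter, volume, surface area from the nominal radius |
| force vectors | 27 | mean surface-normal component, mean tangential magnitude, mean force magnitude (eV/Å) |

The **coordination number** counts neighbours within
$R = 1.2\,(R_M + R_O)$, where $R_M$ and $R_O$ are the ionic radii of the
metal and oxygen ions supplied through `radii_table()` (Shannon radii are
the natural source). For $R_M = 0.74$, $R_O = 1.40$ Å the cutoff is
2.568 Å, which in a rock-salt lattice with $a = 4.2$ Å captures exactly
the six nearest neighbours at 2.1 Å and excludes the second shell at
2.97 Å.

The **surface-normal force component** of an atom at position
$(x, y, z)$ relative to the particle centre of mass, carrying force
$(f_x, f_y, f_z)$, is

$$V = \frac{x f_x + y f_y + z f_z}{d}, \qquad d = \sqrt{x^2+y^2+z^2},$$

signed so that outward-pointing forces are positive. Averaged over the
shell metal atoms this is the "v⊥ Me atoms surface" descriptor served by
the prediction interface (`des606`); the shell-metal mean coordination
number is `des306`. Low surface coordination and large outward surface
forces both indicate dissolution-prone, surface-active particles.

Conventions for degenerate situations, chosen so that small test
particles remain processable: a statistic over an empty scope × region
cell is reported as 0 with a warning; an atom lying exactly on the centre
of mass (possible in perfectly symmetric carved lattices) has no defined
radial direction and contributes $V = 0$, consistent with its
symmetry-forced near-zero force. The centre of mass (mass-weighted, from
tabulated atomic masses) is used for the force projection only; region
assignment uses the carve centre, which defines the nominal radius.

## The read-across pipeline

`qnar_train()` chains the stages below; each is exported on its own.

* **Redundancy filter** (`redundancy_filter()`, criterion 0.2): scanning
  numeric descriptor columns in order, a later column is dropped when it
  shares at least 20% of its values (within $10^{-12}$) with an earlier
  retained column; zero-variance columns are dropped first. This
  reading — fraction of coincident values between column pairs — follows
  the stated removal rule for "double-compatible" descriptors.
* **Z-score normalisation** (`fit_normalizer()` / `apply_normalizer()`):
  per-column mean and *population* standard deviation are fitted on the
  training split only and applied to both splits and to all service
  queries; the endpoint is normalised too, which is why the service
  reports `knnprediction` on the normalised scale. The population/sample
  choice is irrelevant to the mean-0/sd-1 property and is absorbed by the
  train-only fit; population is used for consistency everywhere
  (including the applicability domain).
* **Split** (`split_train_test()`): random 70/30 with
  `|train| = round(0.7 n)`, reproducible under a seed.
* **Feature selection** (`cfs_merit()` + `best_first_select()`): the CFS
  merit of a subset of $k$ features is
  $k\,\bar r_{cf} / \sqrt{k + k(k-1)\bar r_{ff}}$ with $\bar r_{cf}$ the
  mean absolute Pearson correlation to the endpoint and $\bar r_{ff}$ the
  mean absolute pairwise feature correlation; nominal features enter via
  0/1 encoding and constant features contribute zero. Pearson correlation
  on the continuous data is used directly; the entropy-based
  discretisation some CFS implementations apply is deliberately not
  replicated for a continuous endpoint. The search is forward best-first
  with an open list, terminating after 5 consecutive non-improving
  expansions (the conventional termination), ties broken by column order.
  On up to ~10 features it provably attains the exhaustive-search optimum
  in the test suite.
* **kNN regression** (`knn_fit()` / `knn_predict()`): squared distance is
  the sum of squared z-score differences over numeric features plus a 0/1
  mismatch indicator per nominal feature (the assay label). The
  prediction is the unweighted mean endpoint of the `n_neighbors` nearest
  training rows; ties are broken by training-row order. The default is
  **3 neighbours**, and the four nearest neighbours' ids and distances
  are always reported for diagnostics regardless of `n_neighbors` — this
  reconciles a neighbour-count convention ambiguity (a "k = 2" that means
  three neighbours) with a response schema that prints four.

### Validation

`tropsha_suite()` computes, on the held-out test set:
$R^2_\mathrm{pred}$ (squared Pearson correlation),
$R^2_\mathrm{cv,ext} = 1 - \sum(y_i-\tilde y_i)^2 / \sum(y_i-\bar
y_{tr})^2$, the through-origin slopes $k = \sum y\tilde y / \sum \tilde
y^2$ and $k' = \sum y\tilde y / \sum y^2$, and the through-origin
determination coefficients $R_0^2$ and $R_0'^2$ in both regression
directions. The model is flagged predictive when $R^2_\mathrm{cv,ext} >
0.5$, $R^2_\mathrm{pred} > 0.6$, $(R^2 - R_0^2)/R^2 < 0.1$ in both
directions, $0.85 \le k, k' \le 1.15$ and $|R_0^2 - R_0'^2| < 0.3$.
Exactly-constant prediction or observation vectors make the
through-origin statistics undefined and raise an error rather than
returning NaNs.

`y_randomization()` permutes the endpoint (descriptors untouched), reruns
the entire pipeline per round (10 rounds by default) and reports the
per-round statistics next to the original; a real structure–activity
relationship degrades in essentially every round.

`apd_fit()` implements the applicability-domain threshold
$\mathrm{APD} = \langle d\rangle + Z\sigma$ with $Z = 0.5$. The phrase
"Euclidean distances of all particles in the training set" is ambiguous;
following the Enalos lineage, the default computes all pairwise training
distances, keeps those **below their grand mean**, and takes
$\langle d\rangle, \sigma$ over the kept subset (`refine = FALSE`
switches to plain all-pairs statistics, and the refined set falls back to
all pairs when empty). A query is classified *reliable* when its mean
distance to its `n_neighbors` nearest training rows is at most the
threshold — the same statistic the predictor uses, which keeps prediction
and reliability consistent.

Leave-many-out cross-validation is not implemented: the original fold
structure is unrecorded, so any specific k-fold scheme would claim a
fidelity it cannot have, and the external test split plus Y-randomisation
already cover the robustness surface the package validates.

### Service interface

`parse_requests()` / `predict_batch()` / `serialize_predictions()`
reproduce the deployed batch-prediction schema: requests carry exactly
`id, coreSize, hydroSize, ecEv, assay, exposureDose, des306, des606`
(unknown fields are rejected; validation errors name the record and
field), and responses carry the 18 printed fields — identity, APD flag,
four neighbour ids, six normalised inputs, four non-decreasing neighbour
distances and `knnprediction` on the normalised endpoint scale — plus an
additive `viabilityPercent` column with the denormalised prediction,
because a percent-viability number is what a risk assessor ultimately
wants. Transport is CLI/file based (`inst/cli/nanoqnar`); no HTTP server
is bundled, since deployment infrastructure is out of the package's
scope and the record-level contract is fully exercised through files.

## Synthetic fixtures: what they emulate and what they do not

Everything in the test suite and the acceptance script is generated in
code; no downloads are required.

* `make_rocksalt()` — the 8-site conventional rock-salt oxide cell with
  formal charges. `toy_forcefield()` pairs it with synthetic Buckingham
  parameters ($A = 1822.6$ eV, $\rho = 0.32$ Å, $C = 0$ on the metal–
  oxygen pair) chosen to give a bound, stable minimum; they are **not**
  fitted to any real oxide, and real applications must supply their own
  parameter files (`read_forcefield()`).
* `make_material_set()` — 24 toy oxide materials spanning distinct
  lattice constants (4.00–4.46 Å), charges (±1, ±2), metal species and
  ionic radii, exercising the descriptor engine across a family the way
  the curated 24-oxide study does. Descriptor generation for the family
  uses carve radius 8 Å (~300 atoms) with shell depth 4 Å and a capped
  relaxation (40 CG iterations): these sizes keep a full 24-material
  block comfortably desk-scale while preserving non-trivial core/shell
  structure. They are smaller than experimentally typical particles
  (tens of nm), so descriptor *values* are illustrative, not material
  predictions.
* `make_synthetic_table()` — the planted-signal benchmark: standard-normal
  descriptors of which three (weights 8, −7, 6; noise σ = 1) drive the
  endpoint linearly plus a nominal assay offset. The weights are balanced
  so that every planted effect lies clearly above the CFS inclusion
  boundary — with a markedly weaker third weight the CFS-optimal subset
  itself (not merely the search) excludes the weakest feature in a
  substantial fraction of replicates, which would make "recovery" a test
  of the merit definition rather than of the search. Under the defaults,
  best-first selection recovers all three features in ≥ 95% of seeded
  replicates.
* `make_service_table()` — a synthetic screening study over the seven
  service descriptors: 24 distinct oxides with fixed material-level
  descriptor values, crossed with a log-spaced dose series (0.5–50
  µg/mL) and both viability assays (with a systematic LDH offset),
  following a Hill-type dose–response whose potency derives from the
  material descriptors (smaller cores, higher conduction-band energy,
  lower surface coordination, stronger outward surface forces → more
  toxic). This reproduces the *structure* that makes read-across work on
  the real data — repeated measures of a modest number of materials — and
  the trained pipeline passes all external-validation criteria on it.

What the fixtures do **not** emulate: real force-field parameters and
polymorph choices (configuration inputs), quantum-chemical descriptors
($E_V$, $E_C$, $E_g$, electronegativities, formation enthalpy — always
user-supplied), measurement heterogeneity across laboratories, and the
actual descriptor–toxicity relationships of real oxides. Passing tests
demonstrate correctness of the machinery and the statistical contracts,
not toxicological validity of any particular prediction.

## Known limitations

* The pair-potential treatment ignores polarisation/shell-model effects
  and finite temperature; relaxed geometries are 0 K local minima.
* The truncation of the Buckingham and Wolf terms makes the energy
  surface $C^0$ at the cutoffs; the line-searched minimiser tolerates
  this, but force-based convergence below ~$10^{-6}$ eV/Å may require
  cutoffs beyond the particle extent.
* The coordination cutoff assumes a single metal species per particle
  (binary oxides); mixed-metal particles are rejected rather than
  silently mishandled.
* `n_neighbors` above the training size, empty feature selections and
  schema-mismatched service bundles raise errors rather than degrading.
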