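## Deterministic fixtures: toy crystals, a synthetic toy force field and
## planted-signal modelling tables, so the whole toolchain is exercisable
## without any external data.

#' Rock-salt toy unit cell
#'
#' The conventional 8-site rock-salt (NaCl-type) cell of a binary metal
#' oxide: four metal cations and four oxide anions with formal charges
#' `+/- charge`; the nearest-neighbour distance is `a / 2`.
#'
#' @param a cubic lattice constant in Angstrom (default 4.2).
#' @param metal metal species symbol (default `"Mg"`).
#' @param charge formal charge magnitude in elementary charges (default 2).
#' @return A [unit_cell()] with 8 sites and zero net charge.
#' @export
#' @examples
#' make_rocksalt(a = 4.2, metal = "Mg", charge = 2)
make_rocksalt <- function(a = 4.2, metal = "Mg", charge = 2) {
  frac <- rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5),
                c(.5, 0, 0), c(0, .5, 0), c(0, 0, .5), c(.5, .5, .5))
  unit_cell(diag(3) * a,
            c(rep(metal, 4), rep("O", 4)), frac,
            c(rep(charge, 4), rep(-charge, 4)))
}

#' Synthetic toy force field for rock-salt oxides
#'
#' Buckingham metal-oxygen repulsion (A = 1822.6 eV, rho = 0.32 A, C = 0)
#' plus full formal-charge Coulomb under Wolf summation.  These are
#' synthetic demonstration parameters giving a bound, stable minimum for
#' the rock-salt fixtures; they are not fitted to any real oxide.
#'
#' @param metal metal species symbol.
#' @param charge formal charge magnitude.
#' @param cutoff Buckingham cutoff in Angstrom.
#' @param wolf_alpha,wolf_cutoff Wolf electrostatics parameters.
#' @return A [forcefield()].
#' @export
toy_forcefield <- function(metal = "Mg", charge = 2, cutoff = 10,
                           wolf_alpha = 0.3, wolf_cutoff = 10) {
  forcefield(
    data.frame(sp1 = metal, sp2 = "O", A = 1822.6, rho = 0.32, C = 0,
               cutoff = cutoff, stringsAsFactors = FALSE),
    setNames(c(charge, -charge), c(metal, "O")),
    wolf_alpha = wolf_alpha, wolf_cutoff = wolf_cutoff)
}

#' Specification of a synthetic planted-signal modelling table
#'
#' Describes a reproducible synthetic dataset: `n_features` standard-normal
#' descriptor columns of which `informative` (indices) carry linear weights
#' `weights` into the endpoint, Gaussian noise with standard deviation
#' `noise_sd`, an assay offset added when the nominal assay column reads
#' `"LDH"`, and `n_duplicate_pairs` exact copies of leading columns
#' appended to exercise the redundancy filter.
#'
#' @param n_rows,n_features table dimensions.
#' @param informative integer indices of the informative features.
#' @param weights linear weights of the informative features.
#' @param noise_sd endpoint noise standard deviation.
#' @param assay_offset endpoint shift for LDH rows.
#' @param n_duplicate_pairs duplicated columns appended after the features.
#' @param seed RNG seed; the same spec always generates the same table.
#' @return A `synthetic_table_spec` list.
#' @export
synthetic_table_spec <- function(n_rows = 200, n_features = 40,
                                 informative = c(1, 2, 3),
                                 weights = c(8, -7, 6), noise_sd = 1,
                                 assay_offset = 5, n_duplicate_pairs = 0,
                                 seed = 1) {
  stopifnot(all(informative <= n_features), noise_sd >= 0,
            length(informative) == length(weights),
            n_duplicate_pairs <= n_features)
  structure(list(n_rows = n_rows, n_features = n_features,
                 informative = informative, weights = weights,
                 noise_sd = noise_sd, assay_offset = assay_offset,
                 n_duplicate_pairs = n_duplicate_pairs, seed = seed),
            class = "synthetic_table_spec")
}

#' Generate a synthetic planted-signal modelling table
#'
#' The endpoint is a pure linear function of the informative features plus
#' Gaussian noise and the assay offset, so feature selection and
#' Y-randomisation behaviour can be verified against a known ground truth.
#'
#' @param spec a [synthetic_table_spec()].
#' @return A [modeling_table()] with columns `material_id`, `d1..dK`
#'   (numeric), duplicated columns `dup1..`, `assay` (nominal) and
#'   `viability` (endpoint).
#' @export
#' @examples
#' tab <- make_synthetic_table(synthetic_table_spec(n_rows = 20, seed = 3))
#' dim(tab)
make_synthetic_table <- function(spec) {
  with_seed(spec$seed, {
    X <- matrix(rnorm(spec$n_rows * spec$n_features), spec$n_rows)
    colnames(X) <- paste0("d", seq_len(spec$n_features))
    assay <- sample(ASSAY_LEVELS, spec$n_rows, replace = TRUE)
    y <- as.numeric(X[, spec$informative, drop = FALSE] %*% spec$weights) +
      rnorm(spec$n_rows, 0, spec$noise_sd) +
      ifelse(assay == "LDH", spec$assay_offset, 0)
    df <- as.data.frame(X)
    if (spec$n_duplicate_pairs > 0) {
      for (j in seq_len(spec$n_duplicate_pairs))
        df[[paste0("dup", j)]] <- df[[j]]
    }
    df$assay <- assay
    df$viability <- y
    df <- cbind(material_id = sprintf("NP%03d", seq_len(spec$n_rows)), df)
    modeling_table(df, id = "material_id", endpoint = "viability",
                   nominal = "assay")
  })
}

#' Family of fixture materials for descriptor-table generation
#'
#' A deterministic set of `n` toy rock-salt oxide "materials" spanning a
#' range of lattice constants, formal charges and metal species, each with
#' its matching synthetic force field and ionic radii.  Used to exercise the
#' descriptor engine across a whole material family.
#'
#' @param n number of materials (default 24).
#' @return list of length `n`; each element has `id`, `cell`, `ff`,
#'   `radii`.
#' @export
make_material_set <- function(n = 24) {
  metals <- c("Mg", "Ca", "Zn", "Ni", "Co", "Cu", "Fe", "Mn")
  lapply(seq_len(n), function(i) {
    metal <- metals[(i - 1) %% length(metals) + 1]
    a <- 4.0 + 0.02 * (i - 1)                 # distinct per material
    q <- if (i %% 2 == 0) 2 else 1
    list(id = sprintf("%sO_%02d", metal, i),
         cell = make_rocksalt(a = a, metal = metal, charge = q),
         ff = toy_forcefield(metal = metal, charge = q),
         radii = radii_table(setNames(c(0.70 + 0.02 * ((i - 1) %% 5), 1.40),
                                      c(metal, "O"))))
  })
}

#' Synthetic experimental/molecular descriptor table
#'
#' The fifteen experimental and molecular descriptors that accompany the
#' atomistic block in a full modelling table: six physicochemical (chemical
#' formula, core size, specific and total surface area, hydrodynamic size,
#' zeta potential), six molecular (valence/conduction band energies, band
#' gap, cation and oxide electronegativities, formation enthalpy) and three
#' assay-related (assay type, cell species, exposure dose) columns, plus the
#' percent-viability endpoint.
#'
#' @param ids character vector of material identifiers (one row per id).
#' @param seed RNG seed.
#' @return A data frame with 15 descriptor columns, `material_id` and
#'   `viability`.
#' @export
make_experimental_table <- function(ids, seed = 1) {
  n <- length(ids)
  with_seed(seed, {
    ev <- runif(n, -9, -5)
    eg <- runif(n, 1, 5)
    data.frame(
      material_id = ids,
      chemical_formula = ids,
      core_size = runif(n, 10, 80),               # nm
      specific_surface_area = runif(n, 5, 200),   # m^2/g
      total_surface_area = runif(n, 1, 50),       # m^2
      hydro_size = runif(n, 30, 300),             # nm
      zeta_potential = runif(n, -40, 40),         # mV
      E_V = ev, E_C = ev + eg, E_g = eg,          # eV
      chi_cation = runif(n, 1, 2.2),
      chi_oxide = runif(n, 4, 7),                 # eV
      E_dH = runif(n, -1200, -200),               # kJ/mol
      assay = sample(ASSAY_LEVELS, n, replace = TRUE),
      cell_species = sample(c("human", "murine"), n, replace = TRUE),
      exposure_dose = exp(runif(n, log(0.5), log(50))),  # ug/mL
      viability = runif(n, 10, 110),
      stringsAsFactors = FALSE)
  })
}

#' Assemble the full modelling table from experimental and atomistic blocks
#'
#' Joins the 15-column experimental/molecular block with the 62 computed
#' atomistic descriptors by material id, yielding the canonical table of 77
#' independent variables plus endpoint.
#'
#' @param experimental data frame from [make_experimental_table()] (or a
#'   curated-study CSV with the same columns).
#' @param descriptors named list of descriptor vectors from
#'   [compute_descriptors()], names matching `material_id`.
#' @return A [modeling_table()] with 77 descriptor columns.
#' @export
assemble_modeling_table <- function(experimental, descriptors) {
  dd <- do.call(rbind, lapply(descriptors, function(v) as.data.frame(t(v))))
  dd <- cbind(material_id = names(descriptors), dd)
  miss <- setdiff(experimental$material_id, dd$material_id)
  if (length(miss))
    stop("no atomistic descriptors for: ", paste(miss, collapse = ", "))
  df <- merge(experimental, dd, by = "material_id", sort = FALSE)
  modeling_table(df, id = "material_id", endpoint = "viability",
                 nominal = c("chemical_formula", "assay", "cell_species"))
}

#' Synthetic service-schema modelling table
#'
#' A synthetic cytotoxicity study over the seven deployed service
#' descriptors (`coreSize`, `hydroSize`, `assay`, `exposureDose`, `ecEv`,
#' `des306`, `des606`) with a percent-cell-viability endpoint.  The design
#' mirrors a typical curated metal-oxide screening dataset: `n_materials`
#' distinct oxides, each with fixed material-level descriptors, crossed with
#' a log-spaced dose series and both viability assays.  Viability follows a
#' smooth dose-response whose potency is driven by the material descriptors
#' (smaller cores, higher conduction-band energy, lower surface coordination
#' and stronger outward surface forces give more toxic particles), plus a
#' systematic assay offset and measurement noise.
#'
#' @param n_materials number of distinct oxide materials (default 24).
#' @param n_doses doses per material/assay, log-spaced 0.5 to 50 ug/mL.
#' @param noise_sd measurement noise on percent viability (default 3).
#' @param seed RNG seed.
#' @return A [modeling_table()] with `n_materials * n_doses * 2` rows.
#' @export
make_service_table <- function(n_materials = 24, n_doses = 6, noise_sd = 3,
                               seed = 1) {
  with_seed(seed, {
    metals <- c("Cu", "Zn", "Co", "Ni", "Mg", "Ce", "Ti", "Fe", "Mn", "Cr",
                "Al", "Si", "Sn", "Sb", "In", "La", "Gd", "Hf", "Y", "Zr",
                "W", "Mo", "V", "Bi")
    ids <- paste0(metals[seq_len(min(n_materials, length(metals)))], "O")
    if (n_materials > length(metals))
      ids <- c(ids, sprintf("MOx%02d", seq_len(n_materials - length(metals))))
    mat <- data.frame(
      id = ids,
      coreSize = runif(n_materials, 10, 80),            # nm
      ecEv = runif(n_materials, -6, -2),                # eV
      des306 = runif(n_materials, 3, 8),                # avg surface CN
      des606 = runif(n_materials, -0.5, 0),             # eV/A
      stringsAsFactors = FALSE)
    mat$hydroSize <- mat$coreSize * runif(n_materials, 1.2, 3)  # nm
    ## material toxicity potency from the descriptors (higher = more toxic)
    pot <- with(mat, 0.5 * (80 - coreSize) / 70 + 0.8 * (ecEv + 6) / 4 +
                  0.6 * (8 - des306) / 5 + 0.5 * (-des606) / 0.5)
    doses <- exp(seq(log(0.5), log(50), length.out = n_doses))  # ug/mL
    grid <- expand.grid(m = seq_len(n_materials), dose = doses,
                        assay = ASSAY_LEVELS, stringsAsFactors = FALSE)
    ec50 <- 80 * exp(-3.5 * pot[grid$m])    # potent materials act at low dose
    viability <- 100 / (1 + (grid$dose / ec50)^1.3) +
      ifelse(grid$assay == "LDH", 6, 0) +
      rnorm(nrow(grid), 0, noise_sd)
    df <- data.frame(id = mat$id[grid$m],
                     coreSize = mat$coreSize[grid$m],
                     hydroSize = mat$hydroSize[grid$m],
                     ecEv = mat$ecEv[grid$m],
                     assay = grid$assay,
                     exposureDose = grid$dose,
                     des306 = mat$des306[grid$m],
                     des606 = mat$des606[grid$m],
                     viability = viability,
                     stringsAsFactors = FALSE)
    modeling_table(df, id = "id", endpoint = "viability",
                   nominal = "assay")
  })
}
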