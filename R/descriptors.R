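## Core/shell atomistic nanodescriptors.
##
## The 62-descriptor schema is organised over a 3 x 3 grid of atom scopes
## {all, metal, oxygen} x regions {whole, core, shell}:
##   composition      (9): atom counts per scope x region
##   potential energy (9): mean per-atom potential energy per scope x region
##   topology         (9): mean coordination number per scope x region
##   lattice energy   (5): total, per-atom, core total, shell total,
##                         shell-to-total ratio
##   size             (3): diameter, volume, surface area (nominal radius)
##   force vectors   (27): mean surface-normal component, mean tangential
##                         magnitude, mean force magnitude per scope x region
## A statistic over an empty scope x region cell is reported as 0 (with a
## warning) so that very small particles remain processable.

SCOPES <- c("all", "metal", "oxygen")
REGIONS <- c("whole", "core", "shell")

## standard atomic masses (u) for the elements handled by the builder
ATOMIC_MASSES <- c(
  H = 1.008, Li = 6.94, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, K = 39.098,
  Ca = 40.078, Ti = 47.867, V = 50.942, Cr = 51.996, Mn = 54.938,
  Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38,
  Ga = 69.723, Ge = 72.63, Y = 88.906, Zr = 91.224, Nb = 92.906,
  Mo = 95.95, In = 114.818, Sn = 118.71, Sb = 121.76, La = 138.905,
  Ce = 140.116, Gd = 157.25, Hf = 178.49, W = 183.84, Bi = 208.98)

atomic_mass <- function(species) {
  m <- ATOMIC_MASSES[species]
  if (anyNA(m)) {
    warning("no tabulated mass for ",
            paste(unique(species[is.na(m)]), collapse = ", "),
            "; using 1 u")
    m[is.na(m)] <- 1
  }
  unname(m)
}

#' Ionic radii table
#'
#' Per-species ionic radii (Angstrom) used to form the coordination-number
#' cutoff `R = 1.2 * (R_M + R_O)` from the metal-cation and oxide-anion
#' radii.
#'
#' @param ... named radii in Angstrom, e.g. `Mg = 0.72, O = 1.40`.
#' @return A named numeric vector of class `radii_table`.
#' @export
#' @examples
#' radii_table(Mg = 0.72, O = 1.40)
radii_table <- function(...) {
  r <- c(...)
  if (any(r <= 0)) stop("ionic radii must be > 0")
  if (is.null(names(r)) || any(!nzchar(names(r))))
    stop("radii must be named by species")
  structure(r, class = "radii_table")
}

is_oxygen <- function(species) species == "O"

#' Tag atoms as core or shell
#'
#' An atom belongs to the shell when its distance from the carving centre is
#' at least `nominal_radius - shell_depth`; otherwise it is core.  With the
#' default 10 A (1 nm) depth this reproduces the usual surface-layer
#' partition of spherical oxide nanoparticles.
#'
#' @param p a carved [particle()] (its `nominal_radius` must be known).
#' @param shell_depth shell thickness in Angstrom (default 10).
#' @return The particle with a `region` character vector (`"core"` or
#'   `"shell"`) filled in.
#' @export
assign_regions <- function(p, shell_depth = 10) {
  if (is.na(p$nominal_radius))
    stop("particle has no nominal radius; carve it first")
  if (shell_depth <= 0) stop("shell_depth must be > 0")
  if (shell_depth >= p$nominal_radius)
    warning("shell depth >= nominal radius: entire particle is shell")
  d <- sqrt(colSums((t(particle_coords(p)) - particle_center(p))^2))
  p$region <- ifelse(d >= p$nominal_radius - shell_depth, "shell", "core")
  p
}

#' Per-atom coordination numbers
#'
#' Counts, for every atom, the other atoms lying within the cutoff
#' `R = 1.2 * (R_M + R_O)` built from the ionic radii of the particle's
#' metal and oxygen species.
#'
#' @param p a [particle()].
#' @param radii a [radii_table()] covering the particle's species.
#' @return integer vector of coordination numbers.
#' @export
#' @examples
#' cn_cutoff(radii_table(Mg = 0.74, O = 1.40), "Mg")  # 2.568 A
coordination_number <- function(p, radii) {
  R <- cn_cutoff(radii, setdiff(unique(p$atoms$species), "O"))
  X <- particle_coords(p)
  if (nrow(X) == 1) return(0L)
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  as.integer(rowSums(D <= R))
}

#' @describeIn coordination_number The coordination cutoff
#'   `1.2 * (R_M + R_O)` in Angstrom for a given metal species.
#' @param metal metal species symbol (a single metal; the anion is oxygen).
#' @export
cn_cutoff <- function(radii, metal) {
  if (length(metal) != 1)
    stop("coordination cutoff needs exactly one metal species, got: ",
         paste(metal, collapse = ", "))
  miss <- setdiff(c(metal, "O"), names(radii))
  if (length(miss))
    stop("radii table is missing: ", paste(miss, collapse = ", "))
  1.2 * (radii[[metal]] + radii[["O"]])
}

#' Surface-normal force component of one atom
#'
#' Projects an atom's force vector onto the outward radial direction from
#' the particle centre of mass:
#' `V = (x fx + y fy + z fz) / d`, with `(x, y, z)` the atom position
#' relative to the centre and `d` its distance from it.  Positive values
#' point outward.
#'
#' @param pos length-3 atom position (Angstrom).
#' @param force length-3 force vector (eV/A).
#' @param center length-3 reference centre (the particle centre of mass).
#' @return signed normal component in eV/A.
#' @export
#' @examples
#' normal_force_component(c(3, 4, 0), c(1, 1, 0), c(0, 0, 0))  # 1.4
normal_force_component <- function(pos, force, center = c(0, 0, 0)) {
  r <- as.numeric(pos) - as.numeric(center)
  d <- sqrt(sum(r^2))
  if (d == 0) stop("atom coincides with the centre: normal undefined")
  sum(r * as.numeric(force)) / d
}

#' Mass-weighted centre of a particle
#'
#' @param p a [particle()].
#' @return length-3 centre of mass in Angstrom.
#' @export
center_of_mass <- function(p) {
  m <- atomic_mass(p$atoms$species)
  colSums(particle_coords(p) * m) / sum(m)
}

#' Canonical names of the 62 atomistic descriptors
#'
#' @return character vector of length 62 with a `category` attribute giving
#'   the block sizes (9, 9, 9, 5, 3, 27).
#' @export
descriptor_names <- function() {
  grid <- as.vector(t(outer(SCOPES, REGIONS, paste, sep = "_")))
  nm <- c(paste0("n_atoms_", grid),
          paste0("e_pot_mean_", grid),
          paste0("cn_mean_", grid),
          c("e_total", "e_per_atom", "e_core_total", "e_shell_total",
            "e_shell_fraction"),
          c("diameter", "volume", "surface_area"),
          paste0("f_normal_mean_", grid),
          paste0("f_tangential_mean_", grid),
          paste0("f_magnitude_mean_", grid))
  attr(nm, "category") <- rep(c("composition", "potential_energy",
                                "topology", "lattice_energy", "size",
                                "force_vectors"),
                              c(9, 9, 9, 5, 3, 27))
  nm
}

#' Compute the 62 atomistic nanodescriptors of a relaxed particle
#'
#' The particle must already carry per-atom energies and forces (from
#' [minimize_energy()] or a direct [particle_energy()] / [compute_forces()]
#' evaluation) and core/shell region tags ([assign_regions()]).  Statistics
#' are evaluated over the 3 x 3 grid of atom scopes (all / metal / oxygen)
#' and regions (whole particle / core / shell); force statistics use the
#' surface-normal projection taken about the particle centre of mass.
#'
#' @param p a relaxed, region-tagged [particle()] with forces and per-atom
#'   energies.
#' @param radii a [radii_table()] for the coordination cutoff.
#' @return Named numeric vector of length 62 (see [descriptor_names()]),
#'   with the category attribute attached.
#' @export
compute_descriptors <- function(p, radii) {
  if (is.null(p$region)) stop("assign core/shell regions first")
  if (is.null(p$forces) || is.null(p$per_atom_energy))
    stop("particle needs per-atom energies and forces")
  a <- p$atoms
  n <- nrow(a)
  metal <- !is_oxygen(a$species)
  scope_mask <- list(all = rep(TRUE, n), metal = metal, oxygen = !metal)
  region_mask <- list(whole = rep(TRUE, n),
                      core = p$region == "core",
                      shell = p$region == "shell")

  cn <- coordination_number(p, radii)

  com <- center_of_mass(p)
  X <- t(t(particle_coords(p)) - com)
  dcom <- sqrt(rowSums(X^2))
  ## an atom exactly at the centre of mass has no defined radial direction;
  ## by symmetry its force is (near) zero, so its normal component is taken
  ## as 0 rather than aborting the whole descriptor block
  at_center <- dcom < 1e-9
  vnorm <- rowSums(X * p$forces) / ifelse(at_center, 1, dcom)
  vnorm[at_center] <- 0
  fmag <- sqrt(rowSums(p$forces^2))
  vtan <- sqrt(pmax(fmag^2 - vnorm^2, 0))

  empty_warned <- FALSE
  cell_mean <- function(x, m) {
    if (!any(m)) {
      if (!empty_warned) {
        warning("empty scope x region cell: descriptor reported as 0")
        empty_warned <<- TRUE
      }
      return(0)
    }
    mean(x[m])
  }
  over_grid <- function(x, fun = cell_mean) {
    v <- numeric(0)
    for (sc in SCOPES) for (rg in REGIONS)
      v <- c(v, fun(x, scope_mask[[sc]] & region_mask[[rg]]))
    v
  }

  counts <- over_grid(NULL, function(x, m) sum(m))
  epot <- over_grid(p$per_atom_energy)
  cnm <- over_grid(cn)

  etot <- sum(p$per_atom_energy)
  ecore <- sum(p$per_atom_energy[region_mask$core])
  eshell <- sum(p$per_atom_energy[region_mask$shell])
  lattice <- c(etot, etot / n, ecore, eshell,
               if (etot != 0) eshell / etot else 0)

  R <- p$nominal_radius
  if (is.na(R)) stop("particle has no nominal radius")
  size <- c(2 * R, 4 / 3 * pi * R^3, 4 * pi * R^2)

  vals <- c(counts, epot, cnm, lattice, size,
            over_grid(vnorm), over_grid(vtan), over_grid(fmag))
  nm <- descriptor_names()
  stopifnot(length(vals) == 62)
  names(vals) <- nm
  attr(vals, "category") <- attr(nm, "category")
  vals
}

#' Build a particle from a unit cell and compute its descriptors
#'
#' Convenience wrapper over the full construction chain: replicate, carve,
#' neutralise, relax, tag regions and emit the 62 descriptors.
#'
#' @param cell a [unit_cell()].
#' @param ff a [forcefield()].
#' @param radii a [radii_table()].
#' @param radius carving radius in Angstrom.
#' @param shell_depth shell thickness in Angstrom.
#' @param tol convergence controls passed to [minimize_energy()].
#' @return list with the relaxed `particle` and the `descriptors` vector.
#' @export
build_and_describe <- function(cell, ff, radii, radius = 10,
                               shell_depth = 10, tol = list()) {
  counts <- ceiling(2 * radius / sqrt(rowSums(cell$lattice^2))) + 1
  p <- replicate_cell(cell, counts)
  p <- carve_sphere(p, radius)
  p <- neutralize(p)
  p <- minimize_energy(p, ff, tol)
  p <- assign_regions(p, shell_depth)
  list(particle = p, descriptors = compute_descriptors(p, radii))
}

#' Write a descriptor table to CSV
#'
#' One row per particle/material with the 62 canonical descriptor columns
#' prefixed by a material identifier; this is the stable export surface for
#' downstream modelling tables.
#'
#' @param desc named list (or single vector) of descriptor vectors from
#'   [compute_descriptors()]; names become material ids.
#' @param path output CSV path.
#' @return the data frame written, invisibly.
#' @export
write_descriptor_csv <- function(desc, path) {
  if (is.numeric(desc)) desc <- list(material = desc)
  df <- do.call(rbind, lapply(desc, function(v) as.data.frame(t(v))))
  df <- cbind(material_id = names(desc), df)
  rownames(df) <- NULL
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
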