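## Shared fixtures for the test suite; everything is generated in code.

## small relaxed, tagged rock-salt particle with energies and forces
small_described_particle <- function(radius = 6, shell_depth = 3,
                                     maxit = 80) {
  cell <- make_rocksalt()
  p <- replicate_cell(cell, c(4, 4, 4))
  p <- neutralize(carve_sphere(p, radius))
  p <- minimize_energy(p, toy_forcefield(), tol = list(maxit = maxit))
  assign_regions(p, shell_depth)
}

mg_radii <- function() radii_table(Mg = 0.72, O = 1.40)

## rigid rotation of a particle (coordinates, centre and forces)
rotate_particle <- function(p, axis = c(0, 0, 1), angle = pi / 5) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  xyz <- as.matrix(p$atoms[, c("x", "y", "z")]) %*% t(R)
  out <- particle(p$atoms$species, xyz, p$atoms$charge,
                  nominal_radius = p$nominal_radius,
                  center = if (!is.null(p$center))
                    as.numeric(p$center %*% t(R)) else NULL)
  if (!is.null(p$forces)) out$forces <- p$forces %*% t(R)
  out$per_atom_energy <- p$per_atom_energy
  out$energy <- p$energy
  out$region <- p$region
  out
}

## independent single-pair energy (Buckingham + energy-shifted Wolf pair +
## self terms), used as a 1-D oracle for the dimer minimum
dimer_energy_1d <- function(r, ff, q1 = 2, q2 = -2) {
  pr <- ff$pairs[1, ]
  eb <- if (r <= pr$cutoff) pr$A * exp(-r / pr$rho) - pr$C / r^6 else 0
  a <- ff$wolf_alpha; rc <- ff$wolf_cutoff; ke <- 14.399645
  erfc_ <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)
  ew <- if (r <= rc) ke * q1 * q2 * (erfc_(a * r) / r - erfc_(a * rc) / rc)
        else 0
  self <- -ke * (erfc_(a * rc) / (2 * rc) + a / sqrt(pi)) * (q1^2 + q2^2)
  eb + ew + self
}
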