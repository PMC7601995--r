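## Pairwise energetics for finite particles: vectorised over full N x N
## matrices.  An "energy model" caches the per-pair parameter matrices for a
## fixed species list so that repeated evaluations during minimisation only
## pay for distance geometry.

energy_model <- function(species, charge, ff) {
  n <- length(species)
  miss <- setdiff(unique(species), names(ff$charges))
  if (length(miss))
    stop("force field has no charge for species: ",
         paste(miss, collapse = ", "))
  ## consistency: particle formal charges must match force-field charges
  q <- as.numeric(charge)
  A <- Rho <- Cm <- Cut <- matrix(0, n, n)
  Rho[] <- 1
  for (k in seq_len(nrow(ff$pairs))) {
    pr <- ff$pairs[k, ]
    m <- (species[row(A)] == pr$sp1 & species[col(A)] == pr$sp2) |
         (species[row(A)] == pr$sp2 & species[col(A)] == pr$sp1)
    A[m] <- pr$A; Rho[m] <- pr$rho; Cm[m] <- pr$C; Cut[m] <- pr$cutoff
  }
  qq <- outer(q, q)
  alpha <- ff$wolf_alpha; rc <- ff$wolf_cutoff; ke <- ff$k_coulomb
  shift <- erfc(alpha * rc) / rc
  self <- -ke * (erfc(alpha * rc) / (2 * rc) + alpha / sqrt(pi)) * q^2

  dist_mat <- function(X) {
    D <- as.matrix(dist(X))
    diag(D) <- Inf
    D
  }

  list(
    n = n, species = species, charge = q, self = self,
    energy = function(X) {
      D <- dist_mat(X)
      mb <- D <= Cut
      Eb <- matrix(0, n, n)
      Eb[mb] <- A[mb] * exp(-D[mb] / Rho[mb]) - Cm[mb] / D[mb]^6
      mw <- D <= rc
      Ew <- matrix(0, n, n)
      Ew[mw] <- ke * qq[mw] * (erfc(alpha * D[mw]) / D[mw] - shift)
      per_atom <- rowSums(Eb + Ew) / 2 + self
      list(total = sum(per_atom), per_atom = per_atom,
           buckingham = sum(Eb) / 2, coulomb = sum(Ew) / 2 + sum(self))
    },
    forces = function(X) {
      D <- dist_mat(X)
      dEdr <- matrix(0, n, n)
      mb <- D <= Cut & A != 0 | D <= Cut & Cm != 0
      dEdr[mb] <- -A[mb] / Rho[mb] * exp(-D[mb] / Rho[mb]) +
        6 * Cm[mb] / D[mb]^7
      mw <- D <= rc
      dEdr[mw] <- dEdr[mw] - ke * qq[mw] *
        (erfc(alpha * D[mw]) / D[mw]^2 +
           2 * alpha / sqrt(pi) * exp(-alpha^2 * D[mw]^2) / D[mw])
      W <- dEdr / D          # Inf diagonal gives 0/Inf = 0 via dEdr diag 0
      diag(W) <- 0
      F <- matrix(0, n, 3)
      for (k in 1:3)
        F[, k] <- -(rowSums(W) * X[, k] - W %*% X[, k])
      F
    })
}

#' Total and per-atom particle energy
#'
#' Evaluates the Buckingham short-range and Wolf-summed Coulomb energy of a
#' finite particle.  Pair terms are split 50/50 between the two partners so
#' the per-atom energies (including the Wolf self term) sum exactly to the
#' total.
#'
#' @param p a [particle()].
#' @param ff a [forcefield()].
#' @return A list with `total` (eV), `per_atom` (eV per atom), and the
#'   `buckingham` / `coulomb` split.
#' @export
particle_energy <- function(p, ff) {
  em <- energy_model(p$atoms$species, p$atoms$charge, ff)
  em$energy(particle_coords(p))
}

#' Wolf-summed electrostatic energy
#'
#' Damped, energy-shifted pairwise Coulomb sum with the Wolf self term
#' (charge-neutralisation at the cutoff): for `r <= Rc`
#' `E_ij = k q_i q_j (erfc(alpha r)/r - erfc(alpha Rc)/Rc)` and per atom
#' `E_self = -k (erfc(alpha Rc)/(2 Rc) + alpha/sqrt(pi)) q_i^2`.
#'
#' @param p a [particle()].
#' @param ff a [forcefield()] supplying charges and Wolf parameters.
#' @return A list with `total` (eV) and `per_atom` (eV).
#' @export
wolf_electrostatics <- function(p, ff) {
  ff0 <- ff
  ff0$pairs <- ff$pairs[0, ]        # Coulomb part only
  e <- particle_energy(p, ff0)
  list(total = e$total, per_atom = e$per_atom)
}

#' Analytic forces on every atom
#'
#' Gradient of [particle_energy()] with respect to the Cartesian coordinates;
#' Newton's third law holds pairwise by construction.
#'
#' @param p a [particle()].
#' @param ff a [forcefield()].
#' @return n x 3 matrix of forces in eV/Angstrom.
#' @export
compute_forces <- function(p, ff) {
  em <- energy_model(p$atoms$species, p$atoms$charge, ff)
  em$forces(particle_coords(p))
}

#' Brute-force unscreened Coulomb energy
#'
#' Direct `O(n^2)` double sum `k q_i q_j / r_ij` with no damping or cutoff.
#' Used as the independent reference when calibrating the Wolf parameters and
#' in cross-checks.
#'
#' @param p a [particle()].
#' @return total electrostatic energy in eV.
#' @export
direct_coulomb_energy <- function(p) {
  X <- particle_coords(p)
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  qq <- outer(p$atoms$charge, p$atoms$charge)
  sum(COULOMB_EV_A * qq / D) / 2
}

## Direct-sum electrostatic energy per unit cell of growing n x n x n
## clusters, extrapolated linearly in 1/n to the infinite crystal.  The
## surface error of a neutral cubic cluster scales as 1/n, so the linear fit
## removes the leading finite-size term.
reference_lattice_energy <- function(cell, ns = c(2, 4, 6)) {
  epc <- vapply(ns, function(n) {
    p <- replicate_cell(cell, c(n, n, n))
    direct_coulomb_energy(p) / n^3
  }, numeric(1))
  fit <- lm(epc ~ I(1 / ns))
  unname(coef(fit)[1])
}

## Wolf electrostatic energy per unit cell of the infinite crystal: each atom
## of one cell is summed against the periodic images within the cutoff (the
## image shell is built by replicating the unit cell block far enough to
## cover the cutoff).
wolf_lattice_energy <- function(cell, alpha, rc) {
  lat <- cell$lattice
  sites <- frac_to_cart(as.matrix(cell$sites[, c("fx", "fy", "fz")]), lat)
  q <- cell$sites$charge
  ## enough images to cover rc from any atom of the home cell
  nrep <- ceiling(rc / min(sqrt(rowSums(lat^2)))) + 1
  g <- as.matrix(expand.grid(-nrep:nrep, -nrep:nrep, -nrep:nrep))
  shifts <- g %*% lat
  ns <- nrow(sites); ni <- nrow(shifts)
  img <- sites[rep(seq_len(ns), times = ni), , drop = FALSE] +
    shifts[rep(seq_len(ni), each = ns), , drop = FALSE]
  imgq <- rep(q, times = ni)
  shift <- erfc(alpha * rc) / rc
  E <- 0
  for (s in seq_len(ns)) {
    d <- sqrt(colSums((t(img) - sites[s, ])^2))
    m <- d > 1e-9 & d <= rc
    E <- E + q[s] * sum(imgq[m] * (erfc(alpha * d[m]) / d[m] - shift)) / 2
  }
  E <- E - (erfc(alpha * rc) / (2 * rc) + alpha / sqrt(pi)) * sum(q^2)
  COULOMB_EV_A * E
}

#' Calibrate the Wolf damping parameter and cutoff against the bulk crystal
#'
#' Scans a grid of `(alpha, cutoff)` values and returns the point whose Wolf
#' electrostatic energy per unit cell of the infinite crystal best matches an
#' independent reference: the unscreened direct sum over growing cubic
#' clusters extrapolated to infinite size.  The matched quantity is the
#' Madelung (electrostatic lattice) energy per cell.
#'
#' @param cell a [unit_cell()].
#' @param alphas candidate damping parameters (1/Angstrom).
#' @param cutoffs candidate truncation radii (Angstrom).
#' @param tol maximum acceptable relative residual (default 1%%).
#' @param ns cluster sizes for the direct-sum reference extrapolation.
#' @return A list with `alpha`, `cutoff`, `energy_per_cell` (eV), the
#'   `reference` energy (eV) and the relative `residual`.
#' @export
#' @examples
#' \donttest{
#' cal <- calibrate_wolf(make_rocksalt())
#' cal$residual < 0.01
#' }
calibrate_wolf <- function(cell, alphas = seq(0.1, 0.5, by = 0.02),
                           cutoffs = seq(6, 14, by = 1), tol = 0.01,
                           ns = c(2, 4, 6)) {
  eref <- reference_lattice_energy(cell, ns)
  best <- NULL
  for (rc in cutoffs) {
    for (a in alphas) {
      e <- wolf_lattice_energy(cell, a, rc)
      res <- abs(e - eref) / abs(eref)
      if (is.null(best) || res < best$residual)
        best <- list(alpha = a, cutoff = rc, energy_per_cell = e,
                     reference = eref, residual = res)
    }
  }
  if (best$residual > tol)
    stop(sprintf(
      "Wolf calibration failed: best residual %.3g above tolerance %.3g",
      best$residual, tol))
  best
}
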