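#' Relax a particle by Polak-Ribiere conjugate-gradient minimisation
#'
#' Minimises the total Buckingham + Wolf potential energy of a finite
#' particle with the Polak-Ribiere variant of nonlinear conjugate gradients
#' and a backtracking (Armijo) line search.  The iteration stops when the
#' relative energy change per accepted step falls below `tol$energy`, when
#' the largest force component falls below `tol$force` (eV/A), or at the
#' iteration cap.  Energy is non-increasing across accepted steps by
#' construction of the line search.
#'
#' @param p a [particle()].
#' @param ff a [forcefield()].
#' @param tol list of convergence controls: `energy` (relative energy change,
#'   default 1e-8), `force` (max force component in eV/A, default 1e-4),
#'   `maxit` (default 1e5).
#' @return The relaxed [particle()] with `energy`, `per_atom_energy` and
#'   `forces` filled in, plus attributes `trajectory` (energy per iteration),
#'   `converged` and `iterations`.
#' @export
#' @examples
#' p <- neutralize(carve_sphere(replicate_cell(make_rocksalt(), c(3, 3, 3)),
#'                              radius = 5))
#' pm <- minimize_energy(p, toy_forcefield(), tol = list(maxit = 50))
#' attr(pm, "converged")
minimize_energy <- function(p, ff, tol = list()) {
  tol <- modifyList(list(energy = 1e-8, force = 1e-4, maxit = 1e5), tol)
  em <- energy_model(p$atoms$species, p$atoms$charge, ff)
  X <- particle_coords(p)
  n <- nrow(X)

  safe_energy <- function(X) {
    if (n > 1 && min(dist(X)) < 0.5) return(Inf)   # fusion guard
    em$energy(X)$total
  }

  E <- safe_energy(X)
  if (!is.finite(E))
    stop("minimisation failure: initial geometry has overlapping atoms")
  G <- -em$forces(X)                     # gradient = -force
  D <- -G
  traj <- E
  converged <- FALSE
  iter <- 0
  while (iter < tol$maxit) {
    iter <- iter + 1
    if (max(abs(G)) < tol$force) { converged <- TRUE; break }
    ## backtracking Armijo line search along D
    dmax <- max(abs(D))
    step <- min(0.1 / dmax, 1)           # first trial: <= 0.1 A displacement
    slope <- sum(G * D)
    if (slope >= 0) { D <- -G; slope <- sum(G * D); dmax <- max(abs(D)) }
    accepted <- FALSE
    for (ls in 1:40) {
      Enew <- safe_energy(X + step * D)
      if (is.finite(Enew) && Enew <= E + 1e-4 * step * slope) {
        accepted <- TRUE; break
      }
      step <- step / 2
    }
    if (!accepted) {
      ## cannot descend along this direction: restart once from steepest
      if (all(D == -G)) { converged <- max(abs(G)) < tol$force; break }
      D <- -G
      next
    }
    Xnew <- X + step * D
    Gnew <- -em$forces(Xnew)
    relde <- abs(Enew - E) / max(abs(E), 1e-12)
    ## Polak-Ribiere update with automatic reset (beta clipped at 0)
    beta <- max(0, sum(Gnew * (Gnew - G)) / max(sum(G * G), 1e-300))
    D <- -Gnew + beta * D
    X <- Xnew; G <- Gnew; E <- Enew
    traj <- c(traj, E)
    if (relde < tol$energy) { converged <- TRUE; break }
    if (E < -1e8 * n)
      stop("minimisation failure: energy diverging towards -Inf")
  }

  out <- particle(p$atoms$species, X, p$atoms$charge,
                  nominal_radius = p$nominal_radius, center = p$center)
  e <- em$energy(X)
  out$energy <- e$total
  out$per_atom_energy <- e$per_atom
  out$forces <- em$forces(X)
  attr(out, "trajectory") <- traj
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iter
  out
}
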