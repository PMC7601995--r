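#' Finite nanoparticle
#'
#' A `particle` is a finite (non-periodic) collection of point ions: species,
#' Cartesian coordinates in Angstrom and formal charges, optionally decorated
#' with per-atom energies, forces, a core/shell region tag, the carving centre
#' and the nominal (carving) radius.
#'
#' @param species character vector of element symbols.
#' @param xyz numeric n x 3 matrix of Cartesian coordinates in Angstrom.
#' @param charge numeric vector of formal charges (elementary charges).
#' @param nominal_radius carving radius in Angstrom, or `NA` before carving.
#' @param center the carving centre (length-3), or `NULL`.
#'
#' @return An object of class `particle`: a list with `atoms` (data frame
#'   `species`, `x`, `y`, `z`, `charge`), `nominal_radius`, `center`, and the
#'   optional slots `energy`, `per_atom_energy`, `forces`, `region`.
#' @export
particle <- function(species, xyz, charge, nominal_radius = NA_real_,
                     center = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  if (length(species) != n || length(charge) != n)
    stop("species, xyz and charge lengths disagree")
  ## overlap guard; skipped for very large supercells where the O(n^2)
  ## distance matrix would dominate (replication preserves separation anyway)
  if (n > 1 && n <= 4000) {
    dmin <- min(dist(xyz))
    if (dmin < 0.5)
      stop(sprintf("atoms closer than 0.5 A (min %.3f A): unphysical overlap",
                   dmin))
  }
  structure(
    list(atoms = data.frame(species = as.character(species),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            charge = as.numeric(charge),
                            stringsAsFactors = FALSE),
         nominal_radius = nominal_radius,
         center = center,
         energy = NULL, per_atom_energy = NULL, forces = NULL,
         region = NULL),
    class = "particle")
}

#' @export
print.particle <- function(x, ...) {
  cat("Particle:", nrow(x$atoms), "atoms (",
      paste(sprintf("%s:%d", names(table(x$atoms$species)),
                    as.integer(table(x$atoms$species))), collapse = ", "),
      "), net charge", sum(x$atoms$charge), "\n")
  if (!is.na(x$nominal_radius))
    cat("Nominal radius:", x$nominal_radius, "A\n")
  if (!is.null(x$energy))
    cat("Total energy:", format(x$energy), "eV\n")
  invisible(x)
}

particle_coords <- function(p) as.matrix(p$atoms[, c("x", "y", "z")])

#' Number of atoms in a particle
#' @param p a [particle()].
#' @return integer atom count.
#' @export
n_atoms <- function(p) nrow(p$atoms)

## centre actually used for carving/regions; falls back to the centroid
particle_center <- function(p) {
  if (!is.null(p$center)) p$center else colMeans(particle_coords(p))
}

#' Replicate a unit cell into a supercell particle
#'
#' Translates the cell sites by every lattice vector combination
#' `0..counts[k]-1` and converts to Cartesian coordinates.  The result is an
#' (uncarved) finite particle of `sites x prod(counts)` atoms.
#'
#' @param cell a [unit_cell()].
#' @param counts integer triple of repetitions along the three lattice
#'   vectors, each at least 1.
#' @return A [particle()] with `nominal_radius = NA`.
#' @export
#' @examples
#' p <- replicate_cell(make_rocksalt(), c(2, 2, 2))
#' n_atoms(p)  # 64
replicate_cell <- function(cell, counts) {
  counts <- as.integer(counts)
  if (length(counts) != 3 || any(is.na(counts)) || any(counts < 1))
    stop("counts must be three integers >= 1")
  grid <- as.matrix(expand.grid(a = 0:(counts[1] - 1),
                                b = 0:(counts[2] - 1),
                                c = 0:(counts[3] - 1)))
  shifts <- grid %*% cell$lattice            # Cartesian translation vectors
  base <- frac_to_cart(as.matrix(cell$sites[, c("fx", "fy", "fz")]),
                       cell$lattice)
  ns <- nrow(base); nc <- nrow(shifts)
  xyz <- base[rep(seq_len(ns), times = nc), , drop = FALSE] +
    shifts[rep(seq_len(nc), each = ns), , drop = FALSE]
  particle(rep(cell$sites$species, times = nc), xyz,
           rep(cell$sites$charge, times = nc))
}

#' Carve a spherical particle out of a supercell
#'
#' Keeps the atoms within `radius` of `center` and records both as the
#' particle's nominal radius and carving centre.
#'
#' @param p a [particle()] (typically a replicated supercell).
#' @param radius carving radius in Angstrom (> 0).
#' @param center length-3 Cartesian point; default is the geometric centre of
#'   the coordinate extents of `p`.
#' @return The carved [particle()].
#' @export
carve_sphere <- function(p, radius, center = NULL) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  xyz <- particle_coords(p)
  if (is.null(center))
    center <- (apply(xyz, 2, min) + apply(xyz, 2, max)) / 2
  d <- sqrt(colSums((t(xyz) - center)^2))
  keep <- d <= radius
  if (!any(keep))
    stop("empty particle: no atom within ", radius, " A of the centre")
  out <- particle(p$atoms$species[keep], xyz[keep, , drop = FALSE],
                  p$atoms$charge[keep],
                  nominal_radius = radius, center = center)
  out
}

#' Restore electroneutrality by deleting outermost excess ions
#'
#' If the carved particle carries a net charge, atoms of the over-represented
#' charge sign are removed one at a time, outermost first (ties broken by
#' species symbol, then input order), until the total formal charge is exactly
#' zero.
#'
#' @param p a [particle()].
#' @return A neutral [particle()]; unchanged if already neutral.
#' @export
neutralize <- function(p) {
  total <- sum(p$atoms$charge)
  if (total == 0) return(p)
  sgn <- sign(total)
  center <- particle_center(p)
  xyz <- particle_coords(p)
  d <- sqrt(colSums((t(xyz) - center)^2))
  cand <- which(sign(p$atoms$charge) == sgn)
  ## outermost first, then species symbol, then input index
  cand <- cand[order(-d[cand], p$atoms$species[cand], cand)]
  drop <- integer()
  for (i in cand) {
    if (total == 0) break
    if (sign(total) != sgn) break
    total <- total - p$atoms$charge[i]
    drop <- c(drop, i)
  }
  if (total != 0)
    stop("cannot reach exact electroneutrality by removing ions of one sign")
  keep <- setdiff(seq_len(nrow(p$atoms)), drop)
  particle(p$atoms$species[keep], xyz[keep, , drop = FALSE],
           p$atoms$charge[keep],
           nominal_radius = p$nominal_radius, center = p$center)
}

#' Write a particle as an extended XYZ file
#'
#' Standard XYZ layout with charge as a fifth column; region tag appended
#' when present.
#'
#' @param p a [particle()].
#' @param path output path.
#' @param comment single comment line for the XYZ header.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(p, path, comment = "nanoqnar particle") {
  a <- p$atoms
  rows <- sprintf("%-2s %14.8f %14.8f %14.8f %8.3f%s",
                  a$species, a$x, a$y, a$z, a$charge,
                  if (!is.null(p$region)) paste0(" ", p$region) else "")
  writeLines(c(as.character(nrow(a)), comment, rows), path)
  invisible(path)
}
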