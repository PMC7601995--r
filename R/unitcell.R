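#' Bulk crystal unit cell
#'
#' A `unit_cell` holds the lattice vectors of a bulk crystal together with its
#' sites in fractional coordinates and their formal ionic charges.  It is the
#' starting point for nanoparticle construction: the cell is replicated into a
#' supercell, a sphere is carved out and the result is neutralised and relaxed.
#'
#' @param lattice 3x3 numeric matrix, rows are the lattice vectors in Angstrom.
#' @param species character vector of element symbols, one per site.
#' @param frac numeric n x 3 matrix of fractional coordinates in `[0, 1)`.
#' @param charge numeric vector of formal charges in elementary charges; the
#'   cell must be electroneutral.
#'
#' @return An object of class `unit_cell` with components `lattice` and
#'   `sites` (a data frame with columns `species`, `fx`, `fy`, `fz`, `charge`).
#' @export
#' @examples
#' cell <- make_rocksalt(a = 4.2, metal = "Mg", charge = 2)
#' cell$sites
unit_cell <- function(lattice, species, frac, charge) {
  lattice <- matrix(as.numeric(lattice), 3, 3)
  if (abs(det(lattice)) < 1e-10)
    stop("lattice vectors must be linearly independent")
  frac <- matrix(as.numeric(frac), ncol = 3)
  n <- nrow(frac)
  if (length(species) != n || length(charge) != n)
    stop("species, frac and charge must describe the same number of sites")
  if (any(frac < 0 | frac >= 1))
    stop("fractional coordinates must lie in [0, 1)")
  if (abs(sum(charge)) > 1e-9)
    stop("unit cell is not electroneutral (net charge ",
         format(sum(charge)), ")")
  if (!any(charge > 0) || !any(charge < 0))
    stop("cell must contain both cations and anions")
  structure(
    list(lattice = lattice,
         sites = data.frame(species = as.character(species),
                            fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
                            charge = as.numeric(charge),
                            stringsAsFactors = FALSE)),
    class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat("Unit cell:", nrow(x$sites), "sites,",
      paste(unique(x$sites$species), collapse = "/"), "\n")
  cat("Lattice (A):\n")
  print(round(x$lattice, 4))
  invisible(x)
}

#' Lattice vectors from cell parameters
#'
#' Converts the six conventional cell parameters to a lattice-vector matrix in
#' the standard orientation (a along x, b in the xy plane).
#'
#' @param a,b,c cell edge lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @return 3x3 matrix with lattice vectors as rows.
#' @export
lattice_from_parameters <- function(a, b, c, alpha = 90, beta = 90,
                                    gamma = 90) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  vol <- sqrt(max(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
  rbind(c(a, 0, 0),
        c(b * cg, b * sg, 0),
        c(c * cb, c * (ca - cb * cg) / sg, c * vol / sg))
}

frac_to_cart <- function(frac, lattice) {
  matrix(as.numeric(frac), ncol = 3) %*% lattice
}

## --- CIF input / output ----------------------------------------------------

## Evaluate a symmetry operator string such as "-x, y+1/2, z" at fractional
## coordinates xyz.  Only the arithmetic subset used in symmetry operators is
## accepted.
apply_symop <- function(op, xyz) {
  parts <- strsplit(op, ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry operator: ", op)
  env <- list2env(list(x = xyz[1], y = xyz[2], z = xyz[3]))
  vapply(parts, function(p) {
    p <- gsub("'", "", tolower(trimws(p)))
    if (grepl("[^xyz0-9+/. -]", p))
      stop("unsupported symmetry operator token in: ", op)
    eval(parse(text = p), envir = env)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a unit cell from a CIF file
#'
#' A small reader for the subset of the CIF format needed for ionic bulk
#' structures: cell parameters, an `_atom_site` loop in fractional
#' coordinates, an optional `_atom_site_charge` column and an optional
#' symmetry-operator loop.  Symmetry operators are applied and duplicate
#' images removed, so the returned cell is always in P1.
#'
#' @param path path to a CIF file.
#' @param charges optional named numeric vector of formal charges per species,
#'   used when the file carries no `_atom_site_charge` column (symbols such as
#'   `"Mg2+"` in the type column are also understood).
#' @return A [unit_cell()].
#' @export
read_cif <- function(path, charges = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  getnum <- function(tag) {
    ln <- grep(paste0("^\\s*", tag, "\\b"), lines, value = TRUE)
    if (!length(ln)) return(NA_real_)
    val <- strsplit(trimws(ln[1]), "\\s+")[[1]][2]
    as.numeric(sub("\\(.*\\)", "", val))
  }
  a <- getnum("_cell_length_a"); b <- getnum("_cell_length_b")
  cc <- getnum("_cell_length_c")
  if (anyNA(c(a, b, cc))) stop("CIF is missing cell lengths")
  alpha <- getnum("_cell_angle_alpha"); beta <- getnum("_cell_angle_beta")
  gamma <- getnum("_cell_angle_gamma")
  alpha <- if (is.na(alpha)) 90 else alpha
  beta  <- if (is.na(beta))  90 else beta
  gamma <- if (is.na(gamma)) 90 else gamma
  lattice <- lattice_from_parameters(a, b, cc, alpha, beta, gamma)

  ## locate loops: a loop_ line followed by _tags then data rows
  loops <- list()
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1; tags <- character()
      while (j <= length(lines) && grepl("^\\s*_", lines[j])) {
        tags <- c(tags, trimws(lines[j])); j <- j + 1
      }
      rows <- character()
      while (j <= length(lines) && !grepl("^\\s*(loop_|_|$)", lines[j]) &&
             nzchar(trimws(lines[j]))) {
        rows <- c(rows, trimws(lines[j])); j <- j + 1
      }
      loops[[length(loops) + 1]] <- list(tags = tags, rows = rows)
      i <- j
    } else i <- i + 1
  }

  symops <- "x, y, z"
  for (lp in loops) {
    if (any(grepl("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz",
                  lp$tags))) {
      symops <- gsub("^[0-9]+\\s+", "", lp$rows)
      symops <- gsub("^'|'$", "", symops)
    }
  }

  site_loop <- NULL
  for (lp in loops)
    if (any(grepl("_atom_site_fract_x", lp$tags))) site_loop <- lp
  if (is.null(site_loop)) stop("CIF has no _atom_site loop")
  tags <- site_loop$tags
  fields <- strsplit(site_loop$rows, "\\s+")
  col <- function(tag) {
    k <- grep(paste0("^", tag, "$"), tags)
    if (!length(k)) return(NULL)
    vapply(fields, `[[`, character(1), k[1])
  }
  sym <- col("_atom_site_type_symbol") %||% col("_atom_site_label")
  if (is.null(sym)) stop("CIF atom loop has no species column")
  strip <- function(s) sub("[0-9.+-]*$", "", s)
  fx <- as.numeric(sub("\\(.*\\)", "", col("_atom_site_fract_x")))
  fy <- as.numeric(sub("\\(.*\\)", "", col("_atom_site_fract_y")))
  fz <- as.numeric(sub("\\(.*\\)", "", col("_atom_site_fract_z")))
  qcol <- col("_atom_site_charge")

  q <- if (!is.null(qcol)) {
    as.numeric(qcol)
  } else {
    ## charges from "Mg2+"-style symbols or from the `charges` argument
    m <- regmatches(sym, regexpr("([0-9]+)?[+-]$", sym))
    if (all(nzchar(m)) && length(m) == length(sym)) {
      sgn <- ifelse(grepl("-$", m), -1, 1)
      mag <- as.numeric(sub("[+-]$", "", m)); mag[is.na(mag)] <- 1
      sgn * mag
    } else if (!is.null(charges)) {
      unname(charges[strip(sym)])
    } else stop("no charges in CIF; supply `charges=`")
  }
  if (anyNA(q)) stop("could not resolve a formal charge for every site")
  species <- strip(sym)

  ## expand symmetry, wrap into [0,1), drop duplicate images
  allf <- NULL; allsp <- character(); allq <- numeric()
  for (s in seq_along(species)) {
    for (op in symops) {
      f <- apply_symop(op, c(fx[s], fy[s], fz[s])) %% 1
      allf <- rbind(allf, f); allsp <- c(allsp, species[s])
      allq <- c(allq, q[s])
    }
  }
  keep <- !duplicated(round(allf, 6))
  unit_cell(lattice, allsp[keep], allf[keep, , drop = FALSE], allq[keep])
}

#' Write a unit cell as a P1 CIF file
#'
#' @param cell a [unit_cell()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cif <- function(cell, path) {
  lat <- cell$lattice
  len <- sqrt(rowSums(lat^2))
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  s <- cell$sites
  txt <- c(
    "data_nanoqnar",
    "_symmetry_space_group_name_H-M   'P 1'",
    sprintf("_cell_length_a   %.6f", len[1]),
    sprintf("_cell_length_b   %.6f", len[2]),
    sprintf("_cell_length_c   %.6f", len[3]),
    sprintf("_cell_angle_alpha   %.4f", ang(lat[2, ], lat[3, ])),
    sprintf("_cell_angle_beta    %.4f", ang(lat[1, ], lat[3, ])),
    sprintf("_cell_angle_gamma   %.4f", ang(lat[1, ], lat[2, ])),
    "loop_",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_charge",
    sprintf("%s %.6f %.6f %.6f %.3f", s$species, s$fx, s$fy, s$fz, s$charge))
  writeLines(txt, path)
  invisible(path)
}
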