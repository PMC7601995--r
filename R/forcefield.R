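#' Buckingham + Coulomb force-field specification
#'
#' Short-range interactions are Buckingham pairs,
#' `A * exp(-r / rho) - C / r^6`, truncated at a per-pair cutoff;
#' electrostatics are handled with the damped, energy-shifted Wolf summation
#' controlled by `wolf_alpha` (1/Angstrom) and `wolf_cutoff` (Angstrom).
#'
#' @param pairs data frame with columns `sp1`, `sp2`, `A` (eV), `rho` (A),
#'   `C` (eV A^6), `cutoff` (A).  Pair lookup is symmetric in the species
#'   order; unlisted pairs have no short-range term.
#' @param charges named numeric vector of formal charges per species.
#' @param wolf_alpha Wolf damping parameter in 1/Angstrom.
#' @param wolf_cutoff Wolf truncation radius in Angstrom.
#' @return An object of class `forcefield`.
#' @export
#' @examples
#' ff <- toy_forcefield()
#' pair_buckingham(2.1, ff, "Mg", "O")
forcefield <- function(pairs, charges, wolf_alpha = 0.3, wolf_cutoff = 10) {
  stopifnot(is.data.frame(pairs),
            all(c("sp1", "sp2", "A", "rho", "C", "cutoff") %in% names(pairs)))
  if (any(pairs$rho <= 0)) stop("rho must be > 0")
  if (any(pairs$cutoff <= 0)) stop("pair cutoffs must be > 0")
  if (wolf_alpha <= 0 || wolf_cutoff <= 0)
    stop("Wolf parameters must be > 0")
  if (is.null(names(charges)) || any(!nzchar(names(charges))))
    stop("charges must be a named vector")
  structure(list(pairs = pairs, charges = charges,
                 wolf_alpha = wolf_alpha, wolf_cutoff = wolf_cutoff,
                 k_coulomb = COULOMB_EV_A),
            class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat("Force field:", nrow(x$pairs), "Buckingham pair(s);",
      "charges:", paste(sprintf("%s=%+g", names(x$charges), x$charges),
                        collapse = " "),
      sprintf("; Wolf alpha=%g 1/A cutoff=%g A", x$wolf_alpha,
              x$wolf_cutoff), "\n")
  invisible(x)
}

ff_pair <- function(ff, s1, s2) {
  p <- ff$pairs
  hit <- (p$sp1 == s1 & p$sp2 == s2) | (p$sp1 == s2 & p$sp2 == s1)
  if (!any(hit)) return(NULL)
  p[which(hit)[1], ]
}

#' Buckingham pair energy
#'
#' `A * exp(-r/rho) - C/r^6` for `r <= cutoff`, exactly 0 beyond the cutoff.
#'
#' @param r separation in Angstrom (> 0); vectorised.
#' @param ff a [forcefield()], or a single-row pair-parameter data frame.
#' @param sp1,sp2 species symbols selecting the pair (ignored when `ff` is
#'   already a pair entry).
#' @return energy in eV.
#' @export
pair_buckingham <- function(r, ff, sp1 = NULL, sp2 = NULL) {
  if (any(r <= 0)) stop("r must be > 0")
  par <- if (inherits(ff, "forcefield")) {
    p <- ff_pair(ff, sp1, sp2)
    if (is.null(p)) stop("no Buckingham parameters for pair ", sp1, "-", sp2)
    p
  } else ff
  ifelse(r <= par$cutoff, par$A * exp(-r / par$rho) - par$C / r^6, 0)
}

#' Read a force field from a plain-text parameter file
#'
#' Line-oriented format (comments start with `#`):
#' \preformatted{
#' charge <species> <q>
#' pair <sp1> <sp2> <A eV> <rho A> <C eV*A^6> <cutoff A>
#' wolf <alpha 1/A> <cutoff A>
#' }
#'
#' @param path file path.
#' @return A [forcefield()].
#' @export
read_forcefield <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\\s+")
  charges <- numeric(); pairs <- NULL; wolf <- c(0.3, 10)
  for (tk in toks) {
    switch(tk[1],
      charge = { charges[tk[2]] <- as.numeric(tk[3]) },
      pair = {
        pairs <- rbind(pairs, data.frame(
          sp1 = tk[2], sp2 = tk[3], A = as.numeric(tk[4]),
          rho = as.numeric(tk[5]), C = as.numeric(tk[6]),
          cutoff = as.numeric(tk[7]), stringsAsFactors = FALSE))
      },
      wolf = { wolf <- as.numeric(tk[2:3]) },
      stop("unknown force-field directive: ", tk[1]))
  }
  if (is.null(pairs)) pairs <- data.frame(sp1 = character(), sp2 = character(),
                                          A = numeric(), rho = numeric(),
                                          C = numeric(), cutoff = numeric(),
                                          stringsAsFactors = FALSE)
  forcefield(pairs, charges, wolf[1], wolf[2])
}

#' Write a force field to the plain-text parameter format
#'
#' @param ff a [forcefield()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_forcefield <- function(ff, path) {
  txt <- c("# nanoqnar force-field file, format v1",
           sprintf("charge %s %g", names(ff$charges), ff$charges),
           sprintf("pair %s %s %g %g %g %g", ff$pairs$sp1, ff$pairs$sp2,
                   ff$pairs$A, ff$pairs$rho, ff$pairs$C, ff$pairs$cutoff),
           sprintf("wolf %g %g", ff$wolf_alpha, ff$wolf_cutoff))
  writeLines(txt, path)
  invisible(path)
}
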