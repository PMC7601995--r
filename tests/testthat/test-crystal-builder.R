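test_that("replicate_cell enumerates lattice translations", {
  cell <- make_rocksalt(a = 4.2)
  expect_equal(n_atoms(replicate_cell(cell, c(2, 2, 2))), 64)

  ## identity case: (1,1,1) gives the Cartesian images of the cell sites
  p1 <- replicate_cell(cell, c(1, 1, 1))
  expect_equal(n_atoms(p1), 8)
  expect_equal(unname(as.matrix(p1$atoms[, c("x", "y", "z")])),
               unname(as.matrix(cell$sites[, c("fx", "fy", "fz")]) %*%
                        cell$lattice))

  ## brute-force enumeration oracle for (3,3,3)
  p3 <- replicate_cell(cell, c(3, 3, 3))
  expect_equal(n_atoms(p3), 216)
  base <- as.matrix(cell$sites[, c("fx", "fy", "fz")]) %*% cell$lattice
  expected <- NULL
  for (i in 0:2) for (j in 0:2) for (k in 0:2)
    expected <- rbind(expected, sweep(base, 2, c(i, j, k) * 4.2, "+"))
  got <- as.matrix(p3$atoms[, c("x", "y", "z")])
  key <- function(m) sort(apply(round(m, 9), 1, paste, collapse = ","))
  expect_equal(key(got), key(expected))
  expect_equal(max(got), 2 * 4.2 + max(base))

  expect_error(replicate_cell(cell, c(0, 1, 1)), "counts")
})

test_that("carve_sphere retains exactly the in-radius atoms", {
  cell <- make_rocksalt(a = 4.2)
  p <- replicate_cell(cell, c(5, 5, 5))

  ## radius beyond the supercell extent keeps everything
  big <- carve_sphere(p, 1000)
  expect_equal(n_atoms(big), n_atoms(p))

  ## tiny radius about one atom keeps exactly that atom
  at <- as.numeric(p$atoms[17, c("x", "y", "z")])
  one <- carve_sphere(p, 0.1, center = at)
  expect_equal(n_atoms(one), 1)

  ## brute-force distance-scan oracle at radius 10 about a lattice site
  ctr <- as.numeric(p$atoms[1, c("x", "y", "z")]) + c(4.2, 4.2, 4.2)
  carved <- carve_sphere(p, 10, center = ctr)
  xyz <- as.matrix(p$atoms[, c("x", "y", "z")])
  want <- sum(sqrt(colSums((t(xyz) - ctr)^2)) <= 10)
  expect_equal(n_atoms(carved), want)
  expect_equal(carved$nominal_radius, 10)

  ## idempotence at fixed radius and centre
  again <- carve_sphere(carved, 10, center = ctr)
  expect_equal(again$atoms, carved$atoms)

  expect_error(carve_sphere(p, 0.05, center = c(1.1, 1.1, 1.1)),
               "empty particle")
})

test_that("neutralize removes outermost over-represented ions only", {
  cell <- make_rocksalt(a = 4.2)
  p <- neutralize(carve_sphere(replicate_cell(cell, c(4, 4, 4)), 7))
  expect_equal(sum(p$atoms$charge), 0)

  ## already neutral particle is returned unchanged
  expect_identical(neutralize(p), p)

  ## random carve of a +1/-1 lattice: removed set must be a suffix of the
  ## distance-sorted over-represented species (exhaustive oracle)
  for (seed in 1:5) {
    set.seed(seed)
    ctr <- runif(3, 6, 12)
    r <- runif(1, 5, 8)
    carved <- carve_sphere(replicate_cell(make_rocksalt(charge = 1),
                                          c(5, 5, 5)), r, center = ctr)
    net <- sum(carved$atoms$charge)
    neu <- neutralize(carved)
    expect_equal(sum(neu$atoms$charge), 0)
    expect_equal(n_atoms(neu), n_atoms(carved) - abs(net))
    if (net != 0) {
      sgn <- sign(net)
      xyz <- as.matrix(carved$atoms[, c("x", "y", "z")])
      d <- sqrt(colSums((t(xyz) - ctr)^2))
      over <- which(sign(carved$atoms$charge) == sgn)
      over <- over[order(-d[over], carved$atoms$species[over], over)]
      expected_removed <- over[seq_len(abs(net))]
      keykeep <- apply(round(xyz, 9), 1, paste, collapse = ",")
      keyneu <- apply(round(as.matrix(neu$atoms[, c("x", "y", "z")]), 9),
                      1, paste, collapse = ",")
      expect_setequal(setdiff(keykeep, keyneu), keykeep[expected_removed])
    }
  }
})

test_that("replicate-carve-neutralize preserves integer charge balance", {
  for (q in c(1, 2)) {
    p <- neutralize(carve_sphere(
      replicate_cell(make_rocksalt(charge = q), c(4, 4, 4)), 6.5))
    expect_identical(sum(p$atoms$charge), 0)
    expect_true(all(abs(p$atoms$charge) == q))
  }
})

test_that("minimisation descends and honours stationary points", {
  ff <- toy_forcefield(cutoff = 20, wolf_cutoff = 20)

  ## 1-D oracle: the dimer must relax to the minimum of the pair energy
  rstar <- optimize(dimer_energy_1d, c(0.8, 6), ff = ff)$minimum
  dimer <- particle(c("Mg", "O"), rbind(c(0, 0, 0), c(2.8, 0, 0)), c(2, -2))
  relaxed <- minimize_energy(dimer, ff)
  sep <- dist(as.matrix(relaxed$atoms[, c("x", "y", "z")]))[1]
  expect_equal(as.numeric(sep), rstar, tolerance = 1e-4)
  expect_true(attr(relaxed, "converged"))

  ## started at the analytic minimum: no displacement beyond tolerance
  at_min <- particle(c("Mg", "O"), rbind(c(0, 0, 0), c(rstar, 0, 0)),
                     c(2, -2))
  stay <- minimize_energy(at_min, ff)
  expect_lt(max(abs(as.matrix(stay$atoms[, c("x", "y", "z")]) -
                      as.matrix(at_min$atoms[, c("x", "y", "z")]))), 1e-3)

  ## descent property on a perturbed lattice particle
  p <- neutralize(carve_sphere(replicate_cell(make_rocksalt(), c(3, 3, 3)),
                               5))
  e0 <- particle_energy(p, toy_forcefield())$total
  pm <- minimize_energy(p, toy_forcefield(), tol = list(maxit = 60))
  expect_lte(pm$energy, e0)
  expect_true(all(diff(attr(pm, "trajectory")) <= 1e-9))
})

test_that("CIF files round-trip through the P1 reader", {
  cell <- make_rocksalt(a = 4.3, metal = "Ni", charge = 2)
  path <- withr::local_tempfile(fileext = ".cif")
  write_cif(cell, path)
  back <- read_cif(path)
  expect_equal(back$lattice, cell$lattice, tolerance = 1e-6)
  ord <- function(s) s[order(s$fx, s$fy, s$fz), ]
  expect_equal(ord(back$sites)$species, ord(cell$sites)$species)
  expect_equal(ord(back$sites)$charge, ord(cell$sites)$charge)

  ## symmetry expansion: one site + face-centring operators = 4 positions
  sym <- c("data_fcc",
           "_cell_length_a 4.0", "_cell_length_b 4.0", "_cell_length_c 4.0",
           "loop_",
           "_symmetry_equiv_pos_as_xyz",
           "'x, y, z'",
           "'x+1/2, y+1/2, z'",
           "'x+1/2, y, z+1/2'",
           "'x, y+1/2, z+1/2'",
           "loop_",
           "_atom_site_type_symbol",
           "_atom_site_fract_x",
           "_atom_site_fract_y",
           "_atom_site_fract_z",
           "_atom_site_charge",
           "Mg 0 0 0 2",
           "O 0.5 0 0 -2")
  p2 <- withr::local_tempfile(fileext = ".cif")
  writeLines(sym, p2)
  fcc <- read_cif(p2)
  expect_equal(nrow(fcc$sites), 8)
  expect_equal(sum(fcc$sites$charge), 0)
})

test_that("XYZ writer emits one line per atom with charges", {
  p <- small_described_particle(radius = 5, maxit = 10)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(p, path)
  lines <- readLines(path)
  expect_equal(as.integer(lines[1]), n_atoms(p))
  expect_equal(length(lines), n_atoms(p) + 2)
  expect_match(lines[3], "^(Mg|O)\\s+")
})
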