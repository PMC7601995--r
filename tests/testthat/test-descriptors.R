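test_that("core/shell tagging uses nominal radius minus shell depth", {
  ## synthetic particle with known distances from the carve centre
  pos <- rbind(c(0, 0, 0), c(4.9, 0, 0), c(0, 5, 0), c(0, 0, 10))
  p <- particle(c("Mg", "O", "Mg", "O"), pos, c(2, -2, 2, -2),
                nominal_radius = 15, center = c(0, 0, 0))
  p <- assign_regions(p, shell_depth = 10)
  expect_equal(p$region, c("core", "core", "shell", "shell"))

  ## shell depth >= radius: everything is shell, with a warning
  p2 <- particle(c("Mg", "O"), rbind(c(0, 0, 0), c(3, 0, 0)), c(2, -2),
                 nominal_radius = 8, center = c(0, 0, 0))
  expect_warning(p2 <- assign_regions(p2, 10), "entire particle is shell")
  expect_true(all(p2$region == "shell"))
})

test_that("coordination numbers reproduce the lattice neighbour count", {
  radii <- radii_table(Mg = 0.74, O = 1.40)
  expect_equal(cn_cutoff(radii, "Mg"), 2.568)

  lone <- particle("Mg", matrix(0, 1, 3), 2)
  expect_equal(coordination_number(lone, radii), 0L)

  ## interior atom of a rock-salt a = 4.2 lattice: 6 neighbours at 2.1 A,
  ## the 12-atom second shell at 2.97 A lies outside R = 2.568 A
  p <- carve_sphere(replicate_cell(make_rocksalt(a = 4.2), c(5, 5, 5)), 8,
                    center = c(2.1, 2.1, 2.1) * 2)
  cn <- coordination_number(p, radii)
  xyz <- as.matrix(p$atoms[, c("x", "y", "z")])
  ctr <- c(4.2, 4.2, 4.2)
  central <- which(colSums((t(xyz) - ctr)^2) < 1e-9)
  expect_equal(cn[central], 6L)

  ## brute-force neighbour scan oracle over every atom
  D <- as.matrix(dist(xyz)); diag(D) <- Inf
  expect_equal(cn, as.integer(rowSums(D <= 2.568)))

  ## invariant under atom relabelling
  perm <- sample(n_atoms(p))
  pp <- particle(p$atoms$species[perm], xyz[perm, ], p$atoms$charge[perm],
                 nominal_radius = p$nominal_radius, center = p$center)
  expect_equal(coordination_number(pp, radii), cn[perm])
})

test_that("surface-normal force projection follows the radial formula", {
  expect_equal(normal_force_component(c(5, 0, 0), c(2, 0, 0)), 2)
  expect_equal(normal_force_component(c(5, 0, 0), c(0, 3, 0)), 0)
  expect_equal(normal_force_component(c(3, 4, 0), c(1, 1, 0)), 1.4)
  expect_error(normal_force_component(c(0, 0, 0), c(1, 0, 0)),
               "centre")
})

test_that("descriptor vector has the canonical 62-entry schema", {
  p <- small_described_particle(radius = 6, shell_depth = 3, maxit = 40)
  d <- compute_descriptors(p, mg_radii())
  expect_length(d, 62)
  expect_true(all(is.finite(d)))
  cats <- table(attr(d, "category"))
  expect_equal(cats[["composition"]], 9)
  expect_equal(cats[["potential_energy"]], 9)
  expect_equal(cats[["topology"]], 9)
  expect_equal(cats[["lattice_energy"]], 5)
  expect_equal(cats[["size"]], 3)
  expect_equal(cats[["force_vectors"]], 27)
  expect_equal(names(d), as.character(descriptor_names()))
})

test_that("composition counts equal brute-force scope x region counts", {
  p <- small_described_particle(radius = 6, shell_depth = 3, maxit = 20)
  d <- compute_descriptors(p, mg_radii())
  metal <- p$atoms$species != "O"
  shell <- p$region == "shell"
  expect_equal(unname(d["n_atoms_all_whole"]), n_atoms(p))
  expect_equal(unname(d["n_atoms_metal_whole"]), sum(metal))
  expect_equal(unname(d["n_atoms_oxygen_shell"]), sum(!metal & shell))
  expect_equal(unname(d["n_atoms_all_core"]), sum(!shell))
  ## additivity across scopes and regions
  for (rg in c("whole", "core", "shell"))
    expect_equal(d[[paste0("n_atoms_all_", rg)]],
                 d[[paste0("n_atoms_metal_", rg)]] +
                   d[[paste0("n_atoms_oxygen_", rg)]])
})

test_that("whole-particle means are count-weighted core/shell combinations", {
  p <- small_described_particle(radius = 6, shell_depth = 3, maxit = 20)
  d <- compute_descriptors(p, mg_radii())
  for (sc in c("all", "metal", "oxygen")) {
    nc <- d[[paste0("n_atoms_", sc, "_core")]]
    ns <- d[[paste0("n_atoms_", sc, "_shell")]]
    expect_equal(d[[paste0("e_pot_mean_", sc, "_whole")]],
                 (nc * d[[paste0("e_pot_mean_", sc, "_core")]] +
                    ns * d[[paste0("e_pot_mean_", sc, "_shell")]]) /
                   (nc + ns))
  }
})

test_that("descriptors are invariant under rigid rotation", {
  p <- small_described_particle(radius = 6, shell_depth = 3, maxit = 40)
  d0 <- compute_descriptors(p, mg_radii())
  rot <- rotate_particle(p, axis = c(1, 1, 0), angle = 0.9)
  d1 <- compute_descriptors(rot, mg_radii())
  expect_equal(d1, d0, tolerance = 1e-8)
})

test_that("shell fraction grows as the nominal radius shrinks", {
  fracs <- vapply(c(12, 10, 8, 6), function(r) {
    p <- neutralize(carve_sphere(
      replicate_cell(make_rocksalt(), c(7, 7, 7)), r))
    p <- assign_regions(p, shell_depth = 5)
    mean(p$region == "shell")
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("force-free minimum yields vanishing force descriptors", {
  ## relax a small particle hard, then check the force block is ~0
  p <- neutralize(carve_sphere(replicate_cell(make_rocksalt(), c(3, 3, 3)),
                               4.5))
  p <- minimize_energy(p, toy_forcefield(),
                       tol = list(force = 1e-6, energy = 0, maxit = 4000))
  expect_true(attr(p, "converged"))
  p <- assign_regions(p, 2)
  ## tiny particle: some scope x region cells may be empty by construction
  d <- suppressWarnings(compute_descriptors(p, mg_radii()))
  fv <- d[attr(d, "category") == "force_vectors"]
  expect_lt(max(abs(fv)), 1e-4)
})

test_that("descriptor CSV export is one row per material", {
  p <- small_described_particle(radius = 5, shell_depth = 3, maxit = 10)
  d <- suppressWarnings(compute_descriptors(p, mg_radii()))
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_descriptor_csv(list(MgO_test = d), path)
  back <- read.csv(path)
  expect_equal(dim(back), c(1, 63))   # material id + 62 descriptors
  expect_equal(back$material_id, "MgO_test")
  expect_equal(unname(unlist(back[1, -1])), as.numeric(d),
               tolerance = 1e-12)
})
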