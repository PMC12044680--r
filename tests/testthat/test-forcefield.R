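test_that("pair mixing honours explicit table rows, L-B rules and cross scaling", {
  ff <- ff_default
  # explicit tabulated pair wins over mixing
  expect_equal(unname(mix_pair_params("Si", "CH3", ff)), c(0.1596, 3.83))
  expect_equal(unname(mix_pair_params("O", "CH3", ff)), c(0.1247, 3.38))
  # symmetry, exactly
  expect_identical(mix_pair_params("Si", "O", ff), mix_pair_params("O", "Si", ff))
  # identity case: same kind, no explicit entry
  p <- mix_pair_params("OW", "OW", ff)
  expect_equal(unname(p), c(0.1553, 3.166))
  # water-organic cross epsilon scaled by 1.20, sigma arithmetic mean
  p <- mix_pair_params("OW", "CA", ff)
  expect_equal(p[["epsilon"]], 1.20 * sqrt(0.1553 * 0.070), tolerance = 1e-12)
  expect_equal(p[["sigma"]], (3.166 + 3.55) / 2, tolerance = 1e-12)
  # plain L-B for an unscaled pair
  p <- mix_pair_params("CH3", "CA", ff)
  expect_equal(p[["epsilon"]], sqrt(0.1944 * 0.070), tolerance = 1e-12)
  expect_error(mix_pair_params("Si", "Xx", ff), "Xx")
})

test_that("LJ pair energy matches the 12-6 form", {
  expect_equal(lj_pair_energy(3.86, 0.1944, 3.86), 0)
  expect_equal(lj_pair_energy(2^(1 / 6) * 3.86, 0.1944, 3.86), -0.1944,
               tolerance = 1e-12)
  # hand-evaluated value for the refined methyl pair at 5 A
  expect_equal(round(lj_pair_energy(5, 0.1944, 3.86), 4), -0.1298)
  expect_error(lj_pair_energy(0, 1, 1), "r must be")
})

test_that("Coulomb methods: direct value, DSF boundary, short-range limits", {
  expect_equal(coulomb_pair_energy(1, 1, 1, "direct"), 332.0637,
               tolerance = 1e-5)
  expect_equal(coulomb_pair_energy(7, 0, 0.5, "direct"), 0)
  # damped-shifted-force vanishes at the cutoff by construction
  expect_equal(coulomb_pair_energy(12, 1, 1, "damped-shifted-force",
                                   cutoff = 12), 0)
  # both screened forms reduce to direct Coulomb at r << cutoff, weak damping
  for (m in c("damped-shifted-force", "reaction-field")) {
    e <- coulomb_pair_energy(1, 1, 1, m, cutoff = 1e5, alpha = 1e-8)
    expect_equal(e, 332.0637, tolerance = 1e-3)
  }
  expect_error(coulomb_pair_energy(-1, 1, 1), "r must be")
})

test_that("methyl sigma refinement is the documented 3.49% inflation", {
  # forward application of the refinement recovers the refined table value
  expect_equal(apply_ch3_sigma_modification(3.7298), 3.86, tolerance = 1e-4)
  expect_equal(apply_ch3_sigma_modification(1), 1.0349)
  # round trip
  expect_equal(apply_ch3_sigma_modification(2.5) / 1.0349, 2.5,
               tolerance = 1e-12)
})

test_that("bonded energies: equilibrium zero, harmonic convention, breakdown", {
  ff <- ff_default
  kinds <- data.frame(name = "HW", mass = 1, charge = 0, epsilon = 0,
                      sigma = 0, stringsAsFactors = FALSE)
  # single bond, k = 300, stretched by 0.1 A: E = k dr^2 = 3.0
  pos <- rbind(c(0, 0, 0), c(1.6, 0, 0))
  sys <- molecular_system(kinds, c(1L, 1L), c(1L, 1L), "m", pos,
                          box = c(50, 50, 50),
                          bonds = matrix(1:2, 1), bond_k = 300, bond_r0 = 1.5)
  e <- total_potential_energy(sys, ff)
  expect_equal(e$energy, 3.0, tolerance = 1e-12)
  # half-k convention via the config flag
  ffh <- ff; ffh$bonded$half_k <- TRUE
  expect_equal(total_potential_energy(sys, ffh)$energy, 1.5, tolerance = 1e-12)
  # everything at equilibrium: zero
  sys$pos[2, 1] <- 1.5
  expect_equal(total_potential_energy(sys, ff)$energy, 0)
  # breakdown sums to the total on a bonded+nonbonded system
  wsys <- make_water_box(8, 9, seed = 21)
  ew <- total_potential_energy(wsys, ff)
  expect_equal(sum(ew$breakdown), ew$energy, tolerance = 1e-12)
})

test_that("total energy matches an O(N^2) brute-force oracle without cutoff", {
  set.seed(31)
  n <- 50
  # spread sites out to avoid near-singular overlaps
  pos <- matrix(stats::runif(3 * n, 0, 30), n, 3)
  while (TRUE) {
    d <- as.matrix(stats::dist(pos))
    diag(d) <- Inf
    if (min(d) > 2.0) break
    i <- which(d == min(d), arr.ind = TRUE)[1, 1]
    pos[i, ] <- stats::runif(3, 0, 30)
  }
  kinds <- data.frame(name = "CH3x", mass = 15, charge = 0.1,
                      epsilon = 0.1944, sigma = 3.4,
                      stringsAsFactors = FALSE)
  ff <- forcefield(list(site_kind("CH3x", 15, 0.1, 0.1944, 3.4)),
                   cutoff = 1e6, electrostatics = "direct", lj_tail = "none")
  sys <- molecular_system(kinds, rep(1L, n), seq_len(n), rep("m", n), pos,
                          box = c(1e7, 1e7, 1e7),
                          periodic = c(FALSE, FALSE, FALSE))
  e <- total_potential_energy(sys, ff)
  oracle <- brute_force_energy(pos, 0.1944, 3.4, rep(0.1, n),
                               rep(1e7, 3), rep(FALSE, 3), 1e6)
  expect_equal(e$energy, oracle, tolerance = 1e-10)
})

test_that("analytic forces equal the negative finite-difference gradient", {
  set.seed(9)
  # waters: LJ + DSF electrostatics + constraints-excluded intramolecular
  wsys <- make_water_box(6, 9, seed = 13)
  expect_lt(fd_force_err(wsys, ff_default), 1e-6)
  # PDMS oligomer: bonds, angles, dihedrals
  osys <- build_bulk_system(list(build_pdms_oligomer(2, ff_default)), 1L,
                            c(40, 40, 40), ff = ff_default, seed = 2)
  osys$pos <- osys$pos + matrix(stats::rnorm(3 * nrow(osys$pos), 0, 0.07),
                                ncol = 3)
  expect_lt(fd_force_err(osys, ff_default), 1e-6)
  # organic template: full bonded network
  gsys <- build_bulk_system(list(organic_template("guaiacol", ff_default)),
                            1L, c(40, 40, 40), ff = ff_default, seed = 3)
  gsys$pos <- gsys$pos + matrix(stats::rnorm(3 * nrow(gsys$pos), 0, 0.05),
                                ncol = 3)
  expect_lt(fd_force_err(gsys, ff_default), 1e-6)
})

test_that("force properties: Newton's third law, zero at minimum, net zero", {
  kinds <- data.frame(name = "CH3", mass = 15, charge = 0, epsilon = 0.1944,
                      sigma = 3.86, stringsAsFactors = FALSE)
  rmin <- 2^(1 / 6) * 3.86
  pos <- rbind(c(10, 10, 10), c(10 + rmin, 10, 10))
  sys <- molecular_system(kinds, c(1L, 1L), 1:2, c("a", "b"), pos,
                          box = c(50, 50, 50), periodic = rep(FALSE, 3))
  ffn <- ff_default; ffn$lj_tail <- "none"
  e <- total_potential_energy(sys, ffn)
  expect_equal(e$energy, -0.1944, tolerance = 1e-9)
  expect_equal(e$forces[1, ], -e$forces[2, ], tolerance = 1e-12)
  expect_lt(max(abs(e$forces)), 1e-8)
  # net force on an isolated many-body system is zero
  osys <- build_bulk_system(list(build_pdms_oligomer(1, ff_default)), 1L,
                            c(40, 40, 40), ff = ff_default, seed = 4)
  osys$pos <- osys$pos + matrix(stats::rnorm(3 * nrow(osys$pos), 0, 0.05),
                                ncol = 3)
  f <- forces(osys, ff_default)
  expect_lt(max(abs(colSums(f))), 1e-10)
})

test_that("energy is invariant under translation by a box length on a periodic axis", {
  sys <- make_water_box(10, 10, seed = 17)
  e1 <- total_potential_energy(sys, ff_default)$energy
  sys$pos[, 2] <- sys$pos[, 2] + sys$box[2]
  e2 <- total_potential_energy(sys, ff_default)$energy
  expect_equal(e2, e1, tolerance = 1e-10)
})

test_that("overlapping sites raise a singularity error", {
  kinds <- data.frame(name = "CH3", mass = 15, charge = 0, epsilon = 0.1944,
                      sigma = 3.86, stringsAsFactors = FALSE)
  pos <- rbind(c(1, 1, 1), c(1, 1, 1))
  sys <- molecular_system(kinds, c(1L, 1L), 1:2, c("a", "b"), pos,
                          box = c(20, 20, 20))
  expect_error(total_potential_energy(sys, ff_default), "overlap")
})

test_that("parameter file round trip is lossless", {
  ff <- ff_default
  path <- withr::local_tempfile(fileext = ".yaml")
  write_forcefield(ff, path)
  ff2 <- read_forcefield(path)
  expect_equal(ff2, ff)
  # energies agree on a real system
  sys <- make_water_box(5, 9, seed = 23)
  expect_equal(total_potential_energy(sys, ff2)$energy,
               total_potential_energy(sys, ff)$energy)
})
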