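test_that("free flight is exact and n_steps = 0 returns the input state", {
  kinds <- data.frame(name = "HW", mass = 15, charge = 0, epsilon = 0,
                      sigma = 0, stringsAsFactors = FALSE)
  sys <- molecular_system(kinds, 1L, 1L, "p", matrix(c(1, 1, 1), 1),
                          box = c(50, 50, 50))
  sys$vel <- matrix(c(0.01, 0, 0), 1)
  tr <- run_ensemble(sys, ff_default, md_config(ensemble = "NVE"), 100)
  expect_equal(tr$final$pos[1, 1], 2.0, tolerance = 1e-12)
  tr0 <- run_ensemble(sys, ff_default, md_config(ensemble = "NVE"), 0)
  expect_identical(tr0$final$pos, sys$pos)
  expect_equal(n_frames(tr0), 1L)
})

test_that("harmonic bond oscillation period matches the closed form", {
  ffq <- forcefield(list(site_kind("Q", 15, 0, 0, 1)), cutoff = 12)
  kinds <- data.frame(name = "Q", mass = 15, charge = 0, epsilon = 0,
                      sigma = 1, stringsAsFactors = FALSE)
  pos <- rbind(c(10, 10, 10), c(11.6, 10, 10))
  sys <- molecular_system(kinds, c(1L, 1L), c(1L, 1L), "m", pos,
                          box = c(50, 50, 50), bonds = matrix(1:2, 1),
                          bond_k = 300, bond_r0 = 1.5)
  # E = k dr^2 so omega = sqrt(2 k / mu) in engine units
  mu <- 7.5
  k2 <- 2 * 300 / pdms_constants$mvsq_to_kcal
  period <- 2 * pi * sqrt(mu / k2)
  cfg <- md_config(ensemble = "NVE", dt = period / 1000, stride = 1)
  tr <- run_ensemble(sys, ffq, cfg, 2000)
  bl <- vapply(tr$frames, function(p) sqrt(sum((p[2, ] - p[1, ])^2)), 0) - 1.5
  cross <- which(diff(sign(bl)) > 0)
  est <- mean(diff(cross)) * period / 1000
  expect_equal(est, period, tolerance = 1e-3)
})

test_that("NVE conserves energy and the error amplitude scales ~dt^2", {
  sys <- make_lj_fluid(64, 18, seed = 5)
  sys <- initialize_velocities(sys, 150, seed = 7)
  eq <- run_ensemble(sys, ff_default,
                     md_config(ensemble = "NVT", T_target = 150,
                               thermostat = "langevin", stride = 100), 1000)
  amp <- vapply(c(0.5, 1, 2), function(dt) {
    tr <- run_ensemble(eq$final, ff_default,
                       md_config(ensemble = "NVE", dt = dt, stride = 10), 1000)
    E <- tr$records$epot + tr$records$ekin
    stats::sd(E)
  }, 0)
  # quadratic step-size scaling of the energy error, within a loose band
  expect_gt(amp[3] / amp[2], 2.2)
  expect_gt(amp[2] / amp[1], 2.2)
  expect_lt(amp[3] / amp[1], 40)
})

test_that("NVE trajectory energies are reproducible from the stored frames", {
  sys <- make_lj_fluid(27, 14, seed = 3)
  sys <- initialize_velocities(sys, 120, seed = 4)
  tr <- run_ensemble(sys, ff_default, md_config(ensemble = "NVE", stride = 50),
                     200)
  for (f in c(1, 3, 5)) {
    s2 <- sys
    s2$pos <- tr$frames[[f]]
    expect_equal(total_potential_energy(s2, ff_default)$energy,
                 tr$records$epot[f], tolerance = 1e-10)
  }
})

test_that("SHAKE restores constraints, fixes satisfied states, preserves the COM", {
  sys <- make_water_box(1, 12, seed = 1)
  m <- site_masses(sys)
  # stretch one O-H by 5%
  bad <- sys
  bad$pos[2, ] <- bad$pos[1, ] + (bad$pos[2, ] - bad$pos[1, ]) * 1.05
  com0 <- colSums(bad$pos * m) / sum(m)
  fixed <- shake_project(bad, ref = bad)
  expect_equal(sqrt(sum((fixed$pos[1, ] - fixed$pos[2, ])^2)), 1.0,
               tolerance = 1e-8)
  com1 <- colSums(fixed$pos * m) / sum(m)
  expect_equal(com1, com0, tolerance = 1e-12)
  # already-satisfied constraints: zero displacement
  again <- shake_project(fixed, ref = fixed)
  expect_equal(again$pos, fixed$pos, tolerance = 1e-12)
})

test_that("SHAKE holds water rigid at every recorded frame of an NVT run", {
  sys <- make_water_box(16, 9.5, seed = 11)
  sys <- initialize_velocities(sys, 298.15, seed = 2)
  tr <- run_ensemble(sys, ff_default,
                     md_config(ensemble = "NVT", T_target = 298.15,
                               thermostat = "langevin", stride = 100), 2000)
  cm <- sys$constraints; cd <- sys$cons_d
  for (f in seq_len(n_frames(tr))) {
    p <- tr$frames[[f]]
    dev <- vapply(seq_len(nrow(cm)), function(c)
      abs(sqrt(sum((p[cm[c, 1], ] - p[cm[c, 2], ])^2)) - cd[c]) / cd[c], 0)
    expect_lt(max(dev), 1e-7)
  }
})

test_that("thermostatted water relaxes to the target temperature", {
  sys <- make_water_box(24, 10.5, seed = 11)
  sys <- initialize_velocities(sys, 298.15, seed = 2)
  tr <- run_ensemble(sys, ff_default,
                     md_config(ensemble = "NVT", T_target = 298.15,
                               stride = 20), 8000)
  late <- tr$records[tr$records$step > 3000, ]
  expect_gt(mean(late$T), 292)
  expect_lt(mean(late$T), 304)
})

test_that("trajectories are bit-identical under a fixed seed and config", {
  sys <- make_lj_fluid(27, 14, seed = 3)
  run <- function() {
    s <- initialize_velocities(sys, 150, seed = 9)
    run_ensemble(s, ff_default,
                 md_config(ensemble = "NVT", T_target = 150,
                           thermostat = "langevin", stride = 20,
                           seed = 31), 200)
  }
  t1 <- run(); t2 <- run()
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$records, t2$records)
})

test_that("annealing schedule enumerates levels from T_high to T_low inclusive", {
  s <- anneal_schedule(408.15, 298.15, 10)
  expect_length(s$levels, 12)
  expect_equal(s$levels[1], 408.15)
  expect_equal(s$levels[12], 298.15)
  expect_length(anneal_schedule(300, 300, 10)$levels, 1)
})

test_that("wall force is ranged, repulsive, monotone and species-selective", {
  w <- wall_def(0, +1, epsilon = 0.5, sigma = 3.0, species = "pdms")
  # beyond the interaction range: zero
  expect_equal(wall_force(c(10, 5, 5), w, "pdms1"), c(0, 0, 0))
  # inside range: pushes inward (+x), monotone in proximity
  f2 <- wall_force(c(2.5, 0, 0), w, "pdms1")[1]
  f15 <- wall_force(c(1.5, 0, 0), w, "pdms1")[1]
  expect_gt(f2, 0)
  expect_gt(f15, f2)
  # a water site passes freely regardless of distance
  expect_equal(wall_force(c(0.8, 0, 0), w, "water"), c(0, 0, 0))
  # high-x wall pushes in -x
  wh <- wall_def(42, -1, species = "pdms")
  expect_lt(wall_force(c(41, 0, 0), wh, "pdms2")[1], 0)
})

test_that("non-finite forces and thermostat divergence raise stability errors", {
  kinds <- data.frame(name = "CH3", mass = 15, charge = 0, epsilon = 0.1944,
                      sigma = 3.86, stringsAsFactors = FALSE)
  # two sites nearly on top of each other: the first step blows up
  pos <- rbind(c(1, 1, 1), c(1.05, 1, 1))
  sys <- molecular_system(kinds, c(1L, 1L), 1:2, c("a", "b"), pos,
                          box = c(30, 30, 30))
  expect_error(
    run_ensemble(sys, ff_default,
                 md_config(ensemble = "NVT", T_target = 100, stride = 10), 200),
    "divergence|non-finite|overlap")
})
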