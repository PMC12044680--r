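test_that("partition scenarios are validated and deterministic", {
  expect_error(partition_scenario(interfaces = c(90, 30)), "geometry")
  expect_error(partition_scenario(box = c(60, 40, 40),
                                  interfaces = c(50, 78)), "geometry")
  sc <- partition_scenario(frames = 5)
  t1 <- make_partition_trajectory(sc, seed = 9)
  t2 <- make_partition_trajectory(sc, seed = 9)
  expect_identical(t1$frames, t2$frames)
})

test_that("static scenarios round-trip exactly through the analysis chain", {
  sc <- partition_scenario(occupancy = list(organic = c(water = 50, pdms = 140)),
                           frames = 30)
  traj <- make_partition_trajectory(sc, seed = 1)
  part <- partition_counts(traj, "organic", c(50, 78), margin = 3)
  expect_equal(unname(part$counts), c(140, 50, 0))
  # prescribed log P recovered to arithmetic precision
  lp <- log_p(part$counts[["pdms"]], 28 * 1600, part$counts[["water"]],
              96 * 1600)
  expect_equal(lp, log10((140 / 28) / (50 / 96)), tolerance = 1e-12)
  # zero organics: undefined log P flagged
  sc0 <- partition_scenario(occupancy = list(organic = c(water = 5, pdms = 0)),
                            frames = 5)
  tr0 <- make_partition_trajectory(sc0, seed = 2)
  p0 <- partition_counts(tr0, "organic", c(50, 78))
  l0 <- log_p(p0$counts[["pdms"]], 28 * 1600, p0$counts[["water"]], 96 * 1600)
  expect_true(is.na(l0) && isTRUE(attr(l0, "undefined")))
})

test_that("occupancies chosen for a target log P are recovered", {
  # occupancy ratio implying log P = 0.78 under the reference volumes:
  # n_p / n_w = 10^0.78 * (28/96)
  n_w <- 60
  n_p <- round(n_w * 10^0.78 * 28 / 96)
  sc <- partition_scenario(occupancy = list(organic = c(water = n_w,
                                                        pdms = n_p)),
                           frames = 30)
  traj <- make_partition_trajectory(sc, seed = 3)
  part <- partition_counts(traj, "organic", c(50, 78))
  lp <- log_p(part$counts[["pdms"]], 28 * 1600, part$counts[["water"]],
              96 * 1600)
  expect_equal(lp, 0.78, tolerance = 0.02)  # rounding of n_p only
})

test_that("relaxing scenarios approach equilibrium on the prescribed time scale", {
  sc <- partition_scenario(occupancy = list(organic = c(water = 40, pdms = 160)),
                           frames = 120, relax_tau = 15, start_in_water = TRUE)
  traj <- make_partition_trajectory(sc, seed = 4)
  part <- partition_counts(traj, "organic", c(50, 78))
  npdms <- part$per_frame[, "pdms"]
  # starts empty, ends near equilibrium
  expect_lt(npdms[1], 30)
  expect_gt(mean(npdms[80:120]), 140)
  # crossing of 1 - 1/e of equilibrium within ~2 tau
  t63 <- which(npdms > 160 * (1 - exp(-1)))[1]
  expect_lt(t63, 30)
})

test_that("Brownian generator: stationarity at D = 0, ratio recovery, seeding", {
  tb0 <- make_brownian_trajectory(c(a = 0), n_particles = 5, steps = 20,
                                  seed = 1)
  expect_identical(tb0$frames[[1]], tb0$frames[[21]])
  tb <- make_brownian_trajectory(c(slow = 1e-5, fast = 1e-4),
                                 n_particles = 150, dt = 1000, steps = 300,
                                 seed = 2)
  ds <- diffusion_coefficient(msd(tb, "slow", origin_stride = 5))$D
  df <- diffusion_coefficient(msd(tb, "fast", origin_stride = 5))$D
  expect_equal(df / ds, 10, tolerance = 0.1)
  tb2 <- make_brownian_trajectory(c(slow = 1e-5, fast = 1e-4),
                                  n_particles = 150, dt = 1000, steps = 300,
                                  seed = 2)
  expect_identical(tb$frames, tb2$frames)
})

test_that("Widom oracle: ideal gas gives zero, phase swap flips the sign", {
  set.seed(6)
  frames <- replicate(5, matrix(stats::runif(60, 0, 12), 20, 3),
                      simplify = FALSE)
  em0 <- matrix(0, 2, 2); sm <- matrix(3, 2, 2)
  w0 <- widom_log_p(frames, frames, rep(1L, 20), rep(1L, 20), em0, sm,
                    solute_kind = 2, box = rep(12, 3), kT = 0.3,
                    n_insertions = 200, seed = 1)
  expect_equal(w0$mu_A, 0)
  expect_equal(w0$mu_B, 0)
  expect_equal(w0$log_p, 0)
  # antisymmetry: swapping the phase ensembles flips log P exactly
  set.seed(7)
  fa <- replicate(4, matrix(stats::runif(45, 0, 10), 15, 3), simplify = FALSE)
  fb <- replicate(4, matrix(stats::runif(75, 0, 10), 25, 3), simplify = FALSE)
  em <- matrix(c(0.2, 0.2, 0.2, 0), 2, 2)
  w1 <- widom_log_p(fa, fb, rep(1L, 15), rep(1L, 25), em, sm, 2, rep(10, 3),
                    kT = 0.4, n_insertions = 300, seed = 5)
  w2 <- widom_log_p(fb, fa, rep(1L, 25), rep(1L, 15), em, sm, 2, rep(10, 3),
                    kT = 0.4, n_insertions = 300, seed = 5)
  expect_equal(w1$log_p, -w2$log_p, tolerance = 1e-12)
})

test_that("dilute-bath excess chemical potential matches the second-virial form", {
  # dilute LJ bath: mu_ex ~ 2 kT B2 rho with
  # B2 = 2 pi int (1 - exp(-u/kT)) r^2 dr over the truncated potential
  kT <- 0.6; eps <- 0.25; sig <- 3.2; L <- 40; nb <- 35; rc <- 12
  set.seed(12)
  frames <- replicate(40, matrix(stats::runif(3 * nb, 0, L), nb, 3),
                      simplify = FALSE)
  em <- matrix(c(0, eps, eps, 0), 2, 2)
  sm <- matrix(sig, 2, 2)
  w <- widom_log_p(frames, frames, rep(1L, nb), rep(1L, nb), em, sm, 2,
                   rep(L, 3), kT = kT, n_insertions = 4000, cutoff = rc,
                   seed = 3)
  u_fs <- function(r) {
    sr6 <- (sig / r)^6; src6 <- (sig / rc)^6
    frc <- 24 * eps * (2 * src6^2 - src6) / rc
    4 * eps * (sr6^2 - sr6) - 4 * eps * (src6^2 - src6) + frc * (r - rc)
  }
  b2 <- 2 * pi * stats::integrate(function(r)
    (1 - exp(-u_fs(r) / kT)) * r^2, 0, rc)$value
  mu_virial <- 2 * kT * b2 * nb / L^3
  expect_equal(w$mu_A, mu_virial, tolerance = 0.10)
})

test_that("neutral solutes split evenly; contrast drives them into phase A", {
  # symmetric contrast, mobile solvent: long-run occupancies of the two
  # equal-volume phases are statistically equal
  toy <- make_toy_two_phase_system(affinity_contrast = 1, n_per_phase = 42,
                                   n_solute = 16, L = 14, sigma_solute = 2.6,
                                   seed = 3)
  run <- toy_mc_run(toy, kT = 0.45, n_sweeps = 8000, stride = 20,
                    disp = 0.8, jump_prob = 0.1, seed = 101)
  keep <- seq(floor(length(run$frames) * 0.25) + 1, length(run$frames))
  cnt <- toy_phase_counts(toy, run$frames[keep], margin = 2)
  bsA <- block_sem(cnt[, "A"], 25)
  bsB <- block_sem(cnt[, "B"], 25)
  expect_lt(abs(bsA$mean - bsB$mean),
            4 * sqrt(bsA$sem^2 + bsB$sem^2) + 0.5)
  # contrast > 1: both estimation routes agree on the direction
  toy2 <- make_toy_two_phase_system(affinity_contrast = 1.7, n_per_phase = 42,
                                    n_solute = 16, L = 14, sigma_solute = 2.6,
                                    seed = 4)
  r2 <- toy_counting_vs_widom(toy2, kT = 0.45, seed = 102)
  expect_gt(r2$log_p_count, 0)
  expect_gt(r2$log_p_widom, 0)
})

test_that("counting and Widom log P agree on the quenched two-phase medium", {
  toy <- make_toy_two_phase_system(affinity_contrast = 1.7, n_per_phase = 42,
                                   n_solute = 16, L = 14, sigma_solute = 2.6,
                                   seed = 2)
  r <- toy_counting_vs_widom(toy, kT = 0.45, seed = 202)
  # pre-registered band: 3x the combined standard error
  expect_lt(abs(r$diff), 3 * r$combined_se)
})
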