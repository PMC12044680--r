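test_that("molecule coordinate is the site nearest the centre of mass", {
  # single site: its own x
  expect_equal(molecule_coordinate(matrix(c(3, 1, 1), 1), 1), 3)
  # symmetric linear triatomic: the central site
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(molecule_coordinate(pos, c(1, 1, 1)), 1)
  # random oligomer vs exhaustive scan
  set.seed(41)
  for (rep in 1:5) {
    p <- matrix(stats::rnorm(39), 13, 3)
    m <- stats::runif(13, 1, 30)
    com <- colSums(p * m) / sum(m)
    idx <- which.min(rowSums(sweep(p, 2, com)^2))
    expect_equal(molecule_coordinate(p, m), p[idx, 1])
  }
})

test_that("density profile bins conserve counts and recover a step profile", {
  sc <- partition_scenario(occupancy = list(organic = c(water = 30, pdms = 70)),
                           frames = 20)
  traj <- make_partition_trajectory(sc, seed = 3)
  prof <- density_profile(traj, "organic", 1.5)
  # conservation per frame
  expect_true(all(rowSums(prof$counts) == 100))
  # all molecules at one x land in one half-open bin
  sys1 <- pdmslab:::synthetic_system(list(m = 5), c(30, 10, 10))
  tr1 <- pdmslab:::synthetic_traj(sys1, list(cbind(rep(10, 5), 1:5, 1:5)))
  p1 <- density_profile(tr1, "m", 1.5)
  expect_equal(sum(p1$mean_counts > 0), 1)
  expect_equal(max(p1$mean_counts), 5)
  # the occupied bin is [9, 10.5)
  hit <- which(p1$mean_counts > 0)
  expect_equal(p1$edges[hit], 9)
  expect_error(density_profile(traj, "organic", 0), "bin_width")
  # step profile recovered within binning error
  pp <- density_profile(traj, "polymer", 1.5)
  inside <- pp$centers > 53 & pp$centers < 75
  outside <- pp$centers < 45 | pp$centers > 83
  expect_gt(mean(pp$mean_counts[inside]), 10 * max(pp$mean_counts[outside], 0.1))
})

test_that("interface location finds the plateau edges of the polymer slab", {
  sc <- partition_scenario(frames = 40)
  traj <- make_partition_trajectory(sc, seed = 5)
  prof <- density_profile(traj, "polymer", 1.5)
  ifc <- locate_interfaces(prof)
  expect_equal(ifc[1], 50, tolerance = 1.5 / 50)
  expect_equal(ifc[2], 78, tolerance = 1.5 / 78)
  # symmetry about the slab centre to one bin
  expect_lt(abs((ifc[1] + ifc[2]) / 2 - 64), 1.5)
  # nominal positions pass through
  expect_equal(locate_interfaces(prof, nominal = c(50, 78)), c(50, 78))
  # degenerate all-zero profile
  empty <- prof; empty$mean_counts[] <- 0
  expect_error(locate_interfaces(empty), "plateau")
})

test_that("phase classification is exhaustive, exclusive and boundary-closed", {
  sc <- partition_scenario(occupancy = list(organic = c(water = 50, pdms = 140)),
                           frames = 25)
  traj <- make_partition_trajectory(sc, seed = 1)
  part <- partition_counts(traj, "organic", c(50, 78), margin = 3)
  # static scenario: exact counts every frame
  expect_equal(unname(part$counts), c(140, 50, 0))
  expect_true(all(rowSums(part$per_frame) == 190))
  # boundary tie-break: molecule exactly at x_left + margin is polymer phase
  sys1 <- pdmslab:::synthetic_system(list(m = 3), c(128, 40, 40))
  tr1 <- pdmslab:::synthetic_traj(sys1,
    list(cbind(c(53, 46.9, 47.5), c(1, 2, 3), c(1, 2, 3))))
  p1 <- partition_counts(tr1, "m", c(50, 78), margin = 3)
  expect_equal(unname(p1$counts), c(1, 1, 1))  # closed pdms, water, excluded
  # brute-force re-classification on random positions
  set.seed(8)
  x <- stats::runif(1000, 0, 128)
  trr <- pdmslab:::synthetic_traj(
    pdmslab:::synthetic_system(list(m = 1000), c(128, 40, 40)),
    list(cbind(x, 1, 1)))
  pr <- partition_counts(trr, "m", c(50, 78), margin = 3)
  expect_equal(pr$counts[["pdms"]], sum(x >= 53 & x <= 75))
  expect_equal(pr$counts[["water"]], sum(x < 47 | x > 81))
  expect_equal(sum(pr$counts), 1000)
  expect_error(partition_counts(traj, "organic", c(50, 78), margin = 20),
               "margin")
  expect_error(partition_counts(traj, "organic", c(-5, 200)), "interfaces")
})

test_that("log P arithmetic reproduces the reference phase-count ratios", {
  vol_p <- 28 * 40 * 40
  vol_w <- 2 * 48 * 40 * 40
  expect_equal(log_p(140, vol_p, 50, vol_w), 0.98, tolerance = 0.005)
  expect_equal(log_p(86, vol_p, 27, vol_w), 1.04, tolerance = 0.005)
  # equal concentrations
  expect_equal(log_p(10, 100, 20, 200), 0)
  # zero count: undefined, flagged, not an error
  und <- log_p(0, vol_p, 50, vol_w)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
  expect_error(log_p(1, 0, 1, 1), "volumes")
})

test_that("molar solubility conversion has the right scale", {
  vol_p <- 28 * 40 * 40
  expect_equal(molar_solubility(140, vol_p), 5.19, tolerance = 0.005)
  expect_equal(molar_solubility(108, vol_p), 4.00, tolerance = 0.005)
  expect_equal(molar_solubility(0, 1000), 0)
  # unit discipline: 1 molecule in 1660.54 A^3 is 1 mol/L
  expect_equal(molar_solubility(1, 1660.54), 1.0, tolerance = 1e-4)
})

test_that("MSD: stationary, ballistic and Brownian limits", {
  # stationary
  sys <- pdmslab:::synthetic_system(list(m = 4), c(50, 50, 50),
                                    periodic = rep(TRUE, 3))
  pos <- matrix(stats::runif(12, 0, 50), 4, 3)
  trs <- pdmslab:::synthetic_traj(sys, rep(list(pos), 10), dt = 1)
  expect_true(all(msd(trs)$msd == 0))
  # ballistic: msd(t) = v^2 t^2 exactly
  sysb <- pdmslab:::synthetic_system(list(m = 1), c(100, 100, 100),
                                     periodic = rep(TRUE, 3))
  frames <- lapply(0:20, function(s) matrix(c(s * 0.5, 0, 0), 1))
  trb <- pdmslab:::synthetic_traj(sysb, frames, dt = 1)
  mb <- msd(trb)
  expect_equal(mb$msd, (0.5 * mb$time)^2, tolerance = 1e-12)
  # wrapped-only trajectory is refused
  trw <- pdmslab:::synthetic_traj(sysb, frames, dt = 1, unwrapped = FALSE)
  expect_error(msd(trw), "unwrapped")
})

test_that("diffusion coefficient: closed form, zero, and 5% parameter recovery", {
  # exact linear MSD = 6 D t with D = 2 A^2/ps = 2e-4 cm^2/s
  tms <- seq(0, 10000, by = 100)                    # fs
  m6 <- data.frame(time = tms, msd = 6 * 2e-3 * tms)  # 2 A^2/ps = 2e-3 A^2/fs
  d <- diffusion_coefficient(m6, n = 3)
  expect_equal(d$D, 2e-4, tolerance = 1e-12)
  dz <- diffusion_coefficient(data.frame(time = tms, msd = 0 * tms), n = 3)
  expect_equal(dz$D, 0)
  expect_error(diffusion_coefficient(m6, fit_window = c(0, 150)), "3 points")
  # Brownian generator recovery across two decades of D; the low-lag
  # window is unbiased (no ballistic regime) and has the least variance
  for (Dtrue in c(1e-6, 1e-5, 1e-4)) {
    tb <- make_brownian_trajectory(c(s = Dtrue), n_particles = 300, dt = 1000,
                                   steps = 400, seed = 11)
    m <- msd(tb, "s", origin_stride = 2)
    est <- diffusion_coefficient(m, fit_window = c(0, 0.2) * max(m$time))
    expect_equal(est$D, Dtrue, tolerance = 0.05, label = paste("D =", Dtrue))
  }
})

test_that("block averaging: degenerate cases and autocorrelation inflation", {
  b <- block_sem(rep(3.5, 100), 10)
  expect_equal(b$sem, 0)
  expect_equal(b$mean, 3.5)
  expect_equal(block_sem(rep(c(1, -1), 50), 2)$sem, 0)
  expect_error(block_sem(1:5, 5), "2 complete blocks")
  # grand mean invariant to blocking
  set.seed(2); x <- stats::rnorm(1000)
  expect_equal(block_sem(x, 10)$mean, mean(x))
  expect_equal(block_sem(x, 50)$mean, mean(x))
  # AR(1): block SEM at large blocks exceeds the naive i.i.d. SEM and
  # approaches the analytic inflation sqrt((1+phi)/(1-phi))
  set.seed(3)
  phi <- 0.9
  y <- as.numeric(stats::arima.sim(list(ar = phi), 20000))
  naive <- stats::sd(y) / sqrt(length(y))
  bl <- block_sem(y, 500)
  expect_gt(bl$sem / naive, 2.5)
  expect_lt(bl$sem / naive, sqrt((1 + phi) / (1 - phi)) * 1.5)
})

test_that("running log P detects plateaus and drifts", {
  vol_p <- 28 * 1600; vol_w <- 96 * 1600
  # stationary scenario: plateau, final value equals the static estimate
  sc <- partition_scenario(occupancy = list(organic = c(water = 50, pdms = 140)),
                           frames = 60)
  tr <- make_partition_trajectory(sc, seed = 2)
  cv <- logp_convergence(tr, "organic", c(50, 78), vol_p, vol_w, stride = 2)
  expect_true(cv$plateau)
  expect_equal(cv$final, log_p(140, vol_p, 50, vol_w), tolerance = 1e-10)
  # linearly drifting counts: no plateau
  sysd <- pdmslab:::synthetic_system(list(organic = 100), c(128, 40, 40))
  frames <- lapply(1:60, function(f) {
    n_in <- round(min(95, 5 + 1.5 * f))
    x <- c(stats::runif(n_in, 54, 74), stats::runif(100 - n_in, 0, 46))
    cbind(x, stats::runif(100, 0, 40), stats::runif(100, 0, 40))
  })
  trd <- pdmslab:::synthetic_traj(sysd, frames, unwrapped = FALSE)
  cvd <- logp_convergence(trd, "organic", c(50, 78), vol_p, vol_w, stride = 2)
  expect_false(cvd$plateau)
  expect_error(logp_convergence(tr, "organic", c(50, 78), vol_p, vol_w,
                                stride = 30), "10 strided")
})
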