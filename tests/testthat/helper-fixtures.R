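# Shared fixtures built in code: small systems used across test files.

ff_default <- pdms_forcefield()

# n CH3-like LJ sites on a jittered cubic lattice in a periodic box
make_lj_fluid <- function(n = 125, L = 22.5, seed = 5, jitter = 0.2) {
  set.seed(seed)
  k <- ceiling(n^(1 / 3))
  g <- expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k))[seq_len(n), ]
  pos <- as.matrix(g) * (L / k) - L / (2 * k) +
    matrix(stats::runif(3 * n, -jitter, jitter), n, 3)
  kinds <- data.frame(name = "CH3", mass = 15.0345, charge = 0,
                      epsilon = 0.1944, sigma = 3.86,
                      stringsAsFactors = FALSE)
  molecular_system(kinds, rep(1L, n), seq_len(n), rep("lj", n), pos,
                   box = c(L, L, L))
}

# small SPC water box (packed, minimized)
make_water_box <- function(n = 32, L = 11, seed = 11) {
  sys <- build_bulk_system(list(water_template(ff_default)), as.integer(n),
                           c(L, L, L), ff = ff_default, seed = seed,
                           min_dist = 2.0)
  minimize_energy(sys, ff_default)
}

# central-difference force check: max |F_fd - F_analytic| / max |F|
fd_force_err <- function(sys, ff, h = 1e-5) {
  e <- total_potential_energy(sys, ff)
  fd <- matrix(0, nrow(sys$pos), 3)
  for (i in seq_len(nrow(sys$pos))) {
    for (k in 1:3) {
      sp <- sys; sp$pos[i, k] <- sp$pos[i, k] + h
      sm <- sys; sm$pos[i, k] <- sm$pos[i, k] - h
      fd[i, k] <- -(total_potential_energy(sp, ff)$energy -
                      total_potential_energy(sm, ff)$energy) / (2 * h)
    }
  }
  max(abs(fd - e$forces)) / max(abs(e$forces))
}

# plain-R brute-force nonbonded energy oracle (no cutoff tricks shared
# with the C++ path beyond the same formulas)
brute_force_energy <- function(pos, eps, sig, charge, box, periodic,
                               cutoff, kc = pdms_constants$coulomb) {
  n <- nrow(pos)
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      d <- ifelse(periodic, d - box * round(d / box), d)
      r <- sqrt(sum(d^2))
      if (r >= cutoff) next
      sr6 <- (sig / r)^6
      e <- e + 4 * eps * (sr6^2 - sr6) + kc * charge[i] * charge[j] / r
    }
  }
  e
}
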