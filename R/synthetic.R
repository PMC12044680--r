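# Synthetic trajectories and independent thermodynamic oracles: every
# analysis stage is testable against known ground truth without MD.

# minimal single-site-per-molecule system for synthetic trajectories
synthetic_system <- function(n_by_species, box, periodic = c(FALSE, TRUE, TRUE)) {
  species <- rep(names(n_by_species), unlist(n_by_species))
  n <- length(species)
  kinds <- data.frame(name = "P", mass = 1, charge = 0, epsilon = 0,
                      sigma = 1, stringsAsFactors = FALSE)
  molecular_system(kinds, rep(1L, n), seq_len(n), species,
                   pos = matrix(0, n, 3), box = box, periodic = periodic)
}

# wrap frames + system into the md_traj container the analysis expects
synthetic_traj <- function(sys, frames, dt = 1000, unwrapped = TRUE) {
  nf <- length(frames)
  structure(list(system = sys, final = sys, frames = frames,
                 records = data.frame(step = seq_len(nf) - 1,
                                      time = (seq_len(nf) - 1) * dt,
                                      T = NA, epot = NA, ekin = NA, P = NA),
                 box = matrix(rep(sys$box, each = nf), nf),
                 unwrapped = unwrapped, dt = dt, config = NULL),
            class = "md_traj")
}

#' Two-phase partitioning scenario with known ground truth
#'
#' Describes a slab system statistically: box geometry, interface
#' positions and width, per-species equilibrium phase occupancies, and
#' an optional relaxation time constant for the approach to
#' equilibrium. [make_partition_trajectory()] draws trajectories from
#' it.
#'
#' @param box length-3 box, Angstrom.
#' @param interfaces `c(x_left, x_right)` of the polymer slab.
#' @param occupancy named list; each element is `c(water =, pdms =)`
#'   equilibrium molecule counts for that species.
#' @param interface_width softness of the polymer profile edges,
#'   Angstrom.
#' @param margin placement clearance beyond the interfacial exclusion
#'   zone, Angstrom.
#' @param relax_tau relaxation time constant, frames (`Inf` = static
#'   equilibrium sampling with exact counts every frame).
#' @param start_in_water start all organic molecules in the water phase
#'   (only meaningful with finite `relax_tau`).
#' @param frames number of frames.
#' @param n_polymer pseudo-molecules drawn for the polymer density
#'   profile.
#' @return Object of class `"partition_scenario"`.
#' @export
partition_scenario <- function(box = c(128, 40, 40), interfaces = c(50, 78),
                               occupancy = list(organic = c(water = 50,
                                                            pdms = 140)),
                               interface_width = 1, margin = 3,
                               relax_tau = Inf, start_in_water = FALSE,
                               frames = 50L, n_polymer = 400L) {
  if (interfaces[1] <= 0 || interfaces[2] >= box[1] ||
      interfaces[1] >= interfaces[2])
    stop("inconsistent geometry: interfaces must lie inside the box")
  structure(list(box = box, interfaces = interfaces, occupancy = occupancy,
                 interface_width = interface_width, margin = margin,
                 relax_tau = relax_tau, start_in_water = start_in_water,
                 frames = as.integer(frames),
                 n_polymer = as.integer(n_polymer)),
            class = "partition_scenario")
}

#' Draw a synthetic trajectory from a partitioning scenario
#'
#' Each molecule of each species carries a two-state (water/polymer)
#' label. With `relax_tau = Inf` the prescribed equilibrium counts are
#' reproduced exactly in every frame; with a finite time constant the
#' labels evolve as a two-state Markov jump process whose expected
#' occupancy relaxes exponentially to equilibrium with that time
#' constant (in frames). Positions are drawn uniformly inside the
#' assigned phase, clear of the interfacial exclusion margin, so the
#' analysis chain recovers the prescribed counts exactly. A polymer
#' pseudo-species fills the slab (with soft edges of the configured
#' width) so interface location is testable too.
#'
#' @param scenario a [partition_scenario()].
#' @param seed RNG seed.
#' @return An `md_traj` (synthetic; wrapped coordinates, no dynamics).
#' @export
make_partition_trajectory <- function(scenario, seed = 1) {
  set.seed(seed)
  sc <- scenario
  xl <- sc$interfaces[1]; xr <- sc$interfaces[2]
  lx <- sc$box[1]
  pad <- sc$margin + 0.25          # strictly clear of the closed boundary
  n_by <- c(lapply(sc$occupancy, sum), list(polymer = sc$n_polymer))
  sys <- synthetic_system(n_by, sc$box)
  nf <- sc$frames

  draw_water_x <- function(k) {
    left <- stats::runif(k) < (xl - pad) / ((xl - pad) + (lx - xr - pad))
    ifelse(left, stats::runif(k, 0, xl - pad), stats::runif(k, xr + pad, lx))
  }
  draw_pdms_x <- function(k) stats::runif(k, xl + pad, xr - pad)
  draw_polymer_x <- function(k) {
    # plateau with soft (logistic) edges of the configured width
    x <- stats::runif(k, xl - 3 * sc$interface_width,
                      xr + 3 * sc$interface_width)
    keep <- stats::runif(k) < stats::plogis((x - xl) / sc$interface_width) *
      stats::plogis((xr - x) / sc$interface_width)
    x[keep]
  }

  # initial state labels per species (TRUE = polymer phase)
  labels <- lapply(sc$occupancy, function(occ) {
    n <- sum(occ)
    if (sc$start_in_water && is.finite(sc$relax_tau)) rep(FALSE, n)
    else rep(c(TRUE, FALSE), c(occ[["pdms"]], n - occ[["pdms"]]))
  })

  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    xs <- numeric(0)
    for (spn in names(sc$occupancy)) {
      occ <- sc$occupancy[[spn]]
      n <- sum(occ)
      if (is.finite(sc$relax_tau) && n > 0) {
        # two-state Markov jump: equilibrium p = occ_pdms/n, rate 1/tau
        p_eq <- occ[["pdms"]] / n
        a <- (1 - exp(-1 / sc$relax_tau))
        lab <- labels[[spn]]
        to_p <- stats::runif(n) < a * p_eq
        to_w <- stats::runif(n) < a * (1 - p_eq)
        lab <- ifelse(lab, !to_w, to_p)
        labels[[spn]] <- lab
      }
      lab <- labels[[spn]]
      x <- numeric(n)
      x[lab] <- draw_pdms_x(sum(lab))
      x[!lab] <- draw_water_x(sum(!lab))
      xs <- c(xs, x)
    }
    # polymer pseudo-molecules: rejection-sample to the requested count
    px <- numeric(0)
    while (length(px) < sc$n_polymer)
      px <- c(px, draw_polymer_x(2 * sc$n_polymer))
    xs <- c(xs, px[seq_len(sc$n_polymer)])
    frames[[f]] <- cbind(xs, stats::runif(length(xs), 0, sc$box[2]),
                         stats::runif(length(xs), 0, sc$box[3]))
  }
  synthetic_traj(sys, frames, unwrapped = FALSE)
}

#' Synthetic Brownian trajectory with prescribed diffusivities
#'
#' Independent Gaussian displacements per axis with variance
#' `2 D dt` per step; coordinates are unwrapped, so the analysis chain
#' can recover each species' D from the Einstein relation.
#'
#' @param D_cm2s diffusion coefficient(s), cm^2/s; one per species
#'   (names become species labels).
#' @param n_particles particles per species.
#' @param dt frame interval, fs.
#' @param steps number of steps (frames - 1).
#' @param box length-3 box (bookkeeping only).
#' @param seed RNG seed.
#' @return An `md_traj` with unwrapped coordinates.
#' @export
make_brownian_trajectory <- function(D_cm2s, n_particles = 100L, dt = 1000,
                                     steps = 500L, box = c(100, 100, 100),
                                     seed = 1) {
  set.seed(seed)
  if (any(D_cm2s < 0)) stop("D must be >= 0")
  if (is.null(names(D_cm2s)))
    names(D_cm2s) <- paste0("species", seq_along(D_cm2s))
  ns <- length(D_cm2s)
  ntot <- ns * n_particles
  sys <- synthetic_system(setNames(as.list(rep(n_particles, ns)),
                                   names(D_cm2s)),
                          box, periodic = c(TRUE, TRUE, TRUE))
  sig <- rep(sqrt(2 * (D_cm2s * 10) * dt), each = n_particles)  # A per step
  pos <- cbind(stats::runif(ntot, 0, box[1]), stats::runif(ntot, 0, box[2]),
               stats::runif(ntot, 0, box[3]))
  frames <- vector("list", steps + 1)
  frames[[1]] <- pos
  for (s in seq_len(steps)) {
    pos <- pos + matrix(stats::rnorm(3 * ntot), ntot, 3) * sig
    frames[[s + 1]] <- pos
  }
  synthetic_traj(sys, frames, dt = dt, unwrapped = TRUE)
}

# flat pair-parameter list for the monatomic MC/Widom kernels
toy_ffd <- function(eps_mat, sig_mat, cutoff, ljtail = 2L) {
  list(epsmat = eps_mat, sigmat = sig_mat, cutoff = cutoff,
       elec = 0L, alpha = 0.2, ljtail = ljtail, kc = 0,
       excl_pairs = matrix(integer(), 0, 2), excl_lj = numeric(),
       excl_coul = numeric(),
       bonds = matrix(integer(), 0, 2), bond_k = numeric(),
       bond_r0 = numeric(),
       angles = matrix(integer(), 0, 3), angle_k = numeric(),
       angle_th0 = numeric(),
       diheds = matrix(integer(), 0, 4), dihed_v = matrix(0, 0, 4),
       kpref = 1, walls = list())
}

#' Toy two-phase Lennard-Jones system with a tunable-affinity solute
#'
#' Two immiscible LJ fluids (A and B; identical self-interactions, a
#' strongly reduced A-B cross attraction) arranged as adjacent slabs in
#' a fully periodic box, plus dilute solute particles whose attraction
#' to phase A exceeds that to phase B by `affinity_contrast`
#' (solute-solute interactions are ideal). A scaled-down stand-in for
#' the water/PDMS/organic slab with a dialable partition coefficient.
#'
#' @param affinity_contrast ratio `eps_SA / eps_SB` (> 0; 1 = neutral).
#' @param n_per_phase solvent particles per phase.
#' @param n_solute solute particles.
#' @param L half-box edge: each phase occupies an L x L x L cube.
#' @param eps solvent LJ epsilon, kcal/mol.
#' @param sigma solvent LJ sigma, Angstrom.
#' @param sigma_solute solute LJ sigma, Angstrom (smaller solutes
#'   diffuse and insert more readily).
#' @param eps_cross_AB A-B cross epsilon (small = immiscible).
#' @param seed RNG seed for the initial lattice jitter.
#' @return List of class `"toy_two_phase"`: positions, kind index
#'   (1 = A, 2 = B, 3 = S), box, pair tables, geometry.
#' @export
make_toy_two_phase_system <- function(affinity_contrast = 2, n_per_phase = 90L,
                                      n_solute = 8L, L = 18,
                                      eps = 0.3, sigma = 3.4,
                                      sigma_solute = sigma,
                                      eps_cross_AB = 0.03, seed = 1) {
  set.seed(seed)
  eps_SB <- eps
  eps_SA <- affinity_contrast * eps_SB
  em <- matrix(c(eps, eps_cross_AB, eps_SA,
                 eps_cross_AB, eps, eps_SB,
                 eps_SA, eps_SB, 0), 3, 3)   # S-S ideal via `inert` mask
  sx <- (sigma + sigma_solute) / 2
  sm <- matrix(c(sigma, sigma, sx,
                 sigma, sigma, sx,
                 sx, sx, sigma_solute), 3, 3)
  lattice_fill <- function(n, xlo) {
    k <- ceiling(n^(1 / 3))
    s <- L / k
    g <- expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k))[seq_len(n), ]
    jit <- matrix(stats::runif(3 * n, -0.05, 0.05) * s, n, 3)
    cbind(xlo + (g$x - 0.5) * s, (g$y - 0.5) * s, (g$z - 0.5) * s) + jit
  }
  posA <- lattice_fill(n_per_phase, 0)
  posB <- lattice_fill(n_per_phase, L)
  # solutes split between the phases, near the central interface
  xs <- stats::runif(n_solute, L - 4, L + 4)
  posS <- cbind(xs, stats::runif(n_solute, 0, L), stats::runif(n_solute, 0, L))
  structure(list(pos = rbind(posA, posB, posS),
                 kind = c(rep(1L, n_per_phase), rep(2L, n_per_phase),
                          rep(3L, n_solute)),
                 box = c(2 * L, L, L), L = L,
                 eps = eps, sigma = sigma, eps_SA = eps_SA, eps_SB = eps_SB,
                 eps_cross_AB = eps_cross_AB,
                 n_per_phase = n_per_phase, n_solute = n_solute,
                 epsmat = em, sigmat = sm),
            class = "toy_two_phase")
}

#' Metropolis Monte Carlo on a toy system
#'
#' Single-particle translation moves at temperature `kT`; solvent and
#' solute particles all move, solute-solute interactions are ideal
#' (dilute limit). Seeded through R's RNG.
#'
#' @param toy a [make_toy_two_phase_system()] (or compatible list).
#' @param kT thermal energy, kcal/mol.
#' @param n_sweeps MC sweeps (one attempted move per particle each).
#' @param disp maximum displacement, Angstrom.
#' @param stride configuration-recording stride, sweeps.
#' @param cutoff pair cutoff, Angstrom.
#' @param seed RNG seed (optional).
#' @param solute_only move only the solute particles (quenched solvent
#'   medium).
#' @param jump_prob probability of a symmetric whole-box teleport move
#'   in place of a local displacement (ergodicity through a dense or
#'   frozen medium).
#' @return List: `frames` (recorded position matrices), final `pos`,
#'   `acceptance`.
#' @export
toy_mc_run <- function(toy, kT = 0.3, n_sweeps = 2000L, disp = 0.6,
                       stride = 10L, cutoff = 8.5, seed = NULL,
                       solute_only = FALSE, jump_prob = 0) {
  if (!is.null(seed)) set.seed(seed)
  fd <- toy_ffd(toy$epsmat, toy$sigmat, min(cutoff, min(toy$box) / 2))
  inert <- as.integer(toy$kind == 3L)
  movable <- if (solute_only) inert else rep(1L, nrow(toy$pos))
  cpp_mc_run(toy$pos, toy$kind - 1L, fd, toy$box, rep(1L, 3),
             movable = movable, inert = inert,
             kT = kT, disp = disp, n_sweeps = as.integer(n_sweeps),
             stride = as.integer(stride), jump_prob = jump_prob)
}

#' Counting vs Widom partition check on a quenched two-phase medium
#'
#' The package's cross-method consistency experiment. A solvent-only
#' two-phase slab is equilibrated by MC and then frozen; the solute's
#' partition coefficient in that quenched medium is estimated along two
#' fully independent routes that must agree:
#' \itemize{
#'   \item counting: dilute solutes random-walk through the frozen
#'     medium by Metropolis MC (solutes are ideal among themselves) and
#'     their phase occupancies are counted;
#'   \item insertion: Widom ghost insertions into each phase interior
#'     of the same frozen medium give the excess chemical potentials
#'     and hence log P.
#' }
#' Quenching removes the slow solvent-mixing relaxation that would
#' otherwise leave the two estimators sampling different media.
#'
#' @param toy a [make_toy_two_phase_system()].
#' @param kT thermal energy, kcal/mol.
#' @param solvent_sweeps MC sweeps used to equilibrate the medium.
#' @param count_sweeps solute-only MC sweeps for the counting estimate.
#' @param n_insertions Widom insertions per phase.
#' @param margin interfacial exclusion margin, Angstrom.
#' @param stride frame-recording stride for the counting run.
#' @param discard_frac initial fraction of counting frames discarded.
#' @param seed RNG seed (optional).
#' @return List: `log_p_count`, `se_count`, `log_p_widom`, `se_widom`,
#'   `diff`, `combined_se`, `counts` (mean A/B/excluded).
#' @export
toy_counting_vs_widom <- function(toy, kT = 0.45, solvent_sweeps = 3000L,
                                  count_sweeps = 20000L,
                                  n_insertions = 200000L, margin = 2,
                                  stride = 10L, discard_frac = 0.2,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- toy$L
  solv <- toy$kind != 3L
  fd <- toy_ffd(toy$epsmat, toy$sigmat, min(8.5, min(toy$box) / 2))
  med <- cpp_mc_run(toy$pos[solv, , drop = FALSE], toy$kind[solv] - 1L, fd,
                    toy$box, rep(1L, 3), movable = rep(1L, sum(solv)),
                    inert = rep(0L, sum(solv)), kT = kT, disp = 0.6,
                    n_sweeps = as.integer(solvent_sweeps), stride = 1000L,
                    jump_prob = 0)
  medium <- recenter_frame(med$pos, toy$kind[solv] == 1L, 2 * L, L)
  # frozen medium + mobile solutes
  frozen_toy <- toy
  frozen_toy$pos <- rbind(medium, toy$pos[!solv, , drop = FALSE])
  frozen_toy$kind <- c(toy$kind[solv], toy$kind[!solv])
  run <- toy_mc_run(frozen_toy, kT = kT, n_sweeps = count_sweeps,
                    disp = 1.0, stride = stride, solute_only = TRUE,
                    jump_prob = 0.2)
  keep <- seq(floor(length(run$frames) * discard_frac) + 1,
              length(run$frames))
  # medium is fixed: no recentring needed, count in fixed windows
  sol <- which(frozen_toy$kind == 3L)
  cnt <- t(vapply(run$frames[keep], function(p) {
    x <- p[sol, 1] %% (2 * L)
    a <- sum(x >= margin & x <= L - margin)
    b <- sum(x >= L + margin & x <= 2 * L - margin)
    c(A = a, B = b, excluded = length(sol) - a - b)
  }, c(A = 0, B = 0, excluded = 0)))
  bl <- max(2L, length(keep) %/% 12L)
  bsA <- block_sem(cnt[, "A"], bl)
  bsB <- block_sem(cnt[, "B"], bl)
  lp_count <- log10(bsA$mean / bsB$mean)
  se_count <- sqrt((bsA$sem / bsA$mean)^2 + (bsB$sem / bsB$mean)^2) / log(10)
  # Widom into the same frozen medium
  insert_phase <- function(xlo, xhi) {
    bf <- cpp_widom(list(medium), toy$kind[solv] - 1L, fd, toy$box,
                    rep(1L, 3), 2L, kT, as.integer(n_insertions), xlo, xhi)
    m <- mean(bf)
    if (m == 0) return(list(mu = Inf, se_mu = Inf))
    nb <- 20L
    pf <- colMeans(matrix(bf[seq_len((length(bf) %/% nb) * nb)], ncol = nb))
    list(mu = -kT * log(m),
         se_mu = kT * stats::sd(pf) / sqrt(nb) / m)
  }
  a <- insert_phase(margin, L - margin)
  b <- insert_phase(L + margin, 2 * L - margin)
  lp_w <- (b$mu - a$mu) / (kT * log(10))
  se_w <- sqrt(a$se_mu^2 + b$se_mu^2) / (kT * log(10))
  list(log_p_count = lp_count, se_count = se_count,
       log_p_widom = lp_w, se_widom = se_w,
       diff = lp_count - lp_w,
       combined_se = sqrt(se_count^2 + se_w^2),
       counts = colMeans(cnt))
}

# recentre a frame so the circular mean x of the A solvent sits at L/2
# (the periodic slab pattern is free to drift along x during sampling)
recenter_frame <- function(p, amask, lx, L) {
  th <- 2 * pi * (p[amask, 1] %% lx) / lx
  centre <- atan2(mean(sin(th)), mean(cos(th))) / (2 * pi) * lx
  p[, 1] <- (p[, 1] - centre + L / 2) %% lx
  p
}

#' Solute phase counts from toy-system MC frames
#'
#' Each frame is first recentred so the phase-A slab occupies
#' `[0, L]` (the periodic two-slab pattern drifts along x during
#' sampling); solutes are then classified by x into phase A
#' (`[m, L - m]`), phase B (`[L + m, 2L - m]`) or interfacial
#' (excluded).
#'
#' @param toy the toy system.
#' @param frames recorded frames from [toy_mc_run()].
#' @param margin interfacial exclusion, Angstrom.
#' @return Matrix with columns `A`, `B`, `excluded`, one row per frame.
#' @export
toy_phase_counts <- function(toy, frames, margin = 2) {
  L <- toy$L
  lx <- 2 * L
  amask <- toy$kind == 1L
  sol <- which(toy$kind == 3L)
  t(vapply(frames, function(p) {
    p <- recenter_frame(p, amask, lx, L)
    x <- p[sol, 1]
    a <- sum(x >= margin & x <= L - margin)
    b <- sum(x >= L + margin & x <= 2 * L - margin)
    c(A = a, B = b, excluded = length(sol) - a - b)
  }, c(A = 0, B = 0, excluded = 0)))
}

#' Widom test-particle insertion: excess chemical potentials and log P
#'
#' Inserts a ghost solute at uniform random positions into recorded
#' configurations of each phase and Boltzmann-averages the insertion
#' energy: `mu_ex = -kT ln <exp(-dU/kT)>`. The implied partition
#' coefficient is `log P(A/B) = (mu_B - mu_A) / (kT ln 10)`; it changes
#' sign exactly under phase swap. If every insertion overlaps, the
#' result is flagged with `se = Inf`.
#'
#' @param frames_A,frames_B lists of configuration matrices for the two
#'   phases (positions of the phase's solvent particles).
#' @param kind_A,kind_B integer kind vectors for those configurations.
#' @param epsmat,sigmat pair tables including the solute row/column.
#' @param solute_kind 1-based solute kind index into the tables.
#' @param box,periodic simulation box of the phase configurations.
#' @param kT thermal energy, kcal/mol.
#' @param n_insertions insertions per configuration.
#' @param cutoff pair cutoff, Angstrom.
#' @param seed RNG seed (optional).
#' @return Object of class `"widom_result"`: `mu_A`, `mu_B` (kcal/mol),
#'   `log_p`, `se_log_p`, insertion counts, per-phase standard errors.
#' @export
widom_log_p <- function(frames_A, frames_B, kind_A, kind_B,
                        epsmat, sigmat, solute_kind, box,
                        periodic = c(TRUE, TRUE, TRUE), kT = 0.3,
                        n_insertions = 2000L, cutoff = 8.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_insertions <= 0) stop("n_insertions must be > 0")
  fd <- toy_ffd(epsmat, sigmat, min(cutoff, min(box) / 2))
  # both phases reuse the same insertion stream, so swapping the phase
  # arguments flips log P exactly
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  rng_state <- get(".Random.seed", envir = globalenv())
  phase <- function(frames, kinds) {
    assign(".Random.seed", rng_state, envir = globalenv())
    bf <- cpp_widom(frames, kinds - 1L, fd, box, as.integer(periodic),
                    solute_kind - 1L, kT, as.integer(n_insertions),
                    0, box[1])
    m <- mean(bf)
    if (m == 0)
      return(list(mu = Inf, se_mu = Inf, n = length(bf), nonzero = 0L))
    # frames are correlated; block the per-frame insertion means
    pf <- colMeans(matrix(bf, nrow = n_insertions))
    bl <- max(1L, length(pf) %/% 10L)
    se_b <- if (length(pf) >= 2 * bl) block_sem(pf, bl)$sem
            else stats::sd(bf) / sqrt(length(bf))
    list(mu = -kT * log(m), se_mu = kT * se_b / m,
         n = length(bf), nonzero = sum(bf > 0))
  }
  a <- phase(frames_A, kind_A)
  b <- phase(frames_B, kind_B)
  lp <- (b$mu - a$mu) / (kT * log(10))
  se <- sqrt(a$se_mu^2 + b$se_mu^2) / (kT * log(10))
  structure(list(mu_A = a$mu, mu_B = b$mu, log_p = lp, se_log_p = se,
                 n_insertions = c(A = a$n, B = b$n),
                 nonzero = c(A = a$nonzero, B = b$nonzero),
                 failed = !is.finite(lp)),
            class = "widom_result")
}

#' @export
print.widom_result <- function(x, ...) {
  cat(sprintf("Widom insertion: mu_A = %.4f, mu_B = %.4f kcal/mol\n",
              x$mu_A, x$mu_B))
  cat(sprintf("  implied log P(A/B) = %.3f +- %.3f  (%d+%d insertions)\n",
              x$log_p, x$se_log_p, x$n_insertions[1], x$n_insertions[2]))
  invisible(x)
}

#' Widom log P of the toy slab by in-place phase insertion
#'
#' The sharper form of the insertion oracle for the two-phase slab:
#' runs solvent-only MC on the slab (no solutes, so both phase
#' interiors carry the slab's own equilibrium structure including any
#' interfacial densification), then Boltzmann-averages ghost-solute
#' insertions restricted to each phase interior. This is the quantity
#' the occupancy-counting log P estimates in the dilute limit.
#'
#' @param toy a [make_toy_two_phase_system()].
#' @param kT thermal energy, kcal/mol.
#' @param n_sweeps solvent MC sweeps.
#' @param stride recording stride, sweeps.
#' @param discard_frac equilibration fraction discarded.
#' @param n_insertions insertions per phase per frame.
#' @param margin interior margin excluded near each interface, Angstrom
#'   (match the counting margin).
#' @param cutoff pair cutoff, Angstrom.
#' @param seed RNG seed (optional).
#' @return A `widom_result` (`mu_A`, `mu_B`, `log_p`, `se_log_p`).
#' @export
widom_slab_log_p <- function(toy, kT = 0.3, n_sweeps = 4000L, stride = 10L,
                             discard_frac = 0.25, n_insertions = 500L,
                             margin = 2, cutoff = 8.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- toy$L
  solv <- toy$kind != 3L
  fd <- toy_ffd(toy$epsmat, toy$sigmat, min(cutoff, min(toy$box) / 2))
  run <- cpp_mc_run(toy$pos[solv, , drop = FALSE], toy$kind[solv] - 1L, fd,
                    toy$box, rep(1L, 3), movable = rep(1L, sum(solv)),
                    inert = rep(0L, sum(solv)), kT = kT, disp = 0.6,
                    n_sweeps = as.integer(n_sweeps),
                    stride = as.integer(stride), jump_prob = 0)
  keep <- seq(ceiling(discard_frac * length(run$frames)) + 1,
              length(run$frames))
  amask <- toy$kind[solv] == 1L
  frames <- lapply(run$frames[keep], recenter_frame, amask = amask,
                   lx = 2 * L, L = L)
  kinds <- toy$kind[solv]
  phase <- function(xlo, xhi) {
    bf <- cpp_widom(frames, kinds - 1L, fd, toy$box, rep(1L, 3),
                    2L, kT, as.integer(n_insertions), xlo, xhi)
    m <- mean(bf)
    if (m == 0) return(list(mu = Inf, se_mu = Inf))
    pf <- colMeans(matrix(bf, nrow = n_insertions))
    bl <- max(1L, length(pf) %/% 10L)
    se_b <- if (length(pf) >= 2 * bl) block_sem(pf, bl)$sem
            else stats::sd(bf) / sqrt(length(bf))
    list(mu = -kT * log(m), se_mu = kT * se_b / m)
  }
  a <- phase(margin, L - margin)
  b <- phase(L + margin, 2 * L - margin)
  lp <- (b$mu - a$mu) / (kT * log(10))
  structure(list(mu_A = a$mu, mu_B = b$mu, log_p = lp,
                 se_log_p = sqrt(a$se_mu^2 + b$se_mu^2) / (kT * log(10)),
                 n_insertions = c(A = length(frames) * n_insertions,
                                  B = length(frames) * n_insertions),
                 nonzero = c(A = NA, B = NA), failed = !is.finite(lp)),
            class = "widom_result")
}

#' Equilibrated single-phase configurations for Widom insertion
#'
#' Builds a pure solvent cube at the toy system's per-phase density and
#' equilibrates it by MC, returning recorded configurations.
#'
#' @param toy the toy system (provides density, eps, sigma).
#' @param phase `"A"` or `"B"` (identical solvents; kept for clarity).
#' @param n_sweeps equilibration + production sweeps.
#' @param kT thermal energy.
#' @param stride recording stride, sweeps.
#' @param discard_frac fraction of initial frames discarded.
#' @param seed RNG seed (optional).
#' @return List: `frames`, `kind`, `box`.
#' @export
toy_pure_phase <- function(toy, phase = c("A", "B"), n_sweeps = 2000L,
                           kT = 0.3, stride = 10L, discard_frac = 0.3,
                           seed = NULL) {
  phase <- match.arg(phase)
  if (!is.null(seed)) set.seed(seed)
  k <- if (phase == "A") 1L else 2L
  n <- toy$n_per_phase
  kcell <- ceiling(n^(1 / 3))
  s <- toy$L / kcell
  g <- expand.grid(x = seq_len(kcell), y = seq_len(kcell),
                   z = seq_len(kcell))[seq_len(n), ]
  pos <- cbind((g$x - 0.5) * s, (g$y - 0.5) * s, (g$z - 0.5) * s) +
    matrix(stats::runif(3 * n, -0.05, 0.05) * s, n, 3)
  fd <- toy_ffd(toy$epsmat, toy$sigmat, min(8.5, toy$L / 2))
  out <- cpp_mc_run(pos, rep(k - 1L, n), fd, rep(toy$L, 3), rep(1L, 3),
                    movable = rep(1L, n), inert = rep(0L, n),
                    kT = kT, disp = 0.6, n_sweeps = as.integer(n_sweeps),
                    stride = as.integer(stride), jump_prob = 0)
  keep <- seq(ceiling(discard_frac * length(out$frames)) + 1,
              length(out$frames))
  list(frames = out$frames[keep], kind = rep(k, n), box = rep(toy$L, 3))
}
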