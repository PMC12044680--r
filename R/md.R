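#' Integrator configuration
#'
#' Velocity-Verlet settings: 1 fs default time step, ensemble choice,
#' thermostat/barostat targets and coupling times. Temperature control
#' is a Nose-Hoover chain of length 3 by default; a Langevin thermostat
#' is available for tiny systems where chain ergodicity is poor.
#' Pressure control is weak-coupling and acts on the periodic axes
#' only.
#'
#' @param dt time step, fs.
#' @param ensemble `"NVE"`, `"NVT"` or `"NPT"`.
#' @param T_target temperature set point, K (NVT/NPT).
#' @param P_target pressure set point, atm (NPT).
#' @param tau_t,tau_p thermostat / barostat coupling times, fs.
#' @param thermostat `"nose-hoover"` or `"langevin"`.
#' @param langevin_gamma friction, 1/fs.
#' @param stride frame-recording stride, steps.
#' @param shake_tol relative SHAKE tolerance.
#' @param shake_maxit maximum SHAKE iterations.
#' @param seed RNG seed used for initial velocities / Langevin noise.
#' @return Object of class `"md_config"`.
#' @export
md_config <- function(dt = 1, ensemble = c("NVT", "NVE", "NPT"),
                      T_target = 298.15, P_target = 1,
                      tau_t = 100, tau_p = 1000,
                      thermostat = c("nose-hoover", "langevin"),
                      langevin_gamma = 0.01, stride = 10L,
                      shake_tol = 1e-8, shake_maxit = 500L, seed = NULL) {
  ensemble <- match.arg(ensemble)
  thermostat <- match.arg(thermostat)
  stopifnot(dt > 0)
  if (ensemble != "NVE" && T_target <= 0) stop("T_target must be > 0")
  structure(list(dt = dt, ensemble = ensemble, T_target = T_target,
                 P_target = P_target, tau_t = tau_t, tau_p = tau_p,
                 thermostat = thermostat, langevin_gamma = langevin_gamma,
                 stride = as.integer(stride), shake_tol = shake_tol,
                 shake_maxit = as.integer(shake_maxit), seed = seed),
            class = "md_config")
}

# degrees of freedom: 3 per mobile site, minus constraints, minus COM
# drift (only removed when momentum is conserved, i.e. no walls/frozen)
count_dof <- function(sys) {
  nm <- sum(!sys$frozen)
  dof <- 3 * nm - nrow(sys$constraints)
  if (!length(sys$walls) && !any(sys$frozen)) dof <- dof - 3
  max(dof, 1)
}

#' Draw Maxwell-Boltzmann initial velocities
#'
#' Gaussian velocities at the target temperature with the net momentum
#' of the mobile sites removed, then rescaled to hit the target exactly
#' (counting constrained degrees of freedom).
#'
#' @param sys a [molecular_system()].
#' @param T_target temperature, K.
#' @param seed RNG seed (optional).
#' @return The system with velocities set.
#' @export
initialize_velocities <- function(sys, T_target, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- site_masses(sys)
  n <- nrow(sys$pos)
  sd <- sqrt(pdms_constants$kB * T_target / (m * pdms_constants$mvsq_to_kcal))
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  mob <- !sys$frozen
  v[!mob, ] <- 0
  # remove net momentum of mobile sites
  p <- colSums(v[mob, , drop = FALSE] * m[mob])
  v[mob, ] <- sweep(v[mob, , drop = FALSE], 2, p / sum(m[mob]))
  # rescale to the target kinetic temperature
  ke2 <- sum(m[mob] * rowSums(v[mob, , drop = FALSE]^2)) *
    pdms_constants$mvsq_to_kcal
  dof <- count_dof(sys)
  v[mob, ] <- v[mob, , drop = FALSE] *
    sqrt(T_target * dof * pdms_constants$kB / ke2)
  sys$vel <- v
  sys
}

#' Relax a configuration by steepest descent
#'
#' Adaptive-step steepest descent on the potential energy, with SHAKE
#' re-projection after every move when constraints are present. Used to
#' remove packing overlaps before dynamics.
#'
#' @param sys a [molecular_system()].
#' @param ff a [forcefield()].
#' @param max_iter iteration cap.
#' @param fmax_tol convergence threshold on the largest force
#'   component, kcal/mol/A.
#' @param step0 initial displacement scale, Angstrom.
#' @return The relaxed system.
#' @export
minimize_energy <- function(sys, ff, max_iter = 200L, fmax_tol = 10,
                            step0 = 0.05) {
  e <- total_potential_energy(sys, ff)
  step <- step0
  mob <- !sys$frozen
  for (it in seq_len(max_iter)) {
    fmax <- max(abs(e$forces[mob, ]))
    if (fmax < fmax_tol) break
    cand <- sys
    cand$pos[mob, ] <- sys$pos[mob, ] + step * e$forces[mob, ] / fmax
    if (nrow(sys$constraints)) cand <- shake_project(cand, ref = sys)
    e2 <- tryCatch(total_potential_energy(cand, ff), error = function(err) NULL)
    if (!is.null(e2) && e2$energy < e$energy) {
      sys <- cand; e <- e2
      step <- min(step * 1.2, 0.5)
    } else step <- step / 2
    if (step < 1e-6) break
  }
  sys
}

#' Run molecular dynamics
#'
#' Velocity-Verlet integration of the system under the configured
#' ensemble, with SHAKE/RATTLE constraint projection for rigid water,
#' optional walls, and frame recording at the configured stride.
#' `n_steps = 0` returns a single-frame trajectory of the input state.
#'
#' @param sys a [molecular_system()].
#' @param ff a [forcefield()].
#' @param config an [md_config()].
#' @param n_steps number of steps.
#' @return Object of class `"md_traj"`: the (static) system, per-frame
#'   unwrapped positions and thermodynamic records (time fs, T K,
#'   potential/kinetic energy kcal/mol, pressure atm, box).
#' @export
run_ensemble <- function(sys, ff, config = md_config(), n_steps) {
  if (!is.null(config$seed)) set.seed(config$seed)
  fd <- ff_data(sys, ff)
  cfg <- list(dt = config$dt, n_steps = as.integer(n_steps),
              stride = config$stride,
              ensemble = match(config$ensemble, c("NVE", "NVT", "NPT")) - 1L,
              thermostat = match(config$thermostat,
                                 c("nose-hoover", "langevin")) - 1L,
              T_target = config$T_target, tau_t = config$tau_t,
              P_target = config$P_target, tau_p = config$tau_p,
              dof = count_dof(sys), shake_tol = config$shake_tol,
              shake_maxit = config$shake_maxit,
              langevin_gamma = config$langevin_gamma,
              frozen = as.integer(sys$frozen))
  out <- cpp_run_md(sys$pos, sys$vel, site_masses(sys), site_charges(sys),
                    sys$site_kind - 1L, fd, sys$box,
                    as.integer(sys$periodic),
                    sys$constraints - 1L, sys$cons_d, cfg)
  final <- sys
  final$pos <- out$pos
  final$vel <- out$vel
  final$box <- as.numeric(out$box_final)
  structure(list(system = sys, final = final,
                 frames = out$frames,
                 records = data.frame(step = out$step, time = out$time,
                                      T = out$T, epot = out$epot,
                                      ekin = out$ekin, P = out$P),
                 box = out$box, unwrapped = TRUE, dt = config$dt,
                 config = config),
            class = "md_traj")
}

#' @export
print.md_traj <- function(x, ...) {
  r <- x$records
  cat("MD trajectory:", nrow(r), "frames,",
      nrow(x$system$pos), "sites,",
      sprintf("t = %.0f..%.0f fs\n", min(r$time), max(r$time)))
  cat(sprintf("  <T> = %.1f K  <Epot> = %.2f kcal/mol\n",
              mean(r$T), mean(r$epot)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_traj`.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Project positions back onto holonomic constraints (SHAKE)
#'
#' Iterative constraint projection using the system's reference
#' positions as constraint directions; the centre of mass is unchanged
#' by the projection.
#'
#' @param sys system whose `pos` may violate the constraints.
#' @param ref reference system/positions defining the constraint
#'   gradients (defaults to `sys`).
#' @param tol relative tolerance on squared distances.
#' @param maxit maximum sweeps.
#' @return The system with constrained positions.
#' @export
shake_project <- function(sys, ref = sys, tol = 1e-8, maxit = 500L) {
  if (!nrow(sys$constraints)) return(sys)
  refpos <- if (is.matrix(ref)) ref else ref$pos
  sys$pos <- cpp_shake(sys$pos, refpos, site_masses(sys),
                       sys$constraints - 1L, sys$cons_d, tol,
                       as.integer(maxit), sys$box, as.integer(sys$periodic))
  sys
}

#' Annealing schedule
#'
#' Stepwise heating-then-cooling protocol: dwell at the high
#' temperature, then cool to the low temperature in fixed decrements,
#' dwelling at every level.
#'
#' @param T_high,T_low end points, K (`T_high >= T_low`).
#' @param step decrement, K (> 0).
#' @param dwell_steps MD steps per level.
#' @return Object of class `"anneal_schedule"` with the level sequence.
#' @export
#' @examples
#' anneal_schedule(408.15, 298.15, 10)$levels  # 12 levels
anneal_schedule <- function(T_high, T_low, step = 10, dwell_steps = 1000L) {
  stopifnot(T_high >= T_low, step > 0)
  levels <- seq(T_high, T_low, by = -step)
  if (utils::tail(levels, 1) > T_low) levels <- c(levels, T_low)
  structure(list(T_high = T_high, T_low = T_low, step = step,
                 dwell_steps = as.integer(dwell_steps), levels = levels),
            class = "anneal_schedule")
}

#' Anneal a system through a temperature schedule
#'
#' Runs the configured ensemble (NPT for bulk boxes by default) for the
#' dwell time at each level from `T_high` down to `T_low`, and reports
#' per-level mean density and potential energy, each averaged over the
#' second half of the dwell.
#'
#' @param sys a [molecular_system()].
#' @param ff a [forcefield()].
#' @param schedule an [anneal_schedule()].
#' @param config base [md_config()]; its `T_target` is overridden per
#'   level.
#' @return List: `system` (final state), `summary` data frame with
#'   columns `T_level`, `density` (g/cm^3), `epot` (kcal/mol),
#'   `box_x`,`box_y`,`box_z`.
#' @export
anneal <- function(sys, ff, schedule,
                   config = md_config(ensemble = "NPT",
                                      thermostat = "langevin",
                                      tau_p = 50)) {
  mass_g <- system_mass(sys)          # amu == g/mol
  rows <- NULL
  state <- sys
  for (Tl in schedule$levels) {
    cfg <- config
    cfg$T_target <- Tl
    state <- initialize_velocities(state, Tl)
    traj <- run_ensemble(state, ff, cfg, schedule$dwell_steps)
    state <- traj$final
    r <- traj$records
    half <- r[r$step > max(r$step) / 2, ]
    vols <- apply(traj$box[r$step > max(r$step) / 2, , drop = FALSE], 1, prod)
    dens <- mass_g * 1.66054 / vols     # amu/A^3 -> g/cm^3
    rows <- rbind(rows, data.frame(T_level = Tl, density = mean(dens),
                                   epot = mean(half$epot),
                                   box_x = state$box[1], box_y = state$box[2],
                                   box_z = state$box[3]))
  }
  list(system = state, summary = rows)
}
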