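# Trajectory analysis: density profiles, phase assignment, log P,
# solubilities, MSD/diffusion, block averaging.

#' Representative x-coordinate of a molecule
#'
#' The x-coordinate of the site nearest the molecular centre of mass
#' (not the centre of mass itself, so the coordinate always belongs to
#' a physical site). Ties break to the lowest site index.
#'
#' @param pos n x 3 site positions of one molecule.
#' @param masses site masses.
#' @return Scalar x, Angstrom.
#' @export
molecule_coordinate <- function(pos, masses = rep(1, nrow(pos))) {
  if (!nrow(pos)) stop("empty molecule")
  com <- colSums(pos * masses) / sum(masses)
  d2 <- rowSums(sweep(pos, 2, com)^2)
  pos[which.min(d2), 1]
}

# per-frame molecule x-coordinates for the molecules of one species;
# returns frames x molecules matrix
species_coordinates <- function(traj, species) {
  sys <- traj$system
  mols <- which(startsWith(sys$mol_species, species))
  if (!length(mols)) stop("no molecules of species '", species, "'")
  m <- site_masses(sys)
  idx <- split(seq_len(nrow(sys$pos)), sys$site_mol)[as.character(mols)]
  out <- matrix(NA_real_, n_frames(traj), length(mols))
  for (f in seq_len(n_frames(traj))) {
    p <- traj$frames[[f]]
    out[f, ] <- vapply(idx, function(i)
      molecule_coordinate(p[i, , drop = FALSE], m[i]), 0)
  }
  out
}

# wrap x-coordinates into [0, Lx) when x is periodic
wrap_x <- function(x, traj) {
  if (traj$system$periodic[1]) x %% traj$system$box[1] else x
}

#' Per-species number density profile along x
#'
#' Histograms the molecule coordinates (site nearest the centre of
#' mass) into half-open bins `[lo, hi)` of width `bin_width` anchored
#' at the box lower edge, averaged over frames. Per frame the bin
#' counts sum exactly to the number of molecules of the species.
#'
#' @param traj an `md_traj`.
#' @param species species label (prefix match, so `"pdms"` covers both
#'   oligomers).
#' @param bin_width bin size, Angstrom (default 1.5).
#' @return Object of class `"density_profile"`: bin edges/centres, mean
#'   counts, per-frame count matrix.
#' @export
density_profile <- function(traj, species, bin_width = 1.5) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  lx <- traj$system$box[1]
  edges <- seq(0, lx + bin_width, by = bin_width)
  xs <- wrap_x(species_coordinates(traj, species), traj)
  nb <- length(edges) - 1
  counts <- t(apply(xs, 1, function(x)
    tabulate(findInterval(x, edges, left.open = FALSE), nbins = nb)))
  if (nrow(xs) == 1) counts <- matrix(counts, 1)
  structure(list(species = species, bin_width = bin_width, edges = edges,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 mean_counts = colMeans(counts), counts = counts),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat("Density profile of '", x$species, "': ", length(x$centers),
      " bins of ", x$bin_width, " A, ", nrow(x$counts), " frames\n", sep = "")
  invisible(x)
}

#' @export
plot.density_profile <- function(x, ...) {
  plot(x$centers, x$mean_counts, type = "l", xlab = "x (A)",
       ylab = "mean molecules per bin",
       main = paste("Density profile:", x$species), ...)
  invisible(x)
}

#' Locate the polymer-phase interfaces from a density profile
#'
#' Default method: the plateau is the mean density over bins exceeding
#' half the profile maximum; the interfaces are the outermost positions
#' where the profile crosses 50% of that plateau (linear interpolation
#' between bin centres). Nominal positions can be supplied instead via
#' `nominal`.
#'
#' @param profile a [density_profile()] of the polymer species.
#' @param frac crossing fraction of the plateau (default 0.5).
#' @param nominal optional `c(x_left, x_right)` returned as-is.
#' @return Numeric `c(x_left, x_right)`, Angstrom.
#' @export
locate_interfaces <- function(profile, frac = 0.5, nominal = NULL) {
  if (!is.null(nominal)) return(nominal)
  y <- profile$mean_counts
  x <- profile$centers
  if (all(y == 0)) stop("no plateau detected: profile is identically zero")
  plateau_bins <- y > max(y) / 2
  if (!any(plateau_bins)) stop("no plateau detected")
  plateau <- mean(y[plateau_bins])
  thr <- frac * plateau
  above <- which(y >= thr)
  il <- min(above); ir <- max(above)
  cross <- function(i0, i1) {
    # interpolate the threshold crossing between bins i0 (below) and i1
    if (i0 < 1 || i0 > length(y) || y[i1] == y[i0]) return(x[i1])
    x[i0] + (thr - y[i0]) / (y[i1] - y[i0]) * (x[i1] - x[i0])
  }
  c(cross(il - 1, il), cross(ir + 1, ir))
}

#' Assign molecules to phases and count them
#'
#' Per frame, every molecule of the species is classified by its
#' representative coordinate x as polymer phase
#' (`x_left + margin <= x <= x_right - margin`; boundaries closed on
#' the polymer side), water phase (`x < x_left - margin` or
#' `x > x_right + margin`), or excluded interfacial
#' (within `margin` of either interface). Counts are averaged over
#' frames; block averaging gives their standard errors.
#'
#' @param traj an `md_traj`.
#' @param species species to classify.
#' @param interfaces `c(x_left, x_right)` from [locate_interfaces()] or
#'   nominal geometry.
#' @param margin interfacial exclusion margin, Angstrom (default 3).
#' @param block_length frames per block for uncertainty estimates.
#' @return Object of class `"phase_partition"`: mean counts, per-frame
#'   count matrix, SEMs.
#' @export
partition_counts <- function(traj, species, interfaces, margin = 3,
                             block_length = NULL) {
  xl <- interfaces[1]; xr <- interfaces[2]
  lx <- traj$system$box[1]
  if (xl < 0 || xr > lx || xl >= xr) stop("interfaces must lie inside the box")
  if (margin >= (xr - xl) / 2) stop("margin must be below half the slab width")
  xs <- wrap_x(species_coordinates(traj, species), traj)
  classify <- function(x) {
    inner <- x >= xl + margin & x <= xr - margin
    outer <- x < xl - margin | x > xr + margin
    c(pdms = sum(inner), water = sum(outer),
      excluded = sum(!inner & !outer))
  }
  per_frame <- t(apply(xs, 1, classify))
  if (nrow(xs) == 1) per_frame <- matrix(per_frame, 1,
                                         dimnames = list(NULL, c("pdms", "water", "excluded")))
  means <- colMeans(per_frame)
  nf <- nrow(per_frame)
  if (is.null(block_length)) block_length <- max(1L, nf %/% 10L)
  sems <- vapply(colnames(per_frame), function(cn) {
    if (nf >= 2 * block_length && block_length >= 1)
      block_sem(per_frame[, cn], block_length)$sem
    else NA_real_
  }, 0)
  structure(list(species = species, interfaces = interfaces, margin = margin,
                 counts = means, sem = sems, per_frame = per_frame,
                 n_total = ncol(xs)),
            class = "phase_partition")
}

#' @export
print.phase_partition <- function(x, ...) {
  cat("Phase partition of '", x$species, "' (", x$n_total,
      " molecules):\n", sep = "")
  for (p in names(x$counts))
    cat(sprintf("  %-9s %8.2f +- %s\n", p, x$counts[p],
                ifelse(is.na(x$sem[p]), "NA", sprintf("%.2f", x$sem[p]))))
  invisible(x)
}

#' PDMS/water partition coefficient from phase counts and volumes
#'
#' `log P = log10[(count_pdms / vol_pdms) / (count_water / vol_water)]`,
#' the base-10 log of the concentration ratio. A zero count in either
#' phase yields `NA` with attribute `undefined = TRUE` (no error).
#'
#' @param count_pdms,count_water mean molecule counts per phase.
#' @param vol_pdms,vol_water phase volumes, cubic Angstrom (> 0).
#' @return Scalar log P (dimensionless).
#' @export
#' @examples
#' log_p(140, 28 * 40 * 40, 50, 2 * 48 * 40 * 40)  # ~0.98
log_p <- function(count_pdms, vol_pdms, count_water, vol_water) {
  if (vol_pdms <= 0 || vol_water <= 0) stop("phase volumes must be > 0")
  if (count_pdms <= 0 || count_water <= 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  log10((count_pdms / vol_pdms) / (count_water / vol_water))
}

#' First-order uncertainty of log P from count standard errors
#'
#' Propagates independent standard errors of the two phase counts:
#' `se(logP) = sqrt((se_p/n_p)^2 + (se_w/n_w)^2) / ln(10)`.
#'
#' @param count_pdms,count_water mean counts.
#' @param sem_pdms,sem_water their standard errors.
#' @return Standard error of log P.
#' @export
log_p_sem <- function(count_pdms, sem_pdms, count_water, sem_water) {
  sqrt((sem_pdms / count_pdms)^2 + (sem_water / count_water)^2) / log(10)
}

#' Molar solubility from a molecule count and a phase volume
#'
#' `count / (N_A * V)` with V in litres: the concentration, mol/L, of
#' `count` molecules dissolved in `volume` cubic Angstrom.
#'
#' @param count molecule count.
#' @param volume phase volume, cubic Angstrom (> 0).
#' @return Concentration, mol/L.
#' @export
#' @examples
#' molar_solubility(140, 28 * 40 * 40)  # 5.19 mol/L
molar_solubility <- function(count, volume) {
  if (volume <= 0) stop("volume must be > 0")
  count / (pdms_constants$avogadro * volume * pdms_constants$A3_to_L)
}

#' Mean squared displacement with multiple time origins
#'
#' MSD of the molecular centres of mass of one species, averaged over
#' molecules and over time origins spaced `origin_stride` frames apart.
#' Requires unwrapped coordinates.
#'
#' @param traj an `md_traj` with `unwrapped = TRUE`.
#' @param species species label (default: all molecules).
#' @param origin_stride spacing of time origins, frames.
#' @param max_lag maximum lag, frames (default: half the trajectory).
#' @return data frame `time` (fs), `msd` (A^2); `msd[time == 0]` is 0.
#' @export
msd <- function(traj, species = NULL, origin_stride = 1L, max_lag = NULL) {
  if (!isTRUE(traj$unwrapped))
    stop("MSD requires unwrapped coordinates (image flags not available)")
  sys <- traj$system
  mols <- if (is.null(species)) seq_along(sys$mol_species)
          else which(startsWith(sys$mol_species, species))
  if (!length(mols)) stop("no molecules of species '", species, "'")
  m <- site_masses(sys)
  idx <- split(seq_len(nrow(sys$pos)), sys$site_mol)[as.character(mols)]
  nf <- n_frames(traj)
  # molecule COM per frame: nf x nmol x 3
  com <- array(0, c(nf, length(mols), 3))
  for (f in seq_len(nf)) {
    p <- traj$frames[[f]]
    com[f, , ] <- t(vapply(idx, function(i)
      colSums(p[i, , drop = FALSE] * m[i]) / sum(m[i]), numeric(3)))
  }
  if (is.null(max_lag)) max_lag <- (nf - 1) %/% 2
  max_lag <- min(max_lag, nf - 1)
  origins <- seq(1, nf - 1, by = origin_stride)
  lags <- 0:max_lag
  out <- vapply(lags, function(L) {
    o <- origins[origins + L <= nf]
    if (!length(o)) return(NA_real_)
    d <- com[o + L, , , drop = FALSE] - com[o, , , drop = FALSE]
    mean(apply(d, c(1, 2), function(v) sum(v^2)))
  }, 0)
  dtf <- if (nf > 1) traj$records$time[2] - traj$records$time[1] else traj$dt
  data.frame(time = lags * dtf, msd = out)
}

#' Diffusion coefficient from an MSD series (Einstein relation)
#'
#' Least-squares linear fit of MSD vs time over the fit window; the
#' diffusion coefficient is `D = slope / (2 n)` with `n` the spatial
#' dimension, converted to cm^2/s (1 A^2/fs = 0.1 cm^2/s).
#'
#' @param msd_df data frame from [msd()] (`time` fs, `msd` A^2).
#' @param n dimensionality (default 3).
#' @param fit_window `c(t_min, t_max)` in fs (default: 10%..50% of the
#'   series, skipping the ballistic/short-time part).
#' @return Object of class `"transport_estimate"`: `D` (cm^2/s),
#'   `slope` (A^2/fs), `se_D`, the window and the series.
#' @export
diffusion_coefficient <- function(msd_df, n = 3, fit_window = NULL) {
  tmax <- max(msd_df$time)
  if (is.null(fit_window)) fit_window <- c(0.1, 0.5) * tmax
  sel <- msd_df$time >= fit_window[1] & msd_df$time <= fit_window[2] &
    !is.na(msd_df$msd)
  if (sum(sel) < 3) stop("fit window holds fewer than 3 points")
  fit <- stats::lm(msd ~ time, data = msd_df[sel, ])
  slope <- stats::coef(fit)[["time"]]
  # exact synthetic series produce zero-residual fits; the warning from
  # summary() is uninformative there
  se <- suppressWarnings(summary(fit)$coefficients["time", "Std. Error"])
  structure(list(D = slope / (2 * n) * 0.1, slope = slope,
                 se_D = se / (2 * n) * 0.1, n = n,
                 fit_window = fit_window, msd = msd_df),
            class = "transport_estimate")
}

#' @export
print.transport_estimate <- function(x, ...) {
  cat(sprintf("D = %.4g +- %.2g cm^2/s (n = %d, window %.0f..%.0f fs)\n",
              x$D, x$se_D, x$n, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' Block-average standard error of a correlated series
#'
#' Splits the series into consecutive blocks of `block_length`,
#' computes block means, and reports their standard error
#' `sd(block means)/sqrt(n_blocks)`. The grand mean is the mean of the
#' full series regardless of blocking.
#'
#' @param series numeric vector.
#' @param block_length samples per block (must allow >= 2 blocks).
#' @return List of class `"block_average"`: `mean`, `sem`,
#'   `block_means`, `block_length`, `n_blocks`.
#' @export
block_sem <- function(series, block_length) {
  nb <- length(series) %/% block_length
  if (nb < 2) stop("need at least 2 complete blocks")
  use <- series[seq_len(nb * block_length)]
  bm <- colMeans(matrix(use, nrow = block_length))
  structure(list(mean = mean(series), sem = stats::sd(bm) / sqrt(nb),
                 block_means = bm, block_length = block_length,
                 n_blocks = nb),
            class = "block_average")
}

#' Running log P and plateau detection
#'
#' Evaluates log P from cumulative mean phase counts at every `stride`
#' frames; the estimate is declared converged when the magnitude of the
#' least-squares slope of the last 20% of the series, times the span of
#' that window, is below `tol` (i.e. the running value moves by less
#' than `tol` log units across the window).
#'
#' @param traj an `md_traj`.
#' @param species organic species.
#' @param interfaces `c(x_left, x_right)`.
#' @param vol_pdms,vol_water phase volumes, cubic Angstrom.
#' @param stride evaluation stride, frames.
#' @param margin exclusion margin, Angstrom.
#' @param tol plateau threshold, log10 units (default 0.05).
#' @return List: data frame `series` (`time`, `logp`), `plateau`
#'   (logical), `final` (last running value).
#' @export
logp_convergence <- function(traj, species, interfaces, vol_pdms, vol_water,
                             stride = 1L, margin = 3, tol = 0.05) {
  xs <- wrap_x(species_coordinates(traj, species), traj)
  xl <- interfaces[1]; xr <- interfaces[2]
  nf <- nrow(xs)
  evals <- seq(stride, nf, by = stride)
  if (length(evals) < 10) stop("need at least 10 strided evaluations")
  np_c <- cumsum(rowSums(xs >= xl + margin & xs <= xr - margin))
  nw_c <- cumsum(rowSums(xs < xl - margin | xs > xr + margin))
  lp <- vapply(evals, function(f)
    log_p(np_c[f] / f, vol_pdms, nw_c[f] / f, vol_water), 0)
  times <- traj$records$time[evals]
  tail_n <- max(3L, ceiling(0.2 * length(evals)))
  ti <- seq(length(evals) - tail_n + 1, length(evals))
  ok <- is.finite(lp[ti])
  plateau <- FALSE
  if (sum(ok) >= 3) {
    fit <- stats::lm(y ~ x, data = data.frame(x = times[ti][ok],
                                              y = lp[ti][ok]))
    drift <- abs(stats::coef(fit)[["x"]]) * diff(range(times[ti][ok]))
    plateau <- drift < tol
  }
  list(series = data.frame(time = times, logp = lp),
       plateau = plateau, final = lp[length(lp)])
}
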