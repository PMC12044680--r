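#' Molecular system container
#'
#' Holds topology (sites -> molecules, bonds, angles, dihedrals,
#' holonomic constraints), per-site kinds, coordinates/velocities and
#' the orthorhombic box with per-axis periodicity, plus optional
#' repulsive walls at the x boundaries.
#'
#' Positions are in Angstrom and are kept *unwrapped* during dynamics
#' (periodic images are handled inside the force kernels), so mean
#' squared displacements can be computed directly.
#'
#' @param kinds data frame with columns `name`, `mass`, `charge`,
#'   `epsilon`, `sigma` (one row per site kind used).
#' @param site_kind integer index into `kinds` for every site.
#' @param site_mol integer molecule id for every site.
#' @param mol_species character species label per molecule
#'   (e.g. `"water"`, `"pdms1"`, `"phenol"`, `"wall"`).
#' @param pos N x 3 coordinate matrix, Angstrom.
#' @param box numeric length-3 box edge lengths, Angstrom.
#' @param periodic logical length-3 per-axis periodicity.
#' @param vel N x 3 velocities, Angstrom/fs (defaults to zero).
#' @param bonds integer matrix (i, j) with parallel vectors `bond_k`,
#'   `bond_r0`; indices are 1-based sites.
#' @param angles,dihedrals analogous; `angle_th0` in degrees,
#'   `dihed_v` a D x 4 matrix of OPLS coefficients.
#' @param bond_k,bond_r0,angle_k,angle_th0,dihed_v bonded parameters.
#' @param constraints integer matrix (i, j) of rigid distances `cons_d`.
#' @param cons_d constraint target distances, Angstrom.
#' @param walls list of wall definitions from [wall_def()].
#' @param frozen logical per-site; frozen sites exert forces but do not
#'   move (wall atoms).
#' @return Object of class `"molsys"`.
#' @export
molecular_system <- function(kinds, site_kind, site_mol, mol_species,
                             pos, box, periodic = c(TRUE, TRUE, TRUE),
                             vel = NULL,
                             bonds = NULL, bond_k = NULL, bond_r0 = NULL,
                             angles = NULL, angle_k = NULL, angle_th0 = NULL,
                             dihedrals = NULL, dihed_v = NULL,
                             constraints = NULL, cons_d = NULL,
                             walls = list(), frozen = NULL) {
  n <- nrow(pos)
  stopifnot(length(site_kind) == n, length(site_mol) == n,
            max(site_mol) == length(mol_species), length(box) == 3)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  empty2 <- matrix(integer(), 0, 2)
  if (is.null(bonds)) { bonds <- empty2; bond_k <- numeric(); bond_r0 <- numeric() }
  if (is.null(angles)) { angles <- matrix(integer(), 0, 3); angle_k <- numeric(); angle_th0 <- numeric() }
  if (is.null(dihedrals)) { dihedrals <- matrix(integer(), 0, 4); dihed_v <- matrix(0, 0, 4) }
  if (is.null(constraints)) { constraints <- empty2; cons_d <- numeric() }
  if (is.null(frozen)) frozen <- rep(FALSE, n)
  structure(list(kinds = kinds, site_kind = as.integer(site_kind),
                 site_mol = as.integer(site_mol), mol_species = mol_species,
                 pos = pos, vel = vel, box = as.numeric(box),
                 periodic = as.logical(periodic),
                 bonds = bonds, bond_k = bond_k, bond_r0 = bond_r0,
                 angles = angles, angle_k = angle_k, angle_th0 = angle_th0,
                 dihedrals = dihedrals, dihed_v = dihed_v,
                 constraints = constraints, cons_d = cons_d,
                 walls = walls, frozen = frozen),
            class = "molsys")
}

#' @export
print.molsys <- function(x, ...) {
  cat("Molecular system:", nrow(x$pos), "sites,",
      length(x$mol_species), "molecules\n")
  tab <- table(x$mol_species)
  cat("  species:", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
  cat(sprintf("  box %.2f x %.2f x %.2f A, periodic (%s)\n",
              x$box[1], x$box[2], x$box[3],
              paste(ifelse(x$periodic, "p", "f"), collapse = ",")))
  cat("  bonds:", nrow(x$bonds), " angles:", nrow(x$angles),
      " dihedrals:", nrow(x$dihedrals), " constraints:", nrow(x$constraints),
      " walls:", length(x$walls), "\n")
  invisible(x)
}

#' Define a repulsive wall at an x boundary
#'
#' Walls are planar, act along x only, and interact through a truncated,
#' purely repulsive (WCA) Lennard-Jones potential with the sites of the
#' listed species; all other species pass freely. A wall with
#' `species = "pdms"` matches every species whose label starts with
#' `"pdms"`.
#'
#' @param x0 wall plane position, Angstrom.
#' @param side `+1` for a wall at the low-x boundary (pushes toward +x),
#'   `-1` for the high-x boundary.
#' @param epsilon,sigma repulsive LJ parameters (kcal/mol, Angstrom).
#' @param species character vector of species prefixes the wall acts on.
#' @return A list describing the wall.
#' @export
wall_def <- function(x0, side, epsilon = 0.5, sigma = 3.0, species = "pdms") {
  stopifnot(side %in% c(-1, 1))
  list(x0 = x0, side = as.integer(side), epsilon = epsilon, sigma = sigma,
       species = species)
}

#' Per-site masses and charges
#'
#' @param sys a [molecular_system()].
#' @return Numeric vector, one value per site.
#' @export
site_masses <- function(sys) sys$kinds$mass[sys$site_kind]

#' @rdname site_masses
#' @export
site_charges <- function(sys) sys$kinds$charge[sys$site_kind]

#' Total mass of a system, amu
#' @param sys a [molecular_system()].
#' @export
system_mass <- function(sys) sum(site_masses(sys))

# 1-2/1-3/1-4 exclusion pairs from the bond + constraint graph
build_exclusions <- function(sys, scale14) {
  edges <- rbind(sys$bonds, sys$constraints)
  n <- nrow(sys$pos)
  if (!nrow(edges))
    return(list(pairs = matrix(integer(), 0, 2), lj = numeric(), coul = numeric()))
  adj <- vector("list", n)
  for (b in seq_len(nrow(edges))) {
    i <- edges[b, 1]; j <- edges[b, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  h <- new.env(hash = TRUE, size = 4L * nrow(edges))
  add <- function(i, j, d) {
    if (i == j) return()
    key <- paste0(min(i, j), "_", max(i, j))
    old <- h[[key]]
    if (is.null(old) || d < old) h[[key]] <- d
  }
  for (i in seq_len(n)) {
    n1 <- adj[[i]]
    for (j in n1) if (j > i) add(i, j, 2L)
    for (j in n1) {
      n2 <- adj[[j]]
      for (k in n2) if (k != i) {
        add(i, k, 3L)
        for (l in adj[[k]]) if (l != j && l != i) add(i, l, 4L)
      }
    }
  }
  keys <- ls(h)
  ij <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  pairs <- cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))
  d <- vapply(keys, function(k) h[[k]], 0L, USE.NAMES = FALSE)
  lj <- ifelse(d <= 3L, 0, scale14)
  list(pairs = pairs, lj = lj, coul = lj)
}

# Pack a system + force field into the flat list the C++ kernels take.
# Pair matrices are built over the kinds present; wall-atom kinds are
# restricted to the species their wall flag names.
ff_data <- function(sys, ff, wall_only_species = "pdms") {
  kn <- sys$kinds$name
  K <- length(kn)
  epsmat <- matrix(0, K, K)
  sigmat <- matrix(1, K, K)
  for (i in seq_len(K))
    for (j in i:K) {
      p <- mix_pair_params(kn[i], kn[j], ff)
      epsmat[i, j] <- epsmat[j, i] <- p[["epsilon"]]
      sigmat[i, j] <- sigmat[j, i] <- p[["sigma"]]
    }
  # frozen wall atoms repel only the flagged species
  if ("WALL" %in% kn) {
    wi <- match("WALL", kn)
    species_of_kind_ok <- function(j) {
      # does kind j appear in any molecule of a wall-flagged species?
      sp <- unique(sys$mol_species[sys$site_mol[sys$site_kind == j]])
      any(vapply(wall_only_species, function(w) any(startsWith(sp, w)), TRUE))
    }
    for (j in seq_len(K)) {
      if (j == wi) { epsmat[wi, wi] <- 0; next }
      if (!species_of_kind_ok(j)) { epsmat[wi, j] <- epsmat[j, wi] <- 0 }
    }
  }
  ex <- build_exclusions(sys, ff$scale14)
  per_l <- sys$box[sys$periodic]
  cutoff <- ff$cutoff
  if (length(per_l)) cutoff <- min(cutoff, min(per_l) / 2)
  elec <- match(ff$electrostatics,
                c("direct", "damped-shifted-force", "reaction-field")) - 1L
  ljtail <- match(ff$lj_tail, c("none", "shift", "force-shift")) - 1L
  walls <- lapply(sys$walls, function(w) {
    msk <- vapply(sys$mol_species[sys$site_mol], function(sp)
      any(startsWith(sp, w$species)), TRUE)
    list(x0 = w$x0, side = w$side, epsilon = w$epsilon, sigma = w$sigma,
         mask = as.integer(msk & !sys$frozen))
  })
  list(epsmat = epsmat, sigmat = sigmat, cutoff = cutoff,
       elec = elec, alpha = ff$dsf_alpha, ljtail = ljtail,
       kc = ff$coulomb_constant,
       excl_pairs = ex$pairs - 1L, excl_lj = ex$lj, excl_coul = ex$coul,
       bonds = sys$bonds - 1L, bond_k = sys$bond_k, bond_r0 = sys$bond_r0,
       angles = sys$angles - 1L, angle_k = sys$angle_k,
       angle_th0 = sys$angle_th0 * pi / 180,
       diheds = sys$dihedrals - 1L, dihed_v = sys$dihed_v,
       kpref = if (ff$bonded$half_k) 0.5 else 1.0,
       walls = walls)
}

#' Total potential energy of a configuration
#'
#' Sum of bonded (harmonic bonds/angles, cosine-series dihedrals) and
#' nonbonded (12-6 LJ plus short-range Coulomb) energies, with
#' 1-2/1-3 exclusions and scaled 1-4 interactions, periodic minimum
#' image on the periodic axes, and any wall contributions.
#'
#' @param sys a [molecular_system()].
#' @param ff a [forcefield()].
#' @return A list: `energy` (kcal/mol), named `breakdown`, N x 3
#'   `forces` (kcal/mol/A), and scalar `virial`.
#' @export
total_potential_energy <- function(sys, ff) {
  fd <- ff_data(sys, ff)
  cpp_energy_forces(sys$pos, site_charges(sys), sys$site_kind - 1L, fd,
                    sys$box, as.integer(sys$periodic))
}

#' Analytic forces on every site
#'
#' Negative gradient of [total_potential_energy()].
#'
#' @inheritParams total_potential_energy
#' @return N x 3 matrix of forces, kcal/mol/A.
#' @export
forces <- function(sys, ff) total_potential_energy(sys, ff)$forces

#' Repulsive wall force on a single site
#'
#' WCA (truncated, shifted, purely repulsive 12-6) force exerted by a
#' planar x-wall on one site. Zero beyond the interaction range
#' `2^(1/6) sigma` and zero for species the wall is not flagged against.
#'
#' @param site_position length-3 position, Angstrom.
#' @param wall a [wall_def()].
#' @param species species label of the site's molecule.
#' @return Length-3 force vector, kcal/mol/A.
#' @export
wall_force <- function(site_position, wall, species = "pdms") {
  f <- c(0, 0, 0)
  if (!any(startsWith(species, wall$species))) return(f)
  d <- (site_position[1] - wall$x0) * wall$side
  wc <- 2^(1 / 6) * wall$sigma
  if (d <= 0 || d >= wc) return(f)
  sr6 <- (wall$sigma / d)^6
  f[1] <- 24 * wall$epsilon * (2 * sr6^2 - sr6) / d * wall$side
  f
}
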