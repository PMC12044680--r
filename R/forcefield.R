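#' Define an interaction-site kind
#'
#' A site kind is one united-atom or all-atom interaction centre: a name,
#' a mass, a fixed partial charge and 12-6 Lennard-Jones parameters.
#' Hydrogens may carry `epsilon = 0` (LJ-inactive); every LJ-active site
#' must have `sigma > 0`.
#'
#' @param name character label, e.g. `"Si"`, `"CH3"`, `"OW"`.
#' @param mass atomic mass, amu; must be positive.
#' @param charge partial charge, units of the elementary charge.
#' @param epsilon LJ well depth, kcal/mol; non-negative.
#' @param sigma LJ diameter, Angstrom.
#' @return A list of class `"site_kind"`.
#' @export
#' @examples
#' site_kind("CH3", mass = 15.0345, charge = 0, epsilon = 0.1944, sigma = 3.86)
site_kind <- function(name, mass, charge = 0, epsilon = 0, sigma = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(mass) || mass <= 0) stop("site kind '", name, "': mass must be > 0")
  if (epsilon < 0) stop("site kind '", name, "': epsilon must be >= 0")
  if (epsilon > 0 && sigma <= 0)
    stop("site kind '", name, "': sigma must be > 0 for LJ-active sites")
  structure(list(name = name, mass = mass, charge = charge,
                 epsilon = epsilon, sigma = sigma),
            class = "site_kind")
}

#' Pair-interaction table with mixing rules
#'
#' Cross interactions default to Lorentz-Berthelot mixing (geometric mean
#' of epsilon, arithmetic mean of sigma), optionally scaled by a
#' dimensionless cross-term factor, and may be overridden by explicit
#' tabulated pairs (which are used verbatim, taking precedence over
#' mixing).
#'
#' @param explicit_pairs data frame with columns `kindA`, `kindB`,
#'   `epsilon`, `sigma`; symmetric under kind swap (stored once).
#' @param cross_scale data frame with columns `kindA`, `kindB`, `scale`;
#'   multiplies the geometric-mean epsilon for that pair. All factors
#'   must be positive.
#' @return Object of class `"pair_table"`.
#' @export
pair_table <- function(explicit_pairs = NULL, cross_scale = NULL) {
  if (is.null(explicit_pairs))
    explicit_pairs <- data.frame(kindA = character(), kindB = character(),
                                 epsilon = numeric(), sigma = numeric(),
                                 stringsAsFactors = FALSE)
  if (is.null(cross_scale))
    cross_scale <- data.frame(kindA = character(), kindB = character(),
                              scale = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("kindA", "kindB", "epsilon", "sigma") %in% names(explicit_pairs)),
            all(c("kindA", "kindB", "scale") %in% names(cross_scale)))
  if (any(cross_scale$scale <= 0)) stop("cross_scale factors must be > 0")
  structure(list(explicit_pairs = explicit_pairs, cross_scale = cross_scale),
            class = "pair_table")
}

.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Bonded-interaction parameter set
#'
#' Harmonic bonds and angles plus a cosine dihedral series (OPLS form).
#' The harmonic convention is E = K (delta)^2 by default (the engine
#' convention of large MD codes in real units); set
#' `half_k = TRUE` for the E = (1/2) K (delta)^2 convention.
#'
#' @param bonds data frame: `type`, `k` (kcal/mol/A^2), `r0` (A).
#' @param angles data frame: `type`, `k` (kcal/mol/rad^2), `theta0` (degrees).
#' @param dihedrals data frame: `type`, `v1`..`v4` (kcal/mol), OPLS series
#'   E = 1/2[v1(1+cos phi) + v2(1-cos 2phi) + v3(1+cos 3phi) + v4(1-cos 4phi)].
#' @param half_k logical; use the 1/2 K convention for bonds and angles.
#' @return Object of class `"bonded_terms"`.
#' @export
bonded_terms <- function(bonds = NULL, angles = NULL, dihedrals = NULL,
                         half_k = FALSE) {
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
  if (is.null(bonds)) bonds <- empty(type = character(), k = numeric(), r0 = numeric())
  if (is.null(angles)) angles <- empty(type = character(), k = numeric(), theta0 = numeric())
  if (is.null(dihedrals)) dihedrals <- empty(type = character(), v1 = numeric(),
                                             v2 = numeric(), v3 = numeric(), v4 = numeric())
  if (any(bonds$r0 <= 0)) stop("bond r0 must be > 0")
  if (any(angles$theta0 <= 0 | angles$theta0 > 180))
    stop("angle theta0 must lie in (0, 180] degrees")
  structure(list(bonds = bonds, angles = angles, dihedrals = dihedrals,
                 half_k = isTRUE(half_k)),
            class = "bonded_terms")
}

#' Assemble a force-field specification
#'
#' Bundles site kinds, the pair table, bonded terms and the nonbonded
#' global settings (cutoff, electrostatics method, 1-4 scaling) into a
#' single validated object.
#'
#' @param site_kinds list of [site_kind()] objects.
#' @param pairs a [pair_table()].
#' @param bonded a [bonded_terms()].
#' @param cutoff nonbonded cutoff, Angstrom (default 12).
#' @param electrostatics one of `"damped-shifted-force"`,
#'   `"reaction-field"`, `"direct"`.
#' @param dsf_alpha damping parameter for the damped-shifted-force
#'   method, 1/Angstrom.
#' @param scale14 scaling of 1-4 intramolecular nonbonded interactions
#'   (default 0.5, the OPLS convention).
#' @param lj_tail cutoff handling for dynamics: `"force-shift"`
#'   (default; energy and force continuous at the cutoff), `"shift"`
#'   (energy shifted) or `"none"`.
#' @return Object of class `"forcefield"`.
#' @export
forcefield <- function(site_kinds, pairs = pair_table(), bonded = bonded_terms(),
                       cutoff = 12, electrostatics = c("damped-shifted-force",
                                                       "reaction-field", "direct"),
                       dsf_alpha = 0.2, scale14 = 0.5,
                       lj_tail = c("force-shift", "shift", "none")) {
  electrostatics <- match.arg(electrostatics)
  lj_tail <- match.arg(lj_tail)
  stopifnot(length(site_kinds) > 0)
  names(site_kinds) <- vapply(site_kinds, `[[`, "", "name")
  sig <- vapply(site_kinds, `[[`, 0, "sigma")
  if (cutoff <= max(sig)) stop("cutoff must exceed the largest sigma in the table")
  structure(list(site_kinds = site_kinds, pairs = pairs, bonded = bonded,
                 cutoff = cutoff, electrostatics = electrostatics,
                 dsf_alpha = dsf_alpha, scale14 = scale14, lj_tail = lj_tail,
                 coulomb_constant = pdms_constants$coulomb),
            class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat("Force field:", length(x$site_kinds), "site kinds,",
      nrow(x$pairs$explicit_pairs), "explicit pairs,",
      nrow(x$pairs$cross_scale), "cross-scale entries\n")
  cat("  cutoff", x$cutoff, "A; electrostatics:", x$electrostatics,
      "; 1-4 scale", x$scale14, "; LJ tail:", x$lj_tail, "\n")
  invisible(x)
}

#' Mix Lennard-Jones parameters for a pair of site kinds
#'
#' Explicit tabulated pairs are returned verbatim; otherwise
#' Lorentz-Berthelot mixing is applied, with epsilon multiplied by any
#' registered cross-term scale factor (default 1).
#'
#' @param kindA,kindB site-kind names (must be registered in `ff`).
#' @param ff a [forcefield()] (or a bare [pair_table()] plus `site_kinds`).
#' @return Named numeric vector `c(epsilon =, sigma =)`.
#' @export
#' @examples
#' ff <- pdms_forcefield()
#' mix_pair_params("Si", "CH3", ff)   # explicit Table row: 0.1596, 3.83
mix_pair_params <- function(kindA, kindB, ff) {
  sk <- ff$site_kinds
  for (k in c(kindA, kindB))
    if (!k %in% names(sk)) stop("unknown site kind '", k, "'")
  key <- .pair_key(kindA, kindB)
  ep <- ff$pairs$explicit_pairs
  if (nrow(ep)) {
    keys <- .pair_key(ep$kindA, ep$kindB)
    hit <- match(key, keys)
    if (!is.na(hit))
      return(c(epsilon = ep$epsilon[hit], sigma = ep$sigma[hit]))
  }
  scl <- 1
  cs <- ff$pairs$cross_scale
  if (nrow(cs)) {
    hit <- match(key, .pair_key(cs$kindA, cs$kindB))
    if (!is.na(hit)) scl <- cs$scale[hit]
  }
  a <- sk[[kindA]]; b <- sk[[kindB]]
  c(epsilon = scl * sqrt(a$epsilon * b$epsilon),
    sigma = (a$sigma + b$sigma) / 2)
}

#' 12-6 Lennard-Jones pair energy
#'
#' U(r) = 4 epsilon [ (sigma/r)^12 - (sigma/r)^6 ]. Cutoff handling is the
#' caller's responsibility.
#'
#' @param r separation, Angstrom (> 0).
#' @param epsilon well depth, kcal/mol.
#' @param sigma diameter, Angstrom.
#' @return Energy in kcal/mol.
#' @export
lj_pair_energy <- function(r, epsilon, sigma) {
  if (any(r <= 0)) stop("lj_pair_energy: r must be > 0")
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6 * sr6 - sr6)
}

#' Coulomb pair energy under the configured short-range method
#'
#' `direct` is k q_A q_B / r. `damped-shifted-force` (DSF) is the
#' Wolf-type damped, energy- and force-shifted form that vanishes
#' smoothly at the cutoff; `reaction-field` embeds the cutoff sphere in
#' a conducting continuum. Both reduce to the direct form as damping
#' goes to zero and r << cutoff.
#'
#' @param r separation, Angstrom (> 0).
#' @param qA,qB charges, e.
#' @param method `"direct"`, `"damped-shifted-force"` or `"reaction-field"`.
#' @param cutoff cutoff radius, Angstrom (required for the non-direct methods).
#' @param alpha DSF damping parameter, 1/Angstrom.
#' @return Energy in kcal/mol.
#' @export
coulomb_pair_energy <- function(r, qA, qB, method = "direct",
                                cutoff = 12, alpha = 0.2) {
  if (any(r <= 0)) stop("coulomb_pair_energy: r must be > 0")
  k <- pdms_constants$coulomb
  qq <- k * qA * qB
  switch(method,
    direct = qq / r,
    `damped-shifted-force` = {
      rc <- cutoff
      efun <- function(x) erfc_(alpha * x) / x
      dfun <- function(x) erfc_(alpha * x) / x^2 +
        2 * alpha / sqrt(pi) * exp(-(alpha * x)^2) / x
      e <- efun(r) - efun(rc) + dfun(rc) * (r - rc)
      ifelse(r >= rc, 0, qq * e)
    },
    `reaction-field` = {
      # conducting boundary (eps_RF -> Inf): krf = 1/(2 rc^3), shifted to 0 at rc
      rc <- cutoff
      krf <- 1 / (2 * rc^3)
      crf <- 1 / rc + krf * rc^2
      ifelse(r >= rc, 0, qq * (1 / r + krf * r^2 - crf))
    },
    stop("unknown electrostatics method '", method, "'")
  )
}

# complementary error function (base R lacks it)
erfc_ <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

#' Apply the united-atom CH3 diameter refinement
#'
#' The PDMS model used here inflates the methyl-group LJ sigma by 3.49%
#' relative to its parent united-atom parameterisation so that the
#' simulated liquid density of PDMS matches experiment (the unrefined
#' value overestimates density by ~8%).
#'
#' @param base_sigma parent-model CH3 sigma, Angstrom (> 0).
#' @return Refined sigma, `base_sigma * 1.0349`.
#' @export
#' @examples
#' apply_ch3_sigma_modification(3.7298)  # ~3.86
apply_ch3_sigma_modification <- function(base_sigma) {
  if (any(base_sigma <= 0)) stop("base_sigma must be > 0")
  base_sigma * 1.0349
}

#' The refined PDMS / SPC water / organics force field
#'
#' Ships the united-atom PDMS parameter set (explicit 12-6 pair table
#' with the density-refined CH3-CH3 diameter), SPC water, and OPLS-style
#' all-atom parameters for phenol, chlorophenol, guaiacol, benzyl
#' alcohol and phenethyl alcohol. The water-organic cross epsilon is
#' scaled by 1.20 (fitted originally on water-phenol diffusion and
#' applied to all organics); set `water_organic_scale` to change or
#' `scale_all_organics = FALSE` to restrict the scaling to phenol's
#' site kinds only.
#'
#' Partial charges for PDMS and the organics are documented package
#' defaults (the partition arithmetic in this package is
#' charge-independent): Si +0.30, siloxane O -0.30, CH3 0 for PDMS;
#' SPC charges for water; OPLS-style charges for the organics.
#'
#' @param water_organic_scale cross-epsilon factor for water-organic
#'   LJ interactions (default 1.20).
#' @param scale_all_organics apply the factor to every organic site kind
#'   (default) or only to phenol's.
#' @param cutoff nonbonded cutoff, Angstrom.
#' @param electrostatics short-range electrostatics method.
#' @return A [forcefield()].
#' @export
pdms_forcefield <- function(water_organic_scale = 1.20,
                            scale_all_organics = TRUE,
                            cutoff = 12,
                            electrostatics = "damped-shifted-force") {
  kinds <- list(
    # united-atom PDMS (self-interaction values consistent with the
    # explicit pair table below)
    site_kind("Si",  mass = 28.0855, charge = +0.30, epsilon = 0.1310, sigma = 4.29),
    site_kind("O",   mass = 15.9994, charge = -0.30, epsilon = 0.0800, sigma = 3.30),
    site_kind("CH3", mass = 15.0345, charge =  0.00, epsilon = 0.1944, sigma = 3.86),
    # SPC water
    site_kind("OW", mass = 15.9994, charge = -0.82, epsilon = 0.1553, sigma = 3.166),
    site_kind("HW", mass = 1.00794, charge = +0.41, epsilon = 0.0,    sigma = 0.0),
    # OPLS-style organic sites (aromatic carbon/hydrogen, hydroxyl,
    # ether oxygen, methoxy/methylene carbons, chlorine)
    site_kind("CA", mass = 12.011,  charge = -0.115, epsilon = 0.070, sigma = 3.55),
    site_kind("HA", mass = 1.00794, charge = +0.115, epsilon = 0.030, sigma = 2.42),
    site_kind("CO", mass = 12.011,  charge = +0.150, epsilon = 0.070, sigma = 3.55),
    site_kind("OH", mass = 15.9994, charge = -0.585, epsilon = 0.170, sigma = 3.12),
    site_kind("HO", mass = 1.00794, charge = +0.435, epsilon = 0.0,   sigma = 0.0),
    site_kind("OS", mass = 15.9994, charge = -0.400, epsilon = 0.140, sigma = 2.90),
    site_kind("CT", mass = 12.011,  charge = +0.110, epsilon = 0.066, sigma = 3.50),
    site_kind("HC", mass = 1.00794, charge = +0.030, epsilon = 0.030, sigma = 2.50),
    site_kind("Cl", mass = 35.453,  charge = -0.180, epsilon = 0.300, sigma = 3.40),
    # frozen wall atoms (purely repulsive toward PDMS)
    site_kind("WALL", mass = 195.08, charge = 0, epsilon = 0.10, sigma = 3.5)
  )
  # explicit PDMS pair table; entries are authoritative and override mixing
  ep <- data.frame(
    kindA   = c("Si", "Si", "Si",  "O",  "O",   "CH3"),
    kindB   = c("Si", "O",  "CH3", "O",  "CH3", "CH3"),
    epsilon = c(0.1310, 0.0772, 0.1596, 0.0800, 0.1247, 0.1944),
    sigma   = c(4.29,   3.94,   3.83,   3.30,   3.38,   3.86),
    stringsAsFactors = FALSE
  )
  organic_kinds <- c("CA", "HA", "CO", "OH", "HO", "OS", "CT", "HC", "Cl")
  if (!scale_all_organics) organic_kinds <- c("CA", "HA", "CO", "OH", "HO")
  water_kinds <- c("OW", "HW")
  cs <- expand.grid(kindA = water_kinds, kindB = organic_kinds,
                    stringsAsFactors = FALSE)
  cs <- data.frame(kindA = cs$kindA, kindB = cs$kindB,
                   scale = water_organic_scale, stringsAsFactors = FALSE)

  bonded <- bonded_terms(
    bonds = data.frame(
      type = c("Si-O", "Si-CH3", "CA-CA", "CA-HA", "CA-CO", "CO-OH", "OH-HO",
               "CA-Cl", "CA-OS", "OS-CT", "CT-HC", "CA-CT", "CT-CT", "CT-OH"),
      k    = c(350, 190, 469, 367, 469, 450, 553, 300, 450, 320, 340, 317, 268, 320),
      r0   = c(1.64, 1.90, 1.40, 1.08, 1.40, 1.364, 0.945, 1.725, 1.364, 1.41,
               1.09, 1.51, 1.529, 1.41),
      stringsAsFactors = FALSE),
    angles = data.frame(
      type   = c("O-Si-O", "Si-O-Si", "CH3-Si-CH3", "O-Si-CH3",
                 "CA-CA-CA", "CA-CA-HA", "CA-CO-OH", "CO-OH-HO",
                 "CA-OS-CT", "OS-CT-HC", "CA-CA-CT", "CA-CT-HC",
                 "CA-CT-CT", "CT-CT-OH", "CT-OH-HO", "HC-CT-HC",
                 "CA-CA-Cl", "CA-CA-CO", "CA-CA-OS", "CT-CT-HC"),
      k      = c(94.5, 31.1, 49.4, 49.4,
                 63, 35, 70, 35, 75, 35, 70, 35, 63, 50, 55, 33, 75, 63, 70, 37.5),
      theta0 = c(107.8, 146.46, 109.24, 110.0,
                 120, 120, 120, 113, 111, 109.5, 120, 109.5, 112, 109.5, 108.5,
                 107.8, 120, 120, 120, 110.7),
      stringsAsFactors = FALSE),
    dihedrals = data.frame(
      # PDMS backbone torsions are nearly free rotors; aromatic ring
      # torsions handled by the ring's bonded network at desk scale
      type = c("Si-O", "ring", "hydroxyl", "ether"),
      v1 = c(0, 0, 0, 0), v2 = c(0.2, 7.25, 0, 0),
      v3 = c(0, 0, 0.5, 0.76), v4 = c(0, 0, 0, 0),
      stringsAsFactors = FALSE)
  )
  forcefield(kinds, pair_table(ep, cs), bonded,
             cutoff = cutoff, electrostatics = electrostatics)
}

#' Write a force field to a YAML parameter file
#'
#' The file is human-editable structured text; [read_forcefield()]
#' restores an identical object (lossless round trip).
#'
#' @param ff a [forcefield()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_forcefield <- function(ff, path) {
  obj <- list(
    site_kinds = lapply(unname(ff$site_kinds), function(k)
      list(name = k$name, mass = k$mass, charge = k$charge,
           epsilon = k$epsilon, sigma = k$sigma)),
    explicit_pairs = df_to_rows(ff$pairs$explicit_pairs),
    cross_scale = df_to_rows(ff$pairs$cross_scale),
    bonds = df_to_rows(ff$bonded$bonds),
    angles = df_to_rows(ff$bonded$angles),
    dihedrals = df_to_rows(ff$bonded$dihedrals),
    half_k = ff$bonded$half_k,
    cutoff = ff$cutoff,
    electrostatics = ff$electrostatics,
    dsf_alpha = ff$dsf_alpha,
    scale14 = ff$scale14,
    lj_tail = ff$lj_tail
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a force field from a YAML parameter file
#'
#' @param path file written by [write_forcefield()] (or hand-edited in
#'   the same dialect).
#' @return A [forcefield()].
#' @export
read_forcefield <- function(path) {
  obj <- yaml::read_yaml(path)
  kinds <- lapply(obj$site_kinds, function(k)
    site_kind(k$name, k$mass, k$charge, k$epsilon, k$sigma))
  ff <- forcefield(kinds,
                   pair_table(rows_to_df(obj$explicit_pairs,
                                         c("kindA", "kindB", "epsilon", "sigma")),
                              rows_to_df(obj$cross_scale,
                                         c("kindA", "kindB", "scale"))),
                   bonded_terms(rows_to_df(obj$bonds, c("type", "k", "r0")),
                                rows_to_df(obj$angles, c("type", "k", "theta0")),
                                rows_to_df(obj$dihedrals,
                                           c("type", "v1", "v2", "v3", "v4")),
                                half_k = isTRUE(obj$half_k)),
                   cutoff = obj$cutoff, electrostatics = obj$electrostatics,
                   dsf_alpha = obj$dsf_alpha, scale14 = obj$scale14,
                   lj_tail = obj$lj_tail)
  ff
}

df_to_rows <- function(df) {
  if (!nrow(df)) return(list())
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

rows_to_df <- function(rows, cols) {
  if (!length(rows)) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    return(df)
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r[cols], stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df
}
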