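#' Compose the 80:20 (by weight) PDMS oligomer mixture
#'
#' Returns replicated n = 1 and n = 2 oligomer templates together with
#' the achieved n = 1 weight fraction computed from the template masses.
#' The reference composition of the sorptive coating is 75 n = 1 plus
#' 14 n = 2 molecules, which gives a weight fraction of 0.803.
#'
#' @param n1_count,n2_count molecule counts of the n = 1 and n = 2
#'   oligomers (non-negative).
#' @param ff a [forcefield()].
#' @return List with `molecules` (list of templates), `weight_fraction`
#'   (n = 1 mass fraction; `NA` with `degenerate = TRUE` for zero total).
#' @export
#' @examples
#' mix <- build_mixture_80_20(75, 14)
#' round(mix$weight_fraction, 3)  # 0.803
build_mixture_80_20 <- function(n1_count, n2_count, ff = pdms_forcefield()) {
  stopifnot(n1_count >= 0, n2_count >= 0)
  t1 <- build_pdms_oligomer(1, ff)
  t2 <- build_pdms_oligomer(2, ff)
  mols <- c(rep(list(t1), n1_count), rep(list(t2), n2_count))
  m1 <- n1_count * t1$mass
  m2 <- n2_count * t2$mass
  if (m1 + m2 == 0)
    return(list(molecules = list(), weight_fraction = NA_real_,
                degenerate = TRUE))
  list(molecules = mols, weight_fraction = m1 / (m1 + m2), degenerate = FALSE)
}

#' Number of organic molecules at the aqueous solubility limit
#'
#' Converts a solubility expressed as mole percent (relative to the
#' water + organic total) into the number of organic molecules that can
#' be dissolved among `n_water` water molecules:
#' `floor(n_water * s / (100 - s))`.
#'
#' @param solubility_mol_pct solubility, mol % (0 <= s < 100).
#' @param n_water number of water molecules.
#' @return Integer count.
#' @export
#' @examples
#' organics_at_saturation(1.6, 6418)  # 104 phenol molecules
organics_at_saturation <- function(solubility_mol_pct, n_water) {
  s <- solubility_mol_pct
  if (s < 0 || s >= 100) stop("solubility must satisfy 0 <= s < 100 mol %")
  as.integer(floor(n_water * s / (100 - s)))
}

#' Aqueous solubilities of the studied organics
#'
#' Literature solubility-in-water limits used to set the saturated
#' loading of the aqueous phase, as mole percent (the mol % values are
#' authoritative for loading; the companion mg/L figures are not
#' mutually consistent with them under a single density assumption).
#'
#' @return data frame: compound, temperature (K), solubility (mol %).
#' @export
solubility_table <- function() {
  data.frame(
    compound = c("phenol", "phenol", "phenol",
                 "guaiacol", "chlorophenol", "benzyl alcohol",
                 "phenethyl alcohol"),
    T = c(298.15, 330.48, 335.89, 298.15, 298.15, 298.15, 298.15),
    mol_pct = c(1.6, 2.7, 3.5, 0.3, 0.4, 0.71, 0.3),
    stringsAsFactors = FALSE)
}

#' Randomly pack molecules into a region without overlaps
#'
#' Sequential random insertion with random rigid rotation; a candidate
#' placement is accepted when every inter-molecular site distance is at
#' least `min_dist`. Deterministic for a fixed seed.
#'
#' @param templates list of molecule templates.
#' @param counts integer vector, one count per template.
#' @param region numeric `c(xlo, xhi, ylo, yhi, zlo, zhi)`, Angstrom.
#' @param min_dist minimum inter-molecular site distance, Angstrom.
#' @param seed RNG seed (optional; caller's RNG state used if `NULL`).
#' @param max_attempts insertion attempts per molecule before failing.
#' @param obstacles optional matrix of already-occupied site positions
#'   that placements must also clear by `min_dist`.
#' @param periodic logical, scalar or per-axis: on periodic axes
#'   molecule centres may sit anywhere, sites wrap around the region
#'   edges, and distances use the minimum image; on non-periodic axes
#'   every site must fall inside the region.
#' @return List: `pos` (all-site coordinate matrix), `kinds`,
#'   `site_mol`, `mol_species`, `templates_used` (index per molecule).
#' @export
pack_nonoverlapping <- function(templates, counts, region, min_dist = 2.0,
                                seed = NULL, max_attempts = 5000L,
                                obstacles = NULL, periodic = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(templates) == length(counts), length(region) == 6)
  if (length(periodic) == 1) periodic <- rep(periodic, 3)
  lo <- region[c(1, 3, 5)]; hi <- region[c(2, 4, 6)]
  vol <- prod(hi - lo)
  nsites_total <- sum(vapply(templates, function(t) nrow(t$pos), 0) * counts)
  # close-packing bound: each site claims at least min_dist^3/sqrt(2)
  if (nsites_total * min_dist^3 / sqrt(2) > vol)
    stop("packing error: ", nsites_total, " sites at min_dist ", min_dist,
         " cannot fit volume ", round(vol), " A^3 (close-packing bound)")
  placed <- NULL
  kinds <- character(0); site_mol <- integer(0); mol_species <- character(0)
  tmpl_used <- integer(0)
  mol_id <- 0L
  for (t in seq_along(templates)) {
    tm <- templates[[t]]
    p0 <- sweep(tm$pos, 2, colMeans(tm$pos))   # centred internal coords
    ext <- max(sqrt(rowSums(p0^2)))
    for (cnt in seq_len(counts[t])) {
      ok <- FALSE
      per_l <- ifelse(periodic, hi - lo, Inf)
      if (all(!periodic)) per_l <- NULL
      for (att in seq_len(max_attempts)) {
        rot <- random_rotation()
        cand <- p0 %*% rot
        centre <- lo + stats::runif(3) * (hi - lo)
        cand <- sweep(cand, 2, centre, `+`)
        # molecules stay contiguous; periodic axes rely on the minimum
        # image in the distance checks (sites may extend past the edge)
        bad <- FALSE
        for (ax in which(!periodic))
          if (any(cand[, ax] < lo[ax]) || any(cand[, ax] > hi[ax])) {
            bad <- TRUE; break
          }
        if (bad) next
        if (!is.null(placed) &&
            min_cross_dist2(cand, placed, per_l) < min_dist^2) next
        if (!is.null(obstacles) &&
            min_cross_dist2(cand, obstacles, per_l) < min_dist^2) next
        ok <- TRUE
        break
      }
      if (!ok)
        stop("packing error: placed ", mol_id, " of ", sum(counts),
             " molecules, then failed after ", max_attempts, " attempts")
      mol_id <- mol_id + 1L
      placed <- rbind(placed, cand)
      kinds <- c(kinds, tm$kinds)
      site_mol <- c(site_mol, rep(mol_id, nrow(cand)))
      mol_species <- c(mol_species, tm$name)
      tmpl_used <- c(tmpl_used, t)
    }
  }
  list(pos = placed, kinds = kinds, site_mol = site_mol,
       mol_species = mol_species, templates_used = tmpl_used)
}

random_rotation <- function() {
  # uniform random rotation via normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

min_cross_dist2 <- function(a, b, box = NULL) {
  # smallest squared distance between rows of a and rows of b,
  # optionally under the minimum image for an orthorhombic box
  m <- Inf
  if (is.null(box)) {
    bb <- rowSums(b^2)
    for (i in seq_len(nrow(a))) {
      d2 <- bb - 2 * drop(b %*% a[i, ]) + sum(a[i, ]^2)
      m <- min(m, min(d2))
    }
  } else {
    box_f <- ifelse(is.finite(box), box, NA)
    for (i in seq_len(nrow(a))) {
      d <- sweep(b, 2, a[i, ])
      for (ax in which(!is.na(box_f)))
        d[, ax] <- d[, ax] - round(d[, ax] / box_f[ax]) * box_f[ax]
      m <- min(m, min(rowSums(d^2)))
    }
  }
  m
}

#' Slab geometry specification
#'
#' Defines the two-phase slab: a central PDMS layer flanked by two
#' aqueous phases along x, walls at the x extremes, periodic in y and z.
#' The default geometry is a 128 x 40 x 40 Angstrom box: water
#' 1-49 A, a 1 A interface allowance, PDMS 50-78 A (28 A thick),
#' another allowance, water 79-127 A, with 1 A edge gaps at the walls.
#'
#' @param pdms_width PDMS slab thickness, Angstrom.
#' @param water_width width of each aqueous phase, Angstrom.
#' @param cross_section `c(ly, lz)`, Angstrom.
#' @param edge_gap gap between each wall and the adjacent water phase.
#' @param interface_gap initial gap between water and PDMS regions.
#' @param wall_lattice FCC lattice constant for the wall layer, Angstrom.
#' @return Object of class `"slab_spec"` with derived region bounds.
#' @export
slab_spec <- function(pdms_width = 28, water_width = 48,
                      cross_section = c(40, 40),
                      edge_gap = 1, interface_gap = 1,
                      wall_lattice = 3.92) {
  lx <- 2 * edge_gap + 2 * water_width + 2 * interface_gap + pdms_width
  w1 <- c(edge_gap, edge_gap + water_width)
  pd <- c(w1[2] + interface_gap, w1[2] + interface_gap + pdms_width)
  w2 <- c(pd[2] + interface_gap, pd[2] + interface_gap + water_width)
  structure(list(pdms_width = pdms_width, water_width = water_width,
                 cross_section = cross_section, edge_gap = edge_gap,
                 interface_gap = interface_gap, wall_lattice = wall_lattice,
                 box = c(lx, cross_section),
                 water1 = w1, pdms = pd, water2 = w2),
            class = "slab_spec")
}

#' Single-layer FCC(100) wall patch
#'
#' Positions of a frozen square lattice layer (the (100) face of an FCC
#' lattice has spacing a/sqrt(2)) spanning the y-z cross-section at a
#' given x.
#'
#' @param x0 layer plane, Angstrom.
#' @param cross_section `c(ly, lz)`.
#' @param a FCC lattice constant, Angstrom.
#' @return Matrix of wall-atom positions.
#' @export
build_fcc_wall <- function(x0, cross_section, a = 3.92) {
  s <- a / sqrt(2)
  ys <- seq(s / 2, cross_section[1] - s / 4, by = s)
  zs <- seq(s / 2, cross_section[2] - s / 4, by = s)
  g <- expand.grid(y = ys, z = zs)
  cbind(x = x0, y = g$y, z = g$z)
}

#' Build the water / PDMS / water slab system
#'
#' Packs the PDMS oligomer mixture into the central slab region, SPC
#' water into the two flanking aqueous regions, and any organic solute
#' molecules into the water immediately adjacent to the PDMS faces
#' (so the approach to the interface does not rate-limit
#' equilibration). Frozen wall-atom layers sit at both x extremes and
#' repel PDMS only; x is non-periodic, y and z are periodic.
#'
#' @param spec a [slab_spec()].
#' @param n_pdms1,n_pdms2 oligomer counts for the mixture.
#' @param n_water total water molecules (split between the two phases).
#' @param organic organic compound name, or `NULL` for a two-species
#'   system.
#' @param n_organic organic molecule count (e.g. from
#'   [organics_at_saturation()]).
#' @param ff a [forcefield()].
#' @param seed RNG seed for packing.
#' @param min_dist packing distance, Angstrom.
#' @param wall_atoms include frozen FCC wall layers (default) or rely on
#'   analytic walls only.
#' @return A [molecular_system()].
#' @export
build_slab_system <- function(spec = slab_spec(), n_pdms1 = 75, n_pdms2 = 14,
                              n_water = 6418, organic = NULL, n_organic = 0,
                              ff = pdms_forcefield(), seed = 1,
                              min_dist = 2.0, wall_atoms = TRUE) {
  set.seed(seed)
  cs <- spec$cross_section
  mix <- build_mixture_80_20(n_pdms1, n_pdms2, ff)
  templates <- list(); counts <- integer(0); regions <- list()
  add <- function(tm, count, reg) {
    templates[[length(templates) + 1]] <<- tm
    counts <<- c(counts, count)
    regions[[length(regions) + 1]] <<- reg
  }
  # larger molecules first: packing succeeds far more often
  if (n_pdms2 > 0)
    add(build_pdms_oligomer(2, ff), n_pdms2,
        c(spec$pdms, 0, cs[1], 0, cs[2]))
  if (n_pdms1 > 0)
    add(build_pdms_oligomer(1, ff), n_pdms1,
        c(spec$pdms, 0, cs[1], 0, cs[2]))
  wt <- water_template(ff)
  nw1 <- ceiling(n_water / 2); nw2 <- n_water - nw1
  if (n_organic > 0) {
    if (is.null(organic)) stop("organic name required when n_organic > 0")
    ot <- organic_template(organic, ff)
    # initial placement close to the PDMS faces: the 10 A of water
    # adjacent to each interface
    no1 <- ceiling(n_organic / 2); no2 <- n_organic - no1
    if (no1 > 0) add(ot, no1, c(spec$water1[2] - 10, spec$water1[2],
                                0, cs[1], 0, cs[2]))
    if (no2 > 0) add(ot, no2, c(spec$water2[1], spec$water2[1] + 10,
                                0, cs[1], 0, cs[2]))
  }
  if (nw1 > 0) add(wt, nw1, c(spec$water1, 0, cs[1], 0, cs[2]))
  if (nw2 > 0) add(wt, nw2, c(spec$water2, 0, cs[1], 0, cs[2]))

  pos <- NULL; kinds <- character(0); site_mol <- integer(0)
  mol_species <- character(0)
  tmpl_of_mol <- list()
  mol_off <- 0L
  for (r in seq_along(templates)) {
    pk <- pack_nonoverlapping(templates[r], counts[r], regions[[r]],
                              min_dist = min_dist, obstacles = pos,
                              periodic = c(FALSE, TRUE, TRUE))
    pos <- rbind(pos, pk$pos)
    kinds <- c(kinds, pk$kinds)
    site_mol <- c(site_mol, pk$site_mol + mol_off)
    mol_species <- c(mol_species, pk$mol_species)
    tmpl_of_mol <- c(tmpl_of_mol, rep(templates[r], counts[r]))
    mol_off <- mol_off + length(pk$mol_species)
  }

  # frozen wall layers
  frozen <- rep(FALSE, nrow(pos))
  if (wall_atoms) {
    for (x0 in c(0, spec$box[1])) {
      wp <- build_fcc_wall(x0, cs, spec$wall_lattice)
      pos <- rbind(pos, wp)
      kinds <- c(kinds, rep("WALL", nrow(wp)))
      mol_off <- mol_off + 1L
      site_mol <- c(site_mol, rep(mol_off, nrow(wp)))
      mol_species <- c(mol_species, "wall")
      frozen <- c(frozen, rep(TRUE, nrow(wp)))
    }
  }

  sys <- assemble_topology(pos, kinds, site_mol, mol_species, tmpl_of_mol,
                           box = c(spec$box[1], cs), ff = ff,
                           periodic = c(FALSE, TRUE, TRUE), frozen = frozen)
  sys$walls <- list(wall_def(0, +1, species = "pdms"),
                    wall_def(spec$box[1], -1, species = "pdms"))
  sys$slab <- spec
  sys
}

# stitch per-molecule template topology into global index space
assemble_topology <- function(pos, kinds, site_mol, mol_species, tmpl_of_mol,
                              box, ff, periodic, frozen = NULL) {
  kind_names <- unique(kinds)
  ktab <- do.call(rbind, lapply(ff$site_kinds[kind_names], function(k)
    data.frame(name = k$name, mass = k$mass, charge = k$charge,
               epsilon = k$epsilon, sigma = k$sigma,
               stringsAsFactors = FALSE)))
  rownames(ktab) <- NULL
  site_kind <- match(kinds, ktab$name)
  bonds <- NULL; bond_k <- numeric(); bond_r0 <- numeric()
  angles <- NULL; angle_k <- numeric(); angle_th0 <- numeric()
  diheds <- NULL; dihed_v <- NULL
  cons <- NULL; cons_d <- numeric()
  first_site <- match(seq_along(mol_species), site_mol) - 1L  # offset per mol
  for (m in seq_along(tmpl_of_mol)) {
    tm <- tmpl_of_mol[[m]]
    if (is.null(tm)) next
    off <- first_site[m]
    for (b in tm$bonds) {
      p <- lookup_bond(ff, b[[3]])
      bonds <- rbind(bonds, c(b[[1]] + off, b[[2]] + off))
      bond_k <- c(bond_k, p[["k"]]); bond_r0 <- c(bond_r0, p[["r0"]])
    }
    for (a in tm$angles) {
      p <- lookup_angle(ff, a[[4]])
      angles <- rbind(angles, c(a[[1]] + off, a[[2]] + off, a[[3]] + off))
      angle_k <- c(angle_k, p[["k"]]); angle_th0 <- c(angle_th0, p[["theta0"]])
    }
    for (d in tm$dihedrals) {
      v <- lookup_dihed(ff, d[[5]])
      diheds <- rbind(diheds, c(d[[1]], d[[2]], d[[3]], d[[4]]) + off)
      dihed_v <- rbind(dihed_v, v)
    }
    for (cc in tm$constraints) {
      cons <- rbind(cons, c(cc[[1]] + off, cc[[2]] + off))
      cons_d <- c(cons_d, cc[[3]])
    }
  }
  molecular_system(ktab, site_kind, site_mol, mol_species, pos,
                   box = box, periodic = periodic, bonds = bonds,
                   bond_k = bond_k, bond_r0 = bond_r0, angles = angles,
                   angle_k = angle_k, angle_th0 = angle_th0,
                   dihedrals = diheds, dihed_v = dihed_v,
                   constraints = cons, cons_d = cons_d, frozen = frozen)
}

#' Build a bulk (fully periodic) system from templates
#'
#' Convenience wrapper: packs `counts` copies of each template into a
#' periodic box and assembles the global topology.
#'
#' @param templates list of templates.
#' @param counts counts per template.
#' @param box length-3 box, Angstrom.
#' @param ff force field.
#' @param seed packing seed.
#' @param min_dist packing distance.
#' @return A [molecular_system()].
#' @export
build_bulk_system <- function(templates, counts, box,
                              ff = pdms_forcefield(), seed = 1,
                              min_dist = 2.0) {
  pk <- pack_nonoverlapping(templates, counts,
                            c(0, box[1], 0, box[2], 0, box[3]),
                            min_dist = min_dist, seed = seed,
                            periodic = TRUE)
  tmpl_of_mol <- list()
  for (t in seq_along(templates))
    tmpl_of_mol <- c(tmpl_of_mol, rep(templates[t], counts[t]))
  assemble_topology(pk$pos, pk$kinds, pk$site_mol, pk$mol_species,
                    tmpl_of_mol, box = box, ff = ff,
                    periodic = c(TRUE, TRUE, TRUE))
}
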