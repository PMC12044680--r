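# Molecule templates: internal coordinates plus bonded topology, with
# bonded parameters resolved from the force field's type tables at
# construction time.

lookup_bond <- function(ff, type) {
  i <- match(type, ff$bonded$bonds$type)
  if (is.na(i)) stop("no bond type '", type, "' in force field")
  c(k = ff$bonded$bonds$k[i], r0 = ff$bonded$bonds$r0[i])
}
lookup_angle <- function(ff, type) {
  i <- match(type, ff$bonded$angles$type)
  if (is.na(i)) stop("no angle type '", type, "' in force field")
  c(k = ff$bonded$angles$k[i], theta0 = ff$bonded$angles$theta0[i])
}
lookup_dihed <- function(ff, type) {
  i <- match(type, ff$bonded$dihedrals$type)
  if (is.na(i)) stop("no dihedral type '", type, "' in force field")
  unlist(ff$bonded$dihedrals[i, c("v1", "v2", "v3", "v4")])
}

new_template <- function(name, kinds, pos, ff,
                         bonds = NULL, angles = NULL, dihedrals = NULL,
                         constraints = NULL) {
  kt <- vapply(ff$site_kinds[kinds], `[[`, 0, "mass")
  tmpl <- list(name = name, kinds = kinds, pos = pos,
               mass = sum(kt),
               bonds = bonds %||% list(), angles = angles %||% list(),
               dihedrals = dihedrals %||% list(),
               constraints = constraints %||% list())
  class(tmpl) <- "mol_template"
  tmpl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mol_template <- function(x, ...) {
  cat("Molecule template '", x$name, "': ", length(x$kinds), " sites (",
      paste(names(table(x$kinds)), table(x$kinds), sep = "x", collapse = ", "),
      "), mass ", round(x$mass, 3), " amu\n", sep = "")
  invisible(x)
}

#' SPC water template
#'
#' Rigid three-site SPC water: O-H 1.0 Angstrom, H-O-H 109.47 degrees,
#' enforced during dynamics by SHAKE distance constraints (the H-H
#' "bond" is the fictitious constraint closing the triangle).
#'
#' @param ff a [forcefield()] containing `OW`/`HW` site kinds.
#' @return A molecule template.
#' @export
water_template <- function(ff = pdms_forcefield()) {
  half <- 109.47 / 2 * pi / 180
  pos <- rbind(c(0, 0, 0),
               c(sin(half), cos(half), 0),
               c(-sin(half), cos(half), 0))
  hh <- 2 * sin(half)
  new_template("water", c("OW", "HW", "HW"), pos, ff,
               constraints = list(list(1L, 2L, 1.0),
                                  list(1L, 3L, 1.0),
                                  list(2L, 3L, hh)))
}

#' Build a linear PDMS oligomer template
#'
#' United-atom polydimethylsiloxane with `n` repeat units: a
#' -(Si-O)- backbone of (n+2) silicon and (n+1) oxygen sites, each
#' silicon carrying two methyl sites (three at the chain ends), for
#' 2n+6 CH3 sites and 4n+9 sites in total. n = 1, 2, 3 give
#' octamethyltrisiloxane, decamethyltetrasiloxane and
#' dodecamethylpentasiloxane.
#'
#' @param n repeat count, one of 1, 2, 3.
#' @param ff a [forcefield()] with the PDMS site kinds and bonded types.
#' @return A molecule template.
#' @export
#' @examples
#' tm <- build_pdms_oligomer(1)
#' table(tm$kinds)  # 3 Si, 2 O, 8 CH3
build_pdms_oligomer <- function(n, ff = pdms_forcefield()) {
  if (!n %in% 1:3) stop("unsupported repeat count n = ", n, " (use 1, 2 or 3)")
  nsi <- n + 2
  # backbone zig-zag in the xy plane: Si-O 1.64 A, Si-O-Si 146.46 deg
  nb <- 2 * nsi - 1                       # Si O Si O ... Si
  th <- 146.46 / 2 * pi / 180
  step_x <- 1.64 * sin(th)
  step_y <- 1.64 * cos(th)
  bx <- (seq_len(nb) - 1) * step_x
  by <- rep(c(0, step_y), length.out = nb)
  kinds <- character(0); pos <- NULL
  bonds <- list(); angles <- list(); dihedrals <- list()
  idx_backbone <- integer(nb)
  for (b in seq_len(nb)) {
    kinds <- c(kinds, if (b %% 2 == 1) "Si" else "O")
    pos <- rbind(pos, c(bx[b], by[b], 0))
    idx_backbone[b] <- length(kinds)
  }
  bl_sic <- lookup_bond(ff, "Si-CH3")
  for (b in seq_len(nb)) {
    if (b %% 2 == 0) next                 # oxygens carry no methyls
    si <- idx_backbone[b]
    terminal <- (b == 1 || b == nb)
    nme <- if (terminal) 3L else 2L
    # methyls off the backbone plane (and along the axis at chain ends)
    dirs <- list(c(0, -0.5, sqrt(3) / 2), c(0, -0.5, -sqrt(3) / 2),
                 if (b == 1) c(-1, 0.2, 0) else c(1, 0.2, 0))
    for (m in seq_len(nme)) {
      d <- dirs[[m]]; d <- d / sqrt(sum(d^2))
      kinds <- c(kinds, "CH3")
      pos <- rbind(pos, pos[si, ] + bl_sic[["r0"]] * d)
      me <- length(kinds)
      bonds <- c(bonds, list(list(si, me, "Si-CH3")))
    }
  }
  for (b in seq_len(nb - 1))
    bonds <- c(bonds, list(list(idx_backbone[b], idx_backbone[b + 1], "Si-O")))
  # angles along the backbone
  for (b in seq_len(nb - 2)) {
    type <- if (b %% 2 == 1) "Si-O-Si" else "O-Si-O"
    if (b %% 2 == 1) {
      angles <- c(angles, list(list(idx_backbone[b], idx_backbone[b + 1],
                                    idx_backbone[b + 2], "Si-O-Si")))
    } else {
      angles <- c(angles, list(list(idx_backbone[b], idx_backbone[b + 1],
                                    idx_backbone[b + 2], "O-Si-O")))
    }
  }
  # angles at each silicon: CH3-Si-CH3 and O-Si-CH3
  me_of <- split(seq_along(kinds)[kinds == "CH3"],
                 vapply(which(kinds == "CH3"), function(m) {
                   # parent Si is the bonded partner
                   for (bd in bonds) if (bd[[2]] == m) return(bd[[1]])
                   NA_integer_
                 }, 1L))
  for (si_chr in names(me_of)) {
    si <- as.integer(si_chr)
    mes <- me_of[[si_chr]]
    if (length(mes) >= 2)
      for (a in seq_len(length(mes) - 1))
        for (b in (a + 1):length(mes))
          angles <- c(angles, list(list(mes[a], si, mes[b], "CH3-Si-CH3")))
    ob <- idx_backbone[kinds[idx_backbone] == "O"]
    for (o in ob) {
      pos_si <- match(si, idx_backbone)
      pos_o <- match(o, idx_backbone)
      if (!is.na(pos_si) && abs(pos_si - pos_o) == 1)
        for (m in mes)
          angles <- c(angles, list(list(o, si, m, "O-Si-CH3")))
    }
  }
  # backbone torsions
  if (nb >= 4)
    for (b in seq_len(nb - 3))
      dihedrals <- c(dihedrals, list(list(idx_backbone[b], idx_backbone[b + 1],
                                          idx_backbone[b + 2], idx_backbone[b + 3],
                                          "Si-O")))
  new_template(paste0("pdms", n), kinds, pos, ff,
               bonds = bonds, angles = angles, dihedrals = dihedrals)
}

# hexagonal aromatic ring scaffold: returns positions of 6 ring carbons
ring6 <- function(r = 1.40) {
  ang <- (0:5) * pi / 3
  cbind(r * cos(ang), r * sin(ang), 0)
}

# generic aromatic builder: ring positions + substituent spec per ring
# position: "H", "OH", "Cl", "OCH3", "CH2OH", "CH2CH2OH"
build_aromatic <- function(name, subst, ff) {
  rp <- ring6()
  kinds <- character(0); pos <- NULL
  bonds <- list(); angles <- list()
  ring_idx <- integer(6)
  for (i in 1:6) {
    kinds <- c(kinds, if (subst[i] == "OH") "CO" else "CA")
    pos <- rbind(pos, rp[i, ])
    ring_idx[i] <- length(kinds)
  }
  for (i in 1:6) {
    j <- i %% 6 + 1
    bonds <- c(bonds, list(list(ring_idx[i], ring_idx[j],
                                if (subst[i] == "OH" || subst[j] == "OH") "CA-CO" else "CA-CA")))
  }
  for (i in 1:6) {
    h <- i %% 6 + 1; g <- (i - 2) %% 6 + 1
    angles <- c(angles, list(list(ring_idx[g], ring_idx[i], ring_idx[h], "CA-CA-CA")))
  }
  radial <- function(i, d) rp[i, ] + d * rp[i, ] / sqrt(sum(rp[i, ]^2))
  add_site <- function(kind, p) {
    kinds <<- c(kinds, kind)
    pos <<- rbind(pos, p)
    length(kinds)
  }
  for (i in 1:6) {
    s <- subst[i]
    ci <- ring_idx[i]
    g <- ring_idx[(i - 2) %% 6 + 1]; h <- ring_idx[i %% 6 + 1]
    if (s == "H") {
      hi <- add_site("HA", radial(i, 1.08))
      bonds <- c(bonds, list(list(ci, hi, "CA-HA")))
      angles <- c(angles, list(list(g, ci, hi, "CA-CA-HA")),
                  list(list(h, ci, hi, "CA-CA-HA")))
    } else if (s == "OH") {
      oi <- add_site("OH", radial(i, 1.364))
      hi <- add_site("HO", pos[oi, ] + c(0.7, 0.63, 0))
      bonds <- c(bonds, list(list(ci, oi, "CO-OH")), list(list(oi, hi, "OH-HO")))
      angles <- c(angles, list(list(g, ci, oi, "CA-CO-OH")),
                  list(list(h, ci, oi, "CA-CO-OH")),
                  list(list(ci, oi, hi, "CO-OH-HO")))
    } else if (s == "Cl") {
      cl <- add_site("Cl", radial(i, 1.725))
      bonds <- c(bonds, list(list(ci, cl, "CA-Cl")))
      angles <- c(angles, list(list(g, ci, cl, "CA-CA-Cl")),
                  list(list(h, ci, cl, "CA-CA-Cl")))
    } else if (s == "OCH3") {
      oi <- add_site("OS", radial(i, 1.364))
      ct <- add_site("CT", pos[oi, ] + c(0.8, 1.1, 0))
      bonds <- c(bonds, list(list(ci, oi, "CA-OS")), list(list(oi, ct, "OS-CT")))
      angles <- c(angles, list(list(g, ci, oi, "CA-CA-OS")),
                  list(list(h, ci, oi, "CA-CA-OS")),
                  list(list(ci, oi, ct, "CA-OS-CT")))
      for (m in 1:3) {
        hm <- add_site("HC", pos[ct, ] + 1.09 * c(cos(2 * pi * m / 3) * 0.94,
                                                  sin(2 * pi * m / 3) * 0.94, 0.35))
        bonds <- c(bonds, list(list(ct, hm, "CT-HC")))
        angles <- c(angles, list(list(oi, ct, hm, "OS-CT-HC")))
      }
    } else if (s %in% c("CH2OH", "CH2CH2OH")) {
      c1 <- add_site("CT", radial(i, 1.51))
      angles <- c(angles, list(list(g, ci, c1, "CA-CA-CT")),
                  list(list(h, ci, c1, "CA-CA-CT")))
      bonds <- c(bonds, list(list(ci, c1, "CA-CT")))
      for (m in 1:2) {
        hm <- add_site("HC", pos[c1, ] + 1.09 * c(0.2, 0.5 * (-1)^m, 0.82))
        bonds <- c(bonds, list(list(c1, hm, "CT-HC")))
        angles <- c(angles, list(list(ci, c1, hm, "CA-CT-HC")))
      }
      tail_c <- c1
      if (s == "CH2CH2OH") {
        c2 <- add_site("CT", radial(i, 1.51 + 1.45))
        bonds <- c(bonds, list(list(c1, c2, "CT-CT")))
        angles <- c(angles, list(list(ci, c1, c2, "CA-CT-CT")))
        for (m in 1:2) {
          hm <- add_site("HC", pos[c2, ] + 1.09 * c(0.2, 0.5 * (-1)^m, -0.82))
          bonds <- c(bonds, list(list(c2, hm, "CT-HC")))
          angles <- c(angles, list(list(c1, c2, hm, "CT-CT-HC")))
        }
        tail_c <- c2
      }
      oi <- add_site("OH", pos[tail_c, ] + c(1.0, 0, 1.0))
      hi <- add_site("HO", pos[oi, ] + c(0.7, 0.63, 0))
      bonds <- c(bonds, list(list(tail_c, oi, "CT-OH")), list(list(oi, hi, "OH-HO")))
      angles <- c(angles, list(list(if (s == "CH2OH") ci else tail_c,
                                    tail_c, oi, "CT-CT-OH")),
                  list(list(tail_c, oi, hi, "CT-OH-HO")))
    } else stop("unknown substituent '", s, "'")
  }
  new_template(name, kinds, pos, ff, bonds = bonds, angles = angles)
}

#' Templates for the studied organic compounds
#'
#' All-atom OPLS-style templates for phenol, 2-chlorophenol, guaiacol
#' (2-methoxyphenol), benzyl alcohol and phenethyl alcohol.
#'
#' @param name compound name (see Details).
#' @param ff a [forcefield()].
#' @return A molecule template.
#' @export
#' @examples
#' round(organic_template("phenol")$mass, 2)  # 94.11
organic_template <- function(name = c("phenol", "chlorophenol", "guaiacol",
                                      "benzyl alcohol", "phenethyl alcohol"),
                             ff = pdms_forcefield()) {
  name <- match.arg(name)
  subst <- switch(name,
    "phenol"            = c("OH", "H", "H", "H", "H", "H"),
    "chlorophenol"      = c("OH", "Cl", "H", "H", "H", "H"),
    "guaiacol"          = c("OH", "OCH3", "H", "H", "H", "H"),
    "benzyl alcohol"    = c("CH2OH", "H", "H", "H", "H", "H"),
    "phenethyl alcohol" = c("CH2CH2OH", "H", "H", "H", "H", "H"))
  build_aromatic(name, subst, ff)
}
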