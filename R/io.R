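# File formats: extended-XYZ (configurations and trajectories),
# LAMMPS-style data files (topology), LAMMPS dump (read), CSV results.

#' Write a system or trajectory as extended XYZ
#'
#' One block per frame: site count, then a comment line with
#' `Lattice="..."`, `Properties=species:S:1:pos:R:3:mol:I:1` and
#' per-frame metadata (`Step`, `Time` fs, `Temperature` K), then one
#' line per site. Coordinates are written as stored (unwrapped for MD
#' trajectories).
#'
#' @param x a [molecular_system()] or `md_traj`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(sys, pos, step = 0, time = 0, temp = NA) {
    lat <- sprintf("%g 0 0 0 %g 0 0 0 %g", sys$box[1], sys$box[2], sys$box[3])
    meta <- sprintf("Lattice=\"%s\" Properties=species:S:1:pos:R:3:mol:I:1:molspecies:S:1 Step=%d Time=%g%s",
                    lat, step, time,
                    if (is.na(temp)) "" else sprintf(" Temperature=%g", temp))
    writeLines(as.character(nrow(pos)), con)
    writeLines(meta, con)
    sp <- sys$kinds$name[sys$site_kind]
    msp <- sys$mol_species[sys$site_mol]
    writeLines(sprintf("%s %.8f %.8f %.8f %d %s", sp, pos[, 1], pos[, 2],
                       pos[, 3], sys$site_mol, msp), con)
  }
  if (inherits(x, "molsys")) {
    emit(x, x$pos)
  } else if (inherits(x, "md_traj")) {
    r <- x$records
    for (f in seq_len(n_frames(x)))
      emit(x$system, x$frames[[f]], step = r$step[f], time = r$time[f],
           temp = r$T[f])
  } else stop("write_xyz: expected a molecular_system or md_traj")
  invisible(path)
}

#' Read an extended-XYZ file
#'
#' Parses every frame written by [write_xyz()] (species, positions,
#' molecule ids, lattice, step/time/temperature metadata). Truncated
#' files raise a parse error naming the offending line.
#'
#' @param path input file.
#' @return List of frames; each has `species`, `pos`, `mol`, `box`,
#'   `step`, `time`, `temperature`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("parse error at line ", i, ": expected site count")
    n <- as.integer(lines[i])
    if (i + 1 + n > length(lines))
      stop("parse error at line ", i, ": truncated frame (need ", n, " sites)")
    meta <- lines[i + 1]
    get_num <- function(key) {
      m <- regmatches(meta, regexec(paste0(key, "=([-0-9.eE+]+)"), meta))[[1]]
      if (length(m) < 2) NA_real_ else as.numeric(m[2])
    }
    lat <- regmatches(meta, regexec("Lattice=\"([^\"]+)\"", meta))[[1]]
    box <- if (length(lat) >= 2) {
      v <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
      c(v[1], v[5], v[9])
    } else rep(NA_real_, 3)
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(parts, length, 0L) < 4)
    if (length(bad))
      stop("parse error at line ", i + 1 + bad[1], ": malformed site record")
    species <- vapply(parts, `[[`, "", 1)
    pos <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), n, 3,
                  byrow = TRUE)
    nfield <- vapply(parts, length, 0L)
    mol <- if (all(nfield >= 5))
      as.integer(vapply(parts, `[[`, "", 5)) else rep(NA_integer_, n)
    mol_species <- if (all(nfield >= 6))
      vapply(parts, `[[`, "", 6) else NULL
    frames[[length(frames) + 1]] <-
      list(species = species, pos = pos, mol = mol, box = box,
           mol_species = mol_species,
           step = get_num("Step"), time = get_num("Time"),
           temperature = get_num("Temperature"))
    i <- i + 2 + n
  }
  frames
}

#' Write a LAMMPS-style data file (real units, full atom style)
#'
#' Emits header counts, box bounds, Masses, and Atoms
#' (`id mol type q x y z`), plus Bonds/Angles/Dihedrals sections with
#' one numbered type per distinct parameter set.
#'
#' @param sys a [molecular_system()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(sys, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(sys$pos)
  bt <- unique(cbind(sys$bond_k, sys$bond_r0))
  at <- unique(cbind(sys$angle_k, sys$angle_th0))
  dt <- unique(sys$dihed_v)
  w <- function(...) writeLines(sprintf(...), con)
  w("LAMMPS data file generated by pdmslab")
  w("")
  w("%d atoms", n)
  w("%d bonds", nrow(sys$bonds))
  w("%d angles", nrow(sys$angles))
  w("%d dihedrals", nrow(sys$dihedrals))
  w("%d atom types", nrow(sys$kinds))
  if (nrow(sys$bonds)) w("%d bond types", nrow(bt))
  if (nrow(sys$angles)) w("%d angle types", nrow(at))
  if (nrow(sys$dihedrals)) w("%d dihedral types", nrow(dt))
  w("")
  w("0.0 %.6f xlo xhi", sys$box[1])
  w("0.0 %.6f ylo yhi", sys$box[2])
  w("0.0 %.6f zlo zhi", sys$box[3])
  w("")
  w("Masses")
  w("")
  for (k in seq_len(nrow(sys$kinds)))
    w("%d %.6f  # %s", k, sys$kinds$mass[k], sys$kinds$name[k])
  w("")
  w("Atoms  # full")
  w("")
  q <- site_charges(sys)
  for (i in seq_len(n))
    w("%d %d %d %.6f %.8f %.8f %.8f", i, sys$site_mol[i], sys$site_kind[i],
      q[i], sys$pos[i, 1], sys$pos[i, 2], sys$pos[i, 3])
  match_rows <- function(m, tab) {
    key <- apply(m, 1, paste, collapse = "_")
    tkey <- apply(tab, 1, paste, collapse = "_")
    match(key, tkey)
  }
  if (nrow(sys$bonds)) {
    w(""); w("Bonds"); w("")
    ty <- match_rows(cbind(sys$bond_k, sys$bond_r0), bt)
    for (b in seq_len(nrow(sys$bonds)))
      w("%d %d %d %d", b, ty[b], sys$bonds[b, 1], sys$bonds[b, 2])
  }
  if (nrow(sys$angles)) {
    w(""); w("Angles"); w("")
    ty <- match_rows(cbind(sys$angle_k, sys$angle_th0), at)
    for (a in seq_len(nrow(sys$angles)))
      w("%d %d %d %d %d", a, ty[a], sys$angles[a, 1], sys$angles[a, 2],
        sys$angles[a, 3])
  }
  if (nrow(sys$dihedrals)) {
    w(""); w("Dihedrals"); w("")
    ty <- match_rows(sys$dihed_v, dt)
    for (d in seq_len(nrow(sys$dihedrals)))
      w("%d %d %d %d %d %d", d, ty[d], sys$dihedrals[d, 1],
        sys$dihedrals[d, 2], sys$dihedrals[d, 3], sys$dihedrals[d, 4])
  }
  invisible(path)
}

#' Read a LAMMPS-style data file (topology counts and coordinates)
#'
#' Parses the header, Masses, Atoms (full style) and
#' Bonds/Angles/Dihedrals sections written by [write_lammps_data()].
#'
#' @param path input file.
#' @return List: `n_atoms`, `box`, `masses`, `atoms` data frame
#'   (id, mol, type, q, x, y, z), `bonds`, `angles`, `dihedrals`
#'   integer matrices (indices only).
#' @export
read_lammps_data <- function(path) {
  lines <- readLines(path)
  grab_count <- function(what) {
    m <- grep(paste0("^\\s*\\d+\\s+", what, "\\s*$"), lines, value = TRUE)
    if (!length(m)) return(0L)
    as.integer(sub("^\\s*(\\d+).*", "\\1", m[1]))
  }
  n <- grab_count("atoms")
  if (n == 0) stop("parse error: no atom count in header")
  nb <- grab_count("bonds"); na <- grab_count("angles")
  nd <- grab_count("dihedrals")
  bounds <- function(tag) {
    m <- grep(paste0(tag), lines, value = TRUE)[1]
    if (is.na(m)) stop("parse error: missing ", tag)
    v <- as.numeric(strsplit(trimws(m), "\\s+")[[1]][1:2])
    v[2] - v[1]
  }
  box <- c(bounds("xlo xhi"), bounds("ylo yhi"), bounds("zlo zhi"))
  section <- function(name, count, ncol_min) {
    i <- grep(paste0("^", name, "\\b"), lines)[1]
    if (is.na(i)) {
      if (count > 0) stop("parse error: missing section ", name)
      return(NULL)
    }
    body <- lines[(i + 2):(i + 1 + count)]
    if (any(is.na(body)) || length(body) < count)
      stop("parse error: truncated section ", name)
    body <- sub("#.*", "", body)
    parts <- strsplit(trimws(body), "\\s+")
    if (any(vapply(parts, length, 0L) < ncol_min))
      stop("parse error: malformed row in section ", name)
    do.call(rbind, lapply(parts, function(p) as.numeric(p[seq_len(ncol_min)])))
  }
  masses <- section("Masses", max(1, grab_count("atom types")), 2)
  atoms <- section("Atoms", n, 7)
  atoms <- atoms[order(atoms[, 1]), , drop = FALSE]
  res <- list(n_atoms = n, box = box,
              masses = masses,
              atoms = data.frame(id = atoms[, 1], mol = atoms[, 2],
                                 type = atoms[, 3], q = atoms[, 4],
                                 x = atoms[, 5], y = atoms[, 6],
                                 z = atoms[, 7]))
  res$bonds <- if (nb) section("Bonds", nb, 4)[, 3:4, drop = FALSE] else NULL
  res$angles <- if (na) section("Angles", na, 5)[, 3:5, drop = FALSE] else NULL
  res$dihedrals <- if (nd) section("Dihedrals", nd, 6)[, 3:6, drop = FALSE] else NULL
  res
}

#' Read a LAMMPS dump file (`id type x y z` columns)
#'
#' @param path dump file with `ITEM: TIMESTEP / BOX BOUNDS / ATOMS`.
#' @return List of frames: `step`, `box`, `atoms` data frame.
#' @export
read_lammps_dump <- function(path) {
  lines <- readLines(path)
  ts <- grep("^ITEM: TIMESTEP", lines)
  if (!length(ts)) stop("parse error: no ITEM: TIMESTEP found")
  frames <- list()
  for (fi in seq_along(ts)) {
    i <- ts[fi]
    step <- as.integer(lines[i + 1])
    na_i <- grep("^ITEM: NUMBER OF ATOMS", lines[i:length(lines)])[1] + i - 1
    n <- as.integer(lines[na_i + 1])
    bb_i <- grep("^ITEM: BOX BOUNDS", lines[i:length(lines)])[1] + i - 1
    box <- vapply(1:3, function(k) {
      v <- as.numeric(strsplit(trimws(lines[bb_i + k]), "\\s+")[[1]])
      v[2] - v[1]
    }, 0)
    at_i <- grep("^ITEM: ATOMS", lines[i:length(lines)])[1] + i - 1
    cols <- strsplit(sub("^ITEM: ATOMS\\s+", "", lines[at_i]), "\\s+")[[1]]
    if (at_i + n > length(lines))
      stop("parse error: truncated dump frame at line ", at_i)
    body <- do.call(rbind, lapply(lines[(at_i + 1):(at_i + n)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    df <- as.data.frame(body)
    names(df) <- cols[seq_len(ncol(df))]
    df <- df[order(df$id), , drop = FALSE]
    frames[[fi]] <- list(step = step, box = box, atoms = df)
  }
  frames
}

#' Convert frames read from disk into an analysis-ready trajectory
#'
#' Wraps [read_xyz()] or [read_lammps_dump()] output (single species
#' set, constant topology) into the `md_traj` container used by the
#' analysis functions. Molecule ids must be present (extended XYZ) or
#' each atom is treated as its own molecule (dump).
#'
#' @param frames output of [read_xyz()] or [read_lammps_dump()].
#' @param species_of_mol optional character vector naming each
#'   molecule's species; defaults to the species label of the
#'   molecule's first site.
#' @param dt frame interval, fs (used if frames carry no Time).
#' @param unwrapped whether coordinates are continuous across periodic
#'   boundaries.
#' @return An `md_traj`.
#' @export
frames_as_traj <- function(frames, species_of_mol = NULL, dt = 1000,
                           unwrapped = FALSE) {
  f1 <- frames[[1]]
  if (!is.null(f1$atoms)) {   # dump dialect
    pos_list <- lapply(frames, function(f)
      as.matrix(f$atoms[, c("x", "y", "z")]))
    n <- nrow(pos_list[[1]])
    mol <- seq_len(n)
    species <- paste0("type", f1$atoms$type)
    box <- f1$box
    times <- vapply(frames, function(f) f$step * dt, 0)
  } else {
    pos_list <- lapply(frames, `[[`, "pos")
    mol <- f1$mol
    if (any(is.na(mol))) mol <- seq_len(nrow(pos_list[[1]]))
    species <- f1$species
    box <- f1$box
    times <- vapply(frames, function(f)
      if (is.na(f$time)) NA_real_ else f$time, 0)
    if (any(is.na(times))) times <- (seq_along(frames) - 1) * dt
  }
  nmol <- max(mol)
  if (is.null(species_of_mol)) {
    per_site <- if (!is.null(f1$mol_species)) f1$mol_species else species
    species_of_mol <- per_site[match(seq_len(nmol), mol)]
  }
  kinds <- data.frame(name = unique(species), mass = 1, charge = 0,
                      epsilon = 0, sigma = 1, stringsAsFactors = FALSE)
  sys <- molecular_system(kinds, match(species, kinds$name), mol,
                          species_of_mol, pos_list[[1]], box = box,
                          periodic = c(TRUE, TRUE, TRUE))
  nf <- length(pos_list)
  structure(list(system = sys, final = sys, frames = pos_list,
                 records = data.frame(step = seq_len(nf) - 1, time = times,
                                      T = NA, epot = NA, ekin = NA, P = NA),
                 box = matrix(rep(box, each = nf), nf),
                 unwrapped = unwrapped, dt = dt, config = NULL),
            class = "md_traj")
}

#' Write a density profile / partition / MSD result as CSV
#'
#' @param x a `density_profile`, `phase_partition`, data frame, or
#'   `transport_estimate`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_analysis_csv <- function(x, path) {
  df <- if (inherits(x, "density_profile")) {
    data.frame(bin_center = x$centers, mean_count = x$mean_counts)
  } else if (inherits(x, "phase_partition")) {
    cbind(data.frame(frame = seq_len(nrow(x$per_frame))),
          as.data.frame(x$per_frame))
  } else if (inherits(x, "transport_estimate")) {
    x$msd
  } else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
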