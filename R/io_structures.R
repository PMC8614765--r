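# Structure and trajectory containers + PDB / sidecar IO.
#
# Containers follow the bio3d convention: an atom table (data.frame) plus,
# for trajectories, an nframes x 3N coordinate matrix. All lengths are in
# Angstrom, right-handed axes, no periodic wrapping (inputs are assumed
# whole-molecule imaged).

# Three-letter codes treated as protein residues.
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO",
          "SER", "THR", "TRP", "TYR", "VAL")

#' Van der Waals radius tables
#'
#' Named, element-keyed vdW radius tables (Angstrom). The default table
#' (`"bondi"`) uses the standard Bondi radii. Which table is in effect is a
#' configurable, logged parameter of [read_structure()]; per-atom-name
#' overrides can be supplied there.
#'
#' @param name Table name; currently `"bondi"`.
#' @return Named numeric vector, element symbol to radius in Angstrom.
#' @export
#' @examples
#' vdw_radius_table()[["C"]]
vdw_radius_table <- function(name = "bondi") {
  tables <- list(
    bondi = c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
              P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
              SE = 1.90, FE = 2.00, ZN = 1.39, MG = 1.73, "NA" = 2.27,
              K = 2.75, CA = 2.31)
  )
  if (!name %in% names(tables)) {
    stop("unknown vdW radius table: ", name)
  }
  tables[[name]]
}

# Standard atomic weights (amu), used for mass-weighted radius of gyration.
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                    P = 30.974, F = 18.998, CL = 35.45, BR = 79.904,
                    I = 126.904, SE = 78.971, FE = 55.845, ZN = 65.38,
                    MG = 24.305, "NA" = 22.99, K = 39.098, CA = 40.078)

#' Infer the element symbol from a PDB atom name
#'
#' Uses the PDB element field when present, else strips leading digits from
#' the atom name and takes the leading alphabetic character(s), recognising
#' hydrogens named in the `1HB2` / `HG21` styles.
#'
#' @param name Atom-name strings (PDB `elety`).
#' @param elesy Optional element symbols from the PDB element columns.
#' @return Character vector of element symbols (uppercase).
#' @keywords internal
element_from_name <- function(name, elesy = NULL) {
  out <- rep(NA_character_, length(name))
  if (!is.null(elesy)) {
    ok <- !is.na(elesy) & nzchar(trimws(elesy))
    out[ok] <- toupper(trimws(elesy[ok]))
  }
  todo <- is.na(out)
  if (any(todo)) {
    nm <- toupper(gsub("^[0-9']+", "", trimws(name[todo])))
    first <- substr(nm, 1, 1)
    two <- substr(nm, 1, 2)
    el <- first
    el[first == "H"] <- "H"
    # two-letter elements occasionally seen in protein files
    el[two %in% c("CL", "BR", "SE", "FE", "ZN", "MG")] <- two[two %in%
      c("CL", "BR", "SE", "FE", "ZN", "MG")]
    out[todo] <- el
  }
  out
}

#' Render a consensus residue-number key as its display label
#'
#' Integer keys render without a decimal point; half-integer keys (alignment
#' gap positions such as 66.5) keep one decimal.
#'
#' @param x Numeric residue keys.
#' @return Character labels, e.g. `"27"`, `"0"`, `"66.5"`.
#' @export
residue_label <- function(x) {
  ifelse(x %% 1 == 0, as.character(as.integer(round(x))),
         sub("0+$", "", formatC(x, format = "f", digits = 3)))
}

# insertion code <-> +0.5 numeric-key convention: half-integer consensus
# labels cannot live in the integer PDB residue-number field, so they are
# stored on disk as floor(number) with insertion code "A".
.resnum_from_pdb <- function(resno, insert) {
  off <- ifelse(!is.na(insert) & insert == "A", 0.5, 0)
  resno + off
}
.resnum_to_pdb <- function(resnum) {
  frac <- resnum %% 1
  list(resno = as.integer(floor(resnum)),
       insert = ifelse(abs(frac - 0.5) < 1e-9, "A", ""))
}

#' Construct a structure frame
#'
#' A structure frame is one conformation: an atom table with coordinates,
#' element, vdW radius and residue identity in consensus numbering, plus a
#' frame time in ps.
#'
#' @param atoms data.frame with columns `name`, `element`, `vdw`, `x`, `y`,
#'   `z`, `chain`, `resnum` (numeric consensus key), `reslabel`, `resname`,
#'   `is_heavy`, `is_protein`.
#' @param frame_time Time of the frame (ps).
#' @return Object of class `structure_frame`.
#' @export
structure_frame <- function(atoms, frame_time = 0) {
  needed <- c("name", "element", "vdw", "x", "y", "z", "chain",
              "resnum", "reslabel", "resname", "is_heavy", "is_protein")
  miss <- setdiff(needed, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  if (any(atoms$vdw <= 0)) stop("vdW radii must be positive")
  structure(list(atoms = atoms, frame_time = frame_time),
            class = "structure_frame")
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("structure_frame: %d atoms, %d residues, t = %g ps\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resnum))),
              x$frame_time))
  invisible(x)
}

#' Coordinates of a frame as an N x 3 matrix
#' @param frame A `structure_frame`.
#' @return Numeric matrix with columns x, y, z.
#' @export
frame_coords <- function(frame) {
  as.matrix(frame$atoms[, c("x", "y", "z")])
}

# quick format sanity scan so parse errors carry a line number
.scan_pdb_lines <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  at <- grepl("^(ATOM  |HETATM)", lines)
  if (any(at)) {
    bad <- which(at & nchar(lines) < 54)
    if (length(bad)) {
      stop(sprintf("malformed ATOM/HETATM record at line %d of %s (record too short)",
                   bad[1], path))
    }
    xyz <- cbind(substr(lines[at], 31, 38), substr(lines[at], 39, 46),
                 substr(lines[at], 47, 54))
    num <- matrix(suppressWarnings(as.numeric(xyz)), ncol = 3)
    badrow <- which(rowSums(is.na(num)) > 0)
    if (length(badrow)) {
      stop(sprintf("malformed coordinates at line %d of %s",
                   which(at)[badrow[1]], path))
    }
  }
  invisible(sum(at))
}

.atoms_from_bio3d <- function(pdb_atom, radius_set, default_radius,
                              radius_overrides = NULL) {
  element <- element_from_name(pdb_atom$elety, pdb_atom$elesy)
  rt <- vdw_radius_table(radius_set)
  vdw <- unname(rt[element])
  unknown <- is.na(vdw)
  if (any(unknown)) {
    warning(sprintf("%d atom(s) with elements outside the '%s' table assigned default radius %.2f A (elements: %s)",
                    sum(unknown), radius_set, default_radius,
                    paste(unique(element[unknown]), collapse = ", ")))
    vdw[unknown] <- default_radius
  }
  if (!is.null(radius_overrides)) {
    hit <- match(trimws(pdb_atom$elety), names(radius_overrides))
    vdw[!is.na(hit)] <- unname(radius_overrides[hit[!is.na(hit)]])
  }
  chain <- pdb_atom$chain
  chain[is.na(chain)] <- "A"
  resnum <- .resnum_from_pdb(pdb_atom$resno, pdb_atom$insert)
  data.frame(
    name = trimws(pdb_atom$elety),
    element = element,
    vdw = vdw,
    x = pdb_atom$x, y = pdb_atom$y, z = pdb_atom$z,
    chain = chain,
    resnum = resnum,
    reslabel = residue_label(resnum),
    resname = pdb_atom$resid,
    is_heavy = element != "H",
    is_protein = pdb_atom$resid %in% .aa3 & pdb_atom$type == "ATOM",
    stringsAsFactors = FALSE
  )
}

#' Read a single-model PDB file into a structure frame
#'
#' Every atom gets an element and a vdW radius from the chosen table;
#' unknown elements receive `default_radius` with a warning. Half-integer
#' consensus residue numbers are recovered from insertion code `"A"`
#' (e.g. residue 66 with insertion code A reads as key 66.5, label "66.5").
#'
#' @param path PDB file path.
#' @param radius_set Name of the vdW radius table (see [vdw_radius_table()]).
#' @param default_radius Radius (Angstrom) for elements missing from the table.
#' @param radius_overrides Optional named vector of per-atom-name radii.
#' @return A [structure_frame()].
#' @export
read_structure <- function(path, radius_set = "bondi", default_radius = 1.5,
                           radius_overrides = NULL) {
  lines <- readLines(path, warn = FALSE)
  n_at <- .scan_pdb_lines(lines, path)
  if (n_at == 0) stop("empty input: no ATOM/HETATM records in ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- .atoms_from_bio3d(pdb$atom, radius_set, default_radius,
                             radius_overrides)
  structure_frame(atoms, frame_time = 0)
}

#' Write a structure frame (or trajectory) as PDB
#'
#' Half-integer residue keys are written as the floor number plus insertion
#' code `"A"`, the standard escape hatch for an integer-only column.
#'
#' @param x A `structure_frame` or `trajectory`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "trajectory")) {
    atoms <- x$atoms
    xyz <- x$xyz
  } else {
    atoms <- x$atoms
    xyz <- matrix(t(as.matrix(atoms[, c("x", "y", "z")])), nrow = 1)
  }
  pd <- .resnum_to_pdb(atoms$resnum)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = pd$resno, insert = pd$insert,
                   resid = atoms$resname, chain = atoms$chain,
                   elety = atoms$name, elesy = atoms$element)
  invisible(path)
}

#' Read or write the ensemble metadata sidecar
#'
#' The sidecar is a key-value text file (YAML subset) carrying
#' `temperature_K`, `pressure_bar` and `sampling_interval_ps` for one
#' trajectory. The quasiharmonic analysis cannot run without it.
#'
#' @param path Sidecar file path.
#' @return Named list with the three fields.
#' @export
read_sidecar <- function(path) {
  meta <- yaml::read_yaml(path)
  needed <- c("temperature_K", "pressure_bar", "sampling_interval_ps")
  miss <- setdiff(needed, names(meta))
  if (length(miss)) {
    stop("ensemble sidecar ", path, " missing fields: ",
         paste(miss, collapse = ", "))
  }
  meta[needed]
}

#' @rdname read_sidecar
#' @param meta Named list (or trajectory) holding the three fields.
#' @export
write_sidecar <- function(meta, path) {
  if (inherits(meta, "trajectory")) {
    meta <- list(temperature_K = meta$temperature,
                 pressure_bar = meta$pressure,
                 sampling_interval_ps = meta$sampling_interval)
  }
  yaml::write_yaml(meta, path)
  invisible(path)
}

#' Construct a trajectory
#'
#' @param atoms Atom table as in [structure_frame()] (coordinates ignored).
#' @param xyz Numeric matrix, one row per frame, 3N columns (x1,y1,z1,...).
#' @param temperature Temperature (K).
#' @param pressure Pressure (bar).
#' @param sampling_interval Frame spacing (ps).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(atoms, xyz, temperature, pressure,
                       sampling_interval = 1) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (nrow(xyz) < 1) stop("trajectory needs at least one frame")
  if (ncol(xyz) != 3 * nrow(atoms)) {
    stop("xyz has ", ncol(xyz), " columns but atom table implies ",
         3 * nrow(atoms))
  }
  if (is.null(temperature) || is.null(pressure) ||
      is.na(temperature) || is.na(pressure)) {
    stop("trajectory requires temperature (K) and pressure (bar) metadata")
  }
  structure(list(atoms = atoms, xyz = xyz,
                 temperature = temperature, pressure = pressure,
                 sampling_interval = sampling_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, dt = %g ps, T = %g K, P = %g bar\n",
              nrow(x$xyz), nrow(x$atoms), x$sampling_interval,
              x$temperature, x$pressure))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame of a trajectory as a structure frame
#' @param traj A `trajectory`.
#' @param i Frame index (1-based).
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= nrow(traj$xyz))
  atoms <- traj$atoms
  m <- matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
  atoms$x <- m[, 1]; atoms$y <- m[, 2]; atoms$z <- m[, 3]
  structure_frame(atoms, frame_time = (i - 1) * traj$sampling_interval)
}

# per-model atom identity signature used to verify consistent ordering
.model_signatures <- function(lines) {
  at <- grepl("^(ATOM  |HETATM)", lines)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    return(list(paste(substr(lines[at], 13, 27), collapse = "\n")))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  lapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[i]]
    paste(substr(block[grepl("^(ATOM  |HETATM)", block)], 13, 27),
          collapse = "\n")
  })
}

#' Read a (multi-model) PDB trajectory with its ensemble sidecar
#'
#' @param paths One multi-model PDB path, or a vector of single-model paths
#'   in frame order.
#' @param metadata Sidecar file path or a named list with `temperature_K`,
#'   `pressure_bar`, `sampling_interval_ps`.
#' @inheritParams read_structure
#' @return A [trajectory()].
#' @export
read_trajectory <- function(paths, metadata, radius_set = "bondi",
                            default_radius = 1.5, radius_overrides = NULL) {
  if (missing(metadata) || is.null(metadata)) {
    stop("ensemble metadata (temperature_K, pressure_bar, sampling_interval_ps) is required")
  }
  meta <- if (is.character(metadata)) read_sidecar(metadata) else metadata
  needed <- c("temperature_K", "pressure_bar", "sampling_interval_ps")
  miss <- setdiff(needed, names(meta))
  if (length(miss)) stop("metadata missing fields: ", paste(miss, collapse = ", "))

  read_one <- function(p) {
    lines <- readLines(p, warn = FALSE)
    if (.scan_pdb_lines(lines, p) == 0) {
      stop("empty input: no ATOM/HETATM records in ", p)
    }
    sig <- .model_signatures(lines)
    if (length(unique(vapply(sig, identity, ""))) > 1) {
      stop("inconsistent atom ordering/count across models in ", p)
    }
    bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
  }

  pdbs <- lapply(paths, read_one)
  atoms <- .atoms_from_bio3d(pdbs[[1]]$atom, radius_set, default_radius,
                             radius_overrides)
  xyz <- do.call(rbind, lapply(pdbs, function(p) unclass(p$xyz)))
  if (length(pdbs) > 1) {
    ncols <- vapply(pdbs, function(p) ncol(p$xyz), 0L)
    if (length(unique(ncols)) > 1) {
      stop("inconsistent atom count across trajectory files")
    }
  }
  trajectory(atoms, xyz,
             temperature = meta$temperature_K,
             pressure = meta$pressure_bar,
             sampling_interval = meta$sampling_interval_ps)
}

#' Apply a consensus residue-numbering map
#'
#' Renumbers residues into the consensus scheme (alignment against a
#' reference sequence, admitting half-integer keys such as 66.5 for gap
#' positions). Original labels are retained in an `orig_label` column.
#'
#' @param frame A `structure_frame` (or `trajectory`).
#' @param map data.frame with numeric columns `old` and `new`; optionally a
#'   `chain` column to scope rows to one chain.
#' @return Object of the same class with residues renumbered.
#' @export
apply_numbering_map <- function(frame, map) {
  atoms <- frame$atoms
  key <- if ("chain" %in% names(map)) {
    paste(atoms$chain, atoms$resnum)
  } else {
    as.character(atoms$resnum)
  }
  mkey <- if ("chain" %in% names(map)) {
    paste(map$chain, map$old)
  } else {
    as.character(map$old)
  }
  idx <- match(key, mkey)
  if (anyNA(idx)) {
    missing_res <- unique(atoms$reslabel[is.na(idx)])
    stop("numbering map does not cover residue(s): ",
         paste(missing_res, collapse = ", "))
  }
  atoms$orig_label <- atoms$reslabel
  atoms$resnum <- map$new[idx]
  atoms$reslabel <- residue_label(atoms$resnum)
  ord <- order(atoms$chain, atoms$resnum)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  if (inherits(frame, "trajectory")) {
    cols <- as.vector(rbind(3 * ord - 2, 3 * ord - 1, 3 * ord))
    trajectory(atoms, frame$xyz[, cols, drop = FALSE], frame$temperature,
               frame$pressure, frame$sampling_interval)
  } else {
    structure_frame(atoms, frame$frame_time)
  }
}
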