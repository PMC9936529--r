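#' @useDynLib epibind, .registration = TRUE
#' @keywords internal
"_PACKAGE"

# Standard atomic masses (u) for center-of-mass computation.
.ATOMIC_MASSES <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078, "NA" = 22.990,
  K = 39.098,
  MN = 54.938, CU = 63.546
)

#' Construct a structure model
#'
#' A structure model is the atomic unit consumed by all pose and trajectory
#' operations: an ordered table of atoms with coordinates in Angstrom,
#' chain/residue identity and an optional per-atom B-factor (which carries the
#' per-residue pLDDT confidence for predicted models).
#'
#' @param atoms `data.frame` with columns `serial` (integer), `name` (atom
#'   name), `element` (element symbol, upper case), `x`, `y`, `z` (Angstrom),
#'   `chain_id`, `residue_index` (author numbering, integer), `ins` (insertion
#'   code, `""` if none), `residue_name` (3-letter code), `occupancy`,
#'   `bfactor`.
#' @param model_id identifier string.
#' @param source_format string recording where the model came from.
#' @return An object of class `structure_model`. A derived logical column
#'   `is_hydrogen` (`TRUE` iff element is H or D) and a residue key column
#'   `residue_key` (`residue_index` with any insertion code appended) are
#'   added.
#' @export
structure_model <- function(atoms, model_id = "model", source_format = "r") {
  stopifnot(is.data.frame(atoms))
  required <- c("serial", "name", "element", "x", "y", "z", "chain_id",
                "residue_index", "residue_name", "bfactor")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    stop("atoms is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("structure model must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("all atom coordinates must be finite")
  }
  if (is.null(atoms$ins)) atoms$ins <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1.0
  atoms$element <- toupper(trimws(atoms$element))
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  atoms$residue_key <- paste0(atoms$residue_index, atoms$ins)
  key <- paste(atoms$chain_id, atoms$residue_key, atoms$name, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom name) identity: ",
         key[duplicated(key)][1])
  }
  structure(list(atoms = atoms, model_id = model_id,
                 source_format = source_format),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- table(x$atoms$chain_id)
  cat("structure_model '", x$model_id, "': ", nrow(x$atoms), " atoms, ",
      length(ch), " chain(s) [",
      paste(sprintf("%s:%d", names(ch), as.integer(ch)), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Extract the coordinate matrix of a structure model
#'
#' @param model a `structure_model`.
#' @return numeric matrix (n_atoms x 3), Angstrom.
#' @export
coords <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure model
#'
#' @param model a `structure_model`.
#' @param xyz numeric matrix (n_atoms x 3).
#' @return the model with new coordinates.
#' @export
set_coords <- function(model, xyz) {
  stopifnot(inherits(model, "structure_model"),
            is.matrix(xyz), nrow(xyz) == nrow(model$atoms), ncol(xyz) == 3)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# Parse the fixed-column fields of ATOM/HETATM records (vectorised).
# `linenos` are original file line numbers used in error messages.
.parse_atom_records <- function(lines, linenos) {
  short <- nchar(lines) < 54
  if (any(short)) {
    stop("malformed ATOM/HETATM record at line ", linenos[short][1],
         ": record shorter than coordinate fields", call. = FALSE)
  }
  lines <- formatC(lines, width = -80)  # right-pad so optional columns exist
  num <- function(from, to, what) {
    s <- substr(lines, from, to)
    v <- suppressWarnings(as.numeric(s))
    bad <- is.na(v)
    if (any(bad)) {
      stop("malformed ATOM/HETATM record at line ", linenos[bad][1],
           ": cannot parse ", what, " from '", trimws(s[bad][1]), "'",
           call. = FALSE)
    }
    v
  }
  name <- trimws(substr(lines, 13, 16))
  element <- trimws(substr(lines, 77, 78))
  blank <- element == ""
  if (any(blank)) {
    # fall back to the leading alphabetic character of the atom name
    stripped <- gsub("[^A-Za-z]", "", name[blank])
    fb <- ifelse(nchar(stripped) > 0, substr(stripped, 1, 1), "X")
    element[blank] <- fb
  }
  occ <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
  bf <- suppressWarnings(as.numeric(substr(lines, 61, 66)))
  data.frame(
    record = trimws(substr(lines, 1, 6)),
    serial = as.integer(num(7, 11, "serial")),
    name = name,
    altloc = trimws(substr(lines, 17, 17)),
    residue_name = trimws(substr(lines, 18, 20)),
    chain_id = trimws(substr(lines, 22, 22)),
    residue_index = as.integer(num(23, 26, "residue number")),
    ins = trimws(substr(lines, 27, 27)),
    x = num(31, 38, "x"),
    y = num(39, 46, "y"),
    z = num(47, 54, "z"),
    occupancy = ifelse(is.na(occ), 1.0, occ),
    bfactor = ifelse(is.na(bf), 0.0, bf),
    element = toupper(element),
    stringsAsFactors = FALSE
  )
}

# Apply the single-conformer altloc policy: per (chain, residue, atom name)
# keep the highest-occupancy record, ties broken by altloc letter ('A' wins).
.apply_altloc_policy <- function(atoms) {
  alt <- atoms$altloc != ""
  if (!any(alt)) return(atoms)
  key <- paste(atoms$chain_id, atoms$residue_index, atoms$ins, atoms$name,
               sep = "|")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[alt])) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    grp <- atoms[idx, ]
    best <- idx[order(-grp$occupancy, grp$altloc)][1]
    keep[idx] <- FALSE
    keep[best] <- TRUE
  }
  atoms[keep, , drop = FALSE]
}

.atoms_from_lines <- function(lines, linenos, include_het = FALSE) {
  recs <- substr(lines, 1, 6)
  is_atom <- grepl("^ATOM", recs) | (include_het & grepl("^HETATM", recs))
  lines <- lines[is_atom]
  linenos <- linenos[is_atom]
  if (length(lines) == 0) return(NULL)
  parsed <- .parse_atom_records(lines, linenos)
  parsed <- .apply_altloc_policy(parsed)
  parsed$altloc <- NULL
  parsed$record <- NULL
  parsed
}

#' Read a structure from a PDB file
#'
#' Parses PDB v3.3 `ATOM` (and optionally `HETATM`) coordinate records.
#' Coordinates are taken from columns 31-54, the B-factor column (61-66) is
#' preserved verbatim (it carries pLDDT for predicted models), and the element
#' is taken from columns 77-78, falling back to the leading alphabetic
#' character of the atom name. Alternate locations are collapsed to a single
#' conformer: the highest-occupancy record wins, ties broken by altloc letter.
#' If the file contains multiple `MODEL` blocks, the first is returned with a
#' warning (use [read_trajectory()] for ensembles). By default only polymer
#' (`ATOM`) records are read; set `include_het = TRUE` to keep `HETATM`
#' records (waters, ions, ligands).
#'
#' @param path path to a PDB file.
#' @param format only `"pdb"` is supported.
#' @param include_het keep `HETATM` records? Default `FALSE`.
#' @param model_id identifier; defaults to the file name.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, format = "pdb", include_het = FALSE,
                           model_id = NULL) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  linenos <- seq_along(lines)
  model_starts <- which(grepl("^MODEL", lines))
  if (length(model_starts) > 1) {
    warning("multi-model PDB file: returning the first of ",
            length(model_starts), " models")
    ends <- which(grepl("^ENDMDL", lines))
    stopidx <- if (length(ends) > 0) ends[1] else length(lines)
    sel <- seq(model_starts[1], stopidx)
    lines <- lines[sel]
    linenos <- linenos[sel]
  }
  atoms <- .atoms_from_lines(lines, linenos, include_het = include_het)
  if (is.null(atoms)) stop("no atoms found in ", path)
  structure_model(atoms,
                  model_id = if (is.null(model_id)) basename(path) else model_id,
                  source_format = "pdb")
}

.format_atom_name <- function(name, element) {
  # PDB convention: element right-justified in columns 13-14, so 1-3 character
  # names with 1-letter elements start in column 14.
  if (nchar(name) >= 4) return(substr(name, 1, 4))
  if (nchar(element) == 1) formatC(paste0(" ", name), width = -4)
  else formatC(name, width = -4)
}

.atom_lines <- function(atoms) {
  names4 <- mapply(.format_atom_name, atoms$name, atoms$element)
  sprintf("ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000L, names4, atoms$residue_name,
          atoms$chain_id, atoms$residue_index,
          ifelse(atoms$ins == "", " ", atoms$ins),
          atoms$x, atoms$y, atoms$z, atoms$occupancy, atoms$bfactor,
          formatC(atoms$element, width = 2))
}

#' Write a structure model to a PDB file
#'
#' @param model a [structure_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  writeLines(c(.atom_lines(model$atoms), "END"), path)
  invisible(path)
}

#' Construct a trajectory
#'
#' @param topology a [structure_model()] giving atom identities.
#' @param frames numeric array `n_frames x n_atoms x 3` (Angstrom), or a list
#'   of `n_atoms x 3` matrices.
#' @param frame_times numeric vector of frame times in ns, strictly
#'   increasing and non-negative. Defaults to `0, 1, 2, ...`.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, frame_times = NULL) {
  stopifnot(inherits(topology, "structure_model"))
  if (is.list(frames)) {
    frames <- aperm(simplify2array(frames), c(3, 1, 2))
  }
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == 3)
  if (dim(frames)[2] != nrow(topology$atoms)) {
    stop("frame atom count (", dim(frames)[2],
         ") does not match topology atom count (", nrow(topology$atoms), ")")
  }
  n <- dim(frames)[1]
  if (is.null(frame_times)) frame_times <- seq_len(n) - 1
  if (length(frame_times) != n) stop("frame_times length must equal n_frames")
  if (any(frame_times < 0) || any(diff(frame_times) <= 0)) {
    stop("frame_times must be non-negative and strictly increasing")
  }
  structure(list(topology = topology, frames = frames,
                 frame_times = as.numeric(frame_times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory: ", dim(x$frames)[1], " frames x ", dim(x$frames)[2],
      " atoms, t = [", min(x$frame_times), ", ", max(x$frame_times),
      "] ns\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[1]

#' Extract one frame of a trajectory as a coordinate matrix
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, i) {
  m <- traj$frames[i, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame, in file order. All blocks
#' must contain the identical atom identity sequence (chain, residue, name,
#' element). Frame times are taken from `REMARK ... TIME= <t> NS` annotations
#' inside each model block when present, otherwise default to `0, 1, 2, ...`
#' ns. A file without `MODEL` records is read as a single-frame trajectory.
#'
#' @param path path to a multi-model PDB file.
#' @param format only `"pdb-multimodel"` is supported (binary-format adapters
#'   can wrap this contract).
#' @param include_het keep `HETATM` records? Default `FALSE`.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, format = "pdb-multimodel",
                            include_het = FALSE) {
  format <- match.arg(format, "pdb-multimodel")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(grepl("^MODEL", lines))
  if (length(starts) == 0) {
    model <- read_structure(path, include_het = include_het)
    return(trajectory(model,
                      array(coords(model), dim = c(1, nrow(model$atoms), 3)),
                      frame_times = 0))
  }
  ends <- which(grepl("^ENDMDL", lines))
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  blocks <- Map(function(s, e) seq(s, e), starts, ends[seq_along(starts)])

  topo <- NULL
  frames <- vector("list", length(blocks))
  times <- rep(NA_real_, length(blocks))
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    tm <- regmatches(lines[idx],
                     regexpr("TIME[=:] *([0-9.eE+-]+)", lines[idx]))
    if (length(tm) > 0) {
      times[b] <- as.numeric(sub("TIME[=:] *", "", tm[1]))
    }
    atoms <- .atoms_from_lines(lines[idx], idx, include_het = include_het)
    if (is.null(atoms)) stop("model block ", b, " contains no atoms")
    if (b == 1) {
      topo <- structure_model(atoms, model_id = basename(path),
                              source_format = "pdb-multimodel")
      ident1 <- paste(atoms$chain_id, atoms$residue_index, atoms$ins,
                      atoms$name, atoms$element, sep = "|")
    } else {
      ident <- paste(atoms$chain_id, atoms$residue_index, atoms$ins,
                     atoms$name, atoms$element, sep = "|")
      if (length(ident) != length(ident1) || any(ident != ident1)) {
        stop("inconsistent topology: model block ", b,
             " differs in atom identity sequence from block 1")
      }
    }
    frames[[b]] <- as.matrix(atoms[, c("x", "y", "z")])
  }
  if (all(is.na(times))) {
    times <- seq_along(blocks) - 1
  } else if (anyNA(times)) {
    stop("TIME remarks present for some but not all model blocks")
  }
  trajectory(topo, frames, frame_times = times)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Frame times are recorded as `REMARK   6 TIME= <t> NS` lines so that
#' [read_trajectory()] round-trips them.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  out <- character(0)
  model <- traj$topology
  for (i in seq_len(n_frames(traj))) {
    m <- set_coords(model, frame_coords(traj, i))
    out <- c(out,
             sprintf("MODEL     %4d", i),
             sprintf("REMARK   6 TIME= %.6f NS", traj$frame_times[i]),
             .atom_lines(m$atoms),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Construct a replica ensemble
#'
#' A set of independent trajectories of the same system sharing one topology;
#' the unit over which ensemble statistics (mean and standard error across
#' replicas) are computed.
#'
#' @param replicas list of [trajectory()] objects with identical topologies
#'   (atom count and identity sequence).
#' @param complex_label label for the simulated complex.
#' @return an object of class `replica_ensemble`.
#' @export
replica_ensemble <- function(replicas, complex_label = "complex") {
  stopifnot(is.list(replicas), length(replicas) >= 1)
  for (r in replicas) stopifnot(inherits(r, "trajectory"))
  ident <- function(tr) {
    a <- tr$topology$atoms
    paste(a$chain_id, a$residue_key, a$name, a$element, sep = "|")
  }
  id1 <- ident(replicas[[1]])
  for (i in seq_along(replicas)[-1]) {
    if (!identical(ident(replicas[[i]]), id1)) {
      stop("replica ", i, " does not share the ensemble topology")
    }
  }
  structure(list(replicas = replicas, complex_label = complex_label,
                 per_replica_duration = vapply(
                   replicas, function(r) max(r$frame_times), numeric(1))),
            class = "replica_ensemble")
}

#' @export
print.replica_ensemble <- function(x, ...) {
  cat("replica_ensemble '", x$complex_label, "': ", length(x$replicas),
      " replicas, ", paste(vapply(x$replicas, n_frames, integer(1)),
                           collapse = "/"),
      " frames\n", sep = "")
  invisible(x)
}

#' Resolve a selection expression to atom indices
#'
#' Selections are conjunctions of clauses joined by `and`. Supported clauses:
#' `chain <id> [<id> ...]`, `resid <a>[:<b>] [...]` (author numbering,
#' insertion codes appended, e.g. `52A`), `name <atom> [...]`, and the atom
#' classes `all`, `heavy` (non-hydrogen), `hydrogen`, `CA`, `backbone`
#' (N, CA, C, O). The result is a deterministic ordered index vector in file
#' order; an empty result is allowed, but referencing a chain id absent from
#' the model is an error.
#'
#' @param model a [structure_model()].
#' @param sel selection expression string.
#' @return integer vector of atom indices (1-based, file order).
#' @examples
#' \dontrun{resolve_selection(model, "chain A and heavy")}
#' @export
resolve_selection <- function(model, sel) {
  stopifnot(inherits(model, "structure_model"), is.character(sel),
            length(sel) == 1)
  atoms <- model$atoms
  keep <- rep(TRUE, nrow(atoms))
  clauses <- trimws(strsplit(sel, "\\band\\b")[[1]])
  clauses <- clauses[nzchar(clauses)]
  if (length(clauses) == 0) stop("empty selection expression")
  for (cl in clauses) {
    toks <- strsplit(gsub(",", " ", cl), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    head <- toks[1]
    args <- toks[-1]
    if (head == "chain") {
      if (length(args) == 0) stop("selection: 'chain' needs at least one id")
      unknown <- setdiff(args, unique(atoms$chain_id))
      if (length(unknown) > 0) {
        stop("unknown chain id in selection: ",
             paste(unknown, collapse = ", "))
      }
      keep <- keep & atoms$chain_id %in% args
    } else if (head == "resid") {
      if (length(args) == 0) stop("selection: 'resid' needs arguments")
      want <- rep(FALSE, nrow(atoms))
      for (a in args) {
        if (grepl(":", a)) {
          rng <- as.integer(strsplit(a, ":")[[1]])
          if (anyNA(rng) || length(rng) != 2) {
            stop("selection: bad resid range '", a, "'")
          }
          want <- want | (atoms$residue_index >= rng[1] &
                          atoms$residue_index <= rng[2])
        } else {
          want <- want | atoms$residue_key == a
        }
      }
      keep <- keep & want
    } else if (head == "name") {
      if (length(args) == 0) stop("selection: 'name' needs arguments")
      keep <- keep & atoms$name %in% args
    } else if (head == "all" && length(args) == 0) {
      # no-op
    } else if (head == "heavy" && length(args) == 0) {
      keep <- keep & !atoms$is_hydrogen
    } else if (head == "hydrogen" && length(args) == 0) {
      keep <- keep & atoms$is_hydrogen
    } else if (head %in% c("CA", "ca") && length(args) == 0) {
      keep <- keep & atoms$name == "CA"
    } else if (head == "backbone" && length(args) == 0) {
      keep <- keep & atoms$name %in% c("N", "CA", "C", "O")
    } else {
      stop("selection: cannot parse clause '", cl, "'")
    }
  }
  which(keep)
}

#' Center of mass of one residue
#'
#' @param frame `n_atoms x 3` coordinate matrix aligned with `model`.
#' @param model a [structure_model()].
#' @param residue length-2 character vector `c(chain_id, residue_key)`;
#'   the residue key is the author residue number with any insertion code
#'   appended (e.g. `"52"` or `"52A"`).
#' @param mass_weighted if `TRUE` (default) weight by standard atomic masses
#'   of the elements; if `FALSE` take the unweighted arithmetic mean.
#' @return length-3 numeric vector (Angstrom).
#' @export
residue_com <- function(frame, model, residue, mass_weighted = TRUE) {
  stopifnot(inherits(model, "structure_model"), length(residue) == 2)
  atoms <- model$atoms
  idx <- which(atoms$chain_id == residue[1] &
               atoms$residue_key == as.character(residue[2]))
  if (length(idx) == 0) {
    stop("residue not found: chain ", residue[1], " residue ", residue[2])
  }
  xyz <- frame[idx, , drop = FALSE]
  if (!mass_weighted) return(colMeans(xyz))
  el <- atoms$element[idx]
  m <- .ATOMIC_MASSES[el]
  if (anyNA(m)) {
    stop("no standard atomic mass for element(s): ",
         paste(unique(el[is.na(m)]), collapse = ", "))
  }
  as.numeric(colSums(xyz * m) / sum(m))
}

# Residue table: one row per residue in file order, with the index range of
# its atoms. Internal helper shared by trimming, RMSF and epitope mapping.
.residue_table <- function(model) {
  a <- model$atoms
  key <- paste(a$chain_id, a$residue_key, sep = "|")
  first <- !duplicated(key)
  data.frame(chain_id = a$chain_id[first],
             residue_key = a$residue_key[first],
             residue_name = a$residue_name[first],
             key = key[first],
             stringsAsFactors = FALSE)
}
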