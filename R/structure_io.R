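#' @useDynLib mdsie, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd rnorm runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Column order of the atom table carried by every molecular_system.
.atom_cols <- c("serial", "name", "element", "res_name", "res_id", "icode",
                "chain", "x", "y", "z", "occupancy", "charge",
                "lj_rmin_half", "lj_epsilon", "vdw_radius")

#' Construct a molecular system from an atom table
#'
#' A `molecular_system` is the container every analysis stage consumes: an
#' ordered atom table (coordinates in Angstrom, partial charges in e,
#' Lennard-Jones parameters in Angstrom / kcal/mol) plus named atom-index
#' selections (`protein`, `ligand`, ...).
#'
#' @param atoms data.frame with at least columns `name`, `res_name`, `res_id`,
#'   `chain`, `x`, `y`, `z`. Missing annotation columns are filled with `NA`.
#' @param groups named list of integer atom-index vectors.
#' @return object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, groups = list()) {
  stopifnot(is.data.frame(atoms))
  for (col in .atom_cols) {
    if (!col %in% names(atoms)) {
      atoms[[col]] <- switch(col,
        serial = seq_len(nrow(atoms)),
        element = guess_element(atoms$name),
        icode = "",
        occupancy = 1,
        NA_real_)
    }
  }
  atoms <- atoms[, .atom_cols]
  atoms$res_id <- as.integer(atoms$res_id)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in atom table")
  key <- paste(atoms$chain, atoms$res_id, atoms$icode, atoms$name)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate atom identity (chain, res_id, name): ", d)
  }
  n <- nrow(atoms)
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (length(idx) && (min(idx) < 1 || max(idx) > n))
      stop("selection '", g, "' contains invalid atom indices")
  }
  structure(list(atoms = atoms, groups = groups), class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("molecular_system:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$res_id))), "residues\n")
  for (g in names(x$groups))
    cat("  group", g, ":", length(x$groups[[g]]), "atoms\n")
  invisible(x)
}

#' Coordinates of a system as an N x 3 matrix
#' @param system a `molecular_system`
#' @return numeric matrix
#' @export
coords <- function(system) {
  unname(as.matrix(system$atoms[, c("x", "y", "z")]))
}

#' Replace the coordinates of a system
#' @param system a `molecular_system`
#' @param xyz N x 3 matrix
#' @return updated system
#' @export
set_coords <- function(system, xyz) {
  stopifnot(nrow(xyz) == nrow(system$atoms), ncol(xyz) == 3)
  system$atoms$x <- xyz[, 1]
  system$atoms$y <- xyz[, 2]
  system$atoms$z <- xyz[, 3]
  system
}

# Element symbol from a PDB atom name (column 13-16 convention: digits and
# primes stripped, leading element letters kept; two-letter elements only
# when the name starts in column 13).
guess_element <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  el <- substr(nm, 1, 1)
  two <- toupper(substr(nm, 1, 2))
  el[two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")] <-
    two[two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")]
  toupper(el)
}

#' Select atom indices by residue / name / element
#'
#' @param system a `molecular_system`
#' @param chain,res_id,res_name,name,element optional filters (vectors allowed)
#' @param group restrict to a named selection first
#' @return integer vector of atom indices
#' @export
select_atoms <- function(system, chain = NULL, res_id = NULL, res_name = NULL,
                         name = NULL, element = NULL, group = NULL) {
  a <- system$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(group)) {
    if (is.null(system$groups[[group]])) stop("no such group: ", group)
    keep <- keep & seq_len(nrow(a)) %in% system$groups[[group]]
  }
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(res_id)) keep <- keep & a$res_id %in% res_id
  if (!is.null(res_name)) keep <- keep & a$res_name %in% res_name
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(element)) keep <- keep & a$element %in% element
  which(keep)
}

# ---------------------------------------------------------------------------
# PDB reading / writing

parse_pdb_atom_lines <- function(lines, path = "<text>") {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  lines <- lines[is_atom]
  if (!length(lines)) stop("no ATOM/HETATM records in ", path)
  fw <- function(from, to) trimws(substr(lines, from, to))
  num <- function(from, to, what) {
    s <- fw(from, to)
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("malformed ", what, " field in PDB line: ", lines[bad])
    }
    v
  }
  data.frame(
    record = substr(lines, 1, 6),
    serial = as.integer(num(7, 11, "serial")),
    name = fw(13, 16),
    altloc = fw(17, 17),
    res_name = fw(18, 20),
    chain = fw(22, 22),
    res_id = as.integer(num(23, 26, "residue number")),
    icode = fw(27, 27),
    x = num(31, 38, "x coordinate"),
    y = num(39, 46, "y coordinate"),
    z = num(47, 54, "z coordinate"),
    occupancy = {
      o <- suppressWarnings(as.numeric(fw(55, 60)))
      o[is.na(o)] <- 1
      o
    },
    element = toupper(fw(77, 78)),
    stringsAsFactors = FALSE)
}

# Resolve alternate locations: keep highest occupancy, ties -> first seen.
resolve_altloc <- function(tab) {
  has_alt <- tab$altloc != ""
  if (!any(has_alt)) return(tab)
  key <- paste(tab$chain, tab$res_id, tab$icode, tab$name)
  ord <- order(key, -tab$occupancy, seq_len(nrow(tab)))
  keep <- !duplicated(key[ord])
  kept <- sort(ord[keep])
  n_drop <- nrow(tab) - length(kept)
  if (n_drop > 0)
    message("resolved alternate locations: dropped ", n_drop,
            " lower-occupancy records (ties keep first encountered)")
  tab[kept, , drop = FALSE]
}

#' Read a PDB structure file
#'
#' Parses ATOM/HETATM records. Alternate locations are resolved to the
#' highest-occupancy conformer (ties: first encountered); insertion codes are
#' preserved. ATOM records populate the `protein` selection, HETATM records
#' (excluding waters) the `ligand` selection.
#'
#' @param path file path, or a character vector of PDB lines via `text=`
#' @param text optional character vector of PDB lines instead of a file
#' @return a [molecular_system()]
#' @export
read_pdb <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  src <- if (is.null(text)) path else "<text>"
  tab <- parse_pdb_atom_lines(lines, src)
  tab <- resolve_altloc(tab)
  el <- tab$element
  miss <- el == "" | is.na(el)
  el[miss] <- guess_element(tab$name[miss])
  prot <- which(tab$record == "ATOM  ")
  lig <- which(tab$record == "HETATM" & !tab$res_name %in% c("HOH", "WAT"))
  atoms <- data.frame(
    serial = tab$serial, name = tab$name, element = el,
    res_name = tab$res_name, res_id = tab$res_id, icode = tab$icode,
    chain = tab$chain, x = tab$x, y = tab$y, z = tab$z,
    occupancy = tab$occupancy,
    charge = NA_real_, lj_rmin_half = NA_real_, lj_epsilon = NA_real_,
    vdw_radius = NA_real_, stringsAsFactors = FALSE)
  molecular_system(atoms, groups = list(protein = prot, ligand = lig))
}

format_pdb_lines <- function(system, hetatm_groups = "ligand") {
  a <- system$atoms
  het <- rep(FALSE, nrow(a))
  for (g in intersect(hetatm_groups, names(system$groups)))
    het[system$groups[[g]]] <- TRUE
  rec <- ifelse(het, "HETATM", "ATOM  ")
  # PDB v3 atom-name justification: 4-char names flush, shorter start col 14
  nm <- vapply(a$name, function(s) {
    if (nchar(s) >= 4) substr(s, 1, 4) else sprintf(" %-3s", s)
  }, "")
  sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, a$serial %% 100000L, nm, "", a$res_name, a$chain, a$res_id,
          a$icode, a$x, a$y, a$z, a$occupancy, 0, a$element)
}

#' Write a molecular system as a PDB file
#'
#' Atoms in the `ligand` group are written as HETATM records; all others as
#' ATOM. Round-trips with [read_pdb()] to the format's printed precision
#' (0.001 Angstrom).
#'
#' @param system a `molecular_system`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_pdb <- function(system, path) {
  writeLines(c(format_pdb_lines(system), "END"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Trajectories

#' Construct a trajectory
#'
#' @param frames F x N x 3 array of coordinates (Angstrom)
#' @param frame_interval frame spacing, ps (metadata)
#' @return object of class `md_trajectory`
#' @export
trajectory <- function(frames, frame_interval = 2) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == 3, dim(frames)[1] >= 1)
  if (!all(is.finite(frames))) stop("non-finite coordinates in trajectory")
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  d <- dim(x$frames)
  cat("md_trajectory:", d[1], "frames x", d[2], "atoms,",
      x$frame_interval, "ps/frame\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`
#' @return integer
#' @export
n_frames <- function(traj) dim(traj$frames)[1]

#' Extract one frame as an N x 3 matrix
#' @param traj an `md_trajectory`
#' @param i frame index (1-based)
#' @return numeric matrix
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$frames[i, , ], ncol = 3)
}

#' Read a multi-model PDB trajectory
#'
#' Each MODEL/ENDMDL block becomes one frame. Atom count and order must match
#' the parent system; a mismatching model is reported by its index.
#'
#' @param path file path
#' @param system the `molecular_system` the frames belong to
#' @param frame_interval frame spacing in ps (metadata, default 2)
#' @return an `md_trajectory`
#' @export
read_trajectory <- function(path, system, frame_interval = 2) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  n_atoms <- nrow(system$atoms)
  if (!length(starts)) {          # single implicit model
    tab <- parse_pdb_atom_lines(lines, path)
    if (nrow(tab) != n_atoms)
      stop("model 1 has ", nrow(tab), " atoms, system has ", n_atoms)
    fr <- array(0, dim = c(1, n_atoms, 3))
    fr[1, , ] <- as.matrix(tab[, c("x", "y", "z")])
    return(trajectory(fr, frame_interval))
  }
  if (length(starts) != length(ends))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  fr <- array(0, dim = c(length(starts), n_atoms, 3))
  for (m in seq_along(starts)) {
    tab <- parse_pdb_atom_lines(lines[(starts[m] + 1):(ends[m] - 1)], path)
    if (nrow(tab) != n_atoms)
      stop("model ", m, " has ", nrow(tab), " atoms, system has ", n_atoms)
    fr[m, , ] <- as.matrix(tab[, c("x", "y", "z")])
  }
  trajectory(fr, frame_interval)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj an `md_trajectory`
#' @param system the parent `molecular_system` (atom annotations)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, system, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    sys_i <- set_coords(system, frame_coords(traj, i))
    writeLines(c(sprintf("MODEL     %4d", i), format_pdb_lines(sys_i),
                 "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Parameter tables

.param_cols <- c("res_name", "atom_name", "charge", "lj_rmin_half",
                 "lj_epsilon", "vdw_radius")

#' Read a per-atom parameter table
#'
#' TSV with header exactly `res_name, atom_name, charge, lj_rmin_half,
#' lj_epsilon, vdw_radius` (charge in e, rmin/2 in Angstrom, epsilon in
#' kcal/mol, van der Waals radius in Angstrom). This flat table stands in for
#' force-field file parsing: the energetics here need only charges, LJ
#' parameters and radii per atom.
#'
#' @param path file path
#' @return data.frame of class `parameter_table`
#' @export
read_parameter_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(tab), .param_cols))
    stop("parameter table header must be exactly: ",
         paste(.param_cols, collapse = ", "))
  if (any(tab$lj_epsilon < 0)) stop("negative lj_epsilon in parameter table")
  if (any(tab$vdw_radius <= 0)) stop("non-positive vdw_radius in parameter table")
  class(tab) <- c("parameter_table", "data.frame")
  tab
}

#' Write a parameter table
#' @param params a `parameter_table` data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_parameter_table <- function(params, path) {
  write.table(params[, .param_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Assign per-atom parameters to a system
#'
#' Every protein or ligand atom must have a matching (res_name, atom_name)
#' row; missing entries are an error listing the atoms (no silent defaults).
#' After assignment each residue's summed charge is checked to be within
#' `charge_tol` of an integer.
#'
#' @param system a `molecular_system`
#' @param params a `parameter_table`
#' @param charge_tol tolerance on per-residue integer net charge (e)
#' @return the annotated system
#' @export
assign_parameters <- function(system, params, charge_tol = 0.01) {
  a <- system$atoms
  key_sys <- paste(a$res_name, a$name)
  key_par <- paste(params$res_name, params$atom_name)
  idx <- match(key_sys, key_par)
  need <- sort(unique(c(system$groups$protein, system$groups$ligand)))
  if (!length(need)) need <- seq_len(nrow(a))
  missing <- need[is.na(idx[need])]
  if (length(missing)) {
    lab <- paste0(a$res_name[missing], a$res_id[missing], ":",
                  a$name[missing])
    stop("no parameter table entry for atoms: ",
         paste(unique(lab), collapse = ", "))
  }
  ok <- !is.na(idx)
  a$charge[ok] <- params$charge[idx[ok]]
  a$lj_rmin_half[ok] <- params$lj_rmin_half[idx[ok]]
  a$lj_epsilon[ok] <- params$lj_epsilon[idx[ok]]
  a$vdw_radius[ok] <- params$vdw_radius[idx[ok]]
  system$atoms <- a
  chk <- residue_charge_check(system, charge_tol)
  if (nrow(chk)) {
    warning("residue net charge not within ", charge_tol, " e of an integer: ",
            paste(paste0(chk$chain, chk$res_id, " (", round(chk$charge, 3), ")"),
                  collapse = ", "))
  }
  system
}

#' Per-residue integer net-charge check
#' @param system annotated `molecular_system`
#' @param tol tolerance (e)
#' @return data.frame of offending residues (zero rows when all pass)
#' @export
residue_charge_check <- function(system, tol = 0.01) {
  a <- system$atoms
  has <- !is.na(a$charge)
  key <- paste(a$chain[has], a$res_id[has])
  q <- tapply(a$charge[has], key, sum)
  off <- abs(q - round(q)) > tol
  if (!any(off)) return(data.frame(chain = character(), res_id = integer(),
                                   charge = numeric()))
  parts <- strsplit(names(q)[off], " ")
  data.frame(chain = vapply(parts, `[`, "", 1),
             res_id = as.integer(vapply(parts, `[`, "", 2)),
             charge = as.numeric(q[off]), row.names = NULL)
}
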