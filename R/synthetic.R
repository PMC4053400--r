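# Synthetic inputs: a toy protein-ligand complex with a carboxylate ligand
# salt-bridged to an arginine, plus trajectory generators with planted
# statistical structure (correlation blocks, hydrogen-bond distance peaks).
#
# The toy geometry is schematic, not force-field chemistry: hydrogen-bond
# geometries (N-H...O / O-H...O collinear, H...acceptor 1.85-1.95 A), the
# CB->CG truncation axis and nonpolar contact distances are built exactly;
# bond lengths elsewhere are approximate. That is all the analysis stages
# need, and it keeps the system at 80 atoms so the Poisson solve runs in
# seconds.

#' Specification for the synthetic generators
#'
#' The defaults are the stated world of the package's parameter-recovery
#' suite: mobile termini with per-axis fluctuation sigma of 0.4 Angstrom
#' (loop-like mobility) coupled at c = 0.8 into one planted correlation
#' block (mimicking the unbound-protein terminus coupling that vanishes on
#' binding), a nearly rigid binding core (`sigma_scaffold` = 0.02 Angstrom)
#' that superposition fits on -- the analogue of fitting on a stable
#' beta-barrel -- an H...acceptor distance peak at 1.81 Angstrom with sigma
#' 0.1 (a strong, narrow salt-bridge hydrogen bond), and small rigid-body
#' noise so superposition is exercised nontrivially. The near-rigid core is
#' a deliberate idealisation: fitting onto atoms that share the planted
#' correlated motion would project part of it out, so recovery of the
#' planted coefficient is only exact when the fit set is quiet.
#'
#' @param n_residues number of peptide residues (the builder's scaffold has
#'   9)
#' @param sigma per-atom, per-axis fluctuation standard deviation of
#'   residues inside a correlation block, Angstrom
#' @param sigma_scaffold fluctuation of residues outside every block, and
#'   of the ligand, Angstrom (> 0)
#' @param correlation_blocks list of `list(residues = "a-b" (or a vector of
#'   ranges), correlation = c)`: every residue pair inside a block gets the
#'   planted correlation
#' @param hbond_peaks list of `list(mean, sd, weight)` distance peaks,
#'   Angstrom
#' @param n_frames number of frames to generate
#' @param rigid_translation_sd,rigid_rotation_sd per-frame rigid-body noise
#'   (Angstrom / radians)
#' @param seed RNG seed; identical seeds give bitwise-identical output
#' @return list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_residues = 9, sigma = 0.4,
                           sigma_scaffold = 0.02,
                           correlation_blocks = list(
                             list(residues = c("1-3", "7-9"),
                                  correlation = 0.8)),
                           hbond_peaks = list(
                             list(mean = 1.81, sd = 0.1, weight = 1)),
                           n_frames = 2000,
                           rigid_translation_sd = 0.1,
                           rigid_rotation_sd = 0.02, seed = 1) {
  stopifnot(sigma > 0, sigma_scaffold > 0, n_frames >= 1)
  for (b in correlation_blocks)
    if (abs(b$correlation) >= 1) stop("planted correlations must be in (-1, 1)")
  for (p in hbond_peaks) stopifnot(p$mean > 0, p$sd >= 0)
  structure(list(n_residues = n_residues, sigma = sigma,
                 sigma_scaffold = sigma_scaffold,
                 correlation_blocks = correlation_blocks,
                 hbond_peaks = hbond_peaks, n_frames = n_frames,
                 rigid_translation_sd = rigid_translation_sd,
                 rigid_rotation_sd = rigid_rotation_sd, seed = seed),
            class = "synthetic_spec")
}

# Atom helper for the builder
.at <- function(name, element, res_name, res_id, chain, x, y, z) {
  data.frame(name = name, element = element, res_name = res_name,
             res_id = res_id, chain = chain, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

unit3 <- function(v) v / sqrt(sum(v^2))

#' Build the toy protein-ligand complex
#'
#' A 9-residue peptide arc (chain A: ALA-SER-ALA-LEU-ALA-TYR-ALA-ARG-ALA)
#' wrapped around a benzoate-like ligand (chain B, residue LIG, net charge
#' -1). Planted by construction: a bidentate salt bridge ARG8 HH21...O1
#' (1.86 A) and HE...O2 (1.95 A), a TYR6 HH...O2 hydrogen bond (1.85 A), a
#' ligand hydroxyl donating to SER2 OG (1.9 A), and LEU4 CD1/CD2 capping
#' the aromatic ring at ~3.3-3.6 A (hydrophobic contact). All hydrogen
#' bonds are collinear at the donor. Every residue's charges sum to an
#' integer (ARG8 +1, ligand -1, rest 0).
#'
#' @param spec a [synthetic_spec()] (currently only its scaffold size is
#'   consulted)
#' @return list with `system` (annotated `molecular_system`) and `params`
#'   (the `parameter_table` used)
#' @export
build_toy_complex <- function(spec = synthetic_spec()) {
  # --- ligand (chain B), carboxylate + phenyl + hydroxyl, z = 0 plane ----
  lig <- rbind(
    .at("C1", "C", "LIG", 1, "B", 5.950, 0.000, 0),
    .at("C2", "C", "LIG", 1, "B", 6.645, -1.204, 0),
    .at("C3", "C", "LIG", 1, "B", 8.035, -1.204, 0),
    .at("C4", "C", "LIG", 1, "B", 8.730, 0.000, 0),
    .at("C5", "C", "LIG", 1, "B", 8.035, 1.204, 0),
    .at("C6", "C", "LIG", 1, "B", 6.645, 1.204, 0),
    .at("C7", "C", "LIG", 1, "B", 4.450, 0.000, 0),
    .at("O1", "O", "LIG", 1, "B", 3.500, -1.580, 0),
    .at("O2", "O", "LIG", 1, "B", 3.600, 1.590, 0),
    .at("O3", "O", "LIG", 1, "B", 10.090, 0.000, 0),
    .at("H3", "H", "LIG", 1, "B", 10.670, 0.780, 0))

  # --- peptide C-alpha arc (chain A) -------------------------------------
  res_names <- c("ALA", "SER", "ALA", "LEU", "ALA", "TYR", "ALA", "ARG",
                 "ALA")
  ca <- rbind(c(14.50, 6.50, 2.50),
              c(12.20, 4.54, 1.72),
              c(9.00, 5.50, 4.50),
              c(5.40, 5.00, 6.20),
              c(1.80, 6.50, 4.60),
              c(-1.49, 8.72, 2.23),
              c(-4.00, 5.50, 3.00),
              c(-4.57, 1.75, 2.61),
              c(-7.50, 0.50, 3.50))
  n_res <- nrow(ca)
  prot <- NULL
  for (i in seq_len(n_res)) {
    prev <- ca[max(1, i - 1), ]; nxt <- ca[min(n_res, i + 1), ]
    t_i <- unit3(nxt - prev)
    N <- ca[i, ] - 1.2 * t_i + c(0, 0, 0.5)
    C <- ca[i, ] + 1.2 * t_i + c(0, 0, -0.3)
    O <- C + c(0, -0.9, -0.84)
    rn <- res_names[i]
    prot <- rbind(prot,
      .at("N", "N", rn, i, "A", N[1], N[2], N[3]),
      .at("CA", "C", rn, i, "A", ca[i, 1], ca[i, 2], ca[i, 3]),
      .at("C", "C", rn, i, "A", C[1], C[2], C[3]),
      .at("O", "O", rn, i, "A", O[1], O[2], O[3]))
    if (rn == "ALA") {
      cb <- ca[i, ] + c(0, 1.10, 1.06)
      prot <- rbind(prot, .at("CB", "C", rn, i, "A", cb[1], cb[2], cb[3]))
    }
  }

  side <- rbind(
    # SER2: OG accepts the ligand hydroxyl (O3-H3...OG, 1.9 A, collinear)
    .at("CB", "C", "SER", 2, "A", 12.200, 3.500, 0.670),
    .at("OG", "O", "SER", 2, "A", 11.804, 2.304, 0.000),
    .at("HG", "H", "SER", 2, "A", 11.996, 2.496, 0.910),
    # LEU4: isopropyl cap over the aromatic ring (CD1~3.3 A from C5)
    .at("CB", "C", "LEU", 4, "A", 6.000, 4.000, 5.200),
    .at("CG", "C", "LEU", 4, "A", 6.600, 3.000, 4.300),
    .at("CD1", "C", "LEU", 4, "A", 7.300, 1.800, 3.200),
    .at("CD2", "C", "LEU", 4, "A", 6.000, 2.200, 3.400),
    # TYR6: hydroxyl donates to O2 (HH...O2 1.85 A, collinear O-H...O)
    .at("CB", "C", "TYR", 6, "A", -0.190, 8.420, 1.630),
    .at("CG", "C", "TYR", 6, "A", 1.010, 7.620, 1.130),
    .at("CD1", "C", "TYR", 6, "A", -0.540, 6.890, 0.830),
    .at("CD2", "C", "TYR", 6, "A", 2.560, 7.190, 1.430),
    .at("CE1", "C", "TYR", 6, "A", 0.210, 5.690, 0.830),
    .at("CE2", "C", "TYR", 6, "A", 2.710, 5.890, 1.130),
    .at("CZ", "C", "TYR", 6, "A", 1.510, 5.140, 0.830),
    .at("OH", "O", "TYR", 6, "A", 2.198, 3.969, 0.561),
    .at("HH", "H", "TYR", 6, "A", 2.680, 3.149, 0.373),
    # ARG8: guanidinium salt bridge; HH21...O1 1.86 A, HE...O2 1.95 A
    .at("CB", "C", "ARG", 8, "A", -3.170, 1.820, 1.980),
    .at("CG", "C", "ARG", 8, "A", -1.740, 1.820, 1.440),
    .at("CD", "C", "ARG", 8, "A", -0.440, 1.820, 0.660),
    .at("NE", "N", "ARG", 8, "A", 0.665, 1.152, 0.000),
    .at("CZ", "C", "ARG", 8, "A", 0.000, 0.000, 0.000),
    .at("NH1", "N", "ARG", 8, "A", -1.330, 0.000, 0.000),
    .at("NH2", "N", "ARG", 8, "A", 0.665, -1.152, 0.000),
    .at("HE", "H", "ARG", 8, "A", 1.670, 1.300, 0.000),
    .at("HH11", "H", "ARG", 8, "A", -2.300, 0.300, 0.000),
    .at("HH12", "H", "ARG", 8, "A", -1.600, -0.950, 0.000),
    .at("HH21", "H", "ARG", 8, "A", 1.660, -1.300, 0.000),
    .at("HH22", "H", "ARG", 8, "A", 0.470, -2.140, 0.000))

  atoms <- rbind(prot, side, lig)
  # order: chain A by residue then side chains inline, ligand last
  atoms <- atoms[order(match(atoms$chain, c("A", "B")), atoms$res_id), ]
  atoms$serial <- seq_len(nrow(atoms))
  sys <- molecular_system(atoms,
                          groups = list(protein = which(atoms$chain == "A"),
                                        ligand = which(atoms$chain == "B")))
  params <- toy_parameter_table()
  sys <- assign_parameters(sys, params)
  list(system = sys, params = params)
}

#' Parameter table for the toy complex
#'
#' Schematic charges (each residue sums to an integer: ARG +1, LIG -1,
#' others 0) with Amber-like Lennard-Jones parameters and Bondi van der
#' Waals radii per element.
#'
#' @return a `parameter_table`
#' @export
toy_parameter_table <- function() {
  lj <- list(C = c(1.9080, 0.0860, 1.70), N = c(1.8240, 0.1700, 1.55),
             O = c(1.6612, 0.2100, 1.52), H = c(0.6000, 0.0157, 1.20))
  row <- function(res, at, q, el) {
    p <- lj[[el]]
    data.frame(res_name = res, atom_name = at, charge = q,
               lj_rmin_half = p[1], lj_epsilon = p[2], vdw_radius = p[3],
               stringsAsFactors = FALSE)
  }
  bb <- function(res) rbind(row(res, "N", -0.40, "N"),
                            row(res, "CA", 0.20, "C"),
                            row(res, "C", 0.50, "C"),
                            row(res, "O", -0.30, "O"))
  tab <- rbind(
    bb("ALA"), row("ALA", "CB", 0.00, "C"), row("ALA", "HB1", 0.00, "H"),
    bb("SER"), row("SER", "CB", 0.25, "C"), row("SER", "OG", -0.65, "O"),
    row("SER", "HG", 0.40, "H"),
    bb("LEU"), row("LEU", "CB", 0.00, "C"), row("LEU", "CG", 0.00, "C"),
    row("LEU", "CD1", 0.00, "C"), row("LEU", "CD2", 0.00, "C"),
    bb("TYR"), row("TYR", "CB", 0.00, "C"), row("TYR", "CG", 0.00, "C"),
    row("TYR", "CD1", 0.00, "C"), row("TYR", "CD2", 0.00, "C"),
    row("TYR", "CE1", 0.00, "C"), row("TYR", "CE2", 0.00, "C"),
    row("TYR", "CZ", 0.15, "C"), row("TYR", "OH", -0.55, "O"),
    row("TYR", "HH", 0.40, "H"),
    bb("ARG"), row("ARG", "CB", 0.00, "C"), row("ARG", "CG", 0.05, "C"),
    row("ARG", "CD", 0.20, "C"), row("ARG", "NE", -0.60, "N"),
    row("ARG", "HE", 0.35, "H"), row("ARG", "CZ", 0.80, "C"),
    row("ARG", "NH1", -0.80, "N"), row("ARG", "HH11", 0.45, "H"),
    row("ARG", "HH12", 0.45, "H"), row("ARG", "NH2", -0.80, "N"),
    row("ARG", "HH21", 0.45, "H"), row("ARG", "HH22", 0.45, "H"),
    row("LIG", "C1", -0.10, "C"), row("LIG", "C2", 0.00, "C"),
    row("LIG", "C3", 0.00, "C"), row("LIG", "C4", 0.10, "C"),
    row("LIG", "C5", 0.00, "C"), row("LIG", "C6", 0.00, "C"),
    row("LIG", "C7", 0.70, "C"), row("LIG", "O1", -0.80, "O"),
    row("LIG", "O2", -0.80, "O"), row("LIG", "O3", -0.50, "O"),
    row("LIG", "H3", 0.40, "H"))
  class(tab) <- c("parameter_table", "data.frame")
  tab
}

parse_ranges <- function(x) {
  out <- integer()
  for (r in x) {
    m <- regmatches(r, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", r))[[1]]
    if (length(m) == 3) out <- c(out, seq(as.integer(m[2]), as.integer(m[3])))
    else out <- c(out, as.integer(r))
  }
  sort(unique(out))
}

# residue-level correlation matrix implied by the planted blocks
block_correlation_matrix <- function(res_ids, blocks) {
  n <- length(res_ids)
  R <- diag(n)
  for (b in blocks) {
    members <- which(res_ids %in% parse_ranges(b$residues))
    for (i in members) for (j in members)
      if (i != j) R[i, j] <- b$correlation
  }
  R
}

random_rotation_small <- function(sd) {
  ang <- rnorm(3, 0, sd)   # small-angle XYZ Euler composition
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Gaussian fluctuation trajectory with planted correlation blocks
#'
#' Frames are the reference coordinates plus residue-wise Gaussian
#' displacements: each residue (the ligand counts as one rigid unit) draws
#' an isotropic 3-D displacement, with the residue-by-residue correlation
#' structure given by the planted blocks (each coordinate axis
#' independent). Residues belonging to a block fluctuate with per-axis
#' `sigma`; scaffold residues and the ligand with the much smaller
#' `sigma_scaffold`, forming the quiet core one superposes on. Per-frame
#' rigid-body noise (translation + small rotation) is then applied to the
#' whole complex so that the superposition path of the analysis stages is
#' exercised. Deterministic under `spec$seed`.
#'
#' @param system the parent `molecular_system`
#' @param spec a [synthetic_spec()]
#' @return an `md_trajectory`
#' @export
gaussian_trajectory <- function(system, spec = synthetic_spec()) {
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  a <- system$atoms
  unit_key <- ifelse(seq_len(nrow(a)) %in% system$groups$ligand,
                     "LIGAND", paste(a$chain, a$res_id))
  units <- unique(unit_key)
  prot_res <- units[units != "LIGAND"]
  res_ids <- as.integer(sub("^\\S+ ", "", prot_res))
  R <- block_correlation_matrix(res_ids, spec$correlation_blocks)
  L <- tryCatch(chol(R), error = function(e)
    stop("planted correlation blocks do not form a positive-definite ",
         "matrix: ", conditionMessage(e)))
  n_u <- length(units)
  F_ <- spec$n_frames
  ref <- coords(system)
  frames <- array(0, dim = c(F_, nrow(a), 3))
  # displacement per unit: protein residues correlated, ligand independent;
  # block members move with sigma, everything else with sigma_scaffold
  in_block <- res_ids %in% unlist(lapply(spec$correlation_blocks,
                                         function(b) parse_ranges(b$residues)))
  sig_res <- ifelse(in_block, spec$sigma, spec$sigma_scaffold)
  disp <- array(0, dim = c(F_, n_u, 3))
  for (ax in 1:3) {
    Z <- matrix(rnorm(F_ * length(prot_res)), F_) %*% L
    disp[, match(prot_res, units), ax] <- sweep(Z, 2, sig_res, `*`)
    disp[, match("LIGAND", units), ax] <- rnorm(F_, 0, spec$sigma_scaffold)
  }
  u_idx <- match(unit_key, units)
  center <- colMeans(ref)
  for (f in seq_len(F_)) {
    X <- ref + disp[f, u_idx, ]
    Rb <- random_rotation_small(spec$rigid_rotation_sd)
    tb <- rnorm(3, 0, spec$rigid_translation_sd)
    X <- sweep(sweep(X, 2, center) %*% t(Rb), 2, center + tb, `+`)
    frames[f, , ] <- X
  }
  trajectory(frames, frame_interval = 2)
}

#' Trajectory with a planted hydrogen-bond distance distribution
#'
#' The ligand is translated rigidly along the H...acceptor axis so the
#' monitored distance follows the specified Gaussian peak(s) exactly; all
#' other internal geometry is rigid. With `sd = 0` every frame sits at the
#' peak. Deterministic under `spec$seed`.
#'
#' @param system the parent `molecular_system`
#' @param spec a [synthetic_spec()]; `spec$hbond_peaks` gives the mixture
#' @param hydrogen_name,acceptor_name atom names of the monitored pair
#'   (hydrogen in the protein, acceptor in the ligand by default)
#' @return an `md_trajectory`; attribute `distances` records the planted
#'   per-frame distances
#' @export
planted_hbond_trajectory <- function(system, spec = synthetic_spec(),
                                     hydrogen_name = "HH21",
                                     acceptor_name = "O1") {
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  ih <- select_atoms(system, name = hydrogen_name, group = "protein")
  ia <- select_atoms(system, name = acceptor_name, group = "ligand")
  if (length(ih) != 1 || length(ia) != 1)
    stop("monitored hydrogen/acceptor not uniquely found")
  ref <- coords(system)
  v <- ref[ia, ] - ref[ih, ]
  d0 <- sqrt(sum(v^2))
  u <- v / d0
  peaks <- spec$hbond_peaks
  w <- vapply(peaks, function(p) if (is.null(p$weight)) 1 else p$weight, 0)
  F_ <- spec$n_frames
  comp <- sample.int(length(peaks), F_, replace = TRUE, prob = w / sum(w))
  mu <- vapply(peaks, `[[`, 0, "mean")[comp]
  sdv <- vapply(peaks, `[[`, 0, "sd")[comp]
  d <- rnorm(F_, mu, sdv)
  d <- pmax(d, 0.5)              # keep distances physical
  frames <- array(0, dim = c(F_, nrow(ref), 3))
  ilig <- system$groups$ligand
  for (f in seq_len(F_)) {
    X <- ref
    X[ilig, ] <- sweep(X[ilig, , drop = FALSE], 2, (d[f] - d0) * u, `+`)
    frames[f, , ] <- X
  }
  out <- trajectory(frames, frame_interval = 2)
  attr(out, "distances") <- d
  out
}
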