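# Hydrogen-bond detection and empirical energetics, per-residue screened
# Coulomb polar interactions, and hydrophobic contact profiling.

.polar_elements <- c("N", "O", "S")

#' Empirical hydrogen-bond energy model
#'
#' A two-parameter distance well `E(d) = b / d^m - a / d^n` (kcal/mol, d in
#' Angstrom) with calibrated constants a = 5.571 and b = 668.580. With the
#' default exponents (m = 12, n = 2) the well minimum lies at 1.93 Angstrom
#' -- inside the 1.8-2.6 Angstrom band where H...acceptor distance
#' distributions of strong protein-ligand hydrogen bonds peak -- and the
#' energy decays to zero at large separation.
#'
#' @param a attractive calibrated parameter (default 5.571)
#' @param b repulsive calibrated parameter (default 668.580)
#' @param rep_exponent,att_exponent exponents m and n of the well
#' @return object of class `hbond_energy_model`
#' @export
hbond_energy_model <- function(a = 5.571, b = 668.580, rep_exponent = 12,
                               att_exponent = 2) {
  stopifnot(a > 0, b > 0, rep_exponent > att_exponent)
  structure(list(a = a, b = b, rep_exponent = rep_exponent,
                 att_exponent = att_exponent), class = "hbond_energy_model")
}

#' Hydrogen-bond energy at one or more distances
#'
#' @param distance H...acceptor distance(s), Angstrom (> 0)
#' @param model an [hbond_energy_model()]
#' @return kcal/mol (vectorised)
#' @export
hbond_energy <- function(distance, model = hbond_energy_model()) {
  if (any(distance <= 0)) stop("distance must be > 0")
  model$b / distance^model$rep_exponent - model$a / distance^model$att_exponent
}

#' Trajectory mean hydrogen-bond energy of a bond series
#'
#' Per-frame evaluation of the empirical well over the stored H...acceptor
#' distances; spread is the standard deviation over frames (single-bond
#' energies are per-frame quantities).
#'
#' @param series an `hbond_series` (or bare numeric distance vector)
#' @param model an [hbond_energy_model()]
#' @return list with `mean`, `sd`, `n`
#' @export
hbond_energy_mean <- function(series, model = hbond_energy_model()) {
  d <- if (inherits(series, "hbond_series")) series$distances else series
  e <- hbond_energy(d, model)
  list(mean = mean(e), sd = if (length(e) > 1) sd(e) else 0, n = length(e))
}

#' Total hydrogen-bond contribution of a complex
#'
#' Plain arithmetic sum of per-bond mean energies, in the order given
#' (left-to-right, so the result is bit-reproducible).
#'
#' @param per_bond_energies numeric vector of per-bond energies, kcal/mol
#' @return kcal/mol (0 for an empty list)
#' @export
complex_hbond_total <- function(per_bond_energies) {
  x <- as.numeric(unlist(per_bond_energies))
  if (!length(x)) return(0)
  tot <- 0
  for (v in x) tot <- tot + v
  tot
}

atom_label <- function(system, i) {
  a <- system$atoms
  paste0(a$res_name[i], a$res_id[i], ":", a$name[i])
}

# (donor heavy atom, hydrogen) pairs: polar heavy atoms with an H within
# bond_max in the given frame
donor_pairs <- function(system, xyz, candidates, bond_max = 1.25) {
  a <- system$atoms
  hyd <- which(a$element == "H")
  heavies <- candidates[a$element[candidates] %in% .polar_elements]
  out <- NULL
  for (h in intersect(hyd, candidates)) {
    d <- sqrt(rowSums((xyz[heavies, , drop = FALSE] -
                       matrix(xyz[h, ], length(heavies), 3,
                              byrow = TRUE))^2))
    j <- which.min(d)
    if (length(j) && d[j] <= bond_max)
      out <- rbind(out, c(donor = heavies[j], hydrogen = h))
  }
  out
}

#' Detect hydrogen bonds between two groups over a trajectory
#'
#' Geometric criteria evaluated per frame: donor-acceptor distance <=
#' `d_max` and donor-H...acceptor angle (at the hydrogen) >= `angle_min`.
#' Donors are N/O/S atoms with a covalently attached hydrogen (H within
#' 1.25 Angstrom in the first frame); acceptors are N/O/S atoms of the
#' opposite group. A bond is reported when it is formed in at least
#' `occupancy_min` of the frames. Both donor->acceptor directions between
#' the two groups are scanned.
#'
#' @param traj an `md_trajectory`
#' @param system the parent `molecular_system` (must contain hydrogens)
#' @param group_a,group_b group names or index vectors (default protein /
#'   ligand)
#' @param d_max donor-acceptor distance cutoff, Angstrom
#' @param angle_min donor-H...acceptor angle cutoff, degrees
#' @param occupancy_min minimum fraction of frames
#' @return list of `hbond_series` objects, each with atom indices, a
#'   human-readable `label` ("acceptor...RESID H-name"), per-frame
#'   H...acceptor `distances` and the `occupancy`
#' @export
detect_hbonds <- function(traj, system, group_a = "protein",
                          group_b = "ligand", d_max = 3.5, angle_min = 120,
                          occupancy_min = 0.5) {
  if (!any(system$atoms$element == "H"))
    stop("no hydrogens in the structure; hydrogen-bond analysis needs them ",
         "(protonation assignment is out of scope -- supply a protonated ",
         "structure)")
  ia <- group_indices(system, group_a)
  ib <- group_indices(system, group_b)
  x0 <- frame_coords(traj, 1)
  dp_a <- donor_pairs(system, x0, ia)   # their acceptors live in group_b
  dp_b <- donor_pairs(system, x0, ib)
  cand <- rbind(if (!is.null(dp_a)) cbind(dp_a, acc_pool = 1),
                if (!is.null(dp_b)) cbind(dp_b, acc_pool = 2))
  if (is.null(cand)) return(list())
  acc_a <- ia[system$atoms$element[ia] %in% .polar_elements]
  acc_b <- ib[system$atoms$element[ib] %in% .polar_elements]
  F_ <- n_frames(traj)
  out <- list()
  for (r in seq_len(nrow(cand))) {
    don <- cand[r, "donor"]; hyd <- cand[r, "hydrogen"]
    accs <- if (cand[r, "acc_pool"] == 1) acc_b else acc_a
    for (acc in setdiff(accs, don)) {
      da <- ha <- ang <- numeric(F_)
      for (f in seq_len(F_)) {
        X <- frame_coords(traj, f)
        vd <- X[don, ] - X[hyd, ]; va <- X[acc, ] - X[hyd, ]
        da[f] <- sqrt(sum((X[don, ] - X[acc, ])^2))
        ha[f] <- sqrt(sum(va^2))
        cosang <- sum(vd * va) / sqrt(sum(vd^2)) / ha[f]
        ang[f] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      }
      formed <- da <= d_max & ang >= angle_min
      occ <- mean(formed)
      if (occ >= occupancy_min) {
        out[[length(out) + 1]] <- structure(
          list(donor = don, hydrogen = hyd, acceptor = acc,
               label = paste0(atom_label(system, acc), "...",
                              atom_label(system, don), "-",
                              system$atoms$name[hyd]),
               distances = ha, occupancy = occ),
          class = "hbond_series")
      }
    }
  }
  out
}

#' Frequency distribution of a distance series
#'
#' Histogram with fixed-width bins; frequencies sum to 1. The reported peak
#' is the centre of the modal bin.
#'
#' @param series an `hbond_series` or numeric distance vector
#' @param bin_width bin width, Angstrom
#' @return data.frame (`bin_center`, `frequency`) with attribute `peak`
#' @export
distance_distribution <- function(series, bin_width = 0.05) {
  d <- if (inherits(series, "hbond_series")) series$distances else series
  stopifnot(length(d) > 0, bin_width > 0)
  lo <- floor(min(d) / bin_width) * bin_width
  bins <- floor((d - lo) / bin_width)
  counts <- tabulate(bins + 1, nbins = max(bins) + 1)
  centers <- lo + (seq_along(counts) - 0.5) * bin_width
  out <- data.frame(bin_center = centers, frequency = counts / length(d))
  attr(out, "peak") <- centers[which.max(counts)]
  out
}

#' Sigmoidal distance-dependent dielectric (docking-program convention)
#'
#' eps(r) = A + B / (1 + k exp(-lambda B r)) with B = eps0 - A; the
#' Mehler-Solmajer parameterisation as distributed with AutoDock 3.0.5
#' (A = -8.5525, k = 7.7839, lambda = 0.003627, eps0 = 78.4). Monotonically
#' non-decreasing in r and approaching the solvent value at large r.
#'
#' @param r distance(s), Angstrom
#' @param model a [polar_interaction_model()]
#' @return dielectric value(s)
#' @export
sigmoidal_dielectric <- function(r, model = polar_interaction_model()) {
  B <- model$eps0 - model$A
  model$A + B / (1 + model$k * exp(-model$lambda * B * r))
}

#' Screened-Coulomb polar interaction model
#'
#' Parameters of the sigmoidal distance-dependent dielectric plus the
#' overall calibrated scale (default 1.558) applied to the summed screened
#' Coulomb energy.
#'
#' @param scale overall scale (> 0), default 1.558
#' @param eps0 solvent dielectric limit
#' @param A,k,lambda sigmoid constants (AutoDock 3.0.5 values)
#' @return object of class `polar_interaction_model`
#' @export
polar_interaction_model <- function(scale = 1.558, eps0 = 78.4, A = -8.5525,
                                    k = 7.7839, lambda = 0.003627) {
  stopifnot(scale > 0, eps0 > A)
  structure(list(scale = scale, eps0 = eps0, A = A, k = k, lambda = lambda),
            class = "polar_interaction_model")
}

#' Per-residue polar interaction energy with the ligand
#'
#' Per frame, the double sum over residue atoms i and ligand atoms j of
#' `scale * 332.0637 q_i q_j / (eps(r_ij) r_ij)` with the sigmoidal
#' distance-dependent dielectric; reported as mean +/- standard error over
#' frames.
#'
#' @param traj an `md_trajectory`
#' @param system the annotated parent `molecular_system`
#' @param residue_id author residue number of the receptor residue
#' @param chain optional chain filter for the residue
#' @param ligand_group ligand group name or index vector
#' @param model a [polar_interaction_model()]
#' @return list with `mean`, `sem`, `per_frame`
#' @export
residue_polar_energy <- function(traj, system, residue_id, chain = NULL,
                                 ligand_group = "ligand",
                                 model = polar_interaction_model()) {
  ires <- select_atoms(system, chain = chain, res_id = residue_id,
                       group = "protein")
  if (!length(ires)) stop("residue ", residue_id, " not found in protein")
  ilig <- group_indices(system, ligand_group)
  a <- system$atoms
  if (anyNA(a$charge[c(ires, ilig)]))
    stop("charges not assigned; run assign_parameters() first")
  qq <- outer(a$charge[ires], a$charge[ilig])
  F_ <- n_frames(traj)
  per_frame <- numeric(F_)
  for (f in seq_len(F_)) {
    X <- frame_coords(traj, f)
    r <- pair_distances(X[ires, , drop = FALSE], X[ilig, , drop = FALSE])
    r <- pmax(r, 1e-6)
    per_frame[f] <- model$scale *
      sum(.coulomb_k * qq / (sigmoidal_dielectric(r, model) * r))
  }
  list(mean = mean(per_frame),
       sem = if (F_ > 1) sd(per_frame) / sqrt(F_) else 0,
       per_frame = per_frame)
}

#' Total per-residue polar contribution
#'
#' Plain left-to-right arithmetic sum of per-residue polar energies.
#'
#' @param residue_energies numeric vector, kcal/mol
#' @return kcal/mol (0 for empty input)
#' @export
polar_total <- function(residue_energies) {
  complex_hbond_total(residue_energies)
}

#' Hydrophobic contacts between protein residues and the ligand
#'
#' A residue is in contact in a frame when at least one of its carbon or
#' sulfur heavy atoms lies within `cutoff` of a ligand carbon/sulfur atom
#' (the classic LIGPLOT-style nonpolar contact rule, default 3.9 Angstrom).
#'
#' @param traj an `md_trajectory`
#' @param system the parent `molecular_system`
#' @param cutoff contact distance cutoff, Angstrom
#' @param protein,ligand group names or index vectors
#' @return list with `occupancy` (data.frame residue, res_id, occupancy) and
#'   `per_frame` (frames x residues logical matrix)
#' @export
hydrophobic_contacts <- function(traj, system, cutoff = 3.9,
                                 protein = "protein", ligand = "ligand") {
  a <- system$atoms
  ip <- group_indices(system, protein)
  il <- group_indices(system, ligand)
  ip <- ip[a$element[ip] %in% c("C", "S")]
  il <- il[a$element[il] %in% c("C", "S")]
  res_key <- paste(a$chain[ip], a$res_id[ip])
  res_u <- unique(res_key)
  F_ <- n_frames(traj)
  mat <- matrix(FALSE, F_, length(res_u), dimnames = list(NULL, res_u))
  if (length(ip) && length(il)) {
    for (f in seq_len(F_)) {
      X <- frame_coords(traj, f)
      r <- pair_distances(X[ip, , drop = FALSE], X[il, , drop = FALSE])
      hit <- apply(r <= cutoff, 1, any)
      mat[f, ] <- vapply(res_u, function(k) any(hit[res_key == k]), TRUE)
    }
  }
  first <- match(res_u, res_key)
  occ <- data.frame(
    residue = paste0(a$res_name[ip[first]], a$res_id[ip[first]]),
    res_id = a$res_id[ip[first]],
    occupancy = colMeans(mat), row.names = NULL)
  list(occupancy = occ, per_frame = mat)
}
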