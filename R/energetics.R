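# Solvated interaction energy (SIE) machinery: intermolecular Coulomb and
# Lennard-Jones terms, Shrake-Rupley surface area, finite-difference Poisson
# reaction field, and their calibrated linear combination.

# Coulomb constant, kcal/mol * Angstrom / e^2
.coulomb_k <- 332.0637
# Gas constant, kcal/mol/K
.R_gas <- 1.9872e-3

group_indices <- function(system, group) {
  if (is.character(group) && length(group) == 1) {
    idx <- system$groups[[group]]
    if (is.null(idx)) stop("no such group: ", group)
    idx
  } else as.integer(group)
}

pair_distances <- function(xa, xb) {
  # |A| x |B| distance matrix
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * tcrossprod(xa, xb)
  sqrt(pmax(d2, 0))
}

check_overlap <- function(r, system, ia, ib, min_sep = 0.1) {
  bad <- which(r < min_sep, arr.ind = TRUE)
  if (nrow(bad)) {
    a <- system$atoms
    i <- ia[bad[1, 1]]; j <- ib[bad[1, 2]]
    stop(sprintf("overlapping atoms (r = %.3f A < %.1f A): %s%d:%s and %s%d:%s",
                 r[bad[1, 1], bad[1, 2]], min_sep,
                 a$res_name[i], a$res_id[i], a$name[i],
                 a$res_name[j], a$res_id[j], a$name[j]))
  }
}

#' Intermolecular Coulomb energy between two groups
#'
#' Sum over all pairs (a in A, b in B) of `332.0637 q_a q_b / (dielectric
#' r_ab)`, in kcal/mol. No distance cutoff is applied: these are
#' post-analysis energies, not simulation forces.
#'
#' @param system an annotated `molecular_system`
#' @param group_a,group_b group names or atom index vectors (disjoint)
#' @param dielectric uniform dielectric constant (SIE uses the solute
#'   interior value)
#' @return kcal/mol
#' @export
coulomb_energy <- function(system, group_a = "protein", group_b = "ligand",
                           dielectric = 1) {
  ia <- group_indices(system, group_a); ib <- group_indices(system, group_b)
  if (length(intersect(ia, ib))) stop("groups overlap")
  a <- system$atoms
  if (anyNA(a$charge[c(ia, ib)]))
    stop("charges not assigned; run assign_parameters() first")
  r <- pair_distances(coords(system)[ia, , drop = FALSE],
                      coords(system)[ib, , drop = FALSE])
  check_overlap(r, system, ia, ib)
  .coulomb_k * sum(outer(a$charge[ia], a$charge[ib]) / r) / dielectric
}

#' Intermolecular Lennard-Jones energy between two groups
#'
#' 12-6 potential in the rmin/epsilon convention with Lorentz-Berthelot
#' combination: `r_min = rmin_half_a + rmin_half_b`, `eps = sqrt(eps_a
#' eps_b)`; the pair energy is `eps ((rmin/r)^12 - 2 (rmin/r)^6)`, with
#' minimum `-eps` at the combined `r_min`.
#'
#' @inheritParams coulomb_energy
#' @return kcal/mol
#' @export
lj_energy <- function(system, group_a = "protein", group_b = "ligand") {
  ia <- group_indices(system, group_a); ib <- group_indices(system, group_b)
  if (length(intersect(ia, ib))) stop("groups overlap")
  a <- system$atoms
  if (anyNA(a$lj_epsilon[c(ia, ib)]) || anyNA(a$lj_rmin_half[c(ia, ib)]))
    stop("LJ parameters not assigned; run assign_parameters() first")
  r <- pair_distances(coords(system)[ia, , drop = FALSE],
                      coords(system)[ib, , drop = FALSE])
  check_overlap(r, system, ia, ib)
  rmin <- outer(a$lj_rmin_half[ia], a$lj_rmin_half[ib], `+`)
  eps <- sqrt(outer(a$lj_epsilon[ia], a$lj_epsilon[ib]))
  s6 <- (rmin / r)^6
  sum(eps * (s6^2 - 2 * s6))
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical surface area of a group treated as an isolated molecule:
#' each atom's sphere of radius `vdw_radius * radius_scale + probe_radius`
#' is sampled with `n_points` quadrature points; points buried in any other
#' sphere of the group are discarded.
#'
#' @param system an annotated `molecular_system`
#' @param group group name or atom indices (default: all atoms)
#' @param probe_radius solvent probe radius, Angstrom (1.4 = water; 0 gives
#'   the van der Waals surface used as the SIE molecular-surface proxy)
#' @param radius_scale linear scaling of the atomic radii (the SIE rho
#'   coefficient)
#' @param n_points quadrature points per atom
#' @return area in Angstrom^2
#' @export
sasa <- function(system, group = NULL, probe_radius = 1.4, radius_scale = 1,
                 n_points = 960) {
  idx <- if (is.null(group)) seq_len(nrow(system$atoms))
         else group_indices(system, group)
  a <- system$atoms
  rad <- a$vdw_radius[idx]
  if (anyNA(rad)) stop("vdw radii not assigned; run assign_parameters() first")
  if (any(rad <= 0)) stop("non-positive vdw radius")
  rr <- rad * radius_scale + probe_radius
  x <- coords(system)[idx, , drop = FALSE]
  n <- length(idx)
  pts <- sphere_points(n_points)
  d <- pair_distances(x, x)
  total <- 0
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < rr[i] + rr & seq_len(n) != i)
    if (!length(nb)) {
      total <- total + 4 * pi * rr[i]^2
      next
    }
    p <- sweep(pts * rr[i], 2, x[i, ], `+`)
    # accessible = outside every neighbour sphere
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - x[j, 1])^2 + (p[, 2] - x[j, 2])^2 +
             (p[, 3] - x[j, 3])^2
      buried <- buried | dj2 < rr[j]^2
      if (all(buried)) break
    }
    total <- total + 4 * pi * rr[i]^2 * mean(!buried)
  }
  total
}

#' Change in molecular surface area upon binding
#'
#' `MSA(complex) - MSA(protein) - MSA(ligand)`; burying surface on binding
#' makes this negative, so with `gamma > 0` the surface term of the SIE
#' function is negative for a bound pose.
#'
#' @inheritParams sasa
#' @param protein,ligand group names or index vectors
#' @param gamma surface coefficient, kcal/mol/Angstrom^2
#' @return list with `delta_msa` (Angstrom^2) and `gamma_term` (kcal/mol)
#' @export
delta_msa <- function(system, protein = "protein", ligand = "ligand",
                      probe_radius = 1.4, radius_scale = 1.1,
                      n_points = 960, gamma = 0.012894) {
  ip <- group_indices(system, protein); il <- group_indices(system, ligand)
  m_c <- sasa(system, c(ip, il), probe_radius, radius_scale, n_points)
  m_p <- sasa(system, ip, probe_radius, radius_scale, n_points)
  m_l <- sasa(system, il, probe_radius, radius_scale, n_points)
  dm <- m_c - m_p - m_l
  list(delta_msa = dm, gamma_term = gamma * dm)
}

#' Electrostatic solvation (reaction-field) energy of a group
#'
#' Finite-difference two-dielectric Poisson solve on a cubic grid: solute
#' interior dielectric `d_in` inside the scaled van der Waals surface,
#' `d_solvent` outside. The returned energy is the interaction of the
#' charges with their reaction potential, i.e. the Born solvation energy for
#' a single ion.
#'
#' @param system an annotated `molecular_system`
#' @param group group name or atom indices
#' @param d_in solute interior dielectric (>= 1)
#' @param d_solvent solvent dielectric
#' @param radius_scale linear scaling of atomic radii defining the boundary
#' @param grid_spacing grid spacing, Angstrom
#' @param margin solvent margin around the solute, Angstrom
#' @param tol SOR convergence tolerance (max potential update, kcal/mol/e)
#' @param max_iter SOR iteration cap
#' @param edge_samples dielectric boundary samples per grid edge
#' @param n_offsets number of grid-origin offsets to average over; the
#'   union-of-spheres boundary is jagged on the grid, and averaging a few
#'   fractional origin shifts removes the resulting grid-phase noise
#' @return kcal/mol
#' @export
reaction_field <- function(system, group = NULL, d_in = 2.25,
                           d_solvent = 78.4, radius_scale = 1.1,
                           grid_spacing = 0.5, margin = 10, tol = 1e-4,
                           max_iter = 3000, edge_samples = 5,
                           n_offsets = 2) {
  idx <- if (is.null(group)) seq_len(nrow(system$atoms))
         else group_indices(system, group)
  a <- system$atoms
  q <- a$charge[idx]; rad <- a$vdw_radius[idx] * radius_scale
  if (anyNA(q) || anyNA(rad))
    stop("charges/radii not assigned; run assign_parameters() first")
  if (all(q == 0)) return(0)
  e <- vapply(seq_len(n_offsets), function(k)
    rf_energy_cpp(coords(system)[idx, , drop = FALSE], q, rad,
                  d_in, d_solvent, grid_spacing, margin, tol,
                  max_iter, as.integer(edge_samples),
                  (k - 1) / n_offsets)$energy, 0)
  mean(e)
}

#' Change in reaction-field energy upon binding
#'
#' `RF(complex) - RF(protein) - RF(ligand)`. For a charged ligand binding
#' into a pocket this is positive: the desolvation penalty.
#'
#' @inheritParams reaction_field
#' @param protein,ligand group names or index vectors
#' @return kcal/mol
#' @export
delta_reaction_field <- function(system, protein = "protein",
                                 ligand = "ligand", d_in = 2.25,
                                 d_solvent = 78.4, radius_scale = 1.1,
                                 grid_spacing = 0.5, margin = 10,
                                 tol = 1e-4, max_iter = 3000,
                                 edge_samples = 5, n_offsets = 2) {
  ip <- group_indices(system, protein); il <- group_indices(system, ligand)
  rf <- function(g) reaction_field(system, g, d_in, d_solvent, radius_scale,
                                   grid_spacing, margin, tol, max_iter,
                                   edge_samples, n_offsets)
  rf(c(ip, il)) - rf(ip) - rf(il)
}

#' SIE calibration coefficients
#'
#' The published global SIE calibration: `alpha` scales the summed
#' interaction terms (absorbing configurational-entropy loss), `d_in` is the
#' solute interior dielectric, `rho` linearly scales the van der Waals
#' radii, `gamma` converts buried molecular surface to energy, and `c_const`
#' is an additive constant.
#'
#' @param alpha global proportionality coefficient (dimensionless)
#' @param d_in solute interior dielectric (>= 1)
#' @param rho van der Waals radius scaling (> 0)
#' @param gamma surface coefficient, kcal/mol/Angstrom^2
#' @param c_const additive constant, kcal/mol
#' @return list of class `sie_coefficients`
#' @export
sie_coefficients <- function(alpha = 0.104758, d_in = 2.25, rho = 1.1,
                             gamma = 0.012894, c_const = -2.89) {
  if (d_in < 1) stop("d_in must be >= 1")
  if (rho <= 0) stop("rho must be > 0")
  structure(list(alpha = alpha, d_in = d_in, rho = rho, gamma = gamma,
                 c_const = c_const), class = "sie_coefficients")
}

#' Combine SIE components into a binding free energy
#'
#' `dG_bind = alpha (E_c + E_vdw + dG_R + gamma dMSA) + C`. The surface term
#' is passed already multiplied by gamma (as reported in component tables).
#'
#' @param e_coulomb,e_vdw,g_reaction,gamma_msa_term the four components,
#'   kcal/mol; alternatively a single named list/vector as first argument
#' @param coefficients a [sie_coefficients()] object
#' @return kcal/mol
#' @export
sie_combine <- function(e_coulomb, e_vdw = NULL, g_reaction = NULL,
                        gamma_msa_term = NULL,
                        coefficients = sie_coefficients()) {
  if (is.list(e_coulomb) || (is.numeric(e_coulomb) && length(e_coulomb) == 4 &&
                             !is.null(names(e_coulomb)))) {
    comp <- as.list(e_coulomb)
    e_vdw <- comp$e_vdw; g_reaction <- comp$g_reaction
    gamma_msa_term <- comp$gamma_msa_term; e_coulomb <- comp$e_coulomb
  }
  stopifnot(is.finite(e_coulomb), is.finite(e_vdw), is.finite(g_reaction),
            is.finite(gamma_msa_term))
  coefficients$alpha * (e_coulomb + e_vdw + g_reaction + gamma_msa_term) +
    coefficients$c_const
}

#' SIE components of a single configuration
#'
#' Evaluates the intermolecular Coulomb energy (at the interior dielectric),
#' the Lennard-Jones energy, the reaction-field change and the surface term
#' for one structure, and combines them.
#'
#' @param system an annotated `molecular_system` with `protein` and `ligand`
#'   groups
#' @param coefficients a [sie_coefficients()] object
#' @param options list of numerical knobs, see [sie_options()]
#' @return named list of the four components plus `dg_bind`
#' @export
sie_snapshot <- function(system, coefficients = sie_coefficients(),
                         options = sie_options()) {
  e_c <- coulomb_energy(system, "protein", "ligand",
                        dielectric = coefficients$d_in)
  e_v <- lj_energy(system, "protein", "ligand")
  g_r <- delta_reaction_field(system, d_in = coefficients$d_in,
                              d_solvent = options$d_solvent,
                              radius_scale = coefficients$rho,
                              grid_spacing = options$grid_spacing,
                              margin = options$margin, tol = options$tol,
                              max_iter = options$max_iter,
                              edge_samples = options$edge_samples,
                              n_offsets = options$n_offsets)
  dm <- delta_msa(system, probe_radius = options$probe_radius,
                  radius_scale = coefficients$rho,
                  n_points = options$n_points, gamma = coefficients$gamma)
  comp <- list(e_coulomb = e_c, e_vdw = e_v, g_reaction = g_r,
               gamma_msa_term = dm$gamma_term)
  comp$dg_bind <- sie_combine(comp, coefficients = coefficients)
  comp
}

#' Numerical options for SIE evaluation
#'
#' @param d_solvent solvent dielectric
#' @param grid_spacing Poisson grid spacing, Angstrom
#' @param margin Poisson solvent margin, Angstrom
#' @param tol,max_iter,edge_samples,n_offsets Poisson solver controls
#' @param probe_radius,n_points surface-area controls
#' @return list
#' @export
sie_options <- function(d_solvent = 78.4, grid_spacing = 0.5, margin = 10,
                        tol = 1e-4, max_iter = 3000, edge_samples = 5,
                        n_offsets = 2, probe_radius = 1.4, n_points = 960) {
  list(d_solvent = d_solvent, grid_spacing = grid_spacing, margin = margin,
       tol = tol, max_iter = max_iter, edge_samples = edge_samples,
       n_offsets = n_offsets, probe_radius = probe_radius,
       n_points = n_points)
}

#' Construct an energy-components summary
#'
#' Snapshot statistics of the SIE terms: mean and standard error over
#' snapshots for each component; `dg_bind` is the SIE combination of the
#' component means (held to that identity within 1e-9).
#'
#' @param per_frame data.frame with one row per snapshot and columns
#'   `e_coulomb`, `e_vdw`, `g_reaction`, `gamma_msa_term`
#' @param coefficients a [sie_coefficients()] object
#' @return object of class `energy_components` with elements `mean`, `sem`,
#'   `n_snapshots`, `dg_bind`, `dg_bind_sem`
#' @export
energy_components <- function(per_frame, coefficients = sie_coefficients()) {
  comp_names <- c("e_coulomb", "e_vdw", "g_reaction", "gamma_msa_term")
  stopifnot(all(comp_names %in% names(per_frame)), nrow(per_frame) >= 1)
  n <- nrow(per_frame)
  mu <- vapply(per_frame[comp_names], mean, 0)
  sem <- if (n > 1) vapply(per_frame[comp_names], sd, 0) / sqrt(n)
         else setNames(rep(0, 4), comp_names)
  dg_frame <- coefficients$alpha * rowSums(per_frame[comp_names]) +
    coefficients$c_const
  structure(list(mean = mu, sem = sem, n_snapshots = n,
                 dg_bind = sie_combine(as.list(mu),
                                       coefficients = coefficients),
                 dg_bind_sem = if (n > 1) sd(dg_frame) / sqrt(n) else 0,
                 per_frame = per_frame, coefficients = coefficients),
            class = "energy_components")
}

#' @export
print.energy_components <- function(x, ...) {
  lab <- c(e_vdw = "dE_vdw", e_coulomb = "dE_c", gamma_msa_term = "gamma.dMSA",
           g_reaction = "dG_R")
  for (k in c("e_vdw", "e_coulomb", "gamma_msa_term", "g_reaction"))
    cat(sprintf("%-10s %8.2f +/- %.2f kcal/mol\n", lab[k], x$mean[k],
                x$sem[k]))
  cat(sprintf("%-10s %8.2f +/- %.2f kcal/mol  (%d snapshots)\n", "dG_bind",
              x$dg_bind, x$dg_bind_sem, x$n_snapshots))
  invisible(x)
}

#' SIE over a trajectory
#'
#' Evaluates all SIE terms on every `snapshot_stride`-th frame (optionally
#' restricted to an equilibrium window) and summarises them as mean +/-
#' standard error of the mean; `dg_bind` is computed from the component
#' means.
#'
#' @param traj an `md_trajectory`
#' @param system the annotated parent `molecular_system`
#' @param coefficients a [sie_coefficients()] object
#' @param snapshot_stride keep every k-th frame (default 1)
#' @param frames optional explicit frame indices (overrides stride)
#' @param options numerical knobs, see [sie_options()]
#' @return an [energy_components()] object
#' @export
sie_trajectory <- function(traj, system, coefficients = sie_coefficients(),
                           snapshot_stride = 1, frames = NULL,
                           options = sie_options()) {
  if (is.null(frames))
    frames <- seq(1, n_frames(traj), by = snapshot_stride)
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    sys_k <- set_coords(system, frame_coords(traj, frames[k]))
    s <- sie_snapshot(sys_k, coefficients, options)
    rows[[k]] <- as.data.frame(s[c("e_coulomb", "e_vdw", "g_reaction",
                                   "gamma_msa_term")])
  }
  energy_components(do.call(rbind, rows), coefficients)
}

#' Convert an IC50 to a binding free energy
#'
#' The usual endpoint shortcut `dG ~ RT ln(IC50)` with R = 1.9872e-3
#' kcal/mol/K: an IC50 below 1 M gives a negative (favourable) binding free
#' energy; 1 micromolar at 300 K gives -8.24 kcal/mol.
#'
#' @param ic50 IC50 in molar
#' @param temperature Kelvin
#' @return kcal/mol
#' @export
ic50_to_dg <- function(ic50, temperature = 300) {
  stopifnot(all(ic50 > 0), temperature > 0)
  .R_gas * temperature * log(ic50)
}
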