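# Shared fixtures, built in code (no binary files).

# toy complex built once per test process
toy <- build_toy_complex()
toy_sys <- toy$system
toy_params <- toy$params
toy_all <- c(toy_sys$groups$protein, toy_sys$groups$ligand)

# a hand-written 3-atom PDB (known coordinates)
pdb3_lines <- c(
  "ATOM      1  N   ALA A   1      11.104  13.207   2.100  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      12.560  13.300   2.000  1.00  0.00           C",
  "HETATM    3  C1  LIG B   1       3.000  -1.250   0.125  1.00  0.00           C",
  "END")

# bare system from an atom table
make_system <- function(names, elements, xyz, charges = NULL,
                        res_name = "RES", chain = "A", res_id = 1,
                        rmin = 1.8, eps = 0.1, vdw = 1.6,
                        groups = list()) {
  n <- length(names)
  molecular_system(data.frame(
    name = names, element = elements, res_name = res_name,
    res_id = res_id, chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = if (is.null(charges)) NA_real_ else charges,
    lj_rmin_half = rmin, lj_epsilon = eps, vdw_radius = vdw),
    groups = groups)
}

# single ion for Born tests
ion_system <- function(q = 1, radius = 2) {
  make_system("ION", "X", matrix(0, 1, 3), charges = q, vdw = radius)
}

# trajectory from a list of N x 3 matrices
traj_from_frames <- function(frames, dt = 2) {
  arr <- array(0, dim = c(length(frames), nrow(frames[[1]]), 3))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
  trajectory(arr, dt)
}

# constant trajectory replicating one coordinate set
const_traj <- function(xyz, n = 3) {
  traj_from_frames(rep(list(xyz), n))
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

born_energy <- function(q, a, d_in, d_out) {
  -166.03185 * q^2 / a * (1 / d_in - 1 / d_out)
}

# independent analytic area of two overlapping spheres (outer lens surface)
two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  # spherical-cap heights cut by the intersection plane
  x <- (d^2 - r2^2 + r1^2) / (2 * d)
  h1 <- r1 - x
  h2 <- r2 - (d - x)
  4 * pi * r1^2 - 2 * pi * r1 * h1 + 4 * pi * r2^2 - 2 * pi * r2 * h2
}
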