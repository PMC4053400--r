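# Coulomb / Lennard-Jones / surface / reaction-field kernels and the SIE
# combination.

naive_coulomb <- function(sys, ia, ib, dielectric = 1) {
  a <- sys$atoms; x <- coords(sys)
  tot <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((x[i, ] - x[j, ])^2))
    tot <- tot + 332.0637 * a$charge[i] * a$charge[j] / (dielectric * r)
  }
  tot
}

naive_lj <- function(sys, ia, ib) {
  a <- sys$atoms; x <- coords(sys)
  tot <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((x[i, ] - x[j, ])^2))
    rmin <- a$lj_rmin_half[i] + a$lj_rmin_half[j]
    eps <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
    tot <- tot + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }
  tot
}

random_pair_system <- function(n_a = 4, n_b = 4) {
  n <- n_a + n_b
  make_system(paste0("X", 1:n), rep("C", n),
              cbind(runif(n, 0, 6), runif(n, 0, 6),
                    c(rep(0, n_a), rep(8, n_b))),
              charges = round(runif(n, -1, 1), 3),
              res_id = c(rep(1, n_a), rep(2, n_b)),
              chain = rep(c("A", "B"), c(n_a, n_b)),
              rmin = runif(n, 1.2, 2.2), eps = runif(n, 0.02, 0.3),
              groups = list(protein = 1:n_a, ligand = n_a + 1:n_b))
}

test_that("coulomb energy: hand value, zero charges, naive-loop oracle", {
  pair <- make_system(c("P", "Q"), c("N", "O"),
                      rbind(c(0, 0, 0), c(3.32, 0, 0)),
                      charges = c(1, -1), res_id = 1:2,
                      chain = c("A", "B"),
                      groups = list(protein = 1L, ligand = 2L))
  expect_equal(coulomb_energy(pair), -332.0637 / 3.32, tolerance = 1e-12)
  expect_equal(round(coulomb_energy(pair), 2), -100.02)
  expect_equal(coulomb_energy(pair, dielectric = 2),
               -332.0637 / 3.32 / 2, tolerance = 1e-12)
  # all ligand charges zero -> 0
  z <- toy_sys
  z$atoms$charge[z$groups$ligand] <- 0
  expect_equal(coulomb_energy(z), 0)
  set.seed(10)
  for (rep in 1:3) {
    sys <- random_pair_system()
    expect_equal(coulomb_energy(sys, "protein", "ligand", dielectric = 2.25),
                 naive_coulomb(sys, 1:4, 5:8, 2.25), tolerance = 1e-10)
  }
})

test_that("lj energy: minimum depth, long-range decay, oracle", {
  mk <- function(r) make_system(c("P", "Q"), c("C", "C"),
                                rbind(c(0, 0, 0), c(r, 0, 0)),
                                charges = 0, res_id = 1:2,
                                rmin = c(1.9, 1.7), eps = c(0.2, 0.05),
                                groups = list(protein = 1L, ligand = 2L))
  expect_equal(lj_energy(mk(3.6)), -sqrt(0.2 * 0.05), tolerance = 1e-12)
  expect_lt(abs(lj_energy(mk(1e4))), 1e-12)
  set.seed(11)
  for (rep in 1:3) {
    sys <- random_pair_system()
    expect_equal(lj_energy(sys), naive_lj(sys, 1:4, 5:8),
                 tolerance = 1e-10)
  }
})

test_that("overlapping atoms are reported by name", {
  sys <- make_system(c("P", "Q"), c("C", "C"),
                     rbind(c(0, 0, 0), c(0.05, 0, 0)),
                     charges = c(0.1, 0.1), res_id = 1:2,
                     groups = list(protein = 1L, ligand = 2L))
  expect_error(coulomb_energy(sys), "overlapping.*P.*Q")
  expect_error(lj_energy(sys), "overlapping")
})

test_that("shrake-rupley: sphere, additivity, two-sphere lens", {
  one <- make_system("S", "X", matrix(0, 1, 3), charges = 0, vdw = 1.7)
  for (scale in c(1, 1.1)) {
    a <- sasa(one, probe_radius = 1.4, radius_scale = scale)
    expect_equal(a, 4 * pi * (1.7 * scale + 1.4)^2, tolerance = 0.005)
  }
  two_far <- make_system(c("S1", "S2"), c("X", "X"),
                         rbind(c(0, 0, 0), c(100, 0, 0)), charges = 0,
                         vdw = c(1.7, 1.5))
  expect_equal(sasa(two_far, probe_radius = 1.4, radius_scale = 1),
               4 * pi * ((1.7 + 1.4)^2 + (1.5 + 1.4)^2), tolerance = 0.005)
  # overlapping spheres vs the analytic outer-lens area (probe 0)
  d <- 2.0
  two <- make_system(c("S1", "S2"), c("X", "X"),
                     rbind(c(0, 0, 0), c(d, 0, 0)), charges = 0,
                     vdw = c(1.8, 1.4))
  expect_equal(sasa(two, probe_radius = 0, radius_scale = 1),
               two_sphere_area(1.8, 1.4, d), tolerance = 0.01)
  expect_error(sasa(make_system("S", "X", matrix(0, 1, 3), vdw = -1)),
               "non-positive")
})

test_that("delta MSA: far apart ~ 0, bound pose buries surface", {
  far <- toy_sys
  xyz <- coords(far)
  xyz[far$groups$ligand, 1] <- xyz[far$groups$ligand, 1] + 100
  far <- set_coords(far, xyz)
  dm_far <- delta_msa(far, n_points = 480)
  expect_lt(abs(dm_far$delta_msa), 2)      # quadrature noise only
  dm <- delta_msa(toy_sys, n_points = 480)
  expect_lt(dm$delta_msa, 0)
  expect_lt(dm$gamma_term, 0)              # gamma > 0 keeps the sign
})

test_that("reaction field matches the Born closed form across radii", {
  for (a in c(1.5, 2, 3, 4)) {
    rf <- reaction_field(ion_system(1, a), d_in = 2.25, d_solvent = 78.4,
                         radius_scale = 1)
    expect_equal(rf, born_energy(1, a, 2.25, 78.4), tolerance = 0.03)
  }
  # charge scaling is exactly quadratic in the linear solver
  rf1 <- reaction_field(ion_system(1, 2), radius_scale = 1)
  rf2 <- reaction_field(ion_system(2, 2), radius_scale = 1)
  expect_equal(rf2 / rf1, 4, tolerance = 1e-6)
})

test_that("reaction field: zero charges give zero; small grids error", {
  z <- toy_sys
  z$atoms$charge[] <- 0
  expect_equal(reaction_field(z, toy_all), 0)
  expect_error(reaction_field(ion_system(), margin = 0.5, grid_spacing = 1),
               "grid too small")
})

test_that("reaction field self-converges under grid halving", {
  g <- toy_all
  r1 <- reaction_field(toy_sys, g, grid_spacing = 0.5, margin = 6)
  r2 <- reaction_field(toy_sys, g, grid_spacing = 0.25, margin = 6)
  expect_equal(r1, r2, tolerance = 0.02)
})

test_that("binding desolvation penalty is positive on the bound toy", {
  dgr <- delta_reaction_field(toy_sys, grid_spacing = 0.6, margin = 6)
  expect_gt(dgr, 0)
})

test_that("sie_combine is the calibrated linear form", {
  co <- sie_coefficients()
  expect_equal(sie_combine(0, 0, 0, 0, coefficients = co), co$c_const)
  # linearity: doubling components doubles (dg - c)
  d1 <- sie_combine(-10, -5, 8, -2, coefficients = co) - co$c_const
  d2 <- sie_combine(-20, -10, 16, -4, coefficients = co) - co$c_const
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  expect_error(sie_combine(NaN, 0, 0, 0), "finite")
  expect_error(sie_coefficients(d_in = 0.5), "d_in")
  expect_error(sie_coefficients(rho = -1), "rho")
})

test_that("sie_trajectory snapshot statistics behave", {
  opts <- sie_options(grid_spacing = 1, margin = 5, n_points = 240,
                      n_offsets = 1)
  tiny <- make_system(c("P", "Q"), c("N", "O"),
                      rbind(c(0, 0, 0), c(3, 0, 0)),
                      charges = c(1, -1), res_id = 1:2,
                      chain = c("A", "B"), vdw = 1.6,
                      groups = list(protein = 1L, ligand = 2L))
  one <- const_traj(coords(tiny), 1)
  ec1 <- sie_trajectory(one, tiny, options = opts)
  snap <- sie_snapshot(tiny, options = opts)
  expect_equal(ec1$n_snapshots, 1)
  expect_equal(as.numeric(ec1$mean),
               as.numeric(unlist(snap[c("e_coulomb", "e_vdw", "g_reaction",
                                        "gamma_msa_term")])),
               tolerance = 1e-9)
  expect_equal(as.numeric(ec1$sem), rep(0, 4))
  expect_equal(ec1$dg_bind, snap$dg_bind, tolerance = 1e-9)
  # duplicated frame x200: sem 0, mean unchanged
  dup <- const_traj(coords(tiny), 200)
  ec200 <- sie_trajectory(dup, tiny, options = opts)
  expect_equal(as.numeric(ec200$sem), rep(0, 4), tolerance = 1e-9)
  expect_equal(as.numeric(ec200$mean), as.numeric(ec1$mean),
               tolerance = 1e-9)
  expect_equal(ec200$n_snapshots, 200)
  # varying frames: mean/sem match hand statistics of per-frame energies
  seps <- c(2.8, 3.0, 3.4)
  tr <- traj_from_frames(lapply(seps, function(s)
    rbind(c(0, 0, 0), c(s, 0, 0))))
  ec <- sie_trajectory(tr, tiny, options = opts)
  per <- vapply(seps, function(s) {
    coulomb_energy(set_coords(tiny, rbind(c(0, 0, 0), c(s, 0, 0))),
                   dielectric = sie_coefficients()$d_in)
  }, 0)
  expect_equal(ec$mean[["e_coulomb"]], mean(per), tolerance = 1e-9)
  expect_equal(ec$sem[["e_coulomb"]], sd(per) / sqrt(3), tolerance = 1e-9)
  # the components/dg identity of the summary object
  expect_equal(ec$dg_bind,
               sie_combine(as.list(ec$mean)), tolerance = 1e-9)
})

test_that("ic50 conversion follows -RT ln(IC50) with binding sign", {
  expect_equal(ic50_to_dg(1, 300), 0)
  expect_equal(ic50_to_dg(1e-6, 300), 1.9872e-3 * 300 * log(1e-6),
               tolerance = 1e-12)
  expect_equal(ic50_to_dg(1e-6, 300), -8.236, tolerance = 1e-3)
  expect_lt(ic50_to_dg(1e-9, 300), ic50_to_dg(1e-6, 300))
  expect_error(ic50_to_dg(-1), "ic50")
})
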