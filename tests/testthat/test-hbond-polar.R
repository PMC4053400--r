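# Hydrogen bonds, empirical energies, screened-Coulomb polar interactions,
# hydrophobic contacts.

# independent one-line oracles (re-derived here, not shared with R/)
oracle_hbond <- function(d, a = 5.571, b = 668.580) b / d^12 - a / d^2
oracle_eps <- function(r) {
  A <- -8.5525; B <- 78.4 - A; k <- 7.7839; lam <- 0.003627
  A + B / (1 + k * exp(-lam * B * r))
}
oracle_polar_pair <- function(q1, q2, r, scale = 1.558) {
  scale * 332.0637 * q1 * q2 / (oracle_eps(r) * r)
}

test_that("planted hydrogen bonds are detected with correct occupancy", {
  tr <- const_traj(coords(toy_sys), 5)
  hb <- detect_hbonds(tr, toy_sys)
  labels <- vapply(hb, `[[`, "", "label")
  expect_length(hb, 4)
  expect_true(any(grepl("O1.*HH21", labels)))   # ARG8 HH21 -> O1
  expect_true(any(grepl("O2.*HE", labels)))     # ARG8 HE -> O2
  expect_true(any(grepl("O2.*OH-HH", labels)))  # TYR6 HH -> O2
  expect_true(any(grepl("OG.*H3", labels)))     # ligand H3 -> SER2 OG
  expect_equal(vapply(hb, `[[`, 0, "occupancy"), rep(1, 4))
  i <- which(grepl("O1.*HH21", labels))
  expect_equal(hb[[i]]$distances, rep(1.861, 5), tolerance = 1e-3)
})

test_that("geometry beyond the cutoffs is not reported", {
  # pull the ligand 3 A along the salt-bridge axis: D-A distances > 5 A
  far <- toy_sys
  xyz <- coords(far)
  xyz[far$groups$ligand, 1] <- xyz[far$groups$ligand, 1] + 3.5
  far <- set_coords(far, xyz)
  hb <- detect_hbonds(const_traj(coords(far), 3), far)
  expect_length(hb, 0)
  # no hydrogens at all -> explicit policy error
  heavy <- toy_sys$atoms$element != "H"
  noh <- molecular_system(toy_sys$atoms[heavy, ],
                          list(protein = which(toy_sys$atoms$chain[heavy] == "A"),
                               ligand = which(toy_sys$atoms$chain[heavy] == "B")))
  expect_error(detect_hbonds(const_traj(coords(noh), 2), noh),
               "no hydrogens")
})

test_that("occupancy thresholding counts frames", {
  # 60% of frames bonded, 40% pulled out of range
  near <- coords(toy_sys)
  fxyz <- near
  fxyz[toy_sys$groups$ligand, 1] <- fxyz[toy_sys$groups$ligand, 1] + 4
  frames <- c(rep(list(near), 6), rep(list(fxyz), 4))
  tr <- traj_from_frames(frames)
  hb50 <- detect_hbonds(tr, toy_sys, occupancy_min = 0.5)
  expect_gt(length(hb50), 0)
  expect_equal(unique(vapply(hb50, `[[`, 0, "occupancy")), 0.6)
  hb70 <- detect_hbonds(tr, toy_sys, occupancy_min = 0.7)
  expect_length(hb70, 0)
})

test_that("distance distributions are normalised with the right peak", {
  # all identical -> one occupied bin with frequency 1
  h <- distance_distribution(rep(1.9, 100), bin_width = 0.05)
  expect_equal(sum(h$frequency), 1)
  expect_equal(sum(h$frequency > 0), 1)
  expect_equal(attr(h, "peak"), 1.9, tolerance = 0.05)
  # gaussian sample peaks within one bin of the planted mean
  set.seed(21)
  d <- rnorm(20000, 1.81, 0.1)
  h <- distance_distribution(d, bin_width = 0.05)
  expect_equal(sum(h$frequency), 1, tolerance = 1e-12)
  expect_lte(abs(attr(h, "peak") - 1.81), 0.05)
  # random input still sums to 1
  h <- distance_distribution(runif(999, 1, 5), bin_width = 0.07)
  expect_equal(sum(h$frequency), 1, tolerance = 1e-12)
})

test_that("hbond energy matches the independent oracle and decays", {
  expect_equal(hbond_energy(2.0), oracle_hbond(2.0), tolerance = 1e-10)
  for (d in c(0.9, 1.5, 1.93, 2.6, 5)) {
    expect_equal(hbond_energy(d), oracle_hbond(d), tolerance = 1e-10)
  }
  expect_error(hbond_energy(-1), "distance")
  # beyond the optimum the magnitude decays monotonically
  dopt <- (12 * 668.580 / (2 * 5.571))^(1 / 10)
  for (d in c(dopt, 2.5, 3.5, 6)) {
    expect_lt(abs(hbond_energy(d + 2)), abs(hbond_energy(d)))
  }
  # the well is attractive across the observed peak range
  expect_true(all(hbond_energy(seq(1.7, 2.7, by = 0.1)) < 0))
})

test_that("per-bond trajectory statistics: constant series has sd 0", {
  s <- structure(list(distances = rep(2.1, 50)), class = "hbond_series")
  m <- hbond_energy_mean(s)
  expect_equal(m$sd, 0)
  expect_equal(m$mean, hbond_energy(2.1))
  set.seed(22)
  d <- rnorm(500, 2.0, 0.1)
  m <- hbond_energy_mean(d)
  expect_equal(m$mean, mean(oracle_hbond(d)), tolerance = 1e-10)
  expect_equal(m$sd, sd(oracle_hbond(d)), tolerance = 1e-10)
})

test_that("totals are plain ordered sums", {
  expect_equal(complex_hbond_total(list()), 0)
  expect_equal(complex_hbond_total(c(-0.76, -2.50, -1.81, -0.69)), -5.76)
  expect_equal(polar_total(numeric(0)), 0)
  expect_equal(polar_total(c(-1.5, 2.25, -0.75)), 0)
})

test_that("sigmoidal dielectric is monotone and approaches the solvent", {
  r <- seq(0.1, 50, by = 0.1)
  eps <- sigmoidal_dielectric(r)
  expect_true(all(diff(eps) >= 0))
  expect_equal(eps[length(eps)], 78.4, tolerance = 0.5)
  expect_equal(sigmoidal_dielectric(4), oracle_eps(4), tolerance = 1e-12)
  expect_error(polar_interaction_model(scale = -1), "scale")
})

test_that("residue polar energy matches the single-pair oracle", {
  r <- 3.7
  pair <- make_system(c("NZ", "O1"), c("N", "O"),
                      rbind(c(0, 0, 0), c(r, 0, 0)),
                      charges = c(1, -1),
                      res_name = c("LYS", "LIG"), res_id = c(12, 1),
                      chain = c("A", "B"),
                      groups = list(protein = 1L, ligand = 2L))
  tr <- const_traj(coords(pair), 3)
  pe <- residue_polar_energy(tr, pair, 12)
  expect_equal(pe$mean, oracle_polar_pair(1, -1, r), tolerance = 1e-10)
  expect_equal(pe$sem, 0)
  expect_lt(pe$mean, 0)    # opposite charges are favourable
  # neutral residue -> exactly zero
  pair$atoms$charge[1] <- 0
  expect_equal(residue_polar_energy(const_traj(coords(pair), 2),
                                    pair, 12)$mean, 0)
  expect_error(residue_polar_energy(tr, pair, 99), "not found")
})

test_that("arginine-ligand polar interaction is strongly favourable on the toy", {
  tr <- const_traj(coords(toy_sys), 2)
  pe <- residue_polar_energy(tr, toy_sys, 8)
  expect_lt(pe$mean, -5)
  # removing the guanidinium charges kills it (alanine-scan analogue)
  mut <- mutate_to_alanine(toy_sys, mutation_spec("A", 8), toy_params)
  pe0 <- residue_polar_energy(const_traj(coords(mut), 2), mut, 8)
  expect_lt(abs(pe0$mean), 0.5)
})

test_that("hydrophobic contacts: planted pair, distance bound, occupancy range", {
  tr <- const_traj(coords(toy_sys), 5)
  hc <- hydrophobic_contacts(tr, toy_sys)
  leu <- hc$occupancy[hc$occupancy$res_id == 4, ]
  expect_equal(leu$occupancy, 1)       # LEU4 cap is within 3.9 A
  expect_true(all(hc$occupancy$occupancy >= 0 &
                  hc$occupancy$occupancy <= 1))
  # ligand far away -> nothing
  far <- toy_sys
  xyz <- coords(far)
  xyz[far$groups$ligand, 1] <- xyz[far$groups$ligand, 1] + 100
  hc0 <- hydrophobic_contacts(const_traj(xyz, 2), far)
  expect_true(all(hc0$occupancy$occupancy == 0))
  # 80% occupancy when the cap is pulled away in 1 of 5 frames
  frames <- c(rep(list(coords(toy_sys)), 4), list(xyz))
  hc80 <- hydrophobic_contacts(traj_from_frames(frames), toy_sys)
  expect_equal(hc80$occupancy$occupancy[hc80$occupancy$res_id == 4], 0.8)
})
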