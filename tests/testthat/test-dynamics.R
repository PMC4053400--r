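# Superposition, RMSD/RMSF, DCCM.

# Exhaustive rotation-grid oracle for the superposition optimum: coarse
# global Euler-angle scan followed by local refinement around the best
# coarse cell (independent of the closed-form path).
grid_superpose_rmsd <- function(mobile, reference) {
  A0 <- sweep(mobile, 2, colMeans(mobile))
  B0 <- sweep(reference, 2, colMeans(reference))
  rot <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Rz2 %*% Ry %*% Rz1
  }
  eval_rmsd <- function(a, b, c) {
    D <- A0 %*% t(rot(a, b, c)) - B0
    sqrt(mean(rowSums(D^2)))
  }
  scan <- function(as, bs, cs) {
    best <- c(Inf, NA, NA, NA)
    for (a in as) for (b in bs) for (c in cs) {
      v <- eval_rmsd(a, b, c)
      if (v < best[1]) best <- c(v, a, b, c)
    }
    best
  }
  step <- 20 * pi / 180
  best <- scan(seq(0, 2 * pi, by = step), seq(0, pi, by = step),
               seq(0, 2 * pi, by = step))
  for (k in 1:6) {   # shrink around the best point, covering the old cell
    step <- step / 3
    best <- scan(best[2] + seq(-4, 4) * step,
                 best[3] + seq(-4, 4) * step,
                 best[4] + seq(-4, 4) * step)
  }
  best[1]
}

test_that("superposition recovers identity and rigid motions exactly", {
  set.seed(42)
  x <- matrix(rnorm(30, sd = 4), 10, 3)
  fit <- superpose(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  R <- random_rotation_matrix()
  y <- sweep(x %*% t(R), 2, c(3, -2, 7), `+`)
  fit <- superpose(y, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-6)
  expect_equal(fit$transformed, x, tolerance = 1e-6)
  expect_equal(fit$rotation %*% t(fit$rotation), diag(3), tolerance = 1e-9)
})

test_that("superposition rejects degenerate selections", {
  x <- matrix(rnorm(30), 10, 3)
  expect_error(superpose(x, x, selection = 1:2), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line + 0.1), "collinear")
})

test_that("closed-form superposition matches the rotation-grid oracle", {
  set.seed(7)
  for (rep in 1:3) {
    x <- matrix(rnorm(30, sd = 3), 10, 3)
    y <- sweep(x %*% t(random_rotation_matrix()), 2, rnorm(3), `+`) +
      matrix(rnorm(30, sd = 0.3), 10, 3)
    kab <- superpose(y, x)$rmsd
    grid <- grid_superpose_rmsd(y, x)
    expect_lte(kab, grid + 1e-12)       # closed form can't be beaten
    expect_equal(kab, grid, tolerance = 1e-4)
  }
})

test_that("rmsd series: zeros for constant input, hand value for a shift", {
  tr <- const_traj(coords(toy_sys), 4)
  r <- rmsd_series(tr, coords(toy_sys))
  expect_equal(as.numeric(r), rep(0, 4), tolerance = 1e-9)
  expect_equal(attr(r, "mean"), 0, tolerance = 1e-9)
  # two atoms displaced by d on one axis, no refit: rmsd = d exactly
  ref <- rbind(c(0, 0, 0), c(3, 0, 0))
  d <- c(0.5, 1.25, 2)
  tr <- traj_from_frames(lapply(d, function(dd)
    sweep(ref, 2, c(0, 0, dd), `+`)))
  r <- rmsd_series(tr, ref, superpose_frames = FALSE)
  expect_equal(as.numeric(r), d, tolerance = 1e-12)
  expect_equal(attr(r, "mean"), mean(d), tolerance = 1e-12)
})

test_that("rmsf: zeros for constant input, recovers 1-D planted sigma", {
  tr <- const_traj(coords(toy_sys), 5)
  expect_equal(as.numeric(rmsf(tr)), rep(0, nrow(toy_sys$atoms)),
               tolerance = 1e-9)
  # one atom jittering on one axis with sd sigma, 50k frames
  set.seed(1)
  sigma <- 0.7
  n <- 50000
  base <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4))
  arr <- array(rep(base, each = n), dim = c(n, 4, 3))
  arr[, 2, 1] <- arr[, 2, 1] + rnorm(n, 0, sigma)
  tr <- trajectory(arr)
  r <- rmsf(tr, superpose_frames = FALSE)
  expect_equal(as.numeric(r[2]), sigma, tolerance = 0.02)
  expect_equal(as.numeric(r[c(1, 3, 4)]), rep(0, 3), tolerance = 1e-9)
})

test_that("rmsf is invariant to per-frame rigid motion when superposing", {
  set.seed(2)
  base <- coords(toy_sys)
  frames <- lapply(1:20, function(i) base + matrix(rnorm(length(base),
                                                         sd = 0.2),
                                                   nrow(base), 3))
  tr <- traj_from_frames(frames)
  moved <- lapply(frames, function(f)
    sweep(f %*% t(random_rotation_matrix()), 2, rnorm(3, sd = 5), `+`))
  tr2 <- traj_from_frames(moved)
  expect_equal(as.numeric(rmsf(tr2)), as.numeric(rmsf(tr)),
               tolerance = 1e-6)
})

test_that("dccm invariants hold and degenerate cases behave", {
  # rigid co-translation (superposition disabled) -> all entries 1
  base <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0))
  shifts <- rnorm(20)
  tr <- traj_from_frames(lapply(shifts, function(s)
    sweep(base, 2, c(s, 0, 0), `+`)))
  m <- dccm(tr, superpose_frames = FALSE)
  expect_equal(unclass(m), matrix(1, 3, 3), ignore_attr = TRUE,
               tolerance = 1e-9)
  # exact anti-phase on one axis -> -1
  tr <- traj_from_frames(lapply(shifts, function(s)
    base + rbind(c(s, 0, 0), c(-s, 0, 0), c(0, 0, 0))))
  expect_warning(m <- dccm(tr, superpose_frames = FALSE), "zero-variance")
  expect_equal(m[1, 2], -1, tolerance = 1e-9)
  expect_equal(m[1, 3], 0)   # zero-variance atom zeroed off-diagonal
  expect_equal(m[3, 3], 1)
  # general invariants on a random trajectory
  set.seed(3)
  tr <- traj_from_frames(lapply(1:50, function(i)
    coords(toy_sys) + matrix(rnorm(240, sd = 0.3), 80, 3)))
  m <- dccm(tr, selection = select_atoms(toy_sys, name = "CA"))
  expect_equal(unclass(m), t(unclass(m)), tolerance = 1e-12)
  expect_equal(as.numeric(diag(m)), rep(1, 9), tolerance = 1e-9)
  expect_true(all(m >= -1 & m <= 1))
})

test_that("dccm recovers a planted pairwise correlation of 0.8", {
  set.seed(4)
  n <- 20000
  C <- matrix(0.8, 3, 3); diag(C) <- 1
  L <- chol(C)
  base <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0))
  arr <- array(rep(base, each = n), dim = c(n, 3, 3))
  for (ax in 1:3) arr[, , ax] <- arr[, , ax] + matrix(rnorm(3 * n), n) %*% L
  m <- dccm(trajectory(arr), superpose_frames = FALSE)
  off <- m[upper.tri(m)]
  expect_equal(as.numeric(off), rep(0.8, 3), tolerance = 0.02)
})

test_that("region summaries reduce and difference correctly", {
  r <- setNames(c(0.2, 0.4, 0.6, 0.8, 1.0), 1:5)
  regions <- region_spec(list(a = "1-2", single = "4-4", tail = "3-5"))
  s <- region_summary(r, regions)
  expect_equal(s$mean_a, c(0.3, 0.8, 0.8))
  # identical paired inputs -> zero differences
  s2 <- region_summary(r, regions, r)
  expect_equal(s2$difference, rep(0, 3))
  # removing one region's planted correlation dominates the difference
  spec_on <- synthetic_spec(n_frames = 1500, seed = 5)
  spec_off <- synthetic_spec(
    n_frames = 1500, seed = 5,
    correlation_blocks = list(list(residues = "1-3", correlation = 0.8)))
  ca <- select_atoms(toy_sys, name = "CA", group = "protein")
  fit <- c(select_atoms(toy_sys, name = "CA", res_id = 4:6),
           toy_sys$groups$ligand)
  lab <- as.character(1:9)
  m_on <- dccm(gaussian_trajectory(toy_sys, spec_on), ca, fit, labels = lab)
  m_off <- dccm(gaussian_trajectory(toy_sys, spec_off), ca, fit,
                labels = lab)
  reg <- region_spec(list(cterm = "7-9", core = "4-6"))
  s3 <- region_summary(m_on, reg, m_off)
  # the 7-9 block lost its coupling; the core never had any. (Quiet
  # residues keep some spurious common-mode correlation from the fit
  # noise, so the drop is below the planted 0.8 in magnitude.)
  expect_gt(abs(s3$difference[s3$name == "cterm"]),
            abs(s3$difference[s3$name == "core"]))
  expect_lt(s3$difference[s3$name == "cterm"], -0.3)
})

test_that("bad region specs are rejected", {
  expect_error(region_spec(list(a = "9-3")), "end before start")
  expect_error(region_spec(list(a = "x")), "bad region")
  r <- setNames(1:5, 1:5)
  expect_error(region_summary(r, region_spec(list(a = "40-50"))),
               "outside")
})
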