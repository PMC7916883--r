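test_that("superposing a set onto itself gives the identity and zero RMSD", {
  ref <- helix_reference(10)
  k <- kabsch_superpose(ref, ref)
  expect_equal(k$rotation, diag(3), tolerance = 1e-12)
  expect_lt(k$rmsd, 1e-12)
})

test_that("RMSD vanishes under arbitrary rigid motion and rotations stay proper", {
  ref <- helix_reference(25)
  for (seed in 1:5) {
    R <- random_rotation(seed)
    t <- withr::with_seed(seed + 100, rnorm(3, sd = 5))
    mobile <- sweep(ref %*% t(R), 2, t, "+")
    k <- kabsch_superpose(mobile, ref)
    expect_lt(k$rmsd, 1e-10)
    expect_equal(det(k$rotation), 1, tolerance = 1e-10)
    # applying the returned transform reproduces the reference
    back <- sweep(mobile %*% k$rotation, 2, k$translation, "+")
    expect_lt(max(abs(back - ref)), 1e-9)
  }
})

test_that("Kabsch equals brute-force rotational-grid minimization on 4-point instances", {
  for (seed in 1:4) {
    pts <- withr::with_seed(seed, list(
      mobile = matrix(rnorm(12), 4, 3),
      reference = matrix(rnorm(12), 4, 3)
    ))
    k <- kabsch_superpose(pts$mobile, pts$reference)
    expect_equal(k$rmsd, oracle_min_rmsd(pts$mobile, pts$reference), tolerance = 1e-3)
  }
})

test_that("degenerate superposition inputs are rejected", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 atoms")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line + 0.0, line), "collinear|degenerate")
})

test_that("RMSD series is zero for copies and rigid rotations of the reference", {
  ref <- helix_reference(12)
  frames <- list(ref, ref %*% t(random_rotation(3)), sweep(ref, 2, c(1, 2, 3), "+"))
  tr <- make_traj(frames, atoms = ca_atoms(12))
  spec <- fit_spec(1:12, 1:12, ref)
  r <- rmsd_series(tr, spec)
  expect_true(all(r$rmsd_nm < 1e-10))
  expect_s3_class(r, "td_rmsd")
})

test_that("hinge opening separates self- from non-self-fitting RMSD", {
  d <- toy_dimer(8, seed = 2)
  tr <- hinge_dimer_trajectory(d, c(0, 2, 5, 10, 15, 20, 30))
  ref <- frame_coords(tr, 1)
  ia <- select_atoms(d$atoms, chain = "A")
  ib <- select_atoms(d$atoms, chain = "B")
  self_b <- rmsd_series(tr, fit_spec(ib, ib, ref))
  nonself_b <- rmsd_series(tr, fit_spec(ia, ib, ref))
  opened <- which(attr(tr, "angles_deg") > 0)
  # monomer B is internally rigid: self-fitting sees nothing
  expect_true(all(self_b$rmsd_nm < 1e-10))
  # non-self-fitting picks up the relative displacement at every opened frame
  expect_true(all(nonself_b$rmsd_nm[opened] > self_b$rmsd_nm[opened]))
  # and grows monotonically with the hinge angle on [0, 30] degrees
  expect_true(all(diff(nonself_b$rmsd_nm) > 0))
})

test_that("a static trajectory has zero RMSF everywhere", {
  ref <- helix_reference(10)
  tr <- make_traj(list(ref, ref, ref), atoms = ca_atoms(10))
  prof <- rmsf_profile(tr, fit_spec(1:10, 1:10, ref))
  expect_true(all(prof$rmsf_nm < 1e-12))
  expect_error(rmsf_profile(make_traj(list(ref), atoms = ca_atoms(10)),
                            fit_spec(1:10, 1:10, ref)), "single frame")
})

test_that("isotropic Gaussian fluctuation recovers sigma * sqrt(3)", {
  sigma <- 0.05
  ref <- helix_reference(200)
  tr <- gaussian_ensemble(ref, sigma^2, 5000, seed = 42)
  prof <- rmsf_profile(tr, fit_spec(1:200, 1:200, ref))
  expect_equal(mean(prof$rmsf_nm), sigma * sqrt(3), tolerance = 0.03)
})

test_that("atom blocks with doubled noise have uniformly larger RMSF", {
  n <- 40
  ref <- helix_reference(n)
  v <- rep(c(0.08, 0.04)^2, each = 3 * n / 2) # block A sd twice block B
  tr <- gaussian_ensemble(ref, v, 3000, seed = 7)
  prof <- rmsf_profile(tr, fit_spec(1:n, 1:n, ref))
  expect_gt(min(prof$rmsf_nm[1:(n / 2)]), max(prof$rmsf_nm[(n / 2 + 1):n]))
})

test_that("region RMSF statistics use the population SD", {
  prof <- tibble::tibble(chain = "A", resno = 1:3, elety = "CA",
                         rmsf_nm = c(0.1, 0.2, 0.3))
  regs <- tibble::tibble(region = "roof", chain = "A", resno = 1:3)
  st <- region_rmsf_stats(prof, regs, monomer = "A")
  expect_equal(st$mean_nm, 0.2)
  expect_equal(st$sd_nm, sqrt(mean((c(0.1, 0.2, 0.3) - 0.2)^2))) # 0.08165
  one <- region_rmsf_stats(prof, tibble::tibble(region = "r1", chain = "A", resno = 2))
  expect_equal(one$mean_nm, 0.2)
  expect_equal(one$sd_nm, 0)
  expect_error(
    region_rmsf_stats(prof, tibble::tibble(region = "r2", chain = "A", resno = 9)),
    "absent"
  )
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 2) # d/2 for equal masses
  cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  expect_equal(radius_of_gyration(cube), sqrt(3 * 0.25)) # 0.8660
  # mass weighting moves the centroid: heavy atom pins Rg down
  expect_lt(radius_of_gyration(two, masses = c(10, 1)), 2)
  expect_error(radius_of_gyration(two, masses = c(0, 0)), "mass")
})

test_that("sum of squared RMSF equals the covariance trace on identical fits", {
  n <- 15
  ref <- helix_reference(n)
  tr <- gaussian_ensemble(ref, 0.03^2, 400, seed = 5)
  # both routes must fit to the same reference: the starting frame
  spec <- fit_spec(1:n, 1:n, frame_coords(tr, 1))
  prof <- rmsf_profile(tr, spec)
  model <- build_covariance(tr, selection = 1:n, two_pass = FALSE)
  expect_equal(sum(prof$rmsf_nm^2), model$tmsf, tolerance = 1e-10)
})
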