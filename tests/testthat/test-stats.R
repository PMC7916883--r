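make_replica <- function(seed, n_frames = 101, n_atoms = 8, noise = 0.02) {
  ref <- helix_reference(n_atoms)
  tr <- gaussian_ensemble(ref, noise^2, n_frames, seed = seed)
  md_trajectory(tr$coords, times_ps = (seq_len(n_frames) - 1) * 1000,
                atoms = ca_atoms(n_atoms))
}

test_that("replicas of constant structure have zero RMSD SDs", {
  ref <- helix_reference(6)
  reps <- lapply(1:3, function(i) {
    make_traj(rep(list(ref), 11), times = (0:10) * 1000, atoms = ca_atoms(6))
  })
  spec <- fit_spec(1:6, 1:6, ref)
  st <- replica_rmsd_stats(reps, spec, start_ns = 0, end_ns = 10)
  expect_equal(st$sd_nm, rep(0, 3))
  expect_equal(st$mean_nm, rep(0, 3))
})

test_that("per-replica statistics match hand arithmetic on a 3-frame series", {
  ref <- helix_reference(4)
  # frames displaced along +x by 0, 0.1, 0.2 nm on atom 1 only (after no fit
  # ambiguity: use all-atom displacement so the fitted RMSD is clean)
  frames <- lapply(c(0, 0.1, 0.2), function(s) {
    f <- ref
    f[, 1] <- f[, 1] + s
    f
  })
  tr <- make_traj(frames, times = c(0, 1000, 2000), atoms = ca_atoms(4))
  # translation is removed by fitting; make it a deformation instead
  frames2 <- lapply(c(0, 0.1, 0.2), function(s) {
    f <- ref
    f[1, 1] <- f[1, 1] + s
    f
  })
  tr2 <- make_traj(frames2, times = c(0, 1000, 2000), atoms = ca_atoms(4))
  spec <- fit_spec(1:4, 1:4, ref)
  st <- replica_rmsd_stats(list(tr2), spec, start_ns = 0, end_ns = 2)
  r <- rmsd_series(tr2, spec)$rmsd_nm
  expect_equal(st$mean_nm, mean(r))
  expect_equal(st$sd_nm, sd(r))
  expect_gt(st$sd_nm, 0)
})

test_that("replica order does not change the multiset of statistics", {
  reps <- lapply(1:4, make_replica)
  spec <- fit_spec(1:8, 1:8, frame_coords(reps[[1]], 1))
  a <- replica_rmsd_stats(reps, spec, 0, 100)
  b <- replica_rmsd_stats(rev(reps), spec, 0, 100)
  expect_setequal(round(a$mean_nm, 12), round(b$mean_nm, 12))
  expect_setequal(round(a$sd_nm, 12), round(b$sd_nm, 12))
})

test_that("identical groups give t = 0 and one-sided p = 0.5", {
  g <- c(1, 2, 3)
  out <- one_sided_t_test(g, g)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 0.5)
})

test_that("the Welch test matches the closed-form formulas to 1e-10", {
  a <- c(2.1, 2.0, 1.9)
  b <- c(1.0, 1.1, 0.9)
  out <- one_sided_t_test(a, b)
  oracle <- oracle_welch(a, b)
  expect_equal(out$statistic, oracle$t, tolerance = 1e-10)
  expect_equal(out$df, oracle$df, tolerance = 1e-10)
  expect_equal(out$p_value, oracle$p_greater, tolerance = 1e-10)
  # and on less tidy fixtures of unequal size/variance
  a2 <- c(0.31, 0.28, 0.35, 0.4, 0.22)
  b2 <- c(0.11, 0.13, 0.1)
  out2 <- one_sided_t_test(a2, b2)
  oracle2 <- oracle_welch(a2, b2)
  expect_equal(out2$statistic, oracle2$t, tolerance = 1e-10)
  expect_equal(out2$df, oracle2$df, tolerance = 1e-10)
  expect_equal(out2$p_value, oracle2$p_greater, tolerance = 1e-10)
})

test_that("swapping the groups maps p to 1 - p", {
  a <- c(2.1, 2.0, 1.9)
  b <- c(1.0, 1.1, 0.9)
  p1 <- one_sided_t_test(a, b)$p_value
  p2 <- one_sided_t_test(b, a)$p_value
  expect_equal(p1 + p2, 1, tolerance = 1e-12)
})

test_that("degenerate and pooled variants behave as documented", {
  expect_message(out <- one_sided_t_test(c(1, 1), c(1, 1)), "convention")
  expect_equal(out$p_value, 0.5)
  expect_error(one_sided_t_test(c(1, 1), c(2, 2)), "undefined")
  expect_error(one_sided_t_test(1, c(1, 2)), "at least 2")
  pooled <- one_sided_t_test(c(2.1, 2.0, 1.9), c(1.0, 1.1, 0.9), pooled = TRUE)
  expect_equal(pooled$df, 4) # n1 + n2 - 2
})

test_that("comparing a system with itself yields all-zero differences", {
  reps <- lapply(1:3, make_replica)
  res_a <- analyze_system(reps, "sys", start_ns = 0, end_ns = 100,
                          geometry = FALSE, fel_bins = 12)
  res_b <- analyze_system(reps, "sys", start_ns = 0, end_ns = 100,
                          geometry = FALSE, fel_bins = 12)
  rep_out <- build_comparison_report(res_a, res_b)
  expect_equal(rep_out$rmsf$rmsf_a_nm, rep_out$rmsf$rmsf_b_nm, tolerance = 1e-12)
  expect_equal(rep_out$ed$tmsf_nm2[1], rep_out$ed$tmsf_nm2[2], tolerance = 1e-12)
  expect_equal(rep_out$sd_test$p_value, 0.5)
})

test_that("block-scaled fluctuations surface as the known ratio per region", {
  n <- 32
  ref <- helix_reference(n)
  scale <- 3
  mk <- function(noise_front, seed) {
    v <- rep(c(noise_front^2, 0.02^2), each = 3 * n / 2)
    lapply(1:2, function(r) {
      tr <- gaussian_ensemble(ref, v, 600, seed = seed + r)
      md_trajectory(tr$coords, (0:599) * 100, atoms = ca_atoms(n))
    })
  }
  sys_a <- analyze_system(mk(0.02, 1), "a", start_ns = 0, end_ns = 60,
                          geometry = FALSE, fel_bins = 8)
  sys_b <- analyze_system(mk(0.02 * scale, 100), "b", start_ns = 0, end_ns = 60,
                          geometry = FALSE, fel_bins = 8)
  rep_out <- build_comparison_report(sys_a, sys_b)
  front <- rep_out$rmsf$resno <= n / 2
  ratio_front <- mean(rep_out$rmsf$rmsf_b_nm[front] / rep_out$rmsf$rmsf_a_nm[front])
  ratio_back <- mean(rep_out$rmsf$rmsf_b_nm[!front] / rep_out$rmsf$rmsf_a_nm[!front])
  expect_equal(ratio_front, scale, tolerance = 0.15)
  expect_equal(ratio_back, 1, tolerance = 0.15)
})

test_that("a report serializes to TSV and restores losslessly", {
  reps_a <- lapply(1:2, make_replica)
  reps_b <- lapply(5:6, make_replica)
  res_a <- analyze_system(reps_a, "sys_a", start_ns = 0, end_ns = 100,
                          geometry = FALSE, fel_bins = 8)
  res_b <- analyze_system(reps_b, "sys_b", start_ns = 0, end_ns = 100,
                          geometry = FALSE, fel_bins = 8)
  rep_out <- build_comparison_report(res_a, res_b)
  d <- withr::local_tempdir()
  write_report(rep_out, d)
  back <- read_report(d)
  expect_equal(back$systems, c("sys_a", "sys_b"))
  expect_equal(back$ed$tmsf_nm2, rep_out$ed$tmsf_nm2, tolerance = 1e-6)
  expect_equal(nrow(back$rmsf), nrow(rep_out$rmsf))
  expect_equal(back$sd_test$p_value, rep_out$sd_test$p_value, tolerance = 1e-6)
})
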