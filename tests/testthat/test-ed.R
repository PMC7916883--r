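test_that("a static trajectory yields a zero covariance and zero TMSF", {
  ref <- helix_reference(8)
  tr <- make_traj(list(ref, ref, ref))
  m <- build_covariance(tr)
  expect_equal(m$tmsf, 0, tolerance = 1e-20)
  expect_true(all(abs(m$covariance) < 1e-20))
})

test_that("trace equals TMSF equals the eigenvalue sum", {
  tr <- gaussian_ensemble(helix_reference(12), 0.04^2, 300, seed = 3)
  m <- build_covariance(tr)
  expect_equal(sum(diag(m$covariance)), m$tmsf, tolerance = 1e-12)
  expect_equal(sum(m$values), m$tmsf, tolerance = 1e-10)
  # eigenvectors orthonormal
  g <- crossprod(m$vectors)
  expect_lt(max(abs(g - diag(nrow(g)))), 1e-8)
  # rigid fitting removes six degrees of freedom
  expect_lt(abs(m$values[length(m$values)]) +
              abs(m$values[length(m$values) - 5]), 1e-8 * m$tmsf)
})

test_that("prescribed diagonal spectra are recovered without fitting", {
  n <- 10
  # distinct, well-separated top modes over an isotropic floor so the sample
  # eigenvalues estimate each prescribed variance individually
  vars <- c(0.16, 0.09, 0.04, rep(0.002, 3 * n - 3))
  tr <- gaussian_ensemble(helix_reference(n), vars, 10000, seed = 17)
  m <- build_covariance(tr, fit_frames = FALSE)
  # direct sample-covariance oracle on the same frame matrix
  raw <- t(apply(tr$coords, 1, function(f) as.vector(t(f))))
  cov_oracle <- crossprod(sweep(raw, 2, colMeans(raw))) / nrow(raw)
  expect_equal(m$covariance, cov_oracle, tolerance = 1e-12)
  expect_equal(sort(m$values, decreasing = TRUE), sort(eigen(cov_oracle, symmetric = TRUE,
                                                             only.values = TRUE)$values,
                                                       decreasing = TRUE), tolerance = 1e-12)
  # top-3 eigenvalues within 5% relative error of the prescribed variances
  expect_equal(m$values[1:3], c(0.16, 0.09, 0.04), tolerance = 0.05)
})

test_that("a rank-1 ensemble concentrates all fluctuation in mode 1", {
  n <- 6
  ref <- helix_reference(n)
  dir <- matrix(0, n, 3)
  dir[, 1] <- 1 / sqrt(n) # unit 3N-vector along x of every atom
  amp <- seq(-0.2, 0.2, length.out = 9)
  frames <- lapply(amp, function(a) ref + a * dir)
  tr <- make_traj(frames)
  m <- build_covariance(tr, fit_frames = FALSE)
  cc <- cumulative_contribution(pmax(m$values, 0))
  expect_equal(cc$cumulative_pct[1], 100, tolerance = 1e-8)
  expect_lt(m$values[2] / m$values[1], 1e-12)
})

test_that("cumulative contributions follow hand arithmetic and symmetry", {
  cc <- cumulative_contribution(c(4, 3, 2, 1))
  expect_equal(cc$cumulative_pct, c(40, 70, 90, 100))
  eq <- cumulative_contribution(rep(2, 5))
  expect_equal(eq$cumulative_pct, (1:5) / 5 * 100)
  expect_error(cumulative_contribution(c(3, -1)), "non-negative")
  expect_error(cumulative_contribution(c(1, 2)), "descending")
})

test_that("projections are centered with variance equal to the eigenvalue", {
  tr <- gaussian_ensemble(helix_reference(9), 0.05^2, 500, seed = 23)
  m <- build_covariance(tr)
  for (k in c(1, 2, 5)) {
    p <- project_trajectory(tr, m, k)
    expect_lt(abs(mean(p$proj_nm)), 1e-10)
    expect_equal(mean(p$proj_nm^2), m$values[k], tolerance = 1e-8)
  }
  expect_error(project_trajectory(tr, m, 99), "out of range")
})

test_that("the full projection set reconstructs the fitted frames", {
  n <- 7
  tr <- gaussian_ensemble(helix_reference(n), 0.03^2, 50, seed = 31)
  m <- build_covariance(tr)
  projs <- vapply(seq_len(3 * n), function(k) project_trajectory(tr, m, k)$proj_nm,
                  numeric(50))
  recon <- projs %*% t(m$vectors) # frames x 3N deviations
  for (i in c(1, 25, 50)) {
    rebuilt <- m$mean + matrix(recon[i, ], ncol = 3, byrow = TRUE)
    spec <- fit_spec(m$fit, m$selection, m$fit_reference)
    fitted <- tidytraj:::.fit_frame(frame_coords(tr, i), spec)[m$selection, ]
    expect_lt(max(abs(rebuilt - fitted)), 1e-8)
  }
})

test_that("cosine content identifies its own eigenfunction and rejects the overtone", {
  t <- seq(0, 100, length.out = 1000)
  p1 <- cos(pi * t / 100)
  expect_gte(cosine_content(p1, 1, times = t), 0.999)
  p2 <- cos(2 * pi * t / 100)
  expect_lte(cosine_content(p2, 1, times = t), 0.001)
  expect_gte(cosine_content(p2, 2, times = t), 0.999)
})

test_that("cosine content is invariant to scaling of series and time axis", {
  withr::with_seed(4, {
    p <- cumsum(rnorm(200))
  })
  t <- seq_along(p) * 10
  c0 <- cosine_content(p, 1, times = t)
  expect_equal(cosine_content(5 * p, 1, times = t), c0, tolerance = 1e-12)
  expect_equal(cosine_content(p, 1, times = t / 1000), c0, tolerance = 1e-12)
  expect_error(cosine_content(rep(0, 10), 1), "all-zero")
  expect_error(cosine_content(c(1, 2), 1), "3 frames")
})

test_that("random-walk first-PC projections carry cosine content near one", {
  c1 <- vapply(1:25, function(seed) {
    tr <- diffusion_trajectory(10, 200, 0.02, seed = seed)
    m <- build_covariance(tr, fit_frames = FALSE)
    cosine_content(project_trajectory(tr, m, 1), 1)
  }, numeric(1))
  expect_gte(median(c1), 0.8)
})

test_that("porcupine extremes recover the end-points of a linear oscillation", {
  n <- 6
  ref <- helix_reference(n)
  dir <- matrix(0, n, 3)
  dir[, 2] <- 1 / sqrt(n)
  amp <- seq(-0.3, 0.3, length.out = 11)
  tr <- make_traj(lapply(amp, function(a) ref + a * dir))
  m <- build_covariance(tr, fit_frames = FALSE)
  p <- project_trajectory(tr, m, 1)
  ext <- porcupine_extremes(m, p)
  # the two extremes are the first and last conformations of the sweep
  ends <- list(ref + amp[1] * dir, ref + amp[11] * dir)
  err <- min(
    max(abs(ext$conf_min - ends[[1]])) + max(abs(ext$conf_max - ends[[2]])),
    max(abs(ext$conf_min - ends[[2]])) + max(abs(ext$conf_max - ends[[1]]))
  )
  expect_lt(err, 1e-8)
  # per-atom vector norms: sum of squares equals the squared projection range
  expect_equal(sum(ext$vectors$length^2), diff(range(p$proj_nm))^2, tolerance = 1e-10)
  # symmetric series about zero give extremes symmetric about the mean
  expect_equal(ext$conf_min + ext$conf_max, 2 * m$mean, tolerance = 1e-8)
  expect_error(porcupine_extremes(m, transform(p, proj_nm = 0 * proj_nm)), "constant")
})

test_that("porcupine output writes a two-model PDB and a vector table", {
  tr <- gaussian_ensemble(helix_reference(5), 0.05^2, 60, seed = 12)
  m <- build_covariance(tr)
  ext <- porcupine_extremes(m, project_trajectory(tr, m, 1))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_porcupine(ext, pdb, tsv)
  back <- read_trajectory(pdb)
  expect_equal(n_frames(back), 2)
  vt <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(vt), 5)
  expect_true(all(c("dx", "dy", "dz", "length") %in% names(vt)))
})
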