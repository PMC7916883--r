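# Independent oracles used by the tests. Each implements the quantity
# under test by a different route (exhaustive enumeration, closed form,
# brute force) and stays independent of the package code paths it checks.

# ---- exhaustive affine-gap global alignment (tiny instances) ----------------
# Max alignment score by explicit dynamic programming over three states
# (match, gap-in-a, gap-in-b) with affine penalties open + k * extend,
# end gaps penalized (global mode).
oracle_align_score <- function(a, b, open = 10, extend = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- BLOSUM62
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  neg <- -Inf
  M <- matrix(neg, n + 1, m + 1)
  Ia <- matrix(neg, n + 1, m + 1) # gap in b (consume a)
  Ib <- matrix(neg, n + 1, m + 1) # gap in a (consume b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) {
    Ia[i, 1] <- -(open + (i - 1) * extend)
  }
  for (j in 2:(m + 1)) {
    Ib[1, j] <- -(open + (j - 1) * extend)
  }
  for (i in 1:(n + 1)) {
    for (j in 1:(m + 1)) {
      if (i > 1 && j > 1) {
        s <- sub[av[i - 1], bv[j - 1]]
        M[i, j] <- max(M[i - 1, j - 1], Ia[i - 1, j - 1], Ib[i - 1, j - 1]) + s
      }
      if (i > 1) {
        Ia[i, j] <- max(Ia[i, j], M[i - 1, j] - open - extend, Ia[i - 1, j] - extend)
      }
      if (j > 1) {
        Ib[i, j] <- max(Ib[i, j], M[i, j - 1] - open - extend, Ib[i, j - 1] - extend)
      }
    }
  }
  max(M[n + 1, m + 1], Ia[n + 1, m + 1], Ib[n + 1, m + 1])
}

# ---- rotation-grid minimum RMSD (small point sets) --------------------------
# Nested-refinement search over ZYZ Euler angles; coarse 20 deg sweep with
# three 6x zoom stages reaches well below 1e-3 on 4-5 point instances.
oracle_min_rmsd <- function(mobile, reference) {
  rotm <- function(a, b, c) {
    rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
    rz(a) %*% ry(b) %*% rz(c)
  }
  a0 <- sweep(mobile, 2, colMeans(mobile))
  b0 <- sweep(reference, 2, colMeans(reference))
  rmsd_of <- function(a, b, c) {
    f <- a0 %*% t(rotm(a, b, c))
    sqrt(mean(rowSums((f - b0)^2)))
  }
  # coarse sweep, keep several candidates to dodge Euler-angle degeneracies,
  # then refine each by nested grid zooming
  coarse_step <- 15 * pi / 180
  cand <- list()
  for (a in seq(-pi, pi, by = coarse_step)) {
    for (b in seq(0, pi, by = coarse_step)) {
      for (c in seq(-pi, pi, by = coarse_step)) {
        cand[[length(cand) + 1]] <- c(rmsd_of(a, b, c), a, b, c)
      }
    }
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 1]), , drop = FALSE]
  best_val <- cand[1, 1]
  for (k in seq_len(min(8, nrow(cand)))) {
    loc <- cand[k, 2:4]
    loc_val <- cand[k, 1]
    step <- coarse_step
    for (stage in 1:5) {
      new_step <- step / 5
      loc_new <- loc
      for (a in seq(loc[1] - step, loc[1] + step, by = new_step)) {
        for (b in seq(loc[2] - step, loc[2] + step, by = new_step)) {
          for (c in seq(loc[3] - step, loc[3] + step, by = new_step)) {
            v <- rmsd_of(a, b, c)
            if (v < loc_val) {
              loc_val <- v
              loc_new <- c(a, b, c)
            }
          }
        }
      }
      loc <- loc_new
      step <- new_step
    }
    if (loc_val < best_val) best_val <- loc_val
  }
  best_val
}

# ---- brute-force contact count ----------------------------------------------
oracle_contacts <- function(coords, sel_a, sel_b = NULL, cutoff = 6) {
  intra <- is.null(sel_b)
  if (intra) sel_b <- sel_a
  seen <- character(0)
  count <- 0L
  for (i in sel_a) {
    for (j in sel_b) {
      if (i == j) next
      key <- paste(min(i, j), max(i, j))
      if (key %in% seen) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d < cutoff) {
        count <- count + 1L
        seen <- c(seen, key)
      }
    }
  }
  count
}

# ---- analytic SASA of two intersecting solvent-expanded spheres -------------
oracle_two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) {
    return(4 * pi * (r1^2 + r2^2))
  }
  cap_h <- function(ra, rb) ra - (d^2 + ra^2 - rb^2) / (2 * d)
  (4 * pi * r1^2 - 2 * pi * r1 * cap_h(r1, r2)) +
    (4 * pi * r2^2 - 2 * pi * r2 * cap_h(r2, r1))
}

# ---- exhaustive connected-component labeling (8-neighbour) ------------------
# Iterative minimum-label propagation until fixpoint, then count distinct
# root labels.
oracle_n_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        if (!mask[i, j]) next
        for (di in -1:1) {
          for (dj in -1:1) {
            ii <- i + di
            jj <- j + dj
            if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
            if (mask[ii, jj] && lab[ii, jj] < lab[i, j]) {
              lab[i, j] <- lab[ii, jj]
              changed <- TRUE
            }
          }
        }
      }
    }
    if (!changed) break
  }
  length(unique(lab[mask]))
}

# ---- closed-form Welch statistics -------------------------------------------
oracle_welch <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  v1 <- var(a)
  v2 <- var(b)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p_greater = stats::pt(t, df, lower.tail = FALSE))
}

# ---- shared fixtures --------------------------------------------------------
# random proper rotation from a seeded QR decomposition
random_rotation <- function(seed) {
  withr::with_seed(seed, {
    qr_res <- qr(matrix(rnorm(9), 3, 3))
    q <- qr.Q(qr_res)
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

make_traj <- function(frames_list, times = NULL, atoms = NULL) {
  coords <- array(0, dim = c(length(frames_list), nrow(frames_list[[1]]), 3))
  for (i in seq_along(frames_list)) coords[i, , ] <- frames_list[[i]]
  md_trajectory(coords, times_ps = times, atoms = atoms)
}

# minimal CA-only atom table for n residues on one chain
ca_atoms <- function(n, chain = "A") {
  tibble::tibble(
    eleno = seq_len(n), elety = "CA", resid = "ALA", chain = chain,
    resno = seq_len(n), element = "C", type = "ATOM"
  )
}

# D-H...A fixture with prescribed donor-acceptor distance and D-H-A angle
hb_fixture <- function(d_da, angle_deg) {
  # donor N at origin, H at 1.0 A along +x, acceptor placed so that the
  # D-H-A angle at H equals angle_deg and |D-A| = d_da
  th <- angle_deg * pi / 180
  # position A relative to H: direction making angle th with H->D (-x)
  dir <- c(cos(pi - th), sin(pi - th), 0)
  # choose |H-A| so that |D-A| = d_da
  f <- function(r) sqrt(sum((c(1, 0, 0) + r * dir)^2)) - d_da
  r <- uniroot(f, c(0.1, 10))$root
  acc <- c(1, 0, 0) + r * dir
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), acc)
  atoms <- tibble::tibble(
    elety = c("N", "H", "O"), element = c("N", "H", "O"),
    resid = c("ALA", "ALA", "ALA"), chain = "A", resno = c(1, 1, 2)
  )
  list(coords = coords, atoms = atoms)
}
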