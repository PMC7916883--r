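# Seeded synthetic generators with known ground truth for every pipeline
# stage. All generators are pure functions of their arguments: the seed is
# applied locally (withr::with_seed), so the global random state is never
# consumed, and identical calls are bit-identical.

#' Helical C-alpha reference coordinates
#'
#' A regular helix gives a compact, non-collinear reference conformation
#' for synthetic ensembles.
#'
#' @param n_atoms Number of atoms.
#' @param radius_nm,rise_nm Helix radius and per-atom rise in nm.
#' @return An `n_atoms x 3` matrix (nm).
#' @export
helix_reference <- function(n_atoms, radius_nm = 0.23, rise_nm = 0.15) {
  i <- seq_len(n_atoms)
  cbind(radius_nm * cos(i * 100 * pi / 180),
        radius_nm * sin(i * 100 * pi / 180),
        rise_nm * i)
}

# symmetric PSD square root via eigen-decomposition
.psd_sqrt <- function(m, tol = 1e-10) {
  eg <- eigen(m, symmetric = TRUE)
  if (any(eg$values < -tol * max(abs(eg$values), 1))) {
    abort("covariance specification is not positive semidefinite")
  }
  eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
}

#' Gaussian ensemble with prescribed covariance
#'
#' Draws `n_frames` i.i.d. conformations about a reference with a
#' prescribed `3N x 3N` coordinate covariance; the realized spectrum can
#' then be compared against the eigenvalues recovered by
#' [build_covariance()].
#'
#' @param reference `N x 3` reference coordinates (nm).
#' @param covariance Either a numeric vector of per-coordinate variances
#'   (length `3N`, diagonal model; a scalar is recycled) or a full
#'   `3N x 3N` positive-semidefinite matrix (nm^2).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return An `md_trajectory` with the ground-truth covariance attached as
#'   attribute `covariance_true` (vector or matrix, as supplied).
#' @export
gaussian_ensemble <- function(reference, covariance, n_frames, seed = 1) {
  reference <- as.matrix(reference)
  n3 <- 3 * nrow(reference)
  mu <- as.vector(t(reference))
  if (is.matrix(covariance)) {
    if (!all(dim(covariance) == n3)) abort("covariance matrix must be 3N x 3N")
    rt <- .psd_sqrt(covariance)
    draw <- function(z) as.vector(rt %*% z) + mu
  } else {
    v <- rep(as.numeric(covariance), length.out = n3)
    if (any(v < 0)) abort("variances must be non-negative")
    s <- sqrt(v)
    draw <- function(z) s * z + mu
  }
  coords <- withr::with_seed(seed, {
    out <- array(0, dim = c(n_frames, nrow(reference), 3))
    for (i in seq_len(n_frames)) {
      out[i, , ] <- matrix(draw(stats::rnorm(n3)), ncol = 3, byrow = TRUE)
    }
    out
  })
  tr <- md_trajectory(coords)
  attr(tr, "covariance_true") <- covariance
  tr
}

#' Random-diffusion trajectory
#'
#' Independent Gaussian random walks per coordinate; the canonical
#' unconverged-sampling fixture, whose leading principal-component
#' projections carry cosine contents near 1.
#'
#' @param n_atoms,n_frames Dimensions.
#' @param step_sigma Per-step displacement SD (nm).
#' @param seed Integer seed.
#' @return An `md_trajectory`.
#' @export
diffusion_trajectory <- function(n_atoms, n_frames, step_sigma = 0.01, seed = 1) {
  if (step_sigma < 0) abort("step_sigma must be non-negative")
  coords <- withr::with_seed(seed, {
    steps <- array(stats::rnorm(n_frames * n_atoms * 3, sd = step_sigma),
                   dim = c(n_frames, n_atoms, 3))
    apply(steps, c(2, 3), cumsum)
  })
  md_trajectory(coords)
}

#' Two-state conformational mixture
#'
#' Each frame is one of two conformations (state A with probability
#' `p_a`) plus isotropic Gaussian jitter; the true state labels are
#' recorded so that recovered free-energy differences can be checked
#' against `-kB T ln((1-p)/p)`.
#'
#' @param conf_a,conf_b `N x 3` conformations (nm) sharing a topology.
#' @param p_a Probability of state A, in (0, 1]; `p_a = 1` degenerates to a
#'   single-state ensemble.
#' @param jitter_sigma Isotropic per-coordinate jitter SD (nm).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return An `md_trajectory` with attribute `states` (integer vector,
#'   1 = A, 2 = B).
#' @export
two_state_ensemble <- function(conf_a, conf_b, p_a, jitter_sigma, n_frames, seed = 1) {
  conf_a <- as.matrix(conf_a)
  conf_b <- as.matrix(conf_b)
  if (!all(dim(conf_a) == dim(conf_b))) abort("conformations must share a topology")
  if (p_a <= 0 || p_a > 1) abort("p_a must lie in (0, 1]")
  sep <- max(abs(conf_a - conf_b))
  if (sep < 2 * jitter_sigma) {
    warn("states closer than twice the jitter; they will be unresolvable")
  }
  res <- withr::with_seed(seed, {
    states <- ifelse(stats::runif(n_frames) < p_a, 1L, 2L)
    coords <- array(0, dim = c(n_frames, nrow(conf_a), 3))
    for (i in seq_len(n_frames)) {
      base <- if (states[i] == 1L) conf_a else conf_b
      coords[i, , ] <- base + stats::rnorm(length(base), sd = jitter_sigma)
    }
    list(states = states, coords = coords)
  })
  tr <- md_trajectory(res$coords)
  attr(tr, "states") <- res$states
  tr
}

# Rodrigues rotation of points about a unit axis through a pivot
.rotate_about_axis <- function(coords, pivot, axis, angle_deg) {
  th <- angle_deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  p <- sweep(coords, 2, pivot)
  kx <- cbind(
    p[, 2] * k[3] - p[, 3] * k[2],
    p[, 3] * k[1] - p[, 1] * k[3],
    p[, 1] * k[2] - p[, 2] * k[1]
  )
  kdp <- as.numeric(p %*% k)
  rot <- p * cos(th) + kx * sin(th) + outer(kdp, k) * (1 - cos(th))
  sweep(rot, 2, pivot, "+")
}

#' Hinge-opening trajectory of a two-chain dimer
#'
#' Keeps the first chain internally rigid and rotates the second chain
#' about a hinge axis at the interface according to a per-frame angle
#' schedule. Self-fitting on the fixed monomer then yields zero RMSD while
#' non-self-fitting picks up the inter-monomer displacement, the behaviour
#' that separates internal fluctuation from relative monomer motion.
#'
#' @param dimer An `md_structure` with exactly two chains.
#' @param angles_deg Numeric vector: hinge opening per frame, degrees.
#' @param axis Optional length-3 hinge axis direction; defaults to an
#'   in-plane axis perpendicular to the inter-monomer vector.
#' @return An `md_trajectory` with attribute `angles_deg`.
#' @export
hinge_dimer_trajectory <- function(dimer, angles_deg, axis = NULL) {
  stopifnot(inherits(dimer, "md_structure"))
  chains <- unique(dimer$atoms$chain)
  if (length(chains) != 2) abort("hinge generator needs a two-chain dimer")
  xyz <- as.matrix(dimer$atoms[, c("x", "y", "z")]) / 10 # nm
  ia <- dimer$atoms$chain == chains[1]
  ib <- dimer$atoms$chain == chains[2]
  cent_a <- colMeans(xyz[ia, , drop = FALSE])
  cent_b <- colMeans(xyz[ib, , drop = FALSE])
  sep <- cent_b - cent_a
  if (sqrt(sum(sep^2)) < 1e-9) abort("degenerate hinge: chain centroids coincide")
  if (is.null(axis)) {
    axis <- c(-sep[2], sep[1], 0)
    if (sqrt(sum(axis^2)) < 1e-9) axis <- c(1, 0, 0)
  }
  if (sqrt(sum(axis^2)) < 1e-9) abort("degenerate hinge axis")
  pivot <- (cent_a + cent_b) / 2
  nf <- length(angles_deg)
  coords <- array(0, dim = c(nf, nrow(xyz), 3))
  for (i in seq_len(nf)) {
    f <- xyz
    f[ib, ] <- .rotate_about_axis(xyz[ib, , drop = FALSE], pivot, axis, angles_deg[i])
    coords[i, , ] <- f
  }
  tr <- md_trajectory(coords, atoms = dimer$atoms)
  attr(tr, "angles_deg") <- angles_deg
  tr
}

#' Toy two-chain dimer with hydrogen-bond donors and acceptors
#'
#' A minimal polyalanine-like dimer: two parallel extended strands (chains
#' A and B) of `N`, `H`, `CA`, `C`, `O` backbone atoms, arranged so that
#' chain B's amide hydrogens point at chain A's carbonyl oxygens across a
#' 2.9 A N...O ladder. The interface therefore carries inter-chain close
#' contacts and hydrogen bonds by construction, exercising the rule-based
#' donor/acceptor typing on valid PDB naming.
#'
#' @param n_res_per_chain Residues per chain, `>= 3`.
#' @param seed Integer seed for the small coordinate jitter.
#' @param jitter Jitter SD in Angstrom (0 for exact ideal geometry).
#' @return An `md_structure` (coordinates in Angstrom).
#' @export
toy_dimer <- function(n_res_per_chain, seed = 1, jitter = 0.02) {
  if (n_res_per_chain < 3) abort("need at least 3 residues per chain")
  n <- n_res_per_chain
  one_chain <- function(chain, y0, flip, x_off = 0) {
    rows <- lapply(seq_len(n), function(i) {
      x0 <- 3.5 * (i - 1) + x_off
      # flip = +1: carbonyl O points +y (toward the partner chain above);
      # flip = -1: amide H points -y (toward the partner chain below)
      tibble(
        elety = c("N", "H", "CA", "C", "O"),
        resid = "ALA", chain = chain, resno = i,
        x = x0 + c(0, 0, 1.2, 2.4, 2.4),
        y = y0 + flip * c(0, -1.0, 1.0, 0.3, 1.53),
        z = c(0, 0, 0, 0, 0)
      )
    })
    bind_rows(rows)
  }
  a <- one_chain("A", 0, +1) # carbonyl O at y = 1.53, x = x0 + 2.4
  # chain B is a pure translation (+2.4 in x, +4.43 in y) so each of its
  # amide N-H groups sits directly above a carbonyl O of chain A:
  # N...O = 2.9 A with the H collinear between them
  b <- one_chain("B", 4.43, +1, x_off = 2.4)
  atoms <- bind_rows(a, b)
  atoms <- withr::with_seed(seed, {
    if (jitter > 0) {
      atoms$x <- atoms$x + stats::rnorm(nrow(atoms), sd = jitter)
      atoms$y <- atoms$y + stats::rnorm(nrow(atoms), sd = jitter)
      atoms$z <- atoms$z + stats::rnorm(nrow(atoms), sd = jitter)
    }
    atoms
  })
  atoms$eleno <- seq_len(nrow(atoms))
  atoms$insert <- NA_character_
  atoms$alt <- NA_character_
  atoms$o <- 1
  atoms$b <- 0
  atoms$elesy <- NA_character_
  atoms$type <- "ATOM"
  atoms$element <- .infer_element(atoms$elety)
  structure(list(atoms = atoms, title = "synthetic toy dimer"),
            class = "md_structure")
}

#' Add point-solvent waters around a structure
#'
#' Places `n_waters` rigid three-point waters at random positions in a
#' margin around the structure's bounding box (no excluded-volume or
#' water-model physics; just donors/acceptors for hydrogen-bond tests).
#'
#' @param x An `md_structure`.
#' @param n_waters Number of waters.
#' @param seed Integer seed.
#' @param margin Box margin in Angstrom.
#' @return An `md_structure` with `HOH` residues appended on chain `W`.
#' @export
add_point_solvent <- function(x, n_waters, seed = 1, margin = 4) {
  a <- x$atoms
  lo <- c(min(a$x), min(a$y), min(a$z)) - margin
  hi <- c(max(a$x), max(a$y), max(a$z)) + margin
  wat <- withr::with_seed(seed, {
    centers <- cbind(
      stats::runif(n_waters, lo[1], hi[1]),
      stats::runif(n_waters, lo[2], hi[2]),
      stats::runif(n_waters, lo[3], hi[3])
    )
    rows <- lapply(seq_len(n_waters), function(i) {
      c0 <- centers[i, ]
      tibble(
        elety = c("O", "H1", "H2"), resid = "HOH", chain = "W",
        resno = nrow(a) + i,
        x = c0[1] + c(0, 0.96, -0.24),
        y = c0[2] + c(0, 0, 0.93),
        z = c0[3]
      )
    })
    bind_rows(rows)
  })
  wat$eleno <- max(a$eleno %||% nrow(a)) + seq_len(nrow(wat))
  wat$insert <- NA_character_
  wat$alt <- NA_character_
  wat$o <- 1
  wat$b <- 0
  wat$elesy <- NA_character_
  wat$type <- "HETATM"
  wat$element <- .infer_element(wat$elety)
  structure(list(atoms = bind_rows(a, wat), title = x$title),
            class = "md_structure")
}
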