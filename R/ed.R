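# Essential dynamics: C-alpha covariance analysis, eigen-decomposition,
# projections, cosine-content convergence diagnostics, porcupine-mode
# extraction.

#' Build a C-alpha covariance model from a trajectory
#'
#' Frames are least-squares fitted and the `3N x 3N` positional covariance
#' about the ensemble mean is diagonalized. Fitting is two-pass: frames
#' are first fitted to the reference (starting) conformation, the
#' resulting average structure becomes the fit reference, and the
#' covariance is built from frames fitted to that average. Eigenpairs are
#' sorted by decreasing eigenvalue and each eigenvector's sign is fixed so
#' its largest-magnitude component is positive.
#'
#' @param x An `md_trajectory` with at least 2 frames.
#' @param selection Integer atom indices of the analysis set (typically
#'   all C-alpha atoms). Defaults to every atom.
#' @param fit Integer atom indices used for superposition; defaults to
#'   `selection`.
#' @param fit_frames If `FALSE`, frames enter the covariance as stored
#'   (useful for ensembles with a known laboratory-frame covariance).
#' @param two_pass If `FALSE`, the single fit to the starting reference is
#'   kept (the convention under which the covariance trace equals the sum
#'   of squared RMSF values from [rmsf_profile()] exactly).
#' @return A `cov_model`: list with `mean` (`N x 3`, nm), `covariance`
#'   (`3N x 3N`, nm^2), `values` (nm^2, descending), `vectors`
#'   (orthonormal columns), `tmsf` (trace, nm^2), `n_atoms`, `n_frames`,
#'   `selection`, `fit`, `fit_reference`, `atoms`.
#' @export
build_covariance <- function(x, selection = NULL, fit = NULL, fit_frames = TRUE,
                             two_pass = TRUE) {
  nf <- n_frames(x)
  if (nf < 2) abort("covariance needs at least 2 frames")
  selection <- selection %||% seq_len(n_atoms(x))
  fit <- fit %||% selection
  n <- length(selection)
  mat <- matrix(0, nrow = nf, ncol = 3 * n)
  if (fit_frames) {
    spec1 <- fit_spec(fit, selection, frame_coords(x, 1))
    for (i in seq_len(nf)) {
      f <- .fit_frame(frame_coords(x, i), spec1)
      mat[i, ] <- as.vector(t(f[selection, , drop = FALSE]))
    }
    if (two_pass) {
      mu1 <- matrix(colMeans(mat), ncol = 3, byrow = TRUE)
      # second pass: re-fit to the first-pass average structure
      ref2 <- frame_coords(x, 1)
      ref2[selection, ] <- mu1
      spec2 <- fit_spec(fit, selection, ref2)
      for (i in seq_len(nf)) {
        f <- .fit_frame(frame_coords(x, i), spec2)
        mat[i, ] <- as.vector(t(f[selection, , drop = FALSE]))
      }
      fit_reference <- ref2
    } else {
      fit_reference <- spec1$reference
    }
  } else {
    for (i in seq_len(nf)) {
      mat[i, ] <- as.vector(t(frame_coords(x, i)[selection, , drop = FALSE]))
    }
    fit_reference <- NULL
  }
  mu <- colMeans(mat)
  dev <- sweep(mat, 2, mu)
  covm <- crossprod(dev) / nf
  eg <- eigen(covm, symmetric = TRUE)
  vals <- eg$values
  vecs <- eg$vectors
  # sign convention: largest-magnitude component positive
  for (k in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  structure(
    list(
      mean = matrix(mu, ncol = 3, byrow = TRUE),
      covariance = covm, values = vals, vectors = vecs,
      tmsf = sum(diag(covm)), n_atoms = n, n_frames = nf,
      selection = selection, fit = fit, fit_reference = fit_reference,
      atoms = if (!is.null(x$atoms)) x$atoms[selection, , drop = FALSE] else NULL
    ),
    class = "cov_model"
  )
}

#' @export
print.cov_model <- function(x, ...) {
  cc <- cumulative_contribution(pmax(x$values, 0))
  cat(sprintf(
    "<cov_model> %d atoms, %d frames; TMSF %.4g nm^2; top-2 modes %.1f%% of TMSF\n",
    x$n_atoms, x$n_frames, x$tmsf, cc$cumulative_pct[min(2, nrow(cc))]
  ))
  invisible(x)
}

#' Cumulative contribution of eigenvectors to the total fluctuation
#'
#' @param eigenvalues Non-negative eigenvalues sorted in descending order
#'   (small negative round-off is tolerated and clamped).
#' @return A tibble with columns `mode`, `eigenvalue`, `pct`,
#'   `cumulative_pct`; the cumulative column is non-decreasing and ends at
#'   100.
#' @export
#' @examples
#' cumulative_contribution(c(4, 3, 2, 1))$cumulative_pct[2] # 70
cumulative_contribution <- function(eigenvalues) {
  tol <- 1e-8 * max(abs(eigenvalues), 1)
  if (any(eigenvalues < -tol)) abort("eigenvalues must be non-negative")
  if (is.unsorted(rev(eigenvalues))) abort("eigenvalues must be sorted in descending order")
  ev <- pmax(eigenvalues, 0)
  total <- sum(ev)
  if (total <= 0) abort("all eigenvalues are zero")
  tibble(
    mode = seq_along(ev), eigenvalue = ev,
    pct = 100 * ev / total,
    cumulative_pct = 100 * cumsum(ev) / total
  )
}

# Fit frames exactly as build_covariance's final pass did, and return the
# mean-centered row matrix over the analysis selection.
.centered_frame_matrix <- function(x, model) {
  nf <- n_frames(x)
  mat <- matrix(0, nrow = nf, ncol = 3 * model$n_atoms)
  if (!is.null(model$fit_reference)) {
    spec <- fit_spec(model$fit, model$selection, model$fit_reference)
    for (i in seq_len(nf)) {
      f <- .fit_frame(frame_coords(x, i), spec)
      mat[i, ] <- as.vector(t(f[model$selection, , drop = FALSE]))
    }
  } else {
    for (i in seq_len(nf)) {
      mat[i, ] <- as.vector(t(frame_coords(x, i)[model$selection, , drop = FALSE]))
    }
  }
  sweep(mat, 2, as.vector(t(model$mean)))
}

#' Project a trajectory onto an eigenvector
#'
#' Each frame is fitted as during covariance construction, mean-centered,
#' and dotted with the requested eigenvector. By construction the series
#' has mean ~0 and variance equal to the corresponding eigenvalue.
#'
#' @param x An `md_trajectory`.
#' @param model A [build_covariance()] result.
#' @param index Eigenvector index (1 = largest eigenvalue).
#' @return A tibble (class `td_projection`) with columns `frame`,
#'   `time_ps`, `proj_nm`; the eigenvector index and eigenvalue are
#'   attached as attributes.
#' @export
project_trajectory <- function(x, model, index = 1) {
  stopifnot(inherits(model, "cov_model"))
  if (index < 1 || index > ncol(model$vectors)) {
    abort(sprintf("eigenvector index %d out of range 1..%d", index, ncol(model$vectors)))
  }
  dev <- .centered_frame_matrix(x, model)
  p <- as.numeric(dev %*% model$vectors[, index])
  out <- tibble(frame = seq_len(n_frames(x)), time_ps = x$times_ps, proj_nm = p)
  attr(out, "index") <- index
  attr(out, "eigenvalue") <- model$values[index]
  class(out) <- c("td_projection", class(out))
  out
}

#' Cosine content of a projection series
#'
#' Measures how closely a principal-component projection resembles the
#' `i`-th half-period cosine,
#' `c_i = (2/T) (int cos(i pi t / T) p(t) dt)^2 / int p(t)^2 dt`,
#' with the integrals evaluated by the trapezoid rule on the frame time
#' grid. Values near 1 indicate random-diffusion-like, unconverged
#' sampling; values near 0 indicate converged sampling.
#'
#' @param series A [project_trajectory()] tibble, or a numeric vector with
#'   `times` supplied.
#' @param i Harmonic index (1 for the first eigenvector diagnostic).
#' @param times Frame times (only when `series` is a bare numeric vector).
#' @return A number in `[0, 1]`.
#' @export
cosine_content <- function(series, i = 1, times = NULL) {
  if (is.data.frame(series)) {
    p <- series$proj_nm
    t <- series$time_ps
  } else {
    p <- as.numeric(series)
    t <- times %||% seq_along(p)
  }
  if (length(p) < 3) abort("cosine content needs at least 3 frames")
  if (all(p == 0)) abort("cosine content undefined for an all-zero series")
  t <- t - t[1]
  T_tot <- t[length(t)]
  cosv <- cos(i * pi * t / T_tot)
  num <- pracma::trapz(t, cosv * p)^2 * 2 / T_tot
  den <- pracma::trapz(t, p^2)
  max(0, min(1, num / den))
}

#' Extreme conformations along an eigenvector (porcupine mode)
#'
#' Extracts the two conformations at the minimum and maximum of the
#' projection series and the per-atom displacement vectors
#' `(proj_max - proj_min) * eigenvector`, the quantities visualized in a
#' porcupine plot where each cone's direction and length give a C-alpha
#' atom's movement direction and amplitude.
#'
#' @param model A [build_covariance()] result.
#' @param series A [project_trajectory()] series for the same model.
#' @param index Eigenvector index (defaults to the series' own index).
#' @return A list with `conf_min`, `conf_max` (`N x 3` nm), `vectors`
#'   (tibble `atom`, `chain`, `resno`, `dx`, `dy`, `dz`, `length`), and
#'   `proj_range`.
#' @export
porcupine_extremes <- function(model, series, index = NULL) {
  stopifnot(inherits(model, "cov_model"))
  index <- index %||% attr(series, "index") %||% 1
  p <- series$proj_nm
  if (diff(range(p)) == 0) abort("projection series is constant; extremes undefined")
  ev <- matrix(model$vectors[, index], ncol = 3, byrow = TRUE)
  p_min <- min(p)
  p_max <- max(p)
  disp <- (p_max - p_min) * ev
  a <- model$atoms
  structure(list(
    conf_min = model$mean + p_min * ev,
    conf_max = model$mean + p_max * ev,
    vectors = tibble(
      atom = seq_len(nrow(ev)),
      chain = if (!is.null(a)) a$chain else NA_character_,
      resno = if (!is.null(a)) a$resno else seq_len(nrow(ev)),
      dx = disp[, 1], dy = disp[, 2], dz = disp[, 3],
      length = sqrt(rowSums(disp^2))
    ),
    proj_range = c(p_min, p_max), index = index
  ), class = "porcupine")
}

#' Write a porcupine mode as a two-model PDB plus a vector table
#'
#' @param x A [porcupine_extremes()] result.
#' @param pdb_path Output PDB path (two MODEL blocks: min and max
#'   extremes).
#' @param vectors_path Output TSV path for the per-atom displacement
#'   vectors.
#' @return `pdb_path`, invisibly.
#' @export
write_porcupine <- function(x, pdb_path, vectors_path = NULL) {
  a_nm <- rbind(as.vector(t(x$conf_min)), as.vector(t(x$conf_max))) * 10
  n <- nrow(x$conf_min)
  bio3d::write.pdb(
    file = pdb_path, xyz = round(a_nm, 3),
    resno = x$vectors$resno, resid = rep("ALA", n), eleno = seq_len(n),
    elety = rep("CA", n), chain = ifelse(is.na(x$vectors$chain), "A", x$vectors$chain)
  )
  if (!is.null(vectors_path)) .write_tsv_fixed(x$vectors, vectors_path)
  invisible(pdb_path)
}
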