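# Least-squares (Kabsch) superposition and the fluctuation metrics built
# on it: RMSD time series (self- and non-self-fitting), per-residue RMSF,
# region statistics, radius of gyration.

#' Select atom indices from a topology
#'
#' @param atoms Atom tibble (from an `md_structure` or `md_trajectory`).
#' @param chain,elety,resno Optional filters.
#' @param calpha If `TRUE`, restrict to CA atoms of standard residues.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(atoms, chain = NULL, elety = NULL, resno = NULL,
                         calpha = FALSE) {
  keep <- rep(TRUE, nrow(atoms))
  if (calpha) {
    keep <- keep & atoms$elety == "CA" & atoms$resid %in% .standard_aa3
    if ("type" %in% names(atoms)) keep <- keep & atoms$type == "ATOM"
  }
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  if (!is.null(elety)) keep <- keep & atoms$elety %in% elety
  if (!is.null(resno)) keep <- keep & atoms$resno %in% resno
  which(keep)
}

#' Superposition specification
#'
#' Separates the atom subset used to superpose (`fit`) from the subset the
#' metric is computed over (`measure`). Self-fitting of a monomer sets both
#' to the same monomer; non-self-fitting superposes on one monomer and
#' measures the other, so that relative inter-monomer displacement enters
#' the deviation.
#'
#' @param fit,measure Integer atom indices into the trajectory topology.
#' @param reference Reference conformation: an `n_atoms x 3` matrix in nm
#'   covering the full topology (typically the starting structure).
#' @return A `fit_spec`.
#' @export
fit_spec <- function(fit, measure, reference) {
  if (length(fit) < 3) abort("fit selection needs at least 3 atoms")
  if (length(measure) < 1) abort("measure selection must be non-empty")
  ref_fit <- reference[fit, , drop = FALSE]
  if (.points_rank(ref_fit) < 2) abort("fit selection is degenerate (collinear reference atoms)")
  structure(
    list(fit = as.integer(fit), measure = as.integer(measure), reference = reference),
    class = "fit_spec"
  )
}

.points_rank <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  qr(xc)$rank
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) RMSD between two paired coordinate sets, via singular value
#' decomposition of the cross-covariance with the usual sign correction
#' that excludes reflections.
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`.
#' @param weights Optional non-negative per-atom weights.
#' @return A list with `rotation` (3x3, determinant +1), `translation`
#'   (length-3), and `rmsd` (same unit as the input), such that
#'   `mobile %*% rotation + translation` superposes onto `reference`.
#' @export
#' @examples
#' ref <- matrix(rnorm(12), ncol = 3)
#' k <- kabsch_superpose(ref, ref)
#' k$rmsd # 0
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) abort("coordinate sets must have equal atom counts")
  if (n < 3) abort("superposition needs at least 3 atoms")
  w <- weights %||% rep(1, n)
  if (any(w < 0) || sum(w) <= 0) abort("weights must be non-negative with positive sum")
  w <- w / sum(w)
  cm_m <- colSums(mobile * w)
  cm_r <- colSums(reference * w)
  if (.points_rank(reference) < 2) abort("degenerate (collinear) reference coordinates")
  a <- sweep(mobile, 2, cm_m)
  b <- sweep(reference, 2, cm_r)
  h <- t(a * w) %*% b
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rot <- t(rot)
  fitted <- a %*% rot
  rmsd <- sqrt(sum(w * rowSums((fitted - b)^2)))
  list(rotation = rot, translation = as.numeric(cm_r - cm_m %*% rot), rmsd = rmsd)
}

# Fit one frame onto the reference over the fit selection; returns the
# whole transformed frame.
.fit_frame <- function(frame, spec) {
  k <- kabsch_superpose(frame[spec$fit, , drop = FALSE],
                        spec$reference[spec$fit, , drop = FALSE])
  sweep(frame %*% k$rotation, 2, k$translation, "+")
}

#' RMSD time series of a trajectory
#'
#' Every frame is least-squares fitted to the reference over the `fit`
#' selection of `spec`, and the RMSD is then computed over the `measure`
#' selection relative to the reference (by convention, the starting
#' structure).
#'
#' @param x An `md_trajectory`.
#' @param spec A [fit_spec()].
#' @return A tibble (class `td_rmsd`) with columns `frame`, `time_ps`,
#'   `rmsd_nm`.
#' @export
rmsd_series <- function(x, spec) {
  stopifnot(inherits(spec, "fit_spec"))
  if (max(spec$fit, spec$measure) > n_atoms(x)) abort("selection exceeds trajectory topology")
  ref_m <- spec$reference[spec$measure, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(x)), function(i) {
    f <- .fit_frame(frame_coords(x, i), spec)
    sqrt(mean(rowSums((f[spec$measure, , drop = FALSE] - ref_m)^2)))
  }, numeric(1))
  out <- tibble(frame = seq_len(n_frames(x)), time_ps = x$times_ps, rmsd_nm = vals)
  class(out) <- c("td_rmsd", class(out))
  out
}

#' Per-residue RMSF profile
#'
#' Frames are fitted per `spec`; the root-mean-square fluctuation of each
#' measure atom is computed about its time-average position,
#' `RMSF_i = sqrt(<|r_i - <r_i>|^2>)`.
#'
#' @param x An `md_trajectory` with at least two frames.
#' @param spec A [fit_spec()]; the measure selection is typically the
#'   C-alpha set.
#' @return A tibble (class `td_rmsf`) with columns `chain`, `resno`,
#'   `elety`, `rmsf_nm`, one row per measure atom.
#' @export
rmsf_profile <- function(x, spec) {
  stopifnot(inherits(spec, "fit_spec"))
  nf <- n_frames(x)
  if (nf < 2) abort("RMSF is undefined for a single frame")
  m <- length(spec$measure)
  fitted <- array(0, dim = c(nf, m, 3))
  for (i in seq_len(nf)) {
    f <- .fit_frame(frame_coords(x, i), spec)
    fitted[i, , ] <- f[spec$measure, , drop = FALSE]
  }
  avg <- apply(fitted, c(2, 3), mean)
  dev2 <- vapply(seq_len(m), function(j) {
    mean(rowSums(sweep(fitted[, j, , drop = TRUE], 2, avg[j, ])^2))
  }, numeric(1))
  a <- x$atoms
  out <- tibble(
    chain = if (!is.null(a)) a$chain[spec$measure] else NA_character_,
    resno = if (!is.null(a)) a$resno[spec$measure] else spec$measure,
    elety = if (!is.null(a)) a$elety[spec$measure] else NA_character_,
    rmsf_nm = sqrt(dev2)
  )
  class(out) <- c("td_rmsf", class(out))
  out
}

#' Region-wise RMSF statistics
#'
#' Arithmetic mean and population standard deviation of the per-residue
#' RMSF over the member residues of each region, the layout used to
#' summarise active-site components per monomer.
#'
#' @param profile A [rmsf_profile()] tibble.
#' @param regions Resolved regions ([resolve_regions()]): columns `region`,
#'   `chain`, `resno`.
#' @param monomer Label attached to the output rows (e.g. `"A"`).
#' @return A tibble with columns `monomer`, `region`, `n_residues`,
#'   `mean_nm`, `sd_nm`.
#' @export
region_rmsf_stats <- function(profile, regions, monomer = NA_character_) {
  out <- lapply(split(regions, regions$region), function(rg) {
    idx <- match(paste(rg$chain, rg$resno), paste(profile$chain, profile$resno))
    if (anyNA(idx)) {
      miss <- rg[is.na(idx), , drop = FALSE]
      abort(sprintf(
        "region '%s' residue(s) absent from RMSF profile: %s",
        rg$region[1], paste(sprintf("%s:%d", miss$chain, miss$resno), collapse = ", ")
      ))
    }
    v <- profile$rmsf_nm[idx]
    if (length(v) == 0) abort(sprintf("region '%s' is empty", rg$region[1]))
    tibble(
      monomer = monomer, region = rg$region[1], n_residues = length(v),
      mean_nm = mean(v), sd_nm = sqrt(mean((v - mean(v))^2))
    )
  })
  bind_rows(out)
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the atoms from their centre
#' of mass, in the unit of the input coordinates.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param masses Per-atom masses; equal masses by default.
#' @return A single number.
#' @export
#' @examples
#' radius_of_gyration(matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE)) # 0.5
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 1) abort("radius of gyration needs at least one atom")
  m <- masses %||% rep(1, n)
  if (sum(m) <= 0) abort("total mass must be positive")
  w <- m / sum(m)
  cm <- colSums(coords * w)
  sqrt(sum(w * rowSums(sweep(coords, 2, cm)^2)))
}
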