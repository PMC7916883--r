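# Trajectory container and I/O.
#
# Coordinates live in an n_frames x n_atoms x 3 array in nanometres; the
# Angstrom/nm conversion is confined to the PDB boundary. Frame times are
# in picoseconds.

#' Construct a trajectory
#'
#' @param coords Numeric array `n_frames x n_atoms x 3`, in nm.
#' @param times_ps Strictly increasing frame times in ps (default: 10 ps
#'   spacing starting at 0, the usual coordinate-saving interval).
#' @param atoms Topology tibble shared with an [read_structure()] result
#'   (columns at least `elety`, `resid`, `chain`, `resno`).
#' @param provenance Optional tibble mapping each frame to its origin
#'   (`frame`, `replica`, `time_ps_orig`).
#' @return An `md_trajectory`.
#' @export
md_trajectory <- function(coords, times_ps = NULL, atoms = NULL, provenance = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    abort("coords must be an n_frames x n_atoms x 3 array")
  }
  nf <- dim(coords)[1]
  times_ps <- times_ps %||% ((seq_len(nf) - 1) * 10)
  if (length(times_ps) != nf) abort("times_ps length must equal the frame count")
  if (nf > 1 && any(diff(times_ps) <= 0)) abort("frame times must be strictly increasing")
  structure(
    list(coords = coords, times_ps = as.numeric(times_ps), atoms = atoms,
         provenance = provenance),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(
    "<md_trajectory> %d frames x %d atoms, t = %.1f..%.1f ps\n",
    n_frames(x), n_atoms(x), min(x$times_ps), max(x$times_ps)
  ))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param x An `md_trajectory`.
#' @return An integer.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(x) dim(x$coords)[2]

#' Extract one frame as an n_atoms x 3 matrix (nm)
#' @param x An `md_trajectory`.
#' @param i Frame index.
#' @return A numeric matrix.
#' @export
frame_coords <- function(x, i) {
  matrix(x$coords[i, , ], ncol = 3)
}

#' Build a trajectory from a structure plus per-frame coordinates
#'
#' @param x An `md_structure` (coordinates in Angstrom).
#' @param n_copies Number of identical frames.
#' @return An `md_trajectory` whose every frame is the structure, in nm.
#' @export
trajectory_from_structure <- function(x, n_copies = 1) {
  xyz <- as.matrix(x$atoms[, c("x", "y", "z")]) / 10
  coords <- array(0, dim = c(n_copies, nrow(xyz), 3))
  for (i in seq_len(n_copies)) coords[i, , ] <- xyz
  md_trajectory(coords, atoms = x$atoms)
}

#' Read a trajectory from a multi-model PDB file
#'
#' The required interchange dialect is multi-model PDB (`MODEL`/`ENDMDL`
#' records). Frame times are taken from a sidecar TSV (`<path>.times.tsv`,
#' columns `frame`, `time_ps` and optionally `replica`) when present,
#' otherwise a uniform spacing is assumed.
#'
#' @param path Path to the multi-model PDB file.
#' @param dt_ps Frame spacing (ps) used when no sidecar table exists.
#' @return An `md_trajectory` (coordinates converted to nm).
#' @export
read_trajectory <- function(path, dt_ps = 10) {
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- as_tibble(p$atom)
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms$element <- .infer_element(atoms$elety, atoms$elesy)
  nf <- nrow(p$xyz)
  na <- nrow(atoms)
  coords <- array(0, dim = c(nf, na, 3))
  for (i in seq_len(nf)) {
    coords[i, , ] <- matrix(p$xyz[i, ], ncol = 3, byrow = TRUE) / 10
  }
  sidecar <- paste0(path, ".times.tsv")
  times <- (seq_len(nf) - 1) * dt_ps
  provenance <- NULL
  if (file.exists(sidecar)) {
    tt <- read.table(sidecar, header = TRUE, sep = "\t")
    if (nrow(tt) != nf) abort("sidecar time table row count does not match frame count")
    times <- tt$time_ps
    if ("replica" %in% names(tt)) {
      provenance <- tibble(frame = seq_len(nf), replica = tt$replica, time_ps_orig = tt$time_ps)
    }
  }
  md_trajectory(coords, times_ps = times, atoms = atoms, provenance = provenance)
}

#' Write a trajectory to a multi-model PDB file
#'
#' Writes `MODEL`/`ENDMDL` blocks (coordinates back-converted to Angstrom)
#' plus the frame-time sidecar TSV `<path>.times.tsv`.
#'
#' @param x An `md_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path) {
  a <- x$atoms
  if (is.null(a)) abort("trajectory has no atom topology; cannot write PDB")
  nf <- n_frames(x)
  xyz <- matrix(0, nrow = nf, ncol = 3 * n_atoms(x))
  for (i in seq_len(nf)) {
    xyz[i, ] <- as.vector(t(frame_coords(x, i))) * 10
  }
  na <- nrow(a)
  bio3d::write.pdb(
    file = path, xyz = round(xyz, 3),
    type = if ("type" %in% names(a)) a$type else rep("ATOM", na),
    resno = a$resno, resid = a$resid,
    eleno = if ("eleno" %in% names(a)) a$eleno else seq_len(na),
    elety = a$elety, chain = ifelse(a$chain == " ", "", a$chain),
    elesy = if ("element" %in% names(a)) a$element else NULL
  )
  side <- tibble(frame = seq_len(nf), time_ps = x$times_ps)
  if (!is.null(x$provenance)) side$replica <- x$provenance$replica
  .write_tsv_fixed(side, paste0(path, ".times.tsv"))
  invisible(path)
}

#' Discard the equilibration phase of a trajectory
#'
#' Retains frames with `start <= t <= end` (times given in ns). The usual
#' protocol keeps 10-100 ns of each 100-ns replica as its equilibrated
#' portion.
#'
#' @param x An `md_trajectory`.
#' @param start_ns,end_ns Window bounds in ns.
#' @return The trimmed `md_trajectory`; frame times are preserved.
#' @export
trim_equilibration <- function(x, start_ns, end_ns) {
  if (start_ns >= end_ns) abort("window start must be smaller than window end")
  t_ns <- x$times_ps / 1000
  keep <- t_ns >= start_ns & t_ns <= end_ns
  if (!any(keep)) abort("equilibration window lies outside the trajectory's time span")
  md_trajectory(
    x$coords[keep, , , drop = FALSE],
    times_ps = x$times_ps[keep], atoms = x$atoms,
    provenance = if (!is.null(x$provenance)) x$provenance[keep, , drop = FALSE]
  )
}

#' Concatenate replica trajectories into one joined trajectory
#'
#' Frames are kept in replica order and the time axis is re-indexed to a
#' continuous grid (the spacing of the first replica), so that integral
#' diagnostics such as the cosine content see one uninterrupted
#' trajectory. A provenance record maps each output frame back to its
#' (replica, original time).
#'
#' @param replicas List of `md_trajectory` objects sharing one topology.
#' @return A joined `md_trajectory` with a `provenance` tibble.
#' @export
concatenate_replicas <- function(replicas) {
  if (!is.list(replicas) || length(replicas) == 0) abort("need at least one replica")
  if (length(replicas) == 1 && inherits(replicas[[1]], "md_trajectory")) {
    x <- replicas[[1]]
    prov <- tibble(frame = seq_len(n_frames(x)), replica = 1L, time_ps_orig = x$times_ps)
    return(md_trajectory(x$coords, x$times_ps, x$atoms, provenance = prov))
  }
  na0 <- n_atoms(replicas[[1]])
  for (i in seq_along(replicas)) {
    if (n_atoms(replicas[[i]]) != na0) {
      abort(sprintf("replica %d has %d atoms, expected %d", i, n_atoms(replicas[[i]]), na0))
    }
  }
  nf_each <- vapply(replicas, n_frames, integer(1))
  nf <- sum(nf_each)
  coords <- array(0, dim = c(nf, na0, 3))
  dt <- if (n_frames(replicas[[1]]) > 1) diff(replicas[[1]]$times_ps)[1] else 10
  times <- numeric(nf)
  prov <- vector("list", length(replicas))
  at <- 0L
  t_off <- 0
  for (i in seq_along(replicas)) {
    r <- replicas[[i]]
    idx <- at + seq_len(nf_each[i])
    coords[idx, , ] <- r$coords
    times[idx] <- t_off + (seq_len(nf_each[i]) - 1) * dt
    prov[[i]] <- tibble(frame = idx, replica = i, time_ps_orig = r$times_ps)
    t_off <- times[idx[length(idx)]] + dt
    at <- at + nf_each[i]
  }
  md_trajectory(coords, times, replicas[[1]]$atoms, provenance = bind_rows(prov))
}

# Fixed-format TSV writer: numeric columns rendered with a fixed number of
# decimals so re-runs are byte-identical.
.write_tsv_fixed <- function(df, path, digits = 10) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- formatC(out[[nm]], digits = digits, format = "f")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
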