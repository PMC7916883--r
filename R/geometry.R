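# Frame-wise geometric parameters with explicit criteria: solvent
# accessible surface area, close inter-atomic contacts, hydrogen bonds,
# and their trajectory summaries. All cutoffs are strict inequalities, and
# no bonded or same-residue exclusions are applied: a contact is defined
# purely by distance.

#' Geometric criteria configuration
#'
#' @param probe_radius Solvent probe radius in Angstrom (water probe,
#'   1.4 A).
#' @param contact_cutoff Close-contact distance cutoff in Angstrom
#'   (strict `<`).
#' @param hbond_dist Donor-acceptor heavy-atom distance cutoff in Angstrom
#'   (strict `<`).
#' @param hbond_angle Donor-hydrogen-acceptor angle cutoff in degrees
#'   (strict `>`).
#' @param radii Named per-element van der Waals radii (Angstrom).
#' @param sasa_points Number of sphere sample points per atom.
#' @return A `geometry_config` list.
#' @export
geometry_config <- function(probe_radius = 1.4, contact_cutoff = 6,
                            hbond_dist = 3.5, hbond_angle = 120,
                            radii = vdw_radii(), sasa_points = 960) {
  stopifnot(probe_radius > 0, contact_cutoff > 0, hbond_dist > 0,
            hbond_angle > 0, hbond_angle < 180, sasa_points >= 12)
  structure(
    list(probe_radius = probe_radius, contact_cutoff = contact_cutoff,
         hbond_dist = hbond_dist, hbond_angle = hbond_angle,
         radii = radii, sasa_points = sasa_points),
    class = "geometry_config"
  )
}

# Deterministic, evenly distributed unit-sphere point set (golden-spiral
# construction); the same fixed set is used for every atom so results are
# bit-reproducible.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent accessible surface area
#'
#' Shrake-Rupley style numeric SASA: each atom's solvent-expanded sphere
#' (van der Waals radius + probe) is sampled with a fixed golden-spiral
#' point set and the fraction of points not buried inside any neighbour's
#' expanded sphere gives its exposed area.
#'
#' @param coords `n x 3` coordinates in Angstrom.
#' @param elements Per-atom element symbols used to look up radii.
#' @param config A [geometry_config()].
#' @return A list with `total` (Angstrom^2) and `per_atom` (numeric vector,
#'   summing exactly to `total`).
#' @export
sasa <- function(coords, elements, config = geometry_config()) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  elements <- toupper(elements)
  missing_el <- setdiff(unique(elements), names(config$radii))
  if (length(missing_el) > 0) {
    abort(sprintf(
      "no van der Waals radius for element(s): %s",
      paste(missing_el, collapse = ", ")
    ))
  }
  rad <- unname(config$radii[elements]) + config$probe_radius
  pts <- .sphere_points(config$sasa_points)
  per_atom <- numeric(n)
  # neighbour candidates: centre distance below the sum of expanded radii
  max_rad <- max(rad)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
    p <- sweep(pts * rad[i], 2, coords[i, ], "+")
    if (length(nb) > 0) {
      free <- rep(TRUE, nrow(p))
      for (j in nb) {
        if (!any(free)) break
        dj2 <- rowSums(sweep(p[free, , drop = FALSE], 2, coords[j, ])^2)
        free[free] <- dj2 >= rad[j]^2
      }
      n_free <- sum(free)
    } else {
      n_free <- nrow(p)
    }
    per_atom[i] <- 4 * pi * rad[i]^2 * n_free / nrow(p)
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Count close inter-atomic contacts
#'
#' Counts unordered atom pairs closer than the cutoff (strict `<`). With
#' only `sel_a` given, all pairs within the selection are considered
#' (intra-molecular mode); with both selections, pairs spanning the two
#' groups are counted once each (e.g. inter-monomer contacts).
#'
#' @param coords `n x 3` coordinates in Angstrom.
#' @param sel_a,sel_b Integer atom indices; `sel_b = NULL` for the
#'   intra-group mode.
#' @param cutoff Distance cutoff in Angstrom.
#' @param return_pairs If `TRUE`, also return the pair list.
#' @return The count, or (with `return_pairs`) a list with `count` and a
#'   `pairs` tibble (`i`, `j`, `distance`).
#' @export
close_contacts <- function(coords, sel_a, sel_b = NULL, cutoff = 6,
                           return_pairs = FALSE) {
  coords <- as.matrix(coords)
  if (length(sel_a) == 0) abort("selection A is empty")
  intra <- is.null(sel_b)
  if (intra) sel_b <- sel_a
  if (length(sel_b) == 0) abort("selection B is empty")
  a <- coords[sel_a, , drop = FALSE]
  b <- coords[sel_b, , drop = FALSE]
  # squared cross distances in blocks to bound memory
  hits_i <- integer(0)
  hits_j <- integer(0)
  block <- max(1L, floor(2e6 / length(sel_b)))
  for (s in seq(1, length(sel_a), by = block)) {
    rows <- s:min(s + block - 1, length(sel_a))
    d2 <- outer(rowSums(a[rows, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * a[rows, , drop = FALSE] %*% t(b)
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      hits_i <- c(hits_i, sel_a[rows[hit[, 1]]])
      hits_j <- c(hits_j, sel_b[hit[, 2]])
    }
  }
  keep <- hits_i != hits_j
  gi <- pmin(hits_i[keep], hits_j[keep])
  gj <- pmax(hits_i[keep], hits_j[keep])
  key <- paste(gi, gj)
  first <- !duplicated(key)
  gi <- gi[first]
  gj <- gj[first]
  count <- length(gi)
  if (!return_pairs) {
    return(count)
  }
  dist <- sqrt(rowSums((coords[gi, , drop = FALSE] - coords[gj, , drop = FALSE])^2))
  list(count = count, pairs = tibble(i = gi, j = gj, distance = dist))
}

# Assign each hydrogen to its parent heavy atom (nearest N/O/C/S within
# bonding distance).
.hydrogen_parents <- function(coords, elements, max_bond = 1.25) {
  h_idx <- which(elements == "H")
  heavy <- which(elements != "H")
  if (length(h_idx) == 0 || length(heavy) == 0) {
    return(tibble(h = integer(0), parent = integer(0)))
  }
  parent <- vapply(h_idx, function(h) {
    d2 <- rowSums(sweep(coords[heavy, , drop = FALSE], 2, coords[h, ])^2)
    j <- which.min(d2)
    if (d2[j] <= max_bond^2) heavy[j] else NA_integer_
  }, integer(1))
  tibble(h = h_idx, parent = parent)[!is.na(parent), ]
}

#' Detect hydrogen bonds by geometric criteria
#'
#' A hydrogen bond exists iff the donor-acceptor heavy-atom distance is
#' below `hbond_dist` (strict) and the donor-hydrogen-acceptor angle
#' exceeds `hbond_angle` (strict). Donors are N/O atoms with a covalently
#' bound hydrogen (assigned geometrically); acceptors are all N/O atoms.
#' Water oxygens act as both donor parents and acceptors.
#'
#' @param coords `n x 3` coordinates in Angstrom.
#' @param atoms Atom tibble with `element`, `resid`, `chain`, `resno`.
#' @param config A [geometry_config()].
#' @param mode `"intra"` (both partners protein), `"protein_solvent"`
#'   (one partner water), or `"all"`.
#' @return A list with `count` (unique donor-acceptor pairs) and `bonds`
#'   (tibble `donor`, `hydrogen`, `acceptor`, `distance`, `angle`).
#' @export
hydrogen_bonds <- function(coords, atoms, config = geometry_config(),
                           mode = c("intra", "protein_solvent", "all")) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  el <- toupper(atoms$element)
  is_water <- atoms$resid %in% .water_resnames
  polar <- which(el %in% c("N", "O"))
  hp <- .hydrogen_parents(coords, el)
  if (nrow(hp) == 0 && length(polar) > 0) {
    inform("no bound hydrogens found; all potential donors skipped")
  }
  hp <- hp[hp$parent %in% polar, , drop = FALSE]
  acceptors <- polar
  bonds <- list()
  for (r in seq_len(nrow(hp))) {
    d_idx <- hp$parent[r]
    h_idx <- hp$h[r]
    da2 <- rowSums(sweep(coords[acceptors, , drop = FALSE], 2, coords[d_idx, ])^2)
    cand <- acceptors[da2 < config$hbond_dist^2 & acceptors != d_idx]
    if (length(cand) == 0) next
    hd <- coords[d_idx, ] - coords[h_idx, ] # vector H -> donor
    ha <- sweep(coords[cand, , drop = FALSE], 2, coords[h_idx, ], "-") # H -> acceptor
    cosang <- (ha %*% hd) / (sqrt(rowSums(ha^2)) * sqrt(sum(hd^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    ok <- ang > config$hbond_angle
    if (any(ok)) {
      bonds[[length(bonds) + 1]] <- tibble(
        donor = d_idx, hydrogen = h_idx, acceptor = cand[ok],
        distance = sqrt(rowSums(sweep(coords[cand[ok], , drop = FALSE], 2,
                                      coords[d_idx, ])^2)),
        angle = ang[ok]
      )
    }
  }
  bonds <- if (length(bonds) > 0) bind_rows(bonds) else {
    tibble(donor = integer(0), hydrogen = integer(0), acceptor = integer(0),
           distance = numeric(0), angle = numeric(0))
  }
  if (mode == "intra") {
    bonds <- bonds[!is_water[bonds$donor] & !is_water[bonds$acceptor], , drop = FALSE]
  } else if (mode == "protein_solvent") {
    bonds <- bonds[xor(is_water[bonds$donor], is_water[bonds$acceptor]), , drop = FALSE]
  }
  # count unique donor-acceptor pairs (a donor with two hydrogens pointing
  # at the same acceptor contributes one bond)
  count <- nrow(distinct(bonds[, c("donor", "acceptor")]))
  list(count = count, bonds = bonds)
}

#' Trajectory summary of structural/geometrical parameters
#'
#' Computes, for every frame, the solvent accessible surface area (SASA),
#' the number of close inter-atomic contacts (NCIC) within the protein,
#' the mass-weighted radius of gyration (Rg), and the numbers of
#' intra-protein and protein-solvent hydrogen bonds (NHB), then reports
#' the trajectory mean and standard deviation of each.
#'
#' @param x An `md_trajectory` whose topology identifies elements and
#'   water residues.
#' @param config A [geometry_config()].
#' @return A tibble (class `td_geometry`) with columns `parameter`, `unit`,
#'   `mean`, `sd`; the per-frame values are attached as the `per_frame`
#'   attribute. If the system contains no solvent, the protein-solvent NHB
#'   row is 0 and flagged via the `no_solvent` attribute.
#' @export
trajectory_geometry_summary <- function(x, config = geometry_config()) {
  if (n_frames(x) < 1) abort("trajectory has no frames")
  a <- x$atoms
  if (is.null(a)) abort("trajectory has no atom topology")
  is_water <- a$resid %in% .water_resnames
  protein <- which(!is_water)
  masses <- .atomic_masses[toupper(a$element[protein])]
  masses[is.na(masses)] <- 12
  no_solvent <- !any(is_water)
  if (no_solvent) inform("system contains no solvent; protein-solvent NHB reported as 0")
  rows <- lapply(seq_len(n_frames(x)), function(i) {
    xyz <- frame_coords(x, i) * 10 # nm -> Angstrom
    tibble(
      frame = i,
      sasa_A2 = sasa(xyz[protein, , drop = FALSE], a$element[protein], config)$total,
      ncic = close_contacts(xyz, protein, cutoff = config$contact_cutoff),
      rg_A = radius_of_gyration(xyz[protein, , drop = FALSE], masses),
      nhb_intra = hydrogen_bonds(xyz, a, config, mode = "intra")$count,
      nhb_protein_solvent = if (no_solvent) 0L else
        hydrogen_bonds(xyz, a, config, mode = "protein_solvent")$count
    )
  })
  per_frame <- bind_rows(rows)
  vals <- per_frame[, -1]
  out <- tibble(
    parameter = c("SASA", "NCIC", "Rg", "NHB_intra", "NHB_protein_solvent"),
    unit = c("A^2", "count", "A", "count", "count"),
    mean = unname(vapply(vals, mean, numeric(1))),
    sd = unname(vapply(vals, function(v) sqrt(mean((v - mean(v))^2)), numeric(1)))
  )
  attr(out, "per_frame") <- per_frame
  attr(out, "no_solvent") <- no_solvent
  class(out) <- c("td_geometry", class(out))
  out
}
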