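# Replicate-level statistics and the two-system comparative report.

#' Per-replica RMSD statistics over the equilibration window
#'
#' Trims each replica to the equilibration window, computes its RMSD
#' series against the shared reference, and reports the per-replica mean
#' and standard deviation. The per-replica SDs are the quantities compared
#' between systems by the one-sided test of structural-fluctuation
#' magnitude.
#'
#' @param replicas List of `md_trajectory` replicas.
#' @param spec A [fit_spec()] shared by all replicas.
#' @param start_ns,end_ns Equilibration window in ns (default 10-100 ns).
#' @param system Label attached to the rows.
#' @return A tibble with columns `system`, `replica`, `n_frames`,
#'   `mean_nm`, `sd_nm`.
#' @export
replica_rmsd_stats <- function(replicas, spec, start_ns = 10, end_ns = 100,
                               system = NA_character_) {
  if (length(replicas) < 1) abort("need at least one replica")
  rows <- lapply(seq_along(replicas), function(i) {
    tr <- trim_equilibration(replicas[[i]], start_ns, end_ns)
    r <- rmsd_series(tr, spec)
    tibble(
      system = system, replica = i, n_frames = nrow(r),
      mean_nm = mean(r$rmsd_nm), sd_nm = sd(r$rmsd_nm)
    )
  })
  bind_rows(rows)
}

#' One-sided two-sample t test
#'
#' Welch's unequal-variance t test by default (pooled-variance variant by
#' flag), one-sided with alternative "group A greater". Used on the two
#' sets of per-replica RMSD standard deviations to test whether one system
#' fluctuates more than the other.
#'
#' @param a,b Numeric vectors (e.g. per-replica SDs), length >= 2 each.
#' @param alternative `"a_greater"`, `"b_greater"` or `"two_sided"`.
#' @param pooled If `TRUE`, use the equal-variance (pooled) statistic.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `alternative`, `method`.
#' @export
#' @examples
#' one_sided_t_test(c(2.1, 2.0, 1.9), c(1.0, 1.1, 0.9))
one_sided_t_test <- function(a, b, alternative = c("a_greater", "b_greater", "two_sided"),
                             pooled = FALSE) {
  alternative <- match.arg(alternative)
  if (length(a) < 2 || length(b) < 2) abort("each group needs at least 2 values")
  alt <- switch(alternative, a_greater = "greater", b_greater = "less",
                two_sided = "two.sided")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      inform("both groups constant and equal; p = 0.5 by convention")
      return(tibble(
        statistic = 0, df = length(a) + length(b) - 2,
        p_value = if (alternative == "two_sided") 1 else 0.5,
        mean_a = mean(a), mean_b = mean(b),
        alternative = alternative,
        method = if (pooled) "pooled" else "welch"
      ))
    }
    abort("both groups have zero variance with different means; t undefined")
  }
  tt <- stats::t.test(a, b, alternative = alt, var.equal = pooled)
  tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
    alternative = alternative, method = if (pooled) "pooled" else "welch"
  )
}

#' Analyze one simulation system end-to-end
#'
#' Runs the standard comparative pipeline on a set of replicas: trims each
#' to the equilibration window, concatenates them into a joined
#' trajectory, and computes the geometry summary, the per-residue RMSF
#' profile with region statistics, the essential-dynamics model (TMSF,
#' spectrum, cosine contents of the first two eigenvectors) and the 2-D
#' free-energy landscape over the first two eigenvectors.
#'
#' @param replicas List of `md_trajectory` replicas.
#' @param system System label.
#' @param regions Optional region tibble ([region_set()] rows) to
#'   summarise RMSF over; resolved per monomer against the topology.
#' @param chains Chain ids of the two monomers (used for region
#'   resolution and self-fitting); defaults to the chains present.
#' @param start_ns,end_ns Equilibration window (ns).
#' @param temperature Temperature (K) for Boltzmann inversion.
#' @param fel_bins Bins per free-energy-landscape axis.
#' @param geometry Logical: compute the per-frame geometry summary (can be
#'   slow for large systems).
#' @param config A [geometry_config()].
#' @return An `md_system_analysis` list with elements `system`,
#'   `replica_stats`, `joined`, `rmsf`, `region_stats`, `ed` (cov_model),
#'   `spectrum`, `cosine`, `projections`, `fel`, `geometry`.
#' @export
analyze_system <- function(replicas, system = "system", regions = NULL,
                           chains = NULL, start_ns = 10, end_ns = 100,
                           temperature = 300, fel_bins = 32,
                           geometry = TRUE, config = geometry_config()) {
  if (length(replicas) < 1) abort("need at least one replica")
  atoms <- replicas[[1]]$atoms
  ref <- frame_coords(replicas[[1]], 1)
  ca <- if (!is.null(atoms)) select_atoms(atoms, calpha = TRUE) else seq_len(nrow(ref))
  if (length(ca) < 3) ca <- seq_len(nrow(ref))
  spec <- fit_spec(ca, ca, ref)
  rep_stats <- replica_rmsd_stats(replicas, spec, start_ns, end_ns, system = system)
  trimmed <- lapply(replicas, trim_equilibration, start_ns, end_ns)
  joined <- concatenate_replicas(trimmed)
  rmsf <- rmsf_profile(joined, spec)
  region_stats <- NULL
  if (!is.null(regions) && !is.null(atoms)) {
    chains <- chains %||% sort(unique(atoms$chain[ca]))
    if (length(chains) >= 2) {
      region_stats <- bind_rows(
        region_rmsf_stats(rmsf, .resolve_regions_atoms(regions, atoms[ca, ], chains[1], chains[2]), chains[1]),
        region_rmsf_stats(rmsf, .resolve_regions_atoms(regions, atoms[ca, ], chains[2], chains[1]), chains[2])
      )
    } else {
      region_stats <- region_rmsf_stats(
        rmsf, .resolve_regions_atoms(regions, atoms[ca, ], chains[1], chains[1]), chains[1]
      )
    }
  }
  ed <- build_covariance(joined, selection = ca)
  spectrum <- cumulative_contribution(pmax(ed$values, 0))
  p1 <- project_trajectory(joined, ed, 1)
  p2 <- project_trajectory(joined, ed, 2)
  cosine <- tibble(
    eigenvector = c(1L, 2L),
    cosine_content = c(cosine_content(p1, 1), cosine_content(p2, 2))
  )
  fel <- build_fel(p1, p2, nbins = fel_bins, temperature = temperature)
  geom <- if (geometry) trajectory_geometry_summary(joined, config) else NULL
  structure(list(
    system = system, replica_stats = rep_stats, joined = joined,
    rmsf = rmsf, region_stats = region_stats, ed = ed,
    spectrum = spectrum, cosine = cosine,
    projections = list(p1, p2), fel = fel, geometry = geom
  ), class = "md_system_analysis")
}

# region resolution against a bare atom table (C-alpha subset)
.resolve_regions_atoms <- function(regions, atoms, own_chain, other_chain) {
  out <- regions
  out$chain <- ifelse(out$monomer == "own", own_chain, other_chain)
  key <- paste(out$chain, out$resno)
  have <- paste(atoms$chain, atoms$resno)
  if (any(!(key %in% have))) {
    bad <- out[!(key %in% have), , drop = FALSE]
    abort(sprintf(
      "region residue(s) not present: %s",
      paste(sprintf("%s:%d (%s)", bad$chain, bad$resno, bad$region)[
        seq_len(min(5, nrow(bad)))
      ], collapse = ", ")
    ))
  }
  out[, c("region", "chain", "resno")]
}

#' Assemble a two-system comparison report
#'
#' Aligns the analyses of two systems side by side: geometry parameter
#' table, per-region RMSF, essential-dynamics summary (TMSF, cumulative
#' contributions, cosine contents), free-energy-landscape basin census,
#' replica statistics, and the one-sided test on the per-replica RMSD
#' SDs. When the systems' residue numbering differs, a `residue_map`
#' (from [map_residue_numbering()]) is used to place system-B RMSF values
#' on system-A numbering.
#'
#' @param res_a,res_b [analyze_system()] results.
#' @param residue_map Optional residue map tibble (columns `resno_a`,
#'   `resno_b`).
#' @param fel_levels Energy levels (kJ/mol) for the basin census.
#' @return An `md_comparison` list of tibbles.
#' @export
build_comparison_report <- function(res_a, res_b, residue_map = NULL,
                                    fel_levels = c(2, 3, 4)) {
  stopifnot(inherits(res_a, "md_system_analysis"), inherits(res_b, "md_system_analysis"))
  geometry <- NULL
  if (!is.null(res_a$geometry) && !is.null(res_b$geometry)) {
    geometry <- left_join(
      rename(res_a$geometry, mean_a = "mean", sd_a = "sd"),
      rename(as_tibble(res_b$geometry), mean_b = "mean", sd_b = "sd"),
      by = c("parameter", "unit")
    )
    geometry$mean_diff <- geometry$mean_b - geometry$mean_a
  }
  rmsf_b <- res_b$rmsf
  if (!is.null(residue_map)) {
    idx <- match(rmsf_b$resno, residue_map$resno_b)
    rmsf_b$resno <- residue_map$resno_a[idx]
    rmsf_b <- rmsf_b[!is.na(rmsf_b$resno), , drop = FALSE]
  }
  rmsf <- left_join(
    rename(res_a$rmsf, rmsf_a_nm = "rmsf_nm"),
    rename(as_tibble(rmsf_b), rmsf_b_nm = "rmsf_nm"),
    by = c("chain", "resno", "elety")
  )
  region <- NULL
  if (!is.null(res_a$region_stats) && !is.null(res_b$region_stats)) {
    region <- left_join(
      rename(res_a$region_stats, mean_a_nm = "mean_nm", sd_a_nm = "sd_nm"),
      rename(res_b$region_stats, mean_b_nm = "mean_nm", sd_b_nm = "sd_nm"),
      by = c("monomer", "region", "n_residues")
    )
  }
  ed <- tibble(
    system = c(res_a$system, res_b$system),
    n_calpha = c(res_a$ed$n_atoms, res_b$ed$n_atoms),
    tmsf_nm2 = c(res_a$ed$tmsf, res_b$ed$tmsf),
    top2_pct = c(res_a$spectrum$cumulative_pct[2], res_b$spectrum$cumulative_pct[2]),
    top10_pct = c(
      res_a$spectrum$cumulative_pct[min(10, nrow(res_a$spectrum))],
      res_b$spectrum$cumulative_pct[min(10, nrow(res_b$spectrum))]
    ),
    cosine1 = c(res_a$cosine$cosine_content[1], res_b$cosine$cosine_content[1]),
    cosine2 = c(res_a$cosine$cosine_content[2], res_b$cosine$cosine_content[2])
  )
  fel <- bind_rows(
    mutate(fel_report(res_a$fel, fel_levels), system = res_a$system, .before = 1),
    mutate(fel_report(res_b$fel, fel_levels), system = res_b$system, .before = 1)
  )
  sd_test <- one_sided_t_test(res_b$replica_stats$sd_nm, res_a$replica_stats$sd_nm,
                              alternative = "a_greater")
  structure(list(
    systems = c(res_a$system, res_b$system),
    geometry = geometry, rmsf = rmsf, region_stats = region,
    ed = ed, fel_basins = fel,
    replica_stats = bind_rows(res_a$replica_stats, res_b$replica_stats),
    sd_test = sd_test
  ), class = "md_comparison")
}

#' @export
print.md_comparison <- function(x, ...) {
  cat(sprintf("<md_comparison> %s vs %s\n", x$systems[1], x$systems[2]))
  cat(sprintf(
    "  one-sided test on per-replica RMSD SDs (%s > %s): t = %.3f, p = %.4g\n",
    x$systems[2], x$systems[1], x$sd_test$statistic, x$sd_test$p_value
  ))
  invisible(x)
}

#' Serialize / restore a comparison report as a directory of TSV files
#'
#' @param x An `md_comparison`.
#' @param dir Output directory (created if needed).
#' @return `dir` (write) or an `md_comparison` (read).
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "md_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(x$systems, file.path(dir, "systems.txt"))
  for (nm in c("geometry", "rmsf", "region_stats", "ed", "fel_basins",
               "replica_stats", "sd_test")) {
    if (!is.null(x[[nm]])) .write_tsv_fixed(x[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  out <- list(systems = readLines(file.path(dir, "systems.txt")))
  for (nm in c("geometry", "rmsf", "region_stats", "ed", "fel_basins",
               "replica_stats", "sd_test")) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    if (file.exists(f)) {
      out[[nm]] <- as_tibble(read.table(f, header = TRUE, sep = "\t",
                                        stringsAsFactors = FALSE))
    } else {
      out[nm] <- list(NULL)
    }
  }
  structure(out, class = "md_comparison")
}
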