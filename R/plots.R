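# ggplot2 visualisations and broom-style tidiers for result objects.

#' Tidiers for tidytraj result objects
#'
#' `tidy()` returns one row per component (eigenmode, landscape bin);
#' `glance()` returns a one-row model summary.
#'
#' @param x A `cov_model` or `fel_grid`.
#' @param ... Unused.
#' @name tidytraj-tidiers
NULL

#' @rdname tidytraj-tidiers
#' @method tidy cov_model
#' @export
tidy.cov_model <- function(x, ...) {
  cumulative_contribution(pmax(x$values, 0))
}

#' @rdname tidytraj-tidiers
#' @method glance cov_model
#' @export
glance.cov_model <- function(x, ...) {
  cc <- cumulative_contribution(pmax(x$values, 0))
  tibble(
    n_atoms = x$n_atoms, n_frames = x$n_frames, tmsf_nm2 = x$tmsf,
    top2_pct = cc$cumulative_pct[min(2, nrow(cc))],
    top10_pct = cc$cumulative_pct[min(10, nrow(cc))]
  )
}

#' @method autoplot td_rmsd
#' @export
autoplot.td_rmsd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ps / 1000, y = .data$rmsd_nm)) +
    ggplot2::geom_line(...) +
    ggplot2::labs(x = "time (ns)", y = "C-alpha RMSD (nm)")
}

#' @method autoplot td_rmsf
#' @export
autoplot.td_rmsf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$resno, y = .data$rmsf_nm,
                                       colour = .data$chain)) +
    ggplot2::geom_line(...) +
    ggplot2::labs(x = "residue number", y = "C-alpha RMSF (nm)", colour = "monomer")
}

#' @method autoplot cov_model
#' @export
autoplot.cov_model <- function(object, n_modes = 30, ...) {
  df <- head(tidy.cov_model(object), n_modes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(...) +
    ggplot2::labs(x = "eigenvector index", y = "eigenvalue (nm^2)")
}

#' @method autoplot fel_grid
#' @export
autoplot.fel_grid <- function(object, ...) {
  df <- tidy.fel_grid(object)
  df <- df[is.finite(df$free_energy), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ev1, y = .data$ev2,
                                   fill = .data$free_energy)) +
    ggplot2::geom_raster(...) +
    ggplot2::scale_fill_viridis_c(name = "F (kJ/mol)", direction = -1) +
    ggplot2::labs(x = "eigenvector 1 (nm)", y = "eigenvector 2 (nm)")
}

#' Plot an RMSD series, RMSF profile, eigenvalue spectrum or landscape
#'
#' Thin wrappers over the `autoplot()` methods.
#'
#' @param x The result object.
#' @param ... Passed to the underlying geoms.
#' @return A ggplot object.
#' @export
plot_rmsd <- function(x, ...) autoplot.td_rmsd(x, ...)

#' @rdname plot_rmsd
#' @export
plot_rmsf <- function(x, ...) autoplot.td_rmsf(x, ...)

#' @rdname plot_rmsd
#' @export
plot_eigen_spectrum <- function(x, ...) autoplot.cov_model(x, ...)

#' @rdname plot_rmsd
#' @export
plot_fel <- function(x, ...) autoplot.fel_grid(x, ...)
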