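#' Plot a richness sweep
#'
#' Faceted summary of a sweep: proportion of locally stable equilibria,
#' proportion of blow-ups (classical model), mean number of surviving
#' species with the `y = S` reference diagonal, and (bounded runs) the mean
#' interaction-selection statistic, all against initial richness.
#'
#' @param object A `glv_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glv_sweep <- function(object, ...) {
  s <- object$summary
  long <- s |>
    dplyr::select(dplyr::any_of(c("S", "prop_stable", "prop_blow_up",
                                  "mean_n_alive", "mean_delta_interaction"))) |>
    tidyr::pivot_longer(-"S", names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$S, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "initial richness S", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a simulated trajectory
#'
#' Abundance of every species against time, on a log axis.
#'
#' @param object A `glv_sim` run with `keep_trajectory = TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glv_sim <- function(object, ...) {
  if (is.null(object$trajectory))
    stop("simulation was run without keep_trajectory = TRUE", call. = FALSE)
  long <- object$trajectory |>
    tidyr::pivot_longer(-"time", names_to = "species", values_to = "N")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$N,
                                     group = .data$species)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time", y = "abundance") +
    ggplot2::theme_minimal()
}

#' Phase-plane portrait of a two-species model
#'
#' Vector field (arrows), zero-growth and ceiling isoclines (dashed lines)
#' and equilibria coloured by kind, in the style of a classical phase-plane
#' figure.
#'
#' @param object A [two_species_model()].
#' @param N1_range,N2_range Plot window; default upper limit is
#'   `1.2 * Nmax` for bounded models, otherwise 3x the largest single-species
#'   carrying capacity.
#' @param resolution Grid resolution of the vector field.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.two_species_model <- function(object, N1_range = NULL, N2_range = NULL,
                                       resolution = 15, ...) {
  if (is.null(N1_range) || is.null(N2_range)) {
    top <- if (object$bounded) 1.2 * object$Nmax else
      3 * max(-object$r[1] / object$A[1, 1], -object$r[2] / object$A[2, 2], 1)
    if (is.null(N1_range)) N1_range <- c(0, top)
    if (is.null(N2_range)) N2_range <- c(0, top)
  }
  vf <- vector_field_grid(object, N1_range, N2_range, resolution)
  norm <- sqrt(vf$dN1^2 + vf$dN2^2)
  len <- 0.035 * diff(N1_range)
  vf <- vf |> dplyr::mutate(
    u = ifelse(norm > 0, .data$dN1 / norm * len, 0),
    v = ifelse(norm > 0, .data$dN2 / norm * len, 0)
  )
  iso <- isoclines(object, N1_range, N2_range)
  eq <- enumerate_equilibria(object)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = vf,
      ggplot2::aes(x = .data$N1, y = .data$N2,
                   xend = .data$N1 + .data$u, yend = .data$N2 + .data$v),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.08, "cm")),
      linewidth = 0.2, colour = "grey50"
    ) +
    ggplot2::geom_path(
      data = iso,
      ggplot2::aes(x = .data$N1, y = .data$N2,
                   group = interaction(.data$isocline, .data$species),
                   colour = factor(.data$species)),
      linetype = "dashed"
    ) +
    ggplot2::geom_point(
      data = eq,
      ggplot2::aes(x = .data$N1, y = .data$N2, fill = .data$kind,
                   shape = .data$stability),
      size = 3
    ) +
    ggplot2::scale_shape_manual(
      values = c(stable = 21, unstable = 24, saddle = 23, marginal = 22)
    ) +
    ggplot2::coord_cartesian(xlim = N1_range, ylim = N2_range) +
    ggplot2::labs(x = expression(N[1]), y = expression(N[2]),
                  colour = "isocline of", fill = "equilibrium") +
    ggplot2::theme_minimal()
}
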