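#' Plot detected crossing events
#'
#' Event raster: start times along the run, one row per segment, coloured
#' by direction.
#'
#' @param object a `perm_events` tibble.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.perm_events <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     direction = ifelse(.data$direction > 0, "TB", "BT"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_start, y = .data$segment,
                                  colour = .data$direction)) +
    ggplot2::geom_point(shape = 124, size = 4) +
    ggplot2::labs(x = "event start (ns)", y = "segment",
                  colour = "direction") +
    ggplot2::theme_minimal()
}

#' Plot a waiting-time distribution with fitted models
#'
#' Histogram of the waiting times overlaid with the densities of any
#' supplied fitted models (single-Poisson, double-Poisson).
#'
#' @param waiting_times numeric vector, ns.
#' @param ... named waiting-time models ([poisson_model()] /
#'   [double_poisson_model()]) drawn as curves.
#' @return a ggplot object.
#' @export
plot_waiting_fit <- function(waiting_times, ...) {
  models <- list(...)
  d <- tibble::tibble(w = waiting_times)
  tt <- seq(0, max(waiting_times), length.out = 200)
  curves <- purrr::imap_dfr(models, function(m, nm) {
    tibble::tibble(t = tt, density = wait_pdf(m, tt), model = nm)
  })
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$w)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey80", colour = "grey50") +
    ggplot2::labs(x = "waiting time (ns)", y = "density") +
    ggplot2::theme_minimal()
  if (nrow(curves) > 0) {
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$t, y = .data$density, colour = .data$model),
      linewidth = 0.8)
  }
  p
}

#' Plot a channel profile
#'
#' Draws whichever observable the profile carries (pore radius,
#' bulk-normalized ion density, hydration/replacement counts, residue
#' position density) against z.
#'
#' @param object a `perm_profile` tibble.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.perm_profile <- function(object, ...) {
  panel <- attr(object, "panel") %||% "profile"
  d <- tibble::as_tibble(object)
  p <- switch(
    panel,
    pore_radius = ggplot2::ggplot(d, ggplot2::aes(.data$z_mid, .data$radius)) +
      ggplot2::geom_line() + ggplot2::labs(y = "pore radius (Å)"),
    ion_density = ggplot2::ggplot(
      d, ggplot2::aes(.data$z_mid, .data$density, colour = .data$species)) +
      ggplot2::geom_line() + ggplot2::labs(y = "density (bulk-normalized)"),
    hydration = ggplot2::ggplot(d, ggplot2::aes(.data$z_mid)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$hydration, colour = "hydration")) +
      ggplot2::geom_line(ggplot2::aes(y = .data$replacement, colour = "replacement")) +
      ggplot2::labs(y = "oxygens in first shell", colour = NULL),
    residue_positions = ggplot2::ggplot(
      d, ggplot2::aes(.data$z_mid, .data$density, colour = .data$resname)) +
      ggplot2::geom_line() + ggplot2::labs(y = "position density (1/Å)"),
    ggplot2::ggplot(d, ggplot2::aes(.data$z_mid, d[[2]])) + ggplot2::geom_line()
  )
  p + ggplot2::labs(x = "z (Å)") + ggplot2::theme_minimal()
}

#' Plot an I-V relation with branch fits
#'
#' @param points tibble with `ve_mv`, `current_pA`.
#' @param fit optional [fit_iv()] result; branch lines are drawn from it.
#' @return a ggplot object.
#' @export
plot_iv <- function(points, fit = NULL) {
  p <- ggplot2::ggplot(points, ggplot2::aes(.data$ve_mv, .data$current_pA)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Ve (mV)", y = "I (pA)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    lines <- purrr::map_dfr(fit$branches, function(b) {
      vr <- if (b$branch == "negative") range(points$ve_mv[points$ve_mv < 0])
            else range(points$ve_mv[points$ve_mv > 0])
      tibble::tibble(ve_mv = vr,
                     current_pA = b$intercept_pA + b$slope_pS / 1e3 * vr,
                     branch = b$branch)
    })
    p <- p + ggplot2::geom_line(
      data = lines, ggplot2::aes(colour = .data$branch), linewidth = 0.8)
  }
  p
}
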