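#' Classify axial versus lateral-fenestration entries
#'
#' An event's entry leg is lateral if, during a look-back window before its
#' start, the ion's radial distance from the pore axis exceeded the wall
#' threshold while its z lay within the extracellular-domain range — i.e.
#' the ion crossed the channel wall between subunits rather than descending
#' axially through the vestibule mouth. Events whose look-back window
#' extends before the start of the ion's trace are labelled axial with a
#' warning.
#'
#' @param events a `perm_events` tibble.
#' @param bundle the [perm_bundle()] the events were detected on.
#' @param radial_threshold wall radius, Angstrom (default: the counting
#'   cylinder radius).
#' @param ecd_range z-range of the extracellular wall, Angstrom (default
#'   `c(z_top, z_top + 40)`).
#' @param look_back_ns look-back before `t_start`, ns (default 5).
#' @param total_time_ns pooled trajectory time used for the lateral rate;
#'   default the bundle duration.
#' @return a list of class `pathway_report`: `events` (with `pathway`
#'   filled), `summary` (counts per direction/species/pathway), and scalar
#'   fields `lateral_fraction_tb`, `lateral_fraction_all` (potassium-only
#'   denominators), `lateral_rate_per_us`.
#' @export
classify_pathways <- function(events, bundle,
                              radial_threshold = NULL, ecd_range = NULL,
                              look_back_ns = 5, total_time_ns = NULL) {
  g <- bundle$geometry
  radial_threshold <- radial_threshold %||% g$cylinder_radius
  ecd_range <- ecd_range %||% c(g$z_top, g$z_top + 40)
  total_time_ns <- total_time_ns %||% bundle$metadata$duration_ns
  tr <- bundle$traces
  short_lookback <- character(0)

  pathway <- purrr::map_chr(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    d <- tr[tr$ion_id == ev$ion_id, ]
    if (nrow(d) == 0) return("axial")
    if (ev$t_start - look_back_ns < min(d$time_ns)) {
      # look-back precedes the trace: the entry leg cannot be assessed
      short_lookback <<- c(short_lookback, ev$ion_id)
      return("axial")
    }
    win <- d[d$time_ns >= ev$t_start - look_back_ns & d$time_ns <= ev$t_start, ]
    if (nrow(win) == 0) return("axial")
    r <- sqrt(win$x^2 + win$y^2)
    lateral <- any(r > radial_threshold &
                   win$z > ecd_range[1] & win$z < ecd_range[2])
    if (lateral) "lateral" else "axial"
  })
  if (length(short_lookback)) {
    warn(paste0("Look-back window precedes trace start for ",
                length(unique(short_lookback)),
                " ion(s); those events are labelled axial."))
  }
  events$pathway <- pathway
  summary <- events |>
    dplyr::count(.data$direction, .data$species, .data$pathway) |>
    tidyr::pivot_wider(names_from = "pathway", values_from = "n",
                       values_fill = 0L)
  if (!"lateral" %in% names(summary)) summary$lateral <- 0L
  if (!"axial" %in% names(summary)) summary$axial <- 0L
  n_lat <- sum(events$pathway == "lateral")
  n_tb_k <- sum(events$direction == 1 & events$species == "K+")
  n_k <- sum(events$species == "K+")
  structure(
    list(events = events, summary = summary,
         lateral_fraction_tb = if (n_tb_k > 0) n_lat / n_tb_k else NA_real_,
         lateral_fraction_all = if (n_k > 0) n_lat / n_k else NA_real_,
         lateral_rate_per_us = n_lat / (total_time_ns / 1e3)),
    class = "pathway_report"
  )
}

#' Lateral-pathway rates from event counts
#'
#' Counts-level arithmetic for the lateral-fenestration bookkeeping: the
#' lateral fraction of TB events, the lateral fraction of all (potassium)
#' events, and the lateral entry rate per microsecond of pooled simulation
#' time.
#'
#' @param n_lateral number of lateral entries.
#' @param n_tb total TB events (denominator of the TB fraction).
#' @param n_total total events in either direction.
#' @param time_us pooled simulation time, microseconds.
#' @return one-row tibble with `fraction_tb_pct`, `fraction_all_pct`,
#'   `rate_per_us`.
#' @export
pathway_rates <- function(n_lateral, n_tb, n_total, time_us) {
  if (any(c(n_tb, n_total, time_us) <= 0)) {
    abort("Denominators must be positive.")
  }
  tibble::tibble(
    n_lateral = n_lateral,
    fraction_tb_pct = 100 * n_lateral / n_tb,
    fraction_all_pct = 100 * n_lateral / n_total,
    rate_per_us = n_lateral / time_us
  )
}

#' @export
print.pathway_report <- function(x, ...) {
  cat(sprintf(
    "<pathway_report> %d lateral of %d events (TB fraction %.2f%%), %.2f /us\n",
    sum(x$events$pathway == "lateral"), nrow(x$events),
    100 * x$lateral_fraction_tb, x$lateral_rate_per_us))
  invisible(x)
}
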