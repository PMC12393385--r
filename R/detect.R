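#' Detect complete transmembrane crossing events
#'
#' Runs a per-ion three-zone state machine (above the top ring / inside the
#' bounded cylinder / below the bottom ring, with a radial gate at the
#' cylinder radius). A TB event is recorded when an ion passes
#' top -> inside -> bottom without leaving the cylinder radially while
#' inside; BT is symmetric. Only complete traversals count: an ion already
#' inside the region at the first frame (or still inside at the last)
#' contributes no event for that residency. A radial exit while inside
#' resets the ion to "outside on the side of its entry ring". An ion may
#' contribute any number of events.
#'
#' Event start and end times are, by default, linear interpolations of the
#' entry- and exit-ring crossings between the bracketing frames; with
#' `interpolate = FALSE` they are snapped to the first frame inside and the
#' first frame beyond the exit ring.
#'
#' @param bundle a [perm_bundle()] with unwrapped traces and geometry.
#' @param interpolate sub-frame interpolation of ring-crossing times
#'   (default TRUE).
#' @param segment segment identifier attached to the events (default "1").
#' @return a tibble of class `perm_events` with columns `segment`,
#'   `ion_id`, `species`, `charge`, `direction` (+1 TB, -1 BT), `t_start`,
#'   `t_end`, `duration`, `pathway` (axial until classified), ordered by
#'   `t_start`. Ions that skip the whole region between consecutive frames
#'   are flagged via a warning and the `skipped_ions` attribute.
#' @export
detect_crossings <- function(bundle, interpolate = TRUE, segment = "1") {
  g <- bundle$geometry
  if (is.null(g)) abort("Bundle has no channel geometry.")
  tr <- bundle$traces
  events <- list()
  skipped <- character(0)

  rings_at <- function(t) {
    if (!g$time_varying) {
      list(top = rep(g$z_top, length(t)), bottom = rep(g$z_bottom, length(t)))
    } else {
      rg <- g$rings
      idx <- findInterval(t, rg$time_ns, all.inside = TRUE)
      list(top = rg$z_top[idx], bottom = rg$z_bottom[idx])
    }
  }

  for (id in unique(tr$ion_id)) {
    d <- tr[tr$ion_id == id, ]
    d <- d[order(d$time_ns), ]
    n <- nrow(d)
    if (n < 2) next
    rr <- rings_at(d$time_ns)
    ztop <- rr$top; zbot <- rr$bottom
    r <- sqrt(d$x^2 + d$y^2)
    zone <- ifelse(d$z > ztop, 1L,
            ifelse(d$z < zbot, 3L,
            ifelse(r <= g$cylinder_radius, 2L, 4L)))
    runs <- rle(zone)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)

    cross_time <- function(i, boundary) {
      # boundary crossing between frames i-1 and i
      if (!interpolate || i < 2) return(d$time_ns[i])
      z0 <- d$z[i - 1]; z1 <- d$z[i]
      if (z1 == z0) return(d$time_ns[i])
      t0 <- d$time_ns[i - 1]; t1 <- d$time_ns[i]
      f <- (boundary - z0) / (z1 - z0)
      t0 + min(max(f, 0), 1) * (t1 - t0)
    }

    chg <- if ("charge" %in% names(d)) d$charge[1] else ion_charge(d$species[1])
    emit <- function(dirn, t_s, t_e) {
      events[[length(events) + 1]] <<- list(
        ion_id = id, species = d$species[1], charge = chg,
        direction = dirn, t_start = t_s, t_end = t_e)
    }

    state <- "U"      # A above | L below | IT inside-from-top | IB | IU unknown
    t_entry <- NA_real_
    prev_v <- NA_integer_
    for (k in seq_along(runs$values)) {
      v <- runs$values[k]; s <- starts[k]
      if (v == 1L) {                            # above the top ring
        if (state == "IB") emit(-1L, t_entry, cross_time(s, ztop[s]))
        if (state == "L" && identical(prev_v, 3L)) skipped <- c(skipped, id)
        state <- "A"
      } else if (v == 3L) {                     # below the bottom ring
        if (state == "IT") emit(1L, t_entry, cross_time(s, zbot[s]))
        if (state == "A" && identical(prev_v, 1L)) skipped <- c(skipped, id)
        state <- "L"
      } else if (v == 2L) {                     # inside the cylinder
        if (state == "A") { state <- "IT"; t_entry <- cross_time(s, ztop[s]) }
        else if (state == "L") { state <- "IB"; t_entry <- cross_time(s, zbot[s]) }
        else if (state == "U") state <- "IU"
      } else {                                  # radially outside, mid-height
        # radial exit resets the ion to the side of its entry ring
        if (state == "IT") state <- "A"
        else if (state == "IB") state <- "L"
        else if (state == "IU") state <- "U"
      }
      prev_v <- v
    }
  }

  out <- if (length(events)) {
    dplyr::bind_rows(lapply(events, tibble::as_tibble))
  } else {
    tibble::tibble(ion_id = character(), species = character(),
                   charge = integer(), direction = integer(),
                   t_start = numeric(), t_end = numeric())
  }
  out <- out |>
    dplyr::mutate(segment = segment, duration = .data$t_end - .data$t_start,
                  pathway = "axial") |>
    dplyr::select("segment", "ion_id", "species", "charge", "direction",
                  "t_start", "t_end", "duration", "pathway") |>
    dplyr::arrange(.data$t_start)
  skipped <- unique(skipped)
  if (length(skipped)) {
    warn(paste0("Ion(s) skipped the whole region between frames: ",
                paste(skipped, collapse = ", "),
                " (frame interval too coarse)."))
  }
  attr(out, "skipped_ions") <- skipped
  attr(out, "dt_ns") <- bundle$metadata$duration_ns
  attr(out, "ve_mv") <- bundle$metadata$voltage_mV
  class(out) <- c("perm_events", class(out))
  out
}

#' Assign events to fixed-length analysis segments
#'
#' Long runs are conventionally broken into windows (200 ns in the
#' reference analysis) treated as independent segments; an event belongs to
#' the window containing its start time.
#'
#' @param events a `perm_events` tibble.
#' @param segment_ns window length, ns.
#' @return the events with `segment` relabelled `"w1"`, `"w2"`, ...
#' @export
assign_segments <- function(events, segment_ns) {
  if (segment_ns <= 0) abort("`segment_ns` must be positive.")
  events$segment <- paste0("w", floor(events$t_start / segment_ns) + 1)
  events
}

#' Waiting times between consecutive events of one direction
#'
#' The waiting time is the interval between the start times of consecutive
#' events of the same direction. Intervals never span a segment boundary;
#' waiting times from different segments are pooled for distribution
#' fitting.
#'
#' @param events a `perm_events` tibble.
#' @param direction `"TB"`/`+1` or `"BT"`/`-1`.
#' @param species restrict to one species (default `"K+"`).
#' @return numeric vector of waiting times, ns (empty if fewer than 2
#'   events in any segment).
#' @export
waiting_times <- function(events, direction = "TB", species = "K+") {
  dirn <- .direction_code(direction)
  ev <- events[events$direction == dirn & events$species == species, ]
  if (nrow(ev) < 2) return(numeric(0))
  ev |>
    dplyr::group_by(.data$segment) |>
    dplyr::arrange(.data$t_start, .by_group = TRUE) |>
    dplyr::reframe(w = diff(.data$t_start)) |>
    dplyr::pull("w")
}

.direction_code <- function(direction) {
  if (is.character(direction)) {
    switch(toupper(direction), TB = 1L, BT = -1L,
           abort("`direction` must be 'TB' or 'BT'."))
  } else {
    as.integer(sign(direction))
  }
}

#' Event durations
#'
#' Traversal durations `t_end - t_start`, optionally restricted to one
#' direction.
#'
#' @param events a `perm_events` tibble.
#' @param direction optional `"TB"`/`"BT"` filter.
#' @return numeric vector, ns.
#' @export
event_durations <- function(events, direction = NULL) {
  ev <- events
  if (!is.null(direction)) ev <- ev[ev$direction == .direction_code(direction), ]
  ev$duration
}
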