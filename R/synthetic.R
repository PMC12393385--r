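#' Specification for a synthetic permeation run
#'
#' Defines the stochastic structure the analysis assumes: per-direction ion
#' entries following single- or double-Poisson statistics, log-normal
#' transit durations through the counting cylinder, an optional
#' lateral-fenestration entry fraction for top-to-bottom (TB) events, and
#' non-permeant bulk ions at the stated concentration. Defaults follow the
#' conducting-state study conditions: frames every 10 ps, TB potassium
#' entries from a double-Poisson process with component mean times 1 ns
#' (lag) and 3.62 ns (conduction), BT entries with 1.53 ns and 8.14 ns,
#' transits with mean 1.24 ns, chloride rates zero, 150 mM bulk.
#'
#' @param duration_ns run length, ns.
#' @param frame_interval_ps frame spacing, ps (default 10).
#' @param geometry a [channel_geometry()]; default rings at +/-20 A with the
#'   17.3 A counting radius.
#' @param entry_models named list of waiting-time models (or `NULL` for no
#'   entries) for streams `TB_K`, `BT_K`, `TB_Cl`, `BT_Cl`.
#' @param transit_mean_ns mean of the log-normal transit duration (default
#'   1.24).
#' @param transit_sigma_log log-scale sd of transit durations (default 0.45,
#'   which keeps more than 99 percent of transits above three frame
#'   intervals at the default frame spacing).
#' @param lateral_fraction probability that an entering TB ion approaches
#'   through a lateral fenestration in the extracellular wall (default 0).
#' @param box box edges `c(Lx, Ly, Lz)`, Angstrom, centred on the origin.
#' @param n_bulk number of non-permeant bulk ions; default from
#'   `bulk_concentration_mM` and the box volume.
#' @param bulk_concentration_mM bulk salt concentration, mM (default 150).
#' @param jitter_sd per-frame Gaussian positional jitter, Angstrom.
#' @param approach_ns bulk approach time before an entry crossing, ns.
#' @param seed default seed used by [generate_run()].
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duration_ns,
                           frame_interval_ps = 10,
                           geometry = channel_geometry(20, -20),
                           entry_models = list(
                             TB_K = double_poisson_model(1, 1 / 3.62),
                             BT_K = double_poisson_model(1 / 1.53, 1 / 8.14),
                             TB_Cl = NULL,
                             BT_Cl = NULL
                           ),
                           transit_mean_ns = 1.24,
                           transit_sigma_log = 0.45,
                           lateral_fraction = 0,
                           box = c(80, 80, 120),
                           n_bulk = NULL,
                           bulk_concentration_mM = 150,
                           jitter_sd = 1,
                           approach_ns = 2,
                           seed = 1L) {
  if (duration_ns <= 0) abort("`duration_ns` must be positive.")
  if (lateral_fraction < 0 || lateral_fraction > 1) {
    abort("`lateral_fraction` must lie in [0, 1].")
  }
  if (transit_mean_ns <= 0 || transit_sigma_log <= 0) {
    abort("Transit-duration parameters must be positive.")
  }
  if (transit_mean_ns > duration_ns / 2) {
    abort("Infeasible spec: transit duration comparable to the run length.")
  }
  if (box[1] < 2 * geometry$cylinder_radius || box[2] < 2 * geometry$cylinder_radius) {
    abort("Infeasible spec: box narrower than the counting cylinder.")
  }
  if (is.null(n_bulk)) {
    n_bulk <- round(ions_per_A3(bulk_concentration_mM) * prod(box))
  }
  structure(
    list(duration_ns = duration_ns, frame_interval_ps = frame_interval_ps,
         geometry = geometry, entry_models = entry_models,
         transit_mean_ns = transit_mean_ns,
         transit_sigma_log = transit_sigma_log,
         lateral_fraction = lateral_fraction, box = box, n_bulk = n_bulk,
         bulk_concentration_mM = bulk_concentration_mM,
         jitter_sd = jitter_sd, approach_ns = approach_ns, seed = seed),
    class = "synthetic_spec"
  )
}

#' Sample inter-event waiting times from a model
#'
#' Single-Poisson draws are exponential with the model rate; double-Poisson
#' draws are sums of two independent exponentials with the lag and
#' conduction rates.
#'
#' @param model a [poisson_model()] or [double_poisson_model()].
#' @param n number of draws, >= 1.
#' @param seed optional seed for reproducible draws.
#' @return numeric vector of `n` waiting times, ns.
#' @export
sample_waiting_times <- function(model, n, seed = NULL) {
  if (n < 1) abort("`n` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(model, "double_poisson_model")) {
    rexp(n, model$rate_lag) + rexp(n, model$rate_cond)
  } else if (inherits(model, "poisson_model")) {
    if (isTRUE(model$degenerate)) abort("Cannot sample from a degenerate model.")
    rexp(n, model$rate)
  } else {
    abort("Unknown waiting-time model.")
  }
}

# pre-entry bulk history per permeant, ns (covers the 5-ns pathway look-back)
.HISTORY_NS <- 5.5

# reflect a free path into [lo, hi] (triangular fold)
.reflect <- function(v, lo, hi) {
  L <- hi - lo
  u <- (v - lo) %% (2 * L)
  lo + ifelse(u > L, 2 * L - u, u)
}

# entry times of one stream: cumulative waits clipped to the run
.entry_times <- function(model, duration_ns) {
  if (is.null(model)) return(numeric(0))
  n_guess <- max(20, ceiling(2 * predicted_events(model, duration_ns)))
  w <- sample_waiting_times(model, n_guess)
  t <- cumsum(w)
  while (sum(t) > 0 && max(t) < duration_ns) {
    w2 <- sample_waiting_times(model, 20)
    t <- c(t, max(t) + cumsum(w2))
  }
  t[t < duration_ns]
}

# one permeant ion's trace on the global frame grid
.permeant_trace <- function(id, species, dirn, t_entry, transit, lateral,
                            spec, grid) {
  g <- spec$geometry
  dt <- spec$frame_interval_ps / 1000
  z_in <- if (dirn > 0) g$z_top else g$z_bottom
  z_out <- if (dirn > 0) g$z_bottom else g$z_top
  side <- if (dirn > 0) 1 else -1          # approach from above (TB) / below (BT)
  lead <- min(spec$approach_ns, t_entry)
  t_exit <- t_entry + transit
  tail_ns <- 1
  # permeants carry bulk history beyond the approach leg so that pathway
  # classification has a full default look-back window before t_start
  t0 <- max(0, t_entry - max(lead, .HISTORY_NS))
  t1 <- min(max(grid), t_exit + tail_ns + 1)
  tt <- grid[grid >= t0 & grid <= t1]
  if (length(tt) == 0) return(NULL)

  R <- g$cylinder_radius
  r0 <- runif(1, 0.1, 0.45) * R
  th <- runif(1, 0, 2 * pi)
  xc <- r0 * cos(th); yc <- r0 * sin(th)

  z <- numeric(length(tt))
  x <- rep(xc, length(tt))
  y <- rep(yc, length(tt))

  pre <- tt < t_entry
  mid <- tt >= t_entry & tt <= t_exit
  post <- tt > t_exit

  if (lateral && dirn > 0) {
    # side approach: radially outside the wall within the ECD, then descend
    z_ecd <- g$z_top + 8
    t_half <- t_entry - lead / 2
    ph1 <- tt < t_half
    ph2 <- pre & !ph1
    r_start <- R + 10
    frac1 <- (tt[ph1] - (t_entry - lead)) / (lead / 2)
    r_path <- r_start + (r0 - r_start) * pmin(pmax(frac1, 0), 1)
    x[ph1] <- r_path * cos(th); y[ph1] <- r_path * sin(th)
    z[ph1] <- z_ecd
    frac2 <- (tt[ph2] - t_half) / (lead / 2)
    z[ph2] <- z_ecd + (z_in - z_ecd) * frac2
  } else {
    z_far <- z_in + 12 * side
    frac <- if (lead > 0) (tt[pre] - (t_entry - lead)) / lead else numeric(0)
    z[pre] <- z_far + (z_in - z_far) * pmin(pmax(frac, 0), 1)
  }
  z[mid] <- z_in + (z_out - z_in) * (tt[mid] - t_entry) / transit
  fr_post <- pmin((tt[post] - t_exit) / tail_ns, 1)
  z[post] <- z_out - 10 * side * fr_post

  # per-frame jitter; clamped so traversal completion is never undone
  z <- z + rnorm(length(z), 0, spec$jitter_sd * 0.5)
  x <- x + rnorm(length(x), 0, spec$jitter_sd)
  y <- y + rnorm(length(y), 0, spec$jitter_sd)
  if (any(post)) {
    if (dirn > 0) z[post] <- pmin(z[post], z_out - 0.3)
    else          z[post] <- pmax(z[post], z_out + 0.3)
  }
  # keep permeants well inside the counting radius while between the rings
  between <- z < g$z_top & z > g$z_bottom & !pre
  r <- sqrt(x^2 + y^2)
  shrink <- between & r > 0.7 * R
  if (any(shrink)) {
    f <- (0.7 * R) / r[shrink]
    x[shrink] <- x[shrink] * f
    y[shrink] <- y[shrink] * f
  }
  tibble::tibble(time_ns = tt, ion_id = id, species = species,
                 x = x, y = y, z = z)
}

# non-permeant bulk ions random-walking outside the counting cylinder
.bulk_traces <- function(spec, grid) {
  n <- spec$n_bulk
  if (n == 0) return(NULL)
  g <- spec$geometry
  box <- spec$box
  R <- g$cylinder_radius
  nf <- length(grid)
  step_sd <- 0.8
  species <- rep(c("K+", "Cl-"), length.out = n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      x0 <- runif(1, -box[1] / 2, box[1] / 2)
      y0 <- runif(1, -box[2] / 2, box[2] / 2)
      z0 <- runif(1, -box[3] / 2, box[3] / 2)
      if (sqrt(x0^2 + y0^2) > R + 4 ||
          z0 > g$z_top + 4 || z0 < g$z_bottom - 4) break
    }
    x <- .reflect(x0 + c(0, cumsum(rnorm(nf - 1, 0, step_sd))), -box[1] / 2, box[1] / 2)
    y <- .reflect(y0 + c(0, cumsum(rnorm(nf - 1, 0, step_sd))), -box[2] / 2, box[2] / 2)
    z <- .reflect(z0 + c(0, cumsum(rnorm(nf - 1, 0, step_sd))), -box[3] / 2, box[3] / 2)
    # keep bulk ions out of the counting region (push radially to the wall)
    r <- sqrt(x^2 + y^2)
    inside <- r < R + 2 & z < g$z_top + 2 & z > g$z_bottom - 2
    if (any(inside)) {
      f <- (R + 3) / pmax(r[inside], 1e-6)
      x[inside] <- x[inside] * f
      y[inside] <- y[inside] * f
    }
    out[[i]] <- tibble::tibble(
      time_ns = grid, ion_id = sprintf("bulk_%s_%03d", sub("[+-]", "", species[i]), i),
      species = species[i], x = x, y = y, z = z)
  }
  dplyr::bind_rows(out)
}

#' Generate a synthetic permeation run with ground truth
#'
#' Draws entry times per direction from the configured waiting-time
#' processes, gives each permeant a noisy monotone path through the counting
#' cylinder over a log-normal transit duration (lateral entrants first
#' approach through a radial window above the top ring), adds random-walking
#' bulk ions outside the cylinder, and samples frames on the regular grid.
#' Fully reproducible from the seed. Entrants whose traversal would not
#' complete before the final frame are still simulated (they end inside the
#' region) but contribute no ground-truth event, mirroring the
#' complete-events-only counting rule.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return a list of class `perm_run` with elements `bundle` (a
#'   [perm_bundle()]) and `truth` (tibble of true crossing events: `ion_id`,
#'   `species`, `direction`, `t_start`, `t_end`, `pathway`), plus the true
#'   entry models as attribute `models`.
#' @export
generate_run <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  dt <- spec$frame_interval_ps / 1000
  grid <- seq(0, spec$duration_ns, by = dt)
  t_last <- max(grid)

  streams <- list(
    TB_K = list(dirn = 1L, species = "K+"),
    BT_K = list(dirn = -1L, species = "K+"),
    TB_Cl = list(dirn = 1L, species = "Cl-"),
    BT_Cl = list(dirn = -1L, species = "Cl-")
  )
  traces <- list()
  truth <- list()
  for (nm in names(streams)) {
    model <- spec$entry_models[[nm]]
    if (is.null(model)) next
    info <- streams[[nm]]
    entries <- .entry_times(model, spec$duration_ns)
    if (length(entries) == 0) next
    transits <- rlnorm(length(entries),
                       meanlog = log(spec$transit_mean_ns) -
                         spec$transit_sigma_log^2 / 2,
                       sdlog = spec$transit_sigma_log)
    lat <- info$dirn > 0 &
      runif(length(entries)) < spec$lateral_fraction &
      entries >= .HISTORY_NS
    for (k in seq_along(entries)) {
      id <- sprintf("%s_%04d", nm, k)
      tr <- .permeant_trace(id, info$species, info$dirn, entries[k],
                            transits[k], lat[k], spec, grid)
      if (is.null(tr)) next
      traces[[id]] <- tr
      if (entries[k] + transits[k] < t_last) {
        truth[[id]] <- tibble::tibble(
          ion_id = id, species = info$species, direction = info$dirn,
          t_start = entries[k], t_end = entries[k] + transits[k],
          pathway = if (lat[k]) "lateral" else "axial")
      }
    }
  }
  bulk <- .bulk_traces(spec, grid)
  all_tr <- dplyr::bind_rows(c(traces, list(bulk)))
  if (nrow(all_tr) == 0) {
    all_tr <- tibble::tibble(time_ns = numeric(), ion_id = character(),
                             species = character(), x = numeric(),
                             y = numeric(), z = numeric())
  }
  md <- system_metadata(duration_ns = spec$duration_ns,
                        frame_interval_ps = spec$frame_interval_ps,
                        bulk_concentration_mM = spec$bulk_concentration_mM,
                        box = spec$box)
  truth_tbl <- if (length(truth)) {
    dplyr::arrange(dplyr::bind_rows(truth), .data$t_start)
  } else {
    tibble::tibble(ion_id = character(), species = character(),
                   direction = integer(), t_start = numeric(),
                   t_end = numeric(), pathway = character())
  }
  attr(truth_tbl, "models") <- spec$entry_models
  structure(
    list(bundle = perm_bundle(all_tr, spec$geometry, md, validate = FALSE),
         truth = truth_tbl, seed = seed),
    class = "perm_run"
  )
}

#' @export
print.perm_run <- function(x, ...) {
  cat(sprintf("<perm_run> seed %d: %d true events over %.1f ns\n",
              x$seed, nrow(x$truth), x$bundle$metadata$duration_ns))
  invisible(x)
}
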