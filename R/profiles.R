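#' Ion density profile along the pore axis
#'
#' Counts ions inside thin disks (default 0.5 A thick, radius equal to the
#' counting cylinder) stacked along z, averages the per-disk count over the
#' sampled frames, and normalizes by the count expected for bulk solution
#' at the stated concentration (`c * N_A * V_disk`), so bulk regions read
#' ~1.
#'
#' @param bundle a [perm_bundle()].
#' @param bin_width disk thickness, Angstrom (default 0.5).
#' @param radius disk radius, Angstrom (default: counting-cylinder radius).
#' @param stride_ps sampling interval for frames, ps (default 100).
#' @param z_range numeric length-2 range of bin edges; default the z-range
#'   of the traces.
#' @param conc_mM normalizing bulk concentration, mM (default from the
#'   bundle metadata).
#' @return tibble of class `perm_profile` with `z_mid`, `species`,
#'   `density` (bulk-normalized) and `mean_count`.
#' @export
ion_density_profile <- function(bundle, bin_width = 0.5, radius = NULL,
                                stride_ps = 100, z_range = NULL,
                                conc_mM = NULL) {
  tr <- bundle$traces
  if (nrow(tr) == 0) abort("No frames in bundle.")
  radius <- radius %||% bundle$geometry$cylinder_radius
  conc_mM <- conc_mM %||% bundle$metadata$bulk_concentration_mM
  times <- sort(unique(tr$time_ns))
  stride_ns <- stride_ps / 1000
  # keep frames on the stride lattice (exact on regular grids)
  keep_t <- times[abs((times - times[1]) %% stride_ns) < 1e-9 |
                  abs(((times - times[1]) %% stride_ns) - stride_ns) < 1e-9]
  if (length(keep_t) == 0) keep_t <- times
  d <- tr[tr$time_ns %in% keep_t, ]
  d <- d[sqrt(d$x^2 + d$y^2) <= radius, ]
  z_range <- z_range %||% range(tr$z)
  edges <- seq(floor(z_range[1] / bin_width) * bin_width,
               ceiling(z_range[2] / bin_width) * bin_width, by = bin_width)
  v_disk <- pi * radius^2 * bin_width
  expected <- ions_per_A3(conc_mM) * v_disk
  n_frames <- length(keep_t)
  grid <- tidyr::expand_grid(
    species = unique(tr$species),
    z_mid = head(edges, -1) + bin_width / 2)
  counts <- d |>
    dplyr::mutate(z_mid = (findInterval(.data$z, edges,
                   rightmost.closed = TRUE) - 0.5) * bin_width + edges[1]) |>
    dplyr::filter(.data$z >= edges[1], .data$z <= edges[length(edges)]) |>
    dplyr::count(.data$species, .data$z_mid)
  out <- grid |>
    dplyr::left_join(counts, by = c("species", "z_mid")) |>
    dplyr::mutate(mean_count = dplyr::coalesce(.data$n, 0L) / n_frames,
                  density = .data$mean_count / expected) |>
    dplyr::select("z_mid", "species", "mean_count", "density")
  attr(out, "panel") <- "ion_density"
  class(out) <- c("perm_profile", class(out))
  out
}

# default vdW radii by element (A)
.vdw_lookup <- function(element, vdw_table = NULL) {
  tab <- .VDW_DEFAULT
  if (!is.null(vdw_table)) tab[names(vdw_table)] <- vdw_table
  r <- tab[element]
  r[is.na(r)] <- 1.7
  unname(r)
}

# largest sphere centred at (cx, cy, z) clear of all atoms
.clearance <- function(cx, cy, z, ax, ay, az, avdw) {
  min(sqrt((ax - cx)^2 + (ay - cy)^2 + (az - z)^2) - avdw)
}

# deterministic hill-climb on a 0.1 A grid from the axis
.max_inscribed <- function(z, ax, ay, az, avdw, start = c(0, 0),
                           step = 0.1, max_iter = 400) {
  cx <- start[1]; cy <- start[2]
  best <- .clearance(cx, cy, z, ax, ay, az, avdw)
  for (it in seq_len(max_iter)) {
    cand <- rbind(c(cx + step, cy), c(cx - step, cy),
                  c(cx, cy + step), c(cx, cy - step),
                  c(cx + step, cy + step), c(cx - step, cy - step),
                  c(cx + step, cy - step), c(cx - step, cy + step))
    vals <- apply(cand, 1, function(p) .clearance(p[1], p[2], z, ax, ay, az, avdw))
    i <- which.max(vals)
    if (vals[i] <= best + 1e-12) break
    best <- vals[i]; cx <- cand[i, 1]; cy <- cand[i, 2]
  }
  best
}

#' Pore radius profile
#'
#' A simplified inscribed-sphere pore-radius calculation: at each z level
#' the radius is the largest sphere, centred in that plane, clear of all
#' nearby atoms (3-D distance to the atom centre minus its van der Waals
#' radius), maximized over candidate centres by a deterministic local
#' search on a 0.1 A grid starting from the pore axis. Per-frame profiles
#' are averaged over frames.
#'
#' @param protein tibble of protein atoms with `time_ns`, `x`, `y`, `z` and
#'   optionally `element` (defaults to carbon radii).
#' @param vdw_table named numeric vector of van der Waals radii by element,
#'   overriding the built-in defaults.
#' @param bin_width z spacing, Angstrom (default 0.5).
#' @param z_range range of z levels; default the protein z-range.
#' @param axis_xy in-plane starting centre for the search (default origin).
#' @param slab_half_A half-thickness of the atom neighbourhood considered
#'   per level, Angstrom (default 6).
#' @return tibble of class `perm_profile` with `z_mid`, `radius`
#'   (`NA` where no atoms bound the level: marked unbounded).
#' @export
pore_radius_profile <- function(protein, vdw_table = NULL, bin_width = 0.5,
                                z_range = NULL, axis_xy = c(0, 0),
                                slab_half_A = 6) {
  stopifnot(all(c("x", "y", "z") %in% names(protein)))
  if (!"time_ns" %in% names(protein)) protein$time_ns <- 0
  if (!"element" %in% names(protein)) protein$element <- "C"
  z_range <- z_range %||% range(protein$z)
  zs <- seq(z_range[1], z_range[2], by = bin_width)
  frames <- unique(protein$time_ns)
  prof <- purrr::map(frames, function(tf) {
    a <- protein[protein$time_ns == tf, ]
    vdw <- .vdw_lookup(a$element, vdw_table)
    purrr::map_dbl(zs, function(z) {
      near <- abs(a$z - z) <= slab_half_A
      if (!any(near)) return(NA_real_)
      .max_inscribed(z, a$x[near], a$y[near], a$z[near], vdw[near],
                     start = axis_xy)
    })
  })
  radius <- purrr::reduce(prof, `+`) / length(frames)
  out <- tibble::tibble(z_mid = zs, radius = radius)
  attr(out, "panel") <- "pore_radius"
  class(out) <- c("perm_profile", class(out))
  out
}

#' Hydration-shell profile of permeant ions
#'
#' For every potassium ion inside the counting cylinder, counts the water
#' oxygens within the first-shell threshold (3.52 A, strict inequality) and
#' separately the protein oxygens occupying that shell (waters replaced by
#' protein coordination); results are binned by the ion's z and averaged
#' over observations.
#'
#' @param bundle a [perm_bundle()] whose `solvent` element holds oxygen
#'   positions (`time_ns`, `kind` in `water_O`/`protein_O`, `x`, `y`, `z`).
#' @param shell_radius_A first-shell threshold, Angstrom (default 3.52).
#' @param bin_width z bin width, Angstrom (default 0.5).
#' @param species ion species profiled (default `"K+"`).
#' @return tibble of class `perm_profile` with `z_mid`, `hydration`,
#'   `replacement`, `n_obs`.
#' @export
hydration_profile <- function(bundle, shell_radius_A = 3.52, bin_width = 0.5,
                              species = "K+") {
  if (is.null(bundle$solvent)) abort("Bundle has no solvent stream.")
  g <- bundle$geometry
  sv <- bundle$solvent
  ions <- bundle$traces
  ions <- ions[ions$species == species &
               ions$z <= g$z_top & ions$z >= g$z_bottom &
               sqrt(ions$x^2 + ions$y^2) <= g$cylinder_radius, ]
  if (nrow(ions) == 0) abort("No in-region ions to profile.")
  obs <- purrr::map_dfr(seq_len(nrow(ions)), function(i) {
    io <- ions[i, ]
    s <- sv[sv$time_ns == io$time_ns, ]
    dist <- sqrt((s$x - io$x)^2 + (s$y - io$y)^2 + (s$z - io$z)^2)
    in_shell <- dist < shell_radius_A   # strict: a molecule at the threshold is out
    tibble::tibble(z = io$z,
                   hydration = sum(in_shell & s$kind == "water_O"),
                   replacement = sum(in_shell & s$kind == "protein_O"))
  })
  out <- obs |>
    dplyr::mutate(z_mid = (floor(.data$z / bin_width) + 0.5) * bin_width) |>
    dplyr::group_by(.data$z_mid) |>
    dplyr::summarise(hydration = mean(.data$hydration),
                     replacement = mean(.data$replacement),
                     n_obs = dplyr::n(), .groups = "drop")
  attr(out, "panel") <- "hydration"
  class(out) <- c("perm_profile", class(out))
  out
}

#' Residue position density along the pore axis
#'
#' Normalized probability of finding the atoms of selected residue types at
#' each z, counting all atoms (hydrogens included) over all subunits and
#' frames; each residue type is normalized to unit integral.
#'
#' @param protein tibble with `time_ns` (optional), `resname`, `z`.
#' @param residues character vector of residue-type labels to include;
#'   default all present.
#' @param bin_width z bin width, Angstrom (default 0.5).
#' @return tibble of class `perm_profile` with `z_mid`, `resname`,
#'   `density` (integral 1 per residue type).
#' @export
residue_position_density <- function(protein, residues = NULL,
                                     bin_width = 0.5) {
  stopifnot(all(c("resname", "z") %in% names(protein)))
  residues <- residues %||% unique(protein$resname)
  d <- protein[protein$resname %in% residues, ]
  if (nrow(d) == 0) abort("Residue selection matched no atoms.")
  out <- d |>
    dplyr::mutate(z_mid = (floor(.data$z / bin_width) + 0.5) * bin_width) |>
    dplyr::count(.data$resname, .data$z_mid) |>
    dplyr::group_by(.data$resname) |>
    dplyr::mutate(density = .data$n / sum(.data$n) / bin_width) |>
    dplyr::ungroup() |>
    dplyr::select("z_mid", "resname", "density")
  attr(out, "panel") <- "residue_positions"
  class(out) <- c("perm_profile", class(out))
  out
}

#' Axial diffusion coefficient inside the pore
#'
#' One-dimensional mean-square displacement of in-region ion segments along
#' z, fitted as `MSD = 2 D t` over a lag window. Ballistic motion (log-log
#' MSD slope well above 1) indicates drift-dominated dynamics and is
#' refused rather than converted into a diffusion coefficient.
#'
#' @param bundle a [perm_bundle()].
#' @param species ion species (default `"K+"`).
#' @param max_lag_frames largest lag used in the fit (default 20).
#' @param min_frames minimum contiguous in-region residence, frames
#'   (default 10).
#' @param free_reference_m2_s free-diffusion reference for the reported
#'   ratio, m^2/s (default 1.96e-9, potassium in water).
#' @return list of class `diffusion_estimate`: `D_A2_ns`, `D_m2_s`,
#'   `ratio_to_free`, `alpha` (log-log MSD slope), `n_segments`.
#' @export
axial_diffusion <- function(bundle, species = "K+", max_lag_frames = 20,
                            min_frames = 10,
                            free_reference_m2_s = 1.96e-9) {
  g <- bundle$geometry
  tr <- bundle$traces[bundle$traces$species == species, ]
  dt <- bundle$metadata$frame_interval_ps / 1000
  segs <- list()
  for (id in unique(tr$ion_id)) {
    d <- tr[tr$ion_id == id, ]
    d <- d[order(d$time_ns), ]
    inreg <- d$z <= g$z_top & d$z >= g$z_bottom &
      sqrt(d$x^2 + d$y^2) <= g$cylinder_radius
    r <- rle(inreg)
    ends <- cumsum(r$lengths); starts <- c(1, head(ends, -1) + 1)
    for (k in which(r$values & r$lengths >= min_frames)) {
      segs[[length(segs) + 1]] <- d$z[starts[k]:ends[k]]
    }
  }
  if (length(segs) == 0) abort("Insufficient in-region residence for diffusion estimate.")
  lags <- seq_len(max_lag_frames)
  msd <- purrr::map_dbl(lags, function(L) {
    disp2 <- unlist(purrr::map(segs, function(z) {
      if (length(z) > L) (z[seq_len(length(z) - L) + L] - z[seq_len(length(z) - L)])^2
      else numeric(0)
    }))
    if (length(disp2) == 0) NA_real_ else mean(disp2)
  })
  ok <- is.finite(msd)
  if (sum(ok) < 3) abort("Too few usable lags for the MSD fit.")
  tau <- lags[ok] * dt
  alpha <- unname(coef(lm(log(msd[ok]) ~ log(tau)))[2])
  if (alpha > 1.5) {
    abort(sprintf(
      "MSD grows ballistically (log-log slope %.2f): drift-dominated motion, no diffusion coefficient reported.",
      alpha))
  }
  slope <- unname(coef(lm(msd[ok] ~ 0 + tau))[1])  # MSD = 2 D t
  D_A2_ns <- slope / 2
  D_m2_s <- D_A2_ns * 1e-11                        # A^2/ns -> m^2/s
  structure(
    list(D_A2_ns = D_A2_ns, D_m2_s = D_m2_s,
         ratio_to_free = D_m2_s / free_reference_m2_s,
         alpha = alpha, n_segments = length(segs)),
    class = "diffusion_estimate"
  )
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf(
    "<diffusion_estimate> D = %.3g x 1e-9 m^2/s (%.2f of free diffusion; %d segments)\n",
    x$D_m2_s * 1e9, x$ratio_to_free, x$n_segments))
  invisible(x)
}
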