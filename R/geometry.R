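#' Define the cylindrical transmembrane counting region
#'
#' The counting region for crossing events is a right cylinder bounded by two
#' z-planes, each located at the ring of boundary glutamates capping the
#' transmembrane pore (Glu-258 at the extracellular end, Glu-237 at the
#' intracellular end in the alpha7 receptor). The membrane normal is +z and
#' the extracellular side is at larger z.
#'
#' @param z_top z of the boundary ring nearer the extracellular side, in
#'   Angstrom. Must exceed `z_bottom`.
#' @param z_bottom z of the intracellular boundary ring, Angstrom.
#' @param cylinder_radius radius of the counting cylinder, Angstrom. The
#'   default (17.3) is wide enough to capture the obliquity of the pore-lining
#'   helices so that a traversing ion never leaves the cylinder laterally.
#' @param axis pore axis; only the +z axis is supported.
#' @param rings optional tibble with columns `time_ns`, `z_top`, `z_bottom`
#'   giving per-frame (time-varying) boundary planes; when present the scalar
#'   `z_top`/`z_bottom` are the time averages.
#'
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(z_top, z_bottom, cylinder_radius = 17.3,
                             axis = c(0, 0, 1), rings = NULL) {
  if (!is.numeric(z_top) || !is.numeric(z_bottom) || z_top <= z_bottom) {
    abort("`z_top` must be strictly greater than `z_bottom`.")
  }
  if (cylinder_radius <= 0) abort("`cylinder_radius` must be positive.")
  if (!isTRUE(all.equal(as.numeric(axis), c(0, 0, 1)))) {
    abort("Only the +z pore axis is supported.")
  }
  if (!is.null(rings)) {
    stopifnot(all(c("time_ns", "z_top", "z_bottom") %in% names(rings)))
    if (any(rings$z_top <= rings$z_bottom)) {
      abort("Per-frame rings must satisfy z_top > z_bottom in every frame.")
    }
  }
  structure(
    list(z_top = as.numeric(z_top), z_bottom = as.numeric(z_bottom),
         cylinder_radius = as.numeric(cylinder_radius),
         axis = c(0, 0, 1), time_varying = !is.null(rings), rings = rings),
    class = "channel_geometry"
  )
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf(
    "<channel_geometry> z_top = %.2f A, z_bottom = %.2f A, radius = %.2f A%s\n",
    x$z_top, x$z_bottom, x$cylinder_radius,
    if (x$time_varying) sprintf(" (time-varying, %d frames)", nrow(x$rings)) else ""
  ))
  invisible(x)
}

#' Describe a simulation system
#'
#' Holds the box height, applied field, membrane voltage and time base of a
#' run. The membrane voltage obeys `Ve = Lz * EF` (box height times field
#' strength); when both the field and the voltage are supplied they must be
#' consistent.
#'
#' @param duration_ns run length, ns.
#' @param frame_interval_ps interval between stored frames, ps (default 10).
#' @param box_height_A height Lz of the simulation box, Angstrom.
#' @param field_mV_per_A applied uniform field EF, mV/A (optional).
#' @param voltage_mV membrane voltage Ve, mV. Derived from `Lz * EF` when
#'   omitted and both are available.
#' @param bulk_concentration_mM bulk salt concentration, mM (default 150).
#' @param box optional full box edge lengths `c(Lx, Ly, Lz)`, Angstrom;
#'   used for periodic unwrapping.
#'
#' @return An object of class `system_metadata`.
#' @export
system_metadata <- function(duration_ns, frame_interval_ps = 10,
                            box_height_A = NULL, field_mV_per_A = NULL,
                            voltage_mV = NULL, bulk_concentration_mM = 150,
                            box = NULL) {
  if (duration_ns <= 0) abort("`duration_ns` must be positive.")
  if (frame_interval_ps <= 0) abort("`frame_interval_ps` must be positive.")
  if (is.null(box_height_A) && !is.null(box)) box_height_A <- box[3]
  if (is.null(voltage_mV) && !is.null(box_height_A) && !is.null(field_mV_per_A)) {
    voltage_mV <- box_height_A * field_mV_per_A
  }
  if (!is.null(voltage_mV) && !is.null(box_height_A) && !is.null(field_mV_per_A)) {
    if (abs(voltage_mV - box_height_A * field_mV_per_A) >
        1e-6 * max(1, abs(voltage_mV))) {
      abort("`voltage_mV` is inconsistent with `box_height_A * field_mV_per_A`.")
    }
  }
  structure(
    list(duration_ns = duration_ns, frame_interval_ps = frame_interval_ps,
         box_height_A = box_height_A, field_mV_per_A = field_mV_per_A,
         voltage_mV = voltage_mV, bulk_concentration_mM = bulk_concentration_mM,
         box = box),
    class = "system_metadata"
  )
}

#' Charge of an ion species in elementary units
#'
#' @param species character vector of species labels (`"K+"`, `"Cl-"`, other).
#' @return integer charges; unrecognised species map to 0.
#' @export
ion_charge <- function(species) {
  dplyr::case_when(
    species %in% c("K+", "K", "POT", "Na+", "NA+", "SOD") ~ 1L,
    species %in% c("Cl-", "CL", "CLA") ~ -1L,
    TRUE ~ 0L
  )
}

#' Bundle ion traces with geometry and metadata
#'
#' The central container of the package: a long tibble of per-ion, per-frame
#' records plus the counting-region geometry and the system metadata.
#' Positions must be continuity-corrected (unwrapped) across the periodic
#' boundaries; times must be strictly increasing within each ion.
#'
#' @param traces tibble with columns `time_ns`, `ion_id`, `species`, `x`,
#'   `y`, `z` (Angstrom). A `charge` column is added from [ion_charge()] if
#'   absent.
#' @param geometry a [channel_geometry()].
#' @param metadata a [system_metadata()].
#' @param solvent optional tibble of solvent/protein oxygen positions with
#'   columns `time_ns`, `atom_id`, `kind` (`"water_O"` or `"protein_O"`),
#'   `x`, `y`, `z`, for hydration profiles.
#' @param protein optional tibble of protein atom positions with columns
#'   `time_ns`, `x`, `y`, `z` and optionally `element`, `resname`, for pore
#'   radius and residue-position profiles.
#' @param validate check the trace invariants (default TRUE).
#'
#' @return An object of class `perm_bundle`.
#' @export
perm_bundle <- function(traces, geometry, metadata, solvent = NULL,
                        protein = NULL, validate = TRUE) {
  traces <- tibble::as_tibble(traces)
  need <- c("time_ns", "ion_id", "species", "x", "y", "z")
  if (!all(need %in% names(traces))) {
    abort(paste0("`traces` must have columns ", paste(need, collapse = ", "), "."))
  }
  if (!"charge" %in% names(traces)) traces$charge <- ion_charge(traces$species)
  if (!inherits(geometry, "channel_geometry")) abort("`geometry` must be a channel_geometry.")
  if (!inherits(metadata, "system_metadata")) abort("`metadata` must be a system_metadata.")
  b <- structure(
    list(traces = traces, geometry = geometry, metadata = metadata,
         solvent = solvent, protein = protein),
    class = "perm_bundle"
  )
  if (validate) validate_bundle(b)
  b
}

#' Validate a trace bundle
#'
#' Checks that times are strictly increasing within each ion and, when box
#' dimensions are known, that no consecutive displacement exceeds half a box
#' edge (i.e. that coordinates are unwrapped).
#'
#' @param bundle a [perm_bundle()].
#' @return `bundle`, invisibly; errors on violation.
#' @export
validate_bundle <- function(bundle) {
  tr <- bundle$traces
  if (nrow(tr) > 0) {
    bad_t <- tr |>
      dplyr::group_by(.data$ion_id) |>
      dplyr::summarise(ok = all(diff(.data$time_ns) > 0) || dplyr::n() == 1,
                       .groups = "drop")
    if (!all(bad_t$ok)) {
      abort(paste0("Non-monotonic time stamps for ion(s): ",
                   paste(bad_t$ion_id[!bad_t$ok], collapse = ", ")))
    }
    box <- bundle$metadata$box
    if (!is.null(box)) {
      jump <- tr |>
        dplyr::group_by(.data$ion_id) |>
        dplyr::summarise(
          mx = max(abs(diff(.data$x)), 0), my = max(abs(diff(.data$y)), 0),
          mz = max(abs(diff(.data$z)), 0), .groups = "drop")
      if (any(jump$mx >= box[1] / 2 | jump$my >= box[2] / 2 |
              jump$mz >= box[3] / 2)) {
        abort("Traces contain jumps >= half a box edge: coordinates are not unwrapped.")
      }
    }
  }
  invisible(bundle)
}

#' @export
print.perm_bundle <- function(x, ...) {
  cat(sprintf("<perm_bundle> %d ions, %d records, %.3f ns\n",
              dplyr::n_distinct(x$traces$ion_id), nrow(x$traces),
              x$metadata$duration_ns))
  print(x$geometry)
  invisible(x)
}
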