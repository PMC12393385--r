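#' Unwrap periodic-boundary jumps in ion traces
#'
#' Applies minimum-image continuity correction per ion and per axis: every
#' consecutive displacement is reduced modulo the box edge so that its
#' magnitude is below half the edge, and corrections are accumulated along
#' the trace. Idempotent on already-unwrapped traces. Orthorhombic boxes
#' only.
#'
#' @param traces tibble with `time_ns`, `ion_id`, `x`, `y`, `z`.
#' @param box numeric length-3, box edges `c(Lx, Ly, Lz)` in Angstrom.
#' @return the traces with unwrapped coordinates, same row order.
#' @export
unwrap_traces <- function(traces, box) {
  stopifnot(is.numeric(box), length(box) == 3, all(box > 0))
  unwrap1 <- function(v, L) {
    if (length(v) < 2) return(v)
    d <- diff(v)
    d <- d - L * round(d / L)
    v[1] + c(0, cumsum(d))
  }
  traces |>
    dplyr::group_by(.data$ion_id) |>
    dplyr::arrange(.data$time_ns, .by_group = TRUE) |>
    dplyr::mutate(x = unwrap1(.data$x, box[1]),
                  y = unwrap1(.data$y, box[2]),
                  z = unwrap1(.data$z, box[3])) |>
    dplyr::ungroup()
}

#' Read ion traces from the columnar trace format
#'
#' The columnar dialect is UTF-8, tab-separated, with a header line
#' `time_ns  ion_id  species  x  y  z` and `#` comment lines; coordinates in
#' Angstrom, times in ns. Geometry for the counting region is not carried by
#' the file and must be supplied.
#'
#' @param path file path.
#' @param geometry a [channel_geometry()]; required (the columnar format
#'   carries no boundary-residue coordinates).
#' @param metadata a [system_metadata()]; inferred from the time stamps when
#'   omitted.
#' @param unwrap unwrap coordinates with `metadata$box` (default TRUE when a
#'   box is available).
#' @return a [perm_bundle()].
#' @export
read_ion_traces <- function(path, geometry = NULL, metadata = NULL,
                            unwrap = TRUE) {
  if (is.null(geometry)) {
    abort(paste0("No channel geometry available: the columnar trace format ",
                 "does not carry boundary residues; pass `geometry`."))
  }
  tr <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      time_ns = readr::col_double(), ion_id = readr::col_character(),
      species = readr::col_character(), x = readr::col_double(),
      y = readr::col_double(), z = readr::col_double()
    )
  )
  if (is.null(metadata)) {
    dur <- if (nrow(tr)) max(tr$time_ns) else 1
    ts <- sort(unique(tr$time_ns))
    dt_ps <- if (length(ts) > 1) min(diff(ts)) * 1000 else 10
    metadata <- system_metadata(duration_ns = max(dur, dt_ps / 1000),
                                frame_interval_ps = dt_ps)
  }
  if (unwrap && !is.null(metadata$box) && nrow(tr) > 0) {
    tr <- unwrap_traces(tr, metadata$box)
  }
  perm_bundle(tr, geometry, metadata)
}

#' Write ion traces in the columnar trace format
#'
#' Round-trips losslessly through [read_ion_traces()]: times to 1e-6 ns,
#' coordinates to 1e-4 Angstrom.
#'
#' @param bundle a [perm_bundle()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ion_traces <- function(bundle, path) {
  tr <- bundle$traces
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# permeatr ion traces (time ns, coordinates Angstrom)", con)
  writeLines(paste(c("time_ns", "ion_id", "species", "x", "y", "z"),
                   collapse = "\t"), con)
  if (nrow(tr) > 0) {
    out <- sprintf("%.6f\t%s\t%s\t%.4f\t%.4f\t%.4f",
                   tr$time_ns, tr$ion_id, tr$species, tr$x, tr$y, tr$z)
    writeLines(out, con)
  }
  invisible(path)
}

# vdW radii (A) by element, CHARMM-like defaults used for pore profiles too
.VDW_DEFAULT <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Read a multi-model PDB trajectory into a trace bundle
#'
#' Parses `MODEL`/`ATOM`/`HETATM` records of a multi-model PDB file (one
#' MODEL per stored frame). Ion species are recognised from residue names
#' (`POT`/`K` for K+, `CLA`/`CL` for Cl-). The counting-region geometry is
#' taken from the per-frame centroid z of the C-alpha atoms of the two
#' boundary glutamate rings when those residues are present; otherwise an
#' explicit `geometry` must be given.
#'
#' @param path PDB file path.
#' @param frame_interval_ps time between MODELs, ps.
#' @param boundary_resno integer length-2: residue numbers of the
#'   extracellular and intracellular boundary rings (default `c(258, 237)`).
#' @param geometry optional explicit [channel_geometry()]; overrides
#'   residue-derived boundaries.
#' @param time_varying use per-frame ring centroids (default TRUE); when
#'   FALSE the rings are averaged over frames into fixed planes.
#' @param cylinder_radius counting-cylinder radius, Angstrom.
#' @return a [perm_bundle()] with `protein` coordinates attached.
#' @export
read_pdb_trajectory <- function(path, frame_interval_ps = 10,
                                boundary_resno = c(258, 237),
                                geometry = NULL, time_varying = TRUE,
                                cylinder_radius = 17.3) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_no <- cumsum(grepl("^MODEL", lines))
  if (max(model_no) == 0) model_no <- rep(1L, length(lines))
  al <- lines[is_atom]
  if (length(al) == 0) abort("No ATOM/HETATM records in PDB file.")
  frame <- model_no[is_atom]
  frame <- match(frame, sort(unique(frame)))
  atoms <- tibble::tibble(
    frame = frame,
    name = trimws(substr(al, 13, 16)),
    resname = trimws(substr(al, 18, 21)),
    resno = suppressWarnings(as.integer(substr(al, 23, 26))),
    x = as.numeric(substr(al, 31, 38)),
    y = as.numeric(substr(al, 39, 46)),
    z = as.numeric(substr(al, 47, 54)),
    element = trimws(substr(al, 77, 78)),
    serial = trimws(substr(al, 7, 11))
  )
  atoms$element[atoms$element == ""] <- substr(atoms$name[atoms$element == ""], 1, 1)
  atoms$time_ns <- (atoms$frame - 1) * frame_interval_ps / 1000

  box <- NULL
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) >= 1) {
    box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                        substr(cr[1], 25, 33)))
  }

  ion_res <- c(POT = "K+", K = "K+", CLA = "Cl-", CL = "Cl-")
  ions <- atoms[atoms$resname %in% names(ion_res), ]
  if (nrow(ions) == 0) abort("Ion selection matched zero atoms in PDB file.")
  traces <- tibble::tibble(
    time_ns = ions$time_ns,
    ion_id = paste0(ion_res[ions$resname], "_", ions$serial),
    species = unname(ion_res[ions$resname]),
    x = ions$x, y = ions$y, z = ions$z
  )

  if (is.null(geometry)) {
    ca <- atoms[atoms$name == "CA" & atoms$resno %in% boundary_resno, ]
    if (nrow(ca) == 0) {
      abort(paste0("Boundary residues ", paste(boundary_resno, collapse = "/"),
                   " not found and no `geometry` supplied."))
    }
    rings <- ca |>
      dplyr::group_by(.data$time_ns) |>
      dplyr::summarise(
        z_top = mean(.data$z[.data$resno == boundary_resno[1]]),
        z_bottom = mean(.data$z[.data$resno == boundary_resno[2]]),
        .groups = "drop")
    geometry <- channel_geometry(
      z_top = mean(rings$z_top), z_bottom = mean(rings$z_bottom),
      cylinder_radius = cylinder_radius,
      rings = if (time_varying) rings else NULL
    )
  }

  n_frames <- max(atoms$frame)
  metadata <- system_metadata(
    duration_ns = max((n_frames - 1) * frame_interval_ps / 1000,
                      frame_interval_ps / 1000),
    frame_interval_ps = frame_interval_ps, box = box
  )
  if (!is.null(box) && all(is.finite(box))) {
    traces <- unwrap_traces(traces, box)
  }
  protein <- atoms[!(atoms$resname %in% c(names(ion_res), "TIP3", "HOH", "WAT", "SOL")),
                   c("time_ns", "x", "y", "z", "element", "resname", "resno")]
  perm_bundle(traces, geometry, metadata,
              protein = tibble::as_tibble(protein))
}
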