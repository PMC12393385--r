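# shared fixture builders -------------------------------------------------

# hand-built single-ion bundle from (time, z[, x, y]) vectors
hand_bundle <- function(time_ns, z, x = 0, y = 0, species = "K+",
                        geometry = channel_geometry(20, -20),
                        duration_ns = max(time_ns)) {
  tr <- tibble::tibble(time_ns = time_ns, ion_id = "ion1", species = species,
                       x = rep_len(x, length(time_ns)),
                       y = rep_len(y, length(time_ns)), z = z)
  perm_bundle(tr, geometry,
              system_metadata(duration_ns,
                              frame_interval_ps = min(diff(time_ns)) * 1000),
              validate = FALSE)
}

# regular ring of n atoms in a z-plane
ring_atoms <- function(ring_radius, z, n = 5, element = "C",
                       centre = c(0, 0), time_ns = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  tibble::tibble(time_ns = time_ns,
                 x = centre[1] + ring_radius * cos(th),
                 y = centre[2] + ring_radius * sin(th),
                 z = z, element = element)
}

# brute-force 2-D grid-search oracle for the largest inscribed sphere
pore_radius_oracle <- function(z, atoms, vdw, half_width = 3, step = 0.05) {
  g <- expand.grid(cx = seq(-half_width, half_width, by = step),
                   cy = seq(-half_width, half_width, by = step))
  vals <- vapply(seq_len(nrow(g)), function(i) {
    min(sqrt((atoms$x - g$cx[i])^2 + (atoms$y - g$cy[i])^2 +
               (atoms$z - z)^2) - vdw)
  }, numeric(1))
  max(vals)
}

# minimal multi-model PDB text with two Glu C-alpha rings and one K+ ion
make_pdb_text <- function(n_frames = 3, z_top = 20, z_bottom = -20,
                          ion_z = seq(30, 30 - 5 * (3 - 1), length.out = 3)) {
  pdb_line <- function(serial, name, resname, resno, x, y, z, element) {
    sprintf("ATOM  %5d %-4s %-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, resname, resno, x, y, z, element)
  }
  lines <- c("CRYST1   80.000   80.000  120.000  90.00  90.00  90.00 P 1")
  for (f in seq_len(n_frames)) {
    lines <- c(lines, sprintf("MODEL     %4d", f))
    serial <- 0
    for (resno in c(258, 237)) {
      zr <- if (resno == 258) z_top else z_bottom
      th <- 2 * pi * (0:4) / 5
      for (k in 1:5) {
        serial <- serial + 1
        lines <- c(lines, pdb_line(serial, "CA", "GLU", resno,
                                   12 * cos(th[k]), 12 * sin(th[k]), zr, "C"))
      }
    }
    lines <- c(lines, pdb_line(serial + 1, "K", "POT", 500, 1, 1,
                               ion_z[f], "K"))
    lines <- c(lines, "ENDMDL")
  }
  c(lines, "END")
}

# small generator spec for fast tests
quick_spec <- function(duration_ns = 30, seed = 1, n_bulk = 5, ...) {
  synthetic_spec(duration_ns = duration_ns, n_bulk = n_bulk, seed = seed, ...)
}
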