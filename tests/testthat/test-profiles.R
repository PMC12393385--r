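test_that("ideal-gas ion density normalizes to one", {
  set.seed(2)
  box <- c(60, 60, 80)
  nions <- round(0.15 * 6.02214076e23 * 1e-27 * prod(box))
  nf <- 400
  tr <- purrr::map_dfr(seq_len(nf), function(f) tibble::tibble(
    time_ns = (f - 1) * 0.1, ion_id = paste0("i", seq_len(nions)),
    species = "K+", x = runif(nions, -30, 30), y = runif(nions, -30, 30),
    z = runif(nions, -40, 40)))
  b <- perm_bundle(tr, channel_geometry(20, -20),
                   system_metadata(40, 100, box = box), validate = FALSE)
  p <- ion_density_profile(b, stride_ps = 100)
  # mean over bins within 3 sigma of the counting error
  tot_expect <- nions * nf * (pi * 17.3^2 * 80) / prod(box)
  rel_sd <- 1 / sqrt(tot_expect)
  expect_lt(abs(mean(p$density) - 1), 3 * rel_sd + 0.02)
  expect_true(all(p$density >= 0))
})

test_that("bins never visited by an ion have zero density", {
  tr <- tibble::tibble(time_ns = c(0, 0.1), ion_id = "a", species = "K+",
                       x = 0, y = 0, z = c(30, 30))
  b <- perm_bundle(tr, channel_geometry(20, -20), system_metadata(1),
                   validate = FALSE)
  p <- ion_density_profile(b, stride_ps = 100, z_range = c(0, 31))
  expect_equal(p$density[p$z_mid < 29], rep(0, sum(p$z_mid < 29)))
  expect_gt(max(p$density), 0)
})

test_that("pore radius matches geometry on centred and offset rings", {
  ring <- ring_atoms(5, z = 0)
  p <- pore_radius_profile(ring, vdw_table = c(C = 1.7), z_range = c(0, 0))
  expect_equal(p$radius[1], 5 - 1.7, tolerance = 1e-9)
  # ring centre displaced from the nominal axis: the search must find it
  off <- ring_atoms(5, z = 0, centre = c(1, 0))
  p_off <- pore_radius_profile(off, vdw_table = c(C = 1.7), z_range = c(0, 0))
  expect_equal(p_off$radius[1], 3.3, tolerance = 0.051)
  # a fixed-axis evaluation underestimates the offset ring
  fixed_axis <- min(sqrt((off$x)^2 + (off$y)^2) - 1.7)
  expect_lt(fixed_axis, p_off$radius[1])
})

test_that("pore radius agrees with the brute-force grid oracle", {
  two_rings <- dplyr::bind_rows(ring_atoms(4, z = 0),
                                ring_atoms(6.5, z = 4, centre = c(0.8, -0.5)))
  vdw <- rep(1.7, nrow(two_rings))
  p <- pore_radius_profile(two_rings, vdw_table = c(C = 1.7),
                           z_range = c(0, 4), bin_width = 1)
  for (i in seq_along(p$z_mid)) {
    oracle <- pore_radius_oracle(p$z_mid[i], two_rings, vdw)
    expect_lt(abs(p$radius[i] - oracle), 0.05)
  }
  # empty neighbourhood is marked unbounded
  p_far <- pore_radius_profile(ring_atoms(5, z = 0), z_range = c(50, 50))
  expect_true(is.na(p_far$radius[1]))
})

make_hydration_bundle <- function(waters, proteins, rot = 0) {
  rotate <- function(d, a) dplyr::mutate(d, x0 = x, x = x0 * cos(a) - y * sin(a),
                                         y = x0 * sin(a) + y * cos(a),
                                         x0 = NULL)
  ion <- tibble::tibble(time_ns = 0, ion_id = "k1", species = "K+",
                        x = 0, y = 0, z = 0)
  solv <- dplyr::bind_rows(
    dplyr::mutate(waters, kind = "water_O"),
    dplyr::mutate(proteins, kind = "protein_O")) |>
    dplyr::mutate(time_ns = 0, atom_id = dplyr::row_number())
  if (rot != 0) {
    ion <- rotate(ion, rot)
    solv <- rotate(solv, rot)
  }
  perm_bundle(ion, channel_geometry(20, -20), system_metadata(1),
              solvent = solv, validate = FALSE)
}

test_that("hydration counts first-shell waters and protein replacements", {
  th <- 2 * pi * (0:5) / 6
  w6 <- tibble::tibble(x = 3 * cos(th), y = 3 * sin(th), z = 0)
  b <- make_hydration_bundle(w6, w6[0, ])
  h <- hydration_profile(b)
  expect_equal(h$hydration, 6)
  expect_equal(h$replacement, 0)
  b2 <- make_hydration_bundle(w6[1:4, ], w6[5:6, ])
  h2 <- hydration_profile(b2)
  expect_equal(h2$hydration, 4)
  expect_equal(h2$replacement, 2)
  # an oxygen exactly at the threshold is outside the shell (strict rule)
  edge <- tibble::tibble(x = 3.52, y = 0, z = 0)
  h3 <- hydration_profile(make_hydration_bundle(edge, edge[0, ]))
  expect_equal(h3$hydration, 0)
})

test_that("hydration counts are invariant under rotation about the axis", {
  th <- 2 * pi * (0:4) / 5
  w <- tibble::tibble(x = c(3 * cos(th), 2), y = c(3 * sin(th), 1),
                      z = c(rep(0.5, 5), -0.3))
  h0 <- hydration_profile(make_hydration_bundle(w[1:5, ], w[6, ]))
  h1 <- hydration_profile(make_hydration_bundle(w[1:5, ], w[6, ], rot = 1.1))
  expect_equal(h1$hydration, h0$hydration)
  expect_equal(h1$replacement, h0$replacement)
})

test_that("residue position densities normalize to unit integral per type", {
  atoms <- tibble::tibble(
    resname = rep(c("GLU", "ARG"), c(40, 30)),
    z = c(rep(5.1, 40), runif(30, 0, 5)))
  p <- residue_position_density(atoms, bin_width = 0.5)
  sums <- p |>
    dplyr::group_by(resname) |>
    dplyr::summarise(total = sum(density) * 0.5)
  expect_equal(sums$total, rep(1, 2))
  # all atoms in one bin: delta-like density
  glu <- p[p$resname == "GLU", ]
  expect_equal(nrow(glu), 1)
  expect_equal(glu$density, 1 / 0.5)
  expect_error(residue_position_density(atoms, residues = "LYS"), "matched")
})

test_that("axial diffusion is recovered from an in-pore random walk", {
  set.seed(5)
  dt <- 0.01; n <- 2e4; D_true <- 2      # A^2/ns
  z <- permeatr:::.reflect(cumsum(rnorm(n, 0, sqrt(2 * D_true * dt))), -15, 15)
  tr <- tibble::tibble(time_ns = (0:(n - 1)) * dt, ion_id = "a",
                       species = "K+", x = 0, y = 0, z = z)
  b <- perm_bundle(tr, channel_geometry(20, -20), system_metadata(200, 10),
                   validate = FALSE)
  est <- axial_diffusion(b)
  expect_lt(abs(est$D_A2_ns - D_true) / D_true, 0.10)
  expect_equal(est$D_m2_s, est$D_A2_ns * 1e-11)
})

test_that("ballistic drift is refused and empty regions error", {
  tr <- tibble::tibble(time_ns = (0:999) * 0.01, ion_id = "a",
                       species = "K+", x = 0, y = 0,
                       z = seq(15, -15, length.out = 1000))
  b <- perm_bundle(tr, channel_geometry(20, -20), system_metadata(10),
                   validate = FALSE)
  expect_error(axial_diffusion(b), "ballistic")
  out <- dplyr::mutate(tr, z = z + 100)
  b2 <- perm_bundle(out, channel_geometry(20, -20), system_metadata(10),
                    validate = FALSE)
  expect_error(axial_diffusion(b2), "Insufficient")
})
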