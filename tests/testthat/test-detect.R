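test_that("a hand-built traversal gives one TB event with interpolated times", {
  # rings at +/-20; ion descends 30 -> 5 -> -30 on the axis
  b <- hand_bundle(c(0, 1, 2), c(30, 5, -30))
  ev <- detect_crossings(b)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, 1L)
  # crossing of z = 20 between (0, 30) and (1, 5): t = 10/25
  expect_equal(ev$t_start, 10 / 25)
  # crossing of z = -20 between (1, 5) and (2, -30): t = 1 + 25/35
  expect_equal(ev$t_end, 1 + 25 / 35)
  snapped <- detect_crossings(b, interpolate = FALSE)
  expect_equal(snapped$t_start, 1)
  expect_equal(snapped$t_end, 2)
})

test_that("incomplete residencies contribute no event", {
  # starts inside, exits below: disregarded
  b <- hand_bundle(c(0, 1, 2), c(0, -10, -30))
  expect_equal(nrow(detect_crossings(b)), 0)
  # enters from the top but is still inside at the last frame
  b2 <- hand_bundle(c(0, 1, 2), c(30, 10, -5))
  expect_equal(nrow(detect_crossings(b2)), 0)
  # enters and exits the same side
  b3 <- hand_bundle(c(0, 1, 2, 3), c(30, 10, 15, 30))
  expect_equal(nrow(detect_crossings(b3)), 0)
})

test_that("a radial exit resets the residency to the entry side", {
  # inside from the top, leaves the cylinder radially, re-enters, exits below
  tm <- 0:5
  z <- c(30, 10, 0, -5, -10, -30)
  x <- c(0, 0, 25, 0, 0, 0)       # radial excursion beyond 17.3 A at t = 2
  b <- hand_bundle(tm, z, x = x)
  ev <- detect_crossings(b)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, 1L)
  # the completed residency starts at the radial re-entry, not the first entry
  expect_gte(ev$t_start, 2)
})

test_that("ions skipping the whole region between frames are flagged", {
  b <- hand_bundle(c(0, 1), c(30, -30))
  expect_warning(ev <- detect_crossings(b), "coarse")
  expect_equal(nrow(ev), 0)
  expect_equal(attr(ev, "skipped_ions"), "ion1")
})

test_that("detection recovers the synthetic ground truth exactly", {
  spec <- quick_spec(duration_ns = 60, seed = 21, lateral_fraction = 0.2)
  run <- generate_run(spec)
  ev <- detect_crossings(run$bundle)
  expect_equal(nrow(ev), nrow(run$truth))
  tru <- dplyr::arrange(run$truth, ion_id)
  det <- dplyr::arrange(ev, ion_id)
  expect_identical(det$ion_id, tru$ion_id)
  expect_identical(det$direction, tru$direction)
  expect_lt(max(abs(det$t_start - tru$t_start)), 0.2)
})

test_that("time reversal maps TB events to BT events", {
  spec <- quick_spec(duration_ns = 40, seed = 8)
  run <- generate_run(spec)
  fwd <- detect_crossings(run$bundle)
  T_end <- max(run$bundle$traces$time_ns)
  rev_tr <- run$bundle$traces |>
    dplyr::mutate(time_ns = T_end - time_ns) |>
    dplyr::arrange(ion_id, time_ns)
  rev_b <- perm_bundle(rev_tr, run$bundle$geometry, run$bundle$metadata,
                       validate = FALSE)
  bwd <- detect_crossings(rev_b)
  expect_equal(sum(bwd$direction == -1), sum(fwd$direction == 1))
  expect_equal(sum(bwd$direction == 1), sum(fwd$direction == -1))
  expect_equal(sum(bwd$direction), -sum(fwd$direction))
})

test_that("enlarging the radial gate never loses complete events", {
  spec <- quick_spec(duration_ns = 40, seed = 13)
  run <- generate_run(spec)
  counts <- vapply(c(9, 13, 17.3, 25), function(r) {
    g <- channel_geometry(20, -20, cylinder_radius = r)
    b <- perm_bundle(run$bundle$traces, g, run$bundle$metadata,
                     validate = FALSE)
    nrow(detect_crossings(b))
  }, numeric(1))
  expect_false(is.unsorted(counts))
})

test_that("per-frame ring boundaries are honoured", {
  rings <- tibble::tibble(time_ns = 0:4, z_top = c(20, 20, 10, 10, 10),
                          z_bottom = -20)
  g <- channel_geometry(20, -20, rings = rings)
  # descends to z = 12: inside for fixed rings, above for the shifted rings
  b <- hand_bundle(0:4, c(30, 12, 12, 12, 12), geometry = g)
  expect_equal(nrow(detect_crossings(b)), 0)
  b_fixed <- hand_bundle(0:2, c(30, 12, -30),
                         geometry = channel_geometry(20, -20))
  expect_equal(nrow(detect_crossings(b_fixed)), 1)
})

test_that("waiting times are consecutive start differences within a segment", {
  ev <- tibble::tibble(
    segment = c("a", "a", "a", "b", "b"),
    ion_id = paste0("i", 1:5), species = "K+", charge = 1L,
    direction = 1L, t_start = c(1, 3, 8, 100, 104),
    t_end = c(2, 4, 9, 101, 105), duration = 1, pathway = "axial")
  w <- waiting_times(ev, "TB")
  expect_equal(sort(w), c(2, 4, 5))   # no cross-segment interval (92 absent)
  expect_equal(waiting_times(ev, "BT"), numeric(0))
})

test_that("event durations are end minus start", {
  ev <- tibble::tibble(segment = "1", ion_id = "i1", species = "K+",
                       charge = 1L, direction = 1L, t_start = 1.0,
                       t_end = 2.2, duration = 1.2, pathway = "axial")
  expect_equal(event_durations(ev), 1.2)
  expect_equal(event_durations(ev[0, ]), numeric(0))
  spec <- quick_spec(duration_ns = 150, seed = 17, n_bulk = 0)
  run <- generate_run(spec)
  ev2 <- detect_crossings(run$bundle)
  d <- event_durations(ev2)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 1.24), 3 * se + 0.05)
})
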