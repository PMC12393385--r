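test_that("columnar format round-trips losslessly at stated tolerances", {
  spec <- quick_spec(duration_ns = 10, seed = 42)
  run <- generate_run(spec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ion_traces(run$bundle, path)
  back <- read_ion_traces(path, geometry = spec$geometry, unwrap = FALSE)
  a <- dplyr::arrange(run$bundle$traces, ion_id, time_ns)
  b <- dplyr::arrange(back$traces, ion_id, time_ns)
  expect_equal(nrow(a), nrow(b))
  expect_equal(dplyr::n_distinct(b$ion_id), dplyr::n_distinct(a$ion_id))
  expect_equal(b$time_ns, a$time_ns, tolerance = 1e-6)
  expect_lt(max(abs(b$x - a$x), abs(b$y - a$y), abs(b$z - a$z)), 1e-4 + 1e-12)
  expect_identical(b$species, a$species)
})

test_that("an empty bundle writes a header-only file that reads back empty", {
  geom <- channel_geometry(20, -20)
  md <- system_metadata(1)
  empty <- perm_bundle(
    tibble::tibble(time_ns = numeric(), ion_id = character(),
                   species = character(), x = numeric(), y = numeric(),
                   z = numeric()),
    geom, md)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ion_traces(empty, path)
  back <- read_ion_traces(path, geometry = geom)
  expect_equal(nrow(back$traces), 0)
})

test_that("single-ion ingestion is an identity and geometry is mandatory", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time_ns\tion_id\tspecies\tx\ty\tz",
               "0.00\tk1\tK+\t1.0\t2.0\t30.0",
               "0.01\tk1\tK+\t1.1\t2.1\t29.0",
               "0.02\tk1\tK+\t1.2\t2.2\t28.0"), path)
  b <- read_ion_traces(path, geometry = channel_geometry(20, -20))
  expect_equal(nrow(b$traces), 3)
  expect_equal(b$traces$z, c(30, 29, 28))
  expect_equal(unique(b$traces$charge), 1L)
  expect_error(read_ion_traces(path), "geometry")
})

test_that("unwrapping folds large periodic jumps and is idempotent", {
  Lz <- 100
  tr <- tibble::tibble(time_ns = c(0, 0.01, 0.02), ion_id = "a",
                       species = "K+", x = 0, y = 0,
                       z = c(-45, 45, 44))      # +0.9 Lz apparent jump
  un <- unwrap_traces(tr, box = c(80, 80, Lz))
  # the +90 A jump is a wrapped -10 A step
  expect_equal(diff(un$z)[1], -10)
  expect_equal(unwrap_traces(un, box = c(80, 80, Lz)), un)
})

test_that("bundle validation rejects wrapped and non-monotonic traces", {
  geom <- channel_geometry(20, -20)
  md <- system_metadata(1, box = c(80, 80, 100))
  wrapped <- tibble::tibble(time_ns = c(0, 0.01), ion_id = "a",
                            species = "K+", x = 0, y = 0, z = c(-45, 45))
  expect_error(perm_bundle(wrapped, geom, md), "unwrapped")
  backwards <- tibble::tibble(time_ns = c(0.01, 0), ion_id = "a",
                              species = "K+", x = 0, y = 0, z = c(0, 1))
  expect_error(perm_bundle(backwards, geom, md), "monotonic")
})

test_that("multi-model PDB ingestion extracts ions and ring geometry", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(make_pdb_text(n_frames = 3), path)
  b <- read_pdb_trajectory(path, frame_interval_ps = 10)
  expect_s3_class(b, "perm_bundle")
  expect_equal(dplyr::n_distinct(b$traces$ion_id), 1)
  expect_equal(nrow(b$traces), 3)
  expect_equal(b$geometry$z_top, 20)
  expect_equal(b$geometry$z_bottom, -20)
  expect_true(b$geometry$time_varying)
  expect_true(all(b$geometry$rings$z_top > b$geometry$rings$z_bottom))
  # without boundary residues and without explicit geometry: error
  txt <- make_pdb_text(n_frames = 1)
  txt <- txt[!grepl("GLU", txt)]
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(txt, path2)
  expect_error(read_pdb_trajectory(path2), "Boundary residues")
  expect_s3_class(
    read_pdb_trajectory(path2, geometry = channel_geometry(20, -20)),
    "perm_bundle")
})
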