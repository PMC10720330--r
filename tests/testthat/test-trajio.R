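test_that("parse_formula handles the case-study formulas and degenerate input", {
  st <- parse_formula("C24H42O21")
  expect_identical(st, c(C = 24L, H = 42L, O = 21L))
  expect_identical(sum(st), 87L)

  dha <- parse_formula("C22H32O2")
  expect_identical(sum(dha), 56L)
  expect_identical(dha[["H"]], 32L)

  expect_identical(parse_formula("H"), c(H = 1L))
  expect_identical(parse_formula("CH4"), c(C = 1L, H = 4L))
  expect_error(parse_formula("Xx3"), "unknown element")
  expect_error(parse_formula("C2#H"), "cannot parse")
})

test_that("a minimal one-atom xyz file reads with absent optional fields", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "comment without recognised keys", "H 0 0 0"), path)
  ds <- read_extxyz(path)
  expect_s3_class(ds, "configuration_set")
  expect_identical(n_frames(ds), 1L)
  expect_identical(n_atoms(ds), 1L)
  expect_null(ds$energies)
  expect_null(ds$forces)
  expect_identical(ds$symbols, "H")
})

test_that("extxyz round-trip preserves positions, energies and forces", {
  ds <- random_set(n_frames = 3, seed = 7)
  path <- withr::local_tempfile(fileext = ".extxyz")
  write_extxyz(ds, path)
  back <- read_extxyz(path)
  expect_equal(back$positions, ds$positions, tolerance = 1e-6)
  expect_equal(back$energies, ds$energies, tolerance = 1e-6)
  expect_equal(back$forces, ds$forces, tolerance = 1e-6)
  expect_identical(back$symbols, ds$symbols)
})

test_that("malformed or inconsistent extxyz input fails with located errors", {
  bad_header <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "c", "H 0 0 0", "not_a_count", "c", "H 0 0 0"), bad_header)
  expect_error(read_extxyz(bad_header), "frame 2.*malformed frame header")

  varying <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "c", "H 0 0 0", "2", "c", "H 0 0 0", "O 1 0 0"), varying)
  expect_error(read_extxyz(varying), "inconsistent atom counts|atom identities")

  expect_error(read_extxyz(tempfile()), "not found")
})

test_that("make_subset dedups, sorts, and rejects out-of-range indices", {
  ds <- random_set(n_frames = 3)
  v <- make_subset(ds, c(3L, 1L, 3L))
  expect_identical(v$frame_indices, c(1L, 3L))
  expect_identical(make_subset(ds, integer(0))$frame_indices, integer(0))
  expect_error(make_subset(ds, 4L), "out of range.*4")
})

test_that("writing a subset keeps frame order; empty subsets warn", {
  ds <- random_set(n_frames = 3, seed = 11)
  path <- withr::local_tempfile(fileext = ".extxyz")
  write_extxyz(ds, path, selection = make_subset(ds, c(3L, 1L)))
  back <- read_extxyz(path)
  expect_identical(n_frames(back), 2L)
  expect_equal(back$positions[1, , ], ds$positions[1, , ], tolerance = 1e-6)
  expect_equal(back$positions[2, , ], ds$positions[3, , ], tolerance = 1e-6)

  empty <- withr::local_tempfile(fileext = ".extxyz")
  expect_warning(write_extxyz(ds, empty, selection = make_subset(ds, integer(0))), "empty subset")
  expect_identical(length(readLines(empty)), 0L)
})

test_that("a subset of all frames reproduces full-set metrics bit-identically", {
  ds <- random_set(n_frames = 5, seed = 13)
  tab <- compute_error_table(ds, perturbed_predictions(ds))
  full <- error_summary(tab)
  via_subset <- error_summary(tab, frames = make_subset(ds, seq_len(n_frames(ds))))
  expect_identical(full$mae, via_subset$mae)
  expect_identical(full$rmse, via_subset$rmse)
})

test_that("npz bundle round-trip preserves all arrays", {
  ds <- random_set(n_frames = 4, seed = 21)
  path <- withr::local_tempfile(fileext = ".npz")
  write_npz_bundle(ds, path)
  back <- read_npz_bundle(path)
  expect_equal(back$positions, ds$positions, tolerance = 1e-12)
  expect_equal(back$energies, ds$energies, tolerance = 1e-12)
  expect_equal(back$forces, ds$forces, tolerance = 1e-12)
  expect_identical(back$symbols, ds$symbols)

  # optional fields stay absent
  bare <- random_set(n_frames = 2, with_energies = FALSE, with_forces = FALSE)
  path2 <- withr::local_tempfile(fileext = ".npz")
  write_npz_bundle(bare, path2)
  back2 <- read_npz_bundle(path2)
  expect_null(back2$energies)
  expect_null(back2$forces)
})

test_that("a bundle written by numpy.savez reads correctly", {
  # fixture created with numpy (rng seed 12345), stored hex-encoded:
  # R (2x2x3), z = (6, 8), E = (-3.25, 4.5), F (2x2x3)
  hex <- paste(readLines(test_path("fixtures", "numpy_bundle_synthetic.hex")), collapse = "")
  bytes <- as.raw(strtoi(
    substring(hex, seq(1, nchar(hex), 2), seq(2, nchar(hex), 2)),
    base = 16L
  ))
  path <- withr::local_tempfile(fileext = ".npz")
  writeBin(bytes, path)
  ds <- read_npz_bundle(path)
  expect_identical(ds$symbols, c("C", "O"))
  expect_identical(ds$energies, c(-3.25, 4.5))
  expect_equal(ds$positions[1, 1, ], c(-1.423825, 1.263728, -0.870662))
  expect_equal(ds$positions[2, 2, ], c(-1.952863, 2.34741, 0.968497))
  expect_equal(ds$forces[2, 1, ], c(0.575858, 1.398979, 1.322298))
})

test_that("npz key_map supports renames and unit conversion factors", {
  ds <- random_set(n_frames = 2, seed = 31)
  path <- withr::local_tempfile(fileext = ".npz")
  write_npz_bundle(ds, path)
  same <- read_npz_bundle(path, key_map = list(energy_factor = 1))
  expect_identical(same$energies, ds$energies)
  doubled <- read_npz_bundle(path, key_map = list(energy_factor = 2, force_factor = 0.5))
  expect_equal(doubled$energies, 2 * ds$energies)
  expect_equal(doubled$forces, 0.5 * ds$forces)
})

test_that("missing mandatory arrays in a bundle list expected and found keys", {
  path <- withr::local_tempfile(fileext = ".npz")
  ffaudit:::.zip_store(list("E.npy" = ffaudit:::.npy_serialize(c(1, 2))), path)
  expect_error(read_npz_bundle(path), "expected \\{R, z\\}.*found \\{E\\}")
})

test_that("extra per-atom columns and comment metadata survive a round-trip", {
  ds <- random_set(n_frames = 2, seed = 41)
  ds$extra_atom_props <- list(atom_error = matrix(runif(2 * n_atoms(ds)), nrow = 2))
  ds$metadata <- rep(list(c(origin = "synthetic")), 2)
  path <- withr::local_tempfile(fileext = ".extxyz")
  write_extxyz(ds, path)
  back <- read_extxyz(path)
  expect_equal(back$extra_atom_props$atom_error, ds$extra_atom_props$atom_error,
    tolerance = 1e-6, ignore_attr = TRUE
  )
  expect_identical(back$metadata[[1]][["origin"]], "synthetic")
})
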