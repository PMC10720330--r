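audit_fixture_config <- function(fx, out_dir, ..., models = list(m = fx$predictions)) {
  audit_config(fx$dataset, models,
    out_dir = out_dir, window = 11,
    n_total = 8, n_structural = 4, seed = 5, write_plots = FALSE, ...
  )
}

test_that("a null audit (identity predictions) reports zeros and a complete manifest", {
  fx <- fixture_suite("stachyose_like", n_frames = 40, seed = 1)
  out <- withr::local_tempdir()
  cfg <- audit_fixture_config(fx, out,
    models = list(ident = identity_predictions(fx$dataset))
  )
  rep <- run_audit(cfg)
  g <- glance(rep)
  expect_identical(g$force_mae, 0)
  expect_identical(g$energy_rmse, 0)
  expect_identical(g$n_outliers, 0L)
  expect_true(all(file.exists(file.path(out, rep$manifest))))
  js <- jsonlite::read_json(file.path(out, "report.json"))
  expect_identical(js$schema_version, 1L)
  expect_true(all(unlist(js$manifest) %in% list.files(out)))

  ann <- read_extxyz(file.path(out, "annotated_ident.extxyz"))
  expect_true(all(ann$extra_atom_props$atom_error == 0))
})

test_that("per-element audit rows recombine exactly to the overall MAE", {
  fx <- fixture_suite("stachyose_like", n_frames = 60, seed = 2)
  out <- withr::local_tempdir()
  rep <- run_audit(audit_fixture_config(fx, out))
  per_el <- tidy(rep)
  pooled <- pool_stats(per_el)
  overall <- rep$summary[rep$summary$quantity == "force", ]
  expect_equal(pooled$mae, overall$mae, tolerance = 1e-12)
  expect_equal(pooled$rmse, overall$rmse, tolerance = 1e-12)
  counts <- parse_formula("C24H42O21")
  expect_identical(
    setNames(per_el$n / n_frames(fx$dataset), per_el$element)[names(counts)],
    setNames(as.numeric(counts), names(counts))
  )
})

test_that("two models audited together share one clustering", {
  fx <- fixture_suite("dha_like", n_frames = 60, seed = 3)
  second <- perturbed_predictions(fx$dataset, sd = 0.4, seed = 7, source_id = "other")
  out <- withr::local_tempdir()
  rep <- run_audit(audit_fixture_config(fx, out, models = list(a = fx$predictions, b = second)))
  prof_a <- rep$profiles[rep$profiles$model == "a", ]
  prof_b <- rep$profiles[rep$profiles$model == "b", ]
  expect_setequal(prof_a$cluster, prof_b$cluster)
  expect_identical(
    prof_a$size[order(prof_a$cluster)],
    prof_b$size[order(prof_b$cluster)]
  )
})

test_that("audits are byte-identical under a fixed seed", {
  fx <- fixture_suite("dha_like", n_frames = 50, seed = 4)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  run_audit(audit_fixture_config(fx, out1, train_subset = seq(1, 50, 2)))
  run_audit(audit_fixture_config(fx, out2, train_subset = seq(1, 50, 2)))
  for (f in c("report.json", "summary.csv", "cluster_profile.csv", "assignment.csv")) {
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)))
  }
})

test_that("representativeness of a full-coverage subset is near-perfect", {
  fx <- fixture_suite("dha_like", n_frames = 80, seed = 5)
  out <- withr::local_tempdir()
  rep <- run_audit(audit_fixture_config(fx, out, train_subset = seq_len(80)))
  expect_true(all(rep$representativeness$intersection == 1))
  expect_true(all(rep$representativeness$ks == 0))
})

test_that("annotated structures round-trip and rank planted atoms on top", {
  fx <- fixture_suite("stachyose_like", n_frames = 80, seed = 6)
  tab <- compute_error_table(fx$dataset, fx$predictions, convention = "vector_norm")
  path <- withr::local_tempfile(fileext = ".extxyz")
  export_annotated_structure(fx$dataset, tab, frames = "mean", path = path)
  back <- read_extxyz(path)
  expect_equal(
    as.vector(back$extra_atom_props$atom_error),
    colMeans(tab$atom_errors),
    tolerance = 1e-6
  )
  # designated "bond" carbons carry the top annotation values among carbons
  ann <- as.vector(back$extra_atom_props$atom_error)
  carbons <- which(fx$dataset$symbols == "C")
  bond_c <- intersect(fx$truth$bond_atoms, carbons)
  top <- carbons[order(ann[carbons], decreasing = TRUE)][seq_along(bond_c)]
  expect_setequal(top, bond_c)

  pdb_path <- withr::local_tempfile(fileext = ".pdb")
  export_annotated_structure(fx$dataset, tab, frames = "mean", path = pdb_path, format = "pdb")
  lines <- readLines(pdb_path)
  expect_gt(sum(grepl("^ATOM", lines)), 80)
})

test_that("a failing stage aborts with its name and removes partial outputs", {
  fx <- fixture_suite("dha_like", n_frames = 30, seed = 7)
  bad <- fx$dataset
  bad$energies <- NULL
  out <- file.path(withr::local_tempdir(), "aud")
  cfg <- audit_config(bad, list(m = fx$predictions), out_dir = out, write_plots = FALSE)
  expect_error(run_audit(cfg), "audit stage 'load'")
  expect_identical(list.files(out), character(0))
})

test_that("the CLI drives fixture generation and a full audit end-to-end", {
  root <- withr::local_tempdir()
  fd <- file.path(root, "fix")
  expect_identical(
    cli_main(c(
      "fixture", "--name", "dha_like", "--out", fd,
      "--frames", "60", "--seed", "3"
    )),
    0L
  )
  expect_true(all(file.exists(file.path(
    fd, c("dataset.extxyz", "predictions.extxyz", "truth.json")
  ))))

  ad <- file.path(root, "audit_out")
  code <- cli_main(c(
    "audit", "--dataset", file.path(fd, "dataset.extxyz"),
    "--predictions", file.path(fd, "predictions.extxyz"),
    "--out", ad, "--window", "7", "--clusters", "6", "--structural", "3",
    "--seed", "2", "--no-plots"
  ))
  expect_identical(code, 0L)
  js <- jsonlite::read_json(file.path(ad, "report.json"))
  expect_true(all(unlist(js$manifest) %in% list.files(ad)))
  expect_identical(js$n_clusters, 6L)

  # determinism: the same seeded command reproduces the JSON byte-for-byte
  ad2 <- file.path(root, "audit_out2")
  cli_main(c(
    "audit", "--dataset", file.path(fd, "dataset.extxyz"),
    "--predictions", file.path(fd, "predictions.extxyz"),
    "--out", ad2, "--window", "7", "--clusters", "6", "--structural", "3",
    "--seed", "2", "--no-plots"
  ))
  json1 <- readLines(file.path(ad, "report.json"))
  json2 <- readLines(file.path(ad2, "report.json"))
  expect_identical(json1, json2)
})

test_that("the CLI precompute and subset subcommands work on files", {
  root <- withr::local_tempdir()
  fd <- file.path(root, "fix")
  cli_main(c("fixture", "--name", "stachyose_like", "--out", fd, "--frames", "30"))
  stem <- file.path(root, "cache")
  expect_identical(
    cli_main(c(
      "precompute", "--plugin", "reference",
      "--dataset", file.path(fd, "dataset.extxyz"),
      "--out", stem, "--batch-size", "7"
    )),
    0L
  )
  expect_true(file.exists(paste0(stem, ".pred.npz")))
  cached <- read_npz_bundle(paste0(stem, ".pred.npz"))
  orig <- read_extxyz(file.path(fd, "dataset.extxyz"))
  expect_equal(cached$forces, orig$forces, tolerance = 1e-10)

  sub_out <- file.path(root, "sub.extxyz")
  expect_identical(
    cli_main(c(
      "subset", "--dataset", file.path(fd, "dataset.extxyz"),
      "--out", sub_out, "--frames", "5:10"
    )),
    0L
  )
  expect_identical(n_frames(read_extxyz(sub_out)), 6L)
})

test_that("CLI configuration errors exit 2 and runtime problems exit 1", {
  expect_identical(suppressMessages(cli_main(c("audit", "--dataset", "nope.xyz"))), 2L)
  expect_identical(suppressMessages(cli_main(c("audit", "--bogus-flag", "x"))), 2L)
  expect_identical(suppressMessages(cli_main("frobnicate")), 2L)
  expect_identical(suppressMessages(cli_main(character(0))), 2L)
  # structurally broken dataset: a runtime (not configuration) failure
  root <- withr::local_tempdir()
  bad <- file.path(root, "bad.xyz")
  writeLines(c("1", "c", "H 0 0 0", "oops"), bad)
  expect_identical(
    suppressMessages(cli_main(c(
      "audit", "--dataset", bad, "--predictions", bad,
      "--out", file.path(root, "o")
    ))),
    1L
  )
})
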