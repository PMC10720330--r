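# Independent loop-based oracle for the error-table conventions.
oracle_error_table <- function(ds, pred, convention) {
  nf <- n_frames(ds)
  na <- n_atoms(ds)
  ae <- matrix(0, nf, na)
  sq <- matrix(0, nf, na)
  for (f in seq_len(nf)) {
    for (a in seq_len(na)) {
      d <- pred$forces[f, a, ] - ds$forces[f, a, ]
      ae[f, a] <- if (convention == "component_mae") mean(abs(d)) else sqrt(sum(d^2))
      sq[f, a] <- mean(d^2)
    }
  }
  list(atom_errors = ae, atom_sq = sq, energy_errors = pred$energies - ds$energies)
}

test_that("error tables match a brute-force loop oracle in both conventions", {
  ds <- random_set(n_frames = 5, seed = 101)
  pred <- perturbed_predictions(ds, sd = 0.3, seed = 3)
  for (conv in c("component_mae", "vector_norm")) {
    tab <- compute_error_table(ds, pred, convention = conv)
    ora <- oracle_error_table(ds, pred, conv)
    expect_equal(tab$atom_errors, ora$atom_errors, tolerance = 1e-10)
    expect_equal(tab$atom_sq, ora$atom_sq, tolerance = 1e-10)
    expect_equal(tab$energy_errors, ora$energy_errors, tolerance = 1e-10)
  }
})

test_that("single-component error splits as expected between conventions", {
  ds <- configuration_set("H", array(0, c(1, 1, 3)),
    energies = 0, forces = array(0, c(1, 1, 3))
  )
  pred <- prediction_record("p", 0, array(c(0.3, 0, 0), c(1, 1, 3)))
  expect_equal(compute_error_table(ds, pred, convention = "component_mae")$atom_errors[1, 1], 0.1)
  expect_equal(compute_error_table(ds, pred, convention = "vector_norm")$atom_errors[1, 1], 0.3)
})

test_that("identity predictions give exactly zero everywhere", {
  ds <- random_set(n_frames = 4, seed = 103)
  tab <- compute_error_table(ds, identity_predictions(ds))
  expect_true(all(tab$atom_errors == 0))
  expect_true(all(tab$energy_errors == 0))
  expect_identical(error_summary(tab)$rmse, 0)
})

test_that("MAE/MSE pool exactly over any disjoint partition and rmse >= mae", {
  ds <- random_set(n_frames = 6, symbols = c("C", "C", "H", "H", "O", "N"), seed = 104)
  tab <- compute_error_table(ds, perturbed_predictions(ds, sd = 0.2))
  half <- atom_selection(c(1, 3, 5))
  other <- atom_selection(c(2, 4, 6))
  pooled <- pool_stats(dplyr::bind_rows(
    error_summary(tab, atoms = half),
    error_summary(tab, atoms = other)
  ))
  full <- error_summary(tab)
  expect_equal(pooled$mae, full$mae, tolerance = 1e-14)
  expect_equal(pooled$rmse, full$rmse, tolerance = 1e-14)

  by_el <- element_summary(tab)
  expect_equal(pool_stats(by_el)$mae, full$mae, tolerance = 1e-14)
  expect_equal(pool_stats(by_el)$rmse, full$rmse, tolerance = 1e-14)
  expect_true(all(by_el$rmse >= by_el$mae))

  expect_error(error_summary(tab, frames = integer(0)), "empty selection")
})

test_that("degenerate one-atom selections collapse mae and rmse together", {
  ds <- configuration_set("H", array(0, c(1, 1, 3)),
    energies = 0, forces = array(0, c(1, 1, 3))
  )
  pred <- prediction_record("p", 0, array(c(0.2, 0.2, 0.2), c(1, 1, 3)))
  s <- error_summary(compute_error_table(ds, pred))
  expect_equal(s$mae, 0.2)
  expect_equal(s$rmse, 0.2)
})

test_that("planted per-element error scales are recovered from the samples", {
  spec <- fixture_spec("C10H30", 500, thermal_scale = 0.1, seed = 7)
  ds <- generate_trajectory(spec)
  em <- error_model_spec(c(H = 0.1, C = 0.4), seed = 11)
  tab <- compute_error_table(ds, generate_predictions(ds, em))
  samples <- per_element_errors(tab)
  expect_identical(nrow(samples), n_frames(ds) * n_atoms(ds))
  means <- tapply(samples$error, samples$element, mean)
  expect_equal(unname(means[["C"]] / means[["H"]]), 4, tolerance = 0.05)
  # half-normal closed form: E|N(0, s)| = s * sqrt(2/pi)
  expect_equal(unname(means[["H"]]), 0.1 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("relative errors normalise away per-element force scales", {
  ds <- random_set(n_frames = 4, seed = 106)
  pred <- perturbed_predictions(ds, sd = 0.2)
  tab <- compute_error_table(ds, pred)
  rel <- relative_errors(tab, ds)

  # doubling forces and errors together leaves relative samples unchanged
  ds2 <- configuration_set(ds$symbols, ds$positions,
    energies = ds$energies,
    forces = 2 * ds$forces
  )
  pred2 <- prediction_record("p", pred$energies, 2 * pred$forces)
  rel2 <- relative_errors(compute_error_table(ds2, pred2), ds2)
  expect_equal(rel2$rel_error, rel$rel_error, tolerance = 1e-12)

  # direct ratio: error norm 0.5 against reference norm 2.0
  ds1 <- configuration_set("H", array(0, c(1, 1, 3)),
    energies = 0, forces = array(c(2, 0, 0), c(1, 1, 3))
  )
  p1 <- prediction_record("p", 0, array(c(2.5, 0, 0), c(1, 1, 3)))
  r1 <- relative_errors(compute_error_table(ds1, p1, convention = "vector_norm"), ds1)
  expect_equal(r1$rel_error, 0.25)

  # planted equal relative error across elements with unequal force scales
  spec <- fixture_spec("C10H30", 400, thermal_scale = 0.1, seed = 8)
  dsf <- generate_trajectory(spec)
  dsf$forces[, dsf$symbols == "C", ] <- 3 * dsf$forces[, dsf$symbols == "C", ]
  fn <- sqrt(dsf$forces[, , 1]^2 + dsf$forces[, , 2]^2 + dsf$forces[, , 3]^2)
  scale_by_el <- vapply(c(H = "H", C = "C"), function(el) {
    mean(fn[, dsf$symbols == el])
  }, numeric(1))
  emf <- error_model_spec(0.05 * scale_by_el / scale_by_el[["H"]], seed = 12)
  relf <- relative_errors(compute_error_table(dsf, generate_predictions(dsf, emf)), dsf)
  rel_means <- tapply(relf$rel_error, relf$element, mean)
  expect_equal(unname(rel_means[["C"]] / rel_means[["H"]]), 1, tolerance = 0.05)

  zero <- configuration_set("H", array(0, c(1, 1, 3)),
    energies = 0, forces = array(0, c(1, 1, 3))
  )
  ztab <- compute_error_table(zero, prediction_record("p", 0, array(1, c(1, 1, 3))))
  expect_error(relative_errors(ztab, zero), "zero mean reference force norm")
})

test_that("timeline smoothing matches a loop-based centered mean with truncation", {
  set.seed(201)
  x <- rnorm(40)
  expect_identical(smooth_timeline(x, 1), x)
  expect_equal(smooth_timeline(rep(2.5, 10), 5), rep(2.5, 10))
  sm <- smooth_timeline(x, 5)
  oracle <- vapply(seq_along(x), function(i) {
    mean(x[max(1, i - 2):min(length(x), i + 2)])
  }, numeric(1))
  expect_equal(sm, oracle, tolerance = 1e-12)
  expect_identical(length(sm), length(x))
  expect_error(smooth_timeline(x, 0), "positive")
})

test_that("the KDE is normalised and recovers the standard-normal density", {
  set.seed(301)
  x <- rnorm(10000)
  curve <- kde_curve(x)
  expect_gt(curve_integral(curve), 0.99)
  expect_lt(curve_integral(curve), 1.01)
  at0 <- curve$density[which.min(abs(curve$grid))]
  expect_equal(at0, 1 / sqrt(2 * pi), tolerance = 0.1)

  # two samples, small bandwidth: symmetric double peak about the midpoint
  c2 <- kde_curve(c(0, 1), bandwidth = 0.1, n_grid = 401)
  left <- c2$density[c2$grid < 0.5]
  right <- rev(c2$density[c2$grid > 0.5])
  expect_equal(left, right[seq_along(left)], tolerance = 1e-9)

  expect_error(kde_curve(rep(1, 5)), "distinct samples")
})

test_that("scatter outlier flags find planted outliers and ignore translations", {
  ds <- random_set(n_frames = 50, seed = 401)
  none <- correlation_scatter(ds, identity_predictions(ds), "energy")
  expect_identical(sum(none$outlier), 0L)

  pred <- perturbed_predictions(ds, sd = 0.05, seed = 5)
  sigma <- 0.05
  pred$energies[17] <- ds$energies[17] + 50 * sigma
  sc <- correlation_scatter(ds, pred, "energy")
  expect_identical(which(sc$outlier), 17L)

  shifted_ds <- ds
  shifted_ds$energies <- ds$energies + 100
  shifted_pred <- pred
  shifted_pred$energies <- pred$energies + 100
  sc2 <- correlation_scatter(shifted_ds, shifted_pred, "energy")
  expect_identical(sc2$outlier, sc$outlier)

  scf <- correlation_scatter(ds, identity_predictions(ds), "force_component")
  expect_identical(nrow(scf), n_frames(ds) * n_atoms(ds) * 3L)
  expect_identical(sum(scf$outlier), 0L)
})

test_that("distribution comparison is exact for identity and disjoint samples", {
  x <- rnorm(500)
  same <- compare_distributions(x, x)
  expect_equal(same$intersection, 1)
  expect_equal(same$ks, 0)

  disj <- compare_distributions(runif(200, 0, 1), runif(200, 5, 6))
  expect_equal(disj$intersection, 0)
  expect_equal(disj$ks, 1)

  set.seed(501)
  big <- compare_distributions(runif(10000), runif(10000))
  # 1% critical value of the two-sample KS statistic at n = m = 10000
  expect_lt(big$ks, 1.63 * sqrt(2 / 10000))

  expect_error(compare_distributions(numeric(0), x), "nonempty")
})

test_that("metrics are invariant under a consistent frame permutation", {
  ds <- random_set(n_frames = 8, seed = 601)
  pred <- perturbed_predictions(ds, sd = 0.2)
  set.seed(1)
  perm <- sample(8)
  dsp <- configuration_set(ds$symbols, ds$positions[perm, , ],
    energies = ds$energies[perm], forces = ds$forces[perm, , ]
  )
  predp <- prediction_record("p", pred$energies[perm], pred$forces[perm, , ])
  expect_equal(
    error_summary(compute_error_table(ds, pred)),
    error_summary(compute_error_table(dsp, predp)),
    tolerance = 1e-14
  )
  expect_equal(
    dplyr::arrange(element_summary(compute_error_table(ds, pred)), label),
    dplyr::arrange(element_summary(compute_error_table(dsp, predp)), label),
    tolerance = 1e-14
  )
})
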