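# Shared in-code fixtures. All randomness is seeded per call so tests are
# order-independent.

random_set <- function(n_frames = 3L, symbols = c("O", "H", "H", "C"),
                       seed = 42L, with_energies = TRUE, with_forces = TRUE,
                       name = "random_test_set") {
  set.seed(seed)
  na <- length(symbols)
  configuration_set(
    symbols = symbols,
    positions = array(rnorm(n_frames * na * 3, sd = 2), c(n_frames, na, 3)),
    energies = if (with_energies) rnorm(n_frames, mean = -10),
    forces = if (with_forces) array(rnorm(n_frames * na * 3), c(n_frames, na, 3)),
    name = name
  )
}

identity_predictions <- function(ds, source_id = "identity") {
  prediction_record(source_id, ds$energies, ds$forces)
}

perturbed_predictions <- function(ds, sd = 0.1, seed = 1L, source_id = "noisy") {
  set.seed(seed)
  prediction_record(
    source_id,
    ds$energies + rnorm(n_frames(ds), sd = sd),
    ds$forces + array(rnorm(length(ds$forces), sd = sd), dim = dim(ds$forces))
  )
}

# rigid-body transform of every frame: rotation (from a seeded QR) + shift
rigid_transform <- function(ds, seed = 99L, shift = c(5, -3, 2)) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  rot <- qr.Q(qr_)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  pos <- ds$positions
  for (f in seq_len(n_frames(ds))) {
    pos[f, , ] <- matrix(ds$positions[f, , ], ncol = 3) %*% rot +
      matrix(shift, n_atoms(ds), 3, byrow = TRUE)
  }
  configuration_set(ds$symbols, pos,
    energies = ds$energies, forces = ds$forces,
    name = ds$name
  )
}
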