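# Synthetic trajectories with planted statistical structure. Energetics are
# harmonic around per-basin reference geometries, so reference energies and
# forces are analytic (forces are exact gradients) and every planted contrast
# (per-element error scales, per-basin factors, fold-error correlation) has a
# closed-form expectation: for Gaussian force noise of scale sigma the
# expected component MAE is sigma * sqrt(2/pi) (half-normal mean).

#' Recipe for a synthetic trajectory
#'
#' @param formula Molecular formula, e.g. `"C24H42O21"`.
#' @param n_frames Number of frames.
#' @param n_basins Number of distinct reference structures the trajectory
#'   cycles through.
#' @param basin_scale Minimum mean per-atom displacement separating basin
#'   geometries, Angstrom. For separability fixtures keep
#'   `basin_scale > 3 * thermal_scale`.
#' @param thermal_scale Per-frame Gaussian positional jitter, Angstrom.
#' @param fold_cycle Optional period (frames) of a global compactness
#'   oscillation, so the radius of gyration oscillates and "folded" frames
#'   can carry distinct planted errors.
#' @param seed Integer seed; fixtures are bit-identical given the seed.
#' @param spring_k Harmonic force constant, kcal/(mol*A^2).
#' @param basin_energy_gap Energy offset between consecutive basins, kcal/mol.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(formula, n_frames, n_basins = 1L, basin_scale = 2,
                         thermal_scale = 0.1, fold_cycle = NULL, seed = 1L,
                         spring_k = 50, basin_energy_gap = 5) {
  parse_formula(formula) # validates
  stopifnot(n_frames >= 1L, n_basins >= 1L, basin_scale > 0, thermal_scale > 0, spring_k > 0)
  if (!is.null(fold_cycle)) stopifnot(fold_cycle >= 2L)
  structure(
    list(
      formula = formula, n_frames = as.integer(n_frames),
      n_basins = as.integer(n_basins), basin_scale = basin_scale,
      thermal_scale = thermal_scale, fold_cycle = fold_cycle,
      seed = as.integer(seed), spring_k = spring_k,
      basin_energy_gap = basin_energy_gap
    ),
    class = "fixture_spec"
  )
}

#' Generate a synthetic reference trajectory
#'
#' Atoms come from the formula (element blocks in formula order). `n_basins`
#' random reference geometries, separated by at least `basin_scale` (mean
#' per-atom displacement), are visited in contiguous blocks; each frame adds
#' Gaussian jitter of `thermal_scale`. The reference energy is a quadratic
#' function of the displacement from the current basin geometry (plus a
#' per-basin offset) and the reference forces are its exact analytic
#' gradient. With `fold_cycle` set, a global compactness factor oscillates
#' with that period (the reference geometry breathes between an extended and
#' a folded state) and frames in the compact half of the cycle are labelled
#' as the "folded" basin.
#'
#' @param spec A [fixture_spec()].
#' @return A [configuration_set()] with energies and forces; the generating
#'   parameters (basin geometries, per-frame basin labels, compactness,
#'   spring constant) are attached as the `"ground_truth"` attribute.
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  symbols <- formula_to_symbols(spec$formula)
  na <- length(symbols)
  nf <- spec$n_frames
  r0 <- 1.2 * na^(1 / 3)
  base <- matrix(rnorm(na * 3, sd = r0), ncol = 3L)

  fold <- !is.null(spec$fold_cycle)
  if (fold) {
    fold_amp <- 0.3
    s <- 1 - fold_amp * (0.5 - 0.5 * cos(2 * pi * (seq_len(nf) - 1) / spec$fold_cycle))
    basin_of_frame <- 1L + as.integer(s < 1 - fold_amp / 2) # 2 = folded
    disp <- list(matrix(0, na, 3L), matrix(0, na, 3L))
    offsets <- c(0, 0)
  } else {
    s <- rep(1, nf)
    disp <- lapply(seq_len(spec$n_basins), function(b) {
      matrix(rnorm(na * 3, sd = spec$basin_scale), ncol = 3L)
    })
    if (spec$n_basins > 1) {
      min_sep <- min(vapply(
        utils::combn(spec$n_basins, 2, simplify = FALSE),
        function(p) {
          mean(sqrt(rowSums((disp[[p[1]]] - disp[[p[2]]])^2)))
        }, numeric(1)
      ))
      if (min_sep < spec$basin_scale) {
        disp <- lapply(disp, function(u) u * spec$basin_scale / min_sep)
      }
    }
    seg <- max(1L, ceiling(nf / (2L * spec$n_basins)))
    basin_of_frame <- ((seq_len(nf) - 1L) %/% seg) %% spec$n_basins + 1L
    offsets <- (seq_len(spec$n_basins) - 1) * spec$basin_energy_gap
  }

  positions <- array(0, dim = c(nf, na, 3L))
  forces <- array(0, dim = c(nf, na, 3L))
  energies <- numeric(nf)
  k <- spec$spring_k
  for (f in seq_len(nf)) {
    center <- if (fold) s[f] * base else base + disp[[basin_of_frame[f]]]
    dr <- matrix(rnorm(na * 3, sd = spec$thermal_scale), ncol = 3L)
    positions[f, , ] <- center + dr
    forces[f, , ] <- -k * dr
    e0 <- if (fold) 30 * (1 - s[f]) else offsets[basin_of_frame[f]]
    energies[f] <- e0 + 0.5 * k * sum(dr^2)
  }
  ds <- configuration_set(symbols, positions,
    energies = energies, forces = forces,
    name = paste0("synthetic:", spec$formula)
  )
  attr(ds, "ground_truth") <- list(
    spec = spec, base_geometry = base, basin_displacements = if (!fold) disp,
    basin_of_frame = basin_of_frame, compactness = s,
    basin_offsets = offsets, spring_k = k, folded = if (fold) basin_of_frame == 2L
  )
  ds
}

#' Energy of the generating model at arbitrary coordinates
#'
#' Evaluates the synthetic harmonic-basin energy surface of a generated
#' trajectory at given positions for one frame (used to verify that stored
#' forces are exact gradients, e.g. by finite differences).
#'
#' @param ds A [generate_trajectory()] result.
#' @param frame Frame index.
#' @param positions `n_atoms x 3` coordinates at which to evaluate.
#' @return Scalar energy, kcal/mol.
#' @export
fixture_energy <- function(ds, frame, positions) {
  gt <- attr(ds, "ground_truth")
  if (is.null(gt)) stop("not a generated fixture (no ground_truth attribute)", call. = FALSE)
  fold <- !is.null(gt$spec$fold_cycle)
  center <- if (fold) {
    gt$compactness[frame] * gt$base_geometry
  } else {
    gt$base_geometry + gt$basin_displacements[[gt$basin_of_frame[frame]]]
  }
  e0 <- if (fold) 30 * (1 - gt$compactness[frame]) else gt$basin_offsets[gt$basin_of_frame[frame]]
  e0 + 0.5 * gt$spring_k * sum((positions - center)^2)
}

#' Planted error model for pseudo-predictions
#'
#' @param element_scale Named numeric vector mapping element symbol to the
#'   Gaussian force-error scale, kcal/(mol*A); every element of the dataset
#'   must be covered.
#' @param basin_factor Numeric multiplicative error factor per basin
#'   (recycled to the number of basins; default 1).
#' @param energy_noise Gaussian energy-error scale, kcal/mol.
#' @param bias Constant added to every predicted force component,
#'   kcal/(mol*A).
#' @param atom_factor Optional per-atom multiplicative error factor (length
#'   `n_atoms`), for planting elevated errors on designated atoms.
#' @param seed Integer seed.
#' @return An object of class `error_model_spec`.
#' @export
error_model_spec <- function(element_scale, basin_factor = 1, energy_noise = 0,
                             bias = 0, atom_factor = NULL, seed = 1L) {
  stopifnot(
    is.numeric(element_scale), !is.null(names(element_scale)),
    all(element_scale >= 0), all(basin_factor >= 0), energy_noise >= 0
  )
  structure(
    list(
      element_scale = element_scale, basin_factor = basin_factor,
      energy_noise = energy_noise, bias = bias, atom_factor = atom_factor,
      seed = as.integer(seed)
    ),
    class = "error_model_spec"
  )
}

#' Generate pseudo-predictions with planted error structure
#'
#' Each predicted force component is the reference plus `bias` plus Gaussian
#' noise of scale `element_scale[element] * basin_factor[basin] *
#' atom_factor[atom]`; each predicted energy is the reference plus Gaussian
#' noise of scale `energy_noise`. Fully reproducible from the seed. The
#' expected per-element component MAE is the half-normal mean
#' `sigma * sqrt(2/pi)` (plus `|bias|` effects when a bias is planted).
#'
#' @param ds A [configuration_set()] with reference energies and forces
#'   (basin labels are taken from its `"ground_truth"` attribute when
#'   present; otherwise one basin is assumed).
#' @param em An [error_model_spec()].
#' @return A [prediction_record()].
#' @export
generate_predictions <- function(ds, em) {
  stopifnot(inherits(ds, "configuration_set"), inherits(em, "error_model_spec"))
  if (is.null(ds$forces) || is.null(ds$energies)) {
    stop("dataset must carry reference energies and forces", call. = FALSE)
  }
  missing_el <- setdiff(unique(ds$symbols), names(em$element_scale))
  if (length(missing_el) > 0) {
    stop("element_scale missing element(s): ", paste(missing_el, collapse = ", "),
      call. = FALSE
    )
  }
  nf <- n_frames(ds)
  na <- n_atoms(ds)
  gt <- attr(ds, "ground_truth")
  basins <- if (!is.null(gt)) gt$basin_of_frame else rep(1L, nf)
  bf <- rep_len(em$basin_factor, max(basins))
  af <- em$atom_factor %||% rep(1, na)
  stopifnot(length(af) == na)
  sigma <- outer(bf[basins], em$element_scale[ds$symbols] * af) # nf x na
  set.seed(em$seed)
  forces <- ds$forces + em$bias
  for (comp in 1:3) {
    forces[, , comp] <- forces[, , comp] + matrix(rnorm(nf * na), nf, na) * sigma
  }
  energies <- ds$energies + rnorm(nf, sd = em$energy_noise)
  prediction_record("planted_error_model", energies, forces)
}

#' Ready-made audit fixtures with known error structure
#'
#' Two end-to-end fixture suites emulating the package's motivating case
#' studies:
#'
#' * `stachyose_like` — a C24H42O21 trajectory (87 atoms) over 3 structural
#'   basins, with a designated "bond" atom subset (the first 6 carbons and
#'   first 4 oxygens) carrying a 1.5x planted error factor, mimicking the
#'   elevated errors of atoms at glycosidic linkages.
#' * `dha_like` — a C22H32O2 trajectory (56 atoms) whose compactness
#'   oscillates (`fold_cycle = n_frames / 3`) and whose folded frames carry a
#'   2x planted error factor, so error timelines peak on folded geometries.
#'
#' @param name `"stachyose_like"` or `"dha_like"`.
#' @param n_frames Number of frames (default 500).
#' @param seed Integer seed.
#' @return A list with elements `dataset` (a [configuration_set()]),
#'   `predictions` (a [prediction_record()]) and `truth` (a list describing
#'   the planted structure: error scales, designated atoms/frames, factors).
#' @export
fixture_suite <- function(name = c("stachyose_like", "dha_like"),
                          n_frames = 500L, seed = 0L) {
  name <- match.arg(name)
  seed <- as.integer(seed)
  if (name == "stachyose_like") {
    spec <- fixture_spec("C24H42O21", n_frames,
      n_basins = 3L, basin_scale = 3,
      thermal_scale = 0.15, seed = seed
    )
    ds <- generate_trajectory(spec)
    bond_atoms <- c(1:6, 67:70) # first 6 C, first 4 O (element blocks C/H/O)
    af <- rep(1, n_atoms(ds))
    af[bond_atoms] <- 1.5
    element_scale <- c(H = 0.15, C = 0.40, O = 0.30)
    em <- error_model_spec(element_scale,
      energy_noise = 0.5, atom_factor = af,
      seed = seed + 1L
    )
    pred <- generate_predictions(ds, em)
    truth <- list(
      name = name, element_scale = element_scale, bond_atoms = bond_atoms,
      bond_factor = 1.5, energy_noise = 0.5,
      basin_of_frame = attr(ds, "ground_truth")$basin_of_frame
    )
  } else {
    spec <- fixture_spec("C22H32O2", n_frames,
      thermal_scale = 0.12,
      fold_cycle = max(2L, as.integer(round(n_frames / 3))), seed = seed
    )
    ds <- generate_trajectory(spec)
    element_scale <- c(H = 0.10, C = 0.30, O = 0.35)
    em <- error_model_spec(element_scale,
      basin_factor = c(1, 2), energy_noise = 0.5,
      seed = seed + 1L
    )
    pred <- generate_predictions(ds, em)
    truth <- list(
      name = name, element_scale = element_scale, fold_factor = 2,
      folded_frames = which(attr(ds, "ground_truth")$folded),
      energy_noise = 0.5, fold_cycle = spec$fold_cycle
    )
  }
  list(dataset = ds, predictions = pred, truth = truth)
}
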