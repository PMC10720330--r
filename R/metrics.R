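#' Per-frame, per-atom error table
#'
#' Computes the force and energy error bookkeeping that all downstream
#' analyses consume. Two per-atom scalar conventions are supported:
#'
#' * `component_mae` — the mean over the three Cartesian components of the
#'   absolute force-component error. Averaging these scalars over any atom
#'   selection reproduces the component-wise MAE of that selection exactly,
#'   so per-element MAEs recombine (atom-count-weighted) to the overall MAE.
#' * `vector_norm` — the Euclidean norm of the force-error vector, the
#'   natural quantity for per-atom error projections onto a structure.
#'
#' In `reference_magnitude` mode (the "dummy model" audit of the reference
#' data itself) the per-atom scalar is the reference force-vector norm and
#' the per-frame scalar is the reference energy.
#'
#' @param ds A [configuration_set()] with reference energies/forces.
#' @param pred A prediction record aligned 1:1 with `ds` (see
#'   [load_prestored_predictions()]); ignored in `reference_magnitude` mode.
#' @param mode `"model_vs_reference"` (default) or `"reference_magnitude"`.
#' @param convention `"component_mae"` (default) or `"vector_norm"`.
#' @return An object of class `error_table` with fields `atom_errors`
#'   (`n_frames x n_atoms` matrix, kcal/(mol*A)), `atom_sq` (mean squared
#'   component error, for RMSE pooling), `energy_errors` (signed, kcal/mol),
#'   `convention`, `source_mode`, and the atom `symbols`.
#' @export
compute_error_table <- function(ds, pred = NULL,
                                mode = c("model_vs_reference", "reference_magnitude"),
                                convention = c("component_mae", "vector_norm")) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  stopifnot(inherits(ds, "configuration_set"))
  if (mode == "reference_magnitude") {
    if (is.null(ds$forces) || is.null(ds$energies)) {
      stop("reference_magnitude mode requires reference energies and forces", call. = FALSE)
    }
    d <- ds$forces
    energy_errors <- ds$energies
    convention <- "vector_norm"
    atom_errors <- sqrt(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)
    atom_sq <- (d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2) / 3
  } else {
    if (is.null(pred)) stop("pred is required in model_vs_reference mode", call. = FALSE)
    stopifnot(inherits(pred, "prediction_record"))
    if (is.null(ds$forces) || is.null(ds$energies)) {
      stop("model_vs_reference mode requires reference energies and forces on ds",
        call. = FALSE
      )
    }
    check_aligned(ds, pred)
    d <- pred$forces - ds$forces
    energy_errors <- pred$energies - ds$energies
    atom_errors <- switch(convention,
      component_mae = (abs(d[, , 1]) + abs(d[, , 2]) + abs(d[, , 3])) / 3,
      vector_norm = sqrt(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)
    )
    atom_sq <- (d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2) / 3
  }
  atom_errors <- matrix(as.vector(atom_errors), nrow = n_frames(ds), ncol = n_atoms(ds))
  atom_sq <- matrix(as.vector(atom_sq), nrow = n_frames(ds), ncol = n_atoms(ds))
  structure(
    list(
      atom_errors = atom_errors, atom_sq = atom_sq,
      energy_errors = as.numeric(energy_errors),
      convention = convention, source_mode = mode,
      symbols = ds$symbols, name = ds$name,
      source_id = if (!is.null(pred)) pred$source_id else "reference"
    ),
    class = "error_table"
  )
}

#' @export
print.error_table <- function(x, ...) {
  cat("<error_table> ", nrow(x$atom_errors), " frames x ", ncol(x$atom_errors),
    " atoms; convention=", x$convention, ", mode=", x$source_mode, "\n",
    sep = ""
  )
  invisible(x)
}

.resolve_frames <- function(table, frames) {
  if (is.null(frames)) {
    return(seq_len(nrow(table$atom_errors)))
  }
  if (inherits(frames, "subset_view")) {
    return(frames$frame_indices)
  }
  as.integer(frames)
}

.resolve_atoms <- function(table, atoms) {
  if (is.null(atoms)) {
    return(seq_len(ncol(table$atom_errors)))
  }
  if (inherits(atoms, "atom_selection")) {
    return(atoms$atom_indices)
  }
  as.integer(atoms)
}

#' Summarise force errors over a selection
#'
#' MAE and RMSE of the per-atom force errors over an optional frame subset
#' and/or atom selection. MAE is the mean of the per-atom scalars; RMSE is
#' the root of the mean squared component error over the selection, so both
#' pool exactly across disjoint selections (see [pool_stats()]).
#'
#' @param table An [compute_error_table()] result.
#' @param frames Optional [make_subset()] view or integer frame indices.
#' @param atoms Optional [atom_selection()] or integer atom indices.
#' @param label Label for the output row.
#' @return A one-row tibble with columns `label`, `n` (number of atom-frame
#'   samples), `mae`, `rmse`.
#' @export
error_summary <- function(table, frames = NULL, atoms = NULL, label = "all") {
  stopifnot(inherits(table, "error_table"))
  fi <- .resolve_frames(table, frames)
  ai <- .resolve_atoms(table, atoms)
  if (length(fi) == 0 || length(ai) == 0) {
    stop("empty selection: no frames/atoms to aggregate", call. = FALSE)
  }
  e <- table$atom_errors[fi, ai, drop = FALSE]
  s <- table$atom_sq[fi, ai, drop = FALSE]
  tibble(label = label, n = length(e), mae = mean(e), rmse = sqrt(mean(s)))
}

#' Summarise energy errors
#'
#' @inheritParams error_summary
#' @return A one-row tibble with `label`, `n` (frames), `mae`, `rmse` of the
#'   absolute per-frame energy errors, kcal/mol.
#' @export
energy_summary <- function(table, frames = NULL, label = "all") {
  stopifnot(inherits(table, "error_table"))
  fi <- .resolve_frames(table, frames)
  if (length(fi) == 0) stop("empty selection: no frames to aggregate", call. = FALSE)
  e <- table$energy_errors[fi]
  tibble(label = label, n = length(e), mae = mean(abs(e)), rmse = sqrt(mean(e^2)))
}

#' Pool per-group error summaries
#'
#' Recombines disjoint per-group summaries (e.g. per-element rows) into the
#' overall statistics: the pooled MAE is the sample-count-weighted mean of
#' the group MAEs, and the pooled RMSE is the root of the count-weighted
#' mean of the squared group RMSEs.
#'
#' @param stats A tibble/data frame with columns `n`, `mae`, `rmse`.
#' @param label Label for the pooled row.
#' @return A one-row tibble (`label`, `n`, `mae`, `rmse`).
#' @export
pool_stats <- function(stats, label = "pooled") {
  stopifnot(all(c("n", "mae", "rmse") %in% names(stats)))
  n <- sum(stats$n)
  tibble(
    label = label, n = n,
    mae = sum(stats$n * stats$mae) / n,
    rmse = sqrt(sum(stats$n * stats$rmse^2) / n)
  )
}

#' Per-element force-error samples
#'
#' Splits the per-atom error samples by chemical element: every atom
#' contributes one sample per frame to exactly one element's set.
#'
#' @param table An [compute_error_table()] result.
#' @return A tibble with columns `element`, `frame`, `atom`, `error` (one row
#'   per atom-frame sample; `nrow = n_frames * n_atoms`).
#' @export
per_element_errors <- function(table) {
  stopifnot(inherits(table, "error_table"))
  nf <- nrow(table$atom_errors)
  na <- ncol(table$atom_errors)
  tibble(
    element = rep(table$symbols, each = nf),
    frame = rep(seq_len(nf), times = na),
    atom = rep(seq_len(na), each = nf),
    error = as.vector(table$atom_errors)
  )
}

#' Per-element summary table
#'
#' @param table An [compute_error_table()] result.
#' @return A tibble with one row per element: `label`, `n`, `mae`, `rmse`,
#'   ordered by first appearance of the element among the atoms.
#' @export
element_summary <- function(table) {
  stopifnot(inherits(table, "error_table"))
  elems <- unique(table$symbols)
  dplyr::bind_rows(lapply(elems, function(el) {
    error_summary(table, atoms = which(table$symbols == el), label = el)
  }))
}

#' Relative (force-scale-normalised) per-element errors
#'
#' Divides each element's error samples by the mean reference force-vector
#' norm over that element's atoms and all frames, giving dimensionless
#' errors comparable across elements with different typical force scales.
#'
#' @param table An [compute_error_table()] result.
#' @param ds The originating [configuration_set()] (reference forces needed).
#' @return A tibble like [per_element_errors()] with an extra column
#'   `rel_error` and the per-element normaliser `ref_norm`.
#' @export
relative_errors <- function(table, ds) {
  stopifnot(inherits(table, "error_table"), inherits(ds, "configuration_set"))
  if (is.null(ds$forces)) stop("reference forces required", call. = FALSE)
  fn <- sqrt(ds$forces[, , 1]^2 + ds$forces[, , 2]^2 + ds$forces[, , 3]^2)
  fn <- matrix(as.vector(fn), nrow = n_frames(ds), ncol = n_atoms(ds))
  samples <- per_element_errors(table)
  norms <- vapply(
    unique(ds$symbols),
    function(el) mean(fn[, ds$symbols == el, drop = FALSE]), numeric(1)
  )
  if (any(norms == 0)) {
    stop(
      "zero mean reference force norm for element(s): ",
      paste(names(norms)[norms == 0], collapse = ", "),
      call. = FALSE
    )
  }
  samples$ref_norm <- unname(norms[samples$element])
  samples$rel_error <- samples$error / samples$ref_norm
  samples
}

#' Centered moving-average smoothing of a per-frame series
#'
#' Smooths a per-frame scalar series with a centered moving average; near the
#' edges the window truncates to the available frames, so the output has the
#' same length as the input and no padding artifacts. Even window sizes use
#' `floor(window/2)` neighbours on each side.
#'
#' @param series Numeric per-frame values.
#' @param window Positive integer window size; `1` is the identity.
#' @return Numeric vector, same length as `series`.
#' @export
smooth_timeline <- function(series, window = 1L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be a positive integer", call. = FALSE)
  n <- length(series)
  if (window == 1L || n == 0L) {
    return(as.numeric(series))
  }
  half <- window %/% 2L
  cs <- cumsum(c(0, series))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Gaussian kernel-density estimate of an error sample
#'
#' KDE on an even grid spanning `[min - 3h, max + 3h]`. The default
#' bandwidth is Scott's rule, `h = sd(x) * n^(-1/5)`.
#'
#' @param samples Numeric samples (at least two distinct values).
#' @param bandwidth Optional kernel standard deviation; default Scott's rule.
#' @param n_grid Number of grid points.
#' @param label Curve label.
#' @return A tibble of class `density_curve` with columns `grid`, `density`
#'   and attributes `bandwidth` and `label`. The trapezoidal integral of the
#'   curve is 1 to within 1%.
#' @export
kde_curve <- function(samples, bandwidth = NULL, n_grid = 512L, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L || length(unique(samples)) < 2L) {
    stop("need at least two distinct samples for a KDE; use a histogram for ",
      "degenerate samples",
      call. = FALSE
    )
  }
  h <- bandwidth %||% (sd(samples) * length(samples)^(-1 / 5))
  if (!is.numeric(h) || h <= 0) stop("bandwidth must be a positive scalar", call. = FALSE)
  d <- stats::density(samples,
    bw = h, kernel = "gaussian",
    from = min(samples) - 3 * h, to = max(samples) + 3 * h, n = n_grid
  )
  out <- tibble(grid = d$x, density = d$y)
  attr(out, "bandwidth") <- h
  attr(out, "label") <- label
  class(out) <- c("density_curve", class(out))
  out
}

#' Trapezoidal integral of a density curve
#'
#' @param curve A [kde_curve()] result (or any tibble with `grid`, `density`).
#' @return The trapezoidal integral, a scalar.
#' @export
curve_integral <- function(curve) {
  g <- curve$grid
  y <- curve$density
  sum(diff(g) * (head(y, -1) + y[-1]) / 2)
}

#' Predicted-vs-true correlation pairs with robust outlier flags
#'
#' Pairs predicted against reference values in dataset order and flags
#' outliers whose residual exceeds `k` times the robust residual scale
#' (median absolute deviation scaled by 1.4826).
#'
#' @param ds A [configuration_set()] with reference data.
#' @param pred An aligned prediction record.
#' @param quantity `"energy"` (one pair per frame) or `"force_component"`
#'   (one pair per frame/atom/Cartesian component).
#' @param k Outlier threshold in robust-scale units (default 4).
#' @return A tibble with columns `frame` (plus `atom`, `component` for force
#'   components), `true`, `predicted`, `residual`, `outlier`.
#' @export
correlation_scatter <- function(ds, pred, quantity = c("energy", "force_component"),
                                k = 4) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(ds, "configuration_set"), inherits(pred, "prediction_record"))
  check_aligned(ds, pred)
  if (quantity == "energy") {
    out <- tibble(frame = seq_len(n_frames(ds)), true = ds$energies, predicted = pred$energies)
  } else {
    nf <- n_frames(ds)
    na <- n_atoms(ds)
    out <- tibble(
      frame = rep(seq_len(nf), times = na * 3L),
      atom = rep(rep(seq_len(na), each = nf), times = 3L),
      component = rep(c("x", "y", "z"), each = nf * na),
      true = as.vector(ds$forces),
      predicted = as.vector(pred$forces)
    )
    out <- dplyr::arrange(out, .data$frame, .data$atom, .data$component)
  }
  out$residual <- out$predicted - out$true
  scale <- stats::mad(out$residual) # includes the 1.4826 consistency factor
  out$outlier <- abs(out$residual) > k * scale
  attr(out, "robust_scale") <- scale
  attr(out, "k") <- k
  out
}

#' Compare a subset's sample distribution against the full set
#'
#' Quantifies training-set representativeness: the histogram intersection of
#' the two samples on a shared 50-bin grid over the pooled range (1 =
#' identical binned distributions, 0 = disjoint), plus the two-sample
#' Kolmogorov-Smirnov statistic.
#'
#' @param full_samples,subset_samples Nonempty numeric samples (e.g. flattened
#'   force components, energies, or gyradius values).
#' @param n_bins Number of shared histogram bins.
#' @return A one-row tibble with `intersection` and `ks`.
#' @export
compare_distributions <- function(full_samples, subset_samples, n_bins = 50L) {
  full_samples <- as.numeric(full_samples)
  subset_samples <- as.numeric(subset_samples)
  if (length(full_samples) == 0 || length(subset_samples) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  rng <- range(c(full_samples, subset_samples))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  p <- hist(full_samples, breaks = breaks, plot = FALSE)$counts / length(full_samples)
  q <- hist(subset_samples, breaks = breaks, plot = FALSE)$counts / length(subset_samples)
  grid <- sort(unique(c(full_samples, subset_samples)))
  ks <- max(abs(ecdf(full_samples)(grid) - ecdf(subset_samples)(grid)))
  tibble(intersection = sum(pmin(p, q)), ks = ks)
}

#' @importFrom graphics hist
NULL
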