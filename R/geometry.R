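#' Radius of gyration along a trajectory
#'
#' Per-frame radius of gyration
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - r_{cm}|^2 / \sum_i m_i}} with
#' \eqn{r_{cm}} the (mass-weighted) centroid. Small for folded, large for
#' extended conformations, so the series traces folding/unfolding events.
#' The unweighted variant sets all masses to 1.
#'
#' @param ds A [configuration_set()].
#' @param mass_weighted Use standard atomic masses (default) or unit weights.
#' @return A tibble of class `geometry_series` with columns `frame`, `value`
#'   (Angstrom) and attributes `name`, `units`.
#' @export
radius_of_gyration <- function(ds, mass_weighted = TRUE) {
  stopifnot(inherits(ds, "configuration_set"))
  w <- if (mass_weighted) atomic_masses(ds$symbols) else rep(1, n_atoms(ds))
  nf <- n_frames(ds)
  vals <- numeric(nf)
  for (f in seq_len(nf)) {
    r <- matrix(ds$positions[f, , ], ncol = 3L)
    cm <- colSums(r * w) / sum(w)
    vals[f] <- sqrt(sum(w * rowSums(sweep(r, 2, cm)^2)) / sum(w))
  }
  geometry_series("radius_of_gyration", vals, "angstrom")
}

geometry_series <- function(name, values, units) {
  out <- tibble(frame = seq_along(values), value = values)
  attr(out, "name") <- name
  attr(out, "units") <- units
  class(out) <- c("geometry_series", class(out))
  out
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Internal-coordinate series: distance, angle or dihedral
#'
#' Measures one internal coordinate on every frame: 2 atom indices give the
#' interatomic distance (Angstrom); 3 give the angle at the middle atom
#' (degrees, in `[0, 180]`); 4 give the torsion of the two planes in the
#' IUPAC sign convention (degrees, in `(-180, 180]`).
#'
#' @param ds A [configuration_set()].
#' @param atom_indices 2, 3 or 4 distinct atom indices (1-based).
#' @return A `geometry_series` tibble (`frame`, `value`).
#' @export
measure_geometry <- function(ds, atom_indices) {
  stopifnot(inherits(ds, "configuration_set"))
  atom_indices <- as.integer(atom_indices)
  if (anyDuplicated(atom_indices)) stop("atom indices must be distinct", call. = FALSE)
  if (!length(atom_indices) %in% 2:4) {
    stop("need 2 (distance), 3 (angle) or 4 (dihedral) atom indices", call. = FALSE)
  }
  if (any(atom_indices < 1L | atom_indices > n_atoms(ds))) {
    stop("atom index out of range [1, ", n_atoms(ds), "]", call. = FALSE)
  }
  nf <- n_frames(ds)
  vals <- numeric(nf)
  kind <- c("distance", "angle", "dihedral")[length(atom_indices) - 1L]
  for (f in seq_len(nf)) {
    p <- matrix(ds$positions[f, atom_indices, ], ncol = 3L)
    vals[f] <- switch(kind,
      distance = sqrt(sum((p[2, ] - p[1, ])^2)),
      angle = {
        u <- p[1, ] - p[2, ]
        v <- p[3, ] - p[2, ]
        ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
        acos(pmin(1, pmax(-1, ct))) * 180 / pi
      },
      dihedral = {
        b1 <- p[2, ] - p[1, ]
        b2 <- p[3, ] - p[2, ]
        b3 <- p[4, ] - p[3, ]
        n1 <- cross3(b1, b2)
        n2 <- cross3(b2, b3)
        if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
          stop("undefined dihedral: collinear atom triple at frame ", f, call. = FALSE)
        }
        ang <- atan2(
          sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2)),
          sum(n1 * n2)
        ) * 180 / pi
        if (ang <= -180) ang + 360 else ang
      }
    )
  }
  units <- if (kind == "distance") "angstrom" else "degrees"
  geometry_series(kind, vals, units)
}
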