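#' Molecular trajectory container
#'
#' A `configuration_set` holds a labelled molecular trajectory with a fixed
#' atom list: per-frame Cartesian positions and, optionally, per-frame total
#' energies and per-atom force vectors. Canonical units are Angstrom,
#' kcal/mol and kcal/(mol*A); unit conversion belongs at the I/O boundary.
#'
#' @param symbols Character vector of per-atom element symbols (length
#'   `n_atoms`, constant across frames).
#' @param positions Numeric array `n_frames x n_atoms x 3`, Angstrom. A single
#'   `n_atoms x 3` matrix is promoted to one frame.
#' @param energies Optional numeric vector of per-frame total energies,
#'   kcal/mol.
#' @param forces Optional numeric array with the same shape as `positions`,
#'   kcal/(mol*A).
#' @param name Free-text provenance label.
#' @param extra_atom_props Optional named list of `n_frames x n_atoms`
#'   numeric matrices carrying additional per-atom scalar properties (for
#'   example an error annotation column read back from extended XYZ).
#' @param metadata Optional list of opaque per-frame metadata (unrecognised
#'   comment-line keys from extended XYZ are kept here).
#' @return An object of class `configuration_set`.
#' @export
#' @examples
#' pos <- array(rnorm(2 * 3 * 3), dim = c(2, 3, 3))
#' ds <- configuration_set(c("O", "H", "H"), pos, energies = c(-1.2, -1.1))
#' n_frames(ds)
#' n_atoms(ds)
configuration_set <- function(symbols, positions, energies = NULL, forces = NULL,
                              name = "", extra_atom_props = NULL, metadata = NULL) {
  if (is.matrix(positions)) {
    positions <- array(positions, dim = c(1L, dim(positions)))
  }
  stopifnot(is.array(positions), length(dim(positions)) == 3L, dim(positions)[3] == 3L)
  nf <- dim(positions)[1]
  na <- dim(positions)[2]
  if (length(symbols) != na) {
    stop("length(symbols) [", length(symbols), "] must equal the per-frame atom count [",
      na, "]",
      call. = FALSE
    )
  }
  z <- symbol_to_z(symbols)
  if (!is.null(energies)) {
    energies <- as.numeric(energies)
    if (length(energies) != nf) {
      stop("energies must have one value per frame (", nf, "), got ",
        length(energies),
        call. = FALSE
      )
    }
  }
  if (!is.null(forces)) {
    if (is.matrix(forces)) forces <- array(forces, dim = c(1L, dim(forces)))
    if (!identical(dim(forces), dim(positions))) {
      stop("forces must have the same shape as positions", call. = FALSE)
    }
    storage.mode(forces) <- "double"
  }
  storage.mode(positions) <- "double"
  structure(
    list(
      symbols = as.character(symbols),
      atomic_numbers = as.integer(z),
      positions = positions,
      energies = energies,
      forces = forces,
      name = as.character(name),
      extra_atom_props = extra_atom_props,
      metadata = metadata
    ),
    class = "configuration_set"
  )
}

#' @rdname configuration_set
#' @param ds,x A `configuration_set`.
#' @export
n_frames <- function(ds) {
  UseMethod("n_frames")
}

#' @export
n_frames.configuration_set <- function(ds) dim(ds$positions)[1]

#' @rdname configuration_set
#' @export
n_atoms <- function(ds) {
  UseMethod("n_atoms")
}

#' @export
n_atoms.configuration_set <- function(ds) dim(ds$positions)[2]

#' @export
print.configuration_set <- function(x, ...) {
  comp <- table(x$symbols)
  cat(
    "<configuration_set> ", if (nzchar(x$name)) paste0("'", x$name, "' ") else "",
    n_frames(x), " frames x ", n_atoms(x), " atoms (",
    paste0(names(comp), comp, collapse = ""), ")\n",
    sep = ""
  )
  cat(
    "  energies: ", if (is.null(x$energies)) "absent" else "present",
    " | forces: ", if (is.null(x$forces)) "absent" else "present", "\n",
    sep = ""
  )
  invisible(x)
}

#' Frame subsets of a trajectory
#'
#' A `subset_view` is a lightweight, sorted, duplicate-free selection of
#' frames of a parent [configuration_set()]. It can be written out with
#' [write_extxyz()] / [write_npz_bundle()] or passed to metric aggregation.
#'
#' @param ds The parent `configuration_set`.
#' @param indices Integer frame indices (1-based). Duplicates are dropped and
#'   the result is sorted ascending; an empty selection is valid.
#' @param label Free-text label for the subset.
#' @return An object of class `subset_view`.
#' @export
#' @examples
#' ds <- configuration_set("H", array(rnorm(9), c(3, 1, 3)))
#' make_subset(ds, c(3, 1, 3), label = "ends")
make_subset <- function(ds, indices, label = "") {
  stopifnot(inherits(ds, "configuration_set"))
  indices <- as.integer(indices)
  nf <- n_frames(ds)
  bad <- indices[indices < 1L | indices > nf]
  if (length(bad) > 0) {
    stop("frame index out of range [1, ", nf, "]: ", bad[1], call. = FALSE)
  }
  structure(
    list(parent = ds, frame_indices = sort(unique(indices)), label = as.character(label)),
    class = "subset_view"
  )
}

#' @export
print.subset_view <- function(x, ...) {
  cat("<subset_view> ", length(x$frame_indices), " of ", n_frames(x$parent),
    " frames", if (nzchar(x$label)) paste0(" ('", x$label, "')"), "\n",
    sep = ""
  )
  invisible(x)
}

#' Materialise a subset as a standalone configuration_set
#'
#' @param view A [make_subset()] view.
#' @return A `configuration_set` containing only the selected frames, in
#'   ascending index order.
#' @export
as_configuration_set <- function(view) {
  stopifnot(inherits(view, "subset_view"))
  ds <- view$parent
  idx <- view$frame_indices
  configuration_set(
    symbols = ds$symbols,
    positions = ds$positions[idx, , , drop = FALSE],
    energies = if (!is.null(ds$energies)) ds$energies[idx],
    forces = if (!is.null(ds$forces)) ds$forces[idx, , , drop = FALSE],
    name = if (nzchar(view$label)) paste0(ds$name, ":", view$label) else ds$name,
    extra_atom_props = if (!is.null(ds$extra_atom_props)) {
      lapply(ds$extra_atom_props, function(m) m[idx, , drop = FALSE])
    }
  )
}

#' Atom selections
#'
#' Selects atoms by index (1-based) for filtered error aggregation, e.g. the
#' atoms touching glycosidic bonds of a carbohydrate. Duplicates are dropped
#' and indices sorted.
#'
#' @param atom_indices Integer atom indices.
#' @param label Free-text label (e.g. `"glycosidic C"`).
#' @param n_atoms Optional atom count to validate against.
#' @return An object of class `atom_selection`.
#' @export
atom_selection <- function(atom_indices, label = "", n_atoms = NULL) {
  atom_indices <- as.integer(atom_indices)
  if (any(atom_indices < 1L)) {
    stop("atom index out of range: ", atom_indices[atom_indices < 1L][1], call. = FALSE)
  }
  if (!is.null(n_atoms) && any(atom_indices > n_atoms)) {
    stop("atom index out of range [1, ", n_atoms, "]: ",
      atom_indices[atom_indices > n_atoms][1],
      call. = FALSE
    )
  }
  structure(
    list(atom_indices = sort(unique(atom_indices)), label = as.character(label)),
    class = "atom_selection"
  )
}

#' Select atoms of one element
#'
#' @param ds A [configuration_set()].
#' @param element Element symbol, e.g. `"C"`.
#' @return An [atom_selection()] of all atoms of that element.
#' @export
select_element <- function(ds, element) {
  stopifnot(inherits(ds, "configuration_set"))
  idx <- which(ds$symbols == element)
  if (length(idx) == 0) stop("no atoms of element ", element, call. = FALSE)
  atom_selection(idx, label = element, n_atoms = n_atoms(ds))
}
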