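#' Prediction records
#'
#' A `prediction_record` holds model energies and forces aligned frame-by-frame
#' with a [configuration_set()].
#'
#' @param source_id Model/provenance label.
#' @param energies Per-frame predicted energies, kcal/mol.
#' @param forces Predicted forces, `n_frames x n_atoms x 3`, kcal/(mol*A).
#' @return An object of class `prediction_record`.
#' @export
prediction_record <- function(source_id, energies, forces) {
  if (is.matrix(forces)) forces <- array(forces, dim = c(1L, dim(forces)))
  stopifnot(is.array(forces), length(dim(forces)) == 3L, dim(forces)[3] == 3L)
  energies <- as.numeric(energies)
  if (length(energies) != dim(forces)[1]) {
    stop("energies must have one value per frame", call. = FALSE)
  }
  storage.mode(forces) <- "double"
  structure(
    list(source_id = as.character(source_id), energies = energies, forces = forces),
    class = "prediction_record"
  )
}

#' @export
print.prediction_record <- function(x, ...) {
  cat("<prediction_record> '", x$source_id, "': ", dim(x$forces)[1], " frames x ",
    dim(x$forces)[2], " atoms\n",
    sep = ""
  )
  invisible(x)
}

check_aligned <- function(ds, pred) {
  nf <- n_frames(ds)
  na <- n_atoms(ds)
  pf <- dim(pred$forces)[1]
  pa <- dim(pred$forces)[2]
  if (pf != nf || pa != na) {
    stop(
      "prediction/dataset misalignment: dataset has ", nf, " frames x ", na,
      " atoms, predictions have ", pf, " frames x ", pa, " atoms",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Load prestored predictions
#'
#' Reads a prediction file (extended XYZ or NPZ bundle, recognised by
#' extension) whose frames align 1:1 with a dataset, and returns the aligned
#' prediction record. Frame or atom count mismatches are an error reporting
#' both counts.
#'
#' @param path Prediction file (`.xyz`/`.extxyz` or `.npz`).
#' @param ds The [configuration_set()] the predictions belong to.
#' @param source_id Model label; defaults to the file name.
#' @return A [prediction_record()].
#' @export
load_prestored_predictions <- function(path, ds, source_id = basename(path)) {
  stopifnot(inherits(ds, "configuration_set"))
  pds <- if (grepl("\\.npz$", path, ignore.case = TRUE)) {
    read_npz_bundle(path)
  } else {
    read_extxyz(path)
  }
  if (is.null(pds$energies) || is.null(pds$forces)) {
    stop("prediction file must carry both energies and forces: ", path, call. = FALSE)
  }
  pred <- prediction_record(source_id, pds$energies, pds$forces)
  check_aligned(ds, pred)
  pred
}

#' Model-adapter contract
#'
#' Wraps an arbitrary force-field evaluator behind the uniform contract the
#' rest of the package consumes: a function mapping a batch of frames to
#' energies and forces in canonical units (kcal/mol, kcal/(mol*A)). External
#' ML packages are integrated by writing such an adapter; none are bundled.
#'
#' @param identifier Model identifier (also keys the precompute cache).
#' @param evaluate `function(positions, atomic_numbers)` where `positions` is
#'   `n x n_atoms x 3`; must return `list(energies = <n>, forces =
#'   <n x n_atoms x 3>)`.
#' @return An object of class `ff_predictor`.
#' @export
predictor <- function(identifier, evaluate) {
  stopifnot(is.character(identifier), is.function(evaluate))
  structure(list(identifier = identifier, evaluate = evaluate), class = "ff_predictor")
}

#' Batched prediction with a persistent cache
#'
#' Evaluates a [predictor()] over a dataset in batches and persists the
#' result as an NPZ bundle plus a JSON fingerprint (dataset name, frame and
#' atom counts, predictor identifier). A second call with the same inputs
#' loads the cache without invoking the predictor; a fingerprint mismatch is
#' a stale-cache error, never a silent reuse.
#'
#' @param pr A [predictor()].
#' @param ds A [configuration_set()].
#' @param cache_path Cache stem; files `<cache_path>.pred.npz` and
#'   `<cache_path>.pred.json` are created.
#' @param batch_size Frames per predictor call.
#' @return A [prediction_record()].
#' @export
precompute_cache <- function(pr, ds, cache_path, batch_size = 100L) {
  stopifnot(inherits(pr, "ff_predictor"), inherits(ds, "configuration_set"))
  batch_size <- as.integer(batch_size)
  if (batch_size < 1L) stop("batch_size must be positive", call. = FALSE)
  npz <- paste0(cache_path, ".pred.npz")
  fpj <- paste0(cache_path, ".pred.json")
  fingerprint <- list(
    dataset_name = ds$name, n_frames = n_frames(ds), n_atoms = n_atoms(ds),
    predictor_id = pr$identifier
  )
  if (file.exists(npz) || file.exists(fpj)) {
    if (!(file.exists(npz) && file.exists(fpj))) {
      stop("stale cache: incomplete cache pair at ", cache_path, call. = FALSE)
    }
    found <- jsonlite::read_json(fpj, simplifyVector = TRUE)
    if (!identical(
      lapply(fingerprint, as.character),
      lapply(found[names(fingerprint)], as.character)
    )) {
      stop(
        "stale cache at ", cache_path, ": fingerprint mismatch (cache: ",
        jsonlite::toJSON(found, auto_unbox = TRUE), ")",
        call. = FALSE
      )
    }
    cached <- read_npz_bundle(npz)
    return(prediction_record(pr$identifier, cached$energies, cached$forces))
  }
  nf <- n_frames(ds)
  na <- n_atoms(ds)
  energies <- numeric(nf)
  forces <- array(0, dim = c(nf, na, 3L))
  starts <- seq(1L, nf, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, nf)
    out <- pr$evaluate(ds$positions[idx, , , drop = FALSE], ds$atomic_numbers)
    if (length(out$energies) != length(idx) ||
      !identical(dim(out$forces), c(length(idx), na, 3L))) {
      stop("predictor '", pr$identifier, "' violated the evaluate contract",
        call. = FALSE
      )
    }
    energies[idx] <- out$energies
    forces[idx, , ] <- out$forces
  }
  cache_ds <- configuration_set(ds$symbols, ds$positions,
    energies = energies,
    forces = forces, name = ds$name
  )
  write_npz_bundle(cache_ds, npz)
  jsonlite::write_json(fingerprint, fpj, auto_unbox = TRUE)
  prediction_record(pr$identifier, energies, forces)
}

#' Audit the reference data itself ("dummy model" mode)
#'
#' Returns the reference energies/forces as a prediction record flagged for
#' `reference_magnitude` mode: downstream "error" quantities are then the
#' reference magnitudes themselves (per-atom force-vector norms, per-frame
#' energies), which audits the dataset rather than a model.
#'
#' @param ds A [configuration_set()] with reference energies and forces.
#' @return A [prediction_record()] with attribute `source_mode =
#'   "reference_magnitude"`.
#' @export
reference_as_prediction <- function(ds) {
  stopifnot(inherits(ds, "configuration_set"))
  if (is.null(ds$forces) || is.null(ds$energies)) {
    stop("reference_magnitude mode requires reference energies and forces", call. = FALSE)
  }
  pred <- prediction_record("reference", ds$energies, ds$forces)
  attr(pred, "source_mode") <- "reference_magnitude"
  pred
}
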