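# Extended-XYZ I/O.
#
# Dialect: the comment line carries whitespace-separated key=value tokens
# (values may be double-quoted); `energy` is matched case-insensitively; a
# `Properties=species:S:1:pos:R:3:...` token describes the per-atom columns,
# with `forces:R:3` recognised as the force block and any additional `R:1`
# property kept as a named extra column. Unrecognised comment keys are
# preserved verbatim as opaque per-frame metadata. A constant atom list
# across frames is required.

.parse_comment_tokens <- function(line) {
  m <- gregexpr('([A-Za-z_][A-Za-z0-9_:+-]*)=("[^"]*"|\\S+)', line, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(character(0))
  }
  tokens <- regmatches(line, list(m))[[1]]
  keys <- sub("=.*$", "", tokens)
  vals <- sub("^[^=]*=", "", tokens)
  setNames(vals, keys)
}

.unquote <- function(x) sub('^"(.*)"$', "\\1", x)

# Properties string -> data.frame(name, type, ncols)
.parse_properties <- function(prop) {
  parts <- strsplit(prop, ":", fixed = TRUE)[[1]]
  if (length(parts) %% 3 != 0) {
    stop("malformed Properties specification: ", prop, call. = FALSE)
  }
  data.frame(
    name = parts[seq(1, length(parts), 3)],
    type = parts[seq(2, length(parts), 3)],
    ncols = as.integer(parts[seq(3, length(parts), 3)]),
    stringsAsFactors = FALSE
  )
}

#' Read an extended-XYZ trajectory
#'
#' Reads a (multi-frame) extended-XYZ file into a [configuration_set()].
#' Per-frame `energy` keys and per-atom `forces` columns are picked up when
#' present; additional scalar per-atom columns declared in the `Properties`
#' token are kept in `extra_atom_props`; unrecognised comment keys are kept
#' as opaque metadata. All frames must share one atom list.
#'
#' @param path Path to the file.
#' @param name Provenance label; defaults to the file name.
#' @return A [configuration_set()].
#' @export
read_extxyz <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  frames <- list()
  i <- 1L
  f <- 0L
  while (i <= length(lines)) {
    f <- f + 1L
    hdr <- trimws(lines[i])
    if (!grepl("^[0-9]+$", hdr)) {
      stop("frame ", f, ": malformed frame header, expected an atom count, got '",
        hdr, "'",
        call. = FALSE
      )
    }
    na <- as.integer(hdr)
    if (i + 1L + na > length(lines)) {
      stop("frame ", f, ": truncated file (", na, " atom lines expected)", call. = FALSE)
    }
    comment <- lines[i + 1L]
    block <- lines[(i + 2L):(i + 1L + na)]
    fields <- strsplit(trimws(block), "\\s+")
    nfield <- lengths(fields)
    if (length(unique(nfield)) != 1L) {
      stop("frame ", f, ": inconsistent column counts across atom lines", call. = FALSE)
    }
    kv <- .parse_comment_tokens(comment)
    keys_lc <- tolower(names(kv))
    energy <- if (any(keys_lc == "energy")) as.numeric(.unquote(kv[which(keys_lc == "energy")[1]])) else NULL

    if (any(keys_lc == "properties")) {
      props <- .parse_properties(.unquote(kv[which(keys_lc == "properties")[1]]))
    } else {
      # implicit layout: species + pos (+ forces if exactly 7 columns)
      props <- data.frame(
        name = c("species", "pos", if (nfield[1] == 7L) "forces"),
        type = c("S", "R", if (nfield[1] == 7L) "R"),
        ncols = c(1L, 3L, if (nfield[1] == 7L) 3L),
        stringsAsFactors = FALSE
      )
    }
    if (sum(props$ncols) != nfield[1]) {
      stop("frame ", f, ": atom lines have ", nfield[1],
        " columns but Properties declares ", sum(props$ncols),
        call. = FALSE
      )
    }
    mat <- matrix(unlist(fields, use.names = FALSE), nrow = na, byrow = TRUE)
    col0 <- cumsum(c(0L, props$ncols))
    grab <- function(j) mat[, (col0[j] + 1L):(col0[j + 1L]), drop = FALSE]
    spec_j <- which(props$name == "species" & props$type == "S")
    pos_j <- which(props$name == "pos" & props$type == "R")
    if (length(spec_j) != 1L || length(pos_j) != 1L) {
      stop("frame ", f, ": Properties must declare species:S:1 and pos:R:3", call. = FALSE)
    }
    symbols <- as.character(grab(spec_j))
    positions <- matrix(as.numeric(grab(pos_j)), nrow = na)
    frc_j <- which(props$name == "forces" & props$type == "R")
    forces <- if (length(frc_j) == 1L) matrix(as.numeric(grab(frc_j)), nrow = na)
    extra_j <- setdiff(which(props$type == "R" & props$ncols == 1L), c(spec_j, pos_j, frc_j))
    extras <- lapply(extra_j, function(j) as.numeric(grab(j)))
    names(extras) <- props$name[extra_j]
    meta <- kv[!(keys_lc %in% c("energy", "properties"))]
    frames[[f]] <- list(
      symbols = symbols, positions = positions, energy = energy,
      forces = forces, extras = extras, meta = meta
    )
    i <- i + 2L + na
  }
  if (length(frames) == 0) stop("no frames found in ", path, call. = FALSE)

  na <- vapply(frames, function(fr) nrow(fr$positions), integer(1))
  if (length(unique(na)) != 1L) {
    stop("inconsistent atom counts across frames: ", paste(unique(na), collapse = ", "),
      call. = FALSE
    )
  }
  syms <- frames[[1]]$symbols
  for (k in seq_along(frames)) {
    if (!identical(frames[[k]]$symbols, syms)) {
      stop("frame ", k, ": atom identities differ from frame 1 (constant topology required)",
        call. = FALSE
      )
    }
  }
  nf <- length(frames)
  natm <- na[1]
  positions <- array(0, dim = c(nf, natm, 3L))
  for (k in seq_len(nf)) positions[k, , ] <- frames[[k]]$positions
  have_E <- !vapply(frames, function(fr) is.null(fr$energy), logical(1))
  energies <- if (all(have_E)) vapply(frames, function(fr) fr$energy, numeric(1)) else NULL
  have_F <- !vapply(frames, function(fr) is.null(fr$forces), logical(1))
  forces <- NULL
  if (all(have_F)) {
    forces <- array(0, dim = c(nf, natm, 3L))
    for (k in seq_len(nf)) forces[k, , ] <- frames[[k]]$forces
  }
  extra_names <- names(frames[[1]]$extras)
  extra_atom_props <- NULL
  if (length(extra_names) > 0) {
    extra_atom_props <- lapply(extra_names, function(nm) {
      do.call(rbind, lapply(frames, function(fr) fr$extras[[nm]]))
    })
    names(extra_atom_props) <- extra_names
  }
  metadata <- lapply(frames, function(fr) fr$meta)
  if (all(lengths(metadata) == 0)) metadata <- NULL
  configuration_set(
    symbols = syms, positions = positions, energies = energies, forces = forces,
    name = name, extra_atom_props = extra_atom_props, metadata = metadata
  )
}

#' Write an extended-XYZ trajectory
#'
#' Writes a [configuration_set()] (or a frame subset of one) as extended XYZ.
#' Energies are written as an `energy=` comment key and forces as a
#' `forces:R:3` per-atom block when present; extra per-atom scalar
#' properties and opaque metadata tokens are carried through.
#'
#' @param ds A [configuration_set()].
#' @param path Output file path.
#' @param selection Optional [make_subset()] view of `ds`; only its frames are
#'   written, in ascending index order. An empty selection writes a
#'   zero-frame file with a warning.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(ds, path, selection = NULL) {
  stopifnot(inherits(ds, "configuration_set"))
  idx <- seq_len(n_frames(ds))
  if (!is.null(selection)) {
    stopifnot(inherits(selection, "subset_view"))
    idx <- selection$frame_indices
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(idx) == 0) {
    warning("writing empty subset: zero-frame file ", path, call. = FALSE)
    return(invisible(path))
  }
  natm <- n_atoms(ds)
  prop <- "species:S:1:pos:R:3"
  if (!is.null(ds$forces)) prop <- paste0(prop, ":forces:R:3")
  extra_names <- names(ds$extra_atom_props)
  for (nm in extra_names) prop <- paste0(prop, ":", nm, ":R:1")
  fmt_num <- function(x) sprintf("%.17g", x) # full precision: exact round-trips
  for (f in idx) {
    comment <- paste0("Properties=", prop)
    if (!is.null(ds$energies)) {
      comment <- paste0(comment, " energy=", fmt_num(ds$energies[f]))
    }
    if (!is.null(ds$metadata) && length(ds$metadata[[f]]) > 0) {
      kv <- ds$metadata[[f]]
      comment <- paste(comment, paste(names(kv), kv, sep = "=", collapse = " "))
    }
    cols <- list(
      ds$symbols,
      fmt_num(ds$positions[f, , 1]), fmt_num(ds$positions[f, , 2]),
      fmt_num(ds$positions[f, , 3])
    )
    if (!is.null(ds$forces)) {
      cols <- c(cols, list(
        fmt_num(ds$forces[f, , 1]), fmt_num(ds$forces[f, , 2]),
        fmt_num(ds$forces[f, , 3])
      ))
    }
    for (nm in extra_names) {
      cols <- c(cols, list(fmt_num(ds$extra_atom_props[[nm]][f, ])))
    }
    writeLines(c(as.character(natm), comment, do.call(paste, cols)), con)
  }
  invisible(path)
}
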