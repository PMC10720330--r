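# NPZ-style array-bundle I/O, written from scratch: no installed R package
# reads the npy/npz container. Arrays are serialised in npy format v1.0 and
# bundled into a stored (uncompressed) ZIP archive; reading goes through
# utils::unzip()'s internal extractor, so no external zip tool is needed.

# ---- CRC-32 (polynomial 0xEDB88320), table-driven --------------------------

.crc32_tab <- local({
  tab <- integer(256)
  for (i in 0:255) {
    cc <- i
    for (k in 1:8) {
      cc <- if (bitwAnd(cc, 1L)) bitwXor(-306674912L, bitwShiftR(cc, 1L)) else bitwShiftR(cc, 1L)
    }
    tab[i + 1L] <- cc
  }
  tab
})

.crc32 <- function(bytes) {
  b <- as.integer(bytes)
  tab <- .crc32_tab
  crc <- -1L
  for (x in b) {
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, x), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

# little-endian byte helpers; x may exceed .Machine$integer.max as a double
.le_bytes <- function(x, width) {
  x <- as.numeric(x)
  if (x < 0) x <- x + 4294967296
  out <- raw(width)
  for (i in seq_len(width)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# ---- npy format ------------------------------------------------------------

.npy_serialize <- function(x) {
  if (is.array(x)) {
    shape <- dim(x)
    perm <- rev(seq_along(shape))
    data <- aperm(x, perm) # column-major write of reversed dims == C order
  } else {
    shape <- length(x)
    data <- x
  }
  if (is.integer(data)) {
    descr <- "<i4"
    payload <- writeBin(as.vector(data), raw(), size = 4L, endian = "little")
  } else {
    descr <- "<f8"
    payload <- writeBin(as.vector(as.numeric(data)), raw(), size = 8L, endian = "little")
  }
  shape_str <- if (length(shape) == 1L) paste0(shape, ",") else paste(shape, collapse = ", ")
  dict <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%s), }", descr, shape_str)
  header_len <- length(charToRaw(dict)) + 1L # trailing newline
  pad <- (64L - ((10L + header_len) %% 64L)) %% 64L
  header <- c(charToRaw(dict), rep(charToRaw(" "), pad), charToRaw("\n"))
  c(
    as.raw(c(0x93)), charToRaw("NUMPY"), as.raw(c(1L, 0L)),
    .le_bytes(length(header), 2L), header, payload
  )
}

.npy_read <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 10L || bytes[1] != as.raw(0x93) ||
    rawToChar(bytes[2:6]) != "NUMPY") {
    stop("not an npy array: ", path, call. = FALSE)
  }
  major <- as.integer(bytes[7])
  if (major == 1L) {
    hlen <- as.integer(bytes[9]) + 256L * as.integer(bytes[10])
    hstart <- 11L
  } else {
    hlen <- sum(as.integer(bytes[9:12]) * 256^(0:3))
    hstart <- 13L
  }
  header <- rawToChar(bytes[hstart:(hstart + hlen - 1L)])
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape_str <- gsub("[, ]+$", "", shape_str)
  shape <- if (nzchar(shape_str)) {
    as.integer(strsplit(shape_str, ",")[[1]])
  } else {
    integer(0)
  }
  n <- if (length(shape) == 0L) 1L else prod(shape)
  payload <- bytes[(hstart + hlen):length(bytes)]
  kind <- substr(descr, 2, 2)
  size <- as.integer(substr(descr, 3, 3))
  vals <- switch(kind,
    f = readBin(payload, "numeric", n = n, size = size, endian = "little"),
    i = if (size <= 4L) {
      readBin(payload, "integer", n = n, size = size, endian = "little")
    } else {
      # int64: reassemble from bytes, small magnitudes only (atomic numbers etc.)
      m <- matrix(as.integer(payload[seq_len(8L * n)]), nrow = 8L)
      hi_ok <- all(m[5:8, ] == 0L | (m[5:8, ] == 255L & m[4, ] >= 128L))
      if (!hi_ok) stop("int64 value out of supported range in ", path, call. = FALSE)
      lo <- colSums(m[1:4, ] * 256^(0:3))
      as.integer(ifelse(lo > 2147483647, lo - 4294967296, lo))
    },
    u = readBin(payload, "integer", n = n, size = size, endian = "little", signed = FALSE),
    stop("unsupported npy dtype: ", descr, call. = FALSE)
  )
  if (length(shape) <= 1L) {
    return(vals)
  }
  if (fortran) {
    array(vals, dim = shape)
  } else {
    aperm(array(vals, dim = rev(shape)), rev(seq_along(shape)))
  }
}

# ---- stored ZIP container --------------------------------------------------

.zip_store <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offset <- 0
  central <- list()
  for (nm in names(entries)) {
    data <- entries[[nm]]
    name_raw <- charToRaw(nm)
    crc <- .crc32(data)
    local <- c(
      .le_bytes(0x04034b50, 4L), .le_bytes(20L, 2L), .le_bytes(0L, 2L),
      .le_bytes(0L, 2L), .le_bytes(0L, 2L), .le_bytes(0x21, 2L),
      .le_bytes(crc, 4L), .le_bytes(length(data), 4L), .le_bytes(length(data), 4L),
      .le_bytes(length(name_raw), 2L), .le_bytes(0L, 2L), name_raw
    )
    writeBin(local, con)
    writeBin(data, con)
    central[[nm]] <- c(
      .le_bytes(0x02014b50, 4L), .le_bytes(20L, 2L), .le_bytes(20L, 2L),
      .le_bytes(0L, 2L), .le_bytes(0L, 2L), .le_bytes(0L, 2L), .le_bytes(0x21, 2L),
      .le_bytes(crc, 4L), .le_bytes(length(data), 4L), .le_bytes(length(data), 4L),
      .le_bytes(length(name_raw), 2L), .le_bytes(0L, 2L), .le_bytes(0L, 2L),
      .le_bytes(0L, 2L), .le_bytes(0L, 2L), .le_bytes(0L, 4L),
      .le_bytes(offset, 4L), name_raw
    )
    offset <- offset + length(local) + length(data)
  }
  cd <- do.call(c, unname(central))
  writeBin(cd, con)
  eocd <- c(
    .le_bytes(0x06054b50, 4L), .le_bytes(0L, 2L), .le_bytes(0L, 2L),
    .le_bytes(length(central), 2L), .le_bytes(length(central), 2L),
    .le_bytes(length(cd), 4L), .le_bytes(offset, 4L), .le_bytes(0L, 2L)
  )
  writeBin(eocd, con)
  invisible(path)
}

# ---- public bundle API -----------------------------------------------------

.default_key_map <- list(
  positions = "R", atomic_numbers = "z", energies = "E", forces = "F"
)

#' Read an NPZ-style array bundle
#'
#' Reads a zipped bundle of npy arrays (the MD17/MD22 trajectory layout) into
#' a [configuration_set()]. By default the arrays are looked up under the
#' names `R` (positions, `n_frames x n_atoms x 3`), `z` (atomic numbers),
#' `E` (energies) and `F` (forces); energies and forces are optional. Units
#' are assumed to be kcal/mol and kcal/(mol*A) unless conversion factors are
#' supplied.
#'
#' @param path Path to the bundle.
#' @param key_map Named list overriding the logical-field -> array-name
#'   mapping (`positions`, `atomic_numbers`, `energies`, `forces`) and/or
#'   supplying numeric unit conversion factors `energy_factor` /
#'   `force_factor` / `position_factor` applied multiplicatively on read.
#' @param name Provenance label; defaults to the file name.
#' @return A [configuration_set()].
#' @export
read_npz_bundle <- function(path, key_map = list(), name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  km <- utils::modifyList(.default_key_map, key_map)
  td <- tempfile("npz")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  files <- utils::unzip(path, exdir = td)
  arrays <- lapply(files, .npy_read)
  names(arrays) <- sub("\\.npy$", "", basename(files))

  need <- c(km$positions, km$atomic_numbers)
  if (!all(need %in% names(arrays))) {
    stop(
      "bundle is missing mandatory array(s): expected {",
      paste(need, collapse = ", "), "}, found {",
      paste(names(arrays), collapse = ", "), "}",
      call. = FALSE
    )
  }
  pos <- arrays[[km$positions]]
  if (is.matrix(pos)) pos <- array(pos, dim = c(1L, dim(pos)))
  if (!is.null(km$position_factor)) pos <- pos * km$position_factor
  z <- as.integer(round(as.vector(arrays[[km$atomic_numbers]])))
  energies <- NULL
  if (km$energies %in% names(arrays)) {
    energies <- as.vector(arrays[[km$energies]])
    if (!is.null(km$energy_factor)) energies <- energies * km$energy_factor
  }
  forces <- NULL
  if (km$forces %in% names(arrays)) {
    forces <- arrays[[km$forces]]
    if (is.matrix(forces)) forces <- array(forces, dim = c(1L, dim(forces)))
    if (!is.null(km$force_factor)) forces <- forces * km$force_factor
  }
  configuration_set(
    symbols = z_to_symbol(z), positions = pos, energies = energies,
    forces = forces, name = name
  )
}

#' Write an NPZ-style array bundle
#'
#' Writes a [configuration_set()] (or a frame subset) as a zipped bundle of
#' npy arrays under the MD17/MD22-style names `R`, `z` and, when present,
#' `E` and `F`. The archive uses stored (uncompressed) entries and is
#' readable by `numpy.load`.
#'
#' @inheritParams write_extxyz
#' @return `path`, invisibly.
#' @export
write_npz_bundle <- function(ds, path, selection = NULL) {
  stopifnot(inherits(ds, "configuration_set"))
  if (!is.null(selection)) {
    stopifnot(inherits(selection, "subset_view"))
    if (length(selection$frame_indices) == 0) {
      warning("writing empty subset: zero-frame bundle ", path, call. = FALSE)
    }
    ds <- as_configuration_set(selection)
  }
  entries <- list(
    "R.npy" = .npy_serialize(ds$positions),
    "z.npy" = .npy_serialize(ds$atomic_numbers)
  )
  if (!is.null(ds$energies)) entries[["E.npy"]] <- .npy_serialize(ds$energies)
  if (!is.null(ds$forces)) entries[["F.npy"]] <- .npy_serialize(ds$forces)
  .zip_store(entries, path)
  invisible(path)
}
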