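#' Electron-density map container
#'
#' Constructs a `density_map` object holding a 3D grid of density samples plus
#' the crystallographic metadata needed to round-trip the CCP4/MRC map format.
#'
#' @param values Numeric 3D array of density samples (arbitrary map units).
#' @param cell Numeric vector of length 6: unit-cell lengths a, b, c in
#'   Angstrom followed by angles alpha, beta, gamma in degrees.
#' @param origin Integer vector of length 3: grid-unit offset of the first
#'   sample (the NCSTART/NRSTART/NSSTART header words).
#' @param spacegroup Character space-group label (stored as the ISPG header
#'   number on write; non-numeric labels are written as space group 1).
#'
#' @return An object of class `density_map` with elements `values`, `cell`,
#'   `grid_shape`, `origin` and `spacegroup`.
#' @export
density_map <- function(values, cell = c(10, 10, 10, 90, 90, 90),
                        origin = c(0L, 0L, 0L), spacegroup = "1") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  shape <- dim(values)
  if (any(shape <= 0L)) stop("grid_shape must be strictly positive")
  if (length(cell) != 6L || any(cell[1:3] <= 0))
    stop("`cell` must be 6 numbers with positive lengths")
  structure(
    list(values = values, cell = as.numeric(cell),
         grid_shape = as.integer(shape), origin = as.integer(origin),
         spacegroup = as.character(spacegroup)),
    class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %d x %d x %d grid (%d samples)\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              prod(x$grid_shape)))
  cat(sprintf("  cell: a=%.2f b=%.2f c=%.2f  alpha=%.1f beta=%.1f gamma=%.1f\n",
              x$cell[1], x$cell[2], x$cell[3], x$cell[4], x$cell[5], x$cell[6]))
  cat(sprintf("  origin: (%d, %d, %d)  spacegroup: %s\n",
              x$origin[1], x$origin[2], x$origin[3], x$spacegroup))
  invisible(x)
}

map_error <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "mbperf_map_error")))
}

# Header word layout follows the CCP4/MRC2014 convention: 256 4-byte words,
# mixed int32/float32, then NSYMBT bytes of symmetry records, then the data
# block in the declared mode (0 = int8, 1 = int16, 2 = float32).
MAP_MODES <- list(`0` = list(what = "integer", size = 1L, signed = TRUE),
                  `1` = list(what = "integer", size = 2L, signed = TRUE),
                  `2` = list(what = "double",  size = 4L, signed = TRUE))

#' Read a CCP4/MRC electron-density map
#'
#' Parses the 1024-byte header, skips any symmetry block, and decodes the data
#' block in the declared mode (0, 1 or 2). Density values are preserved exactly
#' as stored after the format's data-type decoding.
#'
#' @param path Path to a CCP4/MRC map file.
#' @return A [density_map].
#' @seealso [write_ccp4_map()]
#' @export
read_ccp4_map <- function(path) {
  if (!file.exists(path))
    map_error("mbperf_map_unreadable", sprintf("map file not found: %s", path))
  fsize <- file.size(path)
  if (is.na(fsize) || fsize < 1024)
    map_error("mbperf_map_truncated",
              sprintf("file too small for a map header (%s bytes)", fsize))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1024L)
  ints <- readBin(hdr, "integer", n = 256L, size = 4L, endian = "little")
  flts <- readBin(hdr, "double", n = 256L, size = 4L, endian = "little")

  shape <- ints[1:3]
  mode <- ints[4]
  magic <- rawToChar(hdr[209:212])
  if (!identical(magic, "MAP "))
    map_error("mbperf_map_unreadable",
              sprintf("not a CCP4/MRC map (magic word '%s')", magic))
  if (!as.character(mode) %in% names(MAP_MODES))
    map_error("mbperf_map_unreadable", sprintf("unsupported map mode %d", mode))
  if (any(shape <= 0L))
    map_error("mbperf_map_unreadable", "non-positive grid dimensions in header")

  spec <- MAP_MODES[[as.character(mode)]]
  nsymbt <- ints[24]
  n_expected <- prod(as.numeric(shape))
  data_bytes <- fsize - 1024 - nsymbt
  if (data_bytes < 0 || data_bytes %% spec$size != 0)
    map_error("mbperf_map_truncated",
              "data block is not a whole number of samples")
  n_avail <- data_bytes %/% spec$size
  if (n_avail != n_expected)
    map_error("mbperf_map_size_mismatch",
              sprintf("header declares %d samples but file holds %d",
                      n_expected, n_avail))
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  vals <- readBin(con, spec$what, n = n_expected, size = spec$size,
                  signed = spec$signed, endian = "little")
  if (length(vals) != n_expected)
    map_error("mbperf_map_truncated", "short read in map data block")

  density_map(array(as.numeric(vals), dim = shape),
              cell = flts[11:16],
              origin = ints[5:7],
              spacegroup = as.character(ints[23]))
}

#' Write a map in CCP4/MRC format (mode 2, 32-bit float)
#'
#' @param map A [density_map].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ccp4_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  v <- as.numeric(map$values)
  shape <- map$grid_shape
  ispg <- suppressWarnings(as.integer(map$spacegroup))
  if (is.na(ispg)) ispg <- 1L

  words <- vector("list", 256)
  int_w <- function(x) list(type = "int", val = as.integer(x))
  flt_w <- function(x) list(type = "flt", val = as.numeric(x))
  for (i in 1:256) words[[i]] <- int_w(0L)
  words[1:3] <- lapply(shape, int_w)
  words[[4]] <- int_w(2L)                          # mode 2: float32
  words[5:7] <- lapply(map$origin, int_w)
  words[8:10] <- lapply(shape, int_w)              # sampling = grid shape
  words[11:16] <- lapply(map$cell, flt_w)
  words[17:19] <- lapply(1:3, int_w)               # axis order x,y,z
  words[[20]] <- flt_w(min(v))
  words[[21]] <- flt_w(max(v))
  words[[22]] <- flt_w(mean(v))
  words[[23]] <- int_w(ispg)
  words[[24]] <- int_w(0L)                         # no symmetry block
  words[[55]] <- flt_w(sqrt(mean((v - mean(v))^2)))
  words[[56]] <- int_w(0L)                         # no labels

  con <- file(path, "wb")
  on.exit(close(con))
  for (i in 1:256) {
    if (i == 53) {
      writeBin(charToRaw("MAP "), con)
    } else if (i == 54) {
      # little-endian machine stamp
      writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)
    } else if (words[[i]]$type == "int") {
      writeBin(words[[i]]$val, con, size = 4L, endian = "little")
    } else {
      writeBin(words[[i]]$val, con, size = 4L, endian = "little")
    }
  }
  writeBin(v, con, size = 4L, endian = "little")
  invisible(path)
}
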