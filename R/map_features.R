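#' Map-quality statistics
#'
#' Descriptive statistics of an electron-density map used as predictor
#' features: the r.m.s. deviation of the density from its mean, the third
#' moment about the mean (skew), and the density extrema. All statistics are
#' computed over every grid point of the stored map, with the population
#' (divisor N) convention for moments.
#'
#' @param map A [density_map] with at least one sample.
#' @param standardized For `density_skew`: if `TRUE`, divide the raw third
#'   moment by rmsd^3, giving the unitless skewness coefficient. The default
#'   (`FALSE`) reports the scale-dependent raw third moment in map-units^3.
#' @return A single number.
#' @name map_statistics
NULL

map_samples <- function(map) {
  stopifnot(inherits(map, "density_map"))
  v <- as.numeric(map$values)
  if (length(v) == 0L) stop("map has no samples")
  v
}

#' @rdname map_statistics
#' @export
density_rmsd <- function(map) {
  v <- map_samples(map)
  sqrt(mean((v - mean(v))^2))
}

#' @rdname map_statistics
#' @export
density_skew <- function(map, standardized = FALSE) {
  v <- map_samples(map)
  m3 <- mean((v - mean(v))^3)
  if (!standardized) return(m3)
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) stop("standardized skew undefined for a constant map")
  m3 / s^3
}

#' @rdname map_statistics
#' @export
density_extrema <- function(map) {
  v <- map_samples(map)
  c(min_density = min(v), max_density = max(v))
}

#' Assemble the predictor feature vector for one data set
#'
#' Combines the map-quality statistics with the data-set resolution and, for
#' molecular-replacement (MR) data sets, the sequence identity of the search
#' model. The six features are: resolution, r.m.s.d., skew, maximum density,
#' minimum density and (MR only) sequence identity.
#'
#' Sequence identity is an ingested number computed upstream by structure
#' superposition; it must be supplied if and only if `phasing_mode = "MR"` —
#' supplying it in experimental mode is rejected to catch wiring errors.
#'
#' @param map A [density_map].
#' @param resolution Data-set resolution in Angstrom (> 0).
#' @param phasing_mode `"experimental"` or `"MR"`.
#' @param sequence_identity Fraction in \[0, 1\]; required for MR, forbidden
#'   for experimental phasing.
#' @param standardized_skew Use the unitless skew instead of the raw third
#'   moment (default scale-dependent).
#' @return A one-row data frame of class `map_features` with columns
#'   `resolution`, `rmsd`, `skew`, `max_density`, `min_density`,
#'   `sequence_identity` (NA when absent) and `phasing_mode`.
#' @export
extract_features <- function(map, resolution, phasing_mode = c("experimental", "MR"),
                             sequence_identity = NULL, standardized_skew = FALSE) {
  phasing_mode <- match.arg(phasing_mode)
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("`resolution` must be a single positive number (Angstrom)")
  if (phasing_mode == "MR") {
    if (is.null(sequence_identity))
      stop("MR mode requires `sequence_identity`")
    if (sequence_identity < 0 || sequence_identity > 1)
      stop("`sequence_identity` must be a fraction in [0, 1]")
  } else if (!is.null(sequence_identity)) {
    stop("`sequence_identity` must not be supplied in experimental mode")
  }
  ext <- density_extrema(map)
  out <- data.frame(
    resolution = resolution,
    rmsd = density_rmsd(map),
    skew = density_skew(map, standardized = standardized_skew),
    max_density = unname(ext["max_density"]),
    min_density = unname(ext["min_density"]),
    sequence_identity = if (is.null(sequence_identity)) NA_real_ else sequence_identity,
    phasing_mode = phasing_mode,
    stringsAsFactors = FALSE)
  class(out) <- c("map_features", class(out))
  out
}

#' Write / read feature-vector tables
#'
#' Feature vectors are serialized as tab-delimited text with a header row:
#' `dataset_id, phasing_mode, resolution, rmsd, skew, max_density,
#' min_density, sequence_identity` (empty field when absent).
#'
#' @param features Data frame with the columns above (`dataset_id` added from
#'   row names if missing).
#' @param path File path.
#' @return `read_feature_table` returns the data frame; `write_feature_table`
#'   returns `path` invisibly.
#' @export
write_feature_table <- function(features, path) {
  cols <- c("dataset_id", "phasing_mode", "resolution", "rmsd", "skew",
            "max_density", "min_density", "sequence_identity")
  if (!"dataset_id" %in% names(features))
    features$dataset_id <- rownames(features)
  if (!"sequence_identity" %in% names(features))
    features$sequence_identity <- NA_real_
  missing <- setdiff(cols, names(features))
  if (length(missing))
    stop("feature table lacks columns: ", paste(missing, collapse = ", "))
  utils::write.table(features[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                    stringsAsFactors = FALSE)
}
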