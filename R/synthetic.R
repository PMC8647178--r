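#' Synthetic electron-density map
#'
#' A sum of isotropic Gaussian blobs at uniform-random positions in the cell
#' plus white noise — a stand-in for a real map with controllable signal and
#' noise levels, sufficient for exercising the map statistics (it makes no
#' attempt at physically realistic density; there are no structure factors or
#' Fourier synthesis behind it).
#'
#' @param n_atoms Number of Gaussian blobs (>= 0).
#' @param cell_edge Cubic cell edge in Angstrom.
#' @param grid_shape Integer triple of grid dimensions.
#' @param noise_sigma Standard deviation of the additive white noise (map
#'   units).
#' @param blob_sigma Gaussian width of each blob in Angstrom.
#' @param blob_height Peak height of each blob (map units).
#' @param seed Integer seed; the generator is deterministic per seed.
#' @return A [density_map].
#' @export
make_synthetic_map <- function(n_atoms = 20L, cell_edge = 20,
                               grid_shape = c(32L, 32L, 32L),
                               noise_sigma = 0.1, blob_sigma = 0.8,
                               blob_height = 1, seed = 1L) {
  if (n_atoms < 0L) stop("n_atoms must be >= 0")
  if (any(grid_shape <= 0L)) stop("grid_shape must be positive")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gs <- as.integer(grid_shape)
  ax <- (seq_len(gs[1]) - 1) * cell_edge / gs[1]
  ay <- (seq_len(gs[2]) - 1) * cell_edge / gs[2]
  az <- (seq_len(gs[3]) - 1) * cell_edge / gs[3]
  vals <- array(0, dim = gs)
  if (n_atoms > 0L) {
    pos <- matrix(stats::runif(3 * n_atoms, 0, cell_edge), ncol = 3)
    for (a in seq_len(n_atoms)) {
      gx <- exp(-(ax - pos[a, 1])^2 / (2 * blob_sigma^2))
      gy <- exp(-(ay - pos[a, 2])^2 / (2 * blob_sigma^2))
      gz <- exp(-(az - pos[a, 3])^2 / (2 * blob_sigma^2))
      vals <- vals + blob_height * outer(outer(gx, gy), gz)
    }
  }
  if (noise_sigma > 0)
    vals <- vals + array(stats::rnorm(prod(gs), 0, noise_sigma), dim = gs)
  density_map(vals, cell = c(rep(cell_edge, 3), 90, 90, 90))
}

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Built/deposited model pair with known completeness
#'
#' Constructs a deposited reference model of `n_residues` C-alpha positions
#' along a non-self-approaching path (consecutive C-alpha at least 3.5
#' Angstrom apart) and a built model that reproduces a known fraction of it:
#' `match_fraction` of the residues copied with their type and displaced by
#' `displacement`, `wrong_type_fraction` kept in place but with a mutated
#' residue type, and the remainder omitted. Because the path spacing exceeds
#' twice the 1 Angstrom matching cutoff, the realized completeness equals the
#' matched fraction by construction.
#'
#' Fractions are quantized to whole residue counts by rounding; the realized
#' fraction is returned as `expected_completeness`.
#'
#' @param n_residues Number of residues in the deposited model.
#' @param match_fraction Fraction reproduced with correct type.
#' @param wrong_type_fraction Fraction kept in place with a wrong type.
#' @param displacement C-alpha displacement (Angstrom) of matched residues;
#'   must stay below the matching cutoff of 1.
#' @param seed Integer seed.
#' @return List with `built`, `deposited` ([structure_model]s),
#'   `expected_completeness` and `n_matched`.
#' @export
make_model_pair <- function(n_residues = 20L, match_fraction = 0.8,
                            wrong_type_fraction = 0, displacement = 0.3,
                            seed = 1L) {
  if (match_fraction < 0 || match_fraction > 1 ||
      wrong_type_fraction < 0 || wrong_type_fraction > 1 ||
      match_fraction + wrong_type_fraction > 1)
    stop("fractions must lie in [0,1] and sum to at most 1")
  if (displacement >= 1)
    stop("displacement must be below the 1 Angstrom matching cutoff")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- as.integer(n_residues)
  # straight backbone along x with sub-Angstrom jitter: consecutive C-alpha
  # >= 3.8 apart, non-consecutive >= 7.6, so any built atom displaced by < 1
  # is within the cutoff of exactly one deposited residue
  x <- seq_len(n) * 3.8
  y <- stats::runif(n, -0.4, 0.4)
  z <- stats::runif(n, -0.4, 0.4)
  types <- sample(AA3, n, replace = TRUE)
  deposited <- structure_model(data.frame(
    chain_id = "A", seq_num = seq_len(n), insertion_code = "",
    residue_type = types, x = x, y = y, z = z, stringsAsFactors = FALSE))

  n_match <- round(match_fraction * n)
  n_wrong <- min(round(wrong_type_fraction * n), n - n_match)
  idx <- sample(n)
  m_idx <- sort(idx[seq_len(n_match)])
  w_idx <- if (n_wrong > 0) sort(idx[n_match + seq_len(n_wrong)]) else integer()

  rows <- list()
  if (n_match > 0) {
    dir <- matrix(stats::rnorm(3 * n_match), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    rows$match <- data.frame(
      chain_id = "A", seq_num = m_idx, insertion_code = "",
      residue_type = types[m_idx],
      x = x[m_idx] + displacement * dir[, 1],
      y = y[m_idx] + displacement * dir[, 2],
      z = z[m_idx] + displacement * dir[, 3], stringsAsFactors = FALSE)
  }
  if (n_wrong > 0) {
    mut <- vapply(types[w_idx], function(t) sample(setdiff(AA3, t), 1), "")
    rows$wrong <- data.frame(
      chain_id = "A", seq_num = w_idx, insertion_code = "",
      residue_type = unname(mut),
      x = x[w_idx], y = y[w_idx], z = z[w_idx], stringsAsFactors = FALSE)
  }
  built_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain_id = character(), seq_num = integer(),
               insertion_code = character(), residue_type = character(),
               x = numeric(), y = numeric(), z = numeric(),
               stringsAsFactors = FALSE)
  built_df <- built_df[order(built_df$seq_num), , drop = FALSE]
  built <- structure_model(built_df)
  list(built = built, deposited = deposited,
       expected_completeness = n_match / n, n_matched = n_match)
}

#' Generator specification for feature/outcome tables
#'
#' Describes how synthetic per-dataset features and per-variant outcomes are
#' drawn. Features are sampled parametrically: resolution uniform on
#' `resolution_range` (default 1.0-4.0 Angstrom); map skew decays with
#' resolution (so a strong density histogram accompanies good data); rmsd
#' and the extrema are drawn on realistic map-unit scales; sequence identity
#' (MR only) uniform on `seq_identity_range`. Outcomes are
#' `response(features, variant, measure) + N(0, noise_sigma)`, clamped to the
#' measure's valid range. The default response makes completeness a
#' per-variant logistic in resolution (high below ~2 Angstrom, collapsing
#' beyond ~3.5) with secondary skew and sequence-identity effects, and the R
#' factors increase with resolution.
#'
#' @param phasing_mode `"experimental"` or `"MR"`.
#' @param resolution_range,seq_identity_range Uniform sampling ranges.
#' @param noise_sigma Named vector of noise SDs per measure, or one number
#'   for all measures.
#' @param response `NULL` for the default, or
#'   `function(features, variant_id, measure)` returning the noiseless
#'   expected outcome per row.
#' @param feature_sampler `NULL` for the default, or `function(n)` returning
#'   a data frame of feature columns (called with the RNG already seeded).
#' @return A list of class `outcome_generator_spec`.
#' @export
outcome_generator_spec <- function(phasing_mode = c("experimental", "MR"),
                                   resolution_range = c(1.0, 4.0),
                                   seq_identity_range = c(0.2, 1.0),
                                   noise_sigma = c(completeness = 0.05,
                                                   R_work = 0.02,
                                                   R_free = 0.02),
                                   response = NULL,
                                   feature_sampler = NULL) {
  phasing_mode <- match.arg(phasing_mode)
  if (length(noise_sigma) == 1L && is.null(names(noise_sigma)))
    noise_sigma <- stats::setNames(rep(noise_sigma, 3), MEASURES)
  if (any(noise_sigma < 0)) stop("noise_sigma must be >= 0")
  structure(list(phasing_mode = phasing_mode,
                 resolution_range = resolution_range,
                 seq_identity_range = seq_identity_range,
                 noise_sigma = noise_sigma, response = response,
                 feature_sampler = feature_sampler),
            class = "outcome_generator_spec")
}

variant_params <- function(variant_id) {
  # deterministic per-variant response parameters from the id text
  h <- sum(utf8ToInt(variant_id) * seq_along(utf8ToInt(variant_id)))
  u <- function(k, lo, hi) lo + ((h * k) %% 1000) / 999 * (hi - lo)
  list(r_mid = u(7, 2.2, 3.2),      # resolution at which completeness halves
       r_scale = u(13, 0.3, 0.6),   # logistic width
       skew_coef = u(17, 0.05, 0.25),
       r_base = u(23, 0.14, 0.20))  # base R factor
}

default_response <- function(features, variant_id, measure) {
  p <- variant_params(variant_id)
  comp <- stats::plogis((p$r_mid - features$resolution) / p$r_scale) +
    p$skew_coef * (features$skew - 0.3)
  if (!is.null(features$sequence_identity) &&
      !all(is.na(features$sequence_identity)))
    comp <- comp + 0.25 * (features$sequence_identity - 0.6)
  comp <- pmin(pmax(comp, 0), 1)
  switch(measure,
         completeness = comp,
         R_work = pmin(pmax(p$r_base + 0.05 * (features$resolution - 1) +
                              0.08 * (1 - comp), 0.02), 0.65),
         R_free = pmin(pmax(p$r_base + 0.03 + 0.06 * (features$resolution - 1) +
                              0.08 * (1 - comp), 0.02), 0.70))
}

default_feature_sampler <- function(spec) {
  function(n) {
    res <- stats::runif(n, spec$resolution_range[1], spec$resolution_range[2])
    rmsd <- stats::runif(n, 0.2, 0.5)
    skew <- 0.6 * exp(-(res - 1) / 1.5) + stats::runif(n, 0, 0.05)
    df <- data.frame(resolution = res, rmsd = rmsd, skew = skew,
                     max_density = rmsd * stats::runif(n, 3, 6),
                     min_density = -rmsd * stats::runif(n, 1.5, 3))
    if (spec$phasing_mode == "MR")
      df$sequence_identity <- stats::runif(n, spec$seq_identity_range[1],
                                           spec$seq_identity_range[2])
    df
  }
}

#' Synthetic feature-to-outcome tables with known generative structure
#'
#' Draws `n_datasets` feature vectors and, for every applicable (variant,
#' measure) cell of the registry, generates observed outcomes as the spec's
#' response function plus Gaussian noise (clamped to the measure's valid
#' range). The noiseless truth is returned alongside for recovery tests.
#'
#' @param spec An [outcome_generator_spec()].
#' @param n_datasets Number of datasets (>= 2).
#' @param registry Variant registry (default registry of the spec's phasing
#'   mode).
#' @param seed Integer seed; generation is bit-reproducible per (spec, seed).
#' @return List with `data` (long table: `dataset_id`, features,
#'   `variant_id`, `measure`, `outcome`), `truth` (same rows with the
#'   noiseless expected outcome), and `features` (the per-dataset feature
#'   table).
#' @export
make_outcome_table <- function(spec = outcome_generator_spec(),
                               n_datasets = 100L, registry = NULL,
                               seed = 1L) {
  stopifnot(inherits(spec, "outcome_generator_spec"))
  if (n_datasets < 2L) stop("need at least 2 datasets")
  if (is.null(registry)) registry <- default_registry(spec$phasing_mode)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sampler <- if (is.null(spec$feature_sampler))
    default_feature_sampler(spec) else spec$feature_sampler
  feats <- sampler(as.integer(n_datasets))
  feats$dataset_id <- sprintf("ds%04d", seq_len(n_datasets))
  response <- if (is.null(spec$response)) default_response else spec$response
  cells <- suite_cells(registry)
  data_rows <- vector("list", nrow(cells))
  truth_rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    vid <- cells$variant_id[i]; msr <- cells$measure[i]
    mu <- response(feats, vid, msr)
    sigma <- spec$noise_sigma[[msr]]
    y <- mu + stats::rnorm(n_datasets, 0, sigma)
    y <- if (msr == "completeness") pmin(pmax(y, 0), 1) else
      pmin(pmax(y, 0.001), 0.999)
    base <- cbind(feats, variant_id = vid, measure = msr,
                  stringsAsFactors = FALSE)
    data_rows[[i]] <- cbind(base, outcome = y)
    truth_rows[[i]] <- cbind(base, outcome = mu)
  }
  out_data <- do.call(rbind, data_rows)
  out_truth <- do.call(rbind, truth_rows)
  rownames(out_data) <- rownames(out_truth) <- NULL
  list(data = out_data, truth = out_truth, features = feats)
}
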