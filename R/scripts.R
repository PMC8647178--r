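#' Run configuration
#'
#' Bundles the user-supplied paths and settings consumed by the command-line
#' verbs and by the script generator. Placeholders in the per-pipeline shell
#' templates are substituted from these fields.
#'
#' @param mtz Path to the reflection data (MTZ) handed to the pipelines.
#' @param seq Path to the target sequence file.
#' @param map Path to the starting electron-density map.
#' @param workdir Working directory the generated scripts run in.
#' @param phasing_mode `"experimental"` or `"MR"`.
#' @param sequence_identity MR search-model sequence identity (required for
#'   MR predictions).
#' @param resolution Data-set resolution in Angstrom.
#' @param tolerance Grouping tolerance override.
#' @param confidence Prediction-interval confidence override.
#' @param seed Integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mtz = "input.mtz", seq = "input.seq", map = "input.map",
                       workdir = ".", phasing_mode = "experimental",
                       sequence_identity = NULL, resolution = NULL,
                       tolerance = 0.05, confidence = 0.95, seed = 1L) {
  structure(list(mtz = mtz, seq = seq, map = map, workdir = workdir,
                 phasing_mode = phasing_mode,
                 sequence_identity = sequence_identity,
                 resolution = resolution, tolerance = tolerance,
                 confidence = confidence, seed = as.integer(seed)),
            class = "run_config")
}

template_path <- function(slug) {
  p <- system.file("templates", paste0(slug, ".sh.in"), package = "mbperf")
  if (!nzchar(p)) stop("no shell template for pipeline stage: ", slug)
  p
}

substitute_template <- function(text, values) {
  for (key in names(values)) {
    text <- gsub(paste0("@", key, "@"), values[[key]], text, fixed = TRUE)
  }
  left <- regmatches(text, regexpr("@[A-Z_]+@", text))
  if (length(left) && any(nzchar(left)))
    stop("unsubstituted template placeholder: ", left[nzchar(left)][1])
  text
}

#' Generate a runnable shell script for a pipeline variant
#'
#' Emits the shell-script text for one variant from the per-pipeline
#' templates shipped in `inst/templates/`, with the user's paths substituted.
#' For pairwise variants the first stage's declared output model path feeds
#' the second stage's input; a Parrot-preconditioned variant prepends the
#' density-modification stage. Scripts are emitted, never executed, and the
#' templates carry placeholder invocations users should adapt to their
#' installed pipeline versions.
#'
#' @param variant A [pipeline_variant].
#' @param config A [run_config()].
#' @return The script text (single character string). Deterministic for a
#'   fixed (variant, config).
#' @export
generate_script <- function(variant, config = run_config()) {
  stopifnot(inherits(variant, "pipeline_variant"))
  slugs <- pipeline_slug(variant$stages)
  header <- c("#!/bin/sh", "set -e",
              sprintf("# model-building script for variant '%s'", variant$variant_id),
              sprintf("cd %s", shQuote(config$workdir)), "")
  blocks <- character()
  map_in <- config$map
  if (variant$parrot) {
    tmpl <- readLines(template_path("parrot"))
    blocks <- c(blocks, substitute_template(tmpl, list(
      MTZ = config$mtz, MAP_IN = map_in, MAP_OUT = "parrot.map")), "")
    map_in <- "parrot.map"
  }
  pdb_in <- ""
  for (i in seq_along(slugs)) {
    out <- sprintf("model_stage%d.pdb", i)
    tmpl <- readLines(template_path(slugs[i]))
    blocks <- c(blocks, substitute_template(tmpl, list(
      MTZ = config$mtz, SEQ = config$seq, MAP = map_in,
      PDB_IN = pdb_in, PDB_OUT = out)), "")
    pdb_in <- out
  }
  paste(c(header, blocks), collapse = "\n")
}

#' Write one script per registry variant
#'
#' @param registry Named list of [pipeline_variant]s.
#' @param config A [run_config()].
#' @param dir Output directory.
#' @return Character vector of written file paths (one per variant, named by
#'   variant id — ids are unique so there are no collisions).
#' @export
generate_all_scripts <- function(registry, config = run_config(), dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vapply(registry, function(v) {
    path <- file.path(dir, paste0(v$variant_id, ".sh"))
    writeLines(generate_script(v, config), path)
    path
  }, character(1))
}
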