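#' @name registry
#' @title Pipeline variants and the measure-applicability rules
#'
#' @description
#' A pipeline variant is an ordered recipe of one or two model-building
#' pipelines (ARP/wARP, Buccaneer, Phenix AutoBuild, SHELXE), optionally
#' preconditioned by Parrot density modification. For pairs, the model built
#' by the first pipeline seeds the second. Three evaluation measures are
#' predicted per variant: structure completeness, R_work and R_free — except
#' that R_free is not applicable to variants whose final output is not
#' refined, i.e. individually-run ARP/wARP and individually-run SHELXE
#' (with or without Parrot preconditioning).
NULL

PIPELINES <- c("ARP/wARP", "Buccaneer", "Phenix AutoBuild", "SHELXE")
MEASURES <- c("completeness", "R_work", "R_free")

pipeline_slug <- function(name) {
  slugs <- c("ARP/wARP" = "arpwarp", "Buccaneer" = "buccaneer",
             "Phenix AutoBuild" = "autobuild", "SHELXE" = "shelxe")
  out <- slugs[name]
  if (anyNA(out)) stop("unknown pipeline: ", paste(name[is.na(out)], collapse = ", "))
  unname(out)
}

#' Construct a pipeline variant
#'
#' @param stages Character vector of one or two distinct pipeline names from
#'   `"ARP/wARP"`, `"Buccaneer"`, `"Phenix AutoBuild"`, `"SHELXE"`.
#' @param parrot Precondition the map with Parrot density modification first.
#' @param phasing_mode `"experimental"` or `"MR"`. MR variants must be
#'   single-stage (pairwise combinations were only run for experimental
#'   phasing).
#' @return An object of class `pipeline_variant` with a deterministic
#'   `variant_id` slug.
#' @export
pipeline_variant <- function(stages, parrot = FALSE,
                             phasing_mode = c("experimental", "MR")) {
  phasing_mode <- match.arg(phasing_mode)
  if (length(stages) < 1L || length(stages) > 2L)
    stop("a variant has one or two stages")
  if (!all(stages %in% PIPELINES))
    stop("unknown pipeline(s): ", paste(setdiff(stages, PIPELINES), collapse = ", "))
  if (length(stages) == 2L && stages[1] == stages[2])
    stop("the two stages of a pair must be distinct")
  if (phasing_mode == "MR" && (length(stages) != 1L || parrot))
    stop("MR variants are single individual pipelines without Parrot")
  id <- paste(pipeline_slug(stages), collapse = "-then-")
  if (parrot) id <- paste0("parrot-", id)
  structure(list(variant_id = id, stages = stages, parrot = parrot,
                 phasing_mode = phasing_mode),
            class = "pipeline_variant")
}

#' @export
print.pipeline_variant <- function(x, ...) {
  cat(sprintf("pipeline_variant '%s': %s%s [%s]\n", x$variant_id,
              if (x$parrot) "Parrot -> " else "",
              paste(x$stages, collapse = " -> "), x$phasing_mode))
  invisible(x)
}

#' Measures applicable to a variant
#'
#' R_free requires a refinement step in the final stage; individually-run
#' ARP/wARP and SHELXE (with or without Parrot) therefore only support
#' completeness and R_work.
#'
#' @param variant A [pipeline_variant].
#' @return Character vector of applicable measure names.
#' @export
applicable_measures <- function(variant) {
  stopifnot(inherits(variant, "pipeline_variant"))
  if (length(variant$stages) == 1L &&
      variant$stages %in% c("ARP/wARP", "SHELXE"))
    return(c("completeness", "R_work"))
  MEASURES
}

#' Default variant registries
#'
#' The experimental-phasing registry has 24 variants: the 4 individual
#' pipelines, the 12 ordered pairs, and 8 Parrot-preconditioned variants
#' (Buccaneer, SHELXE and Phenix AutoBuild individually, plus the 5 pairs
#' SHELXE->Buccaneer, SHELXE->AutoBuild, SHELXE->ARP/wARP,
#' Buccaneer->AutoBuild and Buccaneer->ARP/wARP). With R_free dropped for the
#' three refinement-free individual variants this yields 69 (variant,
#' measure) model cells. The MR registry is the 4 individual pipelines,
#' yielding 10 cells.
#'
#' @param phasing_mode `"experimental"` or `"MR"`.
#' @return A named list of [pipeline_variant] objects (names = variant ids).
#' @export
default_registry <- function(phasing_mode = c("experimental", "MR")) {
  phasing_mode <- match.arg(phasing_mode)
  if (phasing_mode == "MR") {
    vars <- lapply(PIPELINES, pipeline_variant, phasing_mode = "MR")
  } else {
    singles <- lapply(PIPELINES, pipeline_variant)
    pairs <- list()
    for (a in PIPELINES) for (b in PIPELINES) if (a != b)
      pairs[[length(pairs) + 1L]] <- pipeline_variant(c(a, b))
    parrot <- c(
      lapply(c("Buccaneer", "SHELXE", "Phenix AutoBuild"),
             pipeline_variant, parrot = TRUE),
      list(pipeline_variant(c("SHELXE", "Buccaneer"), parrot = TRUE),
           pipeline_variant(c("SHELXE", "Phenix AutoBuild"), parrot = TRUE),
           pipeline_variant(c("SHELXE", "ARP/wARP"), parrot = TRUE),
           pipeline_variant(c("Buccaneer", "Phenix AutoBuild"), parrot = TRUE),
           pipeline_variant(c("Buccaneer", "ARP/wARP"), parrot = TRUE)))
    vars <- c(singles, pairs, parrot)
  }
  names(vars) <- vapply(vars, `[[`, "", "variant_id")
  vars
}

#' Enumerate the (variant, measure) cells of a registry
#'
#' @param registry A list of [pipeline_variant] objects.
#' @return Data frame with columns `variant_id` and `measure`, one row per
#'   applicable cell.
#' @export
suite_cells <- function(registry) {
  rows <- lapply(registry, function(v)
    data.frame(variant_id = v$variant_id, measure = applicable_measures(v),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
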