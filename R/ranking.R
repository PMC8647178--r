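higher_is_better <- function(measure) measure == "completeness"

#' Rank pipeline variants by prediction uncertainty
#'
#' Sorts the prediction records for one dataset and one measure in ascending
#' prediction-interval width: narrow intervals first, i.e. most certain
#' predictions first. Ties are broken by the better point prediction (higher
#' completeness / lower R factor), then lexicographically by variant id.
#'
#' @param records Data frame of prediction records (`variant_id`, `measure`,
#'   `point`, `width`) for a single dataset and measure.
#' @return The records sorted into rank order.
#' @export
rank_variants <- function(records) {
  if (nrow(records) < 1L) stop("need at least one prediction record")
  if (length(unique(records$measure)) != 1L)
    stop("records mix measures; rank one measure at a time")
  pt <- if (higher_is_better(records$measure[1])) -records$point else records$point
  out <- records[order(records$width, pt, records$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group near-tied variants by interval width
#'
#' Greedy anchored grouping of rank-sorted records: the first record opens a
#' group and anchors its width; subsequent records join while their width is
#' within the tolerance of the anchor (relative by default: width <= anchor *
#' (1 + tolerance)), otherwise they open a new group. The default tolerance
#' of 0.05 implements the "no more than 5% difference in prediction interval
#' width" rule.
#'
#' @param records Records already sorted by [rank_variants()].
#' @param tolerance Non-negative grouping tolerance.
#' @param relative If `TRUE` (default) the tolerance is relative to the group
#'   anchor width; if `FALSE` it is an absolute width difference.
#' @return The records with an integer `group` column (1 = most certain
#'   group).
#' @export
group_variants <- function(records, tolerance = 0.05, relative = TRUE) {
  if (tolerance < 0) stop("tolerance must be non-negative")
  if (is.unsorted(records$width)) stop("records must be sorted by rank_variants()")
  n <- nrow(records)
  grp <- integer(n)
  g <- 0L; anchor <- -Inf
  for (i in seq_len(n)) {
    w <- records$width[i]
    limit <- if (relative) anchor * (1 + tolerance) else anchor + tolerance
    if (g == 0L || w > limit) {
      g <- g + 1L
      anchor <- w
    }
    grp[i] <- g
  }
  records$group <- grp
  records
}

#' Recommend the best-predicted variant
#'
#' The variant predicted to achieve the best value of the measure: maximum
#' predicted completeness, or minimum predicted R_free/R_work. Ties are
#' broken by narrower interval width, then by variant id.
#'
#' @param records Prediction records for one dataset (may cover several
#'   measures).
#' @param measure The measure to recommend for.
#' @return The recommended `variant_id` (character scalar).
#' @export
recommend <- function(records, measure = c("completeness", "R_free", "R_work")) {
  measure <- match.arg(measure)
  rec <- records[records$measure == measure, , drop = FALSE]
  if (nrow(rec) == 0L) stop("measure '", measure, "' applicable to no variant")
  pt <- if (higher_is_better(measure)) -rec$point else rec$point
  w <- if ("width" %in% names(rec)) rec$width else rep(0, nrow(rec))
  rec$variant_id[order(pt, w, rec$variant_id)][1]
}

#' Ranked uncertainty report for one dataset
#'
#' Combines ranking, grouping and recommendation into the report shown to a
#' user: variants ordered by prediction certainty with near-ties grouped, and
#' the best-predicted variant flagged.
#'
#' @param records Prediction records for one dataset and one measure.
#' @param tolerance,relative Grouping rule, see [group_variants()].
#' @return Object of class `ranked_report`: list with `measure`, `records`
#'   (ranked, with `group` column) and `recommended`.
#' @export
ranked_report <- function(records, tolerance = 0.05, relative = TRUE) {
  ranked <- group_variants(rank_variants(records), tolerance, relative)
  structure(list(measure = ranked$measure[1], records = ranked,
                 recommended = recommend(ranked, ranked$measure[1]),
                 tolerance = tolerance, relative = relative),
            class = "ranked_report")
}

#' @export
print.ranked_report <- function(x, ...) {
  cat(sprintf("ranked_report for %s (tolerance %g%s)\n", x$measure,
              x$tolerance, if (x$relative) ", relative" else ", absolute"))
  df <- x$records
  for (g in unique(df$group)) {
    cat(sprintf(" group %d:\n", g))
    sub <- df[df$group == g, ]
    for (i in seq_len(nrow(sub)))
      cat(sprintf("   %-35s point %.3f  width %.3f%s\n", sub$variant_id[i],
                  sub$point[i], sub$width[i],
                  if (sub$variant_id[i] == x$recommended) "  <- recommended" else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.ranked_report <- function(x, ...) x$records
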