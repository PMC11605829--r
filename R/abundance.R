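#' Per-treatment relative abundance of every compound
#'
#' For each compound i in a validated, deduplicated table, the relative
#' abundance is
#' \deqn{RA_i = \frac{a_i}{\sum_j a_j} \times N,}
#' the compound's peak area divided by the total peak area of all N compounds
#' in that table, multiplied by N. Equivalently, area divided by the mean
#' area, so the RA values of a table sum to N and average exactly 1. The
#' statistic is dimensionless and invariant to any global rescaling of the
#' detector response, which is what makes it comparable across the two
#' separately acquired treatments.
#'
#' Positive- and negative-mode records are pooled into the single table
#' before normalization; N is the per-treatment compound count after
#' deduplication.
#'
#' @param table a `feature_table`.
#' @return an object of class `abundance_table`: list with `treatment_label`,
#'   `entries` (named numeric vector of RA values keyed by compound),
#'   `n_compounds`, `total_area`.
#' @examples
#' ft <- feature_table(
#'   data.frame(compound_key = c("a", "b", "c"), area = c(2, 3, 5)),
#'   treatment_label = "filter_sterilized")
#' relative_abundance(ft)$entries  # 0.6, 0.9, 1.5
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  areas <- table$records$area
  n <- length(areas)
  if (n == 0L) stop("cannot compute relative abundance of an empty table")
  total <- sum(areas)
  ra <- areas / total * n
  structure(
    list(treatment_label = table$treatment_label,
         entries = stats::setNames(ra, table$records$compound_key),
         n_compounds = n, total_area = total),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Relative abundances:", x$treatment_label, "\n")
  cat("  compounds:", x$n_compounds, " total area:",
      format(x$total_area), "\n")
  cat("  RA range: [", format(min(x$entries)), ",",
      format(max(x$entries)), "], mean", format(mean(x$entries)), "\n")
  invisible(x)
}
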