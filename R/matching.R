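#' Partition two treatments' compounds into shared and exclusive sets
#'
#' Matches the filter-sterilized and autoclaved tables by exact normalized
#' annotation identity (no m/z or retention-time tolerance matching: both
#' tables are annotated against the same spectral libraries, so identity is
#' the shared key). Compounds found in both define the shared set — the only
#' compounds that later receive a stability ratio; compounds seen only before
#' autoclaving are heat-degraded, compounds seen only after are presumed
#' heat-degradation products.
#'
#' @param ft_filter `feature_table` of the filter-sterilized medium.
#' @param ft_autoclave `feature_table` of the autoclaved medium.
#' @return object of class `matched_compendium`: `shared` (data.frame with
#'   one row per shared key, paired filter/autoclave areas and metadata),
#'   `filter_only` and `autoclave_only` (character vectors of keys),
#'   `match_policy`.
#' @export
match_compounds <- function(ft_filter, ft_autoclave) {
  stopifnot(inherits(ft_filter, "feature_table"),
            inherits(ft_autoclave, "feature_table"))
  rf <- ft_filter$records
  ra <- ft_autoclave$records
  if (nrow(rf) == 0L || nrow(ra) == 0L)
    stop("both feature tables must contain at least one compound")

  shared_keys <- sort(intersect(rf$compound_key, ra$compound_key))
  fi <- match(shared_keys, rf$compound_key)
  ai <- match(shared_keys, ra$compound_key)
  # superclass: prefer the filter-side label, fall back to autoclave side
  sc <- rf$superclass[fi]
  sc[is.na(sc)] <- ra$superclass[ai][is.na(sc)]
  shared <- data.frame(
    compound_key = shared_keys,
    area_filter = rf$area[fi],
    area_autoclave = ra$area[ai],
    superclass = sc,
    stringsAsFactors = FALSE
  )
  structure(
    list(shared = shared,
         filter_only = sort(setdiff(rf$compound_key, ra$compound_key)),
         autoclave_only = sort(setdiff(ra$compound_key, rf$compound_key)),
         n_filter_total = nrow(rf),
         n_autoclave_total = nrow(ra),
         match_policy = "exact_normalized_name"),
    class = "matched_compendium"
  )
}

#' Partition counts of a matched compendium
#'
#' @param m a `matched_compendium` from [match_compounds()].
#' @return named integer vector: `n_shared`, `n_filter_only`,
#'   `n_autoclave_only`, `n_filter_total`, `n_autoclave_total`. By
#'   construction `n_shared + n_filter_only == n_filter_total` and
#'   `n_shared + n_autoclave_only == n_autoclave_total`.
#' @export
partition_counts <- function(m) {
  stopifnot(inherits(m, "matched_compendium"))
  c(n_shared = nrow(m$shared),
    n_filter_only = length(m$filter_only),
    n_autoclave_only = length(m$autoclave_only),
    n_filter_total = m$n_filter_total,
    n_autoclave_total = m$n_autoclave_total)
}

#' @export
print.matched_compendium <- function(x, ...) {
  cts <- partition_counts(x)
  cat("Matched compendium (", x$match_policy, ")\n", sep = "")
  cat("  shared:         ", cts["n_shared"], "\n")
  cat("  filter-only:    ", cts["n_filter_only"],
      " (of", cts["n_filter_total"], "filter-sterilized compounds)\n")
  cat("  autoclave-only: ", cts["n_autoclave_only"],
      " (of", cts["n_autoclave_total"], "autoclaved compounds)\n")
  invisible(x)
}
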