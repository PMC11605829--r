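#' Classification thresholds for the stability screen
#'
#' The screen uses two strict open windows on the Rf/Ra ratio (relative
#' abundance in the filter-sterilized medium over relative abundance in the
#' autoclaved medium). Shared compounds with a ratio strictly inside
#' `(anti_aging_low, anti_aging_high)` changed little on autoclaving and are
#' heat-stable anti-aging candidates; a ratio strictly above
#' `inhibitor_ratio` marks a heat-sensitive growth-inhibiting candidate. The
#' default inhibitor cutoff of 9 is the field's operational rendering of "at
#' least 90% reduction of relative abundance" (taken literally, a 90%
#' reduction corresponds to a ratio of 10; the conventional cutoff 9 is kept
#' as stated, not silently corrected). Boundary values fall in neither
#' window.
#'
#' @param anti_aging_low,anti_aging_high open-interval bounds of the
#'   heat-stable window (defaults 0.75 and 1.5).
#' @param inhibitor_ratio open lower bound of the growth-inhibitor window
#'   (default 9).
#' @return object of class `screen_thresholds`.
#' @export
screen_thresholds <- function(anti_aging_low = 0.75, anti_aging_high = 1.5,
                              inhibitor_ratio = 9) {
  v <- c(anti_aging_low, anti_aging_high, inhibitor_ratio)
  if (!is.numeric(v) || length(v) != 3L || anyNA(v))
    stop("thresholds must be three numbers")
  if (!(0 < anti_aging_low && anti_aging_low < anti_aging_high &&
        anti_aging_high <= inhibitor_ratio))
    stop("invalid thresholds: need 0 < anti_aging_low < anti_aging_high ",
         "<= inhibitor_ratio")
  structure(list(anti_aging_low = anti_aging_low,
                 anti_aging_high = anti_aging_high,
                 inhibitor_ratio = inhibitor_ratio),
            class = "screen_thresholds")
}

#' Rf/Ra stability ratio
#'
#' Ratio of a shared compound's relative abundance in the filter-sterilized
#' medium (Rf) to that in the autoclaved medium (Ra). Compounds absent from
#' one treatment never reach this function — they are reported as exclusive
#' sets, not as infinite ratios — so both arguments must be strictly
#' positive; a non-positive value signals a matching bug upstream.
#'
#' @param Rf,Ra positive numeric vectors of equal length.
#' @return numeric vector `Rf / Ra`.
#' @export
stability_ratio <- function(Rf, Ra) {
  if (any(!is.finite(Rf)) || any(!is.finite(Ra)) ||
      any(Rf <= 0) || any(Ra <= 0))
    stop("stability_ratio: Rf and Ra must be finite and strictly positive")
  Rf / Ra
}

#' Classify a stability ratio into candidate windows
#'
#' Strict open intervals: `anti_aging_candidate` iff
#' `low < ratio < high`; `growth_inhibiting_candidate` iff
#' `ratio > inhibitor`; otherwise `unclassified`. Ratios exactly on a
#' boundary are unclassified.
#'
#' @param ratio positive numeric vector of Rf/Ra ratios.
#' @param thresholds a [screen_thresholds()] object.
#' @return character vector of labels.
#' @examples
#' classify_compound(c(1, 0.75, 5, 9.0001), screen_thresholds())
#' @export
classify_compound <- function(ratio, thresholds = screen_thresholds()) {
  if (!inherits(thresholds, "screen_thresholds"))
    thresholds <- do.call(screen_thresholds, as.list(thresholds))
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("classify_compound: ratios must be finite and strictly positive")
  out <- rep("unclassified", length(ratio))
  out[ratio > thresholds$anti_aging_low &
        ratio < thresholds$anti_aging_high] <- "anti_aging_candidate"
  out[ratio > thresholds$inhibitor_ratio] <- "growth_inhibiting_candidate"
  out
}

#' Count shared compounds per chemical superclass
#'
#' @param records data.frame with a `superclass` column (typically the
#'   `records` element of a `stability_screen`). Compounds without a
#'   superclass are pooled under `"unclassified_superclass"`.
#' @return named integer vector of counts, decreasing, summing to
#'   `nrow(records)`.
#' @export
superclass_summary <- function(records) {
  if (NROW(records) == 0L) return(stats::setNames(integer(0), character(0)))
  sc <- records$superclass
  sc[is.na(sc) | !nzchar(sc)] <- "unclassified_superclass"
  tab <- table(sc)
  out <- as.integer(tab)
  names(out) <- names(tab)
  sort(out, decreasing = TRUE)
}

#' Run the comparative thermostability screen
#'
#' End-to-end screen contrasting a filter-sterilized against an autoclaved
#' fermented-medium feature table: computes relative abundances within each
#' table, partitions compounds into shared / filter-only (heat-degraded) /
#' autoclave-only (heat-generated) sets, assigns every shared compound its
#' Rf/Ra stability ratio and window label, and tallies shared compounds per
#' chemical superclass. Deterministic for fixed inputs and thresholds.
#'
#' @param ft_filter `feature_table` of the filter-sterilized medium.
#' @param ft_autoclave `feature_table` of the autoclaved medium.
#' @param thresholds a [screen_thresholds()] object.
#' @return object of class `stability_screen` with elements:
#'   \describe{
#'     \item{records}{data.frame over shared compounds: `compound_key`, `Rf`,
#'       `Ra`, `ratio`, `label`, `superclass`.}
#'     \item{counts}{the five [partition_counts()].}
#'     \item{n_anti_aging, n_inhibitor}{candidate counts.}
#'     \item{superclass_summary}{named counts over shared compounds.}
#'     \item{filter_only, autoclave_only}{keys of the exclusive sets.}
#'     \item{thresholds, treatment_labels, provenance}{run metadata.}
#'   }
#' @examples
#' ftf <- feature_table(data.frame(compound_key = c("a", "b", "c"),
#'                                 area = c(2, 3, 5)), "filter_sterilized")
#' fta <- feature_table(data.frame(compound_key = c("b", "c", "d"),
#'                                 area = c(30, 5, 10)), "autoclaved")
#' scr <- stability_screen(ftf, fta)
#' scr$records
#' @export
stability_screen <- function(ft_filter, ft_autoclave,
                             thresholds = screen_thresholds()) {
  stopifnot(inherits(ft_filter, "feature_table"),
            inherits(ft_autoclave, "feature_table"))
  if (!inherits(thresholds, "screen_thresholds"))
    thresholds <- do.call(screen_thresholds, as.list(thresholds))

  ab_f <- relative_abundance(ft_filter)
  ab_a <- relative_abundance(ft_autoclave)
  m <- match_compounds(ft_filter, ft_autoclave)

  keys <- m$shared$compound_key
  Rf <- unname(ab_f$entries[keys])
  Ra <- unname(ab_a$entries[keys])
  if (length(keys)) {
    ratio <- stability_ratio(Rf, Ra)
    label <- classify_compound(ratio, thresholds)
  } else {
    ratio <- numeric(0); label <- character(0)
  }
  records <- data.frame(
    compound_key = keys, Rf = Rf, Ra = Ra, ratio = ratio, label = label,
    superclass = m$shared$superclass, stringsAsFactors = FALSE
  )

  checksum <- function(p) {
    if (!is.null(p) && is.character(p) && file.exists(p))
      unname(tools::md5sum(p)) else NA_character_
  }
  structure(
    list(records = records,
         counts = partition_counts(m),
         n_anti_aging = sum(label == "anti_aging_candidate"),
         n_inhibitor = sum(label == "growth_inhibiting_candidate"),
         superclass_summary = superclass_summary(records),
         filter_only = m$filter_only,
         autoclave_only = m$autoclave_only,
         thresholds = thresholds,
         treatment_labels = c(filter = ft_filter$treatment_label,
                              autoclave = ft_autoclave$treatment_label),
         provenance = list(
           filter = list(path = ft_filter$source_path,
                         md5 = checksum(ft_filter$source_path)),
           autoclave = list(path = ft_autoclave$source_path,
                            md5 = checksum(ft_autoclave$source_path)))),
    class = "stability_screen"
  )
}

#' @export
print.stability_screen <- function(x, ...) {
  cts <- x$counts
  th <- x$thresholds
  cat("Thermostability screen:", x$treatment_labels["filter"], "vs",
      x$treatment_labels["autoclave"], "\n")
  cat(sprintf("  compounds: %d filter-sterilized, %d autoclaved\n",
              cts["n_filter_total"], cts["n_autoclave_total"]))
  cat(sprintf("  shared %d | lost on autoclaving %d | new after autoclaving %d\n",
              cts["n_shared"], cts["n_filter_only"], cts["n_autoclave_only"]))
  cat(sprintf("  anti-aging candidates (%.3g < Rf/Ra < %.3g): %d\n",
              th$anti_aging_low, th$anti_aging_high, x$n_anti_aging))
  cat(sprintf("  growth-inhibiting candidates (Rf/Ra > %.3g): %d\n",
              th$inhibitor_ratio, x$n_inhibitor))
  invisible(x)
}

#' @export
summary.stability_screen <- function(object, ...) {
  structure(list(screen = object), class = "summary.stability_screen")
}

#' @export
print.summary.stability_screen <- function(x, ...) {
  s <- x$screen
  print(s)
  if (length(s$superclass_summary)) {
    cat("  shared compounds by superclass:\n")
    for (i in seq_along(s$superclass_summary))
      cat(sprintf("    %-40s %d\n", names(s$superclass_summary)[i],
                  s$superclass_summary[i]))
  }
  rec <- s$records
  if (nrow(rec)) {
    cat("  ratio quartiles:",
        paste(format(stats::quantile(rec$ratio), digits = 3),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.stability_screen <- function(x, ...) x$records

#' Plot a stability screen
#'
#' Scatter of Ra against Rf on log axes, one point per shared compound,
#' with the anti-aging window (between the two inner lines around the
#' diagonal) and the growth-inhibitor cutoff drawn as reference lines.
#'
#' @param x a `stability_screen`.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.stability_screen <- function(x, ...) {
  rec <- x$records
  if (nrow(rec) == 0L) {
    graphics::plot.new()
    graphics::title(main = "No shared compounds")
    return(invisible(x))
  }
  th <- x$thresholds
  col <- c(anti_aging_candidate = "forestgreen",
           growth_inhibiting_candidate = "firebrick",
           unclassified = "grey50")[rec$label]
  graphics::plot(rec$Ra, rec$Rf, log = "xy", col = col, pch = 19,
                 xlab = "Ra (relative abundance, autoclaved)",
                 ylab = "Rf (relative abundance, filter-sterilized)", ...)
  graphics::abline(a = log10(th$anti_aging_low), b = 1, lty = 2,
                   col = "forestgreen", untf = FALSE)
  graphics::abline(a = log10(th$anti_aging_high), b = 1, lty = 2,
                   col = "forestgreen")
  graphics::abline(a = log10(th$inhibitor_ratio), b = 1, lty = 3,
                   col = "firebrick")
  graphics::legend("topleft", bty = "n", pch = 19,
                   col = c("forestgreen", "firebrick", "grey50"),
                   legend = c("anti-aging candidate",
                              "growth-inhibiting candidate",
                              "unclassified"))
  invisible(x)
}
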