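#' Normalize a compound annotation name into a matching key
#'
#' Annotation strings are the only identifier shared between the two
#' treatments' tables, so matching is done on a normalized form: case-folded,
#' trimmed, with internal whitespace runs collapsed to a single space.
#'
#' @param x character vector of raw annotation names.
#' @return character vector of normalized keys (may be empty strings; callers
#'   reject those).
#' @examples
#' compound_key(c("  Muramic   Acid ", "muramic acid"))
#' @export
compound_key <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Describe the column layout of a delimited feature table
#'
#' Annotated feature-table exports differ in header naming; a dialect maps the
#' logical columns this pipeline needs onto the header names actually present.
#' Only `name` and `area` are required; the rest are optional and read as `NA`
#' when unmapped or absent from the header.
#'
#' @param name header of the compound annotation column.
#' @param area header of the peak-area column.
#' @param ion_mode,mz,rt,adduct,superclass optional headers for ionization
#'   mode, m/z, retention time (minutes), adduct, and chemical superclass.
#' @param delim field delimiter, `"tab"` (default) or `"comma"`.
#' @param label short name for this dialect, recorded in provenance.
#' @return an object of class `feature_dialect`.
#' @examples
#' feature_dialect(name = "Metabolite", area = "Area", delim = "comma")
#' @export
feature_dialect <- function(name = "name", area = "area",
                            ion_mode = "ion_mode", mz = "mz", rt = "rt",
                            adduct = "adduct", superclass = "superclass",
                            delim = c("tab", "comma"), label = "default") {
  delim <- match.arg(delim)
  for (f in list(name, area)) {
    if (!is.character(f) || length(f) != 1L || !nzchar(f))
      stop("dialect: 'name' and 'area' must be single non-empty header names")
  }
  structure(
    list(name = name, area = area, ion_mode = ion_mode, mz = mz, rt = rt,
         adduct = adduct, superclass = superclass, delim = delim,
         label = label),
    class = "feature_dialect"
  )
}

# Canonical empty records data.frame; one row per compound.
.empty_records <- function() {
  data.frame(
    compound_key = character(0), raw_name = character(0),
    ion_mode = character(0), area = numeric(0), mz = numeric(0),
    rt = numeric(0), adduct = character(0), superclass = character(0),
    stringsAsFactors = FALSE
  )
}

.normalize_ion_mode <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unspecified", length(x))
  out[grepl("^pos|^\\+|^esi\\+", x)] <- "positive"
  out[grepl("^neg|^-|^esi-", x)] <- "negative"
  out
}

#' Construct a validated feature table from a records data frame
#'
#' Used internally by [read_feature_table()] and by the synthetic generator.
#' Enforces the table invariants: positive areas, non-empty keys, unique keys
#' after deduplication (largest area retained), at least one record.
#'
#' @param records data.frame with at least `compound_key`, `raw_name`,
#'   `ion_mode`, `area`; optional `mz`, `rt`, `adduct`, `superclass`.
#' @param treatment_label label for the treatment this table describes, e.g.
#'   `"filter_sterilized"` or `"autoclaved"`.
#' @param source_path provenance string (file path or `"<in-memory>"`).
#' @param dialect_name provenance string naming the input dialect.
#' @return an object of class `feature_table` with elements `treatment_label`,
#'   `records`, `source_path`, `dialect_name`, `report` (a
#'   `validation_report`).
#' @export
feature_table <- function(records, treatment_label,
                          source_path = "<in-memory>",
                          dialect_name = "in-memory") {
  stopifnot(is.data.frame(records))
  for (col in c("mz", "rt")) if (is.null(records[[col]])) records[[col]] <- NA_real_
  for (col in c("adduct", "superclass"))
    if (is.null(records[[col]])) records[[col]] <- NA_character_
  if (is.null(records$ion_mode)) records$ion_mode <- "unspecified"
  if (is.null(records$raw_name)) records$raw_name <- records$compound_key

  n_read <- nrow(records)
  msgs <- list()
  note <- function(severity, row, text) {
    msgs[[length(msgs) + 1L]] <<- list(severity = severity, row = row, text = text)
  }

  records$compound_key <- compound_key(records$compound_key)
  records$area <- suppressWarnings(as.numeric(records$area))

  bad_name <- !nzchar(records$compound_key) | is.na(records$compound_key)
  bad_area <- is.na(records$area) | !is.finite(records$area) | records$area <= 0
  for (i in which(bad_name)) note("warning", i, "unannotated feature (empty name) rejected")
  for (i in which(bad_area & !bad_name))
    note("warning", i, "non-positive or non-numeric area rejected")
  keep <- !(bad_name | bad_area)
  n_rejected <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  # optional numeric columns: invalid values are blanked, not fatal
  records$mz <- suppressWarnings(as.numeric(records$mz))
  records$mz[!is.na(records$mz) & records$mz <= 0] <- NA_real_
  records$rt <- suppressWarnings(as.numeric(records$rt))
  records$rt[!is.na(records$rt) & records$rt < 0] <- NA_real_
  records$ion_mode <- .normalize_ion_mode(records$ion_mode)
  for (col in c("adduct", "superclass")) {
    v <- trimws(as.character(records[[col]]))
    v[!nzchar(v)] <- NA_character_
    records[[col]] <- v
  }

  # dedup: one record per key, largest area wins (ties: first occurrence)
  if (nrow(records) > 0L) {
    ord <- order(records$compound_key, -records$area)
    records <- records[ord, , drop = FALSE]
    dup <- duplicated(records$compound_key)
    n_dedup <- sum(dup)
    records <- records[!dup, , drop = FALSE]
  } else {
    n_dedup <- 0L
  }
  rownames(records) <- NULL

  if (nrow(records) == 0L)
    stop("feature table '", treatment_label, "' is empty after validation (",
         n_read, " rows read, ", n_rejected, " rejected)")

  report <- structure(
    list(n_rows_read = n_read, n_rejected = n_rejected,
         n_deduplicated = n_dedup, messages = msgs),
    class = "validation_report"
  )
  structure(
    list(treatment_label = treatment_label,
         records = records[, names(.empty_records())],
         source_path = source_path, dialect_name = dialect_name,
         report = report),
    class = "feature_table"
  )
}

#' Read and validate a delimited compound feature table
#'
#' Reads a UTF-8, headered TSV/CSV export of an annotated LC-MS/MS experiment
#' (one row per identified compound), validates it, and deduplicates repeated
#' annotations (e.g. the same compound seen in both ion modes) by keeping the
#' record with the largest peak area. Rows with an empty annotation or a
#' non-positive area are rejected and reported, never silently kept.
#'
#' @param path path to the delimited file.
#' @param dialect a [feature_dialect()] mapping logical columns to headers.
#' @param treatment_label label for this treatment (e.g.
#'   `"filter_sterilized"`).
#' @return a `feature_table`; its `$report` element is the
#'   `validation_report` (rows read / rejected / deduplicated, with
#'   per-row messages).
#' @export
read_feature_table <- function(path, dialect = feature_dialect(),
                               treatment_label) {
  if (!inherits(dialect, "feature_dialect"))
    stop("'dialect' must be created by feature_dialect()")
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- if (dialect$delim == "tab") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                           colClasses = "character")
  for (req in c("name", "area")) {
    if (!(dialect[[req]] %in% names(raw)))
      stop("required column '", dialect[[req]], "' (", req,
           ") absent from header of ", path)
  }
  pull <- function(logical_col) {
    h <- dialect[[logical_col]]
    if (is.null(h) || !(h %in% names(raw))) return(NULL)
    raw[[h]]
  }
  n <- nrow(raw)
  records <- data.frame(
    compound_key = if (n) raw[[dialect$name]] else character(0),
    raw_name = if (n) raw[[dialect$name]] else character(0),
    stringsAsFactors = FALSE
  )
  records$area <- if (n) raw[[dialect$area]] else numeric(0)
  for (col in c("ion_mode", "mz", "rt", "adduct", "superclass")) {
    v <- pull(col)
    if (!is.null(v)) records[[col]] <- v
  }
  feature_table(records, treatment_label = treatment_label,
                source_path = path, dialect_name = dialect$label)
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", x$treatment_label, "\n")
  cat("  compounds:   ", nrow(x$records), "\n")
  cat("  source:      ", x$source_path, " (dialect: ", x$dialect_name, ")\n",
      sep = "")
  r <- x$report
  cat("  validation:  ", r$n_rows_read, "rows read,", r$n_rejected,
      "rejected,", r$n_deduplicated, "deduplicated\n")
  invisible(x)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report:", x$n_rows_read, "rows read,", x$n_rejected,
      "rejected,", x$n_deduplicated, "deduplicated\n")
  for (m in x$messages)
    cat(sprintf("  [%s] row %d: %s\n", m$severity, m$row, m$text))
  invisible(x)
}

#' Write the results of a stability screen to a directory
#'
#' Emits four files: `per_compound.tsv` (key, Rf, Ra, ratio, class,
#' superclass for every shared compound), `partition_summary.tsv` (the five
#' partition counts plus candidate counts), `superclass_summary.tsv`, and
#' `run_metadata.json` (thresholds, input provenance and checksums, package
#' version). Output is staged in a temporary directory and moved into place
#' only on success, so a failed run never leaves a partial output directory.
#'
#' @param result a `stability_screen` object from [stability_screen()].
#' @param out_dir output directory; created if absent.
#' @return invisibly, a named character vector of the files written.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "stability_screen"))
  stage <- tempfile("thermoscreen_out_")
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  tsv <- function(df, name) {
    p <- file.path(stage, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "", fileEncoding = "UTF-8")
    p
  }
  per_compound <- result$records
  per_compound$ratio <- formatC(per_compound$ratio, digits = 15, format = "g")
  per_compound$Rf <- formatC(per_compound$Rf, digits = 15, format = "g")
  per_compound$Ra <- formatC(per_compound$Ra, digits = 15, format = "g")
  tsv(per_compound, "per_compound.tsv")

  cts <- result$counts
  part <- data.frame(
    quantity = c(names(cts), "n_anti_aging", "n_inhibitor"),
    count = c(unname(cts), result$n_anti_aging, result$n_inhibitor),
    stringsAsFactors = FALSE
  )
  tsv(part, "partition_summary.tsv")

  sc <- result$superclass_summary
  tsv(data.frame(superclass = names(sc), count = unname(sc),
                 stringsAsFactors = FALSE),
      "superclass_summary.tsv")

  meta <- list(
    package = "thermoscreen",
    version = as.character(utils::packageVersion("thermoscreen")),
    thresholds = as.list(unclass(result$thresholds)),
    treatments = result$treatment_labels,
    inputs = result$provenance,
    counts = as.list(cts),
    n_anti_aging = result$n_anti_aging,
    n_inhibitor = result$n_inhibitor
  )
  jsonlite::write_json(meta, file.path(stage, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- c("per_compound.tsv", "partition_summary.tsv",
             "superclass_summary.tsv", "run_metadata.json")
  ok <- file.copy(file.path(stage, files), file.path(out_dir, files),
                  overwrite = TRUE)
  if (!all(ok)) stop("could not write results into ", out_dir)
  invisible(stats::setNames(file.path(out_dir, files), files))
}

#' Read back a per-compound results table written by [write_results()]
#'
#' @param path path to a `per_compound.tsv` file.
#' @return data.frame with columns `compound_key`, `Rf`, `Ra`, `ratio`,
#'   `label`, `superclass`.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8",
                          colClasses = c(compound_key = "character",
                                         Rf = "numeric", Ra = "numeric",
                                         ratio = "numeric",
                                         label = "character",
                                         superclass = "character"))
  df$superclass[!nzchar(df$superclass) | is.na(df$superclass)] <- NA_character_
  df
}
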