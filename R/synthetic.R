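#' Ten-superclass default vocabulary for simulated compounds
#'
#' A coarse chemical-taxonomy vocabulary in the style of ClassyFire
#' superclasses, as annotated metabolite tables typically carry.
#' @export
thermoscreen_superclasses <- c(
  "Lipids and lipid-like molecules",
  "Organic acids and derivatives",
  "Organoheterocyclic compounds",
  "Benzenoids",
  "Organic oxygen compounds",
  "Organic nitrogen compounds",
  "Phenylpropanoids and polyketides",
  "Nucleosides, nucleotides, and analogues",
  "Alkaloids and derivatives",
  "Organosulfur compounds"
)

#' Parameters of the paired-table simulator
#'
#' Defines a synthetic filter-sterilized vs autoclaved experiment with four
#' ground-truth compound classes: `stable` (present in both treatments with
#' unchanged intended area), `sensitive` (strongly depleted after
#' autoclaving: the autoclaved intended area is `base_area * retention` with
#' the retention fraction drawn uniformly from
#' `[retention_min, retention_max]`), `degraded` (present only before
#' autoclaving) and `product` (heat-degradation products, present only
#' after). Base areas are log-normal; observed areas carry independent
#' multiplicative log-normal measurement noise per table; observed areas
#' below `detection_threshold` are dropped from that table.
#'
#' The defaults are "paper-shaped": 89 stable + 13 sensitive shared
#' compounds, 368 degraded, 1141 products, mirroring the magnitudes of the
#' screen the simulator emulates. The default retention range 0.02--0.05
#' places sensitive compounds firmly in the >90%-reduction regime.
#'
#' @param n_stable,n_sensitive,n_degraded,n_products class sizes (>= 0, not
#'   all zero).
#' @param area_log_mean,area_log_sd natural-log mean and sd of base peak
#'   areas (arbitrary detector units).
#' @param noise_log_sd sd of multiplicative measurement noise on the natural
#'   log scale (>= 0).
#' @param retention_min,retention_max retention-fraction range in (0, 1] for
#'   sensitive compounds.
#' @param detection_threshold minimum observed area; smaller peaks are
#'   treated as undetected in that table (>= 0).
#' @param seed integer root seed; all randomness flows from it.
#' @param superclass_pool character vector of superclass labels to draw from.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(n_stable = 89, n_sensitive = 13,
                              n_degraded = 368, n_products = 1141,
                              area_log_mean = log(1e6), area_log_sd = 1.0,
                              noise_log_sd = 0.05,
                              retention_min = 0.02, retention_max = 0.05,
                              detection_threshold = 0, seed = 1L,
                              superclass_pool = thermoscreen_superclasses) {
  ns <- c(n_stable, n_sensitive, n_degraded, n_products)
  if (any(ns < 0) || any(ns != round(ns))) stop("class sizes must be non-negative integers")
  if (sum(ns) == 0) stop("at least one compound class must be non-empty")
  if (!(retention_min > 0 && retention_min <= retention_max && retention_max <= 1))
    stop("need 0 < retention_min <= retention_max <= 1")
  if (area_log_sd < 0 || noise_log_sd < 0 || detection_threshold < 0)
    stop("area_log_sd, noise_log_sd and detection_threshold must be >= 0")
  if (!length(superclass_pool)) stop("superclass_pool must be non-empty")
  structure(
    list(n_stable = as.integer(n_stable), n_sensitive = as.integer(n_sensitive),
         n_degraded = as.integer(n_degraded), n_products = as.integer(n_products),
         area_log_mean = area_log_mean, area_log_sd = area_log_sd,
         noise_log_sd = noise_log_sd,
         retention_min = retention_min, retention_max = retention_max,
         detection_threshold = detection_threshold, seed = as.integer(seed),
         superclass_pool = as.character(superclass_pool)),
    class = "simulation_params"
  )
}

# Three reproducible sub-seeds from the root seed: ground truth, filter-table
# noise, autoclave-table noise. Separate streams keep, e.g., filter-table
# noise unchanged when n_products changes.
.sub_seeds <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, 3L)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Draw a ground-truth compound set
#'
#' Deterministic for a fixed seed: base areas log-normal, sensitive-compound
#' retentions uniform in `[retention_min, retention_max]`, superclasses
#' uniform over the pool.
#'
#' @param params a [simulation_params()] object.
#' @return object of class `synthetic_truth`: `params` plus `compounds`, a
#'   data.frame with `compound_key`, `true_class`, `base_area`, `retention`
#'   (`NA` except for sensitive compounds), `superclass`.
#' @export
generate_truth <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  seeds <- .sub_seeds(params$seed)
  classes <- rep(c("stable", "sensitive", "degraded", "product"),
                 times = c(params$n_stable, params$n_sensitive,
                           params$n_degraded, params$n_products))
  n <- length(classes)
  keys <- sprintf("cpd_%s_%04d", classes, stats::ave(seq_len(n), classes, FUN = seq_along))
  compounds <- .with_seed(seeds[1L], {
    base_area <- exp(stats::rnorm(n, params$area_log_mean, params$area_log_sd))
    retention <- rep(NA_real_, n)
    is_sens <- classes == "sensitive"
    retention[is_sens] <- stats::runif(sum(is_sens), params$retention_min,
                                       params$retention_max)
    superclass <- sample(params$superclass_pool, n, replace = TRUE)
    data.frame(compound_key = keys, true_class = classes,
               base_area = base_area, retention = retention,
               superclass = superclass, stringsAsFactors = FALSE)
  })
  structure(list(params = params, compounds = compounds),
            class = "synthetic_truth")
}

#' Render a ground truth into a pair of observed feature tables
#'
#' The filter-sterilized table contains the stable, sensitive and degraded
#' compounds at their base areas; the autoclaved table contains the stable
#' compounds at base area, the sensitive compounds at
#' `base_area * retention`, and the product compounds at base area. Each
#' observed area is the intended area times `exp(N(0, noise_log_sd^2))`,
#' drawn independently per table from that table's own random stream (product
#' compounds are drawn last, so adding products never perturbs the
#' shared compounds' noise). Observed areas below the detection threshold are
#' dropped from that table only — the truth keeps the intended class, so a
#' dropped peak can legitimately move a compound between partition sets.
#'
#' @param truth a `synthetic_truth` from [generate_truth()].
#' @return list with elements `ft_filter` and `ft_autoclave`, both
#'   `feature_table` objects.
#' @export
render_tables <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  p <- truth$params
  seeds <- .sub_seeds(p$seed)
  cmp <- truth$compounds

  build <- function(sel, intended, noise_seed, label) {
    noisy <- .with_seed(noise_seed,
      intended * exp(stats::rnorm(length(intended), 0, p$noise_log_sd)))
    keep <- noisy >= p$detection_threshold & noisy > 0
    if (!any(keep))
      stop("rendered ", label, " table is empty: no compound class ",
           "contributes a detectable peak")
    df <- data.frame(compound_key = cmp$compound_key[sel][keep],
                     raw_name = cmp$compound_key[sel][keep],
                     ion_mode = "unspecified",
                     area = noisy[keep],
                     superclass = cmp$superclass[sel][keep],
                     stringsAsFactors = FALSE)
    if (nrow(df) == 0L)
      stop("rendered ", label, " table is empty: detection threshold ",
           "removed every compound")
    feature_table(df, treatment_label = label,
                  source_path = "<synthetic>", dialect_name = "synthetic")
  }

  # filter side: stable, sensitive, degraded (in that construction order)
  sel_f <- which(cmp$true_class %in% c("stable", "sensitive", "degraded"))
  sel_f <- sel_f[order(match(cmp$true_class[sel_f],
                             c("stable", "sensitive", "degraded")))]
  ft_filter <- build(sel_f, cmp$base_area[sel_f], seeds[2L], "filter_sterilized")

  # autoclave side: stable, sensitive (depleted), products last
  sel_a <- which(cmp$true_class %in% c("stable", "sensitive", "product"))
  sel_a <- sel_a[order(match(cmp$true_class[sel_a],
                             c("stable", "sensitive", "product")))]
  intended_a <- cmp$base_area[sel_a]
  is_sens <- cmp$true_class[sel_a] == "sensitive"
  intended_a[is_sens] <- intended_a[is_sens] * cmp$retention[sel_a][is_sens]
  ft_autoclave <- build(sel_a, intended_a, seeds[3L], "autoclaved")

  list(ft_filter = ft_filter, ft_autoclave = ft_autoclave)
}

#' Score the pipeline's recovery of planted compound classes
#'
#' Cross-tabulates ground-truth classes against pipeline outcomes. A stable
#' compound called `anti_aging_candidate` and a detected sensitive compound
#' called `growth_inhibiting_candidate` are the true positives of the two
#' candidate windows; degraded compounds should land in the filter-only set
#' and products in the autoclave-only set. Sensitivities are computed over
#' compounds of the relevant true class that the screen actually ratioed
#' (i.e. detected in both tables); specificities over ratioed compounds of
#' any other true class.
#'
#' @param result a `stability_screen` produced from tables rendered from
#'   `truth`.
#' @param truth the matching `synthetic_truth`.
#' @return object of class `recovery_summary`: `confusion` (true class x
#'   outcome contingency table), `anti_aging_sensitivity`,
#'   `anti_aging_specificity`, `inhibitor_sensitivity`,
#'   `inhibitor_specificity` (NA where the denominator is empty).
#' @export
evaluate_recovery <- function(result, truth) {
  stopifnot(inherits(result, "stability_screen"),
            inherits(truth, "synthetic_truth"))
  cmp <- truth$compounds
  seen <- c(result$records$compound_key, result$filter_only,
            result$autoclave_only)
  unknown <- setdiff(seen, cmp$compound_key)
  if (length(unknown))
    stop("screen result contains compounds absent from the truth (e.g. '",
         unknown[1L], "'); result and truth do not match")

  outcome <- stats::setNames(rep("undetected", nrow(cmp)), cmp$compound_key)
  outcome[result$filter_only] <- "filter_only"
  outcome[result$autoclave_only] <- "autoclave_only"
  outcome[result$records$compound_key] <- result$records$label

  lvl_out <- c("anti_aging_candidate", "growth_inhibiting_candidate",
               "unclassified", "filter_only", "autoclave_only", "undetected")
  lvl_cls <- c("stable", "sensitive", "degraded", "product")
  confusion <- table(
    true_class = factor(cmp$true_class, levels = lvl_cls),
    outcome = factor(outcome[cmp$compound_key], levels = lvl_out)
  )

  ratioed <- result$records$compound_key
  cls_of <- stats::setNames(cmp$true_class, cmp$compound_key)[ratioed]
  lab <- result$records$label
  sens <- function(cls, call) {
    n <- sum(cls_of == cls)
    if (n == 0L) NA_real_ else sum(cls_of == cls & lab == call) / n
  }
  spec <- function(cls, call) {
    n <- sum(cls_of != cls)
    if (n == 0L) NA_real_ else sum(cls_of != cls & lab != call) / n
  }
  structure(
    list(confusion = confusion,
         anti_aging_sensitivity = sens("stable", "anti_aging_candidate"),
         anti_aging_specificity = spec("stable", "anti_aging_candidate"),
         inhibitor_sensitivity = sens("sensitive", "growth_inhibiting_candidate"),
         inhibitor_specificity = spec("sensitive", "growth_inhibiting_candidate")),
    class = "recovery_summary"
  )
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat("Recovery of planted compound classes\n")
  print(x$confusion)
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat("  anti-aging  sensitivity:", fmt(x$anti_aging_sensitivity),
      " specificity:", fmt(x$anti_aging_specificity), "\n")
  cat("  inhibitor   sensitivity:", fmt(x$inhibitor_sensitivity),
      " specificity:", fmt(x$inhibitor_specificity), "\n")
  invisible(x)
}

#' Write a rendered synthetic experiment to disk
#'
#' Writes the two observed tables in the default tab-separated dialect
#' [read_feature_table()] reads, plus a `truth.tsv` sidecar with the planted
#' classes.
#'
#' @param truth a `synthetic_truth`.
#' @param out_dir output directory, created if absent.
#' @return invisibly, named paths of `filter.tsv`, `autoclave.tsv`,
#'   `truth.tsv`.
#' @export
write_synthetic <- function(truth, out_dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  tabs <- render_tables(truth)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "", fileEncoding = "UTF-8")
    p
  }
  as_out <- function(ft) {
    r <- ft$records
    data.frame(name = r$raw_name, ion_mode = r$ion_mode,
               area = formatC(r$area, digits = 15, format = "g"),
               superclass = r$superclass, stringsAsFactors = FALSE)
  }
  tr <- truth$compounds
  tr$base_area <- formatC(tr$base_area, digits = 15, format = "g")
  tr$retention <- ifelse(is.na(tr$retention), "",
                         formatC(tr$retention, digits = 15, format = "g"))
  invisible(c(
    filter = emit(as_out(tabs$ft_filter), "filter.tsv"),
    autoclave = emit(as_out(tabs$ft_autoclave), "autoclave.tsv"),
    truth = emit(tr, "truth.tsv")
  ))
}

#' Read back a truth sidecar written by [write_synthetic()]
#'
#' @param path path to `truth.tsv`.
#' @param params optional [simulation_params()] to attach; when omitted, a
#'   minimal parameter stub reflecting the class counts is reconstructed.
#' @return a `synthetic_truth`.
#' @export
read_truth <- function(path, params = NULL) {
  if (!file.exists(path)) stop("truth file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("compound_key", "true_class", "base_area", "retention", "superclass")
  if (!all(need %in% names(df)))
    stop("truth file lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$retention <- suppressWarnings(as.numeric(df$retention))
  if (is.null(params)) {
    cnt <- function(cls) sum(df$true_class == cls)
    rmin <- suppressWarnings(min(df$retention, na.rm = TRUE))
    rmax <- suppressWarnings(max(df$retention, na.rm = TRUE))
    if (!is.finite(rmin)) { rmin <- 0.02; rmax <- 0.05 }
    if (nrow(df) == 0L) {
      # a truth sidecar may legitimately be empty; bypass the constructor's
      # not-all-zero check for this read-back stub
      params <- simulation_params(n_stable = 1L)
      params$n_stable <- 0L
    } else {
      params <- simulation_params(n_stable = cnt("stable"),
                                  n_sensitive = cnt("sensitive"),
                                  n_degraded = cnt("degraded"),
                                  n_products = cnt("product"),
                                  retention_min = rmin, retention_max = rmax)
    }
  }
  structure(list(params = params, compounds = df[, need]),
            class = "synthetic_truth")
}
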