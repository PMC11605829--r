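test_that("ground truth is deterministic per seed and sensitive to it", {
  p <- simulation_params(n_stable = 5, n_sensitive = 0, n_degraded = 0,
                         n_products = 0, seed = 42)
  t1 <- generate_truth(p)
  t2 <- generate_truth(p)
  expect_identical(t1$compounds, t2$compounds)
  expect_equal(nrow(t1$compounds), 5L)
  expect_true(all(t1$compounds$true_class == "stable"))
  p2 <- simulation_params(n_stable = 5, n_sensitive = 0, n_degraded = 0,
                          n_products = 0, seed = 43)
  expect_false(any(generate_truth(p2)$compounds$base_area ==
                     t1$compounds$base_area))
})

test_that("class sizes, retention range and superclass pool are honored", {
  p <- simulation_params(n_stable = 7, n_sensitive = 3, n_degraded = 4,
                         n_products = 6, retention_min = 0.05,
                         retention_max = 0.05, seed = 9,
                         superclass_pool = c("X", "Y"))
  tr <- generate_truth(p)
  expect_equal(as.integer(table(tr$compounds$true_class)[c("stable", "sensitive",
                                                           "degraded", "product")]),
               c(7L, 3L, 4L, 6L))
  sens <- tr$compounds[tr$compounds$true_class == "sensitive", ]
  expect_equal(sens$retention, rep(0.05, 3))  # degenerate interval
  expect_true(all(is.na(tr$compounds$retention[
    tr$compounds$true_class != "sensitive"])))
  expect_true(all(tr$compounds$superclass %in% c("X", "Y")))
  expect_error(simulation_params(n_stable = 0, n_sensitive = 0,
                                 n_degraded = 0, n_products = 0),
               "at least one")
})

test_that("noise-free rendering reproduces intended areas and set structure", {
  p <- simulation_params(n_stable = 6, n_sensitive = 2, n_degraded = 4,
                         n_products = 5, noise_log_sd = 0,
                         detection_threshold = 0, seed = 11)
  tr <- generate_truth(p)
  tabs <- render_tables(tr)
  rf <- tabs$ft_filter$records
  ra <- tabs$ft_autoclave$records
  cmp <- tr$compounds
  # filter-table area of every stable compound equals its base area exactly
  stab <- cmp[cmp$true_class == "stable", ]
  expect_equal(rf$area[match(stab$compound_key, rf$compound_key)],
               stab$base_area)
  # sensitive areas in the autoclave table are base * retention exactly
  sens <- cmp[cmp$true_class == "sensitive", ]
  expect_equal(ra$area[match(sens$compound_key, ra$compound_key)],
               sens$base_area * sens$retention)
  # degraded keys appear only pre-autoclave, products only post
  deg <- cmp$compound_key[cmp$true_class == "degraded"]
  expect_true(all(deg %in% rf$compound_key))
  expect_false(any(deg %in% ra$compound_key))
  prod <- cmp$compound_key[cmp$true_class == "product"]
  expect_false(any(prod %in% rf$compound_key))
  expect_true(all(prod %in% ra$compound_key))
})

test_that("with no detection losses, pipeline partition counts equal the design", {
  p <- simulation_params(n_stable = 30, n_sensitive = 5, n_degraded = 12,
                         n_products = 20, noise_log_sd = 0.3,
                         detection_threshold = 0, seed = 21)
  tabs <- render_tables(generate_truth(p))
  cts <- partition_counts(match_compounds(tabs$ft_filter, tabs$ft_autoclave))
  expect_equal(unname(cts), c(35L, 12L, 20L, 47L, 55L))
})

test_that("a detection threshold drops peaks and can move compounds between sets", {
  p0 <- simulation_params(n_stable = 12, n_sensitive = 4, n_degraded = 3,
                          n_products = 3, noise_log_sd = 0,
                          area_log_mean = log(100), area_log_sd = 0.5,
                          retention_min = 0.001, retention_max = 0.002,
                          detection_threshold = 0, seed = 5)
  tr0 <- generate_truth(p0)
  # threshold above every depleted sensitive peak but below every full peak
  full_min <- min(tr0$compounds$base_area)
  p1 <- p0; p1$detection_threshold <- full_min * 0.5
  tr1 <- tr0; tr1$params <- p1
  tabs <- render_tables(tr1)
  sens_keys <- tr0$compounds$compound_key[tr0$compounds$true_class == "sensitive"]
  expect_true(all(sens_keys %in% tabs$ft_filter$records$compound_key))
  expect_false(any(sens_keys %in% tabs$ft_autoclave$records$compound_key))
  # pipeline now sees them as filter-only even though the truth says sensitive
  m <- match_compounds(tabs$ft_filter, tabs$ft_autoclave)
  expect_true(all(sens_keys %in% m$filter_only))
})

test_that("noise-free depleted compound recovers the composition-corrected retention", {
  # one sensitive compound (retention exactly 0.05) among 20 equal-area
  # stable compounds: Rf/Ra must equal (20 + 0.05)/(0.05 * 21), the
  # retention reciprocal corrected for the autoclave table's smaller total
  p <- simulation_params(n_stable = 20, n_sensitive = 1, n_degraded = 0,
                         n_products = 0, area_log_sd = 0, noise_log_sd = 0,
                         retention_min = 0.05, retention_max = 0.05, seed = 3)
  tabs <- render_tables(generate_truth(p))
  scr <- stability_screen(tabs$ft_filter, tabs$ft_autoclave)
  key <- grep("sensitive", scr$records$compound_key, value = TRUE)
  got <- scr$records$ratio[scr$records$compound_key == key]
  expect_equal(got, 20.05 / (0.05 * 21), tolerance = 1e-9)
  # and the independent oracle agrees on every label
  fa <- stats::setNames(tabs$ft_filter$records$area,
                        tabs$ft_filter$records$compound_key)
  aa <- stats::setNames(tabs$ft_autoclave$records$area,
                        tabs$ft_autoclave$records$compound_key)
  orc <- oracle_screen(fa, aa)
  expect_equal(scr$records$label, unname(orc$label[scr$records$compound_key]))
  expect_equal(scr$records$label[scr$records$compound_key == key],
               "growth_inhibiting_candidate")
})

test_that("recovery scoring cross-tabulates planted classes against outcomes", {
  p <- simulation_params(n_stable = 15, n_sensitive = 3, n_degraded = 5,
                         n_products = 8, noise_log_sd = 0,
                         detection_threshold = 0, seed = 31)
  tr <- generate_truth(p)
  tabs <- render_tables(tr)
  scr <- stability_screen(tabs$ft_filter, tabs$ft_autoclave)
  rec <- evaluate_recovery(scr, tr)
  cf <- rec$confusion
  expect_equal(sum(cf), 31)
  expect_equal(unname(cf["degraded", "filter_only"]), 5)
  expect_equal(unname(cf["product", "autoclave_only"]), 8)
  expect_equal(rec$inhibitor_sensitivity, 1)
  expect_equal(rec$anti_aging_sensitivity, 1)
  # mismatched truth is an error
  tr_bad <- tr
  tr_bad$compounds <- tr$compounds[-1, ]
  expect_error(evaluate_recovery(scr, tr_bad), "do not match")
})

test_that("rendered tables and truth sidecar round-trip through disk", {
  p <- simulation_params(n_stable = 8, n_sensitive = 2, n_degraded = 3,
                         n_products = 4, seed = 17)
  tr <- generate_truth(p)
  dir <- tempfile("sim")
  paths <- write_synthetic(tr, dir)
  expect_true(all(file.exists(paths)))
  ftf <- read_feature_table(paths[["filter"]], treatment_label = "filter_sterilized")
  fta <- read_feature_table(paths[["autoclave"]], treatment_label = "autoclaved")
  tabs <- render_tables(tr)
  expect_equal(ftf$records$compound_key, tabs$ft_filter$records$compound_key)
  expect_equal(ftf$records$area, tabs$ft_filter$records$area, tolerance = 1e-12)
  expect_equal(ftf$records$superclass, tabs$ft_filter$records$superclass)
  tr_back <- read_truth(paths[["truth"]])
  expect_equal(tr_back$compounds$compound_key, tr$compounds$compound_key)
  expect_equal(tr_back$compounds$true_class, tr$compounds$true_class)
  expect_equal(tr_back$compounds$base_area, tr$compounds$base_area,
               tolerance = 1e-12)
  # recovery computed from the on-disk artifacts matches the in-memory one
  scr_disk <- stability_screen(ftf, fta)
  rec_disk <- evaluate_recovery(scr_disk, tr_back)
  rec_mem <- evaluate_recovery(stability_screen(tabs$ft_filter, tabs$ft_autoclave), tr)
  expect_equal(rec_disk$confusion, rec_mem$confusion)
})

test_that("a products-only design cannot render a valid filter table", {
  p <- simulation_params(n_stable = 0, n_sensitive = 0, n_degraded = 0,
                         n_products = 4, seed = 1)
  expect_error(render_tables(generate_truth(p)), "empty")
})
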