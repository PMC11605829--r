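# Shared fixture builders: in-memory feature tables and random table pairs.

make_table <- function(areas, treatment_label = "filter_sterilized",
                       superclass = NULL) {
  df <- data.frame(compound_key = names(areas), area = unname(areas),
                   stringsAsFactors = FALSE)
  if (!is.null(superclass)) df$superclass <- superclass
  feature_table(df, treatment_label = treatment_label)
}

# random named area vector with log-normal areas and keys drawn from a pool
random_areas <- function(n, pool_size = max(2L * n, 4L), prefix = "m") {
  keys <- sample(sprintf("%s%03d", prefix, seq_len(pool_size)), n)
  stats::setNames(exp(stats::rnorm(n, log(1e5), 1.5)), keys)
}

random_table_pair <- function(n_f = sample(2:12, 1), n_a = sample(2:12, 1),
                              pool_size = 15L) {
  list(filter = random_areas(n_f, pool_size),
       autoclave = random_areas(n_a, pool_size))
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
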