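# Independent straight-line re-computation of the whole screen, used as the
# oracle for equivalence tests. Deliberately naive: explicit loops, no shared
# code with the package internals.
oracle_screen <- function(filter_areas, autoclave_areas,
                          low = 0.75, high = 1.5, inhibitor = 9) {
  rel_ab <- function(areas) {
    total <- 0
    for (a in areas) total <- total + a
    n <- length(areas)
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- areas[i] / total * n
    names(out) <- names(areas)
    out
  }
  raf <- rel_ab(filter_areas)
  raa <- rel_ab(autoclave_areas)

  shared <- character(0); fonly <- character(0); aonly <- character(0)
  for (k in names(filter_areas)) {
    if (k %in% names(autoclave_areas)) shared <- c(shared, k)
    else fonly <- c(fonly, k)
  }
  for (k in names(autoclave_areas)) {
    if (!(k %in% names(filter_areas))) aonly <- c(aonly, k)
  }
  shared <- sort(shared)

  ratio <- numeric(0); label <- character(0)
  for (k in shared) {
    r <- raf[[k]] / raa[[k]]
    lab <- if (r > low && r < high) {
      "anti_aging_candidate"
    } else if (r > inhibitor) {
      "growth_inhibiting_candidate"
    } else {
      "unclassified"
    }
    ratio[k] <- r
    label[k] <- lab
  }
  list(shared = shared, filter_only = sort(fonly), autoclave_only = sort(aonly),
       ratio = ratio, label = label)
}
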