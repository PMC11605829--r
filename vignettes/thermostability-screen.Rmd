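---
title: "The comparative thermostability screen: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The comparative thermostability screen: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screen

A fermentation medium that is biologically active through its secreted
metabolites can be probed with a simple physical contrast: sterilize one
aliquot by filtration (0.22 µm, heat-labile chemistry intact) and one by
autoclaving (121 °C for 20 min, heat-labile chemistry destroyed), then
annotate both by untargeted LC-MS/MS. If an activity survives autoclaving,
its carriers must be among the compounds whose abundance the heat did not
change; if an activity is lost, its carriers are among the compounds the
heat depleted. `thermoscreen` implements that comparison as a deterministic
pipeline over two annotated feature tables:

1. **Validation and deduplication** (`read_feature_table`). One row per
   identified compound; rows with an empty annotation or a non-positive
   area are rejected and reported. A compound annotated more than once in
   one table — typically once per ion mode, or under several adducts —
   keeps the record with the largest peak area, the conventional
   quantifier peak. Positive- and negative-mode records are pooled into a
   single per-treatment table: each treatment gets one compound list and
   one abundance per compound.
2. **Relative abundance** (`relative_abundance`). For compound $i$ among
   the $N$ compounds of one table, $RA_i = a_i / \sum_j a_j \times N$ —
   area over mean area. The two treatments are separate acquisitions with
   no shared internal standard, so only within-table, scale-free
   quantities are comparable; by construction $\sum_i RA_i = N$ and
   $\overline{RA} = 1$ in every table.
3. **Matching** (`match_compounds`). Compounds are matched across
   treatments by normalized annotation identity only (case-folded,
   trimmed, internal whitespace collapsed). Both tables are annotated
   against the same spectral libraries, so the annotation string is the
   one key both sides share; no m/z–retention-time tolerance matching is
   attempted, deliberately — inventing an alignment procedure would add a
   free parameter the screen does not need. The match partitions
   compounds into *shared*, *filter-only* (heat-degraded) and
   *autoclave-only* (heat-generated products), and the totals obey
   $|shared| + |exclusive| = |table|$ on each side by construction.
4. **Classification** (`stability_screen`). Every shared compound gets the
   ratio $Rf/Ra$ of its two relative abundances. Ratios strictly inside
   $(0.75, 1.5)$ are *anti-aging candidates* (heat-stable); ratios
   strictly above $9$ are *growth-inhibiting candidates* (heat-sensitive).
   Compounds absent from one treatment never receive a ratio — they are
   reported in the exclusive sets, not as infinite ratios. Shared
   compounds are also tallied by their chemical superclass label, with
   unlabeled compounds pooled under `unclassified_superclass`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `anti_aging_low`, `anti_aging_high` | 0.75, 1.5 | open window of "unchanged" ratios (dimensionless) |
| `inhibitor_ratio` | 9 | open lower cutoff for "strongly depleted" (dimensionless) |
| dialect mapping | `name`/`area`/… | header names of the delimited export |

Two conventions deserve comment. First, the windows are **strict open
intervals**: a ratio of exactly 0.75, 1.5 or 9 is unclassified. The
boundary behaviour of such cutoffs is conventionally unstated; implementing
the printed inequalities literally keeps the rule auditable, and the
thresholds are configurable for anyone who wants closed bounds shifted by
an epsilon. Second, the inhibitor cutoff of 9 is the field's operational
rendering of "at least 90 % reduction of relative abundance". Taken
literally, a 90 % reduction means $Ra \le Rf/10$, i.e. a ratio of at
least 10, whereas ratio > 9 corresponds to a reduction of just over
$8/9 \approx 88.9\,\%$ — slightly more permissive. We implement the stated
cutoff of 9 rather than silently "correcting" it; the discrepancy only
affects ratios in $(9, 10]$.

## The synthetic experiment generator

Real inputs for this screen are supplementary tables of a published
experiment; to make every stage testable without a download, the package
ships a generator (`simulation_params`, `generate_truth`, `render_tables`)
that emulates the design with known ground truth. Four planted classes:

* **stable** — present in both treatments at the same intended area;
* **sensitive** — autoclaved intended area is `base_area × retention`,
  with retention drawn uniformly from `[retention_min, retention_max]`
  (defaults 0.02–0.05, i.e. firmly in the > 90 %-reduction regime);
* **degraded** — present only pre-autoclave;
* **product** — present only post-autoclave.

Base areas are log-normal (`area_log_mean = log(1e6)`,
`area_log_sd = 1.0` on the natural-log scale); each observed area is the
intended area times $e^{\mathcal N(0,\sigma^2)}$ with
$\sigma$ = `noise_log_sd` (default 0.05), drawn independently per table;
observed areas below `detection_threshold` are dropped from that table
only, so a lost peak can legitimately move a compound between partition
sets while the truth keeps its intended class. All randomness flows from
one root seed through three sub-streams (truth, filter-table noise,
autoclave-table noise), with product compounds drawn last in the autoclave
stream — enlarging the product set never perturbs the shared compounds'
noise, which keeps cross-parameter comparisons paired.

The default ("study-scaled") design plants 89 stable + 13 sensitive shared
compounds, 368 degraded and 1141 products, matching the magnitudes of the
screening experiment the package emulates: 470 compounds before
autoclaving, 1243 after, 102 shared.

**The composition effect is real and intended.** Because RA renormalizes
within each table, removing ~370 compounds' worth of signal and adding
~1140 products shifts *every* shared compound's ratio by the common factor
$\overline{a}_{autoclave}/\overline{a}_{filter}$, even when its own area
is untouched. "Stable" therefore means stable in *area*, not in RA. With
`area_log_sd = 1.0` the standard deviation of the log of that common
factor is about 0.12 for tables of a few hundred compounds — comfortably
inside the $(\log 0.75, \log 1.5)$ window — which is why that default was
chosen; much wider area distributions would let the composition shift
alone push whole runs outside the stable window. Recovery assertions in
the test suite are made only after an independent brute-force oracle
confirms the labels on the rendered tables, never by assuming the shift is
negligible.

What the generator does **not** emulate: annotation errors (the same
compound named differently in the two tables), retention-time drift, raw
chromatograms or spectra, adduct structure, censoring correlated with
chemistry, replicate-to-replicate biological variance. Passing tests
therefore show that the arithmetic, set logic and thresholds behave as
specified on tables with realistic magnitudes — not that a real experiment's
annotations are reliable.

## Numerical and design choices

* Double precision throughout; normalization identities are asserted to a
  relative tolerance of 1e-9; deduplication ties (identical areas) keep the
  first record in file order.
* Empty tables are hard errors at every stage: a feature table must retain
  at least one record after validation, and matching refuses empty inputs.
  An empty *shared set* is not an error — the screen then reports only the
  exclusive sets and writes a header-only per-compound table.
* `stability_ratio` refuses non-positive inputs: a zero or negative
  relative abundance cannot arise from validated tables, so it signals an
  upstream bug rather than data.
* Output is staged and moved into place only on success, so a failed run
  never leaves a partial output directory; run metadata records
  thresholds, input checksums and the package version, making repeated
  runs byte-identical and auditable.

## Validation problem sizes

The test suite checks the normalization identities on 1000 random tables
(1–60 compounds, log-normal areas spanning several orders of magnitude),
partition conservation and symmetry on 300 random table pairs, full-screen
equivalence against a straight-line brute-force oracle on 150 pairs of at
most 10 compounds each, the study-scaled design at its exact
102/368/1141/470/1243 partition, and class recovery on a 370-compound
preset (100 stable, 20 sensitive, 50 degraded, 200 products) across 20
seeds and noise levels $\sigma \in \{0, 0.1, 0.3, 0.6\}$, where anti-aging
sensitivity is required to be at least 0.95 at $\sigma = 0.05$ and to
degrade monotonically with noise. These sizes give stable means across
seeds while keeping the whole suite near twenty seconds.

## Known limitations

* Identity matching inherits every weakness of the upstream annotation:
  synonyms, isomer collapses, or library differences between runs produce
  spurious exclusive-set members that the screen cannot detect.
* With no replicates there is no within-treatment variance estimate, hence
  no statistical test — the windows are screening heuristics, not
  hypothesis tests, and compounds near a boundary should be treated as
  such.
* A compound can appear "new after autoclaving" either as a true
  degradation product or because it fell below detection in exactly one
  acquisition; the screen cannot distinguish these without raw-signal
  information.
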