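---
title: "Design-based analysis of continuous-survey releases: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based analysis of continuous-survey releases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhaneskit)
```

This vignette records how the package's pieces work and why they are
built the way they are: the transport decoder, the codebook and
manifest parsers, translation and its remediation tools, cross-cycle
assembly, the design-based estimator, and the synthetic study
population that makes all of it testable offline.

## The data family

Continuous NHANES publishes each 2-year cycle as a set of tables, one
respondent per row, keyed by the respondent sequence number `SEQN`.
Every table ships as a SAS transport (XPT) file plus an HTML codebook
describing each variable and, for coded variables, the meaning of each
integer code. Table names encode the cycle (`DEMO`, `DEMO_B`,
`DEMO_C`, ... with the suffix letter's alphabet position k mapping to
the cycle starting `1999 + 2(k−1)`; a `P_` prefix marks the combined
2017–March 2020 pre-pandemic release). The sampling design is
stratified and clustered, with masked pseudo-strata (`SDMVSTRA`),
pseudo-PSUs (`SDMVPSU`) and person-level weights (e.g. the examination
weight `WTMEC2YR`) released for variance estimation.

## Transport decoding

`read_xpt()`/`write_xpt()` implement the version-5 transport layout:
80-byte card-image records, ASCII headers, and numerics in IBM
System/370 hexadecimal floating point, decoded as
`sign × 16^(exponent − 64) × fraction / 2^56`.

Numerical choices worth recording:

* **Exactness.** The IBM fraction has 56 bits against IEEE's 53, and a
  hexadecimal exponent costs at most 3 leading zero bits, so every
  finite double within the representable magnitude range encodes
  exactly; the decoder splits the fraction into 24-bit and 32-bit
  halves so each partial sum is exact in double arithmetic. The test
  suite asserts bit-exact round-trips on 10^4 random draws and
  relative error below 2^−52 across magnitudes 10^−70 to 10^70.
* **Missing sentinels.** A first byte of `0x2E`, `0x41`–`0x5A` or
  `0x5F` with a zero remainder is the missing value `.`, `.A`–`.Z` or
  `._`. These decode to `NA`, with non-`.` codes preserved in a
  per-column `na_code` attribute so writing is lossless. NHANES itself
  uses only `.`.
* **Short numerics** (storage 2–7 bytes) are zero-extended before
  decoding: transport truncates low-order fraction bytes.
* **Character cells** are right-stripped; an all-blank cell stays `""`
  rather than being promoted to `NA`, because missingness in this data
  family is carried by numeric sentinels.
* **Row-count inference.** The observation section has no row count;
  rows are `data bytes / record length`, a non-blank remainder is a
  truncation error naming the byte offset, and trailing all-blank
  records are treated as the 80-byte padding they are. (A genuinely
  all-blank final row of an all-character table would be swallowed by
  this rule; NHANES rows always contain a numeric `SEQN`.)
* Version 8/9 transports (long names) are rejected with a clear error;
  writing uses a fixed header timestamp so fixture output is
  byte-reproducible.

The reader is cross-checked in the tests against an independent XPORT
implementation (`foreign::read.xport`) cell for cell.

## Codebooks and manifests

`parse_codebook()` accepts the modern dialect (one block per variable:
a definition list with Variable Name / SAS Label / English Text /
Target, then a value table headed "Code or Value", "Value
Description", "Count", "Cumulative", optionally "Skip to Item") and a
plain-tables fallback keyed on those headers. Counts are informational,
so they parse leniently: thousands separators are stripped and a
non-numeric cell becomes 0 with a warning. "End of Section" skip
targets are normalized to a single spelling. Blocks that document no
data column (checklist/routing items) are kept with a `doc_only` flag
rather than dropped — they carry skip logic an analyst may want.
Codebooks serialize to a line-oriented key-value cache format chosen so
that parse → write → read is a fixed point (asserted in the tests).

Manifests parse into one record per data file; rows without a usable
data link (withdrawn or limited-access) are excluded from search but
retained in an attribute. The cycle rule above is applied through an
overrides list consulted first, seeded with the known irregular
`_A`-suffixed 1999–2000 tables and user-extensible; a name matching no
rule is a classification error, never a guess.

## Translation and its remediation tools

Raw categorical answers are integers. `translate_table()` replaces
them with the codebook's descriptions as an R factor whose levels
follow the codebook's code-ascending order — preserving ordinal
structure, and preventing the silent blunder of an integer-coded
category entering a regression as a continuous variable. Design
decisions:

* Translation applies only to entries that are genuinely categorical
  (at least two single-code rows that are not "Range of Values" /
  "Missing"). Variables mixing a range with boundary codes — the
  top-coded ones — are left numeric and surfaced by
  `flag_coarsened()` instead, which reports the boundary code and the
  pile-up count (ages at the 80-year ceiling, the income-to-poverty
  ratio at 5).
* Observed codes absent from the codebook become literal numeral
  categories with a warning; the applied maps are stored so
  `untranslate_table()` reconstructs the raw integers exactly (a
  bijection on observed mapped codes, asserted in the tests).
* "Refused"/"Don't know" stay as explicit categories by default
  (information-preserving); `special_as_missing = TRUE` collapses them,
  matching common analyst practice.
* If the same integer were both a range value and a special code, the
  coarsening report simply lists it; the package does not attempt to
  resolve such collisions.

Questionnaire routing produces *structural* missingness: a gate answer
like "No" skips the follow-up entirely. `apply_skip_fill()` fills the
gate-induced missings with an analyst-chosen label, only where the gate
matches and the target is missing, so
`missing_before = missing_after + filled` holds per rule and
non-structural missingness is untouched. Fill-in is an analytic
judgment, so rules are explicit and never auto-applied;
`suggest_skip_rules()` derives candidates from the codebook's Skip-to
links (the variables lying between the gate and its skip target) but
proposes no fill label.

## Assembly

Within a cycle, tables join on `SEQN` only — supporting arbitrary keys
would make misuse easy and buys nothing here. Cross-cycle work goes
through `align_across_cycles()`, which row-stacks selected variables
with a cycle label and returns an alignment report: shared variables,
per-cycle-only variables, and categorical label sets that differ across
cycles (surfaced, never silently unioned, because question wording
changes can change semantics). Mixing a pre-pandemic `P_` release with
regular cycles is an error unless explicitly overridden: its weights
are not cycle-additive, so the guard is hard by design.

## The estimator

`svy_mean()` computes the weighted (Hajek) mean over the analysis
domain and a Taylor-linearized variance from PSU totals within strata
under the with-replacement first-stage approximation (formulas in the
README). Key choices:

* **Domains, not deletions.** `subset_design()` edits a row mask; the
  stratum/PSU census is frozen at `svy_design()` time. Out-of-domain
  rows (and in-domain rows with missing outcome) contribute zero
  scores but keep their PSU in the between-PSU comparison, and `n_h`
  always counts the full design's PSUs. Deleting rows first can
  silently drop a PSU whose members all fall outside the domain, which
  changes the variance; the suite constructs exactly that situation
  and asserts the two differ.
* **Lonely PSUs.** A stratum with one PSU leaves the between-PSU
  variance undefined. The default is a hard error (conservative);
  `"centered"` takes that stratum's deviation about the grand PSU-total
  mean, and `"certainty"` contributes zero variance.
* **Degenerate designs** collapse to textbook answers and are tested
  to tight tolerances: one stratum with singleton PSUs and equal
  weights gives `se = sd/√n` to 1e−12, and estimates are invariant to
  rescaling all weights.
* **Verification.** The variance is compared on ~300-row fixtures
  against an independent term-by-term loop implementation of the same
  linearization (relative 1e−10), and the whole pipeline is validated
  by parameter recovery on the synthetic population (below). Grouped
  estimation (`svy_mean_by()`) is, by definition, one domain estimate
  per category on the full design, with empty categories kept and
  flagged rather than dropped.

Out of scope by design: totals and ratios of two variables, regression,
replicate-weight (BRR/jackknife) variance, quantiles, and multi-cycle
weight rescaling — the latter documented as analyst responsibility.

## The synthetic study population

`population_spec()` fixes the study conditions; its defaults are the
conditions the whole test suite runs under, chosen once to mirror the
emulated survey's structure at desk scale:

* 15 strata (matching the released design's scale of 15 PSUs per
  year), 6 population PSUs per stratum of which 2 are sampled — the
  minimum for an estimable between-PSU variance and the released
  pseudo-design's shape — and 10 persons per sampled PSU: 300
  respondents per sample, 16 200 persons in the population.
* PSU person counts grow linearly across strata (40 + 20(h−1)) while
  the per-PSU sample size is constant, so sampling fractions fall with
  the stratum index; the outcome mean rises with it (gradient 1
  mmHg per stratum step). The unweighted mean is therefore biased low
  by about 2 mmHg by construction — large against the Monte-Carlo
  standard error of a 500-replicate average, so the designed bias is
  unambiguous — while weights are *exact* inverse inclusion
  probabilities, making the weighted estimator unbiased.
* The outcome is a diastolic-pressure-like measurement (mmHg):
  ethnicity-specific baselines around 72–76, a small age slope, a
  male shift, residual SD 11, rounded to whole mmHg. Five ethnicity
  categories with oversampled minority groups, ages top-coded at 80,
  and an income-to-poverty ratio capped at 5 reproduce the coarsening
  patterns the tools must detect. The questionnaire fixture's gate
  answers (Yes/No/Don't know at 30/62/8%) drive the structural
  missingness of its follow-up, with 2% non-structural missingness
  mixed in so fill logic can be told apart from blanket imputation.
* Every generator call seeds and isolates its RNG stream, so artifacts
  are byte-identical across runs and generation never perturbs the
  session's random state.

What the generator deliberately does **not** emulate: the real
four-stage selection, oversampling calibration, post-stratification and
nonresponse adjustment of the weights, pandemic-combined weighting, and
informative (non-MCAR) item missingness. Passing tests therefore
demonstrate correctness of the *estimators and plumbing* under a known
design — not that any real release satisfies those assumptions.

## Problem sizes and reproducibility

The suite runs entirely offline on fixtures of ≤ 2 000 rows; the
parameter-recovery checks use 500 replicate samples of 300 respondents
drawn from the fixed population, comparing the replicate-averaged
weighted mean to the known population mean within 3 Monte-Carlo
standard errors. `scripts/acceptance.R` re-runs the same computations
from scratch for any seed and writes them as JSON.

One test reproduces a published worked example from the real 2017–2018
release (per-ethnicity diastolic means, raw and design-adjusted, for
respondents over 40). It requires the real `DEMO_J`, `BPX_J` and
`P_DEMO` tables — network access or a pre-warmed cache — and fails with
a cache-miss/network error otherwise; the recipe itself
(`reproduce_dbp_example()`) is deterministic once the cache is warm.
Two reporting ambiguities in that example are handled explicitly
rather than silently: the age threshold ("over 40") defaults to strict
`> 40` with an `inclusive` switch, and zero diastolic readings are kept
unless `drop_zero = TRUE`; the function exposes both so either
convention can be recorded.

## Other design notes

* The command-line surface is an exported R dispatcher
  (`nhanes_cli()`) wrapped by a 3-line Rscript, so tests exercise the
  exact code path users run; outputs are stable-ordered and floats
  print at 5 decimals.
* Configuration (cache directory, base URL template, offline switch,
  default design-variable names, log level) lives in
  `nhanes_options()` and a flat `key = value` config file — the base
  locator is configuration, not code, so mirrors or local containers
  substitute cleanly. Offline mode forbids all network I/O; a cache
  miss names the expected path.
* Translated tables serialize to CSV plus a key-value sidecar carrying
  category maps, provenance and the skip-fill log, so round-trips
  preserve categorical typing.

## Known limitations

No automatic harmonization of renamed variables across cycles (renames
are reported, not guessed); no DXA import; no limited-access data
handling; domain means only (no totals/ratios/regression); the
variance uses the with-replacement approximation, slightly conservative
for without-replacement first stages and mildly optimistic in small
simulations with few PSUs per stratum.
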