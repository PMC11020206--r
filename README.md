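# nhaneskit

Tools for working with NHANES-style continuous-survey releases, end to
end and fully offline-testable: decoding the published SAS transport
(XPT) files, parsing the HTML codebooks and manifests that document
them, translating integer-coded answers into labelled categories,
assembling respondent-level tables within and across 2-year cycles, and
producing *design-based* estimates — weighted means with
Taylor-linearized standard errors under the survey's stratified,
clustered, weighted sampling.

## Who it is for, and why the weights matter

Continuous NHANES deliberately oversamples several demographic groups,
so the raw sample mean of any measurement estimates nothing about the
US population. Each respondent *i* carries a sample weight `w_i` (the
number of people they represent), and released pseudo-stratum and
pseudo-PSU identifiers encode the clustering. The estimator at the
package's core is the weighted (Hajek) mean over an analysis domain *D*

```
ŷ = Σ_{i∈D} w_i y_i / Σ_{i∈D} w_i ,      W = Σ_{i∈D} w_i
```

with a first-order Taylor-linearization variance: per-respondent scores
`u_i = w_i (y_i − ŷ) / W` (zero outside the domain or where `y` is
missing) are summed to PSU totals `z_hj`, and

```
Var(ŷ) = Σ_h  n_h/(n_h − 1)  Σ_j (z_hj − z̄_h)² ,
```

where `n_h` counts the PSUs of stratum *h* in the **full** design.
Subpopulations are handled as domains — a mask over rows, never a
deletion — so every stratum and PSU keeps contributing to the variance.
This is why `svy_design()` must be built before any subsetting, and
`subset_design()` afterwards.

A synthetic-data module generates the whole artifact family (XPT files,
codebook HTML, manifests) from a known finite population with exact
inverse-inclusion-probability weights and a deliberately informative
design, so the estimators are validated by parameter recovery without
any network access.

## Worked example

```r
library(nhaneskit)

# a complete synthetic release, installed into the offline cache
cache <- file.path(tempdir(), "readme-cache")
truth <- install_fixtures(cache, population_spec())
nhanes_options(cache_dir = cache, offline = TRUE, log_level = "quiet")

demo <- translate_table(fetch_table("DEMO_J"), fetch_codebook("DEMO_J"))
bpx  <- translate_table(fetch_table("BPX_J"), translated = FALSE)
merged <- merge_within_cycle(demo, bpx, join = "full")

design <- svy_design(merged)            # SDMVSTRA / SDMVPSU / WTMEC2YR defaults
over40 <- subset_design(design, RIDAGEYR > 40)
compare_means(over40, "BPXDI1", "RIDRETH1")
#> # A tibble: 5 × 5
#>   RIDRETH1                         raw_mean adj_mean adj_se n_obs
#>   <chr>                               <dbl>    <dbl>  <dbl> <int>
#> 1 Mexican American                     74.4     77.7   3.10    21
#> 2 Other Hispanic                       74.2     76.3   2.34    24
#> 3 Non-Hispanic White                   75.7     78.6   2.57    60
#> 4 Non-Hispanic Black                   78.2     80.3   1.30    37
#> 5 Other race—including multiracial     83.7     84.2   2.18    32

svy_mean(over40, "BPXDI1")
#> # A tibble: 1 × 4
#>   y      estimate    se n_obs
#> 1 BPXDI1     79.7  1.13   174
```

`raw_mean` is the unweighted group mean on the same domain; `adj_mean`
and `adj_se` are the design-based estimates. The gap between the two
columns is the oversampling correction, and on the synthetic release
the weighted overall mean tracks the generator's known population mean
(`truth$demo$population_mean`, 77.2 mmHg here) while the naive mean is
biased low by construction.

The same computations are available from a shell through the bundled
CLI (`inst/cli/nhanes`), e.g.

```sh
nhanes estimate --table-join DEMO_J,BPX_J --y BPXDI1 --by RIDRETH1 \
  --filter "RIDAGEYR>40" --design strata=SDMVSTRA,psu=SDMVPSU,weight=WTMEC2YR \
  --cache-dir "$CACHE" --offline
```

Beyond estimation, the toolkit covers the practical hazards of this
data family: `apply_skip_fill()` repairs questionnaire skip-pattern
missingness under explicit analyst rules (with `suggest_skip_rules()`
deriving candidates from the codebook's Skip-to links),
`flag_coarsened()` reports top-coded pile-ups (age ceilings, the
income-to-poverty cap), `nhanes_cycle()` decodes the table-name/cycle
conventions including the pre-pandemic `P_` releases, and
`align_across_cycles()` stacks cycles with explicit compatibility
checks instead of silent unions.

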