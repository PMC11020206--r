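#' Reproduce the adjusted vs raw blood-pressure comparison
#'
#' End-to-end recipe for the canonical worked example on the 2017--2018
#' release: merge the demographics table (`DEMO_J`) with the blood
#' pressure examination table (`BPX_J`) on SEQN, restrict to respondents
#' over 40 years of age, and compare the unweighted per-ethnicity means
#' of the first diastolic reading (`BPXDI1`, mmHg) with the design-based
#' means and Taylor-linearized standard errors under the masked
#' pseudo-stratum / pseudo-PSU design and the examination weight.
#'
#' The age restriction is applied as a domain on the full design, never
#' by dropping rows. Whether "over 40" is strict (`> 40`, the default)
#' or inclusive (`>= 40`) is a reporting ambiguity; both are supported so
#' the conventions can be compared. Diastolic readings of zero are kept
#' unless `drop_zero = TRUE`.
#'
#' Requires `DEMO_J.xpt`, `DEMO_J.htm` and `BPX_J.xpt` to be available
#' in the cache (or the network in online mode); with
#' `p_demo_rows = TRUE` it additionally reports the row count of the
#' pre-pandemic demographics table `P_DEMO`.
#'
#' @param age_threshold Age cut in years.
#' @param inclusive Use `>=` instead of `>` at the threshold.
#' @param drop_zero Exclude zero diastolic readings from the domain.
#' @param p_demo_rows Also fetch `P_DEMO` and report its row count.
#' @param cache_dir,offline Overrides for [nhanes_options()].
#' @return A list with `raw` (per-ethnicity unweighted means), `adjusted`
#'   (design-based means and SEs), `combined` (both side by side),
#'   `overall` (the adjusted overall mean) and optionally `p_demo_rows`.
#' @export
reproduce_dbp_example <- function(age_threshold = 40, inclusive = FALSE,
                                  drop_zero = FALSE, p_demo_rows = FALSE,
                                  cache_dir = NULL, offline = NULL) {
  demo_x <- fetch_table("DEMO_J", cache_dir = cache_dir, offline = offline)
  demo_cb <- fetch_codebook("DEMO_J", cache_dir = cache_dir, offline = offline)
  bpx_x <- fetch_table("BPX_J", cache_dir = cache_dir, offline = offline)

  demo <- suppressWarnings(translate_table(demo_x, demo_cb))
  bpx <- suppressWarnings(translate_table(bpx_x, cb = NULL, translated = FALSE))
  merged <- suppressWarnings(merge_within_cycle(demo, bpx, join = "full"))

  design <- svy_design(merged, lonely_psu = "error")
  keep <- if (inclusive) {
    rlang::expr(RIDAGEYR >= !!age_threshold)
  } else {
    rlang::expr(RIDAGEYR > !!age_threshold)
  }
  design <- rlang::inject(subset_design(design, !!keep))
  if (drop_zero) {
    design <- subset_design(design, BPXDI1 > 0)
  }

  raw <- naive_mean_by(design$data[design$domain, , drop = FALSE],
                       "BPXDI1", "RIDRETH1")
  adjusted <- svy_mean_by(design, "BPXDI1", "RIDRETH1")
  combined <- compare_means(design, "BPXDI1", "RIDRETH1")
  out <- list(
    raw = raw,
    adjusted = adjusted,
    combined = combined,
    overall = svy_mean(design, "BPXDI1")
  )
  if (p_demo_rows) {
    out$p_demo_rows <- n_rows(fetch_table("P_DEMO", cache_dir = cache_dir,
                                          offline = offline))
  }
  out
}
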