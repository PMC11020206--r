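#' Specify a synthetic survey population
#'
#' Defines the finite population and two-stage sample design that the
#' fixture generators draw from, so estimators can be validated by
#' parameter recovery against known ground truth. The population is
#' stratified: each of `n_strata` strata holds `psus_per_stratum`
#' population PSUs whose person counts grow linearly with the stratum
#' index (`psu_size_base + psu_size_step * (h - 1)`). A sample selects
#' `psus_sampled` PSUs per stratum and `sampled_per_psu` persons per
#' selected PSU, both by simple random sampling, and each respondent's
#' weight is the exact inverse of the inclusion probability
#' `(psus_sampled / psus_per_stratum) * (sampled_per_psu / N_psu)`.
#'
#' The design is deliberately informative: the continuous outcome (a
#' diastolic-blood-pressure-like measurement, mmHg) rises with the
#' stratum index through `stratum_gradient`, while the sampling fraction
#' falls with it, so the unweighted sample mean is biased low for the
#' population mean by construction and the weighted estimator must
#' correct it. Demographic composition mimics the survey being emulated:
#' five ethnicity categories with oversampled minority groups, two gender
#' categories, ages reported with a top-code, and an income-to-poverty
#' ratio capped at 5.
#'
#' @param n_strata Number of design strata.
#' @param psus_per_stratum Population PSUs per stratum (at least 2).
#' @param psus_sampled PSUs selected per stratum (at least 2, so the
#'   between-PSU variance is estimable).
#' @param sampled_per_psu Persons sampled per selected PSU.
#' @param psu_size_base,psu_size_step Person count of each PSU in stratum
#'   h is `psu_size_base + psu_size_step * (h - 1)`.
#' @param ethnicity_probs Probabilities for the five ethnicity codes
#'   (must sum to 1).
#' @param eth_effects Mean outcome (mmHg) per ethnicity category.
#' @param age_range Integer range of true ages.
#' @param age_top_code Reported ages above this value are recorded as it.
#' @param age_slope Outcome change per year of age (centered at 50).
#' @param male_effect Outcome shift for the male category.
#' @param stratum_gradient Outcome shift per stratum index step from the
#'   middle stratum.
#' @param outcome_sd Residual standard deviation of the outcome.
#' @param outcome_missing_rate Missingness rate of the examination
#'   outcome in generated examination tables (completely at random).
#' @param pir_ceiling Income-to-poverty ratio ceiling.
#' @param pir_missing_rate Missingness rate of the poverty ratio.
#' @param gate_probs Probabilities of Yes / No / Don't know for the
#'   questionnaire gate question.
#' @param followup_yes_prob P(follow-up answered Yes) among gate-Yes.
#' @param followup_missing_rate Non-structural missingness among
#'   gate-Yes respondents.
#' @param seed Base seed; every generator call derives its stream from
#'   it, so fixture output is byte-reproducible.
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_strata = 15L,
                            psus_per_stratum = 6L,
                            psus_sampled = 2L,
                            sampled_per_psu = 10L,
                            psu_size_base = 40L,
                            psu_size_step = 20L,
                            ethnicity_probs = c(0.14, 0.11, 0.34, 0.24, 0.17),
                            eth_effects = c(74, 74.5, 72.5, 75.7, 74.5),
                            age_range = c(18L, 95L),
                            age_top_code = 80L,
                            age_slope = 0.05,
                            male_effect = 1.5,
                            stratum_gradient = 1.0,
                            outcome_sd = 11,
                            outcome_missing_rate = 0.08,
                            pir_ceiling = 5,
                            pir_missing_rate = 0.04,
                            gate_probs = c(0.30, 0.62, 0.08),
                            followup_yes_prob = 0.55,
                            followup_missing_rate = 0.02,
                            seed = 20170L) {
  spec <- list(
    n_strata = as.integer(n_strata),
    psus_per_stratum = as.integer(psus_per_stratum),
    psus_sampled = as.integer(psus_sampled),
    sampled_per_psu = as.integer(sampled_per_psu),
    psu_size_base = as.integer(psu_size_base),
    psu_size_step = as.integer(psu_size_step),
    ethnicity_probs = ethnicity_probs,
    eth_effects = eth_effects,
    age_range = as.integer(age_range),
    age_top_code = as.integer(age_top_code),
    age_slope = age_slope,
    male_effect = male_effect,
    stratum_gradient = stratum_gradient,
    outcome_sd = outcome_sd,
    outcome_missing_rate = outcome_missing_rate,
    pir_ceiling = pir_ceiling,
    pir_missing_rate = pir_missing_rate,
    gate_probs = gate_probs,
    followup_yes_prob = followup_yes_prob,
    followup_missing_rate = followup_missing_rate,
    seed = as.integer(seed)
  )
  if (abs(sum(spec$ethnicity_probs) - 1) > 1e-8 || length(spec$ethnicity_probs) != 5L) {
    stop("ethnicity_probs must be 5 probabilities summing to 1", call. = FALSE)
  }
  if (abs(sum(spec$gate_probs) - 1) > 1e-8 || length(spec$gate_probs) != 3L) {
    stop("gate_probs must be 3 probabilities summing to 1", call. = FALSE)
  }
  if (spec$psus_per_stratum < 2L || spec$psus_sampled < 2L ||
      spec$psus_sampled > spec$psus_per_stratum) {
    stop("need 2 <= psus_sampled <= psus_per_stratum", call. = FALSE)
  }
  if (spec$sampled_per_psu > spec$psu_size_base) {
    stop("infeasible allocation: sampled_per_psu exceeds the smallest PSU",
         call. = FALSE)
  }
  class(spec) <- "population_spec"
  spec
}

#' The five ethnicity labels used by the fixtures
#' @return Character vector of length 5, in code order 1..5.
#' @export
ethnicity_labels <- function() {
  c("Mexican American", "Other Hispanic", "Non-Hispanic White",
    "Non-Hispanic Black", "Other race\u2014including multiracial")
}

with_isolated_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate the synthetic finite population
#'
#' Realizes the population described by a [population_spec()]: one row
#' per person with stratum, PSU, demographics, the reported (top-coded)
#' age, the capped income-to-poverty ratio, and the continuous outcome
#' `Y` (mmHg). Deterministic given `spec$seed`.
#'
#' @param spec A [population_spec()].
#' @return A tibble; its `"truth"` attribute records the population means
#'   the estimators should recover.
#' @export
generate_population <- function(spec = population_spec()) {
  stopifnot(inherits(spec, "population_spec"))
  with_isolated_seed(spec$seed, {
    H <- spec$n_strata
    M <- spec$psus_per_stratum
    sizes <- spec$psu_size_base + spec$psu_size_step * (seq_len(H) - 1L)
    stratum <- rep(seq_len(H), times = sizes * M)
    psu <- unlist(lapply(seq_len(H), function(h) rep(seq_len(M), each = sizes[h])))
    n <- length(stratum)

    gender <- sample(1:2, n, replace = TRUE)
    ethnicity <- sample(1:5, n, replace = TRUE, prob = spec$ethnicity_probs)
    true_age <- sample(spec$age_range[1]:spec$age_range[2], n, replace = TRUE)
    age <- pmin(true_age, spec$age_top_code)
    pir <- pmin(round(stats::rlnorm(n, meanlog = 0.4, sdlog = 0.6), 2),
                spec$pir_ceiling)

    y <- spec$eth_effects[ethnicity] +
      spec$age_slope * (true_age - 50) +
      ifelse(gender == 1L, spec$male_effect, 0) +
      spec$stratum_gradient * (stratum - (H + 1) / 2) +
      stats::rnorm(n, 0, spec$outcome_sd)
    y <- round(y)

    pop <- tibble::tibble(
      person_id = seq_len(n),
      stratum = stratum,
      psu = psu,
      psu_size = sizes[stratum],
      RIAGENDR = as.double(gender),
      RIDRETH1 = as.double(ethnicity),
      RIDAGEYR = as.double(age),
      INDFMPIR = pir,
      Y = y
    )
    eth_means <- tapply(pop$Y, pop$RIDRETH1, mean)
    over40 <- pop$RIDAGEYR > 40
    attr(pop, "truth") <- list(
      n_population = n,
      population_mean = mean(pop$Y),
      population_mean_by_ethnicity = tibble::tibble(
        ethnicity = ethnicity_labels(),
        mean = as.numeric(eth_means)
      ),
      population_mean_over40 = mean(pop$Y[over40]),
      n_over40 = sum(over40)
    )
    pop
  })
}

#' Draw one two-stage sample from the population
#'
#' Selects `psus_sampled` PSUs per stratum and `sampled_per_psu` persons
#' per selected PSU, both by simple random sampling, and attaches the
#' NHANES-style design columns: `SDMVSTRA` (stratum), `SDMVPSU` (PSU
#' number within stratum, 1..m), and `WTMEC2YR`, the exact inverse
#' inclusion probability. No post-stratification or nonresponse
#' adjustment is applied — sufficient for estimator validation.
#'
#' @param population From [generate_population()].
#' @param spec The same [population_spec()].
#' @param seed Seed for this draw (distinct draws give replicate
#'   samples).
#' @return A tibble with one row per respondent, `SEQN` keyed.
#' @export
draw_sample <- function(population, spec = population_spec(), seed = spec$seed + 1L) {
  with_isolated_seed(seed, {
    H <- spec$n_strata
    M <- spec$psus_per_stratum
    m <- spec$psus_sampled
    k <- spec$sampled_per_psu
    picks <- list()
    for (h in seq_len(H)) {
      chosen <- sort(sample(seq_len(M), m))
      for (j in seq_along(chosen)) {
        in_psu <- which(population$stratum == h & population$psu == chosen[j])
        rows <- sort(sample(in_psu, k))
        picks[[length(picks) + 1L]] <- tibble::tibble(
          row = rows,
          SDMVSTRA = h,
          SDMVPSU = j
        )
      }
    }
    sel <- dplyr::bind_rows(picks)
    out <- population[sel$row, , drop = FALSE]
    out$SDMVSTRA <- as.double(sel$SDMVSTRA)
    out$SDMVPSU <- as.double(sel$SDMVPSU)
    out$WTMEC2YR <- (M / m) * (out$psu_size / k)
    out$SEQN <- as.double(100000L + out$person_id)
    out <- dplyr::select(out, "SEQN", "RIAGENDR", "RIDRETH1", "RIDAGEYR",
                         "INDFMPIR", "SDMVSTRA", "SDMVPSU", "WTMEC2YR", "Y")
    attr(out, "truth") <- NULL
    out
  })
}

#' Generate a demographics-style fixture table
#'
#' Produces the full offline stand-in for a demographics table: the XPT
#' transport table (SEQN, gender, ethnicity, top-coded age, capped
#' poverty ratio, and the design columns), the matching NHANES-dialect
#' codebook HTML whose value-code counts are computed from the generated
#' data, and a truth record carrying the population parameters. All
#' artifacts are synthetic and deterministic given `spec$seed`.
#'
#' @param spec A [population_spec()].
#' @param table_name Member name for the generated table.
#' @return A list with elements `xpt` (an [xpt_table()]), `codebook_html`
#'   (a string), `truth` (a list), and `sample` (the drawn sample,
#'   including the latent outcome `Y` used by the examination fixture).
#' @export
generate_demo_like <- function(spec = population_spec(), table_name = "DEMO_J") {
  pop <- generate_population(spec)
  samp <- draw_sample(pop, spec, seed = spec$seed + 1L)
  data <- dplyr::select(samp, -"Y")
  pir_miss <- with_isolated_seed(spec$seed + 2L, {
    stats::runif(nrow(data)) < spec$pir_missing_rate
  })
  data$INDFMPIR[pir_miss] <- NA_real_

  xpt <- xpt_table(
    data,
    member_name = table_name,
    labels = c(
      SEQN = "Respondent sequence number",
      RIAGENDR = "Gender",
      RIDRETH1 = "Race/Hispanic origin",
      RIDAGEYR = "Age in years at screening",
      INDFMPIR = "Ratio of family income to poverty",
      SDMVSTRA = "Masked variance pseudo-stratum",
      SDMVPSU = "Masked variance pseudo-PSU",
      WTMEC2YR = "Full sample 2 year MEC exam weight"
    ),
    member_label = "Demographic Variables and Sample Weights"
  )

  n <- nrow(data)
  eth <- ethnicity_labels()
  entries <- list(
    cb_entry("SEQN", "Respondent sequence number",
             "Respondent sequence number.", "Both males and females 0 YEARS - 150 YEARS",
             NULL),
    cb_entry("RIAGENDR", "Gender", "Gender of the participant.",
             "Both males and females 0 YEARS - 150 YEARS",
             code_rows(data$RIAGENDR, c(`1` = "Male", `2` = "Female"))),
    cb_entry("RIDRETH1", "Race/Hispanic origin",
             "Recode of reported race and Hispanic origin information.",
             "Both males and females 0 YEARS - 150 YEARS",
             code_rows(data$RIDRETH1, stats::setNames(eth, 1:5))),
    cb_entry("RIDAGEYR", "Age in years at screening",
             "Age in years of the participant at the time of screening.",
             "Both males and females 0 YEARS - 150 YEARS",
             range_rows(data$RIDAGEYR,
                        range_label = paste0("0 to ", spec$age_top_code - 1L),
                        top_code = spec$age_top_code,
                        top_label = paste0(spec$age_top_code,
                                           " years of age and over"))),
    cb_entry("INDFMPIR", "Ratio of family income to poverty",
             "A ratio of family income to poverty guidelines.",
             "Both males and females 0 YEARS - 150 YEARS",
             range_rows(data$INDFMPIR,
                        range_label = paste0("0 to ",
                                             format(spec$pir_ceiling - 0.01)),
                        top_code = spec$pir_ceiling,
                        top_label = paste0("Value greater than or equal to ",
                                           format(spec$pir_ceiling), ".00"))),
    cb_entry("SDMVSTRA", "Masked variance pseudo-stratum",
             "Masked variance unit pseudo-stratum.", "Both males and females", NULL),
    cb_entry("SDMVPSU", "Masked variance pseudo-PSU",
             "Masked variance unit pseudo-PSU.", "Both males and females", NULL),
    cb_entry("WTMEC2YR", "Full sample 2 year MEC exam weight",
             "Full sample examination weight.", "Both males and females", NULL)
  )
  html <- build_codebook_html(table_name, entries, n)

  truth <- attr(pop, "truth")
  truth$n_sample <- n
  truth$n_pir_missing <- sum(pir_miss)
  list(xpt = xpt, codebook_html = html, truth = truth, sample = samp)
}

#' Generate an examination-style fixture table
#'
#' A blood-pressure-style companion table carrying the continuous outcome
#' (`BPXDI1`, mmHg) for most of the demographic fixture's respondents:
#' a small fraction of respondents is absent entirely (exam
#' non-participation, which exercises join semantics) and the outcome is
#' missing completely at random at the spec's examination missingness
#' rate.
#'
#' @param spec A [population_spec()].
#' @param demo Result of [generate_demo_like()].
#' @param table_name Member name.
#' @param outcome_var Name of the outcome column.
#' @return A list with `xpt`, `codebook_html` and `truth` (sample-level
#'   outcome accounting).
#' @export
generate_bpx_like <- function(spec = population_spec(), demo,
                              table_name = "BPX_J", outcome_var = "BPXDI1") {
  samp <- demo$sample
  with_isolated_seed(spec$seed + 3L, {
    present <- stats::runif(nrow(samp)) > 0.05
    data <- tibble::tibble(SEQN = samp$SEQN[present])
    y <- samp$Y[present]
    y[stats::runif(length(y)) < spec$outcome_missing_rate] <- NA_real_
    data[[outcome_var]] <- y

    xpt <- xpt_table(
      data,
      member_name = table_name,
      labels = stats::setNames(
        c("Respondent sequence number", "Diastolic: Blood pres (1st rdg) mm Hg"),
        c("SEQN", outcome_var)
      ),
      member_label = "Blood Pressure"
    )
    entries <- list(
      cb_entry("SEQN", "Respondent sequence number", "Respondent sequence number.",
               "Both males and females 0 YEARS - 150 YEARS", NULL),
      cb_entry(outcome_var, "Diastolic: Blood pres (1st rdg) mm Hg",
               "Diastolic: Blood pressure (first reading) mm Hg.",
               "Both males and females 8 YEARS - 150 YEARS",
               pure_range_rows(data[[outcome_var]]))
    )
    html <- build_codebook_html(table_name, entries, nrow(data))
    list(
      xpt = xpt, codebook_html = html,
      truth = list(n_rows = nrow(data), n_outcome_missing = sum(is.na(y)),
                   sample_complete_mean = mean(y, na.rm = TRUE))
    )
  })
}

#' Generate a questionnaire-style fixture with a skip pattern
#'
#' Emulates the gate / follow-up structure of questionnaire routing: a
#' gate question (`BPQ020`, Yes / No / Don't know), a follow-up
#' (`BPQ030`) that is *structurally* missing exactly when the gate answer
#' is No or Don't know (those answers skip to `BPQ056`, and the codebook
#' rows carry the matching Skip-to annotation), plus the next question
#' asked of everyone (`BPQ056`). A small non-structural missingness is
#' mixed into the follow-up so fill-in logic can be told apart from
#' blanket imputation; the truth record separates the two counts.
#'
#' @param spec A [population_spec()].
#' @param demo Result of [generate_demo_like()] supplying the SEQN
#'   universe.
#' @param table_name Member name.
#' @return A list with `xpt`, `codebook_html` and `truth` (structural and
#'   non-structural missing counts).
#' @export
generate_bpq_like <- function(spec = population_spec(), demo, table_name = "BPQ_J") {
  seqn <- demo$sample$SEQN
  with_isolated_seed(spec$seed + 4L, {
    n <- length(seqn)
    gate <- sample(c(1, 2, 9), n, replace = TRUE, prob = spec$gate_probs)
    followup <- rep(NA_real_, n)
    yes <- gate == 1
    followup[yes] <- ifelse(stats::runif(sum(yes)) < spec$followup_yes_prob, 1, 2)
    nonstructural <- yes & stats::runif(n) < spec$followup_missing_rate
    followup[nonstructural] <- NA_real_
    bp_med <- sample(c(1, 2), n, replace = TRUE, prob = c(0.35, 0.65))

    data <- tibble::tibble(SEQN = seqn, BPQ020 = gate, BPQ030 = followup,
                           BPQ056 = bp_med)
    xpt <- xpt_table(
      data,
      member_name = table_name,
      labels = c(
        SEQN = "Respondent sequence number",
        BPQ020 = "Ever told you had high blood pressure",
        BPQ030 = "Told had high blood pressure - 2+ times",
        BPQ056 = "Now taking prescribed medicine for HBP"
      ),
      member_label = "Blood Pressure & Cholesterol"
    )

    gate_rows <- code_rows(gate, c(`1` = "Yes", `2` = "No", `9` = "Don't know"))
    gate_rows$skip_to <- c(NA, "BPQ056", "BPQ056")[match(gate_rows$code, c("1", "2", "9"))]
    gate_rows$skip_to[gate_rows$description == "Missing"] <- NA
    entries <- list(
      cb_entry("SEQN", "Respondent sequence number", "Respondent sequence number.",
               "Both males and females 0 YEARS - 150 YEARS", NULL),
      cb_entry("BPQ020", "Ever told you had high blood pressure",
               "Has a doctor ever told you that you had high blood pressure?",
               "Both males and females 16 YEARS - 150 YEARS", gate_rows),
      cb_entry("BPQ030", "Told had high blood pressure - 2+ times",
               "Were you told on 2 or more different visits that you had high blood pressure?",
               "Both males and females 16 YEARS - 150 YEARS",
               code_rows(followup, c(`1` = "Yes", `2` = "No"))),
      cb_entry("BPQ056", "Now taking prescribed medicine for HBP",
               "Are you now taking prescribed medicine for high blood pressure?",
               "Both males and females 16 YEARS - 150 YEARS",
               code_rows(bp_med, c(`1` = "Yes", `2` = "No")))
    )
    html <- build_codebook_html(table_name, entries, n)
    list(
      xpt = xpt, codebook_html = html,
      truth = list(
        n_rows = n,
        n_structural_missing = sum(gate %in% c(2, 9)),
        n_nonstructural_missing = sum(nonstructural)
      )
    )
  })
}

cb_entry <- function(variable, label, text, target, rows) {
  list(variable = variable, label = label, text = text, target = target,
       rows = rows)
}

code_rows <- function(x, map) {
  counts <- vapply(as.numeric(names(map)), function(cd) sum(!is.na(x) & x == cd),
                   integer(1))
  rows <- tibble::tibble(
    code = names(map), description = unname(map),
    count = counts, skip_to = NA_character_
  )
  rows <- dplyr::bind_rows(rows, tibble::tibble(
    code = ".", description = "Missing", count = sum(is.na(x)),
    skip_to = NA_character_
  ))
  rows$cumulative <- cumsum(rows$count)
  rows
}

range_rows <- function(x, range_label, top_code, top_label) {
  at_top <- sum(!is.na(x) & x == top_code)
  in_range <- sum(!is.na(x)) - at_top
  rows <- tibble::tibble(
    code = c(range_label, format(top_code), "."),
    description = c("Range of Values", top_label, "Missing"),
    count = c(in_range, at_top, sum(is.na(x))),
    skip_to = NA_character_
  )
  rows$cumulative <- cumsum(rows$count)
  rows
}

pure_range_rows <- function(x) {
  ok <- !is.na(x)
  rows <- tibble::tibble(
    code = c(paste0(min(x[ok]), " to ", max(x[ok])), "."),
    description = c("Range of Values", "Missing"),
    count = c(sum(ok), sum(is.na(x))),
    skip_to = NA_character_
  )
  rows$cumulative <- cumsum(rows$count)
  rows
}

build_codebook_html <- function(table_name, entries, n) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  blocks <- vapply(entries, function(e) {
    tab <- ""
    if (!is.null(e$rows) && nrow(e$rows)) {
      body <- paste(vapply(seq_len(nrow(e$rows)), function(i) {
        r <- e$rows[i, ]
        paste0("<tr><td>", esc(r$code), "</td><td>", esc(r$description),
               "</td><td>", r$count, "</td><td>", r$cumulative, "</td><td>",
               if (is.na(r$skip_to)) "" else esc(r$skip_to), "</td></tr>")
      }, character(1)), collapse = "\n")
      tab <- paste0(
        "<table class=\"values\">\n<thead><tr><th>Code or Value</th>",
        "<th>Value Description</th><th>Count</th><th>Cumulative</th>",
        "<th>Skip to Item</th></tr></thead>\n<tbody>\n", body,
        "\n</tbody></table>\n"
      )
    }
    paste0(
      "<div class=\"pagebreak\">\n<h3 id=\"", e$variable, "\">", e$variable,
      " - ", esc(e$label), "</h3>\n<dl>\n",
      "<dt>Variable Name: </dt><dd>", e$variable, "</dd>\n",
      "<dt>SAS Label: </dt><dd>", esc(e$label), "</dd>\n",
      "<dt>English Text: </dt><dd>", esc(e$text), "</dd>\n",
      "<dt>Target: </dt><dd>", esc(e$target), "</dd>\n</dl>\n", tab, "</div>\n"
    )
  }, character(1))
  paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/><title>", table_name,
    " Codebook</title></head>\n<body>\n<h2>Codebook and Frequencies (", n,
    " participants)</h2>\n", paste(blocks, collapse = "\n"), "</body></html>\n"
  )
}

#' Generate a manifest page for fixture tables
#'
#' Emits an HTML manifest in the dialect [parse_manifest()] reads, with
#' one row per table (cycle years from the naming convention, doc and
#' data links, a publication date) and optionally withdrawn rows that
#' exercise the exclusion path.
#'
#' @param table_names Character vector of table names.
#' @param withdrawn Character vector of table names to list as withdrawn
#'   (no data link).
#' @return The manifest HTML as a string.
#' @export
generate_manifest <- function(table_names, withdrawn = character()) {
  row_html <- function(nm, is_withdrawn) {
    cyc <- nhanes_cycle(nm)
    data_cell <- if (is_withdrawn) {
      "Withdrawn"
    } else {
      paste0("<a href=\"", nm, ".XPT\">", nm, " Data [XPT - 0.1 MB]</a>")
    }
    paste0(
      "<tr><td>", cyc$label, "</td><td>", nm, " fixture table</td><td>",
      "<a href=\"", nm, ".htm\">", nm, " Doc</a></td><td>", data_cell,
      "</td><td>September 2023</td></tr>"
    )
  }
  rows <- c(
    vapply(table_names, row_html, character(1), is_withdrawn = FALSE),
    vapply(withdrawn, row_html, character(1), is_withdrawn = TRUE)
  )
  paste0(
    "<!DOCTYPE html>\n<html><head><title>Data File Manifest</title></head><body>\n",
    "<table id=\"GridView1\">\n<thead><tr><th>Years</th><th>Data File Name</th>",
    "<th>Doc File</th><th>Data File</th><th>Date Published</th></tr></thead>\n<tbody>\n",
    paste(rows, collapse = "\n"), "\n</tbody></table>\n</body></html>\n"
  )
}

#' Install a complete fixture set into a cache directory
#'
#' Writes the demographic, examination and questionnaire fixture tables
#' (XPT + codebook HTML), a manifest covering them plus a family of
#' names exercising every cycle-naming rule, and a `truth.json` ground
#' truth record, all into the layout [fetch_table()] reads in offline
#' mode.
#'
#' @param cache_dir Target directory (created if needed).
#' @param spec A [population_spec()].
#' @return The combined truth record, invisibly.
#' @export
install_fixtures <- function(cache_dir, spec = population_spec()) {
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  demo <- generate_demo_like(spec, table_name = "DEMO_J")
  bpx <- generate_bpx_like(spec, demo, table_name = "BPX_J")
  bpq <- generate_bpq_like(spec, demo, table_name = "BPQ_J")
  for (gen in list(demo = demo, bpx = bpx, bpq = bpq)) {
    nm <- gen$xpt$member_name
    write_xpt(gen$xpt, file.path(cache_dir, paste0(nm, ".xpt")))
    writeLines(gen$codebook_html, file.path(cache_dir, paste0(nm, ".htm")),
               useBytes = TRUE)
  }
  manifest_html <- generate_manifest(
    c("DEMO", "DEMO_B", "DEMO_C", "P_DEMO", "SSAFB_A", "DEMO_J", "BPX_J", "BPQ_J"),
    withdrawn = "SSOL_A"
  )
  writeLines(manifest_html, file.path(cache_dir, "manifest.htm"), useBytes = TRUE)
  truth <- list(demo = demo$truth, bpx = bpx$truth, bpq = bpq$truth)
  jsonlite::write_json(truth, file.path(cache_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}
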