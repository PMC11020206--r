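test_that("integer codes become the codebook's labels, in code order", {
  tr <- fx_translated_demo()
  raw <- fx_demo()$xpt$data
  expect_s3_class(tr$RIAGENDR, "factor")
  expect_identical(levels(tr$RIAGENDR), c("Male", "Female"))
  expect_identical(levels(tr$RIDRETH1), ethnicity_labels())
  # row-wise agreement with the raw codes
  expect_identical(as.character(tr$RIAGENDR),
                   c("Male", "Female")[raw$RIAGENDR])
  expect_identical(as.character(tr$RIDRETH1),
                   ethnicity_labels()[raw$RIDRETH1])
  # untranslatable numerics pass through untouched
  expect_identical(tr$RIDAGEYR, raw$RIDAGEYR)
  expect_identical(tr$WTMEC2YR, raw$WTMEC2YR)
})

test_that("translated = FALSE is the identity on values", {
  raw <- fx_demo()$xpt
  tr <- suppressWarnings(translate_table(raw, fx_demo_cb(), translated = FALSE))
  expect_identical(names(tr), names(raw$data))
  for (col in names(raw$data)) expect_identical(tr[[col]], raw$data[[col]])
  expect_false(attr(tr, "translated"))
})

test_that("translation is lossless: stored maps reconstruct the raw codes exactly", {
  tr <- fx_translated_demo()
  raw <- fx_demo()$xpt$data
  back <- untranslate_table(tr)
  expect_identical(back$RIAGENDR, raw$RIAGENDR)
  expect_identical(back$RIDRETH1, raw$RIDRETH1)
})

test_that("codes missing from the codebook become literal categories with a warning", {
  demo <- fx_demo()
  broken <- demo$xpt
  broken$data$RIAGENDR[5] <- 3
  tr <- NULL
  warns <- character()
  withCallingHandlers(
    tr <- translate_table(broken, fx_demo_cb()),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  expect_true(any(grepl("RIAGENDR.*not in the codebook", warns)))
  expect_identical(levels(tr$RIAGENDR), c("Male", "Female", "3"))
  expect_identical(as.character(tr$RIAGENDR[5]), "3")
})

test_that("special answers collapse to missing only on request", {
  bpq <- fx_bpq()
  tr <- suppressWarnings(translate_table(bpq$xpt, fx_bpq_cb()))
  expect_true("Don't know" %in% levels(tr$BPQ020))
  trm <- suppressWarnings(translate_table(bpq$xpt, fx_bpq_cb(),
                                          special_as_missing = TRUE))
  expect_false("Don't know" %in% levels(trm$BPQ020))
  dk <- bpq$xpt$data$BPQ020 == 9
  expect_true(all(is.na(trm$BPQ020[dk])))
  expect_identical(sum(is.na(trm$BPQ020)) - sum(is.na(tr$BPQ020)), sum(dk))
})

test_that("tables without SEQN or with duplicate SEQN are rejected", {
  no_key <- xpt_table(data.frame(X = c(1, 2)), "NOKEY")
  expect_error(translate_table(no_key, NULL), "SEQN")
  dup <- xpt_table(data.frame(SEQN = c(1, 1)), "DUPKEY")
  expect_error(translate_table(dup, NULL), "duplicate SEQN")
})

test_that("skip-fill fills exactly the gate-induced missings and conserves cells", {
  bpq <- fx_bpq()
  truth <- bpq$truth
  tr <- suppressWarnings(translate_table(bpq$xpt, fx_bpq_cb()))
  n_missing_before <- sum(is.na(tr$BPQ030))
  expect_identical(n_missing_before,
                   truth$n_structural_missing + truth$n_nonstructural_missing)

  rule <- list(list(gate = "BPQ020", gate_values = c("No", "Don't know"),
                    target = "BPQ030", fill = "No"))
  filled <- apply_skip_fill(tr, rule)
  log <- attr(filled, "fill_log")
  expect_identical(log$n_filled, truth$n_structural_missing)
  # conservation: missings before = missings after + filled
  expect_identical(n_missing_before,
                   sum(is.na(filled$BPQ030)) + log$n_filled)
  # non-structural missing (gate = Yes) untouched
  expect_identical(sum(is.na(filled$BPQ030)), truth$n_nonstructural_missing)
  expect_true(all(is.na(filled$BPQ030[tr$BPQ020 == "Yes" & is.na(tr$BPQ030)])))
  # non-missing cells never modified
  keep <- !is.na(tr$BPQ030)
  expect_identical(filled$BPQ030[keep], tr$BPQ030[keep])
})

test_that("a rule whose gate values never occur fills nothing", {
  bpq <- fx_bpq()
  tr <- suppressWarnings(translate_table(bpq$xpt, fx_bpq_cb()))
  # restrict to gate-Yes rows only, where nothing is skip-induced
  rule <- list(list(gate = "BPQ056", gate_values = "NEVER-AN-ANSWER",
                    target = "BPQ030", fill = "No"))
  filled <- apply_skip_fill(tr, rule)
  expect_identical(attr(filled, "fill_log")$n_filled, 0L)
  expect_identical(filled$BPQ030, tr$BPQ030)
})

test_that("fill labels must be existing categories of the target", {
  bpq <- fx_bpq()
  tr <- suppressWarnings(translate_table(bpq$xpt, fx_bpq_cb()))
  expect_error(
    apply_skip_fill(tr, list(list(gate = "BPQ020", gate_values = "No",
                                  target = "BPQ030", fill = "Banana"))),
    "not a category"
  )
})

test_that("suggested rules identify the skipped variable from the codebook links", {
  sug <- suggest_skip_rules(fx_bpq_cb())
  expect_identical(sug$gate, "BPQ020")
  expect_identical(sug$target, "BPQ030")
  expect_setequal(sug$gate_values[[1]], c("No", "Don't know"))
  expect_identical(sug$skip_to, "BPQ056")
})

test_that("top-coded variables are reported with their pile-up counts", {
  tr <- fx_translated_demo()
  cb <- fx_demo_cb()
  spec <- fx_spec()
  rep <- flag_coarsened(tr, cb)
  age <- rep[rep$variable == "RIDAGEYR", ]
  expect_identical(age$code, 80)
  expect_identical(age$n, sum(tr$RIDAGEYR == spec$age_top_code, na.rm = TRUE))
  pir <- rep[rep$variable == "INDFMPIR", ]
  expect_identical(pir$code, 5)
  expect_identical(pir$n, sum(tr$INDFMPIR == 5, na.rm = TRUE))
  # a pure-range variable is not reported
  bpx <- fx_bpx()
  bcb <- parse_codebook(bpx$codebook_html, table_name = "BPX_J")
  braw <- suppressWarnings(translate_table(bpx$xpt, bcb, translated = FALSE))
  expect_identical(nrow(flag_coarsened(braw, bcb)), 0L)
})

test_that("CSV + sidecar serialization round-trips categorical typing and provenance", {
  bpq <- fx_bpq()
  tr <- suppressWarnings(translate_table(bpq$xpt, fx_bpq_cb()))
  tr <- apply_skip_fill(tr, list(list(gate = "BPQ020",
                                      gate_values = c("No", "Don't know"),
                                      target = "BPQ030", fill = "No")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_data_table(tr, path)
  back <- read_data_table(path)
  expect_identical(levels(back$BPQ030), levels(tr$BPQ030))
  expect_identical(as.character(back$BPQ020), as.character(tr$BPQ020))
  expect_identical(attr(back, "nhanes_name"), attr(tr, "nhanes_name"))
  expect_identical(attr(back, "cycle")$label, attr(tr, "cycle")$label)
  expect_identical(attr(back, "fill_log")$n_filled,
                   attr(tr, "fill_log")$n_filled)
})
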