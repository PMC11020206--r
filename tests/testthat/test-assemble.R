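test_that("within-cycle joins on SEQN have the expected row sets", {
  demo <- fx_translated_demo()
  bpx <- fx_bpx()
  bcb <- parse_codebook(fx_bpx()$codebook_html, table_name = "BPX_J")
  bp <- suppressWarnings(translate_table(bpx$xpt, bcb, translated = FALSE))

  full <- merge_within_cycle(demo, bp, join = "full")
  expect_identical(nrow(full), length(union(demo$SEQN, bp$SEQN)))
  inner <- merge_within_cycle(demo, bp, join = "inner")
  expect_identical(nrow(inner), length(intersect(demo$SEQN, bp$SEQN)))
  left <- merge_within_cycle(demo, bp, join = "left")
  expect_identical(sort(left$SEQN), sort(demo$SEQN))
  # left join fills right-only columns with NA for unmatched respondents
  unmatched <- setdiff(demo$SEQN, bp$SEQN)
  expect_true(all(is.na(left$BPXDI1[left$SEQN %in% unmatched])))
  # factors survive the merge
  expect_s3_class(full$RIDRETH1, "factor")
})

test_that("joining disjoint SEQN sets yields zero inner rows", {
  a <- suppressWarnings(translate_table(
    xpt_table(data.frame(SEQN = c(1, 2), X = c(10, 20)), "TAB_J"), NULL,
    translated = FALSE))
  b <- suppressWarnings(translate_table(
    xpt_table(data.frame(SEQN = c(3, 4), Z = c(1, 2)), "TBB_J"), NULL,
    translated = FALSE))
  expect_identical(nrow(merge_within_cycle(a, b, join = "inner")), 0L)
  expect_identical(nrow(merge_within_cycle(a, b, join = "full")), 4L)
})

test_that("cross-cycle merging is refused and redirected", {
  demo_j <- fx_translated_demo()
  demo_c <- suppressWarnings(translate_table(
    generate_demo_like(population_spec(seed = 11L), table_name = "DEMO_C")$xpt,
    NULL, translated = FALSE))
  expect_error(merge_within_cycle(demo_j, demo_c), "align_across_cycles")
})

test_that("overlapping non-key variables are suffixed with a warning", {
  a <- suppressWarnings(translate_table(
    xpt_table(data.frame(SEQN = c(1, 2), X = c(10, 20)), "TAB_J"), NULL,
    translated = FALSE))
  b <- suppressWarnings(translate_table(
    xpt_table(data.frame(SEQN = c(1, 2), X = c(30, 40)), "TBB_J"), NULL,
    translated = FALSE))
  expect_warning(m <- merge_within_cycle(a, b), "renamed")
  expect_setequal(setdiff(names(m), "SEQN"), c("X.TAB_J", "X.TBB_J"))
})

test_that("stacking across cycles conserves rows and labels each cycle", {
  specs <- list(population_spec(seed = 21L), population_spec(seed = 22L),
                population_spec(seed = 23L))
  names3 <- c("DEMO", "DEMO_B", "DEMO_C")
  tabs <- purrr::map2(specs, names3, function(sp, nm) {
    g <- generate_demo_like(sp, table_name = nm)
    suppressWarnings(translate_table(g$xpt, parse_codebook(g$codebook_html,
                                                           table_name = nm)))
  })
  res <- align_across_cycles(tabs, variables = c("RIAGENDR", "RIDAGEYR"))
  expect_identical(nrow(res$data), sum(purrr::map_int(tabs, nrow)))
  expect_setequal(unique(res$data$cycle),
                  c("1999-2000", "2001-2002", "2003-2004"))
  expect_identical(res$report$shared_variables, c("RIAGENDR", "RIDAGEYR"))

  # order invariance: permuting inputs only permutes the cycle blocks
  res2 <- align_across_cycles(tabs[c(3, 1, 2)],
                              variables = c("RIAGENDR", "RIDAGEYR"))
  sorted1 <- dplyr::arrange(res$data, .data$cycle, .data$SEQN)
  sorted2 <- dplyr::arrange(res2$data, .data$cycle, .data$SEQN)
  expect_equal(as.data.frame(sorted1), as.data.frame(sorted2))
})

test_that("variables absent from a cycle are NA-filled, or an error under strict", {
  a <- suppressWarnings(translate_table(
    xpt_table(data.frame(SEQN = c(1, 2), X = c(10, 20)), "TAB"), NULL,
    translated = FALSE))
  b <- suppressWarnings(translate_table(
    xpt_table(data.frame(SEQN = c(3, 4)), "TAB_B"), NULL, translated = FALSE))
  res <- align_across_cycles(list(a, b), variables = "X")
  expect_true(all(is.na(res$data$X[res$data$cycle == "2001-2002"])))
  expect_identical(res$report$per_cycle_only[["1999-2000"]], "X")
  expect_error(align_across_cycles(list(a, b), variables = "X", strict = TRUE),
               "2001-2002")
})

test_that("pre-pandemic releases do not silently mix with regular cycles", {
  demo_j <- fx_translated_demo()
  p_demo <- suppressWarnings(translate_table(
    generate_demo_like(population_spec(seed = 31L), table_name = "P_DEMO")$xpt,
    NULL, translated = FALSE))
  expect_error(align_across_cycles(list(p_demo, demo_j)), "allow_prepandemic")
  res <- align_across_cycles(list(p_demo, demo_j), variables = "RIDAGEYR",
                             allow_prepandemic = TRUE)
  expect_setequal(unique(res$data$cycle), c("2017-March 2020", "2017-2018"))
})

test_that("category mismatches across cycles are surfaced, not unioned silently", {
  a <- suppressWarnings(translate_table(
    xpt_table(data.frame(SEQN = c(1, 2), G = c(1, 2)), "TAB"), NULL,
    translated = FALSE))
  b <- suppressWarnings(translate_table(
    xpt_table(data.frame(SEQN = c(3, 4), G = c(1, 2)), "TAB_B"), NULL,
    translated = FALSE))
  a$G <- factor(c("Yes", "No"), levels = c("Yes", "No"))
  b$G <- factor(c("Yes", "Sometimes"), levels = c("Yes", "Sometimes", "No"))
  expect_warning(res <- align_across_cycles(list(a, b), variables = "G"),
                 "label sets differ")
  expect_true("G" %in% names(res$report$category_mismatch))
})

test_that("duplicate cycles and duplicate SEQN are structural errors", {
  demo_j <- fx_translated_demo()
  expect_error(align_across_cycles(list(demo_j, demo_j)), "distinct cycles")
  dup <- demo_j
  dup$SEQN[2] <- dup$SEQN[1]
  expect_error(merge_within_cycle(dup, demo_j), "duplicate SEQN")
})
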