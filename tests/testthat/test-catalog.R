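test_that("table-name suffixes map to cycles by the alphabet rule", {
  expect_identical(nhanes_cycle("DEMO_B")$label, "2001-2002")
  expect_identical(nhanes_cycle("DEMO_C")$label, "2003-2004")
  expect_identical(nhanes_cycle("DEMO")$label, "1999-2000")
  expect_identical(nhanes_cycle("BPX_J")$label, "2017-2018")
  expect_identical(nhanes_cycle("BPQ_D")$label, "2005-2006")
  expect_identical(nhanes_cycle("SSAFB_A")$label, "1999-2000")
  p <- nhanes_cycle("P_DEMO")
  expect_true(p$prepandemic)
  expect_identical(p$start_year, 2017L)
  expect_identical(p$end_year, 2020L)
  expect_identical(p$label, "2017-March 2020")
})

test_that("unclassifiable names raise instead of guessing, and overrides win", {
  expect_error(nhanes_cycle("demo-x?"), "cannot classify")
  expect_error(nhanes_cycle("DEMO_B2"), "cannot classify")
  ov <- c(cycle_overrides(), list(WEIRD_B = 2017L))
  expect_identical(nhanes_cycle("WEIRD_B", overrides = ov)$start_year, 2017L)
})

test_that("generated manifests parse back to one record per table with matching cycles", {
  names6 <- c("DEMO", "DEMO_B", "DEMO_C", "P_DEMO", "BPX_J", "BPQ_D")
  man <- parse_manifest(generate_manifest(names6))
  expect_setequal(man$table_name, names6)
  expect_identical(nrow(man), 6L)
  for (i in seq_len(nrow(man))) {
    cyc <- nhanes_cycle(man$table_name[i])
    expect_identical(man$start_year[i], cyc$start_year)
    expect_identical(man$years[i], cyc$label)
  }
})

test_that("withdrawn rows are excluded from the records but kept in the attribute", {
  suppressMessages(
    man <- parse_manifest(generate_manifest(c("DEMO", "BPX_J"), withdrawn = "SSOL_A"))
  )
  expect_setequal(man$table_name, c("DEMO", "BPX_J"))
  excluded <- attr(man, "excluded")
  expect_identical(excluded$table_name, "SSOL_A")
  expect_true(excluded$withdrawn)
})

test_that("duplicate manifest rows are an error naming the duplicate", {
  html <- generate_manifest(c("DEMO", "BPX_J"))
  dup <- sub("</tbody>",
             paste0("<tr><td>1999-2000</td><td>again</td>",
                    "<td><a href=\"DEMO.htm\">DEMO Doc</a></td>",
                    "<td><a href=\"DEMO.XPT\">DEMO Data</a></td>",
                    "<td>May 2020</td></tr></tbody>"),
             html, fixed = TRUE)
  expect_error(parse_manifest(dup), "DEMO")
})

test_that("table-name search is case-insensitive substring with an opt-in regex mode", {
  man <- parse_manifest(generate_manifest(
    c("DEMO", "DEMO_B", "DEMO_C", "P_DEMO", "BPX_J", "BPQ_D")))
  expect_setequal(search_table_names(man, "DEMO"),
                  c("DEMO", "DEMO_B", "DEMO_C", "P_DEMO"))
  expect_identical(search_table_names(man, "demo_b"), "DEMO_B")
  expect_identical(search_table_names(man, "^BPX", regex = TRUE), "BPX_J")
  expect_identical(search_table_names(man, "ZZZ"), character(0))
  det <- search_table_names(man, "^BPX", regex = TRUE, details = TRUE)
  expect_identical(det$years, "2017-2018")
  # purity: repeated identical calls give identical ordered output
  expect_identical(search_table_names(man, "DEMO"), search_table_names(man, "DEMO"))
})

test_that("the variable index supports description, name and component search", {
  cbs <- list(fx_demo_cb(), fx_bpq_cb())
  man <- parse_manifest(generate_manifest(c("DEMO_J", "BPQ_J")))
  index <- build_variable_index(cbs, man)
  expect_true(all(c("RIAGENDR", "BPQ020") %in% index$variable))

  hits <- search_variables(index, "blood pressure")
  expect_setequal(unique(hits$table_name), "BPQ_J")
  none <- search_variables(index, "blood pressure", component = "examination")
  expect_identical(nrow(none), 0L)
  byname <- search_variables(index, "RIDRETH", fields = "variable")
  expect_identical(byname$variable, "RIDRETH1")
  expect_identical(nrow(search_variables(index[0, ], "anything")), 0L)
})

test_that("tables containing a variable are found exactly and ordered by cycle", {
  cbs <- list(fx_demo_cb(), fx_bpq_cb())
  index <- build_variable_index(cbs)
  both <- search_tables_by_variable(index, "seqn")
  expect_setequal(both$table_name, c("DEMO_J", "BPQ_J"))
  expect_identical(search_tables_by_variable(index, "BPQ030")$table_name, "BPQ_J")
  expect_identical(nrow(search_tables_by_variable(index, "NOPE")), 0L)
})

test_that("fetch_table serves from cache, errors on offline miss, and is idempotent warm", {
  cache <- withr::local_tempdir()
  demo <- fx_demo()
  write_xpt(demo$xpt, file.path(cache, "DEMO_J.xpt"))

  tab <- fetch_table("DEMO_J", cache_dir = cache, offline = TRUE)
  expect_identical(tab$member_name, "DEMO_J")
  expect_error(fetch_table("BPX_J", cache_dir = cache, offline = TRUE),
               "cache miss.*BPX_J.xpt")

  # warm cache: second call must not touch the file
  before <- file.mtime(file.path(cache, "DEMO_J.xpt"))
  tab2 <- fetch_table("DEMO_J", cache_dir = cache, offline = TRUE)
  expect_identical(file.mtime(file.path(cache, "DEMO_J.xpt")), before)
  expect_identical(as.data.frame(tab2$data), as.data.frame(tab$data))
})

test_that("options are validated and restorable", {
  old <- nhanes_options(offline = TRUE)
  withr::defer(do.call(nhanes_options, old))
  expect_true(nhanes_options()$offline)
  expect_error(nhanes_options(bogus_key = 1), "unknown option")
  expect_error(nhanes_options(TRUE), "named")
})
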