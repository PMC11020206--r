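# Shared fixture set, generated once per test run (deterministic: the
# spec's seed fixes every artifact).
fixture_cache <- new.env(parent = emptyenv())

fx_spec <- function() population_spec()

fx_demo <- function() {
  if (is.null(fixture_cache$demo)) {
    fixture_cache$demo <- generate_demo_like(fx_spec())
  }
  fixture_cache$demo
}

fx_demo_cb <- function() {
  if (is.null(fixture_cache$demo_cb)) {
    fixture_cache$demo_cb <- parse_codebook(fx_demo()$codebook_html,
                                            table_name = "DEMO_J")
  }
  fixture_cache$demo_cb
}

fx_bpx <- function() {
  if (is.null(fixture_cache$bpx)) {
    fixture_cache$bpx <- generate_bpx_like(fx_spec(), fx_demo())
  }
  fixture_cache$bpx
}

fx_bpq <- function() {
  if (is.null(fixture_cache$bpq)) {
    fixture_cache$bpq <- generate_bpq_like(fx_spec(), fx_demo())
  }
  fixture_cache$bpq
}

fx_bpq_cb <- function() {
  if (is.null(fixture_cache$bpq_cb)) {
    fixture_cache$bpq_cb <- parse_codebook(fx_bpq()$codebook_html,
                                           table_name = "BPQ_J")
  }
  fixture_cache$bpq_cb
}

fx_population <- function() {
  if (is.null(fixture_cache$population)) {
    fixture_cache$population <- generate_population(fx_spec())
  }
  fixture_cache$population
}

# A translated demographic table (warnings about design columns lacking
# codebook entries are irrelevant here).
fx_translated_demo <- function() {
  suppressWarnings(translate_table(fx_demo()$xpt, fx_demo_cb()))
}

# Compare two xpt_table objects field by field.
expect_same_xpt <- function(a, b) {
  expect_identical(a$member_name, b$member_name)
  expect_identical(a$member_label, b$member_label)
  expect_identical(a$variables, b$variables)
  expect_identical(a$created, b$created)
  expect_equal(as.data.frame(a$data), as.data.frame(b$data))
  for (col in names(a$data)) {
    expect_identical(attr(a$data[[col]], "na_code"), attr(b$data[[col]], "na_code"))
  }
}
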