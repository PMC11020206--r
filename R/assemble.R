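#' Merge two tables from the same cycle on SEQN
#'
#' Within a cycle every table describes the same respondents, so tables
#' join on the respondent sequence number (SEQN) — the only join key this
#' toolkit supports, by design, to keep accidental many-to-many joins
#' hard. Tables from different cycles never share respondents; attempting
#' to join them is an error directing you to [align_across_cycles()].
#'
#' Overlapping non-key variable names are disambiguated by suffixing with
#' the source table names, with a warning.
#'
#' @param left,right Translated tables (from [translate_table()]) with
#'   cycle provenance.
#' @param join Join type: `"full"` (default; all respondents from either
#'   table), `"inner"` or `"left"`.
#' @return A tibble with merged provenance attributes.
#' @export
merge_within_cycle <- function(left, right, join = c("full", "inner", "left")) {
  join <- match.arg(join)
  for (tab in list(left, right)) {
    if (!"SEQN" %in% names(tab)) {
      stop("both tables must contain SEQN", call. = FALSE)
    }
    if (anyDuplicated(tab$SEQN)) {
      stop("duplicate SEQN values in ",
           attr(tab, "nhanes_name") %||% "input table", call. = FALSE)
    }
  }
  lcyc <- attr(left, "cycle")
  rcyc <- attr(right, "cycle")
  if (!is.null(lcyc) && !is.null(rcyc) && !identical(lcyc$label, rcyc$label)) {
    stop("tables come from different cycles (", lcyc$label, " vs ", rcyc$label,
         "); within-cycle merging is not meaningful across cycles - ",
         "use align_across_cycles()", call. = FALSE)
  }
  lname <- attr(left, "nhanes_name") %||% "left"
  rname <- attr(right, "nhanes_name") %||% "right"
  overlap <- setdiff(intersect(names(left), names(right)), "SEQN")
  if (length(overlap)) {
    warning("variable(s) present in both tables renamed with table suffixes: ",
            paste(overlap, collapse = ", "), call. = FALSE)
  }
  joiner <- switch(join, full = dplyr::full_join, inner = dplyr::inner_join,
                   left = dplyr::left_join)
  out <- joiner(tibble::as_tibble(left), tibble::as_tibble(right),
                by = "SEQN", suffix = paste0(".", c(lname, rname)))
  structure(
    out,
    nhanes_name = paste(lname, rname, sep = "+"),
    cycle = lcyc %||% rcyc,
    translated = isTRUE(attr(left, "translated")) || isTRUE(attr(right, "translated")),
    sources = c(attr(left, "sources") %||% lname, attr(right, "sources") %||% rname),
    translations = c(attr(left, "translations"), attr(right, "translations")),
    class = class(out)
  )
}

#' Stack tables from different cycles with compatibility checks
#'
#' Row-stacks the selected variables from one table per cycle, adding a
#' `cycle` label column. Cross-cycle alignment is where silent errors
#' creep into NHANES analyses — variable names are not guaranteed stable
#' and question wording can change — so the function returns, alongside
#' the stacked data, an alignment report listing the variables shared by
#' all cycles, those present in only some, and categorical variables
#' whose label sets differ between cycles (these are surfaced, never
#' silently unioned away).
#'
#' Mixing a pre-pandemic (`P_`-prefixed, 2017--March 2020) table with
#' regular-cycle tables is an error unless `allow_prepandemic = TRUE`:
#' the combined release has its own weighting and the CDC advises against
#' casual pooling.
#'
#' @param tables A list of translated tables with pairwise distinct
#'   cycles.
#' @param variables Character vector of variables to stack; default all
#'   variables appearing in any table (plus SEQN).
#' @param strict When `TRUE`, a selected variable absent from some cycle
#'   is an error naming the cycle; when `FALSE` (default) it is filled
#'   with `NA` there.
#' @param allow_prepandemic Permit mixing the pre-pandemic release with
#'   regular cycles.
#' @return A list with elements `data` (a tibble with a `cycle` column)
#'   and `report` (an `alignment_report`).
#' @export
align_across_cycles <- function(tables, variables = NULL, strict = FALSE,
                                allow_prepandemic = FALSE) {
  if (length(tables) < 2L) {
    stop("alignment needs at least two tables", call. = FALSE)
  }
  cycles <- purrr::map(tables, ~ attr(.x, "cycle"))
  if (any(purrr::map_lgl(cycles, is.null))) {
    stop("every table needs cycle provenance (translate_table() records it)",
         call. = FALSE)
  }
  labels <- purrr::map_chr(cycles, "label")
  if (anyDuplicated(labels)) {
    stop("tables must come from pairwise distinct cycles; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "), call. = FALSE)
  }
  prepan <- purrr::map_lgl(cycles, "prepandemic")
  if (any(prepan) && !all(prepan) && !isTRUE(allow_prepandemic)) {
    stop("mixing a pre-pandemic (P_) release with regular cycles requires ",
         "allow_prepandemic = TRUE; its weights are not cycle-additive",
         call. = FALSE)
  }

  all_vars <- unique(unlist(purrr::map(tables, names)))
  if (is.null(variables)) variables <- all_vars
  variables <- union("SEQN", variables)
  present <- purrr::map(tables, ~ intersect(variables, names(.x)))
  shared <- Reduce(intersect, present)
  per_cycle_only <- purrr::map2(present, labels, function(p, lab) setdiff(p, shared))
  names(per_cycle_only) <- labels
  if (strict) {
    for (i in seq_along(tables)) {
      absent <- setdiff(variables, names(tables[[i]]))
      if (length(absent)) {
        stop("variable(s) ", paste(absent, collapse = ", "),
             " absent from cycle ", labels[i], call. = FALSE)
      }
    }
  }

  mismatches <- list()
  for (v in shared) {
    lvls <- purrr::map(tables, function(t) if (is.factor(t[[v]])) levels(t[[v]]) else NULL)
    lvls <- purrr::compact(lvls)
    if (length(lvls) >= 2L && length(unique(purrr::map_chr(lvls, paste, collapse = "\r"))) > 1L) {
      mismatches[[v]] <- lvls
    }
  }
  if (length(mismatches)) {
    warning("categorical label sets differ across cycles for: ",
            paste(names(mismatches), collapse = ", "),
            "; see the alignment report before pooling", call. = FALSE)
  }

  stacked <- purrr::map2(tables, labels, function(t, lab) {
    d <- tibble::as_tibble(t)[, intersect(variables, names(t)), drop = FALSE]
    for (v in setdiff(variables, names(d))) d[[v]] <- NA
    d$cycle <- lab
    d[, c("cycle", variables), drop = FALSE]
  })
  data <- dplyr::bind_rows(stacked)
  # a multi-cycle stack has no single table identity; drop inherited provenance
  for (a in c("nhanes_name", "cycle", "translated", "sources", "translations",
              "fill_log")) {
    attr(data, a) <- NULL
  }

  report <- structure(
    list(
      shared_variables = setdiff(shared, "SEQN"),
      per_cycle_only = per_cycle_only,
      category_mismatch = mismatches,
      tables = tibble::tibble(
        table_name = purrr::map_chr(tables, ~ attr(.x, "nhanes_name") %||% "?"),
        cycle = labels,
        n_rows = purrr::map_int(tables, nrow)
      )
    ),
    class = "alignment_report"
  )
  list(data = data, report = report)
}

#' @export
print.alignment_report <- function(x, ...) {
  cat("<alignment_report>\n")
  print(x$tables)
  cat("shared variables: ", paste(x$shared_variables, collapse = ", "), "\n", sep = "")
  only <- purrr::compact(x$per_cycle_only)
  only <- only[purrr::map_int(only, length) > 0]
  for (lab in names(only)) {
    cat("only in ", lab, ": ", paste(only[[lab]], collapse = ", "), "\n", sep = "")
  }
  if (length(x$category_mismatch)) {
    cat("category mismatches: ", paste(names(x$category_mismatch), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
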