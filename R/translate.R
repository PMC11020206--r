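#' Is a codebook entry a translatable categorical?
#'
#' Raw NHANES data encodes categorical answers as integers whose meanings
#' live in the codebook. An entry is considered translatable when it has
#' at least two value rows that are genuine categories: single codes (not
#' ranges such as `"0 to 79"`) whose descriptions are not the structural
#' rows `"Range of Values"` or `"Missing"`. Continuous variables with a
#' top-coded ceiling (for example age recorded as 80 for everyone aged 80
#' and over) mix a range row with a single code and are deliberately *not*
#' translatable; they are surfaced by [flag_coarsened()] instead.
#'
#' @param entry A `codebook_entry`.
#' @return `TRUE` or `FALSE`.
#' @export
is_translatable <- function(entry) {
  stopifnot(inherits(entry, "codebook_entry"))
  rows <- entry$value_rows
  if (nrow(rows) == 0L) return(FALSE)
  cat_rows <- category_rows(rows)
  range_rows <- grepl("range of values", rows$description, ignore.case = TRUE)
  nrow(cat_rows) >= 2L && !any(range_rows)
}

category_rows <- function(rows) {
  single <- grepl("^-?[0-9]+(\\.[0-9]+)?$", rows$code)
  structural <- grepl("^(range of values|missing)$", rows$description, ignore.case = TRUE)
  rows[single & !structural, , drop = FALSE]
}

#' Translate integer codes to labelled categories
#'
#' Converts a raw transport table into an analysis table keyed by the
#' respondent sequence number (SEQN), replacing each translatable
#' column's integer codes with the codebook's value descriptions. The
#' labelled representation matters beyond readability: an untranslated
#' categorical entering a regression would be treated as continuous, so
#' the translated factor is the safe default. Categories keep the
#' codebook's code-ascending order, preserving ordinal structure.
#'
#' Observed codes absent from the codebook map are kept as their literal
#' numeral string with a warning; columns present in the data but absent
#' from the codebook pass through untouched with a warning. Translation is
#' lossless: the applied code-to-label maps are stored in the result's
#' `"translations"` attribute, and [untranslate_table()] reconstructs the
#' raw integer columns exactly.
#'
#' @param raw An [xpt_table()] (or a data frame containing a `SEQN`
#'   column).
#' @param cb The table's `nhanes_codebook`.
#' @param translated When `FALSE`, perform no translation and return the
#'   numeric columns untouched (the raw view).
#' @param special_as_missing When `TRUE`, collapse the explicit
#'   `"Refused"` and `"Don't know"` categories to `NA`, matching common
#'   analyst practice; the information-preserving default keeps them.
#' @return A tibble with provenance attributes `nhanes_name`, `cycle`,
#'   `translated`, `sources` and `translations`.
#' @export
translate_table <- function(raw, cb = NULL, translated = TRUE,
                            special_as_missing = FALSE) {
  if (inherits(raw, "xpt_table")) {
    name <- raw$member_name
    data <- raw$data
  } else {
    data <- tibble::as_tibble(raw)
    name <- attr(raw, "nhanes_name") %||% if (!is.null(cb)) cb$table_name else "TABLE"
  }
  if (!"SEQN" %in% names(data)) {
    stop("table ", name, " has no SEQN column; NHANES tables are keyed by the ",
         "respondent sequence number", call. = FALSE)
  }
  if (anyDuplicated(data$SEQN)) {
    stop("duplicate SEQN values in table ", name,
         "; one row per respondent is required", call. = FALSE)
  }

  translations <- list()
  if (isTRUE(translated) && !is.null(cb)) {
    for (col in setdiff(names(data), "SEQN")) {
      entry <- cb$entries[[toupper(col)]]
      if (is.null(entry)) {
        warning("column ", col, " has no codebook entry; passing through untouched",
                call. = FALSE)
        next
      }
      if (!is.numeric(data[[col]]) || !is_translatable(entry)) next
      rows <- category_rows(entry$value_rows)
      map <- tibble::tibble(code = as.numeric(rows$code), label = rows$description)
      map <- dplyr::arrange(map, .data$code)
      x <- data[[col]]
      observed <- sort(unique(x[!is.na(x)]))
      unmapped <- setdiff(observed, map$code)
      if (length(unmapped)) {
        warning("column ", col, " has code(s) not in the codebook: ",
                paste(format(unmapped), collapse = ", "),
                "; keeping them as literal categories", call. = FALSE)
        map <- dplyr::bind_rows(
          map, tibble::tibble(code = unmapped, label = format(unmapped, trim = TRUE))
        )
      }
      labels <- map$label[match(x, map$code)]
      fac <- factor(labels, levels = map$label)
      if (isTRUE(special_as_missing)) {
        drop <- levels(fac) %in% c("Refused", "Don't know", "Don't Know")
        fac[fac %in% levels(fac)[drop]] <- NA
        fac <- factor(fac, levels = levels(fac)[!drop])
        map <- map[!map$label %in% c("Refused", "Don't know", "Don't Know"), ]
      }
      data[[col]] <- fac
      translations[[col]] <- map
    }
  }

  cyc <- tryCatch(nhanes_cycle(name), error = function(e) NULL)
  structure(
    data,
    nhanes_name = name,
    cycle = cyc,
    translated = isTRUE(translated) && !is.null(cb),
    sources = name,
    translations = translations,
    fill_log = attr(raw, "fill_log"),
    class = class(data)
  )
}

#' Reconstruct raw integer codes from a translated table
#'
#' Inverts the translation applied by [translate_table()] using the
#' stored code-to-label maps; on observed mapped codes the round trip is
#' a bijection.
#'
#' @param data A translated table.
#' @return A tibble with the translated columns returned to their raw
#'   numeric codes.
#' @export
untranslate_table <- function(data) {
  translations <- attr(data, "translations")
  if (is.null(translations) || length(translations) == 0L) {
    return(tibble::as_tibble(data))
  }
  out <- tibble::as_tibble(data)
  for (col in names(translations)) {
    map <- translations[[col]]
    out[[col]] <- map$code[match(as.character(out[[col]]), map$label)]
  }
  out
}

#' Fill structurally skipped answers
#'
#' Questionnaire routing can skip later questions entirely: a respondent
#' answering "No" to a gate question (Ever told you had high blood
#' pressure?) never sees the follow-up (told 2+ times?), and the database
#' stores a missing value there. An analyst may prefer to fill those
#' structural missings with the answer implied by the gate (here "No") to
#' recover complete cases. That is an analytic judgment, so the fill is
#' driven by explicit rules and never applied automatically; use
#' [suggest_skip_rules()] to derive candidate rules from the codebook's
#' Skip-to annotations.
#'
#' Only cells that are missing *and* whose gate answer is in
#' `gate_values` are touched, so missingness from other causes is
#' preserved and `n_missing_before == n_missing_after + n_filled` holds
#' per rule.
#'
#' @param data A translated table from [translate_table()].
#' @param rules A data frame (or list of lists) with columns `gate`,
#'   `gate_values` (character vector, list-column allowed), `target` and
#'   `fill`.
#' @return `data` with the fills applied; the per-rule counts are
#'   appended to the `"fill_log"` attribute (a tibble with columns
#'   `gate`, `target`, `fill`, `n_filled`).
#' @export
apply_skip_fill <- function(data, rules) {
  if (is.data.frame(rules)) {
    rules <- purrr::pmap(rules, function(...) list(...))
  }
  fill_log <- attr(data, "fill_log") %||%
    tibble::tibble(gate = character(), target = character(),
                   fill = character(), n_filled = integer())
  for (r in rules) {
    for (fld in c("gate", "gate_values", "target", "fill")) {
      if (is.null(r[[fld]])) stop("skip-fill rule lacks field '", fld, "'", call. = FALSE)
    }
    gate_values <- unlist(r$gate_values)
    for (v in c(r$gate, r$target)) {
      if (!v %in% names(data)) {
        stop("skip-fill rule refers to absent variable ", v, call. = FALSE)
      }
    }
    target_col <- data[[r$target]]
    if (!is.factor(target_col)) {
      stop("skip-fill target ", r$target, " is not a labelled categorical; ",
           "translate the table first", call. = FALSE)
    }
    if (!r$fill %in% levels(target_col)) {
      stop("fill label '", r$fill, "' is not a category of ", r$target,
           " (levels: ", paste(levels(target_col), collapse = ", "), ")",
           call. = FALSE)
    }
    hit <- !is.na(data[[r$gate]]) & (data[[r$gate]] %in% gate_values) &
      is.na(target_col)
    target_col[hit] <- r$fill
    data[[r$target]] <- target_col
    fill_log <- dplyr::bind_rows(
      fill_log,
      tibble::tibble(gate = r$gate, target = r$target, fill = r$fill,
                     n_filled = sum(hit))
    )
  }
  attr(data, "fill_log") <- fill_log
  data
}

#' Suggest skip-fill rules from codebook Skip-to annotations
#'
#' Scans a codebook for value rows carrying a "Skip to Item" target and
#' proposes, for each gate, the variables that those answers skip over
#' (the entries between the gate and the skip target in codebook order).
#' The suggestions carry no fill label — choosing one is the analyst's
#' judgment — and are never applied automatically.
#'
#' @param cb An `nhanes_codebook`.
#' @return A tibble with columns `gate`, `gate_values` (list-column),
#'   `target`, `skip_to`.
#' @export
suggest_skip_rules <- function(cb) {
  vars <- names(cb$entries)
  out <- list()
  for (i in seq_along(vars)) {
    e <- cb$entries[[i]]
    rows <- e$value_rows
    if (nrow(rows) == 0L || all(is.na(rows$skip_to))) next
    for (tgt in unique(stats::na.omit(rows$skip_to))) {
      gate_values <- rows$description[!is.na(rows$skip_to) & rows$skip_to == tgt]
      skipped <- if (identical(tgt, "End of Section")) {
        vars[-seq_len(i)]
      } else {
        j <- match(toupper(tgt), vars)
        if (is.na(j) || j <= i + 1L) character(0) else vars[(i + 1L):(j - 1L)]
      }
      for (s in skipped) {
        out[[length(out) + 1L]] <- tibble::tibble(
          gate = e$variable_name,
          gate_values = list(gate_values),
          target = s,
          skip_to = tgt
        )
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(gate = character(), gate_values = list(),
                   target = character(), skip_to = character())
  }
}

#' Report top-coded (coarsened) numeric variables
#'
#' NHANES coarsens some numeric variables for privacy: ages above a
#' ceiling are recorded *as* the ceiling (85 in the first four cycles, 80
#' afterwards), and the family income-to-poverty ratio is capped at 5.
#' Such variables show up in the codebook as a "Range of Values" row mixed
#' with one or more single-coded boundary categories. This reports, for
#' each affected variable in `data`, the boundary code and how many rows
#' sit exactly at it, so analysts can handle the pile-up deliberately.
#'
#' @param data A table (translated or raw) containing the variables.
#' @param cb The table's `nhanes_codebook`.
#' @return A tibble with columns `variable`, `code`, `description`, `n`.
#' @export
flag_coarsened <- function(data, cb) {
  out <- list()
  for (col in intersect(names(data), names(cb$entries))) {
    if (!is.numeric(data[[col]])) next
    rows <- cb$entries[[col]]$value_rows
    if (nrow(rows) == 0L) next
    has_range <- any(grepl("range of values", rows$description, ignore.case = TRUE))
    if (!has_range) next
    bound <- category_rows(rows)
    for (k in seq_len(nrow(bound))) {
      code <- as.numeric(bound$code[k])
      out[[length(out) + 1L]] <- tibble::tibble(
        variable = col,
        code = code,
        description = bound$description[k],
        n = sum(!is.na(data[[col]]) & data[[col]] == code)
      )
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(variable = character(), code = double(),
                   description = character(), n = integer())
  }
}
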