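#' Parse an NHANES-dialect HTML codebook
#'
#' NHANES documents every published table with an HTML page holding one
#' block per variable: a definition list (Variable Name, SAS Label,
#' English Text, Target) followed, for coded variables, by a value table
#' with columns "Code or Value", "Value Description", "Count",
#' "Cumulative" and optionally "Skip to Item". This parser accepts that
#' modern dialect and a plain-tables fallback (a definition list followed
#' by any table whose header row matches), and returns a structured
#' codebook used by [translate_table()] and friends.
#'
#' Counts are parsed leniently (thousands separators stripped); a
#' non-numeric count cell becomes 0 with a warning, since counts are
#' informational. "End of Section" skip targets are normalized to the
#' constant spelling `"End of Section"`. Documentation-only blocks (e.g.
#' CHECK ITEM routing notes with no data column) are retained with
#' `doc_only = TRUE` rather than dropped.
#'
#' @param html A path/URL to an HTML document, a string of HTML, or an
#'   `xml2` document.
#' @param table_name Optional table name recorded in the codebook;
#'   defaults to the document title's first word when available.
#' @param source Optional source path recorded for provenance.
#' @return An object of class `nhanes_codebook`: a list with
#'   `table_name`, `source` and `entries` (a named list of
#'   `codebook_entry` objects, each holding `variable_name`, `sas_label`,
#'   `english_text`, `target`, `doc_only` and a `value_rows` tibble with
#'   columns `code`, `description`, `count`, `cumulative`, `skip_to`).
#' @export
parse_codebook <- function(html, table_name = NULL, source = NULL) {
  doc <- as_html_doc(html)
  dls <- xml2::xml_find_all(doc, ".//dl[dt and dd]")
  if (length(dls) == 0L) {
    body <- gsub("\\s+", " ", xml2::xml_text(doc))
    stop("no variable blocks found in codebook document; body starts: ",
         substr(trimws(body), 1L, 200L), call. = FALSE)
  }
  if (is.null(table_name)) {
    title <- xml2::xml_text(xml2::xml_find_first(doc, ".//title"))
    table_name <- if (!is.na(title) && nzchar(trimws(title))) {
      strsplit(trimws(title), "[[:space:]]+")[[1]][1]
    } else {
      "UNKNOWN"
    }
  }

  entries <- list()
  for (dl in dls) {
    dts <- trimws(sub(":\\s*$", "", xml2::xml_text(xml2::xml_find_all(dl, "./dt"))))
    dds <- trimws(xml2::xml_text(xml2::xml_find_all(dl, "./dd")))
    k <- min(length(dts), length(dds))
    fields <- stats::setNames(dds[seq_len(k)], tolower(dts[seq_len(k)]))
    varname <- fields[["variable name"]]
    if (is.null(varname) || !nzchar(varname)) next
    doc_only <- !("sas label" %in% names(fields)) || grepl("[[:space:]]", varname)

    tab <- xml2::xml_find_first(dl, "./following-sibling::table[1]")
    value_rows <- empty_value_rows()
    if (!inherits(tab, "xml_missing")) {
      value_rows <- parse_value_table(tab, varname)
    }
    entry <- structure(
      list(
        variable_name = varname,
        sas_label = fields[["sas label"]] %||% "",
        english_text = fields[["english text"]] %||% "",
        target = fields[["target"]] %||% "",
        doc_only = doc_only,
        value_rows = value_rows
      ),
      class = "codebook_entry"
    )
    key <- toupper(varname)
    if (key %in% names(entries)) {
      warning("duplicate codebook block for ", varname, "; keeping the first",
              call. = FALSE)
    } else {
      entries[[key]] <- entry
    }
  }
  if (length(entries) == 0L) {
    stop("no variable blocks found in codebook document (definition lists ",
         "lack a 'Variable Name' item)", call. = FALSE)
  }
  structure(
    list(table_name = toupper(table_name),
         source = source %||% "",
         entries = entries),
    class = "nhanes_codebook"
  )
}

empty_value_rows <- function() {
  tibble::tibble(code = character(), description = character(),
                 count = integer(), cumulative = integer(),
                 skip_to = character())
}

parse_value_table <- function(tab, varname) {
  header <- tolower(trimws(xml2::xml_text(
    xml2::xml_find_all(tab, ".//tr[1]/th | .//tr[1]/td")
  )))
  code_i <- match(TRUE, grepl("code or value", header))
  desc_i <- match(TRUE, grepl("value description|description", header))
  if (is.na(code_i) || is.na(desc_i)) {
    warning("unrecognized code-table headers for ", varname, ": ",
            paste(header, collapse = " | "), "; keeping entry with no value rows",
            call. = FALSE)
    return(empty_value_rows())
  }
  count_i <- match(TRUE, grepl("^count$|unweighted count", header))
  cum_i <- match(TRUE, grepl("cumulative", header))
  skip_i <- match(TRUE, grepl("skip to item", header))

  rows <- xml2::xml_find_all(tab, ".//tr[td]")
  parse_count <- function(s) {
    s <- gsub(",", "", trimws(s))
    if (!nzchar(s)) return(0L)
    v <- suppressWarnings(as.integer(s))
    if (is.na(v)) {
      warning("non-numeric count cell '", s, "' for ", varname, "; using 0",
              call. = FALSE)
      0L
    } else {
      v
    }
  }
  out <- purrr::map(rows, function(tr) {
    cells <- trimws(xml2::xml_text(xml2::xml_find_all(tr, "./td")))
    if (length(cells) < max(code_i, desc_i)) return(NULL)
    skip <- if (!is.na(skip_i) && length(cells) >= skip_i) cells[skip_i] else ""
    if (grepl("^end of section$", skip, ignore.case = TRUE)) skip <- "End of Section"
    tibble::tibble(
      code = cells[code_i],
      description = cells[desc_i],
      count = if (!is.na(count_i) && length(cells) >= count_i) parse_count(cells[count_i]) else 0L,
      cumulative = if (!is.na(cum_i) && length(cells) >= cum_i) parse_count(cells[cum_i]) else 0L,
      skip_to = if (nzchar(skip)) skip else NA_character_
    )
  })
  out <- purrr::compact(out)
  if (length(out) == 0L) empty_value_rows() else dplyr::bind_rows(out)
}

as_html_doc <- function(html) {
  if (inherits(html, "xml_document")) return(html)
  stopifnot(is.character(html), length(html) == 1L)
  if (grepl("<", html, fixed = TRUE)) {
    # treat as markup; UTF-8 first, Latin-1 fallback
    tryCatch(xml2::read_html(html, encoding = "UTF-8"),
             error = function(e) xml2::read_html(html, encoding = "latin1"))
  } else {
    tryCatch(xml2::read_html(html, encoding = "UTF-8"),
             error = function(e) xml2::read_html(html, encoding = "latin1"))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Look up one variable's codebook entry
#'
#' Case-insensitive lookup of a variable in a parsed codebook. When the
#' variable is absent, the error message suggests near-matches (edit
#' distance at most 2) to catch the common misspellings of NHANES
#' variable names.
#'
#' @param cb An `nhanes_codebook` from [parse_codebook()].
#' @param name Variable name (case-insensitive).
#' @return A `codebook_entry`.
#' @examples
#' \dontrun{codebook_variable(cb, "riagendr")}
#' @export
codebook_variable <- function(cb, name) {
  stopifnot(inherits(cb, "nhanes_codebook"), is.character(name), length(name) == 1L)
  key <- toupper(name)
  if (key %in% names(cb$entries)) {
    return(cb$entries[[key]])
  }
  d <- utils::adist(key, names(cb$entries), ignore.case = TRUE)
  near <- names(cb$entries)[d <= 2L]
  stop("variable '", name, "' not found in codebook for ", cb$table_name,
       if (length(near)) paste0("; did you mean: ", paste(near, collapse = ", "), "?")
       else "",
       call. = FALSE)
}

#' @export
print.nhanes_codebook <- function(x, ...) {
  cat("<nhanes_codebook> ", x$table_name, ": ", length(x$entries),
      " variables\n", sep = "")
  print(as_tibble.nhanes_codebook(x), n = 15)
  invisible(x)
}

#' @export
print.codebook_entry <- function(x, ...) {
  cat(x$variable_name, " - ", x$sas_label,
      if (isTRUE(x$doc_only)) " [documentation-only]" else "", "\n",
      "  ", x$english_text, "\n  Target: ", x$target, "\n", sep = "")
  if (nrow(x$value_rows)) print(x$value_rows) else cat("  (no value-code table)\n")
  invisible(x)
}

#' Summarise a codebook as a tibble
#'
#' One row per variable with its label, target and value-row count.
#'
#' @param x An `nhanes_codebook`.
#' @param ... Unused.
#' @return A tibble.
#' @export
as_tibble.nhanes_codebook <- function(x, ...) {
  tibble::tibble(
    variable = vapply(x$entries, `[[`, character(1), "variable_name"),
    sas_label = vapply(x$entries, `[[`, character(1), "sas_label"),
    target = vapply(x$entries, `[[`, character(1), "target"),
    doc_only = vapply(x$entries, `[[`, logical(1), "doc_only"),
    n_value_rows = vapply(x$entries, function(e) nrow(e$value_rows), integer(1))
  )
}

#' Serialize a codebook to the plain-text cache format
#'
#' Codebooks are cached one file per table in a line-oriented key-value
#' format (tab-separated value rows), chosen so the cache stays
#' human-readable and diffs cleanly. [read_codebook()] parses it back to
#' an identical object: parse, serialize, parse is a fixed point.
#'
#' @param cb An `nhanes_codebook`.
#' @param path Output path; when `NULL` the serialized lines are returned.
#' @return `path` invisibly, or a character vector of lines.
#' @export
write_codebook <- function(cb, path = NULL) {
  stopifnot(inherits(cb, "nhanes_codebook"))
  esc <- function(s) gsub("\n", " ", gsub("\t", " ", s))
  lines <- c(paste0("table\t", esc(cb$table_name)),
             paste0("source\t", esc(cb$source)))
  for (e in cb$entries) {
    lines <- c(lines,
               paste0("variable\t", esc(e$variable_name)),
               paste0("sas_label\t", esc(e$sas_label)),
               paste0("english_text\t", esc(e$english_text)),
               paste0("target\t", esc(e$target)),
               paste0("doc_only\t", if (isTRUE(e$doc_only)) "1" else "0"))
    if (nrow(e$value_rows)) {
      lines <- c(lines, paste("row", esc(e$value_rows$code),
                              esc(e$value_rows$description),
                              e$value_rows$count, e$value_rows$cumulative,
                              ifelse(is.na(e$value_rows$skip_to), "",
                                     esc(e$value_rows$skip_to)),
                              sep = "\t"))
    }
  }
  if (is.null(path)) {
    lines
  } else {
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
  }
}

#' @rdname write_codebook
#' @param input Path to a serialized codebook, or its lines.
#' @export
read_codebook <- function(input) {
  lines <- if (length(input) == 1L && file.exists(input)) readLines(input) else input
  parts <- strsplit(lines, "\t", fixed = TRUE)
  table_name <- ""
  source <- ""
  entries <- list()
  cur <- NULL
  rows <- list()
  flush <- function(entries, cur, rows) {
    if (is.null(cur)) return(entries)
    cur$value_rows <- if (length(rows)) dplyr::bind_rows(rows) else empty_value_rows()
    entries[[toupper(cur$variable_name)]] <- structure(cur, class = "codebook_entry")
    entries
  }
  for (p in parts) {
    key <- p[1]
    val <- if (length(p) >= 2L) p[2] else ""
    if (key == "table") table_name <- val
    else if (key == "source") source <- val
    else if (key == "variable") {
      entries <- flush(entries, cur, rows)
      cur <- list(variable_name = val, sas_label = "", english_text = "",
                  target = "", doc_only = FALSE)
      rows <- list()
    } else if (key %in% c("sas_label", "english_text", "target")) {
      cur[[key]] <- val
    } else if (key == "doc_only") {
      cur$doc_only <- identical(val, "1")
    } else if (key == "row") {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        code = p[2], description = p[3],
        count = as.integer(p[4]), cumulative = as.integer(p[5]),
        skip_to = if (length(p) >= 6L && nzchar(p[6])) p[6] else NA_character_
      )
    }
  }
  entries <- flush(entries, cur, rows)
  structure(list(table_name = table_name, source = source, entries = entries),
            class = "nhanes_codebook")
}
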