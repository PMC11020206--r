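#' Infer the survey cycle from a table name
#'
#' Continuous NHANES table names carry their 2-year cycle as a suffix
#' letter: `_B` is 2001--2002, `_C` is 2003--2004, and so on, with the
#' letter's alphabet position k mapping to the cycle starting
#' `1999 + 2 * (k - 1)`. Tables from the first cycle (1999--2000) usually
#' have no suffix at all (`DEMO`), though a few irregular tables (for
#' example `SSAFB_A`, `SSOL_A`) do carry `_A`. A `P_` prefix marks the
#' pre-pandemic combined release covering 2017--March 2020, which has its
#' own weighting and must not be treated as a regular cycle.
#'
#' Because the convention is not applied perfectly consistently across the
#' archive, an overrides table is consulted first and can be extended by
#' the user; a name that matches no rule raises a classification error
#' rather than guessing.
#'
#' @param name Table name, e.g. `"DEMO_J"`.
#' @param overrides Named list mapping table names to `start_year`
#'   integers; see [cycle_overrides()] for the packaged seed list.
#' @return An object of class `nhanes_cycle`: list with `start_year`,
#'   `end_year`, `suffix`, `prepandemic` and a printable `label`.
#' @examples
#' nhanes_cycle("DEMO_C")
#' nhanes_cycle("P_DEMO")
#' @export
nhanes_cycle <- function(name, overrides = cycle_overrides()) {
  stopifnot(is.character(name), length(name) == 1L)
  name <- toupper(trimws(name))
  if (name %in% names(overrides)) {
    start <- overrides[[name]]
    suffix <- if (grepl("_([A-Z])$", name)) sub(".*_([A-Z])$", "\\1", name) else NA_character_
    return(new_cycle(start, suffix = suffix))
  }
  if (grepl("^P_[A-Z0-9_]+$", name)) {
    return(new_cycle(2017L, prepandemic = TRUE))
  }
  m <- regmatches(name, regexec("^[A-Z][A-Z0-9_]*_([A-Z])$", name))[[1]]
  if (length(m) == 2L) {
    k <- match(m[2], LETTERS)
    return(new_cycle(1999L + 2L * (k - 1L), suffix = m[2]))
  }
  if (grepl("^[A-Z][A-Z0-9]*$", name)) {
    return(new_cycle(1999L))
  }
  stop("cannot classify table name '", name, "' into a cycle; ",
       "add it to the overrides list if it is irregularly named", call. = FALSE)
}

new_cycle <- function(start_year, suffix = NA_character_, prepandemic = FALSE) {
  start_year <- as.integer(start_year)
  if (prepandemic) {
    structure(list(start_year = 2017L, end_year = 2020L, suffix = NA_character_,
                   prepandemic = TRUE, label = "2017-March 2020"),
              class = "nhanes_cycle")
  } else {
    structure(list(start_year = start_year, end_year = start_year + 1L,
                   suffix = suffix, prepandemic = FALSE,
                   label = paste0(start_year, "-", start_year + 1L)),
              class = "nhanes_cycle")
  }
}

#' @export
print.nhanes_cycle <- function(x, ...) {
  cat("<nhanes_cycle> ", x$label,
      if (x$prepandemic) " (pre-pandemic combined release)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
format.nhanes_cycle <- function(x, ...) x$label

#' Packaged cycle-name overrides
#'
#' Seed list of irregularly named tables whose cycle cannot be trusted to
#' the general suffix rule alone; users can extend it and pass the result
#' to [nhanes_cycle()].
#'
#' @return Named list of `start_year` integers.
#' @export
cycle_overrides <- function() {
  list(SSAFB_A = 1999L, SSOL_A = 1999L)
}

#' Parse an NHANES table manifest
#'
#' A manifest page lists the published data files for a survey component:
#' one row per table with its cycle years, documentation and data links,
#' and publication date. Withdrawn or limited-access rows (no usable data
#' link) are excluded from the returned records and reported via a
#' message; they remain available in the `"excluded"` attribute.
#'
#' @param html HTML document (path, markup string, or `xml2` document).
#' @return A tibble with columns `table_name`, `description`, `years`,
#'   `start_year`, `end_year`, `prepandemic`, `doc_url`, `data_url`,
#'   `date_published`.
#' @export
parse_manifest <- function(html) {
  doc <- as_html_doc(html)
  rows <- xml2::xml_find_all(doc, ".//table//tr[td]")
  if (length(rows) == 0L) {
    stop("no data-file rows found in manifest document", call. = FALSE)
  }
  recs <- purrr::map(rows, function(tr) {
    cells <- xml2::xml_find_all(tr, "./td")
    if (length(cells) < 4L) return(NULL)
    txt <- trimws(xml2::xml_text(cells))
    links <- vapply(cells, function(td) {
      a <- xml2::xml_find_first(td, ".//a")
      if (inherits(a, "xml_missing")) NA_character_ else xml2::xml_attr(a, "href")
    }, character(1))
    data_i <- 4L
    doc_i <- 3L
    data_url <- links[data_i]
    tname <- if (!is.na(data_url)) {
      toupper(sub("\\.[Xx][Pp][Tt]$", "", basename(data_url)))
    } else {
      # fall back to the doc link or the visible label
      src <- if (!is.na(links[doc_i])) basename(links[doc_i]) else txt[data_i]
      toupper(sub("\\.[Hh][Tt][Mm][Ll]?$", "", strsplit(trimws(src), "[[:space:]]+")[[1]][1]))
    }
    withdrawn <- is.na(data_url) || grepl("withdrawn|rdc only|limited access",
                                          txt[data_i], ignore.case = TRUE)
    tibble::tibble(
      table_name = tname,
      description = txt[2L],
      years = txt[1L],
      doc_url = links[doc_i],
      data_url = data_url,
      date_published = if (length(txt) >= 5L) txt[5L] else NA_character_,
      withdrawn = withdrawn
    )
  })
  recs <- dplyr::bind_rows(purrr::compact(recs))
  if (nrow(recs) == 0L) {
    stop("no data-file rows found in manifest document", call. = FALSE)
  }
  cyc <- purrr::map(recs$table_name, nhanes_cycle)
  recs$start_year <- vapply(cyc, `[[`, integer(1), "start_year")
  recs$end_year <- vapply(cyc, `[[`, integer(1), "end_year")
  recs$prepandemic <- vapply(cyc, `[[`, logical(1), "prepandemic")

  excluded <- dplyr::filter(recs, .data$withdrawn)
  kept <- dplyr::filter(recs, !.data$withdrawn)
  if (nrow(excluded)) {
    log_msg("info", "excluded ", nrow(excluded),
            " withdrawn/limited-access manifest row(s): ",
            paste(excluded$table_name, collapse = ", "))
  }
  if (anyDuplicated(kept$table_name)) {
    stop("duplicate table name(s) in manifest: ",
         paste(unique(kept$table_name[duplicated(kept$table_name)]), collapse = ", "),
         call. = FALSE)
  }
  kept <- dplyr::select(kept, "table_name", "description", "years",
                        "start_year", "end_year", "prepandemic",
                        "doc_url", "data_url", "date_published")
  attr(kept, "excluded") <- excluded
  kept
}

#' Search table names in a manifest
#'
#' Case-insensitive substring match by default; set `regex = TRUE` for
#' full regular-expression matching (the default avoids surprising
#' metacharacter behaviour for naive queries).
#'
#' @param manifest A manifest tibble from [parse_manifest()].
#' @param pattern Non-empty search string.
#' @param details When `TRUE`, return the matching manifest rows (cycle,
#'   publication date, ...); otherwise just the table names.
#' @param regex Interpret `pattern` as a regular expression.
#' @return Character vector of table names, or a tibble when
#'   `details = TRUE`.
#' @export
search_table_names <- function(manifest, pattern, details = FALSE, regex = FALSE) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  hit <- if (regex) {
    grepl(pattern, manifest$table_name, ignore.case = TRUE)
  } else {
    grepl(toupper(pattern), manifest$table_name, fixed = TRUE)
  }
  out <- manifest[hit, , drop = FALSE]
  if (details) out else out$table_name
}

#' Build a searchable variable index
#'
#' Combines parsed codebooks with a manifest into one record per variable
#' per table, the offline analogue of the comprehensive NHANES variable
#' list. The survey component (demographics, dietary, examination,
#' laboratory, questionnaire) is taken from a `component` column in the
#' manifest when present, otherwise inferred from standard table-name
#' prefixes.
#'
#' @param codebooks A list of `nhanes_codebook` objects.
#' @param manifest Optional manifest tibble supplying cycle years (and
#'   optionally a `component` column).
#' @return A tibble with columns `variable`, `description`, `table_name`,
#'   `begin_year`, `end_year`, `component`.
#' @export
build_variable_index <- function(codebooks, manifest = NULL) {
  purrr::map_dfr(codebooks, function(cb) {
    entries <- purrr::discard(cb$entries, `[[`, "doc_only")
    if (length(entries) == 0L) return(NULL)
    cyc <- nhanes_cycle(cb$table_name)
    comp <- NULL
    if (!is.null(manifest) && "component" %in% names(manifest)) {
      comp <- manifest$component[match(cb$table_name, manifest$table_name)]
    }
    if (is.null(comp) || is.na(comp)) comp <- infer_component(cb$table_name)
    tibble::tibble(
      variable = unname(vapply(entries, `[[`, character(1), "variable_name")),
      description = unname(vapply(entries, `[[`, character(1), "sas_label")),
      table_name = cb$table_name,
      begin_year = cyc$start_year,
      end_year = cyc$end_year,
      component = comp
    )
  })
}

infer_component <- function(table_name) {
  base <- sub("^P_", "", toupper(table_name))
  if (grepl("^DEMO", base)) return("demographics")
  if (grepl("^DR|^DS", base)) return("dietary")
  if (grepl("^BPX|^BMX|^OHX|^DXX", base)) return("examination")
  if (grepl("^SS|^LB|^L[0-9]|^PB|^UR", base)) return("laboratory")
  "questionnaire"
}

#' Search the variable index
#'
#' @param index Variable index from [build_variable_index()].
#' @param pattern Non-empty search string (substring by default).
#' @param fields Which fields to match against: `"description"` (default),
#'   `"variable"`, or both.
#' @param component Optional component filter, one of demographics,
#'   dietary, examination, laboratory, questionnaire.
#' @param regex Interpret `pattern` as a regular expression.
#' @return Matching index rows (a tibble, possibly empty).
#' @export
search_variables <- function(index, pattern, fields = "description",
                             component = NULL, regex = FALSE) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  fields <- match.arg(fields, c("description", "variable"), several.ok = TRUE)
  if (nrow(index) == 0L) return(index)
  hit <- rep(FALSE, nrow(index))
  for (f in fields) {
    hit <- hit | if (regex) {
      grepl(pattern, index[[f]], ignore.case = TRUE)
    } else {
      grepl(toupper(pattern), toupper(index[[f]]), fixed = TRUE)
    }
  }
  out <- index[hit, , drop = FALSE]
  if (!is.null(component)) {
    component <- match.arg(component, c("demographics", "dietary", "examination",
                                        "laboratory", "questionnaire"))
    out <- dplyr::filter(out, .data$component == !!component)
  }
  out
}

#' Find the tables that contain a variable
#'
#' Exact (case-insensitive) variable-name match, sorted by cycle start
#' year — the usual first step when tracing a measurement across cycles.
#'
#' @param index Variable index from [build_variable_index()].
#' @param varname Variable name.
#' @return A tibble with `table_name`, `begin_year`, `end_year`.
#' @export
search_tables_by_variable <- function(index, varname) {
  stopifnot(is.character(varname), length(varname) == 1L)
  out <- index[toupper(index$variable) == toupper(varname), , drop = FALSE]
  out <- dplyr::arrange(out, .data$begin_year, .data$table_name)
  dplyr::select(out, "table_name", "begin_year", "end_year")
}

#' Retrieve a table, using the on-disk cache
#'
#' Returns the decoded transport table for `name`, fetching it into the
#' cache first when necessary. The cache is keyed by table name
#' (`<cache>/<NAME>.xpt`, with an `.md5` checksum sidecar recorded at
#' write time); a warm cache means no network I/O at all. In offline mode
#' a cache miss is an error naming the expected path.
#'
#' @param name Table name, e.g. `"DEMO_J"`.
#' @param cache_dir Cache directory (defaults to `nhanes_options()`).
#' @param offline Forbid network access (defaults to `nhanes_options()`).
#' @param base_url `sprintf` template with two `%s` slots (cycle path,
#'   file name) used for network retrieval.
#' @return An [xpt_table()].
#' @export
fetch_table <- function(name, cache_dir = NULL, offline = NULL, base_url = NULL) {
  name <- toupper(name)
  cache_dir <- config_value("cache_dir", cache_dir)
  offline <- config_value("offline", offline)
  path <- file.path(cache_dir, paste0(name, ".xpt"))
  if (!file.exists(path)) {
    if (isTRUE(offline)) {
      stop("offline cache miss for table ", name, ": expected file at ", path,
           call. = FALSE)
    }
    fetch_into_cache(name, path, "XPT", base_url)
  }
  read_xpt(path)
}

#' @rdname fetch_table
#' @export
fetch_codebook <- function(name, cache_dir = NULL, offline = NULL, base_url = NULL) {
  name <- toupper(name)
  cache_dir <- config_value("cache_dir", cache_dir)
  offline <- config_value("offline", offline)
  path <- file.path(cache_dir, paste0(name, ".htm"))
  if (!file.exists(path)) {
    if (isTRUE(offline)) {
      stop("offline cache miss for codebook ", name, ": expected file at ", path,
           call. = FALSE)
    }
    fetch_into_cache(name, path, "htm", base_url)
  }
  parse_codebook(xml2::read_html(path), table_name = name, source = path)
}

fetch_into_cache <- function(name, path, ext, base_url) {
  base_url <- config_value("base_url", base_url)
  cyc <- nhanes_cycle(name)
  url <- sprintf(base_url, cyc$label, paste0(name, ".", ext))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  log_msg("info", "fetching ", url)
  status <- tryCatch(utils::download.file(url, path, mode = "wb", quiet = TRUE),
                     error = function(e) {
                       stop("network fetch failed for ", url, ": ",
                            conditionMessage(e), " (retriable)", call. = FALSE)
                     })
  if (!identical(status, 0L)) {
    unlink(path)
    stop("network fetch failed for ", url, " with status ", status,
         " (retriable)", call. = FALSE)
  }
  writeLines(unname(tools::md5sum(path)), paste0(path, ".md5"))
  invisible(path)
}
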