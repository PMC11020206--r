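#' Construct an XPT table object
#'
#' An `xpt_table` models one member of a SAS transport library: the decoded
#' data (one column per variable, doubles for numeric variables and
#' character for text), together with the metadata the transport format
#' carries (member name, variable labels, storage lengths, creation
#' timestamp). NHANES publishes one member per file, so the toolkit works
#' with single-member tables throughout.
#'
#' Numeric columns may carry a `"na_code"` character attribute (parallel to
#' the column) recording special missing sentinels (`".A"`...) where the
#' value is `NA`; NHANES itself only uses the plain `"."` sentinel, which
#' needs no annotation.
#'
#' @param data A data frame; columns must be numeric or character. Column
#'   names become variable names (uppercased, at most 8 ASCII characters).
#' @param member_name Member (dataset) name, at most 8 ASCII characters.
#' @param labels Optional named character vector of variable labels (at
#'   most 40 characters each); unnamed variables get an empty label.
#' @param member_label Optional dataset label (at most 40 characters).
#' @param lengths Optional named integer vector of storage lengths
#'   (numeric 2--8 bytes, character 1--200); defaults to 8 for numeric and
#'   the maximum observed width (at least 1) for character columns.
#' @param created Creation timestamp written to the transport header. The
#'   default is a fixed epoch so that fixture output is byte-reproducible.
#' @return An object of class `xpt_table` with fields `member_name`,
#'   `member_label`, `variables` (a tibble of per-variable metadata),
#'   `data` (a tibble) and `created`.
#' @seealso [read_xpt()], [write_xpt()]
#' @export
xpt_table <- function(data, member_name, labels = NULL, member_label = "",
                      lengths = NULL,
                      created = as.POSIXct("2020-01-01 00:00:00", tz = "UTC")) {
  data <- tibble::as_tibble(data)
  if (ncol(data) == 0L) {
    stop("an xpt_table needs at least one variable", call. = FALSE)
  }
  member_name <- toupper(as.character(member_name))
  check_xpt_name(member_name, what = "member name")

  nms <- toupper(names(data))
  for (nm in nms) check_xpt_name(nm, what = "variable name")
  if (anyDuplicated(nms)) {
    stop("variable names must be unique (case-insensitively): ",
         paste(nms[duplicated(nms)], collapse = ", "), call. = FALSE)
  }
  names(data) <- nms

  types <- vapply(data, function(col) {
    if (is.numeric(col)) "numeric" else if (is.character(col)) "character"
    else stop("columns must be numeric or character", call. = FALSE)
  }, character(1))
  data[types == "numeric"] <- lapply(data[types == "numeric"], function(col) {
    nc <- attr(col, "na_code")
    col <- as.double(col)
    if (!is.null(nc)) attr(col, "na_code") <- nc
    col
  })

  lab <- vapply(nms, function(nm) {
    v <- if (!is.null(labels) && nm %in% names(labels)) labels[[nm]] else ""
    if (nchar(v) > 40L) stop("label for ", nm, " exceeds 40 characters", call. = FALSE)
    v
  }, character(1))
  if (nchar(member_label) > 40L) {
    stop("member label exceeds 40 characters", call. = FALSE)
  }

  len <- vapply(seq_along(nms), function(i) {
    nm <- nms[i]
    if (!is.null(lengths) && nm %in% names(lengths)) {
      l <- as.integer(lengths[[nm]])
    } else if (types[i] == "numeric") {
      l <- 8L
    } else {
      w <- nchar(data[[i]], type = "bytes")
      l <- max(1L, w[!is.na(w)], 0L)
    }
    if (types[i] == "numeric" && (l < 2L || l > 8L)) {
      stop("numeric storage length for ", nm, " must be in [2, 8]", call. = FALSE)
    }
    if (types[i] == "character" && (l < 1L || l > 200L)) {
      stop("character storage length for ", nm, " must be in [1, 200]", call. = FALSE)
    }
    l
  }, integer(1))

  structure(
    list(
      member_name = member_name,
      member_label = as.character(member_label),
      variables = tibble::tibble(
        name = nms,
        label = unname(lab),
        type = unname(types),
        length = unname(len),
        position = seq_along(nms)
      ),
      data = data,
      created = created
    ),
    class = "xpt_table"
  )
}

check_xpt_name <- function(x, what) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a non-empty string", call. = FALSE)
  }
  if (nchar(x, type = "bytes") > 8L || grepl("[^A-Z0-9_]", x)) {
    stop(what, " '", x, "' is not a valid 8-character SAS name", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.xpt_table <- function(x, ...) {
  cat("<xpt_table> ", x$member_name,
      if (nzchar(x$member_label)) paste0(" (", x$member_label, ")") else "",
      "\n", sep = "")
  cat("  ", nrow(x$data), " rows x ", nrow(x$variables), " variables; created ",
      format(x$created, "%Y-%m-%d %H:%M:%S", tz = "UTC"), " UTC\n", sep = "")
  print(x$variables, n = 10)
  invisible(x)
}

#' @export
as.data.frame.xpt_table <- function(x, ...) as.data.frame(x$data, ...)

#' Coerce an XPT table to a tibble
#'
#' Drops the transport metadata and returns the decoded data columns.
#'
#' @param x An [xpt_table()].
#' @param ... Passed on to [tibble::as_tibble()].
#' @return A tibble.
#' @export
as_tibble.xpt_table <- function(x, ...) tibble::as_tibble(x$data, ...)

#' Number of observations in an XPT table
#'
#' @param x An [xpt_table()].
#' @return Integer row count.
#' @export
n_rows <- function(x) {
  stopifnot(inherits(x, "xpt_table"))
  nrow(x$data)
}
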