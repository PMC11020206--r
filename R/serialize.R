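#' Write an analysis table to CSV with a metadata sidecar
#'
#' Plain CSV drops the typing that makes a translated table safe to
#' analyse (which columns are labelled categoricals, in which category
#' order) and its provenance. `write_data_table()` therefore writes a
#' sidecar file (`<path>.meta`, line-oriented key-value text) holding the
#' column types, factor level sets and provenance attributes;
#' [read_data_table()] uses it to restore the table exactly.
#'
#' @param data A (translated) table.
#' @param path Output CSV path; the sidecar goes to `<path>.meta`.
#' @return `path`, invisibly.
#' @export
write_data_table <- function(data, path) {
  df <- as.data.frame(data)
  out <- df
  for (col in names(out)) if (is.factor(out[[col]])) out[[col]] <- as.character(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, na = "")

  esc <- function(s) gsub("\t", " ", s)
  lines <- c(
    paste0("name\t", attr(data, "nhanes_name") %||% ""),
    paste0("cycle\t", if (!is.null(attr(data, "cycle"))) attr(data, "cycle")$label else ""),
    paste0("translated\t", if (isTRUE(attr(data, "translated"))) "1" else "0"),
    paste0("sources\t", paste(attr(data, "sources") %||% character(), collapse = ","))
  )
  for (col in names(df)) {
    if (is.factor(df[[col]])) {
      lines <- c(lines, paste0("factor\t", col, "\t",
                               paste(esc(levels(df[[col]])), collapse = "\t")))
    } else if (is.numeric(df[[col]])) {
      lines <- c(lines, paste0("numeric\t", col))
    } else {
      lines <- c(lines, paste0("text\t", col))
    }
  }
  fl <- attr(data, "fill_log")
  if (!is.null(fl) && nrow(fl)) {
    lines <- c(lines, paste("fill", fl$gate, fl$target, fl$fill, fl$n_filled,
                            sep = "\t"))
  }
  writeLines(lines, paste0(path, ".meta"), useBytes = TRUE)
  invisible(path)
}

#' @rdname write_data_table
#' @export
read_data_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) {
    return(tibble::as_tibble(df))
  }
  parts <- strsplit(readLines(meta_path), "\t", fixed = TRUE)
  attrs <- list(fill_log = NULL)
  fills <- list()
  for (p in parts) {
    key <- p[1]
    if (key == "name") attrs$nhanes_name <- p[2] %||% ""
    else if (key == "cycle" && length(p) >= 2L && nzchar(p[2])) {
      attrs$cycle <- tryCatch({
        if (grepl("March", p[2])) new_cycle(2017L, prepandemic = TRUE)
        else new_cycle(as.integer(sub("-.*", "", p[2])))
      }, error = function(e) NULL)
    } else if (key == "translated") attrs$translated <- identical(p[2], "1")
    else if (key == "sources") attrs$sources <- strsplit(p[2] %||% "", ",")[[1]]
    else if (key == "factor") {
      col <- p[2]
      lvls <- p[-(1:2)]
      if (col %in% names(df)) df[[col]] <- factor(df[[col]], levels = lvls)
    } else if (key == "fill") {
      fills[[length(fills) + 1L]] <- tibble::tibble(
        gate = p[2], target = p[3], fill = p[4], n_filled = as.integer(p[5])
      )
    }
  }
  out <- tibble::as_tibble(df)
  for (nm in setdiff(names(attrs), "fill_log")) attr(out, nm) <- attrs[[nm]]
  if (length(fills)) attr(out, "fill_log") <- dplyr::bind_rows(fills)
  out
}
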