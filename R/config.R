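the <- new.env(parent = emptyenv())

default_config <- function() {
  list(
    cache_dir = file.path(tempdir(), "nhaneskit-cache"),
    base_url = "https://wwwn.cdc.gov/Nchs/Nhanes/%s/%s",
    offline = FALSE,
    strata_var = "SDMVSTRA",
    psu_var = "SDMVPSU",
    weight_var = "WTMEC2YR",
    log_level = "info"
  )
}

#' Get or set toolkit options
#'
#' Package-level configuration: the on-disk cache directory, the base URL
#' template used for network retrieval (so mirrors or local containers can
#' be substituted without code changes), the offline switch (when `TRUE`
#' any network operation is an error), the default design-variable names
#' used by [svy_design()] for NHANES tables (the masked-variance
#' pseudo-stratum `SDMVSTRA`, pseudo-PSU `SDMVPSU`, and the examination
#' weight `WTMEC2YR`), and the log level.
#'
#' Called with no arguments, returns the current configuration as a list.
#' Called with named values, updates them and invisibly returns the
#' previous configuration (convenient for restoring in `on.exit()`).
#'
#' @param ... Named options to set, e.g. `nhanes_options(offline = TRUE)`.
#' @return The configuration list (invisibly when setting).
#' @export
nhanes_options <- function(...) {
  if (is.null(the$config)) the$config <- default_config()
  new <- list(...)
  if (length(new) == 0L) {
    return(the$config)
  }
  if (is.null(names(new)) || any(!nzchar(names(new)))) {
    stop("all options must be named", call. = FALSE)
  }
  unknown <- setdiff(names(new), names(default_config()))
  if (length(unknown)) {
    stop("unknown option(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  old <- the$config
  the$config[names(new)] <- new
  invisible(old)
}

config_value <- function(key, override = NULL) {
  if (!is.null(override)) return(override)
  nhanes_options()[[key]]
}

#' Read a key = value configuration file
#'
#' Parses a flat, TOML-style `key = value` text file into a list usable
#' with [nhanes_options()]. Lines starting with `#` and blank lines are
#' ignored; values `true`/`false` become logicals.
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 0L) {
      stop("cannot parse config line: ", ln, call. = FALSE)
    }
    val <- gsub('^"|"$', "", trimws(m[3]))
    if (tolower(val) %in% c("true", "false")) val <- as.logical(toupper(val))
    out[[m[2]]] <- val
  }
  out
}

config_hash <- function(cfg = nhanes_options()) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","),
                                      character(1)), sep = "="), f)
  unname(tools::md5sum(f))
}

log_msg <- function(level, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  cur <- levels[[config_value("log_level")]] %||% 2L
  if (levels[[level]] >= cur) {
    message("[", level, "] ", ...)
  }
  invisible(NULL)
}
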