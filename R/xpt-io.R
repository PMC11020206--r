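#' Read a SAS XPORT v5 transport file
#'
#' Decodes a single-member SAS transport (XPT) library, the format in which
#' NHANES publishes its raw tables: 80-byte card-image records, ASCII
#' headers, and numeric values in IBM System/370 floating point. Numeric
#' cells decode to doubles (`NA` for the `.` missing sentinel, with special
#' sentinels `.A`--`.Z`/`._` recorded in a per-column `"na_code"`
#' attribute); character cells are right-stripped of padding spaces, and an
#' all-blank cell is kept as `""` rather than promoted to missing, because
#' NHANES encodes missingness through numeric sentinels.
#'
#' Only transport version 5 is supported; version 8/9 libraries (long
#' names) are rejected with a clear error.
#'
#' @param input Path to an `.xpt` file, or a raw vector holding its bytes.
#' @return An [xpt_table()].
#' @examples
#' tab <- xpt_table(data.frame(SEQN = 1:3, AGE = c(40, NA, 61)), "DEMO")
#' read_xpt(write_xpt(tab))
#' @export
read_xpt <- function(input) {
  bytes <- if (is.raw(input)) {
    input
  } else {
    stopifnot(is.character(input), length(input) == 1L)
    readBin(input, "raw", n = file.size(input))
  }
  if (length(bytes) %% 80L != 0L) {
    stop("truncated transport file: length ", length(bytes),
         " is not a multiple of 80 bytes (last full record ends at byte ",
         80L * (length(bytes) %/% 80L), ")", call. = FALSE)
  }
  if (length(bytes) < 80L * 9L) {
    stop("malformed transport file: shorter than the minimal header set", call. = FALSE)
  }
  rec <- function(i) rawToChar(bytes[((i - 1L) * 80L + 1L):(i * 80L)])

  r1 <- rec(1L)
  if (grepl("LIBV8|LIBV9", r1)) {
    stop("XPORT version 8/9 transport files are not supported; ",
         "NHANES publishes version 5", call. = FALSE)
  }
  if (!startsWith(r1, "HEADER RECORD*******LIBRARY HEADER RECORD!!!!!!!")) {
    stop("malformed transport file: missing LIBRARY HEADER RECORD magic", call. = FALSE)
  }
  r4 <- rec(4L)
  if (!startsWith(r4, "HEADER RECORD*******MEMBER  HEADER RECORD!!!!!!!")) {
    stop("malformed transport file: missing MEMBER HEADER RECORD", call. = FALSE)
  }
  namestr_len <- suppressWarnings(as.integer(substr(r4, 75L, 78L)))
  if (is.na(namestr_len) || !namestr_len %in% c(136L, 140L)) {
    stop("malformed transport file: unsupported NAMESTR length '",
         substr(r4, 75L, 78L), "'", call. = FALSE)
  }
  if (!startsWith(rec(5L), "HEADER RECORD*******DSCRPTR HEADER RECORD!!!!!!!")) {
    stop("malformed transport file: missing DSCRPTR HEADER RECORD", call. = FALSE)
  }
  r6 <- rec(6L)
  member_name <- trimws(substr(r6, 9L, 16L))
  created <- parse_xpt_datetime(substr(r6, 65L, 80L))
  r7 <- rec(7L)
  member_label <- trimws(substr(r7, 33L, 72L))

  r8 <- rec(8L)
  if (!startsWith(r8, "HEADER RECORD*******NAMESTR HEADER RECORD!!!!!!!")) {
    stop("malformed transport file: missing NAMESTR HEADER RECORD", call. = FALSE)
  }
  nvars <- suppressWarnings(as.integer(substr(r8, 55L, 58L)))
  if (is.na(nvars) || nvars < 1L) {
    stop("malformed transport file: variable count '", substr(r8, 55L, 58L),
         "' in NAMESTR header", call. = FALSE)
  }

  ns_start <- 8L * 80L
  ns_bytes <- as.integer(ceiling(nvars * namestr_len / 80) * 80)
  if (length(bytes) < ns_start + ns_bytes + 80L) {
    stop("corrupt transport file: NAMESTR block for ", nvars,
         " declared variables overruns the file", call. = FALSE)
  }
  int16 <- function(b, off) as.integer(b[off + 1L]) * 256L + as.integer(b[off + 2L])
  vars <- vector("list", nvars)
  for (j in seq_len(nvars)) {
    b <- bytes[(ns_start + (j - 1L) * namestr_len + 1L):(ns_start + j * namestr_len)]
    ntype <- int16(b, 0L)
    if (!ntype %in% c(1L, 2L)) {
      stop("corrupt transport file: NAMESTR ", j, " has variable type ", ntype,
           " (declared count ", nvars, " disagrees with the NAMESTR block)",
           call. = FALSE)
    }
    nvar0 <- int16(b, 6L)
    if (nvar0 != j) {
      stop("corrupt transport file: NAMESTR ", j, " carries variable number ",
           nvar0, " (declared count ", nvars, " disagrees with the NAMESTR block)",
           call. = FALSE)
    }
    vars[[j]] <- list(
      name = trimws(rawToChar(b[9L:16L])),
      label = trimws(rawToChar(b[17L:56L])),
      type = if (ntype == 1L) "numeric" else "character",
      length = int16(b, 4L)
    )
  }

  obs_at <- ns_start + ns_bytes
  obs_rec <- rawToChar(bytes[(obs_at + 1L):(obs_at + 80L)])
  if (!startsWith(obs_rec, "HEADER RECORD*******OBS     HEADER RECORD!!!!!!!")) {
    stop("corrupt transport file: expected OBS HEADER RECORD at byte ", obs_at,
         call. = FALSE)
  }

  data_bytes <- bytes[seq.int(obs_at + 80L + 1L, length.out = length(bytes) - obs_at - 80L)]
  reclen <- sum(vapply(vars, `[[`, integer(1), "length"))
  nrows <- length(data_bytes) %/% reclen
  rem <- length(data_bytes) %% reclen
  if (rem > 0L) {
    tail_bytes <- data_bytes[(nrows * reclen + 1L):length(data_bytes)]
    if (any(tail_bytes != as.raw(0x20L))) {
      stop("truncated final record: ", rem, " stray data bytes at byte offset ",
           obs_at + 80L + nrows * reclen, call. = FALSE)
    }
  }
  # trailing all-blank records are 80-byte padding, not observations
  if (nrows > 0L) {
    dm <- matrix(data_bytes[seq_len(nrows * reclen)], nrow = reclen)
    blank_rec <- colSums(dm != as.raw(0x20L)) == 0L
    while (nrows > 0L && blank_rec[nrows]) nrows <- nrows - 1L
  }

  cols <- vector("list", nvars)
  names(cols) <- vapply(vars, `[[`, character(1), "name")
  offset <- 0L
  for (j in seq_len(nvars)) {
    v <- vars[[j]]
    if (nrows == 0L) {
      cols[[j]] <- if (v$type == "numeric") double(0) else character(0)
    } else {
      cell <- dm[(offset + 1L):(offset + v$length), seq_len(nrows), drop = FALSE]
      if (v$type == "numeric") {
        # short numerics drop low-order fraction bytes; zero-extend to 8
        full <- matrix(as.raw(0L), nrow = 8L, ncol = nrows)
        full[seq_len(v$length), ] <- cell
        cols[[j]] <- ibm_to_ieee(c(full))
      } else {
        cols[[j]] <- sub(" +$", "", apply(cell, 2L, rawToChar))
      }
    }
    offset <- offset + v$length
  }

  xpt_table(
    tibble::as_tibble(cols),
    member_name = member_name,
    labels = stats::setNames(
      vapply(vars, `[[`, character(1), "label"),
      vapply(vars, `[[`, character(1), "name")
    ),
    member_label = member_label,
    lengths = stats::setNames(
      vapply(vars, `[[`, integer(1), "length"),
      vapply(vars, `[[`, character(1), "name")
    ),
    created = created
  )
}

#' Write a SAS XPORT v5 transport file
#'
#' Serializes an [xpt_table()] to the single-member transport layout that
#' [read_xpt()] decodes: every record is 80 bytes, records are padded with
#' ASCII spaces, and numeric cells are encoded in IBM System/370 floating
#' point. The output of a write/read cycle reproduces the input table
#' field-for-field, and a fixed `created` timestamp makes output
#' byte-reproducible across runs.
#'
#' @param x An [xpt_table()].
#' @param path Optional output path. When `NULL` the encoded bytes are
#'   returned as a raw vector.
#' @return `path` invisibly when writing to a file, otherwise the raw
#'   bytes.
#' @export
write_xpt <- function(x, path = NULL) {
  stopifnot(inherits(x, "xpt_table"))
  pad80 <- function(s) {
    b <- charToRaw(s)
    if (length(b) %% 80L == 0L) b else c(b, rep(as.raw(0x20L), 80L - length(b) %% 80L))
  }
  cfield <- function(s, width) {
    b <- charToRaw(substr(s, 1L, width))
    c(b, rep(as.raw(0x20L), width - length(b)))
  }
  int16 <- function(v) as.raw(c(v %/% 256L, v %% 256L))
  int32 <- function(v) as.raw(c(v %/% 16777216L, (v %/% 65536L) %% 256L,
                                (v %/% 256L) %% 256L, v %% 256L))
  dt <- format_xpt_datetime(x$created)

  hdr <- function(kind) {
    paste0("HEADER RECORD*******", kind, " HEADER RECORD!!!!!!!",
           strrep("0", 30), "  ")
  }
  sasline <- function(second) {
    paste0("SAS     ", sprintf("%-8s", second), "SASLIB  ", "6.06    ",
           "bsd4.2  ", strrep(" ", 24), dt)
  }

  out <- list(
    charToRaw(hdr("LIBRARY")),
    charToRaw(sasline("SAS")),
    charToRaw(paste0(dt, strrep(" ", 64))),
    charToRaw(paste0("HEADER RECORD*******MEMBER  HEADER RECORD!!!!!!!",
                     strrep("0", 16), "0160", strrep("0", 7), "140  ")),
    charToRaw(hdr("DSCRPTR")),
    charToRaw(paste0("SAS     ", sprintf("%-8s", x$member_name), "SASDATA ",
                     "6.06    ", "bsd4.2  ", strrep(" ", 24), dt)),
    charToRaw(paste0(dt, strrep(" ", 16), sprintf("%-40s", x$member_label),
                     sprintf("%-8s", ""))),
    charToRaw(paste0("HEADER RECORD*******NAMESTR HEADER RECORD!!!!!!!",
                     strrep("0", 6), sprintf("%04d", nrow(x$variables)),
                     strrep("0", 20), "  "))
  )

  npos <- 0L
  ns <- vector("list", nrow(x$variables))
  for (j in seq_len(nrow(x$variables))) {
    v <- x$variables[j, ]
    ns[[j]] <- c(
      int16(if (v$type == "numeric") 1L else 2L),
      int16(0L),
      int16(v$length),
      int16(j),
      cfield(v$name, 8L),
      cfield(v$label, 40L),
      cfield("", 8L), int16(0L), int16(0L), int16(0L), cfield("", 2L),
      cfield("", 8L), int16(0L), int16(0L),
      int32(npos),
      rep(as.raw(0L), 52L)
    )
    npos <- npos + v$length
  }
  ns_block <- unlist(ns)
  if (length(ns_block) %% 80L != 0L) {
    ns_block <- c(ns_block, rep(as.raw(0x20L), 80L - length(ns_block) %% 80L))
  }
  out <- c(out, list(ns_block, charToRaw(hdr("OBS    "))))

  n <- nrow(x$data)
  reclen <- sum(x$variables$length)
  if (n > 0L) {
    dm <- matrix(as.raw(0x20L), nrow = reclen, ncol = n)
    offset <- 0L
    for (j in seq_len(nrow(x$variables))) {
      v <- x$variables[j, ]
      col <- x$data[[j]]
      if (v$type == "numeric") {
        enc <- matrix(ieee_to_ibm(col, na_code = attr(col, "na_code")), nrow = 8L)
        dm[(offset + 1L):(offset + v$length), ] <- enc[seq_len(v$length), , drop = FALSE]
      } else {
        col[is.na(col)] <- ""
        if (any(nchar(col, type = "bytes") > v$length)) {
          stop("character value longer than the declared storage length for ",
               v$name, call. = FALSE)
        }
        for (i in seq_len(n)) {
          b <- charToRaw(col[i])
          if (length(b)) dm[(offset + 1L):(offset + length(b)), i] <- b
        }
      }
      offset <- offset + v$length
    }
    data_block <- c(dm)
    if (length(data_block) %% 80L != 0L) {
      data_block <- c(data_block, rep(as.raw(0x20L), 80L - length(data_block) %% 80L))
    }
    out <- c(out, list(data_block))
  }

  bytes <- unlist(out)
  stopifnot(length(bytes) %% 80L == 0L)
  if (is.null(path)) {
    bytes
  } else {
    writeBin(bytes, path)
    invisible(path)
  }
}

format_xpt_datetime <- function(t) {
  t <- as.POSIXlt(t, tz = "UTC")
  sprintf("%02d%s%02d:%02d:%02d:%02d",
          t$mday, toupper(month.abb[t$mon + 1L]), t$year %% 100L,
          t$hour, t$min, t$sec)
}

parse_xpt_datetime <- function(s) {
  s <- trimws(s)
  m <- regmatches(s, regexec("^(\\d{2})([A-Z]{3})(\\d{2}):(\\d{2}):(\\d{2}):(\\d{2})$", s))[[1]]
  if (length(m) == 0L) {
    return(as.POSIXct(NA))
  }
  mon <- match(m[3], toupper(month.abb))
  yy <- as.integer(m[4])
  year <- if (yy < 60L) 2000L + yy else 1900L + yy
  as.POSIXct(sprintf("%04d-%02d-%02d %s:%s:%s", year, mon, as.integer(m[2]),
                     m[5], m[6], m[7]), tz = "UTC")
}
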