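#' Construct a complex survey design
#'
#' Binds a respondent-level table to its sampling design: the
#' (pseudo-)stratum and (pseudo-)PSU identifiers released for variance
#' estimation and the person-level sample weight, each weight being the
#' number of people in the target population the respondent represents.
#' All estimation in this package is design-based: point estimates use the
#' weights, and standard errors use Taylor linearization over PSU totals
#' within strata under the with-replacement first-stage approximation.
#'
#' The design must be created over the *full* dataset, before any
#' subsetting: subpopulation estimates come from [subset_design()], which
#' masks rows without removing them, so every stratum and PSU keeps
#' contributing to the variance. Rows with a missing weight are excluded
#' at construction with a count warning; nonpositive weights are an
#' error.
#'
#' @param data A tibble (e.g. a merged, translated table).
#' @param strata_var,psu_var,weight_var Column names; defaults come from
#'   [nhanes_options()] (the NHANES masked design variables `SDMVSTRA`,
#'   `SDMVPSU` and the examination weight `WTMEC2YR`).
#' @param nested Are PSU identifiers nested within strata (the NHANES
#'   convention, where PSUs are numbered 1, 2 within each stratum)? When
#'   `FALSE`, PSU identifiers must be globally unique across strata.
#' @param lonely_psu Policy for strata containing a single PSU, where the
#'   between-PSU variance is undefined: `"error"` (default, conservative),
#'   `"centered"` (deviations taken about the grand PSU-total mean) or
#'   `"certainty"` (the stratum contributes zero variance).
#' @return An object of class `svy_design`.
#' @export
svy_design <- function(data, strata_var = NULL, psu_var = NULL,
                       weight_var = NULL, nested = TRUE,
                       lonely_psu = c("error", "centered", "certainty")) {
  lonely_psu <- match.arg(lonely_psu)
  strata_var <- config_value("strata_var", strata_var)
  psu_var <- config_value("psu_var", psu_var)
  weight_var <- config_value("weight_var", weight_var)
  data <- tibble::as_tibble(data)
  for (v in c(strata_var, psu_var, weight_var)) {
    if (!v %in% names(data)) {
      stop("design column ", v, " not found in the data", call. = FALSE)
    }
  }
  w <- data[[weight_var]]
  if (anyNA(w)) {
    n_drop <- sum(is.na(w))
    warning(n_drop, " row(s) with missing weight excluded from the design",
            call. = FALSE)
    data <- data[!is.na(w), , drop = FALSE]
    w <- data[[weight_var]]
  }
  if (any(w <= 0)) {
    stop("sample weights must be strictly positive; found ",
         sum(w <= 0), " nonpositive value(s)", call. = FALSE)
  }
  if (anyNA(data[[strata_var]]) || anyNA(data[[psu_var]])) {
    stop("strata and PSU identifiers must be non-missing", call. = FALSE)
  }

  stratum <- as.character(data[[strata_var]])
  psu_raw <- as.character(data[[psu_var]])
  psu <- if (nested) paste(stratum, psu_raw, sep = "\r") else psu_raw
  if (!nested) {
    dup <- unique(stats::aggregate(stratum, list(psu = psu), function(s) length(unique(s))))
    if (any(dup$x > 1L)) {
      stop("with nested = FALSE, PSU identifiers must not repeat across strata",
           call. = FALSE)
    }
  }
  census <- dplyr::distinct(tibble::tibble(stratum = stratum, psu = psu))
  n_h <- table(census$stratum)
  if (lonely_psu == "error" && any(n_h == 1L)) {
    stop("lonely PSU: stratum ", paste(names(n_h)[n_h == 1L], collapse = ", "),
         " has a single PSU; set lonely_psu = 'centered' or 'certainty' ",
         "to choose a variance policy", call. = FALSE)
  }

  structure(
    list(
      data = data,
      strata_var = strata_var,
      psu_var = psu_var,
      weight_var = weight_var,
      nested = nested,
      lonely_psu = lonely_psu,
      stratum = stratum,
      psu = psu,
      domain = rep(TRUE, nrow(data)),
      psu_census = census
    ),
    class = "svy_design"
  )
}

#' @export
print.svy_design <- function(x, ...) {
  cat("<svy_design> ", nrow(x$data), " respondents; ",
      length(unique(x$stratum)), " strata, ", nrow(x$psu_census), " PSUs\n",
      "  strata = ", x$strata_var, ", psu = ", x$psu_var,
      ", weight = ", x$weight_var, "\n",
      "  domain: ", sum(x$domain), " of ", length(x$domain), " rows in scope\n",
      sep = "")
  invisible(x)
}

#' Restrict a design to a subpopulation
#'
#' Domain (subpopulation) estimation: the returned design estimates over
#' the rows satisfying the predicate, but no row is deleted — the domain
#' is a mask, and the stratum/PSU census is unchanged. This is what makes
#' subpopulation standard errors valid; deleting rows first and then
#' building a design generally gives a different (wrong) variance,
#' because strata and PSUs that happen to lose all their subpopulation
#' members would silently vanish from the between-PSU comparison.
#'
#' Subsets compose: `subset_design(subset_design(d, A), B)` equals
#' `subset_design(d, A & B)`.
#'
#' @param design A [svy_design()].
#' @param predicate An expression in the data's columns (tidy-evaluated),
#'   or a logical vector over the design's rows. Rows where the predicate
#'   is `NA` leave the domain.
#' @return A `svy_design` with an updated domain mask.
#' @examples
#' \dontrun{over40 <- subset_design(d, RIDAGEYR > 40)}
#' @export
subset_design <- function(design, predicate) {
  stopifnot(inherits(design, "svy_design"))
  q <- rlang::enquo(predicate)
  val <- rlang::eval_tidy(q, data = design$data)
  if (!is.logical(val)) {
    stop("predicate must evaluate to a logical vector", call. = FALSE)
  }
  val <- rep_len(val, nrow(design$data))
  val[is.na(val)] <- FALSE
  new_domain <- design$domain & val
  if (!any(new_domain)) {
    stop("empty domain: the predicate selects no rows", call. = FALSE)
  }
  design$domain <- new_domain
  design
}

#' Design-based mean with Taylor-linearized standard error
#'
#' Estimates the population mean of `y` as the weighted (Hajek) ratio
#' `sum(w * y) / sum(w)` over in-domain rows with non-missing `y`. The
#' standard error comes from first-order Taylor linearization: each
#' contributing row gets the score `u_i = w_i (y_i - est) / W`; scores
#' are summed to PSU totals `z_hj`; and the variance is the stratified
#' between-PSU (with-replacement) estimator
#' `sum_h n_h / (n_h - 1) * sum_j (z_hj - mean_j(z_hj))^2`, where `n_h`
#' counts the PSUs of stratum `h` in the *full* design. Rows outside the
#' domain, or with missing `y`, contribute a zero score but keep their
#' PSU in the comparison — the substantive difference from estimating on
#' a deleted subset.
#'
#' @param design A [svy_design()].
#' @param y Name of a numeric column.
#' @return A one-row tibble of class `svy_estimate` with columns `y`,
#'   `estimate`, `se`, `n_obs`.
#' @export
svy_mean <- function(design, y) {
  stopifnot(inherits(design, "svy_design"))
  yv <- design$data[[y]]
  if (is.null(yv)) stop("column ", y, " not found", call. = FALSE)
  if (!is.numeric(yv)) stop("column ", y, " is not numeric", call. = FALSE)
  D <- design$domain & !is.na(yv)
  n_obs <- sum(D)
  if (n_obs == 0L) {
    stop("empty domain: no in-domain rows with non-missing ", y, call. = FALSE)
  }
  w <- design$data[[design$weight_var]]
  W <- sum(w[D])
  est <- sum(w[D] * yv[D]) / W

  u <- numeric(nrow(design$data))
  u[D] <- w[D] * (yv[D] - est) / W
  variance <- linearized_variance(u, design)

  out <- tibble::tibble(y = y, estimate = est, se = sqrt(variance), n_obs = n_obs)
  class(out) <- c("svy_estimate", class(out))
  out
}

linearized_variance <- function(u, design) {
  key <- paste(design$stratum, design$psu, sep = "\r")
  z <- rowsum(u, key, reorder = TRUE)[, 1L]
  z_stratum <- sub("\r.*$", "", names(z))
  grand_mean <- mean(z)
  variance <- 0
  for (h in unique(z_stratum)) {
    zh <- z[z_stratum == h]
    n_h <- length(zh)
    if (n_h == 1L) {
      variance <- variance + switch(
        design$lonely_psu,
        error = stop("lonely PSU in stratum ", h,
                     "; choose a lonely_psu policy", call. = FALSE),
        centered = (zh - grand_mean)^2,
        certainty = 0
      )
    } else {
      variance <- variance + n_h / (n_h - 1) * sum((zh - mean(zh))^2)
    }
  }
  unname(variance)
}

#' Design-based means by group
#'
#' Computes [svy_mean()] for each category of a labelled-categorical
#' grouping column, each as a domain estimate on the full design (never by
#' splitting the data). A category with no contributing observations is
#' kept in the output, flagged with `n_obs = 0` and `NA` estimates.
#'
#' @param design A [svy_design()].
#' @param y Name of a numeric column.
#' @param group Name of a factor column.
#' @return A tibble of class `svy_estimate`, one row per category, in
#'   category order, with columns `group`, `y`, `estimate`, `se`,
#'   `n_obs`.
#' @export
svy_mean_by <- function(design, y, group) {
  stopifnot(inherits(design, "svy_design"))
  g <- design$data[[group]]
  if (is.null(g)) stop("column ", group, " not found", call. = FALSE)
  if (!is.factor(g)) {
    stop("grouping column ", group, " must be a labelled categorical; ",
         "translate the table first", call. = FALSE)
  }
  rows <- purrr::map(levels(g), function(lv) {
    res <- tryCatch({
      d_g <- subset_design(design, !is.na(g) & g == lv)
      svy_mean(d_g, y)
    }, error = function(e) {
      tibble::tibble(y = y, estimate = NA_real_, se = NA_real_, n_obs = 0L)
    })
    dplyr::bind_cols(tibble::tibble(group = lv), res)
  })
  out <- dplyr::bind_rows(rows)
  names(out)[1] <- group
  class(out) <- c("svy_estimate", class(out))
  out
}

#' Unweighted (naive) group means
#'
#' The plain arithmetic mean per category, ignoring the survey design and
#' missing values of `y`. On its own this estimates nothing about the
#' population — NHANES deliberately oversamples several demographic
#' groups — but it is the standard side-by-side comparison that shows how
#' much the weights matter.
#'
#' @param data A data frame.
#' @param y Name of a numeric column.
#' @param group Optional name of a grouping column; when `NULL` a single
#'   overall row is returned.
#' @return A tibble with columns `group` (absent for the overall mean),
#'   `mean`, `n`.
#' @export
naive_mean_by <- function(data, y, group = NULL) {
  yv <- data[[y]]
  stopifnot(is.numeric(yv))
  if (is.null(group)) {
    return(tibble::tibble(mean = mean(yv, na.rm = TRUE), n = sum(!is.na(yv))))
  }
  g <- data[[group]]
  out <- tibble::tibble(group = g, yv = yv) |>
    dplyr::filter(!is.na(.data$yv), !is.na(.data$group)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = mean(.data$yv), n = dplyr::n(), .groups = "drop")
  names(out)[1] <- group
  out
}
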