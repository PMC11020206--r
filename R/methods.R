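#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a survey design
#'
#' One row per PSU with its stratum and the number of respondents and
#' in-domain respondents it contributes.
#'
#' @param x A [svy_design()].
#' @param ... Unused.
#' @return A tibble with columns `stratum`, `psu`, `n`, `n_domain`.
#' @export
tidy.svy_design <- function(x, ...) {
  tibble::tibble(stratum = x$stratum, psu = x$psu, domain = x$domain) |>
    dplyr::group_by(.data$stratum, .data$psu) |>
    dplyr::summarise(n = dplyr::n(), n_domain = sum(.data$domain), .groups = "drop")
}

#' @rdname tidy.svy_design
#' @export
glance.svy_design <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$data),
    n_strata = length(unique(x$stratum)),
    n_psu = nrow(x$psu_census),
    n_domain = sum(x$domain),
    weight_sum = sum(x$data[[x$weight_var]]),
    lonely_psu = x$lonely_psu
  )
}

#' Tidy survey estimates
#'
#' `svy_estimate` objects are already tidy tibbles; `tidy()` strips the
#' class, and `glance()` summarises the estimation in one row.
#'
#' @param x A `svy_estimate` from [svy_mean()] or [svy_mean_by()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.svy_estimate <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "svy_estimate")
  out
}

#' @rdname tidy.svy_estimate
#' @export
glance.svy_estimate <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x),
    n_obs = sum(x$n_obs),
    n_empty = sum(x$n_obs == 0L)
  )
}

#' Plot survey estimates
#'
#' Point estimates with 95% confidence intervals
#' (estimate +/- 1.96 standard errors), one row per group when the
#' estimate is grouped.
#'
#' @param object A `svy_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.svy_estimate <- function(object, ...) {
  df <- tidy(object)
  group_col <- setdiff(names(df), c("y", "estimate", "se", "n_obs"))
  if (length(group_col) == 0L) {
    df$.group <- df$y
  } else {
    df$.group <- df[[group_col[1]]]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$.group)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$se,
                   xmax = .data$estimate + 1.96 * .data$se),
      height = 0.2
    ) +
    ggplot2::labs(x = unique(df$y), y = NULL) +
    ggplot2::theme_minimal()
}

#' Compare naive and design-based group means side by side
#'
#' Convenience wrapper producing the classic two-column report: the
#' unweighted group means next to the design-based (weighted,
#' Taylor-linearized) means.
#'
#' @param design A [svy_design()].
#' @param y Name of a numeric column.
#' @param group Name of a factor column.
#' @return A tibble with columns `<group>`, `raw_mean`, `adj_mean`,
#'   `adj_se`, `n_obs`.
#' @export
compare_means <- function(design, y, group) {
  adj <- svy_mean_by(design, y, group)
  raw <- naive_mean_by(design$data[design$domain, , drop = FALSE], y, group)
  out <- dplyr::left_join(
    tidy(adj),
    dplyr::rename(raw, raw_mean = "mean", raw_n = "n"),
    by = group
  )
  dplyr::select(out, dplyr::all_of(group), "raw_mean",
                adj_mean = "estimate", adj_se = "se", "n_obs")
}
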