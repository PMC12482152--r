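#' Tidy a differential-result table
#'
#' `ribote_deres` objects are already tidy (one row per gene); `tidy()`
#' strips the class and attributes so the result is a plain tibble.
#'
#' @param x A `ribote_deres` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ribote_deres
#' @export
tidy.ribote_deres <- function(x, ...) {
  as_tibble(unclass_deres(x))
}

unclass_deres <- function(x) {
  attr(x, "contrast") <- NULL
  attr(x, "size_factors") <- NULL
  attr(x, "dispersions") <- NULL
  attr(x, "df_resid") <- NULL
  class(x) <- setdiff(class(x), "ribote_deres")
  x
}

#' One-row summary of a differential-result table
#'
#' @param x A `ribote_deres` object.
#' @param alpha,lfc_min Strict significance thresholds used for the
#'   `n_significant` column.
#' @param ... Unused.
#' @return A one-row tibble: `contrast`, `n_genes`, `n_tested`,
#'   `n_significant`, `df_resid`.
#' @method glance ribote_deres
#' @export
glance.ribote_deres <- function(x, alpha = 0.05, lfc_min = 1, ...) {
  tibble(
    contrast = attr(x, "contrast") %||% unique(x$contrast)[1],
    n_genes = nrow(x),
    n_tested = sum(!is.na(x$pvalue)),
    n_significant = nrow(significance_filter(x, alpha, lfc_min)),
    df_resid = attr(x, "df_resid") %||% NA_integer_
  )
}

#' Tidy a footprint-profile clustering
#'
#' @param x A `ribote_clustering` object.
#' @param ... Unused.
#' @return The cluster assignments as a tibble.
#' @method tidy ribote_clustering
#' @export
tidy.ribote_clustering <- function(x, ...) x$assignments

#' One-row summary of a footprint-profile clustering
#'
#' @param x A `ribote_clustering` object.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `n_profiles`, `separation_achieved`.
#' @method glance ribote_clustering
#' @export
glance.ribote_clustering <- function(x, ...) {
  tibble(k = x$k, n_profiles = nrow(x$assignments),
         separation_achieved = x$separation_achieved)
}

#' Tidy a pipeline report
#'
#' @param x A `ribote_report` object.
#' @param ... Unused.
#' @return The report's summary tibble of headline counts.
#' @method tidy ribote_report
#' @export
tidy.ribote_report <- function(x, ...) x$summary
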