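#' Tidy an adjusted-Spearman fit
#'
#' @param x An `adj_spearman` object.
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `statistic`, `p.value`,
#'   `parameter` (residual df), `estimate.unadjusted`, `p.value.unadjusted`.
#' @export
tidy.adj_spearman <- function(x, ...) {
  tibble::tibble(estimate = x$r, statistic = x$statistic, p.value = x$p,
                 parameter = x$df, estimate.unadjusted = x$r_unadj,
                 p.value.unadjusted = x$p_unadj)
}

#' @rdname tidy.adj_spearman
#' @return `glance()`: one-row tibble with `nobs` and `n.covariate.cols`.
#' @export
glance.adj_spearman <- function(x, ...) {
  tibble::tibble(nobs = x$n, n.covariate.cols = x$n_covariate_cols)
}

#' Tidy a nested-model F comparison
#'
#' @param x A `nested_f` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `df`, `df.residual`, `p.value`.
#' @export
tidy.nested_f <- function(x, ...) {
  tibble::tibble(statistic = x$F, df = x$df1, df.residual = x$df2,
                 p.value = x$p)
}

#' @rdname tidy.nested_f
#' @return `glance()`: one-row tibble with the RSS of both models, their
#'   R-squared and `nobs`.
#' @export
glance.nested_f <- function(x, ...) {
  tibble::tibble(rss.base = x$rss0, rss.full = x$rss1,
                 r.squared.base = x$r2_base, r.squared.full = x$r2_full,
                 nobs = x$n)
}
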