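#' Tidy a DCC model fit
#'
#' @param x A `"dcc_fit"`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @method tidy dcc_fit
#' @export
tidy.dcc_fit <- function(x, ...) {
  tibble::tibble(term = c(if (!is.null(x$m)) "m", "p"),
                 estimate = c(x$m, x$p))
}

#' @rdname tidy.dcc_fit
#' @method glance dcc_fit
#' @export
glance.dcc_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, model = x$model, use = x$use,
                 nobs = x$n_obs)
}

#' Tidy a DCC classification
#'
#' @param x A `"dcc_classification"`.
#' @param ... Unused.
#' @return One row per candidate oligomeric state with the full-data
#'   mismatch coefficient, its bootstrap mean and confidence interval.
#' @method tidy dcc_classification
#' @export
tidy.dcc_classification <- function(x, ...) {
  x$states
}

#' @rdname tidy.dcc_classification
#' @method glance dcc_classification
#' @export
glance.dcc_classification <- function(x, ...) {
  tibble::tibble(n_star = x$n_star, B = x$B, n_poi = x$n_poi,
                 p = x$fit$p, m = x$fit$m %||% NA_real_,
                 r.squared = x$fit$r_squared)
}
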