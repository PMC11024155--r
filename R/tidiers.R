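#' Tidy a paired comparison
#'
#' @param x a `paired_compare` object.
#' @param ... unused.
#' @return a one-row tibble: `method`, `statistic`, `p_value`, `stars`, `n`.
#' @export
tidy.paired_compare <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic,
         p_value = x$p_value, stars = x$stars, n = x$n)
}

#' @rdname tidy.paired_compare
#' @export
glance.paired_compare <- function(x, ...) {
  tibble(normal = x$normal, shapiro_p_x = x$shapiro_p[["x"]],
         shapiro_p_y = x$shapiro_p[["y"]], n = x$n)
}

#' Tidy a ROUT result
#'
#' @param x a `rout` object.
#' @param ... unused.
#' @return a tibble with one row per value: `value`, `residual`, `outlier`.
#' @export
tidy.rout <- function(x, ...) {
  values <- c(x$kept, x$removed)[order(c(which(!x$outlier), which(x$outlier)))]
  tibble(value = values, residual = values - x$center, outlier = x$outlier)
}

#' @rdname tidy.rout
#' @export
glance.rout <- function(x, ...) {
  tibble(n = x$n, n_removed = length(x$removed), center = x$center,
         rsdr = x$rsdr, Q = x$Q)
}
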