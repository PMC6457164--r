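#' Round half away from zero
#'
#' Report rounding for proportions and likelihood ratios. `round()` in R rounds
#' half to even; published accuracy tables conventionally round half up, so
#' 0.405 prints as 0.41.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("twophasedx_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_prob <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || anyNA(x)) stop_config(name, " must be numeric and non-missing")
  lo <- if (allow_zero) 0 else .Machine$double.eps
  hi <- if (allow_one) 1 else 1 - .Machine$double.eps
  if (any(x < lo | x > hi)) stop_config(name, " must lie in [0,1]: got ",
                                        paste(signif(x, 4), collapse = ", "))
  invisible(x)
}

# Monte-Carlo standard error of a mean of iid draws
mc_se <- function(x) stats::sd(x) / sqrt(length(x))
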