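#' @keywords internal
#' @noRd
momcts_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "momcts_error")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == as.integer(x)

stopifnot_scalar_prob <- function(p, what = "p") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    momcts_error(sprintf("%s must be a single value in [0, 1], got %s", what,
                         paste(format(p), collapse = ", ")),
                 "momcts_domain_error")
  }
  invisible(p)
}
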