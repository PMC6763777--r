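#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# stop with a classed condition so tests can target specific failure modes
stop_dsn <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "drugsimnet_error"), ...)
}

warn_dsn <- function(msg, class, ...) {
  rlang::warn(msg, class = c(class, "drugsimnet_warning"), ...)
}

# run `expr` under a temporary RNG seed when `seed` is given, otherwise
# use (and advance) the caller's RNG stream
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_dsn(
      sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
      "dsn_bad_argument"
    )
  }
  invisible(x)
}
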