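#' Internal parameter checks
#'
#' Small guard helpers shared across modules. All user-facing errors are
#' classed conditions so callers can test for them.
#'
#' @name rugosity-checks
#' @keywords internal
NULL

stop_rugosity <- function(message, class) {
  abort(message, class = c(class, "rugosity_error"))
}

warn_rugosity <- function(message, class) {
  warn(message, class = c(class, "rugosity_warning"))
}

check_finite_scalar <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_rugosity(sprintf("`%s` must be a single finite number.", name),
                  "rugosity_invalid_parameter")
  }
  if (positive && x <= 0) {
    stop_rugosity(sprintf("`%s` must be > 0.", name),
                  "rugosity_invalid_parameter")
  }
  if (non_negative && x < 0) {
    stop_rugosity(sprintf("`%s` must be >= 0.", name),
                  "rugosity_invalid_parameter")
  }
  invisible(x)
}

# Evaluate an expression under a fixed seed without disturbing the caller's
# RNG stream; seed = NULL leaves the stream alone.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Truncated-normal draws by rejection; intervals are wide relative to sd in
# every configuration we generate, so rejection is cheap.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    return(rep(pmin(pmax(mean, lower), upper), n))
  }
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw < upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}
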