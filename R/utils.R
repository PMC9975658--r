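# Internal argument checking helpers. All user-facing errors are classed so
# tests can assert on the condition class rather than message wording.

stop_invalid <- function(msg, class = "speechsync_invalid_parameter") {
  rlang::abort(msg, class = c(class, "speechsync_error"))
}

stop_invalid_input <- function(msg) {
  stop_invalid(msg, class = "speechsync_invalid_input")
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    stop_invalid(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    stop_invalid(sprintf("`%s` must be in [%s, %s], got %s.",
                         name, format(lower), format(upper), format(x)))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) {
    stop_invalid(sprintf("`%s` must be a whole number.", name))
  }
  invisible(as.integer(x))
}

# Seeds are applied locally so callers' RNG state is never disturbed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

is_strictly_increasing <- function(x) all(diff(x) > 0)
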