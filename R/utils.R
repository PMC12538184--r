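# internal helpers

# Deterministic 31-bit integer derived from a base seed and string tags, so
# that every (participant, exercise, CL) trial has its own reproducible RNG
# stream independent of generation order.
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1; keeps arithmetic exact in doubles
  h <- as.numeric(seed) %% m
  for (tag in unlist(list(...))) {
    for (code in utf8ToInt(as.character(tag))) {
      h <- (h * 131 + code) %% m
    }
  }
  as.integer(h)
}

# trapezoidal integral at uniform spacing dt
trapz_dt <- function(x, dt) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples to integrate")
  dt * (sum(x) - (x[1] + x[n]) / 2)
}

# cumulative trapezoidal integral, same length as x, starts at 0
cumtrapz_dt <- function(x, dt) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples to integrate")
  c(0, cumsum((x[-1] + x[-n]) / 2 * dt))
}

assert_choice <- function(x, choices, what) {
  if (length(x) != 1 || !x %in% choices) {
    stop(sprintf("invalid %s: '%s' (must be one of %s)", what,
                 paste(x, collapse = ","), paste(choices, collapse = ", ")),
         call. = FALSE)
  }
  x
}

sd0 <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) NA_real_ else stats::sd(x)
}
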