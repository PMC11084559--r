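# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

stop_domain <- function(...) stop(..., call. = FALSE)

check_counts <- function(counts, min_len = 1L) {
  if (!is.numeric(counts) || length(counts) < min_len)
    stop_domain("'counts' must be a numeric vector of length >= ", min_len)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop_domain("'counts' must be non-negative integers")
  as.integer(counts)
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_domain("'", name, "' must be a single finite number")
  if (strict && x <= lower) stop_domain("'", name, "' must be > ", lower)
  if (!strict && x < lower) stop_domain("'", name, "' must be >= ", lower)
  as.numeric(x)
}

# journal-style p-value rounding used in human-readable reports
format_p <- function(p) {
  ifelse(p >= 0.1, sprintf("%.2f", p), sprintf("%.3f", p))
}
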