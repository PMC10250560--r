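# Internal helpers shared across modules.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_dtuemp <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_dtuemp("'%s' must be a single finite number", name)
  }
  if (strict_lower && x <= lower) {
    stop_dtuemp("'%s' must be > %g", name, lower)
  }
  if (!strict_lower && x < lower) {
    stop_dtuemp("'%s' must be >= %g", name, lower)
  }
  if (strict_upper && x >= upper) {
    stop_dtuemp("'%s' must be < %g", name, upper)
  }
  if (!strict_upper && x > upper) {
    stop_dtuemp("'%s' must be <= %g", name, upper)
  }
  invisible(x)
}

# Phase-unwrap an angle sequence in degrees: after unwrapping no consecutive
# step exceeds 180 degrees in magnitude (360-degree jumps removed).
unwrap_deg <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  correction <- -360 * cumsum(round(d / 360))
  theta + c(0, correction)
}

# Full-precision number formatting for the text writers (round-trips doubles).
format_full <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- format(v, digits = 17, scientific = FALSE, trim = TRUE)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1))
}
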