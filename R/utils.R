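# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions that need
#' reproducible draws do not clobber the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
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
  expr
}

# Deterministically derive a stream seed from a master seed; kept < 2^31.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 9973) %% 2147483647
}

# Truncated-normal draws by rejection sampling; bounds may be infinite.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_field(field, "must be a single probability in [0, 1]")
  }
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop_field(field, "must be a single non-negative number")
  }
  invisible(x)
}
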