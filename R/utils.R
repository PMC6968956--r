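# Internal helpers: seeded evaluation, sub-seed derivation, typed errors.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed from (seed, index, salt), kept inside 32-bit range.
# Multiplier is the classic Lehmer/Park-Miller constant; this is stream
# labelling, not cryptography.
derive_seed <- function(seed, index, salt = 0) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919 +
                as.double(salt) * 104729) %% 2147483647)
}

# Stable small hash for participant identifiers (determinism contract of the
# generator depends on id, not list position).
id_hash <- function(id) {
  codes <- utf8ToInt(as.character(id))
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

stop_vicarsep <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "vicarsep_error"),
                      call = call))
}

check_window <- function(window, what = "window") {
  if (!is.numeric(window) || length(window) != 2L || any(!is.finite(window)) ||
      window[1] > window[2]) {
    stop_vicarsep(sprintf("%s must be a finite numeric pair c(start, end) with start <= end", what),
                  "vicarsep_invalid_parameter")
  }
  invisible(window)
}

check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) ||
      rho < 0 || rho >= 1) {
    stop_vicarsep("rho must be a single value in [0, 1)",
                  "vicarsep_invalid_parameter")
  }
  invisible(rho)
}

# Indices of time points falling inside a closed interval [w1, w2] (ms).
window_index <- function(time_ms, window, what = "window") {
  check_window(window, what)
  idx <- which(time_ms >= window[1] - 1e-9 & time_ms <= window[2] + 1e-9)
  if (length(idx) == 0L) {
    stop_vicarsep(sprintf("%s [%g, %g] ms contains no samples", what,
                          window[1], window[2]),
                  "vicarsep_invalid_parameter")
  }
  idx
}
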