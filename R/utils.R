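# Internal helpers shared across modules.

nm_stop <- function(...) stop(..., call. = FALSE)

#' Derive a reproducible RNG seed for a named generator stream
#'
#' Each synthetic generator draws from its own stream derived from the run
#' seed and the generator name, so adding a generator call never perturbs
#' the output of earlier calls made under the same seed.
#'
#' @param seed Integer run seed.
#' @param name Character stream name (e.g. `"expression"`).
#' @return An integer seed below 2^31.
#' @keywords internal
stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1000003
  as.integer(((abs(seed) %% 1000003) * 1009 + h) %% 2147483647)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    nm_stop("configuration error: '", name, "' must be an integer >= ", min)
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  bad <- !is.numeric(x) || length(x) != 1 || is.na(x) ||
    x < lo || x > hi || (lo_open && x == lo) || (hi_open && x == hi)
  if (bad) {
    nm_stop("configuration error: '", name, "' must lie in ",
            if (lo_open) "(" else "[", lo, ", ", hi, if (hi_open) ")" else "]")
  }
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    nm_stop("configuration error: '", name, "' must be > 0")
  }
  as.numeric(x)
}

# Upper-case, whitespace-stripped gene symbols; the canonical join key for
# every cross-dataset comparison in the pipeline. Idempotent.
normalize_symbols <- function(x) toupper(trimws(x))

# Gene symbols G0001, G0002, ... wide enough for n.
synthetic_symbols <- function(n) {
  sprintf(paste0("G%0", max(4, nchar(n)), "d"), seq_len(n))
}
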