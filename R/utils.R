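#' @keywords internal
"_PACKAGE"

# Shared internal helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition so callers can distinguish error kinds.
#' @noRd
abort_autozyg <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "autozyg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

#' Derive a reproducible child seed from a run seed and a stage label.
#' Kept below 2^31 so it is always a valid R integer.
#' @noRd
derive_seed <- function(seed, stage) {
  offset <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

#' Set the RNG seed if one is given, restoring nothing (callers own the RNG
#' stream after a seeded call, matching base R simulation conventions).
#' @noRd
seed_rng <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is_count(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
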