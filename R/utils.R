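# Internal helpers shared across modules.

#' @noRd
stop_ihc <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ihcscore_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Error taxonomy: format (malformed inputs/shape mismatches), parameter
# (bad tuning values), degeneracy (singular/collinear), validation (domain
# violations in tabular data), integrity (impossible internal state),
# insufficient_data (too few observations for a test).
err_format       <- function(msg, ...) stop_ihc("ihc_format_error", msg, ...)
err_parameter    <- function(msg, ...) stop_ihc("ihc_parameter_error", msg, ...)
err_degeneracy   <- function(msg, ...) stop_ihc("ihc_degeneracy_error", msg, ...)
err_validation   <- function(msg, ...) stop_ihc("ihc_validation_error", msg, ...)
err_integrity    <- function(msg, ...) stop_ihc("ihc_integrity_error", msg, ...)
err_insufficient <- function(msg, ...) stop_ihc("ihc_insufficient_data_error", msg, ...)

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# 32-bit FNV-1a over a character scalar, returned as 8 hex digits.
# Used for the provenance header's config hash; multiplication is done in
# 16-bit halves so everything stays exact in doubles.
#' @noRd
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  prime_lo <- 403L  # 16777619 = 256*65536 + 403 -> split as hi=256, lo=403
  prime_hi <- 256L
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    # (hi*2^16 + lo) * (256*2^16 + 403) mod 2^32
    h <- (lo * prime_lo + ((lo * prime_hi + hi * prime_lo) %% 65536) * 65536) %% 4294967296
  }
  lo16 <- h %% 65536
  sprintf("%04x%04x", (h - lo16) / 65536, lo16)
}

#' @noRd
bitwXor_dbl <- function(a, b) {
  # xor of non-negative doubles < 2^32 using 16-bit halves
  a_lo <- a %% 65536; a_hi <- (a - a_lo) / 65536
  b_lo <- b %% 65536; b_hi <- (b - b_lo) / 65536
  bitwXor(as.integer(a_hi), as.integer(b_hi)) * 65536 +
    bitwXor(as.integer(a_lo), as.integer(b_lo))
}

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == round(x)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
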