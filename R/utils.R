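# Internal helpers shared across modules.

# Labelled error conditions so callers can branch on error class rather
# than message text. `class` is one of "input", "config", "numeric", "io".
stop_atersp <- function(class, msg, ...) {
  msg <- sprintf(msg, ...)
  stop(structure(
    class = c(paste0("atersp_", class, "_error"), "atersp_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decibel helpers
#'
#' `db_from_ratio()` converts a power ratio to decibels (10*log10);
#' `amp_scale_from_db()` converts a dB change to the corresponding
#' amplitude scaling factor (10^(db/20)), so that scaling a signal's
#' amplitude by `amp_scale_from_db(d)` changes its power by `d` dB.
#'
#' @param ratio power ratio (unitless, > 0)
#' @param db change in decibels
#' @return numeric vector
#' @export
db_from_ratio <- function(ratio) 10 * log10(ratio)

#' @rdname db_from_ratio
#' @export
amp_scale_from_db <- function(db) 10^(db / 20)

# Standard gravity used for all grams-force <-> newton conversions.
STANDARD_GRAVITY <- 9.80665

#' Grams-force / newton conversion (standard gravity 9.80665)
#' @param f_n force in newtons (sign discarded)
#' @param g load in grams-force
#' @return numeric vector
#' @export
newton_to_gram <- function(f_n) abs(f_n) / STANDARD_GRAVITY * 1000

#' @rdname newton_to_gram
#' @export
gram_to_newton <- function(g) g * STANDARD_GRAVITY / 1000

# Truncated-normal draw by resampling; bounds are hard guarantees.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  for (i in seq_len(50)) {
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  pmin(pmax(x, lower), upper)
  }

# Derive a stream seed from a base seed; keeps results < 2^31 so the
# value is a valid R integer seed.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647)
}

write_tsv <- function(df, path) {
  ok <- tryCatch({
    data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_atersp("io", "failed to write '%s': %s", path,
                conditionMessage(ok))
  }
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop_atersp("io", "file not found: '%s'", path)
  as.data.frame(data.table::fread(path, sep = "\t"))
}
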