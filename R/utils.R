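# 365-day (no-leap) calendar used throughout: month lengths and day-of-year
# to month lookup. Removes leap-day edge cases, matching common climate-model
# calendars.
.noleap_month_lengths <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.noleap_month_of_doy <- rep.int(seq_len(12L), .noleap_month_lengths)

#' Month number for a day of year on the 365-day calendar
#'
#' @param doy Integer day-of-year in 1..365.
#' @return Integer month in 1..12.
#' @export
month_of_doy <- function(doy) {
  stopifnot(all(doy >= 1L), all(doy <= 365L))
  .noleap_month_of_doy[doy]
}

#' Linear-interpolation percentile
#'
#' The single percentile convention used across the package (annual p95
#' metrics and local compound-event thresholds): linear interpolation between
#' order statistics, i.e. `stats::quantile(..., type = 7)`.
#'
#' @param x Numeric values (NAs dropped).
#' @param p Percentile in (0, 100).
#' @return The percentile value, or `NA` if no finite values remain.
#' @export
percentile <- function(x, p) {
  stopifnot(length(p) == 1L, p > 0, p < 100)
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::quantile(x, probs = p / 100, type = 7, names = FALSE)
}

# internal: scalar positivity / range checks with informative errors
.check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` = %g outside [%g, %g]", name, x, lower, upper), call. = FALSE)
  }
  invisible(x)
}

# Derive a reproducible stream seed from a base seed and a stream index,
# kept within the 32-bit integer range R requires.
.stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483647)
}

# Cheap deterministic content hash (FNV-1a over UTF-8 bytes) for run manifests.
.fnv1a <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
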