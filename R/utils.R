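# Shared helpers: printed-style rounding and calendar-month date arithmetic.

#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for the printed percentages in mortality concordance
#' reports (base [round()] uses banker's rounding and would turn 20.065 into
#' 20.06 rather than 20.07).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(20.065)   # 20.07
#' round_half_up(0.005, 2) # 0.01
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # nudge by a relative epsilon so that values which are exactly .5 at the
  # target precision, but sit a hair below it in binary, still round up
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9 * abs(x)) / scale
}

# percentage of num over den, half-up to 2 decimals (printed style)
pct2 <- function(num, den) round_half_up(100 * num / den, 2)

#' Shift dates by whole calendar months
#'
#' Adds `months` calendar months to each date, clipping the day-of-month to
#' the length of the target month (2010-01-31 + 1 month is 2010-02-28).
#'
#' @param dates A `Date` vector.
#' @param months Integer vector (recycled) of months to add; may be negative.
#' @return A `Date` vector.
#' @export
add_months <- function(dates, months) {
  stopifnot(inherits(dates, "Date"))
  lt <- as.POSIXlt(dates)
  total <- lt$year * 12L + lt$mon + as.integer(months)
  y <- total %/% 12L
  m <- total %% 12L
  # clip day to the target month's length
  days_in <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  dim <- days_in[m + 1L]
  leap <- (m == 1L) & ((y + 1900L) %% 4L == 0L) &
    (((y + 1900L) %% 100L != 0L) | ((y + 1900L) %% 400L == 0L))
  dim[leap] <- 29L
  lt$mday <- pmin(lt$mday, dim)
  lt$mon <- m
  lt$year <- y
  as.Date(lt)
}

#' Whole-month difference between two dates
#'
#' Calendar-month distance used for death-date discrepancy screening: the
#' absolute year/month difference, decremented by one when the later date's
#' day-of-month precedes the earlier date's (an incomplete final month does
#' not count). Symmetric in its arguments.
#'
#' @param d1,d2 `Date` vectors (recycled to a common length).
#' @return Integer vector of whole months, always >= 0.
#' @examples
#' month_delta(as.Date("2010-03-10"), as.Date("2010-05-10")) # 2
#' month_delta(as.Date("2010-03-10"), as.Date("2010-04-09")) # 0
#' @export
month_delta <- function(d1, d2) {
  stopifnot(inherits(d1, "Date"), inherits(d2, "Date"))
  n <- max(length(d1), length(d2))
  d1 <- rep_len(d1, n)
  d2 <- rep_len(d2, n)
  swap <- d2 < d1
  lo <- d1
  lo[swap] <- d2[swap]
  hi <- d2
  hi[swap] <- d1[swap]
  l1 <- as.POSIXlt(lo)
  l2 <- as.POSIXlt(hi)
  m <- (l2$year - l1$year) * 12L + (l2$mon - l1$mon)
  m <- m - as.integer(l2$mday < l1$mday)
  pmax(m, 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable integer sub-seed derived from a user seed; keeps set.seed() input
# well inside 32-bit range
sub_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}
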