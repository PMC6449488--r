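# Internal calendar helpers. Tables are keyed on integer day numbers
# (days since 1970-01-01, as in the Date class) so that month/year lookups
# over millions of records reduce to vector indexing.

# month (1-12) and Gregorian year for a vector of Dates
.cal_parts <- function(dates) {
  d <- as.integer(dates)
  lo <- min(d); hi <- max(d)
  span <- as.POSIXlt(as.Date(lo:hi, origin = "1970-01-01"))
  idx <- d - lo + 1L
  list(month = (span$mon + 1L)[idx],
       year = (span$year + 1900L)[idx],
       mday = span$mday[idx])
}

# first day number and length of month m in year y (vectorised)
.month_first_day <- function(year, month) {
  as.integer(as.Date(sprintf("%d-%02d-01", year, month)))
}

.month_length <- function(year, month) {
  nxt_y <- ifelse(month == 12L, year + 1L, year)
  nxt_m <- ifelse(month == 12L, 1L, month + 1L)
  .month_first_day(nxt_y, nxt_m) - .month_first_day(year, month)
}

# Index of a Gregorian month within the local calendar year that starts in
# `year_start_month` (1 = the start month, 12 = the last month).
.local_month_index <- function(month, year_start_month = 1L) {
  ((month - year_start_month) %% 12L) + 1L
}

# Gregorian (year, month) of local-calendar month k (1..12) of the local
# year containing `(year, month)`.
.local_year_start <- function(year, month, year_start_month = 1L) {
  ifelse(month >= year_start_month, year, year - 1L)
}
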