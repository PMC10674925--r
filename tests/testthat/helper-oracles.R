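# Independent brute-force oracles for the CMA9 engine.
#
# The package computes availability by interval arithmetic; the oracle below
# instead simulates a pill stock day by day (add the day's fills, consume one
# unit per covered day, drop whatever is left at the period end). Within each
# inter-refill interval the number of stock-covered days equals the interval's
# credited supply, so averaging coverage per interval reproduces the per-day
# ratio vector by a completely different computational route.

oracle_covered_days <- function(events, period_days) {
  day <- events$day
  keep <- day >= 0 & day < period_days
  day <- day[keep]
  supply <- events$days_supply[keep]
  stock <- 0
  covered <- logical(period_days)
  for (d in seq_len(period_days) - 1) {
    stock <- stock + sum(supply[day == d])
    if (stock >= 1) {
      covered[d + 1] <- TRUE
      stock <- stock - 1
    }
  }
  covered
}

oracle_cma9 <- function(events, period_days) {
  mean(oracle_covered_days(events, period_days))
}

oracle_daily_vector <- function(events, period_days) {
  covered <- oracle_covered_days(events, period_days)
  day <- events$day[events$day >= 0 & events$day < period_days]
  if (!length(day)) return(rep(0, period_days))
  starts <- sort(unique(day))
  ends <- c(starts[-1], period_days)
  out <- rep(0, period_days)
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1):ends[i]
    out[idx] <- mean(covered[idx])
  }
  out
}

oracle_windows <- function(events, period_days, window_days = 30) {
  daily <- oracle_daily_vector(events, period_days)
  n_win <- floor(period_days / window_days)
  colMeans(matrix(daily[seq_len(n_win * window_days)], nrow = window_days))
}

random_event_stream <- function(period_days = 365, max_fills = 15) {
  n <- sample(0:max_fills, 1)
  tibble::tibble(day = sample(0:(period_days - 1), n, replace = TRUE),
                 days_supply = sample(c(7L, 30L, 60L, 90L), n,
                                      replace = TRUE))
}

# partitions equal up to cluster relabeling
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
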