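# Independent brute-force oracles used across the suite.

# Episode collapsing by literal set scanning: the earliest unassigned event
# opens an episode; every event within `collapse_days` of that anchor joins
# it; repeat on what is left. Returns episode onsets.
oracle_collapse_onsets <- function(days, collapse_days = 30L) {
  un <- sort(days)
  onsets <- integer(0)
  while (length(un)) {
    a <- un[1]
    onsets <- c(onsets, a)
    un <- un[un - a > collapse_days]
  }
  onsets
}

# Day-by-day exposure simulation under the stockpiling policy: supplies are
# banked on the fill date and consumed one day at a time; a day is covered
# when the bank is positive. Returns the covered flag for days 0..max_day.
oracle_coverage <- function(day, supply, max_day) {
  bank <- 0
  covered <- logical(max_day + 1L)
  adds <- tapply(supply, day, sum)
  for (d in 0:max_day) {
    a <- adds[as.character(d)]
    if (!is.na(a)) bank <- bank + a
    if (bank > 0) {
      covered[d + 1L] <- TRUE
      bank <- bank - 1
    }
  }
  covered
}

# Persistence decision from the day-level coverage simulation.
# Discontinuation: the first uncovered day r (a runout) from which the
# member stays uncovered for gap_days consecutive days, all observed before
# the horizon (r + gap_days <= horizon). Switch: the first other-DMT claim
# day wins when it precedes both the discontinuation trigger and the
# horizon. Otherwise censored at the horizon.
oracle_persistence <- function(day, supply, other_days, gap_days = 60L,
                               horizon = 360L) {
  max_day <- horizon + gap_days + max(supply) + 5L
  covered <- oracle_coverage(day, supply, max_day)
  disc_runout <- Inf
  for (r in 0:(horizon - gap_days)) {
    uncovered_r <- !covered[r + 1L]
    prev_covered <- (r == 0L) || covered[r]   # r is a runout boundary
    if (uncovered_r && prev_covered &&
        !any(covered[(r + 1L):(r + gap_days)])) {
      disc_runout <- r
      break
    }
  }
  switch_day <- if (length(other_days)) min(other_days) else Inf
  if (switch_day < disc_runout + gap_days && switch_day <= horizon - 1)
    list(days = min(switch_day, horizon), reason = "switched")
  else if (disc_runout < horizon)
    list(days = disc_runout, reason = "discontinued")
  else list(days = horizon, reason = "censored")
}

# random fill/switch streams for the persistence property tests; always
# includes the index fill at day 0
random_fill_stream <- function() {
  n <- sample(1:8, 1)
  day <- c(0L, sort(sample(1:380, n - 1))) [seq_len(n)]
  supply <- sample(c(7L, 14L, 28L, 30L, 60L, 90L), n, replace = TRUE)
  other <- if (runif(1) < 0.4) sort(sample(1:400, sample(1:2, 1))) else integer(0)
  list(fills = data.frame(day = day, days_supply = supply), other = other)
}
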