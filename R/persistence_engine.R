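#' Build an exposure timeline from index-therapy claims
#'
#' Coverage accumulates under a stockpiling policy: an early refill queues
#' its supply after the current coverage end rather than discarding overlap
#' (`stockpile = FALSE` truncates instead: each fill covers from its own
#' date). The runout day is the first day not covered by any supply - the
#' date on which the therapy should next have been dispensed.
#'
#' @param fills data frame with integer `day` (offset from index) and
#'   `days_supply`; administrations (procedure claims with no supply) should
#'   be given `days_supply = admin coverage` by the caller.
#' @param stockpile logical; queue early refills end-to-end (default) or
#'   truncate overlaps.
#' @return object of class `exposure_episode`: list with `segments` (data
#'   frame start/end, end exclusive) and `runout` (first uncovered day).
#' @export
build_exposure <- function(fills, stockpile = TRUE) {
  if (!nrow(fills)) stop2("build_exposure: no fills")
  if (any(is.na(fills$days_supply)))
    stop2("build_exposure: fill with missing days supply (should have been excluded upstream)")
  fills <- fills[order(fills$day), ]
  day <- as.numeric(fills$day); supply <- as.numeric(fills$days_supply)
  n <- length(day)
  start <- numeric(n); end <- numeric(n)
  run <- -Inf
  for (i in seq_len(n)) {
    start[i] <- if (stockpile) max(run, day[i]) else day[i]
    end[i] <- start[i] + supply[i]
    run <- max(run, end[i])
  }
  structure(list(segments = data.frame(start = start, end = end),
                 runout = run),
            class = "exposure_episode")
}

#' @export
print.exposure_episode <- function(x, ...) {
  cat("<exposure_episode> ", nrow(x$segments), " supply segments, runout day ",
      x$runout, "\n", sep = "")
  invisible(x)
}

# runout after each fill under stockpiling, vectorized:
# runout_i = presum_i + cummax(day_j - presum_{j-1}) for j <= i
runout_after_each_fill <- function(day, supply) {
  presum <- cumsum(supply)
  prior <- c(0, presum[-length(presum)])
  presum + cummax(day - prior)
}

#' Determine the persistence end for one member
#'
#' Persistence runs from the index day until the first of: discontinuation
#' (a gap of at least `gap_days` between a runout and the next index-therapy
#' fill, or between a runout and the horizon when no fill follows - the end
#' is the runout day itself, not the end of the gap), a switch (a claim for
#' a different disease-modifying therapy before both the discontinuation
#' trigger and the horizon - the end is the day before the switch claim), or
#' censoring at the horizon. The earliest applicable reason wins and
#' persistence never re-opens.
#'
#' @param fills index-therapy fills: data frame with `day` and `days_supply`
#'   (administrations already credited with their fixed coverage).
#' @param other_dmt_days integer days (offsets >= 1) of claims for other
#'   DMTs of interest (IFN, GA, fingolimod, natalizumab).
#' @param gap_days discontinuation gap threshold ("at least" semantics:
#'   a gap equal to `gap_days` triggers discontinuation).
#' @param horizon end of the observation period in days post-index.
#' @param stockpile see [build_exposure()].
#' @return one-row data frame: days_persistent, end_day (last persistent
#'   day, = days_persistent - 1), reason
#'   ("discontinued"/"switched"/"censored").
#' @export
find_persistence_end <- function(fills, other_dmt_days = integer(0),
                                 gap_days = 60L, horizon = 360L,
                                 stockpile = TRUE) {
  if (!nrow(fills)) stop2("find_persistence_end: no fills")
  if (any(is.na(fills$days_supply)))
    stop2("find_persistence_end: fill with missing days supply (should have been excluded upstream)")
  res <- persistence_core(as.numeric(fills$day),
                          as.numeric(fills$days_supply),
                          as.numeric(other_dmt_days), gap_days, horizon,
                          stockpile)
  data.frame(days_persistent = as.integer(res[1]),
             end_day = as.integer(res[1]) - 1L,
             reason = c("switched", "discontinued", "censored")[res[2]])
}

# returns c(days_persistent, reason code 1=switched 2=discontinued 3=censored)
persistence_core <- function(day, supply, other_days, gap_days, horizon,
                             stockpile = TRUE) {
  o <- order(day)
  day <- day[o]; supply <- supply[o]
  runouts <- if (stockpile) runout_after_each_fill(day, supply)
             else cummax(day + supply)
  next_fill <- c(day[-1], Inf)
  # first runout followed by a gap of >= gap_days (vs next fill, or vs the
  # horizon when no fill follows)
  gap_to_next <- pmin(next_fill, horizon) - runouts
  disc_i <- which(gap_to_next >= gap_days & runouts < horizon)
  disc_runout <- if (length(disc_i)) runouts[disc_i[1]] else Inf
  switch_day <- if (length(other_days)) min(other_days) else Inf

  if (switch_day < disc_runout + gap_days && switch_day <= horizon - 1)
    c(max(0, min(switch_day, horizon)), 1)
  else if (disc_runout < horizon) c(max(0, min(disc_runout, horizon)), 2)
  else c(horizon, 3)
}

#' Persistence for every cohort member
#'
#' Builds each member's index-therapy exposure from pharmacy fills (days
#' supply) and clinic administrations (fixed coverage per procedure claim)
#' and applies the gap/switch/censoring rules of [find_persistence_end()].
#'
#' @param bundle a [claims_bundle()].
#' @param cohort data frame with member_id, index_date, index_dmt.
#' @param gap_days,horizon,stockpile see [find_persistence_end()].
#' @param admin_coverage_days exposure days credited per administration.
#' @return data frame: member_id, days_persistent, end_day, reason,
#'   switch_to (drug class, NA unless reason == "switched").
#' @export
compute_persistence <- function(bundle, cohort, gap_days = 60L, horizon = 360L,
                                admin_coverage_days = 28L, stockpile = TRUE) {
  dict <- bundle$dictionaries
  dmts <- c("IFN", "GA", "fingolimod", "natalizumab")
  idx <- setNames(as.numeric(cohort$index_date), cohort$member_id)
  arm <- setNames(cohort$index_dmt, cohort$member_id)

  rx <- bundle$pharmacy[bundle$pharmacy$member_id %in% cohort$member_id, ]
  rx$class <- classify_ndc(rx$ndc, dict)
  rx <- rx[!is.na(rx$class) & rx$class %in% dmts, ]
  rx$day <- as.numeric(rx$fill_date) - idx[rx$member_id]

  med <- bundle$medical[bundle$medical$member_id %in% cohort$member_id, ]
  med$class <- classify_procedure_joined(med$procedures, dict)
  med <- med[!is.na(med$class) & med$class %in% dmts, ]
  med$day <- if (nrow(med)) as.numeric(med$service_date) - idx[med$member_id]
             else numeric(0)

  cday <- c(rx$day, med$day)
  cclass <- c(rx$class, med$class)
  csupply <- c(as.numeric(rx$days_supply),
               rep(as.numeric(admin_coverage_days), nrow(med)))
  cmember <- c(rx$member_id, med$member_id)
  spl <- split(seq_along(cday), cmember)

  nm <- length(cohort$member_id)
  days_out <- integer(nm); reason_out <- integer(nm)
  switch_out <- rep(NA_character_, nm)
  for (j in seq_len(nm)) {
    m <- cohort$member_id[j]
    ix <- spl[[m]]
    own <- ix[cclass[ix] == arm[[m]] & cday[ix] >= 0 & cday[ix] <= horizon]
    other <- ix[cclass[ix] != arm[[m]] & cday[ix] >= 1]
    if (!length(own)) {
      days_out[j] <- 0L; reason_out[j] <- 2L
      next
    }
    if (anyNA(csupply[own]))
      stop2("compute_persistence: index-therapy fill with missing days supply",
            " for member ", m, " (should have been excluded upstream)")
    res <- persistence_core(cday[own], csupply[own], cday[other],
                            gap_days, horizon, stockpile)
    days_out[j] <- as.integer(res[1]); reason_out[j] <- res[2]
    if (res[2] == 1) switch_out[j] <- cclass[other[which.min(cday[other])]]
  }
  data.frame(member_id = cohort$member_id, days_persistent = days_out,
             end_day = days_out - 1L,
             reason = c("switched", "discontinued", "censored")[reason_out],
             switch_to = switch_out, row.names = NULL)
}

#' Summarize persistence by treatment arm
#'
#' @param persistence output of [compute_persistence()].
#' @param arm character vector of arms aligned with `persistence` rows (or a
#'   named vector indexed by member_id).
#' @param horizon the censoring horizon used.
#' @return data frame per arm: n, n_persistent (censored at horizon),
#'   prop_persistent, mean_days, sd_days, median_days.
#' @export
summarize_persistence <- function(persistence, arm, horizon = 360L) {
  if (!is.null(names(arm))) arm <- arm[persistence$member_id]
  stats_by <- split(persistence, arm)
  out <- lapply(names(stats_by), function(a) {
    p <- stats_by[[a]]
    data.frame(arm = a, n = nrow(p),
               n_persistent = sum(p$reason == "censored"),
               prop_persistent = mean(p$reason == "censored"),
               mean_days = mean(p$days_persistent),
               sd_days = sd(p$days_persistent),
               median_days = median(p$days_persistent))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @importFrom stats median
NULL
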