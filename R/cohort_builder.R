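#' Identify the index medication switch for every member
#'
#' A qualifying index event is the first fingolimod or GA initiation
#' (pharmacy fill or clinic-administration procedure claim) inside the
#' calendar index window whose nearest preceding IFN claim is at most
#' `max_gap_days` earlier. The first qualifying event is the only switch
#' assessed. The gap is measured claim date to claim date.
#'
#' @param bundle a [claims_bundle()].
#' @param index_window `Date` vector of length 2 (inclusive calendar window).
#' @param max_gap_days maximum days between the last IFN claim and the
#'   switch claim.
#' @return data frame: member_id, index_date, index_dmt ("fingolimod"/"GA"),
#'   last_ifn_date, switch_gap_days. Members without a qualifying switch are
#'   absent.
#' @export
find_index_switch <- function(bundle,
                              index_window = as.Date(c("2010-10-01", "2012-03-31")),
                              max_gap_days = 90L) {
  dict <- bundle$dictionaries
  rx <- bundle$pharmacy
  rx_class <- classify_ndc(rx$ndc, dict)
  med <- bundle$medical
  med_class <- classify_procedure_joined(med$procedures, dict)

  dmt <- rbind(
    data.frame(member_id = rx$member_id, date = rx$fill_date, class = rx_class),
    data.frame(member_id = med$member_id, date = med$service_date,
               class = med_class))
  dmt <- dmt[!is.na(dmt$class), ]
  if (!nrow(dmt))
    return(data.frame(member_id = character(0),
                      index_date = as.Date(character(0)),
                      index_dmt = character(0),
                      last_ifn_date = as.Date(character(0)),
                      switch_gap_days = integer(0)))

  cand <- data.table::as.data.table(
    dmt[dmt$class %in% c("fingolimod", "GA") &
          dmt$date >= index_window[1] & dmt$date <= index_window[2], ])
  ifn <- data.table::as.data.table(dmt[dmt$class == "IFN", ])
  if (!nrow(cand) || !nrow(ifn))
    return(data.frame(member_id = character(0),
                      index_date = as.Date(character(0)),
                      index_dmt = character(0),
                      last_ifn_date = as.Date(character(0)),
                      switch_gap_days = integer(0)))

  # nearest IFN claim on or before each candidate date (rolling join)
  data.table::setnames(ifn, "date", "ifn_date")
  ifn[, `:=`(class = NULL, jdate = ifn_date)]
  cand[, jdate := date]
  data.table::setkey(ifn, member_id, jdate)
  data.table::setkey(cand, member_id, jdate)
  m <- ifn[cand, roll = Inf]
  m[, gap := as.integer(date - ifn_date)]
  m <- m[!is.na(ifn_date) & gap >= 0L & gap <= max_gap_days]
  if (!nrow(m))
    return(data.frame(member_id = character(0),
                      index_date = as.Date(character(0)),
                      index_dmt = character(0),
                      last_ifn_date = as.Date(character(0)),
                      switch_gap_days = integer(0)))
  data.table::setorder(m, member_id, date)
  first <- m[, .SD[1], by = member_id]
  out <- data.frame(member_id = first$member_id, index_date = first$date,
                    index_dmt = first$class, last_ifn_date = first$ifn_date,
                    switch_gap_days = first$gap)
  rownames(out) <- NULL
  out
}

#' Apply the study inclusion and exclusion criteria
#'
#' Criteria are applied in order, each counted in the attrition table:
#' (1) evidence of an IFN-to-fingolimod/GA switch in the index window;
#' (2) continuous enrollment for `pre_days` before and `post_days` after
#' index; (3) at least one MS-diagnosis claim inside `ms_window` of index;
#' (4) age `min_age`+ at index. Then exclusions: index DMT received in the
#' pre-index period; missing/zero days supply on a post-index index-therapy
#' fill; data-quality flags from [validate_bundle()]. The criteria are
#' conjunctive, so reordering changes per-row counts but never the final
#' cohort.
#'
#' @param bundle a [claims_bundle()].
#' @param index_events output of [find_index_switch()].
#' @param pre_days,post_days continuous-enrollment requirement around index.
#' @param ms_window inclusive day interval for the MS-diagnosis requirement.
#' @param min_age minimum age (index year minus birth year).
#' @param validation optional precomputed [validate_bundle()] report.
#' @return list with `cohort` (index_events rows for retained members) and
#'   `attrition` (data frame criterion / n_remaining / n_excluded with class
#'   `attrition_table`).
#' @export
apply_selection_criteria <- function(bundle, index_events,
                                     pre_days = 360L, post_days = 360L,
                                     ms_window = c(-360L, 359L),
                                     min_age = 18L, validation = NULL) {
  if (is.null(validation)) validation <- validate_bundle(bundle)
  dict <- bundle$dictionaries
  all_ids <- bundle$members$member_id
  steps <- list(list(label = "Members in bundle", keep = all_ids))
  current <- all_ids

  keep_step <- function(label, keep_ids) {
    current <<- intersect(current, keep_ids)
    steps[[length(steps) + 1L]] <<- list(label = label, keep = current)
  }

  # (1) switch evidence
  keep_step("IFN to fingolimod/GA switch in index window",
            index_events$member_id)
  idx <- index_events[match(current, index_events$member_id), ]

  # (2) continuous enrollment covering [index - pre_days, index + post_days - 1]
  enr <- bundle$enrollment
  idx_num0 <- setNames(as.numeric(idx$index_date), idx$member_id)
  elo <- idx_num0[enr$member_id] - pre_days
  ehi <- idx_num0[enr$member_id] + post_days - 1
  span_ok <- !is.na(enr$start_date) & !is.na(enr$end_date) &
    !is.na(elo) &
    as.numeric(enr$start_date) <= elo & as.numeric(enr$end_date) >= ehi &
    enr$start_date <= enr$end_date
  keep_step(sprintf("Continuous enrollment %d days pre- and post-index",
                    pre_days), unique(enr$member_id[span_ok]))

  # (3) at least one MS-diagnosis claim in ms_window
  idx_map <- setNames(as.numeric(index_events$index_date),
                      index_events$member_id)
  med <- bundle$medical[bundle$medical$member_id %in% current, ]
  med_day <- as.numeric(med$service_date) - idx_map[med$member_id]
  ms_hit <- codes_match_any(med$diagnoses, dict$icd$ms) &
    med_day >= ms_window[1] & med_day <= ms_window[2]
  keep_step(sprintf(">=1 MS diagnosis claim in days [%d, %d] of index",
                    ms_window[1], ms_window[2]),
            unique(med$member_id[ms_hit]))

  # (4) age at index
  by_map <- setNames(bundle$members$birth_year, bundle$members$member_id)
  idx2 <- index_events[index_events$member_id %in% current, ]
  age <- as.integer(format(idx2$index_date, "%Y")) - by_map[idx2$member_id]
  keep_step(sprintf("Age >= %d at index", min_age),
            idx2$member_id[!is.na(age) & age >= min_age])

  # exclusion: index DMT in the pre-index period
  rx <- bundle$pharmacy[bundle$pharmacy$member_id %in% current, ]
  rx$class <- classify_ndc(rx$ndc, dict)
  med2 <- bundle$medical[bundle$medical$member_id %in% current, ]
  med2$class <- classify_procedure_joined(med2$procedures, dict)
  dmt_claims <- rbind(
    data.frame(member_id = rx$member_id, date = rx$fill_date, class = rx$class),
    data.frame(member_id = med2$member_id, date = med2$service_date,
               class = med2$class))
  dmt_claims <- dmt_claims[!is.na(dmt_claims$class), ]
  arm_map <- setNames(index_events$index_dmt, index_events$member_id)
  ddays <- as.numeric(dmt_claims$date) - idx_map[dmt_claims$member_id]
  pre_own <- dmt_claims$class == arm_map[dmt_claims$member_id] &
    ddays >= -pre_days & ddays <= -1
  keep_step("No index DMT claim in pre-index period",
            setdiff(current, unique(dmt_claims$member_id[pre_own])))

  # exclusion: missing/zero days supply on post-index index-therapy fills
  rx2 <- bundle$pharmacy[bundle$pharmacy$member_id %in% current, ]
  rx2$class <- classify_ndc(rx2$ndc, dict)
  rx2_day <- as.numeric(rx2$fill_date) - idx_map[rx2$member_id]
  bad_supply <- rx2$class == arm_map[rx2$member_id] & !is.na(rx2$class) &
    rx2_day >= 0 & rx2_day <= post_days - 1 &
    (rx2$supply_missing | (!is.na(rx2$days_supply) & rx2$days_supply == 0L))
  keep_step("No missing days supply on index therapy",
            setdiff(current, unique(rx2$member_id[bad_supply])))

  # exclusion: data-quality flags
  keep_step("No data quality issues",
            setdiff(current, unique(validation$member_id)))

  n_rem <- vapply(steps, function(s) length(s$keep), 0L)
  attrition <- data.frame(criterion = vapply(steps, `[[`, "", "label"),
                          n_remaining = n_rem,
                          n_excluded = c(0L, -diff(n_rem)))
  class(attrition) <- c("attrition_table", "data.frame")
  cohort <- index_events[index_events$member_id %in% current, ]
  rownames(cohort) <- NULL
  list(cohort = cohort, attrition = attrition)
}

#' @export
print.attrition_table <- function(x, ...) {
  cat("Attrition:\n")
  print.data.frame(x, row.names = FALSE)
  init <- x$n_remaining[1]; final <- x$n_remaining[nrow(x)]
  cat(sprintf("excluded %d of %d (%.1f%%)\n", init - final, init,
              100 * attrition_excluded_fraction(x)))
  invisible(x)
}

#' Fraction of initially identified members excluded
#'
#' @param attrition an `attrition_table`.
#' @return excluded / initial, in [0, 1].
#' @export
attrition_excluded_fraction <- function(attrition) {
  init <- attrition$n_remaining[1]
  (init - attrition$n_remaining[nrow(attrition)]) / init
}

#' Compute baseline covariates for cohort members
#'
#' All flags are derived from pre-index claims by dictionary prefix
#' matching; the Charlson score sums the weights of distinct Charlson
#' categories present; total cost sums paid amounts over all pre-index
#' claims; age is index year minus birth year (claims extracts carry birth
#' year only).
#'
#' @param bundle a [claims_bundle()].
#' @param cohort data frame with member_id, index_date, index_dmt.
#' @param pre_episodes output of [detect_relapse_episodes()] on the
#'   pre-index window (used for the relapse count and 90-day recency flag).
#' @param pre_days pre-index window length.
#' @return data frame keyed by member_id with age, gender, region,
#'   plan_type, prescriber_specialty, charlson_score, dalfampridine_use,
#'   relapse_within_90d_pre, pre_index_total_cost, one logical column per
#'   symptom and comorbidity, and pre_index_relapse_count.
#' @export
compute_baseline_covariates <- function(bundle, cohort, pre_episodes,
                                        pre_days = 360L) {
  dict <- bundle$dictionaries
  ids <- cohort$member_id
  idx_map <- setNames(as.numeric(cohort$index_date), ids)

  med <- bundle$medical[bundle$medical$member_id %in% ids, ]
  med$day <- as.numeric(med$service_date) - idx_map[med$member_id]
  pre_med <- med[med$day >= -pre_days & med$day <= -1, ]
  rx <- bundle$pharmacy[bundle$pharmacy$member_id %in% ids, ]
  rx$day <- as.numeric(rx$fill_date) - idx_map[rx$member_id]
  pre_rx <- rx[rx$day >= -pre_days & rx$day <= -1, ]

  # long code table: one row per (claim, code)
  codes <- split_codes(pre_med$diagnoses)
  lens <- lengths(codes)
  long <- data.frame(member_id = rep(pre_med$member_id, lens),
                     code = strip_dots(unlist(codes, use.names = FALSE)))

  flag_from_prefixes <- function(prefixes) {
    hit <- rep(FALSE, nrow(long))
    for (p in prefixes) hit <- hit | startsWith(long$code, p)
    ids %in% unique(long$member_id[hit])
  }

  sym_flags <- lapply(dict$icd$symptoms, flag_from_prefixes)
  com_flags <- lapply(dict$icd$comorbidities, flag_from_prefixes)

  charlson <- rep(0L, length(ids))
  for (cat_ in dict$charlson) {
    present <- flag_from_prefixes(cat_$prefixes)
    charlson <- charlson + cat_$weight * present
  }

  dalf <- ids %in% pre_rx$member_id[classify_ndc(pre_rx$ndc, dict) %in%
                                      "dalfampridine"]

  cost_med <- tapply(pre_med$paid_amount, factor(pre_med$member_id, levels = ids),
                     sum, default = 0)
  cost_rx <- tapply(pre_rx$paid_amount, factor(pre_rx$member_id, levels = ids),
                    sum, default = 0)

  # modal provider specialty of pre-index medical claims
  spec_spl <- split(pre_med$provider_specialty, pre_med$member_id)
  spec <- vapply(ids, function(m) {
    s <- spec_spl[[m]]
    if (is.null(s)) return("unknown")
    names(sort(table(s), decreasing = TRUE))[1]
  }, "")

  ep_cnt <- count_relapse_episodes(pre_episodes, ids,
                                   window = c(-pre_days, -1L))
  recent <- pre_episodes[pre_episodes$onset_day >= -90L &
                           pre_episodes$onset_day <= -1L, ]

  by_map <- setNames(bundle$members$birth_year, bundle$members$member_id)
  gen_map <- setNames(bundle$members$gender, bundle$members$member_id)
  reg_map <- setNames(bundle$members$region, bundle$members$member_id)
  plan_map <- setNames(bundle$members$plan_type, bundle$members$member_id)

  out <- data.frame(
    member_id = ids,
    age = as.integer(format(cohort$index_date, "%Y")) - by_map[ids],
    gender = gen_map[ids], region = reg_map[ids], plan_type = plan_map[ids],
    prescriber_specialty = spec,
    charlson_score = charlson,
    dalfampridine_use = dalf,
    relapse_within_90d_pre = ids %in% recent$member_id,
    pre_index_total_cost = as.numeric(cost_med[ids]) + as.numeric(cost_rx[ids]),
    pre_index_relapse_count = ep_cnt$n_episodes,
    row.names = NULL)
  for (s in names(sym_flags)) out[[s]] <- sym_flags[[s]]
  for (s in names(com_flags)) out[[s]] <- com_flags[[s]]
  rownames(out) <- NULL
  out
}

#' Pre-index relapse-count strata
#'
#' Bins the pre-index relapse count into the matching strata 0, 1, 2, 3+.
#'
#' @param count integer vector of pre-index relapse counts.
#' @return character vector of stratum labels.
#' @export
relapse_strata <- function(count) {
  ifelse(count >= 3, "3+", as.character(count))
}
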