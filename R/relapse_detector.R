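#' Detect inpatient relapse events
#'
#' An inpatient relapse event is an inpatient claim whose primary (first
#' position) diagnosis is MS (ICD-9 340 prefix), dated inside the window.
#' Detection is one event per qualifying claim; 30-day collapsing into
#' episodes is a separate step ([collapse_events()]).
#'
#' @param medical one member's medical claims with integer column `day`
#'   (offset from the index date) plus `setting` and `diagnoses`
#'   (";"-joined, position 1 primary). A `claim_id` column is carried
#'   through if present.
#' @param dictionaries dictionary list.
#' @param window inclusive integer day interval `c(lo, hi)`.
#' @return data frame of events: day, kind, claim_id, steroid_claim_id.
#' @export
detect_inpatient_events <- function(medical, dictionaries,
                                    window = c(0L, 359L)) {
  if (is.null(medical$claim_id)) medical$claim_id <- NA_character_
  hit <- medical$setting == "inpatient" &
    medical$day >= window[1] & medical$day <= window[2] &
    icd_match(primary_code(medical$diagnoses), dictionaries$icd$ms)
  hit[is.na(hit)] <- FALSE
  data.frame(day = as.integer(medical$day[hit]),
             kind = rep("inpatient", sum(hit)),
             claim_id = medical$claim_id[hit],
             steroid_claim_id = rep(NA_character_, sum(hit)),
             stringsAsFactors = FALSE)
}

#' Detect outpatient relapse events
#'
#' An outpatient relapse event is an outpatient visit carrying an MS
#' diagnosis (any position) with a qualifying corticosteroid claim - an oral
#' steroid fill or an intravenous steroid administration procedure - within
#' `steroid_window_days` of the visit, unless any claim on the visit date
#' carries a primary exclusionary diagnosis (asthma, gout, rheumatoid
#' arthritis, uveitis by default). The steroid window runs forward from the
#' visit (`direction = "after"`, the default) or symmetrically
#' (`direction = "symmetric"`).
#'
#' @param medical one member's medical claims (`day`, `setting`,
#'   `diagnoses`, `procedures`).
#' @param pharmacy one member's pharmacy claims (`day`, `ndc`).
#' @param dictionaries dictionary list.
#' @param window inclusive integer day interval for the visit date.
#' @param steroid_window_days maximum days between visit and steroid claim.
#' @param direction "after" = steroid in [visit, visit + k]; "symmetric" =
#'   within k days either side.
#' @return data frame of events: day, kind, claim_id, steroid_claim_id.
#' @export
detect_outpatient_events <- function(medical, pharmacy, dictionaries,
                                     window = c(0L, 359L),
                                     steroid_window_days = 7L,
                                     direction = c("after", "symmetric")) {
  direction <- match.arg(direction)
  if (is.null(medical$claim_id)) medical$claim_id <- NA_character_
  if (!is.null(pharmacy) && nrow(pharmacy) && is.null(pharmacy$claim_id))
    pharmacy$claim_id <- NA_character_

  visits <- medical$setting == "outpatient" &
    medical$day >= window[1] & medical$day <= window[2] &
    codes_match_any(medical$diagnoses, dictionaries$icd$ms)
  visits[is.na(visits)] <- FALSE
  vd <- medical$day[visits]
  vid <- medical$claim_id[visits]
  if (!length(vd))
    return(data.frame(day = integer(0), kind = character(0),
                      claim_id = character(0), steroid_claim_id = character(0)))

  ster_day <- numeric(0); ster_id <- character(0)
  if (!is.null(pharmacy) && nrow(pharmacy)) {
    oral <- pharmacy$ndc %in% dictionaries$ndc$oral_corticosteroid
    ster_day <- c(ster_day, pharmacy$day[oral])
    ster_id <- c(ster_id, pharmacy$claim_id[oral])
  }
  ivproc <- codes_match_any_exact(medical$procedures,
                                  dictionaries$procedure$iv_corticosteroid)
  ster_day <- c(ster_day, medical$day[ivproc])
  ster_id <- c(ster_id, medical$claim_id[ivproc])

  # nearest qualifying steroid per visit
  match_steroid <- function(v) {
    d <- ster_day - v
    ok <- if (direction == "after") d >= 0 & d <= steroid_window_days
          else abs(d) <= steroid_window_days
    if (!any(ok)) return(NA_integer_)
    which(ok)[which.min(abs(d[ok]))]
  }
  sidx <- vapply(vd, match_steroid, 0L)

  # days on which any claim carries a primary exclusionary diagnosis
  excl_days <- medical$day[icd_match(primary_code(medical$diagnoses),
                                     dictionaries$icd$exclusionary_primary)]
  keep <- !is.na(sidx) & !(vd %in% excl_days)
  data.frame(day = as.integer(vd[keep]),
             kind = rep("outpatient", sum(keep)),
             claim_id = vid[keep],
             steroid_claim_id = ster_id[sidx[keep]],
             stringsAsFactors = FALSE)
}

# exact membership of any ";"-joined code in a code set
codes_match_any_exact <- function(joined, codes) {
  if (!length(joined)) return(logical(0))
  uniq_map(joined, function(j) {
    cs <- strsplit(if (is.na(j)) "" else j, ";", fixed = TRUE)[[1]]
    any(cs %in% codes)
  }, TRUE)
}

#' Collapse relapse events into episodes
#'
#' Greedy anchor scan: the earliest unassigned event opens an episode and
#' every event within `collapse_days` of that anchor joins it; the next
#' unassigned event opens the next episode. With `mode = "rolling"` the
#' window instead restarts at each joined event (chain collapsing). Episode
#' kind is inpatient when any constituent event is inpatient.
#'
#' @param events data frame with integer `day` and `kind`; extra columns are
#'   ignored.
#' @param collapse_days window length in days.
#' @param mode "anchor" (fixed window from the first event; default) or
#'   "rolling".
#' @return data frame of episodes: onset_day, kind, n_events, last_day,
#'   any_inpatient, any_outpatient.
#' @export
collapse_events <- function(events, collapse_days = 30L,
                            mode = c("anchor", "rolling")) {
  mode <- match.arg(mode)
  empty <- data.frame(onset_day = integer(0), kind = character(0),
                      n_events = integer(0), last_day = integer(0),
                      any_inpatient = logical(0), any_outpatient = logical(0))
  if (is.null(events) || !nrow(events)) return(empty)
  cc <- collapse_core(events$day, events$kind == "inpatient", collapse_days,
                      rolling = mode == "rolling")
  data.frame(onset_day = cc$onset,
             kind = ifelse(cc$any_in, "inpatient", "outpatient"),
             n_events = cc$n_events, last_day = cc$last,
             any_inpatient = cc$any_in, any_outpatient = cc$any_out,
             row.names = NULL)
}

# anchor/rolling collapse on bare vectors (hot path)
collapse_core <- function(day, inpt, collapse_days, rolling = FALSE) {
  o <- order(day)
  day <- as.integer(day[o]); inpt <- inpt[o]
  n <- length(day)
  ep <- integer(n); cur <- 1L; ref <- day[1]; ep[1] <- 1L
  if (n > 1) for (i in 2:n) {
    if (day[i] - ref <= collapse_days) {
      ep[i] <- cur
      if (rolling) ref <- day[i]
    } else {
      cur <- cur + 1L; ep[i] <- cur; ref <- day[i]
    }
  }
  starts <- which(!duplicated(ep))
  ends <- c(starts[-1] - 1L, n)
  g <- length(starts)
  any_in <- logical(g); any_out <- logical(g)
  for (j in seq_len(g)) {
    seg <- inpt[starts[j]:ends[j]]
    any_in[j] <- any(seg); any_out[j] <- !all(seg)
  }
  list(onset = day[starts], last = day[ends], n_events = ends - starts + 1L,
       any_in = any_in, any_out = any_out)
}

#' Count relapse episodes in a window, optionally while persistent
#'
#' @param episodes data frame from [collapse_events()] (one member).
#' @param window inclusive day interval the onset must fall in.
#' @param persistence optional persistence result for the member (a one-row
#'   data frame with `days_persistent`, or a single number of persistent
#'   days); when supplied only episodes with onset on a persistent day
#'   (onset <= days_persistent - 1) count.
#' @return list(count, episodes) where `episodes` is the retained subset.
#' @export
count_relapses <- function(episodes, window = c(0L, 359L), persistence = NULL) {
  keep <- episodes$onset_day >= window[1] & episodes$onset_day <= window[2]
  if (!is.null(persistence)) {
    dp <- if (is.data.frame(persistence)) persistence$days_persistent else persistence
    keep <- keep & episodes$onset_day <= dp - 1
  }
  kept <- episodes[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(count = nrow(kept), episodes = kept)
}

#' Detect relapse episodes for every member of a bundle
#'
#' Runs inpatient and outpatient event detection per member on day offsets
#' from each member's index date, then collapses events into episodes.
#'
#' @param bundle a [claims_bundle()].
#' @param index_events data frame from [find_index_switch()] (member_id,
#'   index_date); only these members are scanned.
#' @param window inclusive day interval relative to index.
#' @param collapse_days,mode see [collapse_events()].
#' @param steroid_window_days,direction see [detect_outpatient_events()].
#' @return data frame: member_id, onset_day, kind, n_events, any_inpatient,
#'   any_outpatient.
#' @export
detect_relapse_episodes <- function(bundle, index_events,
                                    window = c(0L, 359L), collapse_days = 30L,
                                    mode = "anchor", steroid_window_days = 7L,
                                    direction = "after") {
  dict <- bundle$dictionaries
  med <- bundle$medical[bundle$medical$member_id %in% index_events$member_id, ]
  rx <- bundle$pharmacy[bundle$pharmacy$member_id %in% index_events$member_id, ]
  idx <- setNames(as.numeric(index_events$index_date), index_events$member_id)
  med$day <- as.numeric(med$service_date) - idx[med$member_id]
  rx$day <- as.numeric(rx$fill_date) - idx[rx$member_id]

  # precompute per-claim flags once, then walk members over index lists
  in_win <- med$day >= window[1] & med$day <= window[2]
  inpt_evt <- med$setting == "inpatient" &
    icd_match(primary_code(med$diagnoses), dict$icd$ms) & in_win
  ms_visit <- med$setting == "outpatient" &
    codes_match_any(med$diagnoses, dict$icd$ms) & in_win
  iv_ster <- codes_match_any_exact(med$procedures,
                                   dict$procedure$iv_corticosteroid)
  excl <- icd_match(primary_code(med$diagnoses),
                    dict$icd$exclusionary_primary)
  oral_ster <- rx$ndc %in% dict$ndc$oral_corticosteroid

  med_day <- med$day
  rx_day <- rx$day
  msp <- split(seq_along(med_day), med$member_id)
  rsp <- split(seq_along(rx_day), rx$member_id)
  fwd <- direction == "after"
  k <- steroid_window_days
  rolling <- mode == "rolling"

  acc_m <- list(); acc_on <- list(); acc_in <- list(); acc_out <- list()
  acc_n <- list(); acc_last <- list(); ai <- 0L
  for (m in index_events$member_id) {
    mi <- msp[[m]]
    if (is.null(mi)) next
    in_days <- med_day[mi][inpt_evt[mi]]
    vd <- med_day[mi][ms_visit[mi]]
    if (length(vd)) {
      ri <- rsp[[m]]
      sd_ <- c(if (!is.null(ri)) rx_day[ri][oral_ster[ri]],
               med_day[mi][iv_ster[mi]])
      has_ster <- if (length(sd_)) vapply(vd, function(v) {
        d <- sd_ - v
        any(if (fwd) d >= 0 & d <= k else abs(d) <= k)
      }, TRUE) else rep(FALSE, length(vd))
      excl_days <- med_day[mi][excl[mi]]
      vd <- vd[has_ster & !(vd %in% excl_days)]
    }
    nall <- length(in_days) + length(vd)
    if (!nall) next
    cc <- collapse_core(c(in_days, vd),
                        rep(c(TRUE, FALSE), c(length(in_days), length(vd))),
                        collapse_days, rolling)
    ai <- ai + 1L
    acc_m[[ai]] <- rep(m, length(cc$onset)); acc_on[[ai]] <- cc$onset
    acc_in[[ai]] <- cc$any_in; acc_out[[ai]] <- cc$any_out
    acc_n[[ai]] <- cc$n_events; acc_last[[ai]] <- cc$last
  }
  if (!ai)
    return(data.frame(member_id = character(0), onset_day = integer(0),
                      kind = character(0), n_events = integer(0),
                      last_day = integer(0), any_inpatient = logical(0),
                      any_outpatient = logical(0)))
  any_in <- unlist(acc_in, use.names = FALSE)
  data.frame(member_id = unlist(acc_m, use.names = FALSE),
             onset_day = unlist(acc_on, use.names = FALSE),
             kind = ifelse(any_in, "inpatient", "outpatient"),
             n_events = unlist(acc_n, use.names = FALSE),
             last_day = unlist(acc_last, use.names = FALSE),
             any_inpatient = any_in,
             any_outpatient = unlist(acc_out, use.names = FALSE),
             row.names = NULL)
}

#' Per-member relapse episode counts
#'
#' Tabulates [detect_relapse_episodes()] output into one row per cohort
#' member (zero-filled), optionally restricted to episodes with onset while
#' the member was persistent with the index therapy.
#'
#' @param episodes output of [detect_relapse_episodes()].
#' @param member_ids every cohort member (members without episodes get 0).
#' @param window inclusive onset-day interval.
#' @param persistence optional data frame (member_id, days_persistent).
#' @return data frame: member_id, n_episodes, any_relapse, first_onset (NA
#'   when none).
#' @export
count_relapse_episodes <- function(episodes, member_ids, window = c(0L, 359L),
                                   persistence = NULL) {
  ep <- episodes[episodes$onset_day >= window[1] &
                   episodes$onset_day <= window[2], , drop = FALSE]
  if (!is.null(persistence)) {
    dp <- setNames(persistence$days_persistent, persistence$member_id)
    ep <- ep[ep$onset_day <= dp[ep$member_id] - 1, , drop = FALSE]
  }
  cnt <- table(factor(ep$member_id, levels = member_ids))
  first <- tapply(ep$onset_day, factor(ep$member_id, levels = member_ids), min)
  data.frame(member_id = member_ids,
             n_episodes = as.integer(cnt[member_ids]),
             any_relapse = as.integer(cnt[member_ids]) > 0,
             first_onset = as.integer(first[member_ids]),
             row.names = NULL)
}
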