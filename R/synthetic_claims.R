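#' Simulation configuration for the synthetic claims generator
#'
#' The defaults encode the study conditions the pipeline is designed for:
#' interferon (IFN) users switching to fingolimod or glatiramer acetate (GA)
#' inside an October 2010 - March 2012 index window, 360-day pre- and
#' post-index observation with enrollment covering both, a pre-index relapse
#' intensity of 0.47 episodes per 360 days, a post-index GA intensity of
#' 0.51 with a fingolimod/GA rate ratio of 0.38, per-member gamma frailty
#' (so relapse counts are overdispersed, as a negative-binomial outcome
#' model assumes), confounded treatment assignment, and arm-specific
#' exponential discontinuation hazards matching 360-day persistence of
#' 73.5% (fingolimod) and 62.9% (GA).
#'
#' @param n_members number of members to generate.
#' @param seed master RNG seed; per-member substreams are derived from it so
#'   that appending members never perturbs existing members' draws.
#' @param enrollment_days length of each member's single enrollment span.
#' @param pre_index_relapse_rate relapse intensity per 360 days pre-index.
#' @param ga_post_rate post-index relapse intensity per 360 days in the GA arm.
#' @param true_rate_ratio fingolimod/GA post-index rate ratio (ground truth).
#' @param frailty_shape gamma frailty shape (mean fixed at 1); smaller =
#'   more overdispersion.
#' @param inpatient_fraction probability a relapse manifests as an inpatient
#'   stay (primary diagnosis 340) rather than an outpatient visit.
#' @param steroid_capture_prob probability an outpatient relapse is followed
#'   (0-7 days) by a qualifying corticosteroid claim.
#' @param steroid_iv_fraction share of captured steroids given intravenously
#'   (procedure claim) rather than as an oral fill.
#' @param confounding_strength multiplier on the built-in log-odds
#'   coefficients linking covariates (pre-index relapse count, fatigue,
#'   depression, diabetes, age) to fingolimod assignment; 0 = randomized.
#' @param treat_intercept intercept of the assignment model.
#' @param disc_hazard named per-day discontinuation hazards for
#'   `fingolimod` and `GA`.
#' @param switch_prob probability of a post-index switch to natalizumab.
#' @param noise_ms_visit_rate routine MS visits (diagnosis 340, no steroid)
#'   per 360 days.
#' @param noise_visit_rate non-MS visits per 360 days.
#' @param stray_steroid_rate steroid fills unrelated to any MS visit per 360
#'   days.
#' @param symptom_prev,comorbidity_prev named prevalence vectors for the
#'   baseline symptom and comorbidity flags (encoded as pre-index claims).
#' @param dalfampridine_prev prevalence of pre-index dalfampridine use.
#' @param female_prob probability of female gender.
#' @param index_window `Date` vector of length 2: calendar index window.
#' @param ifn_gap_range integer range (days) of the IFN-to-switch gap.
#' @param supply_days days supply per pharmacy fill of a DMT.
#' @param admin_coverage_days exposure days credited per clinic
#'   administration (procedure claim).
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_members = 500L,
                       seed = 1L,
                       enrollment_days = 1080L,
                       pre_index_relapse_rate = 0.47,
                       ga_post_rate = 0.51,
                       true_rate_ratio = 0.38,
                       frailty_shape = 1.5,
                       inpatient_fraction = 0.1,
                       steroid_capture_prob = 0.95,
                       steroid_iv_fraction = 0.2,
                       confounding_strength = 1,
                       treat_intercept = -0.35,
                       disc_hazard = c(fingolimod = -log(0.735) / 360,
                                       GA = -log(0.629) / 360),
                       switch_prob = 0.03,
                       noise_ms_visit_rate = 2,
                       noise_visit_rate = 1.5,
                       stray_steroid_rate = 0.3,
                       symptom_prev = c(numbness = 0.20, fatigue = 0.33,
                                        bowel = 0.08, headache = 0.20,
                                        muscle = 0.14, visual = 0.14,
                                        bladder = 0.10, dizziness = 0.09,
                                        respiration = 0.05, walking = 0.18),
                       comorbidity_prev = c(depression = 0.235, diabetes = 0.07,
                                            dyslipidemia = 0.26, tobacco = 0.07,
                                            cvd = 0.06),
                       dalfampridine_prev = 0.08,
                       female_prob = 0.75,
                       index_window = as.Date(c("2010-10-01", "2012-03-31")),
                       ifn_gap_range = c(7L, 60L),
                       supply_days = 30L,
                       admin_coverage_days = 28L) {
  cfg <- list(n_members = as.integer(n_members), seed = as.integer(seed),
              enrollment_days = as.integer(enrollment_days),
              pre_index_relapse_rate = pre_index_relapse_rate,
              ga_post_rate = ga_post_rate, true_rate_ratio = true_rate_ratio,
              frailty_shape = frailty_shape,
              inpatient_fraction = inpatient_fraction,
              steroid_capture_prob = steroid_capture_prob,
              steroid_iv_fraction = steroid_iv_fraction,
              confounding_strength = confounding_strength,
              treat_intercept = treat_intercept, disc_hazard = disc_hazard,
              switch_prob = switch_prob,
              noise_ms_visit_rate = noise_ms_visit_rate,
              noise_visit_rate = noise_visit_rate,
              stray_steroid_rate = stray_steroid_rate,
              symptom_prev = symptom_prev, comorbidity_prev = comorbidity_prev,
              dalfampridine_prev = dalfampridine_prev,
              female_prob = female_prob,
              index_window = as.Date(index_window),
              ifn_gap_range = as.integer(ifn_gap_range),
              supply_days = as.integer(supply_days),
              admin_coverage_days = as.integer(admin_coverage_days))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$inpatient_fraction, cfg$steroid_capture_prob,
             cfg$steroid_iv_fraction, cfg$switch_prob, cfg$symptom_prev,
             cfg$comorbidity_prev, cfg$dalfampridine_prev, cfg$female_prob)
  if (any(probs < 0 | probs > 1)) stop2("sim_config: probabilities must lie in [0, 1]")
  rates <- c(cfg$pre_index_relapse_rate, cfg$ga_post_rate, cfg$true_rate_ratio,
             cfg$disc_hazard, cfg$noise_ms_visit_rate, cfg$noise_visit_rate,
             cfg$stray_steroid_rate)
  if (any(rates < 0)) stop2("sim_config: rates must be non-negative")
  if (cfg$n_members < 0) stop2("sim_config: n_members must be >= 0")
  if (cfg$frailty_shape <= 0) stop2("sim_config: frailty_shape must be > 0")
  if (!all(c("fingolimod", "GA") %in% names(cfg$disc_hazard)))
    stop2("sim_config: disc_hazard needs named fingolimod and GA entries")
  invisible(cfg)
}

# symptom/comorbidity flag -> the claim code that encodes it (first prefix
# of the dictionary set, so prefix matching recovers the flag exactly)
flag_code <- function(dict_set) vapply(dict_set, `[`, "", 1L)

empty_bundle <- function(dict) {
  claims_bundle(
    data.frame(member_id = character(0), birth_year = integer(0),
               gender = character(0), region = character(0),
               plan_type = character(0), payer_type = character(0)),
    data.frame(member_id = character(0), start_date = as.Date(character(0)),
               end_date = as.Date(character(0))),
    data.frame(claim_id = character(0), member_id = character(0),
               service_date = as.Date(character(0)), setting = character(0),
               diagnoses = character(0), procedures = character(0),
               provider_specialty = character(0), paid_amount = numeric(0)),
    data.frame(claim_id = character(0), member_id = character(0),
               fill_date = as.Date(character(0)), ndc = character(0),
               days_supply = integer(0), supply_missing = logical(0),
               paid_amount = numeric(0)),
    dict)
}

#' Generate a synthetic claims bundle with known ground truth
#'
#' Every member carries an IFN treatment history, a qualifying switch claim
#' (fingolimod or GA) at a drawn index date, enrollment covering the 360-day
#' pre- and post-index windows, relapses from a per-member gamma-frailty
#' Poisson process, and claims encoding their baseline covariates. Each
#' relapse emits either one inpatient claim (primary diagnosis 340) or an
#' outpatient 340 visit plus - with `steroid_capture_prob` - a
#' corticosteroid claim 0-7 days later. Treatment assignment is confounded
#' by covariates according to `confounding_strength`.
#'
#' @param config a [sim_config()].
#' @return list with elements `bundle` (a [claims_bundle()] that passes
#'   [validate_bundle()] with an empty report) and `truth` (list of
#'   `members`, `relapses`, `config`): the per-member true arm, index date,
#'   frailty, covariate flags, true relapse dates/kinds and discontinuation
#'   draw.
#' @export
generate_bundle <- function(config = sim_config()) {
  validate_sim_config(config)
  n <- config$n_members
  dict <- default_dictionaries()
  if (n == 0L)
    return(list(bundle = empty_bundle(dict),
                truth = list(members = data.frame(), relapses = data.frame(),
                             config = config)))

  env <- list(
    dict = dict,
    sym_code = flag_code(dict$icd$symptoms),
    com_code = flag_code(dict$icd$comorbidities),
    regions = c("East", "Midwest", "South", "West"),
    plans = c("HMO", "PPO", "POS"),
    payers = c("Commercial", "SelfInsured"),
    specialties = c("neurology", "general", "other"),
    noise_dx = c("401", "7245", "V700", "388"),
    win_days = as.integer(config$index_window[2] - config$index_window[1]) + 1L)

  ids <- sprintf("SM%06d", seq_len(n))
  out <- vector("list", n)
  # one state save/restore around the whole loop; each member re-seeds the
  # stream from its own derived seed, so draws are a function of
  # (master seed, member index) only and appending members never perturbs
  # existing members
  with_seed(config$seed, {
    member_seeds <- floor(runif(n) * 2147483646) + 1
    for (i in seq_len(n)) {
      set.seed(member_seeds[i])
      out[[i]] <- gen_member(config, env)
    }
  })

  pull_n <- function(f) vapply(out, `[[`, 0, f)
  pull_c <- function(f) vapply(out, `[[`, "", f)
  cat_n <- function(f) unlist(lapply(out, `[[`, f), use.names = FALSE)
  cat_c <- function(f) unlist(lapply(out, `[[`, f), use.names = FALSE)
  rep_by <- function(x, f) rep(x, times = vapply(out, function(o) length(o[[f]]), 0L))
  as_date <- function(x) as.Date(x, origin = "1970-01-01")

  index_num <- pull_n("index_date")
  index_year <- as.integer(format(as.Date(index_num, origin = "1970-01-01"), "%Y"))
  enroll_start <- index_num - 540
  members <- data.frame(
    member_id = ids,
    birth_year = index_year - as.integer(pull_n("age")),
    gender = pull_c("gender"), region = pull_c("region"),
    plan_type = pull_c("plan"), payer_type = pull_c("payer"))
  enrollment <- data.frame(member_id = ids, start_date = as_date(enroll_start),
                           end_date = as_date(enroll_start + config$enrollment_days - 1))

  med_member <- rep_by(ids, "med_day")
  medical <- data.frame(
    member_id = med_member,
    service_date = as_date(rep_by(index_num, "med_day") + cat_n("med_day")),
    setting = cat_c("med_setting"), diagnoses = cat_c("med_dx"),
    procedures = cat_c("med_proc"),
    provider_specialty = rep_by(pull_c("specialty"), "med_day"),
    paid_amount = cat_n("med_paid"))
  pharmacy <- data.frame(
    member_id = rep_by(ids, "rx_day"),
    fill_date = as_date(rep_by(index_num, "rx_day") + cat_n("rx_day")),
    ndc = cat_c("rx_ndc"), days_supply = as.integer(cat_n("rx_supply")),
    paid_amount = cat_n("rx_paid"))
  pharmacy$supply_missing <- is.na(pharmacy$days_supply)

  # stable (member, date) order; sort on integer keys (member index is the
  # id's generation order) rather than strings
  medical <- medical[order(rep_by(seq_len(n), "med_day"),
                           as.numeric(medical$service_date)), ]
  pharmacy <- pharmacy[order(rep_by(seq_len(n), "rx_day"),
                             as.numeric(pharmacy$fill_date)), ]
  medical$claim_id <- if (nrow(medical)) paste0("M", seq_len(nrow(medical))) else character(0)
  pharmacy$claim_id <- if (nrow(pharmacy)) paste0("P", seq_len(nrow(pharmacy))) else character(0)
  rownames(medical) <- rownames(pharmacy) <- NULL

  sym_mat <- do.call(rbind, lapply(out, `[[`, "sym"))
  com_mat <- do.call(rbind, lapply(out, `[[`, "com"))
  colnames(sym_mat) <- paste0("symptom_", names(config$symptom_prev))
  colnames(com_mat) <- paste0("comorbidity_", names(config$comorbidity_prev))
  truth_members <- data.frame(
    member_id = ids, arm = pull_c("arm"), index_date = as_date(index_num),
    frailty = pull_n("frailty"), age = as.integer(pull_n("age")),
    gender = pull_c("gender"),
    pre_count = as.integer(pull_n("pre_n")),
    post_count = as.integer(pull_n("post_n")),
    true_disc_day = pull_n("disc_day"), switch_day = pull_n("switch_day"),
    ifn_gap = as.integer(pull_n("ifn_gap")),
    dalfampridine = pull_n("dalf") > 0, sym_mat, com_mat)

  relapses <- data.frame(
    member_id = rep_by(ids, "rel_day"), day = as.integer(cat_n("rel_day")),
    date = as_date(rep_by(index_num, "rel_day") + cat_n("rel_day")),
    kind = cat_c("rel_kind"), captured = cat_n("rel_captured") > 0,
    steroid_day = as.integer(cat_n("rel_steroid_day")))

  bundle <- claims_bundle(
    members, enrollment,
    medical[, c("claim_id", "member_id", "service_date", "setting", "diagnoses",
                "procedures", "provider_specialty", "paid_amount")],
    pharmacy[, c("claim_id", "member_id", "fill_date", "ndc", "days_supply",
                 "supply_missing", "paid_amount")],
    dict)
  list(bundle = bundle,
       truth = list(members = truth_members, relapses = relapses,
                    config = config))
}

# all randomness for one member, drawn in a fixed order from the member's
# private stream; returns flat vectors (day offsets relative to index)
gen_member <- function(cfg, env) {
  gender <- if (runif(1) < cfg$female_prob) "F" else "M"
  age <- max(18L, min(75L, round(rnorm(1, 45.8, 10))))
  region <- env$regions[sample.int(4L, 1L)]
  plan <- env$plans[sample.int(3L, 1L)]
  payer <- env$payers[sample.int(2L, 1L)]
  specialty <- env$specialties[sample.int(3L, 1L, prob = c(0.7, 0.2, 0.1))]

  sym <- setNames(runif(length(cfg$symptom_prev)) < cfg$symptom_prev,
                  names(cfg$symptom_prev))
  com <- setNames(runif(length(cfg$comorbidity_prev)) < cfg$comorbidity_prev,
                  names(cfg$comorbidity_prev))
  dalf <- runif(1) < cfg$dalfampridine_prev

  frailty <- rgamma(1, shape = cfg$frailty_shape, rate = cfg$frailty_shape)
  pre_n <- rpois(1, frailty * cfg$pre_index_relapse_rate)
  pre_days <- if (pre_n) sort(floor(runif(pre_n, -360, 0))) else integer(0)

  eta <- cfg$treat_intercept + cfg$confounding_strength *
    (0.35 * pre_n + 0.30 * sym[["fatigue"]] + 0.25 * com[["depression"]] -
       0.30 * com[["diabetes"]] + 0.015 * (age - 45))
  fingo <- runif(1) < 1 / (1 + exp(-eta))
  arm <- if (fingo) "fingolimod" else "GA"

  index_date <- as.numeric(cfg$index_window[1]) + floor(runif(1) * env$win_days)
  ifn_gap <- cfg$ifn_gap_range[1] +
    sample.int(cfg$ifn_gap_range[2] - cfg$ifn_gap_range[1] + 1L, 1L) - 1L

  disc_day <- rexp(1, cfg$disc_hazard[[arm]])
  switches <- runif(1) < cfg$switch_prob
  switch_day <- if (switches) 30 + sample.int(300L, 1L) - 1 else NA_real_

  post_rate <- frailty * cfg$ga_post_rate * if (fingo) cfg$true_rate_ratio else 1
  post_n <- rpois(1, post_rate)
  post_days <- if (post_n) sort(floor(runif(post_n, 0, 360))) else integer(0)

  rel_days <- c(pre_days, post_days)
  k <- length(rel_days)
  inpt <- runif(k) < cfg$inpatient_fraction
  captured <- runif(k) < cfg$steroid_capture_prob
  delay <- sample.int(8L, k, replace = TRUE) - 1L
  iv <- runif(k) < cfg$steroid_iv_fraction
  captured[inpt] <- TRUE   # inpatient relapses always manifest

  n_ms <- rpois(1, cfg$noise_ms_visit_rate * 2)
  ms_days <- if (n_ms) floor(runif(n_ms, -360, 360)) else numeric(0)
  n_nv <- rpois(1, cfg$noise_visit_rate * 2)
  nv_days <- if (n_nv) floor(runif(n_nv, -360, 360)) else numeric(0)
  nv_dx <- if (n_nv) env$noise_dx[sample.int(length(env$noise_dx), n_nv,
                                             replace = TRUE)] else character(0)
  n_ss <- rpois(1, cfg$stray_steroid_rate * 2)
  ss_days <- if (n_ss) floor(runif(n_ss, -360, 360)) else numeric(0)

  # ---- pharmacy claims ----
  ifn_days <- seq(-ifn_gap, -360L, by = -30L)
  stop_at <- min(disc_day, if (switches) switch_day else Inf, 420)
  idx_days <- seq(0L, 419L, by = cfg$supply_days)
  idx_days <- idx_days[idx_days < stop_at]
  if (!length(idx_days)) idx_days <- 0L   # the index claim always exists
  idx_ndc <- if (fingo) env$dict$ndc$fingolimod[1] else env$dict$ndc$GA[1]

  out_rel <- !inpt
  cap_oral <- which(out_rel & captured & !iv)
  cap_iv <- which(out_rel & captured & iv)
  steroid_day <- rep(NA_real_, k)
  steroid_day[out_rel & captured] <- rel_days[out_rel & captured] +
    delay[out_rel & captured]
  dalf_day <- if (dalf) -30 - sample.int(300L, 1L) + 1 else numeric(0)

  rx_day <- c(ifn_days, idx_days,
              if (switches) switch_day else numeric(0),
              dalf_day, steroid_day[cap_oral], ss_days)
  rx_ndc <- c(rep(env$dict$ndc$IFN[1], length(ifn_days)),
              rep(idx_ndc, length(idx_days)),
              if (switches) env$dict$ndc$natalizumab[1] else character(0),
              if (dalf) env$dict$ndc$dalfampridine[1] else character(0),
              rep(env$dict$ndc$oral_corticosteroid[1], length(cap_oral)),
              rep(env$dict$ndc$oral_corticosteroid[1], length(ss_days)))
  rx_supply <- c(rep(cfg$supply_days, length(ifn_days) + length(idx_days)),
                 if (switches) cfg$supply_days else integer(0),
                 if (dalf) 30L else integer(0),
                 rep(6L, length(cap_oral) + length(ss_days)))

  # ---- medical claims ----
  flags_on <- c(env$sym_code[names(sym)[sym]], env$com_code[names(com)[com]])
  fdays <- if (length(flags_on)) -30 - floor(runif(length(flags_on)) * 300) else numeric(0)

  med_day <- c(rel_days[inpt], rel_days[out_rel], steroid_day[cap_iv],
               fdays, ms_days, nv_days)
  med_setting <- c(rep("inpatient", sum(inpt)),
                   rep("outpatient", sum(out_rel) + length(cap_iv) +
                         length(fdays) + length(ms_days) + length(nv_days)))
  med_dx <- c(rep("340", sum(inpt) + sum(out_rel)),
              rep("V5869", length(cap_iv)), unname(flags_on),
              rep("340", length(ms_days)), nv_dx)
  med_proc <- c(rep("", sum(inpt) + sum(out_rel)),
                rep(env$dict$procedure$iv_corticosteroid[1], length(cap_iv)),
                rep("", length(fdays) + length(ms_days) + length(nv_days)))

  med_paid <- round(rlnorm(length(med_day), 6.5, 0.8), 2)
  rx_paid <- round(rlnorm(length(rx_day), 6.0, 0.6), 2)

  list(gender = gender, age = age, region = region, plan = plan, payer = payer,
       specialty = specialty,
       sym = as.logical(sym), com = as.logical(com), dalf = dalf,
       frailty = frailty, pre_n = pre_n, post_n = post_n, arm = arm,
       index_date = index_date, ifn_gap = ifn_gap, disc_day = disc_day,
       switch_day = switch_day,
       med_day = med_day, med_setting = med_setting, med_dx = med_dx,
       med_proc = med_proc, med_paid = med_paid,
       rx_day = rx_day, rx_ndc = rx_ndc, rx_supply = rx_supply,
       rx_paid = rx_paid,
       rel_day = rel_days, rel_kind = ifelse(inpt, "inpatient", "outpatient"),
       rel_captured = captured, rel_steroid_day = steroid_day)
}

#' Ground-truth relapse episodes
#'
#' Collapses a truth table's true relapse dates with the same 30-day anchor
#' rule the detector uses, giving the per-member episodes the detector
#' should recover on a noise-free bundle.
#'
#' @param truth the `truth` element of [generate_bundle()] output.
#' @param window integer day window (relative to index), inclusive.
#' @param collapse_days episode collapsing window.
#' @param captured_only count only relapses that emitted a detectable claim.
#' @return data frame: member_id, onset_day, kind, n_events.
#' @export
ground_truth_episodes <- function(truth, window = c(0L, 359L),
                                  collapse_days = 30L, captured_only = FALSE) {
  rel <- truth$relapses
  empty <- data.frame(member_id = character(0), onset_day = integer(0),
                      kind = character(0), n_events = integer(0))
  if (is.null(rel) || !nrow(rel)) return(empty)
  if (captured_only) rel <- rel[rel$captured, ]
  rel <- rel[rel$day >= window[1] & rel$day <= window[2], ]
  if (!nrow(rel)) return(empty)
  out <- lapply(split(rel, rel$member_id), function(r) {
    ep <- collapse_events(data.frame(day = r$day, kind = r$kind),
                          collapse_days = collapse_days)
    data.frame(member_id = r$member_id[1], onset_day = ep$onset_day,
               kind = ep$kind, n_events = ep$n_events)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Deterministically corrupt a bundle to exercise attrition paths
#'
#' @param bundle a [claims_bundle()].
#' @param spec named list of member-id vectors; names are pathology kinds:
#'   `missing_days_supply` (index-therapy fills lose their days supply),
#'   `enrollment_gap` (a short hole is cut mid-span),
#'   `underage` (birth year moved so age at index < 18),
#'   `pre_index_dmt` (a fill of the member's index DMT is added 350 days
#'   before index; requires `index_events` or a computable index),
#'   `missing_gender`, `invalid_enrollment` (span end before start).
#' @param index_events optional output of [find_index_switch()]; computed
#'   with default settings when needed.
#' @return the corrupted bundle.
#' @export
inject_pathologies <- function(bundle, spec, index_events = NULL) {
  known <- c("missing_days_supply", "enrollment_gap", "underage",
             "pre_index_dmt", "missing_gender", "invalid_enrollment")
  bad <- setdiff(names(spec), known)
  if (length(bad)) stop2("unknown pathology: ", paste(bad, collapse = ", "))
  all_ids <- unlist(spec, use.names = FALSE)
  missing <- setdiff(all_ids, bundle$members$member_id)
  if (length(missing)) stop2("pathology targets absent member(s): ",
                             paste(missing, collapse = ", "))
  dict <- bundle$dictionaries
  idx_ndcs <- c(dict$ndc$fingolimod, dict$ndc$GA)

  for (m in spec$missing_days_supply) {
    rows <- bundle$pharmacy$member_id == m & bundle$pharmacy$ndc %in% idx_ndcs
    bundle$pharmacy$days_supply[rows] <- NA_integer_
    bundle$pharmacy$supply_missing[rows] <- TRUE
  }
  for (m in spec$enrollment_gap) {
    r <- which(bundle$enrollment$member_id == m)[1]
    mid <- bundle$enrollment$start_date[r] +
      as.integer(bundle$enrollment$end_date[r] - bundle$enrollment$start_date[r]) %/% 2L
    new_row <- bundle$enrollment[r, ]
    new_row$start_date <- mid + 3L
    bundle$enrollment$end_date[r] <- mid - 3L
    bundle$enrollment <- rbind(bundle$enrollment, new_row)
  }
  for (m in spec$underage) {
    r <- which(bundle$enrollment$member_id == m)[1]
    approx_index_year <- as.integer(format(bundle$enrollment$start_date[r] + 540L, "%Y"))
    bundle$members$birth_year[bundle$members$member_id == m] <-
      approx_index_year - 15L
  }
  if (length(spec$pre_index_dmt)) {
    if (is.null(index_events)) index_events <- find_index_switch(bundle)
    for (m in spec$pre_index_dmt) {
      ev <- index_events[index_events$member_id == m, ]
      if (!nrow(ev)) stop2("pre_index_dmt: member ", m, " has no index event")
      ndc <- if (ev$index_dmt == "fingolimod") dict$ndc$fingolimod[1] else dict$ndc$GA[1]
      add <- data.frame(claim_id = paste0("X", m), member_id = m,
                        fill_date = ev$index_date - 350L, ndc = ndc,
                        days_supply = 30L, supply_missing = FALSE,
                        paid_amount = 100)
      bundle$pharmacy <- rbind(bundle$pharmacy, add[, names(bundle$pharmacy)])
    }
  }
  for (m in spec$missing_gender)
    bundle$members$gender[bundle$members$member_id == m] <- NA_character_
  for (m in spec$invalid_enrollment) {
    r <- which(bundle$enrollment$member_id == m)[1]
    s <- bundle$enrollment$start_date[r]
    bundle$enrollment$start_date[r] <- bundle$enrollment$end_date[r]
    bundle$enrollment$end_date[r] <- s
  }
  bundle$enrollment <- bundle$enrollment[order(bundle$enrollment$member_id,
                                               bundle$enrollment$start_date), ]
  rownames(bundle$enrollment) <- NULL
  bundle
}
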