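#' Study configuration
#'
#' Bundles every stage parameter of the pipeline into one serializable
#' object; the configuration hash is stamped into every output so a report
#' is reproducible from (config, seed) alone.
#'
#' @param sim a [sim_config()] for simulated input, or NULL when reading
#'   claims from `bundle_dir`.
#' @param bundle_dir directory of claims tables (see [read_claims_bundle()]);
#'   ignored when `sim` is given.
#' @param index_window calendar index window.
#' @param max_switch_gap_days maximum IFN-to-switch gap.
#' @param pre_days,post_days enrollment requirement around index.
#' @param ms_window MS-diagnosis claim window (days around index).
#' @param min_age minimum age at index.
#' @param collapse_days,collapse_mode episode collapsing rule.
#' @param steroid_window_days,steroid_direction outpatient steroid window.
#' @param gap_days,horizon persistence rule.
#' @param admin_coverage_days exposure credited per administration claim.
#' @param caliper,match_seed matching parameters.
#' @param selection propensity variable selection mode.
#' @param year_days days per person-year for annualization.
#' @return a `study_config` list.
#' @export
study_config <- function(sim = sim_config(), bundle_dir = NULL,
                         index_window = as.Date(c("2010-10-01", "2012-03-31")),
                         max_switch_gap_days = 90L,
                         pre_days = 360L, post_days = 360L,
                         ms_window = c(-360L, 359L), min_age = 18L,
                         collapse_days = 30L, collapse_mode = "anchor",
                         steroid_window_days = 7L, steroid_direction = "after",
                         gap_days = 60L, horizon = 360L,
                         admin_coverage_days = 28L,
                         caliper = 0.01, match_seed = 1L,
                         selection = "fixed", year_days = 360) {
  cfg <- list(sim = sim, bundle_dir = bundle_dir,
              index_window = as.Date(index_window),
              max_switch_gap_days = max_switch_gap_days,
              pre_days = pre_days, post_days = post_days,
              ms_window = ms_window, min_age = min_age,
              collapse_days = collapse_days, collapse_mode = collapse_mode,
              steroid_window_days = steroid_window_days,
              steroid_direction = steroid_direction,
              gap_days = gap_days, horizon = horizon,
              admin_coverage_days = admin_coverage_days,
              caliper = caliper, match_seed = match_seed,
              selection = selection, year_days = year_days)
  structure(cfg, class = "study_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop2("pipeline failed at stage '", name, "': ", conditionMessage(e)))
}

#' Run the full matched-cohort relapse study
#'
#' Executes simulate/read, index-switch identification, selection criteria,
#' pre-index relapse detection, baseline covariates, propensity matching,
#' persistence, post-index relapse detection, and the outcome models, in
#' order, and assembles a study report. Any stage failure aborts with the
#' failing stage named.
#'
#' @param config a [study_config()].
#' @return object of class `study_report`; see the report fields in the
#'   package vignette. Includes the `truth` ground-truth when simulated and
#'   a provenance block (seed, config hash, package version, design
#'   constants).
#' @export
run_study <- function(config = study_config()) {
  truth <- NULL
  if (!is.null(config$sim)) {
    gen <- stage("simulate", generate_bundle(config$sim))
    bundle <- gen$bundle; truth <- gen$truth
  } else if (!is.null(config$bundle_dir)) {
    bundle <- stage("read", read_claims_bundle(
      file.path(config$bundle_dir, "members.csv"),
      file.path(config$bundle_dir, "medical.csv"),
      file.path(config$bundle_dir, "pharmacy.csv"),
      dictionary_path = {
        dp <- file.path(config$bundle_dir, "dictionaries.yaml")
        if (file.exists(dp)) dp else NULL
      }))
  } else stop2("study_config needs either sim or bundle_dir")

  index_events <- stage("index-switch",
    find_index_switch(bundle, config$index_window, config$max_switch_gap_days))
  sel <- stage("selection",
    apply_selection_criteria(bundle, index_events, config$pre_days,
                             config$post_days, config$ms_window,
                             config$min_age))
  cohort <- sel$cohort

  if (!nrow(cohort))
    return(empty_study_report(config, sel, truth))

  pre_eps <- stage("pre-relapses",
    detect_relapse_episodes(bundle, cohort,
                            window = c(-config$pre_days, -1L),
                            collapse_days = config$collapse_days,
                            mode = config$collapse_mode,
                            steroid_window_days = config$steroid_window_days,
                            direction = config$steroid_direction))
  covs <- stage("covariates",
    compute_baseline_covariates(bundle, cohort, pre_eps, config$pre_days))

  treatment <- cohort$index_dmt == "fingolimod"
  ps <- stage("propensity",
    fit_propensity(covs, treatment, selection = config$selection))
  strata <- relapse_strata(covs$pre_index_relapse_count)
  pairs <- stage("matching",
    match_nearest_neighbor(ps$scores, treatment, strata,
                           caliper = config$caliper, seed = config$match_seed))
  balance <- stage("balance", assess_balance(covs, treatment, pairs))
  if (!nrow(pairs))
    return(empty_study_report(config, sel, truth, balance = balance))

  matched_ids <- c(pairs$treated, pairs$control)
  mcohort <- cohort[match(matched_ids, cohort$member_id), ]
  mcovs <- covs[match(matched_ids, covs$member_id), ]
  marm <- mcohort$index_dmt

  persistence <- stage("persistence",
    compute_persistence(bundle, mcohort, config$gap_days, config$horizon,
                        config$admin_coverage_days))
  pers_summary <- summarize_persistence(
    persistence, setNames(marm, mcohort$member_id), config$horizon)

  post_eps <- stage("post-relapses",
    detect_relapse_episodes(bundle, mcohort,
                            window = c(0L, config$post_days - 1L),
                            collapse_days = config$collapse_days,
                            mode = config$collapse_mode,
                            steroid_window_days = config$steroid_window_days,
                            direction = config$steroid_direction))
  post_counts <- count_relapse_episodes(post_eps, mcohort$member_id,
                                        window = c(0L, config$post_days - 1L),
                                        persistence = persistence)
  pre_counts <- count_relapse_episodes(pre_eps, mcohort$member_id,
                                       window = c(-config$pre_days, -1L))

  pair_of <- setNames(rep(seq_len(nrow(pairs)), 2L),
                      c(pairs$treated, pairs$control))
  dp <- setNames(persistence$days_persistent, persistence$member_id)
  outcome <- data.frame(
    member_id = mcohort$member_id, arm = marm,
    pair_id = pair_of[mcohort$member_id],
    days_persistent = dp[mcohort$member_id],
    years = dp[mcohort$member_id] / config$year_days,
    relapse = as.integer(post_counts$any_relapse),
    count = post_counts$n_episodes,
    first_onset = post_counts$first_onset)
  sym_cols <- intersect(names(mcovs),
                        c("headache", "muscle", "visual", "bladder",
                          "dizziness", "respiration", "walking"))
  outcome <- cbind(outcome, mcovs[, sym_cols, drop = FALSE])

  n_zero <- sum(outcome$years <= 0)
  if (n_zero) message(n_zero,
    " matched member(s) with zero persistent days excluded from outcome models")
  odat <- outcome[outcome$years > 0, ]

  or_fit <- stage("relapse-probability", fit_relapse_probability(odat))
  rr_fit <- stage("relapse-rate", fit_relapse_rate(odat))
  sens <- stage("sensitivity", sensitivity_adjusted(odat))

  km_dat <- data.frame(
    time = pmin(ifelse(is.na(odat$first_onset), Inf, odat$first_onset),
                odat$days_persistent),
    event = as.integer(!is.na(odat$first_onset) &
                         odat$first_onset <= odat$days_persistent),
    arm = odat$arm)
  km <- stage("kaplan-meier", km_time_to_first_relapse(km_dat))

  baseline <- stage("baseline-table",
    baseline_table(cbind(mcovs,
                         pre_relapse_stratum = relapse_strata(
                           mcovs$pre_index_relapse_count)),
                   marm))

  arr_pre <- crude_arr_by_arm(pre_counts$n_episodes,
                              rep(config$pre_days, nrow(pre_counts)),
                              marm, config$year_days)
  arr_post <- crude_arr_by_arm(odat$count, odat$days_persistent, odat$arm,
                               config$year_days)
  prop_relapse <- tapply(odat$relapse, odat$arm, mean)
  prop_tab <- table(factor(odat$relapse, levels = c(1, 0)), odat$arm)
  prop_p <- if (all(dim(prop_tab) == c(2, 2)) && all(colSums(prop_tab) > 0))
    suppressWarnings(chisq.test(prop_tab, correct = FALSE)$p.value) else NA_real_

  provenance <- list(
    seed = if (!is.null(config$sim)) config$sim$seed else NA_integer_,
    match_seed = config$match_seed,
    config_hash = config_hash(unclass(config)),
    package_version = as.character(utils::packageVersion("msrelapse")),
    design = list(pre_days = config$pre_days, post_days = config$post_days,
                  max_switch_gap_days = config$max_switch_gap_days,
                  gap_days = config$gap_days,
                  collapse_days = config$collapse_days,
                  steroid_window_days = config$steroid_window_days,
                  caliper = config$caliper, year_days = config$year_days))

  structure(list(
    config = config, provenance = provenance,
    attrition = sel$attrition,
    n_cohort = nrow(cohort), n_pairs = nrow(pairs),
    n_matched = length(matched_ids),
    baseline = baseline, balance = balance,
    persistence_summary = pers_summary,
    relapse_proportions = list(by_arm = prop_relapse, p_value = prop_p),
    arr = list(pre = arr_pre, post_crude = arr_post, post_model = rr_fit$arr),
    odds_ratio = or_fit, rate_ratio = rr_fit,
    sensitivity = sens, km = km,
    outcome_data = odat, pairs = pairs, persistence = persistence,
    truth = truth),
    class = "study_report")
}

# degenerate report (no cohort or no matched pairs): zero-row tables and NA
# estimates so that write_report still produces every file
empty_study_report <- function(config, sel, truth, balance = NULL) {
  na_est <- outcome_estimate("odds_ratio", NA_real_, NA_real_, NA_real_,
                             NA_real_, model = "not fitted (empty cohort)")
  na_rr <- structure(list(
    rate_ratio = outcome_estimate("rate_ratio", NA_real_, NA_real_, NA_real_,
                                  NA_real_, model = "not fitted (empty cohort)"),
    arr = c(fingolimod = NA_real_, GA = NA_real_),
    theta = NA_real_, dispersion = NA_real_, fit = NULL),
    class = "relapse_rate_fit")
  empty_pairs <- data.frame(treated = character(0), control = character(0),
                            stratum = character(0), score_treated = numeric(0),
                            score_control = numeric(0), distance = numeric(0))
  provenance <- list(
    seed = if (!is.null(config$sim)) config$sim$seed else NA_integer_,
    match_seed = config$match_seed,
    config_hash = config_hash(unclass(config)),
    package_version = as.character(utils::packageVersion("msrelapse")),
    design = list(pre_days = config$pre_days, post_days = config$post_days,
                  max_switch_gap_days = config$max_switch_gap_days,
                  gap_days = config$gap_days,
                  collapse_days = config$collapse_days,
                  steroid_window_days = config$steroid_window_days,
                  caliper = config$caliper, year_days = config$year_days))
  structure(list(
    config = config, provenance = provenance, attrition = sel$attrition,
    n_cohort = nrow(sel$cohort), n_pairs = 0L, n_matched = 0L,
    baseline = data.frame(), balance = balance %||% data.frame(),
    persistence_summary = data.frame(),
    relapse_proportions = list(by_arm = c(fingolimod = NA_real_,
                                          GA = NA_real_),
                               p_value = NA_real_),
    arr = list(pre = c(fingolimod = NA_real_, GA = NA_real_),
               post_crude = c(fingolimod = NA_real_, GA = NA_real_),
               post_model = c(fingolimod = NA_real_, GA = NA_real_)),
    odds_ratio = na_est, rate_ratio = na_rr,
    sensitivity = list(odds_ratio = na_est, rate_ratio = na_rr,
                       adjusted_for = character(0)),
    km = list(fit = NULL, curves = data.frame(), chisq = NA_real_,
              p_value = NA_real_, median_days = c(fingolimod = NA_real_,
                                                  GA = NA_real_)),
    outcome_data = data.frame(), pairs = empty_pairs,
    persistence = data.frame(), truth = truth),
    class = "study_report")
}

#' One parameter-recovery replicate of the core pipeline
#'
#' Runs simulate, index-switch identification, selection, pre-index relapse
#' detection, covariates, propensity fitting, stratified matching,
#' persistence, post-index relapse counting while persistent, and the
#' negative-binomial GEE rate model - the estimation path of the study -
#' and returns the rate-ratio estimate. Used by the simulation studies that
#' check the generator's true rate ratio is recovered end to end.
#'
#' @param sim a [sim_config()].
#' @param caliper matching caliper.
#' @param match_seed seed for the matching order (defaults to `sim$seed`).
#' @return list: estimate, conf_low, conf_high, p_value, n_pairs.
#' @export
recovery_replicate <- function(sim, caliper = 0.01, match_seed = NULL) {
  if (is.null(match_seed)) match_seed <- sim$seed
  g <- generate_bundle(sim)
  idx <- find_index_switch(g$bundle)
  sel <- apply_selection_criteria(g$bundle, idx)
  coh <- sel$cohort
  pre <- detect_relapse_episodes(g$bundle, coh, window = c(-360L, -1L))
  cv <- compute_baseline_covariates(g$bundle, coh, pre)
  tr <- coh$index_dmt == "fingolimod"
  ps <- fit_propensity(cv, tr)
  pairs <- match_nearest_neighbor(ps$scores, tr,
                                  relapse_strata(cv$pre_index_relapse_count),
                                  caliper = caliper, seed = match_seed)
  ids <- c(pairs$treated, pairs$control)
  mc <- coh[match(ids, coh$member_id), ]
  pers <- compute_persistence(g$bundle, mc)
  post <- detect_relapse_episodes(g$bundle, mc, window = c(0L, 359L))
  cnt <- count_relapse_episodes(post, ids, persistence = pers)
  dp <- setNames(pers$days_persistent, pers$member_id)
  od <- data.frame(member_id = ids, arm = mc$index_dmt,
                   pair_id = rep(seq_len(nrow(pairs)), 2L),
                   years = dp[ids] / 360, count = cnt$n_episodes)
  od <- od[od$years > 0, ]
  est <- fit_relapse_rate(od)$rate_ratio
  list(estimate = est$estimate, conf_low = est$conf_low,
       conf_high = est$conf_high, p_value = est$p_value,
       n_pairs = nrow(pairs))
}

#' @export
print.study_report <- function(x, ...) {
  cat("Matched-cohort relapse study report\n")
  cat("  cohort:", x$n_cohort, "members;", x$n_pairs, "matched pairs (",
      x$n_matched, "members )\n")
  cat("  attrition: ", sprintf("%.1f%%", 100 * attrition_excluded_fraction(
    x$attrition)), " of identified members excluded\n", sep = "")
  pp <- x$persistence_summary
  for (i in seq_len(nrow(pp)))
    cat(sprintf("  persistence %s: %.1f%% at horizon, %.0f+-%.0f days\n",
                pp$arm[i], 100 * pp$prop_persistent[i], pp$mean_days[i],
                pp$sd_days[i]))
  cat(sprintf("  relapse while persistent: fingolimod %.1f%%, GA %.1f%% (p = %.4f)\n",
              100 * x$relapse_proportions$by_arm[["fingolimod"]],
              100 * x$relapse_proportions$by_arm[["GA"]],
              x$relapse_proportions$p_value))
  cat(sprintf("  ARR pre: fingolimod %.2f, GA %.2f; post (model): %.2f / %.2f\n",
              x$arr$pre[["fingolimod"]], x$arr$pre[["GA"]],
              x$arr$post_model[["fingolimod"]], x$arr$post_model[["GA"]]))
  cat("  ", format(x$odds_ratio), "\n", sep = "")
  cat("  ", format(x$rate_ratio$rate_ratio), "\n", sep = "")
  cat(sprintf("  log-rank chi-square %.2f, p = %.4g\n", x$km$chisq,
              x$km$p_value))
  invisible(x)
}

#' Write a study report to a directory
#'
#' Writes delimited tables (attrition, baseline, balance, persistence,
#' matched pairs, Kaplan-Meier curves), a machine-readable JSON summary of
#' every estimate, and - optionally - a survival plot. File contents are a
#' pure function of (config, seed); no timestamps are embedded, so reruns
#' are byte-identical. Stable file names.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @param plots also write `km.pdf` (PDF metadata includes a creation date,
#'   so plots are excluded from the byte-identical guarantee).
#' @return invisible character vector of files written.
#' @export
write_report <- function(report, dir, plots = FALSE) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop2("cannot create output directory: ", dir)
  wr <- function(df, f) {
    df <- as.data.frame(df)
    if (!ncol(df)) writeLines(character(0), file.path(dir, f))
    else data.table::fwrite(df, file.path(dir, f))
    f
  }
  files <- c(
    wr(report$attrition, "attrition.csv"),
    wr(report$baseline, "baseline.csv"),
    wr(report$balance, "balance.csv"),
    wr(report$persistence_summary, "persistence_summary.csv"),
    wr(report$persistence, "persistence.csv"),
    wr(report$pairs, "pairs.csv"),
    wr(report$km$curves, "km_curves.csv"),
    wr(report$outcome_data, "outcomes.csv"))

  est <- function(e) list(measure = e$measure, estimate = e$estimate,
                          conf_low = e$conf_low, conf_high = e$conf_high,
                          p_value = e$p_value, model = e$model)
  summary <- list(
    provenance = report$provenance,
    n_cohort = report$n_cohort, n_pairs = report$n_pairs,
    n_matched = report$n_matched,
    attrition_excluded_fraction = attrition_excluded_fraction(report$attrition),
    persistence = report$persistence_summary,
    relapse_proportions = report$relapse_proportions,
    arr = report$arr,
    odds_ratio = est(report$odds_ratio),
    rate_ratio = est(report$rate_ratio$rate_ratio),
    sensitivity = list(odds_ratio = est(report$sensitivity$odds_ratio),
                       rate_ratio = est(report$sensitivity$rate_ratio$rate_ratio),
                       adjusted_for = report$sensitivity$adjusted_for),
    km = list(chisq = report$km$chisq, p_value = report$km$p_value,
              median_days = as.list(report$km$median_days)))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  files <- c(files, "summary.json")

  if (plots) {
    grDevices::pdf(file.path(dir, "km.pdf"), width = 7, height = 5)
    graphics::plot(report$km$fit, col = c(1, 2), xlab = "days since index",
         ylab = "relapse-free probability")
    graphics::legend("bottomleft", legend = c("GA", "fingolimod"),
                     col = c(1, 2), lty = 1)
    grDevices::dev.off()
    files <- c(files, "km.pdf")
  }
  invisible(files)
}
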