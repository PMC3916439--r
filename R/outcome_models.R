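#' Construct an outcome estimate
#'
#' @param measure one of "odds_ratio", "rate_ratio", "arr", "proportion".
#' @param estimate point estimate.
#' @param conf_low,conf_high 95% confidence bounds.
#' @param p_value two-sided p-value.
#' @param model model label.
#' @param n_per_arm named vector of arm sizes.
#' @return object of class `outcome_estimate`.
#' @export
outcome_estimate <- function(measure, estimate, conf_low, conf_high, p_value,
                             model = "", n_per_arm = NULL) {
  if (!is.na(estimate) && !is.na(conf_low) &&
      !(conf_low <= estimate && estimate <= conf_high))
    stop2("outcome_estimate: confidence bounds must bracket the estimate")
  structure(list(measure = measure, estimate = estimate, conf_low = conf_low,
                 conf_high = conf_high, p_value = p_value, model = model,
                 n_per_arm = n_per_arm),
            class = "outcome_estimate")
}

#' @export
format.outcome_estimate <- function(x, digits = 2, ...) {
  lab <- switch(x$measure, odds_ratio = "OR", rate_ratio = "RR",
                arr = "ARR", proportion = "proportion", x$measure)
  sprintf("%s %.*f (95%% CI %.*f-%.*f); p = %.4f", lab, digits, x$estimate,
          digits, x$conf_low, digits, x$conf_high, x$p_value)
}

#' @export
print.outcome_estimate <- function(x, ...) {
  cat(format(x, ...), "\n")
  if (!is.null(x$model) && nzchar(x$model)) cat("model: ", x$model, "\n", sep = "")
  invisible(x)
}

#' Relative reduction implied by a ratio estimate
#'
#' A ratio of 0.41 corresponds to a 59% reduction.
#'
#' @param x an `outcome_estimate` (odds or rate ratio) or a bare ratio.
#' @return percentage reduction, 100 * (1 - ratio).
#' @export
relative_reduction <- function(x) {
  r <- if (inherits(x, "outcome_estimate")) x$estimate else x
  100 * (1 - r)
}

check_outcome_frame <- function(data, response) {
  need <- c(response, "arm", "years", "pair_id")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop2("outcome data missing column(s): ",
                          paste(miss, collapse = ", "))
  if (any(data$years <= 0))
    stop2("outcome data contain years <= 0; exclude zero-persistence members first")
  if (length(unique(data$arm)) < 2L) stop2("both arms must be present")
  invisible(data)
}

outcome_model_matrix <- function(data, extra_covariates) {
  data$arm <- factor(data$arm, levels = c("GA", "fingolimod"))
  f <- as.formula(paste("~ arm", if (length(extra_covariates))
    paste("+", paste(extra_covariates, collapse = " + ")) else ""))
  X <- model.matrix(f, data)
  # drop aliased columns (collinear covariates) with a warning
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    drop <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    warning("dropping collinear column(s): ", paste(drop, collapse = ", "),
            call. = FALSE)
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
  }
  X
}

#' Probability of relapse while persistent (GEE logistic with offset)
#'
#' Logistic GEE with exchangeable working correlation, the matched pair as
#' cluster, robust variance, and log years-on-therapy entered as an offset
#' in the linear predictor (as specified for this analysis; offsets in logit
#' models are unusual, so a no-offset companion fit is attached as
#' `attr(, "no_offset")`).
#'
#' @param data data frame with columns `relapse` (0/1, any relapse while
#'   persistent), `arm` ("fingolimod"/"GA"), `years` (> 0, years persistent),
#'   `pair_id`, plus any extra covariate columns.
#' @param extra_covariates character vector of additional adjustment columns.
#' @param offset_log_years include the log-years offset (default TRUE).
#' @return an [outcome_estimate()] (odds ratio, fingolimod vs GA) with the
#'   underlying `gee_fit` in `attr(, "fit")`.
#' @export
fit_relapse_probability <- function(data, extra_covariates = character(0),
                                    offset_log_years = TRUE) {
  check_outcome_frame(data, "relapse")
  events <- tapply(data$relapse, data$arm, sum)
  if (any(events == 0)) {
    warning("zero relapse events in arm(s): ",
            paste(names(events)[events == 0], collapse = ", "),
            "; odds ratio not identifiable", call. = FALSE)
    return(outcome_estimate("odds_ratio", NA_real_, NA_real_, NA_real_,
                            NA_real_, model = "GEE logistic (non-identifiable)",
                            n_per_arm = table(data$arm)))
  }
  X <- outcome_model_matrix(data, extra_covariates)
  off <- if (offset_log_years) log(data$years) else NULL
  fit <- gee_fit(X, as.numeric(data$relapse), data$pair_id,
                 family = "binomial", offset = off)
  est <- gee_exp_estimate(fit, "armfingolimod")
  out <- outcome_estimate("odds_ratio", est$estimate, est$conf_low,
                          est$conf_high, est$p_value,
                          model = paste0("GEE logistic, exchangeable, ",
                                         if (offset_log_years)
                                           "offset log(years)" else "no offset"),
                          n_per_arm = table(data$arm))
  attr(out, "fit") <- fit
  if (offset_log_years) {
    no_off <- fit_relapse_probability(data, extra_covariates,
                                      offset_log_years = FALSE)
    attr(out, "no_offset") <- no_off
  }
  out
}

#' Annualized relapse rate model (negative-binomial GEE with offset)
#'
#' The negative-binomial dispersion is estimated by maximum likelihood on
#' the pooled data (MASS::glm.nb) and then held fixed inside a GEE fit with
#' exchangeable working correlation, pair clusters, robust variance, and log
#' years-on-therapy as the offset. When the pooled fit degenerates towards
#' Poisson (huge theta) the Poisson family is used. Model-based annualized
#' relapse rates (ARRs) per arm are the average predicted rates at one year
#' of exposure.
#'
#' @param data data frame with `count` (relapses while persistent), `arm`,
#'   `years`, `pair_id`, plus extra covariate columns.
#' @param extra_covariates additional adjustment columns.
#' @return list of class `relapse_rate_fit`: `rate_ratio` (an
#'   [outcome_estimate()]), `arr` (named per-arm model ARRs), `theta`,
#'   `dispersion` (1/theta), and `fit`.
#' @export
fit_relapse_rate <- function(data, extra_covariates = character(0)) {
  check_outcome_frame(data, "count")
  if (all(data$count == 0))
    stop2("all relapse counts are zero; rate model is degenerate")
  X <- outcome_model_matrix(data, extra_covariates)
  off <- log(data$years)

  theta <- tryCatch({
    nb <- suppressWarnings(MASS::glm.nb(
      data$count ~ X[, -1, drop = FALSE] + offset(off),
      control = glm.control(maxit = 100)))
    nb$theta
  }, error = function(e) Inf)

  family <- if (!is.finite(theta) || theta > 1e5) "poisson" else "negbin"
  fit <- gee_fit(X, data$count, data$pair_id, family = family,
                 theta = if (family == "negbin") theta else NULL,
                 offset = off)
  est <- gee_exp_estimate(fit, "armfingolimod")

  # model-based ARR: average predicted rate at one year of exposure per arm
  eta1 <- as.numeric(X %*% fit$coefficients)   # offset log(1) = 0
  arr <- tapply(exp(eta1), data$arm, mean)

  rr <- outcome_estimate("rate_ratio", est$estimate, est$conf_low,
                         est$conf_high, est$p_value,
                         model = paste0("GEE ", family,
                                        if (family == "negbin")
                                          sprintf(" (theta = %.3g)", theta)
                                        else "",
                                        ", exchangeable, offset log(years)"),
                         n_per_arm = table(data$arm))
  structure(list(rate_ratio = rr, arr = arr,
                 theta = if (family == "negbin") theta else Inf,
                 dispersion = if (family == "negbin") 1 / theta else 0,
                 fit = fit),
            class = "relapse_rate_fit")
}

#' @export
print.relapse_rate_fit <- function(x, ...) {
  print(x$rate_ratio)
  cat(sprintf("model ARR: fingolimod %.3f, GA %.3f (dispersion %.3g)\n",
              x$arr[["fingolimod"]], x$arr[["GA"]], x$dispersion))
  invisible(x)
}

#' Crude annualized relapse rate
#'
#' Total episodes divided by total person-time, person-time measured in
#' `year_days`-day years (360 by default, matching the study's 360-day
#' observation windows).
#'
#' @param counts episode counts per member.
#' @param days observed (persistent) days per member.
#' @param year_days days per year of person-time.
#' @return the crude ARR (single number).
#' @export
crude_arr <- function(counts, days, year_days = 360) {
  if (any(days <= 0)) stop2("crude_arr: days must be positive")
  sum(counts) / (sum(days) / year_days)
}

#' @rdname crude_arr
#' @param arm arm labels aligned with `counts`.
#' @return `crude_arr_by_arm()`: named vector of per-arm crude ARRs.
#' @export
crude_arr_by_arm <- function(counts, days, arm, year_days = 360) {
  vapply(split(seq_along(counts), arm), function(ix)
    crude_arr(counts[ix], days[ix], year_days), 0)
}

#' Kaplan-Meier time to first relapse with log-rank test
#'
#' Members are followed until first relapse, discontinuation of the index
#' therapy, or the end of the observation period, whichever comes first;
#' discontinuation and period end are censoring events.
#'
#' @param data data frame with `time` (days), `event` (1 = relapse), `arm`.
#' @return list of class `km_result`: `fit` (survfit), `curves` (tidy per-arm
#'   step function), `chisq` (1-df log-rank statistic), `p_value`,
#'   `median_days` per arm.
#' @export
km_time_to_first_relapse <- function(data) {
  data$arm <- factor(data$arm, levels = c("GA", "fingolimod"))
  fit <- survival::survfit(survival::Surv(time, event) ~ arm, data = data)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ arm, data = data)
  chisq <- as.numeric(sd_$chisq)
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  s <- summary(fit)
  curves <- data.frame(arm = sub("^arm=", "", as.character(s$strata)),
                       time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                       surv = s$surv)
  med <- summary(fit)$table
  med_days <- setNames(med[, "median"], sub("^arm=", "", rownames(med)))
  structure(list(fit = fit, curves = curves, chisq = chisq, p_value = p,
                 median_days = med_days),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("log-rank chi-square %.2f, p = %.4g\n", x$chisq, x$p_value))
  invisible(x)
}

#' Baseline characteristics table with arm comparisons
#'
#' Categorical variables are summarized as count (%) per arm and compared
#' with Pearson chi-square tests (no continuity correction); continuous
#' variables as mean +/- SD and median, compared with the Wilcoxon rank-sum
#' test. Constant variables are reported without a test; chi-square cells
#' with expected count below 1 are footnoted.
#'
#' @param covariates data frame of member covariates.
#' @param arm arm labels aligned with rows ("fingolimod"/"GA").
#' @param variables columns to tabulate (default all but member_id).
#' @return data frame: variable, level, fingolimod, GA, p_value, test, note.
#' @export
baseline_table <- function(covariates, arm, variables = NULL) {
  if (is.null(variables)) variables <- setdiff(names(covariates), "member_id")
  arm <- factor(arm, levels = c("fingolimod", "GA"))
  n_f <- sum(arm == "fingolimod"); n_g <- sum(arm == "GA")
  rows <- list()
  for (v in variables) {
    x <- covariates[[v]]
    if (is.logical(x) || is.character(x) || is.factor(x) ||
        (is.numeric(x) && all(x %in% c(0, 1)))) {
      x <- if (is.logical(x) || is.numeric(x)) factor(x, levels = c(FALSE, TRUE),
                                                      labels = c("no", "yes"))
           else factor(x)
      tab <- table(x, arm)
      note <- ""
      if (nlevels(x) < 2L || nlevels(droplevels(x)) < 2L) {
        p <- NA_real_; test <- "none"; note <- "constant"
      } else {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        p <- ct$p.value; test <- "chi-square"
        if (any(ct$expected < 1)) note <- "expected cell < 1"
      }
      for (lev in levels(x)) {
        if (is.logical(covariates[[v]]) && lev == "no") next
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lev,
          fingolimod = sprintf("%d (%.1f%%)", tab[lev, "fingolimod"],
                               100 * tab[lev, "fingolimod"] / n_f),
          GA = sprintf("%d (%.1f%%)", tab[lev, "GA"],
                       100 * tab[lev, "GA"] / n_g),
          p_value = p, test = test, note = note)
        p <- NA_real_; test <- ""; note <- ""   # print p on first level only
      }
    } else {
      x1 <- x[arm == "fingolimod"]; x0 <- x[arm == "GA"]
      if (length(unique(x)) < 2L) {
        p <- NA_real_; test <- "none"; note <- "constant"
      } else {
        p <- suppressWarnings(wilcox.test(x1, x0)$p.value)
        test <- "wilcoxon"; note <- ""
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "mean+-sd; median",
        fingolimod = sprintf("%.2f+-%.2f; %.1f", mean(x1), sd(x1), median(x1)),
        GA = sprintf("%.2f+-%.2f; %.1f", mean(x0), sd(x0), median(x0)),
        p_value = p, test = test, note = note)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity analysis: re-adjust for unmatched baseline symptoms
#'
#' Refits the relapse-probability and relapse-rate GEE models adding the
#' baseline symptoms that were not part of the matching procedure (headache,
#' muscle weakness/spasm/spasticity, visual symptoms, bladder dysfunction,
#' dizziness/vertigo, respiration problems, walking/balance/coordination by
#' default). Constant symptom columns are dropped with a warning; collinear
#' columns are dropped inside the model-matrix step.
#'
#' @param data outcome data frame with `relapse`, `count`, `arm`, `years`,
#'   `pair_id` and the symptom columns.
#' @param symptoms character vector of symptom column names to adjust for.
#' @return list: `odds_ratio` ([outcome_estimate()]), `rate_ratio`
#'   (`relapse_rate_fit`), `adjusted_for` (columns actually used).
#' @export
sensitivity_adjusted <- function(data,
                                 symptoms = c("headache", "muscle", "visual",
                                              "bladder", "dizziness",
                                              "respiration", "walking")) {
  symptoms <- intersect(symptoms, names(data))
  constant <- symptoms[vapply(symptoms, function(s)
    length(unique(data[[s]])) < 2L, TRUE)]
  if (length(constant)) {
    warning("dropping constant symptom column(s): ",
            paste(constant, collapse = ", "), call. = FALSE)
    symptoms <- setdiff(symptoms, constant)
  }
  list(odds_ratio = fit_relapse_probability(data, extra_covariates = symptoms),
       rate_ratio = fit_relapse_rate(data, extra_covariates = symptoms),
       adjusted_for = symptoms)
}
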