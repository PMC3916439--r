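outcome_frame <- function(n_pairs = 132, p1 = 0.15, p0 = 0.25, seed = 1,
                          years = NULL) {
  set.seed(seed)
  n <- 2 * n_pairs
  arm <- rep(c("fingolimod", "GA"), each = n_pairs)
  if (is.null(years)) years <- runif(n, 0.3, 1)
  rel <- rbinom(n, 1, ifelse(arm == "fingolimod", p1, p0))
  data.frame(member_id = sprintf("m%03d", 1:n), arm = arm,
             pair_id = rep(seq_len(n_pairs), 2), years = years,
             relapse = rel, count = rel + rbinom(n, 1, 0.1) * rel)
}

test_that("crude ARR arithmetic (360-day years)", {
  expect_equal(crude_arr(0, 100), 0)
  expect_equal(crude_arr(2, 180), 4)          # 2 / (180/360)
  # full 360-day windows: crude ARR equals the mean per-member count
  cnt <- c(0, 1, 2, 0, 1)
  expect_equal(crude_arr(cnt, rep(360, 5)), mean(cnt))
  by <- crude_arr_by_arm(c(1, 0, 2), c(360, 360, 180), c("a", "a", "b"))
  expect_equal(unname(by), c(0.5, 4))
  expect_error(crude_arr(1, 0), "positive")
})

test_that("log-rank statistic matches the hand-computed small example", {
  # arm A: events at days 5 and 10; arm B: censored at day 10.
  # at t=5: n=3 at risk (2 A), 1 event -> E_A = 2/3, V = 1*(2/3)*(1/3) = 2/9
  # at t=10: n=2 at risk (1 A), 1 event -> E_A = 1/2, V = 1/4
  # O_A - E_A = 2 - 7/6 = 5/6; chi-square = (5/6)^2 / (17/36) = 25/17
  d <- data.frame(time = c(5, 10, 10), event = c(1, 1, 0),
                  arm = c("fingolimod", "fingolimod", "GA"))
  km <- km_time_to_first_relapse(d)
  expect_equal(km$chisq, 25 / 17, tolerance = 1e-10)
  # label swap leaves the statistic unchanged
  d2 <- d; d2$arm <- ifelse(d$arm == "GA", "fingolimod", "GA")
  expect_equal(km_time_to_first_relapse(d2)$chisq, km$chisq)
  # identical arm data: statistic 0
  d3 <- data.frame(time = rep(c(50, 100, 360), 2),
                   event = rep(c(1, 1, 0), 2),
                   arm = rep(c("GA", "fingolimod"), each = 3))
  expect_equal(km_time_to_first_relapse(d3)$chisq, 0, tolerance = 1e-12)
  # survival curves are proper step functions
  expect_true(all(diff(km$curves$surv[km$curves$arm == "fingolimod"]) <= 0))
})

test_that("baseline table: identical arms give p = 1; counts reconstruct printed percentages", {
  cv <- data.frame(member_id = sprintf("m%03d", 1:264),
                   relapse_pre = rep(rep(c(TRUE, FALSE), c(44, 88)), 2))
  armv <- rep(c("fingolimod", "GA"), each = 132)
  tab <- baseline_table(cv, armv)
  expect_equal(tab$p_value[1], 1)
  expect_match(tab$fingolimod[tab$variable == "relapse_pre"], "44 \\(33.3%\\)")

  # relapse while persistent: 17/132 vs 33/132 -> Pearson chi-square 0.0120
  cv2 <- data.frame(member_id = sprintf("m%03d", 1:264),
                    any_relapse = c(rep(c(TRUE, FALSE), c(17, 115)),
                                    rep(c(TRUE, FALSE), c(33, 99))))
  tab2 <- baseline_table(cv2, armv)
  expect_equal(round(tab2$p_value[1], 4), 0.0120)

  cv3 <- data.frame(member_id = "m1", flag = TRUE)
  tab3 <- baseline_table(rbind(cv3, cv3), c("fingolimod", "GA"))
  expect_equal(tab3$note[1], "constant")
})

test_that("continuous covariates use the Wilcoxon rank-sum test", {
  cv <- data.frame(member_id = sprintf("m%02d", 1:40),
                   age = c(rnorm(20, 46, 5), rnorm(20, 50, 5)))
  armv <- rep(c("fingolimod", "GA"), each = 20)
  tab <- baseline_table(cv, armv)
  expect_equal(tab$test, "wilcoxon")
  ref <- wilcox.test(cv$age[1:20], cv$age[21:40])$p.value
  expect_equal(tab$p_value, ref)
})

test_that("relapse probability GEE: offset semantics and degenerate arms", {
  d <- outcome_frame(seed = 11, years = rep(0.75, 264))
  est <- fit_relapse_probability(d)
  no_off <- attr(est, "no_offset")
  # equal offsets only shift the intercept: identical odds ratio
  expect_equal(est$estimate, no_off$estimate, tolerance = 1e-6)
  expect_s3_class(est, "outcome_estimate")
  expect_true(est$conf_low <= est$estimate & est$estimate <= est$conf_high)

  d0 <- d; d0$relapse[d0$arm == "fingolimod"] <- 0
  expect_warning(bad <- fit_relapse_probability(d0), "not identifiable")
  expect_true(is.na(bad$estimate))

  dz <- d; dz$years[1] <- 0
  expect_error(fit_relapse_probability(dz), "years <= 0")
})

test_that("null odds ratio: CI covers 1 at the nominal rate (132 pairs)", {
  cover <- 0
  for (s in 1:100) {
    d <- outcome_frame(p1 = 0.2, p0 = 0.2, seed = 300 + s)
    if (sum(d$relapse[d$arm == "fingolimod"]) == 0 ||
        sum(d$relapse[d$arm == "GA"]) == 0) { cover <- cover + 1; next }
    est <- fit_relapse_probability(d)
    if (est$conf_low <= 1 && est$conf_high >= 1) cover <- cover + 1
  }
  expect_gte(cover, 93)
})

test_that("relapse rate model collapses to Poisson without overdispersion", {
  set.seed(21)
  n <- 4000
  arm <- rep(c("fingolimod", "GA"), each = n / 2)
  years <- runif(n, 0.5, 1)
  mu <- ifelse(arm == "fingolimod", 0.8, 1.6) * years
  d <- data.frame(member_id = seq_len(n), arm = arm, years = years,
                  pair_id = rep(seq_len(n / 2), 2),
                  count = rpois(n, mu))
  fit <- fit_relapse_rate(d)
  expect_lt(fit$dispersion, 0.05)
  ref <- glm(count ~ factor(arm, c("GA", "fingolimod")) +
               offset(log(years)), poisson(), data = d)
  expect_equal(fit$rate_ratio$estimate, unname(exp(coef(ref)[2])),
               tolerance = 0.01)
  # crude and model ARR agree on Poisson, covariate-free data
  crude <- crude_arr_by_arm(d$count, d$years * 360, d$arm)
  expect_equal(as.numeric(fit$arr[names(crude)]), as.numeric(crude),
               tolerance = 0.02)
  expect_error(fit_relapse_rate(transform(d, count = 0)), "zero")
})

test_that("sensitivity adjustment is inert when symptoms carry no signal", {
  d <- outcome_frame(seed = 31)
  d$headache <- FALSE; d$visual <- FALSE
  main_or <- fit_relapse_probability(d)
  expect_warning(sens <- sensitivity_adjusted(d), "constant symptom")
  expect_equal(sens$odds_ratio$estimate, main_or$estimate, tolerance = 1e-8)
  expect_equal(sens$adjusted_for, character(0))
  set.seed(5)
  d$headache <- runif(nrow(d)) < 0.2   # independent of outcome and arm
  sens2 <- sensitivity_adjusted(d, symptoms = "headache")
  expect_equal(sens2$odds_ratio$estimate, main_or$estimate, tolerance = 0.15)
  expect_equal(sens2$adjusted_for, "headache")
})

test_that("estimates format in the study's reporting layout", {
  est <- outcome_estimate("odds_ratio", 0.41, 0.21, 0.80, 0.0091)
  expect_equal(format(est), "OR 0.41 (95% CI 0.21-0.80); p = 0.0091")
  expect_equal(relative_reduction(est), 59)
  rr <- outcome_estimate("rate_ratio", 0.38, 0.21, 0.68, 0.0013)
  expect_equal(format(rr), "RR 0.38 (95% CI 0.21-0.68); p = 0.0013")
  expect_equal(relative_reduction(rr), 62)
  expect_error(outcome_estimate("arr", 0.5, 0.6, 0.7, 1), "bracket")
})
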