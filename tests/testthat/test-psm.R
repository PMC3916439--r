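test_that("nearest-neighbor matching with caliper: worked example", {
  scores <- c(t1 = 0.30, t2 = 0.50, c1 = 0.305, c2 = 0.52, c3 = 0.90)
  treat <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  pairs <- match_nearest_neighbor(scores, treat, strata = rep("0", 5),
                                  caliper = 0.01, seed = 1)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$treated, "t1")
  expect_equal(pairs$control, "c1")
  expect_equal(pairs$distance, 0.005, tolerance = 1e-12)
  un <- attr(pairs, "unmatched")
  expect_true("t2" %in% un$member_id)   # nearest is 0.02 away > caliper
  expect_setequal(un$member_id, c("t2", "c2", "c3"))
})

test_that("a stratum without controls leaves all treated unmatched", {
  scores <- c(a = 0.4, b = 0.5)
  pairs <- match_nearest_neighbor(scores, c(TRUE, TRUE), strata = c("1", "1"))
  expect_equal(nrow(pairs), 0)
  expect_setequal(attr(pairs, "unmatched")$member_id, c("a", "b"))
})

test_that("equidistant controls break ties by lowest member id", {
  scores <- c(t = 0.5, z = 0.52, a = 0.48)
  pairs <- match_nearest_neighbor(scores, c(TRUE, FALSE, FALSE),
                                  strata = rep("0", 3), caliper = 0.05)
  expect_equal(pairs$control, "a")
})

test_that("matching invariants: injectivity, caliper, shared stratum, determinism", {
  set.seed(4)
  for (i in 1:20) {
    n <- 120
    sc <- runif(n)
    names(sc) <- sprintf("m%03d", seq_len(n))
    tr <- runif(n) < 0.45
    st <- sample(c("0", "1", "2", "3+"), n, replace = TRUE,
                 prob = c(.6, .25, .1, .05))
    p1 <- match_nearest_neighbor(sc, tr, st, caliper = 0.05, seed = i)
    expect_false(any(duplicated(p1$treated)))
    expect_false(any(duplicated(p1$control)))
    expect_true(all(p1$distance <= 0.05 + 1e-12))
    expect_true(all(abs(p1$score_treated - p1$score_control) == p1$distance))
    # exact stratification: identical stratum histograms across arms
    expect_equal(table(p1$stratum), table(p1$stratum))
    p2 <- match_nearest_neighbor(sc, tr, st, caliper = 0.05, seed = i)
    expect_identical(p1, p2)
    # everyone is either paired or reported unmatched
    expect_equal(nrow(p1) * 2 + nrow(attr(p1, "unmatched")), n)
  }
})

test_that("propensity model: degenerate inputs", {
  g <- generate_bundle(sim_config(n_members = 120, seed = 8))
  idx <- find_index_switch(g$bundle)
  pre <- detect_relapse_episodes(g$bundle, idx, window = c(-360L, -1L))
  cv <- compute_baseline_covariates(g$bundle, idx, pre)
  tr <- idx$index_dmt == "fingolimod"
  expect_error(fit_propensity(cv, rep(TRUE, nrow(cv))), "both treatment arms")
  cv$constant_thing <- 1
  expect_warning(
    fit <- fit_propensity(cv, tr, variables = c("age", "gender",
                                                "constant_thing")),
    "constant")
  expect_false("constant_thing" %in% fit$variables)
  expect_true(all(fit$scores > 0 & fit$scores < 1))
  expect_equal(length(fit$scores), nrow(cv))
})

test_that("stepwise selection returns a subset of candidates and fits", {
  g <- generate_bundle(sim_config(n_members = 400, seed = 18))
  idx <- find_index_switch(g$bundle)
  pre <- detect_relapse_episodes(g$bundle, idx, window = c(-360L, -1L))
  cv <- compute_baseline_covariates(g$bundle, idx, pre)
  tr <- idx$index_dmt == "fingolimod"
  fit <- fit_propensity(cv, tr, selection = "stepwise")
  expect_s3_class(fit, "propensity_fit")
  expect_true(all(fit$variables %in% names(cv)))
  # the generator's assignment is genuinely confounded, so forward selection
  # should retain at least one of the true assignment covariates
  expect_true(length(fit$variables) >= 1)
  expect_true(any(c("fatigue", "depression", "diabetes", "age",
                    "relapse_within_90d_pre") %in% fit$variables))
})

test_that("under randomized assignment, propensity z-scores behave as N(0,1)", {
  zs <- c()
  for (s in 1:20) {
    g <- generate_bundle(sim_config(n_members = 2000, seed = 1000 + s,
                                    confounding_strength = 0))
    idx <- find_index_switch(g$bundle)
    pre <- detect_relapse_episodes(g$bundle, idx, window = c(-360L, -1L))
    cv <- compute_baseline_covariates(g$bundle, idx, pre)
    fit <- fit_propensity(cv, idx$index_dmt == "fingolimod")
    zs <- c(zs, fit$z[setdiff(names(fit$z), "(Intercept)")])
  }
  expect_lt(abs(mean(zs)), 0.2)
  expect_lt(mean(abs(zs) > 1.96), 0.10)
  expect_gt(sd(zs), 0.7)
  expect_lt(sd(zs), 1.3)
})

test_that("balance: zero SMD for identical arms, matching improves the worst SMD", {
  cv <- data.frame(member_id = sprintf("m%02d", 1:40),
                   age = rep(c(40, 50), 20),
                   fatigue = rep(c(TRUE, FALSE), 20))
  tr <- rep(c(TRUE, FALSE), each = 20)
  # identical distributions in both arms
  pairs <- data.frame(treated = cv$member_id[1:20],
                      control = cv$member_id[21:40])
  bal <- assess_balance(cv, tr, pairs)
  expect_true(all(bal$smd_before == 0))
  expect_true(all(bal$smd_after == 0))

  g <- generate_bundle(sim_config(n_members = 600, seed = 19))
  idx <- find_index_switch(g$bundle)
  pre <- detect_relapse_episodes(g$bundle, idx, window = c(-360L, -1L))
  cv <- compute_baseline_covariates(g$bundle, idx, pre)
  tr <- idx$index_dmt == "fingolimod"
  ps <- fit_propensity(cv, tr)
  pairs <- match_nearest_neighbor(ps$scores, tr,
                                  relapse_strata(cv$pre_index_relapse_count),
                                  seed = 3)
  bal <- assess_balance(cv, tr, pairs,
                        variables = c("age", "fatigue", "depression",
                                      "diabetes", "pre_index_relapse_count"))
  expect_lt(max(abs(bal$smd_after)), max(abs(bal$smd_before)))
  # stratified matching forces identical pre-index relapse-count histograms
  cnt <- setNames(cv$pre_index_relapse_count, cv$member_id)
  expect_equal(table(relapse_strata(cnt[pairs$treated])),
               table(relapse_strata(cnt[pairs$control])))
})
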