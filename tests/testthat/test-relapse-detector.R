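dayframe <- function(day, setting = "outpatient", dx = "340", proc = "") {
  n <- max(length(day), length(dx), length(setting), length(proc))
  data.frame(day = rep_len(day, n), setting = rep_len(setting, n),
             diagnoses = rep_len(dx, n), procedures = rep_len(proc, n))
}
rxframe <- function(day, ndc = DICT$ndc$oral_corticosteroid[1]) {
  data.frame(day = day, ndc = rep_len(ndc, length(day)))
}

test_that("inpatient events require a primary MS diagnosis in window", {
  ev <- detect_inpatient_events(dayframe(10, "inpatient"), DICT)
  expect_equal(ev$day, 10L)
  expect_equal(ev$kind, "inpatient")
  # 340 in secondary position only: not an inpatient relapse
  ev <- detect_inpatient_events(dayframe(10, "inpatient", "4930;340"), DICT)
  expect_equal(nrow(ev), 0)
  # detection is per claim; collapsing happens later
  ev <- detect_inpatient_events(dayframe(c(10, 12), "inpatient"), DICT)
  expect_equal(ev$day, c(10L, 12L))
  # window bounds are inclusive
  ev <- detect_inpatient_events(dayframe(c(-1, 0, 359, 360), "inpatient"),
                                DICT, window = c(0L, 359L))
  expect_equal(ev$day, c(0L, 359L))
})

test_that("outpatient events need a steroid within the window and no exclusionary primary dx", {
  med <- dayframe(10)
  expect_equal(detect_outpatient_events(med, rxframe(14), DICT)$day, 10L)
  expect_equal(nrow(detect_outpatient_events(med, rxframe(20), DICT)), 0)
  # IV steroid procedure claims qualify too
  iv <- rbind(med, dayframe(12, dx = "V5869",
                            proc = DICT$procedure$iv_corticosteroid[1]))
  expect_equal(detect_outpatient_events(iv, NULL, DICT)$day, 10L)
  # same-day claim with primary exclusionary dx (asthma) suppresses the event
  excl <- rbind(med, dayframe(10, dx = "49390"))
  expect_equal(nrow(detect_outpatient_events(excl, rxframe(12), DICT)), 0)
  # window runs forward by default; symmetric mode accepts earlier steroids
  expect_equal(nrow(detect_outpatient_events(med, rxframe(5), DICT)), 0)
  expect_equal(detect_outpatient_events(med, rxframe(5), DICT,
                                        direction = "symmetric")$day, 10L)
  # MS dx may sit in any position for outpatient visits
  any_pos <- dayframe(10, dx = "7840;340")
  expect_equal(detect_outpatient_events(any_pos, rxframe(11), DICT)$day, 10L)
})

test_that("30-day collapsing follows the anchor rule", {
  ev <- function(day, kind = "outpatient")
    data.frame(day = day, kind = rep_len(kind, length(day)))
  expect_equal(collapse_events(ev(10))$onset_day, 10L)
  expect_equal(nrow(collapse_events(ev(c(10, 35)))), 1)   # 25 <= 30
  got <- collapse_events(ev(c(10, 35, 45)))
  expect_equal(got$onset_day, c(10L, 45L))                # 45 - 10 = 35 > 30
  # rolling mode chains instead
  expect_equal(nrow(collapse_events(ev(c(0, 25, 50)), mode = "rolling")), 1)
  expect_equal(collapse_events(ev(c(0, 25, 50)))$onset_day, c(0L, 50L))
})

test_that("collapsing matches the brute-force oracle on random event sets", {
  set.seed(42)
  for (i in 1:200) {
    days <- sample(0:360, sample(1:12, 1), replace = TRUE)
    got <- collapse_events(data.frame(day = days, kind = "outpatient"))
    expect_equal(got$onset_day, oracle_collapse_onsets(days))
  }
})

test_that("collapsing is idempotent on episode onsets", {
  set.seed(7)
  for (i in 1:50) {
    days <- sample(0:360, sample(1:10, 1), replace = TRUE)
    ep <- collapse_events(data.frame(day = days, kind = "outpatient"))
    ep2 <- collapse_events(data.frame(day = ep$onset_day, kind = "outpatient"))
    expect_equal(ep2$onset_day, ep$onset_day)
  }
})

test_that("adding one event changes the episode count by at most +1", {
  set.seed(11)
  for (i in 1:100) {
    days <- sample(0:360, sample(1:10, 1), replace = TRUE)
    n0 <- nrow(collapse_events(data.frame(day = days, kind = "outpatient")))
    extra <- sample(0:360, 1)
    n1 <- nrow(collapse_events(data.frame(day = c(days, extra),
                                          kind = "outpatient")))
    expect_lte(n1, n0 + 1)
  }
})

test_that("episode kind: inpatient dominates; both-kind flags are kept", {
  ep <- collapse_events(data.frame(day = c(5, 20),
                                   kind = c("inpatient", "outpatient")))
  expect_equal(nrow(ep), 1)
  expect_equal(ep$kind, "inpatient")
  expect_true(ep$any_inpatient & ep$any_outpatient)
})

test_that("count_relapses restricts to window and the persistent period", {
  eps <- data.frame(onset_day = c(50L, 300L), kind = "outpatient")
  got <- count_relapses(eps, window = c(0L, 359L),
                        persistence = data.frame(days_persistent = 200L))
  expect_equal(got$count, 1)
  expect_equal(got$episodes$onset_day, 50L)
  # an episode with onset on the last persistent day (199) counts; 200 not
  expect_equal(count_relapses(data.frame(onset_day = 199L, kind = "x"),
                              persistence = 200L)$count, 1)
  expect_equal(count_relapses(data.frame(onset_day = 200L, kind = "x"),
                              persistence = 200L)$count, 0)
  expect_equal(count_relapses(data.frame(onset_day = -100L, kind = "x"),
                              window = c(-360L, -1L))$count, 1)
})

test_that("bundle-level detection agrees with the per-member primitives", {
  g <- generate_bundle(sim_config(n_members = 30, seed = 13))
  idx <- find_index_switch(g$bundle)
  eps <- detect_relapse_episodes(g$bundle, idx, window = c(0L, 359L))
  # recompute one member by hand through the exported primitives
  m <- eps$member_id[1]
  i0 <- idx$index_date[idx$member_id == m]
  med <- g$bundle$medical[g$bundle$medical$member_id == m, ]
  med$day <- as.numeric(med$service_date - i0)
  rx <- g$bundle$pharmacy[g$bundle$pharmacy$member_id == m, ]
  rx$day <- as.numeric(rx$fill_date - i0)
  ev <- rbind(detect_inpatient_events(med, DICT, c(0L, 359L)),
              detect_outpatient_events(med, rx, DICT, c(0L, 359L)))
  ref <- collapse_events(ev)
  expect_equal(eps$onset_day[eps$member_id == m], ref$onset_day)
  expect_equal(eps$kind[eps$member_id == m], ref$kind)
})
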