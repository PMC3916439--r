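test_that("write/read round-trip preserves accepted rows and counts", {
  g <- generate_bundle(sim_config(n_members = 5, seed = 21))
  dir <- withr::local_tempdir()
  write_bundle(g$bundle, dir)
  b2 <- read_claims_bundle(file.path(dir, "members.csv"),
                           file.path(dir, "medical.csv"),
                           file.path(dir, "pharmacy.csv"),
                           file.path(dir, "dictionaries.yaml"))
  expect_equal(nrow(b2$members), 5)
  expect_equal(nrow(attr(b2, "rejects")), 0)
  expect_equal(nrow(b2$medical), nrow(g$bundle$medical))
  expect_equal(nrow(b2$pharmacy), nrow(g$bundle$pharmacy))
  for (col in c("member_id", "service_date", "setting", "diagnoses",
                "procedures"))
    expect_equal(b2$medical[[col]], g$bundle$medical[[col]])
  for (col in c("member_id", "fill_date", "ndc", "days_supply",
                "supply_missing"))
    expect_equal(b2$pharmacy[[col]], g$bundle$pharmacy[[col]])

  # canonical formatting: a second write is byte-identical
  dir2 <- withr::local_tempdir()
  write_bundle(b2, dir2)
  for (f in c("members.csv", "medical.csv", "pharmacy.csv"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})

test_that("malformed rows go to the rejects report, missing supply is flagged", {
  dir <- withr::local_tempdir()
  writeLines(c("member_id,birth_year,gender,region,plan_type,payer_type,enroll_start,enroll_end",
               "m1,1970,F,East,PPO,Commercial,2010-01-01,2012-12-31"),
             file.path(dir, "members.csv"))
  writeLines(c("member_id,service_date,setting,diagnoses,procedures,provider_specialty,paid_amount",
               "m1,2011-06-01,outpatient,340,,neurology,100",
               "m1,2011-06-02,outpatient,,,neurology,100",       # empty dx
               "zz,2011-06-03,outpatient,340,,neurology,100"),   # unknown member
             file.path(dir, "medical.csv"))
  writeLines(c("member_id,fill_date,ndc,days_supply,paid_amount",
               "m1,2011-06-01,60000000301,30,50",
               "m1,2011-07-01,60000000301,,50"),                 # empty supply
             file.path(dir, "pharmacy.csv"))
  b <- read_claims_bundle(file.path(dir, "members.csv"),
                          file.path(dir, "medical.csv"),
                          file.path(dir, "pharmacy.csv"))
  rej <- attr(b, "rejects")
  expect_equal(nrow(b$medical), 1)
  expect_equal(sum(rej$table == "medical"), 2)
  # missing days_supply is retained, not rejected
  expect_equal(nrow(b$pharmacy), 2)
  expect_equal(b$pharmacy$supply_missing, c(FALSE, TRUE))
  expect_true(is.na(b$pharmacy$days_supply[2]))
})

test_that("schema violations are fatal and name the problem", {
  dir <- withr::local_tempdir()
  writeLines(c("member_id,birth_year,gender,region,plan_type,payer_type,enroll_start",
               "m1,1970,F,East,PPO,Commercial,2010-01-01"),
             file.path(dir, "members.csv"))
  writeLines("member_id,fill_date,ndc,days_supply,paid_amount",
             file.path(dir, "pharmacy.csv"))
  writeLines("member_id,service_date,setting,diagnoses,procedures,provider_specialty,paid_amount",
             file.path(dir, "medical.csv"))
  expect_error(read_claims_bundle(file.path(dir, "members.csv"),
                                  file.path(dir, "medical.csv"),
                                  file.path(dir, "pharmacy.csv")),
               "enroll_end")
  writeLines(c("member_id,birth_year,gender,region,plan_type,payer_type,enroll_start,enroll_end"),
             file.path(dir, "members.csv"))
  expect_error(read_claims_bundle(file.path(dir, "members.csv"),
                                  file.path(dir, "medical.csv"),
                                  file.path(dir, "pharmacy.csv")),
               "empty member table")
})

test_that("claims classify by exact NDC / procedure lookup", {
  d <- default_dictionaries()
  expect_equal(classify_claim(list(ndc = d$ndc$GA[1]), d), "GA")
  expect_equal(classify_claim(list(procedures = d$procedure$IFN[1]), d), "IFN")
  expect_true(is.na(classify_claim(list(ndc = "99999999999"), d)))
  expect_equal(classify_ndc(c(d$ndc$fingolimod[1], "x", d$ndc$IFN[2]), d),
               c("fingolimod", NA, "IFN"))
})

test_that("ICD-9 matching is prefix-based on dot-stripped codes", {
  expect_true(icd_match("340.0", "340"))
  expect_true(icd_match("49390", "493"))
  expect_false(icd_match("34", "340"))
  expect_equal(icd_match(c("340", "3409", "341"), "340"),
               c(TRUE, TRUE, FALSE))
})

test_that("dictionary config validates and round-trips through YAML", {
  d <- default_dictionaries()
  p <- withr::local_tempfile(fileext = ".yaml")
  write_dictionaries(d, p)
  d2 <- read_dictionaries(p)
  expect_equal(d2$ndc, d$ndc)
  expect_equal(d2$icd$symptoms, d$icd$symptoms)
  expect_equal(d2$charlson, d$charlson)

  d$ndc$GA <- c(d$ndc$GA, d$ndc$IFN[1])   # one code, two classes
  expect_error(write_dictionaries(d, p), "more than one drug class")
  d <- default_dictionaries(); d$icd$ms <- "123"
  expect_error(write_dictionaries(d, p), "340")
})

test_that("validate_bundle flags the data-quality exclusions", {
  fx <- fx_member("m1")
  fx$enrollment$end_date <- fx$enrollment$start_date - 1   # end before start
  b <- fx_bundle(fx_medical("m1", 10), fx_ifn_history("m1"), members = fx)
  v <- validate_bundle(b)
  expect_true("invalid_enrollment" %in% v$violation)

  fx2 <- fx_member("m2", gender = NA)
  b2 <- fx_bundle(fx_medical("m2", 10), members = fx2)
  expect_true("missing_gender" %in% validate_bundle(b2)$violation)

  fx3 <- fx_member("m3", enroll = c(-10L, 10L))
  b3 <- fx_bundle(fx_medical("m3", 50), members = fx3)  # claim outside span
  expect_true("claim_outside_enrollment" %in% validate_bundle(b3)$violation)

  g <- generate_bundle(sim_config(n_members = 40, seed = 5))
  expect_equal(nrow(validate_bundle(g$bundle)), 0)
})

test_that("classification is invariant to claim row order", {
  g <- generate_bundle(sim_config(n_members = 20, seed = 9))
  b <- g$bundle
  set.seed(1)
  b$medical <- b$medical[sample(nrow(b$medical)), ]
  b$pharmacy <- b$pharmacy[sample(nrow(b$pharmacy)), ]
  idx1 <- find_index_switch(g$bundle)
  idx2 <- find_index_switch(b)
  idx2 <- idx2[match(idx1$member_id, idx2$member_id), ]
  expect_equal(idx1$index_date, idx2$index_date)
  expect_equal(idx1$index_dmt, idx2$index_dmt)
})
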