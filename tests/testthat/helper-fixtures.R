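# Hand-built bundle fixtures. Day offsets are relative to a fixed index
# date inside the study's calendar window.

FIX_INDEX <- as.Date("2011-06-01")

fx_member <- function(id = "m1", birth_year = 1970L, gender = "F",
                      enroll = c(-540L, 539L)) {
  list(member = data.frame(member_id = id, birth_year = birth_year,
                           gender = gender, region = "East",
                           plan_type = "PPO", payer_type = "Commercial"),
       enrollment = data.frame(member_id = id,
                               start_date = FIX_INDEX + enroll[1],
                               end_date = FIX_INDEX + enroll[2]))
}

fx_medical <- function(id, day, setting = "outpatient", dx = "340",
                       proc = "", specialty = "neurology", paid = 100) {
  n <- if (!length(day)) 0L else max(length(day), length(dx), length(setting))
  data.frame(claim_id = paste0("m", id, "_", seq_len(n), recycle0 = TRUE),
             member_id = rep_len(id, n),
             service_date = FIX_INDEX + rep_len(day, n),
             setting = rep_len(setting, n), diagnoses = rep_len(dx, n),
             procedures = rep_len(proc, n),
             provider_specialty = rep_len(specialty, n),
             paid_amount = rep_len(paid, n))
}

fx_pharmacy <- function(id, day, ndc, supply = 30L, paid = 50) {
  n <- if (!length(day)) 0L else max(length(day), length(ndc), length(supply))
  supply <- rep_len(as.integer(supply), n)
  data.frame(claim_id = paste0("p", id, "_", seq_len(n), recycle0 = TRUE),
             member_id = rep_len(id, n),
             fill_date = FIX_INDEX + rep_len(day, n),
             ndc = rep_len(if (!n) character(0) else ndc, n),
             days_supply = supply, supply_missing = is.na(supply),
             paid_amount = rep_len(paid, n))
}

empty_medical <- function() fx_medical("x", integer(0))
empty_pharmacy <- function() fx_pharmacy("x", integer(0), character(0))

# a one-member bundle from claim pieces
fx_bundle <- function(..., members = fx_member()) {
  pieces <- list(...)
  med <- do.call(rbind, c(Filter(function(p) "service_date" %in% names(p),
                                 pieces), list(empty_medical())))
  rx <- do.call(rbind, c(Filter(function(p) "fill_date" %in% names(p),
                                pieces), list(empty_pharmacy())))
  claims_bundle(members$member, members$enrollment, med, rx)
}

# standard IFN history ending `gap` days before index
fx_ifn_history <- function(id, gap = 20L) {
  d <- default_dictionaries()
  fx_pharmacy(id, seq(-gap, -360L, by = -30L), d$ndc$IFN[1])
}

DICT <- default_dictionaries()
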