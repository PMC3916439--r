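#' Default code dictionaries
#'
#' Builds the code dictionaries that drive every classification step:
#' NDC sets per drug class, procedure-code sets for clinic-administered
#' drugs, and ICD-9 prefix sets for the MS diagnosis, exclusionary primary
#' diagnoses on outpatient relapse days, comorbidities, symptoms, and a
#' compact Charlson comorbidity map with integer weights.
#'
#' The NDC and procedure lists shipped here are synthetic but structurally
#' valid placeholders (real national drug code lists for these products are
#' distributed under license); the ICD-9 prefixes are the public, standard
#' ones. All sets are plain character vectors and can be edited or replaced
#' wholesale via [read_dictionaries()].
#'
#' @return a list with elements `ndc`, `procedure`, `icd` (containing `ms`,
#'   `exclusionary_primary`, `comorbidities`, `symptoms`) and `charlson`
#'   (named list of `list(weight=, prefixes=)`).
#' @export
default_dictionaries <- function() {
  list(
    ndc = list(
      IFN                 = c("60000000101", "60000000102", "60000000103", "60000000104"),
      GA                  = c("60000000201"),
      fingolimod          = c("60000000301"),
      natalizumab         = c("60000000401"),
      dalfampridine       = c("60000000501"),
      oral_corticosteroid = c("60000000601", "60000000602")
    ),
    procedure = list(
      IFN               = c("PIFN01"),
      GA                = c("PGA01"),
      natalizumab       = c("PNTZ01"),
      iv_corticosteroid = c("PIVS01")
    ),
    icd = list(
      ms = c("340"),
      # primary diagnoses that disqualify an outpatient steroid-linked visit:
      # asthma, gout, rheumatoid arthritis, uveitis
      exclusionary_primary = c("493", "274", "714", "364"),
      comorbidities = list(
        depression   = c("296", "311"),
        diabetes     = c("250"),
        dyslipidemia = c("272"),
        tobacco      = c("3051"),
        cvd          = c("410", "411", "412", "413", "414", "428")
      ),
      symptoms = list(
        numbness    = c("7820"),
        fatigue     = c("7807"),
        bowel       = c("5640", "5641"),
        headache    = c("7840"),
        muscle      = c("72885", "7281"),
        visual      = c("368"),
        bladder     = c("5966"),
        dizziness   = c("7804"),
        respiration = c("7860"),
        walking     = c("7812", "7813")
      )
    ),
    charlson = list(
      mi         = list(weight = 1L, prefixes = c("410", "412")),
      chf        = list(weight = 1L, prefixes = c("428")),
      copd       = list(weight = 1L, prefixes = c("490", "491", "492", "496")),
      diabetes   = list(weight = 1L, prefixes = c("250")),
      liver_mild = list(weight = 1L, prefixes = c("571")),
      renal      = list(weight = 2L, prefixes = c("582", "585", "586")),
      cancer     = list(weight = 2L, prefixes = c("140", "162", "174"))
    )
  )
}

#' Read / write code dictionaries as YAML
#'
#' @param path file path of a YAML dictionary config.
#' @return `read_dictionaries()` returns the dictionary list;
#'   `write_dictionaries()` returns `path` invisibly.
#' @export
read_dictionaries <- function(path) {
  if (!file.exists(path)) stop2("dictionary file not found: ", path)
  d <- yaml::read_yaml(path)
  for (top in c("ndc", "procedure", "icd", "charlson"))
    if (is.null(d[[top]])) stop2("dictionary config missing section '", top, "'")
  # yaml reads scalars as length-1 vectors; coerce code sets to character
  d$ndc <- lapply(d$ndc, as.character)
  d$procedure <- lapply(d$procedure, as.character)
  d$icd$ms <- as.character(d$icd$ms)
  d$icd$exclusionary_primary <- as.character(d$icd$exclusionary_primary)
  d$icd$comorbidities <- lapply(d$icd$comorbidities, as.character)
  d$icd$symptoms <- lapply(d$icd$symptoms, as.character)
  d$charlson <- lapply(d$charlson, function(x)
    list(weight = as.integer(x$weight), prefixes = as.character(x$prefixes)))
  validate_dictionaries(d)
  d
}

#' @rdname read_dictionaries
#' @param dictionaries a dictionary list as from [default_dictionaries()].
#' @export
write_dictionaries <- function(dictionaries, path) {
  validate_dictionaries(dictionaries)
  yaml::write_yaml(dictionaries, path)
  invisible(path)
}

validate_dictionaries <- function(d) {
  if (!"340" %in% strip_dots(d$icd$ms))
    stop2("MS diagnosis set must contain code 340")
  # a code maps to at most one drug class
  for (tab in c("ndc", "procedure")) {
    all_codes <- unlist(d[[tab]], use.names = FALSE)
    dup <- unique(all_codes[duplicated(all_codes)])
    if (length(dup))
      stop2("codes mapped to more than one drug class in '", tab, "': ",
            paste(dup, collapse = ", "))
  }
  invisible(d)
}

#' Construct a claims bundle
#'
#' A claims bundle links the three study tables (members with enrollment
#' spans, medical claims, pharmacy claims) and the code dictionaries; it is
#' the universe every pipeline stage consumes.
#'
#' Schemas (all dates ISO-8601 `Date`):
#' * `members`: member_id, birth_year, gender ("F"/"M"), region, plan_type,
#'   payer_type
#' * `enrollment`: member_id, start_date, end_date (closed intervals)
#' * `medical`: claim_id, member_id, service_date, setting
#'   ("inpatient"/"outpatient"), diagnoses (";"-joined, position 1 primary),
#'   procedures (";"-joined, may be empty), provider_specialty, paid_amount
#' * `pharmacy`: claim_id, member_id, fill_date, ndc, days_supply
#'   (integer; NA = missing), supply_missing (logical), paid_amount
#'
#' @param members,enrollment,medical,pharmacy data frames per the schema.
#' @param dictionaries dictionary list, see [default_dictionaries()].
#' @return an object of class `claims_bundle`.
#' @export
claims_bundle <- function(members, enrollment, medical, pharmacy,
                          dictionaries = default_dictionaries()) {
  members <- as.data.frame(members); enrollment <- as.data.frame(enrollment)
  medical <- as.data.frame(medical); pharmacy <- as.data.frame(pharmacy)
  if (nrow(medical) && !all(medical$member_id %in% members$member_id))
    stop2("medical claims reference unknown member ids")
  if (nrow(pharmacy) && !all(pharmacy$member_id %in% members$member_id))
    stop2("pharmacy claims reference unknown member ids")
  enrollment <- merge_adjacent_spans(enrollment)
  dates <- c(medical$service_date, pharmacy$fill_date,
             enrollment$start_date, enrollment$end_date)
  bounds <- if (length(dates)) range(dates) else as.Date(c(NA, NA))
  structure(list(members = members, enrollment = enrollment,
                 medical = medical, pharmacy = pharmacy,
                 dictionaries = dictionaries, calendar_bounds = bounds),
            class = "claims_bundle")
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle> ", nrow(x$members), " members, ",
      nrow(x$medical), " medical claims, ",
      nrow(x$pharmacy), " pharmacy claims\n", sep = "")
  if (!any(is.na(x$calendar_bounds)))
    cat("  calendar: ", format(x$calendar_bounds[1]), " .. ",
        format(x$calendar_bounds[2]), "\n", sep = "")
  invisible(x)
}

# administrative spans that abut (end + 1 day == next start) are one
# continuous enrollment; merge them at load time
merge_adjacent_spans <- function(enrollment) {
  if (!nrow(enrollment)) return(enrollment)
  if (!anyDuplicated(enrollment$member_id)) {
    rownames(enrollment) <- NULL
    return(enrollment)   # one span per member: nothing to merge
  }
  enrollment <- enrollment[order(enrollment$member_id, enrollment$start_date), ]
  out <- lapply(split(enrollment, enrollment$member_id), function(e) {
    keep <- list(e[1, ])
    if (nrow(e) > 1) for (i in 2:nrow(e)) {
      last <- keep[[length(keep)]]
      if (as.integer(e$start_date[i] - last$end_date) <= 1L) {
        last$end_date <- max(last$end_date, e$end_date[i])
        keep[[length(keep)]] <- last
      } else keep[[length(keep) + 1L]] <- e[i, ]
    }
    do.call(rbind, keep)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

required_cols <- list(
  member   = c("member_id", "birth_year", "gender", "region", "plan_type",
               "payer_type", "enroll_start", "enroll_end"),
  medical  = c("member_id", "service_date", "setting", "diagnoses",
               "procedures", "provider_specialty", "paid_amount"),
  pharmacy = c("member_id", "fill_date", "ndc", "days_supply", "paid_amount")
)

char_cols <- list(
  member = c("member_id", "gender", "region", "plan_type", "payer_type"),
  medical = c("member_id", "setting", "diagnoses", "procedures",
              "provider_specialty"),
  pharmacy = c("member_id", "ndc"))

read_table_checked <- function(path, what) {
  if (!file.exists(path)) stop2(what, " table not found: ", path)
  dt <- data.table::fread(path, colClasses = list(character = char_cols[[what]]),
                          na.strings = c("", "NA"))
  missing <- setdiff(required_cols[[what]], names(dt))
  if (length(missing))
    stop2("schema error in ", what, " table (", path, "): missing column(s) ",
          paste(missing, collapse = ", "))
  as.data.frame(dt)
}

#' Read a claims bundle from delimited text files
#'
#' Delimiters (comma or tab) are auto-detected. One row per enrollment span
#' in the member table (`enroll_start`/`enroll_end` columns); member
#' attributes are taken from each member's first row. Unparseable or
#' invariant-violating rows (e.g. a medical claim with an empty diagnosis
#' list) are collected into a rejects report attached as
#' `attr(bundle, "rejects")`, never silently dropped. A pharmacy row with an
#' empty `days_supply` is retained with `supply_missing = TRUE`.
#'
#' @param member_path,medical_path,pharmacy_path paths to the three tables.
#' @param dictionary_path path to a YAML dictionary config; `NULL` uses
#'   [default_dictionaries()].
#' @return a [claims_bundle()] with a `rejects` attribute (data frame of
#'   table, row number, reason).
#' @export
read_claims_bundle <- function(member_path, medical_path, pharmacy_path,
                               dictionary_path = NULL) {
  dict <- if (is.null(dictionary_path)) default_dictionaries()
          else read_dictionaries(dictionary_path)
  mem_raw <- read_table_checked(member_path, "member")
  if (!nrow(mem_raw)) stop2("empty member table: ", member_path)
  med_raw <- read_table_checked(medical_path, "medical")
  rx_raw  <- read_table_checked(pharmacy_path, "pharmacy")

  rejects <- list()
  note <- function(table, rows, reason) {
    if (length(rows)) rejects[[length(rejects) + 1L]] <<-
      data.frame(table = table, row = rows, reason = reason)
  }

  members <- unique(mem_raw[, c("member_id", "birth_year", "gender", "region",
                                "plan_type", "payer_type")])
  members <- members[!duplicated(members$member_id), ]
  enrollment <- data.frame(member_id = mem_raw$member_id,
                           start_date = as.Date(mem_raw$enroll_start),
                           end_date = as.Date(mem_raw$enroll_end))

  med_raw$service_date <- as.Date(med_raw$service_date)
  med_raw$diagnoses <- ifelse(is.na(med_raw$diagnoses), "", med_raw$diagnoses)
  med_raw$procedures <- ifelse(is.na(med_raw$procedures), "", med_raw$procedures)
  bad_med <- which(med_raw$diagnoses == "" | is.na(med_raw$service_date) |
                     !med_raw$setting %in% c("inpatient", "outpatient"))
  note("medical", bad_med, "empty diagnosis list, bad date or unknown setting")
  medical <- if (length(bad_med)) med_raw[-bad_med, ] else med_raw
  medical$claim_id <- if (nrow(medical)) paste0("M", seq_len(nrow(medical))) else character(0)

  rx_raw$fill_date <- as.Date(rx_raw$fill_date)
  bad_rx <- which(is.na(rx_raw$fill_date) | is.na(rx_raw$ndc) |
                    (!is.na(rx_raw$days_supply) & rx_raw$days_supply < 0))
  note("pharmacy", bad_rx, "bad fill date, missing NDC or negative supply")
  pharmacy <- if (length(bad_rx)) rx_raw[-bad_rx, ] else rx_raw
  pharmacy$days_supply <- as.integer(pharmacy$days_supply)
  pharmacy$supply_missing <- is.na(pharmacy$days_supply)
  pharmacy$claim_id <- if (nrow(pharmacy)) paste0("P", seq_len(nrow(pharmacy))) else character(0)

  # claims referencing unknown members are rejects, not a fatal error
  bad_mm <- which(!medical$member_id %in% members$member_id)
  note("medical", bad_mm, "unknown member_id")
  if (length(bad_mm)) medical <- medical[-bad_mm, ]
  bad_pm <- which(!pharmacy$member_id %in% members$member_id)
  note("pharmacy", bad_pm, "unknown member_id")
  if (length(bad_pm)) pharmacy <- pharmacy[-bad_pm, ]

  bundle <- claims_bundle(members, enrollment,
                          medical[, c("claim_id", required_cols$medical)],
                          pharmacy[, c("claim_id", "member_id", "fill_date",
                                       "ndc", "days_supply", "supply_missing",
                                       "paid_amount")],
                          dict)
  attr(bundle, "rejects") <- if (length(rejects)) do.call(rbind, rejects)
    else data.frame(table = character(0), row = integer(0), reason = character(0))
  bundle
}

#' Write a claims bundle to a directory of delimited text files
#'
#' Canonical formatting: comma-separated, ISO dates, stable column order, so
#' that a write/read cycle reproduces accepted rows exactly.
#'
#' @param bundle a [claims_bundle()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly. Files: `members.csv`,
#'   `medical.csv`, `pharmacy.csv`, `dictionaries.yaml`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  enr <- bundle$enrollment
  mem <- merge(bundle$members, enr, by = "member_id", sort = FALSE)
  mem <- data.frame(mem[, c("member_id", "birth_year", "gender", "region",
                            "plan_type", "payer_type")],
                    enroll_start = format(mem$start_date),
                    enroll_end = format(mem$end_date))
  mem <- mem[order(mem$member_id, mem$enroll_start), ]
  data.table::fwrite(mem, file.path(dir, "members.csv"))
  med <- bundle$medical
  med$service_date <- format(med$service_date)
  data.table::fwrite(med[, required_cols$medical],
                     file.path(dir, "medical.csv"))
  rx <- bundle$pharmacy
  rx$fill_date <- format(rx$fill_date)
  data.table::fwrite(rx[, required_cols$pharmacy],
                     file.path(dir, "pharmacy.csv"))
  write_dictionaries(bundle$dictionaries, file.path(dir, "dictionaries.yaml"))
  invisible(dir)
}

#' Data-quality validation of a claims bundle
#'
#' Report-only screen for the data-quality exclusions applied at cohort
#' entry: invalid or overlapping enrollment spans, missing/implausible age,
#' missing gender, and claims dated outside any enrollment span.
#'
#' @param bundle a [claims_bundle()].
#' @return data frame with columns `member_id`, `violation`; zero rows when
#'   the bundle is clean.
#' @export
validate_bundle <- function(bundle) {
  out <- list()
  add <- function(ids, what) if (length(ids)) out[[length(out) + 1L]] <<-
    data.frame(member_id = unique(ids), violation = what)

  enr <- bundle$enrollment
  bad_span <- enr$member_id[!is.na(enr$start_date) & !is.na(enr$end_date) &
                              enr$end_date < enr$start_date]
  miss_span <- enr$member_id[is.na(enr$start_date) | is.na(enr$end_date)]
  # overlapping spans (after adjacent-span merging these indicate bad data)
  enr2 <- enr[order(enr$member_id, enr$start_date), ]
  ov <- enr2$member_id[-1][enr2$member_id[-1] == enr2$member_id[-nrow(enr2)] &
                             enr2$start_date[-1] <= enr2$end_date[-nrow(enr2)]]
  add(c(bad_span, miss_span, ov), "invalid_enrollment")

  m <- bundle$members
  yr_hi <- as.integer(format(bundle$calendar_bounds[2], "%Y"))
  add(m$member_id[is.na(m$birth_year) |
                    (!is.na(yr_hi) & m$birth_year > yr_hi)], "missing_age")
  add(m$member_id[is.na(m$gender) | !m$gender %in% c("F", "M")], "missing_gender")

  single_span <- !anyDuplicated(enr$member_id)
  in_span <- function(ids, dates) {
    if (single_span) {
      r <- match(ids, enr$member_id)
      ok <- !is.na(r) & dates >= enr$start_date[r] & dates <= enr$end_date[r]
      ok[is.na(ok)] <- FALSE
      return(ok)
    }
    ok <- rep(FALSE, length(ids))
    key <- split(seq_along(ids), ids)
    espl <- split(enr, enr$member_id)
    for (mid in names(key)) {
      e <- espl[[mid]]
      if (is.null(e)) next
      d <- dates[key[[mid]]]
      hit <- rep(FALSE, length(d))
      for (r in seq_len(nrow(e)))
        hit <- hit | (d >= e$start_date[r] & d <= e$end_date[r])
      ok[key[[mid]]] <- hit
    }
    ok
  }
  if (nrow(bundle$medical)) {
    ok <- in_span(bundle$medical$member_id, bundle$medical$service_date)
    add(bundle$medical$member_id[!ok], "claim_outside_enrollment")
  }
  if (nrow(bundle$pharmacy)) {
    ok <- in_span(bundle$pharmacy$member_id, bundle$pharmacy$fill_date)
    add(bundle$pharmacy$member_id[!ok], "claim_outside_enrollment")
  }
  res <- if (length(out)) unique(do.call(rbind, out))
    else data.frame(member_id = character(0), violation = character(0))
  rownames(res) <- NULL
  res
}

#' Classify a claim into a drug class
#'
#' Pharmacy claims are classified by exact NDC lookup, medical claims by
#' exact procedure-code lookup. Pure function of (code, dictionary).
#'
#' @param claim one-row data frame: a pharmacy claim (has `ndc`) or a
#'   medical claim (has `procedures`).
#' @param dictionaries dictionary list.
#' @return the drug class name (e.g. "GA", "IFN", "fingolimod"), or `NA` when
#'   no dictionary entry matches.
#' @export
classify_claim <- function(claim, dictionaries) {
  if (!is.null(claim$ndc)) return(classify_ndc(claim$ndc, dictionaries))
  if (!is.null(claim$procedures)) {
    codes <- split_codes(claim$procedures)[[1]]
    cls <- classify_procedure(codes, dictionaries)
    hit <- cls[!is.na(cls)]
    return(if (length(hit)) hit[[1]] else NA_character_)
  }
  NA_character_
}

#' @rdname classify_claim
#' @param ndc character vector of NDCs.
#' @export
classify_ndc <- function(ndc, dictionaries) {
  map <- dictionaries$ndc
  out <- rep(NA_character_, length(ndc))
  for (cls in names(map)) out[ndc %in% map[[cls]]] <- cls
  out
}

#' @rdname classify_claim
#' @param procedure character vector of procedure codes.
#' @export
classify_procedure <- function(procedure, dictionaries) {
  map <- dictionaries$procedure
  out <- rep(NA_character_, length(procedure))
  for (cls in names(map)) out[procedure %in% map[[cls]]] <- cls
  out
}

# classify every ";"-joined procedure string to its first matching class
classify_procedure_joined <- function(joined, dictionaries) {
  if (!length(joined)) return(character(0))
  uniq_map(joined, function(j) {
    cs <- strsplit(if (is.na(j)) "" else j, ";", fixed = TRUE)[[1]]
    cls <- classify_procedure(cs, dictionaries)
    hit <- cls[!is.na(cls)]
    if (length(hit)) hit[[1]] else NA_character_
  }, NA_character_)
}
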