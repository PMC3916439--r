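#' @import data.table
#' @importFrom stats aggregate anova as.formula binomial chisq.test coef
#'   glm glm.control model.matrix model.offset model.response pchisq pnorm
#'   poisson predict qlogis quantile rbinom rexp rgamma rlnorm rnorm rpois
#'   runif sd setNames wilcox.test
#' @importFrom utils head modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Strip decimal points from ICD-9 codes
#'
#' Claims extracts vary in decimal formatting ("340" vs "340.0"); all code
#' matching in this package is prefix matching on the dot-stripped code.
#'
#' @param codes character vector of diagnosis codes.
#' @return character vector with "." removed.
#' @keywords internal
strip_dots <- function(codes) gsub(".", "", codes, fixed = TRUE)

#' Prefix-match ICD-9 codes against a prefix set
#'
#' @param codes character vector of codes (possibly dotted).
#' @param prefixes character vector of dot-free prefixes.
#' @return logical vector, TRUE where any prefix matches.
#' @export
icd_match <- function(codes, prefixes) {
  if (length(codes) == 0L) return(logical(0))
  codes <- strip_dots(codes)
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

# diagnosis / procedure lists are stored as ";"-joined strings so that claim
# tables round-trip through delimited text
split_codes <- function(x) {
  if (!length(x)) return(list())
  strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
}
join_codes <- function(lst) vapply(lst, paste, "", collapse = ";")

# apply f over the unique values of x and expand; claim tables carry few
# distinct code strings, so this turns per-row work into per-value work
uniq_map <- function(x, f, template) {
  u <- unique(x)
  vapply(u, f, template, USE.NAMES = FALSE)[match(x, u)]
}

# any code in a ";"-joined string matches a prefix set
codes_match_any <- function(joined, prefixes) {
  if (!length(joined)) return(logical(0))
  uniq_map(joined, function(j) {
    cs <- strsplit(if (is.na(j)) "" else j, ";", fixed = TRUE)[[1]]
    any(icd_match(cs, prefixes))
  }, TRUE)
}

# first (primary) code of a ";"-joined string
primary_code <- function(joined) {
  if (!length(joined)) return(character(0))
  uniq_map(joined, function(j) {
    cs <- strsplit(if (is.na(j)) "" else j, ";", fixed = TRUE)[[1]]
    if (length(cs)) cs[[1]] else NA_character_
  }, NA_character_)
}

# run code with a private RNG stream, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# small FNV-1a digest over a canonical serialization; used to stamp outputs
# with a config fingerprint without an external digest dependency
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2, xdr = TRUE)
  h <- 2166136261
  for (b in as.integer(raw)) {
    # xor acts on the low byte only (b < 256); done in doubles since the
    # running value exceeds R's 32-bit integer range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

stop2 <- function(...) stop(..., call. = FALSE)
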