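#' Fit the propensity model
#'
#' Logistic regression of fingolimod use on pre-index characteristics. The
#' default (`selection = "fixed"`) uses the study's final variable list:
#' age, gender, region, health-plan type, prescriber specialty, Charlson
#' score, dalfampridine use, relapse within 90 days pre-index, pre-index
#' total costs, the matched symptoms (numbness, fatigue, bowel) and
#' comorbidities (depression, diabetes). `selection = "stepwise"` performs
#' forward selection with likelihood-ratio entry/stay thresholds over the
#' same candidates.
#'
#' Constant covariates are dropped with a warning. Quasi-separation (fitted
#' probabilities numerically at 0/1) triggers a warning and a
#' ridge-penalized refit so that scores remain inside (0, 1).
#'
#' @param covariates data frame from [compute_baseline_covariates()].
#' @param treatment logical/0-1 vector (TRUE = fingolimod), aligned with
#'   `covariates` rows.
#' @param variables character vector of covariate columns; NULL = the fixed
#'   study list.
#' @param selection "fixed" or "stepwise".
#' @param entry_p,stay_p stepwise thresholds (likelihood-ratio p-values).
#' @return object of class `propensity_fit`: coefficients, per-member
#'   `scores` (named by member_id), `z` (coefficient z-scores), `variables`,
#'   `separation` flag, the underlying `model` when unpenalized.
#' @export
fit_propensity <- function(covariates, treatment, variables = NULL,
                           selection = c("fixed", "stepwise"),
                           entry_p = 0.15, stay_p = 0.15) {
  selection <- match.arg(selection)
  treatment <- as.integer(treatment)
  if (length(unique(treatment)) < 2L)
    stop2("fit_propensity: both treatment arms must be present")
  if (is.null(variables))
    variables <- c("age", "gender", "region", "plan_type",
                   "prescriber_specialty", "charlson_score",
                   "dalfampridine_use", "relapse_within_90d_pre",
                   "pre_index_total_cost", "numbness", "fatigue", "bowel",
                   "depression", "diabetes")
  variables <- intersect(variables, names(covariates))

  constant <- variables[vapply(variables, function(v)
    length(unique(covariates[[v]])) < 2L, TRUE)]
  if (length(constant)) {
    warning("dropping constant covariate(s): ", paste(constant, collapse = ", "),
            call. = FALSE)
    variables <- setdiff(variables, constant)
  }
  dat <- covariates[, variables, drop = FALSE]
  dat$.treat <- treatment

  if (selection == "stepwise")
    variables <- stepwise_select(dat, variables, entry_p, stay_p)

  f <- as.formula(paste(".treat ~", if (length(variables))
    paste(variables, collapse = " + ") else "1"))
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(f, data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep) {
    warning("quasi-separation detected; falling back to a ridge-penalized fit",
            call. = FALSE)
    X <- model.matrix(f, dat)
    rf <- ridge_logistic(X, treatment, lambda = 1e-3)
    scores <- as.numeric(1 / (1 + exp(-X %*% rf$beta)))
    res <- list(coefficients = setNames(as.numeric(rf$beta), colnames(X)),
                z = setNames(rep(NA_real_, ncol(X)), colnames(X)),
                scores = setNames(scores, covariates$member_id),
                variables = variables, separation = TRUE, model = NULL,
                converged = rf$converged)
    return(structure(res, class = "propensity_fit"))
  }
  sm <- summary(fit)$coefficients
  res <- list(coefficients = coef(fit),
              z = setNames(sm[, "z value"], rownames(sm)),
              scores = setNames(as.numeric(fit$fitted.values),
                                covariates$member_id),
              variables = variables, separation = FALSE, model = fit,
              converged = fit$converged)
  structure(res, class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("<propensity_fit> ", length(x$scores), " members, ",
      length(x$variables), " covariates",
      if (x$separation) " (ridge fallback after separation)", "\n", sep = "")
  invisible(x)
}

# forward selection with LRT entry, then backward pruning with LRT stay
stepwise_select <- function(dat, candidates, entry_p, stay_p) {
  selected <- character(0)
  repeat {
    changed <- FALSE
    remaining <- setdiff(candidates, selected)
    if (length(remaining)) {
      base_f <- as.formula(paste(".treat ~", if (length(selected))
        paste(selected, collapse = " + ") else "1"))
      base <- glm(base_f, data = dat, family = binomial())
      ps <- vapply(remaining, function(v) {
        ext <- suppressWarnings(glm(as.formula(paste(
          ".treat ~", paste(c(selected, v), collapse = " + "))),
          data = dat, family = binomial()))
        stat <- base$deviance - ext$deviance
        df <- base$df.residual - ext$df.residual
        pchisq(stat, df, lower.tail = FALSE)
      }, 0)
      if (min(ps) < entry_p) {
        selected <- c(selected, remaining[which.min(ps)])
        changed <- TRUE
      }
    }
    if (length(selected) > 1L) {
      full <- suppressWarnings(glm(as.formula(paste(
        ".treat ~", paste(selected, collapse = " + "))),
        data = dat, family = binomial()))
      ps <- vapply(selected, function(v) {
        red <- suppressWarnings(glm(as.formula(paste(
          ".treat ~", paste(setdiff(selected, v), collapse = " + "))),
          data = dat, family = binomial()))
        stat <- red$deviance - full$deviance
        df <- red$df.residual - full$df.residual
        pchisq(stat, df, lower.tail = FALSE)
      }, 0)
      if (max(ps) > stay_p) {
        selected <- setdiff(selected, selected[which.max(ps)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  selected
}

# minimal ridge-penalized logistic regression (Newton iterations); used only
# as the separation fallback so fitted scores stay strictly inside (0, 1)
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0   # don't penalize intercept
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  list(beta = beta, converged = converged)
}

#' Stratified 1:1 nearest-neighbor propensity matching
#'
#' Within each stratum (pre-index relapse count bin), treated members are
#' processed in seeded random order; each takes the unused control with the
#' smallest absolute score difference, provided that difference is within
#' the caliper. Equidistant controls are broken by lowest member id.
#' Unmatched members are reported in the `unmatched` attribute, never
#' silently dropped.
#'
#' @param scores named numeric vector of propensity scores (names =
#'   member ids).
#' @param treatment logical vector aligned with `scores` (TRUE = treated).
#' @param strata stratum labels aligned with `scores`.
#' @param caliper maximum |score difference| on the probability scale.
#' @param seed seed realizing the random processing order.
#' @return data frame of pairs: treated, control, stratum, score_treated,
#'   score_control, distance; attribute `unmatched` lists members left
#'   unpaired with their arm and stratum.
#' @export
match_nearest_neighbor <- function(scores, treatment, strata, caliper = 0.01,
                                   seed = 1L) {
  ids <- names(scores)
  if (is.null(ids)) stop2("match_nearest_neighbor: scores must be named by member id")
  stopifnot(length(treatment) == length(scores),
            length(strata) == length(scores))
  strata <- as.character(strata)

  pairs <- list(); unmatched <- list()
  with_seed(seed, {
    for (s in sort(unique(strata))) {
      t_ids <- ids[treatment & strata == s]
      c_ids <- ids[!treatment & strata == s]
      if (length(t_ids) > 1L) t_ids <- sample(t_ids)
      c_sc <- scores[c_ids]
      used <- rep(FALSE, length(c_ids))
      for (t in t_ids) {
        avail <- which(!used)
        if (!length(avail)) {
          unmatched[[length(unmatched) + 1L]] <-
            data.frame(member_id = t, arm = "treated", stratum = s)
          next
        }
        d <- abs(c_sc[avail] - scores[[t]])
        dmin <- min(d)
        if (dmin > caliper) {
          unmatched[[length(unmatched) + 1L]] <-
            data.frame(member_id = t, arm = "treated", stratum = s)
          next
        }
        cand <- avail[d == dmin]
        pick <- cand[order(c_ids[cand])[1]]   # lowest id among ties
        used[pick] <- TRUE
        pairs[[length(pairs) + 1L]] <- data.frame(
          treated = t, control = c_ids[pick], stratum = s,
          score_treated = scores[[t]], score_control = c_sc[pick],
          distance = dmin)
      }
      leftover <- c_ids[!used]
      if (length(leftover)) unmatched[[length(unmatched) + 1L]] <-
        data.frame(member_id = leftover, arm = "control", stratum = s)
    }
  })
  res <- if (length(pairs)) do.call(rbind, pairs)
    else data.frame(treated = character(0), control = character(0),
                    stratum = character(0), score_treated = numeric(0),
                    score_control = numeric(0), distance = numeric(0))
  rownames(res) <- NULL
  attr(res, "unmatched") <- if (length(unmatched)) do.call(rbind, unmatched)
    else data.frame(member_id = character(0), arm = character(0),
                    stratum = character(0))
  res
}

#' Covariate balance before and after matching
#'
#' Standardized mean differences (SMD) per covariate: for numeric
#' covariates, mean difference over the pooled standard deviation; for
#' binary covariates, proportion difference over the pooled binomial
#' standard deviation; categorical covariates are expanded to one indicator
#' per level. SMD is 0 when group moments coincide, and 0/0 is reported
#' as 0.
#'
#' @param covariates data frame with member_id and covariate columns.
#' @param treatment logical aligned with `covariates` rows.
#' @param pairs output of [match_nearest_neighbor()].
#' @param variables covariate columns to assess (default: all but
#'   member_id).
#' @return data frame: covariate, smd_before, smd_after; attribute `n` gives
#'   group sizes.
#' @export
assess_balance <- function(covariates, treatment, pairs, variables = NULL) {
  if (is.null(variables))
    variables <- setdiff(names(covariates), "member_id")
  matched_ids <- c(pairs$treated, pairs$control)
  in_match <- covariates$member_id %in% matched_ids

  smd_one <- function(x, g) {
    if (is.character(x) || is.factor(x)) stop("expand first")
    x1 <- x[g]; x0 <- x[!g]
    if (!length(x1) || !length(x0)) return(NA_real_)
    if (is.logical(x) || all(x %in% c(0, 1))) {
      p1 <- mean(x1); p0 <- mean(x0)
      den <- sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
      if (den == 0) return(0)
      (p1 - p0) / den
    } else {
      den <- sqrt((stats::var(x1) + stats::var(x0)) / 2)
      if (is.na(den) || den == 0) return(if (mean(x1) == mean(x0)) 0 else NA_real_)
      (mean(x1) - mean(x0)) / den
    }
  }

  rows <- list()
  for (v in variables) {
    x <- covariates[[v]]
    if (is.character(x) || is.factor(x)) {
      for (lev in sort(unique(as.character(x)))) {
        xi <- as.integer(as.character(x) == lev)
        rows[[paste0(v, "=", lev)]] <- c(
          smd_one(xi, treatment),
          smd_one(xi[in_match], treatment[in_match]))
      }
    } else {
      rows[[v]] <- c(smd_one(as.numeric(x), treatment),
                     smd_one(as.numeric(x[in_match]), treatment[in_match]))
    }
  }
  out <- data.frame(covariate = names(rows),
                    smd_before = vapply(rows, `[`, 0, 1),
                    smd_after = vapply(rows, `[`, 0, 2))
  rownames(out) <- NULL
  attr(out, "n") <- c(before = nrow(covariates), after = sum(in_match))
  out
}
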