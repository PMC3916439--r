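#' Generalized estimating equations for clustered outcomes
#'
#' Marginal regression with an exchangeable (or independence) working
#' correlation and robust (sandwich) variance, supporting the logistic,
#' Poisson and negative-binomial (fixed dispersion) families with an offset
#' in the linear predictor. Written for pair-clustered matched-cohort data
#' but general in cluster size.
#'
#' Estimation follows the usual iterative scheme: given the current
#' coefficients, the scale is estimated from Pearson residuals, the
#' exchangeable correlation from their within-cluster cross-products, and
#' the coefficients are updated by Fisher scoring on the estimating
#' equations. With singleton clusters or an independence working
#' correlation the coefficient path coincides with maximum-likelihood GLM
#' fitting (a property the tests exploit as an oracle).
#'
#' @param x model matrix (including intercept column).
#' @param y response vector.
#' @param id cluster identifiers.
#' @param family "binomial" (logit link), "poisson" or "negbin" (log link).
#' @param theta negative-binomial dispersion (variance mu + mu^2/theta);
#'   required for `family = "negbin"`.
#' @param offset optional offset added to the linear predictor.
#' @param corstr working correlation structure.
#' @param maxit,tol Fisher-scoring control.
#' @return object of class `gee_fit`: coefficients, robust `vcov`,
#'   `naive_vcov`, working correlation `alpha`, scale `phi`, `fitted`,
#'   `converged`, `n_clusters`.
#' @export
gee_fit <- function(x, y, id, family = c("binomial", "poisson", "negbin"),
                    theta = NULL, offset = NULL,
                    corstr = c("exchangeable", "independence"),
                    maxit = 50L, tol = 1e-8) {
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  x <- as.matrix(x)
  n <- length(y); p <- ncol(x)
  if (is.null(offset)) offset <- rep(0, n)
  if (family == "negbin" && (is.null(theta) || theta <= 0))
    stop2("gee_fit: family 'negbin' requires a positive theta")

  # clamp the mean away from the boundary so quasi-separated fits keep a
  # positive variance function (they surface as huge robust SEs instead of
  # NaN estimating equations)
  linkinv <- if (family == "binomial")
    function(e) pmin(pmax(1 / (1 + exp(-e)), 1e-8), 1 - 1e-8)
  else function(e) pmin(pmax(exp(e), 1e-10), 1e10)
  varfun <- switch(family,
                   binomial = function(mu) mu * (1 - mu),
                   poisson = function(mu) mu,
                   negbin = function(mu) mu + mu^2 / theta)
  # canonical logit / log links: dmu/deta equals mu(1-mu) / mu
  dmu <- if (family == "binomial") function(mu) mu * (1 - mu) else function(mu) mu

  # initialize at the independence GLM solution
  init_fam <- if (family == "binomial") binomial() else poisson()
  beta <- suppressWarnings(
    coef(glm.fit(x, y, family = init_fam, offset = offset)))
  beta[is.na(beta)] <- 0

  cl <- split(seq_len(n), id)
  sizes <- lengths(cl)
  n_cl <- length(cl)
  npairs <- sum(sizes * (sizes - 1) / 2)
  alpha <- 0; phi <- 1
  converged <- FALSE

  for (it in seq_len(maxit)) {
    eta <- as.numeric(x %*% beta) + offset
    mu <- linkinv(eta)
    v <- varfun(mu)
    rp <- (y - mu) / sqrt(v)

    phi <- sum(rp^2) / (n - p)
    if (corstr == "exchangeable" && npairs > 0) {
      cross <- sum(vapply(cl, function(ix) {
        r <- rp[ix]
        (sum(r)^2 - sum(r^2)) / 2
      }, 0))
      alpha <- cross / ((npairs - p) * phi)
      maxsz <- max(sizes)
      alpha <- max(min(alpha, 0.99), -1 / (maxsz - 1 + 1e-8) + 1e-6)
      if (!is.finite(alpha)) alpha <- 0
    } else alpha <- 0

    B <- matrix(0, p, p)
    score <- numeric(p)
    d <- dmu(mu)
    for (ix in cl) {
      ni <- length(ix)
      Di <- x[ix, , drop = FALSE] * d[ix]
      si <- sqrt(v[ix])
      ri <- y[ix] - mu[ix]
      if (ni == 1L || alpha == 0) {
        Vinv_r <- ri / (v[ix] * phi)
        DtVinv <- t(Di / (v[ix] * phi))
      } else {
        # closed-form inverse of the exchangeable correlation matrix
        c1 <- 1 / (1 - alpha)
        c2 <- -alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
        z <- ri / si
        Rz <- c1 * z + c2 * sum(z)
        Vinv_r <- Rz / (si * phi)
        Zi <- Di / si
        RZ <- c1 * Zi + matrix(c2 * colSums(Zi), ni, p, byrow = TRUE)
        DtVinv <- t(RZ / si) / phi
      }
      B <- B + DtVinv %*% Di
      score <- score + as.numeric(DtVinv %*% ri)
    }
    step <- tryCatch(as.numeric(solve(B, score)),
                     error = function(e) rep(NA_real_, p))
    if (any(!is.finite(step))) {
      warning("GEE scoring step is not finite (degenerate design); ",
              "stopping early", call. = FALSE)
      break
    }
    # damp wild steps from near-separated fits
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }

  # robust (sandwich) covariance at the solution
  eta <- as.numeric(x %*% beta) + offset
  mu <- linkinv(eta)
  v <- varfun(mu)
  d <- dmu(mu)
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ix in cl) {
    ni <- length(ix)
    Di <- x[ix, , drop = FALSE] * d[ix]
    si <- sqrt(v[ix])
    ri <- y[ix] - mu[ix]
    if (ni == 1L || alpha == 0) {
      DtVinv <- t(Di / (v[ix] * phi))
    } else {
      c1 <- 1 / (1 - alpha)
      c2 <- -alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
      Zi <- Di / si
      RZ <- c1 * Zi + matrix(c2 * colSums(Zi), ni, p, byrow = TRUE)
      DtVinv <- t(RZ / si) / phi
    }
    B <- B + DtVinv %*% Di
    u <- as.numeric(DtVinv %*% ri)
    M <- M + tcrossprod(u)
  }
  Binv <- solve(B)
  vcov <- Binv %*% M %*% Binv
  dimnames(vcov) <- list(colnames(x), colnames(x))
  naive <- Binv   # B already carries the 1/phi scaling of V
  dimnames(naive) <- dimnames(vcov)

  structure(list(coefficients = setNames(as.numeric(beta), colnames(x)),
                 vcov = vcov, naive_vcov = naive, alpha = alpha, phi = phi,
                 fitted = mu, family = family, theta = theta,
                 converged = converged, n_clusters = n_cl),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tab <- data.frame(estimate = x$coefficients, robust_se = se, z = z,
                    p = 2 * pnorm(-abs(z)))
  cat("GEE (", x$family, ", exchangeable alpha = ", round(x$alpha, 4),
      ", ", x$n_clusters, " clusters)\n", sep = "")
  print(round(tab, 5))
  invisible(x)
}

# Wald estimate/CI/p for one coefficient on the exp scale
gee_exp_estimate <- function(fit, term, level = 0.95) {
  b <- fit$coefficients[[term]]
  se <- sqrt(fit$vcov[term, term])
  zq <- -qnorm((1 - level) / 2)
  list(estimate = exp(b), conf_low = exp(b - zq * se),
       conf_high = exp(b + zq * se),
       p_value = 2 * pnorm(-abs(b / se)), se = se)
}

#' @importFrom stats glm.fit qnorm
NULL
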