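#' Compress proportions away from the boundary
#'
#' Beta regression requires responses strictly inside (0, 1), but observed
#' small-area prevalences can be exactly 0 (and occasionally 1). The
#' standard compression `(y * (n - 1) + 0.5) / n` maps [0, 1] into (0, 1)
#' with vanishing effect as n grows.
#'
#' @param y proportions in `[0, 1]`.
#' @param n sample size used in the compression (default `length(y)`).
#' @return compressed proportions in (0, 1).
#' @export
squeeze_proportions <- function(y, n = length(y)) {
  stopifnot(all(y >= 0 & y <= 1, na.rm = TRUE), n > 1)
  (y * (n - 1) + 0.5) / n
}

beta_negloglik <- function(par, y, X) {
  k <- ncol(X)
  beta <- par[seq_len(k)]
  phi <- exp(par[k + 1])
  mu <- stats::plogis(drop(X %*% beta))
  a <- mu * phi
  b <- (1 - mu) * phi
  -sum(lgamma(phi) - lgamma(a) - lgamma(b) +
         (a - 1) * log(y) + (b - 1) * log1p(-y))
}

beta_neggrad <- function(par, y, X) {
  k <- ncol(X)
  beta <- par[seq_len(k)]
  phi <- exp(par[k + 1])
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  ystar <- stats::qlogis(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  dbeta <- drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  dlogphi <- phi * sum(mu * (ystar - mustar) + log1p(-y) -
                         digamma((1 - mu) * phi) + digamma(phi))
  -c(dbeta, dlogphi)
}

#' Beta regression with logit link and constant precision
#'
#' Maximum-likelihood fit of `y ~ Beta(mu * phi, (1 - mu) * phi)` with
#' `logit(mu) = X beta` and a single precision parameter `phi`. Under the
#' logit link each coefficient is the change in the logit of the expected
#' proportion per unit change of its covariate. Standard errors come from
#' the observed information (numerical Hessian at the optimum); 95%
#' confidence intervals are `beta +/- 1.96 SE`. Optimisation is BFGS with
#' analytic gradient from logit-scale least-squares starting values, so the
#' fit is deterministic given the data.
#'
#' @param formula model formula; the response must lie strictly in (0, 1)
#'   (see [squeeze_proportions()]).
#' @param data data.frame of covariates.
#' @param maxit optimiser iteration cap (default 500).
#' @return object of class `beta_fit`: coefficients, `se`, `ci` (matrix),
#'   `phi`, `log_lik`, `n`, `converged`, `mu` (fitted means), `vcov`.
#' @export
beta_regression <- function(formula, data, maxit = 500) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (any(y <= 0 | y >= 1))
    stop("response must lie strictly in (0, 1); use squeeze_proportions()",
         " for boundary values")
  if (qr(X)$rank < ncol(X))
    stop("model matrix is rank deficient (duplicated or collinear covariates)")
  # starting values: least squares on the logit scale
  eta0 <- stats::qlogis(y)
  b0 <- stats::lm.fit(X, eta0)$coefficients
  b0[is.na(b0)] <- 0
  mu0 <- stats::plogis(drop(X %*% b0))
  s2 <- stats::var(eta0 - drop(X %*% b0)) * (mu0 * (1 - mu0))^2
  phi0 <- max(mean(mu0 * (1 - mu0) / pmax(s2, 1e-8)) - 1, 1)
  par0 <- c(b0, log(phi0))
  opt <- stats::optim(par0, beta_negloglik, beta_neggrad, y = y, X = X,
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("beta regression did not converge (code ", opt$convergence,
         "): ", opt$message %||% "", " after ", opt$counts[1],
         " function evaluations")
  k <- ncol(X)
  hess <- stats::optimHess(opt$par, beta_negloglik, beta_neggrad,
                           y = y, X = X)
  vc <- tryCatch(solve(hess), error = function(e) {
    warning("singular observed information; SEs unavailable")
    matrix(NA_real_, k + 1, k + 1)
  })
  se <- sqrt(pmax(diag(vc)[seq_len(k)], 0))
  coefs <- stats::setNames(opt$par[seq_len(k)], colnames(X))
  se <- stats::setNames(se, colnames(X))
  zq <- stats::qnorm(0.975)
  ci <- cbind(lower = coefs - zq * se, upper = coefs + zq * se)
  structure(list(coefficients = coefs, se = se, ci = ci,
                 phi = unname(exp(opt$par[k + 1])),
                 log_lik = -opt$value, n = length(y),
                 converged = TRUE,
                 mu = stats::plogis(drop(X %*% coefs)),
                 vcov = vc, formula = formula),
            class = "beta_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.beta_fit <- function(x, ...) {
  cat("Beta regression (logit link, constant precision)\n")
  cat("n =", x$n, " log-likelihood =", format(x$log_lik, digits = 6),
      " phi =", format(x$phi, digits = 4), "\n\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    ci_low = x$ci[, "lower"], ci_high = x$ci[, "upper"])
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.beta_fit <- function(object, ...) object$coefficients

#' @export
logLik.beta_fit <- function(object, ...) {
  structure(object$log_lik, df = length(object$coefficients) + 1,
            nobs = object$n, class = "logLik")
}

#' Tidy coefficient table from a beta fit
#' @param fit a `beta_fit`.
#' @param stratum optional stratum label column.
#' @return data.frame `term`, `estimate`, `se`, `ci_low`, `ci_high`.
#' @export
tidy_beta_fit <- function(fit, stratum = NA_character_) {
  data.frame(stratum = stratum, term = names(fit$coefficients),
             estimate = unname(fit$coefficients), se = unname(fit$se),
             ci_low = unname(fit$ci[, "lower"]),
             ci_high = unname(fit$ci[, "upper"]), row.names = NULL)
}

#' All-area, urban-only and rural-only beta regressions
#'
#' Fits the pooled model (including an urbanicity indicator) plus models
#' stratified to urban and rural areas (dropping the indicator). An empty
#' stratum is skipped with a warning; a covariate that is constant within a
#' stratum (e.g. a smoke-control flag in rural areas) carries no
#' information there and is dropped from that stratum's model with a
#' message.
#'
#' @param data data.frame with the response, covariates and a logical
#'   `urban` column.
#' @param response response column name (proportions strictly in (0, 1)).
#' @param covariates covariate column names (excluding urban).
#' @param urban_col name of the urbanicity flag column.
#' @return named list of `beta_fit`s: `all`, `urban`, `rural`.
#' @export
stratified_models <- function(data, response = "prevalence",
                              covariates = c("imd_score", "median_age",
                                             "pct_white", "sca"),
                              urban_col = "urban") {
  f_all <- stats::reformulate(c(covariates, urban_col), response)
  f_strat <- stats::reformulate(covariates, response)
  out <- list(all = beta_regression(f_all, data))
  for (lvl in c("urban", "rural")) {
    sub <- data[(data[[urban_col]] %in% TRUE) == (lvl == "urban"), ,
                drop = FALSE]
    if (!nrow(sub)) {
      warning("empty ", lvl, " stratum; model skipped")
      out[[lvl]] <- NULL
    } else {
      keep <- vapply(covariates, function(cv) {
        v <- sub[[cv]][!is.na(sub[[cv]])]
        length(unique(v)) > 1L
      }, logical(1))
      if (any(!keep))
        message("dropping constant covariate(s) in ", lvl, " stratum: ",
                paste(covariates[!keep], collapse = ", "))
      f_strat <- stats::reformulate(covariates[keep], response)
      out[[lvl]] <- beta_regression(f_strat, sub)
    }
  }
  out
}

rank_deciles <- function(x, ids, k = 10) {
  ord <- order(x, ids)
  r <- integer(length(x)); r[ord] <- seq_along(x)
  as.integer(ceiling(r * k / length(x)))
}

#' Socio-economic indicators by prevalence decile
#'
#' Ranks areas by wood-burner prevalence, splits them into deciles (ties
#' broken by area code; row counts differ by at most one), and reports the
#' mean of each covariate per decile.
#'
#' @param data data.frame with `lsoa`, the prevalence column and numeric or
#'   logical covariates.
#' @param prevalence prevalence column name.
#' @param covariates columns to summarise (logical columns are reported as
#'   percentages).
#' @return data.frame, one row per decile (1 = lowest prevalence).
#' @export
prevalence_decile_table <- function(data, prevalence = "prevalence_pct",
                                    covariates = c("imd_score", "pct_white",
                                                   "median_age", "urban")) {
  stopifnot(nrow(data) >= 10, all(c("lsoa", prevalence) %in% names(data)))
  d <- data[is.finite(data[[prevalence]]), , drop = FALSE]
  dec <- rank_deciles(d[[prevalence]], d$lsoa)
  out <- data.frame(decile = sort(unique(dec)))
  out$n_lsoas <- as.vector(table(dec))
  out[[prevalence]] <- tapply(d[[prevalence]], dec, mean)
  for (cv in covariates) {
    v <- d[[cv]]
    if (is.logical(v)) v <- 100 * v
    out[[cv]] <- as.numeric(tapply(v, dec, mean))
  }
  rownames(out) <- NULL
  out
}

#' Region-stratified covariate-decile points
#'
#' For scatter charts of prevalence against a socio-economic covariate:
#' within each region (urban areas only by default), areas are grouped into
#' deciles of the covariate; each point is the decile's mean covariate,
#' mean prevalence and total weight. Regions with fewer than 10 areas
#' degrade to the available number of quantile groups and are flagged.
#'
#' @param data data.frame with `lsoa`, `region`, the covariate, the
#'   prevalence column, optionally `urban` and a weight column.
#' @param covariate covariate column name.
#' @param prevalence prevalence column name.
#' @param urban_only restrict to urban areas (default TRUE).
#' @param weight weight column (default `"population"` if present, else 1
#'   per area).
#' @return data.frame `region`, `decile`, `mean_covariate`,
#'   `mean_prevalence`, `weight`, `n_lsoas`, `degraded`.
#' @export
region_decile_points <- function(data, covariate = "imd_score",
                                 prevalence = "prevalence_pct",
                                 urban_only = TRUE,
                                 weight = "population") {
  stopifnot(all(c("lsoa", "region", covariate, prevalence) %in% names(data)))
  d <- data
  if (urban_only && "urban" %in% names(d))
    d <- d[d$urban %in% TRUE, , drop = FALSE]
  d <- d[is.finite(d[[covariate]]) & is.finite(d[[prevalence]]), ,
         drop = FALSE]
  w <- if (weight %in% names(d)) d[[weight]] else rep(1, nrow(d))
  rows <- list()
  for (rg in sort(unique(d$region))) {
    i <- d$region == rg
    k <- min(10L, sum(i))
    dec <- rank_deciles(d[[covariate]][i], d$lsoa[i], k = k)
    for (dd in sort(unique(dec))) {
      j <- which(i)[dec == dd]
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, decile = dd,
        mean_covariate = mean(d[[covariate]][j]),
        mean_prevalence = mean(d[[prevalence]][j]),
        weight = sum(w[j]), n_lsoas = length(j),
        degraded = k < 10L)
    }
  }
  do.call(rbind, rows)
}
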