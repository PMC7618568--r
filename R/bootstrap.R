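#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks). Pairs
#' with missing values are dropped. Returns `NA` with a warning when either
#' variable has zero rank variance (no ordering information).
#'
#' @param x,y paired numeric vectors.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    warning("zero rank variance; Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Nonparametric bootstrap interval adjusting the percentile interval for
#' median bias (`z0`, the normal quantile of the fraction of bootstrap
#' statistics below the observed one) and for skewness (acceleration `a`
#' from the jackknife third/second moment ratio). Resampling is over rows,
#' so for site-level statistics the monitoring site is the sampling unit.
#'
#' When the bootstrap distribution is degenerate the interval collapses to
#' the point estimate; when the bias fraction is 0 or 1, `z0` is clamped to
#' `+/- z_max` with a warning. With `z0 = 0` and `a = 0` the interval
#' equals the percentile interval.
#'
#' @param data vector, matrix or data.frame of observations (rows are the
#'   resampling units).
#' @param statistic function mapping a data subset (same type as `data`) to
#'   a scalar.
#' @param B number of bootstrap replications (default 10000).
#' @param alpha two-sided level (default 0.05 for a 95% interval).
#' @param seed optional integer seed; with a fixed seed intervals are
#'   reproducible.
#' @param z_max clamp for the bias term (default 4).
#' @return numeric `c(lo, hi)` with attributes `estimate`, `z0`, `a`, `B`.
#' @export
bca_ci <- function(data, statistic, B = 10000, alpha = 0.05, seed = NULL,
                   z_max = 4) {
  if (!is.null(seed)) set.seed(seed)
  take <- function(d, idx) {
    if (is.null(dim(d))) d[idx] else d[idx, , drop = FALSE]
  }
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  stopifnot(n >= 2, B >= 100)
  theta_hat <- statistic(data)
  thetas <- vapply(seq_len(B), function(b) {
    statistic(take(data, sample.int(n, n, replace = TRUE)))
  }, numeric(1))
  thetas <- thetas[is.finite(thetas)]
  if (!length(thetas) || stats::var(thetas) == 0) {
    out <- c(theta_hat, theta_hat)
    return(structure(out, estimate = theta_hat, z0 = 0, a = 0, B = B))
  }
  p_below <- mean(thetas < theta_hat)
  if (p_below <= 0 || p_below >= 1) {
    warning("degenerate bootstrap bias fraction; clamping z0 to +/-", z_max)
    z0 <- if (p_below <= 0) -z_max else z_max
  } else {
    z0 <- stats::qnorm(p_below)
    z0 <- pmin(pmax(z0, -z_max), z_max)
  }
  # jackknife acceleration
  tjack <- vapply(seq_len(n), function(i) statistic(take(data, -i)),
                  numeric(1))
  tbar <- mean(tjack)
  num <- sum((tbar - tjack)^3)
  den <- 6 * (sum((tbar - tjack)^2))^1.5
  a <- if (den == 0) 0 else num / den
  zl <- stats::qnorm(alpha / 2)
  zu <- stats::qnorm(1 - alpha / 2)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  probs <- pmin(pmax(c(adj(zl), adj(zu)), 0), 1)
  ci <- unname(stats::quantile(thetas, probs, type = 7))
  structure(ci, estimate = theta_hat, z0 = z0, a = a, B = B)
}

#' Bootstrap interval for the winter minus summer correlation difference
#'
#' Computes a BCa interval for `R_winter - R_summer`, the difference
#' between the Spearman correlations of an exposure with a winter outcome
#' and with a summer outcome at the same sites. Default resampling is
#' paired over sites: each bootstrap draw resamples whole site rows, so the
#' winter and summer statistics are evaluated on the same resampled sites.
#' The unpaired option resamples the two seasons independently and reports
#' a percentile interval.
#'
#' @param data data.frame with one row per site.
#' @param x,winter,summer column names of the exposure and the two seasonal
#'   outcomes.
#' @param B,alpha,seed,z_max as in [bca_ci()].
#' @param paired paired site resampling (default TRUE).
#' @return `c(lo, hi)` with attributes `estimate` (the observed
#'   difference), `r_winter`, `r_summer`.
#' @export
season_difference_ci <- function(data, x = "x", winter = "winter",
                                 summer = "summer", B = 10000,
                                 alpha = 0.05, seed = NULL, paired = TRUE,
                                 z_max = 4) {
  stopifnot(all(c(x, winter, summer) %in% names(data)))
  d <- data[stats::complete.cases(data[c(x, winter, summer)]), , drop = FALSE]
  stat <- function(dd) spearman_r(dd[[x]], dd[[winter]]) -
    spearman_r(dd[[x]], dd[[summer]])
  rw <- spearman_r(d[[x]], d[[winter]])
  rs <- spearman_r(d[[x]], d[[summer]])
  if (paired) {
    ci <- suppressWarnings(bca_ci(d, stat, B = B, alpha = alpha,
                                  seed = seed, z_max = z_max))
  } else {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(d)
    diffs <- vapply(seq_len(B), function(b) {
      iw <- sample.int(n, n, replace = TRUE)
      is <- sample.int(n, n, replace = TRUE)
      suppressWarnings(spearman_r(d[[x]][iw], d[[winter]][iw]) -
                         spearman_r(d[[x]][is], d[[summer]][is]))
    }, numeric(1))
    ci <- unname(stats::quantile(diffs, c(alpha / 2, 1 - alpha / 2),
                                 na.rm = TRUE, type = 7))
    ci <- structure(ci, estimate = rw - rs, B = B)
  }
  attr(ci, "estimate") <- rw - rs
  attr(ci, "r_winter") <- rw
  attr(ci, "r_summer") <- rs
  ci
}
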