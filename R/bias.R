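#' Probability limit of the naive Wald estimator under a coarsened exposure
#'
#' For a binary instrument `Z` with effect `alpha` on the latent exposure and
#' a binary measurement `D = I{L >= 0}`, the naive Wald estimand
#' `cov(Z, Y)/cov(Z, D)` equals
#' \deqn{\beta_D = \frac{\beta\,\alpha}{F_V(\mu+\alpha) - F_V(\mu)}}
#' where \eqn{F_V(v) = F(v/\sigma_V)} is the CDF of the environmental share.
#' By the mean value theorem the denominator equals
#' \eqn{\alpha f_V(\mu^*)} for some \eqn{\mu^* \in [\mu, \mu+\alpha]}, so the
#' naive estimand is the true effect divided by a density value: a
#' multiplicative bias that rescales but never flips the sign. The point
#' \eqn{\mu^*} is not identified; the exact ratio form and the bracketing
#' interval are returned instead.
#'
#' This closed form is specific to a binary instrument; for dosage
#' instruments use simulation.
#'
#' @param beta true structural effect of `L` on `Y`.
#' @param mu genetic-share intercept.
#' @param alpha instrument effect (nonzero).
#' @param v_family environmental-share family (name or [mr_v_family]).
#' @param sigma_v SD of the environmental share.
#' @return An object of class `mr_naive_limit`: list with `beta_D`,
#'   `inflation` (`= beta_D / beta`, i.e. \eqn{1/f_V(\mu^*)}), and
#'   `mu_star_bracket`.
#' @examples
#' naive_limit(beta = 1, mu = 0, alpha = 0.1)          # ~2.51-fold inflation
#' naive_limit(beta = 1, mu = -2, alpha = 0.1)         # rarer D, more inflation
#' @export
naive_limit <- function(beta, mu, alpha, v_family = "normal", sigma_v = 1) {
  stopifnot(is.finite(beta), is.finite(mu), is.finite(alpha), sigma_v > 0)
  if (alpha == 0) stop("`alpha` must be nonzero (instrument relevance)", call. = FALSE)
  fam <- as_v_family(v_family)
  FV <- function(v) fam$cdf(v / sigma_v)
  denom <- FV(mu + alpha) - FV(mu)
  if (!is.finite(denom) || denom == 0) {
    stop("F_V(mu + alpha) = F_V(mu): the instrument does not move the ",
         "coarsened measure (instrument relevance fails for D)", call. = FALSE)
  }
  inflation <- alpha / denom
  structure(
    list(beta_D = beta * inflation, inflation = inflation,
         mu_star_bracket = sort(c(mu, mu + alpha)),
         beta = beta, mu = mu, alpha = alpha, sigma_v = sigma_v,
         family = fam$name),
    class = "mr_naive_limit"
  )
}

#' @export
print.mr_naive_limit <- function(x, ...) {
  cat("Naive Wald probability limit (binary instrument)\n")
  cat(sprintf("  beta_D = %.6g  (true beta = %g, inflation factor = %.6g)\n",
              x$beta_D, x$beta, x$inflation))
  cat(sprintf("  mu* bracketed in [%.4g, %.4g], V ~ %s(sd = %g)\n",
              x$mu_star_bracket[1], x$mu_star_bracket[2], x$family, x$sigma_v))
  invisible(x)
}

#' Inflation of the naive estimand across a grid of thresholds/prevalences
#'
#' Evaluates [naive_limit()] along a grid of genetic-share intercepts `mu`.
#' The prevalence reported for each `mu` is the marginal
#' `pr(D = 1) = (F_V(mu) + F_V(mu + alpha))/2`, i.e. the population
#' frequency of `D` under a balanced binary instrument. For light-tailed
#' families the inflation factor grows as the prevalence approaches 0 or 1
#' (the density in the denominator shrinks in the tails), so naive
#' estimates for rare outcomes are the most inflated; for a symmetric
#' family the inflation is strictly monotone in the distance of the
#' prevalence from 1/2.
#'
#' @inheritParams naive_limit
#' @param mu_grid numeric vector of intercept values.
#' @return A data frame with columns `mu`, `prevalence`, `beta_D`,
#'   `inflation`.
#' @export
inflation_curve <- function(beta, mu_grid, alpha, v_family = "normal",
                            sigma_v = 1) {
  stopifnot(length(mu_grid) >= 1, all(is.finite(mu_grid)))
  fam <- as_v_family(v_family)
  rows <- lapply(mu_grid, function(m) {
    nl <- naive_limit(beta, m, alpha, fam, sigma_v)
    prev <- (fam$cdf(m / sigma_v) + fam$cdf((m + alpha) / sigma_v)) / 2
    data.frame(mu = m, prevalence = prev,
               beta_D = nl$beta_D, inflation = nl$inflation)
  })
  do.call(rbind, rows)
}

#' Intercept implied by a target prevalence
#'
#' Inverse of the prevalence map used by [inflation_curve()]: returns `mu`
#' such that the marginal `pr(D = 1) = (F_V(mu) + F_V(mu + alpha))/2` under
#' a balanced binary instrument equals `prevalence`. With `alpha = 0`
#' (default) this is simply the quantile `mu = sigma_v * F^{-1}(p)`.
#'
#' @param prevalence target prevalence(s) in (0, 1).
#' @param alpha instrument effect used in the marginal prevalence.
#' @inheritParams naive_limit
#' @export
mu_for_prevalence <- function(prevalence, alpha = 0, v_family = "normal",
                              sigma_v = 1) {
  stopifnot(all(prevalence > 0 & prevalence < 1))
  fam <- as_v_family(v_family)
  if (alpha == 0) return(sigma_v * fam$quantile(prevalence))
  vapply(prevalence, function(p) {
    lo <- sigma_v * fam$quantile(p / 2) - abs(alpha)
    hi <- sigma_v * fam$quantile((1 + p) / 2) + abs(alpha)
    stats::uniroot(function(m) {
      (fam$cdf(m / sigma_v) + fam$cdf((m + alpha) / sigma_v)) / 2 - p
    }, c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}
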