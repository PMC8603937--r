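#' Structural parameters of the liability-threshold data-generating model
#'
#' Collects every parameter of the structural model
#' \deqn{L = \mu + \alpha' Z + \gamma' X - V, \quad
#'       D = \mathrm{coarsen}(L), \quad
#'       Y = \beta L + \delta D + \varepsilon,}
#' where `Z` are instrument SNPs (dosages 0/1/2, Binomial(2, p) under HWE),
#' `X` are auxiliary (possibly pleiotropic) variants, `V` is the
#' environmental share with SD `sigma_v` drawn from `v_family`, and
#' `D` is the coarsened measurement: binary (`thresholds` empty,
#' `D = I{L >= 0}`) or ordered with latent cutpoints `0 < d1 < ... < d(K-1)`.
#'
#' Confounding between the environmental share and the outcome disturbance is
#' parameterised as \eqn{\varepsilon = c \cdot V/\sigma_V + \eta}, with
#' `c = confounding` and \eqn{\eta \sim N(0, \sigma_\varepsilon^2)}
#' independent of everything else, so that
#' \eqn{\mathrm{cov}(V, \varepsilon) = c\,\sigma_V}.
#'
#' @param mu intercept of the genetic share, on the latent-exposure scale.
#' @param alpha numeric vector of instrument effects, one per instrument SNP.
#' @param gamma numeric vector of auxiliary-variant effects (may be empty).
#' @param beta structural effect of `L` on `Y` (outcome units per latent unit).
#' @param delta direct effect of `D` on `Y`; default 0 (the base model assumes
#'   no distinct threshold effect).
#' @param sigma_v SD of the environmental share `V` (> 0).
#' @param v_family family of `V / sigma_v`: `"normal"` (default),
#'   `"logistic"`, or an [mr_v_family] object.
#' @param snp_freqs effect-allele frequencies in (0, 1) for the `Z` columns
#'   followed by the `X` columns; recycled to length `J + K` if scalar.
#' @param thresholds strictly increasing positive cutpoints for an ordered
#'   `D`; `numeric(0)` (default) gives the binary single-threshold model.
#' @param r_dist optional random individual-specific diagnosis threshold `R`:
#'   either `NULL` (deterministic threshold), a positive scalar (SD of a
#'   mean-zero normal `R`), or a function `function(n)` returning `n` draws of
#'   a mean-zero variable independent of `Z` and `X`.
#' @param confounding covariance knob `c` linking `V` to the outcome
#'   disturbance (see Details).
#' @param sigma_eps SD of the independent component of the outcome
#'   disturbance (> 0).
#' @param genotype `"dosage"` (default, Binomial(2, p) per SNP under HWE) or
#'   `"binary"` (Bernoulli(p) carriers; the setting of the closed-form bias
#'   derivation in [naive_limit()]).
#' @return An object of class `mr_model_params`.
#' @examples
#' p <- mr_model_params(mu = 0, alpha = 0.5, beta = 1, snp_freqs = 0.5)
#' p
#' @export
mr_model_params <- function(mu = 0, alpha, gamma = numeric(0), beta,
                            delta = 0, sigma_v = 1, v_family = "normal",
                            snp_freqs = 0.5, thresholds = numeric(0),
                            r_dist = NULL, confounding = 0, sigma_eps = 1,
                            genotype = c("dosage", "binary")) {
  genotype <- match.arg(genotype)
  alpha <- as.numeric(alpha)
  gamma <- as.numeric(gamma)
  J <- length(alpha)
  K <- length(gamma)
  if (J < 1L) stop("at least one instrument effect `alpha` is required", call. = FALSE)
  snp_freqs <- as.numeric(snp_freqs)
  if (length(snp_freqs) == 1L) snp_freqs <- rep(snp_freqs, J + K)
  if (length(snp_freqs) != J + K) {
    stop("`snp_freqs` must have length J + K = ", J + K, call. = FALSE)
  }
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (!all(is.finite(alpha)) || !all(is.finite(gamma))) {
    stop("non-finite effect parameters", call. = FALSE)
  }
  if (!is.finite(sigma_v) || sigma_v <= 0) stop("`sigma_v` must be > 0", call. = FALSE)
  if (!is.finite(sigma_eps) || sigma_eps <= 0) stop("`sigma_eps` must be > 0", call. = FALSE)
  if (any(snp_freqs <= 0 | snp_freqs >= 1)) {
    stop("all `snp_freqs` must lie strictly in (0, 1)", call. = FALSE)
  }
  thresholds <- as.numeric(thresholds)
  if (length(thresholds)) {
    if (any(!is.finite(thresholds)) || any(thresholds <= 0) ||
        is.unsorted(thresholds, strictly = TRUE)) {
      stop("`thresholds` must be strictly increasing and > 0", call. = FALSE)
    }
  }
  if (!is.null(r_dist)) {
    if (is.numeric(r_dist) && length(r_dist) == 1L && r_dist > 0) {
      sd_r <- r_dist
      r_dist <- function(n) stats::rnorm(n, 0, sd_r)
    } else if (!is.function(r_dist)) {
      stop("`r_dist` must be NULL, a positive SD, or a function(n)", call. = FALSE)
    }
  }
  structure(
    list(mu = mu, alpha = alpha, gamma = gamma, beta = beta, delta = delta,
         sigma_v = sigma_v, v_family = as_v_family(v_family),
         snp_freqs = snp_freqs, thresholds = thresholds, r_dist = r_dist,
         confounding = confounding, sigma_eps = sigma_eps,
         genotype = genotype, J = J, K = K),
    class = "mr_model_params"
  )
}

#' @export
print.mr_model_params <- function(x, ...) {
  cat("Liability-threshold model parameters\n")
  cat(sprintf("  instruments J = %d, auxiliary variants K = %d\n", x$J, x$K))
  cat(sprintf("  mu = %g, beta = %g, delta = %g\n", x$mu, x$beta, x$delta))
  cat(sprintf("  sigma_v = %g (%s family), sigma_eps = %g, confounding = %g\n",
              x$sigma_v, x$v_family$name, x$sigma_eps, x$confounding))
  if (length(x$thresholds)) {
    cat("  ordered D with cutpoints 0,", paste(x$thresholds, collapse = ", "), "\n")
  } else {
    cat("  binary D = I{L >= 0}\n")
  }
  if (!is.null(x$r_dist)) cat("  random individual-specific threshold R active\n")
  invisible(x)
}

# population variance of the genetic share implied by the parameters
# (HWE dosage variance 2p(1-p) per SNP, mutually independent SNPs;
# p(1-p) for binary carriers)
genetic_share_variance <- function(params) {
  p <- params$snp_freqs
  eff <- c(params$alpha, params$gamma)
  mult <- if (identical(params$genotype, "binary")) 1 else 2
  sum(eff^2 * mult * p * (1 - p))
}

# latent-exposure SD and theta^2 implied by the parameters
latent_moments <- function(params) {
  s2g <- genetic_share_variance(params)
  s2l <- s2g + params$sigma_v^2
  list(sigma_g2 = s2g, sigma_l2 = s2l,
       sigma_l = sqrt(s2l), theta2 = s2g / s2l,
       beta_l = sqrt(s2l) * params$beta,
       beta_g = sqrt(s2g) * params$beta)
}
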