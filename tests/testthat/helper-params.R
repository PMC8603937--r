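# shared parameter builders for the simulation-based tests

# single-SNP probit-friendly DGP: alpha = 0.5, freq 0.5, sigma_v = 1
# => sigma_G^2 = 0.125, sigma_L^2 = 1.125, theta^2 = 1/9, beta_L = sqrt(1.125)
base_params <- function(beta = 1, mu = 0, alpha = 0.5, freq = 0.5, ...) {
  mr_model_params(mu = mu, alpha = alpha, beta = beta, snp_freqs = freq, ...)
}

true_moments <- function(params) coarseMR:::latent_moments(params)

# directly dichotomise a simulated continuous latent exposure at a quantile
# cutoff: the "dichotomise-and-recover" design used in the recovery tests
dichotomise_at <- function(dataset, q) {
  cut <- stats::quantile(dataset$latent$L, q)
  d2 <- dataset
  d2$data$D <- as.integer(dataset$latent$L >= cut)
  d2
}
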