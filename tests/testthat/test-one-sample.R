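test_that("standardise is exact, affine-invariant and idempotent", {
  expect_equal(standardise(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(50)
  s <- standardise(x)
  expect_equal(mean(s), 0, tolerance = 1e-12)
  expect_equal(sd(s), 1, tolerance = 1e-12)
  # positive affine transforms leave the result unchanged: this is the
  # property that removes the unknown environmental scale sigma_V
  expect_equal(standardise(3 + 2.7 * x), s)
  expect_equal(standardise(s), s)
  expect_error(standardise(rep(2, 10)), "constant")
})

test_that("fit_naive reduces to the Wald ratio and handles nulls", {
  p <- base_params(beta = 1)
  d <- simulate_individual(p, n = 5e4, seed = 101)
  fn <- fit_naive(d)
  expect_equal(fn$beta_D_hat,
               cov(d$data$Z_1, d$data$Y) / cov(d$data$Z_1, d$data$D),
               tolerance = 1e-10)
  expect_equal(fn$method, "Wald ratio")

  # identity exposure/outcome: regress D on itself through the instrument
  d_id <- d$data
  d_id$Y <- d_id$D
  fid <- fit_naive(d_id, instruments = "Z_1")
  expect_equal(fid$beta_D_hat, 1, tolerance = 1e-10)

  # null DGP: estimate within 4 SE of zero
  p0 <- base_params(beta = 0)
  d0 <- simulate_individual(p0, n = 5e4, seed = 102)
  f0 <- fit_naive(d0)
  expect_lt(abs(f0$beta_D_hat), 4 * f0$se)

  # no first-stage covariance: D unrelated to Z
  bad <- data.frame(Z_1 = rep(c(0, 1), 50), D = rep(c(0, 1), each = 50),
                    Y = rnorm(100))
  bad$D <- rep(0:1, 50)[sample(100)]  # scramble
  bad$Z_1 <- rep(0, 100)
  expect_error(fit_naive(bad, instruments = "Z_1"), "rank|covariance")
})

test_that("first-stage GLM recovers the scaled coefficients", {
  # probit on normal V: alpha_tilde = alpha / sigma_v, checked at n = 1e6
  p <- mr_model_params(mu = 0.3, alpha = 0.5, beta = 1, sigma_v = 2,
                       snp_freqs = 0.5)
  d <- simulate_individual(p, n = 1e6, seed = 111)
  fs <- fit_first_stage(d, link = "probit")
  expect_equal(unname(fs$coefficients["Z_1"]), 0.25, tolerance = 0.02)
  expect_equal(unname(fs$coefficients["(Intercept)"]), 0.15, tolerance = 0.02)
  # linear predictor is exactly the coefficient combination
  expect_equal(fs$g_tilde,
               unname(fs$coefficients["(Intercept)"] +
                        fs$coefficients["Z_1"] * d$data$Z_1))

  # logit on logistic V: natural log-odds scale carries the pi/sqrt(3) factor
  pl <- mr_model_params(alpha = 0.5, beta = 1, sigma_v = 2,
                        v_family = "logistic", snp_freqs = 0.5)
  dl <- simulate_individual(pl, n = 1e6, seed = 112)
  fsl <- fit_first_stage(dl, link = "logit")
  expect_equal(unname(fsl$coefficients["Z_1"]), 0.25 * pi / sqrt(3),
               tolerance = 0.02)

  # all-zero alpha: coefficient near zero
  p0 <- mr_model_params(alpha = c(0, 0), beta = 1, snp_freqs = 0.5)
  d0 <- simulate_individual(p0, n = 5e4, seed = 113)
  fs0 <- fit_first_stage(d0)
  expect_lt(max(abs(fs0$coefficients[c("Z_1", "Z_2")])), 0.03)
})

test_that("grouped first-stage fit equals the row-level GLM oracle", {
  p <- mr_model_params(alpha = c(0.4, 0.2), beta = 1, snp_freqs = c(0.5, 0.3))
  d <- simulate_individual(p, n = 5000, seed = 115)
  fs_grouped <- fit_first_stage(d)
  oracle <- glm(D ~ Z_1 + Z_2, data = d$data,
                family = binomial(link = "probit"))
  expect_equal(unname(fs_grouped$coefficients), unname(coef(oracle)),
               tolerance = 1e-6)
  # covariates take the ungrouped path and are excluded from the genetic
  # linear predictor
  set.seed(99)
  d$data$age <- rnorm(5000)
  fs_cov <- fit_first_stage(d, covariates = "age")
  expect_length(fs_cov$coefficients, 3L)
})

test_that("ordered-response first stage matches the latent parameterisation", {
  p <- mr_model_params(mu = 0.5, alpha = 0.6, beta = 1, sigma_v = 1.25,
                       thresholds = c(1, 2), snp_freqs = 0.5)
  d <- simulate_individual(p, n = 2e5, seed = 116)
  fs <- fit_first_stage(d, link = "ordered-probit")
  expect_equal(unname(fs$coefficients["Z_1"]), 0.6 / 1.25, tolerance = 0.03)
  expect_equal(unname(fs$coefficients["(Intercept)"]), 0.5 / 1.25,
               tolerance = 0.05)
  expect_error(fit_first_stage(d, link = "probit"), "binary")
  db <- d
  db$data$D <- as.integer(db$data$D >= 1)
  expect_error(fit_first_stage(db, link = "ordered-probit"), "3 observed")
})

test_that("fit_latent identities hold to machine precision", {
  p <- base_params(beta = 1)
  d <- simulate_individual(p, n = 5000, seed = 121)
  grid <- c(0.02, 0.1111, 0.5, 1)
  # the smallest theta2 deliberately trips the sanity diagnostic
  f <- suppressWarnings(fit_latent(d, theta2 = grid, boot_B = 0))
  # beta_L * theta = beta_G exactly, for every theta
  expect_equal(f$beta_L$beta_L * sqrt(grid), rep(f$beta_G_hat, 4),
               tolerance = 1e-13)
  # theta2 = 1 collapses beta_L to beta_G
  expect_equal(f$beta_L$beta_L[4], f$beta_G_hat)
  # standardised linear predictor diagnostics
  expect_lt(abs(f$g_tilde_mean), 1e-10)
  expect_lt(abs(f$g_tilde_sd - 1), 1e-10)
  expect_error(fit_latent(d, theta2 = 0, boot_B = 0), "theta2")
  expect_error(fit_latent(d, theta2 = -0.1, boot_B = 0), "theta2")
})

test_that("beta_G is invariant to rescaling of the first-stage predictor", {
  p <- base_params(beta = 1)
  d <- simulate_individual(p, n = 5000, seed = 122)
  fs <- fit_first_stage(d)
  iv <- function(g) coarseMR:::iv_2sls(d$data$Y, standardise(g),
                                       as.matrix(d$data["Z_1"]))$estimate
  b0 <- iv(fs$g_tilde)
  expect_equal(iv(5 + 3 * fs$g_tilde), b0, tolerance = 1e-12)
  expect_equal(iv(0.001 * fs$g_tilde), b0, tolerance = 1e-12)
})

test_that("fit_latent recovers the true latent effect at the true theta2", {
  p <- base_params(beta = 1)
  tm <- true_moments(p)   # beta_L = sqrt(1.125), theta2 = 1/9
  d <- simulate_individual(p, n = 1e5, seed = 123)
  f <- fit_latent(d, theta2 = tm$theta2, boot_B = 0)
  # oracle: direct 2SLS of Y on the held-out standardised latent exposure
  oracle <- coarseMR:::iv_2sls(d$data$Y,
                               d$latent$L / sd(d$latent$L),
                               as.matrix(d$data["Z_1"]))
  expect_equal(f$beta_L$beta_L[1], tm$beta_l, tolerance = 0.05)
  expect_equal(f$beta_L$beta_L[1], oracle$estimate,
               tolerance = 4 * oracle$se / abs(oracle$estimate))
})

test_that("direct threshold effects shift the target to the total effect", {
  # delta != 0: the latent estimator targets beta_L + delta * d E[D]/d L
  # scaled effects; we assert the estimate exceeds the delta = 0 target and
  # matches the oracle 2SLS of Y on standardised L
  p <- mr_model_params(alpha = 0.5, beta = 1, delta = 0.8, snp_freqs = 0.5)
  tm <- true_moments(p)
  d <- simulate_individual(p, n = 1e5, seed = 124)
  f <- fit_latent(d, theta2 = tm$theta2, boot_B = 0)
  oracle <- coarseMR:::iv_2sls(d$data$Y, d$latent$L / sd(d$latent$L),
                               as.matrix(d$data["Z_1"]))
  expect_equal(f$beta_L$beta_L[1], oracle$estimate, tolerance = 0.05)
  expect_gt(f$beta_L$beta_L[1], tm$beta_l)
})

test_that("theta2 sanity diagnostic fires when genetics already explain more", {
  p <- mr_model_params(alpha = 1.5, beta = 1, snp_freqs = 0.5)  # strong SNP
  d <- simulate_individual(p, n = 2e4, seed = 125)
  expect_warning(fit_latent(d, theta2 = 0.01, boot_B = 0), "theta2")
})

test_that("bootstrap_ci matches the closed-form CI for the sample mean", {
  set.seed(7)
  x <- data.frame(v = rnorm(4000))
  bs <- bootstrap_ci(function(d) mean(d$v), x, B = 600, seed = 3)
  closed <- mean(x$v) + c(-1.96, 1.96) / sqrt(4000)
  expect_lt(max(abs(bs$ci - closed)), 0.006)
  expect_equal(bs$n_failed, 0)

  # identical rows: zero-width interval
  same <- data.frame(v = rep(2.5, 100))
  bs0 <- bootstrap_ci(function(d) mean(d$v), same, B = 50, seed = 1)
  expect_equal(diff(bs0$ci), 0)

  # failing resamples are skipped and counted
  y <- data.frame(v = c(1, rep(0, 9)))
  stat <- function(d) if (sum(d$v) == 0) stop("degenerate") else mean(d$v)
  bsf <- bootstrap_ci(stat, y, B = 100, seed = 2)
  expect_gt(bsf$n_failed, 0)
  expect_lt(bsf$n_failed, 100)
})

test_that("prune_instruments keeps only conditionally strong SNPs", {
  p <- mr_model_params(alpha = c(0.5, 0), beta = 1, snp_freqs = 0.5)
  d <- simulate_individual(p, n = 1e5, seed = 131)
  kept <- prune_instruments(d, t_threshold = 4)
  expect_identical(as.character(kept), "Z_1")
  expect_named(attr(kept, "statistics"), c("Z_1", "Z_2"))

  # vacuous threshold keeps everything; infinite threshold errors
  expect_setequal(as.character(prune_instruments(d, t_threshold = 0)),
                  c("Z_1", "Z_2"))
  expect_error(prune_instruments(d, t_threshold = Inf), "survive")

  # continuous-exposure path (prune on the latent measure directly)
  d$data$bmi <- d$latent$L
  kept_c <- prune_instruments(d, exposure = "bmi", t_threshold = 4)
  expect_identical(as.character(kept_c), "Z_1")
})

test_that("auxiliary variants enter the genetic share but not the IV stage", {
  p <- mr_model_params(alpha = 0.4, gamma = 0.3, beta = 1,
                       snp_freqs = c(0.5, 0.4))
  tm <- true_moments(p)
  d <- simulate_individual(p, n = 1e5, seed = 141)
  f <- fit_latent(d, theta2 = tm$theta2, boot_B = 0)
  expect_equal(f$J, 1L)
  expect_equal(f$K, 1L)
  expect_named(f$first_stage, c("(Intercept)", "Z_1", "X_1"))
  expect_equal(f$beta_L$beta_L[1], tm$beta_l, tolerance = 0.06)
})
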