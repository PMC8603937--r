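#' Naive IV estimator using the coarsened measurement as the exposure
#'
#' With a single instrument this is the Wald ratio
#' `cov(Z, Y)/cov(Z, D)`; with several instruments (or covariates) it is
#' two-stage least squares with `D` as the endogenous exposure. Under the
#' liability-threshold model this estimand equals the true latent effect
#' divided by an unidentified density value (see [naive_limit()]): the sign
#' is preserved but the magnitude is distorted, increasingly so for rare
#' outcomes.
#'
#' @param data an `mr_dataset` or data frame.
#' @param instruments,exposure,outcome,covariates column roles; defaults are
#'   taken from the `mr_dataset` or from the `Z_*`/`D`/`Y` naming
#'   convention.
#' @param level confidence level for the Wald interval.
#' @return Object of class `mr_naive_fit`: list with `beta_D_hat`, `se`,
#'   `ci`, `n`, `method`.
#' @export
fit_naive <- function(data, instruments = NULL, exposure = NULL,
                      outcome = NULL, covariates = NULL, level = 0.95) {
  d <- as_mr_data(data, instruments = instruments, exposure = exposure,
                  outcome = outcome, covariates = covariates)
  df <- d$df
  Zm <- as.matrix(df[d$instruments])
  exog <- if (length(d$covariates)) as.matrix(df[d$covariates]) else NULL
  iv <- iv_2sls(df[[d$outcome]], as.numeric(df[[d$exposure]]), Zm, exog)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(beta_D_hat = iv$estimate, se = iv$se,
         ci = c(iv$estimate - z * iv$se, iv$estimate + z * iv$se),
         n = iv$n,
         method = if (length(d$instruments) == 1L && is.null(exog))
           "Wald ratio" else "2SLS"),
    class = "mr_naive_fit"
  )
}

#' @export
print.mr_naive_fit <- function(x, ...) {
  cat(sprintf("Naive coarsened-exposure IV (%s): beta_D = %.4g (se %.4g, 95%% CI %.4g to %.4g)\n",
              x$method, x$beta_D_hat, x$se, x$ci[1], x$ci[2]))
  invisible(x)
}

link_info <- function(link) {
  link <- match.arg(link, c("probit", "logit", "ordered-probit", "ordered-logit"))
  list(link = link,
       ordered = link %in% c("ordered-probit", "ordered-logit"),
       glm_link = sub("ordered-", "", link),
       polr_method = if (grepl("logit", link)) "logistic" else "probit")
}

# group rows with an identical (small, integer-valued) design into cells so
# the GLM is fitted on counts: identical MLE, near O(1) in n for dosage data
design_group_id <- function(M) {
  if (!all(M == round(M)) || min(M) < 0 || max(M) > 8) return(NULL)
  base <- max(M) + 1
  if (ncol(M) * log2(base) > 30) return(NULL)  # id must stay within integer range
  id <- 0
  for (j in seq_len(ncol(M))) id <- id * base + M[, j]
  as.integer(id)
}

#' First-stage generalised linear model for the coarsened exposure
#'
#' Step 1 of the latent-variable procedure. Because
#' `pr(D = 1 | Z, X) = F((mu + alpha'Z + gamma'X)/sigma_V)`, the CDF of the
#' standardised environmental share acts as a GLM link and the rescaled
#' parameters `mu/sigma_V`, `alpha/sigma_V`, `gamma/sigma_V` are identified
#' from a binary (or ordered) regression of `D` on the genetic variants.
#' The per-individual linear predictor restricted to the genetic terms
#' (covariate contributions excluded) is the estimated genetic share
#' `G_tilde = G/sigma_V` up to scale.
#'
#' For an ordered `D` the model is an ordered-response regression whose
#' first cutpoint plays the role of `-mu/sigma_V`; the slope vector is
#' unchanged.
#'
#' @inheritParams fit_naive
#' @param link `"probit"` (default), `"logit"`, `"ordered-probit"`, or
#'   `"ordered-logit"`.
#' @param auxiliary auxiliary-variant columns entering the genetic share but
#'   not used as instruments.
#' @return List with `coefficients` (named: `(Intercept)` then one per
#'   genetic column), `g_tilde` (per-individual genetic linear predictor),
#'   `link`, `n`, and the fitted model's convergence info.
#' @export
fit_first_stage <- function(data, link = "probit", instruments = NULL,
                            auxiliary = NULL, exposure = NULL,
                            covariates = NULL) {
  li <- link_info(link)
  d <- as_mr_data(data, instruments = instruments, auxiliary = auxiliary,
                  exposure = exposure, covariates = covariates)
  df <- d$df
  Dv <- df[[d$exposure]]
  lev <- sort(unique(Dv))
  if (!li$ordered) {
    if (!all(lev %in% c(0, 1)) || length(lev) != 2L) {
      stop("binary links need D coded 0/1 with both classes present; ",
           "use an ordered-* link for multivalued D", call. = FALSE)
    }
  } else {
    if (length(lev) < 3L) {
      stop("ordered links need D with at least 3 observed categories", call. = FALSE)
    }
    if (!identical(as.numeric(lev), as.numeric(0:(length(lev) - 1L)))) {
      stop("ordered D must be coded as contiguous integers 0..K with no ",
           "empty categories", call. = FALSE)
    }
  }
  gen_cols <- c(d$instruments, d$auxiliary)
  Gm <- as.matrix(df[gen_cols])
  storage.mode(Gm) <- "double"
  has_cov <- length(d$covariates) > 0L

  if (!li$ordered) {
    if (!has_cov) {
      gid <- design_group_id(Gm)
      if (!is.null(gid) && length(unique(gid)) <= 512L) {
        # grouped binomial fit on design cells
        ugid <- sort(unique(gid))
        fidx <- match(gid, ugid)
        cells <- as.data.frame(Gm[match(ugid, gid), , drop = FALSE])
        succ <- drop(rowsum(as.numeric(Dv), fidx))
        tot <- tabulate(fidx, nbins = length(ugid))
        fit <- suppressWarnings(stats::glm(
          cbind(succ, tot - succ) ~ ., data = cells,
          family = stats::binomial(link = li$glm_link)))
        co <- stats::coef(fit)
        if (any(!is.finite(co))) stop("first-stage GLM failed (separation?)", call. = FALSE)
        g_tilde <- drop(co[1] + Gm %*% co[gen_cols])
        return(list(coefficients = co[c("(Intercept)", gen_cols)],
                    g_tilde = g_tilde, link = li$link, n = nrow(df),
                    converged = fit$converged))
      }
    }
    dat <- data.frame(.D = Dv, df[c(gen_cols, d$covariates)], check.names = FALSE)
    fml <- stats::reformulate(c(gen_cols, d$covariates), response = ".D")
    fit <- suppressWarnings(stats::glm(fml, data = dat,
                                       family = stats::binomial(link = li$glm_link)))
    co <- stats::coef(fit)
    if (any(!is.finite(co[c("(Intercept)", gen_cols)]))) {
      stop("first-stage GLM failed (perfect separation or collinearity)", call. = FALSE)
    }
    g_tilde <- drop(co["(Intercept)"] + Gm %*% co[gen_cols])
    return(list(coefficients = co[c("(Intercept)", gen_cols)],
                g_tilde = g_tilde, link = li$link, n = nrow(df),
                converged = fit$converged))
  }

  # ordered-response first stage via MASS::polr; frequency-weight grouping
  # when the design allows it
  if (!has_cov) {
    gid <- design_group_id(Gm)
  } else gid <- NULL
  if (!is.null(gid) && length(unique(gid)) <= 512L) {
    cellkey <- gid * (max(Dv) + 1L) + as.integer(Dv)
    ug <- !duplicated(cellkey)
    dat <- as.data.frame(Gm[ug, , drop = FALSE])
    dat$.D <- factor(Dv[ug], levels = lev, ordered = TRUE)
    dat$.w <- as.numeric(table(cellkey)[as.character(cellkey[ug])])
  } else {
    dat <- data.frame(df[c(gen_cols, d$covariates)], check.names = FALSE)
    dat$.D <- factor(Dv, levels = lev, ordered = TRUE)
    dat$.w <- 1
  }
  rhs <- c(gen_cols, if (has_cov) d$covariates)
  fml <- stats::reformulate(rhs, response = ".D")
  fit <- suppressWarnings(MASS::polr(fml, data = dat, weights = dat$.w,
                                     method = li$polr_method, Hess = FALSE))
  slope <- stats::coef(fit)
  mu_tilde <- -unname(fit$zeta[1])  # first cutpoint is -mu/sigma_V
  co <- c("(Intercept)" = mu_tilde, slope[gen_cols])
  g_tilde <- drop(mu_tilde + Gm %*% slope[gen_cols])
  list(coefficients = co, g_tilde = g_tilde, link = li$link, n = nrow(df),
       converged = fit$convergence == 0)
}

#' Standardise a vector to sample mean 0 and SD 1
#'
#' Step 2 of the latent-variable procedure. Standardising the estimated
#' genetic linear predictor removes the unknown environmental scale:
#' `(G/sigma_V) / sd(G/sigma_V) = G/sigma_G`. Uses the `n - 1` sample-SD
#' denominator; the result is invariant to any positive affine
#' transformation of the input and idempotent.
#'
#' @param g_tilde numeric vector (non-constant).
#' @return Numeric vector with mean 0 and SD 1.
#' @examples
#' standardise(c(1, 2, 3))   # -1 0 1
#' @export
standardise <- function(g_tilde) {
  s <- stats::sd(g_tilde)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardise a constant vector (zero variance)", call. = FALSE)
  }
  (g_tilde - mean(g_tilde)) / s
}

# steps 1-3 on a plain data frame: returns beta_G_hat (scalar)
latent_beta_g <- function(df, roles, li) {
  fs <- fit_first_stage(df, link = li$link, instruments = roles$instruments,
                        auxiliary = roles$auxiliary, exposure = roles$exposure,
                        covariates = roles$covariates)
  g <- standardise(fs$g_tilde)
  exog <- if (length(roles$covariates)) as.matrix(df[roles$covariates]) else NULL
  iv <- iv_2sls(df[[roles$outcome]], g, as.matrix(df[roles$instruments]), exog)
  list(beta_g = iv$estimate, g = g, first_stage = fs, iv = iv)
}

#' Latent-variable IV estimator for a coarsened exposure
#'
#' The four-step procedure: (1) fit a GLM of the coarsened measurement `D`
#' on the genetic variants and form the genetic linear predictor; (2)
#' standardise it to mean 0, SD 1; (3) use it as the exposure in an IV
#' (2SLS) regression of `Y`, instrumented by the declared instruments,
#' giving `beta_G_hat` (effect per SD of the genetic share); (4) rescale by
#' the sensitivity parameter, `beta_L_hat = beta_G_hat / sqrt(theta2)`,
#' where `theta2 = sigma_G^2 / sigma_L^2` is the liability-scale genetic
#' variance of the latent exposure. `theta2` may come from GWAS
#' (liability-scale R^2) or be varied over a plausible grid.
#'
#' Because the exposure is a generated regressor, analytic IV standard
#' errors are invalid; confidence intervals are percentile bootstrap over
#' the full four-step pipeline (resampling individuals).
#'
#' @inheritParams fit_first_stage
#' @param theta2 numeric vector of sensitivity-parameter values in (0, 1].
#' @param outcome outcome column.
#' @param boot_B number of bootstrap resamples (0 disables the bootstrap).
#' @param boot_seed seed for the bootstrap stream.
#' @param level confidence level.
#' @return Object of class `mr_latent_fit` with `beta_G_hat`,
#'   `beta_L` (data frame: `theta2`, `beta_L`, `ci_lo`, `ci_hi`),
#'   diagnostics `g_tilde_mean`, `g_tilde_sd`, first-stage coefficients,
#'   bootstrap metadata.
#' @examples
#' p <- mr_model_params(alpha = 0.5, beta = 1)
#' d <- simulate_individual(p, n = 2000, seed = 7)
#' fit_latent(d, theta2 = c(0.05, 0.111), boot_B = 50, boot_seed = 1)
#' @export
fit_latent <- function(data, link = "probit", theta2, instruments = NULL,
                       auxiliary = NULL, exposure = NULL, outcome = NULL,
                       covariates = NULL, boot_B = 1000, boot_seed = 1,
                       level = 0.95) {
  li <- link_info(link)
  theta2 <- as.numeric(theta2)
  if (!length(theta2) || any(!is.finite(theta2)) || any(theta2 <= 0) ||
      any(theta2 > 1)) {
    stop("`theta2` values must lie in (0, 1]", call. = FALSE)
  }
  roles <- as_mr_data(data, instruments = instruments, auxiliary = auxiliary,
                      exposure = exposure, outcome = outcome,
                      covariates = covariates)
  df <- roles$df
  core <- latent_beta_g(df, roles, li)
  beta_g <- core$beta_g

  # sanity diagnostic: with a probit link and correct specification the
  # modelled variants alone already explain var(G_tilde)/(1 + var(G_tilde))
  # of the liability, a lower bound for theta2
  if (li$glm_link == "probit") {
    vg <- stats::var(core$first_stage$g_tilde)
    implied <- vg / (1 + vg)
    if (any(theta2 < 0.5 * implied)) {
      warning(sprintf(paste0(
        "theta2 value(s) below half the variance already explained by the ",
        "modelled variants on the liability scale (approx. %.3g); ",
        "beta_L may be overstated"), implied))
    }
  }

  boot <- NULL
  ci <- matrix(NA_real_, length(theta2), 2)
  if (boot_B > 0) {
    used <- unique(c(roles$instruments, roles$auxiliary, roles$exposure,
                     roles$outcome, roles$covariates))
    boot <- bootstrap_ci(function(dd) latent_beta_g(dd, roles, li)$beta_g,
                         df[used], B = boot_B, seed = boot_seed, level = level)
    ci_g <- boot$ci
    for (i in seq_along(theta2)) ci[i, ] <- ci_g / sqrt(theta2[i])
  }
  structure(
    list(beta_G_hat = beta_g,
         beta_L = data.frame(theta2 = theta2,
                             beta_L = beta_g / sqrt(theta2),
                             ci_lo = ci[, 1], ci_hi = ci[, 2]),
         link = li$link,
         g_tilde_mean = mean(core$g), g_tilde_sd = stats::sd(core$g),
         first_stage = core$first_stage$coefficients,
         n = nrow(df), J = length(roles$instruments),
         K = length(roles$auxiliary),
         boot = if (!is.null(boot))
           list(B = boot$B, n_failed = boot$n_failed, seed = boot_seed,
                estimates = boot$estimates)),
    class = "mr_latent_fit"
  )
}

#' @export
print.mr_latent_fit <- function(x, ...) {
  cat(sprintf("Latent-variable IV fit (%s link; n = %d, J = %d, K = %d)\n",
              x$link, x$n, x$J, x$K))
  cat(sprintf("  beta_G = %.4g (per SD of the genetic share)\n", x$beta_G_hat))
  tab <- x$beta_L
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  theta2 = %-8.4g beta_L = %.4g", tab$theta2[i], tab$beta_L[i]))
    if (is.finite(tab$ci_lo[i])) {
      cat(sprintf("  [%.4g, %.4g]", tab$ci_lo[i], tab$ci_hi[i]))
    }
    cat("\n")
  }
  if (!is.null(x$boot) && x$boot$n_failed > 0) {
    cat(sprintf("  bootstrap: %d of %d resamples failed and were skipped\n",
                x$boot$n_failed, x$boot$B))
  }
  invisible(x)
}

#' Percentile bootstrap confidence interval over a full pipeline
#'
#' Resamples rows of `data` with replacement, re-runs `statistic` on each
#' resample, and returns the percentile interval. Resamples on which the
#' statistic errors (for instance, a degenerate resample where the
#' coarsened exposure collapses to a single class) are skipped and counted.
#'
#' @param statistic function taking a data frame and returning a scalar.
#' @param data data frame of individuals.
#' @param B number of resamples (>= 2).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return List with `ci` (length-2), `estimates`, `B`, `n_failed`.
#' @export
bootstrap_ci <- function(statistic, data, B = 1000, seed = 1, level = 0.95) {
  stopifnot(B >= 2)
  data <- as.data.frame(data)
  n <- nrow(data)
  set.seed(as.integer(seed))
  est <- rep(NA_real_, B)
  cols <- as.list(data)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    # column-wise resampling avoids the row-name bookkeeping of `[.data.frame`
    resample <- data.frame(lapply(cols, `[`, idx), check.names = FALSE)
    est[b] <- tryCatch(statistic(resample), error = function(e) NA_real_)
  }
  ok <- is.finite(est)
  if (sum(ok) < 2) stop("bootstrap failed on nearly all resamples", call. = FALSE)
  a <- (1 - level) / 2
  list(ci = unname(stats::quantile(est[ok], c(a, 1 - a))),
       estimates = est, B = B, n_failed = sum(!ok))
}

#' Prune candidate instruments by conditional first-stage strength
#'
#' Fits one joint first-stage model of the exposure on all candidate SNPs
#' (linear regression when the exposure is continuous; the configured GLM or
#' ordered-response model when it is coarsened) and keeps the SNPs whose
#' conditional |t| (or |z|) statistic exceeds `t_threshold`. This guards
#' against weak-instrument bias before IV estimation.
#'
#' @inheritParams fit_first_stage
#' @param candidates candidate SNP columns (default: the dataset's
#'   instruments).
#' @param t_threshold keep SNPs with `|t| > t_threshold` (default 4).
#' @param link used when the exposure is coarsened; ignored for a
#'   continuous exposure.
#' @return Character vector of retained columns, with a `"statistics"`
#'   attribute holding the per-SNP conditional statistics.
#' @export
prune_instruments <- function(data, candidates = NULL, exposure = NULL,
                              t_threshold = 4, link = "probit",
                              covariates = NULL) {
  d <- as_mr_data(data, instruments = candidates, exposure = exposure,
                  covariates = covariates)
  df <- d$df
  ev <- df[[d$exposure]]
  lev <- unique(ev)
  continuous <- is.numeric(ev) && length(lev) > 10L
  rhs <- c(d$instruments, d$covariates)
  if (continuous) {
    dat <- data.frame(.E = ev, df[rhs], check.names = FALSE)
    fit <- stats::lm(stats::reformulate(rhs, response = ".E"), data = dat)
    sm <- summary(fit)$coefficients
    stat <- sm[d$instruments, "t value"]
  } else if (length(lev) == 2L) {
    li <- link_info(sub("^ordered-", "", link))
    dat <- data.frame(.E = ev, df[rhs], check.names = FALSE)
    fit <- suppressWarnings(stats::glm(stats::reformulate(rhs, response = ".E"),
                                       data = dat,
                                       family = stats::binomial(li$glm_link)))
    sm <- summary(fit)$coefficients
    stat <- sm[d$instruments, "z value"]
  } else {
    li <- link_info(if (grepl("^ordered-", link)) link else paste0("ordered-", link))
    dat <- data.frame(df[rhs], check.names = FALSE)
    dat$.E <- factor(ev, ordered = TRUE)
    fit <- suppressWarnings(MASS::polr(stats::reformulate(rhs, response = ".E"),
                                       data = dat, method = li$polr_method,
                                       Hess = TRUE))
    sm <- summary(fit)$coefficients
    stat <- sm[d$instruments, "t value"]
  }
  keep <- d$instruments[abs(stat) > t_threshold]
  if (!length(keep)) {
    stop("no instruments survive pruning at |t| > ", t_threshold, call. = FALSE)
  }
  structure(keep, statistics = stat)
}
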