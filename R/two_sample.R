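#' SNP dosage variance from an effect-allele frequency
#'
#' Under Hardy–Weinberg equilibrium a biallelic dosage (0/1/2) with
#' effect-allele frequency `p` has variance `2 p (1 - p)`. Used to convert
#' reported allele frequencies into the instrument variances needed by the
#' two-sample estimator.
#'
#' @param eaf effect-allele frequency, strictly in (0, 1); vectorised.
#' @return `2 * eaf * (1 - eaf)`.
#' @examples
#' snp_variance_from_af(0.5)   # 0.5
#' snp_variance_from_af(0.2)   # 0.32
#' @export
snp_variance_from_af <- function(eaf) {
  if (any(!is.finite(eaf)) || any(eaf <= 0) || any(eaf >= 1)) {
    stop("`eaf` must lie strictly in (0, 1)", call. = FALSE)
  }
  2 * eaf * (1 - eaf)
}

validate_summary_df <- function(df, what) {
  need <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(what, " summary statistics missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"n" %in% names(df)) df$n <- NA_real_
  df$snp <- as.character(df$snp)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  if (anyDuplicated(df$snp)) {
    stop("duplicated snp ids in ", what, " summary statistics", call. = FALSE)
  }
  if (any(!is.finite(df$se)) || any(df$se <= 0)) {
    stop("all standard errors must be finite and > 0 (", what, ")", call. = FALSE)
  }
  if (any(!is.finite(df$beta))) {
    stop("non-finite effect estimates in ", what, " summary statistics", call. = FALSE)
  }
  snp_variance_from_af(df$eaf)  # range check
  df[c("snp", "effect_allele", "other_allele", "eaf", "beta", "se", "n")]
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonise outcome summary statistics to the exposure's effect alleles
#'
#' Matches outcome SNPs to the exposure set by id, flips the outcome effect
#' sign when the coded alleles are swapped, drops SNPs whose allele pairs
#' cannot be reconciled, and drops strand-ambiguous palindromic SNPs
#' (A/T, C/G) with exposure allele frequency in \[0.42, 0.58\], where the
#' strand cannot be inferred from frequency. Dropping palindromic SNPs is
#' standard two-sample hygiene beyond the structural model itself.
#'
#' @param exposure,outcome data frames with columns `snp`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se` (and optionally `n`).
#' @return A list with the validated `exposure` table and the harmonised
#'   `outcome` table (aligned to exposure effect alleles), plus a `report`
#'   data frame of dropped SNPs and reasons.
#' @export
harmonise_summary <- function(exposure, outcome) {
  exposure <- validate_summary_df(as.data.frame(exposure), "exposure")
  outcome <- validate_summary_df(as.data.frame(outcome), "outcome")
  drops <- list()
  extra <- setdiff(outcome$snp, exposure$snp)
  if (length(extra)) {
    warning("dropping ", length(extra),
            " outcome SNP(s) absent from the exposure set")
    drops[["not_in_exposure"]] <- extra
    outcome <- outcome[!outcome$snp %in% extra, ]
  }
  idx <- match(outcome$snp, exposure$snp)
  exp_m <- exposure[idx, ]
  same <- outcome$effect_allele == exp_m$effect_allele &
    outcome$other_allele == exp_m$other_allele
  swapped <- outcome$effect_allele == exp_m$other_allele &
    outcome$other_allele == exp_m$effect_allele
  mismatch <- !(same | swapped)
  if (any(mismatch)) {
    warning("dropping ", sum(mismatch), " outcome SNP(s) with irreconcilable alleles")
    drops[["allele_mismatch"]] <- outcome$snp[mismatch]
  }
  if (any(swapped)) {
    outcome$beta[swapped] <- -outcome$beta[swapped]
    outcome$eaf[swapped] <- 1 - outcome$eaf[swapped]
    tmp <- outcome$effect_allele[swapped]
    outcome$effect_allele[swapped] <- outcome$other_allele[swapped]
    outcome$other_allele[swapped] <- tmp
  }
  pal <- is_palindromic(exp_m$effect_allele, exp_m$other_allele) &
    exp_m$eaf >= 0.42 & exp_m$eaf <= 0.58
  if (any(pal & !mismatch)) {
    warning("dropping ", sum(pal & !mismatch),
            " ambiguous palindromic SNP(s) with eaf in [0.42, 0.58]")
    drops[["palindromic"]] <- outcome$snp[pal & !mismatch]
  }
  keep <- !(mismatch | pal)
  report <- if (length(drops)) {
    data.frame(snp = unlist(drops, use.names = FALSE),
               reason = rep(names(drops), lengths(drops)))
  } else data.frame(snp = character(0), reason = character(0))
  list(exposure = exposure, outcome = outcome[keep, , drop = FALSE],
       report = report)
}

new_summary_pair <- function(exposure, outcome) {
  h <- harmonise_summary(exposure, outcome)
  if (!nrow(h$exposure)) stop("empty exposure SNP set", call. = FALSE)
  structure(list(exposure = h$exposure, outcome = h$outcome,
                 harmonisation = h$report),
            class = "mr_summary_pair")
}

#' Construct a two-sample summary-statistic pair
#'
#' Bundles exposure-GWAS and outcome-GWAS per-SNP associations, validating
#' and harmonising them (see [harmonise_summary()]). The exposure
#' associations must be on the first-stage GLM linear-predictor scale
#' (log-odds for a logistic fit, probit scale for a probit fit); the scale
#' itself cancels in the estimator provided it is common to all SNPs.
#'
#' @inheritParams harmonise_summary
#' @return An object of class `mr_summary_pair`.
#' @export
summary_pair <- function(exposure, outcome) new_summary_pair(exposure, outcome)

#' @export
print.mr_summary_pair <- function(x, ...) {
  cat(sprintf("mr_summary_pair: %d exposure SNP(s) (Z_J), %d outcome SNP(s) (Z_J0)\n",
              nrow(x$exposure), nrow(x$outcome)))
  if (nrow(x$harmonisation)) {
    cat(sprintf("  %d SNP(s) dropped during harmonisation\n", nrow(x$harmonisation)))
  }
  invisible(x)
}

# core of the summary-statistic estimator: the scale factor
# [sum_j alpha_j^2 sigma_Zj^2]^(1/2) over the full exposure set Z_J times the
# standard IVW estimate over the instrument subset Z_J0 with weights
# w_j = alpha_j^2 / se(Gamma_j)^2
eval_two_sample <- function(a_all, v_all, a_sub, g_sub, gse_sub) {
  scale_term <- sqrt(sum(a_all^2 * v_all))
  w <- a_sub^2 / gse_sub^2
  ivw_term <- sum(w * (g_sub / a_sub)) / sum(w)
  list(scale_term = scale_term, ivw_term = ivw_term,
       beta_G = scale_term * ivw_term, w = w)
}

match_pair <- function(pair) {
  if (!inherits(pair, "mr_summary_pair")) stop("need an mr_summary_pair", call. = FALSE)
  if (!nrow(pair$outcome)) stop("empty outcome SNP set", call. = FALSE)
  idx <- match(pair$outcome$snp, pair$exposure$snp)
  exp_sub <- pair$exposure[idx, ]
  if (any(exp_sub$beta == 0)) {
    stop("instrument-exposure association is exactly 0 for SNP(s) ",
         paste(exp_sub$snp[exp_sub$beta == 0], collapse = ", "),
         ": Wald ratio undefined", call. = FALSE)
  }
  list(a_all = pair$exposure$beta,
       v_all = snp_variance_from_af(pair$exposure$eaf),
       a_se_all = pair$exposure$se,
       a_sub = exp_sub$beta, a_se_sub = exp_sub$se,
       v_sub = snp_variance_from_af(exp_sub$eaf),
       g_sub = pair$outcome$beta, g_se_sub = pair$outcome$se,
       in_sub = pair$exposure$snp %in% pair$outcome$snp)
}

#' Two-sample latent-variable IVW estimator
#'
#' Estimates the effect per SD of the genetic share from GWAS summary
#' statistics as the product of a scale factor
#' \eqn{[\sum_{j \in Z_J} \tilde\alpha_j^2 \sigma_{Z_j}^2]^{1/2}}
#' (computed over the full exposure SNP set) and the standard
#' inverse-variance weighted estimate
#' \eqn{\sum_{j \in Z_{J_0}} w_j (\hat\Gamma_j/\tilde\alpha_j) / \sum_j w_j}
#' with weights \eqn{w_j = \tilde\alpha_j^2/\sigma_{\hat\Gamma_j}^2}
#' (over the instrument subset). SNP variances come from allele frequencies
#' via [snp_variance_from_af()]; the instruments are assumed mutually
#' independent (no LD). Rescaling by `1/sqrt(theta2)` gives the effect per
#' SD of the latent exposure.
#'
#' When the user supplies only the instrument subset, the scale factor is
#' necessarily subset-based and the genetic-share SD is understated; a
#' warning is not raised because the two sets are identical by
#' construction in that case.
#'
#' @param pair an `mr_summary_pair`.
#' @param theta2 numeric vector of sensitivity values in (0, 1].
#' @param se_method `"delta"` (default, propagates both the IVW variance
#'   and the exposure-association noise in the scale factor),
#'   `"delta_conditional"` (conditions on the exposure associations), or
#'   `"bootstrap"` (parametric bootstrap; see [two_sample_se()]).
#' @param level confidence level.
#' @param boot_draws,boot_seed parametric-bootstrap controls.
#' @return Object of class `mr_two_sample_fit` with `scale_term`,
#'   `ivw_term`, `beta_G_hat`, `se_beta_G`, and `beta_L` (data frame over
#'   the `theta2` grid with Wald confidence intervals).
#' @export
ivw_latent <- function(pair, theta2 = 1, se_method = "delta", level = 0.95,
                       boot_draws = 10000, boot_seed = 1) {
  theta2 <- as.numeric(theta2)
  if (!length(theta2) || any(theta2 <= 0) || any(theta2 > 1)) {
    stop("`theta2` values must lie in (0, 1]", call. = FALSE)
  }
  m <- match_pair(pair)
  est <- eval_two_sample(m$a_all, m$v_all, m$a_sub, m$g_sub, m$g_se_sub)
  se <- two_sample_se(pair, method = se_method, n_draws = boot_draws,
                      seed = boot_seed)
  z <- stats::qnorm(1 - (1 - level) / 2)
  bl <- data.frame(theta2 = theta2,
                   beta_L = est$beta_G / sqrt(theta2),
                   se = se / sqrt(theta2))
  bl$ci_lo <- bl$beta_L - z * bl$se
  bl$ci_hi <- bl$beta_L + z * bl$se
  structure(
    list(scale_term = est$scale_term, ivw_term = est$ivw_term,
         beta_G_hat = est$beta_G, se_beta_G = se, beta_L = bl,
         J = nrow(pair$exposure), J0 = nrow(pair$outcome),
         se_method = se_method, level = level),
    class = "mr_two_sample_fit"
  )
}

#' @export
print.mr_two_sample_fit <- function(x, ...) {
  cat(sprintf("Two-sample latent-variable IVW fit (J = %d, J0 = %d)\n", x$J, x$J0))
  cat(sprintf("  scale factor = %.4g, IVW component = %.4g\n",
              x$scale_term, x$ivw_term))
  cat(sprintf("  beta_G = %.4g (se %.4g, %s)\n", x$beta_G_hat, x$se_beta_G,
              x$se_method))
  for (i in seq_len(nrow(x$beta_L))) {
    cat(sprintf("  theta2 = %-8.4g beta_L = %.4g  [%.4g, %.4g]\n",
                x$beta_L$theta2[i], x$beta_L$beta_L[i],
                x$beta_L$ci_lo[i], x$beta_L$ci_hi[i]))
  }
  invisible(x)
}

#' Large-sample standard error of the two-sample estimator
#'
#' Delta-method propagation treating the exposure and outcome samples as
#' independent. Conditioning on the exposure associations gives the
#' familiar IVW form `scale_term / sqrt(sum(w))`; the default additionally
#' propagates first-order noise in the exposure associations through both
#' the scale factor and the weighted ratios. A parametric bootstrap that
#' redraws each reported association from its normal sampling distribution
#' is available as a cross-check.
#'
#' @param pair an `mr_summary_pair`.
#' @param method `"delta"`, `"delta_conditional"`, or `"bootstrap"`.
#' @param n_draws,seed parametric-bootstrap controls.
#' @return Scalar standard error of `beta_G_hat`.
#' @export
two_sample_se <- function(pair, method = c("delta", "delta_conditional",
                                           "bootstrap"),
                          n_draws = 10000, seed = 1) {
  method <- match.arg(method)
  m <- match_pair(pair)
  est <- eval_two_sample(m$a_all, m$v_all, m$a_sub, m$g_sub, m$g_se_sub)
  s <- est$scale_term; mu <- est$ivw_term; sw <- sum(est$w)
  var_ivw <- s^2 / sw
  if (method == "delta_conditional") return(sqrt(var_ivw))
  if (method == "delta") {
    # d betaG / d alpha_j: through the scale factor for every j in Z_J,
    # plus through the weights and ratios for j in Z_J0
    dscale <- mu * (m$a_all * m$v_all) / s
    dsub <- s * (m$g_sub - 2 * mu * m$a_sub) / (m$g_se_sub^2 * sw)
    grad <- dscale
    grad[m$in_sub] <- grad[m$in_sub] + dsub
    return(sqrt(var_ivw + sum(grad^2 * m$a_se_all^2)))
  }
  set.seed(as.integer(seed))
  J <- length(m$a_all); J0 <- length(m$a_sub)
  idx_sub <- which(m$in_sub)
  draws <- vapply(seq_len(n_draws), function(i) {
    a <- stats::rnorm(J, m$a_all, m$a_se_all)
    g <- stats::rnorm(J0, m$g_sub, m$g_se_sub)
    eval_two_sample(a, m$v_all, a[idx_sub], g, m$g_se_sub)$beta_G
  }, numeric(1))
  stats::sd(draws)
}

#' Sensitivity-grid reanalysis table
#'
#' Convenience wrapper producing a per-`theta2` table of latent-exposure
#' effects with Wald confidence intervals, optionally exponentiated to odds
#' ratios when the outcome association is on the log-odds scale. Smaller
#' `theta2` (less of the latent variance attributed to genetics) gives a
#' larger implied effect per latent SD.
#'
#' @inheritParams ivw_latent
#' @param exponentiate report `exp(beta_L)` (odds-ratio convention).
#' @return Data frame with `theta2`, `estimate`, `ci_lo`, `ci_hi`, `scale`.
#' @export
reanalysis_grid <- function(pair, theta2, exponentiate = FALSE,
                            se_method = "delta", level = 0.95) {
  fit <- ivw_latent(pair, theta2 = theta2, se_method = se_method, level = level)
  out <- fit$beta_L
  res <- data.frame(theta2 = out$theta2, estimate = out$beta_L,
                    ci_lo = out$ci_lo, ci_hi = out$ci_hi,
                    scale = "per-SD (linear)")
  if (exponentiate) {
    res$estimate <- exp(res$estimate)
    res$ci_lo <- exp(res$ci_lo)
    res$ci_hi <- exp(res$ci_hi)
    res$scale <- "odds ratio"
  }
  res
}
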