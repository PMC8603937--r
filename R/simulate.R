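#' Coarsen a latent exposure into a binary or ordered measurement
#'
#' Binary single-threshold rule: `D = 1` iff `L >= 0` (or `L >= R` when a
#' random individual-specific threshold `R` is supplied). Ordered rule with
#' cutpoints `0 < d1 < ... < d(K-1)`: `D = 0` iff `L <= 0`, `D = k` iff
#' `d(k-1) < L <= dk`, and `D = K` iff `L > d(K-1)` — left-open, right-closed
#' bins with the top bin open. Note the boundary conventions differ at
#' exactly `L = 0`: the binary rule maps it to 1, the ordered rule to 0;
#' both are measure-zero events for continuous `L`.
#'
#' @param L numeric vector of latent-exposure values.
#' @param thresholds strictly increasing positive cutpoints; `numeric(0)`
#'   for the binary case.
#' @param R optional vector of individual-specific thresholds, same length
#'   as `L`; the rules above are applied to `L - R`.
#' @return Integer vector of categories `0..K`.
#' @examples
#' coarsen(c(-0.3, 0, 0.7))                      # 0 1 1
#' coarsen(c(-0.1, 0.5, 1.5), thresholds = 1)    # 0 1 2
#' coarsen(0.2, R = 0.5)                         # 0
#' @export
coarsen <- function(L, thresholds = numeric(0), R = NULL) {
  L <- as.numeric(L)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) && (any(thresholds <= 0) ||
      is.unsorted(thresholds, strictly = TRUE))) {
    stop("`thresholds` must be strictly increasing and > 0", call. = FALSE)
  }
  if (!is.null(R)) {
    if (length(R) != length(L)) stop("`R` must match the length of `L`", call. = FALSE)
    L <- L - R
  }
  if (!length(thresholds)) {
    return(as.integer(L >= 0))
  }
  cuts <- c(0, thresholds)
  D <- integer(length(L))
  for (ct in cuts) D <- D + as.integer(L > ct)
  D
}

# deterministic stream splitting: child seeds derived from one master seed
split_seed <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate individual-level data from the liability-threshold model
#'
#' Draws genotypes `Z`, `X` independently as Binomial(2, p) dosages (HWE),
#' the environmental share `V` from the configured family scaled to SD
#' `sigma_v`, forms the latent exposure
#' `L = mu + alpha'Z + gamma'X - V`, coarsens it into `D` (see [coarsen()]),
#' and generates the outcome `Y = beta L + delta D + eps` with
#' `cov(V, eps)` controlled by the `confounding` parameter.
#'
#' @param params an [mr_model_params] object.
#' @param n sample size (>= 1).
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @return An object of class `mr_dataset`: a list with the analysis
#'   data frame `$data` (columns `id`, `Z_1..Z_J`, `X_1..X_K`, `D`, `Y`),
#'   role attributes (`$instruments`, `$auxiliary`, `$exposure`, `$outcome`),
#'   and `$latent` (data frame of `L`, `G`, `V`, held out from estimators).
#' @examples
#' p <- mr_model_params(alpha = 0.5, beta = 1)
#' d <- simulate_individual(p, n = 100, seed = 1)
#' head(d$data)
#' @export
simulate_individual <- function(params, n, seed) {
  stopifnot(inherits(params, "mr_model_params"), n >= 1)
  set.seed(as.integer(seed))
  J <- params$J; K <- params$K
  pz <- params$snp_freqs[seq_len(J)]
  px <- if (K) params$snp_freqs[J + seq_len(K)] else numeric(0)

  ncopies <- if (identical(params$genotype, "binary")) 1L else 2L
  Z <- vapply(pz, function(p) stats::rbinom(n, ncopies, p), numeric(n))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = n)
  colnames(Z) <- paste0("Z_", seq_len(J))
  X <- if (K) {
    m <- vapply(px, function(p) stats::rbinom(n, ncopies, p), numeric(n))
    if (is.null(dim(m))) m <- matrix(m, nrow = n)
    colnames(m) <- paste0("X_", seq_len(K))
    m
  } else NULL

  V <- params$sigma_v * params$v_family$sample(n)
  G <- params$mu + drop(Z %*% params$alpha) +
    (if (K) drop(X %*% params$gamma) else 0)
  L <- G - V
  R <- if (!is.null(params$r_dist)) params$r_dist(n) else NULL
  D <- coarsen(L, params$thresholds, R)
  eps <- params$confounding * (V / params$sigma_v) +
    params$sigma_eps * stats::rnorm(n)
  Y <- params$beta * L + params$delta * D + eps

  df <- data.frame(id = seq_len(n), Z, check.names = FALSE)
  if (K) df <- cbind(df, as.data.frame(X))
  df$D <- D
  df$Y <- Y
  structure(
    list(data = df,
         instruments = colnames(Z),
         auxiliary = if (K) colnames(X) else character(0),
         exposure = "D", outcome = "Y", covariates = character(0),
         latent = if (is.null(R)) data.frame(L = L, G = G, V = V)
                  else data.frame(L = L, G = G, V = V, R = R),
         params = params, n = n, seed = as.integer(seed)),
    class = "mr_dataset"
  )
}

#' @export
print.mr_dataset <- function(x, ...) {
  cat(sprintf("mr_dataset: n = %d, %d instrument(s), %d auxiliary variant(s)\n",
              nrow(x$data), length(x$instruments), length(x$auxiliary)))
  cat(sprintf("  exposure '%s' with %d categories; outcome '%s'\n",
              x$exposure, length(unique(x$data[[x$exposure]])), x$outcome))
  invisible(x)
}

#' @export
as.data.frame.mr_dataset <- function(x, ...) x$data

# fast per-SNP marginal GLM of a binary D on one dosage column, fitted on
# cells grouped by dosage value (identical MLE, O(1) in n)
marginal_binary_glm <- function(z, d, link) {
  tab <- stats::aggregate(d, by = list(z = z), FUN = function(v) c(sum(v), length(v)))
  succ <- tab$x[, 1]; tot <- tab$x[, 2]
  fit <- suppressWarnings(stats::glm(cbind(succ, tot - succ) ~ tab$z,
                                     family = stats::binomial(link = link)))
  sm <- summary(fit)$coefficients
  c(beta = unname(sm[2, 1]), se = unname(sm[2, 2]))
}

# per-SNP marginal ordered-response fit (grouped frequency weights)
marginal_ordered_fit <- function(z, d, link) {
  method <- if (link == "logit") "logistic" else "probit"
  tab <- as.data.frame(table(z = z, d = d), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  tab$z <- as.numeric(tab$z)
  tab$d <- factor(as.integer(tab$d), ordered = TRUE)
  fit <- suppressWarnings(MASS::polr(d ~ z, data = tab, weights = tab$Freq,
                                     method = method, Hess = TRUE))
  sm <- summary(fit)$coefficients
  c(beta = unname(sm["z", 1]), se = unname(sm["z", 2]))
}

# closed-form per-SNP linear regression slope and SE
marginal_lm <- function(z, y) {
  n <- length(y)
  vz <- stats::var(z)
  b <- stats::cov(z, y) / vz
  res <- y - mean(y) - b * (z - mean(z))
  se <- sqrt(sum(res^2) / (n - 2) / ((n - 1) * vz))
  c(beta = b, se = se)
}

#' Simulate a two-sample GWAS summary-statistic pair
#'
#' Draws two independent samples from the same structural model. In the
#' exposure sample, each instrument SNP is regressed marginally on the
#' coarsened exposure with the requested GLM link (binary D: logistic or
#' probit regression; ordered D: ordered logit/probit), yielding the
#' instrument–exposure association on the linear-predictor scale (log-odds
#' for the logit link). In the outcome sample, each SNP is regressed
#' linearly on `Y`. Effect-allele frequencies are taken from the exposure
#' sample. Because the instruments are mutually independent by construction,
#' the marginal associations identify the quantities entering the
#' summary-statistic estimator up to a common scale factor that cancels
#' there.
#'
#' @param params an [mr_model_params] object.
#' @param n_exposure,n_outcome sample sizes of the two GWAS.
#' @param seed master integer seed; two independent child streams are
#'   derived from it deterministically.
#' @param link first-stage link: `"probit"`, `"logit"`, or `NULL` to match
#'   `params$v_family` (normal -> probit, logistic -> logit).
#' @param outcome_snps instrument names to keep in the outcome set `ZJ0`
#'   (default: all of `ZJ`).
#' @return An object of class `mr_summary_pair` with data frames
#'   `$exposure` and `$outcome`, columns `snp`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `n`.
#' @export
simulate_two_sample <- function(params, n_exposure, n_outcome, seed,
                                link = NULL, outcome_snps = NULL) {
  stopifnot(inherits(params, "mr_model_params"))
  if (identical(params$genotype, "binary")) {
    stop("two-sample summary simulation assumes 0/1/2 dosages ",
         "(allele-frequency-based SNP variances)", call. = FALSE)
  }
  if (is.null(link)) {
    link <- if (params$v_family$name == "logistic") "logit" else "probit"
  }
  link <- match.arg(link, c("probit", "logit"))
  seeds <- split_seed(seed, 2L)
  dx <- simulate_individual(params, n_exposure, seeds[1])
  dy <- simulate_individual(params, n_outcome, seeds[2])
  snps <- dx$instruments
  ordered <- length(params$thresholds) > 0L

  # simulated SNPs get fixed non-palindromic alleles
  ea <- "A"; oa <- "G"
  exp_rows <- lapply(snps, function(s) {
    z <- dx$data[[s]]
    est <- tryCatch(
      if (ordered) marginal_ordered_fit(z, dx$data$D, link)
      else marginal_binary_glm(z, dx$data$D, link),
      error = function(e) c(beta = NA_real_, se = NA_real_)
    )
    data.frame(snp = s, effect_allele = ea, other_allele = oa,
               eaf = mean(z) / 2, beta = est[["beta"]], se = est[["se"]],
               n = n_exposure)
  })
  exposure <- do.call(rbind, exp_rows)
  bad <- !is.finite(exposure$beta) | !is.finite(exposure$se) |
    exposure$se > 100 | abs(exposure$beta) > 50
  if (any(bad)) {
    warning(sprintf("dropping %d SNP(s) with separated/degenerate exposure fits: %s",
                    sum(bad), paste(exposure$snp[bad], collapse = ", ")))
    exposure <- exposure[!bad, ]
  }

  keep <- if (is.null(outcome_snps)) exposure$snp else intersect(outcome_snps, exposure$snp)
  out_rows <- lapply(keep, function(s) {
    z <- dy$data[[s]]
    est <- marginal_lm(z, dy$data$Y)
    data.frame(snp = s, effect_allele = ea, other_allele = oa,
               eaf = mean(z) / 2, beta = est[["beta"]], se = est[["se"]],
               n = n_outcome)
  })
  outcome <- do.call(rbind, out_rows)
  rownames(exposure) <- rownames(outcome) <- NULL
  new_summary_pair(exposure, outcome)
}
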