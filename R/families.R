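#' Distribution family of the standardised environmental share
#'
#' The liability-threshold model writes the latent exposure as
#' \eqn{L = G - V} where the environmental share \eqn{V} has mean zero,
#' standard deviation \eqn{\sigma_V}, and \eqn{V/\sigma_V} belongs to a
#' known continuous family with CDF \eqn{F} and density \eqn{f}. All
#' functions in a family object are parameterised for the *standardised*
#' variable (mean 0, SD 1), so that `cdf(v / sigma_v)` is the CDF of `V`
#' itself.
#'
#' The built-in `"logistic"` family is the logistic distribution rescaled
#' to unit SD (scale \eqn{\sqrt{3}/\pi}); a logit-link first stage fitted to
#' data generated under it therefore recovers coefficients on the natural
#' logistic (log-odds) scale up to that constant.
#'
#' @param family `"normal"`, `"logistic"`, or `"user"`.
#' @param cdf,pdf,quantile for `family = "user"`: vectorised CDF, density and
#'   quantile function of a continuous distribution with mean 0 and SD 1.
#' @return An object of class `mr_v_family`: a list with elements `name`,
#'   `cdf`, `pdf`, `quantile` and `sample(n)`.
#' @examples
#' fam <- mr_v_family("normal")
#' fam$cdf(0)            # 0.5
#' mr_v_family("logistic")$cdf(0)
#' @export
mr_v_family <- function(family = c("normal", "logistic", "user"),
                        cdf = NULL, pdf = NULL, quantile = NULL) {
  if (is.list(family) && inherits(family, "mr_v_family")) return(family)
  family <- match.arg(family)
  fam <- switch(family,
    normal = list(
      name = "normal",
      cdf = stats::pnorm,
      pdf = stats::dnorm,
      quantile = stats::qnorm,
      sample = function(n) stats::rnorm(n)
    ),
    logistic = {
      k <- sqrt(3) / pi  # scale giving unit SD
      list(
        name = "logistic",
        cdf = function(x) stats::plogis(x / k),
        pdf = function(x) stats::dlogis(x / k) / k,
        quantile = function(p) k * stats::qlogis(p),
        sample = function(n) k * stats::rlogis(n)
      )
    },
    user = {
      if (!is.function(cdf) || !is.function(pdf) || !is.function(quantile)) {
        stop("a user-supplied family needs `cdf`, `pdf` and `quantile` functions",
             call. = FALSE)
      }
      list(
        name = "user",
        cdf = cdf, pdf = pdf, quantile = quantile,
        sample = function(n) quantile(stats::runif(n))
      )
    }
  )
  structure(fam, class = "mr_v_family")
}

as_v_family <- function(x) {
  if (inherits(x, "mr_v_family")) return(x)
  if (is.character(x)) return(mr_v_family(x))
  if (is.list(x)) {
    return(mr_v_family("user", cdf = x$cdf, pdf = x$pdf, quantile = x$quantile))
  }
  stop("cannot interpret `v_family`; give a family name or an mr_v_family object",
       call. = FALSE)
}
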