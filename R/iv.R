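# Two-stage least squares with a single endogenous regressor.
# X = [1, endog, exog], instruments [1, inst, exog]; classical 2SLS
# covariance sigma^2 (Xhat' Xhat)^{-1} with residuals from the
# second-stage coefficients applied to the *original* regressors.
iv_2sls <- function(y, endog, inst, exog = NULL) {
  n <- length(y)
  inst <- as.matrix(inst)
  if (!is.null(exog)) exog <- as.matrix(exog)
  X <- cbind(1, endog, exog)
  Zm <- cbind(1, inst, exog)
  ZtZ <- crossprod(Zm)
  ZtX <- crossprod(Zm, X)
  proj <- tryCatch(solve(ZtZ, ZtX), error = function(e)
    stop("instrument matrix is rank deficient for the requested model",
         call. = FALSE))
  XhtXh <- crossprod(ZtX, proj)           # Xhat'Xhat = X'Z (Z'Z)^-1 Z'X
  Xhty <- crossprod(proj, crossprod(Zm, y))
  b <- tryCatch(drop(solve(XhtXh, Xhty)), error = function(e)
    stop("2SLS failed: zero or collinear first-stage covariance",
         call. = FALSE))
  if (any(!is.finite(b))) {
    stop("2SLS failed: zero or collinear first-stage covariance", call. = FALSE)
  }
  res <- y - drop(X %*% b)
  k <- ncol(X)
  sigma2 <- sum(res^2) / (n - k)
  V <- sigma2 * solve(XhtXh)
  list(estimate = unname(b[2]), se = sqrt(V[2, 2]),
       coefficients = b, vcov = V, n = n)
}

# Normalise estimator inputs: an mr_dataset carries its own column roles,
# a plain data.frame needs them spelled out.
as_mr_data <- function(data, instruments = NULL, auxiliary = NULL,
                       exposure = NULL, outcome = NULL, covariates = NULL) {
  if (inherits(data, "mr_dataset")) {
    df <- data$data
    instruments <- instruments %||% data$instruments
    auxiliary <- auxiliary %||% data$auxiliary
    exposure <- exposure %||% data$exposure
    outcome <- outcome %||% data$outcome
    covariates <- covariates %||% data$covariates
  } else {
    df <- as.data.frame(data)
    exposure <- exposure %||% "D"
    outcome <- outcome %||% "Y"
    if (is.null(instruments)) {
      instruments <- grep("^Z_", names(df), value = TRUE)
    }
    if (is.null(auxiliary)) auxiliary <- grep("^X_", names(df), value = TRUE)
    covariates <- covariates %||% character(0)
  }
  cols <- c(instruments, auxiliary, exposure, outcome, covariates)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("columns not found in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!length(instruments)) stop("at least one instrument column is required",
                                 call. = FALSE)
  list(df = df, instruments = instruments, auxiliary = auxiliary,
       exposure = exposure, outcome = outcome, covariates = covariates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
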