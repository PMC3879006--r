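#' Ordinary least squares on an explicit design matrix
#'
#' Shared least-squares core used by the 2SLS estimator, the genome-wide
#' scan and the nested F test. Fits `y = X b + e` by QR decomposition and
#' returns classical homoskedastic standard errors.
#'
#' @param y Numeric response vector.
#' @param X Numeric design matrix (include an intercept column yourself).
#'
#' @return A list with elements `coefficients`, `se`, `t`, `p`, `residuals`,
#'   `fitted`, `rss`, `sigma2`, `df.residual`, `vcov`, `n`.
#' @examples
#' x <- 1:10
#' fit <- ols_fit(2 * x + rnorm(10), cbind(1, x))
#' fit$coefficients
#' @export
ols_fit <- function(y, X) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("design matrix and response have different lengths")
  qr_X <- qr(X)
  if (qr_X$rank < p) stop("design matrix is rank deficient")
  if (n <= p) stop("need more observations (", n, ") than parameters (", p, ")")
  coef <- qr.coef(qr_X, y)
  fitted <- drop(X %*% coef)
  res <- y - fitted
  rss <- sum(res^2)
  df <- n - p
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qr_X))
  vcov <- sigma2 * XtX_inv
  se <- sqrt(diag(vcov))
  tval <- coef / se
  list(coefficients = coef, se = se, t = tval,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       residuals = res, fitted = fitted, rss = rss, sigma2 = sigma2,
       df.residual = df, vcov = vcov, n = n)
}

#' Two-stage least squares with a single instrument
#'
#' Fits the instrumental-variable model in two stages: the exposure is
#' regressed on the instrument (plus covariates), then the outcome is
#' regressed on the fitted exposure (plus the same covariates). Standard
#' errors for the second stage use the conventional 2SLS correction:
#' residuals are recomputed from the *observed* exposure, so that
#' `sigma^2 = RSS_corrected / (n - p)` and the covariance is
#' `sigma^2 (Xhat' Xhat)^{-1}`. In the just-identified case with one
#' instrument this estimator equals the Wald ratio.
#'
#' @param y Outcome vector (e.g. arcsine square-root transformed methylation).
#' @param exposure Exposure vector (e.g. log RBC folate).
#' @param instrument Instrument vector (e.g. additive MTHFR variant count);
#'   must not be constant.
#' @param covariates Optional numeric vector or matrix of measured
#'   covariates included in both stages (e.g. conception intention).
#'
#' @return An object of class `"tsls"`; see [tsls()] for its contents.
#' @seealso [tsls()] for the formula interface.
#' @examples
#' # single binary instrument, no covariates: equals the Wald ratio
#' fit <- tsls_fit(y = c(2, 3, 7, 10), exposure = c(1, 2, 3, 6),
#'                 instrument = c(0, 0, 1, 1))
#' coef(fit)[["exposure"]]  # 2
#' @export
tsls_fit <- function(y, exposure, instrument, covariates = NULL) {
  y <- as.numeric(y)
  exposure <- as.numeric(exposure)
  instrument <- as.numeric(instrument)
  n <- length(y)
  if (length(exposure) != n || length(instrument) != n)
    stop("y, exposure and instrument must have the same length")
  if (stats::var(instrument) == 0)
    stop("instrument is constant: first-stage variance is zero")
  C <- NULL
  cov_names <- character(0)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (nrow(C) != n) stop("covariates have ", nrow(C), " rows, expected ", n)
    cov_names <- colnames(C)
    if (is.null(cov_names)) cov_names <- paste0("covariate", seq_len(ncol(C)))
  }

  # Stage 1: exposure ~ instrument + covariates
  D1 <- cbind(`(Intercept)` = 1, instrument = instrument, C)
  colnames(D1) <- c("(Intercept)", "instrument", cov_names)
  s1 <- ols_fit(exposure, D1)
  xhat <- s1$fitted

  # first-stage F for the instrument (instrument vs covariates-only model)
  D1r <- cbind(`(Intercept)` = rep(1, n), C)
  rss_r <- ols_fit(exposure, D1r)$rss
  fs_df2 <- s1$df.residual
  fs_F <- (rss_r - s1$rss) / (s1$rss / fs_df2)
  fs_p <- stats::pf(fs_F, 1, fs_df2, lower.tail = FALSE)

  # Stage 2: y ~ fitted exposure + covariates
  D2 <- cbind(`(Intercept)` = 1, exposure = xhat, C)
  colnames(D2) <- c("(Intercept)", "exposure", cov_names)
  s2 <- ols_fit(y, D2)
  p2 <- ncol(D2)
  df2 <- n - p2

  # 2SLS SE correction: residuals from the observed exposure
  D2_obs <- D2
  D2_obs[, "exposure"] <- exposure
  res_corr <- y - drop(D2_obs %*% s2$coefficients)
  sigma2 <- sum(res_corr^2) / df2
  vcov <- sigma2 * chol2inv(chol(crossprod(D2)))
  dimnames(vcov) <- list(colnames(D2), colnames(D2))
  se <- sqrt(diag(vcov))
  tval <- s2$coefficients / se
  pval <- 2 * stats::pt(abs(tval), df2, lower.tail = FALSE)

  structure(list(
    coefficients = s2$coefficients,
    se = se, t = tval, p = pval, vcov = vcov, sigma2 = sigma2,
    residuals = res_corr,
    fitted = drop(D2_obs %*% s2$coefficients),
    first_stage = list(coefficients = s1$coefficients, se = s1$se,
                       F = fs_F, p = fs_p, df = c(1, fs_df2)),
    df.residual = df2, n = n,
    exposure = exposure, instrument = instrument, covariates = C,
    y = y, call = match.call()
  ), class = "tsls")
}

#' Two-stage least squares (formula interface)
#'
#' Formula interface to [tsls_fit()]. The right-hand side has two parts
#' separated by `|`: regressors (the exposure plus any covariates), then
#' instruments (the instrument plus the same covariates), e.g.
#' `meth ~ folate + planned | variants + planned`. Exactly one regressor
#' may be endogenous (absent from the instrument part); it is instrumented
#' by the variable absent from the regressor part.
#'
#' @param formula Two-part formula `outcome ~ exposure + covars | instrument + covars`.
#' @param data A data frame in which to evaluate the formula.
#'
#' @return An object of class `"tsls"` with components `coefficients`
#'   (second stage, named `(Intercept)`, `exposure`, covariates), `se`, `t`,
#'   `p`, `vcov` (corrected), `first_stage` (coefficients and the
#'   instrument-strength F test), `residuals` and `fitted` (both from the
#'   observed exposure), `df.residual`, `n`.
#' @examples
#' d <- data.frame(z = rep(0:2, each = 20))
#' d$a <- 6.5 + 0.3 * d$z + rnorm(60, sd = 0.3)
#' d$y <- 1 + 0.2 * d$a + rnorm(60, sd = 0.1)
#' fit <- tsls(y ~ a | z, data = d)
#' summary(fit)
#' @export
tsls <- function(formula, data = environment(formula)) {
  rhs <- formula[[3L]]
  if (!(is.call(rhs) && identical(rhs[[1L]], as.name("|"))))
    stop("formula must have the form outcome ~ exposure + covars | instrument + covars")
  f_reg <- stats::as.formula(call("~", formula[[2L]], rhs[[2L]]))
  f_ins <- stats::as.formula(call("~", rhs[[3L]]))
  environment(f_reg) <- environment(f_ins) <- environment(formula)

  mf <- stats::model.frame(f_reg, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X_reg <- stats::model.matrix(f_reg, mf)[, -1L, drop = FALSE]
  X_ins <- stats::model.matrix(f_ins, stats::model.frame(f_ins, data = data,
                                                         na.action = stats::na.fail))[, -1L, drop = FALSE]
  endo <- setdiff(colnames(X_reg), colnames(X_ins))
  inst <- setdiff(colnames(X_ins), colnames(X_reg))
  if (length(endo) != 1L || length(inst) != 1L)
    stop("exactly one endogenous regressor and one instrument are supported; ",
         "found ", length(endo), " and ", length(inst))
  covars <- X_reg[, setdiff(colnames(X_reg), endo), drop = FALSE]
  if (ncol(covars) == 0L) covars <- NULL
  fit <- tsls_fit(y, X_reg[, endo], X_ins[, inst], covariates = covars)
  fit$call <- match.call()
  names(fit$coefficients)[2L] <- endo
  names(fit$se)[2L] <- names(fit$t)[2L] <- names(fit$p)[2L] <- endo
  dimnames(fit$vcov) <- list(names(fit$coefficients), names(fit$coefficients))
  fit
}

#' @export
print.tsls <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Two-stage least squares fit\n")
  if (!is.null(x$call)) {
    cat("Call: ")
    print(x$call)
  }
  cat("\nCoefficients (second stage):\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nFirst-stage F = %.3f (p = %.4g), n = %d\n",
              x$first_stage$F, x$first_stage$p, x$n))
  invisible(x)
}

#' @export
summary.tsls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$t, `Pr(>|t|)` = object$p)
  structure(list(call = object$call, coefficients = tab,
                 first_stage = object$first_stage,
                 sigma = sqrt(object$sigma2),
                 df.residual = object$df.residual, n = object$n),
            class = "summary.tsls")
}

#' @export
print.summary.tsls <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Two-stage least squares\n")
  if (!is.null(x$call)) {
    cat("Call: ")
    print(x$call)
  }
  cat("\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\nResidual standard error: %.4g on %d degrees of freedom\n",
              x$sigma, x$df.residual))
  cat(sprintf("First-stage (instrument strength) F = %.3f on %d and %d DF, p = %.4g\n",
              x$first_stage$F, x$first_stage$df[1], x$first_stage$df[2],
              x$first_stage$p))
  invisible(x)
}

#' @export
coef.tsls <- function(object, ...) object$coefficients

#' @export
vcov.tsls <- function(object, ...) object$vcov

#' @export
residuals.tsls <- function(object, ...) object$residuals

#' @export
fitted.tsls <- function(object, ...) object$fitted

#' @export
nobs.tsls <- function(object, ...) object$n

#' @export
confint.tsls <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  a <- (1 - level) / 2
  q <- stats::qt(c(a, 1 - a), object$df.residual)
  ci <- cf[parm] + outer(object$se[parm], q)
  dimnames(ci) <- list(parm, sprintf("%.1f %%", 100 * c(a, 1 - a)))
  ci
}

#' @export
predict.tsls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  exposure <- as.numeric(newdata[[names(object$coefficients)[2L]]])
  D <- cbind(1, exposure)
  if (!is.null(object$covariates)) {
    cn <- colnames(object$covariates)
    D <- cbind(D, as.matrix(newdata[, cn, drop = FALSE]))
  }
  drop(D %*% object$coefficients)
}
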