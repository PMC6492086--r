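#' Construct a causal-effect estimate record
#'
#' @param method method label.
#' @param estimate point estimate of the causal exposure effect.
#' @param se standard error, or `NA` when the method reports none (sisVIVE
#'   itself carries no SE; only post-selection estimates do).
#' @param valid_set optional character vector of SNPs classed as valid
#'   instruments (selection-based methods only).
#' @param intercept optional intercept (MR-Egger).
#' @param extras named list of method-specific diagnostics.
#' @return An object of class `causal_estimate` with a normal-approximation
#'   95\% confidence interval when `se` is available.
#' @export
causal_estimate <- function(method, estimate, se = NA_real_,
                            valid_set = NULL, intercept = NULL,
                            extras = list()) {
  est <- list(method = method, estimate = as.numeric(estimate),
              se = as.numeric(se),
              ci_low = if (is.na(se)) NA_real_ else estimate - 1.96 * se,
              ci_high = if (is.na(se)) NA_real_ else estimate + 1.96 * se,
              valid_set = valid_set, intercept = intercept, extras = extras)
  class(est) <- "causal_estimate"
  est
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("<causal_estimate> %s: %.4f", x$method, x$estimate))
  if (!is.na(x$se))
    cat(sprintf(" (se %.4f, 95%% CI %.4f to %.4f)", x$se, x$ci_low, x$ci_high))
  cat("\n")
  if (!is.null(x$valid_set))
    cat(sprintf("  valid instruments selected: %d\n", length(x$valid_set)))
  invisible(x)
}

#' Single-SNP ratio estimate of the causal effect
#'
#' The Wald/ratio estimator: the SNP-outcome coefficient divided by the
#' SNP-exposure coefficient. The standard error uses the delta method; by
#' default only the first-order term `se_gamma / |b_hat|`, optionally with
#' the second-order term propagating the uncertainty in the denominator.
#'
#' @param gamma_hat,b_hat SNP-outcome and SNP-exposure coefficients.
#' @param se_gamma,se_b their standard errors.
#' @param second_order include the denominator term in the delta-method SE.
#' @param weak_threshold warn when `|b_hat|` falls below this value
#'   (weak-denominator diagnostic).
#' @return A [causal_estimate()].
#' @export
ratio_estimate <- function(gamma_hat, b_hat, se_gamma = NA_real_,
                           se_b = NA_real_, second_order = FALSE,
                           weak_threshold = 0) {
  if (b_hat == 0) stop("division by zero: SNP-exposure coefficient is 0")
  if (abs(b_hat) < weak_threshold)
    warning(sprintf("weak denominator: |b_hat| = %.3g below threshold %.3g",
                    abs(b_hat), weak_threshold))
  est <- gamma_hat / b_hat
  se <- if (is.na(se_gamma)) NA_real_ else if (second_order && !is.na(se_b)) {
    sqrt(se_gamma^2 / b_hat^2 + gamma_hat^2 * se_b^2 / b_hat^4)
  } else abs(se_gamma / b_hat)
  causal_estimate("ratio", est, se)
}

#' Polygenic-risk-score weights
#'
#' @param scheme `"SPRS"` (unit weights), `"IPRS"` (in-sample SNP-exposure
#'   coefficients) or `"EPRS"` (externally supplied associations).
#' @param weights length-J numeric weights; required for EPRS, computed from
#'   the data for IPRS, forced to 1 for SPRS.
#' @return An object of class `prs_weights`.
#' @export
prs_weights <- function(scheme = c("SPRS", "IPRS", "EPRS"), weights = NULL) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme, weights = weights), class = "prs_weights")
}

#' Polygenic-risk-score IV estimate
#'
#' Builds the weighted allele score `sum_j w_j G_j` and uses it as the single
#' instrument in 2SLS (equivalently, the ratio estimator with the score as
#' the IV). SPRS sets all weights to 1; IPRS uses the in-sample first-stage
#' coefficients from the joint regression of the exposure on the selected
#' SNPs (so the score is the fitted exposure and the estimate coincides
#' with multiple-instrument 2SLS); EPRS uses external association
#' estimates.
#'
#' @param data a prepared [study_data()].
#' @param weights a [prs_weights()]; for IPRS with `weights = NULL` the
#'   joint first-stage coefficients are computed from the data (pass
#'   explicit weights for the marginal-coefficient variant).
#' @param snps optional subset of SNP ids to score over (all by default).
#' @return A [causal_estimate()] labelled after the scheme.
#' @export
prs_estimate <- function(data, weights, snps = NULL) {
  stopifnot(inherits(weights, "prs_weights"))
  g <- centered_genotypes(data, snps)
  j <- ncol(g)
  w <- switch(weights$scheme,
    SPRS = rep(1, j),
    IPRS = if (is.null(weights$weights)) {
      # joint first-stage coefficients (one regression of X on all selected
      # SNPs), so the score is the fitted exposure and the score-IV estimate
      # coincides with multiple-instrument 2SLS
      qr.coef(qr(g), data$exposure)
    } else weights$weights,
    EPRS = {
      if (is.null(weights$weights))
        stop("EPRS requires externally supplied weights")
      weights$weights
    })
  if (length(w) != j) stop("weights length must match the number of SNPs")
  if (all(w == 0)) stop("degenerate score: all weights are zero")
  score <- as.numeric(g %*% w)
  if (stats::var(score) == 0) stop("degenerate score: zero variance")
  fit <- iv_fit(data$outcome, data$exposure, cbind(score))
  causal_estimate(weights$scheme, fit$estimate, fit$se,
                  extras = list(score_variance = stats::var(score)))
}

# Core one-sample IV fit of centered y on centered x with instrument matrix z
# (no intercept; all variables centered). Returns the 2SLS estimate with the
# classical homoskedastic IV standard error, residual variance evaluated at
# the original exposure.
iv_fit <- function(y, x, z) {
  q <- qr(z)
  if (q$rank < ncol(z))
    stop("singular design: instrument matrix is rank deficient")
  xhat <- qr.fitted(q, x)
  sxx <- sum(xhat * x)            # x' P_z x
  if (abs(sxx) < .Machine$double.eps * length(y))
    stop("singular design: projected exposure has no variation")
  est <- sum(xhat * y) / sxx
  resid <- y - est * x
  sigma2 <- sum(resid^2) / (length(y) - 2)
  list(estimate = est, se = sqrt(sigma2 / sum(xhat^2)), xhat = xhat)
}

#' Two-stage least squares with multiple genetic instruments
#'
#' One-sample mode regresses the exposure on the selected SNPs (stage one)
#' and the outcome on the fitted exposure (stage two). Two-sample mode takes
#' an externally predicted exposure (`exposure_override`, typically the
#' allele score weighted by external association estimates) and runs only
#' the second stage, treating the external weights as fixed.
#'
#' @param data a prepared [study_data()].
#' @param instrument_set character vector of SNP ids to instrument with
#'   (default: all SNPs in the panel).
#' @param exposure_override optional length-N predicted exposure for the
#'   two-sample pathway.
#' @return A [causal_estimate()] labelled `"2SLS"`.
#' @export
tsls <- function(data, instrument_set = NULL, exposure_override = NULL) {
  g <- centered_genotypes(data, instrument_set)
  if (ncol(g) == 0L) stop("no instrument: empty instrument set")
  if (is.null(exposure_override)) {
    fit <- iv_fit(data$outcome, data$exposure, g)
    causal_estimate("2SLS", fit$estimate, fit$se)
  } else {
    xt <- as.numeric(exposure_override)
    if (length(xt) != length(data$outcome))
      stop("exposure_override must have length N")
    sxx <- sum(xt^2)
    if (sxx == 0) stop("degenerate override: zero variance")
    est <- sum(xt * data$outcome) / sxx
    resid <- data$outcome - est * data$exposure
    se <- sqrt(sum(resid^2) / (length(xt) - 2) / sxx)
    causal_estimate("2SLS", est, se)
  }
}

#' Limited-information maximum likelihood (LIML) estimator
#'
#' The k-class estimator with k equal to the smallest eigenvalue of the
#' generalized eigenproblem comparing total and instrument-orthogonal
#' cross-products of (outcome, exposure); less biased than 2SLS under many
#' weak instruments. One-sample only: with external first-stage weights
#' there is no many-weak-instrument problem for LIML to fix, and the
#' likelihood it maximizes is not defined.
#'
#' @inheritParams tsls
#' @param two_sample requesting `TRUE` is an error (unsupported mode).
#' @return A [causal_estimate()] labelled `"LIML"` with the k value in
#'   `extras$k`.
#' @export
liml <- function(data, instrument_set = NULL, two_sample = FALSE) {
  if (isTRUE(two_sample))
    stop("unsupported mode: LIML is defined here for one-sample analyses only")
  g <- centered_genotypes(data, instrument_set)
  if (ncol(g) == 0L) stop("no instrument: empty instrument set")
  y <- data$outcome
  x <- data$exposure
  q <- qr(g)
  if (q$rank < ncol(g))
    stop("singular design: instrument matrix is rank deficient")
  w <- cbind(y, x)
  wpw <- crossprod(w)                       # W'W
  wfit <- qr.fitted(q, w)
  wmw <- wpw - crossprod(w, wfit)           # W' M_Z W
  k <- min(Re(eigen(solve(wmw, wpw), only.values = TRUE)$values))
  # k-class moments: X'(I - k M_Z)X and X'(I - k M_Z)Y
  xmx <- wmw[2, 2]; xmy <- wmw[2, 1]
  sxx <- wpw[2, 2] - k * xmx
  sxy <- wpw[2, 1] - k * xmy
  est <- sxy / sxx
  resid <- y - est * x
  sigma2 <- sum(resid^2) / (length(y) - 2)
  causal_estimate("LIML", est, sqrt(sigma2 / sxx), extras = list(k = k))
}

#' Two-sided Wald test for a causal estimate
#'
#' @param est a [causal_estimate()] with a standard error.
#' @param null_value the null value of the causal effect (default 0).
#' @param level test size (default 0.05).
#' @return A list with the z statistic, two-sided p-value and the rejection
#'   indicator at `level`.
#' @export
wald_test <- function(est, null_value = 0, level = 0.05) {
  if (is.null(est$se) || is.na(est$se))
    stop("no standard error available for a Wald test")
  z <- (est$estimate - null_value) / est$se
  p <- 2 * stats::pnorm(-abs(z))
  # 1.96 (not qnorm) at the 5% level, matching the CI convention
  crit <- if (level == 0.05) 1.96 else stats::qnorm(1 - level / 2)
  list(z = z, pvalue = p, reject = abs(z) > crit)
}
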