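#' Weighted MR-Egger regression with intercept (pleiotropy) test
#'
#' Regresses the SNP-outcome coefficients on the SNP-exposure coefficients
#' with an intercept. Under the InSIDE condition the slope estimates the
#' causal effect and the intercept estimates the average pleiotropic effect;
#' a nonzero intercept is evidence that not all SNPs are valid instruments
#' (the "Egger test").
#'
#' Default weights are the inverse squared standard errors of the
#' SNP-outcome coefficients, `1/se_gamma^2`, the standard weighted-Egger
#' choice: it embeds both the residual variance of the outcome regression
#' and the genotype variance, so SNPs with low minor-allele frequency
#' contribute little. A literal residual-variance weighting can be supplied
#' through `weights`.
#'
#' @param summary a [snp_summary()]; `b_hat` holds in-sample or external
#'   SNP-exposure associations depending on the strategy.
#' @param weighted use weighted least squares (default) or an unweighted fit.
#' @param weights optional explicit positive weights overriding the default.
#' @return An object of class `egger_fit` with elements `slope`,
#'   `intercept`, `se_slope`, `se_intercept`, `intercept_pvalue` (two-sided
#'   t-test, J - 2 df) and `weights`.
#' @export
mr_egger <- function(summary, weighted = TRUE, weights = NULL) {
  j <- nrow(summary)
  if (j < 3L)
    stop("insufficient SNPs: MR-Egger needs at least 3 (slope, intercept, residual df)")
  b <- summary$b_hat
  if (max(b) - min(b) == 0)
    stop("degenerate regressor: no spread in the SNP-exposure coefficients")
  w <- if (!is.null(weights)) {
    if (any(weights <= 0)) stop("weights must be strictly positive")
    weights
  } else if (weighted) 1 / summary$se_gamma^2 else rep(1, j)
  fit <- stats::lm(gamma_hat ~ b_hat, data = summary, weights = w)
  cf <- summary(fit)$coefficients
  structure(list(slope = cf["b_hat", "Estimate"],
                 intercept = cf["(Intercept)", "Estimate"],
                 se_slope = cf["b_hat", "Std. Error"],
                 se_intercept = cf["(Intercept)", "Std. Error"],
                 intercept_pvalue = cf["(Intercept)", "Pr(>|t|)"],
                 weights = w, n_snps = j),
            class = "egger_fit")
}

#' @export
print.egger_fit <- function(x, ...) {
  cat(sprintf("<egger_fit> slope %.4f (se %.4f); intercept %.4f (se %.4f, p = %.3f)\n",
              x$slope, x$se_slope, x$intercept, x$se_intercept,
              x$intercept_pvalue))
  invisible(x)
}

#' Convert an MR-Egger fit to a causal-estimate record
#'
#' @param fit an `egger_fit`.
#' @return A [causal_estimate()] for the slope, carrying the intercept and
#'   its test in `intercept` / `extras`.
#' @export
egger_estimate <- function(fit) {
  causal_estimate("MR-Egger", fit$slope, fit$se_slope,
                  intercept = fit$intercept,
                  extras = list(se_intercept = fit$se_intercept,
                                intercept_pvalue = fit$intercept_pvalue))
}

# Weighted 50th percentile of ordered ratios with linear interpolation of
# the standardized weighted CDF evaluated at the midpoints (Bowden's
# weighted-median construction; equal weights reproduce the sample median).
weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  cw <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= cw[1L]) return(r[1L])
  if (0.5 >= cw[length(cw)]) return(r[length(r)])
  stats::approx(cw, r, xout = 0.5, ties = "ordered")$y
}

#' MR-Median estimator of the causal effect
#'
#' The (weighted) median of the per-SNP ratio estimates. The simple form is
#' consistent when more than half of the SNPs are valid instruments (the
#' majority rule) and requires no InSIDE-type condition. The weighted form
#' uses inverse-variance weights `b_hat^2 / se_gamma^2`, the first-order
#' precision of each ratio. Standard errors come from a parametric
#' bootstrap: the SNP-outcome coefficients (and, when their standard errors
#' are nonzero, the SNP-exposure coefficients) are redrawn from normal
#' distributions centred on the estimates, and the bootstrap SD of the
#' median is reported.
#'
#' @param summary a [snp_summary()].
#' @param weighted weighted (`TRUE`) or simple (`FALSE`) median.
#' @param n_boot number of parametric bootstrap draws for the SE (0 for no
#'   SE).
#' @param seed integer seed for the bootstrap draws.
#' @return A [causal_estimate()] labelled `"MR-Median"` or
#'   `"Weighted MR-Median"`.
#' @export
mr_median <- function(summary, weighted = FALSE, n_boot = 1000, seed = 1) {
  if (any(summary$b_hat == 0))
    stop("division by zero in ratio for SNP: ",
         paste(summary$snp[summary$b_hat == 0], collapse = ", "))
  point <- function(gam, b) {
    r <- gam / b
    if (weighted) weighted_median(r, b^2 / summary$se_gamma^2)
    else stats::median(r)
  }
  est <- point(summary$gamma_hat, summary$b_hat)
  se <- NA_real_
  if (n_boot >= 1) {
    j <- nrow(summary)
    boots <- withr_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        gam <- stats::rnorm(j, summary$gamma_hat, summary$se_gamma)
        b <- summary$b_hat + ifelse(summary$se_b > 0,
                                    stats::rnorm(j, 0, summary$se_b), 0)
        b[b == 0] <- .Machine$double.eps
        point(gam, b)
      }, numeric(1))
    })
    se <- stats::sd(boots)
  }
  causal_estimate(if (weighted) "Weighted MR-Median" else "MR-Median",
                  est, se)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Shared preparation for the penalized IV problem. Profiling the causal
# slope out of
#   0.5 || P_Z (y - gamma x - Z pi) ||^2 + lambda ||pi||_1
# leaves a lasso in pi on the instrument-projected variables:
#   ytil = M_xhat P_Z y,  Ztil = M_xhat Z,  xhat = P_Z x,
# and gamma(pi) = (x' P_Z y - (Z' x)' pi) / (x' P_Z x). Everything needed is
# expressible through the cross-products Z'Z, Z'y, Z'x.
sisvive_gram <- function(y, x, z) {
  a <- crossprod(z)
  q <- qr(a)
  if (q$rank < ncol(a))
    stop("singular design: instrument matrix is rank deficient")
  zy <- as.numeric(crossprod(z, y))
  zx <- as.numeric(crossprod(z, x))
  ai_zx <- solve(q, zx)
  xpx <- sum(zx * ai_zx)               # x' P_Z x
  if (xpx <= 0) stop("singular design: projected exposure has no variation")
  xpy <- sum(ai_zx * zy)               # x' P_Z y
  list(A = a, zy = zy, zx = zx, xpx = xpx, xpy = xpy,
       gram = a - tcrossprod(zx) / xpx,      # Ztil' Ztil
       cvec = zy - zx * (xpy / xpx),         # Ztil' ytil
       n = nrow(z))
}

sisvive_solve <- function(gm, lambda_grid, tol_scale = 1e-7) {
  lmax <- max(abs(gm$cvec))
  tol <- tol_scale * max(lmax, 1)
  pi_path <- .lasso_gram_path(gm$gram, gm$cvec, lambda_grid, tol, 20000L)
  gamma_path <- as.numeric(gm$xpy - crossprod(pi_path, gm$zx)) / gm$xpx
  list(pi_path = t(pi_path), gamma_path = gamma_path, lambda_max = lmax)
}

default_lambda_grid <- function(lambda_max, n_lambda = 100,
                                lambda_min_ratio = 1e-3) {
  g <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
               length.out = n_lambda))
  g[1L] <- lambda_max  # exact, so the top of the path is exactly all-zero
  g
}

#' sisVIVE solution path over a penalty grid
#'
#' Solves the L1-penalized instrumental-variable problem of the "some
#' invalid, some valid IV estimator": outcome residuals are projected onto
#' the instruments and per-SNP direct-effect terms are penalized so that
#' SNPs whose term is shrunk exactly to zero are classed as valid
#' instruments. For each penalty the exact minimizer is computed by
#' profiling out the causal slope (closed form given the direct effects)
#' and solving the remaining lasso by coordinate descent with a KKT
#' stopping rule. At or above the largest data-driven penalty the solution
#' has all direct effects zero and the slope equals 2SLS.
#'
#' @param data a prepared [study_data()].
#' @param lambda_grid optional decreasing positive penalty grid; by default
#'   100 geometric points from the smallest penalty with an all-zero
#'   solution down by a factor of 1e-3.
#' @param exposure_override optional predicted exposure for the two-sample
#'   pathway (e.g. the allele score under external association estimates).
#' @param n_lambda,lambda_min_ratio grid shape when `lambda_grid` is `NULL`.
#' @return An object of class `sisvive_result` with the grid, the matrix of
#'   penalized direct effects (`pi_path`, one row per penalty), the slope
#'   path (`gamma_path`), and `lambda_max`. Cross-validation fields are
#'   filled by [sisvive()].
#' @export
sisvive_path <- function(data, lambda_grid = NULL, exposure_override = NULL,
                         n_lambda = 100, lambda_min_ratio = 1e-3) {
  z <- centered_genotypes(data)
  x <- if (is.null(exposure_override)) data$exposure
       else as.numeric(exposure_override)
  gm <- sisvive_gram(data$outcome, x, z)
  if (is.null(lambda_grid)) {
    lambda_grid <- default_lambda_grid(max(abs(gm$cvec)), n_lambda,
                                       lambda_min_ratio)
  } else {
    if (any(lambda_grid <= 0) || any(diff(lambda_grid) >= 0))
      stop("grid error: lambda_grid must be positive and strictly decreasing")
  }
  sol <- sisvive_solve(gm, lambda_grid)
  structure(list(snp_ids = data$panel$snp_ids, lambda_grid = lambda_grid,
                 pi_path = sol$pi_path, gamma_path = sol$gamma_path,
                 lambda_max = sol$lambda_max,
                 cv_errors = NULL, cv_se = NULL, lambda_min = NA_real_,
                 lambda_1se = NA_real_, chosen = NA_integer_,
                 valid_set = NULL, estimate = NA_real_),
            class = "sisvive_result")
}

#' sisVIVE with cross-validated penalty and the one-standard-error rule
#'
#' Runs [sisvive_path()] on the full sample, then K-fold cross-validation
#' of the projected prediction error over the same penalty grid: for each
#' held-out fold the residual `y - gamma x - Z pi` is projected onto the
#' fold's instruments and its mean squared projection is the fold error.
#' `lambda_min` minimizes the mean CV error; the reported solution uses
#' `lambda_1se`, the largest penalty whose mean CV error is within one
#' standard error (across folds) of the minimum — the conservative side,
#' flagging fewer SNPs as invalid and reducing the chance of classing an
#' invalid instrument as valid. SNPs with a zero direct-effect term at the
#' chosen penalty form the selected valid set. No standard error is
#' attached to the sisVIVE estimate itself.
#'
#' @inheritParams sisvive_path
#' @param k_folds number of CV folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @param zero_tol absolute threshold under which a penalized coefficient
#'   counts as zero (guards round-off only; coordinate-descent solutions
#'   are exactly sparse).
#' @param cv_error held-out error definition: `"projected"` scores the
#'   instrument-projected residual (consistent with the objective being
#'   cross-validated), `"raw"` the plain residual `y - gamma x - Z pi`.
#' @param one_se direction of the one-standard-error rule relative to the
#'   CV minimum: `"above"` (default) picks the largest penalty whose mean
#'   CV error is within one SE of the minimum; `"below"` picks the
#'   smallest such penalty (treating fewer SNPs as valid); `"none"` uses
#'   the CV minimum itself.
#' @return A `sisvive_result` with CV fields, the selected `valid_set` and
#'   the point `estimate` at `lambda_1se`.
#' @export
sisvive <- function(data, k_folds = 10, seed = 1, exposure_override = NULL,
                    lambda_grid = NULL, n_lambda = 100,
                    lambda_min_ratio = 1e-3, zero_tol = 1e-8,
                    cv_error = c("projected", "raw"),
                    one_se = c("above", "below", "none")) {
  cv_error <- match.arg(cv_error)
  one_se <- match.arg(one_se)
  if (k_folds < 2) stop("k_folds must be at least 2")
  n <- length(data$outcome)
  if (n < 10 * k_folds)
    stop("sample too small for ", k_folds, "-fold cross-validation")
  res <- sisvive_path(data, lambda_grid, exposure_override, n_lambda,
                      lambda_min_ratio)
  grid <- res$lambda_grid
  z <- centered_genotypes(data)
  x <- if (is.null(exposure_override)) data$exposure
       else as.numeric(exposure_override)
  y <- data$outcome
  folds <- withr_seed(seed, sample(rep(seq_len(k_folds), length.out = n)))
  fold_err <- matrix(NA_real_, k_folds, length(grid))
  for (k in seq_len(k_folds)) {
    te <- folds == k
    gm_tr <- sisvive_gram(y[!te], x[!te], z[!te, , drop = FALSE])
    sol <- sisvive_solve(gm_tr, grid)
    # held-out projected residual: r = Z_te'(y - gamma x - Z pi),
    # error = r' (Z_te'Z_te)^{-1} r / n_te  (= mean of squared projections)
    zte <- z[te, , drop = FALSE]
    if (cv_error == "projected") {
      a_te <- crossprod(zte)
      r <- outer(as.numeric(crossprod(zte, y[te])), rep(1, length(grid))) -
        outer(as.numeric(crossprod(zte, x[te])), sol$gamma_path) -
        a_te %*% t(sol$pi_path)
      fold_err[k, ] <- colSums(r * solve(a_te, r)) / sum(te)
    } else {
      r <- outer(y[te], rep(1, length(grid))) -
        outer(x[te], sol$gamma_path) - zte %*% t(sol$pi_path)
      fold_err[k, ] <- colMeans(r^2)
    }
  }
  res$cv_errors <- colMeans(fold_err)
  res$cv_se <- apply(fold_err, 2L, stats::sd) / sqrt(k_folds)
  imin <- which.min(res$cv_errors)
  res$lambda_min <- grid[imin]
  cutoff <- res$cv_errors[imin] + res$cv_se[imin]
  # grid is decreasing: "above" = smallest index within the cutoff,
  # "below" = largest index within the cutoff at or past the minimum
  within <- which(res$cv_errors <= cutoff)
  i1se <- switch(one_se,
                 none = imin,
                 above = min(within),
                 below = max(within[within >= imin]))
  res$lambda_1se <- grid[i1se]
  res$chosen <- i1se
  res$valid_set <- res$snp_ids[abs(res$pi_path[i1se, ]) < zero_tol]
  res$estimate <- res$gamma_path[i1se]
  res$folds <- folds
  res
}

#' @export
print.sisvive_result <- function(x, ...) {
  cat(sprintf("<sisvive_result> %d SNPs, %d penalties (lambda_max %.4g)\n",
              length(x$snp_ids), length(x$lambda_grid), x$lambda_max))
  if (!is.na(x$chosen))
    cat(sprintf("  chosen lambda (1-SE rule) %.4g; %d SNPs selected valid; estimate %.4f\n",
                x$lambda_1se, length(x$valid_set), x$estimate))
  invisible(x)
}

#' Convert a tuned sisVIVE result to a causal-estimate record
#'
#' @param result a cross-validated `sisvive_result`.
#' @return A [causal_estimate()] labelled `"sisVIVE"`; no standard error is
#'   reported for the penalized estimate.
#' @export
sisvive_estimate <- function(result) {
  if (is.na(result$chosen)) stop("run sisvive() to choose a penalty first")
  causal_estimate("sisVIVE", result$estimate, NA_real_,
                  valid_set = result$valid_set,
                  extras = list(lambda = result$lambda_1se))
}

#' Post-selection re-estimation using the sisVIVE valid set
#'
#' Re-runs a valid-instrument estimator using only the SNPs that sisVIVE
#' classed as valid, removing the shrinkage bias of the penalized slope
#' (the post-lasso idea). Downstream choices: simple score (`"sprs"`),
#' internally weighted score (`"iprs"`), externally weighted score
#' (`"eprs"`), or multiple-instrument 2SLS (`"tsls"`, two-sample when
#' `external_betas` is supplied).
#'
#' @param data a prepared [study_data()].
#' @param result a cross-validated `sisvive_result` with a nonempty valid
#'   set.
#' @param downstream which valid-IV estimator to re-run.
#' @param external_betas named vector of external SNP-exposure associations
#'   (required for `"eprs"`; switches `"tsls"` to its two-sample form).
#' @return A [causal_estimate()] labelled `"sisVIVE-<downstream>"`.
#' @export
post_sisvive <- function(data, result,
                         downstream = c("sprs", "iprs", "eprs", "tsls"),
                         external_betas = NULL) {
  downstream <- match.arg(downstream)
  v <- result$valid_set
  if (is.null(v) || length(v) == 0L)
    stop("no valid instrument: sisVIVE selected an empty valid set")
  ext <- NULL
  if (!is.null(external_betas)) {
    if (is.null(names(external_betas)))
      stop("external_betas must be named by SNP id")
    ext <- external_betas[v]
    if (anyNA(ext)) stop("external_betas missing for selected SNPs")
  }
  est <- switch(downstream,
    sprs = prs_estimate(data, prs_weights("SPRS"), snps = v),
    iprs = prs_estimate(data, prs_weights("IPRS"), snps = v),
    eprs = {
      if (is.null(ext)) stop("EPRS requires external_betas")
      prs_estimate(data, prs_weights("EPRS", ext), snps = v)
    },
    tsls = {
      if (is.null(ext)) tsls(data, instrument_set = v)
      else {
        xt <- as.numeric(centered_genotypes(data, v) %*% ext)
        tsls(data, instrument_set = v, exposure_override = xt)
      }
    })
  est$method <- paste0("sisVIVE-", toupper(est$method))
  est$valid_set <- v
  est
}
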