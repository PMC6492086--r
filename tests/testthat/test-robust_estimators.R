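test_that("MR-Egger recovers an exact line and matches a normal-equations solve", {
  b <- c(0.1, 0.2, 0.35, 0.5, 0.8)
  gam <- 0.1 + 0.3 * b
  s <- snp_summary(paste0("s", 1:5), gam, rep(0.05, 5), b, rep(0.01, 5))
  fit <- suppressWarnings(  # perfect fit makes lm warn about its SEs
    mr_egger(s, weighted = TRUE, weights = c(1, 2, 0.5, 4, 1)))
  expect_equal(fit$intercept, 0.1, tolerance = 1e-10)
  expect_equal(fit$slope, 0.3, tolerance = 1e-10)

  set.seed(77)
  s2 <- snp_summary(paste0("s", 1:20), rnorm(20), runif(20, 0.02, 0.2),
                    runif(20, 0.05, 0.6), runif(20, 0.01, 0.05))
  w <- 1 / s2$se_gamma^2
  fit2 <- mr_egger(s2, weighted = TRUE)
  xm <- cbind(1, s2$b_hat)
  oracle <- solve(t(xm) %*% (w * xm), t(xm) %*% (w * s2$gamma_hat))
  expect_equal(fit2$intercept, oracle[1], tolerance = 1e-10)
  expect_equal(fit2$slope, oracle[2], tolerance = 1e-10)
})

test_that("unweighted MR-Egger reduces to OLS of the summary coefficients", {
  set.seed(8)
  s <- snp_summary(paste0("s", 1:10), rnorm(10), runif(10, .02, .1),
                   runif(10, .1, .5), runif(10, .01, .03))
  fit <- mr_egger(s, weighted = FALSE)
  ols <- coef(lm(gamma_hat ~ b_hat, data = s))
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-12)
  expect_equal(fit$slope, unname(ols[2]), tolerance = 1e-12)
})

test_that("MR-Egger guards insufficient or degenerate summaries", {
  s <- snp_summary(c("a", "b"), c(1, 2), c(.1, .1), c(1, 2), c(.1, .1))
  expect_error(mr_egger(s), "insufficient SNPs")
  s2 <- snp_summary(c("a", "b", "c"), 1:3, rep(.1, 3), rep(0.3, 3),
                    rep(.1, 3))
  expect_error(mr_egger(s2), "degenerate regressor")
})

test_that("Egger intercept is null when all instruments are valid", {
  fx <- fixture_cohort(n = 10000, j = 30, s = 0, seed = 311, f_target = 10,
                       accuracy = "true")
  s1 <- snp_summaries(fx$data)
  bt <- gen_external_betas(fx$effects, "true")
  s <- snp_summary(s1$snp, s1$gamma_hat, s1$se_gamma, bt,
                   rep(0, length(bt)), source = "two-sample")
  fit <- mr_egger(s)
  expect_lt(abs(fit$intercept), 3 * fit$se_intercept)
  expect_gt(fit$intercept_pvalue, 0.001)
})

test_that("MR-Median point estimates follow the standard median conventions", {
  mk <- function(r) snp_summary(paste0("s", seq_along(r)), r, rep(.1,
    length(r)), rep(1, length(r)), rep(.1, length(r)))
  expect_equal(mr_median(mk(c(1, 2, 3)), n_boot = 0)$estimate, 2)
  expect_equal(mr_median(mk(c(1, 2, 3, 4)), n_boot = 0)$estimate, 2.5)
  # equal weights: weighted median equals the simple median
  expect_equal(mr_median(mk(c(1, 4, 2, 9, 3)), weighted = TRUE,
                         n_boot = 0)$estimate, 3)
  expect_equal(mr_median(mk(c(5, 1, 4, 2)), weighted = TRUE,
                         n_boot = 0)$estimate, 3)
  s0 <- snp_summary(c("a", "b"), c(1, 1), c(.1, .1), c(0, 1), c(.1, .1))
  expect_error(mr_median(s0, n_boot = 0), "division by zero.*a")
})

test_that("MR-Median is permutation invariant and monotone in each ratio", {
  set.seed(12)
  gam <- rnorm(9); b <- runif(9, 0.2, 1); seg <- runif(9, .05, .2)
  s <- snp_summary(paste0("s", 1:9), gam, seg, b, rep(.01, 9))
  perm <- sample(9)
  sp <- snp_summary(paste0("s", 1:9), gam[perm], seg[perm], b[perm],
                    rep(.01, 9))
  for (wt in c(FALSE, TRUE))
    expect_equal(mr_median(sp, weighted = wt, n_boot = 0)$estimate,
                 mr_median(s, weighted = wt, n_boot = 0)$estimate)
  # raising any single ratio never lowers the weighted median
  base <- mr_median(s, weighted = TRUE, n_boot = 0)$estimate
  for (j in 1:9) {
    g2 <- gam; g2[j] <- g2[j] + abs(b[j])  # ratio_j increases by 1
    s2 <- snp_summary(paste0("s", 1:9), g2, seg, b, rep(.01, 9))
    expect_gte(mr_median(s2, weighted = TRUE, n_boot = 0)$estimate, base)
  }
})

test_that("MR-Median bootstrap SE is seed-reproducible", {
  set.seed(3)
  s <- snp_summary(paste0("s", 1:12), rnorm(12), runif(12, .05, .2),
                   runif(12, .2, .8), runif(12, .01, .05))
  a <- mr_median(s, weighted = TRUE, n_boot = 200, seed = 9)
  b <- mr_median(s, weighted = TRUE, n_boot = 200, seed = 9)
  expect_identical(a$se, b$se)
  expect_true(is.finite(a$se) && a$se > 0)
})

test_that("penalized path hits the 2SLS endpoint and saturates at small penalties", {
  fx <- fixture_cohort(n = 400, j = 6, s = 2, scenario = 2, seed = 41)
  res <- sisvive_path(fx$data)
  t2 <- tsls(fx$data)$estimate
  # at the top of the grid (lambda = lambda_max) everything is zero
  expect_true(all(res$pi_path[1, ] == 0))
  expect_equal(res$gamma_path[1], t2, tolerance = 1e-8)
  big <- sisvive_path(fx$data, lambda_grid = c(10, 5) * res$lambda_max)
  expect_true(all(big$pi_path == 0))
  expect_equal(big$gamma_path, rep(t2, 2), tolerance = 1e-8)
  # unpenalized limit: the profiled problem saturates (J or J-1 nonzeros)
  expect_gte(sum(res$pi_path[nrow(res$pi_path), ] != 0), ncol(res$pi_path) - 1)
})

test_that("KKT subgradient conditions hold at every grid penalty", {
  fx <- fixture_cohort(n = 500, j = 10, s = 4, scenario = 2, seed = 43)
  res <- sisvive_path(fx$data)
  z <- fx$data$g_centered
  x <- fx$data$exposure
  y <- fx$data$outcome
  # rebuild the profiled-lasso gradient independently and densely
  q <- qr(z)
  xhat <- qr.fitted(q, x)
  mz <- function(v) v - xhat * sum(xhat * v) / sum(xhat^2)
  ytil <- mz(qr.fitted(q, y))
  ztil <- apply(z, 2, mz)
  viol <- vapply(seq_along(res$lambda_grid), function(l) {
    pi <- res$pi_path[l, ]
    grad <- as.numeric(crossprod(ztil, ytil - ztil %*% pi))
    lam <- res$lambda_grid[l]
    max(ifelse(pi != 0, abs(grad - lam * sign(pi)),
               pmax(abs(grad) - lam, 0)))
  }, numeric(1))
  expect_lt(max(viol) / res$lambda_max, 1e-6)
})

test_that("path solutions beat brute-force candidates on a small instance", {
  fx <- fixture_cohort(n = 50, j = 6, s = 2, scenario = 2, seed = 47,
                       f_target = 4)
  res <- sisvive_path(fx$data, n_lambda = 12)
  z <- fx$data$g_centered
  x <- fx$data$exposure
  y <- fx$data$outcome
  set.seed(99)
  for (l in c(1, 6, 12)) {
    lam <- res$lambda_grid[l]
    obj_hat <- sisvive_objective(y, x, z, res$gamma_path[l],
                                 res$pi_path[l, ], lam)
    # 2SLS corner
    expect_lte(obj_hat,
               sisvive_objective(y, x, z, tsls(fx$data)$estimate,
                                 rep(0, 6), lam) + 1e-9)
    cands <- replicate(1000, {
      gam <- res$gamma_path[l] + rnorm(1, 0, 0.5)
      pi <- res$pi_path[l, ] + rnorm(6, 0, 0.3) *
        rbinom(6, 1, 0.5)
      sisvive_objective(y, x, z, gam, pi, lam)
    })
    expect_lte(obj_hat, min(cands) + 1e-9)
  }
})

test_that("profiled lasso agrees with an independent solver on transformed data", {
  skip_if_not_installed("glmnet")
  fx <- fixture_cohort(n = 300, j = 8, s = 3, scenario = 2, seed = 53)
  res <- sisvive_path(fx$data, n_lambda = 20)
  z <- fx$data$g_centered
  q <- qr(z)
  xhat <- qr.fitted(q, fx$data$exposure)
  mz <- function(v) v - xhat * sum(xhat * v) / sum(xhat^2)
  ytil <- mz(qr.fitted(q, fx$data$outcome))
  ztil <- apply(z, 2, mz)
  n <- length(ytil)
  gfit <- glmnet::glmnet(ztil, ytil, lambda = res$lambda_grid / n,
                         standardize = FALSE, intercept = FALSE,
                         thresh = 1e-14)
  expect_equal(unname(as.matrix(gfit$beta)), unname(t(res$pi_path)),
               tolerance = 1e-6)
})

test_that("cross-validated sisVIVE is deterministic and ordered in its penalties", {
  fx <- fixture_cohort(n = 600, j = 8, s = 3, scenario = 2, seed = 59)
  a <- sisvive(fx$data, k_folds = 5, seed = 21)
  b <- sisvive(fx$data, k_folds = 5, seed = 21)
  expect_identical(a$valid_set, b$valid_set)
  expect_identical(a$estimate, b$estimate)
  expect_gte(a$lambda_1se, a$lambda_min)
  expect_length(a$cv_errors, length(a$lambda_grid))
  expect_true(all(a$valid_set %in% fx$effects$snp_ids))
  # a different fold seed may move the choice but stays on the grid
  expect_true(sisvive(fx$data, k_folds = 5, seed = 22)$lambda_1se %in%
                a$lambda_grid)
})

test_that("post-selection re-estimation reduces to the downstream estimator", {
  fx <- fixture_cohort(n = 600, j = 6, s = 0, seed = 61)
  res <- sisvive(fx$data, k_folds = 5, seed = 31)
  # force the full valid set: equivalent to the downstream fit on all SNPs
  res$valid_set <- fx$effects$snp_ids
  ps <- post_sisvive(fx$data, res, "sprs")
  expect_equal(ps$estimate,
               prs_estimate(fx$data, prs_weights("SPRS"))$estimate,
               tolerance = 1e-10)
  expect_equal(ps$method, "sisVIVE-SPRS")
  # single selected SNP with 2SLS downstream equals that SNP's ratio
  res$valid_set <- fx$effects$snp_ids[2]
  s <- snp_summaries(fx$data)
  expect_equal(post_sisvive(fx$data, res, "tsls")$estimate,
               s$gamma_hat[2] / s$b_hat[2], tolerance = 1e-9)
  res$valid_set <- character(0)
  expect_error(post_sisvive(fx$data, res, "sprs"), "no valid instrument")
})

test_that("two-sample pathway accepts a predicted exposure override", {
  fx <- fixture_cohort(n = 800, j = 6, s = 0, seed = 67, f_target = 20)
  bt <- gen_external_betas(fx$effects, "true")
  xt <- as.numeric(fx$data$g_centered %*% bt)
  res <- sisvive_path(fx$data, exposure_override = xt)
  t2 <- tsls(fx$data, exposure_override = xt)$estimate
  expect_equal(res$gamma_path[1], t2, tolerance = 1e-8)
  sv <- sisvive(fx$data, k_folds = 5, seed = 71, exposure_override = xt)
  expect_true(length(sv$valid_set) >= 1)
  ps <- post_sisvive(fx$data, sv, "eprs", external_betas = bt)
  expect_equal(ps$method, "sisVIVE-EPRS")
})
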