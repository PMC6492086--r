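#' Configuration for the Monte-Carlo simulation design
#'
#' Encodes a weak-instrument, many-SNP Mendelian randomization design:
#' independent trinomial genotypes, a shared standard-normal confounder
#' entering both exposure and outcome, a true causal effect of -0.2, and
#' three pleiotropy scenarios for the invalid SNPs:
#' \describe{
#'   \item{1}{balanced direct pleiotropy, direct effects
#'     `alpha ~ U(-0.2, 0.2)` (InSIDE holds);}
#'   \item{2}{unbalanced direct pleiotropy, `alpha ~ U(0, 0.2)`;}
#'   \item{3}{as 2 plus indirect pleiotropy through the confounder,
#'     `theta ~ U(0, 0.4)`, so the SNP-exposure association of an invalid
#'     SNP becomes `beta + theta` and InSIDE fails.}
#' }
#'
#' @param n_samples cohort size per replicate (default 10,000).
#' @param n_snps number of SNPs (default 71).
#' @param n_invalid number of pleiotropic SNPs S; must not exceed half the
#'   SNPs (the majority rule of the design).
#' @param scenario pleiotropy scenario, 1, 2 or 3.
#' @param gamma_x true causal exposure effect (default -0.2).
#' @param gamma_u confounder effect on the outcome (default 1).
#' @param accuracy `"one-sample"`, or the two-sample accuracy of the
#'   external SNP-exposure associations: `"true"` (exact), `"precise"`
#'   (N(b, 0.01^2)) or `"imprecise"` (N(b, 0.05^2)).
#' @param replicates Monte-Carlo replicates (default 1000).
#' @param master_seed master seed; every random stream in the experiment is
#'   derived deterministically from it.
#' @param effect_source `"synthetic"` or the path of a two-column
#'   (snp, beta) table of SNP-exposure effects.
#' @param f_target synthetic-mode calibration target for the theoretical
#'   average per-SNP first-stage F-statistic at `n_samples` (default 2.5,
#'   a deliberately weak-instrument regime).
#' @param eaf_range effect-allele frequency range for synthetic genotype
#'   frequencies (Hardy-Weinberg proportions).
#' @param invalid_choice which SNPs are made invalid: the S largest |beta|
#'   (default), a seeded random subset, or the first S.
#' @param n_boot bootstrap draws for MR-Median standard errors.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 10000, n_snps = 71, n_invalid = 0,
                       scenario = 1, gamma_x = -0.2, gamma_u = 1,
                       accuracy = c("one-sample", "true", "precise",
                                    "imprecise"),
                       replicates = 1000, master_seed = 1,
                       effect_source = "synthetic", f_target = 2.5,
                       eaf_range = c(0.1, 0.9),
                       invalid_choice = c("largest", "random", "first"),
                       n_boot = 1000) {
  accuracy <- match.arg(accuracy)
  invalid_choice <- match.arg(invalid_choice)
  if (!scenario %in% 1:3) stop("scenario must be 1, 2 or 3")
  if (n_invalid > n_snps / 2)
    stop("n_invalid must not exceed half the SNPs (majority rule)")
  alpha_range <- if (scenario == 1) c(-0.2, 0.2) else c(0, 0.2)
  theta_range <- if (scenario == 3) c(0, 0.4) else c(0, 0)
  structure(list(n_samples = n_samples, n_snps = n_snps,
                 n_invalid = n_invalid, scenario = scenario,
                 gamma_x = gamma_x, gamma_u = gamma_u,
                 alpha_range = alpha_range, theta_range = theta_range,
                 accuracy = accuracy, replicates = replicates,
                 master_seed = master_seed, effect_source = effect_source,
                 f_target = f_target, eaf_range = eaf_range,
                 invalid_choice = invalid_choice, n_boot = n_boot),
            class = "sim_config")
}

# Lehmer LCG step mod 2^31 - 1 (Schrage), exact in double arithmetic.
lcg_step <- function(s) {
  a <- 48271; m <- 2147483647
  q <- m %/% a; r <- m %% a
  s <- a * (s %% q) - r * (s %/% q)
  if (s <= 0) s + m else s
}

#' Derive a per-replicate stream seed from the master seed
#'
#' Counter-based: deterministic in (master seed, replicate index, stream id)
#' and independent of how many replicates are run or in what order, so
#' experiment output does not depend on parallelism.
#'
#' @param master_seed master integer seed.
#' @param index replicate index (0 for experiment-level streams).
#' @param stream small integer distinguishing random streams within a
#'   replicate.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, index, stream = 0) {
  m <- 2147483647
  s <- master_seed %% m
  if (s == 0) s <- 1
  for (v in c(index + 1, stream + 1)) {
    s <- (s + v) %% m
    if (s == 0) s <- 1
    s <- lcg_step(lcg_step(s))
  }
  as.integer(s)
}

#' Synthetic genotype-class frequencies under Hardy-Weinberg proportions
#'
#' Effect-allele frequencies are drawn uniformly on `eaf_range` and
#' converted to the (p0, p1, p2) trinomial class probabilities.
#'
#' @param n_snps number of SNPs.
#' @param seed integer seed.
#' @param eaf_range effect-allele frequency range.
#' @param snp_ids optional SNP identifiers (default `snp1..snpJ`).
#' @return A `J x 3` matrix with rows `(p0, p1, p2)`.
#' @export
synthetic_freqs <- function(n_snps, seed = 1, eaf_range = c(0.1, 0.9),
                            snp_ids = NULL) {
  f <- withr_seed(seed, stats::runif(n_snps, eaf_range[1], eaf_range[2]))
  fr <- cbind(p0 = (1 - f)^2, p1 = 2 * f * (1 - f), p2 = f^2)
  rownames(fr) <- if (is.null(snp_ids)) paste0("snp", seq_len(n_snps))
                  else snp_ids
  fr
}

# Genotype variance implied by trinomial class probabilities.
genotype_variance <- function(genotype_freqs) {
  m1 <- genotype_freqs[, 2] + 2 * genotype_freqs[, 3]
  genotype_freqs[, 2] + 4 * genotype_freqs[, 3] - m1^2
}

#' Theoretical per-SNP first-stage F-statistics
#'
#' Closed form for the expected single-SNP F-statistic of the exposure
#' regression at sample size `n_samples`, under the design's error structure
#' (`Var(exposure error) = error_var`, the confounder plus idiosyncratic
#' part): `F_j = 1 + n * beta_j^2 Var(G_j) / (Var(X) - beta_j^2 Var(G_j))`,
#' with `Var(X) = sum_k beta_k^2 Var(G_k) + error_var`. The `1 +` term is
#' the null expectation of the F statistic, so the average of these values
#' matches the average observed first-stage F in large samples.
#'
#' @param beta SNP-exposure effects.
#' @param genotype_freqs `J x 3` genotype-class probabilities.
#' @param n_samples sample size.
#' @param error_var variance of the non-genetic part of the exposure
#'   (default 2: unit-variance confounder plus unit-variance noise).
#' @return A length-J vector of theoretical F values.
#' @export
theoretical_first_stage_f <- function(beta, genotype_freqs, n_samples,
                                      error_var = 2) {
  vg <- genotype_variance(genotype_freqs)
  explained <- beta^2 * vg
  var_x <- sum(explained) + error_var
  1 + n_samples * explained / (var_x - explained)
}

#' SNP effect panel for one simulated experiment
#'
#' Builds the per-SNP causal exposure effects `beta` and the pleiotropy
#' parameters of the configured scenario. In synthetic mode, `beta`
#' magnitudes are drawn from a right-skewed Gamma(shape 4, mean 1) shape —
#' mimicking the skew of consortium-reported per-allele BMI effects — and
#' deterministically rescaled so the theoretical average first-stage
#' F-statistic ([theoretical_first_stage_f()]) at `n_samples` equals
#' `f_target`. In table mode, `beta` is read verbatim from a two-column
#' (snp, beta) file. Direct effects `alpha` (and, under scenario 3,
#' confounder effects `theta`) are drawn uniformly on the scenario's ranges
#' for the invalid SNPs and are zero elsewhere.
#'
#' @param config a [sim_config()].
#' @param genotype_freqs `J x 3` genotype-class probabilities (rownames used
#'   as SNP ids when present).
#' @param seed integer seed for the random draws.
#' @param beta optional fixed effect vector; when supplied only the
#'   pleiotropy parameters are (re)drawn, emulating fixed consortium values
#'   across replicates.
#' @return A list of class `effect_panel` with `snp_ids`, `beta`, `alpha`,
#'   `theta`, `invalid_ids` and `b_true = beta + theta`.
#' @export
make_effects <- function(config, genotype_freqs, seed = 1, beta = NULL) {
  j <- config$n_snps
  if (nrow(genotype_freqs) != j)
    stop("genotype_freqs rows must match n_snps")
  snp_ids <- rownames(genotype_freqs)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(j))
  if (is.null(beta)) {
    if (identical(config$effect_source, "synthetic")) {
      raw <- withr_seed(seed, stats::rgamma(j, shape = 4, rate = 4))
      vg <- genotype_variance(genotype_freqs)
      target <- config$f_target
      fbar <- function(scale) {
        mean(theoretical_first_stage_f(scale * raw, genotype_freqs,
                                       config$n_samples)) - target
      }
      scale <- stats::uniroot(fbar, c(1e-8, 10), tol = 1e-14)$root
      beta <- scale * raw
    } else {
      tab <- utils::read.table(config$effect_source, header = TRUE,
                               stringsAsFactors = FALSE)
      if (!all(c("snp", "beta") %in% names(tab)))
        stop("effect table must have columns snp, beta")
      if (nrow(tab) != j)
        stop("length error: effect table has ", nrow(tab),
             " rows but n_snps = ", j)
      snp_ids <- tab$snp
      beta <- tab$beta
    }
  }
  if (length(beta) != j) stop("length error: beta must have n_snps entries")
  s <- config$n_invalid
  invalid_idx <- switch(config$invalid_choice,
    largest = order(abs(beta), decreasing = TRUE)[seq_len(s)],
    random = withr_seed(seed + 1L, sample.int(j, s)),
    first = seq_len(s))
  alpha <- theta <- numeric(j)
  if (s > 0) {
    draws <- withr_seed(seed + 2L, list(
      a = stats::runif(s, config$alpha_range[1], config$alpha_range[2]),
      t = if (config$scenario == 3)
            stats::runif(s, config$theta_range[1], config$theta_range[2])
          else numeric(s)))
    alpha[invalid_idx] <- draws$a
    theta[invalid_idx] <- draws$t
  }
  structure(list(snp_ids = snp_ids, beta = beta, alpha = alpha,
                 theta = theta, invalid_ids = snp_ids[invalid_idx],
                 b_true = beta + theta),
            class = "effect_panel")
}

#' Draw independent trinomial genotypes
#'
#' Each SNP column is drawn independently from its (p0, p1, p2) class
#' probabilities; columns are mutually independent (the independence
#' assumption of the design: SNPs from distinct gene regions).
#'
#' @param config a [sim_config()] (supplies the sample size).
#' @param genotype_freqs `J x 3` class probabilities, rows summing to 1.
#' @param seed integer seed.
#' @return A [genotype_panel()] carrying the generating frequencies.
#' @export
gen_genotypes <- function(config, genotype_freqs, seed = 1) {
  if (any(genotype_freqs < 0) ||
      any(abs(rowSums(genotype_freqs) - 1) > 1e-12))
    stop("invalid frequencies: rows must be nonnegative and sum to 1")
  n <- config$n_samples
  j <- nrow(genotype_freqs)
  g <- withr_seed(seed, {
    u <- matrix(stats::runif(n * j), n, j)
    t0 <- matrix(genotype_freqs[, 1], n, j, byrow = TRUE)
    t1 <- t0 + matrix(genotype_freqs[, 2], n, j, byrow = TRUE)
    (u > t0) + (u > t1)
  })
  snp_ids <- rownames(genotype_freqs)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(j))
  colnames(g) <- snp_ids
  genotype_panel(g, snp_ids = snp_ids, genotype_freqs = genotype_freqs)
}

#' Generate one exposure/outcome cohort under the configured scenario
#'
#' Error structure: a shared standard-normal confounder U enters the
#' exposure with coefficient 1 and the outcome with coefficient `gamma_u`;
#' idiosyncratic standard-normal noise is added to each. Under scenarios 1
#' and 2 the exposure is `X = G beta + U + noise` and the outcome
#' `Y = gamma_x X + G alpha + gamma_u U + noise`. Under scenario 3 the
#' indirect pleiotropy is routed through the confounder: the invalid SNPs
#' shift U to `U' = G_S theta + U`, which makes the SNP-exposure association
#' of an invalid SNP `beta + theta` while contributing
#' `(alpha + theta * gamma_u) G` to the outcome — exactly the direct-plus-
#' indirect pleiotropy pattern of the design. The routing is pluggable via
#' `indirect_mechanism`.
#'
#' @param config a [sim_config()].
#' @param effects an [make_effects()] panel.
#' @param panel a [gen_genotypes()] panel.
#' @param seed integer seed for the error draws.
#' @param indirect_mechanism function `(u, g_invalid, theta_invalid)`
#'   returning the shifted confounder; the default implements the
#'   confounder route described above.
#' @return An unprepared [study_data()].
#' @export
gen_dataset <- function(config, effects, panel, seed = 1,
                        indirect_mechanism = NULL) {
  g <- panel$genotypes
  if (ncol(g) != length(effects$beta)) stop("dimension mismatch")
  n <- nrow(g)
  err <- withr_seed(seed, list(u = stats::rnorm(n), ex = stats::rnorm(n),
                               ey = stats::rnorm(n)))
  u <- err$u
  if (config$scenario == 3 && length(effects$invalid_ids)) {
    mech <- if (is.null(indirect_mechanism)) {
      function(u, g_inv, theta_inv) u + as.numeric(g_inv %*% theta_inv)
    } else indirect_mechanism
    inv <- effects$invalid_ids
    u <- mech(u, g[, inv, drop = FALSE],
              effects$theta[match(inv, effects$snp_ids)])
  }
  x <- as.numeric(g %*% effects$beta) + u + err$ex
  y <- config$gamma_x * x + as.numeric(g %*% effects$alpha) +
    config$gamma_u * u + err$ey
  study_data(exposure = x, outcome = y, panel = panel)
}

#' External (second-sample) SNP-exposure association estimates
#'
#' Emulates consortium-reported associations at three accuracy levels:
#' `"true"` returns the true associations exactly; `"precise"` adds
#' N(0, 0.01^2) noise; `"imprecise"` adds N(0, 0.05^2) noise. The noisy
#' levels represent graded failure of the no-measurement-error (NOME)
#' condition.
#'
#' @param effects an [make_effects()] panel.
#' @param accuracy `"true"`, `"precise"` or `"imprecise"`.
#' @param seed integer seed for the noise.
#' @param use_beta return values centred on the causal effects `beta`
#'   instead of the observed associations `b_true = beta + theta` (the
#'   "effects known" variant relevant under indirect pleiotropy).
#' @return A named length-J vector of external associations.
#' @export
gen_external_betas <- function(effects,
                               accuracy = c("true", "precise", "imprecise"),
                               seed = 1, use_beta = FALSE) {
  accuracy <- match.arg(accuracy)
  base <- if (use_beta) effects$beta else effects$b_true
  sdev <- c(true = 0, precise = 0.01, imprecise = 0.05)[[accuracy]]
  out <- if (sdev == 0) base
         else base + withr_seed(seed, stats::rnorm(length(base), 0, sdev))
  names(out) <- effects$snp_ids
  out
}

#' @rdname gen_external_betas
#' @export
external_beta_sd <- function(accuracy = c("true", "precise", "imprecise")) {
  c(true = 0, precise = 0.01, imprecise = 0.05)[[match.arg(accuracy)]]
}
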