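#' False-selection rates of an instrument-selection step
#'
#' FSI ("false select in") is the percentage of truly pleiotropic SNPs
#' incorrectly classed as valid instruments; FSO ("false select out") is the
#' percentage of truly valid SNPs incorrectly classed as invalid. FSI is
#' undefined (`NA`) when there are no invalid SNPs.
#'
#' @param true_invalid SNP ids of the truly pleiotropic SNPs.
#' @param selected_valid SNP ids the selection step classed as valid.
#' @param all_snps the full SNP id set.
#' @return A list with `fsi` and `fso`, both in percent.
#' @export
fsi_fso <- function(true_invalid, selected_valid, all_snps) {
  if (!all(true_invalid %in% all_snps) || !all(selected_valid %in% all_snps))
    stop("id error: selection sets must be subsets of all_snps")
  true_valid <- setdiff(all_snps, true_invalid)
  selected_invalid <- setdiff(all_snps, selected_valid)
  fsi <- if (length(true_invalid) == 0) NA_real_ else
    100 * length(intersect(true_invalid, selected_valid)) /
      length(true_invalid)
  fso <- if (length(true_valid) == 0) NA_real_ else
    100 * length(intersect(true_valid, selected_invalid)) /
      length(true_valid)
  list(fsi = fsi, fso = fso)
}

#' Summarize replicate estimates of a causal effect
#'
#' @param estimates a data frame with columns `estimate` and `se` (one row
#'   per replicate; `se` may be `NA` throughout for methods reporting no
#'   standard error), or a list of [causal_estimate()] objects.
#' @param true_gamma the true causal effect.
#' @param method optional label for the output row.
#' @return A one-row data frame with the mean and SD of the estimates, the
#'   mean standard error, the MSE (direct mean of squared errors), the
#'   coverage percentage of the nominal 95\% intervals, the power percentage
#'   against a zero effect at the two-sided 5\% level, and the replicate
#'   count. Coverage/power/mean SE are `NA` when no standard errors are
#'   available.
#' @export
summarize_estimates <- function(estimates, true_gamma, method = NA_character_) {
  if (!is.data.frame(estimates)) {
    method <- if (is.na(method) && length(estimates))
      estimates[[1]]$method else method
    estimates <- data.frame(
      estimate = vapply(estimates, `[[`, numeric(1), "estimate"),
      se = vapply(estimates, `[[`, numeric(1), "se"))
  }
  est <- estimates$estimate
  se <- estimates$se
  keep <- !is.na(est)
  est <- est[keep]; se <- se[keep]
  r <- length(est)
  if (r == 0) stop("no data: no successful replicates to summarize")
  have_se <- all(!is.na(se))
  cover <- if (have_se)
    100 * mean(true_gamma >= est - 1.96 * se &
               true_gamma <= est + 1.96 * se) else NA_real_
  power <- if (have_se) 100 * mean(abs(est) > 1.96 * se) else NA_real_
  data.frame(method = method, n_replicates = r,
             mean_estimate = mean(est),
             sd_estimate = if (r > 1) stats::sd(est) else NA_real_,
             mean_se = if (have_se) mean(se) else NA_real_,
             mse = mean((est - true_gamma)^2),
             coverage_pct = cover, power_pct = power,
             stringsAsFactors = FALSE)
}

method_label <- function(method, two_sample) {
  switch(method,
    sprs = "SPRS", iprs = "IPRS", eprs = "EPRS",
    tsls = "2SLS", liml = "LIML",
    egger = "Weighted MR-Egger",
    median = "MR-Median", wmedian = "Weighted MR-Median",
    sisvive = "sisVIVE",
    `sisvive-sprs` = "sisVIVE-SPRS", `sisvive-iprs` = "sisVIVE-IPRS",
    `sisvive-eprs` = "sisVIVE-EPRS", `sisvive-tsls` = "sisVIVE-2SLS",
    stop("unknown method: ", method))
}

known_methods <- function(two_sample) {
  if (two_sample)
    c("eprs", "sprs", "tsls", "egger", "median", "wmedian", "sisvive",
      "sisvive-sprs", "sisvive-eprs", "sisvive-tsls")
  else
    c("sprs", "iprs", "tsls", "liml", "egger", "median", "wmedian",
      "sisvive", "sisvive-sprs", "sisvive-iprs", "sisvive-tsls")
}

# One replicate of the experiment: generate, estimate with every requested
# method, and report the selection rates when sisVIVE ran.
run_replicate <- function(config, freqs, beta_fixed, r, methods) {
  ms <- config$master_seed
  two_sample <- config$accuracy != "one-sample"
  effects <- make_effects(config, freqs, seed = derive_seed(ms, r, 3),
                          beta = beta_fixed)
  panel <- gen_genotypes(config, freqs, seed = derive_seed(ms, r, 4))
  dat <- prepare_variables(
    gen_dataset(config, effects, panel, seed = derive_seed(ms, r, 5)))
  summ <- snp_summaries(dat)
  bt <- xt <- NULL
  if (two_sample) {
    bt <- gen_external_betas(effects, config$accuracy,
                             seed = derive_seed(ms, r, 6))
    xt <- as.numeric(centered_genotypes(dat) %*% bt)
    summ <- snp_summary(summ$snp, summ$gamma_hat, summ$se_gamma, bt,
                        rep(external_beta_sd(config$accuracy), length(bt)),
                        source = "two-sample")
  }
  sv <- NULL
  if (any(startsWith(methods, "sisvive")))
    sv <- sisvive(dat, k_folds = 10, seed = derive_seed(ms, r, 7),
                  exposure_override = xt)
  one <- function(m) {
    switch(m,
      sprs = prs_estimate(dat, prs_weights("SPRS")),
      iprs = prs_estimate(dat, prs_weights("IPRS")),
      eprs = prs_estimate(dat, prs_weights("EPRS", unname(bt))),
      tsls = tsls(dat, exposure_override = xt),
      liml = liml(dat),
      egger = egger_estimate(mr_egger(summ, weighted = TRUE)),
      median = mr_median(summ, weighted = FALSE, n_boot = config$n_boot,
                         seed = derive_seed(ms, r, 8)),
      wmedian = mr_median(summ, weighted = TRUE, n_boot = config$n_boot,
                          seed = derive_seed(ms, r, 9)),
      sisvive = sisvive_estimate(sv),
      `sisvive-sprs` = post_sisvive(dat, sv, "sprs"),
      `sisvive-iprs` = post_sisvive(dat, sv, "iprs"),
      `sisvive-eprs` = post_sisvive(dat, sv, "eprs", external_betas = bt),
      `sisvive-tsls` = post_sisvive(dat, sv, "tsls", external_betas = bt))
  }
  ests <- lapply(methods, function(m) {
    tryCatch(one(m), error = function(e) e)
  })
  names(ests) <- methods
  sel <- if (!is.null(sv))
    fsi_fso(effects$invalid_ids, sv$valid_set, effects$snp_ids)
  else list(fsi = NA_real_, fso = NA_real_)
  list(estimates = ests, fsi = sel$fsi, fso = sel$fso)
}

#' Run a full Monte-Carlo experiment
#'
#' For each replicate: draw genotypes and a confounded cohort under the
#' configured pleiotropy scenario, apply every requested estimator (under
#' the one- or two-sample strategy implied by `config$accuracy`), and
#' collect the estimates plus, when sisVIVE is among the methods, the
#' false-selection rates of its valid-instrument choice. The SNP-exposure
#' effects `beta` are drawn once and held fixed across replicates (as fixed
#' consortium values would be); the pleiotropy draws, genotypes, errors and
#' external associations are redrawn each replicate from seeds derived
#' deterministically from the master seed, so results are identical for any
#' degree of parallelism.
#'
#' @param config a [sim_config()].
#' @param methods character vector of method ids among `"sprs"`, `"iprs"`,
#'   `"eprs"`, `"tsls"`, `"liml"`, `"egger"`, `"median"`, `"wmedian"`,
#'   `"sisvive"`, `"sisvive-sprs"`, `"sisvive-iprs"`, `"sisvive-eprs"`,
#'   `"sisvive-tsls"` (availability depends on the strategy).
#' @param jobs number of worker processes (forked; 1 = serial).
#' @return A list of class `mr_experiment` with `summaries` (one row per
#'   method), `selection` (mean FSI/FSO percentages), `estimates` (the
#'   replicate-level long table), `failures` (per-method counts of excluded
#'   replicates, reported, never silently dropped) and the `config`.
#' @export
run_experiment <- function(config, methods, jobs = 1) {
  stopifnot(inherits(config, "sim_config"), length(methods) > 0)
  two_sample <- config$accuracy != "one-sample"
  bad <- setdiff(methods, known_methods(two_sample))
  if (length(bad))
    stop("method not available under the ", config$accuracy, " strategy: ",
         paste(bad, collapse = ", "))
  ms <- config$master_seed
  freqs <- synthetic_freqs(config$n_snps, seed = derive_seed(ms, 0, 1),
                           eaf_range = config$eaf_range)
  beta_fixed <- make_effects(config, freqs,
                             seed = derive_seed(ms, 0, 2))$beta
  reps <- seq_len(config$replicates)
  worker <- function(r) run_replicate(config, freqs, beta_fixed, r, methods)
  out <- if (jobs > 1) {
    parallel::mclapply(reps, worker, mc.cores = jobs, mc.preschedule = TRUE)
  } else lapply(reps, worker)
  long <- do.call(rbind, lapply(reps, function(r) {
    es <- out[[r]]$estimates
    data.frame(replicate = r, method = methods,
               estimate = vapply(es, function(e)
                 if (inherits(e, "error")) NA_real_ else e$estimate,
                 numeric(1)),
               se = vapply(es, function(e)
                 if (inherits(e, "error")) NA_real_ else e$se, numeric(1)),
               failed = vapply(es, inherits, logical(1), "error"),
               stringsAsFactors = FALSE)
  }))
  summaries <- do.call(rbind, lapply(methods, function(m) {
    rows <- long[long$method == m & !long$failed, c("estimate", "se")]
    s <- summarize_estimates(rows, config$gamma_x,
                             method = method_label(m, two_sample))
    s$excluded <- sum(long$method == m & long$failed)
    s
  }))
  fsi <- vapply(out, `[[`, numeric(1), "fsi")
  fso <- vapply(out, `[[`, numeric(1), "fso")
  structure(list(
    summaries = summaries,
    selection = list(mean_fsi_pct = mean(fsi, na.rm = TRUE),
                     mean_fso_pct = mean(fso, na.rm = TRUE),
                     sd_fsi_pct = stats::sd(fsi[!is.na(fsi)]),
                     sd_fso_pct = stats::sd(fso[!is.na(fso)]),
                     n_replicates = sum(!is.na(fso))),
    estimates = long,
    failures = stats::setNames(summaries$excluded, methods),
    config = config), class = "mr_experiment")
}

#' @export
print.mr_experiment <- function(x, ...) {
  cat(sprintf("<mr_experiment> scenario %d, S = %d invalid of %d SNPs, %s, %d replicates\n",
              x$config$scenario, x$config$n_invalid, x$config$n_snps,
              x$config$accuracy, x$config$replicates))
  print(render_tables(x, "table3"))
  if (!is.nan(x$selection$mean_fso_pct))
    cat(sprintf("sisVIVE selection: mean FSI %s, mean FSO %.1f%%\n",
                if (is.nan(x$selection$mean_fsi_pct)) "-" else
                  sprintf("%.1f%%", x$selection$mean_fsi_pct),
                x$selection$mean_fso_pct))
  invisible(x)
}

#' Render experiment results in the standard report layouts
#'
#' `"table3"` renders per-method performance (mean, SD, mean SE, MSE,
#' coverage, power); `"table2"` renders selection accuracy (mean FSI/FSO)
#' across scenario rows. Undefined cells (e.g. FSI with no invalid SNPs, or
#' standard-error columns for methods reporting none) render as "-". When
#' `path` is given a TSV with full-precision numbers is written alongside.
#'
#' @param x for `"table3"`, an `mr_experiment` or its `summaries` data
#'   frame; for `"table2"`, an `mr_experiment`, a list of them, or a data
#'   frame with columns `scenario`, `n_invalid`, `mfsi_pct`, `mfso_pct`.
#' @param layout `"table3"` or `"table2"`.
#' @param path optional TSV output path.
#' @return The formatted character data frame, invisibly when printing.
#' @export
render_tables <- function(x, layout = c("table3", "table2"), path = NULL) {
  layout <- match.arg(layout)
  if (layout == "table3") {
    df <- if (inherits(x, "mr_experiment")) x$summaries else x
    need <- c("method", "mean_estimate", "sd_estimate", "mean_se", "mse",
              "coverage_pct", "power_pct")
    if (!all(need %in% names(df)))
      stop("layout error: missing columns: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    raw <- df[, c(need, intersect("n_replicates", names(df)))]
    fmt <- data.frame(
      Method = df$method,
      `Mean (SD)` = sprintf("%.3f (%.3f)", df$mean_estimate,
                            df$sd_estimate),
      `Mean SE` = ifelse(is.na(df$mean_se), "-",
                         sprintf("%.3f", df$mean_se)),
      MSE = sprintf("%.3f", df$mse),
      `Coverage, %` = ifelse(is.na(df$coverage_pct), "-",
                             sprintf("%.1f", df$coverage_pct)),
      `Power, %` = ifelse(is.na(df$power_pct), "-",
                          sprintf("%.1f", df$power_pct)),
      check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- x
    if (inherits(df, "mr_experiment")) df <- list(df)
    if (is.list(df) && !is.data.frame(df) &&
        all(vapply(df, inherits, logical(1), "mr_experiment"))) {
      df <- do.call(rbind, lapply(df, function(e)
        data.frame(scenario = e$config$scenario,
                   n_invalid = e$config$n_invalid,
                   mfsi_pct = e$selection$mean_fsi_pct,
                   mfso_pct = e$selection$mean_fso_pct)))
    }
    need <- c("scenario", "n_invalid", "mfsi_pct", "mfso_pct")
    if (!is.data.frame(df) || !all(need %in% names(df)))
      stop("layout error: need columns ", paste(need, collapse = ", "))
    raw <- df[, need]
    fmt <- data.frame(
      Scenario = df$scenario, `No. invalid` = df$n_invalid,
      `MFSI, %` = ifelse(is.na(df$mfsi_pct) | is.nan(df$mfsi_pct), "-",
                         sprintf("%.1f", df$mfsi_pct)),
      `MFSO, %` = sprintf("%.1f", df$mfso_pct),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (!is.null(path)) {
    num <- raw
    for (j in seq_along(num)) if (is.numeric(num[[j]]))
      num[[j]] <- ifelse(is.na(num[[j]]) | is.nan(num[[j]]), NA,
                         formatC(num[[j]], digits = 17, format = "g"))
    utils::write.table(num, path, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "-")
  }
  fmt
}

#' Parse a TSV written by [render_tables()]
#'
#' @param path TSV path.
#' @return A data frame with numeric columns; "-" cells become `NA`.
#' @export
parse_rendered_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "-",
                    stringsAsFactors = FALSE)
}
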