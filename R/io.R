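#' Construct a genotype panel
#'
#' A genotype panel holds an `N x J` matrix of effect-allele counts (0, 1 or
#' 2 copies per sample) together with SNP identifiers and the per-SNP
#' genotype-class frequencies (the probabilities of carrying 0, 1 and 2
#' copies). Frequencies default to the empirical class proportions of the
#' supplied matrix.
#'
#' @param genotypes integer matrix, samples in rows, SNPs in columns, entries
#'   in \{0, 1, 2\}.
#' @param snp_ids character vector of unique SNP identifiers; defaults to the
#'   column names of `genotypes`.
#' @param genotype_freqs optional `J x 3` matrix of class probabilities
#'   `(p0, p1, p2)`, one row per SNP, each row summing to 1.
#' @return An object of class `genotype_panel` with elements `snp_ids`,
#'   `genotypes` and `genotype_freqs`.
#' @export
genotype_panel <- function(genotypes, snp_ids = colnames(genotypes),
                           genotype_freqs = NULL) {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) < 2L || ncol(genotypes) < 1L)
    stop("genotype panel needs N >= 2 samples and J >= 1 SNPs")
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(genotypes)))
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) != ncol(genotypes))
    stop("snp_ids length does not match the number of genotype columns")
  if (anyDuplicated(snp_ids))
    stop("format error: duplicate SNP id: ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  bad <- which(!(genotypes %in% c(0, 1, 2)) | is.na(genotypes))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(genotypes)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(genotypes)) + 1L
    stop(sprintf(
      "malformed genotype: entry not in {0,1,2} at row %d, column %s", i,
      snp_ids[j]))
  }
  storage.mode(genotypes) <- "integer"
  colnames(genotypes) <- snp_ids
  if (is.null(genotype_freqs)) {
    genotype_freqs <- t(apply(genotypes, 2L, function(g)
      tabulate(g + 1L, nbins = 3L) / length(g)))
  }
  genotype_freqs <- as.matrix(genotype_freqs)
  if (!identical(dim(genotype_freqs), c(ncol(genotypes), 3L)) &&
      !all(dim(genotype_freqs) == c(ncol(genotypes), 3L)))
    stop("genotype_freqs must be a J x 3 matrix")
  if (any(genotype_freqs < 0) || any(abs(rowSums(genotype_freqs) - 1) > 1e-12))
    stop("each genotype frequency row must be nonnegative and sum to 1")
  dimnames(genotype_freqs) <- list(snp_ids, c("p0", "p1", "p2"))
  structure(list(snp_ids = snp_ids, genotypes = genotypes,
                 genotype_freqs = genotype_freqs),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d SNPs\n",
              nrow(x$genotypes), length(x$snp_ids)))
  invisible(x)
}

#' Read a genotype matrix from a delimited file
#'
#' The file must have a header row of SNP identifiers and an integer body of
#' effect-allele counts in \{0, 1, 2\}, one sample per row. Genotype-class
#' frequencies are computed empirically from the matrix. The reader never
#' re-orients alleles: the effect-allele orientation of the file is taken as
#' given (harmonization against a reference is out of scope).
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "numeric")
  if (anyDuplicated(names(df)))
    stop("format error: duplicate SNP id in header of ", path)
  m <- as.matrix(df)
  if (any(is.na(m)))
    stop("missing genotype values are not supported (row ",
         which(rowSums(is.na(m)) > 0)[1L], ")")
  genotype_panel(m, snp_ids = names(df))
}

#' Write a genotype matrix to a delimited file
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  utils::write.table(panel$genotypes, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Bundle exposure, outcome, covariates and genotypes for one analysis sample
#'
#' @param exposure numeric vector of length N (e.g. standardized BMI).
#' @param outcome numeric vector of length N (e.g. standardized income).
#' @param panel a [genotype_panel()] with N rows.
#' @param covariates optional `N x C` numeric matrix of baseline covariates.
#' @return An object of class `study_data`.
#' @export
study_data <- function(exposure, outcome, panel, covariates = NULL) {
  n <- nrow(panel$genotypes)
  exposure <- as.numeric(exposure)
  outcome <- as.numeric(outcome)
  if (length(exposure) != n || length(outcome) != n)
    stop("exposure/outcome length must equal the number of genotype rows")
  if (anyNA(exposure) || anyNA(outcome))
    stop("missing values in exposure/outcome are rejected, not imputed")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows must equal N")
    if (anyNA(covariates)) stop("missing covariate values are rejected")
  }
  structure(list(exposure = exposure, outcome = outcome,
                 covariates = covariates, panel = panel, prepared = FALSE),
            class = "study_data")
}

#' @export
print.study_data <- function(x, ...) {
  cat(sprintf("<study_data> N = %d, J = %d SNPs, %s covariates, %sprepared\n",
              length(x$exposure), length(x$panel$snp_ids),
              if (is.null(x$covariates)) "no" else ncol(x$covariates),
              if (isTRUE(x$prepared)) "" else "not "))
  invisible(x)
}

#' Residualize and mean-center the analysis variables
#'
#' Replaces exposure and outcome by the residuals from an OLS regression on
#' an intercept plus the covariates (when present), and mean-centers every
#' genotype column. With all variables centered, every downstream model can
#' drop its intercept. Covariate adjustment deliberately residualizes only
#' the exposure and the outcome, not the genotypes.
#'
#' @param data a [study_data()].
#' @return A new, prepared `study_data`; the input is not modified. The
#'   centered genotype matrix is stored in `$g_centered` (double), alongside
#'   the untouched integer panel.
#' @export
prepare_variables <- function(data) {
  stopifnot(inherits(data, "study_data"))
  if (isTRUE(data$prepared)) return(data)
  n <- length(data$exposure)
  if (!is.null(data$covariates)) {
    dm <- cbind(1, data$covariates)
    q <- qr(dm)
    if (q$rank < ncol(dm))
      stop("singular design: covariate matrix is rank deficient after adding a constant")
    resid_on <- function(y) qr.resid(q, y)
    x <- resid_on(data$exposure)
    y <- resid_on(data$outcome)
  } else {
    x <- data$exposure - mean(data$exposure)
    y <- data$outcome - mean(data$outcome)
  }
  g <- data$panel$genotypes
  storage.mode(g) <- "double"
  g <- sweep(g, 2L, colMeans(g), "-")
  out <- data
  out$exposure <- x
  out$outcome <- y
  out$g_centered <- g
  out$prepared <- TRUE
  out
}

centered_genotypes <- function(data, snps = NULL) {
  if (!isTRUE(data$prepared))
    stop("data must be prepared with prepare_variables() first")
  g <- data$g_centered
  if (!is.null(snps)) {
    miss <- setdiff(snps, data$panel$snp_ids)
    if (length(miss)) stop("unknown SNP id: ", paste(miss, collapse = ", "))
    g <- g[, snps, drop = FALSE]
  }
  g
}

#' Construct a per-SNP summary-statistics table
#'
#' @param snp_ids character vector.
#' @param gamma_hat,se_gamma SNP-outcome coefficients and standard errors.
#' @param b_hat,se_b SNP-exposure coefficients and standard errors. `se_b`
#'   may be zero only for externally supplied association values treated as
#'   exact (the "True" accuracy level of a two-sample design).
#' @param source `"one-sample"` or `"two-sample"`.
#' @return A data frame of class `snp_summary`.
#' @export
snp_summary <- function(snp_ids, gamma_hat, se_gamma, b_hat, se_b,
                        source = c("one-sample", "two-sample")) {
  source <- match.arg(source)
  n <- length(snp_ids)
  if (anyDuplicated(snp_ids)) stop("format error: duplicate SNP id")
  if (length(gamma_hat) != n || length(se_gamma) != n ||
      length(b_hat) != n || length(se_b) != n)
    stop("all summary columns must have one entry per SNP")
  # zero SEs arise only for noise-free fits or exact external associations
  if (any(se_gamma < 0)) stop("se_gamma must be nonnegative")
  if (any(se_b < 0)) stop("se_b must be nonnegative")
  out <- data.frame(snp = as.character(snp_ids), gamma_hat = gamma_hat,
                    se_gamma = se_gamma, b_hat = b_hat, se_b = se_b,
                    stringsAsFactors = FALSE)
  attr(out, "source") <- source
  class(out) <- c("snp_summary", "data.frame")
  out
}

#' Marginal per-SNP association estimates
#'
#' For each SNP j, fits the two simple regressions outcome ~ G_j and
#' exposure ~ G_j by OLS (marginal, one SNP at a time, matching the
#' construction of the per-SNP ratio estimator) and returns the slopes with
#' their classical homoskedastic standard errors.
#'
#' @param data a prepared [study_data()].
#' @return A [snp_summary()] with source `"one-sample"`.
#' @export
snp_summaries <- function(data) {
  g <- centered_genotypes(data)
  n <- nrow(g)
  sxx <- colSums(g^2)
  degen <- sxx <= 0
  if (any(degen))
    stop("degenerate SNP (zero genotype variance): ",
         paste(data$panel$snp_ids[degen], collapse = ", "))
  slope_se <- function(y) {
    sxy <- as.numeric(crossprod(g, y))
    b <- sxy / sxx
    rss <- sum(y^2) - b^2 * sxx
    se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
    list(b = b, se = se)
  }
  yy <- slope_se(data$outcome)
  xx <- slope_se(data$exposure)
  snp_summary(data$panel$snp_ids, yy$b, yy$se, xx$b, xx$se,
              source = "one-sample")
}

#' Read or write a GWAS-style summary-statistics table
#'
#' Layout: TSV/CSV with columns `snp`, `beta_exposure`, `se_exposure`,
#' `beta_outcome`, `se_outcome`, harmonized to the effect allele upstream.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param source stored provenance label, see [snp_summary()].
#' @return A `snp_summary`.
#' @export
read_summary_stats <- function(path, dialect = c("tsv", "csv"),
                               source = c("two-sample", "one-sample")) {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, header = TRUE,
                          sep = if (dialect == "tsv") "\t" else ",",
                          stringsAsFactors = FALSE)
  need <- c("snp", "beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  if (!all(need %in% names(df)))
    stop("summary-statistics file must have columns: ",
         paste(need, collapse = ", "))
  snp_summary(df$snp, df$beta_outcome, df$se_outcome, df$beta_exposure,
              df$se_exposure, source = match.arg(source))
}

#' @rdname read_summary_stats
#' @param summary a [snp_summary()] to write.
#' @export
write_summary_stats <- function(summary, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  df <- data.frame(snp = summary$snp, beta_exposure = summary$b_hat,
                   se_exposure = summary$se_b,
                   beta_outcome = summary$gamma_hat,
                   se_outcome = summary$se_gamma)
  utils::write.table(df, path, sep = if (dialect == "tsv") "\t" else ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
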