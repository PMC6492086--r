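---
title: "Pleiotropy-robust Mendelian randomization: models, estimators and the simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pleiotropy-robust Mendelian randomization: models, estimators and the simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables (IVs) to estimate the causal effect of a modifiable exposure
(say, body mass index) on an outcome (say, income) from observational data
subject to unobserved confounding. A SNP $G_j \in \{0,1,2\}$ (effect-allele
count) is a valid instrument if it is (i) associated with the exposure,
(ii) has no direct effect on the outcome, and (iii) is unrelated to the
unobserved confounders. With many GWAS-discovered SNPs, some are likely
*pleiotropic* — violating (ii) ("direct" pleiotropy, a nonzero per-SNP
outcome effect $\alpha_j$) or (iii) ("indirect" pleiotropy, an association
$\theta_j$ with the confounders).

The structural model is linear,
$$Y = \gamma_X X + \textstyle\sum_j (\alpha_j + \theta_j) G_j + \epsilon_Y,
\qquad X = \mathbf{G}\boldsymbol\beta + \epsilon_X,$$
with all variables mean-centered (and, in applied use, residualized on
measured covariates first — `prepare_variables()` residualizes exposure and
outcome but deliberately *not* the genotypes). At the summary level the
per-SNP associations obey $\Gamma_j = \pi_j + \gamma_X b_j$ with
$\pi_j = \alpha_j + \theta_j$; this identity is what both the robust
estimators and the simulator are built around, and it is verified in the
test suite by regression at $N = 10^5$.

## Estimators

**Valid-IV methods.** The per-SNP ratio $\hat\Gamma_j/\hat b_j$
(delta-method SE, first-order by default, second-order optional);
polygenic-score IV estimators (`prs_estimate()`): SPRS with unit weights,
IPRS with the joint first-stage coefficients — so its score is the fitted
exposure and it coincides with multiple-instrument 2SLS, which is also why
the two agree to machine precision in the tests — and EPRS with external
weights; multiple-IV 2SLS (`tsls()`); and LIML (`liml()`), the k-class
estimator with $k$ the smallest generalized eigenvalue, retained for its
resistance to many-weak-instrument bias and restricted to one-sample use.
2SLS standard errors use the homoskedastic IV form with residuals evaluated
at the original exposure. Rank decisions use QR with the default relative
tolerance.

**Weighted MR-Egger** (`mr_egger()`) regresses $\hat\Gamma_j$ on $\hat b_j$
*with* an intercept; the slope estimates $\gamma_X$ under the InSIDE
condition (instrument strength independent of direct effects) and the
intercept test ($t$, $J-2$ df) is the pleiotropy diagnostic. Weights
default to $1/\mathrm{se}(\hat\Gamma_j)^2$: the stated purpose of the
weighting — letting low-MAF SNPs contribute little — needs the genotype
variance embedded in that SE, which a literal residual-variance weight
would drop; explicit weights can be supplied for the literal reading.

**MR-Median** (`mr_median()`): the (weighted) median of the per-SNP
ratios, consistent under the majority rule (more than half the SNPs
valid). The simple form is the standard sample median — the even/odd
case-split sometimes quoted for it is internally inconsistent (selecting a
single order statistic where averaging is required), so the conventional
median is used. The weighted form uses inverse-variance weights
$\hat b_j^2/\mathrm{se}(\hat\Gamma_j)^2$ and linear interpolation of the
weighted CDF at 0.5 (equal weights then reproduce the simple median
exactly). SEs come from a 1000-draw parametric bootstrap of the summary
coefficients, seed-controlled.

**sisVIVE** (`sisvive_path()`, `sisvive()`) minimizes
$$\tfrac12\,\big\|P_Z\,(y - \gamma_X x - Z\boldsymbol\pi)\big\|^2
  + \lambda \|\boldsymbol\pi\|_1,$$
classifying SNPs with $\hat\pi_j = 0$ as valid. Profiling out $\gamma_X$
(closed form given $\boldsymbol\pi$) leaves a lasso on the
instrument-projected variables, solved exactly by coordinate descent on the
$J\times J$ Gram representation (compiled code, warm starts along the
penalty path). Numerical contract: the subgradient (KKT) conditions hold at
every grid penalty within $10^{-6}\lambda_{\max}$ (the solver targets
$10^{-7}$), and at $\lambda \ge \lambda_{\max}$ the solution is exactly
$\hat\pi = 0$ with $\hat\gamma_X$ equal to 2SLS. The profiled Gram has rank
$J-1$ by construction, so the smallest penalties sit on an exactly singular
problem; the solver tolerates a stall between its target and the contract
bound there. The penalty grid is 100 geometric points from
$\lambda_{\max}$ (computed from the gradient at $\boldsymbol\pi = 0$) down
by a factor $10^{-3}$. Coefficients below $10^{-8}$ in absolute value count
as zero — a round-off guard only, since coordinate-descent solutions are
exactly sparse.

**Penalty choice.** `sisvive()` runs K-fold cross-validation (K = 10;
folds drawn from the supplied seed) over the grid and applies the
one-standard-error rule. Two conventions were genuinely open and both are
exposed:

* `cv_error`: `"projected"` (default) scores the *instrument-projected*
  held-out residual, consistent with the objective being cross-validated;
  `"raw"` scores the plain residual, as some reference implementations do.
* `one_se`: `"above"` (default) takes the largest penalty within one SE of
  the CV minimum; `"below"` and `"none"` are available.

The defaults were fixed by checking which convention reproduces the
published selection behaviour of this design class: the projected error
with the large-$\lambda$ rule reproduces the scenario-level false-selection
rates and the post-selection estimator ordering well. One consequence is
structural and worth knowing: with *no* pleiotropy present, the projected
CV error is minimized at large penalties and the one-SE rule lands at
$\lambda_{\max}$, so essentially every SNP is classed valid and the false
"select-out" rate is near zero; implementations scoring raw residuals
report a few percent instead. `sisvive()` reports no standard error for
the penalized estimate itself — shrinkage makes it unreliable — and
post-selection estimates (`post_sisvive()`, re-running SPRS/IPRS/EPRS/2SLS
on the selected valid set) carry the downstream estimator's SE.

**Two-sample strategies.** When external SNP-exposure associations
$\tilde b_j$ are available, EPRS uses them as score weights, 2SLS and
sisVIVE replace the first stage by $\tilde X = Z\tilde b$ (the external
weights treated as fixed — anti-conservative if they are noisy), and
Egger/Median regress on or divide by $\tilde b_j$. Noise in $\tilde b_j$
is a failure of the no-measurement-error (NOME) condition and attenuates
estimates toward zero.

## The synthetic cohort generator

`sim_config()` + `make_effects()` + `gen_genotypes()` + `gen_dataset()`
emulate a weak-instrument BMI-like design: $J = 71$ independent trinomial
SNPs, $N = 10{,}000$, true effect $\gamma_X = -0.2$, a shared standard
normal confounder entering the exposure with coefficient 1 and the outcome
with $\gamma_U = 1$, and unit-variance idiosyncratic noise in both
equations. Pleiotropy scenarios for the $S$ invalid SNPs
($S \le J/2$, the majority rule): (1) balanced direct,
$\alpha_s \sim U(-0.2, 0.2)$; (2) unbalanced direct,
$\alpha_s \sim U(0, 0.2)$; (3) additionally indirect,
$\theta_s \sim U(0, 0.4)$, routed through the confounder as
$U' = \sum_s \theta_s G_s + U$. The routing reproduces both consequences
the design requires — the SNP-exposure association of an invalid SNP
becomes $b_s = \beta_s + \theta_s$ while its outcome-side pleiotropy is
$(\alpha_s + \theta_s\gamma_U)G_s$ — and breaks InSIDE, since instrument
strength and pleiotropic effect now share $\theta_s$. The mechanism is a
pluggable function for studying variants. External associations come at
three accuracy levels: `true` ($\tilde b = b$ exactly), `precise`
($+N(0, 0.01^2)$), `imprecise` ($+N(0, 0.05^2)$).

**Effect sizes and calibration.** Genotype-class frequencies follow
Hardy-Weinberg proportions with effect-allele frequency $\sim U(0.1,
0.9)$. SNP-exposure effects $\beta_j$ can be read verbatim from a
two-column table; in synthetic mode their magnitudes are drawn from a
right-skewed Gamma(shape 4, mean 1) shape — consortium per-allele BMI
effects are strongly right-skewed with a coefficient of variation near
one half — and rescaled once, deterministically, so the *theoretical
average first-stage F-statistic* equals 2.5 at $N = 10{,}000$:
$$F_j = 1 + \frac{N\,\beta_j^2\,\mathrm{Var}(G_j)}
  {\mathrm{Var}(X) - \beta_j^2 \mathrm{Var}(G_j)},$$
the expected value of the observed per-SNP F. The $1+{}$ null term
matters: with it, a mean F of 2.5 implies an expected in-sample 71-SNP
$R^2$ of about 1.8%, matching the percent-level exposure variance such
panels explain; without it the implied $R^2$ would be nearly half that.
This is a deliberately weak-instrument regime ($F \ll 10$), which is the
point of the study design. Invalid SNPs default to the $S$ largest
$|\beta|$ (`invalid_choice` offers `random`/`first`); $\beta$ is drawn
once per experiment and held fixed across replicates (as fixed consortium
values would be) while $\alpha$, $\theta$, genotypes, errors and external
noise are redrawn each replicate.

**What it does not emulate.** Linkage disequilibrium (SNPs are mutually
independent by design), population stratification, genotyping error,
allele flip-flopping, nonlinear exposure effects, and — importantly — any
*particular* real effect-size panel: with synthetic $\beta$, quantities
that depend on the realized effect-size profile (e.g. the bias of a
simple allele score under unbalanced pleiotropy, which involves
$\sum_s \mathrm{Var}(G_s) / \sum_j \beta_j \mathrm{Var}(G_j)$) vary by
several hundredths across master seeds. Passing tests therefore
demonstrate the estimators' *behaviour* under the design class, not
agreement with any one cohort's digits.

## Evaluation layer

`run_experiment()` runs the full replicate loop (generation → every
requested estimator → collection), deterministically for any degree of
parallelism: every random stream is derived from the master seed with a
counter-based Lehmer-LCG scheme (`derive_seed()`), so replicate $r$ is
bit-identical whether computed serially or on forked workers. Failed
replicate-estimator combinations are counted and excluded from that
estimator's summary only, never silently dropped. `summarize_estimates()`
reports mean, SD, mean SE, MSE (the direct mean of squared errors — the
identity $\mathrm{MSE} = \text{bias}^2 + \widehat{\mathrm{Var}}\,(R-1)/R$
is asserted to $10^{-9}$), coverage of the nominal 95% interval
($\pm 1.96\,\mathrm{se}$; the same 1.96 convention as the Wald test, so
coverage and power are mutually consistent) and power against a zero
effect at the two-sided 5% level. `fsi_fso()` scores the selection step:
FSI = % of truly invalid SNPs classed valid (undefined when $S = 0$),
FSO = % of truly valid SNPs classed invalid. `render_tables()` lays both
out in the two standard report shapes, with "-" for undefined cells and a
full-precision TSV sidecar.

## Problem sizes

The test suite exercises the full design point ($N = 10{,}000$, $J = 71$)
at 100–200 replicates per configuration and smaller cohorts for the exact
identities; `scripts/acceptance.R` uses 100–150 replicates per scenario.
These counts were chosen so a complete run takes a few minutes on one
core while keeping Monte-Carlo standard errors of scenario means near
0.01; the full 1000-replicate design is a `replicates` argument away.

## Known limitations

* One-sample estimators inherit many-weak-instrument bias by design
  (average F = 2.5); this is a feature of the emulated regime, not a bug,
  and is asserted directionally in the tests.
* LIML is one-sample only; no CUE/GMM estimators; no
  heteroskedasticity-robust inference.
* Two-sample SEs treat external weights as fixed (anti-conservative under
  NOME failure).
* The sisVIVE valid set is a point selection; no selection-uncertainty is
  propagated into post-selection SEs.
* `fsi_fso()` and the experiment runner assume the invalid set is known
  (simulation use); applied use of sisVIVE reports the selected set only.
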