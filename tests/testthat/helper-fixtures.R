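# Small simulated cohorts shared across tests. Everything is generated in
# code under fixed seeds; no fixture files.

# A prepared cohort at the given design point.
fixture_cohort <- function(n = 2000, j = 8, s = 0, scenario = 1,
                           seed = 101, f_target = 25, beta = NULL,
                           accuracy = "one-sample") {
  cfg <- sim_config(n_samples = n, n_snps = j, n_invalid = s,
                    scenario = scenario, accuracy = accuracy,
                    f_target = f_target, master_seed = seed)
  freqs <- synthetic_freqs(j, seed = seed + 1)
  eff <- make_effects(cfg, freqs, seed = seed + 2, beta = beta)
  panel <- gen_genotypes(cfg, freqs, seed = seed + 3)
  dat <- prepare_variables(gen_dataset(cfg, eff, panel, seed = seed + 4))
  list(config = cfg, freqs = freqs, effects = eff, panel = panel,
       data = dat)
}

# Dense, independent evaluation of the penalized IV objective
#   0.5 * || P_Z (y - gamma x - Z pi) ||^2 + lambda * sum |pi|
# using an explicit projection, for use as a brute-force oracle.
sisvive_objective <- function(y, x, z, gamma, pi, lambda) {
  q <- qr(z)
  r <- qr.fitted(q, y - gamma * x - as.numeric(z %*% pi))
  0.5 * sum(r^2) + lambda * sum(abs(pi))
}
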