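# shared small fixtures, all generated in code

small_config <- function(...) {
  sim_config(n_accessions = 20, n_transcripts = 30, n_snps = 100,
             n_chromosomes = 2, chrom_length = 5e6, seed = 42L, ...)
}

# balanced toy design: a accessions x 2 envs x r reps, block = replicate
toy_design <- function(a = 2, r = 2) {
  cfg <- sim_config(n_accessions = max(a, 2), n_transcripts = 1,
                    n_snps = 60, n_replicates = r, seed = 1L)
  d <- sim_design(cfg)
  d[d$accession_id %in% sprintf("acc%03d", seq_len(a)), ]
}

# brute-force two-way sums of squares (balanced), independent of the
# package implementation
anova_oracle <- function(y, acc, env) {
  acc <- as.character(acc); env <- as.character(env)
  grand <- mean(y)
  accs <- unique(acc); envs <- unique(env)
  a <- length(accs); e <- length(envs)
  r <- length(y) / (a * e)
  cell_mean <- function(i, j) mean(y[acc == i & env == j])
  acc_mean <- vapply(accs, function(i) mean(y[acc == i]), 0)
  env_mean <- vapply(envs, function(j) mean(y[env == j]), 0)
  ss_G <- e * r * sum((acc_mean - grand)^2)
  ss_E <- a * r * sum((env_mean - grand)^2)
  ss_GxE <- 0; ss_res <- 0
  for (i in accs) for (j in envs) {
    cm <- cell_mean(i, j)
    ss_GxE <- ss_GxE + r * (cm - acc_mean[i] - env_mean[j] + grand)^2
    ss_res <- ss_res + sum((y[acc == i & env == j] - cm)^2)
  }
  list(ss_G = ss_G, ss_E = ss_E, ss_GxE = unname(ss_GxE), ss_res = ss_res,
       ss_total = sum((y - grand)^2))
}
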