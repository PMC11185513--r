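# small planted-eQTL dataset shared across scan tests
eqtl_sim <- function(n_acc = 150, seed = 51L, ...) {
  cfg <- sim_config(n_accessions = n_acc, n_transcripts = 40, n_snps = 300,
                    n_cis_genes = 6, n_trans_genes = 6,
                    cis_beta = 1, trans_beta = 1,
                    sigma2_G = 0.2, sigma2_E = 0, sigma2_GxE = 0.1,
                    sigma2_res = 0.5, mu_range = c(6, 10), seed = seed, ...)
  simulate_dataset(cfg)
}

test_that("vectorized scan equals naive per-pair OLS", {
  cfg <- sim_config(n_accessions = 30, n_transcripts = 8, n_snps = 20,
                    seed = 53L)
  sim <- simulate_dataset(cfg)
  means <- accession_means(sim$expression, sim$design, "normal")
  K <- compute_kinship(sim$genotypes)
  out <- map_eqtl(means, sim$genotypes, n_covariate_pcs = 3, kinship = K,
                  return_all = TRUE, environment = "normal")
  C <- eigen(K, symmetric = TRUE)$vectors[, 1:3]
  for (k in sample(nrow(out), 25)) {
    x <- sim$genotypes$dosages[rownames(means), out$snp_id[k]]
    y <- means[, out$transcript_id[k]]
    fit <- summary(lm(y ~ x + C))
    expect_equal(out$beta[k], fit$coefficients["x", 1], tolerance = 1e-8)
    expect_equal(out$se[k], fit$coefficients["x", 2], tolerance = 1e-8)
    expect_equal(out$p[k], fit$coefficients["x", 4], tolerance = 1e-8)
  }
})

test_that("planted cis/trans effects are detected with accurate betas", {
  sim <- eqtl_sim()
  means <- accession_means(sim$expression, sim$design, "normal")
  out <- map_eqtl(means, sim$genotypes, fdr = 0.001, environment = "normal")
  truth <- sim$truth$eqtl
  hits <- 0
  for (i in seq_len(nrow(truth))) {
    row <- out[out$snp_id == truth$snp_id[i] &
                 out$transcript_id == truth$transcript_id[i], ]
    if (nrow(row) == 1) {
      hits <- hits + 1
      expect_lt(abs(row$beta - truth$beta[i]), 3 * row$se + 0.05)
    }
  }
  expect_gt(hits / nrow(truth), 0.9)  # power > 0.9
})

test_that("null scan controls the false-discovery proportion", {
  cfg <- sim_config(n_accessions = 100, n_transcripts = 100, n_snps = 500,
                    sigma2_G = 0, sigma2_E = 0, sigma2_GxE = 0,
                    sigma2_res = 1, mu_range = c(6, 10), seed = 57L)
  sim <- simulate_dataset(cfg)
  means <- accession_means(sim$expression, sim$design, "normal")
  out <- map_eqtl(means, sim$genotypes, fdr = 0.05, environment = "normal")
  # fully null: any q < 0.05 call is false; expected count is tiny
  n_tests <- 100 * 500
  expect_lt(nrow(out), 0.05 * n_tests * 0.01 + 10)
})

test_that("cis/trans classification follows the distance rules", {
  assoc <- tibble::tibble(
    snp_id = c("s1", "s2", "s3", "s4"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(50e3, 500e3, 1.5e6, 100),
    transcript_id = "g", beta = 1, se = 0.1, p = 1e-9, q = 1e-8,
    environment = "normal"
  )
  positions <- tibble::tibble(transcript_id = "g", chrom = "chr1",
                              tss_pos = 1)
  out <- classify_cis_trans(assoc, positions)
  expect_equal(out$cis_trans, c("cis", "unclassified", "trans", "trans"))
  # missing position -> unclassified with flag
  out2 <- classify_cis_trans(assoc,
                             tibble::tibble(transcript_id = "other",
                                            chrom = "chr1", tss_pos = 1))
  expect_true(all(out2$cis_trans == "unclassified"))
  expect_true(all(out2$missing_position))
})

test_that("environment overlap reproduces union-percent arithmetic", {
  expect_equal(overlap_percent(29623, 59669), 49.64, tolerance = 0.005)
  expect_equal(overlap_percent(25528, 137100), 18.62, tolerance = 0.005)
  mk <- function(keys) tibble::tibble(
    snp_id = sub("_.*", "", keys), transcript_id = sub(".*_", "", keys),
    beta = 1, cis_trans = "cis")
  a <- mk(sprintf("s%d_g", 1:10))
  b <- mk(sprintf("s%d_g", 6:20))
  ov <- compare_environment_overlap(a, b)$overlap
  cis <- ov[ov$class == "cis", ]
  expect_equal(cis$n_common, 5)
  expect_equal(cis$n_union, 20)
  expect_equal(cis$pct_common, 25)
  # disjoint
  ov2 <- compare_environment_overlap(a, mk(sprintf("s%d_g", 11:20)))$overlap
  expect_equal(ov2$pct_common[ov2$class == "cis"], 0)
})

test_that("GxE scan detects environment-specific but not shared eQTLs", {
  cfg <- sim_config(n_accessions = 150, n_transcripts = 30, n_snps = 200,
                    n_cis_genes = 4, n_env_genes = 4, cis_beta = 1,
                    trans_beta = 1, sigma2_G = 0.2, sigma2_GxE = 0.1,
                    sigma2_res = 0.4, mu_range = c(6, 10), seed = 61L)
  sim <- simulate_dataset(cfg)
  mn <- accession_means(sim$expression, sim$design, "normal")
  ms <- accession_means(sim$expression, sim$design, "saline")
  out <- map_gxe(mn, ms, sim$genotypes, fdr = 0.05)
  truth <- sim$truth$eqtl
  env_specific <- truth[truth$env == "saline", ]
  shared <- truth[truth$role == "single_cis", ]
  key <- paste(out$snp_id, out$transcript_id)
  found <- paste(env_specific$snp_id, env_specific$transcript_id) %in% key
  expect_gt(mean(found), 0.7)
  # saline-specific effect: normal - saline convention flips the sign
  k <- match(paste(env_specific$snp_id, env_specific$transcript_id), key)
  k <- k[!is.na(k)]
  b_true <- env_specific$beta[found]
  expect_true(all(sign(out$beta[k]) == -sign(b_true)))
  # shared eQTLs cancel in the difference
  expect_lt(mean(paste(shared$snp_id, shared$transcript_id) %in% key), 0.3)
})

test_that("lead SNPs and hotspot thresholds behave as specified", {
  mk_assoc <- function(n_genes, chrom = "chr1", pos = 5e4) {
    tibble::tibble(
      snp_id = "hot", chrom = chrom, pos = pos,
      transcript_id = sprintf("g%02d", seq_len(n_genes)),
      beta = 1, se = 0.1, p = 1e-9, q = 1e-8, environment = "normal",
      cis_trans = "trans"
    )
  }
  h31 <- lead_and_hotspots(mk_assoc(31), min_genes = 30)$hotspots
  expect_true(h31$hotspot[1])
  h30 <- lead_and_hotspots(mk_assoc(30), min_genes = 30)$hotspots
  expect_false(h30$hotspot[1])  # strict inequality
  # tie-breaking and minimum p
  assoc <- tibble::tibble(
    snp_id = c("a", "b", "c"), chrom = "chr1", pos = c(10, 20, 30),
    transcript_id = "g", beta = 1, se = 0.1,
    p = c(1e-5, 1e-8, 1e-8), q = 1e-4, environment = "normal",
    cis_trans = "trans"
  )
  out <- lead_and_hotspots(assoc)$assoc
  expect_equal(out$snp_id[out$is_lead], "b")  # lowest p, then lower pos
})

test_that("architecture calls follow the 60% rule on constructed dosages", {
  n <- 20
  dos <- cbind(s_cis = rep(c(0, 2), each = n / 2),
               s_trans = rep(c(0, 2), each = n / 2))
  rownames(dos) <- sprintf("acc%03d", 1:n)
  geno <- structure(list(dosages = dos, chrom = c("chr1", "chr2"),
                         pos = c(1, 1), ref = c("A", "A"), alt = c("T", "T")),
                    class = "genotype_matrix")
  mk <- function(b_cis, b_trans) tibble::tibble(
    snp_id = c("s_cis", "s_trans"), chrom = c("chr1", "chr2"), pos = 1,
    transcript_id = "g", beta = c(b_cis, b_trans), se = 0.1, p = 1e-9,
    q = 1e-8, environment = "normal", cis_trans = c("cis", "trans"),
    is_lead = TRUE
  )
  same <- call_cis_trans_architecture(mk(1, 1), geno)
  expect_equal(same$same_direction_fraction, 1)
  expect_equal(same$call, "reinforcing")
  opp <- call_cis_trans_architecture(mk(1, -1), geno)
  expect_equal(opp$same_direction_fraction, 0)
  expect_equal(opp$call, "compensating")
})

test_that("independent dosages give ~50% same-direction fraction", {
  set.seed(67)
  n <- 200
  fracs <- vapply(1:30, function(i) {
    dos <- cbind(s_cis = 2 * rbinom(n, 1, 0.5), s_trans = 2 * rbinom(n, 1, 0.5))
    rownames(dos) <- sprintf("acc%03d", 1:n)
    geno <- structure(list(dosages = dos, chrom = c("chr1", "chr2"),
                           pos = c(1, 1), ref = c("A", "A"),
                           alt = c("T", "T")), class = "genotype_matrix")
    assoc <- tibble::tibble(
      snp_id = c("s_cis", "s_trans"), chrom = c("chr1", "chr2"), pos = 1,
      transcript_id = "g", beta = 1, se = 0.1, p = 1e-9, q = 1e-8,
      environment = "normal", cis_trans = c("cis", "trans"), is_lead = TRUE)
    call_cis_trans_architecture(assoc, geno)$same_direction_fraction
  }, numeric(1))
  # binomial oracle: mean 0.5, SE ~ 0.5/sqrt(200) per replicate
  expect_lt(abs(mean(fracs) - 0.5), 3 * 0.5 / sqrt(200 * 30))
})

test_that("planted reinforcing/compensating genes are recovered end to end", {
  # equal planted magnitudes: under cis-trans LD the marginal effect of a
  # compensating gene's cis SNP shrinks by r * |beta_trans|, so unequal
  # magnitudes would push one class below the detection threshold
  cfg <- sim_config(n_accessions = 200, n_transcripts = 40, n_snps = 300,
                    n_arch_genes = 10, prop_reinforcing = 0.5,
                    cis_beta = 1.2, trans_beta = 1.2,
                    sigma2_G = 0.1, sigma2_E = 0, sigma2_GxE = 0.1,
                    sigma2_res = 0.4, mu_range = c(6, 10), seed = 71L)
  sim <- simulate_dataset(cfg)
  means <- accession_means(sim$expression, sim$design, "normal")
  assoc <- map_eqtl(means, sim$genotypes, fdr = 0.001,
                    environment = "normal")
  assoc <- classify_cis_trans(assoc, sim$positions)
  assoc <- lead_and_hotspots(assoc)$assoc
  arch <- call_cis_trans_architecture(assoc, sim$genotypes)
  truth <- sim$truth$arch
  merged <- dplyr::inner_join(arch, truth, by = "transcript_id")
  expect_gte(nrow(merged), 8)
  acc <- mean(merged$call == merged$planted_call)
  expect_gte(acc, 0.9)
})

test_that("r2 matches brute force and the permutation test calibrates", {
  cfg <- sim_config(n_accessions = 200, n_snps = 200, seed = 73L)
  geno <- simulate_genotypes(cfg)
  pairs <- cbind(sample(200, 10), sample(200, 10))
  res <- ld_permutation_test(geno, pairs, n_perm = 200, seed = 5)
  brute <- mean(vapply(1:10, function(k) {
    cor(geno$dosages[, pairs[k, 1]], geno$dosages[, pairs[k, 2]])^2
  }, numeric(1)))
  expect_equal(res$observed_mean_r2, brute, tolerance = 1e-10)
  # independent SNPs: E[r2] ~ 1/n, p not significant
  expect_gt(res$permutation_p, 0.05)
  expect_lt(abs(res$observed_mean_r2 - res$background_mean_r2), 0.05)
  # identical SNP with itself: r2 = 1 (degenerate bin widened with warning)
  self_pair <- rbind(c(1, 1), c(2, 2))
  res_self <- suppressWarnings(
    ld_permutation_test(geno, self_pair, n_perm = 50, seed = 5))
  expect_equal(res_self$observed_mean_r2, 1)
})

test_that("planted long-range LD pairs are detected by the permutation test", {
  # cis-trans fixation LD: distant SNP pairs whose dosages are near-copies,
  # against a matched-distance null of independent pairs
  set.seed(79)
  cfg <- sim_config(n_accessions = 200, n_snps = 400, seed = 79L)
  geno <- simulate_genotypes(cfg)
  on_chr1 <- which(geno$chrom == "chr1")
  on_chr2 <- which(geno$chrom == "chr2")
  a <- sample(on_chr1, 20)
  b <- sample(on_chr2, 20)
  for (k in seq_len(20)) {  # copy with 10% flips -> r2 ~ 0.7
    col <- geno$dosages[, a[k]]
    flip <- runif(200) < 0.1
    col[flip] <- 2L * rbinom(sum(flip), 1L, 0.5)
    geno$dosages[, b[k]] <- col
  }
  res <- ld_permutation_test(geno, cbind(a, b), n_perm = 1000, seed = 7)
  expect_lte(res$permutation_p, 0.002)
  expect_gt(res$observed_mean_r2, res$background_mean_r2)
})

test_that("pi and MAF follow closed forms and planted SFS shifts are detected", {
  # 4 accessions, allele counts 2/2 -> pi = 2 * 0.25 * 4/3
  dos <- matrix(c(0, 0, 2, 2,   0, 0, 0, 0), 4, 2,
                dimnames = list(sprintf("acc%03d", 1:4), c("s1", "s2")))
  geno <- structure(list(dosages = dos, chrom = c("chr1", "chr1"),
                         pos = c(100, 200), ref = c("A", "A"),
                         alt = c("T", "T")), class = "genotype_matrix")
  div <- sfs_and_diversity(geno, list(focal = "s1"), flank = 50,
                           block = 100)
  expect_equal(div$maf$pi[1], 2 * 0.25 * 4 / 3, tolerance = 1e-12)
  expect_equal(div$maf$pi[2], 0)        # monomorphic
  expect_false(div$maf$polymorphic[2])  # excluded from MAF set
  expect_equal(div$maf$maf[1], 0.5)

  # brute-force pairwise-difference oracle for pi on <= 10 accessions
  set.seed(83)
  n_acc <- 8
  m <- 30
  dos2 <- matrix(2L * rbinom(n_acc * m, 1, 0.3), n_acc, m,
                 dimnames = list(sprintf("acc%03d", 1:n_acc),
                                 sprintf("s%02d", 1:m)))
  geno2 <- structure(list(dosages = dos2, chrom = rep("chr1", m),
                          pos = seq_len(m) * 10, ref = rep("A", m),
                          alt = rep("T", m)), class = "genotype_matrix")
  div2 <- sfs_and_diversity(geno2, list(all = colnames(dos2)))
  hap <- dos2 / 2
  pi_brute <- vapply(seq_len(m), function(s) {
    d <- 0; np <- 0
    for (i in 1:(n_acc - 1)) for (j in (i + 1):n_acc) {
      d <- d + (hap[i, s] != hap[j, s]); np <- np + 1
    }
    d / np
  }, numeric(1))
  expect_equal(div2$maf$pi, unname(pi_brute), tolerance = 1e-12)

  # planted MAF shift: low-MAF set vs uniform background
  set.seed(89)
  n_acc <- 120
  low <- vapply(runif(300, 0.05, 0.10),
                function(p) 2L * rbinom(n_acc, 1, p), integer(n_acc))
  bg <- vapply(runif(300, 0.05, 0.5),
               function(p) 2L * rbinom(n_acc, 1, p), integer(n_acc))
  dos3 <- cbind(low, bg)
  colnames(dos3) <- sprintf("s%03d", seq_len(600))
  rownames(dos3) <- sprintf("acc%03d", seq_len(n_acc))
  geno3 <- structure(list(dosages = dos3, chrom = rep("chr1", 600),
                          pos = seq_len(600) * 1000, ref = rep("A", 600),
                          alt = rep("T", 600)), class = "genotype_matrix")
  div3 <- sfs_and_diversity(geno3, list(eqtl = sprintf("s%03d", 1:300)))
  tt <- div3$maf_tests[div3$maf_tests$set == "eqtl", ]
  expect_lt(tt$p, 0.01)
  expect_lt(tt$mean_maf_set, tt$mean_maf_background)  # left-shifted SFS
})
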