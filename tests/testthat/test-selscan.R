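test_that("relative fitness drops zeros and normalizes to mean 1", {
  d <- toy_design(a = 3, r = 1)
  fit <- tibble::tibble(sample_id = d$sample_id,
                        fecundity = c(100, 200, 300, 0, 0, 400))
  w <- prepare_relative_fitness(fit, d)
  expect_false(any(w$w == 0))
  for (env in c("normal", "saline")) {
    expect_equal(mean(w$w[w$environment == env]), 1, tolerance = 1e-12)
  }
  # hand check on one environment: {100, 300} -> {0.5, 1.5}
  d2 <- d[d$environment == "normal", ]
  f2 <- tibble::tibble(sample_id = d2$sample_id, fecundity = c(0, 100, 300))
  w2 <- prepare_relative_fitness(f2, d2)
  expect_equal(sort(w2$w), c(0.5, 1.5))
  expect_equal(nrow(w2), 2)
})

test_that("all-zero environment is rejected", {
  d <- toy_design(a = 2, r = 1)
  fit <- tibble::tibble(sample_id = d$sample_id, fecundity = c(1, 1, 0, 0))
  # saline all zero
  fit$fecundity[d$environment == "saline"] <- 0
  expect_error(prepare_relative_fitness(fit, d), "nonzero")
})

# build an exact fitness surface over one environment with >= 20 samples
exact_surface_fixture <- function(f, n = 40, seed = 5) {
  set.seed(seed)
  cfg <- sim_config(n_accessions = n, n_replicates = 1, n_transcripts = 2,
                    n_snps = 60, seed = 9L)
  d <- sim_design(cfg)
  d <- d[d$environment == "normal", ]
  z <- rnorm(n, mean = 5, sd = 1)
  expr <- cbind(t1 = z, t2 = rnorm(n, 5))
  rownames(expr) <- d$sample_id
  w <- tibble::tibble(sample_id = d$sample_id, environment = "normal",
                      w = f(z - mean(z)))
  list(design = d, expr = expr, w = w, z = z)
}

test_that("exact linear and quadratic surfaces are recovered", {
  fx <- exact_surface_fixture(function(zc) 1 + 0.2 * zc)
  rec <- estimate_differentials(fx$expr, fx$w, fx$design, "normal")
  r1 <- rec[rec$transcript_id == "t1", ]
  expect_equal(r1$S, 0.2, tolerance = 1e-10)
  expect_lt(r1$p_S, 1e-12)

  fx2 <- exact_surface_fixture(function(zc) 1 + 0.1 * zc^2)
  rec2 <- estimate_differentials(fx2$expr, fx2$w, fx2$design, "normal")
  r2 <- rec2[rec2$transcript_id == "t1", ]
  expect_equal(r2$C, 0.2, tolerance = 1e-10)  # twice the coefficient
  expect_lt(r2$p_C, 1e-12)
})

test_that("Lande-Arnold identity: S equals cov(w, z)/var(z) with one block", {
  fx <- exact_surface_fixture(function(zc) 1 + 0.15 * zc + rnorm(40, 0, 0.1),
                              seed = 11)
  rec <- estimate_differentials(fx$expr, fx$w, fx$design, "normal")
  r1 <- rec[rec$transcript_id == "t1", ]
  zc <- fx$z
  expect_equal(r1$S, cov(fx$w$w, zc) / var(zc), tolerance = 1e-8)
  # variance-standardized S equals cov(w, z_std) (z scaled to unit SD)
  expect_equal(r1$S_s, cov(fx$w$w, zc / sd(zc)), tolerance = 1e-8)
})

test_that("standardization identities hold and match rescaled regressions", {
  rec <- tibble::tibble(S = 0.2, C = 0.2, trait_mean = 5, trait_sd = 2)
  out <- standardize_differentials(rec)
  expect_equal(out$S_s, 0.4)
  expect_equal(out$S_m, 1.0)
  expect_equal(out$C_s, 0.8)
  expect_equal(out$C_m, 5.0)
  zero <- standardize_differentials(
    tibble::tibble(S = 0.2, C = 0.1, trait_mean = 5, trait_sd = 0))
  expect_true(is.na(zero$S_s))

  # re-running the regression on the variance-scaled trait reproduces S_s
  fx <- exact_surface_fixture(function(zc) 1 + 0.15 * zc + rnorm(40, 0, 0.1),
                              seed = 13)
  rec <- estimate_differentials(fx$expr, fx$w, fx$design, "normal")
  r1 <- rec[rec$transcript_id == "t1", ]
  expr_scaled <- fx$expr
  expr_scaled[, 1] <- expr_scaled[, 1] / sd(expr_scaled[, 1])
  rec_s <- estimate_differentials(expr_scaled, fx$w, fx$design, "normal")
  expect_equal(rec_s$S[rec_s$transcript_id == "t1"], r1$S_s,
               tolerance = 1e-8)
})

test_that("outlier trimming and the min-n rule drop the right transcripts", {
  fx <- exact_surface_fixture(function(zc) 1 + 0.2 * zc)
  expr <- fx$expr
  expr[1, 1] <- 50  # > 3 SD outlier
  rec <- estimate_differentials(expr, fx$w, fx$design, "normal")
  expect_equal(rec$n_used[rec$transcript_id == "t1"], 39)
  # sparse transcript: expressed in fewer than 20 individuals
  expr[, 2] <- 0
  expr[1:19, 2] <- 1
  rec2 <- estimate_differentials(expr, fx$w, fx$design, "normal")
  expect_false("t2" %in% rec2$transcript_id)
  expect_true("t2" %in% attr(rec2, "skipped")$transcript_id)
})

test_that("planted selection is recovered without bias and null p is uniform", {
  n_tr <- 150
  s_true <- matrix(0, n_tr, 2)
  set.seed(17)
  s_true[1:50, 1] <- runif(50, -0.1, 0.1)
  cfg <- sim_config(n_accessions = 120, n_transcripts = n_tr, n_snps = 60,
                    sigma2_G = 1, sigma2_E = 0, sigma2_GxE = 0.3,
                    sigma2_res = 0.5, s_true = s_true,
                    fitness_noise_sd = 0.3, zero_fecundity_rate = 0,
                    mu_range = c(6, 10), seed = 19L)
  sim <- simulate_dataset(cfg)
  w <- prepare_relative_fitness(sim$fitness, sim$design)
  rec <- estimate_differentials(sim$expression, w, sim$design, "normal")
  # S is per log2-expression unit; planted surface is per SD unit, so the
  # comparable estimate is the variance-standardized S_s
  err <- rec$S_s - s_true[match(rec$transcript_id,
                                colnames(sim$expression)), 1]
  expect_lt(abs(mean(err)), 2 * mean(rec$se_S * rec$trait_sd) /
              sqrt(nrow(rec)) * 3 + 0.01)
  # null transcripts: uniform p -> type-I rate about 0.05
  null_ids <- colnames(sim$expression)[51:n_tr]
  p_null <- rec$p_S[rec$transcript_id %in% null_ids]
  rate <- mean(p_null < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(p_null)) + 0.01)
})

test_that("trade-off classification follows the threshold rules", {
  rn <- tibble::tibble(transcript_id = c("a", "b", "c", "d", "e"),
                       p_S = c(0.01, 0.03, 0.03, 0.2, 0.03),
                       S = c(1, 1, 1, 1, 1))
  rs <- tibble::tibble(transcript_id = c("a", "b", "c", "d", "f"),
                       p_S = c(0.2, 0.04, 0.04, 0.01, 0.04),
                       S = c(1, -1, 1, 1, -1))
  calls <- classify_tradeoffs(rn, rs)
  get <- function(id) calls$call[calls$transcript_id == id]
  expect_equal(get("a"), "CN_normal")
  expect_equal(get("b"), "AP_normal_beneficial")
  expect_equal(get("c"), "concordant")
  expect_equal(get("d"), "CN_saline")
  expect_equal(get("e"), "none")  # missing in saline
  expect_true(calls$missing_one_env[calls$transcript_id == "e"])
})

test_that("null CN/AP rates match the enumeration oracle", {
  # independent uniform p-values in both environments, random signs:
  # P(CN) = 2 * 0.025 * 0.95; P(AP) = 0.05^2 * 0.5
  set.seed(23)
  n <- 60000
  rn <- tibble::tibble(transcript_id = as.character(1:n), p_S = runif(n),
                       S = sample(c(-1, 1), n, TRUE))
  rs <- tibble::tibble(transcript_id = as.character(1:n), p_S = runif(n),
                       S = sample(c(-1, 1), n, TRUE))
  calls <- classify_tradeoffs(rn, rs)
  p_cn <- mean(grepl("^CN", calls$call))
  p_ap <- mean(grepl("^AP", calls$call))
  cn_expect <- 2 * 0.025 * 0.95
  ap_expect <- 0.05^2 * 0.5
  expect_lt(abs(p_cn - cn_expect), 3 * sqrt(cn_expect / n))
  expect_lt(abs(p_ap - ap_expect), 3 * sqrt(ap_expect / n))
})

test_that("GO term selection applies the size filter and CI rule", {
  set.seed(29)
  n <- 300
  rec <- tibble::tibble(transcript_id = sprintf("t%03d", 1:n),
                        S = rnorm(n, 0, 0.05), environment = "normal")
  rec$S[1:25] <- 0.5  # a strongly selected term
  ann <- dplyr::bind_rows(
    tibble::tibble(transcript_id = sprintf("t%03d", 1:25),
                   term_id = "GO:strong"),
    tibble::tibble(transcript_id = sprintf("t%03d", 26:44),
                   term_id = "GO:small"),       # only 19 transcripts
    tibble::tibble(transcript_id = sprintf("t%03d", sample(1:n, 40)),
                   term_id = "GO:null")
  )
  out <- go_term_selection(rec, ann, n_boot = 500, seed = 7)
  expect_false("GO:small" %in% out$term_id)
  strong <- out[out$term_id == "GO:strong", ]
  expect_true(strong$significant)
  expect_equal(strong$median_strength, 0.5)
  # deterministic under seed
  out2 <- go_term_selection(rec, ann, n_boot = 500, seed = 7)
  expect_identical(out, out2)
})

test_that("null GO terms are significant at about the nominal rate", {
  set.seed(31)
  n <- 400
  hits <- vapply(1:200, function(i) {
    rec <- tibble::tibble(transcript_id = as.character(1:n),
                          S = rnorm(n, 0, 0.1), environment = "normal")
    ann <- tibble::tibble(transcript_id = as.character(sample(1:n, 30)),
                          term_id = "GO:null")
    out <- go_term_selection(rec, ann, n_boot = 200, seed = i)
    out$significant
  }, logical(1))
  # one-sided 95% CI exceedance: expected <= ~2.5%, allow up to 8%
  expect_lt(mean(hits), 0.08)
})

test_that("distribution comparisons report medians and detect planted shifts", {
  set.seed(37)
  rn <- tibble::tibble(S = rnorm(2000, 0, 0.05), C = rnorm(2000, 0, 0.05))
  rs <- tibble::tibble(S = rnorm(2000, 0, 0.08), C = rnorm(2000, 0, 0.05))
  out <- compare_selection_distributions(rn, rs)
  abs_s <- out[out$comparison == "abs_S", ]
  expect_lt(abs_s$p, 0.05)  # planted |S| shift
  expect_equal(abs_s$median_normal, median(abs(rn$S)))
  # identical tables: p near 1
  out_same <- compare_selection_distributions(rn, rn)
  expect_true(all(out_same$p[out_same$comparison %in%
                               c("abs_S", "S_positive")] > 0.9))
})

test_that("proportion z-test matches the closed form", {
  expect_equal(proportion_ztest(94, 130, 0.5)$p, 3.639e-7,
               tolerance = 1e-3)
  expect_equal(proportion_ztest(65, 130, 0.5)$p, 1)
  r <- proportion_ztest(9, 10, 0.5)
  expect_equal(r$z, 2.5298, tolerance = 1e-4)
  expect_equal(r$p, 0.0114, tolerance = 1e-2)
  expect_error(proportion_ztest(11, 10, 0.5), "k must be")
})
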