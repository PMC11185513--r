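#' Relative fitness from fecundity
#'
#' Drops zero-fecundity individuals, then divides fecundity by the mean
#' fecundity of the retained individuals within each environment, so mean
#' relative fitness is exactly 1 per environment.
#'
#' @param fitness tibble with `sample_id`, `fecundity`.
#' @param design study design tibble.
#' @return tibble with `sample_id`, `environment`, `w`.
#' @export
prepare_relative_fitness <- function(fitness, design) {
  df <- dplyr::inner_join(fitness, design[, c("sample_id", "environment")],
                          by = "sample_id")
  stop_if_not(nrow(df) == nrow(fitness), "fitness samples missing from design")
  df <- dplyr::filter(df, .data$fecundity > 0)
  counts <- table(factor(df$environment, levels = unique(design$environment)))
  stop_if_not(all(counts >= 2),
              "need >= 2 nonzero-fecundity samples per environment")
  df |>
    dplyr::group_by(.data$environment) |>
    dplyr::mutate(w = .data$fecundity / mean(.data$fecundity)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "environment", "w")
}

#' Univariate selection differentials on transcript abundance
#'
#' Per transcript and environment: linear (`S`) and quadratic (`C`)
#' selection differentials from regressions of relative fitness on
#' expression with block as a categorical fixed covariate. `S` is the
#' slope of `w ~ expression + block`; `C` is twice the squared-term
#' coefficient of `w ~ expression + expression^2 + block` (linear term
#' retained). Samples whose expression is more than `trim_sd` SDs from the
#' transcript mean are removed first; transcripts expressed (> 0) in fewer
#' than `min_n` retained individuals are skipped. Standardized variants
#' and a Bonferroni flag (family = all tested transcripts) are attached.
#'
#' @param expr samples x transcripts matrix, log2(TPM+1).
#' @param w relative fitness tibble from [prepare_relative_fitness()].
#' @param design study design tibble.
#' @param environment environment to analyse.
#' @param trim_sd outlier threshold in SD units (default 3).
#' @param min_n minimum number of retained individuals with expression > 0
#'   (default 20).
#' @return tibble, one row per tested transcript: `S`, `se_S`, `p_S`, `C`,
#'   `se_C`, `p_C`, variance-standardized (`S_s`, `C_s`) and
#'   mean-standardized (`S_m`, `C_m`) differentials, trait mean/SD on the
#'   retained samples, `n_used`, `bonferroni_sig`, and a `skipped` table of
#'   untested transcripts as attribute "skipped".
#' @export
estimate_differentials <- function(expr, w, design, environment,
                                   trim_sd = 3, min_n = 20) {
  stop_if_not(environment %in% design$environment,
              "environment '%s' not in design", environment)
  wenv <- dplyr::filter(w, .data$environment == !!environment)
  idx <- match(wenv$sample_id, rownames(expr))
  stop_if_not(!anyNA(idx), "fitness samples missing from expression matrix")
  X <- expr[idx, , drop = FALSE]
  wv <- wenv$w
  block <- factor(design$block[match(wenv$sample_id, design$sample_id)])
  n_t <- ncol(X)
  ids <- colnames(X) %||% sprintf("t%04d", seq_len(n_t))

  res <- vector("list", n_t)
  skipped <- character(0); skip_reason <- character(0)
  for (j in seq_len(n_t)) {
    x <- X[, j]
    mu0 <- mean(x); sd0 <- sd(x)
    keep <- if (sd0 > 0) abs(x - mu0) <= trim_sd * sd0 else rep(TRUE, length(x))
    xk <- x[keep]; wk <- wv[keep]; bk <- droplevels(block[keep])
    if (sum(xk > 0) < min_n) {
      skipped <- c(skipped, ids[j]); skip_reason <- c(skip_reason, "min_n")
      next
    }
    mu <- mean(xk); sdv <- sd(xk)
    if (sdv == 0) {
      skipped <- c(skipped, ids[j]); skip_reason <- c(skip_reason, "constant")
      next
    }
    use_block <- nlevels(bk) >= 2
    M1 <- if (use_block) stats::model.matrix(~ xk + bk) else
      stats::model.matrix(~ xk)
    f1 <- tryCatch(stats::lm.fit(M1, wk), error = function(e) NULL)
    if (is.null(f1) || is.na(f1$coefficients["xk"])) {
      skipped <- c(skipped, ids[j]); skip_reason <- c(skip_reason, "collinear")
      next
    }
    st1 <- ols_term_stats(f1, M1, "xk")
    M2 <- if (use_block) stats::model.matrix(~ xk + I(xk^2) + bk) else
      stats::model.matrix(~ xk + I(xk^2))
    f2 <- stats::lm.fit(M2, wk)
    st2 <- ols_term_stats(f2, M2, "I(xk^2)")
    res[[j]] <- tibble::tibble(
      transcript_id = ids[j], environment = environment,
      S = st1$beta, se_S = st1$se, p_S = st1$p,
      C = 2 * st2$beta, se_C = 2 * st2$se, p_C = st2$p,
      trait_mean = mu, trait_sd = sdv, n_used = length(xk)
    )
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) > 0) {
    out <- standardize_differentials(out)
    n_tested <- nrow(out)
    out$p_S_bonferroni <- pmin(1, out$p_S * n_tested)
    out$bonferroni_sig <- out$p_S_bonferroni < 0.05
  }
  attr(out, "skipped") <- tibble::tibble(transcript_id = skipped,
                                         reason = skip_reason)
  out
}

# coefficient, se and two-sided t-test p for one term of an lm.fit,
# handling pivoting / rank deficiency
ols_term_stats <- function(fit, M, term) {
  cf <- fit$coefficients
  if (!term %in% names(cf) || is.na(cf[term])) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_))
  }
  df <- fit$df.residual
  if (df <= 0) return(list(beta = unname(cf[term]), se = NA_real_,
                           p = NA_real_))
  sigma2 <- sum(fit$residuals^2) / df
  r <- fit$rank
  piv <- fit$qr$pivot[seq_len(r)]
  Rm <- qr.R(fit$qr)[seq_len(r), seq_len(r), drop = FALSE]
  vcv_diag <- diag(chol2inv(Rm)) * sigma2
  pos <- match(match(term, colnames(M)), piv)
  if (is.na(pos)) return(list(beta = NA_real_, se = NA_real_, p = NA_real_))
  se <- sqrt(vcv_diag[pos])
  beta <- unname(cf[term])
  t <- beta / se
  list(beta = beta, se = se, p = 2 * pt(-abs(t), df))
}

#' Variance- and mean-standardized selection differentials
#'
#' `S_s = S * sd`, `C_s = C * sd^2`, `S_m = S * mean`, `C_m = C * mean^2`,
#' equivalent to re-running the selection regressions on variance- or
#' mean-scaled traits. Trait means/SDs default to the `trait_mean` /
#' `trait_sd` columns computed on the retained samples.
#'
#' @param records selection record tibble from [estimate_differentials()].
#' @param trait_means,trait_sds optional overrides, aligned with `records`.
#' @return `records` with `S_s`, `C_s`, `S_m`, `C_m` filled (NA where the
#'   trait SD is zero).
#' @export
standardize_differentials <- function(records, trait_means = records$trait_mean,
                                      trait_sds = records$trait_sd) {
  ok <- trait_sds > 0
  records$S_s <- ifelse(ok, records$S * trait_sds, NA_real_)
  records$C_s <- ifelse(ok, records$C * trait_sds^2, NA_real_)
  records$S_m <- records$S * trait_means
  records$C_m <- records$C * trait_means^2
  records
}

#' Classify cross-environment selection trade-offs
#'
#' Conditional neutrality (CN): `p_S < 0.025` in exactly one environment
#' and `p_S > 0.05` in the other (asymmetric thresholds correct the
#' detection bias toward CN). Antagonistic pleiotropy (AP): `p_S < 0.05`
#' in both environments with opposite signs of `S`, sub-labelled by the
#' environment where expression is beneficial (`S > 0`). Same-sign
#' significance in both environments is `concordant`; anything else is
#' `none`.
#'
#' @param records_normal,records_saline selection record tibbles for the
#'   two environments.
#' @return tibble with `transcript_id` and `call`.
#' @export
classify_tradeoffs <- function(records_normal, records_saline) {
  df <- dplyr::full_join(
    dplyr::select(records_normal, "transcript_id", p_n = "p_S", S_n = "S"),
    dplyr::select(records_saline, "transcript_id", p_s = "p_S", S_s2 = "S"),
    by = "transcript_id"
  )
  call <- rep("none", nrow(df))
  missing <- is.na(df$p_n) | is.na(df$p_s)
  ap <- !missing & df$p_n < 0.05 & df$p_s < 0.05 &
    sign(df$S_n) != sign(df$S_s2)
  conc <- !missing & df$p_n < 0.05 & df$p_s < 0.05 &
    sign(df$S_n) == sign(df$S_s2)
  cn_n <- !missing & df$p_n < 0.025 & df$p_s > 0.05
  cn_s <- !missing & df$p_s < 0.025 & df$p_n > 0.05
  call[cn_n] <- "CN_normal"
  call[cn_s] <- "CN_saline"
  call[conc] <- "concordant"
  call[ap & df$S_n > 0] <- "AP_normal_beneficial"
  call[ap & df$S_s2 > 0] <- "AP_saline_beneficial"
  tibble::tibble(transcript_id = df$transcript_id, call = call,
                 missing_one_env = missing)
}

#' Selection on GO biological-process terms
#'
#' The selection strength of a term is the median |S| over its annotated,
#' tested transcripts (terms with fewer than `min_transcripts` are
#' excluded). A percentile bootstrap over the term's transcripts gives a
#' 95% CI; a term is significantly under stronger selection than the
#' transcriptome when the transcriptome-wide median strength lies below the
#' CI lower bound. The signed median of `S` is reported alongside.
#'
#' @param records selection record tibble for one environment.
#' @param annotation tibble with `transcript_id`, `term_id`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param min_transcripts minimum annotated, tested transcripts per term.
#' @return tibble per retained term: `term_id`, `n_transcripts`,
#'   `median_strength`, `median_signed`, `ci_low`, `ci_high`,
#'   `global_median`, `significant`, `environment`.
#' @export
go_term_selection <- function(records, annotation, n_boot = 1000, seed = 1,
                              min_transcripts = 20) {
  ann <- dplyr::inner_join(annotation, records[, c("transcript_id", "S")],
                           by = "transcript_id")
  ann$strength <- abs(ann$S)
  keep <- ann |>
    dplyr::count(.data$term_id) |>
    dplyr::filter(.data$n >= min_transcripts)
  if (nrow(keep) == 0) {
    return(tibble::tibble(term_id = character(), n_transcripts = integer(),
                          median_strength = double(), median_signed = double(),
                          ci_low = double(), ci_high = double(),
                          global_median = double(), significant = logical(),
                          environment = character()))
  }
  global_median <- median(abs(records$S))
  set.seed(derive_seed(seed, 31L))
  env <- records$environment[1] %||% NA_character_
  ann |>
    dplyr::filter(.data$term_id %in% keep$term_id) |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(
      n_transcripts = dplyr::n(),
      median_strength = median(.data$strength),
      median_signed = median(.data$S),
      ci = list({
        boots <- vapply(seq_len(n_boot), function(i) {
          median(sample(.data$strength, length(.data$strength),
                        replace = TRUE))
        }, numeric(1))
        quantile(boots, c(0.025, 0.975), names = FALSE)
      }),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_low = purrr::map_dbl(.data$ci, 1),
      ci_high = purrr::map_dbl(.data$ci, 2),
      global_median = global_median,
      significant = global_median < .data$ci_low,
      environment = env
    ) |>
    dplyr::select(-"ci")
}

#' Compare selection-differential distributions between environments
#'
#' Two-sided Mann-Whitney U tests on: |S| overall between environments;
#' S restricted to positive values; S restricted to negative values; C
#' positive; C negative; plus within-environment comparisons of positive S
#' versus |negative S|. Medians accompany every test.
#'
#' @param records_normal,records_saline selection record tibbles.
#' @return tibble with `comparison`, `median_normal`, `median_saline`,
#'   `n_normal`, `n_saline`, `p`, `skipped`.
#' @export
compare_selection_distributions <- function(records_normal, records_saline) {
  one <- function(name, a, b) {
    skipped <- length(a) == 0 || length(b) == 0
    tibble::tibble(
      comparison = name,
      median_normal = if (length(a)) median(a) else NA_real_,
      median_saline = if (length(b)) median(b) else NA_real_,
      n_normal = length(a), n_saline = length(b),
      p = if (skipped) NA_real_ else
        suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value),
      skipped = skipped
    )
  }
  rn <- records_normal; rs <- records_saline
  within <- function(name, r) {
    a <- r$S[r$S > 0]; b <- abs(r$S[r$S < 0])
    out <- one(name, a, b)
    names(out)[2:5] <- c("median_normal", "median_saline",
                         "n_normal", "n_saline")
    out
  }
  dplyr::bind_rows(
    one("abs_S", abs(rn$S), abs(rs$S)),
    one("S_positive", rn$S[rn$S > 0], rs$S[rs$S > 0]),
    one("S_negative", rn$S[rn$S < 0], rs$S[rs$S < 0]),
    one("C_positive", rn$C[rn$C > 0], rs$C[rs$C > 0]),
    one("C_negative", rn$C[rn$C < 0], rs$C[rs$C < 0]),
    within("normal_pos_vs_absneg", rn),
    within("saline_pos_vs_absneg", rs)
  )
}

#' One-sample proportion z-test
#'
#' Normal-approximation test of a sample proportion against `p0`, without
#' continuity correction: `z = (k/n - p0) / sqrt(p0 (1 - p0) / n)`,
#' two-sided p-value `2 (1 - Phi(|z|))`.
#'
#' @param k successes, `n` trials, `p0` null proportion.
#' @param n number of trials.
#' @param p0 null proportion (0 < p0 < 1).
#' @return tibble with `k`, `n`, `p0`, `estimate`, `z`, `p`.
#' @export
#' @examples
#' proportion_ztest(94, 130, 0.5)
proportion_ztest <- function(k, n, p0 = 0.5) {
  stop_if_not(n >= 1, "n must be positive")
  stop_if_not(k >= 0 && k <= n, "k must be in [0, n]")
  stop_if_not(p0 > 0 && p0 < 1, "p0 must be in (0, 1)")
  est <- k / n
  z <- (est - p0) / sqrt(p0 * (1 - p0) / n)
  tibble::tibble(k = k, n = n, p0 = p0, estimate = est, z = z,
                 p = 2 * pnorm(-abs(z)))
}
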