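#' Transcript filter for decoherence analysis
#'
#' Keeps transcripts with selection strength |S| > `s_threshold` in at
#' least one environment and expression > 0 in at least `expr_fraction` of
#' individuals (pooled over environments).
#'
#' @param records_normal,records_saline selection record tibbles.
#' @param expr samples x transcripts matrix.
#' @param s_threshold |S| cutoff (default 0.1).
#' @param expr_fraction minimum fraction of individuals with expression > 0
#'   (default 0.5).
#' @return character vector of transcript ids.
#' @export
select_decoherence_transcripts <- function(records_normal, records_saline,
                                           expr, s_threshold = 0.1,
                                           expr_fraction = 0.5) {
  s_ok <- union(
    records_normal$transcript_id[abs(records_normal$S) > s_threshold],
    records_saline$transcript_id[abs(records_saline$S) > s_threshold]
  )
  frac <- colMeans(expr > 0)
  expr_ok <- colnames(expr)[frac >= expr_fraction]
  intersect(s_ok, expr_ok)
}

#' Correlation-by-individual-level-product (CILP) test for decoherence
#'
#' Individuals are accession means per environment (replicates averaged).
#' Each transcript is z-scored within each environment with the population
#' (n-denominator) SD, so the mean of the per-individual products equals
#' that environment's Pearson correlation. For each unordered transcript
#' pair the product is regressed on an environment indicator (plus optional
#' covariates); the two-sided t-test p-value of the environment coefficient
#' measures the correlation change, with BH q-values across all tested
#' pairs.
#'
#' @param expr samples x transcripts matrix.
#' @param design study design tibble.
#' @param transcripts transcript ids to test (all unordered pairs).
#' @param covariates optional numeric matrix/data frame of per-individual
#'   covariates, rows aligned with accessions stacked
#'   (normal accessions, then saline accessions).
#' @return tibble per pair: `transcript_a`, `transcript_b`, `r_normal`,
#'   `r_saline`, `effect` (environment coefficient, saline minus normal),
#'   `p`, `q`, `skipped`.
#' @export
cilp <- function(expr, design, transcripts = colnames(expr),
                 covariates = NULL) {
  mn <- accession_means(expr, design, "normal")[, transcripts, drop = FALSE]
  ms <- accession_means(expr, design, "saline")[, transcripts, drop = FALSE]
  stop_if_not(nrow(mn) >= 10 && nrow(ms) >= 10,
              "need >= 10 individuals per environment")

  zscore_pop <- function(M) {
    mu <- colMeans(M)
    sdv <- sqrt(colMeans(sweep(M, 2, mu)^2))  # population (n) denominator
    Z <- sweep(sweep(M, 2, mu), 2, sdv, "/")
    list(Z = Z, ok = sdv > 0)
  }
  zn <- zscore_pop(mn); zs <- zscore_pop(ms)
  ok <- zn$ok & zs$ok

  g <- length(transcripts)
  stop_if_not(g >= 2, "need >= 2 transcripts")
  pair_idx <- which(upper.tri(matrix(0, g, g)), arr.ind = TRUE)
  ia <- pair_idx[, 1]; ib <- pair_idx[, 2]

  # per-environment correlations = mean of products under population z-scores
  Pn <- zn$Z[, ia, drop = FALSE] * zn$Z[, ib, drop = FALSE]
  Ps <- zs$Z[, ia, drop = FALSE] * zs$Z[, ib, drop = FALSE]
  r_normal <- unname(colMeans(Pn))
  r_saline <- unname(colMeans(Ps))

  # joint regression of products on the environment indicator: vectorized
  # OLS with a common design matrix across pairs
  env <- c(rep(0, nrow(mn)), rep(1, nrow(ms)))
  X <- cbind(1, env)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stop_if_not(nrow(covariates) == length(env),
                "covariates must have one row per stacked individual")
    X <- cbind(X, covariates)
  }
  Y <- rbind(Pn, Ps)
  qrX <- qr(X)
  cf <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  df <- nrow(X) - qrX$rank
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  # environment column is the 2nd column of X (pivoting: map back)
  pos <- match(2L, qrX$pivot)
  se <- sqrt(sigma2 * XtXinv[pos, pos])
  effect <- unname(cf[2, ])
  tstat <- effect / se
  p <- unname(2 * pt(-abs(tstat), df))

  skipped <- !(ok[ia] & ok[ib])
  p[skipped] <- NA_real_
  out <- tibble::tibble(
    transcript_a = transcripts[ia], transcript_b = transcripts[ib],
    r_normal = r_normal, r_saline = r_saline,
    effect = unname(effect), p = p, skipped = skipped
  )
  out$q <- NA_real_
  out$q[!skipped] <- bh_adjust(out$p[!skipped])
  out
}

#' Summarize decoherence pair tests
#'
#' Counts significant pairs (q below `fdr`) per transcript, the median
#' count among transcripts with at least one significant pair, and the set
#' of transcripts above that median (the input for downstream enrichment).
#'
#' @param pairs tibble from [cilp()].
#' @param fdr significance threshold on q (default 0.05).
#' @return list with `n_pairs_tested`, `n_significant`, `per_transcript`
#'   (tibble of counts), `median_significant_pairs`, `above_median` (ids).
#' @export
summarize_decoherence <- function(pairs, fdr = 0.05) {
  tested <- pairs[!pairs$skipped & !is.na(pairs$q), ]
  sig <- tested[tested$q < fdr, ]
  counts <- table(c(sig$transcript_a, sig$transcript_b))
  per_transcript <- tibble::tibble(
    transcript_id = names(counts),
    n_significant_pairs = as.integer(counts)
  )
  med <- if (nrow(per_transcript)) {
    median(per_transcript$n_significant_pairs)
  } else NA_real_
  above <- if (nrow(per_transcript)) {
    per_transcript$transcript_id[per_transcript$n_significant_pairs > med]
  } else character(0)
  list(n_pairs_tested = nrow(tested), n_significant = nrow(sig),
       per_transcript = per_transcript,
       median_significant_pairs = med, above_median = above)
}
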