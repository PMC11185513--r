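#' Partition expression variance into G, E and GxE components
#'
#' Two-way mixed ANOVA per transcript with environment (E) as a fixed
#' effect and genotype (G) and GxE as random effects. Sums of squares are
#' computed from accession-by-environment cell means with replicates;
#' F-tests follow the classic expected-mean-squares scheme for a random
#' interaction: `F_G = MS_G / MS_GxE`, `F_E = MS_E / MS_GxE`,
#' `F_GxE = MS_GxE / MS_res`. Variance components are method-of-moments
#' estimates from the expected mean squares, truncated at zero (flagged)
#' when negative. Broad-sense heritability is computed with the residual
#' (within-genotype environmental) variance in the environmental slot:
#' `H2 = s2_G / (s2_G + s2_GxE/e + s2_res/(r e))`.
#'
#' Unbalanced (but non-empty) cells are handled by an unweighted-means
#' analysis — sums of squares from cell means scaled by the harmonic mean
#' replicate number — with a warning.
#'
#' @param values numeric matrix (samples x transcripts) or a single numeric
#'   vector (e.g. fecundity) aligned with `design`.
#' @param design study design tibble with `sample_id`, `accession_id`,
#'   `environment` (see [sim_design()]).
#' @param fdr false-discovery rate used only to flag significance of the
#'   BH-adjusted q-values (default 0.001).
#' @return tibble, one row per transcript: sums of squares, mean squares,
#'   F statistics, p-values, BH q-values per term, method-of-moments
#'   `sigma2_G`, `sigma2_E` (fixed-effect quasi-component), `sigma2_GxE`,
#'   `sigma2_res`, truncation flag, `e`, `r`, and `H2`.
#' @export
partition_variance <- function(values, design, fdr = 0.001) {
  if (is.vector(values)) values <- matrix(values, ncol = 1,
                                          dimnames = list(NULL, "trait"))
  stop_if_not(nrow(values) == nrow(design),
              "values rows (%d) must match design rows (%d)",
              nrow(values), nrow(design))
  acc <- factor(design$accession_id)
  env <- factor(design$environment)
  a <- nlevels(acc); e <- nlevels(env)
  stop_if_not(a >= 2, "need >= 2 accession levels")
  stop_if_not(e >= 2, "need >= 2 environment levels")

  cell <- interaction(acc, env, drop = FALSE)
  n_cell <- as.vector(table(cell))
  stop_if_not(all(n_cell >= 1), "every accession x environment cell needs data")
  balanced <- length(unique(n_cell)) == 1L
  r_h <- length(n_cell) / sum(1 / n_cell)  # harmonic mean replicates
  if (!balanced) {
    warning("unbalanced cells: using unweighted-means analysis (harmonic ",
            "mean r = ", signif(r_h, 4), ")")
  }
  stop_if_not(r_h >= 2, "need >= 2 replicates per cell for variance partitioning")

  G <- ncol(values)
  # cell means matrix: (a*e) x G
  cm <- rowsum(values, cell, reorder = TRUE) / n_cell
  cell_lv <- levels(cell)
  acc_of_cell <- factor(sub("\\..*$", "", cell_lv), levels = levels(acc))
  env_of_cell <- factor(sub("^.*\\.", "", cell_lv), levels = levels(env))

  acc_means <- rowsum(cm, acc_of_cell) / e          # a x G
  env_means <- rowsum(cm, env_of_cell) / a          # e x G
  grand <- colMeans(cm)                             # over cell means

  ss_G <- r_h * e * colSums((acc_means - matrix(grand, a, G, byrow = TRUE))^2)
  ss_E <- r_h * a * colSums((env_means - matrix(grand, e, G, byrow = TRUE))^2)
  dev <- cm - acc_means[acc_of_cell, , drop = FALSE] -
    env_means[env_of_cell, , drop = FALSE] +
    matrix(grand, a * e, G, byrow = TRUE)
  ss_GxE <- r_h * colSums(dev^2)
  ss_res <- colSums((values - cm[cell, , drop = FALSE])^2)

  df_G <- a - 1; df_E <- e - 1; df_GxE <- (a - 1) * (e - 1)
  df_res <- sum(n_cell) - a * e
  ms_G <- ss_G / df_G; ms_E <- ss_E / df_E
  ms_GxE <- ss_GxE / df_GxE; ms_res <- ss_res / df_res

  F_G <- ms_G / ms_GxE; F_E <- ms_E / ms_GxE; F_GxE <- ms_GxE / ms_res
  p_G <- pf(F_G, df_G, df_GxE, lower.tail = FALSE)
  p_E <- pf(F_E, df_E, df_GxE, lower.tail = FALSE)
  p_GxE <- pf(F_GxE, df_GxE, df_res, lower.tail = FALSE)
  # degenerate all-zero transcripts: F = 0/0
  p_G[is.nan(F_G)] <- NA; p_E[is.nan(F_E)] <- NA; p_GxE[is.nan(F_GxE)] <- NA

  s2_res <- ms_res
  s2_GxE_raw <- (ms_GxE - ms_res) / r_h
  s2_G_raw <- (ms_G - ms_GxE) / (r_h * e)
  s2_E_raw <- (ms_E - ms_GxE) / (r_h * a)
  truncated <- s2_GxE_raw < 0 | s2_G_raw < 0 | s2_E_raw < 0
  s2_GxE <- pmax(s2_GxE_raw, 0)
  s2_G <- pmax(s2_G_raw, 0)
  s2_E <- pmax(s2_E_raw, 0)

  H2 <- broad_sense_heritability(s2_G, s2_GxE, s2_res, e = e, r = r_h)

  ss_G <- unname(ss_G); ss_E <- unname(ss_E)
  ss_GxE <- unname(ss_GxE); ss_res <- unname(ss_res)
  ms_G <- unname(ms_G); ms_E <- unname(ms_E)
  ms_GxE <- unname(ms_GxE); ms_res <- unname(ms_res)
  F_G <- unname(F_G); F_E <- unname(F_E); F_GxE <- unname(F_GxE)
  p_G <- unname(p_G); p_E <- unname(p_E); p_GxE <- unname(p_GxE)
  s2_G <- unname(s2_G); s2_E <- unname(s2_E)
  s2_GxE <- unname(s2_GxE); s2_res <- unname(s2_res)
  truncated <- unname(truncated); H2 <- unname(H2)
  tibble::tibble(
    transcript_id = colnames(values) %||% sprintf("t%04d", seq_len(G)),
    ss_G = ss_G, ss_E = ss_E, ss_GxE = ss_GxE, ss_res = ss_res,
    ms_G = ms_G, ms_E = ms_E, ms_GxE = ms_GxE, ms_res = ms_res,
    F_G = F_G, F_E = F_E, F_GxE = F_GxE,
    p_G = p_G, p_E = p_E, p_GxE = p_GxE,
    q_G = bh_adjust(p_G), q_E = bh_adjust(p_E), q_GxE = bh_adjust(p_GxE),
    sig_G = .data$q_G < fdr, sig_E = .data$q_E < fdr,
    sig_GxE = .data$q_GxE < fdr,
    sigma2_G = s2_G, sigma2_E = s2_E, sigma2_GxE = s2_GxE,
    sigma2_res = s2_res, truncated = truncated,
    e = e, r = r_h, H2 = H2
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Broad-sense heritability of a replicated two-environment trait
#'
#' `H2 = sigma2_G / (sigma2_G + sigma2_GE / e + sigma2_E / (r e))`, where
#' `sigma2_E` is the within-genotype environmental (residual) variance, `e`
#' the number of environments and `r` the replicates per environment.
#' Returns `NA` when all components are zero (undefined).
#'
#' @param sigma2_G,sigma2_GE,sigma2_E non-negative variance components
#'   (vectors recycle).
#' @param e,r number of environments and replicates per environment.
#' @return numeric vector of heritabilities in \[0, 1\].
#' @export
#' @examples
#' broad_sense_heritability(2, 0, 0, e = 2, r = 3)  # 1
#' broad_sense_heritability(1, 1, 6, e = 2, r = 3)  # 0.4
broad_sense_heritability <- function(sigma2_G, sigma2_GE, sigma2_E, e, r) {
  stop_if_not(all(sigma2_G >= 0) && all(sigma2_GE >= 0) && all(sigma2_E >= 0),
              "variance components must be non-negative")
  stop_if_not(e >= 1 && r >= 1, "e and r must be >= 1")
  denom <- sigma2_G + sigma2_GE / e + sigma2_E / (r * e)
  out <- sigma2_G / denom
  out[denom == 0] <- NA_real_
  out
}

#' Inter-varietal variance of expression within one environment
#'
#' Replicates are averaged within accession; the population-wide variance
#' (denominator n - 1) across accession mean expression levels is returned
#' per transcript.
#'
#' @param expr samples x transcripts matrix.
#' @param design study design tibble.
#' @param environment which environment to use ("normal" or "saline").
#' @return tibble with `transcript_id` and `intervar_variance`.
#' @export
intervarietal_variance <- function(expr, design, environment) {
  stop_if_not(environment %in% design$environment,
              "environment '%s' not present in design", environment)
  sel <- design$environment == environment
  means <- accession_means(expr, design, environment)
  stop_if_not(nrow(means) >= 2, "need >= 2 accessions")
  tibble::tibble(
    transcript_id = colnames(expr) %||% sprintf("t%04d", seq_len(ncol(expr))),
    intervar_variance = unname(apply(means, 2, var))
  )
}

#' Average replicates to accession-level expression
#'
#' @param expr samples x transcripts matrix.
#' @param design study design tibble.
#' @param environment environment label to subset to.
#' @return accessions x transcripts matrix of replicate means, rows named
#'   by accession.
#' @export
accession_means <- function(expr, design, environment) {
  sel <- design$environment == environment
  stop_if_not(any(sel), "environment '%s' not present in design", environment)
  sub <- expr[sel, , drop = FALSE]
  acc <- design$accession_id[sel]
  rowsum(sub, acc, reorder = TRUE) / as.vector(table(factor(acc)))
}
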