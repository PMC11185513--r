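#' PCA of expression within one environment
#'
#' Column-centered PCA via SVD on the samples-by-transcripts matrix of one
#' environment. A deterministic sign convention is applied (the
#' largest-magnitude loading of each PC is positive). PCs explaining more
#' than `var_threshold` of the variance are marked selected.
#'
#' @param expr samples x transcripts matrix.
#' @param design study design tibble.
#' @param environment environment to analyse.
#' @param var_threshold minimum fraction of variance explained for a PC to
#'   be selected (default 0.005, i.e. 0.5%).
#' @return an object of class `pc_model`: list with `loadings`
#'   (transcripts x PCs), `scores` (samples x PCs), `var_explained`,
#'   `selected_pcs` (integer indices), `center`, `environment`.
#' @export
fit_pca <- function(expr, design, environment, var_threshold = 0.005) {
  sel <- design$environment == environment
  stop_if_not(any(sel), "environment '%s' not in design", environment)
  X <- expr[design$sample_id[sel], , drop = FALSE]
  stop_if_not(nrow(X) >= 2 && ncol(X) >= 2, "need >= 2 samples and transcripts")
  stop_if_not(any(apply(X, 2, sd) > 0), "constant expression matrix")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  # sign convention: largest-|loading| entry positive
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation, scores = pc$x, var_explained = ve,
                 selected_pcs = which(ve > var_threshold),
                 center = pc$center, environment = environment),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("pc_model (%s): %d samples x %d transcripts, %d selected PCs\n",
              x$environment, nrow(x$scores), nrow(x$loadings),
              length(x$selected_pcs)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pc_model <- function(x, ...) {
  tibble::tibble(pc = seq_along(x$var_explained),
                 var_explained = x$var_explained,
                 selected = seq_along(x$var_explained) %in% x$selected_pcs)
}

#' @exportS3Method generics::glance
glance.pc_model <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$scores), n_transcripts = nrow(x$loadings),
                 n_selected = length(x$selected_pcs),
                 environment = x$environment)
}

#' Multivariate selection gradients on expression PCs
#'
#' Linear gradients (beta) come from one joint multiple regression of
#' relative fitness on all selected PC scores; quadratic gradients (gamma)
#' are twice the squared-term coefficients of the quadratic extension
#' (linear terms retained). Each PC is assigned a direction by majority
#' vote over its top 1% |loading| transcripts, comparing the sign of the
#' loading with the sign of the univariate selection differential.
#'
#' @param pc a `pc_model` from [fit_pca()].
#' @param w relative fitness tibble from [prepare_relative_fitness()].
#' @param records optional univariate selection record tibble used for the
#'   direction vote (`NULL` skips the vote).
#' @param top_frac fraction of transcripts counted as top loadings (0.01).
#' @return tibble per selected PC: `pc`, `beta`, `se_beta`, `p_beta`,
#'   `gamma`, `se_gamma`, `p_gamma`, `var_explained`, `assigned_direction`.
#' @export
estimate_gradients <- function(pc, w, records = NULL, top_frac = 0.01) {
  stopifnot(inherits(pc, "pc_model"))
  sel <- pc$selected_pcs
  stop_if_not(length(sel) >= 1, "no selected PCs")
  wenv <- dplyr::filter(w, .data$environment == pc$environment)
  idx <- match(wenv$sample_id, rownames(pc$scores))
  wv <- wenv$w[!is.na(idx)]
  S <- pc$scores[idx[!is.na(idx)], sel, drop = FALSE]
  stop_if_not(nrow(S) > 2 * length(sel) + 2, "more PCs than samples support")

  M1 <- cbind(1, S)
  colnames(M1) <- c("(Intercept)", colnames(S))
  f1 <- stats::lm.fit(M1, wv)
  M2 <- cbind(1, S, S^2)
  colnames(M2) <- c("(Intercept)", colnames(S), paste0(colnames(S), "_sq"))
  f2 <- stats::lm.fit(M2, wv)

  st1 <- lapply(colnames(S), function(nm) ols_term_stats(f1, M1, nm))
  st2 <- lapply(paste0(colnames(S), "_sq"),
                function(nm) ols_term_stats(f2, M2, nm))

  ve <- pc$var_explained[sel]
  env <- pc$environment
  out <- tibble::tibble(
    pc = sel,
    pc_id = colnames(S),
    beta = vapply(st1, `[[`, 0, "beta"),
    se_beta = vapply(st1, `[[`, 0, "se"),
    p_beta = vapply(st1, `[[`, 0, "p"),
    gamma = 2 * vapply(st2, `[[`, 0, "beta"),
    se_gamma = 2 * vapply(st2, `[[`, 0, "se"),
    p_gamma = vapply(st2, `[[`, 0, "p"),
    var_explained = ve,
    environment = env
  )
  out$assigned_direction <- NA_character_
  if (!is.null(records)) {
    n_top <- max(1L, ceiling(top_frac * nrow(pc$loadings)))
    for (i in seq_along(sel)) {
      ld <- pc$loadings[, sel[i]]
      top <- names(sort(abs(ld), decreasing = TRUE))[seq_len(n_top)]
      sgn <- sign(ld[top]) *
        sign(records$S[match(top, records$transcript_id)])
      sgn <- sgn[!is.na(sgn) & sgn != 0]
      if (length(sgn) > 0) {
        out$assigned_direction[i] <-
          if (mean(sgn > 0) >= 0.5) "positive" else "negative"
      }
    }
  }
  out
}

#' Genomic relationship (kinship) matrix
#'
#' VanRaden-form genomic relationship matrix:
#' `K = (X - 2p)(X - 2p)' / (2 sum p(1-p))` over MAF-polymorphic SNPs,
#' with missing dosages mean-imputed for this computation. For a fully
#' inbred population the mean diagonal approaches 1 + f = 2.
#'
#' @param genotypes a `genotype_matrix`.
#' @return symmetric accessions x accessions matrix.
#' @export
compute_kinship <- function(genotypes) {
  X <- genotypes$dosages
  stop_if_not(nrow(X) >= 2, "need >= 2 accessions")
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  stop_if_not(any(poly), "no polymorphic SNPs")
  X <- X[, poly, drop = FALSE]; p <- p[poly]
  Z <- sweep(X, 2, 2 * p)
  if (anyNA(Z)) Z[is.na(Z)] <- 0  # mean-imputed (centered) missing calls
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  (K + t(K)) / 2
}

#' Additive genetic (co)variance matrix of expression PCs
#'
#' PC scores are averaged to accession level ("eigengenes"); a
#' single-component spectral REML with the kinship matrix plus an identity
#' residual estimates the additive variance of each selected PC.
#' Covariances come from the polarization identity
#' `Cov(x, y) = [VarA(x+y) - VarA(x) - VarA(y)] / 2` using the same REML
#' on sums. The matrix is symmetrized and near-positive-semidefiniteness
#' is enforced by clipping negative eigenvalues at zero (flagged).
#'
#' @param pc a `pc_model` from [fit_pca()].
#' @param design study design tibble.
#' @param kinship accession x accession matrix from [compute_kinship()].
#' @param pcs which PCs to include (default the model's selected PCs).
#' @return object of class `g_matrix`: list with `G` (the matrix),
#'   `h2` (per-PC heritability estimates), `clipped` flag, `environment`.
#' @export
estimate_G <- function(pc, design, kinship, pcs = pc$selected_pcs) {
  stopifnot(inherits(pc, "pc_model"))
  env <- pc$environment
  dsub <- design[design$environment == env, ]
  acc <- intersect(rownames(kinship), unique(dsub$accession_id))
  stop_if_not(length(acc) >= 10, "need >= 10 accessions with kinship")
  # eigengene: accession means of PC scores
  Sc <- pc$scores[dsub$sample_id, pcs, drop = FALSE]
  M <- rowsum(Sc, dsub$accession_id, reorder = TRUE) /
    as.vector(table(factor(dsub$accession_id)))
  M <- M[acc, , drop = FALSE]
  K <- kinship[acc, acc]
  ek <- eigen(K, symmetric = TRUE)
  stop_if_not(min(ek$values) > -1e-6 * max(ek$values),
              "kinship matrix is not positive semidefinite")

  k <- length(pcs)
  G <- matrix(0, k, k, dimnames = list(colnames(M), colnames(M)))
  h2 <- numeric(k)
  varA <- function(y) reml_variance(y, ek)
  va <- apply(M, 2, function(y) {
    f <- varA(y); c(f$sigma2_A, f$h2)
  })
  diag(G) <- va[1, ]
  h2 <- va[2, ]
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        vsum <- varA(M[, i] + M[, j])$sigma2_A
        G[i, j] <- G[j, i] <- (vsum - G[i, i] - G[j, j]) / 2
      }
    }
  }
  eg <- eigen(G, symmetric = TRUE)
  clipped <- any(eg$values < 0)
  if (clipped) {
    vals <- pmax(eg$values, 0)
    G <- eg$vectors %*% diag(vals, k) %*% t(eg$vectors)
    dimnames(G) <- list(colnames(M), colnames(M))
    G <- (G + t(G)) / 2
  }
  structure(list(G = G, h2 = setNames(h2, colnames(M)), clipped = clipped,
                 environment = env, pcs = pcs),
            class = "g_matrix")
}

# single-component REML: y = 1 mu + g + e, g ~ N(0, s2A K), e ~ N(0, s2e I),
# maximized over h2 = s2A / (s2A + s2e) using the spectral decomposition of K
reml_variance <- function(y, ek, tol = 1e-6) {
  U <- ek$vectors; d <- pmax(ek$values, 0)
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, length(y))))
  n <- length(y)
  nll <- function(h2) {
    v <- h2 * d + (1 - h2)            # V0 eigenvalues
    v <- pmax(v, 1e-12)
    xvx <- sum(xt^2 / v)
    bhat <- sum(xt * yt / v) / xvx
    r <- yt - xt * bhat
    s2 <- sum(r^2 / v) / (n - 1)
    0.5 * ((n - 1) * log(s2) + sum(log(v)) + log(xvx))
  }
  opt <- optimize(nll, c(0, 1), tol = tol)
  h2 <- opt$minimum
  v <- pmax(h2 * d + (1 - h2), 1e-12)
  xvx <- sum(xt^2 / v)
  bhat <- sum(xt * yt / v) / xvx
  r <- yt - xt * bhat
  s2 <- sum(r^2 / v) / (n - 1)
  # compare boundary h2 = 0 explicitly (optimize can miss the edge)
  if (nll(0) <= opt$objective) {
    h2 <- 0
    s2 <- sum((y - mean(y))^2) / (n - 1)
  }
  list(sigma2_A = h2 * s2, sigma2_e = (1 - h2) * s2, h2 = h2)
}

#' @export
print.g_matrix <- function(x, ...) {
  cat(sprintf("g_matrix (%s): %d PCs, %sclipped\n", x$environment,
              nrow(x$G), if (x$clipped) "" else "not "))
  print(round(x$G, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.g_matrix <- function(x, ...) {
  G <- x$G
  idx <- which(upper.tri(G, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(pc_a = rownames(G)[idx[, 1]], pc_b = colnames(G)[idx[, 2]],
                 value = G[idx],
                 component = ifelse(idx[, 1] == idx[, 2],
                                    "variance", "covariance"))
}

#' @exportS3Method generics::glance
glance.g_matrix <- function(x, ...) {
  tibble::tibble(n_pcs = nrow(x$G), trace = sum(diag(x$G)),
                 min_eigenvalue = min(eigen(x$G, symmetric = TRUE,
                                            only.values = TRUE)$values),
                 clipped = x$clipped, environment = x$environment)
}

#' Predicted response to selection (multivariate breeder's equation)
#'
#' `total = G beta`; the direct response of PC i is `G_ii beta_i` and the
#' indirect response is the remainder. PCs whose direct and indirect
#' responses are nonzero with opposite signs are flagged as constrained.
#'
#' @param G a `g_matrix` or a plain symmetric matrix.
#' @param gradients gradient tibble from [estimate_gradients()] (uses
#'   `beta`), or a bare numeric vector.
#' @return tibble per PC: `pc_id`, `beta`, `direct`, `indirect`, `total`,
#'   `constraint_flag`.
#' @export
predict_response <- function(G, gradients) {
  Gm <- if (inherits(G, "g_matrix")) G$G else G
  beta <- if (is.numeric(gradients)) gradients else gradients$beta
  stop_if_not(length(beta) == nrow(Gm),
              "gradient length (%d) must match G dimension (%d)",
              length(beta), nrow(Gm))
  total <- unname(drop(Gm %*% beta))
  direct <- unname(diag(Gm) * beta)
  indirect <- total - direct
  tibble::tibble(
    pc_id = rownames(Gm) %||% paste0("PC", seq_along(beta)),
    beta = beta, direct = direct, indirect = indirect, total = total,
    constraint_flag = direct != 0 & indirect != 0 &
      sign(direct) != sign(indirect)
  )
}
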