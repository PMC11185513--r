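#' Map eQTLs by a vectorized linear-model scan
#'
#' For every SNP-transcript pair, ordinary least squares of accession-mean
#' expression on dosage plus the leading kinship eigenvector covariates,
#' with a two-sided t-test on the dosage slope and BH q-values across all
#' pairs in the environment. The scan residualizes expression and dosage
#' on the covariates then correlates the residuals, which is
#' mathematically identical to per-pair OLS (asserted in the test suite).
#' Monomorphic SNPs are skipped; missing dosages are handled per SNP by
#' complete-case analysis.
#'
#' @param expr_means accessions x transcripts matrix (replicates averaged;
#'   see [accession_means()]).
#' @param genotypes a `genotype_matrix`; accession rows must cover the
#'   rows of `expr_means`.
#' @param n_covariate_pcs number of kinship-matrix eigenvectors used as
#'   covariates (default 5).
#' @param fdr BH false-discovery threshold for retained associations
#'   (default 0.001).
#' @param environment label attached to the output.
#' @param kinship optional precomputed kinship matrix.
#' @param return_all return every tested pair instead of only q < fdr.
#' @return tibble: `snp_id`, `chrom`, `pos`, `transcript_id`, `beta`,
#'   `se`, `p`, `q`, `environment`.
#' @export
map_eqtl <- function(expr_means, genotypes, n_covariate_pcs = 5,
                     fdr = 0.001, environment = NA_character_,
                     kinship = NULL, return_all = FALSE) {
  acc <- rownames(expr_means)
  stop_if_not(!is.null(acc), "expr_means must have accession rownames")
  stop_if_not(all(acc %in% rownames(genotypes$dosages)),
              "accessions missing from genotype matrix")
  X <- genotypes$dosages[acc, , drop = FALSE]
  n <- nrow(X)

  if (is.null(kinship)) kinship <- compute_kinship(genotypes)
  kinship <- kinship[acc, acc]
  C <- cbind(1, eigen(kinship, symmetric = TRUE)$vectors[,
             seq_len(min(n_covariate_pcs, n - 2)), drop = FALSE])

  poly <- apply(X, 2, function(x) {
    x <- x[!is.na(x)]
    length(unique(x)) > 1
  })
  keep_snps <- which(poly)

  qrC <- qr(C)
  Yr <- qr.resid(qrC, expr_means)
  has_na <- anyNA(X)
  df <- n - ncol(C) - 1

  if (!has_na) {
    Xr <- qr.resid(qrC, X[, keep_snps, drop = FALSE])
    sx2 <- colSums(Xr^2)
    sy2 <- colSums(Yr^2)
    XtY <- crossprod(Xr, Yr)                       # snps x transcripts
    beta <- XtY / sx2
    rss <- outer(rep(1, length(sx2)), sy2) - beta^2 * sx2
    sigma2 <- pmax(rss, 0) / df
    se <- sqrt(sigma2 / sx2)
    tstat <- beta / se
    p <- 2 * pt(-abs(tstat), df)
  } else {
    # per-SNP complete-case fallback (missing dosages excluded pairwise)
    ns <- length(keep_snps); ng <- ncol(expr_means)
    beta <- se <- p <- matrix(NA_real_, ns, ng)
    for (i in seq_len(ns)) {
      x <- X[, keep_snps[i]]
      cc <- !is.na(x)
      qrCc <- qr(C[cc, , drop = FALSE])
      xr <- qr.resid(qrCc, x[cc])
      yr <- qr.resid(qrCc, expr_means[cc, , drop = FALSE])
      sx2 <- sum(xr^2)
      if (sx2 <= 0) next
      b <- drop(crossprod(xr, yr)) / sx2
      rssd <- colSums(yr^2) - b^2 * sx2
      dfi <- sum(cc) - qrCc$rank - 1
      if (dfi <= 0) next
      s2 <- pmax(rssd, 0) / dfi
      sei <- sqrt(s2 / sx2)
      beta[i, ] <- b; se[i, ] <- sei
      p[i, ] <- 2 * pt(-abs(b / sei), dfi)
    }
  }

  snp_ids <- colnames(genotypes$dosages)[keep_snps]
  out <- tibble::tibble(
    snp_id = rep(snp_ids, times = ncol(expr_means)),
    chrom = rep(genotypes$chrom[keep_snps], times = ncol(expr_means)),
    pos = rep(genotypes$pos[keep_snps], times = ncol(expr_means)),
    transcript_id = rep(colnames(expr_means), each = length(keep_snps)),
    beta = as.vector(beta), se = as.vector(se), p = as.vector(p)
  )
  out <- out[!is.na(out$p), ]
  out$q <- bh_adjust(out$p)
  out$environment <- environment
  if (!return_all) out <- out[out$q < fdr, ]
  out[order(out$p), ]
}

#' Classify associations as cis or trans
#'
#' cis: same chromosome and SNP-to-TSS distance < `cis_kb` kilobases.
#' trans: different chromosome, or distance >= `trans_mb` megabases.
#' Same-chromosome associations in between are `unclassified`, as are
#' transcripts without a position (flagged).
#'
#' @param assoc association tibble from [map_eqtl()].
#' @param positions tibble with `transcript_id`, `chrom`, `tss_pos`.
#' @param cis_kb,trans_mb distance thresholds (defaults 100 kb / 1 Mb).
#' @return `assoc` with `distance` and `cis_trans` columns.
#' @export
classify_cis_trans <- function(assoc, positions, cis_kb = 100, trans_mb = 1) {
  m <- match(assoc$transcript_id, positions$transcript_id)
  gchrom <- positions$chrom[m]
  gpos <- positions$tss_pos[m]
  distance <- ifelse(assoc$chrom == gchrom, abs(assoc$pos - gpos), NA_real_)
  cls <- dplyr::case_when(
    is.na(gchrom) ~ "unclassified",
    assoc$chrom != gchrom ~ "trans",
    distance < cis_kb * 1e3 ~ "cis",
    distance >= trans_mb * 1e6 ~ "trans",
    TRUE ~ "unclassified"
  )
  assoc$distance <- distance
  assoc$cis_trans <- cls
  assoc$missing_position <- is.na(gchrom)
  assoc
}

#' Environment overlap of significant associations
#'
#' For each cis/trans class, counts associations (SNP-transcript pairs)
#' shared between the two environments, with the percentage computed
#' against the union ("of a total" = union of both environments'
#' significant sets). Mean |beta| is compared between classes within each
#' environment and between environments by Welch t-tests.
#'
#' @param assoc_normal,assoc_saline classified association tibbles.
#' @return list with `overlap` (tibble per class: `n_common`, `n_union`,
#'   `pct_common`) and `effect_sizes` (tibble of mean |beta| with t-tests).
#' @export
compare_environment_overlap <- function(assoc_normal, assoc_saline) {
  key <- function(a) paste(a$snp_id, a$transcript_id)
  overlap <- purrr::map_dfr(c("cis", "trans"), function(cl) {
    a <- key(assoc_normal[assoc_normal$cis_trans == cl, ])
    b <- key(assoc_saline[assoc_saline$cis_trans == cl, ])
    n_common <- length(intersect(a, b))
    n_union <- length(union(a, b))
    tibble::tibble(class = cl, n_normal = length(a), n_saline = length(b),
                   n_common = n_common, n_union = n_union,
                   pct_common = if (n_union > 0) 100 * n_common / n_union
                   else NA_real_)
  })
  eff <- purrr::map_dfr(c("cis", "trans"), function(cl) {
    a <- abs(assoc_normal$beta[assoc_normal$cis_trans == cl])
    b <- abs(assoc_saline$beta[assoc_saline$cis_trans == cl])
    tibble::tibble(
      class = cl, mean_abs_beta_normal = mean(a), mean_abs_beta_saline = mean(b),
      p_between_env = safe_t_test(a, b)
    )
  })
  cis_vs_trans <- purrr::map_dfr(
    list(normal = assoc_normal, saline = assoc_saline),
    function(a) {
      ci <- abs(a$beta[a$cis_trans == "cis"])
      tr <- abs(a$beta[a$cis_trans == "trans"])
      tibble::tibble(
        mean_abs_beta_cis = mean(ci), mean_abs_beta_trans = mean(tr),
        p_cis_vs_trans = safe_t_test(ci, tr)
      )
    }, .id = "environment")
  list(overlap = overlap, effect_sizes = eff, cis_vs_trans = cis_vs_trans)
}

# Welch t-test returning NA on degenerate inputs
safe_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
}

#' Overlap percentage from common and union counts
#'
#' `100 * n_common / n_union`, the "common in both environments (of a
#' total)" percentage used when comparing eQTL sets across environments.
#'
#' @param n_common associations shared by both environments.
#' @param n_union size of the union of both significant sets.
#' @return percentage (numeric scalar).
#' @export
overlap_percent <- function(n_common, n_union) {
  stop_if_not(n_union >= n_common && n_common >= 0, "invalid counts")
  100 * n_common / n_union
}

#' Map GxE eQTLs on the expression difference between environments
#'
#' The response is the per-accession difference of replicate-mean
#' expression (normal minus saline); the scan is identical to
#' [map_eqtl()]. Use [classify_cis_trans()] and [gxe_cis_fraction()] on
#' the result.
#'
#' @param expr_means_normal,expr_means_saline accession x transcript
#'   matrices for the two environments (same accessions).
#' @param genotypes a `genotype_matrix`.
#' @param fdr BH threshold (default 0.05).
#' @param ... passed to [map_eqtl()].
#' @return association tibble with `environment = "gxe"`.
#' @export
map_gxe <- function(expr_means_normal, expr_means_saline, genotypes,
                    fdr = 0.05, ...) {
  acc <- intersect(rownames(expr_means_normal), rownames(expr_means_saline))
  stop_if_not(length(acc) >= 10, "need >= 10 shared accessions")
  diffm <- expr_means_normal[acc, , drop = FALSE] -
    expr_means_saline[acc, , drop = FALSE]
  map_eqtl(diffm, genotypes, fdr = fdr, environment = "gxe", ...)
}

#' Fraction of cis associations among significant GxE eQTLs
#'
#' @param assoc classified GxE association tibble.
#' @return tibble with `n_cis`, `n_total`, `pct_cis`.
#' @export
gxe_cis_fraction <- function(assoc) {
  n_cis <- sum(assoc$cis_trans == "cis")
  n_total <- nrow(assoc)
  tibble::tibble(n_cis = n_cis, n_total = n_total,
                 pct_cis = if (n_total > 0) 100 * n_cis / n_total else NA_real_)
}

#' Lead SNPs per 100-kb window and trans-eQTL hotspots
#'
#' For every (transcript, chromosome, window) the most significant SNP is
#' the lead (ties broken by lower position). A window is a hotspot when
#' its lead SNPs trans-regulate strictly more than `min_genes` distinct
#' transcripts.
#'
#' @param assoc classified association tibble.
#' @param window window width in bp (default 1e5).
#' @param min_genes hotspot threshold: unique trans genes must exceed this
#'   (default 30).
#' @return list with `assoc` (input plus `is_lead` and `window_start`,
#'   1-based) and `hotspots` (tibble: `chrom`, `window_start`,
#'   `window_end`, `n_unique_genes`, `lead_snps`, `hotspot`).
#' @export
lead_and_hotspots <- function(assoc, window = 1e5, min_genes = 30) {
  assoc$window_start <- (assoc$pos - 1L) %/% as.integer(window) *
    as.integer(window) + 1L
  assoc <- assoc |>
    dplyr::group_by(.data$transcript_id, .data$chrom, .data$window_start) |>
    dplyr::mutate(is_lead = seq_along(.data$p) ==
                    order(.data$p, .data$pos)[1]) |>
    dplyr::ungroup()
  leads <- assoc[assoc$is_lead & assoc$cis_trans == "trans", ]
  hotspots <- leads |>
    dplyr::group_by(.data$chrom, .data$window_start) |>
    dplyr::summarise(
      n_unique_genes = dplyr::n_distinct(.data$transcript_id),
      lead_snps = list(sort(unique(.data$snp_id))),
      .groups = "drop"
    ) |>
    dplyr::mutate(window_end = .data$window_start + as.integer(window) - 1L,
                  hotspot = .data$n_unique_genes > min_genes) |>
    dplyr::arrange(dplyr::desc(.data$n_unique_genes))
  list(assoc = assoc, hotspots = hotspots)
}

#' Cis-trans compensation / reinforcement calls
#'
#' For every transcript with a lead cis eQTL and at least one lead trans
#' eQTL in an environment: the cis contribution of each accession is
#' `beta_cis * (dosage - mean dosage)`; the trans contribution is the mean
#' of the analogous terms over the lead trans SNPs. The fraction of
#' accessions whose cis and trans contributions have the same sign
#' (strictly positive product; zero products excluded from the
#' denominator) drives the call: reinforcing when >= `threshold`,
#' compensating when the opposite fraction is >= `threshold`, otherwise
#' unclassified.
#'
#' @param assoc association tibble with `is_lead` (see
#'   [lead_and_hotspots()]) and `cis_trans`.
#' @param genotypes a `genotype_matrix`.
#' @param threshold same/opposite-direction fraction needed for a call
#'   (default 0.6).
#' @return tibble per qualifying transcript: `transcript_id`,
#'   `cis_snp`, `cis_beta`, `n_trans`, `mean_trans_beta`,
#'   `same_direction_fraction`, `call`.
#' @export
call_cis_trans_architecture <- function(assoc, genotypes, threshold = 0.6) {
  leads <- assoc[assoc$is_lead, ]
  dos <- genotypes$dosages
  genes <- intersect(
    unique(leads$transcript_id[leads$cis_trans == "cis"]),
    unique(leads$transcript_id[leads$cis_trans == "trans"])
  )
  empty <- tibble::tibble(
    transcript_id = character(), cis_snp = character(), cis_beta = double(),
    n_trans = integer(), mean_trans_beta = double(),
    same_direction_fraction = double(), call = character()
  )
  if (length(genes) == 0) return(empty)
  purrr::map_dfr(genes, function(gid) {
    sub <- leads[leads$transcript_id == gid, ]
    cis <- sub[sub$cis_trans == "cis", ]
    cis <- cis[order(cis$p), ][1, ]          # lead cis = most significant
    trans <- sub[sub$cis_trans == "trans", ]
    xc <- dos[, cis$snp_id]
    cis_contrib <- cis$beta * (xc - mean(xc, na.rm = TRUE))
    tc <- vapply(seq_len(nrow(trans)), function(i) {
      xt <- dos[, trans$snp_id[i]]
      trans$beta[i] * (xt - mean(xt, na.rm = TRUE))
    }, numeric(nrow(dos)))
    trans_contrib <- rowMeans(matrix(tc, nrow = nrow(dos)), na.rm = TRUE)
    prod <- cis_contrib * trans_contrib
    nonzero <- !is.na(prod) & prod != 0
    frac <- if (any(nonzero)) mean(prod[nonzero] > 0) else NA_real_
    call <- dplyr::case_when(
      is.na(frac) ~ "unclassified",
      frac >= threshold ~ "reinforcing",
      (1 - frac) >= threshold ~ "compensating",
      TRUE ~ "unclassified"
    )
    tibble::tibble(
      transcript_id = gid, cis_snp = cis$snp_id, cis_beta = cis$beta,
      n_trans = nrow(trans), mean_trans_beta = mean(trans$beta),
      same_direction_fraction = frac, call = call
    )
  })
}

#' Reinforcing fraction among classified architecture genes
#'
#' @param arch tibble from [call_cis_trans_architecture()].
#' @return tibble with counts and the percentage of reinforcing genes
#'   among reinforcing + compensating calls.
#' @export
architecture_summary <- function(arch) {
  n_re <- sum(arch$call == "reinforcing")
  n_co <- sum(arch$call == "compensating")
  tibble::tibble(
    n_reinforcing = n_re, n_compensating = n_co,
    n_unclassified = sum(arch$call == "unclassified"),
    pct_reinforcing = if (n_re + n_co > 0) 100 * n_re / (n_re + n_co)
    else NA_real_
  )
}

#' LD permutation test for focal SNP pairs
#'
#' The observed statistic is the mean squared dosage correlation (r2) over
#' the focal pairs. The null is built from `n_perm` random pair sets
#' matched to the focal inter-SNP distance distribution: same-chromosome
#' pairs are matched by log10-distance bin (bins widened when too few
#' candidates exist), different-chromosome pairs by chromosome-pair
#' category. The two-tailed p-value is
#' `(1 + #{|null - median(null)| >= |observed - median(null)|}) / (n_perm + 1)`.
#'
#' @param genotypes a `genotype_matrix`.
#' @param focal_pairs two-column matrix or data frame of SNP ids or column
#'   indices.
#' @param n_perm permutation replicates (default 1000).
#' @param seed integer seed.
#' @param bin_width log10-distance bin width (default 0.5).
#' @return tibble: `observed_mean_r2`, `background_mean_r2`,
#'   `permutation_p`, `n_perm`, `n_pairs`.
#' @export
ld_permutation_test <- function(genotypes, focal_pairs, n_perm = 1000,
                                seed = 1, bin_width = 0.5) {
  fp <- as.matrix(focal_pairs)
  stop_if_not(nrow(fp) >= 2, "need >= 2 focal pairs")
  if (is.character(fp)) {
    fp <- matrix(match(fp, colnames(genotypes$dosages)), ncol = 2)
    stop_if_not(!anyNA(fp), "unknown SNP ids in focal_pairs")
  }
  X <- genotypes$dosages
  m <- ncol(X)
  # standardized dosage columns make r2 a plain cross-product
  Z <- scale(X)
  Z[is.na(Z)] <- 0
  n1 <- nrow(X) - 1
  r2_pairs <- function(i, j) (colSums(Z[, i, drop = FALSE] *
                                        Z[, j, drop = FALSE]) / n1)^2
  obs_r2 <- r2_pairs(fp[, 1], fp[, 2])
  observed <- mean(obs_r2, na.rm = TRUE)

  chrom <- genotypes$chrom; pos <- genotypes$pos
  pair_cat <- function(i, j) {
    same <- chrom[i] == chrom[j]
    d <- abs(pos[i] - pos[j])
    ifelse(same,
           paste0("d", floor(log10(pmax(d, 1)) / bin_width)),
           paste0("x ", pmin(chrom[i], chrom[j]), "_",
                  pmax(chrom[i], chrom[j])))
  }
  cats <- pair_cat(fp[, 1], fp[, 2])
  cat_counts <- table(cats)

  # enumerate all unordered pairs once and bucket them by category; for
  # very dense panels the candidate universe is subsampled to bound memory
  set.seed(derive_seed(seed, 40L))
  univ <- if (m > 1500) sort(sample.int(m, 1500)) else seq_len(m)
  idx <- which(upper.tri(matrix(0, length(univ), length(univ))),
               arr.ind = TRUE)
  idx <- cbind(univ[idx[, 1]], univ[idx[, 2]])
  all_cat <- pair_cat(idx[, 1], idx[, 2])
  pools <- split(seq_len(nrow(idx)), all_cat)
  pool_for <- function(cat) {
    pool <- pools[[cat]]
    if (!is.null(pool) && length(pool) >= 2) return(pool)
    warning("too few candidate pairs in distance bin '", cat,
            "'; bin widened", call. = FALSE)
    if (startsWith(cat, "d")) {
      unlist(pools[startsWith(names(pools), "d")], use.names = FALSE)
    } else {
      unlist(pools[startsWith(names(pools), "x")], use.names = FALSE)
    }
  }
  cat_pools <- lapply(names(cat_counts), pool_for)

  set.seed(derive_seed(seed, 41L))
  null_means <- vapply(seq_len(n_perm), function(b) {
    take <- unlist(lapply(seq_along(cat_pools), function(ci) {
      pool <- cat_pools[[ci]]
      pool[sample.int(length(pool), cat_counts[[ci]],
                      replace = length(pool) < cat_counts[[ci]])]
    }), use.names = FALSE)
    mean(r2_pairs(idx[take, 1], idx[take, 2]), na.rm = TRUE)
  }, numeric(1))

  med <- median(null_means)
  pval <- (1 + sum(abs(null_means - med) >= abs(observed - med))) /
    (n_perm + 1)
  tibble::tibble(observed_mean_r2 = observed,
                 background_mean_r2 = mean(null_means),
                 permutation_p = pval, n_perm = n_perm, n_pairs = nrow(fp))
}

#' Folded SFS, MAF comparisons and nucleotide diversity around eQTLs
#'
#' Per-SNP folded minor allele frequencies (heterozygous dosages count
#' half an alternate allele) with Welch t-tests of each eQTL SNP set
#' against the background (all SNPs outside the set). Per-site nucleotide
#' diversity `pi = 2 p (1-p) n / (n-1)` is averaged over `flank`-bp
#' windows either side of each SNP in a set and compared against tiling
#' `block`-bp background blocks that exclude the flank regions.
#'
#' @param genotypes a `genotype_matrix`.
#' @param eqtl_snp_sets named list of character vectors of SNP ids.
#' @param flank half-width of eQTL flank regions, bp (default 5e4).
#' @param block background block width, bp (default 1e5).
#' @param sfs_breaks breakpoints for the folded SFS histogram.
#' @return list with `maf` (per-SNP tibble with set membership),
#'   `maf_tests` (tibble per set), `sfs` (per-set histograms),
#'   `pi_regions` (per-region mean pi), `pi_tests` (tibble per set).
#' @export
sfs_and_diversity <- function(genotypes, eqtl_snp_sets, flank = 5e4,
                              block = 1e5, sfs_breaks = seq(0, 0.5, 0.05)) {
  X <- genotypes$dosages
  snp_ids <- colnames(X)
  n_called <- unname(colSums(!is.na(X)))
  p <- unname(colMeans(X, na.rm = TRUE) / 2)
  maf <- pmin(p, 1 - p)
  polymorphic <- maf > 0
  pi_site <- 2 * p * (1 - p) * n_called / pmax(n_called - 1, 1)

  maf_tbl <- tibble::tibble(snp_id = snp_ids, chrom = genotypes$chrom,
                            pos = genotypes$pos, maf = maf,
                            pi = pi_site, polymorphic = polymorphic)

  maf_tests <- purrr::map_dfr(names(eqtl_snp_sets), function(nm) {
    set <- intersect(eqtl_snp_sets[[nm]], snp_ids)
    if (length(set) == 0) {
      return(tibble::tibble(set = nm, n_set = 0L, mean_maf_set = NA_real_,
                            mean_maf_background = NA_real_, p = NA_real_,
                            skipped = TRUE))
    }
    in_set <- snp_ids %in% set & polymorphic
    bg <- !snp_ids %in% set & polymorphic
    tibble::tibble(
      set = nm, n_set = sum(in_set),
      mean_maf_set = mean(maf[in_set]),
      mean_maf_background = mean(maf[bg]),
      p = safe_t_test(maf[in_set], maf[bg]),
      skipped = FALSE
    )
  })

  sfs <- purrr::map(eqtl_snp_sets, function(set) {
    sel <- snp_ids %in% set & polymorphic
    hist(maf[sel], breaks = sfs_breaks, plot = FALSE)$counts
  })
  sfs$background <- hist(maf[polymorphic], breaks = sfs_breaks,
                         plot = FALSE)$counts

  # region-level pi: flanks around each set SNP vs tiling background blocks
  region_pi <- function(chrom_r, start_r, end_r) {
    sel <- genotypes$chrom == chrom_r & genotypes$pos >= start_r &
      genotypes$pos <= end_r
    if (!any(sel)) return(NA_real_)
    mean(pi_site[sel])
  }
  pi_regions <- purrr::map_dfr(names(eqtl_snp_sets), function(nm) {
    set <- intersect(eqtl_snp_sets[[nm]], snp_ids)
    if (length(set) == 0) return(NULL)
    i <- match(set, snp_ids)
    tibble::tibble(
      set = nm, snp_id = set, chrom = genotypes$chrom[i],
      start = pmax(1, genotypes$pos[i] - flank),
      end = genotypes$pos[i] + flank
    )
  })
  if (nrow(pi_regions) > 0) {
    pi_regions$mean_pi <- purrr::pmap_dbl(
      pi_regions[, c("chrom", "start", "end")],
      function(chrom, start, end) region_pi(chrom, start, end))
  }

  bg_blocks <- purrr::map_dfr(unique(genotypes$chrom), function(cc) {
    maxpos <- max(genotypes$pos[genotypes$chrom == cc])
    starts <- seq(1, maxpos, by = block)
    tibble::tibble(chrom = cc, start = starts,
                   end = pmin(starts + block - 1, maxpos))
  })
  # exclude blocks overlapping any flank region
  if (nrow(pi_regions) > 0) {
    overlaps <- purrr::pmap_lgl(
      bg_blocks, function(chrom, start, end) {
        any(pi_regions$chrom == chrom & pi_regions$start <= end &
              pi_regions$end >= start)
      })
    bg_blocks <- bg_blocks[!overlaps, ]
  }
  bg_blocks$mean_pi <- purrr::pmap_dbl(
    bg_blocks, function(chrom, start, end) region_pi(chrom, start, end))
  bg_pi <- bg_blocks$mean_pi[!is.na(bg_blocks$mean_pi)]

  pi_tests <- purrr::map_dfr(names(eqtl_snp_sets), function(nm) {
    x <- pi_regions$mean_pi[pi_regions$set == nm]
    x <- x[!is.na(x)]
    tibble::tibble(
      set = nm, n_regions = length(x), mean_pi_set = mean(x),
      mean_pi_background = mean(bg_pi),
      p = safe_t_test(x, bg_pi)
    )
  })

  list(maf = maf_tbl, maf_tests = maf_tests, sfs = sfs,
       sfs_breaks = sfs_breaks, pi_regions = pi_regions,
       pi_background_blocks = bg_blocks, pi_tests = pi_tests)
}
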