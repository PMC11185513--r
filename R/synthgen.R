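#' Simulation configuration for the synthetic field experiment
#'
#' Builds the configuration object consumed by [simulate_genotypes()],
#' [simulate_expression_fitness()] and [simulate_dataset()]. The generator
#' emulates a two-environment (normal / saline paddy) field trial of inbred
#' rice accessions with replicated plants per block, planted cis/trans eQTL
#' effects, planted selection coefficients on transcripts and planted
#' environment-dependent pair correlations, so that every downstream stage
#' of the package can be exercised against known ground truth.
#'
#' Expression for gene \eqn{g} in sample \eqn{s} (accession \eqn{i},
#' environment \eqn{j}, replicate in block \eqn{b}) is generated as
#' \deqn{y = \mu_g + \alpha_{gj} + a_{gi} + (ge)_{gij} + \beta_{gb} + \epsilon,}
#' where \eqn{a} is the genetic (accession) effect including planted eQTL
#' dosage contributions topped up with a polygenic residual so that the
#' realized genetic variance matches `sigma2_G`, \eqn{(ge)} carries
#' environment-specific eQTL effects plus a polygenic interaction term, and
#' \eqn{\epsilon} is residual noise (bivariate within decoherent pairs).
#' Relative fitness is a linear-quadratic function of standardized
#' expression with planted selection differentials, mapped to integer
#' fecundity (filled-grain counts) with truncation at zero and structural
#' zeros.
#'
#' @param n_accessions number of accessions (genotypes).
#' @param n_transcripts number of transcripts.
#' @param n_snps number of biallelic SNPs.
#' @param n_replicates replicates per accession per environment; replicate
#'   k is planted in block k, as in a randomized complete block design.
#' @param n_blocks number of blocks (must equal `n_replicates`).
#' @param n_chromosomes,chrom_length genome layout for SNP/gene placement.
#' @param maf_shape1,maf_shape2 Beta parameters for allele frequencies;
#'   frequencies are resampled until the folded MAF is at least `min_maf`.
#' @param min_maf minimum folded minor allele frequency.
#' @param het_rate per-call probability of a heterozygous dosage (rice is
#'   inbred; default 0, nonzero only to exercise QC filters).
#' @param missing_rate per-call missingness probability.
#' @param ld_blocks logical; generate haplotype-block LD by a
#'   copy-with-mutation founder scheme.
#' @param ld_block_length mean SNPs per LD block (geometric lengths).
#' @param ld_n_founders founder haplotypes per block.
#' @param ld_mutation_rate per-SNP probability of resampling from the
#'   marginal frequency within a copied block.
#' @param mu_range range of per-gene mean expression, log2(TPM+1) units.
#' @param sigma2_G,sigma2_E,sigma2_GxE,sigma2_res,sigma2_block variance
#'   components (scalars or per-transcript vectors), log2 expression units
#'   squared. `sigma2_E` is the variance of the fixed environment effect.
#' @param s_true,c_true planted linear / quadratic selection differentials:
#'   `n_transcripts x 2` matrices (columns normal, saline) or `NULL` for no
#'   planted selection.
#' @param n_cis_genes,n_trans_genes genes given a single cis (resp. trans)
#'   eQTL active in both environments.
#' @param n_env_genes genes given one saline-specific eQTL (GxE signal).
#' @param n_arch_genes genes given one cis plus `n_trans_per_arch_gene`
#'   trans eQTLs for compensation/reinforcement analysis.
#' @param prop_reinforcing fraction of architecture genes planted as
#'   reinforcing (cis and trans effects pushing the same direction).
#' @param n_trans_per_arch_gene trans eQTLs per architecture gene.
#' @param arch_ld_flip per-accession probability that an architecture
#'   gene's trans dosage deviates from its cis partner. Compensating and
#'   reinforcing trans alleles are modelled as largely fixed with the cis
#'   allele (high cis-trans LD); the flip rate controls how far r2 falls
#'   below 1.
#' @param cis_beta,trans_beta effect-size magnitudes per dosage unit
#'   (defaults follow typical cis < trans effect ordering).
#' @param hotspot_n_genes if > 0, one SNP trans-regulates this many genes
#'   (a planted hotspot).
#' @param hotspot_beta hotspot effect magnitude.
#' @param n_decoh_pairs transcript pairs given environment-dependent
#'   residual correlation.
#' @param rho_normal,rho_saline planted residual correlations of decoherent
#'   pairs in each environment.
#' @param n_go_terms,go_term_size GO annotation: number of terms and the
#'   (inclusive) range of transcripts per term.
#' @param fitness_scale mean fecundity (filled grains) at relative fitness 1.
#' @param fitness_noise_sd SD of noise added to relative fitness.
#' @param zero_fecundity_rate probability a plant sets no filled grain at
#'   all (structural zero).
#' @param seed integer seed; a fixed seed makes all outputs byte-identical.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_accessions = 130,
                       n_transcripts = 1000,
                       n_snps = 2000,
                       n_replicates = 3,
                       n_blocks = n_replicates,
                       n_chromosomes = 2,
                       chrom_length = 25e6,
                       maf_shape1 = 0.5,
                       maf_shape2 = 0.5,
                       min_maf = 0.05,
                       het_rate = 0,
                       missing_rate = 0,
                       ld_blocks = FALSE,
                       ld_block_length = 20,
                       ld_n_founders = 4,
                       ld_mutation_rate = 0.05,
                       mu_range = c(4, 9),
                       sigma2_G = 1,
                       sigma2_E = 0.1,
                       sigma2_GxE = 1.4,
                       sigma2_res = 1,
                       sigma2_block = 0,
                       s_true = NULL,
                       c_true = NULL,
                       n_cis_genes = 0,
                       n_trans_genes = 0,
                       n_env_genes = 0,
                       n_arch_genes = 0,
                       prop_reinforcing = 0.5,
                       n_trans_per_arch_gene = 1,
                       arch_ld_flip = 0.45,
                       cis_beta = 0.8,
                       trans_beta = 1.05,
                       hotspot_n_genes = 0,
                       hotspot_beta = 1,
                       n_decoh_pairs = 0,
                       rho_normal = 0.8,
                       rho_saline = 0,
                       n_go_terms = 0,
                       go_term_size = c(20, 60),
                       fitness_scale = 1000,
                       fitness_noise_sd = 0.3,
                       zero_fecundity_rate = 0.02,
                       seed = 1L) {
  stop_if_not(n_accessions >= 2, "n_accessions must be >= 2")
  stop_if_not(n_transcripts >= 1 && n_snps >= 1, "sizes must be positive")
  stop_if_not(n_replicates >= 1, "n_replicates must be >= 1")
  stop_if_not(n_blocks == n_replicates,
              "replicate k is planted in block k: n_blocks must equal n_replicates")
  stop_if_not(min_maf > 0 && min_maf < 0.5, "min_maf must be in (0, 0.5)")
  stop_if_not(het_rate >= 0 && het_rate <= 0.05,
              "het_rate must be in [0, 0.05] (inbred population)")
  stop_if_not(missing_rate >= 0 && missing_rate < 1, "invalid missing_rate")
  for (v in list(sigma2_G, sigma2_E, sigma2_GxE, sigma2_res, sigma2_block)) {
    stop_if_not(all(v >= 0), "variance components must be non-negative")
    stop_if_not(length(v) == 1L || length(v) == n_transcripts,
                "variance components must be scalar or per-transcript")
  }
  stop_if_not(abs(rho_normal) < 1 && abs(rho_saline) < 1, "|rho| must be < 1")
  stop_if_not(zero_fecundity_rate >= 0 && zero_fecundity_rate < 1,
              "invalid zero_fecundity_rate")
  stop_if_not(fitness_scale > 0, "fitness_scale must be positive")
  for (m in list(s_true, c_true)) {
    if (!is.null(m)) {
      stop_if_not(is.matrix(m) && nrow(m) == n_transcripts && ncol(m) == 2,
                  "s_true/c_true must be n_transcripts x 2 matrices")
    }
  }
  n_special <- n_cis_genes + n_trans_genes + n_env_genes + n_arch_genes +
    hotspot_n_genes
  stop_if_not(n_special <= n_transcripts,
              "more eQTL genes requested than transcripts available")
  stop_if_not(2 * n_decoh_pairs <= n_transcripts,
              "too many decoherent pairs for the number of transcripts")

  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Study design table for a simulated experiment
#'
#' One row per plant: both environments, `n_replicates` plants per accession
#' per environment, replicate k in block k.
#'
#' @param config a [sim_config()] object.
#' @return tibble with columns `sample_id`, `accession_id`, `replicate`,
#'   `block`, `environment`.
#' @export
sim_design <- function(config) {
  acc <- sprintf("acc%03d", seq_len(config$n_accessions))
  design <- tidyr::expand_grid(
    accession_id = acc,
    environment = ENVS,
    replicate = seq_len(config$n_replicates)
  )
  design$block <- design$replicate
  design$sample_id <- sprintf("%s_%s_r%d", design$accession_id,
                              substr(design$environment, 1, 3),
                              design$replicate)
  tibble::as_tibble(design[, c("sample_id", "accession_id", "replicate",
                               "block", "environment")])
}

#' Simulate a genotype matrix for an inbred population
#'
#' Per-SNP allele frequencies are Beta-distributed, resampled until the
#' folded minor allele frequency reaches `min_maf`. Accessions are
#' homozygous (dosage 0 or 2) apart from an optional small heterozygote
#' rate; optional LD blocks are built by copying founder haplotype segments
#' with mutation, which yields controllable within-block r2.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `genotype_matrix`: list with `dosages`
#'   (accessions x SNPs matrix, entries 0/1/2/NA), `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 11L))
  n <- config$n_accessions
  m <- config$n_snps

  # allele frequencies with folded MAF >= min_maf (rejection sampling)
  p <- rbeta(m, config$maf_shape1, config$maf_shape2)
  bad <- pmin(p, 1 - p) < config$min_maf
  while (any(bad)) {
    p[bad] <- rbeta(sum(bad), config$maf_shape1, config$maf_shape2)
    bad <- pmin(p, 1 - p) < config$min_maf
  }

  if (isTRUE(config$ld_blocks)) {
    dos <- matrix(0L, n, m)
    start <- 1L
    while (start <= m) {
      len <- min(m - start + 1L, 1L + rgeom(1, 1 / config$ld_block_length))
      idx <- start:(start + len - 1L)
      nf <- config$ld_n_founders
      # founders stay polymorphic at every SNP: round(nf * p) of them carry
      # the alternate allele (clamped to [1, nf - 1])
      founders <- vapply(p[idx], function(pp) {
        k_alt <- min(nf - 1L, max(1L, round(nf * pp)))
        f <- integer(nf)
        f[sample.int(nf, k_alt)] <- 2L
        f
      }, integer(nf))
      founders <- matrix(founders, nrow = nf)
      pick <- sample.int(nf, n, replace = TRUE)
      blk <- founders[pick, , drop = FALSE]
      mut <- matrix(runif(n * len) < config$ld_mutation_rate, n, len)
      if (any(mut)) {
        pm <- matrix(rep(p[idx], each = n), n, len)
        blk[mut] <- 2L * rbinom(sum(mut), 1L, pm[mut])
      }
      dos[, idx] <- blk
      start <- start + len
    }
  } else {
    dos <- matrix(2L * rbinom(n * m, 1L, rep(p, each = n)), n, m)
  }

  if (config$het_rate > 0) {
    het <- matrix(runif(n * m) < config$het_rate, n, m)
    dos[het] <- 1L
  }
  if (config$missing_rate > 0) {
    dos[matrix(runif(n * m) < config$missing_rate, n, m)] <- NA_integer_
  }

  # positions: SNPs split evenly over chromosomes, strictly increasing
  chrom_idx <- rep(seq_len(config$n_chromosomes), length.out = m)
  chrom_idx <- sort(chrom_idx)
  pos <- integer(m)
  for (cc in seq_len(config$n_chromosomes)) {
    sel <- chrom_idx == cc
    pos[sel] <- sort(sample.int(config$chrom_length, sum(sel)))
  }
  chrom <- sprintf("chr%d", chrom_idx)

  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), character(1))

  dimnames(dos) <- list(sprintf("acc%03d", seq_len(n)),
                        sprintf("snp%05d", seq_len(m)))
  structure(list(dosages = dos, chrom = chrom, pos = pos,
                 ref = unname(ref), alt = unname(alt)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$chrom))))
  invisible(x)
}

# plan gene positions + eQTL architecture; returns positions tibble and the
# planted eQTL table. Genes with a cis eQTL get their TSS placed within the
# cis window of the chosen SNP; trans SNPs are drawn from a different
# chromosome than the gene.
plan_architecture <- function(genotypes, config, cis_window = 1e5) {
  m <- ncol(genotypes$dosages)
  g <- config$n_transcripts
  gene_ids <- sprintf("t%04d", seq_len(g))

  gene_chrom_idx <- sample.int(config$n_chromosomes, g, replace = TRUE)
  tss <- sample.int(config$chrom_length, g, replace = TRUE)

  n_need <- config$n_cis_genes + config$n_trans_genes + config$n_env_genes +
    config$n_arch_genes + config$hotspot_n_genes
  special <- if (n_need > 0) sample.int(g, n_need) else integer(0)
  take <- function(k) {
    if (k == 0) return(integer(0))
    out <- special[seq_len(k)]
    special <<- special[-seq_len(k)]
    out
  }
  cis_genes  <- take(config$n_cis_genes)
  trans_genes <- take(config$n_trans_genes)
  env_genes  <- take(config$n_env_genes)
  arch_genes <- take(config$n_arch_genes)
  hot_genes  <- take(config$hotspot_n_genes)

  snp_chrom_idx <- as.integer(sub("chr", "", genotypes$chrom))
  rows <- list()
  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
  used_snps <- integer(0)  # planted SNPs are never reused across genes

  place_cis <- function(gene) {
    # pick an unused SNP, then move the gene TSS near it
    free <- setdiff(seq_len(m), used_snps)
    stop_if_not(length(free) >= 1, "no free SNPs left for cis placement")
    s <- free[sample.int(length(free), 1L)]
    used_snps <<- c(used_snps, s)
    gene_chrom_idx[gene] <<- snp_chrom_idx[s]
    lo <- max(1L, genotypes$pos[s] - as.integer(cis_window) + 1L)
    hi <- min(config$chrom_length, genotypes$pos[s] + as.integer(cis_window) - 1L)
    tss[gene] <<- sample(seq(lo, hi), 1L)
    s
  }
  pick_trans <- function(gene, k = 1L) {
    cand <- setdiff(which(snp_chrom_idx != gene_chrom_idx[gene]), used_snps)
    if (length(cand) < k) {  # single-chromosome genomes: use >= 1 Mb distance
      cand <- setdiff(which(abs(genotypes$pos - tss[gene]) >= 1e6), used_snps)
    }
    stop_if_not(length(cand) >= k, "no SNPs available in trans to gene %d", gene)
    out <- cand[sample.int(length(cand), k)]
    used_snps <<- c(used_snps, out)
    out
  }

  for (gene in cis_genes) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene = gene, snp = place_cis(gene), beta = sgn(1) * config$cis_beta,
      env = "both", class = "cis", role = "single_cis")
  }
  for (gene in trans_genes) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene = gene, snp = pick_trans(gene), beta = sgn(1) * config$trans_beta,
      env = "both", class = "trans", role = "single_trans")
  }
  for (gene in env_genes) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene = gene, snp = pick_trans(gene), beta = sgn(1) * config$trans_beta,
      env = "saline", class = "trans", role = "env_specific")
  }
  n_reinf <- round(config$prop_reinforcing * length(arch_genes))
  arch_mode <- rep(c("reinforcing", "compensating"),
                   c(n_reinf, length(arch_genes) - n_reinf))
  n_acc_g <- nrow(genotypes$dosages)
  for (ii in seq_along(arch_genes)) {
    gene <- arch_genes[ii]
    cs <- place_cis(gene)
    b_cis <- sgn(1) * config$cis_beta
    k <- config$n_trans_per_arch_gene
    ts <- pick_trans(gene, k)
    # compensating/reinforcing trans alleles are modelled as largely fixed
    # with the cis allele: copy the cis dosage with a small flip rate,
    # which plants the elevated cis-trans LD that makes the allelic
    # configuration informative
    for (s in ts) {
      flip <- runif(n_acc_g) < config$arch_ld_flip
      newcol <- genotypes$dosages[, cs]
      p_s <- mean(newcol, na.rm = TRUE) / 2
      newcol[flip] <- 2L * rbinom(sum(flip), 1L, p_s)
      genotypes$dosages[, s] <- newcol
    }
    b_dir <- if (arch_mode[ii] == "reinforcing") sign(b_cis) else -sign(b_cis)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene = gene, snp = c(cs, ts),
      beta = c(b_cis, rep(b_dir * config$trans_beta, k)),
      env = "both", class = c("cis", rep("trans", k)),
      role = paste0("arch_", arch_mode[ii]))
  }
  hotspot_snp <- NA_integer_
  if (length(hot_genes) > 0) {
    free <- setdiff(seq_len(m), used_snps)
    hotspot_snp <- free[sample.int(length(free), 1L)]
    for (gene in hot_genes) {
      # ensure the hotspot SNP is in trans to each target gene
      if (snp_chrom_idx[hotspot_snp] == gene_chrom_idx[gene] &&
          abs(genotypes$pos[hotspot_snp] - tss[gene]) < 1e6) {
        gene_chrom_idx[gene] <- (snp_chrom_idx[hotspot_snp] %%
                                   config$n_chromosomes) + 1L
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = gene, snp = hotspot_snp, beta = sgn(1) * config$hotspot_beta,
        env = "both", class = "trans", role = "hotspot")
    }
  }

  eqtl <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(gene = integer(), snp = integer(), beta = double(),
                   env = character(), class = character(), role = character())
  eqtl$transcript_id <- gene_ids[eqtl$gene]
  eqtl$snp_id <- colnames(genotypes$dosages)[eqtl$snp]

  positions <- tibble::tibble(
    transcript_id = gene_ids,
    chrom = sprintf("chr%d", gene_chrom_idx),
    tss_pos = tss
  )
  arch <- tibble::tibble(
    transcript_id = gene_ids[arch_genes],
    planted_call = arch_mode
  )
  list(positions = positions, eqtl = eqtl, arch = arch,
       hotspot_snp = hotspot_snp,
       hotspot_genes = gene_ids[hot_genes],
       genotypes = genotypes)
}

#' Simulate expression, fitness and the planted truth set
#'
#' Generates the replicated two-environment expression matrix with G, E,
#' GxE, block and residual structure (planted eQTL effects folded into the
#' genetic and interaction terms), integer fecundity from a
#' linear-quadratic fitness surface on standardized expression, and a
#' `TruthSet` recording everything planted. Gene positions and GO
#' annotation are generated alongside because cis eQTLs constrain gene
#' placement.
#'
#' @param genotypes a `genotype_matrix` from [simulate_genotypes()].
#' @param config the same [sim_config()] used for the genotypes.
#' @return list with elements `expression` (samples x transcripts matrix,
#'   log2(TPM+1) scale), `design` (tibble), `fitness` (tibble:
#'   `sample_id`, `fecundity`), `positions`, `annotation`, `truth`, and
#'   `genotypes` (the input matrix, with architecture-gene trans SNPs
#'   rewritten in LD with their cis partner).
#' @export
simulate_expression_fitness <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genotypes, "genotype_matrix"))
  set.seed(derive_seed(config$seed, 23L))
  design <- sim_design(config)
  n_acc <- config$n_accessions
  g <- config$n_transcripts
  n_s <- nrow(design)

  plan <- plan_architecture(genotypes, config)
  genotypes <- plan$genotypes  # arch trans SNPs rewritten in LD with cis
  gene_ids <- plan$positions$transcript_id

  rep_len_ <- function(v) if (length(v) == 1L) rep(v, g) else v
  s2G <- rep_len_(config$sigma2_G); s2E <- rep_len_(config$sigma2_E)
  s2GxE <- rep_len_(config$sigma2_GxE); s2res <- rep_len_(config$sigma2_res)
  s2blk <- rep_len_(config$sigma2_block)

  acc_ids <- rownames(genotypes$dosages)[seq_len(n_acc)]
  idx_acc <- match(design$accession_id, acc_ids)
  idx_env <- match(design$environment, ENVS)
  idx_cell <- (idx_acc - 1L) * 2L + idx_env

  mu <- runif(g, config$mu_range[1], config$mu_range[2])
  Ef <- matrix(rnorm(2 * g), 2, g) * rep(sqrt(s2E), each = 2)

  # genetic effects: planted "both"-environment eQTL contributions, topped
  # up with a polygenic term so var over accessions ~ sigma2_G
  A <- matrix(0, n_acc, g)
  GEc <- matrix(0, n_acc * 2L, g)  # accession x environment cells
  dos <- genotypes$dosages
  dos[is.na(dos)] <- matrix(rep(colMeans(dos, na.rm = TRUE), each = nrow(dos)),
                            nrow(dos))[is.na(dos)]
  eqtl <- plan$eqtl
  if (nrow(eqtl) > 0) {
    for (r in which(eqtl$env == "both")) {
      x <- dos[seq_len(n_acc), eqtl$snp[r]]
      A[, eqtl$gene[r]] <- A[, eqtl$gene[r]] + eqtl$beta[r] * (x - mean(x))
    }
    for (r in which(eqtl$env != "both")) {
      x <- dos[seq_len(n_acc), eqtl$snp[r]]
      je <- match(eqtl$env[r], ENVS)
      cells <- (seq_len(n_acc) - 1L) * 2L + je
      contrib <- eqtl$beta[r] * (x - mean(x))
      GEc[cells, eqtl$gene[r]] <- GEc[cells, eqtl$gene[r]] + contrib
    }
  }
  v_eqtl_G <- apply(A, 2, var)
  poly_sd <- sqrt(pmax(0, s2G - v_eqtl_G))
  A <- A + matrix(rnorm(n_acc * g), n_acc, g) * rep(poly_sd, each = n_acc)

  v_eqtl_GE <- apply(GEc, 2, var)
  ge_sd <- sqrt(pmax(0, s2GxE - v_eqtl_GE))
  GEc <- GEc + matrix(rnorm(n_acc * 2L * g), n_acc * 2L, g) *
    rep(ge_sd, each = n_acc * 2L)

  Blk <- matrix(rnorm(config$n_blocks * g), config$n_blocks, g) *
    rep(sqrt(s2blk), each = config$n_blocks)

  Eps <- matrix(rnorm(n_s * g), n_s, g) * rep(sqrt(s2res), each = n_s)

  # decoherent pairs: environment-specific residual correlation
  decoh <- NULL
  if (config$n_decoh_pairs > 0) {
    pool <- setdiff(seq_len(g), unique(eqtl$gene))
    stop_if_not(length(pool) >= 2 * config$n_decoh_pairs,
                "not enough eQTL-free transcripts for decoherent pairs")
    pick <- sample(pool, 2L * config$n_decoh_pairs)
    pa <- pick[seq_len(config$n_decoh_pairs)]
    pb <- pick[config$n_decoh_pairs + seq_len(config$n_decoh_pairs)]
    rho_env <- c(config$rho_normal, config$rho_saline)
    for (q in seq_len(config$n_decoh_pairs)) {
      for (je in 1:2) {
        sel <- idx_env == je
        ns <- sum(sel)
        rho <- rho_env[je]
        e1 <- rnorm(ns); e2 <- rho * e1 + sqrt(1 - rho^2) * rnorm(ns)
        Eps[sel, pa[q]] <- e1 * sqrt(s2res[pa[q]])
        Eps[sel, pb[q]] <- e2 * sqrt(s2res[pb[q]])
      }
    }
    decoh <- tibble::tibble(transcript_a = gene_ids[pa],
                            transcript_b = gene_ids[pb],
                            rho_normal = config$rho_normal,
                            rho_saline = config$rho_saline)
  }

  Y <- matrix(mu, n_s, g, byrow = TRUE) +
    Ef[idx_env, , drop = FALSE] +
    A[idx_acc, , drop = FALSE] +
    GEc[idx_cell, , drop = FALSE] +
    Blk[design$block, , drop = FALSE] +
    Eps
  Y <- pmax(Y, 0)  # log2(TPM+1) scale is non-negative
  dimnames(Y) <- list(design$sample_id, gene_ids)

  # fitness surface on within-environment standardized expression
  s_true <- if (is.null(config$s_true)) matrix(0, g, 2) else config$s_true
  c_true <- if (is.null(config$c_true)) matrix(0, g, 2) else config$c_true
  w <- rep(1, n_s)
  for (je in 1:2) {
    sel <- idx_env == je
    Z <- scale(Y[sel, , drop = FALSE])
    Z[is.nan(Z)] <- 0  # constant transcripts carry no selection signal
    w[sel] <- 1 + as.vector(Z %*% s_true[, je]) +
      0.5 * as.vector(Z^2 %*% c_true[, je])
  }
  w <- w + rnorm(n_s, 0, config$fitness_noise_sd)
  fec <- round(pmax(0, config$fitness_scale * w))
  fec[runif(n_s) < config$zero_fecundity_rate] <- 0
  fitness <- tibble::tibble(sample_id = design$sample_id,
                            fecundity = as.integer(fec))

  annotation <- simulate_annotation(gene_ids, config)

  truth <- list(
    s_true = `dimnames<-`(s_true, list(gene_ids, ENVS)),
    c_true = `dimnames<-`(c_true, list(gene_ids, ENVS)),
    eqtl = plan$eqtl,
    arch = plan$arch,
    hotspot_snp = if (is.na(plan$hotspot_snp)) NULL else
      colnames(genotypes$dosages)[plan$hotspot_snp],
    hotspot_genes = plan$hotspot_genes,
    decoherent_pairs = decoh,
    realized = tibble::tibble(
      transcript_id = gene_ids,
      sigma2_G = apply(A, 2, var),
      sigma2_GxE = apply(GEc, 2, var),
      sigma2_res = s2res,
      sigma2_E = s2E
    )
  )

  list(expression = Y, design = design, fitness = fitness,
       positions = plan$positions, annotation = annotation, truth = truth,
       genotypes = genotypes)
}

#' Simulate a GO-style annotation table
#'
#' Terms draw transcripts with replacement across terms (many-to-many).
#' @param transcript_ids character vector of transcripts to annotate.
#' @param config a [sim_config()]; uses `n_go_terms` and `go_term_size`.
#' @return tibble with columns `transcript_id`, `term_id`.
#' @export
simulate_annotation <- function(transcript_ids, config) {
  if (config$n_go_terms == 0) {
    return(tibble::tibble(transcript_id = character(), term_id = character()))
  }
  sizes <- sample(seq(config$go_term_size[1], config$go_term_size[2]),
                  config$n_go_terms, replace = TRUE)
  sizes <- pmin(sizes, length(transcript_ids))
  purrr::map2_dfr(seq_len(config$n_go_terms), sizes, function(i, k) {
    tibble::tibble(transcript_id = sample(transcript_ids, k),
                   term_id = sprintf("GO:%07d", i))
  })
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_genotypes()] then
#' [simulate_expression_fitness()].
#'
#' @param config a [sim_config()] object.
#' @return list with `design`, `genotypes`, `expression`, `fitness`,
#'   `positions`, `annotation`, `truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  genotypes <- simulate_genotypes(config)
  ef <- simulate_expression_fitness(genotypes, config)
  c(list(config = config), ef)
}
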