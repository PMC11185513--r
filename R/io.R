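#' Write a simulated dataset to interchange files
#'
#' Writes the expression matrix (transcripts x samples TSV), design,
#' fitness, gene positions, GO annotation and truth JSON, plus genotypes
#' both as a dosage TSV and as a minimal VCFv4.2 (GT field, 1-based
#' coordinates). Everything round-trips through the package readers.
#'
#' @param expr samples x transcripts matrix.
#' @param design,fitness,positions,annotation tibbles as produced by
#'   [simulate_dataset()].
#' @param genotypes a `genotype_matrix`.
#' @param truth truth list (written as JSON), or `NULL` to skip.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named character vector of the files written.
#' @export
write_dataset <- function(expr, design, fitness, genotypes, positions,
                          annotation, truth = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(out_dir, "expression.tsv"),
    design = file.path(out_dir, "design.tsv"),
    fitness = file.path(out_dir, "fitness.tsv"),
    dosages = file.path(out_dir, "genotypes_dosage.tsv"),
    vcf = file.path(out_dir, "genotypes.vcf"),
    positions = file.path(out_dir, "positions.tsv"),
    annotation = file.path(out_dir, "annotation.tsv")
  )
  expr_out <- data.frame(transcript_id = colnames(expr), t(expr),
                         check.names = FALSE)
  utils::write.table(expr_out, paths["expression"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(design, paths["design"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fitness, paths["fitness"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dos_out <- data.frame(snp_id = colnames(genotypes$dosages),
                        chrom = genotypes$chrom, pos = genotypes$pos,
                        ref = genotypes$ref, alt = genotypes$alt,
                        t(genotypes$dosages), check.names = FALSE)
  utils::write.table(dos_out, paths["dosages"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_vcf(genotypes, paths["vcf"])
  utils::write.table(positions, paths["positions"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    paths["truth"] <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
  }
  invisible(paths)
}

# minimal VCFv4.2 writer: CHROM POS ID REF ALT QUAL FILTER INFO FORMAT GT
write_vcf <- function(genotypes, path) {
  gt_code <- function(d) {
    ifelse(is.na(d), "./.",
           ifelse(d == 0, "0/0", ifelse(d == 1, "0/1", "1/1")))
  }
  gt <- apply(genotypes$dosages, 2, gt_code)      # accessions x snps
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes$dosages)), collapse = "\t")
  )
  body <- paste(genotypes$chrom, genotypes$pos,
                colnames(genotypes$dosages), genotypes$ref, genotypes$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
}

#' Read a genotype matrix from VCF or dosage TSV
#'
#' VCF files (GT field required) are parsed with vcfR; dosage TSVs must
#' have columns `snp_id`, `chrom`, `pos`, `ref`, `alt` followed by one
#' column per accession. Dosage is the alternate-allele count (0/1/2,
#' missing left missing). Optional QC, applied in order: call rate >=
#' `min_call_rate`, folded MAF >= `min_maf`, heterozygote fraction <=
#' `max_het`, and 1-SNP-per-kb thinning (first SNP in each kb window
#' kept).
#'
#' @param path VCF (`.vcf`) or dosage TSV file.
#' @param min_call_rate,min_maf,max_het,thin_kb QC thresholds; `NULL`
#'   disables a filter. `thin_kb = TRUE` enables 1-per-kb thinning.
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, min_call_rate = NULL, min_maf = NULL,
                           max_het = NULL, thin_kb = FALSE) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      ifelse(is.na(g) | g %in% c("./.", ".|."), NA_integer_,
             vapply(strsplit(gsub("\\|", "/", g), "/"),
                    function(a) sum(a == "1"), integer(1)))
    }
    dos <- t(apply(gt, 2, count_alt))
    dimnames(dos) <- list(colnames(gt), rownames(gt))
    fix <- vcfR::getFIX(v)
    geno <- structure(list(
      dosages = dos, chrom = unname(fix[, "CHROM"]),
      pos = as.integer(fix[, "POS"]),
      ref = unname(fix[, "REF"]), alt = unname(fix[, "ALT"])
    ), class = "genotype_matrix")
  } else {
    df <- utils::read.delim(path, check.names = FALSE)
    meta <- c("snp_id", "chrom", "pos", "ref", "alt")
    stop_if_not(all(meta %in% names(df)),
                "dosage TSV must have columns %s", paste(meta, collapse = ", "))
    dos <- t(as.matrix(df[, setdiff(names(df), meta), drop = FALSE]))
    colnames(dos) <- df$snp_id
    geno <- structure(list(dosages = dos, chrom = as.character(df$chrom),
                           pos = as.integer(df$pos),
                           ref = as.character(df$ref),
                           alt = as.character(df$alt)),
                      class = "genotype_matrix")
  }
  keep <- rep(TRUE, ncol(geno$dosages))
  if (!is.null(min_call_rate)) {
    keep <- keep & colMeans(!is.na(geno$dosages)) >= min_call_rate
  }
  if (!is.null(min_maf)) {
    keep <- keep & folded_maf(geno$dosages) >= min_maf
  }
  if (!is.null(max_het)) {
    keep <- keep & colMeans(geno$dosages == 1, na.rm = TRUE) <= max_het
  }
  if (isTRUE(thin_kb)) {
    kb <- paste(geno$chrom, (geno$pos - 1L) %/% 1000L)
    keep <- keep & !duplicated(kb)
  }
  subset_genotypes(geno, keep)
}

subset_genotypes <- function(geno, keep) {
  structure(list(dosages = geno$dosages[, keep, drop = FALSE],
                 chrom = geno$chrom[keep], pos = geno$pos[keep],
                 ref = geno$ref[keep], alt = geno$alt[keep]),
            class = "genotype_matrix")
}

#' Read the expression matrix written by [write_dataset()]
#'
#' @param path transcripts x samples TSV with a `transcript_id` column.
#' @return samples x transcripts numeric matrix.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stop_if_not("transcript_id" %in% names(df),
              "expression TSV needs a transcript_id column")
  stop_if_not(!anyDuplicated(df$transcript_id), "duplicate transcript ids")
  m <- as.matrix(df[, -1, drop = FALSE])
  stop_if_not(is.numeric(m), "non-numeric expression values")
  t(`rownames<-`(m, df$transcript_id))
}

#' Read design / fitness / positions / annotation tables
#'
#' Typed readers with ID cross-checking against an expression matrix where
#' relevant.
#'
#' @param path TSV file.
#' @param expr optional expression matrix for ID validation.
#' @return tibble.
#' @export
read_design <- function(path, expr = NULL) {
  df <- tibble::as_tibble(utils::read.delim(path))
  need <- c("sample_id", "accession_id", "replicate", "block", "environment")
  stop_if_not(all(need %in% names(df)), "design TSV must have columns %s",
              paste(need, collapse = ", "))
  if (!is.null(expr)) {
    missing <- setdiff(df$sample_id, rownames(expr))
    stop_if_not(length(missing) == 0,
                "design samples absent from expression: %s",
                paste(utils::head(missing, 3), collapse = ", "))
  }
  df
}

#' @rdname read_design
#' @export
read_fitness <- function(path, expr = NULL) {
  df <- tibble::as_tibble(utils::read.delim(path))
  stop_if_not(all(c("sample_id", "fecundity") %in% names(df)),
              "fitness TSV must have sample_id and fecundity")
  stop_if_not(all(df$fecundity >= 0), "fecundity must be non-negative")
  if (!is.null(expr)) {
    missing <- setdiff(df$sample_id, rownames(expr))
    stop_if_not(length(missing) == 0,
                "fitness samples absent from expression: %s",
                paste(utils::head(missing, 3), collapse = ", "))
  }
  df
}

#' @rdname read_design
#' @export
read_positions <- function(path, expr = NULL) {
  df <- tibble::as_tibble(utils::read.delim(path))
  stop_if_not(all(c("transcript_id", "chrom", "tss_pos") %in% names(df)),
              "positions TSV must have transcript_id, chrom, tss_pos")
  df
}

#' @rdname read_design
#' @export
read_annotation <- function(path, expr = NULL) {
  df <- tibble::as_tibble(utils::read.delim(path))
  stop_if_not(all(c("transcript_id", "term_id") %in% names(df)),
              "annotation TSV must have transcript_id and term_id")
  df
}

#' Hypergeometric enrichment of a transcript set
#'
#' One-sided hypergeometric upper-tail test per term of foreground
#' membership against the background, with BH q-values. Terms absent from
#' the background are skipped.
#'
#' @param foreground character vector, subset of `background`.
#' @param background character vector of all eligible transcripts.
#' @param annotation tibble with `transcript_id`, `term_id`.
#' @return tibble per term: sizes, `fold_enrichment`, `p`, `q`.
#' @export
hypergeometric_enrichment <- function(foreground, background, annotation) {
  stop_if_not(length(foreground) > 0, "empty foreground")
  stop_if_not(all(foreground %in% background),
              "foreground must be a subset of background")
  ann <- annotation[annotation$transcript_id %in% background, ]
  N <- length(unique(background))
  n <- length(unique(foreground))
  out <- ann |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(
      n_term = dplyr::n_distinct(.data$transcript_id),
      n_overlap = dplyr::n_distinct(
        intersect(.data$transcript_id, foreground)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fold_enrichment = (.data$n_overlap / n) / (.data$n_term / N),
      p = phyper(.data$n_overlap - 1, .data$n_term, N - .data$n_term, n,
                 lower.tail = FALSE),
      q = bh_adjust(.data$p)
    )
  out
}

#' Run the full analysis pipeline on in-memory data
#'
#' Executes the stages in dependency order: variance partitioning,
#' selection analysis, then (as enabled) multivariate selection,
#' decoherence and eQTL architecture, and returns all result tables plus a
#' summary list mirroring the structure of a study report (selection
#' counts and medians, trade-off calls, overlap percentages, hotspots,
#' architecture counts, MAF/pi tests). Deterministic under `seed`.
#'
#' @param data list with `expression`, `design`, `fitness`, `genotypes`,
#'   `positions`, `annotation` (see [simulate_dataset()]).
#' @param stages character subset of
#'   `c("varcomp", "selection", "multivar", "decohere", "eqtl")`.
#' @param fdr_eqtl,fdr_gxe,fdr_decohere,fdr_varcomp FDR thresholds.
#' @param s_threshold,expr_fraction decoherence transcript filters.
#' @param trim_sd,min_n selection-analysis filters.
#' @param hotspot_min_genes hotspot threshold.
#' @param n_covariate_pcs kinship eigenvector covariates for the eQTL scan.
#' @param seed integer seed for bootstrap/permutation stages.
#' @param out_dir optional directory: result tables are written as TSV and
#'   the summary as JSON.
#' @return list of stage results plus `summary` and the resolved
#'   configuration.
#' @export
run_pipeline <- function(data,
                         stages = c("varcomp", "selection", "multivar",
                                    "decohere", "eqtl"),
                         fdr_eqtl = 0.001, fdr_gxe = 0.05,
                         fdr_decohere = 0.05, fdr_varcomp = 0.001,
                         s_threshold = 0.1, expr_fraction = 0.5,
                         trim_sd = 3, min_n = 20,
                         hotspot_min_genes = 30, n_covariate_pcs = 5,
                         seed = 1, out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  need <- c("expression", "design", "fitness")
  if (any(c("multivar", "eqtl") %in% stages)) need <- c(need, "genotypes")
  if ("eqtl" %in% stages) need <- c(need, "positions")
  missing <- setdiff(need, names(data))
  stop_if_not(length(missing) == 0, "missing pipeline inputs: %s",
              paste(missing, collapse = ", "))

  cfg <- list(stages = stages, fdr_eqtl = fdr_eqtl, fdr_gxe = fdr_gxe,
              fdr_decohere = fdr_decohere, fdr_varcomp = fdr_varcomp,
              s_threshold = s_threshold, expr_fraction = expr_fraction,
              trim_sd = trim_sd, min_n = min_n,
              hotspot_min_genes = hotspot_min_genes,
              n_covariate_pcs = n_covariate_pcs, seed = seed,
              package_version = as.character(utils::packageVersion("riceqx")))
  out <- list(config = cfg)
  summary <- list()

  if ("varcomp" %in% stages) {
    out$varcomp <- partition_variance(data$expression, data$design,
                                      fdr = fdr_varcomp)
    summary$varcomp <- list(
      n_transcripts = nrow(out$varcomp),
      n_sig_G = sum(out$varcomp$sig_G, na.rm = TRUE),
      n_sig_E = sum(out$varcomp$sig_E, na.rm = TRUE),
      n_sig_GxE = sum(out$varcomp$sig_GxE, na.rm = TRUE),
      median_H2 = median(out$varcomp$H2, na.rm = TRUE)
    )
  }

  w <- records <- NULL
  if (any(c("selection", "multivar", "decohere") %in% stages)) {
    w <- prepare_relative_fitness(data$fitness, data$design)
    records <- lapply(setNames(ENVS, ENVS), function(env) {
      estimate_differentials(data$expression, w, data$design, env,
                             trim_sd = trim_sd, min_n = min_n)
    })
  }
  if ("selection" %in% stages) {
    out$selection <- dplyr::bind_rows(records)
    out$tradeoffs <- classify_tradeoffs(records$normal, records$saline)
    out$selection_comparison <-
      compare_selection_distributions(records$normal, records$saline)
    if (!is.null(data$annotation) && nrow(data$annotation) > 0) {
      out$go_selection <- dplyr::bind_rows(lapply(records, function(r) {
        go_term_selection(r, data$annotation, seed = seed)
      }))
    }
    tab <- table(out$tradeoffs$call)
    summary$selection <- list(
      median_abs_S = lapply(records, function(r) median(abs(r$S))),
      n_S_positive = lapply(records, function(r) sum(r$S > 0)),
      n_S_negative = lapply(records, function(r) sum(r$S < 0)),
      tradeoff_calls = as.list(tab),
      pct_CN = 100 * sum(tab[grepl("^CN", names(tab))]) / nrow(out$tradeoffs),
      pct_AP = 100 * sum(tab[grepl("^AP", names(tab))]) / nrow(out$tradeoffs)
    )
  }

  kin <- NULL
  if (any(c("multivar", "eqtl") %in% stages)) {
    kin <- compute_kinship(data$genotypes)
  }
  if ("multivar" %in% stages) {
    out$multivar <- lapply(setNames(ENVS, ENVS), function(env) {
      pc <- fit_pca(data$expression, data$design, env)
      grad <- estimate_gradients(pc, w, records[[env]])
      G <- estimate_G(pc, data$design, kin)
      resp <- predict_response(G, grad)
      list(pc = pc, gradients = grad, G = G, response = resp)
    })
    summary$multivar <- lapply(out$multivar, function(mv) {
      list(n_selected_pcs = length(mv$pc$selected_pcs),
           n_constrained = sum(mv$response$constraint_flag))
    })
  }

  if ("decohere" %in% stages) {
    keep <- select_decoherence_transcripts(records$normal, records$saline,
                                           data$expression,
                                           s_threshold = s_threshold,
                                           expr_fraction = expr_fraction)
    if (length(keep) >= 2) {
      out$cilp <- cilp(data$expression, data$design, keep)
      out$decoherence <- summarize_decoherence(out$cilp, fdr = fdr_decohere)
      summary$decoherence <- out$decoherence[c("n_pairs_tested",
                                               "n_significant",
                                               "median_significant_pairs")]
    } else {
      summary$decoherence <- list(note = "fewer than 2 transcripts passed filters")
    }
  }

  if ("eqtl" %in% stages) {
    means <- lapply(setNames(ENVS, ENVS), function(env) {
      accession_means(data$expression, data$design, env)
    })
    assoc <- lapply(setNames(ENVS, ENVS), function(env) {
      a <- map_eqtl(means[[env]], data$genotypes,
                    n_covariate_pcs = n_covariate_pcs, fdr = fdr_eqtl,
                    environment = env, kinship = kin)
      classify_cis_trans(a, data$positions)
    })
    lh <- lapply(assoc, lead_and_hotspots, min_genes = hotspot_min_genes)
    out$eqtl <- lapply(lh, `[[`, "assoc")
    out$hotspots <- lapply(lh, `[[`, "hotspots")
    out$overlap <- compare_environment_overlap(assoc$normal, assoc$saline)
    gxe <- map_gxe(means$normal, means$saline, data$genotypes,
                   fdr = fdr_gxe, kinship = kin)
    out$gxe <- classify_cis_trans(gxe, data$positions)
    out$architecture <- lapply(out$eqtl, call_cis_trans_architecture,
                               genotypes = data$genotypes)
    sets <- lapply(setNames(c("cis", "trans"), c("cis", "trans")),
                   function(cl) {
      unique(unlist(lapply(assoc, function(a) a$snp_id[a$cis_trans == cl])))
    })
    sets <- sets[vapply(sets, length, 0L) > 0]
    out$diversity <- if (length(sets) > 0) {
      sfs_and_diversity(data$genotypes, sets)
    }
    summary$eqtl <- list(
      n_assoc = lapply(assoc, nrow),
      overlap_pct = setNames(out$overlap$overlap$pct_common,
                             out$overlap$overlap$class),
      n_hotspots = lapply(out$hotspots, function(h) sum(h$hotspot)),
      gxe = as.list(gxe_cis_fraction(out$gxe)),
      architecture = lapply(out$architecture,
                            function(a) as.list(architecture_summary(a))),
      maf_tests = if (!is.null(out$diversity))
        as.list(out$diversity$maf_tests[, c("set", "mean_maf_set",
                                            "mean_maf_background", "p")])
    )
  }

  out$summary <- summary
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tbl <- function(x, nm) {
      if (!is.null(x) && is.data.frame(x)) {
        utils::write.table(x, file.path(out_dir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    write_tbl(out$varcomp, "varcomp")
    write_tbl(out$selection, "selection")
    write_tbl(out$tradeoffs, "tradeoffs")
    if (!is.null(out$eqtl)) {
      write_tbl(dplyr::bind_rows(out$eqtl), "eqtl")
      write_tbl(hotspots_to_bed(dplyr::bind_rows(out$hotspots,
                                                 .id = "environment")),
                "hotspots_bed")
    }
    jsonlite::write_json(c(summary, list(config = cfg)),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}

#' Convert hotspot windows to BED-like records (0-based half-open)
#'
#' @param hotspots hotspot tibble from [lead_and_hotspots()] (1-based
#'   inclusive windows).
#' @return tibble with `chrom`, `start` (0-based), `end` (exclusive) and
#'   the remaining columns.
#' @export
hotspots_to_bed <- function(hotspots) {
  if (nrow(hotspots) == 0) return(hotspots)
  out <- hotspots
  out$start <- out$window_start - 1L
  out$end <- out$window_end
  out$lead_snps <- vapply(out$lead_snps, paste, "", collapse = ",")
  dplyr::select(out, "chrom", "start", "end",
                dplyr::everything(), -"window_start", -"window_end")
}

#' Convert BED-like records back to 1-based windows
#'
#' @param bed tibble with 0-based half-open `start`, `end`.
#' @return tibble with 1-based `window_start`, `window_end`.
#' @export
bed_to_windows <- function(bed) {
  out <- bed
  out$window_start <- out$start + 1L
  out$window_end <- out$end
  dplyr::select(out, -"start", -"end")
}
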