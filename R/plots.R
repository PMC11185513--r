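#' Plot the distribution of selection differentials by environment
#'
#' Density curves of the linear (or quadratic) selection differential in
#' each environment, the standard way to compare the strength of selection
#' between the normal and saline fields.
#'
#' @param records selection record tibble covering both environments
#'   (e.g. `bind_rows` of per-environment results).
#' @param which `"S"`, `"C"` or `"abs_S"`.
#' @return a ggplot object.
#' @export
plot_selection_differentials <- function(records, which = c("S", "C",
                                                            "abs_S")) {
  which <- match.arg(which)
  df <- records
  df$value <- switch(which, S = df$S, C = df$C, abs_S = abs(df$S))
  lab <- switch(which, S = "linear selection differential (S)",
                C = "quadratic selection differential (C)",
                abs_S = "selection strength |S|")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                   colour = .data$environment)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = lab, y = "density", colour = "environment") +
    ggplot2::theme_minimal()
}

#' Plot the broad-sense heritability distribution
#'
#' @param varcomp tibble from [partition_variance()].
#' @return a ggplot object.
#' @export
plot_heritability <- function(varcomp) {
  ggplot2::ggplot(varcomp, ggplot2::aes(x = .data$H2)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::labs(x = expression(H^2), y = "transcripts") +
    ggplot2::theme_minimal()
}

#' Plot the folded site-frequency spectrum of eQTL SNP sets
#'
#' @param diversity result of [sfs_and_diversity()].
#' @return a ggplot object.
#' @export
plot_sfs <- function(diversity) {
  br <- diversity$sfs_breaks
  mid <- (br[-1] + br[-length(br)]) / 2
  df <- purrr::imap_dfr(diversity$sfs, function(counts, nm) {
    tibble::tibble(set = nm, maf = mid,
                   fraction = counts / max(1, sum(counts)))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$maf, y = .data$fraction,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "minor allele frequency", y = "fraction of SNPs") +
    ggplot2::theme_minimal()
}

#' Plot direct / indirect / total responses to selection on PCs
#'
#' @param response tibble from [predict_response()].
#' @return a ggplot object.
#' @export
plot_response <- function(response) {
  df <- tidyr::pivot_longer(response, c("direct", "indirect", "total"),
                            names_to = "component", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc_id, y = .data$value,
                                   fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "predicted response (score units)") +
    ggplot2::theme_minimal()
}

#' Scree plot for a pc_model
#'
#' @param object a `pc_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pc_model <- function(object, ...) {
  df <- tidy(object)
  df <- df[seq_len(min(30, nrow(df))), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc, y = .data$var_explained,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "principal component", y = "variance explained") +
    ggplot2::theme_minimal()
}
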