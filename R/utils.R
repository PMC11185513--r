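#' @importFrom stats rnorm rbeta rbinom runif var sd cor median qf pf pt pnorm
#'   quantile rgeom p.adjust lm coef optimize wilcox.test t.test complete.cases
#'   prcomp phyper setNames
#' @importFrom graphics hist
#' @importFrom rlang .data
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# single environment labels used throughout
ENVS <- c("normal", "saline")

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper kept for explicitness in pipeline code.
#' @param p numeric vector of p-values.
#' @return numeric vector of BH q-values.
#' @noRd
bh_adjust <- function(p) p.adjust(p, method = "BH")

# folded minor allele frequency from a dosage matrix (0/1/2, NA allowed);
# heterozygotes contribute half an alternate allele
folded_maf <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

# deterministic derived seeds, kept below 2^31
derive_seed <- function(seed, k) (as.integer(seed) %% 1000000L) * 1000L + k
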