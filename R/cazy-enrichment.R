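#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n): the chance of
#' drawing at least k class genes in a MAG of n genes when the background of
#' N genes holds K class genes. Computed via the log-space stable
#' distribution function.
#'
#' @param k class genes observed in the MAG.
#' @param n genes in the MAG.
#' @param K class genes in the background.
#' @param N genes in the background.
#' @return the upper-tail probability.
#' @export
hypergeomUpper <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0))
    stop("counts must be non-negative")
  if (any(k > n) || any(n > N) || any(K > N) || any(k > K))
    stop("inconsistent counts: need k <= min(n, K) and n, K <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving in the input.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return q-values in input order.
#' @export
bhFdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' CAZyme-class enrichment of MAGs
#'
#' Tests each (MAG, CAZy class) pair with at least one class gene for
#' over-representation against the pooled background of all genes in the
#' retained MAGs, using the upper-tail hypergeometric probability.
#' Benjamini-Hochberg q-values are computed across all tests. The primary
#' significance call uses the raw-p rule \code{p < alphaP} (default 1e-5);
#' q-values are reported alongside.
#'
#' @param cazyTable data.frame (mag_id, gene_id, cazy_class); rows with NA
#'   class are unannotated genes and count only toward gene totals.
#' @param quality optional quality table; when given, only MAGs in
#'   \code{tiers} enter the analysis (and the background).
#' @param tiers tiers retained when \code{quality} is supplied.
#' @param alphaP raw-p significance cutoff.
#' @return data.frame: mag_id, cazy_class, k, n, K, N, p, q, significant.
#' @export
enrichCazy <- function(cazyTable, quality = NULL, tiers = c("HQ", "MHQ"),
                       alphaP = 1e-5) {
  tab <- cazyTable
  if (!is.null(quality)) {
    keep_mags <- quality$mag_id[as.character(quality$tier) %in% tiers]
    tab <- tab[tab$mag_id %in% keep_mags, , drop = FALSE]
  }
  if (nrow(tab) == 0) stop("empty background: no genes after tier filtering")
  N <- nrow(tab)
  n_by_mag <- table(tab$mag_id)
  ann <- tab[!is.na(tab$cazy_class), , drop = FALSE]
  K_by_class <- table(ann$cazy_class)
  if (nrow(ann) == 0)
    return(data.frame(mag_id = character(), cazy_class = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      significant = logical()))
  counts <- as.data.frame(table(ann$mag_id, ann$cazy_class),
                          stringsAsFactors = FALSE)
  names(counts) <- c("mag_id", "cazy_class", "k")
  counts <- counts[counts$k > 0, , drop = FALSE]
  counts$n <- as.integer(n_by_mag[counts$mag_id])
  counts$K <- as.integer(K_by_class[counts$cazy_class])
  counts$N <- N
  counts$p <- hypergeomUpper(counts$k, counts$n, counts$K, counts$N)
  counts$q <- bhFdr(counts$p)
  counts$significant <- counts$p < alphaP
  counts <- counts[order(counts$p, counts$mag_id, counts$cazy_class), ]
  rownames(counts) <- NULL
  counts
}
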