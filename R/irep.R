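#' Admission filter for replication-index estimation
#'
#' A MAG/sample combination enters iRep estimation only when the MAG is
#' near-complete and clean (Cp > 90, Ct < 5), well assembled (fewer than
#' 175 scaffolds per Mbp), covered deeply enough (mean coverage > 5), and
#' -- for archaeal MAGs, where multiple replication origins break the
#' single-gradient model -- carries exactly one known replication origin
#' (origin counts are consumed as metadata).
#'
#' @param quality one-row slice of a quality table (or a list with cp, ct,
#'   scaffolds_per_mbp).
#' @param meanCoverage mean x-fold coverage of the MAG in the sample.
#' @param isArchaeal logical; origin rule applies only to archaea.
#' @param originCount replication origin count (required for archaea).
#' @return list: pass (logical) and reasons (character vector of failed
#'   filters, empty when passing).
#' @export
admitIrep <- function(quality, meanCoverage, isArchaeal = FALSE,
                      originCount = NA_integer_) {
  if (is.null(quality) || !all(c("cp", "ct") %in% names(quality)))
    stop("quality record with cp and ct required")
  reasons <- character()
  if (!(quality$cp > 90)) reasons <- c(reasons, "completeness <= 90")
  if (!(quality$ct < 5)) reasons <- c(reasons, "contamination >= 5")
  spm <- quality$scaffolds_per_mbp
  if (!is.null(spm) && !is.na(spm) && !(spm < 175))
    reasons <- c(reasons, "scaffolds/Mbp >= 175")
  if (!(meanCoverage > 5)) reasons <- c(reasons, "coverage <= 5")
  if (isArchaeal && (is.na(originCount) || originCount != 1L))
    reasons <- c(reasons, "archaeal origin count != 1")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Estimate the index of replication (iRep) from window coverage
#'
#' Implements the sorted-coverage log-linear model of replication: window
#' depths are log2-transformed, sorted ascending, the stated tails trimmed,
#' and log2 depth regressed on cumulative genome fraction in [0, 1]. The
#' fitted slope is the log2 origin:terminus coverage ratio, so
#' \code{irep = 2^slope}. Sorting makes the estimate invariant to circular
#' rotation of the genome (the origin position need not be known) and to
#' multiplicative depth scaling. Zero-depth windows are excluded before the
#' log transform and counted.
#'
#' Before sorting, depths are smoothed with a circular moving average over
#' \code{smoothWindows} adjacent windows (in genome order), mirroring the
#' averaging that overlapping sliding windows perform in the reference
#' formulation; this suppresses the upward bias that independent per-window
#' noise would otherwise impose on flat (non-replicating) profiles. Table
#' input is ordered by contig and window start first, so the estimate is
#' invariant to the row order of the depth table.
#'
#' @param depths numeric vector of window depths in genome order, or a
#'   data.frame with \code{depth} (and optionally \code{contig_id},
#'   \code{window_start}) columns as written by
#'   \code{\link{generateWindowCoverage}}.
#' @param trim fraction trimmed from each tail after sorting (default 0.05).
#' @param minWindows minimum windows required after trimming (default 50).
#' @param minR2 fit-quality threshold for the \code{fit_ok} verdict.
#' @param smoothWindows adjacent windows averaged before sorting (default 5;
#'   1 disables smoothing).
#' @return data.frame: n_windows, n_zero_windows, slope, r2, irep, fit_ok.
#' @export
estimateIrep <- function(depths, trim = 0.05, minWindows = 50L,
                         minR2 = 0.90, smoothWindows = 5L) {
  if (is.data.frame(depths)) {
    ord <- if (all(c("contig_id", "window_start") %in% names(depths)))
      order(depths$contig_id, depths$window_start) else seq_len(nrow(depths))
    d <- depths$depth[ord]
  } else d <- as.numeric(depths)
  n_zero <- sum(d <= 0)
  d <- d[d > 0]
  if (smoothWindows > 1L && length(d) >= smoothWindows)
    d <- as.numeric(stats::filter(d, rep(1 / smoothWindows, smoothWindows),
                                  sides = 2, circular = TRUE))
  y <- sort(log2(d))
  n <- length(y)
  ntrim <- floor(trim * n)
  keep <- if (ntrim > 0) (ntrim + 1):(n - ntrim) else seq_len(n)
  m <- length(keep)
  if (m < minWindows)
    stop(sprintf("too few windows after trimming (%d < %d)", m, minWindows))
  # genome fraction keeps the untrimmed scale so trimming does not shrink
  # the fitted gradient
  x <- (keep - 0.5) / n
  y <- y[keep]
  if (max(y) - min(y) < 1e-12) {
    # exactly constant coverage: zero slope, iRep exactly 1
    return(data.frame(n_windows = m, n_zero_windows = n_zero, slope = 0,
                      r2 = NA_real_, irep = 1.0, fit_ok = TRUE))
  }
  fit <- lm(y ~ x)
  slope <- coef(fit)[[2]]
  r2 <- summary(fit)$r.squared
  data.frame(n_windows = m, n_zero_windows = n_zero, slope = slope,
             r2 = r2, irep = 2^slope, fit_ok = r2 >= minR2)
}

#' Median iRep per MAG across samples
#'
#' @param estimates data.frame with mag_id and irep columns (one row per
#'   MAG x sample estimate); only rows with \code{fit_ok} are used when the
#'   column is present.
#' @return data.frame: mag_id, median_irep, n_estimates.
#' @export
medianIrep <- function(estimates) {
  e <- estimates
  if ("fit_ok" %in% names(e)) e <- e[e$fit_ok, , drop = FALSE]
  mags <- sort(unique(e$mag_id))
  data.frame(
    mag_id = mags,
    median_irep = vapply(mags, function(m) median(e$irep[e$mag_id == m]),
                         numeric(1)),
    n_estimates = vapply(mags, function(m) sum(e$mag_id == m), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise group comparison of iRep values
#'
#' Two-sided Wilcoxon rank-sum tests between all group pairs (normal
#' approximation with mid-rank tie correction), Bonferroni-corrected over
#' the number of pairs tested. Groups with fewer than \code{minSize}
#' values are skipped with a warning.
#'
#' @param values numeric vector of estimates.
#' @param groups group labels (taxon, metabolic guild, ...).
#' @param minSize minimum group size (default 3).
#' @return list: \code{table} (group_a, group_b, median_a, median_b,
#'   p_raw, p_bonferroni), \code{skipped} (undersized groups),
#'   \code{medians}.
#' @export
compareGroups <- function(values, groups, minSize = 3L) {
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < minSize]
  if (length(small))
    warning("group(s) skipped (fewer than ", minSize, " values): ",
            paste(small, collapse = ", "))
  keep <- !(groups %in% small)
  values <- values[keep]; groups <- groups[keep]
  gl <- sort(unique(groups))
  if (length(gl) < 2) stop("need at least two groups of sufficient size")
  med <- vapply(gl, function(g) median(values[groups == g]), numeric(1))
  pairs <- combn(gl, 2)
  np <- ncol(pairs)
  rows <- lapply(seq_len(np), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    p <- wilcox.test(values[groups == a], values[groups == b],
                     exact = FALSE, correct = TRUE)$p.value
    data.frame(group_a = a, group_b = b, median_a = med[[a]],
               median_b = med[[b]], p_raw = p,
               p_bonferroni = min(1, p * np), stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), skipped = small, medians = med)
}
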