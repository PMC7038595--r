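#' CC3 composite quality score
#'
#' Combines CheckM-style completeness (Cp) and contamination (Ct) estimates
#' into the single score \eqn{CC3 = Cp - 3 Ct}, weighting contamination three
#' times as heavily as missing completeness. The score may be negative.
#'
#' @param cp completeness percentage, in [0, 100]. Vectorised.
#' @param ct contamination percentage, >= 0. Vectorised.
#' @return numeric vector of CC3 scores.
#' @examples
#' cc3(90, 10)  # 60
#' @export
cc3 <- function(cp, ct) {
  if (any(!is.finite(cp)) || any(cp < 0 | cp > 100))
    stop("completeness (cp) must be within [0, 100]")
  if (any(!is.finite(ct)) || any(ct < 0))
    stop("contamination (ct) must be non-negative")
  cp - 3 * ct
}

#' Assign MAG quality tiers
#'
#' Tiers MAGs by completeness/contamination with a MIMAG-derived scheme
#' extended by a medium-high class. Thresholds are nested so that every
#' (Cp, Ct) pair maps to exactly one tier:
#' \itemize{
#'   \item \code{CONTAMINATED}: Ct > 10
#'   \item \code{HQ}: Cp > 90 and Ct < 5
#'   \item \code{MHQ}: Cp >= 70 and Ct <= 10 (and not HQ)
#'   \item \code{MQ}: Cp >= 50 (and not above)
#'   \item \code{LQ}: Cp < 50
#' }
#'
#' @inheritParams cc3
#' @return factor with levels HQ, MHQ, MQ, LQ, CONTAMINATED.
#' @examples
#' assignTier(c(92, 45, 80), c(4, 2, 12))
#' @export
assignTier <- function(cp, ct) {
  if (any(!is.finite(cp)) || any(cp < 0 | cp > 100))
    stop("completeness (cp) must be within [0, 100]")
  if (any(!is.finite(ct)) || any(ct < 0))
    stop("contamination (ct) must be non-negative")
  n <- max(length(cp), length(ct))
  cp <- rep_len(cp, n); ct <- rep_len(ct, n)
  tier <- rep("LQ", n)
  tier[cp >= 50] <- "MQ"
  tier[cp >= 70 & ct <= 10] <- "MHQ"
  tier[cp > 90 & ct < 5] <- "HQ"
  tier[ct > 10] <- "CONTAMINATED"
  factor(tier, levels = TIER_LEVELS)
}

#' Build a MAG quality table
#'
#' Assembles per-MAG quality records (CC3 score, tier, scaffolds per Mbp)
#' from completeness/contamination estimates and assembly statistics.
#'
#' @param mag_id character MAG identifiers (unique).
#' @param cp,ct completeness / contamination percentages.
#' @param n_scaffolds scaffold counts (optional).
#' @param genome_size genome sizes in bp (optional).
#' @return data.frame with columns mag_id, cp, ct, cc3, tier,
#'   scaffolds_per_mbp, genome_size.
#' @export
qualityTable <- function(mag_id, cp, ct, n_scaffolds = NA_integer_,
                         genome_size = NA_real_) {
  if (anyDuplicated(mag_id)) stop("duplicate MAG ids in quality table")
  spm <- ifelse(is.na(n_scaffolds) | is.na(genome_size), NA_real_,
                n_scaffolds / (genome_size / 1e6))
  data.frame(mag_id = as.character(mag_id), cp = cp, ct = ct,
             cc3 = cc3(cp, ct), tier = assignTier(cp, ct),
             scaffolds_per_mbp = spm, genome_size = genome_size,
             stringsAsFactors = FALSE)
}

#' Filter quality records by tier
#'
#' Subsets a quality table to the requested tiers (typically HQ + MHQ, the
#' set carried into functional analysis), preserving input order.
#'
#' @param records data.frame as returned by \code{\link{qualityTable}}.
#' @param tiers character vector of tier labels to keep.
#' @return the matching subset of \code{records}, order-stable.
#' @export
filterForAnalysis <- function(records, tiers = c("HQ", "MHQ")) {
  if (length(tiers) == 0L) stop("tiers must be non-empty")
  bad <- setdiff(tiers, TIER_LEVELS)
  if (length(bad))
    stop("unknown tier label(s): ", paste(bad, collapse = ", "))
  records[as.character(records$tier) %in% tiers, , drop = FALSE]
}
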