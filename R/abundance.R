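#' Relative abundance matrix from counts or depth mass
#'
#' Column-normalises a MAG x sample table of read counts (or depth x length
#' mass) to percentages summing to 100 per sample, and attaches strict
#' presence calls at the stated threshold (default 0.001\%).
#'
#' @param counts numeric matrix or data.frame, MAG rows x sample columns,
#'   with dimnames.
#' @param threshold presence threshold in percent.
#' @return a \code{\linkS4class{MagAbundance}}.
#' @export
relativeAbundance <- function(counts, threshold = 0.001) {
  m <- as.matrix(counts)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("counts must carry MAG rownames and sample colnames")
  if (any(m < 0)) stop("counts must be non-negative")
  cs <- colSums(m)
  if (any(cs == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(m)[cs == 0], collapse = ", "))
  vals <- sweep(m, 2, cs, "/") * 100
  new("MagAbundance", values = vals, threshold = threshold)
}

#' Subsampling consistency check
#'
#' Verifies that relative abundances computed from a fixed-size read
#' subsample agree with full-data abundances: for each sample, n reads are
#' drawn (multinomial approximation to sampling without replacement) and
#' the Pearson correlation between subsampled and full relative abundances
#' is computed over MAGs above the presence threshold in the full data.
#' When \code{n} equals the sample total the subsample is the full sample.
#'
#' @param counts integer MAG x sample count matrix.
#' @param n subsample size in reads (default 1e6).
#' @param seed integer seed.
#' @param threshold presence threshold in percent.
#' @return named numeric vector: per-sample Pearson r.
#' @export
subsampleCheck <- function(counts, n = 1e6, seed, threshold = 0.001) {
  m <- as.matrix(counts)
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  tot <- colSums(m)
  if (any(tot < n))
    stop("subsample size exceeds total reads in sample(s): ",
         paste(colnames(m)[tot < n], collapse = ", "))
  r <- setNames(numeric(ncol(m)), colnames(m))
  for (s in seq_len(ncol(m))) {
    full_rel <- 100 * m[, s] / tot[s]
    sub <- if (tot[s] == n) m[, s] else rmultinom(1, n, prob = m[, s])[, 1]
    sub_rel <- 100 * sub / n
    keep <- full_rel > threshold
    r[s] <- if (sum(keep) >= 2) cor(full_rel[keep], sub_rel[keep]) else NA_real_
  }
  r
}

#' Fraction of MAGs shared between two samples
#'
#' Jaccard similarity of the presence sets of two samples: shared present
#' MAGs over MAGs present in either. Defined as 0 when no MAG is present
#' in either sample.
#'
#' @param abundance a \code{\linkS4class{MagAbundance}}.
#' @param a,b sample ids.
#' @return numeric in [0, 1].
#' @export
sharedFraction <- function(abundance, a, b) {
  pres <- presenceCalls(abundance)
  for (s in c(a, b)) if (!s %in% colnames(pres))
    stop("sample not in matrix: ", s)
  pa <- pres[, a]; pb <- pres[, b]
  uni <- sum(pa | pb)
  if (uni == 0) return(0)
  sum(pa & pb) / uni
}

#' Per-sample Bacteria : Archaea abundance ratio
#'
#' @param abundance a \code{\linkS4class{MagAbundance}}.
#' @param domainMap named character, MAG id -> "Bacteria" or "Archaea";
#'   every present MAG must be labelled.
#' @return named numeric vector; \code{Inf} when the archaeal sum is 0.
#' @export
domainRatio <- function(abundance, domainMap) {
  vals <- abundanceValues(abundance)
  pres <- presenceCalls(abundance)
  present_mags <- rownames(vals)[rowSums(pres) > 0]
  unl <- setdiff(present_mags, names(domainMap))
  if (length(unl))
    stop("present MAG(s) without domain label: ",
         paste(head(unl, 5), collapse = ", "))
  dom <- domainMap[rownames(vals)]
  bac <- colSums(vals[which(dom == "Bacteria"), , drop = FALSE])
  arc <- colSums(vals[which(dom == "Archaea"), , drop = FALSE])
  ifelse(arc == 0, Inf, bac / arc)
}

#' Abundance/prevalence classification of MAGs
#'
#' Labels each MAG abundant (maximum relative abundance above 1\%) or
#' low-abundant, and widespread (present above the presence threshold in
#' more than 10\% of samples) or sporadic.
#'
#' @param abundance a \code{\linkS4class{MagAbundance}}.
#' @param abundantCutoff percent abundance a MAG must exceed somewhere.
#' @param prevalenceCutoff fraction of samples that must be exceeded.
#' @return data.frame: mag_id, max_abundance, prevalence,
#'   abundance_class, prevalence_class.
#' @export
classifyPrevalence <- function(abundance, abundantCutoff = 1,
                               prevalenceCutoff = 0.10) {
  vals <- abundanceValues(abundance)
  pres <- presenceCalls(abundance)
  if (ncol(vals) < 1) stop("at least one sample required")
  max_ab <- apply(vals, 1, max)
  prev <- rowMeans(pres)
  data.frame(
    mag_id = rownames(vals),
    max_abundance = max_ab,
    prevalence = prev,
    abundance_class = ifelse(max_ab > abundantCutoff, "abundant",
                             "low-abundant"),
    prevalence_class = ifelse(prev > prevalenceCutoff, "widespread",
                              "sporadic"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate MAG abundances by taxonomic label
#'
#' Sums the relative abundances of MAGs sharing a taxonomic assignment;
#' column sums are preserved.
#'
#' @param abundance a \code{\linkS4class{MagAbundance}}.
#' @param taxonomy named character, MAG id -> taxon label (total).
#' @return taxon x sample numeric matrix.
#' @export
aggregateByTaxon <- function(abundance, taxonomy) {
  vals <- abundanceValues(abundance)
  unl <- setdiff(rownames(vals), names(taxonomy))
  if (length(unl))
    stop("MAG(s) without taxonomy label: ", paste(head(unl, 5), collapse = ", "))
  lab <- taxonomy[rownames(vals)]
  rowsum(vals, group = lab, reorder = TRUE)
}

#' Cluster abundance profiles (Pearson distance, average linkage)
#'
#' Hierarchically clusters MAG (or sample) abundance profiles with distance
#' 1 - Pearson correlation and UPGMA (average) linkage; rows are ordered
#' lexicographically first so merge order and tie-breaks are deterministic.
#'
#' @param abundance a \code{\linkS4class{MagAbundance}}.
#' @param axis cluster "mags" (rows) or "samples" (columns).
#' @return list with \code{hclust} (the tree) and \code{newick} (string).
#' @export
clusterProfiles <- function(abundance, axis = c("mags", "samples")) {
  axis <- match.arg(axis)
  m <- abundanceValues(abundance)
  if (axis == "samples") m <- t(m)
  m <- m[order(rownames(m)), , drop = FALSE]
  if (nrow(m) < 2) stop("need at least two profiles to cluster")
  sds <- apply(m, 1, sd)
  if (any(sds == 0))
    stop("constant profile(s), correlation undefined: ",
         paste(rownames(m)[sds == 0], collapse = ", "))
  d <- as.dist(1 - cor(t(m)))
  hc <- hclust(d, method = "average")
  list(hclust = hc, newick = ape::write.tree(ape::as.phylo(hc)))
}
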