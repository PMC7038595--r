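#' Alpha-diversity indices for one sample
#'
#' Computes the standard index family on per-MAG read counts: observed
#' richness S, dominance \eqn{\sum p_i^2}, Simpson \eqn{1 - \sum p_i^2},
#' Shannon \eqn{H = -\sum p_i \ln p_i}, evenness \eqn{e^H / S},
#' Berger-Parker \eqn{\max p_i}, Chao-1
#' \eqn{S + F_1^2 / (2 F_2)} (bias-corrected fallback
#' \eqn{S + F_1 (F_1 - 1) / 2} when there are no doubletons), and Fisher's
#' alpha, the root of \eqn{S = \alpha \ln(1 + N / \alpha)} found by
#' bracketed root-finding (tolerance 1e-9; \code{Inf} when every taxon is a
#' singleton, where no finite root exists).
#'
#' @param counts non-negative per-MAG read counts (integers required for
#'   Fisher alpha and Chao-1 singleton/doubleton counting).
#' @param sampleId optional sample id carried into the output.
#' @return one-row data.frame: sample_id, s_obs, dominance, simpson,
#'   shannon_h, evenness, fisher_alpha, berger_parker, chao1.
#' @export
alphaDiversity <- function(counts, sampleId = NA_character_) {
  x <- as.numeric(counts)
  if (any(x < 0)) stop("counts must be non-negative")
  x <- x[x > 0]
  if (length(x) == 0) stop("all counts are zero")
  N <- sum(x)
  S <- length(x)
  p <- x / N
  dominance <- sum(p^2)
  H <- -sum(p * log(p))
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  chao1 <- if (f2 > 0) S + f1^2 / (2 * f2) else S + f1 * (f1 - 1) / 2
  fisher <- if (any(abs(x - round(x)) > 1e-8)) {
    NA_real_
  } else if (S >= N) {
    Inf
  } else {
    f <- function(a) a * log(1 + N / a) - S
    uniroot(f, lower = 1e-10, upper = 1e10, tol = 1e-12)$root
  }
  data.frame(sample_id = sampleId, s_obs = S, dominance = dominance,
             simpson = 1 - dominance, shannon_h = H,
             evenness = exp(H) / S, fisher_alpha = fisher,
             berger_parker = max(p), chao1 = chao1,
             stringsAsFactors = FALSE)
}

#' Whittaker beta diversity between two samples
#'
#' \eqn{\beta_W = S_{union} / \bar{S} - 1} on presence sets, ranging from 0
#' (identical composition) to 1 (disjoint, equal-size sets).
#'
#' @param a,b presence sets: character vectors of taxon ids, or logical
#'   vectors over a shared taxon ordering.
#' @return the dissimilarity.
#' @export
betaWhittaker <- function(a, b) {
  if (is.logical(a)) a <- which(a)
  if (is.logical(b)) b <- which(b)
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must have at least one taxon present")
  s_union <- length(union(a, b))
  s_union / mean(c(length(a), length(b))) - 1
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{\sum |a_i - b_i| / \sum (a_i + b_i)}, in [0, 1].
#'
#' @param a,b non-negative abundance vectors over the same taxon ordering.
#' @return the dissimilarity.
#' @export
brayCurtis <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("abundances must be non-negative")
  tot <- sum(a + b)
  if (tot == 0) stop("both vectors are all-zero")
  sum(abs(a - b)) / tot
}

#' Pairwise distance matrix under a chosen dissimilarity
#'
#' @param m taxon x sample matrix.
#' @param method "bray" (abundance) or "whittaker" (presence at
#'   \code{threshold}).
#' @param threshold presence threshold for the Whittaker method.
#' @return symmetric sample x sample matrix with zero diagonal.
#' @export
distanceMatrix <- function(m, method = c("bray", "whittaker"),
                           threshold = 0.001) {
  method <- match.arg(method)
  ns <- ncol(m)
  out <- matrix(0, ns, ns, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(ns)) for (j in seq_len(ns)) if (j > i) {
    d <- if (method == "bray") brayCurtis(m[, i], m[, j])
         else betaWhittaker(m[, i] > threshold, m[, j] > threshold)
    out[i, j] <- d; out[j, i] <- d
  }
  out
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration producing an ultrametric tree; leaves sit
#' at half the merge distance. Input rows are ordered lexicographically so
#' tie-breaks are deterministic.
#'
#' @param d symmetric distance matrix with zero diagonal (asymmetry beyond
#'   1e-9 is an error).
#' @return list: \code{hclust}, \code{phylo} (ape), \code{newick}.
#' @export
upgmaTree <- function(d) {
  d <- as.matrix(d)
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- hclust(as.dist(d), method = "average")
  ph <- ape::as.phylo(hc)
  list(hclust = hc, phylo = ph, newick = ape::write.tree(ph))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres \eqn{-\frac{1}{2} D^2}, eigendecomposes, and returns
#' coordinates scaled by the square roots of the positive eigenvalues;
#' axes with negative eigenvalues (non-Euclidean distances) are dropped and
#' their eigenvalues reported.
#'
#' @param d symmetric distance matrix (at least 3 samples).
#' @return list: coordinates (sample x axis, centred), eigenvalues
#'   (positive, descending), negative_eigenvalues.
#' @export
pcoaOrdination <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("PCoA requires at least 3 samples")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  n <- nrow(d)
  sc <- cmdscale(as.dist(d), k = n - 1, eig = TRUE)
  eig <- sc$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  coords <- sc$points[, seq_len(sum(pos[seq_len(ncol(sc$points))])),
                      drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig[pos],
       negative_eigenvalues = eig[eig < 0])
}

#' Group comparison tests for per-sample statistics
#'
#' Mann-Whitney (two-sided Wilcoxon rank-sum, normal approximation with
#' mid-rank tie correction) between all group pairs with Bonferroni
#' correction, or Welch's t-test (the choice used for comparing species
#' richness between feedstock groups). Groups smaller than 2 are skipped
#' with a warning.
#'
#' @param values numeric per-sample statistic.
#' @param groups group labels.
#' @param method "mann-whitney" or "t-test".
#' @return data.frame: group_a, group_b, n_a, n_b, statistic, p_raw,
#'   p_bonferroni.
#' @export
groupTests <- function(values, groups, method = c("mann-whitney", "t-test")) {
  method <- match.arg(method)
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small))
    warning("group(s) skipped (fewer than 2 values): ",
            paste(small, collapse = ", "))
  keep <- !(groups %in% small)
  values <- values[keep]; groups <- groups[keep]
  gl <- sort(unique(groups))
  if (length(gl) < 2) stop("need at least two groups")
  pairs <- combn(gl, 2)
  np <- ncol(pairs)
  rows <- lapply(seq_len(np), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    va <- values[groups == a]; vb <- values[groups == b]
    ht <- if (method == "mann-whitney")
      wilcox.test(va, vb, exact = FALSE, correct = TRUE)
    else t.test(va, vb)
    data.frame(group_a = a, group_b = b, n_a = length(va), n_b = length(vb),
               statistic = unname(ht$statistic), p_raw = ht$p.value,
               p_bonferroni = min(1, ht$p.value * np),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
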