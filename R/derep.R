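#' MinHash sketch of a genome
#'
#' Bottom-s MinHash sketch over canonical k-mers (lexicographic minimum of
#' the strand pair), using a fixed 64-bit mixing hash with a constant seed
#' so sketches are bit-reproducible across runs and machines. Hash values
#' are truncated to 53 bits so they are exact doubles.
#'
#' @param genome a \code{DNAStringSet} of contigs, or a character vector.
#' @param k k-mer length (default 21).
#' @param s sketch size (default 1000).
#' @param magId optional identifier stored with the sketch.
#' @return object of class \code{mash_sketch}: list with mag_id, k, s and
#'   the sorted hash values.
#' @export
sketchGenome <- function(genome, k = 21L, s = 1000L, magId = NA_character_) {
  seqs <- if (methods::is(genome, "DNAStringSet")) as.character(genome)
          else as.character(genome)
  if (sum(nchar(seqs)) < k) stop("genome shorter than k")
  hashes <- minhash_sketch_cpp(seqs, as.integer(k), as.integer(s))
  structure(list(mag_id = magId, k = as.integer(k), s = as.integer(s),
                 hashes = hashes), class = "mash_sketch")
}

#' Mash distance between two sketches
#'
#' Estimates the Jaccard index j from the shared fraction of the merged
#' bottom-s sketch and converts it to the Mash distance
#' \eqn{d = -\frac{1}{k} \ln \frac{2j}{1+j}}, which approximates sequence
#' divergence (1 - ANI/100). When no hashes are shared the distance is
#' reported as 1.
#'
#' @param a,b \code{mash_sketch} objects with identical k.
#' @return list with \code{distance}, \code{jaccard} and
#'   \code{shared_hashes}.
#' @export
mashDistance <- function(a, b) {
  if (!inherits(a, "mash_sketch") || !inherits(b, "mash_sketch"))
    stop("inputs must be mash_sketch objects")
  if (a$k != b$k) stop("sketches built with different k")
  s <- min(a$s, b$s)
  merged <- sort(unique(c(a$hashes, b$hashes)))
  sprime <- min(s, length(merged))
  bottom <- merged[seq_len(sprime)]
  shared <- sum(bottom %in% a$hashes & bottom %in% b$hashes)
  j <- shared / sprime
  d <- if (j <= 0) 1 else min(1, -log(2 * j / (1 + j)) / a$k)
  list(distance = d, jaccard = j, shared_hashes = shared)
}

#' Fragment-based average nucleotide identity
#'
#' Cuts the query genome into non-overlapping fragments (default 1020 bp,
#' trailing partial fragments dropped), places each fragment on its best
#' target locus by exact seed-word voting on both strands, and scores the
#' placement by gap-free identity over the aligned overlap. A placement
#' must cover at least \code{minFragCoverage} of the fragment (fragments
#' clipped at a scaffold end beyond that are no-hits, rather than being
#' charged mismatches). ANI is the mean identity of fragments reaching
#' \code{minFragIdentity}; the aligned fraction is the percentage of query
#' fragments that qualify -- the genome coverage used by the species rule.
#'
#' @param query,target \code{DNAStringSet}s of contigs (or character).
#' @param fragment fragment length in bp (default 1020).
#' @param minFragIdentity minimum percent identity for a fragment to count
#'   (default 70).
#' @param seedK seed word length for locus finding (default 16).
#' @param stride spacing between seed words (default 4).
#' @param minFragCoverage minimum fraction of the fragment the best
#'   placement must cover (default 0.7).
#' @return list with \code{ani} (percent; NA when no fragment qualifies),
#'   \code{aligned_fraction} (percent), \code{n_fragments} and the raw
#'   per-fragment identities.
#' @export
aniPair <- function(query, target, fragment = 1020L, minFragIdentity = 70,
                    seedK = 16L, stride = 4L, minFragCoverage = 0.7) {
  q <- if (methods::is(query, "DNAStringSet")) as.character(query)
       else as.character(query)
  t <- if (methods::is(target, "DNAStringSet")) as.character(target)
       else as.character(target)
  if (!sum(nchar(q)) || !sum(nchar(t))) stop("empty genome")
  ani_fragments_cpp(q, t, as.integer(fragment), as.integer(seedK),
                    as.integer(stride), minFragIdentity, minFragCoverage)
}

#' Dereplicate MAGs into species-level clusters
#'
#' Applies the two-stage species rule: a permissive MinHash (Mash) distance
#' pre-filter proposes candidate pairs, fragment ANI is computed in both
#' directions for each candidate, and a pair is joined when at least one
#' direction shows ANI above \code{aniCutoff} (strict) with an aligned
#' fraction of at least \code{covCutoff}. Species clusters are the connected
#' components of the resulting graph (single linkage); each cluster's
#' representative is the member with the highest CC3 score, ties broken by
#' larger genome then lexicographic id.
#'
#' @param mags a \code{\linkS4class{MagSet}} or named list of
#'   \code{DNAStringSet}s.
#' @param quality optional data.frame from \code{\link{qualityTable}} used
#'   for representative selection; without it the largest genome is chosen.
#' @param mashCutoff candidate pairs must have Mash distance <= this value
#'   (default 0.05, roughly 95\% ANI). Set \code{usePrefilter = FALSE} to
#'   compute ANI for all pairs.
#' @param aniCutoff percent ANI that must be exceeded (default 95).
#' @param covCutoff minimum aligned fraction percent (default 50).
#' @param k,sketchSize MinHash parameters.
#' @param fragment ANI fragment length.
#' @param usePrefilter logical; disable to brute-force all pairs.
#' @return list with \code{clusters} (data.frame cluster_id, mag_id,
#'   is_representative), \code{pairs} (pairwise ANI results for evaluated
#'   pairs) and \code{n_clusters}.
#' @export
clusterSpecies <- function(mags, quality = NULL, mashCutoff = 0.05,
                           aniCutoff = 95, covCutoff = 50, k = 21L,
                           sketchSize = 1000L, fragment = 1020L,
                           usePrefilter = TRUE) {
  genomes <- if (methods::is(mags, "MagSet")) genomeSeqs(mags) else mags
  ids <- sort(names(genomes))
  n <- length(ids)
  if (n == 0)
    return(list(clusters = data.frame(cluster_id = character(),
                                      mag_id = character(),
                                      is_representative = logical()),
                pairs = data.frame(), n_clusters = 0L))
  glen <- vapply(genomes, function(x) sum(nchar(as.character(x))), numeric(1))
  pair_rows <- list()
  edges <- matrix(character(), ncol = 2, nrow = 0)
  if (n >= 2) {
    cand <- combn(ids, 2)
    if (usePrefilter) {
      sk <- lapply(genomes[ids], sketchGenome, k = k, s = sketchSize)
      keepp <- vapply(seq_len(ncol(cand)), function(i) {
        mashDistance(sk[[cand[1, i]]], sk[[cand[2, i]]])$distance <= mashCutoff
      }, logical(1))
      cand <- cand[, keepp, drop = FALSE]
    }
    for (i in seq_len(ncol(cand))) {
      a <- cand[1, i]; b <- cand[2, i]
      fwd <- aniPair(genomes[[a]], genomes[[b]], fragment = fragment)
      rev <- aniPair(genomes[[b]], genomes[[a]], fragment = fragment)
      ok <- function(x) !is.na(x$ani) && x$ani > aniCutoff &&
        x$aligned_fraction >= covCutoff
      hit <- ok(fwd) || ok(rev)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        query = c(a, b), target = c(b, a),
        ani = c(fwd$ani, rev$ani),
        aligned_fraction = c(fwd$aligned_fraction, rev$aligned_fraction),
        is_edge = hit, stringsAsFactors = FALSE)
      if (hit) edges <- rbind(edges, c(a, b))
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership[ids]
  cc3v <- rep(NA_real_, n); names(cc3v) <- ids
  if (!is.null(quality)) {
    qm <- quality[match(ids, quality$mag_id), , drop = FALSE]
    cc3v <- setNames(qm$cc3, ids)
  }
  rows <- list()
  for (ci in sort(unique(comp))) {
    members <- sort(ids[comp == ci])
    key <- order(-ifelse(is.na(cc3v[members]), -Inf, cc3v[members]),
                 -glen[members], members)
    rep_id <- members[key[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = NA_character_, mag_id = members,
      is_representative = members == rep_id, stringsAsFactors = FALSE)
  }
  clusters <- do.call(rbind, rows)
  # stable cluster ids: ordered by lexicographically smallest member
  grp <- rep(seq_along(rows), vapply(rows, nrow, 1L))
  firsts <- tapply(clusters$mag_id, grp, min)
  ord <- order(firsts)
  newid <- setNames(sprintf("SC%03d", seq_along(ord)), names(firsts)[ord])
  clusters$cluster_id <- newid[as.character(grp)]
  clusters <- clusters[order(clusters$cluster_id, clusters$mag_id), ]
  rownames(clusters) <- NULL
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else data.frame()
  rownames(pairs) <- NULL
  list(clusters = clusters, pairs = pairs,
       n_clusters = length(unique(clusters$cluster_id)))
}
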