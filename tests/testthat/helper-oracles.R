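# Independent oracles used to cross-check the package's implementations.
# Each is deliberately written along a different code path (brute force,
# enumeration, base-R evaluation) than the function it validates.

# exhaustive upper-tail hypergeometric by summing the mass function
enumHypergeomUpper <- function(k, n, K, N) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# O(n^3) UPGMA recomputing every cluster-pair average from the original
# matrix; returns the cophenetic distance matrix
naiveUpgmaCophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) if (j > i) {
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < best[1]) best <- c(avg, i, j)
    }
    i <- best[2]; j <- best[3]
    for (a in clusters[[i]]) for (b in clusters[[j]])
      coph[a, b] <- coph[b, a] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# module-block evaluation through R's own parser: strip optional parts,
# substitute KO presence, translate operators to logical syntax
oracleBlocksMissing <- function(definition, kos) {
  splitDepth0 <- function(s, sep) {
    out <- character(); depth <- 0; buf <- ""
    for (ch in strsplit(s, "")[[1]]) {
      if (ch == "(") depth <- depth + 1
      if (ch == ")") depth <- depth - 1
      if (ch == sep && depth == 0) { out <- c(out, buf); buf <- "" }
      else buf <- paste0(buf, ch)
    }
    c(out, buf)
  }
  blocks <- Filter(nzchar, trimws(splitDepth0(definition, " ")))
  missing <- 0L
  for (b in blocks) {
    e <- b
    e <- gsub("-\\([^()]*\\)", "", e)       # optional groups
    e <- gsub("-K[0-9]{5}", "", e)          # optional KOs
    if (!grepl("K[0-9]{5}", e)) next        # block became vacuous -> satisfied
    e <- gsub("(K[0-9]{5})", "@\\1@", e)
    for (ko in unique(regmatches(e, gregexpr("K[0-9]{5}", e))[[1]]))
      e <- gsub(paste0("@", ko, "@"), if (ko %in% kos) "TRUE" else "FALSE",
                e, fixed = TRUE)
    e <- gsub("\\+", "&", e)
    e <- gsub(",", "|", e)
    e <- gsub("\\) *\\(", ")&(", e)
    e <- gsub("(TRUE|FALSE) +(?=[(TF])", "\\1&", e, perl = TRUE)
    e <- gsub("\\) +(?=[(TF])", ")&", e, perl = TRUE)
    ok <- eval(parse(text = e))
    if (!ok) missing <- missing + 1L
  }
  missing
}

# exact canonical k-mer Jaccard via Biostrings (full enumeration)
exactCanonicalJaccard <- function(a, b, k = 21) {
  kmerSet <- function(seqs) {
    out <- character()
    for (s in as.character(seqs)) {
      if (nchar(s) < k) next
      starts <- seq_len(nchar(s) - k + 1)
      km <- substring(s, starts, starts + k - 1)
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(km)))
      out <- c(out, pmin(km, rc))
    }
    unique(out)
  }
  ka <- kmerSet(a); kb <- kmerSet(b)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# bracketed bisection for Fisher's alpha
bisectFisherAlpha <- function(S, N, tol = 1e-10) {
  f <- function(a) a * log(1 + N / a) - S
  lo <- 1e-9; hi <- 1e9
  while (hi - lo > tol * max(1, lo)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# connected components by plain transitive closure over an edge list
closureComponents <- function(ids, edges) {
  comp <- stats::setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    if (nrow(edges)) for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# canonical form of a partition for equality testing
canonicalPartition <- function(members, groups) {
  sp <- split(members, groups)
  sp <- lapply(sp, sort)
  unname(sp[order(vapply(sp, `[`, "", 1))])
}

# parse fixture modules once per test file
fixtureModules <- function() readModuleDefinitions()
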