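makeCounts <- function() {
  m <- matrix(c(3, 1, 0,
                1, 1, 2,
                0, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("S1", "S2", "S3")))
  m
}

test_that("relative abundance normalises columns to 100 and is idempotent", {
  ab <- relativeAbundance(makeCounts())
  vals <- abundanceValues(ab)
  expect_equal(unname(colSums(vals)), c(100, 100, 100))
  expect_equal(unname(vals[, "S1"]), c(75, 25, 0))
  twice <- relativeAbundance(abundanceValues(ab))
  expect_equal(abundanceValues(twice), vals)
  m <- makeCounts(); m[, 2] <- 0
  expect_error(relativeAbundance(m), "S2")
  expect_error(relativeAbundance(-makeCounts()), "non-negative")
})

test_that("presence is a strict call at the 0.001 percent threshold", {
  vals <- matrix(c(0.0009, 99.9991,
                   0.0011, 99.9989), ncol = 2,
                 dimnames = list(c("rare", "dom"), c("S1", "S2")))
  ab <- new("MagAbundance", values = vals, threshold = 0.001)
  pres <- presenceCalls(ab)
  expect_false(pres["rare", "S1"])   # 0.0009% is absent
  expect_true(pres["rare", "S2"])
  expect_true(all(pres["dom", ]))
})

test_that("subsampling a synthetic 5M-read sample is self-consistent", {
  set.seed(21)
  nmag <- 600
  probs <- rlnorm(nmag, sdlog = 2)
  counts <- matrix(rmultinom(1, 5e6, probs), ncol = 1,
                   dimnames = list(sprintf("m%03d", 1:nmag), "S1"))
  r <- subsampleCheck(counts, n = 1e6, seed = 7)
  expect_gt(r[["S1"]], 0.999)
  # subsample equal to the full sample is exact
  r_full <- subsampleCheck(counts, n = 5e6, seed = 7)
  expect_equal(r_full[["S1"]], 1)
  # permutation of MAG rows leaves r unchanged up to the independent draw
  perm <- sample(nmag)
  r_perm <- subsampleCheck(counts[perm, , drop = FALSE], n = 1e6, seed = 7)
  expect_equal(r_perm[["S1"]], r[["S1"]], tolerance = 1e-3)
  expect_gt(r_perm[["S1"]], 0.999)
  expect_error(subsampleCheck(counts, n = 1e7, seed = 1), "exceeds")
})

test_that("shared fraction is presence Jaccard with symmetric edge cases", {
  vals <- matrix(0.0005, nrow = 4, ncol = 3,
                 dimnames = list(c("m1", "m2", "m3", "m4"),
                                 c("A", "B", "C")))
  vals["m1", ] <- c(30, 0.0005, 30)
  vals["m2", ] <- c(30, 30, 30)
  vals["m3", ] <- c(30, 30, 0.0005)
  vals["m4", ] <- 100 - colSums(vals[1:3, , drop = FALSE])
  ab <- new("MagAbundance", values = vals, threshold = 0.001)
  # A: {m1,m2,m3,m4}; B: {m2,m3,m4}; C: {m1,m2,m4}
  expect_equal(sharedFraction(ab, "A", "B"), 3 / 4)
  expect_equal(sharedFraction(ab, "A", "B"), sharedFraction(ab, "B", "A"))
  expect_equal(sharedFraction(ab, "A", "A"), 1)
  expect_equal(sharedFraction(ab, "B", "C"), 2 / 4)
  expect_error(sharedFraction(ab, "A", "Z"), "Z")
})

test_that("domain ratio reproduces arithmetic and the infinity sentinel", {
  vals <- matrix(c(93.33, 6.67,
                   50, 50,
                   100, 0), ncol = 3,
                 dimnames = list(c("bac", "arc"), c("S1", "S2", "S3")))
  ab <- new("MagAbundance", values = vals, threshold = 0.001)
  dm <- c(bac = "Bacteria", arc = "Archaea")
  r <- domainRatio(ab, dm)
  expect_equal(unname(r["S1"]), 14.0, tolerance = 0.01)
  expect_equal(unname(r["S2"]), 1)
  expect_equal(unname(r["S3"]), Inf)
  expect_error(domainRatio(ab, dm["bac"]), "without domain")
})

test_that("prevalence classification applies the 1% / 10%-of-samples rules", {
  ns <- 20
  vals <- matrix(0.0004, nrow = 3, ncol = ns,
                 dimnames = list(c("spike", "flat", "ghost"),
                                 paste0("S", 1:ns)))
  vals["spike", 1] <- 2                      # abundant in one sample only
  vals["flat", ] <- 0.01                     # low but everywhere
  filler <- 100 - colSums(vals)
  vals <- rbind(vals, filler = filler)
  ab <- new("MagAbundance", values = vals, threshold = 0.001)
  cls <- classifyPrevalence(ab)
  pick <- function(id, col) cls[[col]][cls$mag_id == id]
  expect_equal(pick("spike", "abundance_class"), "abundant")
  expect_equal(pick("spike", "prevalence_class"), "sporadic")   # 1/20 = 5%
  expect_equal(pick("flat", "abundance_class"), "low-abundant")
  expect_equal(pick("flat", "prevalence_class"), "widespread")
  expect_equal(pick("ghost", "prevalence_class"), "sporadic")
  # stable under column permutation
  perm <- sample(ns)
  cls2 <- classifyPrevalence(new("MagAbundance",
                                 values = vals[, perm], threshold = 0.001))
  expect_equal(cls2[order(cls2$mag_id), ], cls[order(cls$mag_id), ])
})

test_that("taxon aggregation preserves column sums and is associative", {
  gen <- generateAbundances(sprintf("m%02d", 1:12), 4, seed = 5)
  ab <- gen$abundance
  phylum <- setNames(rep(c("Firmicutes", "Bacteroidetes", "Euryarchaeota"),
                         each = 4), sprintf("m%02d", 1:12))
  domain_of <- c(Firmicutes = "Bacteria", Bacteroidetes = "Bacteria",
                 Euryarchaeota = "Archaea")
  tax <- aggregateByTaxon(ab, phylum)
  expect_equal(unname(colSums(tax)), rep(100, 4))
  # aggregating the phylum matrix to domain equals direct domain aggregation
  domain <- setNames(domain_of[phylum], names(phylum))
  direct <- aggregateByTaxon(ab, domain)
  via_phylum <- rowsum(tax, domain_of[rownames(tax)])
  expect_equal(direct, via_phylum[rownames(direct), ])
})

test_that("profile clustering is UPGMA on 1 - Pearson with named errors", {
  vals <- matrix(c(10, 20, 30,
                   10, 20, 30,
                   30, 20, 10,
                   50, 40, 30), nrow = 4, byrow = TRUE,
                 dimnames = list(c("a", "b", "anti", "d"), c("S1", "S2", "S3")))
  vals <- rbind(vals, filler = 100 - colSums(vals))
  expect_error(
    clusterProfiles(new("MagAbundance", values = vals, threshold = 0.001)),
    "filler")   # the filler row is constant
  vals2 <- vals[1:4, ]
  vals2 <- sweep(vals2, 2, colSums(vals2), "/") * 100
  ab <- new("MagAbundance", values = vals2, threshold = 0.001)
  res <- clusterProfiles(ab)
  hc <- res$hclust
  # identical profiles merge at height 0; anticorrelated pair at distance 2
  expect_equal(min(hc$height), 0, tolerance = 1e-12)
  d <- 1 - cor(t(vals2))
  expect_equal(max(d), 2, tolerance = 1e-12)
  expect_match(res$newick, "^\\(")
})

test_that("5-profile UPGMA dendrogram matches the brute-force oracle", {
  set.seed(41)
  m <- matrix(runif(25, 1, 10), nrow = 5,
              dimnames = list(paste0("m", 1:5), paste0("S", 1:5)))
  m <- sweep(m, 2, colSums(m), "/") * 100
  ab <- new("MagAbundance", values = m, threshold = 0.001)
  res <- clusterProfiles(ab)
  d <- 1 - cor(t(m[order(rownames(m)), ]))
  expect_equal(as.matrix(cophenetic(res$hclust))[rownames(d), colnames(d)],
               naiveUpgmaCophenetic(d), tolerance = 1e-12)
})
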