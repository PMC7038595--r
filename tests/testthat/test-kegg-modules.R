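test_that("definition parsing produces the expected block structure", {
  m1 <- parseDefinition("M1", "K00001 K00002")
  expect_equal(length(m1@blocks), 2)
  expect_true(all(vapply(m1@blocks, function(b) b$kind, "") == "ko"))

  m2 <- parseDefinition("M2", "K00001 (K00002,K00003) K00004+K00005")
  expect_equal(length(m2@blocks), 3)
  expect_equal(m2@blocks[[2]]$kind, "or")
  expect_equal(m2@blocks[[3]]$kind, "complex")
  expect_equal(length(m2@blocks[[3]]$required), 2)

  # adjacent parenthesised alternatives are separate blocks, not a product
  m3 <- parseDefinition("M3", "(K00001,K00002) (K00003,K00004)")
  expect_equal(length(m3@blocks), 2)
  expect_true(all(vapply(m3@blocks, function(b) b$kind, "") == "or"))

  # optional components parse and never gate satisfaction
  m4 <- parseDefinition("M4", "K00001-K00002 -K00003 K00004")
  expect_equal(length(m4@blocks), 3)
  expect_equal(blocksMissing(m4, c("K00001", "K00004"))$blocks_missing, 0)

  expect_error(parseDefinition("M5", "K00001 (K00002"), "parenthes")
  expect_error(parseDefinition("M6", "K00001,,K00002"), "empty")
  expect_error(parseDefinition("M7", "KABCDE"), "KO identifier")
})

test_that("parse/deparse round-trips every fixture module", {
  for (m in fixtureModules()) {
    m2 <- parseDefinition(m@moduleId, deparseDefinition(m))
    expect_equal(deparseDefinition(m2), deparseDefinition(m))
    expect_equal(blocksMissing(m2, koLeaves(m))$blocks_missing, 0)
  }
})

test_that("blocks-missing categories follow the 0/1/2/3+ thresholds", {
  m <- parseDefinition("M", "K00001 K00002 K00003 K00004")
  ks <- c("K00001", "K00002", "K00003", "K00004")
  for (drop in 0:4) {
    rec <- blocksMissing(m, ks[seq_len(4 - drop)])
    expect_equal(rec$blocks_missing, drop)
    expect_equal(as.character(rec$category),
                 c("complete", "1bm", "2bm", "incomplete", "incomplete")[drop + 1])
  }
})

test_that("evaluator agrees with the base-R expression oracle on all KO subsets", {
  for (m in fixtureModules()) {
    leaves <- koLeaves(m)
    if (length(leaves) > 10 || length(m@blocks) > 4) next
    for (mask in 0:(2^length(leaves) - 1)) {
      kos <- leaves[bitwAnd(mask, 2^(seq_along(leaves) - 1)) > 0]
      expect_equal(blocksMissing(m, kos)$blocks_missing,
                   oracleBlocksMissing(m@definition, kos),
                   label = paste(m@moduleId, mask))
    }
  }
})

test_that("blocks-missing is monotone non-increasing under KO supersets", {
  set.seed(31)
  mods <- fixtureModules()
  for (rep in 1:50) {
    m <- mods[[sample(length(mods), 1)]]
    leaves <- koLeaves(m)
    base <- leaves[runif(length(leaves)) < 0.5]
    extra <- union(base, leaves[runif(length(leaves)) < 0.5])
    expect_lte(blocksMissing(m, extra)$blocks_missing,
               blocksMissing(m, base)$blocks_missing)
  }
  # the full leaf set always completes the module
  for (m in mods)
    expect_equal(blocksMissing(m, koLeaves(m))$blocks_missing, 0)
})

test_that("KO hit filtering applies the e-value/bitscore/identity cutoffs", {
  hits <- data.frame(gene_id = paste0("g", 1:5), ko_id = "K00001",
                     evalue = c(1e-6, 1e-4, 1e-6, 1e-6, 0),
                     bitscore = c(60, 60, 40, 60, 50),
                     identity = c(30, 30, 30, 20, 25))
  kept <- filterKoHits(hits)
  expect_equal(kept$gene_id, c("g1", "g5"))
  expect_equal(nrow(filterKoHits(hits[0, ])), 0)
  bad <- hits; bad$bitscore <- as.character(bad$bitscore); bad$bitscore[3] <- "oops"
  expect_error(filterKoHits(bad), "row 3")
  expect_error(filterKoHits(hits[, 1:2]), "missing columns")
})

test_that("module prevalence classes partition at the 10/90 thresholds", {
  mods <- fixtureModules()[c("MSYN001", "MSYN003", "MSYN005")]
  mags <- sprintf("m%02d", 1:40)
  planted <- rbind(
    data.frame(mag_id = mags, module_id = "MSYN001", category = "complete"),
    data.frame(mag_id = mags, module_id = "MSYN003",
               category = rep(c("complete", "absent"), each = 20)),
    data.frame(mag_id = mags, module_id = "MSYN005", category = "absent"))
  ann <- generateAnnotations(mags, mods, planted, seed = 17)
  rec <- completenessTable(mods, ann$ko, magIds = mags)
  cls <- classifyModulePrevalence(rec, nMags = 40)
  expect_equal(cls$class[cls$module_id == "MSYN001"], factor("core",
               levels = c("core", "soft-core", "shell")))
  expect_equal(as.character(cls$class[cls$module_id == "MSYN003"]),
               "soft-core")
  expect_equal(cls$fraction[cls$module_id == "MSYN003"], 50)
  expect_equal(as.character(cls$class[cls$module_id == "MSYN005"]), "shell")
  expect_false(any(is.na(cls$class)))
  expect_error(classifyModulePrevalence(rec, nMags = 0), "no HQ-MHQ")
})

test_that("MAG functional breadth uses the 80/180 encoded-module thresholds", {
  rec <- data.frame(
    mag_id = rep(c("multi", "oligo", "mid"), times = c(181, 79, 120)),
    module_id = c(sprintf("A%03d", 1:181), sprintf("B%03d", 1:79),
                  sprintf("C%03d", 1:120)),
    category = "complete")
  br <- classifyMagBreadth(rec)
  expect_equal(as.character(br$breadth[br$mag_id == "multi"]),
               "multifunctional")
  expect_equal(as.character(br$breadth[br$mag_id == "oligo"]),
               "oligofunctional")
  expect_equal(as.character(br$breadth[br$mag_id == "mid"]), "intermediate")
})

test_that("module abundance sums qualifying MAG abundances only", {
  vals <- matrix(c(10, 5, 20, 2,
                   30, 1, 4, 0.5), ncol = 2,
                 dimnames = list(c("a", "b", "c", "d"), c("S1", "S2")))
  vals <- rbind(vals, filler = 100 - colSums(vals))
  ab <- new("MagAbundance", values = vals, threshold = 0.001)
  rec <- data.frame(
    mag_id = c("a", "b", "c", "d"), module_id = "M0",
    category = c("complete", "1bm", "2bm", "incomplete"))
  q <- qualityTable(c("a", "b", "c", "d", "filler"),
                    cp = c(95, 95, 95, 95, 95), ct = c(1, 1, 1, 1, 1))
  mab <- moduleAbundance(ab, rec, quality = q)
  expect_equal(mab["M0", ], c(S1 = 15, S2 = 31))   # complete + 1bm only
  expect_true(all(mab <= 100))
  # tier filtering removes contributions
  q2 <- q; q2$tier[q2$mag_id == "a"] <- factor("LQ", levels = levels(q$tier))
  expect_equal(moduleAbundance(ab, rec, quality = q2)["M0", "S1"],
               unname(vals["b", "S1"]))
  rec_bad <- rbind(rec, data.frame(mag_id = "ghost", module_id = "M0",
                                   category = "complete"))
  expect_error(moduleAbundance(ab, rec_bad, quality = q), "ghost")
})

test_that("methanogenesis ratio handles zero denominators", {
  mab <- matrix(c(10, 0, 5,
                  10, 5, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("ACE", "HYD"), NULL))
  colnames(mab) <- c("S1", "S2", "S3")
  r <- methanogenesisRatio(mab, "ACE", "HYD")
  expect_equal(unname(r["S1"]), 1)
  expect_equal(unname(r["S2"]), 0)
  expect_true(is.na(r["S3"]))
  expect_error(methanogenesisRatio(mab, "ACE", "NOPE"), "NOPE")
})

test_that("metadata correlation: exact fits, planted recovery, and size", {
  x <- 1:20
  fit <- correlateWithMetadata(2 * x, x)
  expect_equal(fit$r2, 1)
  # planted linear relation with noise at n = 50 recovers planted R^2 on
  # average (a single draw of R^2 has sd ~ 0.08 at this size)
  set.seed(99)
  n <- 50; b <- 1; sigma <- 0.8
  planted_r2 <- b^2 / (b^2 + sigma^2)
  r2s <- replicate(25, {
    xs <- rnorm(n); ys <- b * xs + rnorm(n, 0, sigma)
    correlateWithMetadata(ys, xs)$r2
  })
  expect_lt(abs(mean(r2s) - planted_r2), 0.05)
  # type-I error of the slope test is nominal
  set.seed(100)
  rej <- mean(replicate(1000, {
    correlateWithMetadata(rnorm(200), rnorm(200))$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.02)
  expect_error(correlateWithMetadata(c(1, 2), c(1, 2)), "3")
  # missing metadata dropped and counted
  f2 <- correlateWithMetadata(c(1, 2, 3, 4, NA), c(2, 4, 6, NA, 10))
  expect_equal(f2$n_used, 3)
  expect_equal(f2$n_dropped, 2)
})
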