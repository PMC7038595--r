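test_that("genome generator is seed-deterministic down to FASTA bytes", {
  g1 <- generateGenomes(2, 2, genomeLength = 20000, seed = 42)
  g2 <- generateGenomes(2, 2, genomeLength = 20000, seed = 42)
  f1 <- tempfile(); f2 <- tempfile()
  writeGenomeDir(g1, f1); writeGenomeDir(g2, f2)
  for (fn in list.files(f1)) {
    expect_identical(readBin(file.path(f1, fn), "raw", 1e6),
                     readBin(file.path(f2, fn), "raw", 1e6))
  }
  g3 <- generateGenomes(2, 2, genomeLength = 20000, seed = 43)
  expect_false(identical(as.character(genomeSeqs(g1)[[1]]),
                         as.character(genomeSeqs(g3)[[1]])))
})

test_that("zero mutation rate reproduces the ancestor exactly", {
  g <- generateGenomes(1, 2, genomeLength = 20000, mutationRates = 0,
                       seed = 5)
  seqs <- lapply(genomeSeqs(g), function(x)
    paste(as.character(x), collapse = ""))
  expect_identical(seqs[[1]], seqs[[2]])
})

test_that("planted substitution rate is recovered by positionwise comparison", {
  rate <- 0.05; L <- 100000
  g <- generateGenomes(1, 2, genomeLength = L, mutationRates = c(0, rate),
                       seed = 7)
  seqs <- vapply(genomeSeqs(g), function(x)
    paste(as.character(x), collapse = ""), "")
  a <- strsplit(seqs[[1]], "")[[1]]
  b <- strsplit(seqs[[2]], "")[[1]]
  observed <- mean(a != b)
  expect_lt(abs(observed - rate), 3 * sqrt(rate * (1 - rate) / L))
})

test_that("genome generator validates its arguments", {
  expect_error(generateGenomes(0, 2, seed = 1), "positive")
  expect_error(generateGenomes(1, 1, genomeLength = 1000, seed = 1), "20 kbp")
  expect_error(generateGenomes(1, 1, mutationRates = 0.5, seed = 1),
               "0, 0.35")
  expect_error(generateGenomes(1, 1), "seed")
})

test_that("contig breakpoints recorded in truth match the emitted contigs", {
  g <- generateGenomes(2, 3, genomeLength = 25000, seed = 9)
  br <- communityTruth(g)@contigBreaks
  for (id in magIds(g)) {
    expect_equal(unname(Biostrings::width(genomeSeqs(g)[[id]])),
                 unname(br[[id]]))
    expect_equal(sum(br[[id]]), 25000)
  }
})

test_that("abundance generator plants core/rare structure summing to 100", {
  mags <- sprintf("m%02d", 1:30)
  gen <- generateAbundances(mags, 6, coreFraction = 0.5, seed = 1)
  vals <- abundanceValues(gen$abundance)
  expect_equal(unname(colSums(vals)), rep(100, 6), tolerance = 1e-9)
  # core MAGs present everywhere
  expect_true(all(vals[gen$core, ] > 0.001))
  # presence matrix equals recorded truth exactly
  expect_identical(presenceCalls(gen$abundance), gen$truth@presenceTruth)
  # some non-core MAG absent somewhere (planted rare structure)
  noncore <- setdiff(mags, gen$core)
  expect_true(any(vals[noncore, ] == 0))
})

test_that("full core fraction makes every MAG present in every sample", {
  gen <- generateAbundances(sprintf("m%d", 1:10), 4, coreFraction = 1,
                            seed = 2)
  expect_true(all(presenceCalls(gen$abundance)))
})

test_that("abundance truth round-trips through the TSV writer bit-identically", {
  gen <- generateAbundances(sprintf("m%02d", 1:12), 5, seed = 3)
  vals <- abundanceValues(gen$abundance)
  path <- tempfile(fileext = ".tsv")
  writeTsv(vals, path, rowLabel = "mag_id")
  back <- readTsv(path)
  m <- as.matrix(back[, -1]); rownames(m) <- back$mag_id
  expect_identical(m, vals)    # write.table prints full double precision
})

test_that("abundance generator rejects empty designs", {
  expect_error(generateAbundances(character(), 3, seed = 1), "non-empty")
  expect_error(generateAbundances("m1", 0, seed = 1), "positive")
  expect_error(generateAbundances("m1", 3, coreFraction = 2, seed = 1),
               "0, 1")
})

test_that("window coverage generator plants exact gradients", {
  flat <- generateWindowCoverage("m", 2e6, meanDepth = 25, oriTerRatio = 1,
                                 noiseSd = 0, seed = 4)
  expect_equal(flat$depth, rep(25, nrow(flat)), tolerance = 1e-12)
  grad <- generateWindowCoverage("m", 2e6, meanDepth = 25, oriTerRatio = 2,
                                 noiseSd = 0, seed = 4)
  expect_equal(max(grad$depth) / min(grad$depth), 2, tolerance = 1e-9)
  expect_equal(mean(grad$depth), 25, tolerance = 0.01)
  # windows are 0-based half-open on a fixed grid
  expect_equal(grad$window_start[1], 0)
  expect_equal(diff(grad$window_start[1:2]), 5000)
  expect_error(generateWindowCoverage("m", 2e6, meanDepth = 0, seed = 1),
               "positive")
  expect_error(generateWindowCoverage("m", 2e6, meanDepth = 1,
                                      oriTerRatio = 0.5, seed = 1), ">= 1")
})

test_that("annotation generator closes the loop with the evaluator", {
  mods <- fixtureModules()
  mags <- c("A", "B", "C")
  planted <- expand.grid(mag_id = mags,
                         module_id = c("MSYN001", "MSYN003", "MSYN005"),
                         stringsAsFactors = FALSE)
  planted$category <- c("complete", "1bm", "absent",
                        "1bm", "2bm", "complete",
                        "complete", "absent", "2bm")
  ann <- generateAnnotations(mags, mods, planted, seed = 11)
  for (i in seq_len(nrow(planted))) {
    kos <- ann$ko$ko_id[ann$ko$mag_id == planted$mag_id[i] &
                          grepl(planted$module_id[i], ann$ko$gene_id)]
    rec <- blocksMissing(mods[[planted$module_id[i]]], kos)
    want <- switch(planted$category[i], complete = 0, "1bm" = 1, "2bm" = 2,
                   absent = rec$blocks_total)
    if (planted$category[i] == "absent") {
      expect_equal(length(kos), 0)
    } else {
      expect_equal(rec$blocks_missing, want,
                   label = paste(planted$mag_id[i], planted$module_id[i]))
    }
  }
})

test_that("unachievable planted categories raise errors", {
  mods <- fixtureModules()
  planted <- data.frame(mag_id = "A", module_id = "MSYN008",
                        category = "2bm", stringsAsFactors = FALSE)
  expect_error(generateAnnotations("A", mods, planted, seed = 1),
               "cannot plant")
  bad <- data.frame(mag_id = "A", module_id = "MSYN001",
                    category = "mostly", stringsAsFactors = FALSE)
  expect_error(generateAnnotations("A", mods, bad, seed = 1), "unknown")
})

test_that("metadata generator plants a recoverable log-linear ammonia effect", {
  meta <- generateMetadata(60, seed = 13)
  expect_true(all(meta$tan_g_l >= 0))
  fit <- correlateWithMetadata(log(meta$aceto_hydro_ratio), meta$tan_g_l)
  expect_lt(fit$p, 1e-6)
  expect_lt(fit$slope, 0)
})
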