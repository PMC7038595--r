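#' Write a complete synthetic scenario to disk
#'
#' Generates a self-contained input bundle for \code{\link{runPipeline}}:
#' per-MAG FASTA genomes with planted species clusters, a quality table,
#' MAG x sample read counts with planted core/rare structure, KO and CAZyme
#' annotation tables with planted module-completeness categories and one or
#' more planted enrichments, per-window depth tables with planted
#' replication gradients, sample metadata, the synthetic module
#' definitions, and truth tables for every planted quantity. All files are
#' plain text (FASTA/TSV/YAML).
#'
#' @param dir output directory.
#' @param seed integer seed driving every generator.
#' @param nSpecies,genomesPerSpecies planted species-cluster structure.
#' @param nSingletons additional unrelated single-genome species.
#' @param genomeLength genome length (bp).
#' @param nSamples number of samples.
#' @param totalReads reads per sample for the count table.
#' @param irepRatios named numeric: planted ori:ter ratio per profiled MAG
#'   (defaults to ratios 1.5 and 2 on the first two MAGs).
#' @param depthWindow window size (bp) for the depth tables.
#' @return (invisibly) the path to the written \code{config.yaml}.
#' @export
makeSyntheticScenario <- function(dir, seed, nSpecies = 3,
                                  genomesPerSpecies = 4, nSingletons = 18,
                                  genomeLength = 30000L, nSamples = 6,
                                  totalReads = 2e6, irepRatios = NULL,
                                  depthWindow = 500L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  # genomes: clustered species plus unrelated singletons
  clustered <- generateGenomes(nSpecies, genomesPerSpecies,
                               genomeLength = genomeLength, seed = seed)
  singles <- generateGenomes(nSingletons, 1L, genomeLength = genomeLength,
                             mutationRates = 0, seed = seed + 1L)
  sing_ids <- setNames(sprintf("SG%02d", seq_len(nSingletons)),
                       magIds(singles))
  genomes <- c(genomeSeqs(clustered),
               setNames(genomeSeqs(singles), sing_ids[magIds(singles)]))
  species <- c(communityTruth(clustered)@speciesAssignments,
               setNames(paste0("sp_", sing_ids), sing_ids))
  mags <- names(genomes)
  writeGenomeDir(new("MagSet", genomes = genomes), file.path(dir, "genomes"))
  writeTsv(data.frame(mag_id = names(species), species_id = unname(species)),
           file.path(dir, "truth_species.tsv"))

  # quality: all HQ so every MAG enters the functional stages
  set.seed(seed + 2L)
  qual <- qualityTable(
    mag_id = mags,
    cp = round(runif(length(mags), 92, 99), 1),
    ct = round(runif(length(mags), 0.2, 2.5), 1),
    n_scaffolds = vapply(genomes, length, integer(1)),
    genome_size = vapply(genomes, function(g) sum(Biostrings::width(g)),
                         numeric(1)))
  writeTsv(qual[, c("mag_id", "cp", "ct")], file.path(dir, "quality.tsv"))

  # abundance counts with planted core/rare structure
  gen_ab <- generateAbundances(mags, nSamples, coreFraction = 0.6,
                               seed = seed + 3L)
  abv <- abundanceValues(gen_ab$abundance)
  counts <- round(abv / 100 * totalReads)
  writeTsv(counts, file.path(dir, "counts.tsv"), rowLabel = "mag_id")
  writeTsv(abv, file.path(dir, "truth_abundance.tsv"), rowLabel = "mag_id")

  # module plants: per planted class, a module is completed in a chosen
  # fraction of MAGs (core > 90%, soft-core ~50%, shell < 10%)
  modules <- readModuleDefinitions()
  plant_frac <- c(MSYN001 = 1.0, MSYN002 = 0.97, MSYN003 = 0.5,
                  MSYN004 = 0.3, MSYN005 = 0.05, MSYN006 = 0.03,
                  MSYN007 = 0.5)
  plant_frac <- plant_frac[names(plant_frac) %in% names(modules)]
  set.seed(seed + 4L)
  plant_rows <- list()
  for (m in names(plant_frac)) {
    ncomp <- round(plant_frac[[m]] * length(mags))
    who <- if (ncomp > 0) sample(mags, ncomp) else character()
    plant_rows[[m]] <- data.frame(
      mag_id = mags, module_id = m,
      category = ifelse(mags %in% who, "complete", "absent"),
      stringsAsFactors = FALSE)
  }
  planted <- do.call(rbind, plant_rows)
  rownames(planted) <- NULL
  writeTsv(planted, file.path(dir, "truth_modules.tsv"))

  # one planted CAZy enrichment
  cazy_plan <- data.frame(mag_id = mags[1], cazy_class = "GH",
                          stringsAsFactors = FALSE)
  ann <- generateAnnotations(mags, modules, planted, cazyPlan = cazy_plan,
                             seed = seed + 5L)
  writeTsv(ann$ko, file.path(dir, "ko.tsv"))
  writeTsv(ann$cazy, file.path(dir, "cazy.tsv"))
  writeTsv(cazy_plan, file.path(dir, "truth_enrichment.tsv"))

  # depth tables with planted replication gradients
  if (is.null(irepRatios))
    irepRatios <- setNames(c(1.5, 2.0), mags[1:2])
  depth_rows <- list()
  for (i in seq_along(irepRatios)) {
    mag <- names(irepRatios)[i]
    dd <- generateWindowCoverage(mag, genomeLength = genomeLength,
                                 meanDepth = 30, oriTerRatio = irepRatios[[i]],
                                 noiseSd = 0.05, window = depthWindow,
                                 seed = seed + 10L + i)
    dd$sample_id <- "S01"
    depth_rows[[i]] <- dd
  }
  depth <- do.call(rbind, depth_rows)
  writeTsv(depth, file.path(dir, "depth.tsv"))
  writeTsv(data.frame(mag_id = names(irepRatios),
                      ori_ter_ratio = unname(irepRatios)),
           file.path(dir, "truth_irep.tsv"))

  meta <- generateMetadata(nSamples, seed = seed + 20L)
  writeTsv(meta, file.path(dir, "metadata.tsv"))

  file.copy(system.file("extdata", "synthetic_modules.tsv",
                        package = "magcentric"),
            file.path(dir, "modules.tsv"), overwrite = TRUE)

  config <- list(
    seed = seed,
    paths = list(genomes = "genomes", quality = "quality.tsv",
                 counts = "counts.tsv", ko = "ko.tsv", cazy = "cazy.tsv",
                 depth = "depth.tsv", metadata = "metadata.tsv",
                 modules = "modules.tsv"),
    thresholds = list(presence = 0.001, mash = 0.05, ani = 95, coverage = 50,
                      enrichment_alpha = 1e-5, irep_min_r2 = 0.90),
    stages = c("quality", "derep", "abundance", "modules", "enrich",
               "irep", "ecology"),
    methanogenesis = list(acetoclastic = "MSYN003",
                          hydrogenotrophic = "MSYN007"))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}

pipelineStage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full genome-centric analysis pipeline
#'
#' Orders the analysis stages -- quality tiering, species dereplication,
#' abundance profiling, module completeness, CAZyme enrichment, iRep
#' estimation and community ecology -- over the input bundle described by a
#' YAML config (as written by \code{\link{makeSyntheticScenario}}), writing
#' every stage output as a headered TSV plus a machine-readable
#' \code{manifest.json} (inputs, parameters, seed, package version). Reruns
#' with the same config produce byte-identical result tables.
#'
#' @param config path to a YAML config, or the equivalent list.
#' @param inputDir directory the config's relative paths resolve against
#'   (defaults to the config file's directory).
#' @param outDir output directory (default: \code{<inputDir>/results}).
#' @return (invisibly) a named list of stage results.
#' @export
runPipeline <- function(config, inputDir = NULL, outDir = NULL) {
  if (is.character(config)) {
    if (is.null(inputDir)) inputDir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(inputDir)) stop("inputDir required when config is a list")
  if (is.null(outDir)) outDir <- file.path(inputDir, "results")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(key) {
    p <- config$paths[[key]]
    if (is.null(p)) return(NULL)
    file.path(inputDir, p)
  }
  stages <- config$stages
  thr <- config$thresholds
  results <- list()
  log <- character()
  note <- function(fmt, ...) {
    log <<- c(log, sprintf(fmt, ...))
    message(sprintf(fmt, ...))
  }

  qual <- pipelineStage("quality", {
    qt <- readTsv(pth("quality"))
    q <- qualityTable(qt$mag_id, qt$cp, qt$ct)
    note("quality: %d MAGs in, %d HQ+MHQ",
         nrow(q), sum(q$tier %in% c("HQ", "MHQ")))
    writeTsv(q, file.path(outDir, "quality_scored.tsv"))
    q
  })
  results$quality <- qual

  if ("derep" %in% stages) {
    results$derep <- pipelineStage("derep", {
      mags <- readGenomeDir(pth("genomes"))
      cl <- clusterSpecies(mags, quality = qual,
                           mashCutoff = thr$mash %||% 0.05,
                           aniCutoff = thr$ani %||% 95,
                           covCutoff = thr$coverage %||% 50)
      note("derep: %d MAGs -> %d species clusters",
           length(magIds(mags)), cl$n_clusters)
      writeTsv(cl$clusters, file.path(outDir, "clusters.tsv"))
      if (nrow(cl$pairs))
        writeTsv(cl$pairs, file.path(outDir, "ani_pairs.tsv"))
      cl
    })
  }

  ab <- NULL
  if ("abundance" %in% stages) {
    results$abundance <- pipelineStage("abundance", {
      counts <- readTsv(pth("counts"))
      m <- as.matrix(counts[, -1, drop = FALSE])
      rownames(m) <- counts[[1]]
      ab <- relativeAbundance(m, threshold = thr$presence %||% 0.001)
      note("abundance: %d MAGs x %d samples; %d presence calls",
           nrow(m), ncol(m), sum(presenceCalls(ab)))
      writeTsv(abundanceValues(ab), file.path(outDir, "abundance.tsv"),
               rowLabel = "mag_id")
      prev <- classifyPrevalence(ab)
      writeTsv(prev, file.path(outDir, "prevalence.tsv"))
      dend <- clusterProfiles(ab, axis = "samples")
      writeLines(dend$newick, file.path(outDir, "sample_dendrogram.nwk"))
      list(abundance = ab, prevalence = prev)
    })
  }

  comp <- NULL
  if ("modules" %in% stages) {
    results$modules <- pipelineStage("modules", {
      modules <- readModuleDefinitions(pth("modules"))
      ko <- readTsv(pth("ko"))
      hq <- filterForAnalysis(qual, c("HQ", "MHQ"))
      comp <- completenessTable(modules, ko, magIds = hq$mag_id)
      writeTsv(comp, file.path(outDir, "completeness.tsv"))
      prevcl <- classifyModulePrevalence(comp, nMags = nrow(hq))
      writeTsv(prevcl, file.path(outDir, "module_classes.tsv"))
      breadth <- classifyMagBreadth(comp)
      writeTsv(breadth, file.path(outDir, "mag_breadth.tsv"))
      note("modules: %d modules over %d HQ+MHQ MAGs (%d core, %d soft-core, %d shell)",
           length(modules), nrow(hq), sum(prevcl$class == "core"),
           sum(prevcl$class == "soft-core"), sum(prevcl$class == "shell"))
      out <- list(completeness = comp, classes = prevcl, breadth = breadth)
      if (!is.null(ab)) {
        mab <- moduleAbundance(ab, comp, quality = qual)
        writeTsv(mab, file.path(outDir, "module_abundance.tsv"),
                 rowLabel = "module_id")
        out$module_abundance <- mab
        mg <- config$methanogenesis
        if (!is.null(mg)) {
          ratio <- methanogenesisRatio(mab, mg$acetoclastic,
                                       mg$hydrogenotrophic)
          writeTsv(data.frame(sample_id = names(ratio),
                              aceto_hydro_ratio = unname(ratio)),
                   file.path(outDir, "methanogenesis_ratio.tsv"))
          out$methanogenesis_ratio <- ratio
        }
      }
      out
    })
  }

  if ("enrich" %in% stages) {
    results$enrich <- pipelineStage("enrich", {
      cazy <- readTsv(pth("cazy"))
      cazy$cazy_class[cazy$cazy_class == ""] <- NA
      enr <- enrichCazy(cazy, quality = qual,
                        alphaP = thr$enrichment_alpha %||% 1e-5)
      note("enrich: %d tests, %d significant at p < %g",
           nrow(enr), sum(enr$significant), thr$enrichment_alpha %||% 1e-5)
      writeTsv(enr, file.path(outDir, "enrichment.tsv"))
      enr
    })
  }

  if ("irep" %in% stages) {
    results$irep <- pipelineStage("irep", {
      dp <- pth("depth")
      if (is.null(dp) || !file.exists(dp))
        stop("depth table required for the irep stage: ",
             if (is.null(dp)) "no path configured" else dp)
      depth <- readTsv(dp)
      if (!"sample_id" %in% names(depth)) depth$sample_id <- "S01"
      combos <- unique(depth[, c("mag_id", "sample_id")])
      rows <- lapply(seq_len(nrow(combos)), function(i) {
        sel <- depth$mag_id == combos$mag_id[i] &
          depth$sample_id == combos$sample_id[i]
        qrec <- qual[qual$mag_id == combos$mag_id[i], ]
        adm <- admitIrep(qrec, meanCoverage = mean(depth$depth[sel]))
        est <- estimateIrep(depth$depth[sel],
                            minR2 = thr$irep_min_r2 %||% 0.90)
        cbind(combos[i, , drop = FALSE], est, admitted = adm$pass)
      })
      est <- do.call(rbind, rows)
      rownames(est) <- NULL
      note("irep: %d MAG x sample profiles, %d admitted and fit_ok",
           nrow(est), sum(est$admitted & est$fit_ok))
      writeTsv(est, file.path(outDir, "irep.tsv"))
      est
    })
  }

  if ("ecology" %in% stages) {
    results$ecology <- pipelineStage("ecology", {
      counts <- readTsv(pth("counts"))
      m <- as.matrix(counts[, -1, drop = FALSE])
      rownames(m) <- counts[[1]]
      div <- do.call(rbind, lapply(colnames(m), function(s)
        alphaDiversity(m[, s], sampleId = s)))
      writeTsv(div, file.path(outDir, "diversity.tsv"))
      rel <- sweep(m, 2, colSums(m), "/") * 100
      d <- distanceMatrix(rel, method = "bray")
      writeTsv(d, file.path(outDir, "bray_curtis.tsv"), rowLabel = "sample_id")
      tr <- upgmaTree(d)
      writeLines(tr$newick, file.path(outDir, "upgma.nwk"))
      ord <- pcoaOrdination(d)
      writeTsv(ord$coordinates, file.path(outDir, "pcoa.tsv"),
               rowLabel = "sample_id")
      note("ecology: %d samples, %d positive PCoA axes",
           ncol(m), length(ord$eigenvalues))
      list(diversity = div, distances = d, tree = tr, ordination = ord)
    })
  }

  manifest <- list(
    package = "magcentric",
    version = as.character(utils::packageVersion("magcentric")),
    seed = config$seed,
    inputs = lapply(config$paths, identity),
    thresholds = thr,
    stages = stages,
    log = log,
    outputs = sort(list.files(outDir)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
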