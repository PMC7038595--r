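#' Generate a synthetic community of genome bins with planted species
#'
#' Simulates species clusters of MAGs for validating ANI-based
#' dereplication. Each species has an i.i.d.-uniform ACGT ancestor genome;
#' genome \code{j} within a species is the ancestor with independent
#' substitutions at \code{mutationRates[j]} (recycled), so its expected ANI
#' to the ancestor is \code{100 * (1 - rate)}. Genomes from different
#' species are independent random sequences. Each genome is emitted as 1-10
#' contigs to exercise per-scaffold handling; breakpoints are recorded in
#' the truth container. Substitution-only (no indels) keeps planted ANI
#' analytically predictable.
#'
#' @param nSpecies number of species clusters.
#' @param genomesPerSpecies genomes per cluster (a scalar, recycled).
#' @param genomeLength genome length in bp (>= 20000).
#' @param mutationRates substitution fractions in [0, 0.35], recycled across
#'   the genomes of each species. The default \code{c(0, 0.01, 0.02, 0.03)}
#'   keeps every within-species pair above the 95\% ANI species boundary.
#' @param seed integer seed; identical seeds give byte-identical genomes.
#' @param maxContigs upper bound on contigs per genome (1-10 by default).
#' @return a \code{\linkS4class{MagSet}} whose truth records species
#'   assignments, expected pairwise ANI and contig breakpoints.
#' @export
generateGenomes <- function(nSpecies, genomesPerSpecies,
                            genomeLength = 100000L,
                            mutationRates = c(0, 0.01, 0.02, 0.03),
                            seed, maxContigs = 10L) {
  if (nSpecies < 1 || genomesPerSpecies < 1)
    stop("nSpecies and genomesPerSpecies must be positive")
  if (genomeLength < 20000) stop("genomeLength must be at least 20 kbp")
  if (any(mutationRates < 0 | mutationRates > 0.35))
    stop("mutationRates must lie in [0, 0.35]")
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  rates <- rep_len(mutationRates, genomesPerSpecies)
  genomes <- list()
  species <- character()
  breaks <- list()
  genome_rate <- list()
  for (sp in seq_len(nSpecies)) {
    spid <- sprintf("SP%02d", sp)
    anc <- sample.int(4L, genomeLength, replace = TRUE)
    for (g in seq_len(genomesPerSpecies)) {
      mid <- sprintf("%s_G%02d", spid, g)
      rate <- rates[g]
      gen <- anc
      if (rate > 0) {
        hit <- which(runif(genomeLength) < rate)
        if (length(hit)) {
          # shift to one of the three other bases, uniformly
          gen[hit] <- ((gen[hit] - 1L + sample.int(3L, length(hit),
                                                   replace = TRUE)) %% 4L) + 1L
        }
      }
      seqchr <- paste(bases[gen], collapse = "")
      nctg <- sample.int(maxContigs, 1L)
      if (nctg > 1L) {
        cuts <- sort(sample.int(genomeLength - 1L, nctg - 1L))
        starts <- c(1L, cuts + 1L)
        ends <- c(cuts, genomeLength)
      } else {
        starts <- 1L; ends <- genomeLength
      }
      ctgs <- substring(seqchr, starts, ends)
      names(ctgs) <- sprintf("%s_c%02d", mid, seq_along(ctgs))
      genomes[[mid]] <- Biostrings::DNAStringSet(ctgs)
      species[mid] <- spid
      breaks[[mid]] <- ends - starts + 1L
      genome_rate[[mid]] <- rate
    }
  }
  # expected ANI for within-species pairs: P(differ) = r1 + r2 - (4/3) r1 r2
  pairs <- list()
  for (sp in unique(species)) {
    ids <- names(species)[species == sp]
    if (length(ids) >= 2) {
      cb <- combn(ids, 2)
      for (i in seq_len(ncol(cb))) {
        r1 <- genome_rate[[cb[1, i]]]; r2 <- genome_rate[[cb[2, i]]]
        pairs[[length(pairs) + 1L]] <- data.frame(
          mag_a = cb[1, i], mag_b = cb[2, i],
          expected_ani = 100 * (1 - (r1 + r2 - 4 * r1 * r2 / 3)),
          stringsAsFactors = FALSE)
      }
    }
  }
  ani_tab <- if (length(pairs)) do.call(rbind, pairs) else data.frame()
  truth <- new("CommunityTruth", speciesAssignments = species,
               aniTarget = ani_tab, contigBreaks = breaks)
  new("MagSet", genomes = genomes, truth = truth)
}

#' Generate per-sample MAG abundance profiles with planted structure
#'
#' Draws MAG base abundances from a log-normal distribution (the default for
#' microbial community rank-abundance structure; configurable via
#' \code{sdlog}), perturbs them per sample, and plants core/rare structure:
#' a designated core fraction of MAGs is guaranteed present (> threshold) in
#' every sample, while the remaining MAGs are zeroed out in a random,
#' recorded subset of samples. Columns are normalised to 100.
#'
#' @param magIds character vector of MAG ids.
#' @param nSamples number of samples (>= 1).
#' @param coreFraction fraction of MAGs planted as core, in [0, 1].
#' @param seed integer seed.
#' @param threshold presence threshold in percent (default 0.001).
#' @param sdlog log-normal spread of base abundances.
#' @param dropProb per-sample probability that a non-core MAG is absent.
#' @return list with elements \code{abundance}
#'   (\code{\linkS4class{MagAbundance}}), \code{truth} (a
#'   \code{CommunityTruth} holding the abundance and presence truth) and
#'   \code{core} (character vector of core MAG ids).
#' @export
generateAbundances <- function(magIds, nSamples, coreFraction = 0.5, seed,
                               threshold = 0.001, sdlog = 1.5,
                               dropProb = 0.4) {
  n <- length(magIds)
  if (n < 1) stop("magIds must be non-empty")
  if (nSamples < 1) stop("nSamples must be positive")
  if (coreFraction < 0 || coreFraction > 1)
    stop("coreFraction must lie in [0, 1]")
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  samples <- sprintf("S%02d", seq_len(nSamples))
  ncore <- ceiling(coreFraction * n)
  core <- if (ncore > 0) sample(magIds, ncore) else character()
  base <- rlnorm(n, meanlog = 0, sdlog = sdlog)
  m <- matrix(0, n, nSamples, dimnames = list(magIds, samples))
  for (s in seq_len(nSamples)) {
    x <- base * rlnorm(n, meanlog = 0, sdlog = 0.5)
    absent <- !(magIds %in% core) & (runif(n) < dropProb)
    x[absent] <- 0
    # guarantee core MAGs clear the presence threshold after normalisation
    floor_mass <- 10 * (threshold / 100) * sum(x)
    x[magIds %in% core & x < floor_mass] <- floor_mass
    m[, s] <- 100 * x / sum(x)
  }
  ab <- new("MagAbundance", values = m, threshold = threshold)
  truth <- new("CommunityTruth",
               abundanceTruth = m, presenceTruth = m > threshold)
  list(abundance = ab, truth = truth, core = sort(core))
}

#' Generate window coverage with a planted replication gradient
#'
#' Emits a per-window sequencing-depth table in which expected log2 depth
#' declines linearly with (circular) distance from a planted replication
#' origin, so that depth at the origin over depth at the terminus equals
#' \code{oriTerRatio} -- the signature bidirectional replication leaves in
#' coverage. Gaussian noise with the stated sd is added in log2 space.
#' Windows are 0-based half-open; the origin is placed at a random window so
#' estimates must be rotation-invariant.
#'
#' @param magId MAG identifier for the output table.
#' @param genomeLength genome length in bp.
#' @param meanDepth mean sequencing depth (x-fold, > 0).
#' @param oriTerRatio planted origin:terminus coverage ratio (>= 1).
#' @param noiseSd log2-space noise sd (>= 0).
#' @param window,slide window size and step in bp (window >= slide > 0;
#'   equal by default, i.e. non-overlapping).
#' @param seed integer seed.
#' @return data.frame with columns mag_id, contig_id, window_start, depth,
#'   plus attributes \code{ori_window} and \code{truth_ratio}.
#' @export
generateWindowCoverage <- function(magId, genomeLength, meanDepth,
                                   oriTerRatio = 1, noiseSd = 0,
                                   window = 5000L, slide = window, seed) {
  if (meanDepth <= 0) stop("meanDepth must be positive")
  if (oriTerRatio < 1) stop("oriTerRatio must be >= 1")
  if (slide <= 0 || window < slide)
    stop("window/slide must satisfy window >= slide > 0")
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  starts <- seq.int(0L, genomeLength - window, by = slide)
  nw <- length(starts)
  if (nw < 2) stop("genome too short for the requested window size")
  ori <- sample.int(nw, 1L) - 1L
  idx <- seq_len(nw) - 1L
  circ <- pmin(abs(idx - ori), nw - abs(idx - ori))
  d <- circ / (nw / 2)                      # distance fraction in [0, 1]
  l2r <- log2(oriTerRatio)
  # mean of 2^(-d * l2r) over d ~ U(0,1) is (1 - r^-1) / (l2r ln 2)
  meanfac <- if (oriTerRatio > 1) (1 - 1 / oriTerRatio) / (l2r * log(2)) else 1
  l2 <- log2(meanDepth / meanfac) - d * l2r
  if (noiseSd > 0) l2 <- l2 + rnorm(nw, 0, noiseSd)
  out <- data.frame(mag_id = magId, contig_id = paste0(magId, "_c01"),
                    window_start = starts, depth = 2^l2,
                    stringsAsFactors = FALSE)
  attr(out, "ori_window") <- ori
  attr(out, "truth_ratio") <- oriTerRatio
  out
}

#' Generate KO and CAZyme annotation tables with planted truth
#'
#' For each (MAG, module) pair the emitted KO set is constructed to yield
#' exactly the planted blocks-missing count under the completeness
#' evaluator: a \code{complete} plant emits every KO leaf of the module,
#' \code{1bm}/\code{2bm} plants withhold the leaves of one/two randomly
#' chosen blocks (withheld leaves are removed from the emitted set), and
#' \code{absent} emits nothing. The construction is verified against
#' \code{\link{blocksMissing}} and an error is raised when a category is
#' unachievable (e.g. planting \code{2bm} on a 1-block module, or block KO
#' sets so entangled that withholding cannot unsatisfy the block).
#'
#' CAZyme counts are drawn per MAG from background class frequencies;
#' planted (MAG, class) enrichments multiply the class rate by
#' \code{enrichFactor}.
#'
#' @param magIds character MAG ids.
#' @param modules list of \code{\linkS4class{KeggModule}}.
#' @param plantedCategories data.frame (mag_id, module_id, category) with
#'   category in complete/1bm/2bm/absent.
#' @param cazyPlan data.frame (mag_id, cazy_class) of planted enrichments;
#'   may have zero rows.
#' @param seed integer seed.
#' @param genesPerMag genes drawn per MAG for the CAZy table.
#' @param backgroundRates named numeric; baseline per-gene probability of
#'   each CAZy class (remainder of the probability mass is unannotated).
#' @param enrichFactor rate multiplier for planted enrichments.
#' @return list with \code{ko} (mag_id, gene_id, ko_id) and \code{cazy}
#'   (mag_id, gene_id, cazy_class) data.frames.
#' @export
generateAnnotations <- function(magIds, modules, plantedCategories,
                                cazyPlan = data.frame(), seed,
                                genesPerMag = 500L,
                                backgroundRates = c(GH = 0.03, GT = 0.02,
                                                    PL = 0.004, CE = 0.008,
                                                    AA = 0.004, CBM = 0.012),
                                enrichFactor = 10) {
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  modmap <- setNames(modules, vapply(modules, function(m) m@moduleId, ""))
  ko_rows <- list()
  for (i in seq_len(nrow(plantedCategories))) {
    mag <- plantedCategories$mag_id[i]
    mod_id <- plantedCategories$module_id[i]
    cat_i <- plantedCategories$category[i]
    if (!cat_i %in% c("complete", "1bm", "2bm", "absent"))
      stop("unknown planted category: ", cat_i)
    if (cat_i == "absent") next
    mod <- modmap[[mod_id]]
    if (is.null(mod)) stop("planted module not in module set: ", mod_id)
    nb <- length(mod@blocks)
    miss <- switch(cat_i, complete = 0L, "1bm" = 1L, "2bm" = 2L)
    if (miss >= max(nb, 1L) && miss > 0 && nb <= miss)
      stop(sprintf("cannot plant '%s' on a %d-block module (%s)",
                   cat_i, nb, mod_id))
    leaves <- lapply(mod@blocks, koLeaves)
    # only blocks unsatisfiable-by-absence can be planted missing (a wholly
    # optional block is always satisfied)
    droppable <- which(!vapply(mod@blocks, evalNode, logical(1),
                               kos = character()))
    if (miss > length(droppable))
      stop(sprintf("cannot plant '%s' on module %s: only %d droppable block(s)",
                   cat_i, mod_id, length(droppable)))
    drop_blocks <- if (miss > 0)
      droppable[sample.int(length(droppable), miss)] else integer()
    kos <- unique(unlist(leaves[setdiff(seq_len(nb), drop_blocks)]))
    kos <- setdiff(kos, unlist(leaves[drop_blocks]))
    got <- blocksMissing(mod, kos)$blocks_missing
    if (got != miss)
      stop(sprintf(
        "category '%s' unachievable for module %s (shared KOs across blocks)",
        cat_i, mod_id))
    if (length(kos))
      ko_rows[[length(ko_rows) + 1L]] <- data.frame(
        mag_id = mag,
        gene_id = sprintf("%s_mod%s_g%03d", mag, mod_id, seq_along(kos)),
        ko_id = kos, stringsAsFactors = FALSE)
  }
  ko <- if (length(ko_rows)) do.call(rbind, ko_rows) else
    data.frame(mag_id = character(), gene_id = character(),
               ko_id = character(), stringsAsFactors = FALSE)
  rownames(ko) <- NULL

  classes <- names(backgroundRates)
  cazy_rows <- list()
  for (mag in magIds) {
    rates <- backgroundRates
    if (nrow(cazyPlan)) {
      planted <- cazyPlan$cazy_class[cazyPlan$mag_id == mag]
      rates[planted] <- pmin(rates[planted] * enrichFactor, 0.5)
    }
    p <- c(rates, none = max(0, 1 - sum(rates)))
    lab <- sample(names(p), genesPerMag, replace = TRUE, prob = p)
    cazy_rows[[mag]] <- data.frame(
      mag_id = mag, gene_id = sprintf("%s_g%04d", mag, seq_len(genesPerMag)),
      cazy_class = ifelse(lab == "none", NA_character_, lab),
      stringsAsFactors = FALSE)
  }
  cazy <- do.call(rbind, cazy_rows)
  rownames(cazy) <- NULL
  list(ko = ko, cazy = cazy)
}

#' Generate sample metadata with a planted ammonia effect
#'
#' Emits per-sample process metadata for an anaerobic-digestion community:
#' temperature regime (mesophilic 37 C / thermophilic 55 C), feedstock
#' label, and total ammonia nitrogen (TAN, g/L). A log-linear relation
#' between TAN and the acetoclastic:hydrogenotrophic methanogenesis ratio is
#' planted (high ammonia suppresses acetoclastic methanogens), giving the
#' correlation stage a recoverable signal:
#' \code{log(ratio) = intercept + slope * TAN + noise}.
#'
#' @param nSamples number of samples.
#' @param seed integer seed.
#' @param slope,intercept planted log-linear coefficients (slope < 0 mirrors
#'   ammonia inhibition of acetoclastic methanogenesis).
#' @param noiseSd sd of the log-scale noise.
#' @return data.frame with sample_id, temperature, feedstock, tan_g_l and
#'   the planted aceto_hydro_ratio.
#' @export
generateMetadata <- function(nSamples, seed, slope = -0.6, intercept = 0.5,
                             noiseSd = 0.4) {
  if (nSamples < 1) stop("nSamples must be positive")
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  tan <- round(runif(nSamples, 0.5, 7), 2)
  ratio <- exp(intercept + slope * tan + rnorm(nSamples, 0, noiseSd))
  data.frame(
    sample_id = sprintf("S%02d", seq_len(nSamples)),
    temperature = sample(c(37, 55), nSamples, replace = TRUE),
    feedstock = sample(c("manure", "sludge", "acetate", "whey"),
                       nSamples, replace = TRUE),
    tan_g_l = tan,
    aceto_hydro_ratio = ratio,
    stringsAsFactors = FALSE)
}
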