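#' @import methods
#' @importFrom stats cor lm median na.omit p.adjust pairwise.wilcox.test
#'   phyper rbinom rlnorm rmultinom rnorm runif sd setNames t.test uniroot
#'   wilcox.test hclust as.dist cophenetic cmdscale coef rnbinom
#' @importFrom utils read.delim write.table combn head
#' @importFrom Rcpp sourceCpp
#' @useDynLib magcentric, .registration = TRUE
NULL

TIER_LEVELS <- c("HQ", "MHQ", "MQ", "LQ", "CONTAMINATED")
MODULE_CATEGORIES <- c("complete", "1bm", "2bm", "incomplete")

#' Ground truth planted by the synthetic-community generators
#'
#' Container recording, for a generated community, the quantities every
#' downstream stage is expected to recover: the species membership of each
#' MAG, expected within-species ANI, the abundance and presence structure,
#' per-sample replication (ori:ter coverage) ratios, planted KEGG-module
#' completeness categories, planted CAZyme enrichments and sample metadata.
#'
#' @slot speciesAssignments named character; MAG id -> species id.
#' @slot aniTarget data.frame with columns \code{mag_a}, \code{mag_b},
#'   \code{expected_ani} for within-species pairs (percent).
#' @slot abundanceTruth numeric matrix, MAG x sample, percent; columns sum
#'   to 100.
#' @slot presenceTruth logical matrix matching \code{abundanceTruth} at the
#'   0.001\% presence threshold.
#' @slot replicationTruth numeric matrix, MAG x sample ori:ter ratios
#'   (dimensionless, >= 1).
#' @slot moduleTruth data.frame with columns \code{mag_id},
#'   \code{module_id}, \code{category}.
#' @slot enrichmentTruth data.frame with columns \code{mag_id},
#'   \code{cazy_class} of planted enrichments.
#' @slot metadataTruth data.frame of per-sample metadata (TAN g/L,
#'   temperature, feedstock, ...).
#' @slot contigBreaks named list; per MAG, the contig lengths used when the
#'   genome was split into scaffolds.
#' @export
setClass("CommunityTruth",
  representation(
    speciesAssignments = "character",
    aniTarget          = "data.frame",
    abundanceTruth     = "matrix",
    presenceTruth      = "matrix",
    replicationTruth   = "matrix",
    moduleTruth        = "data.frame",
    enrichmentTruth    = "data.frame",
    metadataTruth      = "data.frame",
    contigBreaks       = "list"
  ),
  prototype(
    speciesAssignments = character(),
    aniTarget = data.frame(),
    abundanceTruth = matrix(numeric(), 0, 0),
    presenceTruth = matrix(logical(), 0, 0),
    replicationTruth = matrix(numeric(), 0, 0),
    moduleTruth = data.frame(),
    enrichmentTruth = data.frame(),
    metadataTruth = data.frame(),
    contigBreaks = list()
  )
)

setValidity("CommunityTruth", function(object) {
  msg <- character()
  sa <- object@speciesAssignments
  if (length(sa) && (is.null(names(sa)) || anyDuplicated(names(sa))))
    msg <- c(msg, "speciesAssignments must be uniquely named by MAG id")
  ab <- object@abundanceTruth
  if (length(ab)) {
    cs <- colSums(ab)
    if (any(abs(cs - 100) > 1e-6))
      msg <- c(msg, "abundanceTruth columns must sum to 100 (tolerance 1e-6)")
  }
  rt <- object@replicationTruth
  if (length(rt) && any(rt < 1))
    msg <- c(msg, "replication ratios must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A set of genome bins (MAGs) with optional planted truth
#'
#' The central sequence container: one \code{\link[Biostrings]{DNAStringSet}}
#' of contigs per MAG, keyed by MAG id. Generated communities carry their
#' \code{\linkS4class{CommunityTruth}}.
#'
#' @slot genomes named list of \code{DNAStringSet}, one element per MAG.
#' @slot truth a \code{CommunityTruth} (may be empty for imported bins).
#' @export
setClass("MagSet",
  representation(genomes = "list", truth = "CommunityTruth"),
  prototype(genomes = list(), truth = new("CommunityTruth"))
)

setValidity("MagSet", function(object) {
  g <- object@genomes
  if (length(g)) {
    if (is.null(names(g)) || anyDuplicated(names(g)))
      return("genomes must be a uniquely named list of DNAStringSet")
    ok <- vapply(g, function(x) methods::is(x, "DNAStringSet"), logical(1))
    if (!all(ok)) return("every genome must be a DNAStringSet of contigs")
  }
  TRUE
})

#' MAG x sample relative-abundance matrix with presence calls
#'
#' Relative abundances on the 0--100 percent scale; every sample column sums
#' to 100. Presence is a strict threshold call (abundance > threshold, with
#' the field-standard default of 0.001\%).
#'
#' @slot values numeric matrix (MAG rows, sample columns), percent.
#' @slot threshold presence threshold in percent (default 0.001).
#' @export
setClass("MagAbundance",
  representation(values = "matrix", threshold = "numeric"),
  prototype(values = matrix(numeric(), 0, 0), threshold = 0.001)
)

setValidity("MagAbundance", function(object) {
  v <- object@values
  msg <- character()
  if (length(v)) {
    if (is.null(rownames(v)) || is.null(colnames(v)))
      msg <- c(msg, "values must carry MAG rownames and sample colnames")
    if (any(v < 0)) msg <- c(msg, "abundances must be non-negative")
    cs <- colSums(v)
    if (any(abs(cs - 100) > 1e-6))
      msg <- c(msg, "each sample column must sum to 100 (tolerance 1e-6)")
  }
  if (length(object@threshold) != 1L || object@threshold < 0)
    msg <- c(msg, "threshold must be a single non-negative percentage")
  if (length(msg)) msg else TRUE
})

#' A parsed KEGG module definition
#'
#' A module is an ordered list of reaction blocks; each block is a boolean
#' expression tree over KO identifiers (nodes: \code{ko} leaf, \code{and},
#' \code{or}, \code{complex} with required/optional subunits, and
#' \code{optional} wrappers that never affect satisfaction).
#'
#' @slot moduleId character module identifier.
#' @slot name human-readable module name.
#' @slot definition the original DEFINITION string.
#' @slot blocks list of expression-tree nodes, one per block.
#' @export
setClass("KeggModule",
  representation(moduleId = "character", name = "character",
                 definition = "character", blocks = "list")
)

setValidity("KeggModule", function(object) {
  if (length(object@blocks) < 1L) return("a module must have at least one block")
  TRUE
})

## ---- generics ----

#' @rdname MagSet-class
#' @param object,x a \code{MagSet}
#' @export
setGeneric("magIds", function(x) standardGeneric("magIds"))
#' @rdname MagSet-class
#' @export
setGeneric("genomeSeqs", function(x) standardGeneric("genomeSeqs"))
#' @rdname MagSet-class
#' @export
setGeneric("communityTruth", function(x) standardGeneric("communityTruth"))
#' @rdname MagAbundance-class
#' @export
setGeneric("abundanceValues", function(x) standardGeneric("abundanceValues"))
#' @rdname MagAbundance-class
#' @export
setGeneric("presenceCalls", function(x) standardGeneric("presenceCalls"))
#' @rdname MagAbundance-class
#' @export
setGeneric("presenceThreshold", function(x) standardGeneric("presenceThreshold"))

#' @rdname MagSet-class
#' @export
setMethod("magIds", "MagSet", function(x) names(x@genomes))
#' @rdname MagSet-class
#' @export
setMethod("genomeSeqs", "MagSet", function(x) x@genomes)
#' @rdname MagSet-class
#' @export
setMethod("communityTruth", "MagSet", function(x) x@truth)
#' @rdname MagAbundance-class
#' @export
setMethod("abundanceValues", "MagAbundance", function(x) x@values)
#' @rdname MagAbundance-class
#' @export
setMethod("presenceCalls", "MagAbundance", function(x) x@values > x@threshold)
#' @rdname MagAbundance-class
#' @export
setMethod("presenceThreshold", "MagAbundance", function(x) x@threshold)

setMethod("show", "MagSet", function(object) {
  n <- length(object@genomes)
  cat(sprintf("MagSet with %d MAG%s\n", n, if (n == 1) "" else "s"))
  if (n) {
    len <- vapply(object@genomes, function(x) sum(Biostrings::width(x)),
                  numeric(1))
    cat(sprintf("  genome size: %d - %d bp\n", min(len), max(len)))
  }
  if (length(object@truth@speciesAssignments))
    cat(sprintf("  planted species: %d\n",
                length(unique(object@truth@speciesAssignments))))
  invisible(object)
})

setMethod("show", "MagAbundance", function(object) {
  cat(sprintf("MagAbundance: %d MAGs x %d samples (presence threshold %g%%)\n",
              nrow(object@values), ncol(object@values), object@threshold))
  invisible(object)
})

setMethod("show", "KeggModule", function(object) {
  cat(sprintf("KeggModule %s (%d block%s): %s\n", object@moduleId,
              length(object@blocks),
              if (length(object@blocks) == 1) "" else "s", object@definition))
  invisible(object)
})
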