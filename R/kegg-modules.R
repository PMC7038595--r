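## KEGG DEFINITION grammar, as used by module completeness evaluation:
##   space (outside parentheses, top level)  -> serial reaction blocks
##   space (inside an expression)            -> AND
##   comma                                   -> OR (lowest precedence)
##   "+"                                     -> complex, all subunits required
##   "-"                                     -> optional component, ignored
##   parentheses                             -> grouping

splitTopLevel <- function(s, sep) {
  depth <- 0L
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  parts <- character()
  buf <- character()
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced parentheses in definition: ", s)
    if (ch == sep && depth == 0L) {
      parts <- c(parts, paste(buf, collapse = ""))
      buf <- character()
    } else buf <- c(buf, ch)
  }
  if (depth != 0L) stop("unbalanced parentheses in definition: ", s)
  c(parts, paste(buf, collapse = ""))
}

koNode <- function(id) list(kind = "ko", ko = id)

parseAtom <- function(s) {
  s <- trimws(s)
  if (startsWith(s, "(")) {
    if (!endsWith(s, ")")) stop("malformed group: ", s)
    inner <- substr(s, 2, nchar(s) - 1)
    return(parseExpr(inner))
  }
  if (!grepl("^K[0-9]{5}$", s))
    stop("not a valid KO identifier: '", s, "'")
  koNode(s)
}

# "+" joins required subunits, "-" marks optional ones; units may be
# parenthesised groups
parseComplexUnit <- function(s) {
  s <- trimws(s)
  units <- list()
  signs <- character()
  depth <- 0L
  buf <- character()
  cur_sign <- "+"
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  flush <- function() {
    if (length(buf) == 0L) stop("empty component in complex: ", s)
    units[[length(units) + 1L]] <<- paste(buf, collapse = "")
    signs[length(signs) + 1L] <<- cur_sign
    buf <<- character()
  }
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth == 0L && (ch == "+" || ch == "-")) {
      flush()
      cur_sign <- ch
    } else buf <- c(buf, ch)
  }
  flush()
  if (length(units) == 1L) {
    if (signs[1] == "-")          # standalone leading "-": wholly optional
      return(list(kind = "optional", child = parseAtom(units[[1]])))
    return(parseAtom(units[[1]]))
  }
  req <- lapply(units[signs == "+"], parseAtom)
  opt <- lapply(units[signs == "-"], parseAtom)
  list(kind = "complex", required = req, optional = opt)
}

parseSeq <- function(s) {
  parts <- Filter(nzchar, trimws(splitTopLevel(trimws(s), " ")))
  if (length(parts) == 0L) stop("empty expression")
  nodes <- lapply(parts, function(p) {
    # leading "-" on a unit marks it optional
    if (startsWith(p, "-"))
      list(kind = "optional", child = parseComplexUnit(substring(p, 2)))
    else parseComplexUnit(p)
  })
  if (length(nodes) == 1L) nodes[[1]] else list(kind = "and", children = nodes)
}

parseExpr <- function(s) {
  parts <- trimws(splitTopLevel(trimws(s), ","))
  if (any(!nzchar(parts))) stop("empty alternative in definition: ", s)
  nodes <- lapply(parts, parseSeq)
  if (length(nodes) == 1L) nodes[[1]] else list(kind = "or", children = nodes)
}

#' Parse a KEGG module DEFINITION string
#'
#' Splits the definition into serial reaction blocks (top-level
#' space-separated units) and parses each block into a boolean expression
#' tree over KO identifiers. Commas are alternatives (OR, lowest
#' precedence), spaces inside parentheses are AND, \code{+} joins the
#' subunits of a complex (all required) and \code{-} marks optional
#' components that never affect satisfaction.
#'
#' @param moduleId module identifier (e.g. "M00001").
#' @param definition the DEFINITION string.
#' @param name optional module name.
#' @return a \code{\linkS4class{KeggModule}}.
#' @examples
#' m <- parseDefinition("M90001", "K00001 (K00002,K00003) K00004+K00005")
#' length(m@blocks)  # 3
#' @export
parseDefinition <- function(moduleId, definition, name = moduleId) {
  def <- trimws(definition)
  if (!nzchar(def)) stop("empty definition for ", moduleId)
  block_txt <- Filter(nzchar, trimws(splitTopLevel(def, " ")))
  blocks <- lapply(block_txt, function(b) {
    if (startsWith(b, "-"))
      list(kind = "optional", child = parseComplexUnit(substring(b, 2)))
    else parseExpr(b)
  })
  new("KeggModule", moduleId = moduleId, name = name, definition = def,
      blocks = blocks)
}

evalNode <- function(node, kos) {
  switch(node$kind,
    ko = node$ko %in% kos,
    and = all(vapply(node$children, evalNode, logical(1), kos = kos)),
    or = any(vapply(node$children, evalNode, logical(1), kos = kos)),
    complex = all(vapply(node$required, evalNode, logical(1), kos = kos)),
    optional = TRUE,
    stop("unknown node kind: ", node$kind))
}

#' KO leaves of an expression tree or module
#'
#' All KO identifiers appearing in a block tree (or whole module),
#' including optional components.
#' @param node a block tree node or \code{KeggModule}.
#' @return character vector of KO ids.
#' @export
koLeaves <- function(node) {
  if (methods::is(node, "KeggModule"))
    return(unique(unlist(lapply(node@blocks, koLeaves))))
  switch(node$kind,
    ko = node$ko,
    and = ,
    or = unique(unlist(lapply(node$children, koLeaves))),
    complex = unique(unlist(lapply(c(node$required, node$optional), koLeaves))),
    optional = koLeaves(node$child),
    stop("unknown node kind: ", node$kind))
}

deparseNode <- function(node, top = FALSE) {
  wrap <- function(x, cond) if (cond) paste0("(", x, ")") else x
  switch(node$kind,
    ko = node$ko,
    and = paste(vapply(node$children, function(c)
      wrap(deparseNode(c), c$kind %in% c("or")), ""), collapse = " "),
    or = paste(vapply(node$children, function(c)
      wrap(deparseNode(c), c$kind %in% c("and")), ""), collapse = ","),
    complex = {
      req <- vapply(node$required, function(c)
        wrap(deparseNode(c), !c$kind %in% c("ko")), "")
      opt <- vapply(node$optional, function(c)
        wrap(deparseNode(c), !c$kind %in% c("ko")), "")
      paste0(paste(req, collapse = "+"),
             if (length(opt)) paste0("-", paste(opt, collapse = "-")) else "")
    },
    optional = paste0("-", wrap(deparseNode(node$child),
                                !node$child$kind %in% c("ko"))),
    stop("unknown node kind: ", node$kind))
}

#' Serialise a parsed module back to DEFINITION syntax
#' @param module a \code{KeggModule}.
#' @return the definition string.
#' @export
deparseDefinition <- function(module) {
  blocks <- vapply(module@blocks, function(b)
    if (b$kind == "or") paste0("(", deparseNode(b), ")") else deparseNode(b),
    "")
  paste(blocks, collapse = " ")
}

#' Module completeness: count of missing blocks
#'
#' Evaluates each block tree against the MAG's KO set. A block is satisfied
#' when its expression is true (AND = all children, OR = any, complex = all
#' required subunits, optional components ignored). The record's category
#' follows the missing-block count: 0 = complete, 1 = "1bm", 2 = "2bm",
#' 3 or more = incomplete.
#'
#' @param module a \code{\linkS4class{KeggModule}}.
#' @param kos character vector of KO ids annotated in the MAG.
#' @param magId optional MAG id carried into the record.
#' @return one-row data.frame: mag_id, module_id, blocks_total,
#'   blocks_missing, category.
#' @export
blocksMissing <- function(module, kos, magId = NA_character_) {
  sat <- vapply(module@blocks, evalNode, logical(1), kos = kos)
  miss <- sum(!sat)
  category <- if (miss == 0) "complete" else if (miss == 1) "1bm"
    else if (miss == 2) "2bm" else "incomplete"
  data.frame(mag_id = magId, module_id = module@moduleId,
             blocks_total = length(sat), blocks_missing = miss,
             category = factor(category, levels = MODULE_CATEGORIES),
             stringsAsFactors = FALSE)
}

#' Completeness records for every MAG x module combination
#'
#' @param modules list of \code{KeggModule}s.
#' @param koTable data.frame (mag_id, gene_id, ko_id) of filtered KO hits.
#' @param magIds MAGs to evaluate (default: those present in the table).
#' @return data.frame of \code{\link{blocksMissing}} records.
#' @export
completenessTable <- function(modules, koTable, magIds = NULL) {
  if (is.null(magIds)) magIds <- sort(unique(koTable$mag_id))
  rows <- list()
  for (mag in magIds) {
    kos <- unique(koTable$ko_id[koTable$mag_id == mag])
    for (m in modules)
      rows[[length(rows) + 1L]] <- blocksMissing(m, kos, magId = mag)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter KO alignment hits
#'
#' Keeps alignment-based KO assignments passing the annotation thresholds:
#' e-value <= 1e-5, bit score >= 50 and percent identity >= 25.
#'
#' @param hits data.frame with columns gene_id, ko_id, evalue, bitscore,
#'   identity (extra columns preserved).
#' @param maxEvalue,minBitscore,minIdentity the thresholds.
#' @return the filtered data.frame.
#' @export
filterKoHits <- function(hits, maxEvalue = 1e-5, minBitscore = 50,
                         minIdentity = 25) {
  need <- c("evalue", "bitscore", "identity")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  for (col in need) {
    v <- suppressWarnings(as.numeric(hits[[col]]))
    bad <- which(is.na(v) & !is.na(hits[[col]]) | is.na(hits[[col]]))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at row %d", col, bad[1]))
    hits[[col]] <- v
  }
  hits[hits$evalue <= maxEvalue & hits$bitscore >= minBitscore &
         hits$identity >= minIdentity, , drop = FALSE]
}

#' Classify modules as core / soft-core / shell
#'
#' A module counts as present in a MAG when its category is complete or
#' "1bm" (the working definition for downstream prevalence statements; set
#' \code{presentCategories = "complete"} for the stricter reading). With
#' the fraction of HQ-MHQ MAGs carrying the module: core > 90\%, soft-core
#' 10--90\%, shell < 10\%.
#'
#' @param records completeness records restricted to HQ/MHQ MAGs.
#' @param nMags total number of HQ-MHQ MAGs (default: distinct mag_id in
#'   \code{records}).
#' @param presentCategories categories counted as present.
#' @return data.frame: module_id, n_present, fraction (percent), class.
#' @export
classifyModulePrevalence <- function(records, nMags = NULL,
                                     presentCategories = c("complete", "1bm")) {
  if (is.null(nMags)) nMags <- length(unique(records$mag_id))
  if (nMags < 1) stop("no HQ-MHQ MAGs to classify against")
  mods <- sort(unique(records$module_id))
  pres <- records[as.character(records$category) %in% presentCategories, ]
  n_present <- vapply(mods, function(m)
    length(unique(pres$mag_id[pres$module_id == m])), numeric(1))
  frac <- 100 * n_present / nMags
  cls <- ifelse(frac > 90, "core", ifelse(frac < 10, "shell", "soft-core"))
  data.frame(module_id = mods, n_present = n_present, fraction = frac,
             class = factor(cls, levels = c("core", "soft-core", "shell")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify MAGs by functional breadth
#'
#' Counts, per MAG, the modules encoded (complete or "1bm") and labels
#' MAGs with more than 180 encoded modules multifunctional and those with
#' fewer than 80 oligofunctional.
#'
#' @param records completeness records.
#' @param presentCategories categories counted as encoded.
#' @return data.frame: mag_id, n_modules, breadth.
#' @export
classifyMagBreadth <- function(records,
                               presentCategories = c("complete", "1bm")) {
  mags <- sort(unique(records$mag_id))
  pres <- records[as.character(records$category) %in% presentCategories, ]
  n <- vapply(mags, function(m)
    length(unique(pres$module_id[pres$mag_id == m])), numeric(1))
  breadth <- ifelse(n > 180, "multifunctional",
                    ifelse(n < 80, "oligofunctional", "intermediate"))
  data.frame(mag_id = mags, n_modules = n,
             breadth = factor(breadth, levels = c("multifunctional",
                                                  "intermediate",
                                                  "oligofunctional")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-sample module abundance
#'
#' The abundance of a module in a sample is the summed relative abundance
#' of the qualifying MAGs encoding it: MAGs in the requested quality tiers
#' whose completeness category is complete or "1bm".
#'
#' @param abundance a \code{\linkS4class{MagAbundance}}.
#' @param records completeness records covering the MAGs.
#' @param quality quality table (needed when \code{tiers} is not NULL).
#' @param tiers tiers whose MAGs may contribute (default HQ + MHQ); NULL
#'   disables tier filtering.
#' @param presentCategories categories that qualify.
#' @return module x sample numeric matrix (percent).
#' @export
moduleAbundance <- function(abundance, records, quality = NULL,
                            tiers = c("HQ", "MHQ"),
                            presentCategories = c("complete", "1bm")) {
  vals <- abundanceValues(abundance)
  missing_mags <- setdiff(unique(records$mag_id), rownames(vals))
  if (length(missing_mags))
    stop("MAG(s) in completeness records missing from abundance matrix: ",
         paste(head(missing_mags, 5), collapse = ", "))
  keep <- records[as.character(records$category) %in% presentCategories, ]
  if (!is.null(tiers)) {
    if (is.null(quality)) stop("quality table required for tier filtering")
    ok_mags <- quality$mag_id[as.character(quality$tier) %in% tiers]
    keep <- keep[keep$mag_id %in% ok_mags, ]
  }
  mods <- sort(unique(records$module_id))
  out <- matrix(0, length(mods), ncol(vals),
                dimnames = list(mods, colnames(vals)))
  for (m in mods) {
    mags <- unique(keep$mag_id[keep$module_id == m])
    if (length(mags))
      out[m, ] <- colSums(vals[mags, , drop = FALSE])
  }
  out
}

#' Acetoclastic : hydrogenotrophic methanogenesis ratio
#'
#' Per-sample ratio of the module abundances of the acetoclastic and
#' hydrogenotrophic methanogenesis modules. Samples with zero
#' hydrogenotrophic abundance get NA (undefined), mirroring division by
#' zero; zero acetoclastic abundance gives 0.
#'
#' @param moduleAbundance module x sample matrix from
#'   \code{\link{moduleAbundance}}.
#' @param acetoclasticModule,hydrogenotrophicModule module ids.
#' @return named numeric vector of per-sample ratios.
#' @export
methanogenesisRatio <- function(moduleAbundance, acetoclasticModule,
                                hydrogenotrophicModule) {
  for (m in c(acetoclasticModule, hydrogenotrophicModule))
    if (!m %in% rownames(moduleAbundance))
      stop("module not in abundance matrix: ", m)
  a <- moduleAbundance[acetoclasticModule, ]
  h <- moduleAbundance[hydrogenotrophicModule, ]
  ifelse(h == 0, NA_real_, a / h)
}

#' Ordinary least-squares association with a metadata covariate
#'
#' Regresses a per-sample statistic (e.g. the acetoclastic:hydrogenotrophic
#' ratio) on a metadata covariate (e.g. TAN ammonia). Pairs with missing
#' values are dropped and counted.
#'
#' @param values named numeric per-sample statistic.
#' @param covariate named numeric metadata values (matched by name when
#'   both are named, else by position).
#' @return list: r2, p (two-sided slope p-value), slope, n_used, n_dropped.
#' @export
correlateWithMetadata <- function(values, covariate) {
  if (!is.null(names(values)) && !is.null(names(covariate)))
    covariate <- covariate[names(values)]
  ok <- is.finite(values) & is.finite(covariate)
  n_drop <- sum(!ok)
  if (sum(ok) < 3) stop("fewer than 3 complete pairs")
  fit <- lm(values[ok] ~ covariate[ok])
  sm <- summary(fit)
  list(r2 = sm$r.squared, p = sm$coefficients[2, 4],
       slope = coef(fit)[[2]], n_used = sum(ok), n_dropped = n_drop)
}
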