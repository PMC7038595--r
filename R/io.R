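#' Read a FASTA file of contigs
#'
#' Reads sequences with Biostrings, upper-casing mixed-case input (with a
#' warning) and rejecting duplicate ids or characters outside ACGTN.
#'
#' @param path FASTA file path.
#' @return a \code{DNAStringSet}; empty set (with a warning) for an empty
#'   file.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(Biostrings::DNAStringSet())
  }
  seqs <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  chr <- as.character(seqs)
  if (any(grepl("[a-z]", chr))) {
    warning("mixed-case sequence in ", path, "; upper-casing")
    chr <- toupper(chr)
  }
  bad <- grepl("[^ACGTN]", chr)
  if (any(bad)) {
    off <- unique(unlist(strsplit(gsub("[ACGTN]", "", chr[bad]), "")))
    stop("non-ACGTN character(s) in ", path, ": ",
         paste(off, collapse = ", "))
  }
  Biostrings::DNAStringSet(setNames(chr, names(seqs)))
}

#' Write sequences as wrapped FASTA
#' @param seqs a \code{DNAStringSet} (or named character vector).
#' @param path output path.
#' @export
writeFasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, width = 80L)
  invisible(path)
}

#' Read a directory of per-MAG FASTA files
#'
#' One file per MAG (\code{<mag_id>.fasta} / \code{.fa} / \code{.fna}).
#' @param dir directory path.
#' @return a \code{\linkS4class{MagSet}} without truth.
#' @export
readGenomeDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(fa|fna|fasta)$",
                           full.names = TRUE))
  if (!length(files)) stop("no FASTA files in ", dir)
  genomes <- lapply(files, readFasta)
  names(genomes) <- sub("\\.(fa|fna|fasta)$", "", basename(files))
  new("MagSet", genomes = genomes)
}

#' Write the genomes of a MagSet as per-MAG FASTA files
#' @param mags a \code{\linkS4class{MagSet}}.
#' @param dir output directory (created if needed).
#' @export
writeGenomeDir <- function(mags, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in magIds(mags))
    writeFasta(genomeSeqs(mags)[[id]], file.path(dir, paste0(id, ".fasta")))
  invisible(dir)
}

#' Tab-separated table I/O
#'
#' Thin wrappers enforcing the package's interchange conventions: header
#' row, tab separation, no quoting, no row names.
#' @param x data.frame or matrix to write (matrices keep rownames in a
#'   leading id column).
#' @param path file path.
#' @param rowLabel column name for matrix rownames.
#' @return \code{readTsv}: a data.frame.
#' @export
writeTsv <- function(x, path, rowLabel = "id") {
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- rowLabel
    x <- df
  }
  # 17 significant digits so doubles survive a write/read round trip exactly
  for (j in seq_along(x))
    if (is.double(x[[j]])) x[[j]] <- sprintf("%.17g", x[[j]])
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Read module definitions from a TSV file
#'
#' Expects columns \code{module_id}, \code{name}, \code{definition}. The
#' package ships a synthetic fixture set (including three-block
#' methanogenesis stand-ins) under \code{inst/extdata} so tests need no
#' external module database.
#'
#' @param path TSV path; defaults to the bundled synthetic module set.
#' @return named list of \code{\linkS4class{KeggModule}}s.
#' @export
readModuleDefinitions <- function(path = system.file("extdata",
                                    "synthetic_modules.tsv",
                                    package = "magcentric")) {
  tab <- readTsv(path)
  need <- c("module_id", "name", "definition")
  if (!all(need %in% names(tab)))
    stop("module table must have columns: ", paste(need, collapse = ", "))
  mods <- lapply(seq_len(nrow(tab)), function(i)
    parseDefinition(tab$module_id[i], tab$definition[i], name = tab$name[i]))
  setNames(mods, tab$module_id)
}
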