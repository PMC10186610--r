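#' Read and write the pipeline's plain-text interchange formats
#'
#' Counts and expression matrices travel as TSV (genes in rows, samples in
#' columns) with an optional MatrixMarket alternative; gene sets as GMT lines;
#' sample metadata as TSV with columns sample, group, age, sex, batch,
#' library.
#'
#' @param x matrix to write (row names = gene ids, col names = sample ids).
#' @param path file path.
#' @return \code{readMatrixTSV} returns a numeric matrix with dimnames.
#' @name lhasig-io
NULL

#' @rdname lhasig-io
#' @export
writeMatrixTSV <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname lhasig-io
#' @export
readMatrixTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname lhasig-io
#' @param counts a counts \code{SummarizedExperiment}.
#' @param dir output directory; files \code{matrix.mtx}, \code{genes.txt},
#'   \code{samples.txt} are written there.
#' @export
writeCountsMTX <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- SummarizedExperiment::assay(counts)
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.txt"))
  writeLines(colnames(m), file.path(dir, "samples.txt"))
  invisible(dir)
}

#' @rdname lhasig-io
#' @export
readCountsMTX <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readLines(file.path(dir, "genes.txt"))
  colnames(m) <- readLines(file.path(dir, "samples.txt"))
  m
}

#' Read and write GMT gene-set files
#'
#' One set per line: name, description, then tab-separated members.
#'
#' @param sets list of \linkS4class{GeneSet} objects (or one).
#' @param path file path.
#' @return \code{readGMT} returns a named list of \linkS4class{GeneSet}s.
#' @export
writeGMT <- function(sets, path) {
  if (is(sets, "GeneSet")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s@name, s@direction, s@members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGMT
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    dirn <- if (f[2] %in% c("up", "down")) f[2] else "none"
    geneSet(f[-(1:2)], name = f[1], direction = dirn)
  })
  names(sets) <- vapply(sets, setName, character(1))
  sets
}

#' @rdname lhasig-io
#' @param metadata per-sample data.frame with a \code{sample} column.
#' @export
writeMetadataTSV <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname lhasig-io
#' @export
readMetadataTSV <- function(path) read.delim(path, check.names = FALSE)

#' Read/write BED interval files (0-based half-open on disk)
#'
#' Wraps \pkg{rtracklayer}; intervals live in memory as \code{GRanges}
#' (1-based closed) and round-trip exactly.
#'
#' @param gr a \code{GRanges} with a \code{name} metadata column.
#' @param path file path ending in .bed.
#' @export
writeBED <- function(gr, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for BED i/o")
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname writeBED
#' @export
readBED <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for BED i/o")
  rtracklayer::import(path, format = "BED")
}

# Internal: assemble a counts SummarizedExperiment with validated metadata.
makeCountsSE <- function(counts, metadata) {
  stopifnot(!anyDuplicated(rownames(counts)),
            !anyDuplicated(colnames(counts)),
            nrow(metadata) == ncol(counts))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(metadata, row.names = colnames(counts)))
}
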