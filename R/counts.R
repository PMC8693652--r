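#' Gene-by-cell count matrix container
#'
#' A thin wrapper around a dense base matrix (rows = genes, columns = cells)
#' carrying a layer tag that records what the values are: `"raw"` integer
#' counts, `"normalized"` library-size-scaled values, or `"smoothed"`
#' neighbour-averaged values. Row and column names are the gene and cell
#' identifiers and must be unique.
#'
#' @param values Numeric matrix with unique rownames (genes) and colnames
#'   (cells); non-negative. For the raw layer all entries must be integers.
#' @param layer One of `"raw"`, `"normalized"`, `"smoothed"`.
#' @return An `sc_counts` object (a matrix with a `layer` attribute).
#' @export
sc_counts <- function(values, layer = c("raw", "normalized", "smoothed")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix", class = "scregnet_format_error")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene rownames and cell colnames",
          class = "scregnet_validation_error")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    abort("duplicate gene or cell identifiers",
          class = "scregnet_validation_error")
  }
  if (anyNA(values) || any(values < 0)) {
    abort("counts must be non-negative and non-missing",
          class = "scregnet_format_error")
  }
  if (layer == "raw" && any(values != floor(values))) {
    abort("raw layer must contain integer counts",
          class = "scregnet_format_error")
  }
  structure(values, layer = layer, class = c("sc_counts", "matrix", "array"))
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("<sc_counts> %d genes x %d cells, layer \"%s\"\n",
              nrow(x), ncol(x), counts_layer(x)))
  invisible(x)
}

#' @rdname sc_counts
#' @param x An `sc_counts` object.
#' @export
counts_layer <- function(x) attr(x, "layer") %||% "raw"

# keep class/layer when subsetting with drop = FALSE
#' @export
`[.sc_counts` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    out <- structure(out, layer = attr(x, "layer"),
                     class = c("sc_counts", "matrix", "array"))
  }
  out
}

gene_ids <- function(x) rownames(x)
cell_ids <- function(x) colnames(x)

#' Read a count matrix from TSV or MatrixMarket files
#'
#' TSV input is a dense table whose first column holds gene identifiers and
#' whose header row holds cell identifiers. MatrixMarket input is the sparse
#' `.mtx` triplet accompanied by two sidecar files listing gene and cell
#' identifiers one per line, named `<stem>.genes.txt` and `<stem>.cells.txt`
#' next to the `.mtx` file (or given explicitly).
#'
#' @param path Path to the `.tsv` or `.mtx` file.
#' @param format `"auto"` (from extension), `"tsv"`, or `"mtx"`.
#' @param genes_path,cells_path Optional explicit sidecar paths for MTX input.
#' @return An [sc_counts()] raw-layer matrix, identifiers in file order.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx"),
                        genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
    # data.frame subsetting mangles duplicate headers; restore the originals
    hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
    colnames(m) <- hdr[-1]
  } else {
    stem <- sub("\\.mtx$", "", path)
    genes_path <- genes_path %||% paste0(stem, ".genes.txt")
    cells_path <- cells_path %||% paste0(stem, ".cells.txt")
    for (p in c(genes_path, cells_path)) {
      if (!file.exists(p)) abort(paste0("missing identifier sidecar: ", p))
    }
    sp <- Matrix::readMM(path)
    m <- as.matrix(sp)
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(cells_path)
  }
  if (anyNA(m)) abort("non-numeric entries in count file",
                      class = "scregnet_format_error")
  if (any(m < 0) || any(m != floor(m))) {
    abort("raw counts must be non-negative integers",
          class = "scregnet_format_error")
  }
  sc_counts(m, layer = "raw")
}

#' Write a count matrix
#'
#' @param x An [sc_counts()] object.
#' @param path Output path; `.mtx` writes MatrixMarket plus `.genes.txt` /
#'   `.cells.txt` sidecars, anything else writes a dense TSV with a `gene`
#'   first column.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  if (grepl("\\.mtx$", path)) {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(unclass(x), sparse = TRUE), path)
    writeLines(rownames(x), paste0(stem, ".genes.txt"))
    writeLines(colnames(x), paste0(stem, ".cells.txt"))
  } else {
    tab <- data.frame(gene = rownames(x), unclass(x),
                      check.names = FALSE, stringsAsFactors = FALSE)
    readr::write_tsv(tab, path, progress = FALSE)
  }
  invisible(path)
}

#' Library-size normalisation (counts per 10k, optional log1p)
#'
#' Scales every cell to 10,000 total counts; the standard scale-free
#' normalisation used before marker scoring, classification and smoothing.
#'
#' @param x Raw-layer [sc_counts()].
#' @param log1p If `TRUE`, return `log(1 + cp10k)` values.
#' @return A normalized-layer `sc_counts`.
#' @export
normalize_counts <- function(x, log1p = FALSE) {
  stopifnot(inherits(x, "sc_counts"))
  tot <- colSums(x)
  tot[tot == 0] <- 1
  v <- sweep(unclass(x), 2, tot / 1e4, "/")
  if (log1p) v <- log1p(v)
  sc_counts(v, layer = "normalized")
}
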