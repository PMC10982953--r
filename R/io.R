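# Plain-text readers and writers: dense CSV/TSV and MatrixMarket triplets.
# Gene identifiers are opaque strings matched exactly and case-sensitively.

read_dense_matrix <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

# MTX triplet directory: matrix.mtx (rows = cells/spots), genes.tsv,
# barcodes.tsv (one identifier per line).
read_mtx_triplet <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readLines(file.path(dir, "genes.tsv"))
  ids <- readLines(file.path(dir, "barcodes.tsv"))
  genes <- vapply(strsplit(genes, "\t"), `[[`, character(1), 1L)
  if (nrow(m) == length(genes) && ncol(m) == length(ids) &&
      length(genes) != length(ids))
    m <- t(m)  # genes-in-rows convention
  dimnames(m) <- list(ids, genes)
  m
}

read_expression <- function(path) {
  if (dir.exists(path)) read_mtx_triplet(path) else read_dense_matrix(path)
}

#' Read a single-cell dataset from plain-text files
#'
#' @param path dense CSV/TSV (cells in rows, first column = cell id) or a
#'   directory holding an MTX triplet (`matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`).
#' @param labels path to a one- or two-column CSV/TSV of cell-type labels
#'   (aligned by order, or by cell id when two columns), or a character
#'   vector of labels.
#' @return an [sc_data] object.
#' @export
read_sc_data <- function(path, labels) {
  m <- read_expression(path)
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    sep <- if (grepl("\\.tsv$", labels, ignore.case = TRUE)) "\t" else ","
    lab <- utils::read.table(labels, header = TRUE, sep = sep,
                             check.names = FALSE)
    labels <- if (ncol(lab) >= 2) {
      stats::setNames(as.character(lab[[2]]), lab[[1]])[rownames(m)]
    } else as.character(lab[[1]])
  }
  sc_data(m, labels)
}

#' Read a spatial dataset from plain-text files
#'
#' @param path expression matrix as in [read_sc_data()] (spots in rows).
#' @param coordinates optional CSV/TSV with columns x, y (spot id as first
#'   column or aligned by order).
#' @return an [st_data] object.
#' @export
read_st_data <- function(path, coordinates = NULL) {
  m <- read_expression(path)
  coords <- NULL
  if (!is.null(coordinates)) {
    sep <- if (grepl("\\.tsv$", coordinates, ignore.case = TRUE)) "\t" else ","
    cf <- utils::read.table(coordinates, header = TRUE, sep = sep,
                            row.names = 1, check.names = FALSE)
    coords <- as.matrix(cf[rownames(m), 1:2])
  }
  st_data(m, coordinates = coords)
}

#' Write a mapping matrix (or any labelled matrix) as CSV
#'
#' @param x matrix, `mapping_matrix` or `spot_deconv` fit.
#' @param path output file.
#' @export
write_matrix_csv <- function(x, path) {
  m <- if (inherits(x, "spot_deconv")) x$M
       else if (inherits(x, "mapping_matrix")) x$M else as.matrix(x)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Write a simulated dataset as a CSV trio
#'
#' Writes `<prefix>_counts.csv`, `<prefix>_coordinates.csv` and (when
#' available) `<prefix>_proportions.csv`.
#'
#' @param sim a `simulated_st` object.
#' @param prefix output path prefix.
#' @export
write_simulated_csv <- function(sim, prefix) {
  stopifnot(inherits(sim, "simulated_st"))
  write_matrix_csv(sim$counts, paste0(prefix, "_counts.csv"))
  write_matrix_csv(sim$coordinates, paste0(prefix, "_coordinates.csv"))
  if (!is.null(sim$proportions))
    write_matrix_csv(sim$proportions, paste0(prefix, "_proportions.csv"))
  invisible(prefix)
}
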