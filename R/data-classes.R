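#' Construct a single-cell expression dataset
#'
#' Bundles a non-negative cells x genes count (or normalised) matrix with a
#' cell-type label per cell. Gene names must be unique; every cell must carry
#' a label.
#'
#' @param counts numeric matrix, cells in rows, genes in columns; no negative
#'   entries.
#' @param cell_types character or factor of length `nrow(counts)`.
#' @param gene_names optional gene identifiers; defaults to `colnames(counts)`.
#' @param cell_ids optional cell identifiers; defaults to `rownames(counts)`.
#' @return an object of class `sc_data` with elements `counts`, `cell_types`,
#'   `gene_names`, `cell_ids`.
#' @export
sc_data <- function(counts, cell_types, gene_names = NULL, cell_ids = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("sc_data: empty matrix")
  if (any(counts < 0)) stop("sc_data: negative entries in counts")
  gene_names <- gene_names %||% colnames(counts) %||%
    paste0("gene", seq_len(ncol(counts)))
  cell_ids <- cell_ids %||% rownames(counts) %||%
    paste0("cell", seq_len(nrow(counts)))
  if (anyDuplicated(gene_names)) stop("sc_data: duplicated gene names")
  if (length(cell_types) != nrow(counts))
    stop("sc_data: one cell-type label required per cell")
  if (anyNA(cell_types)) stop("sc_data: missing cell-type labels")
  dimnames(counts) <- list(cell_ids, gene_names)
  structure(
    list(counts = counts,
         cell_types = as.character(cell_types),
         gene_names = as.character(gene_names),
         cell_ids = as.character(cell_ids)),
    class = "sc_data"
  )
}

#' Construct a spatial transcriptomics dataset
#'
#' Bundles a non-negative spots x genes matrix with optional 2-D spot
#' coordinates (arbitrary units).
#'
#' @param counts numeric matrix, spots in rows, genes in columns.
#' @param coordinates optional numeric matrix/data.frame with columns x, y and
#'   one row per spot.
#' @param gene_names,spot_ids optional identifiers.
#' @return an object of class `st_data`.
#' @export
st_data <- function(counts, coordinates = NULL, gene_names = NULL,
                    spot_ids = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("st_data: empty matrix")
  if (any(counts < 0)) stop("st_data: negative entries in counts")
  gene_names <- gene_names %||% colnames(counts) %||%
    paste0("gene", seq_len(ncol(counts)))
  spot_ids <- spot_ids %||% rownames(counts) %||%
    paste0("spot", seq_len(nrow(counts)))
  if (anyDuplicated(gene_names)) stop("st_data: duplicated gene names")
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)[, 1:2, drop = FALSE]
    colnames(coordinates) <- c("x", "y")
    if (nrow(coordinates) != nrow(counts))
      stop("st_data: one coordinate pair required per spot")
    if (any(!is.finite(coordinates)))
      stop("st_data: non-finite coordinates")
    rownames(coordinates) <- spot_ids
  }
  dimnames(counts) <- list(spot_ids, gene_names)
  structure(
    list(counts = counts,
         coordinates = coordinates,
         gene_names = as.character(gene_names),
         spot_ids = as.character(spot_ids)),
    class = "st_data"
  )
}

#' @export
print.sc_data <- function(x, ...) {
  cat(sprintf("sc_data: %d cells x %d genes, %d cell types\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_types))))
  invisible(x)
}

#' @export
print.st_data <- function(x, ...) {
  cat(sprintf("st_data: %d spots x %d genes%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$coordinates)) "" else ", with coordinates"))
  invisible(x)
}

#' @export
dim.sc_data <- function(x) dim(x$counts)

#' @export
dim.st_data <- function(x) dim(x$counts)
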