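# Quality filtering, normalisation, marker selection and matrix stacking.

#' Quality-control filtering of single-cell and spatial datasets
#'
#' Removes cells with a high mitochondrial read fraction, cells/spots
#' expressing too few genes, genes detected in too few cells (resp. spots),
#' and cell types with too few member cells. The single-cell and spatial
#' datasets are filtered independently. Cell/gene filters are iterated to a
#' fixed point so the operation is idempotent.
#'
#' @param sc an [sc_data] object.
#' @param st an [st_data] object.
#' @param min_genes minimum number of expressed genes per cell/spot
#'   (cells expressing fewer are removed).
#' @param min_cells_per_gene minimum number of cells (spots) a gene must be
#'   detected in.
#' @param min_cells_per_type cell types with fewer member cells are dropped.
#' @param mito_fraction_max cells whose fraction of counts on mitochondrial
#'   genes (gene name prefix `MT-`/`mt-`) exceeds this are removed. Applied to
#'   cells only.
#' @return list with elements `sc` and `st`, the filtered datasets.
#' @export
apply_qc_filters <- function(sc, st, min_genes = 5L, min_cells_per_gene = 1L,
                             min_cells_per_type = 2L,
                             mito_fraction_max = 0.2) {
  stopifnot(inherits(sc, "sc_data"), inherits(st, "st_data"))

  ## mitochondrial fraction filter (cells only)
  mito <- grepl("^(MT-|mt-)", sc$gene_names)
  if (any(mito)) {
    tot <- rowSums(sc$counts)
    frac <- ifelse(tot > 0, rowSums(sc$counts[, mito, drop = FALSE]) / tot, 0)
    keep <- frac <= mito_fraction_max
    if (!any(keep))
      stop("apply_qc_filters: mitochondrial-fraction filter removed all cells")
    sc <- subset_cells(sc, keep)
  }

  sc_mat <- filter_matrix_fixed_point(sc$counts, min_genes, min_cells_per_gene,
                                      what = "cell")
  sc <- sc_data(sc_mat$m, sc$cell_types[sc_mat$rows],
                gene_names = sc$gene_names[sc_mat$cols],
                cell_ids = sc$cell_ids[sc_mat$rows])

  ## small cell types
  tab <- table(sc$cell_types)
  keep_types <- names(tab)[tab >= min_cells_per_type]
  if (length(keep_types) == 0L)
    stop("apply_qc_filters: cell-type-size filter removed all cell types")
  sc <- subset_cells(sc, sc$cell_types %in% keep_types)

  st_mat <- filter_matrix_fixed_point(st$counts, min_genes, min_cells_per_gene,
                                      what = "spot")
  coords <- st$coordinates
  if (!is.null(coords)) coords <- coords[st_mat$rows, , drop = FALSE]
  st <- st_data(st_mat$m, coordinates = coords,
                gene_names = st$gene_names[st_mat$cols],
                spot_ids = st$spot_ids[st_mat$rows])
  list(sc = sc, st = st)
}

subset_cells <- function(sc, keep) {
  sc_data(sc$counts[keep, , drop = FALSE], sc$cell_types[keep],
          gene_names = sc$gene_names, cell_ids = sc$cell_ids[keep])
}

# Iterate row/column detection filters until stable; returns logical index
# vectors into the original matrix plus the filtered matrix.
filter_matrix_fixed_point <- function(m, min_genes, min_cells_per_gene, what) {
  rows <- rep(TRUE, nrow(m)); cols <- rep(TRUE, ncol(m))
  repeat {
    sub <- m[rows, cols, drop = FALSE]
    rk <- rowSums(sub > 0) >= min_genes
    ck <- colSums(sub[rk, , drop = FALSE] > 0) >= min_cells_per_gene
    if (!any(rk))
      stop(sprintf("apply_qc_filters: min_genes filter removed all %ss", what))
    if (!any(ck))
      stop(sprintf("apply_qc_filters: gene-detection filter removed all genes (%s data)", what))
    changed <- !all(rk) || !all(ck)
    rows[rows] <- rk
    cols[cols] <- ck
    if (!changed) break
  }
  list(m = m[rows, cols, drop = FALSE], rows = rows, cols = cols)
}

#' Library-size normalisation of single cells
#'
#' Scales every cell so its expression sums to one, preserving within-cell
#' relative proportions.
#'
#' @param sc an [sc_data] object with no all-zero cells (run QC first).
#' @return an [sc_data] object whose rows each sum to 1.
#' @export
normalize_cells <- function(sc) {
  stopifnot(inherits(sc, "sc_data"))
  tot <- rowSums(sc$counts)
  if (any(tot == 0))
    stop("normalize_cells: all-zero cell encountered; run apply_qc_filters first")
  sc_data(sc$counts / tot, sc$cell_types,
          gene_names = sc$gene_names, cell_ids = sc$cell_ids)
}

#' One-vs-rest marker gene selection
#'
#' Ranks genes per cell type with a one-vs-rest Wilcoxon rank-sum (AUC) score
#' and returns the top `top_n` genes for each type. Ranks are computed on the
#' expression values directly; any monotone transform (e.g. log1p) yields the
#' same ordering. Ties are broken by gene index for determinism.
#'
#' @param sc a normalised [sc_data] object with at least two cell types.
#' @param top_n number of genes kept per type (types with fewer expressed
#'   genes contribute all of them).
#' @param top_frac optional proportional threshold: when set, each type keeps
#'   `ceiling(top_frac * <detectable genes in that type>)` genes and `top_n`
#'   is ignored.
#' @return named list mapping each cell type to its ordered marker genes.
#' @export
select_marker_genes <- function(sc, top_n = 200L, top_frac = NULL) {
  stopifnot(inherits(sc, "sc_data"))
  types <- sort(unique(sc$cell_types))
  if (length(types) < 2L)
    stop("select_marker_genes: need at least two cell types")
  n <- nrow(sc$counts)
  # column-wise ranks across all cells, once
  R <- apply(sc$counts, 2, rank)
  out <- vector("list", length(types)); names(out) <- types
  for (t in types) {
    grp <- sc$cell_types == t
    n1 <- sum(grp); n2 <- n - n1
    # Wilcoxon U statistic -> AUC in [0, 1]
    U <- colSums(R[grp, , drop = FALSE]) - n1 * (n1 + 1) / 2
    auc <- U / (n1 * n2)
    detectable <- colSums(sc$counts[grp, , drop = FALSE] > 0) > 0
    k <- if (!is.null(top_frac)) {
      max(1L, ceiling(top_frac * sum(detectable)))
    } else top_n
    ord <- order(-auc, seq_along(auc))
    ord <- ord[detectable[ord]]
    out[[t]] <- sc$gene_names[utils::head(ord, k)]
  }
  out
}

#' Aggregate cells into cell-type expression profiles
#'
#' Sums the (normalised) expression of all cells sharing a label, restricted
#' to a given gene set, yielding the cell types x genes matrix `C`.
#'
#' @param sc a normalised [sc_data] object.
#' @param genes character vector of genes to keep (e.g. the union of marker
#'   sets); must all be present in `sc`.
#' @param marker_sets optional per-type marker lists stored alongside the
#'   profile.
#' @return object of class `celltype_profile` with elements `profile`
#'   (types x genes), `type_names`, `gene_names`, `marker_sets` (optional).
#' @export
build_celltype_profile <- function(sc, genes, marker_sets = NULL) {
  stopifnot(inherits(sc, "sc_data"))
  genes <- as.character(genes)
  missing <- setdiff(genes, sc$gene_names)
  if (length(missing))
    stop("build_celltype_profile: unknown genes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  types <- sort(unique(sc$cell_types))
  sub <- sc$counts[, genes, drop = FALSE]
  prof <- t(vapply(types,
                   function(t) colSums(sub[sc$cell_types == t, , drop = FALSE]),
                   numeric(length(genes))))
  dimnames(prof) <- list(types, genes)
  structure(
    list(profile = prof, type_names = types, gene_names = genes,
         marker_sets = marker_sets),
    class = "celltype_profile"
  )
}

#' Stack the cell-type profile on top of the spatial matrix
#'
#' Restricts both blocks to their common genes (in profile gene order) and
#' row-binds them into the (m+n) x g input matrix of the graph network. The
#' spatial counts are kept on their original scale.
#'
#' @param profile a `celltype_profile`.
#' @param st an [st_data] object.
#' @return object of class `stacked_matrix`: `X`, `node_roles`
#'   (`"celltype"`/`"spot"` per row), `gene_names`, `m`, `n`.
#' @export
align_and_stack <- function(profile, st) {
  stopifnot(inherits(profile, "celltype_profile"), inherits(st, "st_data"))
  common <- intersect(profile$gene_names, st$gene_names)
  if (length(common) == 0L)
    stop("align_and_stack: no genes shared between cell-type profile and spatial data")
  C <- profile$profile[, common, drop = FALSE]
  S <- st$counts[, common, drop = FALSE]
  X <- rbind(C, S)
  structure(
    list(X = X,
         node_roles = c(rep("celltype", nrow(C)), rep("spot", nrow(S))),
         gene_names = common,
         m = nrow(C), n = nrow(S),
         type_names = rownames(C), spot_ids = rownames(S)),
    class = "stacked_matrix"
  )
}
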