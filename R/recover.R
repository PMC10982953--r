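# Recovery of undetected transcripts through the fitted mapping matrix.

#' Recover spot expression of genes through the mapping matrix
#'
#' Computes `M %*% C_full`, predicting the spatial distribution of every gene
#' in the profile, including genes absent from the spot data used for
#' training. The prediction is linear in the profile and non-negative.
#'
#' @param M a `spot_deconv` fit, a `mapping_matrix`, or a plain spots x
#'   cell-types matrix with column names.
#' @param profile a `celltype_profile` or matrix (cell types x genes) whose
#'   row names match the cell types of `M`.
#' @return spots x genes predicted expression matrix.
#' @export
recover_genes <- function(M, profile) {
  Mm <- if (inherits(M, "spot_deconv")) M$M
        else if (inherits(M, "mapping_matrix")) M$M
        else as.matrix(M)
  Cm <- if (inherits(profile, "celltype_profile")) profile$profile
        else as.matrix(profile)
  if (!is.null(colnames(Mm)) && !is.null(rownames(Cm))) {
    if (!setequal(colnames(Mm), rownames(Cm)))
      stop("recover_genes: cell types of the mapping matrix and the profile differ: ",
           paste(union(setdiff(colnames(Mm), rownames(Cm)),
                       setdiff(rownames(Cm), colnames(Mm))), collapse = ", "))
    Cm <- Cm[colnames(Mm), , drop = FALSE]
  } else if (ncol(Mm) != nrow(Cm)) {
    stop("recover_genes: dimension mismatch between M and profile")
  }
  Mm %*% Cm
}

#' Cross-validated recovery of held-out spatial genes
#'
#' Partitions the genes of the spot data into `folds` disjoint fractions
#' (seeded shuffle). For each fold the deconvolution pipeline is trained on
#' the spot data restricted to the other fractions, and the held-out genes
#' are predicted via [recover_genes()] from the full single-cell profile.
#' Aggregated predictions cover every spot gene exactly once; per-gene
#' metrics against the observed expression are attached.
#'
#' @param sc an [sc_data] reference.
#' @param st an [st_data] object with at least `folds` genes.
#' @param folds number of gene fractions (default 10).
#' @param seed integer seed for the gene shuffle and the per-fold fits.
#' @param config pipeline configuration overrides, see [spotgcn_config()].
#' @return list with `predicted` (spots x genes matrix over all spot genes),
#'   `folds` (named fold assignment), and `metrics` (per-gene
#'   [evaluate_gene_recovery()] table; genes absent from the reference are
#'   predicted as zero and flagged in `missing_genes`).
#' @export
crossval_gene_recovery <- function(sc, st, folds = 10L, seed = 1L,
                                   config = list()) {
  stopifnot(inherits(sc, "sc_data"), inherits(st, "st_data"))
  genes <- st$gene_names
  if (length(genes) < folds)
    stop("crossval_gene_recovery: fewer spot genes than folds")
  set.seed(derive_seed(seed, 17L))
  shuffled <- sample(genes)
  fold_id <- rep_len(seq_len(folds), length(genes))
  assignment <- split(shuffled, fold_id)
  if (any(lengths(assignment) == 0L))
    stop("crossval_gene_recovery: empty fold")

  # Full reference profile over all reference genes (normalised scale).
  scn <- normalize_cells(sc)
  full_profile <- build_celltype_profile(scn, scn$gene_names)

  pred <- matrix(0, nrow(st$counts), length(genes),
                 dimnames = list(st$spot_ids, genes))
  missing <- character(0)
  for (f in seq_len(folds)) {
    held <- assignment[[f]]
    train_genes <- setdiff(genes, held)
    st_f <- st_data(st$counts[, train_genes, drop = FALSE],
                    coordinates = st$coordinates,
                    gene_names = train_genes, spot_ids = st$spot_ids)
    cfg <- utils::modifyList(config, list(seed = derive_seed(seed, 100L + f)))
    fit <- deconvolve(sc, st_f, config = cfg)
    predictable <- intersect(held, full_profile$gene_names)
    missing <- c(missing, setdiff(held, predictable))
    if (length(predictable)) {
      sub <- full_profile$profile[fit$type_names, predictable, drop = FALSE]
      pr <- fit$M %*% sub
      pred[rownames(pr), predictable] <- pr
    }
  }
  metrics <- evaluate_gene_recovery(pred, st)
  list(predicted = pred, folds = assignment, metrics = metrics,
       missing_genes = missing)
}
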