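# End-to-end deconvolution: preprocess -> VAE co-embedding -> link graph ->
# co-GCN fit, packaged as a classed model object.

#' Default pipeline configuration
#'
#' Returns the full list of tunable parameters with their defaults; any
#' subset can be overridden through the `config` argument of [deconvolve()].
#'
#' @return named list of defaults.
#' @export
spotgcn_config <- function() {
  list(
    seed = 1L,
    # preprocess
    min_genes = 5L, min_cells_per_gene = 1L, min_cells_per_type = 2L,
    mito_fraction_max = 0.2,
    top_n = 200L, top_frac = NULL,
    normalize = "sc",          # "sc", "none", "st", "both" (ablation configs)
    # VAE co-embedding
    latent_dim = 30L, vae_hidden = 512L, vae_epochs = 1000L, vae_lr = 5e-4,
    vae_input_scaling = "lognorm",
    # link graph
    k = 20L, max_scope = "edges",
    # co-GCN
    gcn_hidden = 64L, gcn_epochs = 2000L, gcn_lr = 1e-3,
    gcn_feature_scaling = "lognorm", gcn_n_init = 1L
  )
}

merge_config <- function(config) {
  def <- spotgcn_config()
  if (is.null(config)) return(def)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(def, config)
}

#' Deconvolve spatial spots into cell-type proportions
#'
#' Runs the full pipeline: quality filtering, per-cell library-size
#' normalisation of the single-cell reference, one-vs-rest marker selection,
#' aggregation into cell-type profiles, gene alignment and stacking,
#' variational co-embedding, mutual-nearest-neighbour link graph
#' construction, and self-supervised training of the two-layer graph
#' convolution network. The result is a row-stochastic mapping matrix `M`
#' (spots x cell types) such that `M C` approximates the spot expression.
#'
#' All randomness derives from `config$seed`; per-stage seeds are derived
#' with a counter scheme so identical configurations reproduce results
#' bitwise.
#'
#' @param sc an [sc_data] reference with cell-type labels.
#' @param st an [st_data] object sharing at least one gene with `sc`.
#' @param config named list overriding entries of [spotgcn_config()].
#' @return object of class `spot_deconv` with components `M` (proportions),
#'   `C`, `S` (aligned matrices), `vae`, `graph`, `gcn`, `log`, `config`,
#'   and the filtered inputs.
#' @export
deconvolve <- function(sc, st, config = list()) {
  cfg <- merge_config(config)
  if (length(intersect(sc$gene_names, st$gene_names)) == 0L)
    stop("deconvolve [preprocess]: no shared genes between reference and spatial data")

  qc <- tryCatch(
    apply_qc_filters(sc, st, min_genes = cfg$min_genes,
                     min_cells_per_gene = cfg$min_cells_per_gene,
                     min_cells_per_type = cfg$min_cells_per_type,
                     mito_fraction_max = cfg$mito_fraction_max),
    error = function(e) stop("deconvolve [preprocess]: ", conditionMessage(e)))
  scn <- if (cfg$normalize %in% c("sc", "both")) normalize_cells(qc$sc) else qc$sc
  stq <- qc$st
  if (cfg$normalize %in% c("st", "both")) {
    tot <- rowSums(stq$counts); tot[tot == 0] <- 1
    stq <- st_data(stq$counts / tot, coordinates = stq$coordinates,
                   gene_names = stq$gene_names, spot_ids = stq$spot_ids)
  }

  single_type <- length(unique(scn$cell_types)) < 2L
  markers <- if (single_type) {
    ms <- list(scn$gene_names); names(ms) <- unique(scn$cell_types); ms
  } else {
    select_marker_genes(scn, top_n = cfg$top_n, top_frac = cfg$top_frac)
  }
  genes <- unique(unlist(markers))
  profile <- build_celltype_profile(scn, genes, marker_sets = markers)
  X <- tryCatch(align_and_stack(profile, stq),
                error = function(e) stop("deconvolve [preprocess]: ",
                                         conditionMessage(e)))

  vae <- tryCatch(
    train_vae(X, latent_dim = cfg$latent_dim, hidden_dim = cfg$vae_hidden,
              epochs = cfg$vae_epochs, lr = cfg$vae_lr,
              seed = derive_seed(cfg$seed, 1L),
              input_scaling = cfg$vae_input_scaling),
    error = function(e) stop("deconvolve [coembed]: ", conditionMessage(e)))
  Z <- vae_encode(vae, X)

  graph <- tryCatch(
    build_link_graph(Z, k = cfg$k, max_scope = cfg$max_scope),
    error = function(e) stop("deconvolve [linkgraph]: ", conditionMessage(e)))

  fit <- tryCatch(
    fit_cogcn(X, graph, hidden = cfg$gcn_hidden, epochs = cfg$gcn_epochs,
              lr = cfg$gcn_lr, seed = derive_seed(cfg$seed, 2L),
              feature_scaling = cfg$gcn_feature_scaling,
              n_init = cfg$gcn_n_init),
    error = function(e) stop("deconvolve [cogcn]: ", conditionMessage(e)))

  structure(
    list(M = fit$M$M, M_raw = fit$M$M_raw,
         C = X$X[X$node_roles == "celltype", , drop = FALSE],
         S = X$X[X$node_roles == "spot", , drop = FALSE],
         genes = X$gene_names,
         type_names = X$type_names, spot_ids = X$spot_ids,
         markers = markers, profile = profile,
         vae = vae, embedding = Z, graph = graph,
         gcn = fit$model, log = fit$log,
         sc = scn, st = stq,
         coordinates = stq$coordinates,
         config = cfg),
    class = "spot_deconv"
  )
}

#' @export
print.spot_deconv <- function(x, ...) {
  cat(sprintf("spot_deconv: %d spots deconvolved into %d cell types over %d genes\n",
              nrow(x$M), ncol(x$M), length(x$genes)))
  cat(sprintf("  final self-supervised loss: %.4f (epoch %d)\n",
              x$log$loss[nrow(x$log)], nrow(x$log)))
  invisible(x)
}

#' @export
summary.spot_deconv <- function(object, ...) {
  mp <- colMeans(object$M)
  out <- list(
    n_spots = nrow(object$M), n_types = ncol(object$M),
    n_genes = length(object$genes),
    mean_proportions = mp,
    dominant_type = table(factor(object$type_names[max.col(object$M, "first")],
                                 levels = object$type_names)),
    final_loss = object$log$loss[nrow(object$log)]
  )
  class(out) <- "summary.spot_deconv"
  out
}

#' @export
print.summary.spot_deconv <- function(x, ...) {
  cat(sprintf("Deconvolution of %d spots into %d cell types (%d genes)\n",
              x$n_spots, x$n_types, x$n_genes))
  cat(sprintf("Final loss: %.4f\n", x$final_loss))
  cat("Mean cell-type proportions:\n")
  print(round(x$mean_proportions, 4))
  cat("Spots per dominant cell type:\n")
  print(x$dominant_type)
  invisible(x)
}

#' Extract the mapping matrix of a fitted deconvolution
#'
#' @param object a `spot_deconv` fit.
#' @param ... unused.
#' @return the row-stochastic spots x cell-types matrix.
#' @export
coef.spot_deconv <- function(object, ...) object$M

#' @export
fitted.spot_deconv <- function(object, ...) object$M %*% object$C

#' @export
residuals.spot_deconv <- function(object, ...) object$S - fitted(object)

#' Predict spot expression for arbitrary gene profiles
#'
#' Applies the fitted mapping matrix to a cell-type profile, recovering the
#' spatial distribution of any gene present in the profile — including genes
#' never seen during training.
#'
#' @param object a `spot_deconv` fit.
#' @param profile a `celltype_profile` (or matrix with cell types in rows);
#'   defaults to the training profile.
#' @param ... unused.
#' @return spots x genes matrix of predicted expression.
#' @export
predict.spot_deconv <- function(object, profile = NULL, ...) {
  if (is.null(profile)) return(fitted(object))
  recover_genes(object, profile)
}

#' @export
plot.spot_deconv <- function(x, type = NULL, ...) {
  if (is.null(x$coordinates)) {
    graphics::barplot(colMeans(x$M), las = 2,
                      ylab = "mean proportion",
                      main = "Mean cell-type proportions")
  } else {
    type <- type %||% x$type_names[1]
    p <- x$M[, type]
    cols <- grDevices::gray(1 - p / max(p, 1e-12))
    graphics::plot(x$coordinates[, "x"], x$coordinates[, "y"],
         pch = 16, col = cols,
         xlab = "x", ylab = "y",
         main = sprintf("Proportion of %s per spot", type), ...)
  }
  invisible(x)
}
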