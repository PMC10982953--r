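# Benchmark metrics for deconvolution and gene recovery: Pearson
# correlation, structural similarity, cosine similarity, RMSE,
# Jensen-Shannon divergence, average rank score, and the spatial
# expression correlation statistic.

#' Pearson correlation between two vectors
#'
#' Returns 0 when either vector has zero variance (the same convention used
#' by the training loss, avoiding NaN on constant vectors).
#'
#' @param a,b numeric vectors of equal length (>= 2).
#' @return correlation in `[-1, 1]`.
#' @export
metric_pcc <- function(a, b) {
  if (length(a) != length(b)) stop("metric_pcc: length mismatch")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Structural similarity between two non-negative vectors
#'
#' Each vector is first scaled by its own maximum (zero vectors are left as
#' zeros), then the scalar SSIM formula is applied with the means, population
#' variances and covariance of the scaled vectors and stabilisation
#' constants `alpha = 0.01`, `beta = 0.03` (entering squared).
#'
#' @param a,b non-negative numeric vectors of equal length.
#' @param alpha,beta stabilisation constants.
#' @return similarity value, at most 1.
#' @export
metric_ssim <- function(a, b, alpha = 0.01, beta = 0.03) {
  if (length(a) != length(b)) stop("metric_ssim: length mismatch")
  if (any(a < 0) || any(b < 0)) stop("metric_ssim: negative entries")
  n <- length(a)
  as <- if (max(a) > 0) a / max(a) else a
  bs <- if (max(b) > 0) b / max(b) else b
  mu1 <- mean(as); mu2 <- mean(bs)
  v1 <- sum((as - mu1)^2) / n
  v2 <- sum((bs - mu2)^2) / n
  cv <- sum((as - mu1) * (bs - mu2)) / n
  ((2 * mu1 * mu2 + alpha^2) * (2 * cv + beta^2)) /
    ((mu1^2 + mu2^2 + alpha^2) * (v1 + v2 + beta^2))
}

#' Cosine similarity between two vectors
#'
#' Returns 0 when either vector has zero norm.
#'
#' @param a,b numeric vectors of equal length.
#' @return cosine of the angle between the vectors; in `[0, 1]` for
#'   non-negative inputs.
#' @export
metric_cossim <- function(a, b) {
  if (length(a) != length(b)) stop("metric_cossim: length mismatch")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Root-mean-square error between two vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return non-negative RMSE.
#' @export
metric_rmse <- function(a, b) {
  if (length(a) != length(b)) stop("metric_rmse: length mismatch")
  sqrt(mean((a - b)^2))
}

#' Jensen-Shannon divergence between two distributions
#'
#' Both arguments are renormalised to sum to one when needed. With the
#' default base-2 logarithm the divergence lies in `[0, 1]`, reaching 1 for
#' distributions with disjoint support; `0 * log 0` is taken as 0.
#'
#' @param p,q non-negative vectors with positive sums.
#' @param base logarithm base (default 2).
#' @return divergence in `[0, 1]` (base 2).
#' @export
metric_jsd <- function(p, q, base = 2) {
  if (length(p) != length(q)) stop("metric_jsd: length mismatch")
  if (any(p < 0) || any(q < 0)) stop("metric_jsd: negative entries")
  sp <- sum(p); sq <- sum(q)
  if (sp <= 0 || sq <= 0) stop("metric_jsd: zero-sum distribution")
  p <- p / sp; q <- q / sq
  m <- (p + q) / 2
  kl <- function(x, y) {
    i <- x > 0
    sum(x[i] * log(x[i] / y[i], base = base))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Average rank score across methods
#'
#' Aggregates the five metric means of several methods into one score. For
#' each metric, methods are ranked so the best method receives rank `M`
#' (higher values rank higher for PCC/SSIM/COSSIM, lower values rank higher
#' for RMSE/JSD); ties receive averaged ranks. The score of a method is the
#' sum of its five ranks divided by `5 M`, so the uniformly best method
#' scores 1 and the uniformly worst `1/M`.
#'
#' @param metric_means data.frame or matrix with one row per method and
#'   columns `pcc`, `ssim`, `cossim`, `rmse`, `jsd`; row names identify the
#'   methods.
#' @return object of class `method_ranking`: the input means, the per-metric
#'   rank matrix and the `ars` vector.
#' @export
ars <- function(metric_means) {
  mm <- as.data.frame(metric_means)
  needed <- c("pcc", "ssim", "cossim", "rmse", "jsd")
  if (!all(needed %in% names(mm)))
    stop("ars: missing metric columns: ",
         paste(setdiff(needed, names(mm)), collapse = ", "))
  if (nrow(mm) < 2L) stop("ars: need at least two methods")
  M <- nrow(mm)
  ranks <- cbind(
    pcc = rank(mm$pcc), ssim = rank(mm$ssim), cossim = rank(mm$cossim),
    rmse = rank(-mm$rmse), jsd = rank(-mm$jsd)
  )
  rownames(ranks) <- rownames(mm)
  score <- rowSums(ranks) / (5 * M)
  structure(list(means = mm, ranks = ranks, ars = score, n_methods = M),
            class = "method_ranking")
}

#' @export
print.method_ranking <- function(x, ...) {
  cat("Average rank score over", x$n_methods, "methods:\n")
  print(round(sort(x$ars, decreasing = TRUE), 4))
  invisible(x)
}

metric_row <- function(a, b) {
  c(pcc = metric_pcc(a, b), ssim = metric_ssim(a, b),
    cossim = metric_cossim(a, b), rmse = metric_rmse(a, b),
    jsd = if (sum(a) > 0 && sum(b) > 0) metric_jsd(a, b) else NA_real_)
}

#' Per-spot evaluation of predicted cell-type proportions
#'
#' Computes PCC, SSIM, COSSIM, RMSE and JSD between the predicted and the
#' ground-truth proportion vector of every spot (cell types matched by
#' name), plus their means.
#'
#' @param M predicted proportions (`spot_deconv`, `mapping_matrix` or
#'   matrix with cell-type column names).
#' @param truth ground-truth proportions matrix with matching spot rows and
#'   cell-type columns.
#' @return object of class `metric_table`: data.frame of per-spot values
#'   with attribute `means`.
#' @export
evaluate_deconvolution <- function(M, truth) {
  Mm <- if (inherits(M, "spot_deconv")) M$M
        else if (inherits(M, "mapping_matrix")) M$M else as.matrix(M)
  truth <- as.matrix(truth)
  if (!is.null(colnames(Mm)) && !is.null(colnames(truth))) {
    unmatched <- union(setdiff(colnames(Mm), colnames(truth)),
                       setdiff(colnames(truth), colnames(Mm)))
    if (length(unmatched))
      stop("evaluate_deconvolution: unmatched cell types: ",
           paste(unmatched, collapse = ", "))
    truth <- truth[, colnames(Mm), drop = FALSE]
  }
  if (!is.null(rownames(Mm)) && !is.null(rownames(truth)) &&
      all(rownames(Mm) %in% rownames(truth)))
    truth <- truth[rownames(Mm), , drop = FALSE]
  if (!all(dim(Mm) == dim(truth)))
    stop("evaluate_deconvolution: dimension mismatch")
  vals <- t(vapply(seq_len(nrow(Mm)),
                   function(i) metric_row(Mm[i, ], truth[i, ]),
                   numeric(5)))
  out <- data.frame(unit = rownames(Mm) %||% as.character(seq_len(nrow(Mm))),
                    vals)
  attr(out, "means") <- colMeans(vals, na.rm = TRUE)
  class(out) <- c("metric_table", "data.frame")
  out
}

#' Per-gene evaluation of recovered expression
#'
#' Computes the five metrics between the predicted and observed expression
#' of each shared gene across spots. For JSD each gene's expression vector
#' is renormalised to a distribution over spots; genes whose observed or
#' predicted vector sums to zero get `NA` there.
#'
#' @param pred spots x genes predicted expression matrix.
#' @param observed an [st_data] object (or spots x genes matrix).
#' @return `metric_table` with one row per gene and attribute `means`.
#' @export
evaluate_gene_recovery <- function(pred, observed) {
  obs <- if (inherits(observed, "st_data")) observed$counts else as.matrix(observed)
  pred <- as.matrix(pred)
  shared <- intersect(colnames(pred), colnames(obs))
  if (length(shared) == 0L) {
    if (ncol(pred) == ncol(obs)) shared <- NULL
    else stop("evaluate_gene_recovery: no shared genes")
  }
  if (!is.null(shared)) {
    pred <- pred[, shared, drop = FALSE]
    obs <- obs[, shared, drop = FALSE]
  }
  if (!is.null(rownames(pred)) && !is.null(rownames(obs)) &&
      all(rownames(pred) %in% rownames(obs)))
    obs <- obs[rownames(pred), , drop = FALSE]
  vals <- t(vapply(seq_len(ncol(pred)),
                   function(j) metric_row(pred[, j], obs[, j]),
                   numeric(5)))
  out <- data.frame(unit = colnames(pred) %||% as.character(seq_len(ncol(pred))),
                    vals)
  attr(out, "means") <- colMeans(vals, na.rm = TRUE)
  class(out) <- c("metric_table", "data.frame")
  out
}

#' @export
print.metric_table <- function(x, ...) {
  cat(sprintf("metric_table: %d units\n", nrow(x)))
  cat("means:\n")
  print(round(attr(x, "means"), 4))
  invisible(x)
}

#' Spatial expression correlation of a slide
#'
#' Quantifies the spatial structure of expression: for each radius multiple
#' `f`, every spot's expression profile is correlated (Pearson) with each
#' neighbour within `f * r`, the per-spot mean is taken, and the statistic is
#' the average over spots that have at least one neighbour. The base radius
#' `r` defaults to the median nearest-neighbour distance between spots.
#'
#' @param st an [st_data] object with coordinates (a
#'   `simulated_st` works too).
#' @param radius_multiples numeric vector of radius multiples (default
#'   `c(1, 2, 4)`).
#' @param base_radius optional absolute base radius overriding the median
#'   nearest-neighbour distance.
#' @return named numeric vector, one mean correlation per multiple, with
#'   attribute `n_spots_used` counting spots with neighbours per multiple.
#' @export
spatial_expression_correlation <- function(st, radius_multiples = c(1, 2, 4),
                                           base_radius = NULL) {
  if (inherits(st, "simulated_st")) st <- st$st
  stopifnot(inherits(st, "st_data"))
  if (is.null(st$coordinates))
    stop("spatial_expression_correlation: coordinates required")
  n <- nrow(st$counts)
  if (n < 2L) stop("spatial_expression_correlation: need at least two spots")
  D <- pairwise_dist(st$coordinates)
  diag(D) <- Inf
  r <- base_radius %||% stats::median(apply(D, 1, min))
  out <- numeric(length(radius_multiples))
  used <- integer(length(radius_multiples))
  names(out) <- names(used) <- paste0("r", radius_multiples)
  E <- st$counts
  for (k in seq_along(radius_multiples)) {
    rad <- radius_multiples[k] * r
    per_spot <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      nb <- which(D[i, ] <= rad)
      if (length(nb) == 0L) next
      per_spot[i] <- mean(vapply(nb, function(j) metric_pcc(E[i, ], E[j, ]),
                                 numeric(1)))
    }
    used[k] <- sum(!is.na(per_spot))
    if (used[k] == 0L)
      stop("spatial_expression_correlation: no spot has a neighbour at multiple ",
           radius_multiples[k])
    out[k] <- mean(per_spot, na.rm = TRUE)
  }
  attr(out, "n_spots_used") <- used
  attr(out, "base_radius") <- r
  out
}
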