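# Two-layer co-graph convolution network: forward pass, the self-supervised
# correlation + cosine loss with analytic gradients, and the training loop.

#' Symmetric normalisation of the link-graph adjacency
#'
#' Computes `Ahat = D^{-1/2} (A + I) D^{-1/2}` where `D` is the diagonal
#' degree matrix of `A + I`; self-loops guarantee strictly positive degrees.
#' `degree_of = "A"` uses the degrees of `A` itself with an epsilon guard.
#'
#' @param A a `link_graph` or a symmetric non-negative matrix.
#' @param degree_of `"Atilde"` (default) or `"A"`.
#' @return symmetric matrix with spectral radius at most 1.
#' @export
normalize_adjacency <- function(A, degree_of = "Atilde") {
  if (inherits(A, "link_graph")) A <- A$A
  A <- as.matrix(A)
  if (any(A < 0)) stop("normalize_adjacency: negative entries")
  At <- A + diag(nrow(A))
  deg <- if (degree_of == "A") pmax(rowSums(A), 1e-12) else rowSums(At)
  dinv <- 1 / sqrt(deg)
  Ahat <- At * tcrossprod(dinv)
  dimnames(Ahat) <- dimnames(A)
  Ahat
}

# Library-size + log scaling of the network input features. Mixing
# per-cell-normalised profile rows with raw spot counts in one feature
# matrix is badly conditioned for a shared weight matrix; this puts all
# node features on a comparable log scale.
gcn_feature_transform <- function(Xm, feature_scaling) {
  switch(feature_scaling,
    lognorm = {
      tot <- rowSums(Xm)
      tot[tot == 0] <- 1
      log1p(Xm / tot * 1e4)
    },
    none = Xm,
    stop("unknown gcn feature scaling: ", feature_scaling)
  )
}

# Parameter initialisation for the two-layer network. The output layer is
# initialised two orders of magnitude below the He scale so every type
# column starts near softplus(0) — symmetric and equally active — which
# prevents individual output columns from dying early in training.
init_cogcn <- function(g, m, hidden = 64L, seed = 1L) {
  set.seed(seed)
  list(
    W0 = matrix(stats::rnorm(g * hidden, 0, sqrt(2 / g)), g, hidden),
    W1 = matrix(stats::rnorm(hidden * m, 0, 0.01 * sqrt(2 / hidden)),
                hidden, m)
  )
}

#' Forward pass of the co-graph convolution network
#'
#' Two propagation layers: `Y = softplus(Ahat relu(Ahat X W0) W1)`. Row count
#' is preserved; the softplus output transform keeps the raw mapping values
#' non-negative.
#'
#' When the model carries `feature_scaling = "lognorm"` (the training
#' default), rows of `X` are library-size normalised and log1p-transformed
#' before entering the first layer; this is a conditioning device internal
#' to the network — the self-supervised loss is always computed against the
#' untransformed matrices.
#'
#' @param X `stacked_matrix` or numeric matrix.
#' @param Ahat normalised adjacency from [normalize_adjacency()].
#' @param model list with weight matrices `W0` (g x h) and `W1` (h x m),
#'   optionally `feature_scaling`.
#' @return list with `Y` ((m+n) x m), and the intermediates `H1`, `pre`
#'   used for backpropagation.
#' @export
gcn_forward <- function(X, Ahat, model) {
  Xm <- if (inherits(X, "stacked_matrix")) X$X else as.matrix(X)
  if (nrow(Xm) != nrow(Ahat)) stop("gcn_forward: X/Ahat row mismatch")
  if (ncol(Xm) != nrow(model$W0)) stop("gcn_forward: X/W0 width mismatch")
  Xm <- gcn_feature_transform(Xm, model$feature_scaling %||% "none")
  AX <- Ahat %*% Xm
  H1 <- relu(AX %*% model$W0)
  pre <- (Ahat %*% H1) %*% model$W1
  list(Y = softplus(pre), H1 = H1, pre = pre, AX = AX)
}

#' Extract and row-normalise the spot block of the network output
#'
#' Takes the spot-to-celltype block of `Y`, and divides each row by its sum
#' so that predicted proportions are non-negative and sum to one. All-zero
#' rows (possible only in degenerate inputs) become uniform `1/m`.
#'
#' @param Y network output matrix (or the list from [gcn_forward()]).
#' @param node_roles per-row role flags; rows flagged `"spot"` are kept.
#' @return object of class `mapping_matrix`: row-stochastic matrix `M`
#'   (spots x cell types) plus the raw values `M_raw`.
#' @export
extract_and_normalize_mapping <- function(Y, node_roles) {
  if (is.list(Y)) Y <- Y$Y
  Mraw <- Y[node_roles == "spot", , drop = FALSE]
  s <- rowSums(Mraw)
  zero <- s <= 0
  M <- Mraw / ifelse(zero, 1, s)
  if (any(zero)) M[zero, ] <- 1 / ncol(Mraw)
  structure(list(M = M, M_raw = Mraw), class = "mapping_matrix")
}

# Vectorised Pearson correlation of matching columns of two matrices;
# zero-variance columns yield 0 by convention.
col_pcc <- function(P, S) {
  Pc <- sweep(P, 2, colMeans(P))
  Sc <- sweep(S, 2, colMeans(S))
  np <- sqrt(colSums(Pc^2)); ns <- sqrt(colSums(Sc^2))
  ok <- np > 0 & ns > 0
  r <- numeric(ncol(P))
  r[ok] <- colSums(Pc[, ok, drop = FALSE] * Sc[, ok, drop = FALSE]) /
    (np[ok] * ns[ok])
  list(r = r, Pc = Pc, Sc = Sc, np = np, ns = ns, ok = ok)
}

col_cossim <- function(P, S) {
  np <- sqrt(colSums(P^2)); ns <- sqrt(colSums(S^2))
  ok <- np > 0 & ns > 0
  cs <- numeric(ncol(P))
  cs[ok] <- colSums(P[, ok, drop = FALSE] * S[, ok, drop = FALSE]) /
    (np[ok] * ns[ok])
  list(cs = cs, np = np, ns = ns, ok = ok)
}

# Loss of Eq-style self-supervision and its gradient with respect to P = MC.
# L = (1/g) sum_cols [(1-PCC)+(1-COSSIM)] + (1/n) sum_rows [(1-PCC)+(1-COSSIM)]
loss_and_grad_P <- function(P, S) {
  g <- ncol(P); n <- nrow(P)
  G <- matrix(0, n, g)

  cp <- col_pcc(P, S)
  cc <- col_cossim(P, S)
  loss_cols <- sum(2 - cp$r - cc$cs) / g
  ok <- cp$ok
  if (any(ok)) {
    gr <- sweep(cp$Sc[, ok, drop = FALSE], 2, cp$np[ok] * cp$ns[ok], "/") -
      sweep(cp$Pc[, ok, drop = FALSE], 2, cp$r[ok] / cp$np[ok]^2, "*")
    G[, ok] <- G[, ok] - gr / g
  }
  ok <- cc$ok
  if (any(ok)) {
    gr <- sweep(S[, ok, drop = FALSE], 2, cc$np[ok] * cc$ns[ok], "/") -
      sweep(P[, ok, drop = FALSE], 2, cc$cs[ok] / cc$np[ok]^2, "*")
    G[, ok] <- G[, ok] - gr / g
  }

  tP <- t(P); tS <- t(S)
  rp <- col_pcc(tP, tS)
  rc <- col_cossim(tP, tS)
  loss_rows <- sum(2 - rp$r - rc$cs) / n
  Gt <- matrix(0, g, n)
  ok <- rp$ok
  if (any(ok)) {
    gr <- sweep(rp$Sc[, ok, drop = FALSE], 2, rp$np[ok] * rp$ns[ok], "/") -
      sweep(rp$Pc[, ok, drop = FALSE], 2, rp$r[ok] / rp$np[ok]^2, "*")
    Gt[, ok] <- Gt[, ok] - gr / n
  }
  ok <- rc$ok
  if (any(ok)) {
    gr <- sweep(tS[, ok, drop = FALSE], 2, rc$np[ok] * rc$ns[ok], "/") -
      sweep(tP[, ok, drop = FALSE], 2, rc$cs[ok] / rc$np[ok]^2, "*")
    Gt[, ok] <- Gt[, ok] - gr / n
  }
  list(loss = loss_cols + loss_rows, grad = G + t(Gt))
}

#' Self-supervised reconstruction loss of a mapping matrix
#'
#' Measures how far the reconstructed spot expression `M C` is from the
#' observed spot matrix `S`: the mean over genes of `(1 - PCC) + (1 -
#' COSSIM)` between matching gene columns plus the mean over spots of the
#' same quantity between matching spot rows. Both similarities are
#' scale-free, so the loss is invariant to positive rescaling of `S`.
#' Zero-variance (or zero-norm) vectors contribute a similarity of 0.
#'
#' @param M a `mapping_matrix` (or plain n x m matrix).
#' @param C a `celltype_profile` (or plain m x g matrix).
#' @param S an [st_data] (or plain n x g matrix) over the same genes.
#' @return non-negative scalar loss.
#' @export
reconstruction_loss <- function(M, C, S) {
  Mm <- if (inherits(M, "mapping_matrix")) M$M else as.matrix(M)
  Cm <- if (inherits(C, "celltype_profile")) C$profile else as.matrix(C)
  Sm <- if (inherits(S, "st_data")) S$counts else as.matrix(S)
  if (ncol(Mm) != nrow(Cm)) stop("reconstruction_loss: M/C dimension mismatch")
  if (!all(dim(Sm) == c(nrow(Mm), ncol(Cm))))
    stop("reconstruction_loss: S dimension mismatch")
  P <- Mm %*% Cm
  l <- loss_and_grad_P(P, Sm)$loss
  if (!is.finite(l)) stop("reconstruction_loss: non-finite loss")
  l
}

#' Fit the co-graph convolution network
#'
#' Trains the two layer weights by full-graph Adam on the self-supervised
#' loss of [reconstruction_loss()], with the embedding and link graph held
#' fixed. The mapping matrix from the final epoch is returned.
#'
#' @param X `stacked_matrix` (cell-type block on top of the spot block).
#' @param A `link_graph` (or raw adjacency matrix).
#' @param C cell-type profile matrix aligned to `X`'s genes (defaults to the
#'   cell-type block of `X`).
#' @param S spot matrix aligned to `X`'s genes (defaults to the spot block).
#' @param hidden hidden width (default 64).
#' @param epochs gradient steps (default 2000).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed integer seed for weight initialisation.
#' @param feature_scaling `"lognorm"` (default) applies library-size + log1p
#'   scaling to the network input rows (the loss still compares against the
#'   raw matrices); `"none"` feeds the stacked matrix as is.
#' @param n_init number of random restarts; the run with the lowest final
#'   self-supervised loss is kept (the loss needs no ground truth, so this
#'   is ordinary model selection). Default 1.
#' @param verbose print loss every 200 epochs.
#' @return list with `M` (a `mapping_matrix`), `model` (weights), and `log`
#'   (data.frame of per-epoch loss); with restarts, `log` is that of the
#'   winning run and `restart_losses` records every final loss.
#' @export
fit_cogcn <- function(X, A, C = NULL, S = NULL, hidden = 64L, epochs = 2000L,
                      lr = 1e-3, seed = 1L, feature_scaling = "lognorm",
                      n_init = 1L, verbose = FALSE) {
  if (n_init > 1L) {
    runs <- lapply(seq_len(n_init), function(i) {
      fit_cogcn(X, A, C = C, S = S, hidden = hidden, epochs = epochs,
                lr = lr, seed = derive_seed(seed, 1000L + i),
                feature_scaling = feature_scaling, n_init = 1L,
                verbose = verbose)
    })
    finals <- vapply(runs, function(r) r$log$loss[nrow(r$log)], numeric(1))
    best <- runs[[which.min(finals)]]
    best$restart_losses <- finals
    return(best)
  }
  stopifnot(inherits(X, "stacked_matrix"))
  roles <- X$node_roles
  m <- X$m; n <- X$n; g <- ncol(X$X)
  Cm <- if (is.null(C)) X$X[roles == "celltype", , drop = FALSE] else {
    if (inherits(C, "celltype_profile")) C$profile else as.matrix(C)
  }
  Sm <- if (is.null(S)) X$X[roles == "spot", , drop = FALSE] else {
    if (inherits(S, "st_data")) S$counts else as.matrix(S)
  }
  Ahat <- normalize_adjacency(A)
  model <- init_cogcn(g, m, hidden = hidden, seed = seed)
  st <- adam_init(model)
  AX <- Ahat %*% gcn_feature_transform(X$X, feature_scaling)
  spot_rows <- which(roles == "spot")
  tC <- t(Cm)
  losses <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    H1 <- relu(AX %*% model$W0)
    AH1 <- Ahat %*% H1
    pre <- AH1 %*% model$W1
    Y <- softplus(pre)
    Mraw <- Y[spot_rows, , drop = FALSE]
    s <- rowSums(Mraw)
    zero <- s <= 0
    sdiv <- ifelse(zero, 1, s)
    M <- Mraw / sdiv
    if (any(zero)) M[zero, ] <- 1 / m

    P <- M %*% Cm
    lg <- loss_and_grad_P(P, Sm)
    losses[ep] <- lg$loss
    if (!is.finite(lg$loss))
      stop("fit_cogcn: non-finite loss at epoch ", ep)

    GM <- lg$grad %*% tC                       # dL/dM
    # through row normalisation M = Mraw / s
    inner <- rowSums(GM * M)
    GMraw <- (GM - inner) / sdiv
    if (any(zero)) GMraw[zero, ] <- 0
    # through softplus and into the graph layers
    dpre <- matrix(0, m + n, m)
    dpre[spot_rows, ] <- GMraw * sigmoid(pre[spot_rows, , drop = FALSE])
    gW1 <- crossprod(AH1, dpre)
    dH1 <- (Ahat %*% (dpre %*% t(model$W1))) * (H1 > 0)
    gW0 <- crossprod(AX, dH1)

    upd <- adam_step(model, list(W0 = gW0, W1 = gW1), st, lr = lr)
    model <- upd$params; st <- upd$state
    if (verbose && ep %% 200L == 0L)
      message(sprintf("epoch %d  loss %.5f", ep, lg$loss))
  }

  model$feature_scaling <- feature_scaling
  fwd <- gcn_forward(X, Ahat, model)
  Mfinal <- extract_and_normalize_mapping(fwd$Y, roles)
  dimnames(Mfinal$M) <- list(X$spot_ids, X$type_names)
  dimnames(Mfinal$M_raw) <- dimnames(Mfinal$M)
  list(M = Mfinal,
       model = c(model[c("W0", "W1")],
                 list(hidden = hidden, seed = seed,
                      feature_scaling = feature_scaling)),
       log = data.frame(epoch = seq_len(epochs), loss = losses))
}
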