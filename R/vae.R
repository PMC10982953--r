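# Variational autoencoder co-embedding of cell-type and spot nodes.
#
# A single-hidden-layer Gaussian VAE trained full-batch with Adam and
# analytic gradients. The posterior mean is used downstream so the link
# graph is a deterministic function of the trained model.

#' Closed-form terms of the evidence lower bound
#'
#' Returns the Gaussian reconstruction loss and the Kullback-Leibler
#' divergence of a diagonal-Gaussian posterior from the standard-normal
#' prior. For vector inputs the terms are sums over dimensions; for matrix
#' inputs they are means over rows of the per-row sums.
#'
#' @param x observed input (vector or matrix).
#' @param reconstruction decoder output, same shape as `x`.
#' @param mu,sigma2 posterior mean and variance, same shape; `sigma2 > 0`.
#' @return list with `reconstruction_loss` and `kl`, both finite scalars.
#' @export
elbo_terms <- function(x, reconstruction, mu, sigma2) {
  if (any(sigma2 <= 0)) stop("elbo_terms: sigma2 must be positive")
  if (!all(dim(as.matrix(x)) == dim(as.matrix(reconstruction))))
    stop("elbo_terms: shape mismatch between x and reconstruction")
  nrows <- if (is.matrix(x)) nrow(x) else 1L
  recon <- 0.5 * sum((x - reconstruction)^2) / nrows
  kl <- 0.5 * sum(mu^2 + sigma2 - 1 - log(sigma2)) / nrows
  if (!is.finite(recon) || !is.finite(kl))
    stop("elbo_terms: non-finite ELBO term")
  list(reconstruction_loss = recon, kl = kl)
}

# Row scaling applied before encoding. The graph network still consumes the
# raw stacked matrix; this transform exists only inside the embedding.
vae_input_transform <- function(X, scaling) {
  switch(scaling,
    lognorm = {
      tot <- rowSums(X)
      tot[tot == 0] <- 1
      log1p(X / tot * 1e4)
    },
    log1p = log1p(X),
    none = X,
    stop("unknown vae input scaling: ", scaling)
  )
}

#' Train the co-embedding variational autoencoder
#'
#' Fits a Gaussian VAE (one hidden layer in encoder and decoder, rectifier
#' activations, diagonal posterior, standard-normal prior) on the rows of the
#' stacked matrix, treating cell-type and spot rows as draws from one mixture
#' without distinguishing their source. Training maximises the ELBO
#' (reconstruction term minus KL penalty) by full-batch Adam. Identical seed
#' and input give bitwise-identical parameters.
#'
#' @param X a `stacked_matrix` or a plain numeric matrix (rows = nodes).
#' @param latent_dim embedding dimensionality (default 30).
#' @param hidden_dim hidden-layer width (default 512).
#' @param epochs full-batch gradient steps (default 1000).
#' @param lr Adam learning rate (default 5e-4).
#' @param seed integer seed controlling initialisation and the
#'   reparameterisation noise.
#' @param input_scaling `"lognorm"` (library-size normalise each row to 1e4
#'   then log1p; default), `"log1p"`, or `"none"`.
#' @return object of class `vae_model` with the trained parameters, the loss
#'   trace (`$log`, one row per epoch with reconstruction and KL terms) and
#'   the configuration.
#' @export
train_vae <- function(X, latent_dim = 30L, hidden_dim = 512L, epochs = 1000L,
                      lr = 5e-4, seed = 1L, input_scaling = "lognorm") {
  Xm <- if (inherits(X, "stacked_matrix")) X$X else as.matrix(X)
  if (nrow(Xm) < 2L) stop("train_vae: need at least two rows")
  if (any(!is.finite(Xm))) stop("train_vae: non-finite input")
  if (latent_dim < 2L) stop("train_vae: latent_dim must be >= 2")
  Xt <- vae_input_transform(Xm, input_scaling)
  N <- nrow(Xt); G <- ncol(Xt)
  H <- hidden_dim; D <- latent_dim

  set.seed(seed)
  rinit <- function(fi, fo) matrix(stats::rnorm(fi * fo, 0, sqrt(2 / fi)), fi, fo)
  par <- list(
    We = rinit(G, H), be = rep(0, H),
    Wmu = rinit(H, D), bmu = rep(0, D),
    Wlv = matrix(0, H, D), blv = rep(0, D),
    Wd1 = rinit(D, H), bd1 = rep(0, H),
    Wd2 = rinit(H, G), bd2 = rep(0, G)
  )
  st <- adam_init(par)
  logr <- matrix(NA_real_, epochs, 3,
                 dimnames = list(NULL, c("loss", "reconstruction", "kl")))

  for (ep in seq_len(epochs)) {
    H1 <- relu(sweep(Xt %*% par$We, 2, par$be, "+"))
    mu <- sweep(H1 %*% par$Wmu, 2, par$bmu, "+")
    lv <- sweep(H1 %*% par$Wlv, 2, par$blv, "+")
    lv <- pmin(pmax(lv, -15), 15)
    sdv <- exp(0.5 * lv)
    epsn <- matrix(stats::rnorm(N * D), N, D)
    z <- mu + sdv * epsn
    Hd <- relu(sweep(z %*% par$Wd1, 2, par$bd1, "+"))
    xhat <- sweep(Hd %*% par$Wd2, 2, par$bd2, "+")

    recon <- 0.5 * sum((xhat - Xt)^2) / N
    kl <- 0.5 * sum(mu^2 + exp(lv) - 1 - lv) / N
    loss <- recon + kl
    if (!is.finite(loss))
      stop("train_vae: non-finite loss at epoch ", ep)
    logr[ep, ] <- c(loss, recon, kl)

    dxhat <- (xhat - Xt) / N
    gWd2 <- crossprod(Hd, dxhat); gbd2 <- colSums(dxhat)
    dHd <- tcrossprod(dxhat, par$Wd2) * (Hd > 0)
    gWd1 <- crossprod(z, dHd); gbd1 <- colSums(dHd)
    dz <- dHd %*% t(par$Wd1)
    dmu <- dz + mu / N
    dlv <- 0.5 * dz * epsn * sdv + 0.5 * (exp(lv) - 1) / N
    gWmu <- crossprod(H1, dmu); gbmu <- colSums(dmu)
    gWlv <- crossprod(H1, dlv); gblv <- colSums(dlv)
    dH1 <- (dmu %*% t(par$Wmu) + dlv %*% t(par$Wlv)) * (H1 > 0)
    gWe <- crossprod(Xt, dH1); gbe <- colSums(dH1)

    grads <- list(We = gWe, be = gbe, Wmu = gWmu, bmu = gbmu,
                  Wlv = gWlv, blv = gblv, Wd1 = gWd1, bd1 = gbd1,
                  Wd2 = gWd2, bd2 = gbd2)
    upd <- adam_step(par, grads, st, lr = lr)
    par <- upd$params; st <- upd$state
  }

  structure(
    list(params = par, latent_dim = D, hidden_dim = H, input_dim = G,
         input_scaling = input_scaling, seed = seed, lr = lr,
         epochs = epochs, log = as.data.frame(logr)),
    class = "vae_model"
  )
}

#' Encode rows into the latent co-embedding space
#'
#' Returns the posterior mean of each row under the trained encoder; no
#' sampling is involved, so the embedding is a pure function of the model and
#' the input.
#'
#' @param model a trained [train_vae()] model.
#' @param X `stacked_matrix` or numeric matrix with `model$input_dim` columns.
#' @return object of class `latent_embedding`: matrix `Z` (rows x latent_dim)
#'   plus `node_roles` when available from `X`.
#' @export
vae_encode <- function(model, X) {
  stopifnot(inherits(model, "vae_model"))
  roles <- NULL
  if (inherits(X, "stacked_matrix")) {
    roles <- X$node_roles
    Xm <- X$X
  } else Xm <- as.matrix(X)
  if (ncol(Xm) != model$input_dim)
    stop("vae_encode: input width ", ncol(Xm), " does not match model width ",
         model$input_dim)
  Xt <- vae_input_transform(Xm, model$input_scaling)
  H1 <- relu(sweep(Xt %*% model$params$We, 2, model$params$be, "+"))
  Z <- sweep(H1 %*% model$params$Wmu, 2, model$params$bmu, "+")
  rownames(Z) <- rownames(Xm)
  structure(list(Z = Z, node_roles = roles), class = "latent_embedding")
}

#' @export
print.vae_model <- function(x, ...) {
  cat(sprintf("vae_model: %d -> %d -> %d, %d epochs, final loss %.4g\n",
              x$input_dim, x$hidden_dim, x$latent_dim, x$epochs,
              x$log$loss[x$epochs]))
  invisible(x)
}
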