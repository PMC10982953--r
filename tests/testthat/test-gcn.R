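# Adjacency normalisation, forward propagation, mapping extraction, the
# self-supervised loss, analytic gradients and small-scale fitting.

test_that("adjacency normalisation matches hand computations and is bounded", {
  expect_equal(normalize_adjacency(matrix(0, 1, 1)), matrix(1, 1, 1))
  # two nodes, weight-1 edge: Atilde = [[1,1],[1,1]], degrees 2 -> all 0.5
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalize_adjacency(A2), matrix(0.5, 2, 2))
  set.seed(14)
  W <- matrix(runif(49), 7, 7); W <- (W + t(W)) / 2; diag(W) <- 0
  Ahat <- normalize_adjacency(W)
  expect_equal(Ahat, t(Ahat))
  expect_lte(max(abs(eigen(Ahat, symmetric = TRUE)$values)), 1 + 1e-12)
  expect_error(normalize_adjacency(-A2), "negative")
})

test_that("forward pass matches a hand-computed two-layer propagation", {
  X <- toy_stacked(m = 2, n = 3, g = 3, seed = 2)
  A <- matrix(0, 5, 5)
  A[1, 3] <- A[3, 1] <- 0.6; A[3, 4] <- A[4, 3] <- 0.4
  A[2, 5] <- A[5, 2] <- 1
  Ahat <- normalize_adjacency(A)
  model <- spotGCN:::init_cogcn(3, 2, hidden = 4, seed = 5)
  out <- gcn_forward(X, Ahat, model)
  # manual propagation with plain matrix algebra
  H1 <- pmax(Ahat %*% X$X %*% model$W0, 0)
  pre <- Ahat %*% H1 %*% model$W1
  manual <- log1p(exp(-abs(pre))) + pmax(pre, 0)
  expect_equal(out$Y, manual, tolerance = 1e-12)
  expect_equal(nrow(out$Y), 5)          # row count preserved
  expect_error(gcn_forward(X, Ahat[1:4, 1:4], model), "mismatch")
})

test_that("forward pass is equivariant to node permutation", {
  X <- toy_stacked(m = 2, n = 4, g = 3, seed = 8)
  set.seed(3)
  A <- matrix(runif(36), 6, 6); A <- (A + t(A)) / 2; diag(A) <- 0
  A[1:2, 1:2] <- 0
  model <- spotGCN:::init_cogcn(3, 2, hidden = 4, seed = 1)
  Y1 <- gcn_forward(X, normalize_adjacency(A), model)$Y
  p <- c(2, 1, 5, 3, 6, 4)
  Xp <- X; Xp$X <- X$X[p, ]; Xp$node_roles <- X$node_roles[p]
  Yp <- gcn_forward(Xp, normalize_adjacency(A[p, p]), model)$Y
  expect_equal(Yp, Y1[p, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("mapping extraction yields row-stochastic matrices with edge cases", {
  Y <- rbind(c(1, 1), c(2, 2), c(0, 3), c(0, 0))
  roles <- c("celltype", "spot", "spot", "spot")
  M <- extract_and_normalize_mapping(Y, roles)
  expect_equal(M$M[1, ], c(0.5, 0.5))
  expect_equal(M$M[2, ], c(0, 1))
  expect_equal(M$M[3, ], c(0.5, 0.5))   # all-zero row -> uniform
  expect_equal(rowSums(M$M), rep(1, 3))
})

test_that("reconstruction loss has its analytic zeros and scale invariance", {
  set.seed(21)
  M <- matrix(runif(12), 4, 3); M <- M / rowSums(M)
  C <- matrix(runif(15, 0.5, 2), 3, 5)
  S <- M %*% C
  expect_equal(reconstruction_loss(M, C, S), 0, tolerance = 1e-9)
  expect_equal(reconstruction_loss(M, C, 2 * S), 0, tolerance = 1e-9)
  S2 <- S + matrix(runif(20), 4, 5)
  expect_gt(reconstruction_loss(M, C, S2), 0)
  expect_equal(reconstruction_loss(M, C, 3 * S2),
               reconstruction_loss(M, C, S2), tolerance = 1e-9)
})

test_that("loss matches a scalar-by-scalar hand computation", {
  M <- rbind(c(1, 0), c(0.5, 0.5), c(0.2, 0.8))
  C <- rbind(c(4, 0), c(0, 2))
  S <- rbind(c(3, 1), c(2, 2), c(1, 2))
  P <- M %*% C
  per <- function(a, b) {
    pcc <- if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
    cs <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    (1 - pcc) + (1 - cs)
  }
  manual <- mean(sapply(1:2, function(j) per(P[, j], S[, j]))) +
    mean(sapply(1:3, function(i) per(P[i, ], S[i, ])))
  expect_equal(reconstruction_loss(M, C, S), manual, tolerance = 1e-12)
})

test_that("analytic gradient of the loss agrees with finite differences", {
  lgP <- spotGCN:::loss_and_grad_P
  set.seed(33)
  n <- 5; g <- 4
  P <- matrix(runif(n * g, 0.2, 2), n, g)
  S <- matrix(runif(n * g, 0.2, 2), n, g)
  lg <- lgP(P, S)
  h <- 1e-6
  for (idx in sample(n * g, 8)) {
    Pp <- P; Pp[idx] <- Pp[idx] + h
    Pm <- P; Pm[idx] <- Pm[idx] - h
    expect_equal(lg$grad[idx], (lgP(Pp, S)$loss - lgP(Pm, S)$loss) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("fitting decreases the loss deterministically and recovers pure spots", {
  sc <- tiny_sc()
  scn <- normalize_cells(sc)
  prof <- build_celltype_profile(scn, scn$gene_names)
  # pure spots: each spot is a sum of cells from a single type
  set.seed(44)
  types <- sort(unique(sc$cell_types))
  spots <- t(vapply(rep(types, each = 10), function(t) {
    cells <- sample(which(sc$cell_types == t), 6, replace = TRUE)
    colSums(sc$counts[cells, , drop = FALSE])
  }, numeric(ncol(sc$counts))))
  rownames(spots) <- paste0("s", seq_len(nrow(spots)))
  st <- st_data(spots, gene_names = sc$gene_names)
  X <- align_and_stack(prof, st)
  vae <- train_vae(X, latent_dim = 8, hidden_dim = 32, epochs = 80, seed = 2)
  graph <- build_link_graph(vae_encode(vae, X), k = 5)
  fit1 <- fit_cogcn(X, graph, epochs = 400, seed = 3)
  fit2 <- fit_cogcn(X, graph, epochs = 400, seed = 3)
  expect_identical(fit1$M$M, fit2$M$M)            # seeded determinism
  expect_lt(fit1$log$loss[400], fit1$log$loss[1]) # optimisation progress
  expect_true(all(is.finite(fit1$log$loss)))
  expect_true(all(fit1$M$M >= 0))
  expect_equal(rowSums(fit1$M$M), rep(1, 30), tolerance = 1e-6,
               ignore_attr = TRUE)
  truth_type <- rep(types, each = 10)
  called <- colnames(fit1$M$M)[max.col(fit1$M$M)]
  expect_gte(mean(called == truth_type), 0.95)
})
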