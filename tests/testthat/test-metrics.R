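# Metric implementations against independent scalar oracles and their
# analytic properties.

test_that("all five metrics agree with independent scalar oracles", {
  set.seed(123)
  for (rep in 1:100) {
    k <- sample(3:12, 1)
    a <- runif(k); b <- runif(k)
    expect_equal(metric_pcc(a, b), oracle_pcc(a, b), tolerance = 1e-10)
    expect_equal(metric_ssim(a, b), oracle_ssim(a, b), tolerance = 1e-10)
    expect_equal(metric_cossim(a, b), oracle_cossim(a, b), tolerance = 1e-10)
    expect_equal(metric_rmse(a, b), oracle_rmse(a, b), tolerance = 1e-10)
    expect_equal(metric_jsd(a, b), oracle_jsd(a, b), tolerance = 1e-10)
  }
})

test_that("metric identities and boundary conventions hold", {
  a <- c(1, 2, 3); b <- c(2, 4, 7)
  expect_equal(metric_pcc(a, a), 1)
  expect_equal(metric_pcc(a, -a), -1)
  expect_equal(metric_pcc(a, b), cor(a, b), tolerance = 1e-12)
  expect_equal(metric_pcc(rep(1, 3), b), 0)  # zero-variance convention

  expect_equal(metric_ssim(a, a), 1, tolerance = 1e-12)
  expect_equal(metric_ssim(a, 3 * a), 1, tolerance = 1e-12)  # max-scaling

  expect_equal(metric_cossim(c(0.6, 0.8), c(1, 0)), 0.6, tolerance = 1e-12)
  expect_equal(metric_cossim(c(1, 0), c(0, 1)), 0)
  expect_equal(metric_cossim(c(0, 0, 0), b), 0)

  expect_equal(metric_rmse(a, a), 0)
  expect_equal(metric_rmse(c(1, 0), c(0, 1)), 1)

  expect_equal(metric_jsd(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(metric_jsd(c(1, 0), c(0, 1)), 1)  # disjoint support, base 2
  p <- c(0.5, 0.5); q <- c(0.9, 0.1)
  expect_equal(metric_jsd(p, q), metric_jsd(q, p))
  expect_lte(metric_jsd(runif(5), runif(5)), 1)
})

test_that("pcc and cossim are scale-invariant while rmse is not", {
  set.seed(5)
  a <- runif(8); b <- runif(8)
  expect_equal(metric_pcc(3 * a, b), metric_pcc(a, b), tolerance = 1e-12)
  expect_equal(metric_cossim(a, 5 * b), metric_cossim(a, b), tolerance = 1e-12)
  expect_gt(abs(metric_rmse(2 * a, b) - metric_rmse(a, b)), 0)
})

test_that("average rank score matches hand-ranked tables", {
  mm <- data.frame(
    pcc = c(0.9, 0.5, 0.7), ssim = c(0.8, 0.4, 0.6),
    cossim = c(0.95, 0.6, 0.8), rmse = c(0.05, 0.3, 0.1),
    jsd = c(0.02, 0.4, 0.2),
    row.names = c("best", "worst", "mid"))
  r <- ars(mm)
  # best dominates: rank 3 everywhere -> 15/15; worst: 5/15; mid: 10/15
  expect_equal(unname(r$ars["best"]), 1)
  expect_equal(unname(r$ars["worst"]), 1 / 3)
  expect_equal(unname(r$ars["mid"]), 2 / 3)

  # dominating method among M = 10 scores 1, dominated scores 1/10
  set.seed(2)
  mm10 <- data.frame(pcc = runif(10, 0.2, 0.8), ssim = runif(10, 0.2, 0.8),
                     cossim = runif(10, 0.2, 0.8),
                     rmse = runif(10, 0.1, 0.5), jsd = runif(10, 0.1, 0.5))
  mm10[1, ] <- c(0.99, 0.99, 0.99, 0.01, 0.01)
  mm10[2, ] <- c(0.01, 0.01, 0.01, 0.99, 0.99)
  r10 <- ars(mm10)
  expect_equal(unname(r10$ars[1]), 1)
  expect_equal(unname(r10$ars[2]), 0.1)
})

test_that("ars is invariant to relabeling and monotone transforms", {
  set.seed(9)
  mm <- data.frame(pcc = runif(4), ssim = runif(4), cossim = runif(4),
                   rmse = runif(4), jsd = runif(4),
                   row.names = paste0("m", 1:4))
  r1 <- ars(mm)$ars
  perm <- c(3, 1, 4, 2)
  r2 <- ars(mm[perm, ])$ars
  expect_equal(r2[names(r1)], r1)
  mm2 <- mm
  mm2$pcc <- 2 * mm$pcc + 1          # monotone within a metric
  mm2$rmse <- exp(mm$rmse)
  expect_equal(ars(mm2)$ars, r1)
})

test_that("evaluate_deconvolution composes per-spot metric calls", {
  set.seed(31)
  truth <- matrix(runif(9), 3, 3)
  truth <- truth / rowSums(truth)
  dimnames(truth) <- list(paste0("s", 1:3), paste0("t", 1:3))
  pred <- matrix(runif(9), 3, 3); pred <- pred / rowSums(pred)
  dimnames(pred) <- dimnames(truth)

  mt <- evaluate_deconvolution(pred, truth)
  for (i in 1:3) {
    expect_equal(mt$pcc[i], metric_pcc(pred[i, ], truth[i, ]))
    expect_equal(mt$jsd[i], metric_jsd(pred[i, ], truth[i, ]))
  }
  ideal <- evaluate_deconvolution(truth, truth)
  expect_equal(unname(attr(ideal, "means")[c("pcc", "ssim", "cossim")]),
               c(1, 1, 1), tolerance = 1e-9)
  expect_equal(unname(attr(ideal, "means")[c("rmse", "jsd")]), c(0, 0),
               tolerance = 1e-12)

  # shuffling columns without relabeling degrades the metrics
  shuffled <- pred[, c(2, 3, 1)]
  colnames(shuffled) <- colnames(truth)
  expect_lt(attr(evaluate_deconvolution(shuffled, truth), "means")["cossim"],
            attr(mt, "means")["cossim"] + 1e-9)
  expect_error(evaluate_deconvolution(pred[, 1:2], truth), "unmatched")
})

test_that("evaluate_gene_recovery works per gene and flags scale error", {
  set.seed(12)
  obs <- matrix(rpois(40, 5), 8, 5,
                dimnames = list(paste0("s", 1:8), paste0("g", 1:5)))
  st <- st_data(obs)
  perfect <- evaluate_gene_recovery(obs, st)
  expect_equal(perfect$pcc, rep(1, 5), tolerance = 1e-9)
  expect_equal(perfect$rmse, rep(0, 5))
  doubled <- evaluate_gene_recovery(2 * obs, st)
  expect_equal(doubled$pcc, rep(1, 5), tolerance = 1e-9)
  expect_true(all(doubled$rmse > 0))
  for (j in 1:4) {
    one <- evaluate_gene_recovery(obs * 0.9, st)
    expect_equal(one$cossim[j], metric_cossim(0.9 * obs[, j], obs[, j]))
  }
})

test_that("spatial expression correlation detects structure and nulls", {
  # identical profiles -> correlation undefined per pair is 0 under the
  # zero-variance convention unless profiles vary; use two-zone slide
  set.seed(77)
  n_side <- 10
  coords <- expand.grid(x = 1:n_side, y = 1:n_side)
  zone <- ifelse(coords$x <= n_side / 2, 1, 2)
  base1 <- runif(30, 0, 5); base2 <- runif(30, 0, 5)
  zoned <- t(vapply(seq_len(nrow(coords)), function(i) {
    mu <- if (zone[i] == 1) base1 else base2
    rpois(30, mu + 0.1)
  }, numeric(30)))
  st_zoned <- st_data(zoned, coordinates = as.matrix(coords))
  sec <- spatial_expression_correlation(st_zoned)
  expect_gt(sec["r1"], sec["r4"])   # decay with radius

  iid <- matrix(rpois(nrow(coords) * 30, runif(nrow(coords) * 30, 0, 5)),
                nrow(coords), 30)
  st_iid <- st_data(iid, coordinates = as.matrix(coords))
  sec_iid <- spatial_expression_correlation(st_iid, radius_multiples = c(1, 2))
  expect_lt(abs(sec_iid["r1"]), 0.1)

  shared <- matrix(rep(rpois(30, 4), each = 9), 9, 30)
  st_same <- st_data(shared, coordinates = cbind(rep(1:3, 3), rep(1:3, each = 3)))
  expect_equal(unname(spatial_expression_correlation(st_same)["r1"]), 1)
})
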