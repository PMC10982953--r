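# Independent scalar oracle implementations used by unit and acceptance
# tests. Loop-based, written directly from the defining formulas, and kept
# separate from the package implementations they check.

oracle_pcc <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  if (da == 0 || db == 0) return(0)
  num / sqrt(da * db)
}
oracle_ssim <- function(a, b, al = 0.01, be = 0.03) {
  if (max(a) > 0) a <- a / max(a)
  if (max(b) > 0) b <- b / max(b)
  n <- length(a)
  m1 <- mean(a); m2 <- mean(b)
  v1 <- mean((a - m1)^2); v2 <- mean((b - m2)^2)
  cv <- mean((a - m1) * (b - m2))
  (2 * m1 * m2 + al^2) * (2 * cv + be^2) /
    ((m1^2 + m2^2 + al^2) * (v1 + v2 + be^2))
}
oracle_cossim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  s <- 0
  for (i in seq_along(a)) s <- s + a[i] * b[i]
  s / (na * nb)
}
oracle_rmse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s / length(a))
}
oracle_jsd <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + 0.5 * p[i] * log2(p[i] / m[i])
    if (q[i] > 0) s <- s + 0.5 * q[i] * log2(q[i] / m[i])
  }
  s
}


# Exhaustive oracle: mutual-NN edge set over roles, O(N^2) sorting.
oracle_link_graph <- function(Z, roles, k) {
  D <- as.matrix(dist(Z))
  n_all <- nrow(Z)
  ct <- which(roles == "celltype"); sp <- which(roles == "spot")
  topk <- function(i, cand) {
    cand <- setdiff(cand, i)
    cand[order(D[i, cand], cand)][seq_len(min(k, length(cand)))]
  }
  edges <- list()
  for (i in sp) for (j in sp) if (i < j) {
    if (j %in% topk(i, sp) && i %in% topk(j, sp))
      edges[[length(edges) + 1]] <- c(i, j)
  }
  for (t in ct) for (s in sp) {
    spot_types <- if (length(ct) <= k) ct else topk(s, ct)
    if (s %in% topk(t, sp) && t %in% spot_types)
      edges[[length(edges) + 1]] <- c(min(t, s), max(t, s))
  }
  if (length(edges) == 0) return(matrix(numeric(0), 0, 3))
  e <- do.call(rbind, edges)
  d <- D[e]
  w <- 1 - d / max(d)
  cbind(e, w)[order(e[, 1], e[, 2]), , drop = FALSE]
}

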