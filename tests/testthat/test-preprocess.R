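# QC filtering, normalisation, marker selection, aggregation and stacking.

make_toy_sc <- function() {
  # 10 cells, 8 genes, 3 types; one type with a single cell
  counts <- matrix(rpois(80, 3) + 1, 10, 8,
                   dimnames = list(paste0("c", 1:10), paste0("g", 1:8)))
  sc_data(counts, c(rep("A", 5), rep("B", 4), "C"))
}

test_that("QC removes under-expressing cells, silent genes and tiny types", {
  counts <- matrix(5, 10, 8,
                   dimnames = list(paste0("c", 1:10), paste0("g", 1:8)))
  counts[1, ] <- 0; counts[1, 1:4] <- 1          # cell 1 expresses 4 genes
  counts[, 8] <- 0                               # gene 8 never detected
  sc <- sc_data(counts, c(rep("A", 5), rep("B", 4), "C"))
  st <- st_data(matrix(4, 6, 8, dimnames = list(NULL, paste0("g", 1:8))))
  out <- apply_qc_filters(sc, st)
  expect_false("c1" %in% out$sc$cell_ids)        # boundary: 4 < 5 genes
  expect_false("g8" %in% out$sc$gene_names)      # all-zero column dropped
  # type C had 1 cell among 3 types -> dropped, 2 types remain
  expect_setequal(unique(out$sc$cell_types), c("A", "B"))
  expect_equal(nrow(out$sc$counts), 9 - 1 + 1 - 1)  # 10 - c1 - the C cell
})

test_that("QC removes high-mitochondrial cells and is idempotent", {
  set.seed(4)
  counts <- matrix(rpois(60, 5) + 1, 6, 10)
  colnames(counts) <- c(paste0("g", 1:8), "MT-CO1", "MT-ND1")
  counts[, 9:10] <- 1                             # low mito background
  counts[1, 9:10] <- 500                          # cell 1 dominated by mito
  sc <- sc_data(counts, rep(c("A", "B"), 3))
  st <- st_data(matrix(3, 5, 10, dimnames = list(NULL, colnames(counts))))
  out <- apply_qc_filters(sc, st)
  expect_equal(nrow(out$sc$counts), 5)
  twice <- apply_qc_filters(out$sc, out$st)
  expect_identical(twice$sc$counts, out$sc$counts)
  expect_identical(twice$st$counts, out$st$counts)
})

test_that("QC failure names the filter that removed everything", {
  sc <- sc_data(matrix(1, 3, 6), rep("A", 3))     # 6 genes expressed, fine
  st <- st_data(matrix(c(1, 1, 1, 0, 0, 0), 2, 3, byrow = TRUE))
  expect_error(apply_qc_filters(sc, st, min_genes = 5), "min_genes")
})

test_that("normalize_cells yields unit rows and preserves proportions", {
  sc <- sc_data(matrix(c(2, 2, 4, 1, 1, 2), 2, 3, byrow = TRUE),
                c("A", "B"))
  out <- normalize_cells(sc)
  expect_equal(out$counts[1, ], c(gene1 = 0.25, gene2 = 0.25, gene3 = 0.5))
  expect_equal(normalize_cells(out)$counts, out$counts)   # idempotent
  set.seed(10)
  big <- sc_data(matrix(rpois(100 * 20, 4) + 1, 100, 20), rep("A", 100))
  expect_equal(rowSums(normalize_cells(big)$counts), rep(1, 100),
               tolerance = 1e-9, ignore_attr = TRUE)
  zero <- sc_data(rbind(c(1, 1), c(0, 0)), c("A", "B"))
  expect_error(normalize_cells(zero), "all-zero")
})

test_that("marker selection ranks exclusive genes first and recovers planted markers", {
  counts <- matrix(1, 6, 4, dimnames = list(NULL, paste0("g", 1:4)))
  counts[1:3, 1] <- 50      # gene 1 exclusive to type A
  counts[4:6, 1] <- 0
  sc <- normalize_cells(sc_data(counts, rep(c("A", "B"), each = 3)))
  mk <- select_marker_genes(sc, top_n = 2)
  expect_equal(mk$A[1], "g1")
  all_mk <- select_marker_genes(sc, top_n = 100)
  expect_true(all(lengths(all_mk) <= 4))

  sc2 <- make_synthetic_scrna(
    synthetic_config(n_types = 3, n_cells = 120, n_genes = 300,
                     markers_per_type = 50, marker_fold_change = 10,
                     seed = 21))
  planted <- attr(sc2, "marker_map")
  mk2 <- select_marker_genes(normalize_cells(sc2), top_n = 50)
  recovery <- mean(vapply(names(planted), function(t) {
    mean(planted[[t]] %in% mk2[[t]])
  }, numeric(1)))
  expect_gte(recovery, 0.9)
})

test_that("cell-type profiles are group-wise column sums conserving mass", {
  sc <- normalize_cells(make_toy_sc())
  prof <- build_celltype_profile(sc, sc$gene_names)
  for (t in c("A", "B", "C")) {
    expect_equal(prof$profile[t, ],
                 colSums(sc$counts[sc$cell_types == t, , drop = FALSE]))
  }
  # single-cell type row equals that cell's row
  expect_equal(prof$profile["C", ], sc$counts[10, ])
  # mass conservation on a gene subset
  sub <- sc$gene_names[1:4]
  prof_sub <- build_celltype_profile(sc, sub)
  expect_equal(sum(prof_sub$profile), sum(sc$counts[, sub]))
  expect_error(build_celltype_profile(sc, c("g1", "nope")), "nope")
})

test_that("align_and_stack intersects genes and is column-order insensitive", {
  sc <- normalize_cells(make_toy_sc())
  prof <- build_celltype_profile(sc, c("g1", "g2", "g3"))
  st <- st_data(matrix(rpois(20, 4), 4, 5,
                       dimnames = list(NULL, c("g2", "g3", "g9", "g10", "g1"))))
  X <- align_and_stack(prof, st)
  expect_equal(X$gene_names, c("g1", "g2", "g3"))
  expect_equal(nrow(X$X), 3 + 4)
  expect_equal(X$node_roles, c(rep("celltype", 3), rep("spot", 4)))

  st_perm <- st_data(st$counts[, c(4, 1, 5, 2, 3)])
  X2 <- align_and_stack(prof, st_perm)
  expect_identical(X$X, X2$X)

  st_disjoint <- st_data(matrix(1, 2, 2, dimnames = list(NULL, c("zz", "yy"))))
  expect_error(align_and_stack(prof, st_disjoint), "no genes shared")
})
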