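# Spot simulators: regular sampling laws, hexagonal geometry, rebalancing,
# neighbour noise arithmetic and square-bin blurring.

test_that("regular simulation obeys the per-spot sampling laws", {
  sc <- tiny_sc()
  sim <- simulate_regular(sc, n_spots = 300, seed = 5)
  m <- length(unique(sc$cell_types))
  ncells <- lengths(sim$cell_assignment)
  expect_true(all(ncells >= 5 & ncells <= 15))
  ntypes <- vapply(sim$cell_assignment, function(cells)
    length(unique(sc$cell_types[cells])), integer(1))
  expect_true(all(ntypes >= 2 & ntypes <= min(6, m)))
  expect_equal(rowSums(sim$proportions), rep(1, 300), ignore_attr = TRUE)
  # counts are member-cell sums; proportions are member-type fractions
  for (i in c(1, 57, 300)) {
    cells <- sim$cell_assignment[[i]]
    expect_equal(sim$counts[i, ], colSums(sc$counts[cells, , drop = FALSE]),
                 ignore_attr = TRUE)
    tab <- table(factor(sc$cell_types[cells],
                        levels = sort(unique(sc$cell_types))))
    expect_equal(sim$proportions[i, ], as.numeric(tab) / length(cells),
                 ignore_attr = TRUE)
  }
  # total expression conserved
  all_cells <- unlist(sim$cell_assignment)
  expect_equal(sum(sim$counts), sum(sc$counts[all_cells, ]))
})

test_that("regular simulation coordinates are row-major with column wrap 40", {
  sc <- tiny_sc()
  sim <- simulate_regular(sc, n_spots = 85, seed = 1)
  expect_equal(sim$coordinates[1, ], c(x = 1, y = 1))
  expect_equal(sim$coordinates[40, ], c(x = 1, y = 40))
  expect_equal(sim$coordinates[41, ], c(x = 2, y = 1))
  expect_equal(sim$coordinates[85, ], c(x = 3, y = 5))
  expect_lte(max(sim$coordinates[, "y"]), 40)
  expect_error(simulate_regular(sc, 0), "positive")
})

test_that("simulators are seed-deterministic and seed-sensitive", {
  sc <- tiny_sc()
  s1 <- simulate_regular(sc, 50, seed = 9)
  s2 <- simulate_regular(sc, 50, seed = 9)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$cell_assignment, s2$cell_assignment)
  s3 <- simulate_regular(sc, 50, seed = 10)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("hexagonal binning matches a point-in-hexagon oracle", {
  set.seed(66)
  pts <- cbind(runif(120, 0, 10), runif(120, 0, 10))
  hs <- 1.3
  hx <- hex_bin_cells(pts, hs)
  centers <- hx$centers
  # oracle: a point belongs to the hexagon whose center is nearest
  # (true for regular hexagonal tessellations)
  for (i in sample(120, 40)) {
    d <- sqrt((centers[, "x"] - (pts[i, 1]))^2 +
              (centers[, "y"] - (pts[i, 2]))^2)
    ctr <- centers[as.character(hx$bin[i]), ]
    dself <- sqrt(sum((ctr - pts[i, ])^2))
    expect_lte(dself, min(d) + 1e-9)
  }
  # every cell in exactly one hexagon; center distance bounded by circumradius
  expect_false(anyNA(hx$bin))
  dist_to_center <- sqrt(rowSums((pts - centers[as.character(hx$bin), ])^2))
  expect_true(all(dist_to_center <= hs + 1e-9))

  # hexagon larger than the bounding box -> single bin
  one <- hex_bin_cells(cbind(runif(10), runif(10)), hex_size = 100)
  expect_equal(nlevels(one$bin), 1)
  # a cell exactly at a hexagon center stays in that hexagon (pick an
  # interior center so the grid origin is unchanged by the extra point)
  interior <- which(centers[, "x"] > min(pts[, 1]) + hs &
                    centers[, "y"] > min(pts[, 2]) + hs)[1]
  ctr1 <- centers[interior, ]
  hx2 <- hex_bin_cells(rbind(pts, unname(ctr1)), hs)
  expect_equal(as.character(hx2$bin[121]), rownames(centers)[interior])
  expect_error(hex_bin_cells(cbind(NA, 1), 1), "non-finite")
})

test_that("rebalancing transfers extras to hexagonal neighbours and drops tiny spots", {
  # 20 cells in a single central hexagon, empty neighbours
  pts <- matrix(rep(c(5, 5), each = 20), 20, 2) +
    matrix(runif(40, -0.05, 0.05), 20, 2)
  hx <- hex_bin_cells(pts, hex_size = 2)
  expect_equal(nlevels(droplevels(hx$bin)), 1)
  rb <- rebalance_bins(hx, seed = 2)
  tab <- table(as.character(rb$bin))
  # 15 remain in some bin, 5 moved to adjacent hexagons but then dropped
  # (each receiving bin holds < 4 cells)
  expect_equal(max(tab), 15)
  expect_equal(attr(rb, "dropped")$n_cells, 5)
  expect_equal(sum(is.na(rb$bin)), 5)

  # an in-band spot is untouched
  pts10 <- matrix(rep(c(3, 3), each = 10), 10, 2)
  hx10 <- hex_bin_cells(pts10, 1)
  rb10 <- rebalance_bins(hx10, seed = 1)
  expect_identical(as.character(rb10$bin), as.character(hx10$bin))
})

test_that("neighbour noise reproduces the mixing arithmetic exactly", {
  # 3 collinear spots at unit spacing: middle spot has two neighbours
  counts <- rbind(c(4, 4), c(10, 10), c(8, 8))
  st <- st_data(counts, coordinates = cbind(x = c(0, 1, 2), y = c(0, 0, 0)))
  sim <- structure(list(st = st, counts = st$counts,
                        coordinates = st$coordinates,
                        proportions = NULL, cell_assignment = NULL,
                        provenance = list(simulator = "manual"), hex = NULL),
                   class = "simulated_st")
  # choose the seed so that the middle spot is among the selected
  noisy <- NULL
  for (s in 1:50) {
    cand <- add_neighbor_noise(sim, fraction = 1 / 3, alpha = 0.2, seed = s)
    if (identical(cand$provenance$noise$selected, 2L)) { noisy <- cand; break }
  }
  expect_false(is.null(noisy))
  # E = 10, neighbours {4, 8}: 0.8*10 + 0.2*6 = 9.2
  expect_equal(noisy$counts[2, ], c(9.2, 9.2), ignore_attr = TRUE)
  expect_equal(noisy$counts[c(1, 3), ], counts[c(1, 3), ],
               ignore_attr = TRUE)

  # alpha = 0 is the identity
  id <- add_neighbor_noise(sim, fraction = 1, alpha = 0, seed = 1)
  expect_equal(id$counts, sim$counts, ignore_attr = TRUE)
  # alpha = 1 replaces the spot by its neighbour mean
  full <- add_neighbor_noise(sim, fraction = 1, alpha = 1, seed = 1)
  expect_equal(full$counts[2, ], c(6, 6), ignore_attr = TRUE)
})

test_that("neighbour noise modifies exactly the selected fraction of rows", {
  sc <- tiny_sc()
  sim <- simulate_regular(sc, 80, seed = 3)
  noisy <- add_neighbor_noise(sim, fraction = 0.25, alpha = 0.1, seed = 4)
  changed <- which(rowSums(noisy$counts != sim$counts) > 0)
  sel <- noisy$provenance$noise$selected
  expect_equal(length(sel), round(0.25 * 80))
  expect_true(all(changed %in% sel))
  expect_identical(noisy$proportions, sim$proportions)  # metadata untouched
  untouched <- setdiff(seq_len(80), sel)
  expect_identical(noisy$counts[untouched, ], sim$counts[untouched, ])
})

test_that("square-bin blurring sums members and records label fractions", {
  # 3x3 grid of cells at unit spacing, bin = spacing -> 9 singleton spots
  coords <- as.matrix(expand.grid(x = (0:2) + 0.5, y = (0:2) + 0.5))
  counts <- matrix(rpois(9 * 4, 5), 9, 4)
  st <- st_data(counts, coordinates = coords)
  labels <- rep(c("A", "B", "C"), 3)
  b1 <- blur_bins(st, bin_x = 1, cell_types = labels)
  expect_equal(nrow(b1$counts), 9)
  expect_true(all(apply(b1$proportions, 1, max) == 1))  # one-hot
  expect_equal(sum(b1$counts), sum(counts))             # mass conserved

  # bin spanning the slide -> a single pooled spot
  b2 <- blur_bins(st, bin_x = 10, cell_types = labels)
  expect_equal(nrow(b2$counts), 1)
  expect_equal(b2$counts[1, ], colSums(counts), ignore_attr = TRUE)
  expect_equal(b2$proportions[1, ], c(A = 1/3, B = 1/3, C = 1/3))

  # 2 type-A + 2 type-B cells pooled -> proportions (0.5, 0.5)
  st4 <- st_data(matrix(1, 4, 3), coordinates = cbind(runif(4), runif(4)))
  b3 <- blur_bins(st4, bin_x = 5, cell_types = c("A", "A", "B", "B"))
  expect_equal(b3$proportions[1, ], c(A = 0.5, B = 0.5))
  expect_equal(b3$counts[1, ], c(4, 4, 4), ignore_attr = TRUE)
  # labels optional: expression still produced
  b4 <- blur_bins(st4, bin_x = 5)
  expect_null(b4$proportions)
})
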