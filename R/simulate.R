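# Spot simulators: regular pseudo-spot sampling, spatial-information-aware
# simulation (coordinate prediction + hexagonal binning + rebalancing),
# neighbour-diffusion noise and square-bin blurring.

new_simulated_st <- function(counts, coordinates, proportions,
                             cell_assignment, provenance, extra = list()) {
  st <- st_data(counts, coordinates = coordinates)
  structure(
    c(list(st = st, counts = st$counts, coordinates = st$coordinates,
           proportions = proportions, cell_assignment = cell_assignment,
           provenance = provenance),
      extra),
    class = "simulated_st"
  )
}

#' @export
print.simulated_st <- function(x, ...) {
  cat(sprintf("simulated_st (%s): %d spots x %d genes, %d cell types\n",
              x$provenance$simulator, nrow(x$counts), ncol(x$counts),
              ncol(x$proportions)))
  invisible(x)
}

proportions_from_assignment <- function(assignment, types, type_levels) {
  t(vapply(assignment, function(cells) {
    tab <- table(factor(types[cells], levels = type_levels))
    as.numeric(tab) / length(cells)
  }, numeric(length(type_levels))))
}

#' Regular pseudo-spot simulation from single-cell data
#'
#' Emulates the classical reference-free spot simulation: each spot draws
#' its number of cells uniformly from `cells_range` and its number of
#' distinct cell types uniformly from `types_range` (capped at the available
#' types); every chosen type contributes at least one cell, the remaining
#' cells are assigned uniformly among the chosen types, and member cells are
#' sampled with replacement from each type's pool. Spot expression is the
#' sum of the raw counts of its member cells; ground-truth proportions are
#' the member-cell type fractions. Spots receive 1-based row-major integer
#' coordinates `(1,1), (1,2), ...`, wrapping after column `max_col`.
#'
#' @param sc an [sc_data] object (raw counts).
#' @param n_spots number of spots to simulate.
#' @param seed integer seed; fixed seed reproduces the dataset bitwise.
#' @param cells_range integer range of cells per spot (default 5-15).
#' @param types_range integer range of distinct types per spot (default 2-6).
#' @param max_col maximum column coordinate (default 40).
#' @return object of class `simulated_st` with `counts`, `coordinates`,
#'   `proportions`, `cell_assignment` and `provenance`.
#' @export
simulate_regular <- function(sc, n_spots, seed = 1L,
                             cells_range = c(5L, 15L),
                             types_range = c(2L, 6L), max_col = 40L) {
  stopifnot(inherits(sc, "sc_data"))
  if (n_spots <= 0L) stop("simulate_regular: n_spots must be positive")
  set.seed(seed)
  type_levels <- sort(unique(sc$cell_types))
  m <- length(type_levels)
  pools <- split(seq_len(nrow(sc$counts)), sc$cell_types)[type_levels]
  tmin <- min(types_range[1], m); tmax <- min(types_range[2], m)

  assignment <- vector("list", n_spots)
  counts <- matrix(0, n_spots, ncol(sc$counts),
                   dimnames = list(paste0("simspot", seq_len(n_spots)),
                                   sc$gene_names))
  for (i in seq_len(n_spots)) {
    ncells <- sample(cells_range[1]:cells_range[2], 1L)
    ntypes <- sample(tmin:tmax, 1L)
    ntypes <- min(ntypes, ncells)
    chosen <- sample(type_levels, ntypes)
    alloc <- c(chosen, sample(chosen, ncells - ntypes, replace = TRUE))
    cells <- vapply(alloc, function(t) {
      pool <- pools[[t]]
      pool[sample.int(length(pool), 1L)]
    }, integer(1))
    assignment[[i]] <- unname(cells)
    counts[i, ] <- colSums(sc$counts[cells, , drop = FALSE])
  }
  props <- proportions_from_assignment(assignment, sc$cell_types, type_levels)
  dimnames(props) <- list(rownames(counts), type_levels)
  idx <- seq_len(n_spots) - 1L
  coords <- cbind(x = idx %/% max_col + 1L, y = idx %% max_col + 1L)
  new_simulated_st(counts, coords, props, assignment,
                   provenance = list(simulator = "regular", seed = seed,
                                     cells_range = cells_range,
                                     types_range = types_range,
                                     max_col = max_col))
}

#' Predict 2-D coordinates for single cells from a reference slide
#'
#' Co-embeds the cells and the reference spots with the variational
#' autoencoder (over their common genes), finds each cell's `k` nearest
#' spots in the latent space, and places the cell at the arithmetic mean of
#' those spots' coordinates (the midpoint for the default `k = 2`; with
#' `k = 1` cells coincide with existing spot positions).
#'
#' @param sc an [sc_data] object.
#' @param ref_st an [st_data] reference with coordinates.
#' @param k number of nearest spots (default 2).
#' @param seed seed for VAE training.
#' @param vae_epochs,vae_hidden embedding training controls.
#' @return object of class `cell_coordinates`: matrix `coords` (cells x 2),
#'   `nearest_spots` (cells x k spot indices) and the embedding.
#' @export
predict_cell_coordinates <- function(sc, ref_st, k = 2L, seed = 1L,
                                     vae_epochs = 300L, vae_hidden = 512L) {
  stopifnot(inherits(sc, "sc_data"), inherits(ref_st, "st_data"))
  if (is.null(ref_st$coordinates))
    stop("predict_cell_coordinates: reference has no coordinates")
  common <- intersect(sc$gene_names, ref_st$gene_names)
  if (length(common) == 0L)
    stop("predict_cell_coordinates: no common genes")
  Xc <- rbind(sc$counts[, common, drop = FALSE],
              ref_st$counts[, common, drop = FALSE])
  nc <- nrow(sc$counts); ns <- nrow(ref_st$counts)
  vae <- train_vae(Xc, epochs = vae_epochs, hidden_dim = vae_hidden,
                   seed = seed)
  Z <- vae_encode(vae, Xc)$Z
  Zc <- Z[seq_len(nc), , drop = FALSE]
  Zs <- Z[nc + seq_len(ns), , drop = FALSE]
  kk <- min(k, ns)
  nearest <- matrix(0L, nc, kk)
  coords <- matrix(0, nc, 2, dimnames = list(sc$cell_ids, c("x", "y")))
  for (i in seq_len(nc)) {
    d <- sqrt(colSums((t(Zs) - Zc[i, ])^2))
    nb <- order(d, seq_along(d))[seq_len(kk)]
    nearest[i, ] <- nb
    coords[i, ] <- colMeans(ref_st$coordinates[nb, , drop = FALSE])
  }
  structure(list(coords = coords, nearest_spots = nearest, k = kk,
                 embedding = Z),
            class = "cell_coordinates")
}

## ---- hexagonal grid (flat-top, axial indexing, origin at bounding-box min)

hex_axial_of_points <- function(xy, hex_size) {
  ox <- min(xy[, 1]); oy <- min(xy[, 2])
  x <- (xy[, 1] - ox) / hex_size
  y <- (xy[, 2] - oy) / hex_size
  qf <- 2 / 3 * x
  rf <- -1 / 3 * x + sqrt(3) / 3 * y
  cube_round(qf, rf)
}

# Round fractional axial coordinates to the nearest hexagon (cube rounding).
cube_round <- function(qf, rf) {
  sf <- -qf - rf
  q <- round(qf); r <- round(rf); s <- round(sf)
  dq <- abs(q - qf); dr <- abs(r - rf); ds <- abs(s - sf)
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  q[fix_q] <- -r[fix_q] - s[fix_q]
  r[fix_r] <- -q[fix_r] - s[fix_r]
  cbind(q = as.integer(q), r = as.integer(r))
}

hex_center <- function(q, r, hex_size, origin = c(0, 0)) {
  cbind(x = origin[1] + hex_size * 1.5 * q,
        y = origin[2] + hex_size * sqrt(3) * (r + q / 2))
}

#' Assign cells to a hexagonal grid
#'
#' Tessellates the plane with flat-top regular hexagons (circumradius
#' `hex_size`, axial indexing, grid origin at the coordinate bounding-box
#' minimum) and assigns every cell to the hexagon containing it; boundary
#' points are resolved deterministically by cube rounding.
#'
#' @param coords a `cell_coordinates` object or a numeric matrix of (x, y)
#'   positions.
#' @param hex_size hexagon circumradius (> 0), i.e. the spot resolution.
#' @return object of class `hex_assignment`: integer axial indices per cell
#'   (`axial`), a factor `bin` keying cells to hexagons, the hexagon center
#'   table `centers`, and the grid parameters.
#' @export
hex_bin_cells <- function(coords, hex_size) {
  xy <- if (inherits(coords, "cell_coordinates")) coords$coords
        else as.matrix(coords)
  if (hex_size <= 0) stop("hex_bin_cells: hex_size must be positive")
  if (any(!is.finite(xy))) stop("hex_bin_cells: non-finite coordinates")
  ax <- hex_axial_of_points(xy, hex_size)
  key <- paste(ax[, "q"], ax[, "r"], sep = ",")
  bins <- factor(key, levels = unique(key))
  uq <- ax[!duplicated(key), , drop = FALSE]
  centers <- hex_center(uq[, "q"], uq[, "r"], hex_size,
                        origin = c(min(xy[, 1]), min(xy[, 2])))
  rownames(centers) <- unique(key)
  structure(list(axial = ax, bin = bins, centers = centers,
                 hex_size = hex_size,
                 origin = c(min(xy[, 1]), min(xy[, 2]))),
            class = "hex_assignment")
}

hex_neighbors_axial <- function(q, r) {
  cbind(q = q + c(1L, 1L, 0L, -1L, -1L, 0L),
        r = r + c(0L, -1L, -1L, 0L, 1L, 1L))
}

#' Rebalance overfull hexagonal spots
#'
#' Spots holding more than `max_cells` cells transfer uniformly chosen
#' extra cells to uniformly chosen ones of their six hexagonal neighbours,
#' for up to `max_passes` sweeps. Spots still holding fewer than
#' `min_cells` cells afterwards are dropped (their count is reported in the
#' `dropped` attribute).
#'
#' @param assignment a `hex_assignment` from [hex_bin_cells()].
#' @param max_cells,min_cells per-spot occupancy band (defaults 15 and 4).
#' @param seed integer seed for the random transfers.
#' @param max_passes maximum rebalancing sweeps (default 10).
#' @return a `hex_assignment` whose surviving bins all hold between
#'   `min_cells` and `max_cells` cells; cells in dropped bins have `NA` bin.
#' @export
rebalance_bins <- function(assignment, max_cells = 15L, min_cells = 4L,
                           seed = 1L, max_passes = 10L) {
  stopifnot(inherits(assignment, "hex_assignment"))
  set.seed(seed)
  ax <- assignment$axial
  key <- as.character(assignment$bin)

  for (pass in seq_len(max_passes)) {
    tab <- table(key)
    over <- names(tab)[tab > max_cells]
    if (length(over) == 0L) break
    for (b in over) {
      qr <- as.integer(strsplit(b, ",")[[1]])
      members <- which(key == b)
      extra <- length(members) - max_cells
      move <- sample(members, extra)
      nb <- hex_neighbors_axial(qr[1], qr[2])
      dest <- nb[sample.int(6L, extra, replace = TRUE), , drop = FALSE]
      ax[move, ] <- dest
      key[move] <- paste(dest[, "q"], dest[, "r"], sep = ",")
    }
  }
  tab <- table(key)
  if (any(tab > max_cells))
    warning("rebalance_bins: overfull spots remain after ", max_passes,
            " passes")
  small <- names(tab)[tab < min_cells]
  dropped_cells <- sum(tab[small])
  key[key %in% small] <- NA_character_
  bins <- factor(key, levels = setdiff(unique(stats::na.omit(key)), NA))
  uq_keys <- levels(bins)
  uq <- do.call(rbind, lapply(strsplit(uq_keys, ","), as.integer))
  centers <- hex_center(uq[, 1], uq[, 2], assignment$hex_size,
                        origin = assignment$origin)
  rownames(centers) <- uq_keys
  out <- assignment
  out$axial <- ax
  out$bin <- bins
  out$centers <- centers
  attr(out, "dropped") <- list(n_bins = length(small),
                               n_cells = dropped_cells)
  out
}

#' Spatial-information-aware spot simulation
#'
#' Composes [predict_cell_coordinates()], [hex_bin_cells()] and
#' [rebalance_bins()]: cells are placed on the reference slide through the
#' co-embedding, binned into hexagonal spots, occupancy is rebalanced into
#' the 4-15 cell band, and every surviving spot aggregates its member
#' cells' expression — by default the per-cell average rescaled to the
#' median member library size (`aggregation = "sum"` uses the plain sum,
#' which conserves total counts). Ground-truth proportions and the member
#' cells of each spot are recorded.
#'
#' @param sc an [sc_data] object (raw counts).
#' @param ref_st an [st_data] reference slide with coordinates.
#' @param hex_size hexagon circumradius controlling spot resolution.
#' @param seed integer seed (fixed seed reproduces the dataset).
#' @param aggregation `"average"` (default) or `"sum"`.
#' @param k nearest spots for coordinate prediction (default 2).
#' @param vae_epochs,vae_hidden embedding controls passed through.
#' @return object of class `simulated_st`; the extra field `hex` keeps the
#'   final hexagon assignment (used for neighbour-aware noise).
#' @export
simulate_spatial <- function(sc, ref_st, hex_size, seed = 1L,
                             aggregation = c("average", "sum"), k = 2L,
                             vae_epochs = 300L, vae_hidden = 512L) {
  aggregation <- match.arg(aggregation)
  cc <- predict_cell_coordinates(sc, ref_st, k = k,
                                 seed = derive_seed(seed, 1L),
                                 vae_epochs = vae_epochs,
                                 vae_hidden = vae_hidden)
  hx <- hex_bin_cells(cc, hex_size)
  hx <- rebalance_bins(hx, seed = derive_seed(seed, 2L))
  keep <- !is.na(hx$bin)
  bins <- droplevels(hx$bin[keep])
  cells_by_bin <- split(which(keep), bins[drop = TRUE])
  type_levels <- sort(unique(sc$cell_types))

  counts <- matrix(0, length(cells_by_bin), ncol(sc$counts),
                   dimnames = list(names(cells_by_bin), sc$gene_names))
  for (b in seq_along(cells_by_bin)) {
    cells <- cells_by_bin[[b]]
    sub <- sc$counts[cells, , drop = FALSE]
    if (aggregation == "sum") {
      counts[b, ] <- colSums(sub)
    } else {
      avg <- colMeans(sub)
      lib <- stats::median(rowSums(sub))
      s <- sum(avg)
      counts[b, ] <- if (s > 0) avg / s * lib else avg
    }
  }
  coords <- hx$centers[names(cells_by_bin), , drop = FALSE]
  props <- proportions_from_assignment(cells_by_bin, sc$cell_types,
                                       type_levels)
  dimnames(props) <- list(names(cells_by_bin), type_levels)
  new_simulated_st(counts, coords, props, cells_by_bin,
                   provenance = list(simulator = "spatial", seed = seed,
                                     hex_size = hex_size, k = k,
                                     aggregation = aggregation,
                                     dropped = attr(hx, "dropped")),
                   extra = list(hex = hx, cell_coords = cc))
}

#' Neighbour-diffusion noise on a simulated slide
#'
#' Emulates transcript leakage into neighbouring spots: exactly
#' `round(fraction * n)` distinct spots (seeded, without replacement) are
#' replaced by `(1 - alpha) * E_i + alpha * mean(E_j over neighbours j)`,
#' computed synchronously from the original matrix. Neighbourhood is the
#' hexagonal adjacency when the dataset is hex-gridded, otherwise all spots
#' within the median nearest-neighbour distance. Unselected spots and the
#' ground-truth proportions are untouched; a selected spot without
#' neighbours is left unchanged.
#'
#' @param sim a `simulated_st` (or [st_data] with coordinates).
#' @param fraction fraction of spots affected, in `[0, 1]`.
#' @param alpha neighbour influence, in `[0, 1]`.
#' @param seed integer seed for spot selection.
#' @return object of the same class with modified counts; the selected spot
#'   indices are kept in `provenance$noise`.
#' @export
add_neighbor_noise <- function(sim, fraction, alpha, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("add_neighbor_noise: bad fraction")
  if (alpha < 0 || alpha > 1) stop("add_neighbor_noise: bad alpha")
  is_sim <- inherits(sim, "simulated_st")
  counts <- if (is_sim) sim$counts else sim$counts
  coords <- if (is_sim) sim$coordinates else sim$coordinates
  if (is.null(coords)) stop("add_neighbor_noise: coordinates required")
  n <- nrow(counts)
  set.seed(seed)
  n_sel <- round(fraction * n)
  sel <- if (n_sel > 0) sort(sample.int(n, n_sel)) else integer(0)

  hex <- if (is_sim) sim$hex else NULL
  if (!is.null(hex)) {
    keys <- rownames(counts)
    ax <- do.call(rbind, lapply(strsplit(keys, ","), as.integer))
    neighbors <- lapply(seq_len(n), function(i) {
      nb <- hex_neighbors_axial(ax[i, 1], ax[i, 2])
      nbk <- paste(nb[, "q"], nb[, "r"], sep = ",")
      which(keys %in% nbk)
    })
  } else {
    D <- pairwise_dist(coords)
    diag(D) <- Inf
    r <- stats::median(apply(D, 1, min))
    neighbors <- lapply(seq_len(n), function(i) which(D[i, ] <= r))
  }

  new_counts <- counts
  skipped <- integer(0)
  for (i in sel) {
    nb <- neighbors[[i]]
    if (length(nb) == 0L) { skipped <- c(skipped, i); next }
    nbmean <- colMeans(counts[nb, , drop = FALSE])
    new_counts[i, ] <- (1 - alpha) * counts[i, ] + alpha * nbmean
  }
  if (is_sim) {
    out <- sim
    out$counts <- new_counts
    out$st <- st_data(new_counts, coordinates = coords)
    out$provenance$noise <- list(fraction = fraction, alpha = alpha,
                                 seed = seed, selected = sel,
                                 skipped = skipped)
    out
  } else {
    st_data(new_counts, coordinates = coords)
  }
}

#' Blur a single-cell-resolution slide into square bins
#'
#' Bins cells (or subcellular spots) of a high-resolution slide into
#' axis-aligned rectangles of size `bin_x` x `bin_y` anchored at the
#' coordinate origin, summing member expression per bin. When per-cell type
#' labels are given, the ground-truth proportions per bin are the label
#' fractions; empty bins do not appear.
#'
#' @param st an [st_data] object with coordinates, one row per cell.
#' @param bin_x,bin_y bin edge lengths (> 0).
#' @param cell_types optional label per row of `st`.
#' @return object of class `simulated_st` (`proportions` is `NULL` without
#'   labels).
#' @export
blur_bins <- function(st, bin_x, bin_y = bin_x, cell_types = NULL) {
  stopifnot(inherits(st, "st_data"))
  if (is.null(st$coordinates)) stop("blur_bins: coordinates required")
  if (bin_x <= 0 || bin_y <= 0) stop("blur_bins: bin sizes must be positive")
  bx <- floor(st$coordinates[, "x"] / bin_x)
  by <- floor(st$coordinates[, "y"] / bin_y)
  key <- paste(bx, by, sep = ",")
  bins <- factor(key, levels = unique(key))
  idx <- split(seq_len(nrow(st$counts)), bins)
  counts <- t(vapply(idx, function(i) colSums(st$counts[i, , drop = FALSE]),
                     numeric(ncol(st$counts))))
  colnames(counts) <- st$gene_names
  centers <- t(vapply(idx, function(i) {
    b <- strsplit(key[i[1]], ",")[[1]]
    c((as.numeric(b[1]) + 0.5) * bin_x, (as.numeric(b[2]) + 0.5) * bin_y)
  }, numeric(2)))
  colnames(centers) <- c("x", "y")
  props <- NULL
  if (!is.null(cell_types)) {
    type_levels <- sort(unique(cell_types))
    props <- proportions_from_assignment(idx, cell_types, type_levels)
    dimnames(props) <- list(names(idx), type_levels)
  }
  new_simulated_st(counts, centers, props, idx,
                   provenance = list(simulator = "blur", bin_x = bin_x,
                                     bin_y = bin_y))
}
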