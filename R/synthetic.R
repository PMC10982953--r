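# Seeded synthetic-data generators: cell-type-structured scRNA-seq counts
# with planted markers, and spatially zoned reference slides.

#' Configuration for the synthetic generators
#'
#' @param n_types number of cell types (default 5).
#' @param n_cells total cells, balanced across types up to +/-1 (default 600).
#' @param n_genes genes (default 1500).
#' @param markers_per_type planted marker genes per type (default 50);
#'   `markers_per_type * n_types` must not exceed `n_genes`.
#' @param marker_fold_change mean fold elevation of a marker in its own type
#'   (default 10; 1 plants no signal).
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`, default 0.5).
#' @param zone_layout `"striped"`, `"concentric"` or `"random"` spatial zone
#'   arrangement for the reference slide.
#' @param slide_width,slide_height slide extent in coordinate units.
#' @param n_ref_spots reference spots placed on a grid (default 300).
#' @param seed integer seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_types = 5L, n_cells = 600L, n_genes = 1500L,
                             markers_per_type = 50L, marker_fold_change = 10,
                             dispersion = 0.5, zone_layout = "striped",
                             slide_width = 20, slide_height = 20,
                             n_ref_spots = 300L, seed = 1L) {
  cfg <- list(n_types = n_types, n_cells = n_cells, n_genes = n_genes,
              markers_per_type = markers_per_type,
              marker_fold_change = marker_fold_change,
              dispersion = dispersion, zone_layout = zone_layout,
              slide_width = slide_width, slide_height = slide_height,
              n_ref_spots = n_ref_spots, seed = seed)
  if (any(unlist(cfg[c("n_types", "n_cells", "n_genes", "markers_per_type",
                       "n_ref_spots")]) <= 0))
    stop("synthetic_config: counts must be positive")
  if (markers_per_type * n_types > n_genes)
    stop("synthetic_config: marker allocation exceeds gene count")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate synthetic single-cell data with planted cell types
#'
#' Draws counts from a negative-binomial model with log-normal per-gene
#' baseline means; each type owns a disjoint block of
#' `markers_per_type` marker genes whose mean is multiplied by
#' `marker_fold_change` in cells of that type. Type sizes are balanced to
#' within one cell. Fully deterministic under the seed.
#'
#' @param cfg a [synthetic_config()].
#' @return an [sc_data] object; the planted marker map is attached as
#'   attribute `marker_map` (named list type -> marker genes).
#' @export
make_synthetic_scrna <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  types <- paste0("type", seq_len(cfg$n_types))
  base_mu <- stats::rlnorm(cfg$n_genes, meanlog = log(0.5), sdlog = 1)
  marker_map <- lapply(seq_len(cfg$n_types), function(t) {
    genes[((t - 1) * cfg$markers_per_type + 1):(t * cfg$markers_per_type)]
  })
  names(marker_map) <- types

  sizes <- rep(cfg$n_cells %/% cfg$n_types, cfg$n_types)
  extra <- cfg$n_cells %% cfg$n_types
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep(types, sizes)

  nb_size <- 1 / cfg$dispersion
  counts <- matrix(0L, cfg$n_cells, cfg$n_genes,
                   dimnames = list(sprintf("c%04d", seq_len(cfg$n_cells)),
                                   genes))
  for (t in seq_len(cfg$n_types)) {
    mu <- base_mu
    mi <- ((t - 1) * cfg$markers_per_type + 1):(t * cfg$markers_per_type)
    mu[mi] <- mu[mi] * cfg$marker_fold_change
    rows <- which(labels == types[t])
    counts[rows, ] <- matrix(
      stats::rnbinom(length(rows) * cfg$n_genes, mu = rep(mu, each = length(rows)),
                     size = nb_size),
      length(rows), cfg$n_genes)
  }
  out <- sc_data(counts, labels)
  attr(out, "marker_map") <- marker_map
  out
}

#' Generate a spatially zoned synthetic reference slide
#'
#' Places `n_ref_spots` on a regular grid over the slide and assembles each
#' spot from 4-15 cells drawn with zone-dependent type probabilities: each
#' zone is dominated by one cell type (sampling probability 0.8, remainder
#' uniform over the other types). Zones are vertical stripes, concentric
#' rings, or a spatially random assignment. Spot expression is the sum of
#' member-cell counts.
#'
#' @param cfg a [synthetic_config()].
#' @param sc the matching [make_synthetic_scrna()] dataset.
#' @return an [st_data] object with coordinates; attributes `zone_map`
#'   (dominant type per spot) and `proportions` (true member-type fractions)
#'   support test assertions.
#' @export
make_synthetic_spatial_reference <- function(cfg, sc) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(sc, "sc_data"))
  set.seed(derive_seed(cfg$seed, 7L))
  type_levels <- sort(unique(sc$cell_types))
  m <- length(type_levels)
  n <- cfg$n_ref_spots
  ncol_grid <- ceiling(sqrt(n * cfg$slide_width / cfg$slide_height))
  nrow_grid <- ceiling(n / ncol_grid)
  gx <- ((seq_len(n) - 1) %% ncol_grid + 0.5) * cfg$slide_width / ncol_grid
  gy <- ((seq_len(n) - 1) %/% ncol_grid + 0.5) * cfg$slide_height / nrow_grid

  zone <- switch(cfg$zone_layout,
    striped = pmin(floor(gx / cfg$slide_width * m) + 1, m),
    concentric = {
      cx <- cfg$slide_width / 2; cy <- cfg$slide_height / 2
      d <- sqrt((gx - cx)^2 + (gy - cy)^2)
      rmax <- max(d) * (1 + 1e-9)
      floor(d / rmax * m) + 1
    },
    random = sample.int(m, n, replace = TRUE),
    stop("make_synthetic_spatial_reference: unknown zone layout: ",
         cfg$zone_layout)
  )

  pools <- split(seq_len(nrow(sc$counts)), sc$cell_types)[type_levels]
  counts <- matrix(0, n, ncol(sc$counts),
                   dimnames = list(sprintf("ref%04d", seq_len(n)),
                                   sc$gene_names))
  assignment <- vector("list", n)
  for (i in seq_len(n)) {
    ncells <- sample(4:15, 1L)
    probs <- rep(0.2 / max(m - 1, 1), m)
    probs[zone[i]] <- if (m == 1) 1 else 0.8
    drawn_types <- sample.int(m, ncells, replace = TRUE, prob = probs)
    cells <- vapply(drawn_types, function(t) {
      pool <- pools[[t]]
      pool[sample.int(length(pool), 1L)]
    }, integer(1))
    assignment[[i]] <- cells
    counts[i, ] <- colSums(sc$counts[cells, , drop = FALSE])
  }
  out <- st_data(counts, coordinates = cbind(x = gx, y = gy))
  attr(out, "zone_map") <- type_levels[zone]
  props <- proportions_from_assignment(assignment, sc$cell_types, type_levels)
  dimnames(props) <- list(out$spot_ids, type_levels)
  attr(out, "proportions") <- props
  attr(out, "cell_assignment") <- assignment
  out
}
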