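# Shared fixtures, built in code. Heavy pipeline results are memoised in a
# session-level cache so several tests can share one fit.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# Tiny single-cell fixture: 3 types, strong markers, fast everywhere.
tiny_cfg <- function(seed = 101) {
  synthetic_config(n_types = 3L, n_cells = 90L, n_genes = 120L,
                   markers_per_type = 10L, marker_fold_change = 10,
                   n_ref_spots = 64L, slide_width = 8, slide_height = 8,
                   seed = seed)
}

tiny_sc <- function() memo("tiny_sc", make_synthetic_scrna(tiny_cfg()))

tiny_ref <- function() memo("tiny_ref", {
  make_synthetic_spatial_reference(tiny_cfg(), tiny_sc())
})

# Small configuration for pipeline smoke tests: keeps the architecture but
# shrinks the training budget.
small_pipeline_config <- function(seed = 1L) {
  list(seed = seed, vae_epochs = 60L, vae_hidden = 64L,
       gcn_epochs = 300L, top_n = 30L)
}

# The full-scale recovery benchmark shared by the acceptance tests:
# 5 types x 600 cells x 1500 genes, fold-change 10, 200 regular spots,
# pipeline defaults.
recovery_benchmark <- function() memo("recovery_benchmark", {
  cfg <- synthetic_config(seed = 11)
  sc <- make_synthetic_scrna(cfg)
  sim <- simulate_regular(sc, n_spots = 200L, seed = 12)
  fit <- deconvolve(sc, sim$st, config = list(seed = 13))
  truth <- sim$proportions[fit$spot_ids, fit$type_names]
  list(sc = sc, sim = sim, fit = fit, truth = truth,
       metrics = evaluate_deconvolution(fit, truth))
})

# Deterministic toy stacked matrix + graph for network unit tests.
toy_stacked <- function(m = 3, n = 6, g = 4, seed = 7) {
  set.seed(seed)
  X <- matrix(runif((m + n) * g, 0, 2), m + n, g)
  rownames(X) <- c(paste0("t", seq_len(m)), paste0("s", seq_len(n)))
  structure(list(X = X,
                 node_roles = c(rep("celltype", m), rep("spot", n)),
                 gene_names = paste0("g", seq_len(g)), m = m, n = n,
                 type_names = paste0("t", seq_len(m)),
                 spot_ids = paste0("s", seq_len(n))),
            class = "stacked_matrix")
}
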