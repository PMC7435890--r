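#' Project latent embeddings to two UMAP dimensions
#'
#' Runs Uniform Manifold Approximation and Projection (via the umap-learn
#' reference implementation) on the embedding's numeric columns with default
#' parameters and a fixed, recorded seed.  The first two UMAP dimensions are
#' the coordinate space of the EU-Sim metric and of chemical-space maps.
#' UMAP is a stochastic embedding: coordinates are reproducible only for the
#' same input set, seed and library version.
#'
#' @param emb Embedding tibble (`id` + numeric columns) with at least 10
#'   rows.
#' @param seed Integer random state for the projection.
#' @param n_neighbors,min_dist UMAP parameters (defaults 15 and 0.1, the
#'   library defaults).
#' @return Embedding tibble with columns `id`, `u1`, `u2` and attributes
#'   `umap_seed` and `normalization`.
#' @export
umap_project <- function(emb, seed = 42L, n_neighbors = 15L, min_dist = 0.1) {
  m <- embedding_matrix(emb)
  if (nrow(m) < 10L) {
    abort(sprintf("UMAP projection needs at least 10 points, got %d", nrow(m)))
  }
  if (n_neighbors >= nrow(m)) {
    abort(sprintf("n_neighbors = %d requires more than %d points",
                  n_neighbors, n_neighbors))
  }
  csv <- apply(m, 1L, function(r) paste(format(r, digits = 17), collapse = ","))
  out <- run_chem_tool(
    c("umap", "--seed", as.integer(seed),
      "--n-neighbors", as.integer(n_neighbors),
      "--min-dist", format(min_dist)),
    input = csv
  )
  coords <- do.call(rbind, lapply(strsplit(out, ","), as.numeric))
  if (nrow(coords) != nrow(m) || ncol(coords) != 2L) {
    abort("UMAP helper returned malformed coordinates")
  }
  res <- tibble(id = emb$id, u1 = coords[, 1L], u2 = coords[, 2L])
  attr(res, "umap_seed") <- as.integer(seed)
  attr(res, "normalization") <- attr(emb, "normalization") %||% "none"
  res
}
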