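# Latent-space similarity: sim(x, y) = 1 / (1 + d(x, y)) with d the
# Euclidean distance.  E-Sim is this metric on the full latent vectors
# (100-d at reference scale); EU-Sim is the same functional form on the 2-d
# UMAP projection.  1/sim - 1 recovers d, a true metric.

#' Euclidean latent similarity (E-Sim)
#'
#' `1 / (1 + d(x, y))` where `d` is the Euclidean distance
#' `sqrt(sum((x - y)^2))`.  The value lies in `(0, 1]`, equals 1 exactly when
#' `x == y`, is symmetric, and decreases strictly with distance.  Set
#' `squared = TRUE` for the variant that divides by `1 +` the *squared*
#' distance (the formula as typeset, without the radical).
#'
#' @param x,y Numeric vectors of equal length (100 at reference scale).
#' @param squared Use the squared-distance variant.
#' @return Scalar similarity in `(0, 1]`.
#' @examples
#' e_sim(1:100, 1:100)            # 1
#' x <- rep(0, 100); y <- x; y[1] <- 3
#' e_sim(x, y)                    # 1 / (1 + 3) = 0.25
#' @export
e_sim <- function(x, y, squared = FALSE) {
  if (length(x) != length(y)) {
    abort(sprintf("length mismatch: %d vs %d", length(x), length(y)))
  }
  d2 <- sum((x - y)^2)
  1 / (1 + if (squared) d2 else sqrt(d2))
}

#' Euclidean similarity in UMAP space (EU-Sim)
#'
#' [e_sim()] restricted to 2-dimensional projected coordinates.
#'
#' @param u,v Numeric vectors of length 2.
#' @inheritParams e_sim
#' @return Scalar similarity in `(0, 1]`.
#' @examples
#' eu_sim(c(0, 0), c(3, 4))  # 1 / (1 + 5) = 1/6
#' @export
eu_sim <- function(u, v, squared = FALSE) {
  if (length(u) != 2L || length(v) != 2L) {
    abort("eu_sim expects 2-dimensional coordinates")
  }
  e_sim(u, v, squared = squared)
}

## ---- embedding tibbles ----

embedding_matrix <- function(emb) {
  stopifnot(is.data.frame(emb), "id" %in% names(emb))
  m <- as.matrix(emb[setdiff(names(emb), "id")])
  if (!is.numeric(m)) abort("embedding columns must be numeric")
  if (anyNA(m) || any(!is.finite(m))) abort("embedding contains non-finite values")
  if (anyDuplicated(emb$id)) abort("embedding ids must be unique")
  rownames(m) <- emb$id
  m
}

#' Normalize latent vectors across a corpus
#'
#' The reference protocol associates each molecule with a *normalised* latent
#' vector; the scheme itself is a modelling choice recorded in the output.
#' The default rescales each latent dimension to `[0, 1]` over the corpus
#' (min-max); `"zscore"` centres and scales instead, `"none"` passes through.
#' A dimension with zero range carries no information and is set to 0 with a
#' warning.
#'
#' @param emb Embedding tibble (`id` + numeric columns) with at least 2 rows.
#' @param scheme `"minmax"`, `"zscore"` or `"none"`.
#' @return Embedding tibble of the same shape, with attribute
#'   `normalization` recording the scheme.
#' @export
normalize_latents <- function(emb, scheme = c("minmax", "zscore", "none")) {
  scheme <- match.arg(scheme)
  m <- embedding_matrix(emb)
  if (nrow(m) < 2L && scheme != "none") {
    abort("need at least 2 vectors to normalize over a corpus")
  }
  if (scheme == "minmax") {
    rng <- apply(m, 2L, range)
    span <- rng[2L, ] - rng[1L, ]
    flat <- span == 0
    if (any(flat)) {
      warn(sprintf("%d zero-range dimension(s) set to 0", sum(flat)))
      span[flat] <- 1
    }
    m <- sweep(sweep(m, 2L, rng[1L, ], "-"), 2L, span, "/")
    m[, flat] <- 0
  } else if (scheme == "zscore") {
    mu <- colMeans(m)
    sdv <- apply(m, 2L, stats::sd)
    flat <- sdv == 0
    if (any(flat)) {
      warn(sprintf("%d zero-range dimension(s) set to 0", sum(flat)))
      sdv[flat] <- 1
    }
    m <- sweep(sweep(m, 2L, mu, "-"), 2L, sdv, "/")
    m[, flat] <- 0
  }
  out <- dplyr::bind_cols(tibble(id = emb$id), as_tibble(m, .name_repair = "minimal"))
  attr(out, "normalization") <- scheme
  out
}

## ---- similarity matrices ----

metric_fun <- function(metric) {
  if (is.function(metric)) return(metric)
  switch(match.arg(metric, c("e", "eu")), e = e_sim, eu = eu_sim)
}

#' All-vs-all similarity matrix
#'
#' Computes `metric(a_i, b_j)` for every row pair of two embedding sets (or
#' one set against itself), vectorised through the cross squared-distance
#' identity rather than a double loop.
#'
#' @param set_a,set_b Embedding tibbles (`id` + numeric columns) of equal
#'   dimensionality; `set_b` defaults to `set_a`.
#' @param metric `"e"`, `"eu"`, or a function of two vectors.
#' @param squared Use the squared-distance similarity variant.
#' @return A `sim_matrix`: numeric matrix in `(0, 1]` with row/column names
#'   from the ids, symmetric with unit diagonal for a set against itself.
#' @export
all_vs_all <- function(set_a, set_b = set_a, metric = "e", squared = FALSE) {
  A <- embedding_matrix(set_a)
  B <- embedding_matrix(set_b)
  if (ncol(A) != ncol(B)) {
    abort(sprintf("dimension mismatch: %d vs %d", ncol(A), ncol(B)))
  }
  if (is.function(metric)) {
    vals <- outer(seq_len(nrow(A)), seq_len(nrow(B)),
                  Vectorize(function(i, j) metric(A[i, ], B[j, ])))
  } else {
    metric_fun(metric)   # validates the name
    # row-wise differences rather than the ||a||^2 + ||b||^2 - 2ab identity:
    # the latter loses precision and breaks the exact unit diagonal
    tB <- t(B)
    d2 <- vapply(seq_len(nrow(A)),
                 function(i) colSums((tB - A[i, ])^2),
                 numeric(nrow(B)))
    d2 <- t(matrix(d2, nrow = nrow(B)))
    vals <- 1 / (1 + if (squared) d2 else sqrt(d2))
  }
  dimnames(vals) <- list(rownames(A), rownames(B))
  structure(vals, class = c("sim_matrix", "matrix"))
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat(sprintf("<sim_matrix> %d x %d, values in [%.3f, %.3f]\n",
              nrow(x), ncol(x), min(x), max(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE])
  invisible(x)
}

#' Rank drugs by their closest similarity to any metabolite
#'
#' For each row of `drugs`, the single best similarity over all rows of
#' `metabolites`, sorted most-similar first (ties broken by drug id).  This
#' is the rank-ordering used to compare similarity measures across a
#' drug/metabolite panel.
#'
#' @param drugs,metabolites Embedding tibbles of equal dimensionality.
#' @param metric `"e"`, `"eu"` or a function of two vectors.
#' @param squared Use the squared-distance similarity variant.
#' @return Tibble `drug_id`, `best_metabolite_id`, `similarity`, ordered by
#'   descending similarity.
#' @export
rank_order_best_match <- function(drugs, metabolites, metric = "e",
                                  squared = FALSE) {
  S <- all_vs_all(drugs, metabolites, metric = metric, squared = squared)
  best_j <- apply(S, 1L, which.max)
  out <- tibble(
    drug_id = rownames(S),
    best_metabolite_id = colnames(S)[best_j],
    similarity = S[cbind(seq_len(nrow(S)), best_j)]
  )
  dplyr::arrange(out, dplyr::desc(.data$similarity), .data$drug_id)
}

#' Top-k nearest neighbours of a query molecule
#'
#' The `k` corpus members most similar to the query (the query itself, when a
#' corpus row, is excluded), in descending similarity with ties broken by id.
#' The canonical screening question is "the 50 most similar molecules".
#'
#' @param query_id Id of the query row within `corpus`, or a one-row
#'   embedding tibble for an external query.
#' @param corpus Embedding tibble.
#' @param metric `"e"`, `"eu"` or a function of two vectors.
#' @param k Number of neighbours (default 50); if `k` exceeds the number of
#'   candidates all are returned with a warning.
#' @param squared Use the squared-distance similarity variant.
#' @return Tibble `id`, `similarity` with at most `k` rows.
#' @export
top_k_neighbors <- function(query_id, corpus, metric = "e", k = 50L,
                            squared = FALSE) {
  if (is.data.frame(query_id)) {
    stopifnot(nrow(query_id) == 1L)
    q <- query_id
    drop_id <- NULL
  } else {
    if (!query_id %in% corpus$id) {
      abort(sprintf("query id '%s' not found in corpus", query_id))
    }
    q <- corpus[corpus$id == query_id, , drop = FALSE]
    drop_id <- query_id
  }
  S <- all_vs_all(q, corpus, metric = metric, squared = squared)
  sims <- tibble(id = colnames(S), similarity = as.numeric(S[1L, ]))
  if (!is.null(drop_id)) sims <- sims[sims$id != drop_id, , drop = FALSE]
  if (k > nrow(sims)) {
    warn(sprintf("k = %d exceeds corpus size %d; returning all", k, nrow(sims)))
    k <- nrow(sims)
  }
  sims <- dplyr::arrange(sims, dplyr::desc(.data$similarity), .data$id)
  sims[seq_len(k), , drop = FALSE]
}
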