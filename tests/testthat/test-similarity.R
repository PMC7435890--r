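test_that("similarity closed forms hold exactly", {
  expect_identical(e_sim(1:100, 1:100), 1)
  x <- rep(0, 100); y <- x; y[17] <- 3
  expect_equal(e_sim(x, y), 0.25)            # 1 / (1 + 3)
  expect_equal(eu_sim(c(0, 0), c(3, 4)), 1 / 6)  # 3-4-5 triangle
  expect_equal(eu_sim(c(1, 2), c(4, 6)), eu_sim(c(4, 6), c(1, 2)))
  # squared-distance variant divides by 1 + d^2
  expect_equal(e_sim(x, y, squared = TRUE), 1 / 10)
  expect_error(e_sim(1:3, 1:4), "mismatch")
  expect_error(eu_sim(1:3, 1:3), "2-dimensional")
})

test_that("similarity metrics satisfy the metric axioms on random triples", {
  vaesim:::with_local_seed(99, {
    for (i in 1:200) {
      d <- sample(c(2L, 10L, 100L), 1)
      x <- rnorm(d); y <- rnorm(d); z <- rnorm(d)
      f <- if (d == 2L) eu_sim else e_sim
      sxy <- f(x, y); sxz <- f(x, z); syz <- f(y, z)
      for (s in c(sxy, sxz, syz)) { expect_gt(s, 0); expect_lte(s, 1) }
      expect_equal(f(x, x), 1)
      expect_equal(sxy, f(y, x))
      # 1/sim - 1 recovers the Euclidean distance: triangle inequality
      dxy <- 1 / sxy - 1; dxz <- 1 / sxz - 1; dyz <- 1 / syz - 1
      expect_lte(dxy, dxz + dyz + 1e-12)
      # strict monotone decrease with distance
      expect_equal(sxy, 1 / (1 + sqrt(sum((x - y)^2))))
    }
  })
})

test_that("normalization schemes behave and are recorded", {
  emb <- fake_embedding(2, d = 3)
  mm <- normalize_latents(emb, "minmax")
  m <- vaesim:::embedding_matrix(mm)
  expect_true(all(sort(unique(as.numeric(m))) %in% c(0, 1)))
  expect_identical(attr(mm, "normalization"), "minmax")

  emb5 <- fake_embedding(5, d = 3)
  once <- normalize_latents(emb5, "minmax")
  twice <- normalize_latents(once, "minmax")
  expect_equal(vaesim:::embedding_matrix(once),
               vaesim:::embedding_matrix(twice))

  expect_identical(vaesim:::embedding_matrix(normalize_latents(emb5, "none")),
                   vaesim:::embedding_matrix(emb5))

  zs <- normalize_latents(emb5, "zscore")
  expect_equal(unname(colMeans(vaesim:::embedding_matrix(zs))), rep(0, 3))

  flat <- emb5
  flat$d2 <- 1
  expect_warning(out <- normalize_latents(flat, "minmax"), "zero-range")
  expect_identical(unique(out$d2), 0)
})

test_that("all-vs-all matrices are symmetric with unit diagonal and match direct calls", {
  emb <- fake_embedding(8, d = 5)
  S <- all_vs_all(emb, metric = "e")
  expect_s3_class(S, "sim_matrix")
  expect_equal(unname(diag(S)), rep(1, 8))
  expect_equal(unclass(S), t(unclass(S)), ignore_attr = TRUE)
  expect_true(all(S > 0 & S <= 1))

  one <- fake_embedding(1, d = 5)
  expect_equal(as.numeric(all_vs_all(one, one)), 1)

  # spot-check random cells against the scalar metric
  m <- vaesim:::embedding_matrix(emb)
  vaesim:::with_local_seed(4, {
    for (r in 1:10) {
      i <- sample(8, 1); j <- sample(8, 1)
      expect_equal(S[i, j], e_sim(m[i, ], m[j, ]))
    }
  })

  expect_error(all_vs_all(emb, fake_embedding(3, d = 2)), "mismatch")
})

test_that("rank ordering picks each drug's best metabolite and sorts", {
  drugs <- fake_embedding(6, d = 4, seed = 21, prefix = "drug")
  mets <- fake_embedding(9, d = 4, seed = 22, prefix = "met")
  ranked <- rank_order_best_match(drugs, mets)
  expect_identical(nrow(ranked), 6L)
  expect_true(all(diff(ranked$similarity) <= 0))
  S <- all_vs_all(drugs, mets)
  for (i in seq_len(nrow(ranked))) {
    row <- S[ranked$drug_id[i], ]
    expect_equal(ranked$similarity[i], max(row))
    expect_identical(ranked$best_metabolite_id[i], names(which.max(row)))
  }

  # a drug identical to a metabolite ranks first with similarity 1
  drugs2 <- drugs
  drugs2[1, -1] <- mets[5, -1]
  r2 <- rank_order_best_match(drugs2, mets)
  expect_identical(r2$drug_id[1], drugs2$id[1])
  expect_equal(r2$similarity[1], 1)
  expect_identical(r2$best_metabolite_id[1], mets$id[5])
})

test_that("top-k agrees with the exhaustive-sort oracle and is permutation-invariant", {
  corpus <- fake_embedding(60, d = 6, seed = 31)
  got <- top_k_neighbors("m010", corpus, k = 10)
  expect_identical(nrow(got), 10L)

  m <- vaesim:::embedding_matrix(corpus)
  sims <- apply(m, 1, function(r) e_sim(m["m010", ], r))
  oracle <- sort(sims[names(sims) != "m010"], decreasing = TRUE)
  expect_equal(got$similarity, unname(oracle[1:10]))
  expect_identical(got$id, names(oracle)[1:10])

  # permutation invariance
  perm <- vaesim:::with_local_seed(1, sample(nrow(corpus)))
  got2 <- top_k_neighbors("m010", corpus[perm, ], k = 10)
  expect_identical(got, got2)

  # duplicate of the query ranks first at similarity 1
  dup <- corpus
  dup[3, -1] <- dup[corpus$id == "m010", -1]
  expect_identical(top_k_neighbors("m010", dup, k = 3)$id[1], dup$id[3])
  expect_equal(top_k_neighbors("m010", dup, k = 3)$similarity[1], 1)

  expect_warning(all_nb <- top_k_neighbors("m010", corpus, k = 500), "exceeds")
  expect_identical(nrow(all_nb), 59L)
  full <- top_k_neighbors("m010", corpus, k = 59)
  expect_identical(full, all_nb)
})

test_that("UMAP projection is 2-d, seeded-deterministic, and keeps duplicates close", {
  emb <- fake_embedding(40, d = 8, seed = 41)
  emb[40, -1] <- emb[1, -1]    # exact duplicate of the first point
  p1 <- umap_project(emb, seed = 42)
  expect_identical(names(p1), c("id", "u1", "u2"))
  expect_identical(nrow(p1), 40L)
  expect_identical(attr(p1, "umap_seed"), 42L)

  p2 <- umap_project(emb, seed = 42)
  expect_identical(p1, p2)

  d_dup <- sqrt((p1$u1[40] - p1$u1[1])^2 + (p1$u2[40] - p1$u2[1])^2)
  spread <- stats::median(stats::dist(cbind(p1$u1, p1$u2)))
  expect_lt(d_dup, spread / 2)

  expect_error(umap_project(fake_embedding(5, d = 4)), "at least 10")
  expect_error(umap_project(emb, n_neighbors = 40L), "n_neighbors")
})
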