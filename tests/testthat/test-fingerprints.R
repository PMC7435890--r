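drug_smiles <- function(id) {
  set <- load_bundled_set("table1_inhibitors")
  set$smiles[set$id == id]
}

test_that("fingerprints are pure functions of the molecule, with standard dimensions", {
  clz <- drug_smiles("clozapine")
  fp <- compute_fingerprint(clz, "maccs")
  expect_s3_class(fp, "fingerprint")
  expect_identical(fp$nbits, 167L)          # MACCS keys
  expect_gt(length(fp$bits), 0)

  # two spellings of ethanol give identical bits for every method family
  for (m in c("maccs", "morgan", "atompair", "torsion", "rdkit")) {
    a <- compute_fingerprint("CCO", m)
    b <- compute_fingerprint("OCC", m)
    expect_identical(a$bits, b$bits)
  }

  mg <- compute_fingerprint(clz, "morgan", nbits = 2048L)
  expect_identical(mg$nbits, 2048L)
  expect_error(compute_fingerprint("C1CC", "maccs"), "invalid SMILES")
  expect_error(compute_fingerprint("CCO", "nosuch"), "arg")
})

test_that("tanimoto has the set-algebra closed forms", {
  mk <- function(bits) structure(list(bits = bits, nbits = 8L,
                                      method = "morgan",
                                      params = list()),
                                 class = "fingerprint")
  expect_identical(tanimoto(mk(c(0L, 3L, 5L)), mk(c(0L, 3L, 5L))), 1)
  expect_identical(tanimoto(mk(c(0L, 1L)), mk(c(2L, 3L))), 0)
  # a = 1100, b = 1010: one common bit, three in the union
  expect_equal(tanimoto(mk(c(0L, 1L)), mk(c(0L, 2L))), 1 / 3)
  expect_identical(tanimoto(mk(integer(0)), mk(integer(0))), 1)
  bad <- mk(1L); bad$method <- "maccs"
  expect_error(tanimoto(mk(1L), bad), "mismatch")

  real <- compute_fingerprints(c("CCO", "CCN"), "maccs")
  expect_equal(tanimoto(real[[1]], real[[2]]),
               tanimoto(real[[2]], real[[1]]))
})

test_that("top-k table populates cells only for top-ranked candidates", {
  panel <- load_bundled_set("table1_inhibitors")
  cand <- panel[panel$id != "clozapine", ]
  clz <- drug_smiles("clozapine")

  # fewer candidates than k: every cell present
  tab <- top50_table(clz, cand, methods = c("maccs", "torsion"))
  expect_identical(tab$id, cand$id)
  expect_false(anyNA(tab$maccs))
  expect_false(anyNA(tab$torsion))
  expect_identical(attr(tab, "k"), 50L)
  expect_type(attr(tab, "rdkit_version"), "character")

  # cells match direct tanimoto computation
  fps <- compute_fingerprints(c(clz, cand$smiles), "maccs")
  direct <- vapply(fps[-1], function(f) tanimoto(fps[[1]], f), numeric(1))
  expect_equal(tab$maccs, unname(direct))

  # k = 2 keeps exactly the two best per method
  tab2 <- top50_table(clz, cand, methods = "maccs", k = 2L)
  expect_identical(sum(!is.na(tab2$maccs)), 2L)
  expect_setequal(tab2$id[!is.na(tab2$maccs)],
                  cand$id[rank(-direct, ties.method = "min") <= 2])
})

test_that("published clozapine similarity panel reproduces at the default parameters", {
  panel <- load_bundled_set("table1_inhibitors")
  get <- function(other, method) {
    fps <- compute_fingerprints(c(drug_smiles("clozapine"),
                                  drug_smiles(other)), method)
    tanimoto(fps[[1]], fps[[2]])
  }
  expect_lt(abs(get("olanzapine", "maccs") - 0.80), 0.0105)
  expect_lt(abs(get("olanzapine", "morgan") - 0.53), 0.0105)
  expect_lt(abs(get("olanzapine", "atompair") - 0.68), 0.0105)
  expect_lt(abs(get("chlorpromazine", "maccs") - 0.66), 0.0105)
  expect_lt(abs(get("quetiapine", "atompair") - 0.51), 0.0105)
  expect_lt(abs(get("prazosin", "torsion") - 0.37), 0.0105)
})

test_that("fingerprint-vs-latent scatter agrees with the independent rank ordering", {
  smi <- test_corpus()
  n <- 50L
  drugs <- tibble::tibble(id = sprintf("drug%03d", 1:n), smiles = smi[1:n])
  mets <- tibble::tibble(id = sprintf("met%03d", 1:n),
                         smiles = smi[n + 1:n])
  vae <- local({
    vocab <- build_vocabulary(smi)
    smiles_vae(vocab, reduced_vae_config(vocab$size), seed = 3)
  })
  emb <- encode_latent(vae, dplyr::bind_rows(drugs, mets))
  sc <- fingerprint_vs_vae_scatter(drugs, mets, "maccs", emb)
  expect_identical(nrow(sc), n)
  expect_identical(sc$drug_id, drugs$id)

  # latent column equals the similarity module's own computation
  ranked <- rank_order_best_match(emb[match(drugs$id, emb$id), ],
                                  emb[match(mets$id, emb$id), ])
  joined <- ranked[match(sc$drug_id, ranked$drug_id), ]
  expect_equal(sc$esim_best, joined$similarity)
  expect_identical(sc$esim_best_metabolite, joined$best_metabolite_id)

  # fingerprint column equals a brute-force scan
  fp_d <- compute_fingerprints(drugs$smiles, "maccs")
  fp_m <- compute_fingerprints(mets$smiles, "maccs")
  for (i in c(1L, 17L, 50L)) {
    v <- vapply(fp_m, function(f) tanimoto(fp_d[[i]], f), numeric(1))
    expect_equal(sc$ts_best[i], max(v))
  }

  # identical measures on both axes give Spearman correlation 1
  sc_same <- fingerprint_vs_vae_scatter(drugs, mets, "maccs", emb)
  expect_equal(stats::cor(sc_same$ts_best, sc_same$ts_best,
                          method = "spearman"), 1)
  expect_true(abs(attr(sc, "spearman")) <= 1)

  expect_error(fingerprint_vs_vae_scatter(drugs, mets, "maccs", emb[-1, ]),
               "missing")
})
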