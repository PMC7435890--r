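test_that("full-scale configuration reproduces every printed layer size", {
  cfg <- vae_config()
  # convolved axis shrinks 40 -> 32 -> 24 -> 14 under kernels 9/9/11
  expect_identical(cfg$conv_out_len,
                   cfg$vocab_size - sum(cfg$conv_kernels - 1L))
  expect_identical(cfg$conv_out_len, 14L)
  expect_identical(cfg$flatten_dim, 140L)
  expect_identical(cfg$latent_dim, 100L)
  expect_identical(cfg$dec_head_out, 248L)
  expect_identical(cfg$dec_steps, 40L)

  # the flatten feeds a Linear(140 -> 100)
  vocab <- build_vocabulary(c("CCO"))
  cfg2 <- vae_config(vocab_size = vocab$size, conv_kernels = c(1L, 1L, 1L))
  expect_error(vae_config(vocab_size = 10L), "do not fit")
})

test_that("encoder emits a finite latent posterior of the configured width", {
  vae <- tiny_vae()
  cfg <- vae$config
  onehot <- encode_one_hot("CCO", vae$vocab, cfg$max_len)
  post <- encoder_forward(vae, onehot)
  expect_s3_class(post, "latent_posterior")
  expect_length(post$mu, cfg$latent_dim)
  expect_length(post$logvar, cfg$latent_dim)
  expect_true(all(is.finite(post$mu)) && all(is.finite(post$logvar)))

  # all-pad input is still finite
  pad <- encode_one_hot("", vae$vocab, cfg$max_len)
  post2 <- encoder_forward(vae, pad)
  expect_true(all(is.finite(c(post2$mu, post2$logvar))))

  expect_error(encoder_forward(vae, matrix(0, 3, 3)), "expected")
})

test_that("reparameterization is seeded, centred on mu, and collapses at zero variance", {
  post <- structure(list(mu = c(1, -2, 0.5), logvar = c(0, 0, 0)),
                    class = "latent_posterior")
  z1 <- reparameterize(post, seed = 5)
  z2 <- reparameterize(post, seed = 5)
  expect_identical(z1, z2)

  frozen <- structure(list(mu = c(1, -2, 0.5), logvar = rep(-1e6, 3)),
                      class = "latent_posterior")
  expect_equal(reparameterize(frozen, seed = 1), frozen$mu)

  # Monte-Carlo mean over many draws approaches mu
  post2 <- structure(list(mu = c(2, -1), logvar = c(0.3, -0.2)),
                     class = "latent_posterior")
  draws <- vaesim:::with_local_seed(42, {
    rowMeans(vapply(1:1e5, function(i) reparameterize(post2), numeric(2)))
  })
  expect_equal(draws, post2$mu, tolerance = 0.02)
})

test_that("decoder output is a deterministic probability-like matrix", {
  for (orientation in c("conventional", "paper")) {
    vae <- tiny_vae(orientation = orientation,
                    conv_kernels = c(2L, 2L, 3L), max_len = 16L)
    cfg <- vae$config
    z <- vaesim:::with_local_seed(3, rnorm(cfg$latent_dim))
    p1 <- decoder_forward(vae, z)
    p2 <- decoder_forward(vae, z)
    expect_identical(p1, p2)
    expect_identical(dim(p1), c(cfg$max_len, cfg$vocab_size))
    expect_true(all(p1 >= 0 & p1 <= 1))
    sums <- if (orientation == "paper") colSums(p1) else rowSums(p1)
    expect_equal(unname(sums), rep(1, length(sums)), tolerance = 1e-12)
  }
  expect_error(decoder_forward(tiny_vae(), 1:3), "length")
})

test_that("KL divergence matches its closed form", {
  expect_equal(kl_divergence(rep(0, 100), rep(0, 100)), 0)
  e1 <- c(1, rep(0, 99))
  expect_equal(kl_divergence(e1, rep(0, 100)), 0.5)
  # hand-computed general case: mu = 0.3, logvar = 0.7, one dimension
  mu <- 0.3; lv <- 0.7
  expect_equal(kl_divergence(mu, lv), -0.5 * (1 + lv - mu^2 - exp(lv)))
  expect_true(kl_divergence(rnorm(10), rnorm(10)) >= 0)
})

test_that("loss is BCE + KL, zero only at perfect reconstruction and standard posterior", {
  v <- build_vocabulary("CCO")
  target <- encode_one_hot("CCO", v, 6L)
  post0 <- structure(list(mu = rep(0, 4), logvar = rep(0, 4)),
                     class = "latent_posterior")
  probs <- pmin(pmax(target, 1e-7), 1 - 1e-7)
  l <- vae_loss(probs, target, post0)
  expect_equal(as.numeric(l), 0, tolerance = 1e-4)
  expect_equal(attr(l, "kl"), 0)

  post1 <- structure(list(mu = c(1, 0, 0, 0), logvar = rep(0, 4)),
                     class = "latent_posterior")
  l1 <- vae_loss(probs, target, post1)
  expect_equal(attr(l1, "kl"), 0.5)
  expect_gt(as.numeric(l1), 0)

  expect_error(vae_loss(probs * 2, target, post0), "0, 1")
})

test_that("analytic gradients match central finite differences", {
  # jitter parameters so no ReLU unit sits exactly at its kink (the one-hot
  # input otherwise leaves untouched conv windows at exactly zero)
  check_orientation <- function(orientation) {
    cfg <- vae_config(max_len = 10L, vocab_size = 8L,
                      conv_channels = c(3L, 3L, 4L),
                      conv_kernels = c(2L, 2L, 3L), latent_dim = 5L,
                      gru_hidden = 7L, gru_layers = 2L,
                      orientation = orientation)
    vaesim:::with_local_seed(3, {
      params <- vaesim:::init_vae_params(cfg)
      params <- rapply(params, function(x) x + rnorm(length(x), sd = 0.05),
                       how = "replace")
      B <- 2L
      X <- array(0, dim = c(B, cfg$max_len, cfg$vocab_size))
      for (b in seq_len(B)) {
        X[cbind(b, seq_len(cfg$max_len),
                sample(cfg$vocab_size, cfg$max_len, TRUE))] <- 1
      }
      eps <- matrix(rnorm(B * cfg$latent_dim), B)
      res <- vaesim:::vae_forward_backward(cfg, params, X, eps, pad_col = 1L)
      lossfn <- function(p) {
        vaesim:::vae_forward_backward(cfg, p, X, eps, pad_col = 1L)$loss
      }
      flat_paths <- function(p, prefix = character()) {
        if (!is.list(p)) return(list(prefix))
        unlist(lapply(names(p), function(nm) {
          flat_paths(p[[nm]], c(prefix, nm))
        }), recursive = FALSE)
      }
      assign_leaf <- function(p, pa, val) {
        if (length(pa) == 1) p[[pa]] <- val
        else p[[pa[1]]] <- assign_leaf(p[[pa[1]]], pa[-1], val)
        p
      }
      h <- 1e-5
      for (pa in flat_paths(params)) {
        leaf <- params; g <- res$grads
        for (nm in pa) { leaf <- leaf[[nm]]; g <- g[[nm]] }
        for (i in sample(length(leaf), min(2, length(leaf)))) {
          l1 <- leaf; l1[i] <- l1[i] + h
          l2 <- leaf; l2[i] <- l2[i] - h
          num <- (lossfn(assign_leaf(params, pa, l1)) -
                    lossfn(assign_leaf(params, pa, l2))) / (2 * h)
          expect_equal(g[i], num, tolerance = 1e-4,
                       label = paste(orientation, paste(pa, collapse = "$")))
        }
      }
    })
  }
  check_orientation("conventional")
  check_orientation("paper")
})

test_that("checkpoints round-trip the model exactly", {
  vae <- tiny_vae()
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(vae, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, vae$params, tolerance = 1e-12)
  expect_identical(back$vocab$characters, vae$vocab$characters)
  expect_identical(unclass(back$config)[order(names(back$config))],
                   unclass(vae$config)[order(names(vae$config))])
  # identical encodings through the restored model
  s <- "CCO"
  oh <- encode_one_hot(s, vae$vocab, vae$config$max_len)
  expect_equal(encoder_forward(back, oh)$mu, encoder_forward(vae, oh)$mu,
               tolerance = 1e-12)
  expect_error(load_checkpoint(withr::local_tempfile(lines = "{}")),
               "format")
})
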