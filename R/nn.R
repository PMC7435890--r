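# Minimal neural-network layer library: forward passes cache what the
# hand-derived backward passes need.  Batches are stored as arrays with the
# batch index first, (B, T, C), so that flattening the first two axes is a
# plain dim<- in column-major order.  Everything is double precision and
# deterministic given the RNG state; correctness is pinned by a central
# finite-difference gradient check in the test suite.

## ---- initialisation ----

xavier_uniform <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  a <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -a, a), dim = dims)
}

## ---- activations ----

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}
relu_bwd <- function(x, dy) dy * (x > 0)

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

selu_fwd <- function(x) {
  SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * expm1(x))
}
selu_bwd <- function(x, dy) {
  dy * SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(x))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax of a matrix (numerically stabilised).
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}
# d(loss)/d(logits) given probs p and upstream gradient g, row-wise groups.
softmax_rows_bwd <- function(p, g) {
  p * (g - rowSums(p * g))
}

## ---- linear ----

linear_fwd <- function(x, W, b) {
  list(out = sweep(x %*% W, 2L, b, "+"), x = x)
}
linear_bwd <- function(cache, W, dy) {
  list(dx = dy %*% t(W),
       dW = crossprod(cache$x, dy),
       db = colSums(dy))
}

## ---- 1-d convolution (valid, stride 1) ----
# x: (B, L, Cin); W: (k*Cin, Cout) with rows ordered kernel-position-major
# (j = 1..k, each block of Cin channels); b: (Cout).  Output (B, L-k+1, Cout).

conv1d_im2col <- function(x, k) {
  d <- dim(x)
  B <- d[1]; L <- d[2]; Cin <- d[3]
  Lout <- L - k + 1L
  cols <- vector("list", k)
  for (j in seq_len(k)) {
    sl <- x[, j:(j + Lout - 1L), , drop = FALSE]
    dim(sl) <- c(B * Lout, Cin)
    cols[[j]] <- sl
  }
  do.call(cbind, cols)
}

conv1d_fwd <- function(x, W, b) {
  d <- dim(x)
  k <- nrow(W) / d[3]
  Lout <- d[2] - k + 1L
  M <- conv1d_im2col(x, k)
  y <- sweep(M %*% W, 2L, b, "+")
  dim(y) <- c(d[1], Lout, ncol(W))
  list(out = y, M = M, in_dim = d, k = k)
}

conv1d_bwd <- function(cache, W, dy) {
  d <- cache$in_dim
  B <- d[1]; L <- d[2]; Cin <- d[3]
  k <- cache$k
  Lout <- L - k + 1L
  dy2 <- dy
  dim(dy2) <- c(B * Lout, dim(dy)[3])
  dW <- crossprod(cache$M, dy2)
  db <- colSums(dy2)
  dM <- dy2 %*% t(W)
  dx <- array(0, dim = d)
  for (j in seq_len(k)) {
    blk <- dM[, ((j - 1L) * Cin + 1L):(j * Cin), drop = FALSE]
    dim(blk) <- c(B, Lout, Cin)
    dx[, j:(j + Lout - 1L), ] <- dx[, j:(j + Lout - 1L), , drop = FALSE] + blk
  }
  list(dx = dx, dW = dW, db = db)
}

## ---- GRU ----
# Gate layout in the weight matrices: columns [reset | update | new], each of
# width H.  Wi: (input_dim, 3H); Wh: (H, 3H); separate input/hidden biases so
# the reset gate can act inside the candidate term:
#   r = s(x Wi_r + bi_r + h Wh_r + bh_r)
#   z = s(x Wi_z + bi_z + h Wh_z + bh_z)
#   n = tanh(x Wi_n + bi_n + r * (h Wh_n + bh_n))
#   h' = (1 - z) * n + z * h

gru_init <- function(input_dim, hidden) {
  list(Wi = xavier_uniform(input_dim, 3L * hidden),
       Wh = xavier_uniform(hidden, 3L * hidden),
       bi = numeric(3L * hidden),
       bh = numeric(3L * hidden))
}

gru_layer_fwd <- function(x, p) {
  d <- dim(x)
  B <- d[1]; Tt <- d[2]
  H <- ncol(p$Wh) / 3L
  iR <- seq_len(H); iZ <- H + iR; iN <- 2L * H + iR
  h <- matrix(0, B, H)
  out <- array(0, dim = c(B, Tt, H))
  steps <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    xt <- matrix(x[, t, ], nrow = B)
    gi <- sweep(xt %*% p$Wi, 2L, p$bi, "+")
    gh <- sweep(h %*% p$Wh, 2L, p$bh, "+")
    r <- sigmoid(gi[, iR, drop = FALSE] + gh[, iR, drop = FALSE])
    z <- sigmoid(gi[, iZ, drop = FALSE] + gh[, iZ, drop = FALSE])
    ghn <- gh[, iN, drop = FALSE]
    n <- tanh(gi[, iN, drop = FALSE] + r * ghn)
    steps[[t]] <- list(x = xt, h_prev = h, r = r, z = z, n = n, ghn = ghn)
    h <- (1 - z) * n + z * h
    out[, t, ] <- h
  }
  list(out = out, steps = steps, H = H)
}

gru_layer_bwd <- function(cache, p, dout) {
  H <- cache$H
  iR <- seq_len(H); iZ <- H + iR; iN <- 2L * H + iR
  Tt <- length(cache$steps)
  B <- nrow(cache$steps[[1]]$x)
  dWi <- matrix(0, nrow(p$Wi), ncol(p$Wi))
  dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  dbi <- numeric(3L * H); dbh <- numeric(3L * H)
  dx <- array(0, dim = c(B, Tt, nrow(p$Wi)))
  dh <- matrix(0, B, H)
  for (t in rev(seq_len(Tt))) {
    st <- cache$steps[[t]]
    dh_t <- dh + matrix(dout[, t, ], nrow = B)
    dz <- dh_t * (st$h_prev - st$n)
    dn <- dh_t * (1 - st$z)
    dh_direct <- dh_t * st$z
    dn_pre <- dn * (1 - st$n^2)
    dr <- dn_pre * st$ghn
    dghn <- dn_pre * st$r
    dz_pre <- dz * st$z * (1 - st$z)
    dr_pre <- dr * st$r * (1 - st$r)
    dgi <- cbind(dr_pre, dz_pre, dn_pre)
    dgh <- cbind(dr_pre, dz_pre, dghn)
    dWi <- dWi + crossprod(st$x, dgi)
    dWh <- dWh + crossprod(st$h_prev, dgh)
    dbi <- dbi + colSums(dgi)
    dbh <- dbh + colSums(dgh)
    dx[, t, ] <- dgi %*% t(p$Wi)
    dh <- dgh %*% t(p$Wh) + dh_direct
  }
  list(dx = dx, dWi = dWi, dWh = dWh, dbi = dbi, dbh = dbh)
}

gru_stack_fwd <- function(x, layers) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    res <- gru_layer_fwd(x, layers[[l]])
    caches[[l]] <- res
    x <- res$out
  }
  list(out = x, caches = caches)
}

gru_stack_bwd <- function(cache, layers, dout) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    g <- gru_layer_bwd(cache$caches[[l]], layers[[l]], dout)
    grads[[l]] <- g[c("dWi", "dWh", "dbi", "dbh")]
    dout <- g$dx
  }
  list(dx = dout, grads = grads)
}

## ---- losses ----

BCE_EPS <- 1e-7

bce_sum <- function(p, target) {
  p <- pmin(pmax(p, BCE_EPS), 1 - BCE_EPS)
  -sum(target * log(p) + (1 - target) * log(1 - p))
}

bce_sum_bwd <- function(p, target) {
  p <- pmin(pmax(p, BCE_EPS), 1 - BCE_EPS)
  (p - target) / (p * (1 - p))
}

kl_standard_normal <- function(mu, logvar) {
  -0.5 * sum(1 + logvar - mu^2 - exp(logvar))
}

## ---- Adam ----

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- purrr::pmap(list(p, g, m, v), upd)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}
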