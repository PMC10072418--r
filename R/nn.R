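# Small CNN backbone: hand-rolled layers over the C++ conv/pool kernels.
# Batches are arrays dim (H, W, 3, N) with raw pixel values in [0, 255];
# forward() normalizes to [-0.5, 0.5]. Architecture ("small_cnn"):
#   avgpool2 stem -> [conv3x3 -> ReLU -> maxpool2] x2 -> conv3x3 -> ReLU
#   -> global average pool (embedding, `embed_dim` channels)
#   -> FC(embed_dim -> embed_dim/2) -> ReLU -> FC(-> 1) -> sigmoid.
# Input side must be a multiple of 8 so every pooling stage divides evenly.

sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

nn_channels <- function(embed_dim) {
  stopifnot(embed_dim >= 4, embed_dim %% 4 == 0)
  c(embed_dim %/% 4, embed_dim %/% 2, embed_dim)
}

# He-style initialization; all randomness comes from the caller's RNG state.
nn_init_params <- function(embed_dim = 64L, in_channels = 3L) {
  ch <- nn_channels(embed_dim)
  hidden <- embed_dim %/% 2L
  conv_init <- function(cin, cout) {
    fan_in <- 9L * cin
    matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
  }
  fc_init <- function(din, dout) {
    matrix(rnorm(din * dout, sd = sqrt(2 / din)), din, dout)
  }
  list(
    w1 = conv_init(in_channels, ch[1]), b1 = numeric(ch[1]),
    w2 = conv_init(ch[1], ch[2]),       b2 = numeric(ch[2]),
    w3 = conv_init(ch[2], ch[3]),       b3 = numeric(ch[3]),
    wf1 = fc_init(embed_dim, hidden),   bf1 = numeric(hidden),
    wf2 = fc_init(hidden, 1L),          bf2 = numeric(1L)
  )
}

nn_add_bias <- function(x, b) {
  d <- dim(x)
  x + rep(rep(b, each = d[1] * d[2]), times = d[4])
}

nn_gap <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3] * d[4])
  m <- colMeans(x)
  matrix(m, d[3], d[4])  # C x N
}

# Forward pass; with cache = TRUE returns intermediates for backprop.
nn_forward <- function(params, x, cache = FALSE) {
  x <- x / 255 - 0.5
  s0 <- cpp_avgpool_fw(x)
  r1 <- cpp_relu_fw(nn_add_bias(cpp_conv_fw(s0, params$w1, 3L), params$b1))
  p1 <- cpp_maxpool_fw(r1)
  r2 <- cpp_relu_fw(nn_add_bias(cpp_conv_fw(p1$out, params$w2, 3L), params$b2))
  p2 <- cpp_maxpool_fw(r2)
  r3 <- cpp_relu_fw(nn_add_bias(cpp_conv_fw(p2$out, params$w3, 3L), params$b3))
  emb <- nn_gap(r3)                       # embed_dim x N
  h <- pmax(crossprod(params$wf1, emb) + params$bf1, 0)   # hidden x N
  logit <- drop(crossprod(params$wf2, h)) + params$bf2    # length N
  prob <- sigmoid(logit)
  out <- list(prob = prob, logit = logit, embedding = emb)
  if (cache) {
    out$cache <- list(s0 = s0, r1 = r1, p1 = p1, r2 = r2, p2 = p2,
                      r3 = r3, emb = emb, h = h)
  }
  out
}

# Backward pass from d(loss)/d(logit) (length N); returns gradients shaped
# like params. The stem avgpool and input normalization need no gradients.
nn_backward <- function(params, fw, dlogit) {
  ca <- fw$cache
  n <- length(dlogit)
  dbf2 <- sum(dlogit)
  dwf2 <- matrix(ca$h %*% dlogit, ncol = 1L)
  dh <- params$wf2 %*% matrix(dlogit, nrow = 1L)          # hidden x N
  dh[ca$h <= 0] <- 0
  dbf1 <- rowSums(dh)
  dwf1 <- ca$emb %*% t(dh)                                # embed x hidden
  demb <- params$wf1 %*% dh                               # embed x N
  d3 <- dim(ca$r3)
  dr3 <- array(rep(demb, each = d3[1] * d3[2]) / (d3[1] * d3[2]), dim = d3)
  dr3 <- cpp_relu_bw(dr3, ca$r3)
  db3 <- cpp_bias_grad(dr3)
  g3 <- cpp_conv_bw(ca$p2$out, params$w3, 3L, dr3)
  dp2 <- cpp_relu_bw(cpp_maxpool_bw(ca$p2$idx, g3$dx, dim(ca$r2)), ca$r2)
  db2 <- cpp_bias_grad(dp2)
  g2 <- cpp_conv_bw(ca$p1$out, params$w2, 3L, dp2)
  dp1 <- cpp_relu_bw(cpp_maxpool_bw(ca$p1$idx, g2$dx, dim(ca$r1)), ca$r1)
  db1 <- cpp_bias_grad(dp1)
  g1 <- cpp_conv_bw(ca$s0, params$w1, 3L, dp1)
  list(w1 = g1$dw, b1 = db1, w2 = g2$dw, b2 = db2, w3 = g3$dw, b3 = db3,
       wf1 = dwf1, bf1 = dbf1, wf2 = dwf2, bf2 = dbf2)
}

# Adam optimizer over a named list of numeric arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 2e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
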