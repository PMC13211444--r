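# Differentiable primitives used throughout the network.  Every *_fwd
# returns list(out=..., <cache fields>); the matching *_bwd consumes the
# cache plus the upstream gradient and returns gradients for inputs and
# parameters.  All activations operate on B x d matrices (rows = samples).

LN_EPS <- 1e-5

linear_fwd <- function(x, W, b) {
  out <- x %*% W
  out <- sweep(out, 2L, b, `+`)
  list(out = out, x = x)
}

linear_bwd <- function(cache, W, dout) {
  list(dx = dout %*% t(W),
       dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

relu_fwd <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_bwd <- function(cache, dout) dout * cache$mask

gelu_fwd <- function(x) list(out = x * pnorm(x), x = x)
gelu_bwd <- function(cache, dout) {
  x <- cache$x
  dout * (pnorm(x) + x * dnorm(x))
}

# Row-wise layer normalization with learnable gain/shift.  An all-constant
# row has zero variance; the epsilon keeps the op total and maps it to the
# shift vector (zeros at initialization), the documented convention.
layernorm_fwd <- function(x, g, b, eps = LN_EPS) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(xhat, 2L, g, `*`)
  out <- sweep(out, 2L, b, `+`)
  list(out = out, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(cache, g, dout) {
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dout * xhat), db = colSums(dout))
}

softmax_bwd <- function(p, dout) {
  # p: row-softmax output, dout: upstream gradient; returns grad wrt logits
  p * (dout - rowSums(dout * p))
}

# ---- initializers -----------------------------------------------------------

init_dense <- function(fan_in, fan_out, scheme = c("he", "xavier")) {
  scheme <- match.arg(scheme)
  sd <- switch(scheme,
               he = sqrt(2 / fan_in),
               xavier = sqrt(2 / (fan_in + fan_out)))
  matrix(rnorm(fan_in * fan_out, sd = sd), fan_in, fan_out)
}

init_ln <- function(d) list(g = rep(1, d), b = rep(0, d))
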