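# Random weight builders shared by the backbone/neck tests.

rand_block_wts <- function(C, M, heads, mlp_ratio = 2, sd = 0.1,
                           zero_bias_tab = FALSE) {
  list(
    ln1.g = runif(C, 0.8, 1.2), ln1.b = rnorm(C, sd = 0.05),
    qkv.W = matrix(rnorm(C * 3 * C, sd = sd), C, 3 * C),
    qkv.b = rnorm(3 * C, sd = 0.05),
    bias  = if (zero_bias_tab) matrix(0, (2 * M - 1)^2, heads) else
              matrix(rnorm((2 * M - 1)^2 * heads, sd = 0.2), (2 * M - 1)^2, heads),
    proj.W = matrix(rnorm(C * C, sd = sd), C, C),
    proj.b = rnorm(C, sd = 0.05),
    ln2.g = runif(C, 0.8, 1.2), ln2.b = rnorm(C, sd = 0.05),
    mlp.W1 = matrix(rnorm(C * C * mlp_ratio, sd = sd), C, C * mlp_ratio),
    mlp.b1 = rnorm(C * mlp_ratio, sd = 0.05),
    mlp.W2 = matrix(rnorm(C * mlp_ratio * C, sd = sd), C * mlp_ratio, C),
    mlp.b2 = rnorm(C, sd = 0.05)
  )
}

# dense multi-head attention oracle on one set of tokens (rows), with
# optional additive bias matrix per head and allowed-pair mask
dense_attention_oracle <- function(X, qkv.W, qkv.b, heads,
                                   bias = NULL, allowed = NULL) {
  C <- ncol(X)
  d <- C / heads
  QKV <- sweep(X %*% qkv.W, 2, qkv.b, "+")
  Q <- QKV[, 1:C, drop = FALSE]
  K <- QKV[, C + 1:C, drop = FALSE]
  V <- QKV[, 2 * C + 1:C, drop = FALSE]
  out <- matrix(0, nrow(X), C)
  for (h in seq_len(heads)) {
    cls <- (h - 1) * d + 1:d
    S <- Q[, cls, drop = FALSE] %*% t(K[, cls, drop = FALSE]) / sqrt(d)
    if (!is.null(bias)) S <- S + bias[[h]]
    if (!is.null(allowed)) S[!allowed] <- -Inf
    P <- exp(S - apply(S, 1, max))
    P <- P / rowSums(P)
    out[, cls] <- P %*% V[, cls, drop = FALSE]
  }
  out
}
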