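# Central-difference numerical gradient of a scalar-valued function of a
# matrix/vector, used to validate every autodiff operation.
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Analytic gradient of `loss_fn(node)` w.r.t. the wrapped value.
ana_grad <- function(loss_fn, x) {
  ag_tape_start()
  on.exit(ag_tape_stop())
  p <- ag_param(x)
  loss <- loss_fn(p)
  ag_backward(loss)
  p$grad
}

check_op_grad <- function(loss_fn, x, tol = 1e-6) {
  ga <- ana_grad(loss_fn, x)
  gn <- num_grad(function(v) {
    p <- ag_const(v)
    loss_fn(p)$val
  }, x)
  expect_equal(as.vector(ga), as.vector(gn), tolerance = tol)
}
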