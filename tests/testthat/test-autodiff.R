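# The reverse-mode engine behind training: every op gradient-checked
# against central finite differences.

num_grad <- function(f, p, k, eps = 1e-6) {
  v0 <- p$val[k]
  p$val[k] <- v0 + eps; lp <- f()
  p$val[k] <- v0 - eps; lm <- f()
  p$val[k] <- v0
  (lp - lm) / (2 * eps)
}

check_grads <- function(f, params, n_probe = 4, tol = 2e-3) {
  base <- f()
  for (nm in names(params)) {
    p <- params[[nm]]
    expect_false(is.null(p$grad), label = sprintf("gradient present for %s", nm))
    ks <- sample(length(p$val), min(n_probe, length(p$val)))
    for (k in ks) {
      ng <- num_grad(f, p, k)
      ag <- as.numeric(p$grad)[k]
      expect_equal(ag, ng, tolerance = tol,
                   label = sprintf("d loss / d %s[%d] (ad %.6g vs fd %.6g)", nm, k, ag, ng))
    }
  }
  invisible(base)
}

test_that("elementwise and linear op gradients match finite differences", {
  set.seed(1)
  X <- matrix(rnorm(12), 4, 3)
  params <- list(W = diffecg:::ad_param(matrix(rnorm(6), 3, 2)),
                 b = diffecg:::ad_param(rnorm(2)),
                 g = diffecg:::ad_param(runif(3, 0.5, 1.5)),
                 s = diffecg:::ad_param(rnorm(3)))
  target <- matrix(rnorm(8), 4, 2)
  f <- function() {
    diffecg:::ad_reset_tape()
    diffecg:::ad_zero_grads(params)
    h <- diffecg:::ad_layernorm(diffecg:::ad_const(X), params$g, params$s)
    h <- diffecg:::ad_gelu(diffecg:::ad_linear(h, params$W, params$b))
    h <- diffecg:::ad_tanh(diffecg:::ad_mul(h, h))
    loss <- diffecg:::ad_mse(h, target)
    diffecg:::ad_backward(loss)
    loss$val
  }
  check_grads(f, params)
})

test_that("softmax, banded softmax and attention-style composition gradients", {
  set.seed(2)
  X <- matrix(rnorm(20), 5, 4)
  bi <- diffecg:::band_index(5L, 1L)
  params <- list(Wq = diffecg:::ad_param(matrix(rnorm(16), 4, 4)),
                 Wk = diffecg:::ad_param(matrix(rnorm(16), 4, 4)),
                 Wv = diffecg:::ad_param(matrix(rnorm(16), 4, 4)))
  target <- matrix(rnorm(20), 5, 4)
  f <- function() {
    diffecg:::ad_reset_tape()
    diffecg:::ad_zero_grads(params)
    Xn <- diffecg:::ad_const(X)
    S <- diffecg:::ad_tcrossprod(diffecg:::ad_matmul(Xn, params$Wq),
                                 diffecg:::ad_matmul(Xn, params$Wk), scale = 0.5)
    P <- diffecg:::ad_softmax_band(S, bi)
    O <- diffecg:::ad_matmul(P, diffecg:::ad_matmul(Xn, params$Wv))
    loss <- diffecg:::ad_mse(O, target)
    diffecg:::ad_backward(loss)
    loss$val
  }
  check_grads(f, params)
})

test_that("causal convolution and kernel-basis gradients", {
  set.seed(3)
  L <- 10L
  u <- matrix(rnorm(2 * L), L, 2)
  Mt <- list(matrix(rnorm(L * 3), L, 3), matrix(rnorm(L * 3), L, 3))
  params <- list(C = diffecg:::ad_param(matrix(rnorm(6), 2, 3)),
                 W = diffecg:::ad_param(matrix(rnorm(4), 2, 2)))
  target <- matrix(rnorm(2 * L), L, 2)
  f <- function() {
    diffecg:::ad_reset_tape()
    diffecg:::ad_zero_grads(params)
    un <- diffecg:::ad_linear(diffecg:::ad_const(u), params$W)
    K <- diffecg:::ad_ssm_kernels(params$C, Mt)
    y <- diffecg:::ad_causal_conv(un, K)
    loss <- diffecg:::ad_mse(y, target)
    diffecg:::ad_backward(loss)
    loss$val
  }
  check_grads(f, params)
})

test_that("bce-with-logits and shift/colmeans gradients", {
  set.seed(4)
  X <- matrix(rnorm(18), 6, 3)
  y <- matrix(rbinom(4, 1, 0.5), 1, 4)
  params <- list(W = diffecg:::ad_param(matrix(rnorm(12), 3, 4)),
                 b = diffecg:::ad_param(rnorm(4)))
  f <- function() {
    diffecg:::ad_reset_tape()
    diffecg:::ad_zero_grads(params)
    h <- diffecg:::ad_shift_rows(diffecg:::ad_const(X), 1L)
    z <- diffecg:::ad_linear(diffecg:::ad_colmeans(h), params$W, params$b)
    loss <- diffecg:::ad_bce_logits(z, y)
    diffecg:::ad_backward(loss)
    loss$val
  }
  check_grads(f, params)
})

test_that("a gradient step on a linear predictor decreases a fixed-batch loss", {
  set.seed(5)
  W <- diffecg:::ad_param(matrix(0, 3, 3))
  X <- matrix(rnorm(60), 20, 3)
  target <- X %*% matrix(c(1, 0.5, 0, 0, 1, 0, 0.2, 0, 1), 3, 3)
  loss_fn <- function() {
    diffecg:::ad_reset_tape()
    diffecg:::ad_zero_grads(list(W))
    loss <- diffecg:::ad_mse(diffecg:::ad_matmul(diffecg:::ad_const(X), W), target)
    diffecg:::ad_backward(loss)
    loss$val
  }
  opt <- diffecg:::adam_init(list(W = W), lr = 0.05)
  l0 <- loss_fn()
  diffecg:::adam_step(opt)
  l1 <- loss_fn()
  expect_lt(l1, l0)
})

test_that("ad_no_grad suppresses tape growth but not values", {
  diffecg:::ad_reset_tape()
  X <- matrix(1:6, 2, 3)
  v1 <- diffecg:::ad_no_grad(diffecg:::ad_val(diffecg:::ad_gelu(diffecg:::ad_const(X))))
  n_after <- diffecg:::.ad$k
  expect_equal(n_after, 0L)
  v2 <- diffecg:::ad_val(diffecg:::ad_gelu(diffecg:::ad_const(X)))
  expect_equal(v1, v2)
})
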