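# ssm_core: HiPPO construction, bilinear discretization, recurrent vs
# convolutional application.

test_that("build_hippo reproduces the printed formulas", {
  # N = 1: P0 = sqrt(1/2), B0 = 1, A00 = 1/2 - 1/2 = 0
  p1 <- build_hippo(1, delta = 0.01)
  expect_equal(p1$B, 1)
  expect_equal(p1$A[1, 1], 0)

  # N = 2: B_i = sqrt(2 i + 1)
  p2 <- build_hippo(2, delta = 0.01)
  expect_equal(p2$B, c(1, sqrt(3)))

  # N = 4: full matrix against independent entrywise evaluation, both forms
  for (form in c("printed", "s4")) {
    p4 <- build_hippo(4, delta = 0.01, form = form)
    expect_equal(p4$A, oracle_hippo_A(4, form), tolerance = 1e-12)
    expect_equal(p4$B, sqrt(2 * (0:3) + 1))
    expect_equal(p4$D, 0)
  }

  expect_error(build_hippo(0), "positive integer")
  expect_error(build_hippo(-3), "positive integer")
})

test_that("build_hippo's C draw is seeded and reproducible", {
  a <- build_hippo(6, seed = 42)
  b <- build_hippo(6, seed = 42)
  c2 <- build_hippo(6, seed = 43)
  expect_identical(a$C, b$C)
  expect_false(identical(a$C, c2$C))
})

test_that("discretize applies the bilinear transform", {
  # zero A: Abar = I, Bbar = delta B
  N <- 3
  p <- ssm_params(matrix(0, N, N), 1:3, c(1, 0, 0), delta = 0.2)
  d <- discretize(p, 4)
  expect_equal(d$A_bar, diag(N))
  expect_equal(d$B_bar, 0.2 * (1:3))

  # scalar A = a: closed form (1 + delta a / 2) / (1 - delta a / 2)
  for (a in c(-2, -0.5, 0.7)) {
    ps <- ssm_params(matrix(a, 1, 1), 1, 1, delta = 0.1)
    ds <- discretize(ps, 2)
    expect_equal(ds$A_bar[1, 1], (1 + 0.05 * a) / (1 - 0.05 * a), tolerance = 1e-14)
  }

  # random N = 3 system against explicit inversion
  set.seed(7)
  A <- matrix(rnorm(9), 3, 3); B <- rnorm(3); C <- rnorm(3)
  ps <- ssm_params(A, B, C, delta = 0.05)
  ds <- discretize(ps, 8)
  M <- solve(diag(3) - 0.025 * A)
  expect_equal(ds$A_bar, M %*% (diag(3) + 0.025 * A), tolerance = 1e-10)
  expect_equal(ds$B_bar, as.numeric(M %*% (0.05 * B)), tolerance = 1e-10)
  expect_equal(ds$C_bar, C)

  # singular (I - delta/2 A): a = 2/delta makes 1 - delta a/2 = 0
  psing <- ssm_params(matrix(20, 1, 1), 1, 1, delta = 0.1)
  expect_error(discretize(psing, 4), "delta")
})

test_that("kernel entries equal C Abar^k Bbar", {
  sys <- oracle_random_ssm(4, 12, seed = 11)
  d <- discretize(sys$params, sys$L)
  Ap <- diag(4)
  for (k in 0:(sys$L - 1)) {
    expect_equal(d$K_bar[k + 1], sum(d$C_bar * (Ap %*% d$B_bar)), tolerance = 1e-12)
    Ap <- d$A_bar %*% Ap
  }
})

test_that("recurrent application matches the expanded sum oracle", {
  sys <- oracle_random_ssm(4, 16, seed = 3)
  d <- discretize(sys$params, 16)
  set.seed(4)
  u <- rnorm(16)
  expect_equal(ssm_apply_recurrent(d, u),
               oracle_ssm_expanded(d$A_bar, d$B_bar, d$C_bar, u),
               tolerance = 1e-10)
})

test_that("impulse response returns the kernel; zeros map to zeros", {
  sys <- oracle_random_ssm(5, 20, seed = 9)
  d <- discretize(sys$params, 20)
  impulse <- c(1, numeric(19))
  expect_equal(ssm_apply_recurrent(d, impulse), d$K_bar, tolerance = 1e-12)
  expect_equal(ssm_apply_conv(d, impulse), d$K_bar, tolerance = 1e-9)
  expect_equal(ssm_apply_recurrent(d, numeric(20)), numeric(20))
  expect_error(ssm_apply_recurrent(d, numeric(5)), "length")
})

test_that("convolutional and recurrent paths agree (oracle equivalence)", {
  for (s in 1:25) {
    N <- sample(1:8, 1)
    L <- sample(4:64, 1)
    sys <- oracle_random_ssm(N, L, seed = 1000 + s)
    d <- discretize(sys$params, L)
    u <- rnorm(L)
    expect_lt(max(abs(ssm_apply_conv(d, u) - ssm_apply_recurrent(d, u))), 1e-6)
  }
})

test_that("SSM application is linear", {
  sys <- oracle_random_ssm(4, 32, seed = 21)
  d <- discretize(sys$params, 32)
  set.seed(22)
  u <- rnorm(32); v <- rnorm(32)
  y <- ssm_apply_conv(d, 2.5 * u - 1.25 * v)
  expect_equal(y, 2.5 * ssm_apply_conv(d, u) - 1.25 * ssm_apply_conv(d, v),
               tolerance = 1e-8)
})

test_that("stable HiPPO form yields finite kernels up to L = 1024", {
  for (delta in c(1e-3, 1e-2, 1e-1)) {
    p <- build_hippo(12, delta = delta, form = "s4", seed = 5)
    d <- discretize(p, 1024)
    expect_true(all(is.finite(d$K_bar)))
  }
  # the printed form is documented as unstable: its continuous A has
  # positive eigenvalues
  ap <- build_hippo(8, form = "printed")
  expect_gt(max(Re(eigen(ap$A, only.values = TRUE)$values)), 0)
})

test_that("ssm_params validates its inputs", {
  expect_error(ssm_params(matrix(1, 2, 2), 1:2, 1:2, delta = -1), "delta")
  expect_error(ssm_params(matrix(1, 2, 3), 1:2, 1:2, delta = 0.1), "square")
  expect_error(ssm_params(matrix(c(1, Inf, 0, 1), 2, 2), 1:2, 1:2, delta = 0.1),
               "finite")
})
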