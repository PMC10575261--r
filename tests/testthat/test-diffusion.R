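# diffusion_process: schedule, forward marginals, loss, reverse sampler.

test_that("make_schedule builds the linear schedule", {
  s <- make_schedule(200, 1e-4, 0.02)
  expect_equal(s$beta[1], 1e-4)
  expect_equal(s$beta[200], 0.02)
  expect_true(all(diff(s$beta) >= 0))
  expect_true(all(s$beta > 0 & s$beta < 1))
  expect_equal(s$alpha, 1 - s$beta)
  expect_true(all(diff(s$alpha_bar) < 0))
  # exact chaining and conservation: abar_t * prod_{i>t} alpha_i = abar_T
  expect_equal(s$alpha_bar[-1], s$alpha_bar[-200] * s$alpha[-1])
  for (t in c(1, 57, 199))
    expect_equal(s$alpha_bar[t] * prod(s$alpha[(t + 1):200]), s$alpha_bar[200],
                 tolerance = 1e-12)

  s2 <- make_schedule(2, 0.1, 0.3)
  expect_equal(s2$beta, c(0.1, 0.3))
  expect_equal(s2$alpha_bar, c(0.9, 0.9 * 0.7))

  # cumulative product oracle for the final abar of the reference schedule
  expect_equal(s$alpha_bar[200], prod(1 - seq(1e-4, 0.02, length.out = 200)),
               tolerance = 1e-12)

  expect_error(make_schedule(0), "positive integer")
  expect_error(make_schedule(10, 0.3, 0.1), "beta")
  expect_error(make_schedule(10, 0, 0.1), "beta")
})

test_that("forward_diffuse applies the closed-form noising", {
  s <- make_schedule(50, 1e-3, 0.05)
  x0 <- matrix(1:6 / 6, 2, 3)
  z <- matrix(0, 2, 3)
  expect_equal(forward_diffuse(x0, 10, z, s), sqrt(s$alpha_bar[10]) * x0)
  eps <- matrix(rnorm(6), 2, 3)
  expect_equal(forward_diffuse(z, 25, eps, s), sqrt(1 - s$alpha_bar[25]) * eps)
  # audit switch: printed no-root weighting
  expect_equal(forward_diffuse(z, 25, eps, s, no_root_noise = TRUE),
               (1 - s$alpha_bar[25]) * eps)
  expect_error(forward_diffuse(x0, 51, eps, s), "t must be")
  expect_error(forward_diffuse(x0, 10, matrix(0, 3, 2), s), "shape")
})

test_that("forward marginals match N(sqrt(abar) x0, 1 - abar)", {
  s <- make_schedule(200, 1e-4, 0.02)
  n <- 10000
  set.seed(31)
  for (t in c(1, 100, 200)) {
    xt <- forward_diffuse(rep(1, n), t, rnorm(n), s)
    mu_th <- sqrt(s$alpha_bar[t]); v_th <- 1 - s$alpha_bar[t]
    se_mu <- sqrt(v_th / n); se_v <- v_th * sqrt(2 / (n - 1))
    expect_lt(abs(mean(xt) - mu_th), 4 * se_mu)
    expect_lt(abs(var(xt) - v_th), 4 * se_v)
  }
})

test_that("training loss behaves as an eps-regression MSE", {
  s <- make_schedule(20, 1e-3, 0.05)
  set.seed(32)
  batch <- list(x0 = list(matrix(rnorm(8), 2, 4), matrix(rnorm(8), 2, 4)),
                t = c(3L, 17L),
                c = list(c(1, 0), c(0, 1)),
                eps = list(matrix(rnorm(8), 2, 4), matrix(rnorm(8), 2, 4)))
  # oracle that returns the injected noise -> zero loss
  i_call <- 0
  oracle <- function(xt, t, cvec) { i_call <<- i_call + 1; batch$eps[[i_call]] }
  expect_equal(training_loss(oracle, batch, s), 0)
  # zero predictor: loss = mean eps^2
  zero <- function(xt, t, cvec) matrix(0, 2, 4)
  expect_equal(training_loss(zero, batch, s),
               mean(c(batch$eps[[1]]^2, batch$eps[[2]]^2)))
  expect_gte(training_loss(function(x, t, cv) matrix(rnorm(8), 2, 4), batch, s), 0)
})

test_that("zero predictor expected loss is 1 by simulation", {
  s <- make_schedule(20, 1e-3, 0.05)
  set.seed(33)
  n <- 200
  batch <- list(x0 = replicate(n, matrix(rnorm(16), 2, 8), simplify = FALSE),
                t = sample(20, n, replace = TRUE),
                c = replicate(n, c(1, 0), simplify = FALSE),
                eps = replicate(n, matrix(rnorm(16), 2, 8), simplify = FALSE))
  l <- training_loss(function(xt, t, cv) matrix(0, 2, 8), batch, s)
  expect_lt(abs(l - 1), 4 * sqrt(2 / (16 * n)))
})

test_that("reverse sampling is reproducible and honors the T = 1 boundary", {
  s <- make_schedule(5, 0.01, 0.1)
  pred <- function(xt, t, cvec) 0.1 * xt
  a <- reverse_sample(pred, c(1, 0), s, shape = c(2, 6), seed = 7)
  b <- reverse_sample(pred, c(1, 0), s, shape = c(2, 6), seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, reverse_sample(pred, c(1, 0), s, shape = c(2, 6), seed = 8)))

  # T = 1: single fully deterministic step given x_T
  s1 <- make_schedule(1, 0.02, 0.02)
  set.seed(diffecg:::derive_seed(3, 0))
  xT <- array(rnorm(4), dim = 4)
  out <- reverse_sample(pred, c(1), s1, shape = 4, seed = 3)
  expect_equal(out,
               (xT - 0.02 / sqrt(1 - 0.98) * (0.1 * xT)) / sqrt(0.98),
               tolerance = 1e-12)
})

test_that("the posterior-variance option shrinks early-step noise", {
  s <- make_schedule(10, 0.05, 0.2)
  pred <- function(xt, t, cvec) xt * 0
  a <- reverse_sample(pred, 1, s, shape = 2000, seed = 5, variance = "fixed")
  b <- reverse_sample(pred, 1, s, shape = 2000, seed = 5, variance = "posterior")
  expect_false(identical(a, b))
  expect_lt(var(b), var(a))
})

test_that("reverse sampling with the analytic optimal predictor recovers a
           Gaussian data distribution", {
  # For x0 ~ N(mu, s2) i.i.d. and x_t = sqrt(abar) x0 + sqrt(1-abar) eps,
  # E[eps | x_t] = (x_t - sqrt(abar) mu) * sqrt(1-abar) / (1-abar+abar*s2).
  sch <- make_schedule(200, 1e-4, 0.02)
  mu <- 0.7; s2 <- 0.25
  opt <- function(xt, t, cvec) {
    ab <- sch$alpha_bar[t]
    (xt - sqrt(ab) * mu) * sqrt(1 - ab) / (1 - ab + ab * s2)
  }
  n <- 5000
  x0 <- reverse_sample(opt, 1, sch, shape = n, seed = 99)
  # generous Monte-Carlo bands (the sampler adds schedule-level bias ~ beta)
  expect_lt(abs(mean(x0) - mu), 5 * sqrt(s2 / n) + 0.01)
  expect_lt(abs(var(x0) - s2), 5 * s2 * sqrt(2 / (n - 1)) + 0.02)
})
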