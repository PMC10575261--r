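# evaluation: DTW, MMD, multilabel metrics, protocols — each against its
# brute-force oracle.

test_that("dtw boundary cases", {
  expect_equal(dtw_distance(c(1, 5, -2, 0.3), c(1, 5, -2, 0.3)), 0)
  expect_equal(dtw_distance(0, 3), 9)
  expect_equal(dtw_distance(c(1, 2, 3), c(2, 3, 4)), 2)
  expect_error(dtw_distance(numeric(0), 1), "empty")
  expect_error(dtw_distance(c(1, NA), c(1, 2)), "finite")
})

test_that("dtw equals exhaustive path enumeration on short random series", {
  set.seed(1)
  for (i in 1:50) {
    x <- sample(-4:4, sample(2:8, 1), replace = TRUE)
    y <- sample(-4:4, sample(2:8, 1), replace = TRUE)
    expect_identical(dtw_distance(x, y), oracle_dtw(x, y))
  }
})

test_that("mmd matches the explicit double sum and its degenerate cases", {
  # identical point masses -> exactly 0
  X <- matrix(2.5, 4, 3); Y <- matrix(2.5, 6, 3)
  expect_equal(mmd_rbf(X, Y, sigma = 1)$mmd, 0)

  # the derived two-set example: X = {0, 1}, Y = {0, 2}, sigma = 1
  v <- mmd_rbf(c(0, 1), c(0, 2), sigma = 1)$mmd
  k <- function(a, b) exp(-(a - b)^2 / 2)
  expect_equal(v, k(0, 1) + k(0, 2) - (k(0, 0) + k(0, 2) + k(1, 0) + k(1, 2)) / 2,
               tolerance = 1e-12)

  set.seed(2)
  for (i in 1:10) {
    n <- sample(2:20, 1); m <- sample(2:20, 1); d <- sample(1:4, 1)
    X <- matrix(rnorm(n * d), n, d); Y <- matrix(rnorm(m * d, 0.5), m, d)
    sg <- runif(1, 0.5, 2)
    expect_equal(mmd_rbf(X, Y, sg)$mmd, oracle_mmd(X, Y, sg), tolerance = 1e-12)
    expect_equal(mmd_rbf(X, Y, sg)$mmd, mmd_rbf(Y, X, sg)$mmd, tolerance = 1e-12)
  }
  expect_error(mmd_rbf(matrix(0, 1, 2), matrix(0, 3, 2)), "two samples")
})

test_that("mmd with the median heuristic shrinks for same-distribution samples", {
  set.seed(3)
  small <- abs(mmd_rbf(matrix(rnorm(20 * 4), 20), matrix(rnorm(20 * 4), 20))$mmd)
  large <- abs(mmd_rbf(matrix(rnorm(200 * 4), 200), matrix(rnorm(200 * 4), 200))$mmd)
  expect_lt(large, small)
})

test_that("multilabel accuracy is the fraction of matching positions", {
  t0 <- matrix(c(1, 0, 1, 0, 1, 1), 2, 3)
  expect_equal(multilabel_accuracy(t0, t0), 1)
  expect_equal(multilabel_accuracy(1 - t0, t0), 0)
  p <- t0; p[1, 1] <- 1 - p[1, 1]
  expect_equal(multilabel_accuracy(p, t0), 5 / 6)
  big <- matrix(rbinom(12, 1, 0.5), 3, 4)
  pred <- big; pred[c(1, 5)] <- 1 - pred[c(1, 5)]
  expect_equal(multilabel_accuracy(pred, big), 10 / 12)
  expect_error(multilabel_accuracy(t0, t0[, 1:2]), "mismatch")
  expect_error(multilabel_accuracy(t0 * 2, t0), "binary")
})

test_that("macro AUROC matches pair counting, with boundary values exact", {
  truth <- matrix(c(1, 1, 0, 0, 1, 0), 6, 2)
  perfect <- matrix(c(0.9, 0.8, 0.1, 0.2, 0.95, 0.05), 6, 2)
  truth[, 2] <- c(0, 1, 1, 0, 0, 1)
  perfect[, 2] <- c(0.1, 0.7, 0.8, 0.2, 0.3, 0.9)
  expect_equal(multilabel_auroc(perfect, truth)$auroc, 1)
  expect_equal(multilabel_auroc(-perfect, truth)$auroc, 0)
  ties <- matrix(0.5, 6, 2)
  expect_equal(multilabel_auroc(ties, truth)$auroc, 0.5)

  set.seed(4)
  for (i in 1:20) {
    n <- sample(4:12, 1); C <- sample(1:4, 1)
    truth <- matrix(rbinom(n * C, 1, 0.5), n, C)
    scores <- matrix(sample(seq(0, 1, 0.1), n * C, replace = TRUE), n, C)
    ok <- apply(truth, 2, function(col) any(col == 1) && any(col == 0))
    if (!any(ok)) next
    expect_equal(multilabel_auroc(scores, truth)$auroc,
                 oracle_auroc(scores, truth), tolerance = 1e-12)
  }

  deg <- matrix(1, 4, 2)
  expect_error(multilabel_auroc(matrix(runif(8), 4, 2), deg), "degenerate")
  # partial degeneracy: skipped column reported
  tr <- cbind(c(1, 1, 1, 1), c(1, 0, 1, 0))
  r <- multilabel_auroc(matrix(runif(8), 4, 2), tr)
  expect_equal(r$skipped, 1L)
})

test_that("quality protocol: identity gives zero DTW; batching is neutral", {
  set.seed(5)
  recs <- replicate(10, matrix(rnorm(2 * 20), 2, 20), simplify = FALSE)
  q <- quality_protocol(recs, recs, batch_size = 4)
  expect_equal(q$avg_dtw, 0)
  expect_equal(q$batch_size, 4L)

  gen <- replicate(10, matrix(rnorm(2 * 20), 2, 20), simplify = FALSE)
  q16 <- quality_protocol(recs, gen, batch_size = 16)
  q3 <- quality_protocol(recs, gen, batch_size = 3)
  q1 <- quality_protocol(recs, gen, batch_size = 1)
  expect_equal(q16$avg_dtw, q3$avg_dtw, tolerance = 1e-9)
  expect_equal(q16$avg_dtw, q1$avg_dtw, tolerance = 1e-9)
  expect_equal(q16$mmd, q3$mmd, tolerance = 1e-12)

  # naive unbatched recomputation oracle (per-lead mean of pairwise DTW)
  naive <- mean(sapply(seq_along(recs), function(i)
    mean(c(dtw_distance(recs[[i]][1, ], gen[[i]][1, ]),
           dtw_distance(recs[[i]][2, ], gen[[i]][2, ])))))
  expect_equal(q16$avg_dtw, naive, tolerance = 1e-9)

  # concat mode differs but is finite and non-negative
  qc <- quality_protocol(recs, gen, dtw_mode = "concat")
  expect_gte(qc$avg_dtw, 0)

  expect_error(quality_protocol(list(), recs), "empty")
})

test_that("authenticity protocol: identical sets give zero gaps; random
           classifier sits near chance", {
  set.seed(6)
  recs <- replicate(40, matrix(rnorm(2 * 16), 2, 16), simplify = FALSE)
  labs <- matrix(rbinom(80, 1, 0.5), 40, 2)
  clf <- classifier_init(classifier_config(n_filters = 4, label_dim = 2,
                                           signal_channels = 2), seed = 7)
  a <- authenticity_protocol(clf, recs, labs, recs, labs)
  expect_equal(a$accuracy_gap, 0)
  expect_equal(a$auroc_gap, 0)
  expect_equal(a$real_auroc, a$gen_auroc)

  # frozen random classifier on label-independent data: AUROC near 0.5
  gen <- replicate(40, matrix(rnorm(2 * 16), 2, 16), simplify = FALSE)
  glabs <- matrix(rbinom(80, 1, 0.5), 40, 2)
  b <- authenticity_protocol(clf, recs, labs, gen, glabs)
  expect_lt(abs(b$real_auroc - 0.5), 0.25)
  expect_lt(abs(b$gen_auroc - 0.5), 0.25)

  expect_error(authenticity_protocol(clf, recs, labs, gen, glabs[, 1, drop = FALSE]),
               "label spaces")
})

test_that("eval report aggregates, prints and serializes", {
  set.seed(8)
  recs <- replicate(6, matrix(rnorm(2 * 12), 2, 12), simplify = FALSE)
  gen <- replicate(6, matrix(rnorm(2 * 12), 2, 12), simplify = FALSE)
  rep <- eval_report(quality_protocol(recs, gen))
  expect_s3_class(rep, "eval_report")
  expect_output(print(rep), "Avg DTW")
  tf <- tempfile(); cf <- tempfile(fileext = ".csv")
  write_eval_report(rep, tf, cf)
  expect_true(any(grepl("avg_dtw", readLines(tf))))
  expect_true("avg_dtw" %in% utils::read.csv(cf)$metric)
})
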