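# Quality metrics (DTW, MMD) and authenticity metrics (multilabel accuracy,
# macro AUROC via a classifier-transfer protocol).

#' Dynamic time warping distance with squared-difference cost
#'
#' `D[i,j] = (x_i - y_j)^2 + min(D[i,j-1], D[i-1,j], D[i-1,j-1])` with
#' `D[0,0] = 0` and infinite borders; returns `D[N,M]`.
#'
#' @param x,y non-empty finite numeric vectors
#' @return non-negative scalar
#' @export
dtw_distance <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("dtw_distance: empty input")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("dtw_distance: non-finite input")
  N <- length(x); M <- length(y)
  prev <- c(0, rep(Inf, M))
  for (i in seq_len(N)) {
    cur <- numeric(M + 1L)
    cur[1L] <- Inf
    cost <- (x[i] - y)^2
    for (j in seq_len(M)) {
      cur[j + 1L] <- cost[j] + min(cur[j], prev[j + 1L], prev[j])
    }
    prev <- cur
  }
  prev[M + 1L]
}

#' Unbiased maximum mean discrepancy with a Gaussian RBF kernel
#'
#' Within-set terms use the unbiased i != j sums with weights 1/(n(n-1)) and
#' 1/(m(m-1)); the cross term is -2/(nm) * sum k(x_i, y_j), with
#' k(x, y) = exp(-||x - y||^2 / (2 sigma^2)).
#'
#' @param X,Y numeric matrices (rows are samples) or vectors (one sample per
#'   entry); both sets need at least two samples
#' @param sigma kernel bandwidth; `NULL` selects the median pairwise
#'   distance of the pooled sample
#' @return list with `mmd` and the `sigma` actually used
#' @export
mmd_rbf <- function(X, Y, sigma = NULL) {
  X <- if (is.null(dim(X))) matrix(X, ncol = 1L) else as.matrix(X)
  Y <- if (is.null(dim(Y))) matrix(Y, ncol = 1L) else as.matrix(Y)
  n <- nrow(X); m <- nrow(Y)
  if (n < 2L || m < 2L) stop("mmd_rbf: need at least two samples per set")
  if (ncol(X) != ncol(Y)) stop("mmd_rbf: sample dimensions differ")
  sq <- function(A, B) {
    # squared Euclidean distances, rows of A vs rows of B
    an <- rowSums(A^2); bn <- rowSums(B^2)
    d <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
    pmax(d, 0)
  }
  dxx <- sq(X, X); dyy <- sq(Y, Y); dxy <- sq(X, Y)
  if (is.null(sigma)) {
    pool <- sqrt(c(dxx[upper.tri(dxx)], dyy[upper.tri(dyy)], as.vector(dxy)))
    sigma <- stats::median(pool)
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  if (sigma <= 0) stop("mmd_rbf: sigma must be positive")
  k <- function(d) exp(-d / (2 * sigma^2))
  kxx <- k(dxx); kyy <- k(dyy); kxy <- k(dxy)
  mmd <- (sum(kxx) - sum(diag(kxx))) / (n * (n - 1)) +
         (sum(kyy) - sum(diag(kyy))) / (m * (m - 1)) -
         2 * sum(kxy) / (n * m)
  list(mmd = mmd, sigma = sigma)
}

#' Multilabel accuracy
#'
#' Fraction of label positions predicted correctly: correct / (n * C).
#'
#' @param pred,truth binary matrices of equal shape
#' @return scalar in `[0, 1]`
#' @export
multilabel_accuracy <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("entries must be binary")
  mean(pred == truth)
}

# AUROC of one score column by the rank (Mann-Whitney) formula; ties 1/2
.auroc_one <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged multilabel AUROC
#'
#' Per-label AUROC from the Mann-Whitney statistic (ties counted 1/2),
#' averaged over labels that have at least one positive and one negative;
#' degenerate labels are skipped and reported.
#'
#' @param scores numeric n x C matrix of scores
#' @param truth binary n x C matrix
#' @return list with `auroc`, per-label values `per_label`, and
#'   `skipped` label indices
#' @export
multilabel_auroc <- function(scores, truth) {
  scores <- as.matrix(scores); truth <- as.matrix(truth)
  if (!identical(dim(scores), dim(truth))) stop("shape mismatch")
  per <- vapply(seq_len(ncol(truth)),
                function(j) .auroc_one(scores[, j], truth[, j]), numeric(1))
  skipped <- which(is.na(per))
  if (length(skipped) == ncol(truth))
    stop("multilabel_auroc: every label column is degenerate")
  list(auroc = mean(per, na.rm = TRUE), per_label = per, skipped = skipped)
}

#' Quality protocol: average DTW and MMD between real and generated sets
#'
#' Records are paired by index; DTW is computed per lead and averaged
#' (or on concatenated leads with `dtw_mode = "concat"`), processed in
#' batches of `batch_size` (the batching is organizational and does not
#' change the result). MMD is computed over flattened records with the
#' median-heuristic bandwidth unless `sigma` is given.
#'
#' @param real,generated lists of channels x L matrices (equal shapes), or
#'   n x channels x L arrays
#' @param batch_size evaluation batch size (default 16)
#' @param dtw_mode "per_lead" or "concat"
#' @param sigma optional MMD bandwidth
#' @return list with `avg_dtw`, `mmd`, `mmd_sigma`, `n_real`, `n_generated`,
#'   `batch_size`
#' @export
quality_protocol <- function(real, generated, batch_size = 16L,
                             dtw_mode = c("per_lead", "concat"), sigma = NULL) {
  dtw_mode <- match.arg(dtw_mode)
  real <- .as_record_list(real); generated <- .as_record_list(generated)
  if (length(real) == 0L || length(generated) == 0L) stop("empty record set")
  n <- min(length(real), length(generated))
  dtws <- numeric(0)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    for (i in idx) {
      r <- real[[i]]; g <- generated[[i]]
      if (!identical(dim(r), dim(g))) stop("record shape mismatch")
      if (dtw_mode == "per_lead") {
        dtws <- c(dtws, mean(vapply(seq_len(nrow(r)),
                                    function(l) dtw_distance(r[l, ], g[l, ]),
                                    numeric(1))))
      } else {
        dtws <- c(dtws, dtw_distance(as.vector(t(r)), as.vector(t(g))))
      }
    }
  }
  Xf <- t(vapply(real, as.vector, numeric(length(real[[1]]))))
  Yf <- t(vapply(generated, as.vector, numeric(length(generated[[1]]))))
  mm <- mmd_rbf(Xf, Yf, sigma = sigma)
  list(avg_dtw = mean(dtws), mmd = mm$mmd, mmd_sigma = mm$sigma,
       n_real = length(real), n_generated = length(generated),
       batch_size = as.integer(batch_size))
}

.as_record_list <- function(x) {
  if (is.list(x)) return(lapply(x, as.matrix))
  if (is.array(x) && length(dim(x)) == 3L)
    return(lapply(seq_len(dim(x)[1]), function(i) x[i, , ]))
  stop("records must be a list of matrices or an n x channels x L array")
}

#' Authenticity protocol: classifier transfer from real to generated data
#'
#' Applies a classifier trained on real training data to a real test set and
#' a generated test set; authenticity is read off the absolute gaps in
#' multilabel accuracy and macro AUROC.
#'
#' @param classifier object with a `predict_scores(records)` closure field
#'   (see [classifier_init()]), returning an n x C score matrix
#' @param real_records,real_labels the real test set
#' @param gen_records,gen_labels the generated test set (same label space)
#' @param threshold binarization threshold for accuracy (default 0.5)
#' @return list with per-set accuracy/AUROC, `accuracy_gap` and `auroc_gap`
#' @export
authenticity_protocol <- function(classifier, real_records, real_labels,
                                  gen_records, gen_labels, threshold = 0.5) {
  real_labels <- as.matrix(real_labels); gen_labels <- as.matrix(gen_labels)
  if (ncol(real_labels) != ncol(gen_labels))
    stop("label spaces differ between real and generated sets")
  eval_one <- function(records, labels) {
    sc <- classifier$predict_scores(records)
    acc <- multilabel_accuracy((sc >= threshold) * 1, labels)
    auc <- multilabel_auroc(sc, labels)$auroc
    list(accuracy = acc, auroc = auc)
  }
  r <- eval_one(real_records, real_labels)
  g <- eval_one(gen_records, gen_labels)
  list(real_accuracy = r$accuracy, real_auroc = r$auroc,
       gen_accuracy = g$accuracy, gen_auroc = g$auroc,
       accuracy_gap = abs(r$accuracy - g$accuracy),
       auroc_gap = abs(r$auroc - g$auroc))
}

#' Aggregate an evaluation report
#'
#' @param quality result of [quality_protocol()]
#' @param authenticity optional result of [authenticity_protocol()]
#' @return object of class `eval_report`
#' @export
eval_report <- function(quality, authenticity = NULL) {
  r <- c(quality, authenticity)
  stopifnot(r$avg_dtw >= 0)
  structure(r, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Quality (lower is better)\n")
  cat(sprintf("  Avg DTW : %.4f\n", x$avg_dtw))
  cat(sprintf("  MMD     : %.4e  (sigma = %.4g)\n", x$mmd, x$mmd_sigma))
  if (!is.null(x$gen_accuracy)) {
    cat("Authenticity (gaps lower is better)\n")
    cat(sprintf("  Accuracy: real %.4f  generated %.4f  gap %.4f\n",
                x$real_accuracy, x$gen_accuracy, x$accuracy_gap))
    cat(sprintf("  AUROC   : real %.4f  generated %.4f  gap %.4f\n",
                x$real_auroc, x$gen_auroc, x$auroc_gap))
  }
  cat(sprintf("  n_real = %d, n_generated = %d, batch_size = %d\n",
              x$n_real, x$n_generated, x$batch_size))
  invisible(x)
}

#' Write an evaluation report as a flat key-value text file and a CSV table
#' @param report an [eval_report()]
#' @param path_txt,path_csv output file paths (either may be `NULL`)
#' @return invisibly, the report
#' @export
write_eval_report <- function(report, path_txt = NULL, path_csv = NULL) {
  flat <- unlist(report[vapply(report, is.numeric, logical(1))])
  if (!is.null(path_txt))
    writeLines(sprintf("%s = %.10g", names(flat), flat), path_txt)
  if (!is.null(path_csv))
    utils::write.csv(data.frame(metric = names(flat), value = as.numeric(flat)),
                     path_csv, row.names = FALSE)
  invisible(report)
}
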