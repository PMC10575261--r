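# Evaluation harness: a small 1-D residual convolutional multilabel
# classifier with sigmoid outputs. It stands in for a full ResNet-1D; depth
# and width are configurable. Trained with the same autodiff engine as the
# generator.

#' Configure the harness classifier
#' @param n_filters convolutional width
#' @param kernel_size odd convolution kernel width
#' @param n_res_blocks number of residual conv blocks
#' @param label_dim number of output labels
#' @param signal_channels input leads
#' @return object of class `classifier_config`
#' @export
classifier_config <- function(n_filters = 16L, kernel_size = 5L,
                              n_res_blocks = 1L, label_dim = 2L,
                              signal_channels = 2L) {
  stopifnot(n_filters >= 1, kernel_size >= 1, kernel_size %% 2 == 1,
            n_res_blocks >= 0, label_dim >= 1, signal_channels >= 1)
  structure(list(n_filters = as.integer(n_filters),
                 kernel_size = as.integer(kernel_size),
                 n_res_blocks = as.integer(n_res_blocks),
                 label_dim = as.integer(label_dim),
                 signal_channels = as.integer(signal_channels)),
            class = "classifier_config")
}

# 1-D convolution as a sum of shifted affine maps; X node is L x Cin,
# W a list of Cin x F weight nodes (one per tap), b length-F bias node
.conv1d_node <- function(X, W, b, half) {
  acc <- NULL
  for (i in seq_along(W)) {
    o <- i - half - 1L
    term <- ad_linear(ad_shift_rows(X, o), W[[i]])
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  ad_add_rowvec(acc, b)
}

#' Initialize the harness classifier
#' @param cfg a [classifier_config()]
#' @param seed parameter seed
#' @return object of class `ecg_classifier` with a `predict_scores` closure
#' @export
classifier_init <- function(cfg = classifier_config(), seed = 1L) {
  set.seed(seed)
  k <- cfg$kernel_size; nf <- cfg$n_filters
  params <- list()
  conv_params <- function(cin, cout, prefix) {
    for (i in seq_len(k))
      params[[sprintf("%s.W%d", prefix, i)]] <<- ad_param(.init_mat(cin, cout, scale = sqrt(2 / (k * cin + cout))))
    params[[paste0(prefix, ".b")]] <<- ad_param(rep(0, cout))
  }
  conv_params(cfg$signal_channels, nf, "conv0")
  for (b in seq_len(cfg$n_res_blocks)) {
    conv_params(nf, nf, sprintf("rb%d.c1", b))
    conv_params(nf, nf, sprintf("rb%d.c2", b))
  }
  params[["head.W"]] <- ad_param(.init_mat(nf, cfg$label_dim))
  params[["head.b"]] <- ad_param(rep(0, cfg$label_dim))
  obj <- list(cfg = cfg, params = params)
  obj$predict_scores <- function(records) classifier_scores(obj, records)
  class(obj) <- "ecg_classifier"
  obj
}

# logits node for one record (channels x L matrix)
.classifier_logits_node <- function(clf, rec) {
  cfg <- clf$cfg; p <- clf$params
  half <- (cfg$kernel_size - 1L) %/% 2L
  getW <- function(prefix) lapply(seq_len(cfg$kernel_size),
                                  function(i) p[[sprintf("%s.W%d", prefix, i)]])
  X <- ad_const(t(as.matrix(rec)))
  h <- ad_relu(.conv1d_node(X, getW("conv0"), p[["conv0.b"]], half))
  for (b in seq_len(cfg$n_res_blocks)) {
    z <- ad_relu(.conv1d_node(h, getW(sprintf("rb%d.c1", b)), p[[sprintf("rb%d.c1.b", b)]], half))
    z <- .conv1d_node(z, getW(sprintf("rb%d.c2", b)), p[[sprintf("rb%d.c2.b", b)]], half)
    h <- ad_relu(ad_add(h, z))
  }
  ad_linear(ad_colmeans(h), p[["head.W"]], p[["head.b"]])
}

#' Sigmoid scores of a classifier on a set of records
#' @param clf an [classifier_init()] object
#' @param records list of channels x L matrices or n x channels x L array
#' @return n x label_dim matrix of scores in (0, 1)
#' @export
classifier_scores <- function(clf, records) {
  records <- .as_record_list(records)
  out <- matrix(0, length(records), clf$cfg$label_dim)
  for (i in seq_along(records)) {
    z <- ad_no_grad(ad_val(.classifier_logits_node(clf, records[[i]])))
    out[i, ] <- 1 / (1 + exp(-as.numeric(z)))
  }
  out
}

#' Train the harness classifier with binary cross-entropy
#'
#' @param clf an [classifier_init()] object
#' @param records training records (list or array)
#' @param labels n x label_dim binary matrix
#' @param steps optimization steps
#' @param batch_size records per step
#' @param lr Adam learning rate
#' @param seed seed for batch sampling
#' @param verbose print running loss every 50 steps
#' @return the classifier (parameters updated in place), with a `loss_trace`
#'   attribute
#' @export
classifier_train <- function(clf, records, labels, steps = 300L,
                             batch_size = 16L, lr = 1e-2, seed = 1L,
                             verbose = FALSE) {
  records <- .as_record_list(records)
  labels <- as.matrix(labels)
  stopifnot(length(records) == nrow(labels))
  opt <- adam_init(clf$params, lr = lr)
  set.seed(derive_seed(seed, 7L))
  trace <- numeric(steps)
  for (s in seq_len(steps)) {
    idx <- sample.int(length(records), min(batch_size, length(records)))
    ad_reset_tape()
    ad_zero_grads(clf$params)
    losses <- lapply(idx, function(i)
      ad_bce_logits(.classifier_logits_node(clf, records[[i]]),
                    matrix(labels[i, ], 1L)))
    loss <- ad_mean_list(losses)
    ad_backward(loss)
    adam_step(opt)
    trace[s] <- loss$val
    if (verbose && s %% 50L == 0L)
      message(sprintf("classifier step %d loss %.4f", s, mean(utils::tail(trace[1:s], 50))))
  }
  ad_reset_tape()
  attr(clf, "loss_trace") <- trace
  clf
}
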