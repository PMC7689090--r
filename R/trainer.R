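#' Training configuration
#'
#' Collects every knob of a training run. Defaults follow the package's
#' standard recipe: target learning rate `eta_t = 0.5`, weight learning
#' rate `eta_w = 0.015`, minibatches of 10, orthogonal initialization, and
#' the default LIF constants.
#'
#' @param layer_sizes neuron counts per layer (input first, classes last).
#' @param epochs number of passes over the training data.
#' @param batch_size minibatch size.
#' @param eta_t target learning rate (penultimate transpose path).
#' @param eta_w weight learning rate.
#' @param seed master seed: weights, feedback draws and per-epoch shuffles
#'   all derive from it, so a config reproduces bit-exactly.
#' @param n_feedback_layers how many hidden layers below the penultimate
#'   receive direct-feedback targets (deep to shallow). `NULL` means all
#'   (`L - 3`); layers without targets keep their incoming weights frozen.
#' @param init_scheme forward weight initialization, see [init_network()].
#' @param params LIF constants, a [neuron_params()] object.
#' @param feedback_scale,feedback_bias_scale draw scales for
#'   [init_feedback()].
#' @param batch_reduction `"mean"` or `"sum"` over each minibatch.
#' @param record_spikes record spike tensors during *evaluation* passes
#'   (training never needs them).
#' @return An object of class `train_config`.
#' @export
train_config <- function(layer_sizes, epochs = 100L, batch_size = 10L,
                         eta_t = 0.5, eta_w = 0.015, seed = 0L,
                         n_feedback_layers = NULL,
                         init_scheme = "orthogonal",
                         params = neuron_params(),
                         feedback_scale = 1.0, feedback_bias_scale = 0,
                         batch_reduction = "mean",
                         record_spikes = FALSE) {
  layer_sizes <- as.integer(layer_sizes)
  L <- length(layer_sizes)
  if (L < 2L) stop("layer_sizes must name at least 2 layers", call. = FALSE)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  max_fb <- max(0L, L - 3L)
  if (!is.null(n_feedback_layers)) {
    n_feedback_layers <- as.integer(n_feedback_layers)
    if (n_feedback_layers < 0L || n_feedback_layers > max_fb) {
      stop(sprintf("n_feedback_layers must be in 0..%d for this depth",
                   max_fb), call. = FALSE)
    }
  } else {
    n_feedback_layers <- max_fb
  }
  stopifnot(inherits(params, "neuron_params"))
  structure(list(layer_sizes = layer_sizes,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 eta_t = as.double(eta_t), eta_w = as.double(eta_w),
                 seed = as.integer(seed),
                 n_feedback_layers = n_feedback_layers,
                 init_scheme = init_scheme, params = params,
                 feedback_scale = as.double(feedback_scale),
                 feedback_bias_scale = as.double(feedback_bias_scale),
                 batch_reduction = batch_reduction,
                 record_spikes = isTRUE(record_spikes)),
            class = "train_config")
}

#' Classification accuracy of a network
#'
#' Runs the forward simulation and reads the prediction off the output
#' layer's final-step surrogate by argmax; ties break to the lowest class
#' index. Accuracy is reported in percent.
#'
#' @param net an [snn_network()].
#' @param params a [neuron_params()] object.
#' @param X inputs (samples x input dim), values in `[0, 1]`.
#' @param y integer labels in `[0, n_classes)`.
#' @return Accuracy in `[0, 100]`.
#' @export
snn_evaluate <- function(net, params, X, y) {
  X <- as_act(X)
  if (nrow(X) == 0L) stop("cannot evaluate on an empty dataset", call. = FALSE)
  if (nrow(X) != length(y)) {
    stop_dim("X has %d rows but y has %d labels", nrow(X), length(y))
  }
  trace <- simulate_forward(net, X, params)
  S_out <- trace$S_layers[[length(net$layer_sizes)]]
  pred <- max.col(S_out, ties.method = "first") - 1L
  100 * mean(pred == as.integer(y))
}

#' Train a spiking network with global feedback targets and local STDP
#'
#' One epoch repeats, over shuffled minibatches: (1) simulate the LIF
#' forward pass and keep the final-step surrogates, (2) form the signed
#' output error and per-layer targets — transpose path for the penultimate
#' layer, frozen random direct feedback for the enabled deeper hidden
#' layers, the one-hot itself for the output — and (3) update all weight
#' matrices simultaneously by the differential STDP rule from that one
#' frozen trace. Plain SGD, no momentum, no regularization.
#'
#' Fully deterministic given `cfg$seed`: weight and feedback draws and each
#' epoch's shuffle derive from it. Training data are reshuffled every epoch;
#' test order is left alone.
#'
#' @param cfg a [train_config()].
#' @param train_set,test_set [snn_dataset()] objects (test may be `NULL`).
#' @param verbose print one structured log line per epoch
#'   (`epoch= train_acc= test_acc= loss=`).
#' @return An object of class `train_result`: per-epoch `train_acc`,
#'   `test_acc`, `loss` (mean batch L2 loss), the final `network`, the
#'   frozen `feedback` draws, the `config`, and per-epoch wall-clock
#'   `seconds` (informational).
#' @examples
#' d <- make_blobs(30, dim = 5, n_classes = 2, separation = 6,
#'                 noise_sd = 0.05, seed = 1)
#' cfg <- train_config(c(5, 16, 2), epochs = 5, seed = 1)
#' res <- snn_train(cfg, d$train, d$test)
#' tail(res$test_acc, 1)
#' @export
snn_train <- function(cfg, train_set, test_set = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"), inherits(train_set, "snn_dataset"))
  L <- length(cfg$layer_sizes)
  if (ncol(train_set$X) != cfg$layer_sizes[1L]) {
    stop_dim("data width %d does not match input layer size %d",
             ncol(train_set$X), cfg$layer_sizes[1L])
  }
  if (train_set$n_classes > cfg$layer_sizes[L]) {
    stop("more classes than output neurons", call. = FALSE)
  }

  net <- init_network(cfg$layer_sizes, derive_seed(cfg$seed, 1L),
                      cfg$init_scheme)
  fb <- init_feedback(cfg$layer_sizes, derive_seed(cfg$seed, 2L),
                      scale = cfg$feedback_scale,
                      bias_scale = cfg$feedback_bias_scale,
                      eta_t = cfg$eta_t)

  n <- nrow(train_set$X)
  train_acc <- test_acc <- loss <- seconds <- numeric(cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- local({
      old_seed <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                             envir = globalenv()))
      set.seed(derive_seed(cfg$seed, 3L, epoch))
      sample.int(n)
    })
    batch_starts <- seq(1L, n, by = cfg$batch_size)
    epoch_loss <- 0
    for (bs in batch_starts) {
      idx <- ord[bs:min(bs + cfg$batch_size - 1L, n)]
      Xb <- train_set$X[idx, , drop = FALSE]
      yb <- train_set$y[idx]
      step <- tryCatch({
        trace <- simulate_forward(net, Xb, cfg$params)
        targets <- compute_all_targets(trace, net, fb, yb,
                                       n_feedback_layers = cfg$n_feedback_layers)
        batch_loss <- l2_loss(trace$S_layers[[L]], targets$S_T)
        if (!is.finite(batch_loss)) stop("non-finite loss", call. = FALSE)
        list(loss = batch_loss,
             net = update_all_layers(net, trace, targets, cfg$eta_w,
                                     cfg$batch_reduction))
      }, error = function(e) {
        stop(sprintf(
          "training diverged at epoch %d, batch starting at sample %d: %s",
          epoch, bs, conditionMessage(e)), call. = FALSE)
      })
      epoch_loss <- epoch_loss + step$loss
      net <- step$net
    }
    loss[epoch] <- epoch_loss / length(batch_starts)
    train_acc[epoch] <- snn_evaluate(net, cfg$params, train_set$X,
                                     train_set$y)
    test_acc[epoch] <- if (is.null(test_set)) NA_real_ else {
      snn_evaluate(net, cfg$params, test_set$X, test_set$y)
    }
    seconds[epoch] <- proc.time()[["elapsed"]] - t0
    if (verbose) {
      cat(sprintf("epoch=%d train_acc=%.2f test_acc=%s loss=%.6g\n",
                  epoch, train_acc[epoch],
                  if (is.na(test_acc[epoch])) "NA"
                  else sprintf("%.2f", test_acc[epoch]),
                  loss[epoch]))
    }
  }

  structure(list(train_acc = train_acc, test_acc = test_acc, loss = loss,
                 network = net, feedback = fb, config = cfg,
                 seconds = seconds),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  e <- length(x$loss)
  cat(sprintf("Training result: %d epochs on [%s]\n", e,
              paste(x$config$layer_sizes, collapse = "-")))
  cat(sprintf("  final: train %.2f%%  test %s  loss %.4g\n",
              x$train_acc[e],
              if (is.na(x$test_acc[e])) "-" else sprintf("%.2f%%", x$test_acc[e]),
              x$loss[e]))
  invisible(x)
}

#' Feedback-layer ablation
#'
#' Trains one network per requested feedback-layer count, all from the same
#' seed (hence identical initial weights and data order), and returns the
#' results in the given order. Count 0 removes every random-feedback
#' projection, so only the top two weight matrices can change — the output
#' weights (one-hot target) and the penultimate layer's incoming weights
#' (transpose-path target); each added feedback layer unfreezes the next
#' shallower hidden layer, bottom layer last.
#'
#' @param base_cfg a [train_config()]; its `n_feedback_layers` is
#'   overridden per run.
#' @param feedback_counts integer vector of counts, each in `0..L-3`.
#' @param train_set,test_set [snn_dataset()] objects.
#' @return List of `train_result`, one per count, named by count.
#' @export
run_ablation <- function(base_cfg, feedback_counts, train_set,
                         test_set = NULL) {
  stopifnot(inherits(base_cfg, "train_config"))
  max_fb <- max(0L, length(base_cfg$layer_sizes) - 3L)
  feedback_counts <- as.integer(feedback_counts)
  if (any(feedback_counts < 0L | feedback_counts > max_fb)) {
    stop(sprintf("feedback counts must lie in 0..%d", max_fb), call. = FALSE)
  }
  out <- lapply(feedback_counts, function(k) {
    cfg <- base_cfg
    cfg$n_feedback_layers <- k
    snn_train(cfg, train_set, test_set)
  })
  names(out) <- as.character(feedback_counts)
  out
}

#' Depth sweep at fixed hidden width
#'
#' Trains one network per hidden-layer count, sharing the input width,
#' class count, seed and all other settings of `base_cfg`, and tabulates
#' final accuracies.
#'
#' @param base_cfg a [train_config()]; its first and last layer sizes are
#'   kept, the hidden stack is replaced.
#' @param hidden_layer_counts integer vector of hidden-layer counts.
#' @param hidden_width neurons per hidden layer.
#' @param train_set,test_set [snn_dataset()] objects.
#' @return A `data.frame` with columns `n_hidden`, `layer_sizes`,
#'   `train_acc`, `test_acc`, `loss`; one row per depth. The per-run
#'   results are attached as attribute `"results"`.
#' @export
depth_sweep <- function(base_cfg, hidden_layer_counts, hidden_width,
                        train_set, test_set = NULL) {
  stopifnot(inherits(base_cfg, "train_config"))
  n_in <- base_cfg$layer_sizes[1L]
  n_out <- base_cfg$layer_sizes[length(base_cfg$layer_sizes)]
  hidden_layer_counts <- as.integer(hidden_layer_counts)
  if (any(hidden_layer_counts < 1L)) {
    stop("hidden layer counts must be >= 1", call. = FALSE)
  }
  max_depth <- n_steps(base_cfg$params) - 1L  # weight layers <= T/dt
  if (any(hidden_layer_counts > max_depth)) {
    stop(sprintf(paste0("a %d-hidden-layer network needs more than the %d",
                        " simulation steps available (T/dt)"),
                 max(hidden_layer_counts), n_steps(base_cfg$params)),
         call. = FALSE)
  }
  results <- lapply(hidden_layer_counts, function(h) {
    cfg <- base_cfg
    cfg$layer_sizes <- as.integer(c(n_in, rep(hidden_width, h), n_out))
    cfg$n_feedback_layers <- max(0L, length(cfg$layer_sizes) - 3L)
    snn_train(cfg, train_set, test_set)
  })
  tab <- data.frame(
    n_hidden = hidden_layer_counts,
    layer_sizes = vapply(results, function(r) {
      paste(r$config$layer_sizes, collapse = "-")
    }, character(1)),
    train_acc = vapply(results, function(r) tail(r$train_acc, 1), numeric(1)),
    test_acc = vapply(results, function(r) tail(r$test_acc, 1), numeric(1)),
    loss = vapply(results, function(r) tail(r$loss, 1), numeric(1)),
    stringsAsFactors = FALSE
  )
  attr(tab, "results") <- results
  tab
}
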