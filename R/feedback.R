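#' Fixed random feedback projections
#'
#' Direct feedback carries the output error straight to each hidden layer
#' (no layer-by-layer chaining): layer `l`'s target shift is
#' `B_l %*% e + b_l` with `B_l` and `b_l` drawn once at initialization and
#' frozen for the whole of training. Only the hidden layers *below* the
#' penultimate one need feedback matrices — the penultimate layer's target
#' comes through the transpose of the top forward weights instead.
#'
#' `B[[l]]` (for layer index `l` in `2 ... L-2`) has shape `n_l x n_L`
#' with entries `N(0, (scale/sqrt(n_l))^2)` — normalized by the *receiving*
#' layer's width, so the projected shift `B_l e` has about the same norm as
#' the error `e` itself regardless of layer size or class count. (Scaling
#' by the error's dimension instead makes the shift's largest singular
#' direction grow like `sqrt(n_l / n_out)` and destabilizes training for
#' small class counts.) `b[[l]]` has `n_l` entries `N(0, bias_scale^2)`.
#' With fewer than 4 layers there is nothing to draw and the feedback set
#' is empty (valid: only the transpose path applies).
#'
#' @param layer_sizes neuron counts per layer.
#' @param seed integer seed; identical seeds give identical draws.
#' @param scale feedback weight scale; entries have sd `scale/sqrt(n_l)`.
#' @param bias_scale sd of the feedback biases (0 disables them).
#' @param eta_t target learning rate used by the penultimate layer's
#'   transpose path.
#' @return An object of class `feedback_params` with fields `B`, `b`
#'   (lists indexed by hidden layer, `NULL` where no feedback applies)
#'   and `eta_t`.
#' @export
init_feedback <- function(layer_sizes, seed, scale = 1.0, bias_scale = 0,
                          eta_t = 0.5) {
  layer_sizes <- as.integer(layer_sizes)
  L <- length(layer_sizes)
  if (L < 2L) stop("need at least 2 layers", call. = FALSE)
  n_out <- layer_sizes[L]
  B <- vector("list", L)
  b <- vector("list", L)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  if (L >= 4L) {
    for (l in 2:(L - 2L)) {
      n_l <- layer_sizes[l]
      B[[l]] <- matrix(stats::rnorm(n_l * n_out, sd = scale / sqrt(n_l)),
                       n_l, n_out)
      b[[l]] <- stats::rnorm(n_l, sd = bias_scale)
    }
  }
  structure(list(B = B, b = b, eta_t = as.double(eta_t),
                 layer_sizes = layer_sizes),
            class = "feedback_params")
}

#' @export
print.feedback_params <- function(x, ...) {
  n_fb <- sum(!vapply(x$B, is.null, logical(1)))
  cat(sprintf("Fixed random feedback: %d projection(s), eta_t = %g\n",
              n_fb, x$eta_t))
  invisible(x)
}

#' Batch L2 loss
#'
#' Sum over samples of the squared Euclidean distance between output-layer
#' surrogates and targets.
#'
#' @param S_out output matrix (samples x classes) or vector.
#' @param S_T target matrix of the same shape.
#' @return Scalar loss.
#' @export
l2_loss <- function(S_out, S_T) {
  check_same_shape(S_out, S_T, "S_out", "S_T")
  sum((S_out - S_T)^2)
}

#' Signed per-sample prediction error
#'
#' The gradient of [l2_loss()] with respect to the outputs:
#' `e = 2 (S_out - S_T)`, kept per sample (one row each) because the layer
#' targets built from it must have the same shape as the layer activities.
#'
#' @inheritParams l2_loss
#' @return Matrix (or vector) of the same shape as `S_out`.
#' @export
prediction_error <- function(S_out, S_T) {
  check_same_shape(S_out, S_T, "S_out", "S_T")
  2 * (S_out - S_T)
}

#' Total absolute prediction error (scalar diagnostic)
#'
#' `2 * sum(|S_out - S_T|)`, an unsigned batch aggregate useful for
#' monitoring. It carries no direction information, so the layer targets
#' are built from [prediction_error()] instead.
#'
#' @inheritParams l2_loss
#' @return A scalar.
#' @export
abs_error_sum <- function(S_out, S_T) {
  check_same_shape(S_out, S_T, "S_out", "S_T")
  2 * sum(abs(S_out - S_T))
}

#' Penultimate-layer target via the forward-weight transpose
#'
#' The layer feeding the output can use the top weights themselves to pull
#' the error back: `S_hat = S_pen - eta_t * e W_out^T`. No random feedback
#' is involved, so this path exists even when all feedback projections are
#' ablated.
#'
#' @param S_pen penultimate-layer surrogate outputs (samples x n_pen).
#' @param W_out top weight matrix (n_pen x n_out).
#' @param e signed error from [prediction_error()] (samples x n_out).
#' @param eta_t target learning rate.
#' @return Target activations, same shape as `S_pen`.
#' @export
penultimate_target <- function(S_pen, W_out, e, eta_t) {
  S_pen <- as_act(S_pen)
  e <- as_act(e)
  if (!is.matrix(W_out)) stop("W_out must be a matrix", call. = FALSE)
  if (ncol(S_pen) != nrow(W_out) || ncol(e) != ncol(W_out)) {
    stop_dim("penultimate_target: S_pen is %dx%d, W_out %dx%d, e %dx%d",
             nrow(S_pen), ncol(S_pen), nrow(W_out), ncol(W_out),
             nrow(e), ncol(e))
  }
  if (nrow(S_pen) != nrow(e)) {
    stop_dim("batch sizes differ: S_pen has %d rows, e has %d",
             nrow(S_pen), nrow(e))
  }
  S_pen - eta_t * (e %*% t(W_out))
}

#' Hidden-layer target via direct random feedback
#'
#' `S_hat_l = S_l - (e B_l^T + b_l)`: the frozen random projection of the
#' output error, plus a frozen bias, subtracted from the forward state.
#'
#' @param S_l hidden-layer surrogate outputs (samples x n_l).
#' @param B_l feedback matrix (n_l x n_out).
#' @param b_l feedback bias (length n_l).
#' @param e signed error (samples x n_out).
#' @return Target activations, same shape as `S_l`.
#' @export
hidden_target <- function(S_l, B_l, b_l, e) {
  S_l <- as_act(S_l)
  e <- as_act(e)
  if (!is.matrix(B_l)) stop("B_l must be a matrix", call. = FALSE)
  if (ncol(S_l) != nrow(B_l) || ncol(e) != ncol(B_l) ||
      length(b_l) != nrow(B_l) || nrow(S_l) != nrow(e)) {
    stop_dim("hidden_target: S_l is %dx%d, B_l %dx%d, b_l length %d, e %dx%d",
             nrow(S_l), ncol(S_l), nrow(B_l), ncol(B_l), length(b_l),
             nrow(e), ncol(e))
  }
  shift <- e %*% t(B_l)
  sweep(S_l - shift, 2L, b_l, "-")
}

#' Compute every layer target for a batch
#'
#' Builds the one-hot output target, forms the signed error, and assigns:
#' the penultimate layer its transpose-path target, and each enabled hidden
#' layer below it a direct-feedback target. Counting from the deepest
#' feedback-eligible hidden layer, only the first `n_feedback_layers`
#' receive targets; the rest get `NULL` (their incoming weights stay
#' frozen). The input layer never gets a target.
#'
#' @param trace a `forward_trace` from [simulate_forward()] on this batch.
#' @param net the [snn_network()] that produced it.
#' @param fb [init_feedback()] parameters (carries `eta_t`).
#' @param labels integer class labels in `[0, n_classes)`.
#' @param n_feedback_layers how many hidden layers (beyond the penultimate)
#'   receive direct-feedback targets, counted deep to shallow; default all.
#' @param amplitude one-hot target amplitude.
#' @return An object of class `target_set`: `S_hat` (list indexed by layer,
#'   `NULL` for layers without a target), `S_T` (samples x classes), and
#'   `e` (the signed error).
#' @export
compute_all_targets <- function(trace, net, fb, labels,
                                n_feedback_layers = NULL, amplitude = 1.0) {
  stopifnot(inherits(trace, "forward_trace"), inherits(net, "snn_network"),
            inherits(fb, "feedback_params"))
  L <- length(net$layer_sizes)
  n_classes <- net$layer_sizes[L]
  max_fb <- max(0L, L - 3L)
  if (is.null(n_feedback_layers)) n_feedback_layers <- max_fb
  if (n_feedback_layers < 0L || n_feedback_layers > max_fb) {
    stop(sprintf("n_feedback_layers must be in 0..%d for %d layers",
                 max_fb, L), call. = FALSE)
  }
  S_T <- one_hot(labels, n_classes, amplitude)
  S_out <- trace$S_layers[[L]]
  if (nrow(S_T) != nrow(S_out)) {
    stop_dim("batch size mismatch: %d labels, %d outputs",
             nrow(S_T), nrow(S_out))
  }
  e <- prediction_error(S_out, S_T)

  S_hat <- vector("list", L)
  S_hat[[L - 1L]] <- penultimate_target(trace$S_layers[[L - 1L]],
                                        net$weights[[L - 1L]], e, fb$eta_t)
  if (n_feedback_layers > 0L) {
    enabled <- seq(L - 2L, by = -1L, length.out = n_feedback_layers)
    for (l in enabled) {
      if (is.null(fb$B[[l]])) {
        stop(sprintf("no feedback projection initialized for layer %d", l),
             call. = FALSE)
      }
      S_hat[[l]] <- hidden_target(trace$S_layers[[l]], fb$B[[l]],
                                  fb$b[[l]], e)
    }
  }
  structure(list(S_hat = S_hat, S_T = S_T, e = e), class = "target_set")
}
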