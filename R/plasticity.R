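#' Differential STDP weight change
#'
#' The local rule: each synapse's change is the presynaptic surrogate
#' output times the postsynaptic difference between forward state and
#' target, `dW = S_pre^T (S_post - S_hat_post)`, oriented like the forward
#' weight (pre-dim x post-dim). Samples in a batch are combined by the mean
#' (default, which makes the learning rate batch-size invariant) or the
#' sum.
#'
#' Only quantities local to the two layers the synapse connects appear:
#' no other layer's state or target can influence the update.
#'
#' @param S_pre presynaptic surrogates (samples x n_pre).
#' @param S_post postsynaptic forward surrogates (samples x n_post).
#' @param S_post_hat postsynaptic targets, same shape as `S_post`.
#' @param reduction `"mean"` or `"sum"` over the batch.
#' @return Weight-shaped update matrix (n_pre x n_post).
#' @export
stdp_delta <- function(S_pre, S_post, S_post_hat,
                       reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  S_pre <- as_act(S_pre)
  S_post <- as_act(S_post)
  S_post_hat <- as_act(S_post_hat)
  check_same_shape(S_post, S_post_hat, "S_post", "S_post_hat")
  if (nrow(S_pre) != nrow(S_post)) {
    stop_dim("batch sizes differ: S_pre has %d rows, S_post has %d",
             nrow(S_pre), nrow(S_post))
  }
  dW <- crossprod(S_pre, S_post - S_post_hat)
  if (reduction == "mean") dW <- dW / nrow(S_pre)
  dW
}

#' Plain gradient step on a weight matrix
#'
#' `W' = W - eta_w * dW`. No momentum, no clipping, no decay, no
#' normalization — the rule is applied bare. The input matrix is not
#' modified.
#'
#' @param W weight matrix.
#' @param dW update from [stdp_delta()], same shape.
#' @param eta_w weight learning rate (>= 0).
#' @return The updated matrix.
#' @export
apply_update <- function(W, dW, eta_w) {
  check_same_shape(W, dW, "W", "dW")
  if (eta_w < 0) stop("eta_w must be >= 0", call. = FALSE)
  W - eta_w * dW
}

#' Update every weight matrix from one frozen forward trace
#'
#' All layers are updated simultaneously from the same pre-update forward
#' pass — no re-simulation between layer updates. Weight `l` (feeding layer
#' `l+1`) uses layer `l`'s surrogates as the presynaptic factor and layer
#' `l+1`'s forward/target difference as the postsynaptic one; the top
#' weights use the one-hot output target directly. Weights into layers
#' without a target (`NULL` in the target set) are returned bit-identical.
#'
#' @param net an [snn_network()].
#' @param trace the `forward_trace` from this batch.
#' @param targets the `target_set` computed from the same trace.
#' @param eta_w weight learning rate.
#' @param reduction batch reduction, `"mean"` (default) or `"sum"`.
#' @return A new [snn_network()] with updated weights.
#' @export
update_all_layers <- function(net, trace, targets, eta_w,
                              reduction = c("mean", "sum")) {
  stopifnot(inherits(net, "snn_network"), inherits(trace, "forward_trace"),
            inherits(targets, "target_set"))
  reduction <- match.arg(reduction)
  L <- length(net$layer_sizes)
  weights <- net$weights
  for (l in seq_len(L - 1L)) {
    post_hat <- if (l + 1L == L) targets$S_T else targets$S_hat[[l + 1L]]
    if (is.null(post_hat)) next  # frozen: no target for the post layer
    dW <- stdp_delta(trace$S_layers[[l]], trace$S_layers[[l + 1L]],
                     post_hat, reduction)
    weights[[l]] <- apply_update(weights[[l]], dW, eta_w)
  }
  snn_network(net$layer_sizes, weights)
}
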