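#' Feedforward spiking network
#'
#' A fully connected network is its layer sizes `[n_1 ... n_L]` (input
#' width first, class count last) plus `L - 1` forward weight matrices,
#' `weights[[l]]` of shape `n_l x n_{l+1}` mapping layer `l` surrogate
#' outputs to layer `l+1` drives. There are no bias terms.
#'
#' @param layer_sizes integer vector of neuron counts, length >= 2.
#' @param weights list of `length(layer_sizes) - 1` weight matrices.
#' @return An object of class `snn_network`.
#' @export
snn_network <- function(layer_sizes, weights) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L) {
    stop("a network needs at least an input and an output layer",
         call. = FALSE)
  }
  if (any(layer_sizes < 1L)) stop("all layer sizes must be >= 1", call. = FALSE)
  if (length(weights) != length(layer_sizes) - 1L) {
    stop_dim("expected %d weight matrices, got %d",
             length(layer_sizes) - 1L, length(weights))
  }
  for (l in seq_along(weights)) {
    W <- weights[[l]]
    if (!is.matrix(W) || !identical(dim(W), c(layer_sizes[l], layer_sizes[l + 1L]))) {
      stop_dim("weights[[%d]] must be a %d x %d matrix", l,
               layer_sizes[l], layer_sizes[l + 1L])
    }
    check_finite(W, sprintf("weights[[%d]]", l))
  }
  structure(list(layer_sizes = layer_sizes, weights = weights),
            class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cat(sprintf("Spiking network [%s], %d weight matrices, %d parameters\n",
              paste(x$layer_sizes, collapse = "-"),
              length(x$weights),
              sum(vapply(x$weights, length, integer(1)))))
  invisible(x)
}

# Orthogonal init: QR of a Gaussian matrix, sign-fixed by the diagonal of R
# so the draw is a deterministic function of the RNG stream. Orthogonality
# holds on the smaller dimension of a nonsquare matrix.
random_orthogonal <- function(n_rows, n_cols) {
  if (n_rows >= n_cols) {
    A <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
    qr_d <- qr(A)
    Q <- qr.Q(qr_d)
    Q * rep(sign(diag(qr.R(qr_d)) + (diag(qr.R(qr_d)) == 0)), each = n_rows)
  } else {
    t(random_orthogonal(n_cols, n_rows))
  }
}

#' Initialize forward weights
#'
#' Two reproducible schemes:
#' \describe{
#'   \item{`orthogonal`}{QR-based random (semi-)orthogonal matrices — the
#'     default, matching target-propagation practice; for nonsquare shapes
#'     orthonormality holds on the smaller dimension.}
#'   \item{`scaled_uniform`}{zero-mean uniform on
#'     `[-sqrt(6/(fan_in+fan_out)), +sqrt(6/(fan_in+fan_out))]`.}
#' }
#'
#' @param layer_sizes neuron counts per layer, length >= 2, all >= 1.
#' @param seed integer seed; the same seed always yields the same weights.
#' @param scheme `"orthogonal"` or `"scaled_uniform"`.
#' @return An [snn_network()].
#' @examples
#' net <- init_network(c(4, 4), seed = 1)
#' crossprod(net$weights[[1]])  # ~ identity
#' @export
init_network <- function(layer_sizes, seed, scheme = c("orthogonal", "scaled_uniform")) {
  scheme <- match.arg(scheme)
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stop("layer_sizes must have length >= 2 with all sizes >= 1",
         call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  weights <- vector("list", length(layer_sizes) - 1L)
  for (l in seq_along(weights)) {
    n_in <- layer_sizes[l]
    n_out <- layer_sizes[l + 1L]
    weights[[l]] <- switch(scheme,
      orthogonal = random_orthogonal(n_in, n_out),
      scaled_uniform = {
        bound <- sqrt(6 / (n_in + n_out))
        matrix(stats::runif(n_in * n_out, -bound, bound), n_in, n_out)
      }
    )
  }
  snn_network(layer_sizes, weights)
}

#' Simulate the feedforward pass
#'
#' Runs a batch of inputs through the network for `T/dt` steps of the
#' discrete LIF dynamics. At every step the input layer's surrogate output
#' is the raw input vector itself (held constant — a constant-current-style
#' encoding, not stochastic spike coding), and layers advance once per step
#' in ascending order, each consuming the surrogate output its predecessor
#' just produced within the same step. Per-sample state is independent:
#' batch elements never interact.
#'
#' The learning rule only reads the surrogate outputs at the final step, so
#' that is what the trace stores; full per-step spike trains are recorded
#' only on request (for rasters).
#'
#' Networks deeper than the step budget are rejected: the number of weight
#' layers must not exceed `T/dt`, so every layer's dynamics get at least one
#' settled step of input-driven activity.
#'
#' @param net an [snn_network()].
#' @param X input matrix (samples x `n_1`), values expected in `[0, 1]`;
#'   a vector is treated as a single sample.
#' @param params a [neuron_params()] object.
#' @param record_spikes if `TRUE`, keep the full binary spike tensor per
#'   layer (`steps x neurons x samples`).
#' @return An object of class `forward_trace` with fields
#'   \describe{
#'     \item{S_layers}{list of `L` matrices of final-step surrogate outputs,
#'       `S_layers[[1]]` being the encoded input.}
#'     \item{spike_counts}{list of `L` matrices (samples x neurons) of
#'       per-neuron spike totals over the simulation; the input layer, which
#'       never spikes, has all zeros.}
#'     \item{spikes}{when recorded, list of `L` arrays
#'       (`steps x neurons x samples`); `NULL` entries otherwise.}
#'     \item{n_steps}{simulation steps executed.}
#'   }
#' @export
simulate_forward <- function(net, X, params, record_spikes = FALSE) {
  stopifnot(inherits(net, "snn_network"), inherits(params, "neuron_params"))
  X <- as_act(X)
  check_finite(X, "X")
  L <- length(net$layer_sizes)
  if (ncol(X) != net$layer_sizes[1L]) {
    stop_dim("input width %d does not match input layer size %d",
             ncol(X), net$layer_sizes[1L])
  }
  steps <- n_steps(params)
  if (L - 1L > steps) {
    stop(sprintf(paste0("network has %d weight layers but only %d simulation",
                        " steps (T/dt); deepen T or shrink the network"),
                 L - 1L, steps), call. = FALSE)
  }
  batch <- nrow(X)

  states <- vector("list", L)
  spikes <- vector("list", L)
  spike_counts <- vector("list", L)
  spike_counts[[1L]] <- matrix(0, batch, net$layer_sizes[1L])
  for (l in 2:L) {
    states[[l]] <- initial_state(net$layer_sizes[l], params, batch)
    spike_counts[[l]] <- matrix(0, batch, net$layer_sizes[l])
    if (record_spikes) {
      spikes[[l]] <- array(0, dim = c(steps, net$layer_sizes[l], batch))
    }
  }

  for (t in seq_len(steps)) {
    S_prev <- X
    for (l in 2:L) {
      drive <- S_prev %*% net$weights[[l - 1L]]
      states[[l]] <- lif_step(states[[l]], drive, params)
      S_prev <- states[[l]]$S
      spike_counts[[l]] <- spike_counts[[l]] + states[[l]]$delta
      if (record_spikes) {
        spikes[[l]][t, , ] <- t(states[[l]]$delta)
      }
    }
  }

  S_layers <- vector("list", L)
  S_layers[[1L]] <- X
  for (l in 2:L) S_layers[[l]] <- states[[l]]$S
  structure(list(S_layers = S_layers, spike_counts = spike_counts,
                 spikes = if (record_spikes) spikes else NULL,
                 n_steps = steps),
            class = "forward_trace")
}

#' Export spike rasters as delimited text
#'
#' Writes one tab-separated file per (sample, layer): a binary matrix with
#' one row per simulation step and one column per neuron, suitable for
#' raster plots. Requires a trace produced with `record_spikes = TRUE`.
#'
#' @param trace a `forward_trace` with recorded spikes.
#' @param dir output directory (created if missing).
#' @param samples which batch elements to export (default: all).
#' @param prefix filename prefix.
#' @return Invisibly, the paths written (named `sample<i>_layer<l>.tsv`).
#' @export
write_spike_rasters <- function(trace, dir, samples = NULL, prefix = "raster") {
  stopifnot(inherits(trace, "forward_trace"))
  if (is.null(trace$spikes)) {
    stop("trace has no recorded spikes; rerun simulate_forward(record_spikes = TRUE)",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- length(trace$S_layers)
  batch <- nrow(trace$S_layers[[1L]])
  if (is.null(samples)) samples <- seq_len(batch)
  paths <- character(0)
  for (i in samples) {
    for (l in 2:L) {
      m <- trace$spikes[[l]][, , i, drop = FALSE]
      dim(m) <- dim(trace$spikes[[l]])[1:2]
      path <- file.path(dir, sprintf("%s_sample%d_layer%d.tsv", prefix, i, l))
      utils::write.table(m, path, sep = "\t", row.names = FALSE,
                         col.names = FALSE)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}
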