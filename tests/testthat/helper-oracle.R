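# Independent scalar-loop reference implementations. Everything here is
# written with explicit per-neuron / per-sample loops and no shared code
# with the package internals, so agreement is a real cross-check.

oracle_lif_step <- function(V, g_E, drive, p) {
  n <- length(V)
  V_new <- numeric(n)
  g_new <- numeric(n)
  delta <- numeric(n)
  S <- numeric(n)
  for (i in seq_len(n)) {
    v <- V[i] - (p$dt / p$tau_m) *
      ((V[i] - p$V_L) + (g_E[i] / p$g_L) * (V[i] - p$V_E))
    g_new[i] <- g_E[i] + (p$dt / p$tau_E) * (-g_E[i] + drive[i])
    if (v > p$V_th) {
      delta[i] <- 1
      v <- p$V_reset
    }
    V_new[i] <- v
    S[i] <- drive[i] + p$tau_s * delta[i]
  }
  list(V = V_new, g_E = g_new, delta = delta, S = S)
}

# Whole forward pass for ONE sample: layers advance in ascending order
# within each global step, each consuming the surrogate its predecessor
# just produced.
oracle_forward_sample <- function(weights, x, p) {
  steps <- as.integer(round(p$T / p$dt))
  Lw <- length(weights)
  st <- lapply(seq_len(Lw), function(l) {
    n <- ncol(weights[[l]])
    list(V = rep(p$V_reset, n), g_E = numeric(n), delta = numeric(n),
         S = numeric(n))
  })
  counts <- lapply(st, function(s) numeric(length(s$V)))
  for (t in seq_len(steps)) {
    s_prev <- x
    for (l in seq_len(Lw)) {
      W <- weights[[l]]
      drive <- numeric(ncol(W))
      for (j in seq_len(ncol(W))) {
        acc <- 0
        for (i in seq_len(nrow(W))) acc <- acc + s_prev[i] * W[i, j]
        drive[j] <- acc
      }
      st[[l]] <- oracle_lif_step(st[[l]]$V, st[[l]]$g_E, drive, p)
      counts[[l]] <- counts[[l]] + st[[l]]$delta
      s_prev <- st[[l]]$S
    }
  }
  list(S = c(list(x), lapply(st, `[[`, "S")), counts = counts)
}

# One full learning step on a single sample, composed by hand from the
# rule's pieces: signed error, transpose-path target for the penultimate
# layer, random-feedback targets below, outer-product STDP, plain SGD.
oracle_one_update <- function(weights, B, b, x, label, n_classes,
                              p, eta_t, eta_w) {
  Lw <- length(weights)
  fwd <- oracle_forward_sample(weights, x, p)
  S <- fwd$S                       # list of length Lw + 1, S[[1]] = input
  s_T <- numeric(n_classes)
  s_T[label + 1] <- 1
  e <- 2 * (S[[Lw + 1]] - s_T)

  hats <- vector("list", Lw + 1)   # target for layer index (input = 1)
  hats[[Lw + 1]] <- s_T
  # penultimate: pull e back through the top weights
  W_top <- weights[[Lw]]
  shift <- numeric(nrow(W_top))
  for (i in seq_len(nrow(W_top))) {
    for (j in seq_len(ncol(W_top))) {
      shift[i] <- shift[i] + W_top[i, j] * e[j]
    }
  }
  hats[[Lw]] <- S[[Lw]] - eta_t * shift
  # deeper hidden layers: fixed random projections
  if (Lw >= 2) {
    for (l in seq_len(Lw - 1)[-1]) {  # layer indices 2 .. Lw-1 (if any)
      Bl <- B[[l]]
      sh <- numeric(nrow(Bl))
      for (i in seq_len(nrow(Bl))) {
        for (j in seq_len(ncol(Bl))) sh[i] <- sh[i] + Bl[i, j] * e[j]
        sh[i] <- sh[i] + b[[l]][i]
      }
      hats[[l]] <- S[[l]] - sh
    }
  }

  new_w <- weights
  for (l in seq_len(Lw)) {
    pre <- S[[l]]
    diff <- S[[l + 1]] - hats[[l + 1]]
    for (i in seq_along(pre)) {
      for (j in seq_along(diff)) {
        new_w[[l]][i, j] <- new_w[[l]][i, j] - eta_w * pre[i] * diff[j]
      }
    }
  }
  new_w
}

random_net <- function(layer_sizes, seed) {
  set.seed(seed)
  weights <- lapply(seq_len(length(layer_sizes) - 1), function(l) {
    matrix(rnorm(layer_sizes[l] * layer_sizes[l + 1], sd = 0.5),
           layer_sizes[l], layer_sizes[l + 1])
  })
  snn_network(layer_sizes, weights)
}
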