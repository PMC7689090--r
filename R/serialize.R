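#' Save a model archive
#'
#' Stores the network, the frozen feedback draws and (optionally) the
#' config in one RDS archive, so a run is fully resumable: weights and
#' feedback matrices round-trip bit-exactly.
#'
#' @param net an [snn_network()].
#' @param fb a `feedback_params` object (or `NULL`).
#' @param path output path.
#' @param config optional [train_config()] to embed.
#' @return `path`, invisibly.
#' @export
save_model <- function(net, fb = NULL, path, config = NULL) {
  stopifnot(inherits(net, "snn_network"))
  saveRDS(list(format = "lifnet-model-1", network = net, feedback = fb,
               config = config), path)
  invisible(path)
}

#' Load a model archive
#'
#' @param path path written by [save_model()].
#' @return List with `network`, `feedback`, `config`.
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) NULL)
  if (!identical(obj$format, "lifnet-model-1")) {
    stop(sprintf("not a lifnet model archive: %s", path), call. = FALSE)
  }
  obj[c("network", "feedback", "config")]
}

#' Read a sectioned key-value config file
#'
#' Flat INI-style text: `[section]` headers, `key = value` lines, `#`
#' comments and blank lines ignored. Values stay character; callers coerce.
#'
#' @param path file path.
#' @return Named list of sections, each a named character vector.
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  sections <- list()
  current <- "default"
  for (line in lines) {
    if (grepl("^\\[.+\\]$", line)) {
      current <- gsub("^\\[|\\]$", "", line)
      if (is.null(sections[[current]])) sections[[current]] <- character(0)
    } else if (grepl("=", line, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", line))
      val <- trimws(sub("^[^=]*=", "", line))
      sections[[current]] <- c(sections[[current]],
                               stats::setNames(val, key))
    } else {
      stop(sprintf("cannot parse config line: '%s'", line), call. = FALSE)
    }
  }
  sections
}

#' Write a sectioned key-value config file
#'
#' @param sections named list of sections, each coercible to a named
#'   character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config_file <- function(sections, path) {
  out <- character(0)
  for (sec in names(sections)) {
    out <- c(out, sprintf("[%s]", sec))
    kv <- sections[[sec]]
    out <- c(out, sprintf("%s = %s", names(kv), as.character(kv)), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Build a train_config from a config file plus overrides
#'
#' Sections: `[neuron]` (keys of [neuron_params()]), `[network]`
#' (`layer_sizes` as comma-separated counts, `init_scheme`), `[train]`
#' (`epochs`, `batch_size`, `eta_t`, `eta_w`, `seed`, `n_feedback_layers`,
#' `feedback_scale`, `feedback_bias_scale`, `batch_reduction`). Entries in
#' `overrides` (same keys, flat) win over file values.
#'
#' @param path config file path, or `NULL` for pure defaults + overrides.
#' @param overrides named list of flat overrides.
#' @return A [train_config()].
#' @export
config_from_file <- function(path = NULL, overrides = list()) {
  sections <- if (is.null(path)) list() else read_config_file(path)
  neuron_kv <- as.list(sections[["neuron"]])
  net_kv <- as.list(sections[["network"]])
  train_kv <- as.list(sections[["train"]])
  flat <- c(net_kv, train_kv)
  for (k in names(overrides)) {
    v <- overrides[[k]]
    if (is.null(v)) next
    if (k %in% neuron_param_keys) neuron_kv[[k]] <- v else flat[[k]] <- v
  }
  params <- neuron_params_from_config(neuron_kv)
  if (is.null(flat$layer_sizes)) {
    stop("layer_sizes must be given (config [network] or override)",
         call. = FALSE)
  }
  sizes <- as.integer(strsplit(as.character(flat$layer_sizes), ",")[[1]])
  get_or <- function(key, default, coerce = identity) {
    if (is.null(flat[[key]])) default else coerce(flat[[key]])
  }
  train_config(
    layer_sizes = sizes,
    epochs = get_or("epochs", 100L, as.integer),
    batch_size = get_or("batch_size", 10L, as.integer),
    eta_t = get_or("eta_t", 0.5, as.double),
    eta_w = get_or("eta_w", 0.015, as.double),
    seed = get_or("seed", 0L, as.integer),
    n_feedback_layers = get_or("n_feedback_layers", NULL, as.integer),
    init_scheme = get_or("init_scheme", "orthogonal", as.character),
    params = params,
    feedback_scale = get_or("feedback_scale", 1.0, as.double),
    feedback_bias_scale = get_or("feedback_bias_scale", 0.01, as.double),
    batch_reduction = get_or("batch_reduction", "mean", as.character)
  )
}
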