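# Portable JSON checkpoints for trained release probabilities. Doubles are
# serialized with 17 significant digits, the shortest precision that makes
# an IEEE-754 save/load round trip bit-exact.

probs_to_list <- function(probs, gain = NULL) {
  out <- list(values = as.numeric(probs), shape = dim(probs),
              clip_eps = clip_eps_of(probs))
  if (!is.null(gain)) out$gain <- gain
  out
}

list_to_probs <- function(x) {
  new_release_probs(matrix(as.numeric(x$values), nrow = x$shape[1L]),
                    x$clip_eps)
}

#' Save release probabilities to a JSON checkpoint
#'
#' Stores each layer's probability matrix with its shape, gain and clipping
#' threshold, plus the seed and a digest of the training configuration.
#'
#' @param layers named list of [ei_layer()]s (or a trained `rsrp_training`
#'   object, whose layers and config are extracted).
#' @param path output file.
#' @param config optional [train_config()] recorded alongside.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(layers, path, config = NULL) {
  if (inherits(layers, "rsrp_training")) {
    config <- config %||% layers$config
    layers <- layers$layers %||% layers$spec$layers
  }
  payload <- list(
    format = "rsrp-checkpoint-1",
    layers = lapply(layers, function(l) {
      c(probs_to_list(l$probs, gain = l$gain),
        list(fan_in = l$fan_in, fan_out = l$fan_out))
    })
  )
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$lif <- unclass(cfg$lif)
    payload$seed <- cfg$seed
    payload$config <- cfg
    payload$config_digest <- sum(utf8ToInt(paste(
      names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                         character(1)), collapse = ";")))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a JSON checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return list with `layers` (named list of [ei_layer()]s) and the stored
#'   `config` fields (as a plain list), `seed` and `config_digest` when
#'   present.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "rsrp-checkpoint-1")) {
    stop("not an rsrp checkpoint: ", path)
  }
  layers <- lapply(payload$layers, function(l) {
    l$values <- unlist(l$values)
    l$shape <- unlist(l$shape)
    ei_layer(l$fan_in, l$fan_out, gain = l$gain, probs = list_to_probs(l))
  })
  list(layers = layers, config = payload$config,
       seed = if (is.null(payload$seed)) NULL else as.integer(payload$seed),
       config_digest = payload$config_digest)
}

#' Write a training log as CSV
#'
#' One row per iteration: raw-reward statistics, transformed-reward
#' checksum, evaluation metric and per-layer entropies.
#'
#' @param training an `rsrp_training` object.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(training, path) {
  utils::write.csv(training$log, path, row.names = FALSE)
  invisible(path)
}
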