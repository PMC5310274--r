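MODEL_FORMAT_VERSION <- 1L

#' Save / load a trained model
#'
#' Models are stored as plain JSON. Numeric values are written with 17
#' significant digits, which round-trips IEEE double precision exactly, so a
#' save/load cycle is lossless: every parameter is bit-identical.
#'
#' @param model An `rnn_model` from [train_model()] (an `rnn_params` object
#'   is also accepted and wrapped as an untrained model).
#' @param path File path.
#' @return `load_model` returns the `rnn_model`; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "rnn_params")) {
    model <- structure(list(spec = attr(model, "spec"), params = model,
                            history = NULL, selected_epoch = 0L,
                            config = NULL),
                       class = "rnn_model")
  }
  stopifnot(inherits(model, "rnn_model"))
  p <- model$params
  obj <- list(
    version = MODEL_FORMAT_VERSION,
    spec = list(unit_type = model$spec$unit_type, hidden = model$spec$hidden,
                alphabet_size = model$spec$alphabet_size),
    params = lapply(p, function(m) list(dim = dim(m), data = as.numeric(m))),
    history = model$history,
    selected_epoch = model$selected_epoch,
    config = unclass(model$config)
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_fmt("model file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$version) || obj$version != MODEL_FORMAT_VERSION)
    stop_fmt("unsupported model format version in %s", path)
  spec <- rnn_spec(obj$spec$unit_type, obj$spec$hidden)
  shapes <- param_shapes(spec)
  raw <- obj$params
  if (!setequal(names(raw), names(shapes)))
    stop_fmt("model file parameter set does not match a %s spec (expected %s)",
             spec$unit_type, paste(names(shapes), collapse = ", "))
  params <- vector("list", length(shapes))
  names(params) <- names(shapes)
  for (nm in names(shapes)) {
    entry <- raw[[nm]]
    dm <- as.integer(entry$dim)
    if (!identical(dm, as.integer(shapes[[nm]])) ||
        length(entry$data) != prod(shapes[[nm]]))
      stop_fmt("parameter %s has shape %s, expected %s", nm,
               paste(dm, collapse = "x"),
               paste(shapes[[nm]], collapse = "x"))
    params[[nm]] <- matrix(as.numeric(entry$data), dm[1L], dm[2L])
  }
  params <- structure(params, class = "rnn_params", spec = spec)
  history <- if (!is.null(obj$history) && length(obj$history))
    as.data.frame(obj$history) else NULL
  config <- if (!is.null(obj$config)) {
    cf <- obj$config
    train_config(epochs = cf$epochs, batch_size = cf$batch_size,
                 learning_rate = cf$learning_rate, optimizer = cf$optimizer,
                 clip = cf$clip, seed = cf$seed, init_scale = cf$init_scale)
  }
  structure(list(spec = spec, params = params, history = history,
                 selected_epoch = as.integer(obj$selected_epoch),
                 config = config),
            class = "rnn_model")
}
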