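#' Save a trained model as a JSON checkpoint
#'
#' Single self-describing text archive holding the model kind, its
#' configuration, all weights, and any attached standardization statistics.
#' The schema is versioned (`schema_version`) so later revisions can read
#' older checkpoints. Supported objects: `lstm_network`, `svr_model`,
#' `external_predictor`, `correlator`.
#'
#' @param model the model object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(schema_version = 1L,
                  kind = class(model)[1],
                  body = encode_obj(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param path checkpoint file path.
#' @return the restored model object.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyMatrix = FALSE,
                                 simplifyDataFrame = FALSE)
  if (is.null(payload$schema_version) || payload$schema_version != 1L) {
    stop_arg("unsupported checkpoint schema")
  }
  decode_obj(payload$body)
}

# Recursive encoder: numeric arrays become {".array": dim, data}; classed
# lists record their class for reconstruction.
encode_obj <- function(x) {
  if (is.numeric(x) || is.logical(x) || is.character(x)) {
    if (is.matrix(x) || is.array(x)) {
      return(list(`.array` = dim(x), data = as.vector(x)))
    }
    if (is.numeric(x) && length(x) != 1L) {
      return(list(`.vector` = length(x), data = as.vector(x),
                  names = names(x)))
    }
    return(x)
  }
  if (is.list(x)) {
    out <- lapply(unclass(x), encode_obj)
    cls <- class(x)
    if (!identical(cls, "list")) out$`.class` <- cls
    return(out)
  }
  if (is.null(x)) return(NULL)
  stop_arg("cannot checkpoint object of type ", typeof(x))
}

decode_obj <- function(x) {
  if (!is.list(x)) return(x)
  if (!is.null(x$`.array`)) {
    return(array(as.numeric(x$data), dim = as.integer(x$`.array`)))
  }
  if (!is.null(x$`.vector`)) {
    v <- as.numeric(x$data)
    if (!is.null(x$names) && length(x$names)) names(v) <- unlist(x$names)
    return(v)
  }
  cls <- x$`.class`
  x$`.class` <- NULL
  out <- lapply(x, decode_obj)
  # scalars arrive as length-1 lists from read_json in places; unwrap
  out <- lapply(out, function(e) {
    if (is.list(e) && length(e) == 1L && is.null(names(e)) &&
        !is.list(e[[1]])) e[[1]] else e
  })
  if (!is.null(cls)) class(out) <- unlist(cls)
  out
}
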