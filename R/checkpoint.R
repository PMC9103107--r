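#' Write a model or encoder checkpoint
#'
#' Checkpoints are plain JSON with an embedded config header, so a file
#' is self-describing: an encoder-only checkpoint supports transfer
#' fine-tuning on another dataset; a full checkpoint restores
#' encoder + classifier. Weights are serialized at full double precision,
#' flattened column-major with their dimensions.
#'
#' @param object A `clr_encoder`, `clr_pretrain` or `clr_model`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(object, path) {
  if (inherits(object, "clr_pretrain")) object <- object$encoder
  pack <- function(m) list(dim = dim(m), data = as.vector(m))
  payload <- if (inherits(object, "clr_encoder")) {
    list(kind = "encoder",
         encoder = list(config = unclass(object$config),
                        W = pack(object$W), b = object$b))
  } else if (inherits(object, "clr_model")) {
    list(kind = "model",
         encoder = list(config = unclass(object$encoder$config),
                        W = pack(object$encoder$W), b = object$encoder$b),
         classifier = list(config = unclass(object$classifier$config),
                           input_dim = object$classifier$input_dim,
                           W1 = pack(object$classifier$W1),
                           b1 = object$classifier$b1,
                           W2 = pack(object$classifier$W2),
                           b2 = object$classifier$b2),
         best_epoch = object$best_epoch,
         validation_accuracy = object$validation_accuracy)
  } else {
    abort("Unsupported object; expected clr_encoder, clr_pretrain or clr_model.")
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a checkpoint written by [write_checkpoint()]
#'
#' @param path Checkpoint path.
#' @return A `clr_encoder` or `clr_model`, matching what was written.
#' @export
read_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(p) matrix(p$data, nrow = p$dim[1], ncol = p$dim[2])
  rebuild_encoder <- function(e) {
    cfg <- encoder_config(kernel_size = e$config$kernel_size,
                          num_kernels = e$config$num_kernels,
                          seed = e$config$seed)
    structure(list(W = unpack(e$W), b = as.numeric(e$b), config = cfg),
              class = "clr_encoder")
  }
  enc <- rebuild_encoder(payload$encoder)
  if (identical(payload$kind, "encoder")) return(enc)
  cc <- payload$classifier
  cfg <- classifier_config(hidden_units = cc$config$hidden_units,
                           dropout_rate = cc$config$dropout_rate,
                           seed = cc$config$seed)
  cls <- structure(list(
    W1 = unpack(cc$W1), b1 = as.numeric(cc$b1),
    W2 = unpack(cc$W2), b2 = as.numeric(cc$b2),
    config = cfg, input_dim = as.integer(cc$input_dim)
  ), class = "clr_classifier")
  structure(list(encoder = enc, classifier = cls,
                 best_epoch = payload$best_epoch,
                 validation_accuracy = payload$validation_accuracy,
                 history = NULL, finetune_config = NULL,
                 architecture = architecture_hash(enc, cls)),
            class = "clr_model")
}
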