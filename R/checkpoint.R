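# Versioned, self-describing JSON checkpoints. A checkpoint records the
# model class, its architecture fields, the vocabulary, a parameter-shape
# hash and the flat parameters, so a saved model restores without any
# side-channel state.

arch_hash <- function(params) {
  shapes <- vapply(names(params), function(nm) {
    d <- dim(params[[nm]])
    paste(nm, paste(if (is.null(d)) length(params[[nm]]) else d,
                    collapse = "x"))
  }, "")
  codes <- utf8ToInt(paste(shapes, collapse = ";"))
  sum(codes * seq_along(codes)) %% 999999937
}

#' Save a paraphraser or classifier checkpoint
#'
#' @param model a [paraphraser_init()] or [classifier_init()] state.
#' @param path destination JSON file.
#' @export
model_save <- function(model, path) {
  kind <- if (inherits(model, "metapara_paraphraser")) "paraphraser"
          else if (inherits(model, "metapara_classifier")) "classifier"
          else stop("unsupported model class")
  meta <- model[setdiff(names(model), c("params", "vocab"))]
  obj <- list(format = paste0("metapara-", kind), version = 1L,
              meta = meta, tokens = model$vocab$tokens[-(1:4)],
              arch_hash = arch_hash(model$params),
              params = lapply(model$params, as.vector))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Load a model checkpoint written by [model_save()]
#' @param path checkpoint file.
#' @export
model_load <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                  collapse = "\n"))
  vocab <- vocab_build(extra_tokens = obj$tokens)
  m <- obj$meta
  model <- if (identical(obj$format, "metapara-paraphraser"))
    paraphraser_init(vocab, emb_dim = m$emb_dim, min_len = m$min_len,
                     max_len = m$max_len, seed = 0L)
  else if (identical(obj$format, "metapara-classifier"))
    classifier_init(vocab, m$n_classes, emb_dim = m$emb_dim,
                    units1 = m$units1, units2 = m$units2,
                    dense_units = m$dense_units, dropout = m$dropout,
                    max_len = m$max_len, seed = 0L)
  else stop("not a metapara model checkpoint: ", path)
  for (nm in names(model$params)) {
    v <- obj$params[[nm]]
    dim(v) <- dim(model$params[[nm]])
    model$params[[nm]] <- v
  }
  if (abs(arch_hash(model$params) - as.numeric(obj$arch_hash)) > 0.5)
    stop("checkpoint architecture hash mismatch")
  model
}
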