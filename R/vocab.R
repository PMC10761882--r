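# Whitespace tokenizer and shared vocabulary. The paraphraser and classifier
# operate over one vocabulary so that decoder output distributions can be fed
# to the classifier as expected embeddings (the soft coupling).

PAD_TOKEN <- "<pad>"
BOS_TOKEN <- "<s>"
EOS_TOKEN <- "</s>"
UNK_TOKEN <- "<unk>"

#' Tokenize text by whitespace
#' @param text character scalar.
#' @return character vector of tokens.
#' @export
tokenize <- function(text) {
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Build a vocabulary from texts
#'
#' Tokens are collected with a whitespace tokenizer, deduplicated and sorted
#' lexicographically (so the id assignment is independent of input order).
#' Four special tokens occupy the first ids: pad, bos, eos, unk.
#'
#' @param texts character vector of documents.
#' @param extra_tokens tokens to include even if absent from `texts`.
#' @return object of class `metapara_vocab` with fields `tokens`, `index`,
#'   and special ids `pad`, `bos`, `eos`, `unk`.
#' @export
vocab_build <- function(texts = character(), extra_tokens = character()) {
  words <- unique(c(unlist(lapply(texts, tokenize), use.names = FALSE),
                    extra_tokens))
  words <- sort(setdiff(words, c(PAD_TOKEN, BOS_TOKEN, EOS_TOKEN, UNK_TOKEN)))
  tokens <- c(PAD_TOKEN, BOS_TOKEN, EOS_TOKEN, UNK_TOKEN, words)
  index <- stats::setNames(seq_along(tokens), tokens)
  structure(list(tokens = tokens, index = index,
                 pad = 1L, bos = 2L, eos = 3L, unk = 4L),
            class = "metapara_vocab")
}

#' @export
print.metapara_vocab <- function(x, ...) {
  cat(sprintf("<metapara_vocab> %d tokens (4 special)\n", length(x$tokens)))
  invisible(x)
}

vocab_size <- function(vocab) length(vocab$tokens)

#' Encode text to token ids
#' @param vocab a `metapara_vocab`.
#' @param text character scalar.
#' @return integer vector of token ids (unknown tokens map to the unk id).
#' @export
encode_text <- function(vocab, text) {
  toks <- tokenize(text)
  ids <- unname(vocab$index[toks])
  ids[is.na(ids)] <- vocab$unk
  as.integer(ids)
}

#' Decode token ids to text
#' @param vocab a `metapara_vocab`.
#' @param ids integer vector of token ids; special tokens are dropped.
#' @export
decode_ids <- function(vocab, ids) {
  ids <- ids[ids > 4L]
  paste(vocab$tokens[ids], collapse = " ")
}
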