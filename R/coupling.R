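# Soft coupling between paraphraser and classifier.
#
# Discrete decoding breaks the gradient path from the classifier's loss back
# to the paraphraser, yet the hypergradient needs d(generated loss)/dS to be
# non-zero. The package's differentiable route: greedy-decode a paraphrase,
# re-run the decoder with teacher forcing over that decode to obtain
# per-position distributions over the vocabulary, and feed the classifier
# the expectation of its input embeddings under those distributions. The
# decoded token sequence itself is held fixed (it is piecewise constant in
# the parameters); the smooth branch through the distributions carries the
# gradient. When the distributions are one-hot this reduces exactly to the
# hard-decoded classifier loss.

check_shared_vocab <- function(C, S) {
  if (!identical(C$vocab$tokens, S$vocab$tokens))
    stop("classifier and paraphraser must share one vocabulary")
}

# greedy paraphrase decodes (token id sequences) for a set of texts
hard_generations <- function(S, texts, min_len = S$min_len,
                             max_len = S$max_len) {
  lapply(texts, function(tx) {
    ids <- encode_text(S$vocab, tx)
    if (length(ids) == 0L) stop("text tokenizes to length 0")
    decode_greedy(S, ids, min_len, max_len)
  })
}

# loss and gradients of the soft generated-data cross-entropy.
# gens: list of decoded id sequences (one per example); computed if NULL.
# want: which gradients to assemble ("C", "S").
soft_gen_grad <- function(C, S, texts, labels, gens = NULL,
                          want = c("C", "S")) {
  check_shared_vocab(C, S)
  n <- length(texts)
  stopifnot(n == length(labels), n >= 1L)
  if (is.null(gens)) gens <- hard_generations(S, texts)
  emb <- C$params$emb
  loss <- 0
  grad_C <- if ("C" %in% want) par_zero_like(C$params) else NULL
  grad_S <- if ("S" %in% want) par_zero_like(S$params) else NULL
  for (i in seq_len(n)) {
    src_ids <- encode_text(S$vocab, texts[i])
    dec_ids <- gens[[i]]
    if (length(dec_ids) == 0L) stop("empty generation for example ", i)
    dd <- decoder_distributions(S, src_ids, dec_ids)
    # restrict to the support a hard decode can emit (special tokens are
    # suppressed during decoding) and renormalize: the expectation then
    # collapses exactly onto the decode as distributions sharpen
    P <- dd$P                              # V x T
    P[1:4, ] <- 0
    P <- P / matrix(colSums(P), nrow(P), ncol(P), byrow = TRUE)
    X <- t(P) %*% emb                      # T x emb_dim, expected embeddings
    fw <- clf_forward(C, X)
    loss <- loss - log(fw$probs[labels[i] + 1L])
    if (length(want)) {
      dlogits <- (fw$probs - onehot(labels[i] + 1L, C$n_classes)) / n
      bk <- clf_backward(C, fw$cache, dlogits)
      if ("C" %in% want) {
        grad_C <- par_axpy(grad_C, bk$grad)
        grad_C$emb <- grad_C$emb + P %*% bk$dX
      }
      if ("S" %in% want) {
        dP <- emb %*% t(bk$dX)             # V x T
        dz <- P * dP                       # restricted-softmax jacobian
        dz <- dz - P * matrix(colSums(dz), nrow(P), ncol(P), byrow = TRUE)
        grad_S <- par_axpy(grad_S, s2s_backward(S, dd$cache, dz))
      }
    }
  }
  list(loss = loss / n, grad_C = grad_C, grad_S = grad_S, gens = gens)
}

#' Soft generated-data classifier loss
#'
#' Mean cross-entropy of the classifier on paraphrases of the given labeled
#' examples, computed through the expected-embedding coupling so the value
#' is differentiable in both the classifier and the paraphraser. Labels are
#' inherited from the source examples.
#'
#' @param C a [classifier_init()] state.
#' @param S a [paraphraser_init()] state sharing `C`'s vocabulary.
#' @param texts,labels the source examples.
#' @param gens optional list of pre-computed decoded token-id sequences.
#' @return scalar loss with attribute `"gens"` (the decodes used).
#' @export
soft_generated_loss <- function(C, S, texts, labels, gens = NULL) {
  out <- soft_gen_grad(C, S, texts, labels, gens, want = character(0))
  structure(Re(out$loss), gens = out$gens)
}

# hard-decoded generated loss (no gradient path to S); used by the
# paraphraser-separate ablation
hard_generated_loss_grad <- function(C, S, texts, labels, gens = NULL) {
  if (is.null(gens)) gens <- hard_generations(S, texts)
  gtexts <- vapply(gens, function(ids) decode_ids(S$vocab, ids), "")
  out <- clf_loss_grad(C, gtexts, labels)
  out$gens <- gens
  out
}

#' Combined classifier objective of the middle optimization level
#'
#' `L(C, D) + gamma * L_gen`, the training loss on the original examples
#' plus the weighted generated-data loss. The only-augmentation ablation
#' drops the original-data term.
#'
#' @param C a [classifier_init()] state.
#' @param texts,labels original training examples.
#' @param generated_loss_value scalar generated-data loss (e.g. from
#'   [soft_generated_loss()]).
#' @param gamma trade-off weight on the generated term (default 0.85).
#' @param only_aug drop the original-data term.
#' @return scalar objective value.
#' @export
combined_classifier_loss <- function(C, texts, labels, generated_loss_value,
                                     gamma = 0.85, only_aug = FALSE) {
  if (gamma < 0) stop("gamma must be >= 0")
  base <- if (only_aug) 0 else classifier_loss(C, texts, labels)
  base + gamma * generated_loss_value
}
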