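# Reference tiny paraphraser S: an attention-free encoder-decoder over the
# shared vocabulary.
#
#   context      c      = mean of source token embeddings
#   initial      h_0    = tanh(W_enc c + b_enc)
#   decoder      h_t    = tanh(W_x e(prev_t) + W_c e(src_t) + W_h h_{t-1} + b_h)
#   output       z_t    = W_o h_t + b_o,  p_t = softmax(z_t)
#
# where e(src_t) is the embedding of the source token aligned with decoding
# position t (pad beyond the source length). The monotonic source feed gives
# the decoder position-wise access to its input - the natural inductive bias
# for paraphrasing, where alignments are near-monotonic - while keeping the
# model a one-layer recurrent network with tractable hand-written gradients.
# Pretrained transformer paraphrasers plug in through the same contract
# (teacher-forcing loss, generate, decoder distributions, parameters).

#' Initialize the reference paraphraser
#'
#' @param vocab shared [vocab_build()] vocabulary.
#' @param emb_dim embedding and hidden width d.
#' @param min_len,max_len decode length bounds (defaults 65 and 128; the
#'   synthetic desk-scale profile overrides them).
#' @param seed integer seed for the parameter draw.
#' @return object of class `metapara_paraphraser`.
#' @export
paraphraser_init <- function(vocab, emb_dim = 16L, min_len = 65L,
                             max_len = 128L, seed = 1L) {
  stopifnot(inherits(vocab, "metapara_vocab"))
  if (min_len > max_len) stop("min_len must not exceed max_len")
  V <- vocab_size(vocab)
  d <- as.integer(emb_dim)
  params <- with_seed(seed, list(
    emb = rand_mat(V, d, sd = 0.1),
    W_enc = rand_mat(d, d), b_enc = zero_vec(d),
    W_x = rand_mat(d, d), W_c = rand_mat(d, d), W_h = rand_mat(d, d),
    b_h = zero_vec(d),
    W_o = rand_mat(V, d, sd = 0.1), b_o = zero_vec(V)
  ))
  structure(list(params = params, vocab = vocab, emb_dim = d,
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "metapara_paraphraser")
}

#' @export
print.metapara_paraphraser <- function(x, ...) {
  cat(sprintf(
    "<metapara_paraphraser> V=%d, d=%d, decode bounds [%d, %d], %d parameters\n",
    vocab_size(x$vocab), x$emb_dim, x$min_len, x$max_len, par_count(x$params)))
  invisible(x)
}

softmax_col <- function(z) {
  z <- z - max(Re(z))
  e <- exp(z)
  e / sum(e)
}

# aligned source token id for decoding position t
aligned_src <- function(src_ids, t, pad) {
  if (t <= length(src_ids)) src_ids[t] else pad
}

# teacher-forced forward pass; tgt_ids are the tokens the decoder must
# reproduce. include_eos appends the end-of-sequence prediction step.
s2s_forward_tf <- function(S, src_ids, tgt_ids, include_eos = TRUE) {
  p <- S$params
  vb <- S$vocab
  d <- S$emb_dim
  V <- nrow(p$emb)
  targets <- if (include_eos) c(tgt_ids, vb$eos) else tgt_ids
  prev <- c(vb$bos, tgt_ids)[seq_along(targets)]
  Tn <- length(targets)
  if (Tn == 0L) stop("target tokenizes to length 0")
  src_al <- vapply(seq_len(Tn), function(t) aligned_src(src_ids, t, vb$pad), 0L)
  ctx <- colMeans(p$emb[src_ids, , drop = FALSE])
  h0 <- tanh(drop(p$W_enc %*% ctx) + p$b_enc)
  H <- matrix(ctx[1] * 0, d, Tn)   # inherits complex type from parameters
  P <- matrix(ctx[1] * 0, V, Tn)
  h <- h0
  loss <- 0
  for (t in seq_len(Tn)) {
    a <- drop(p$W_x %*% p$emb[prev[t], ] + p$W_c %*% p$emb[src_al[t], ] +
                p$W_h %*% h) + p$b_h
    h <- tanh(a)
    H[, t] <- h
    z <- drop(p$W_o %*% h) + p$b_o
    pr <- softmax_col(z)
    P[, t] <- pr
    loss <- loss - log(pr[targets[t]])
  }
  loss <- loss / Tn
  list(loss = loss, P = P, H = H, h0 = h0, ctx = ctx,
       src_ids = src_ids, prev = prev, src_al = src_al, targets = targets)
}

# backward pass given d(loss)/d(logits) as a V x T matrix; returns the
# parameter gradient list (same layout as S$params)
s2s_backward <- function(S, cache, dlogits) {
  p <- S$params
  g <- par_zero_like(p)
  Tn <- ncol(dlogits)
  H <- cache$H
  g$W_o <- dlogits %*% t(H)
  g$b_o <- rowSums(dlogits)
  dH <- t(p$W_o) %*% dlogits
  dh_next <- H[, 1] * 0
  tWx <- t(p$W_x); tWc <- t(p$W_c); tWh <- t(p$W_h)
  for (t in rev(seq_len(Tn))) {
    dh <- dH[, t] + dh_next
    da <- dh * (1 - H[, t]^2)
    h_prev <- if (t == 1L) cache$h0 else H[, t - 1L]
    e_prev <- p$emb[cache$prev[t], ]
    e_src <- p$emb[cache$src_al[t], ]
    g$W_x <- g$W_x + da %*% t(e_prev)
    g$W_c <- g$W_c + da %*% t(e_src)
    g$W_h <- g$W_h + da %*% t(h_prev)
    g$b_h <- g$b_h + da
    g$emb[cache$prev[t], ] <- g$emb[cache$prev[t], ] + drop(tWx %*% da)
    g$emb[cache$src_al[t], ] <- g$emb[cache$src_al[t], ] + drop(tWc %*% da)
    dh_next <- drop(tWh %*% da)
  }
  da0 <- dh_next * (1 - cache$h0^2)
  g$W_enc <- da0 %*% t(cache$ctx)
  g$b_enc <- da0
  dctx <- drop(t(p$W_enc) %*% da0) / length(cache$src_ids)
  for (i in cache$src_ids)
    g$emb[i, ] <- g$emb[i, ] + dctx
  g
}

# logit gradient of the mean negative log-likelihood
nll_dlogits <- function(cache) {
  d <- cache$P
  Tn <- ncol(d)
  for (t in seq_len(Tn))
    d[cache$targets[t], t] <- d[cache$targets[t], t] - 1
  d / Tn
}

# loss and parameter gradient of one teacher-forced pair (id sequences)
s2s_loss_grad <- function(S, src_ids, tgt_ids) {
  cache <- s2s_forward_tf(S, src_ids, tgt_ids)
  list(loss = cache$loss, grad = s2s_backward(S, cache, nll_dlogits(cache)),
       cache = cache)
}

encode_pair <- function(S, source_text, target_text) {
  src <- encode_text(S$vocab, source_text)
  tgt <- encode_text(S$vocab, target_text)
  if (length(src) == 0L) stop("source tokenizes to length 0")
  if (length(tgt) == 0L) stop("target tokenizes to length 0")
  list(src = src, tgt = tgt)
}

#' Teacher-forcing loss of one paraphrase pair
#'
#' Mean per-token negative log-likelihood of the target sequence (including
#' the end-of-sequence token) given the source, under teacher forcing. The
#' per-token mean keeps losses comparable across target lengths, so the
#' meta-weight network sees a length-invariant input scale.
#'
#' @param S a [paraphraser_init()] state.
#' @param source_text,target_text the pair's texts.
#' @return non-negative scalar loss.
#' @export
teacher_forcing_loss <- function(S, source_text, target_text) {
  ids <- encode_pair(S, source_text, target_text)
  Re(s2s_forward_tf(S, ids$src, ids$tgt)$loss)
}

#' Meta-weighted paraphrase training loss
#'
#' `sum_i W(l_i) * l_i` over a batch of pairs, where `l_i` is the pair's
#' teacher-forcing loss and `W` the meta-weight network. A `"mean"` variant
#' divides by the batch size.
#'
#' @param S paraphraser state.
#' @param mwn meta-weight network ([mwn_init()]).
#' @param batch a [paraphrase_corpus()] (or subset of rows).
#' @param reduce `"sum"` (default) or `"mean"`.
#' @return scalar loss; attribute `"weights"` carries the per-pair weights.
#' @export
weighted_paraphrase_loss <- function(S, mwn, batch, reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  if (nrow(batch) == 0L) stop("batch must be non-empty")
  losses <- vapply(seq_len(nrow(batch)), function(i)
    teacher_forcing_loss(S, batch$source[i], batch$target[i]), numeric(1))
  w <- mwn_forward(mwn, losses)
  total <- sum(w * losses)
  if (reduce == "mean") total <- total / length(losses)
  structure(total, weights = w, losses = losses)
}

#' Generate a paraphrase
#'
#' Decodes with the length bounds enforced: the end-of-sequence token is
#' suppressed while the decode is shorter than `min_len` and forced once
#' `max_len` is reached. Greedy and beam decoding are deterministic; ties
#' break toward the lowest token id.
#'
#' @param S paraphraser state.
#' @param text input text (non-empty).
#' @param min_len,max_len decode length bounds; default to the state's.
#' @param strategy `"greedy"` or `"beam"`.
#' @param beam_width beam size when `strategy = "beam"`.
#' @param seed kept for interface stability (greedy/beam decoding is
#'   deterministic).
#' @return the decoded text.
#' @export
generate <- function(S, text, min_len = S$min_len, max_len = S$max_len,
                     strategy = c("greedy", "beam"), beam_width = 3L,
                     seed = 1L) {
  strategy <- match.arg(strategy)
  ids <- encode_text(S$vocab, text)
  if (length(ids) == 0L) stop("input tokenizes to length 0")
  out <- if (strategy == "greedy")
    decode_greedy(S, ids, min_len, max_len)
  else
    decode_beam(S, ids, min_len, max_len, beam_width)
  decode_ids(S$vocab, out)
}

decode_step <- function(S, prev_id, src_id, h) {
  p <- S$params
  a <- drop(p$W_x %*% p$emb[prev_id, ] + p$W_c %*% p$emb[src_id, ] +
              p$W_h %*% h) + p$b_h
  h <- tanh(a)
  z <- drop(p$W_o %*% h) + p$b_o
  list(h = h, logp = z - log(sum(exp(z - max(z)))) - max(z))
}

decode_greedy <- function(S, src_ids, min_len, max_len) {
  p <- S$params
  vb <- S$vocab
  ctx <- colMeans(p$emb[src_ids, , drop = FALSE])
  h <- tanh(drop(p$W_enc %*% ctx) + p$b_enc)
  prev <- vb$bos
  out <- integer(0)
  for (t in seq_len(max_len + 1L)) {
    if (length(out) >= max_len) break
    st <- decode_step(S, prev, aligned_src(src_ids, t, vb$pad), h)
    h <- st$h
    lp <- st$logp
    lp[c(vb$pad, vb$bos, vb$unk)] <- -Inf
    if (length(out) < min_len) lp[vb$eos] <- -Inf
    nxt <- which.max(lp)
    if (nxt == vb$eos) break
    out <- c(out, nxt)
    prev <- nxt
  }
  out
}

decode_beam <- function(S, src_ids, min_len, max_len, width) {
  p <- S$params
  vb <- S$vocab
  ctx <- colMeans(p$emb[src_ids, , drop = FALSE])
  h0 <- tanh(drop(p$W_enc %*% ctx) + p$b_enc)
  beams <- list(list(ids = integer(0), prev = vb$bos, h = h0, score = 0,
                     done = FALSE))
  for (t in seq_len(max_len)) {
    if (all(vapply(beams, `[[`, TRUE, "done"))) break
    cand <- list()
    for (b in beams) {
      if (b$done) { cand[[length(cand) + 1L]] <- b; next }
      st <- decode_step(S, b$prev, aligned_src(src_ids, t, vb$pad), b$h)
      lp <- st$logp
      lp[c(vb$pad, vb$bos, vb$unk)] <- -Inf
      if (length(b$ids) < min_len) lp[vb$eos] <- -Inf
      top <- order(lp, decreasing = TRUE)[seq_len(width)]
      for (v in top) {
        nb <- if (v == vb$eos)
          list(ids = b$ids, prev = b$prev, h = b$h,
               score = b$score + lp[v], done = TRUE)
        else
          list(ids = c(b$ids, v), prev = v, h = st$h,
               score = b$score + lp[v],
               done = length(b$ids) + 1L >= max_len)
        cand[[length(cand) + 1L]] <- nb
      }
    }
    scores <- vapply(cand, `[[`, numeric(1), "score")
    beams <- cand[order(-scores)[seq_len(min(width, length(cand)))]]
  }
  scores <- vapply(beams, `[[`, numeric(1), "score")
  beams[[which.max(scores)]]$ids
}

#' Per-position decoder distributions under teacher forcing
#'
#' Re-runs the decoder over a fixed decoded sequence and returns the softmax
#' distribution over the vocabulary at each position. This is the
#' differentiable surface that the soft coupling feeds to the classifier.
#'
#' @param S paraphraser state.
#' @param src_ids source token ids.
#' @param dec_ids decoded token ids the decoder is forced through.
#' @return list with `P` (V x T matrix of distributions) and the forward
#'   cache.
#' @export
decoder_distributions <- function(S, src_ids, dec_ids) {
  cache <- s2s_forward_tf(S, src_ids, dec_ids, include_eos = FALSE)
  list(P = cache$P, cache = cache)
}
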