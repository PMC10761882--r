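# Reference classifier C: embedding -> bi-LSTM(u1) returning sequences ->
# dropout -> bi-LSTM(u2) returning final states -> dropout -> dense with
# ReLU -> softmax over K classes. Default sizes follow the common lightweight
# text-classification stack (64 and 32 LSTM units per direction, 20 dense
# units, dropout 0.5, inputs truncated at 128 tokens); the synthetic profile
# shrinks them. Any classifier exposing loss / predict_proba / parameters
# plugs into the engine through the same contract.

#' Initialize the reference bi-LSTM classifier
#'
#' @param vocab shared [vocab_build()] vocabulary.
#' @param n_classes number of classes K (>= 2).
#' @param emb_dim embedding width.
#' @param units1,units2 LSTM units per direction in the first and second
#'   bidirectional layers.
#' @param dense_units width of the ReLU dense layer before the softmax head.
#' @param dropout dropout probability (train mode only).
#' @param max_len maximum input length in tokens; longer inputs are
#'   truncated.
#' @param seed integer seed for the parameter draw.
#' @return object of class `metapara_classifier`.
#' @export
classifier_init <- function(vocab, n_classes, emb_dim = 100L, units1 = 64L,
                            units2 = 32L, dense_units = 20L, dropout = 0.5,
                            max_len = 128L, seed = 1L) {
  stopifnot(inherits(vocab, "metapara_vocab"), n_classes >= 2L)
  V <- vocab_size(vocab)
  d <- as.integer(emb_dim); u1 <- as.integer(units1); u2 <- as.integer(units2)
  du <- as.integer(dense_units); K <- as.integer(n_classes)
  params <- with_seed(seed, list(
    emb = rand_mat(V, d, sd = 0.1),
    l1f_W = rand_mat(4L * u1, d + u1), l1f_b = zero_vec(4L * u1),
    l1b_W = rand_mat(4L * u1, d + u1), l1b_b = zero_vec(4L * u1),
    l2f_W = rand_mat(4L * u2, 2L * u1 + u2), l2f_b = zero_vec(4L * u2),
    l2b_W = rand_mat(4L * u2, 2L * u1 + u2), l2b_b = zero_vec(4L * u2),
    W_d = rand_mat(du, 2L * u2), b_d = zero_vec(du),
    W_k = rand_mat(K, du, sd = 0.1), b_k = zero_vec(K)
  ))
  structure(list(params = params, vocab = vocab, emb_dim = d, units1 = u1,
                 units2 = u2, dense_units = du, dropout = dropout,
                 max_len = as.integer(max_len), n_classes = K),
            class = "metapara_classifier")
}

#' @export
print.metapara_classifier <- function(x, ...) {
  cat(sprintf(
    "<metapara_classifier> V=%d, emb %d, bi-LSTM(%d) -> bi-LSTM(%d) -> dense(%d) -> softmax(%d), %d parameters\n",
    vocab_size(x$vocab), x$emb_dim, x$units1, x$units2, x$dense_units,
    x$n_classes, par_count(x$params)))
  invisible(x)
}

#' Audit the classifier layer stack
#'
#' Returns the shape of every parameter tensor, grouped by layer, so tests
#' can verify the architecture (two bidirectional LSTM layers, a ReLU dense
#' layer and a softmax head).
#' @param C a [classifier_init()] state.
#' @export
classifier_shape_audit <- function(C) {
  lapply(C$params, dim_or_len <- function(x)
    if (is.matrix(x)) dim(x) else length(x))
}

relu <- function(x) x * (Re(x) > 0)

lstm_units <- function(b) length(b) %/% 4L

# one LSTM pass over X (T x in_dim); returns hidden sequence (T x u, in
# original time order), the final hidden state of the pass, and a cache
lstm_forward <- function(W, b, X, reverse = FALSE) {
  Tn <- nrow(X)
  u <- lstm_units(b)
  ord <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  zero <- X[1, 1] * 0
  h <- rep(zero, u); cc <- rep(zero, u)
  H <- matrix(zero, Tn, u)
  I <- Fg <- G <- O <- Ct <- Cprev <- Hprev <- matrix(zero, u, Tn)
  for (k in seq_along(ord)) {
    t <- ord[k]
    Hprev[, k] <- h; Cprev[, k] <- cc
    a <- drop(W %*% c(X[t, ], h)) + b
    i <- sigmoid(a[seq_len(u)])
    f <- sigmoid(a[u + seq_len(u)])
    g <- tanh(a[2L * u + seq_len(u)])
    o <- sigmoid(a[3L * u + seq_len(u)])
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    I[, k] <- i; Fg[, k] <- f; G[, k] <- g; O[, k] <- o; Ct[, k] <- tc
    H[t, ] <- h
  }
  list(H = H, h_final = h,
       cache = list(W = W, X = X, ord = ord, u = u,
                    I = I, Fg = Fg, G = G, O = O, Ct = Ct,
                    Cprev = Cprev, Hprev = Hprev))
}

# backward through one LSTM pass. dH is T x u (zero where unused);
# dh_final is injected at the last step of the pass. Returns dW, db, dX.
lstm_backward <- function(cache, dH, dh_final = NULL) {
  W <- cache$W; X <- cache$X; ord <- cache$ord; u <- cache$u
  Tn <- nrow(X)
  in_dim <- ncol(X)
  zero <- X[1, 1] * 0
  dW <- W * 0
  db <- rep(zero, 4L * u)
  dX <- X * 0
  dh_carry <- rep(zero, u)
  dc_carry <- rep(zero, u)
  tW <- t(W)
  for (k in rev(seq_along(ord))) {
    t <- ord[k]
    dh <- dH[t, ] + dh_carry
    if (!is.null(dh_final) && k == length(ord)) dh <- dh + dh_final
    i <- cache$I[, k]; f <- cache$Fg[, k]; g <- cache$G[, k]
    o <- cache$O[, k]; tc <- cache$Ct[, k]
    do_ <- dh * tc
    dct <- dh * o * (1 - tc^2) + dc_carry
    di <- dct * g
    dg <- dct * i
    df <- dct * cache$Cprev[, k]
    dc_carry <- dct * f
    da <- c(di * i * (1 - i), df * f * (1 - f), dg * (1 - g^2),
            do_ * o * (1 - o))
    dW <- dW + da %*% t(c(X[t, ], cache$Hprev[, k]))
    db <- db + da
    dxh <- drop(tW %*% da)
    dX[t, ] <- dX[t, ] + dxh[seq_len(in_dim)]
    dh_carry <- dxh[in_dim + seq_len(u)]
  }
  list(dW = dW, db = db, dX = dX)
}

# forward on one embedded sequence X (T x emb_dim); mode "train" samples
# the two dropout masks, "eval" is the deterministic identity
clf_forward <- function(C, X, mode = "eval") {
  p <- C$params
  f1 <- lstm_forward(p$l1f_W, p$l1f_b, X, reverse = FALSE)
  b1 <- lstm_forward(p$l1b_W, p$l1b_b, X, reverse = TRUE)
  H1 <- cbind(f1$H, b1$H)
  m1 <- NULL; m2 <- NULL
  if (identical(mode, "train") && C$dropout > 0) {
    m1 <- matrix(stats::rbinom(length(H1), 1L, 1 - C$dropout),
                 nrow(H1), ncol(H1)) / (1 - C$dropout)
    H1 <- H1 * m1
  }
  f2 <- lstm_forward(p$l2f_W, p$l2f_b, H1, reverse = FALSE)
  b2 <- lstm_forward(p$l2b_W, p$l2b_b, H1, reverse = TRUE)
  v <- c(f2$h_final, b2$h_final)
  if (identical(mode, "train") && C$dropout > 0) {
    m2 <- stats::rbinom(length(v), 1L, 1 - C$dropout) / (1 - C$dropout)
    v <- v * m2
  }
  zpre <- drop(p$W_d %*% v) + p$b_d
  z <- relu(zpre)
  logits <- drop(p$W_k %*% z) + p$b_k
  probs <- softmax_col(logits)
  list(probs = probs,
       cache = list(X = X, f1 = f1, b1 = b1, H1 = H1, f2 = f2, b2 = b2,
                    v = v, zpre = zpre, z = z, m1 = m1, m2 = m2))
}

# backward on one example given dlogits; returns parameter gradients and the
# gradient w.r.t. the embedded input sequence
clf_backward <- function(C, cache, dlogits) {
  p <- C$params
  g <- par_zero_like(p)
  g$W_k <- dlogits %*% t(cache$z)
  g$b_k <- dlogits
  dz <- drop(t(p$W_k) %*% dlogits) * (Re(cache$zpre) > 0)
  g$W_d <- dz %*% t(cache$v)
  g$b_d <- dz
  dv <- drop(t(p$W_d) %*% dz)
  if (!is.null(cache$m2)) dv <- dv * cache$m2
  u2 <- C$units2
  dH0 <- matrix(cache$H1[1, 1] * 0, nrow(cache$H1), u2)
  bk2f <- lstm_backward(cache$f2$cache, dH0, dh_final = dv[seq_len(u2)])
  bk2b <- lstm_backward(cache$b2$cache, dH0, dh_final = dv[u2 + seq_len(u2)])
  g$l2f_W <- bk2f$dW; g$l2f_b <- bk2f$db
  g$l2b_W <- bk2b$dW; g$l2b_b <- bk2b$db
  dH1 <- bk2f$dX + bk2b$dX
  if (!is.null(cache$m1)) dH1 <- dH1 * cache$m1
  u1 <- C$units1
  bk1f <- lstm_backward(cache$f1$cache, dH1[, seq_len(u1), drop = FALSE])
  bk1b <- lstm_backward(cache$b1$cache,
                        dH1[, u1 + seq_len(u1), drop = FALSE])
  g$l1f_W <- bk1f$dW; g$l1f_b <- bk1f$db
  g$l1b_W <- bk1b$dW; g$l1b_b <- bk1b$db
  list(grad = g, dX = bk1f$dX + bk1b$dX)
}

clf_encode <- function(C, text) {
  ids <- encode_text(C$vocab, text)
  if (length(ids) > C$max_len) ids <- ids[seq_len(C$max_len)]
  if (length(ids) == 0L) stop("text tokenizes to length 0")
  ids
}

onehot <- function(k, K) { v <- numeric(K); v[k] <- 1; v }

#' Mean cross-entropy loss of the classifier on labeled texts
#'
#' @param C a [classifier_init()] state.
#' @param texts character vector.
#' @param labels integer labels in `[0, K)`.
#' @return non-negative scalar (mean over the batch).
#' @export
classifier_loss <- function(C, texts, labels) {
  stopifnot(length(texts) == length(labels))
  if (any(labels < 0L | labels >= C$n_classes))
    stop("label out of range [0, ", C$n_classes, ")")
  tot <- 0
  for (i in seq_along(texts)) {
    ids <- clf_encode(C, texts[i])
    fw <- clf_forward(C, C$params$emb[ids, , drop = FALSE])
    tot <- tot - log(fw$probs[labels[i] + 1L])
  }
  Re(tot) / length(texts)
}

# mean cross-entropy loss + gradient over hard (token-id) examples;
# mode "eval" keeps dropout off so gradients are deterministic
clf_loss_grad <- function(C, texts, labels, mode = "eval") {
  n <- length(texts)
  grad <- par_zero_like(C$params)
  loss <- 0
  for (i in seq_len(n)) {
    ids <- clf_encode(C, texts[i])
    fw <- clf_forward(C, C$params$emb[ids, , drop = FALSE], mode = mode)
    loss <- loss - log(fw$probs[labels[i] + 1L])
    dlogits <- (fw$probs - onehot(labels[i] + 1L, C$n_classes)) / n
    bk <- clf_backward(C, fw$cache, dlogits)
    grad <- par_axpy(grad, bk$grad)
    for (k in seq_along(ids))
      grad$emb[ids[k], ] <- grad$emb[ids[k], ] + bk$dX[k, ]
  }
  list(loss = loss / n, grad = grad)
}

#' Class probabilities for texts
#'
#' @param C a [classifier_init()] state.
#' @param texts character vector.
#' @return n x K matrix of probabilities (rows sum to 1).
#' @export
predict_proba <- function(C, texts) {
  out <- matrix(0, length(texts), C$n_classes)
  for (i in seq_along(texts)) {
    ids <- clf_encode(C, texts[i])
    out[i, ] <- Re(clf_forward(C, C$params$emb[ids, , drop = FALSE])$probs)
  }
  out
}

#' Predicted class labels (0-based)
#' @param C a [classifier_init()] state.
#' @param texts character vector.
#' @export
predict_label <- function(C, texts) {
  max.col(predict_proba(C, texts), ties.method = "first") - 1L
}
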