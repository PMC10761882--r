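# Meta-weight network (MWN): a scalar-input MLP mapping a training example's
# loss l to a data weight a = W(l) in (0,1).
#
# Architecture: 1 -> h -> h -> 1 with tanh hidden activations, a dropout
# layer (rate 0.2 by default) after the second hidden layer, and a terminal
# sigmoid bounding the output. Hidden activations are tanh rather than ReLU
# because the learned weighting enters the hypergradient through first and
# second derivatives of W; a smooth activation keeps those derivatives
# defined everywhere.

#' Initialize a meta-weight network
#'
#' Weights are drawn as small Gaussians and biases start at zero, so initial
#' data weights cluster around sigmoid(0) = 0.5: a neutral starting point in
#' which no training pair is favored.
#'
#' @param hidden hidden width h (default 25, giving the 1-25-25-1 layout).
#' @param dropout dropout probability applied after the second hidden layer
#'   in train mode only.
#' @param seed integer seed for the parameter draw.
#' @return object of class `metapara_mwn`.
#' @export
mwn_init <- function(hidden = 25L, dropout = 0.2, seed = 1L) {
  if (hidden < 1L) stop("hidden must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  params <- with_seed(seed, list(
    w1 = rand_mat(hidden, 1L, sd = 0.1),
    b1 = zero_vec(hidden),
    W2 = rand_mat(hidden, hidden, sd = 0.1),
    b2 = zero_vec(hidden),
    w3 = rand_mat(1L, hidden, sd = 0.1),
    b3 = zero_vec(1L)
  ))
  structure(list(params = params, hidden = as.integer(hidden),
                 dropout = dropout), class = "metapara_mwn")
}

#' @export
print.metapara_mwn <- function(x, ...) {
  cat(sprintf("<metapara_mwn> 1 -> %d -> %d -> 1, dropout %.2f, %d parameters\n",
              x$hidden, x$hidden, x$dropout, par_count(x$params)))
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# forward over a vector of losses; returns list(weights, cache)
mwn_forward_cache <- function(mwn, losses, mode = "eval") {
  p <- mwn$params
  m <- length(losses)
  l_row <- matrix(losses, nrow = 1L)
  S1 <- p$w1 %*% l_row + p$b1        # h x m
  Z1 <- tanh(S1)
  S2 <- p$W2 %*% Z1 + p$b2
  Z2 <- tanh(S2)
  mask <- NULL
  if (identical(mode, "train") && mwn$dropout > 0) {
    mask <- matrix(stats::rbinom(length(Z2), 1L, 1 - mwn$dropout),
                   nrow(Z2), ncol(Z2)) / (1 - mwn$dropout)
    Z2 <- Z2 * mask
  }
  s3 <- drop(p$w3 %*% Z2) + p$b3     # length m
  a <- sigmoid(s3)
  list(weights = a, cache = list(l = losses, Z1 = Z1, Z2 = Z2, a = a,
                                 mask = mask))
}

#' Evaluate the meta-weight network
#'
#' Maps each loss to a weight strictly in (0,1). In eval mode the map is a
#' deterministic element-wise function of the loss vector; in train mode the
#' configured dropout is sampled.
#'
#' @param mwn a [mwn_init()] object.
#' @param losses numeric vector of finite, non-negative losses.
#' @param mode `"eval"` (default) or `"train"`.
#' @return numeric vector of weights, one per loss.
#' @export
mwn_forward <- function(mwn, losses, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (!is.complex(losses) && any(!is.finite(losses)))
    stop("losses must be finite")
  mwn_forward_cache(mwn, losses, mode)$weights
}

# gradient of sum_i coef_i * W(l_i) with respect to the MWN parameters;
# complex-safe (used with complex-step perturbed inputs by the oracle)
mwn_grad_params <- function(mwn, losses, coef, cache = NULL) {
  p <- mwn$params
  if (is.null(cache)) cache <- mwn_forward_cache(mwn, losses, "eval")$cache
  a <- cache$a; Z1 <- cache$Z1; Z2 <- cache$Z2
  ds3 <- coef * a * (1 - a)                       # length m
  dw3 <- matrix(Z2 %*% ds3, nrow = 1L)            # 1 x h -> stored transposed
  dZ2 <- t(p$w3)[, rep(1L, length(ds3)), drop = FALSE] *
    matrix(ds3, nrow(Z2), length(ds3), byrow = TRUE)
  if (!is.null(cache$mask)) dZ2 <- dZ2 * cache$mask
  dS2 <- dZ2 * (1 - Z2^2)
  dW2 <- dS2 %*% t(Z1)
  db2 <- rowSums(dS2)
  dZ1 <- t(p$W2) %*% dS2
  dS1 <- dZ1 * (1 - Z1^2)
  dw1 <- matrix(dS1 %*% cache$l, ncol = 1L)
  db1 <- rowSums(dS1)
  list(w1 = dw1, b1 = db1, W2 = dW2, b2 = db2,
       w3 = matrix(dw3, 1L), b3 = sum(ds3))
}

# derivative of the weight with respect to its scalar loss input, W'(l_i),
# evaluated element-wise (eval mode)
mwn_input_grad <- function(mwn, losses, cache = NULL) {
  p <- mwn$params
  if (is.null(cache)) cache <- mwn_forward_cache(mwn, losses, "eval")$cache
  t1 <- (1 - cache$Z1^2) * as.vector(p$w1)        # h x m
  t2 <- (1 - cache$Z2^2) * (p$W2 %*% t1)
  drop(p$w3 %*% t2) * cache$a * (1 - cache$a)
}

# gradient of sum_i W(l_i) * l_i w.r.t. the MWN parameters (Eq.-10-style
# term: the loss values are held fixed, so the coefficient on a_i is l_i)
mwn_grad_weighted_sum <- function(mwn, losses) {
  mwn_grad_params(mwn, losses, coef = losses)
}

#' Save a meta-weight network checkpoint
#'
#' Writes a versioned JSON checkpoint (architecture plus flat parameters).
#' @param mwn a [mwn_init()] object.
#' @param path destination file.
#' @export
mwn_save <- function(mwn, path) {
  obj <- list(format = "metapara-mwn", version = 1L, hidden = mwn$hidden,
              dropout = mwn$dropout,
              params = lapply(mwn$params, as.vector))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Load a meta-weight network checkpoint
#' @param path file written by [mwn_save()].
#' @export
mwn_load <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                  collapse = "\n"))
  if (!identical(obj$format, "metapara-mwn"))
    stop("not a metapara MWN checkpoint: ", path)
  h <- as.integer(obj$hidden)
  mwn <- mwn_init(hidden = h, dropout = obj$dropout, seed = 0L)
  mwn$params <- list(
    w1 = matrix(obj$params$w1, h, 1L),
    b1 = as.numeric(obj$params$b1),
    W2 = matrix(obj$params$W2, h, h),
    b2 = as.numeric(obj$params$b2),
    w3 = matrix(obj$params$w3, 1L, h),
    b3 = as.numeric(obj$params$b3)
  )
  mwn
}
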