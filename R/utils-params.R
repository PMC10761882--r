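# Parameter containers are plain named lists of numeric (or complex) matrices
# and vectors. Every model in the package (meta-weight network, paraphraser,
# classifier) stores its weights this way so that one set of helpers covers
# flattening, linear combinations, norms and optimizer steps.

#' Flatten a parameter list to a single numeric vector
#'
#' @param p named list of numeric arrays.
#' @return numeric vector concatenating all elements in list order.
#' @keywords internal
par_flatten <- function(p) {
  unlist(lapply(p, as.vector), use.names = FALSE)
}

#' Rebuild a parameter list from a flat vector
#'
#' @param v flat vector as produced by [par_flatten()].
#' @param skeleton a parameter list giving names and shapes.
#' @keywords internal
par_unflatten <- function(v, skeleton) {
  out <- skeleton
  pos <- 0L
  for (nm in names(skeleton)) {
    n <- length(skeleton[[nm]])
    x <- v[(pos + 1L):(pos + n)]
    dim(x) <- dim(skeleton[[nm]])
    out[[nm]] <- x
    pos <- pos + n
  }
  stopifnot(pos == length(v))
  out
}

# p + scale * q, elementwise over the shared layout
par_axpy <- function(p, q, scale = 1) {
  out <- p
  for (nm in names(p)) out[[nm]] <- p[[nm]] + scale * q[[nm]]
  out
}

par_scale <- function(p, s) lapply(p, function(x) s * x)

par_zero_like <- function(p) lapply(p, function(x) x * 0)

par_dot <- function(p, q) {
  s <- 0
  for (nm in names(p)) s <- s + sum(p[[nm]] * q[[nm]])
  s
}

par_norm <- function(p) sqrt(sum(vapply(p, function(x) sum(x^2), numeric(1))))

par_count <- function(p) sum(vapply(p, length, integer(1)))

par_finite <- function(p) all(vapply(p, function(x) all(is.finite(x)), logical(1)))

# promote a real parameter list to complex with an imaginary perturbation
# h * dir; used by the complex-step directional derivatives of the oracle
par_complex_step <- function(p, dir, h) {
  out <- p
  for (nm in names(p)) out[[nm]] <- p[[nm]] + (0+1i) * h * dir[[nm]]
  out
}

par_imag <- function(p, h) lapply(p, function(x) Im(x) / h)

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so that library internals
#' never disturb user-level random streams.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Gaussian init scaled by fan-in; biases start at zero so that zero-input
# activations are exactly zero (uniform-output identities in the tests rely
# on this).
rand_mat <- function(nrow, ncol, sd = NULL) {
  if (is.null(sd)) sd <- 1 / sqrt(ncol)
  matrix(stats::rnorm(nrow * ncol, sd = sd), nrow, ncol)
}

zero_vec <- function(n) numeric(n)

#' AdamW optimizer state
#'
#' Adaptive-moment estimation with decoupled weight decay. Defaults follow the
#' common configuration beta1 = 0.9, beta2 = 0.999, eps = 1e-8.
#'
#' @param params parameter list the state will track.
#' @param lr learning rate.
#' @param beta1,beta2 exponential decay rates for the moment estimates.
#' @param eps numerical stabilizer inside the square root.
#' @param weight_decay decoupled weight decay coefficient.
#' @return an object of class `metapara_adamw`.
#' @export
adamw_init <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0) {
  structure(list(
    m = par_zero_like(params), v = par_zero_like(params), t = 0L,
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
    weight_decay = weight_decay
  ), class = "metapara_adamw")
}

#' One AdamW step
#'
#' @param opt optimizer state from [adamw_init()].
#' @param params current parameter list.
#' @param grad gradient list with the same layout.
#' @return list with elements `params` (updated) and `opt` (updated state).
#' @export
adamw_step <- function(opt, params, grad) {
  stopifnot(inherits(opt, "metapara_adamw"))
  t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  out <- params
  for (nm in names(params)) {
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * grad[[nm]]
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * grad[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - b1^t)
    vhat <- opt$v[[nm]] / (1 - b2^t)
    out[[nm]] <- params[[nm]] -
      opt$lr * (mhat / (sqrt(vhat) + opt$eps) + opt$weight_decay * params[[nm]])
  }
  opt$t <- t
  list(params = out, opt = opt)
}

# plain gradient-descent step, used for the one-step unroll commits
sgd_step <- function(params, grad, lr) par_axpy(params, grad, -lr)
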