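# Shared fixtures and numerical utilities for the suite. Everything is
# generated in code; no stored fixtures.

par_flatten <- metapara:::par_flatten
par_unflatten <- metapara:::par_unflatten
par_axpy <- metapara:::par_axpy
par_zero_like <- metapara:::par_zero_like
par_norm <- metapara:::par_norm
par_dot <- metapara:::par_dot
par_scale <- metapara:::par_scale

flat_relerr <- function(a, b) {
  fa <- par_flatten(a); fb <- par_flatten(b)
  sqrt(sum((fa - fb)^2)) / max(sqrt(sum(fb^2)), 1e-300)
}

flat_cosine <- function(a, b) {
  fa <- par_flatten(a); fb <- par_flatten(b)
  sum(fa * fb) / sqrt(sum(fa^2) * sum(fb^2))
}

# central-difference gradient of a scalar function of a parameter list
num_grad <- function(f, params, eps = 1e-6) {
  flat <- par_flatten(params)
  g <- numeric(length(flat))
  for (j in seq_along(flat)) {
    up <- flat; up[j] <- up[j] + eps
    dn <- flat; dn[j] <- dn[j] - eps
    g[j] <- (f(par_unflatten(up, params)) - f(par_unflatten(dn, params))) /
      (2 * eps)
  }
  par_unflatten(g, params)
}

# small vocabulary over two synthetic token families
tiny_vocab <- function(n = 10) {
  vocab_build(extra_tokens = c(sprintf("a%02d", seq_len(n)),
                               sprintf("b%02d", seq_len(n))))
}

zeroed <- function(model) {
  model$params <- par_zero_like(model$params)
  model
}

# a small synthetic task (V ~ 30) for engine-level tests
tiny_task <- function(seed, n_pairs = 8, n_train = 16, n_val = 8,
                      n_test = 8) {
  make_synthetic_task(synthetic_spec(
    vocab_size_per_domain = 13, n_paraphrase_pairs = n_pairs,
    n_train = n_train, n_val = n_val, n_test = n_test,
    len_min = 3, len_max = 5, seed = seed))
}

# a random tiny engine instance; warm-up steps move the models off the
# degenerate random-init point where decoder distributions are near-uniform
# (every soft input collapses to the mean embedding), which no training
# trajectory revisits
tiny_instance <- function(seed, warm = 24, mwn_hidden = 25L) {
  task <- tiny_task(seed)
  S <- paraphraser_init(task$vocab, emb_dim = 8, min_len = 1, max_len = 8,
                        seed = seed + 1)
  C <- classifier_init(task$vocab, 2, emb_dim = 8, units1 = 4, units2 = 3,
                       dense_units = 5, dropout = 0, max_len = 16,
                       seed = seed + 2)
  W <- mwn_init(hidden = mwn_hidden, seed = seed + 3)
  if (warm > 0) {
    opt <- adamw_init(C$params, lr = 3e-3)
    for (k in seq_len(warm)) {
      pidx <- ((k - 1) * 4) %% 8 + 1:4
      cidx <- ((k - 1) * 4) %% 16 + 1:4
      S <- stage1_update(S, W, task$paraphrase[pidx, ], 0.2)
      g <- metapara:::clf_loss_grad(C, task$train$text[cidx],
                                    task$train$label[cidx])
      st <- adamw_step(opt, C$params, g$grad)
      C$params <- st$params
      opt <- st$opt
    }
  }
  list(task = task, S = S, C = C, W = W,
       pbatch = task$paraphrase[1:4, ],
       cbatch = task$train[1:4, ],
       vbatch = task$val[1:4, ])
}

tiny_config <- function(seed, ...) {
  mlo_config_synthetic(seed = seed, mwn_standardize = FALSE, eta_c = 0.2,
                       ...)
}
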