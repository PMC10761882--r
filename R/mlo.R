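# The three-stage alternating optimization engine.
#
# Per iteration (one minibatch triple from the paraphrase corpus, MLO-train
# and MLO-val):
#   stage I    S' = S - eta_s * grad_S sum_i W(l_i) * l_i          (one step)
#   stage II   C' = C - eta_c * grad_C [L(C,tr) + gamma * L_gen(C,S')]
#   stage III  W <- W - eta_w * hypergradient                      (AdamW)
# where the hypergradient of the MLO-validation loss with respect to the
# meta-weight network is approximated by nested finite differences: the
# classifier-side mixed second derivative via symmetric perturbations
# C +/- alpha*v (v the validation gradient), and the paraphraser-side mixed
# second derivative via symmetric perturbations of S along the two generated-
# loss gradients, each with an adaptively scaled step alpha = a/||.||_2.
# After the configured epochs the classifier is fine-tuned on the full
# training set.

#' MLO engine configuration
#'
#' Defaults mirror the reference training protocol: trade-off gamma = 0.85,
#' perturbation numerator 0.01, batch size 8, learning rates 2e-5 (S),
#' 3e-3 (C), 1e-4 (W), 10 MLO epochs plus 20 fine-tuning epochs, decode
#' bounds 65-128, AdamW (beta1 0.9, beta2 0.999, eps 1e-8) for the
#' meta-weight network and fine-tuning. [mlo_config_synthetic()] provides
#' the desk-scale profile used with the synthetic two-domain task.
#'
#' @param eta_s,eta_c,eta_w learning rates of the three levels.
#' @param eta_finetune AdamW learning rate of the final fine-tuning phase.
#' @param gamma trade-off weight on the generated-data loss.
#' @param alpha_scale numerator of the adaptive perturbation steps.
#' @param batch_para,batch_class minibatch sizes.
#' @param mlo_epochs,finetune_epochs epoch counts for the alternating phase
#'   and the final supervised fine-tuning.
#' @param seed master seed; every random draw in the engine derives from it.
#' @param para_sep ablation: train paraphraser and classifier separately
#'   (hypergradient step skipped, meta-weight network frozen).
#' @param only_aug ablation: the classifier trains on generated data only.
#' @param detach_mwn_input drop the `W'(l) * l` product-rule term from the
#'   stage-I gradient (treat the MWN input as a constant).
#' @param mwn_standardize feed the meta-weight network z-scored losses
#'   (statistics frozen per iteration and treated as constants) instead of
#'   raw losses, so its input coordinate is stationary while the losses
#'   drift during training.
#' @param cache_generations reuse paraphrase decodes across an epoch instead
#'   of regenerating per iteration.
#' @param finetune_augment include one paraphrase per training example
#'   (weight gamma) in the fine-tuning objective.
#' @param min_len,max_len decode length bounds.
#' @param s_optimizer optimizer for the committed paraphraser update:
#'   `"sgd"` (default) commits the unrolled candidate `S'` itself;
#'   `"adamw"` takes an AdamW step on the same gradient.
#' @param c_optimizer optimizer for the committed classifier update:
#'   `"adamw"` (default, the reference protocol's optimizer) or `"sgd"`
#'   (commit the candidate `C'`). The candidates inside the hypergradient
#'   are always the plain one-step-descent unrolls.
#' @param mwn_optimizer `"adamw"` (default) or `"sgd"` for the W update.
#' @param mwn_weight_decay decoupled weight decay on W.
#' @param s_weight_decay decoupled weight decay used when fine-tuning S-side
#'   components (reserved; the one-step unroll commits are plain descent).
#' @param denom_floor floor under every perturbation denominator; hitting it
#'   flags the iteration degenerate and zeroes the hypergradient.
#' @param s_emb_dim,c_emb_dim,c_units1,c_units2,c_dense,c_dropout,mwn_hidden,mwn_dropout
#'   reference model sizes.
#' @return object of class `metapara_config` (a list).
#' @export
mlo_config <- function(eta_s = 2e-5, eta_c = 3e-3, eta_w = 1e-4,
                       eta_finetune = 3e-3,
                       gamma = 0.85, alpha_scale = 0.01,
                       batch_para = 8L, batch_class = 8L,
                       mlo_epochs = 10L, finetune_epochs = 20L, seed = 1L,
                       para_sep = FALSE, only_aug = FALSE,
                       detach_mwn_input = FALSE, mwn_standardize = FALSE,
                       cache_generations = FALSE,
                       finetune_augment = TRUE,
                       min_len = 65L, max_len = 128L,
                       s_optimizer = c("sgd", "adamw"),
                       c_optimizer = c("adamw", "sgd"),
                       mwn_optimizer = c("adamw", "sgd"),
                       mwn_weight_decay = 0, s_weight_decay = 0.01,
                       denom_floor = 1e-12,
                       s_emb_dim = 16L, c_emb_dim = 100L, c_units1 = 64L,
                       c_units2 = 32L, c_dense = 20L, c_dropout = 0.5,
                       mwn_hidden = 25L, mwn_dropout = 0.2) {
  s_optimizer <- match.arg(s_optimizer)
  c_optimizer <- match.arg(c_optimizer)
  mwn_optimizer <- match.arg(mwn_optimizer)
  if (eta_s < 0 || eta_c < 0 || eta_w < 0) stop("learning rates must be >= 0")
  if (gamma < 0) stop("gamma must be >= 0")
  if (alpha_scale <= 0) stop("alpha_scale must be > 0")
  structure(as.list(environment()), class = "metapara_config")
}

#' Desk-scale configuration for the synthetic two-domain task
#'
#' Tiny model sizes and SGD-scale learning rates chosen so the full MLO loop
#' runs in about a minute on one CPU while preserving every structural
#' property of the full-scale protocol.
#' @param seed master seed.
#' @param ... overrides passed on to [mlo_config()].
#' @export
mlo_config_synthetic <- function(seed = 1L, ...) {
  defaults <- list(eta_s = 0.2, eta_c = 5e-4, eta_w = 0.01,
                   eta_finetune = 3e-3, gamma = 0.85,
                   mwn_standardize = TRUE,
                   min_len = 1L, max_len = 16L, s_emb_dim = 8L,
                   c_emb_dim = 8L, c_units1 = 4L, c_units2 = 3L,
                   c_dense = 5L, c_dropout = 0, mwn_hidden = 25L,
                   mwn_dropout = 0.2, seed = seed)
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(mlo_config, defaults)
}

pair_losses <- function(S, batch) {
  vapply(seq_len(nrow(batch)), function(i) {
    ids <- encode_pair(S, batch$source[i], batch$target[i])
    s2s_forward_tf(S, ids$src, ids$tgt)$loss
  }, numeric(1))
}

# pair losses for complex-valued parameter states
pair_losses_any <- function(S, batch) {
  sapply(seq_len(nrow(batch)), function(i) {
    ids <- encode_pair(S, batch$source[i], batch$target[i])
    s2s_forward_tf(S, ids$src, ids$tgt)$loss
  })
}

# z-score a loss vector; stats optionally frozen (supplied), returned as
# constants for reuse within the iteration
std_losses <- function(lvec, stats = NULL) {
  if (is.null(stats)) {
    mu <- mean(Re(lvec))
    sg <- stats::sd(Re(lvec))
    if (!is.finite(sg) || sg < 1e-8) sg <- 1
    stats <- c(mu = mu, sd = sg)
  }
  list(z = (lvec - stats[["mu"]]) / stats[["sd"]], stats = stats)
}

# Stage-I gradient of the meta-weighted paraphrase loss w.r.t. S. The MWN is
# treated strictly as a constant here (its parameters receive no gradient
# from this stage - learning W by stage-I descent would collapse all data
# weights to zero). With the full product rule the per-pair coefficient on
# grad_S l_i is W(l_i) + W'(l_i) * l_i; detach reduces it to W(l_i).
stage1_grad <- function(S, W, batch, detach = FALSE,
                        keep_pair_grads = FALSE, standardize = FALSE,
                        std_stats = NULL) {
  if (nrow(batch) == 0L) stop("batch must be non-empty")
  n <- nrow(batch)
  losses <- vector("list", n)
  grads <- vector("list", n)
  for (i in seq_len(n)) {
    ids <- encode_pair(S, batch$source[i], batch$target[i])
    lg <- s2s_loss_grad(S, ids$src, ids$tgt)
    losses[[i]] <- lg$loss
    grads[[i]] <- lg$grad
  }
  lvec <- if (is.complex(losses[[1]])) sapply(losses, identity)
          else vapply(losses, identity, numeric(1))
  if (standardize) {
    st <- std_losses(lvec, std_stats)
    zin <- st$z
    dz <- 1 / st$stats[["sd"]]
    std_stats <- st$stats
  } else {
    zin <- lvec
    dz <- 1
  }
  w <- mwn_forward(W, zin)
  coef <- if (detach) w else w + mwn_input_grad(W, zin) * dz * lvec
  total <- par_zero_like(S$params)
  for (i in seq_len(n)) total <- par_axpy(total, grads[[i]], coef[i])
  list(grad = total, losses = lvec, z = zin, dz = dz, weights = w,
       loss = sum(w * lvec), std_stats = std_stats,
       pair_grads = if (keep_pair_grads) grads else NULL)
}

#' One-step unrolled update of the paraphraser (stage I)
#'
#' `S' = S - eta_s * grad_S sum_i W(l_i) * l_i` on the batch. The input
#' state is not modified; the meta-weight network receives no gradient.
#'
#' @param S paraphraser state.
#' @param W meta-weight network.
#' @param paraphrase_batch rows of a [paraphrase_corpus()].
#' @param eta_s learning rate.
#' @param detach_mwn_input drop the product-rule term `W'(l) * l`.
#' @return the updated paraphraser state `S'`.
#' @export
stage1_update <- function(S, W, paraphrase_batch, eta_s,
                          detach_mwn_input = FALSE) {
  s1 <- stage1_grad(S, W, paraphrase_batch, detach_mwn_input)
  if (!par_finite(s1$grad)) stop("non-finite stage-I gradient")
  out <- S
  out$params <- par_axpy(S$params, s1$grad, -eta_s)
  attr(out, "stage1_loss") <- s1$loss
  attr(out, "weights") <- s1$weights
  out
}

# Stage-II gradient w.r.t. C. soft = TRUE uses the differentiable coupling
# (retaining the S' dependence needed by stage III); FALSE uses hard decodes.
stage2_grad <- function(C, S_prime, texts, labels, gamma, gens = NULL,
                        only_aug = FALSE, soft = TRUE) {
  if (length(texts) == 0L) stop("batch must be non-empty")
  gen <- if (soft)
    soft_gen_grad(C, S_prime, texts, labels, gens, want = "C")
  else
    hard_generated_loss_grad(C, S_prime, texts, labels, gens)
  g <- par_scale(if (soft) gen$grad_C else gen$grad, gamma)
  train_loss <- NA_real_
  if (!only_aug) {
    tr <- clf_loss_grad(C, texts, labels)
    g <- par_axpy(g, tr$grad)
    train_loss <- tr$loss
  }
  list(grad = g, train_loss = train_loss, gen_loss = gen$loss,
       gens = gen$gens)
}

#' One-step unrolled update of the classifier (stage II)
#'
#' `C' = C - eta_c * grad_C [L(C, batch) + gamma * L_gen(C, S')]` where the
#' generated-data term goes through the soft coupling and therefore retains
#' its differentiable dependence on `S'`. The input state is not modified.
#'
#' @param C classifier state.
#' @param S_prime unrolled paraphraser state from [stage1_update()].
#' @param class_batch rows of a [labeled_corpus()].
#' @param gamma trade-off weight.
#' @param eta_c learning rate.
#' @param gens optional pre-computed decodes.
#' @param only_aug drop the original-data term.
#' @return the updated classifier state `C'`.
#' @export
stage2_update <- function(C, S_prime, class_batch, gamma, eta_c, gens = NULL,
                          only_aug = FALSE) {
  s2 <- stage2_grad(C, S_prime, class_batch$text, class_batch$label, gamma,
                    gens, only_aug)
  if (!par_finite(s2$grad)) stop("non-finite stage-II gradient")
  out <- C
  out$params <- par_axpy(C$params, s2$grad, -eta_c)
  attr(out, "train_loss") <- s2$train_loss
  attr(out, "gen_loss") <- s2$gen_loss
  out
}

hypergrad_result <- function(grad_w, alpha = NA_real_,
                             alpha_s_plus = NA_real_,
                             alpha_s_minus = NA_real_,
                             val_grad_norm = NA_real_, degenerate = FALSE,
                             extra = list()) {
  c(list(grad_w = grad_w, alpha = alpha, alpha_s_plus = alpha_s_plus,
         alpha_s_minus = alpha_s_minus, val_grad_norm = val_grad_norm,
         degenerate = degenerate), extra)
}

#' Finite-difference hypergradient of the MLO-validation loss w.r.t. W
#'
#' Runs both one-step unrolls, then approximates the two mixed second
#' derivatives of the chain rule by symmetric finite differences with
#' adaptively scaled steps: `alpha = alpha_scale / ||grad_val||_2` on the
#' classifier side and `alpha_s = alpha_scale / ||grad_S L_gen(C+/-)||_2` on
#' the paraphraser side. Every perturbation denominator is floored; a floored
#' denominator yields a flagged zero ("degenerate") hypergradient rather
#' than a division error.
#'
#' @param W meta-weight network.
#' @param S,C current paraphraser and classifier states.
#' @param paraphrase_batch,class_batch,val_batch minibatches of the three
#'   corpora.
#' @param config a [mlo_config()].
#' @param gens optional pre-computed decodes for the class batch (epoch-level
#'   caching); freshly decoded from `S'` when NULL.
#' @return list with `grad_w` (layout of `W$params`), the perturbation
#'   scalars `alpha`, `alpha_s_plus`, `alpha_s_minus`, `val_grad_norm`, a
#'   `degenerate` flag, the committed candidates `S_prime` / `C_prime`, the
#'   decodes `gens`, and loss diagnostics.
#' @export
fd_hypergradient <- function(W, S, C, paraphrase_batch, class_batch,
                             val_batch, config, gens = NULL) {
  stopifnot(config$alpha_scale > 0)
  floor_ <- config$denom_floor
  s1 <- stage1_grad(S, W, paraphrase_batch, config$detach_mwn_input,
                    standardize = config$mwn_standardize)
  S_prime <- S
  S_prime$params <- par_axpy(S$params, s1$grad, -config$eta_s)
  texts <- class_batch$text; labels <- class_batch$label
  if (is.null(gens))
    gens <- hard_generations(S_prime, texts, config$min_len, config$max_len)
  s2 <- stage2_grad(C, S_prime, texts, labels, config$gamma, gens,
                    config$only_aug)
  C_prime <- C
  C_prime$params <- par_axpy(C$params, s2$grad, -config$eta_c)

  vg <- clf_loss_grad(C_prime, val_batch$text, val_batch$label)
  vnorm <- par_norm(vg$grad)
  diag_ <- list(S_prime = S_prime, C_prime = C_prime, gens = gens,
                s_grad = s1$grad, c_grad = s2$grad,
                stage1_loss = s1$loss, weights = s1$weights,
                stage2_train_loss = s2$train_loss,
                stage2_gen_loss = s2$gen_loss, val_loss = vg$loss)
  zero <- par_zero_like(W$params)
  if (config$gamma == 0)
    return(hypergrad_result(zero, val_grad_norm = vnorm, extra = diag_))
  if (vnorm < floor_)
    return(hypergrad_result(zero, val_grad_norm = vnorm, degenerate = TRUE,
                            extra = diag_))
  alpha <- config$alpha_scale / vnorm
  C_plus <- C; C_plus$params <- par_axpy(C$params, vg$grad, alpha)
  C_minus <- C; C_minus$params <- par_axpy(C$params, vg$grad, -alpha)
  g_plus <- soft_gen_grad(C_plus, S_prime, texts, labels, gens,
                          want = "S")$grad_S
  g_minus <- soft_gen_grad(C_minus, S_prime, texts, labels, gens,
                           want = "S")$grad_S
  np <- par_norm(g_plus); nm <- par_norm(g_minus)
  if (np < floor_ || nm < floor_)
    return(hypergrad_result(zero, alpha = alpha, val_grad_norm = vnorm,
                            degenerate = TRUE, extra = diag_))
  a_p <- config$alpha_scale / np
  a_m <- config$alpha_scale / nm
  h_at <- function(dir, scale) {
    Sx <- S
    Sx$params <- par_axpy(S$params, dir, scale)
    lv <- pair_losses(Sx, paraphrase_batch)
    zin <- if (config$mwn_standardize)
      std_losses(lv, s1$std_stats)$z else lv
    mwn_grad_params(W, zin, coef = lv)
  }
  d_plus <- par_axpy(h_at(g_plus, a_p), h_at(g_plus, -a_p), -1)
  d_minus <- par_axpy(h_at(g_minus, a_m), h_at(g_minus, -a_m), -1)
  comb <- par_axpy(par_scale(d_plus, 1 / (2 * a_p)),
                   par_scale(d_minus, 1 / (2 * a_m)), -1)
  grad_w <- par_scale(comb,
                      config$eta_s * config$eta_c * config$gamma / (2 * alpha))
  if (!par_finite(grad_w)) stop("non-finite hypergradient")
  hypergrad_result(grad_w, alpha = alpha, alpha_s_plus = a_p,
                   alpha_s_minus = a_m, val_grad_norm = vnorm,
                   extra = diag_)
}

#' Exact hypergradient oracle (verification tool)
#'
#' Differentiates the MLO-validation loss through both one-step unrolls
#' exactly, by the analytic chain rule with the two mixed second-derivative
#' contractions evaluated as complex-step directional derivatives of the
#' backward passes (step 1e-20, exact to machine precision). Intended for
#' tests and diagnostics on small instances; guarded by `size_guard` total
#' inner-model parameters.
#'
#' @inheritParams fd_hypergradient
#' @param size_guard maximum combined parameter count of S and C.
#' @return gradient list matching `W$params`.
#' @export
exact_hypergradient_oracle <- function(W, S, C, paraphrase_batch,
                                       class_batch, val_batch, config,
                                       size_guard = 50000L) {
  np <- par_count(S$params) + par_count(C$params)
  if (np > size_guard)
    stop("instance too large for the exact oracle (", np, " parameters)")
  zero <- par_zero_like(W$params)
  if (config$gamma == 0 || config$eta_s == 0) return(zero)
  h <- 1e-20
  s1 <- stage1_grad(S, W, paraphrase_batch, config$detach_mwn_input,
                    keep_pair_grads = TRUE,
                    standardize = config$mwn_standardize)
  S_prime <- S
  S_prime$params <- par_axpy(S$params, s1$grad, -config$eta_s)
  texts <- class_batch$text; labels <- class_batch$label
  gens <- hard_generations(S_prime, texts, config$min_len, config$max_len)
  s2 <- stage2_grad(C, S_prime, texts, labels, config$gamma, gens,
                    config$only_aug)
  C_prime <- C
  C_prime$params <- par_axpy(C$params, s2$grad, -config$eta_c)
  v <- clf_loss_grad(C_prime, val_batch$text, val_batch$label)$grad
  # dL/dS' = -eta_c * gamma * d/dS' [ v . grad_C L_gen(C, S') ]
  C_c <- C
  C_c$params <- par_complex_step(C$params, v, h)
  gS_c <- soft_gen_grad(C_c, S_prime, texts, labels, gens, want = "S")$grad_S
  p <- par_scale(par_imag(gS_c, h), -config$eta_c * config$gamma)
  # dL/dW = -eta_s * grad_W [ p . grad_S F(S, W) ]
  ci <- vapply(s1$pair_grads, function(g) par_dot(p, g), numeric(1))
  lvec <- s1$losses
  zin <- s1$z
  grad <- mwn_grad_params(W, zin, coef = ci)
  if (!config$detach_mwn_input) {
    termB <- par_imag(mwn_grad_params(W, zin + (0+1i) * h,
                                      coef = ci * s1$dz * lvec), h)
    grad <- par_axpy(grad, termB)
  }
  par_scale(grad, -config$eta_s)
}

#' Brute-force numerical hypergradient (second verification route)
#'
#' Central differences of the MLO-validation loss with respect to each
#' meta-weight-network parameter, re-running both one-step unrolls per
#' evaluation. The decoded paraphrase sequences are held fixed at the
#' unperturbed unroll's decodes (they are piecewise constant in the
#' parameters; the smooth branch is what is being differentiated).
#'
#' @inheritParams fd_hypergradient
#' @param eps half-width of the central difference.
#' @return gradient list matching `W$params`.
#' @export
numerical_hypergradient <- function(W, S, C, paraphrase_batch, class_batch,
                                    val_batch, config, eps = 1e-3) {
  texts <- class_batch$text; labels <- class_batch$label
  base1 <- stage1_grad(S, W, paraphrase_batch, config$detach_mwn_input,
                       standardize = config$mwn_standardize)
  S0 <- S; S0$params <- par_axpy(S$params, base1$grad, -config$eta_s)
  gens <- hard_generations(S0, texts, config$min_len, config$max_len)
  outer_obj <- function(Wx) {
    s1 <- stage1_grad(S, Wx, paraphrase_batch, config$detach_mwn_input,
                      standardize = config$mwn_standardize)
    Sp <- S; Sp$params <- par_axpy(S$params, s1$grad, -config$eta_s)
    s2 <- stage2_grad(C, Sp, texts, labels, config$gamma, gens,
                      config$only_aug)
    Cp <- C; Cp$params <- par_axpy(C$params, s2$grad, -config$eta_c)
    classifier_loss(Cp, val_batch$text, val_batch$label)
  }
  flat <- par_flatten(W$params)
  gflat <- numeric(length(flat))
  for (j in seq_along(flat)) {
    up <- flat; up[j] <- up[j] + eps
    dn <- flat; dn[j] <- dn[j] - eps
    Wu <- W; Wu$params <- par_unflatten(up, W$params)
    Wd <- W; Wd$params <- par_unflatten(dn, W$params)
    gflat[j] <- (outer_obj(Wu) - outer_obj(Wd)) / (2 * eps)
  }
  par_unflatten(gflat, W$params)
}

#' Update the meta-weight network from a hypergradient
#'
#' One optimizer step on W. The default is AdamW (beta1 0.9, beta2 0.999,
#' eps 1e-8, weight decay from the optimizer state); `optimizer = "sgd"`
#' gives the plain step `W - eta_w * grad_w`.
#'
#' @param W meta-weight network.
#' @param grad_w gradient list matching `W$params`.
#' @param opt optional [adamw_init()] state (created on first use).
#' @param eta_w learning rate.
#' @param optimizer `"adamw"` or `"sgd"`.
#' @param weight_decay decay used when creating the AdamW state.
#' @return list with updated `mwn` and `opt`.
#' @export
mwn_update <- function(W, grad_w, opt = NULL, eta_w = 1e-4,
                       optimizer = c("adamw", "sgd"), weight_decay = 0) {
  optimizer <- match.arg(optimizer)
  if (!par_finite(grad_w)) stop("non-finite hypergradient")
  out <- W
  if (optimizer == "sgd") {
    out$params <- par_axpy(W$params, grad_w, -eta_w)
    return(list(mwn = out, opt = opt))
  }
  if (is.null(opt))
    opt <- adamw_init(W$params, lr = eta_w, weight_decay = weight_decay)
  st <- adamw_step(opt, W$params, grad_w)
  out$params <- st$params
  list(mwn = out, opt = st$opt)
}

take_cycle <- function(perm, start, len) {
  n <- length(perm)
  idx <- ((start - 1L + seq_len(len) - 1L) %% n) + 1L
  perm[idx]
}

#' Run the full multi-level optimization
#'
#' Alternates the three stages over minibatch triples for
#' `config$mlo_epochs`, committing the one-step candidates `S'` and `C'`
#' each iteration and updating the meta-weight network from the
#' finite-difference hypergradient, then fine-tunes the classifier on the
#' full training set for `config$finetune_epochs`.
#'
#' @param config a [mlo_config()].
#' @param paraphrase_corpus a [paraphrase_corpus()].
#' @param mlo_train,mlo_val the [split_mlo()] halves of the training set.
#' @param full_train the full training [labeled_corpus()] for fine-tuning.
#' @param vocab optional shared vocabulary (built from all texts when NULL).
#' @param models optional list with pre-built `S`, `C`, `W` states.
#' @return list with `classifier`, `paraphraser`, `mwn`, `history` (one row
#'   per iteration), `finetune_history`, `config`, `vocab`.
#' @export
train_mlo <- function(config, paraphrase_corpus, mlo_train, mlo_val,
                      full_train, vocab = NULL, models = NULL) {
  stopifnot(inherits(config, "metapara_config"))
  if (is.null(vocab))
    vocab <- vocab_build(c(paraphrase_corpus$source, paraphrase_corpus$target,
                           full_train$text))
  K <- label_count(full_train)
  S <- if (!is.null(models$S)) models$S else
    paraphraser_init(vocab, emb_dim = config$s_emb_dim,
                     min_len = config$min_len, max_len = config$max_len,
                     seed = config$seed + 1L)
  C <- if (!is.null(models$C)) models$C else
    classifier_init(vocab, K, emb_dim = config$c_emb_dim,
                    units1 = config$c_units1, units2 = config$c_units2,
                    dense_units = config$c_dense, dropout = config$c_dropout,
                    max_len = config$max_len, seed = config$seed + 2L)
  W <- if (!is.null(models$W)) models$W else
    mwn_init(hidden = config$mwn_hidden, dropout = config$mwn_dropout,
             seed = config$seed + 3L)
  opt_w <- NULL; opt_s <- NULL; opt_c <- NULL
  n_pairs <- nrow(paraphrase_corpus)
  n_tr <- nrow(mlo_train)
  n_val <- nrow(mlo_val)
  records <- list()
  for (epoch in seq_len(config$mlo_epochs)) {
    perms <- with_seed(config$seed + 7919L * epoch,
                       list(p = sample(n_pairs), t = sample(n_tr),
                            v = sample(n_val)))
    n_iter <- max(1L, ceiling(n_tr / config$batch_class))
    epoch_gens <- if (config$cache_generations)
      hard_generations(S, mlo_train$text, config$min_len, config$max_len)
    else NULL
    for (it in seq_len(n_iter)) {
      pidx <- take_cycle(perms$p, (it - 1L) * config$batch_para + 1L,
                         min(config$batch_para, n_pairs))
      tidx <- take_cycle(perms$t, (it - 1L) * config$batch_class + 1L,
                         min(config$batch_class, n_tr))
      vidx <- take_cycle(perms$v, (it - 1L) * config$batch_class + 1L,
                         min(config$batch_class, n_val))
      pbatch <- paraphrase_corpus[pidx, , drop = FALSE]
      cbatch <- mlo_train[tidx, , drop = FALSE]
      vbatch <- mlo_val[vidx, , drop = FALSE]
      if (config$para_sep) {
        s1 <- stage1_grad(S, W, pbatch, config$detach_mwn_input,
                          standardize = config$mwn_standardize)
        S2 <- S
        S2$params <- par_axpy(S$params, s1$grad, -config$eta_s)
        gens <- if (is.null(epoch_gens))
          hard_generations(S2, cbatch$text, config$min_len, config$max_len)
        else epoch_gens[tidx]
        s2 <- stage2_grad(C, S2, cbatch$text, cbatch$label, config$gamma,
                          gens, config$only_aug, soft = FALSE)
        hg <- list(s_grad = s1$grad, c_grad = s2$grad, S_prime = S2,
                   C_prime = NULL, stage1_loss = s1$loss,
                   weights = s1$weights, stage2_train_loss = s2$train_loss,
                   stage2_gen_loss = s2$gen_loss, val_loss = NA_real_,
                   grad_w = NULL, degenerate = FALSE)
      } else {
        hg <- fd_hypergradient(W, S, C, pbatch, cbatch, vbatch, config,
                               gens = if (is.null(epoch_gens)) NULL
                                      else epoch_gens[tidx])
      }
      if (config$s_optimizer == "adamw") {
        if (is.null(opt_s))
          opt_s <- adamw_init(S$params, lr = config$eta_s,
                              weight_decay = config$s_weight_decay)
        st <- adamw_step(opt_s, S$params, hg$s_grad)
        S$params <- st$params; opt_s <- st$opt
      } else {
        S <- hg$S_prime
      }
      if (config$c_optimizer == "adamw") {
        if (is.null(opt_c))
          opt_c <- adamw_init(C$params, lr = config$eta_c)
        st <- adamw_step(opt_c, C$params, hg$c_grad)
        C$params <- st$params; opt_c <- st$opt
      } else {
        C$params <- par_axpy(C$params, hg$c_grad, -config$eta_c)
      }
      if (config$para_sep) {
        vloss <- classifier_loss(C, vbatch$text, vbatch$label)
        hg$val_loss <- vloss
      } else {
        upd <- mwn_update(W, hg$grad_w, opt_w, config$eta_w,
                          optimizer = config$mwn_optimizer,
                          weight_decay = config$mwn_weight_decay)
        W <- upd$mwn; opt_w <- upd$opt
      }
      rec <- data.frame(epoch = epoch, iter = it,
                        stage1_loss = Re(hg$stage1_loss),
                        stage2_train_loss = hg$stage2_train_loss,
                        stage2_gen_loss = hg$stage2_gen_loss,
                        val_loss = hg$val_loss,
                        w_mean = mean(hg$weights),
                        w_min = min(hg$weights), w_max = max(hg$weights),
                        hypergrad_norm = if (is.null(hg$grad_w)) NA_real_
                                         else par_norm(hg$grad_w),
                        degenerate = hg$degenerate)
      records[[length(records) + 1L]] <- rec
    }
  }
  aug <- NULL
  if (config$finetune_augment && config$finetune_epochs > 0L)
    aug <- augment_dataset(S, full_train, min_len = config$min_len,
                           max_len = config$max_len)
  C <- finetune(C, full_train, epochs = config$finetune_epochs,
                eta_c = config$eta_finetune, batch_size = config$batch_class,
                gamma = config$gamma, augmented = aug,
                only_aug = config$only_aug,
                seed = config$seed + 104729L)
  list(classifier = C, paraphraser = S, mwn = W,
       history = do.call(rbind, records),
       finetune_history = attr(C, "finetune_history"),
       augmented = aug, config = config, vocab = vocab)
}

#' Paraphrase every example of a labeled corpus
#'
#' One greedy-decoded generation per input example; the label is preserved
#' from the source and `source_id` records provenance. Failures on single
#' examples are recorded and skipped.
#'
#' @param S paraphraser state.
#' @param corpus a [labeled_corpus()].
#' @param min_len,max_len decode bounds (default the paraphraser's).
#' @return a [generated_examples()] data.frame; attribute `"n_failed"`
#'   counts skipped examples.
#' @export
augment_dataset <- function(S, corpus, min_len = S$min_len,
                            max_len = S$max_len) {
  texts <- character(0); labels <- integer(0); src <- character(0)
  failed <- 0L
  for (i in seq_len(nrow(corpus))) {
    out <- tryCatch(
      generate(S, corpus$text[i], min_len = min_len, max_len = max_len),
      error = function(e) NULL)
    if (is.null(out) || !nzchar(out)) { failed <- failed + 1L; next }
    texts <- c(texts, out)
    labels <- c(labels, corpus$label[i])
    src <- c(src, corpus$id[i])
  }
  if (failed > 0L)
    message(failed, " example(s) skipped during augmentation")
  structure(generated_examples(texts, labels, src), n_failed = failed)
}

#' Supervised fine-tuning of the classifier
#'
#' AdamW epochs over the full training set; when `augmented` is supplied the
#' per-batch objective is `L(C, batch) + gamma * L(C, generated batch)`,
#' mirroring the middle-level objective. `epochs = 0` returns the classifier
#' unchanged.
#'
#' @param C classifier state.
#' @param corpus full training [labeled_corpus()].
#' @param epochs number of epochs (default 20).
#' @param eta_c learning rate.
#' @param batch_size minibatch size.
#' @param gamma weight on the generated term.
#' @param augmented optional [generated_examples()] aligned to `corpus` by
#'   `source_id`.
#' @param only_aug train on the generated examples only.
#' @param seed shuffle seed.
#' @return fine-tuned classifier; attribute `"finetune_history"` holds the
#'   per-epoch mean training loss.
#' @export
finetune <- function(C, corpus, epochs = 20L, eta_c = 3e-3, batch_size = 8L,
                     gamma = 0.85, augmented = NULL, only_aug = FALSE,
                     seed = 1L) {
  if (epochs < 0L) stop("epochs must be >= 0")
  if (epochs == 0L) return(C)
  n <- nrow(corpus)
  gen_for <- NULL
  if (!is.null(augmented))
    gen_for <- match(corpus$id, augmented$source_id)
  opt <- adamw_init(C$params, lr = eta_c)
  hist <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    perm <- with_seed(seed + 7919L * epoch, sample(n))
    tot <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      grad <- par_zero_like(C$params)
      loss <- 0
      if (!only_aug) {
        tr <- clf_loss_grad(C, corpus$text[idx], corpus$label[idx])
        grad <- par_axpy(grad, tr$grad)
        loss <- loss + tr$loss
      }
      if (!is.null(gen_for)) {
        gidx <- gen_for[idx]
        gidx <- gidx[!is.na(gidx)]
        if (length(gidx)) {
          ag <- clf_loss_grad(C, augmented$text[gidx], augmented$label[gidx])
          grad <- par_axpy(grad, ag$grad, gamma)
          loss <- loss + gamma * ag$loss
        }
      }
      st <- adamw_step(opt, C$params, grad)
      C$params <- st$params
      opt <- st$opt
      tot <- tot + loss; nb <- nb + 1L
    }
    hist[epoch] <- tot / nb
  }
  attr(C, "finetune_history") <- hist
  C
}

#' Per-pair meta weights over a paraphrase corpus
#'
#' Evaluates each pair's teacher-forcing loss under `S` and maps it through
#' the meta-weight network; the main diagnostic for domain-adaptive
#' reweighting.
#'
#' @param W meta-weight network.
#' @param S paraphraser state.
#' @param corpus a [paraphrase_corpus()].
#' @param standardize z-score the losses (corpus-level statistics) before
#'   the meta-weight network, matching an engine run with
#'   `mwn_standardize = TRUE`.
#' @return data.frame with id, loss, weight and (if present) domain_tag.
#' @export
mwn_pair_weights <- function(W, S, corpus, standardize = FALSE) {
  losses <- vapply(seq_len(nrow(corpus)), function(i)
    teacher_forcing_loss(S, corpus$source[i], corpus$target[i]), numeric(1))
  zin <- if (standardize) std_losses(losses)$z else losses
  out <- data.frame(id = corpus$id, loss = losses,
                    weight = mwn_forward(W, zin))
  if (!is.null(corpus$domain_tag)) out$domain_tag <- corpus$domain_tag
  out
}
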