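test_that("zero learning rates make the unrolled updates identities", {
  inst <- tiny_instance(41, warm = 0)
  S2 <- stage1_update(inst$S, inst$W, inst$pbatch, eta_s = 0)
  expect_equal(S2$params, inst$S$params)
  C2 <- stage2_update(inst$C, inst$S, inst$cbatch, gamma = 0.85, eta_c = 0)
  expect_equal(C2$params, inst$C$params)
})

test_that("stage updates leave their input states unmodified", {
  inst <- tiny_instance(43, warm = 0)
  s_before <- par_flatten(inst$S$params)
  c_before <- par_flatten(inst$C$params)
  invisible(stage1_update(inst$S, inst$W, inst$pbatch, eta_s = 0.3))
  invisible(stage2_update(inst$C, inst$S, inst$cbatch, gamma = 0.85,
                          eta_c = 0.3))
  expect_identical(par_flatten(inst$S$params), s_before)
  expect_identical(par_flatten(inst$C$params), c_before)
})

test_that("stage-I step equals an independently assembled SGD step", {
  inst <- tiny_instance(45, warm = 0)
  batch <- inst$pbatch[1, , drop = FALSE]
  eta <- 0.17
  S2 <- stage1_update(inst$S, inst$W, batch, eta_s = eta)
  # independent gradient of W(l) * l via central differences on S
  f <- function(p) {
    Sx <- inst$S; Sx$params <- p
    l <- teacher_forcing_loss(Sx, batch$source, batch$target)
    as.numeric(mwn_forward(inst$W, l) * l)
  }
  gn <- num_grad(f, inst$S$params)
  manual <- par_axpy(inst$S$params, gn, -eta)
  expect_lt(flat_relerr(S2$params, manual), 1e-5)
})

test_that("stage-II step with gamma 0 is a plain supervised step", {
  inst <- tiny_instance(47, warm = 0)
  eta <- 0.11
  C2 <- stage2_update(inst$C, inst$S, inst$cbatch, gamma = 0, eta_c = eta)
  g <- metapara:::clf_loss_grad(inst$C, inst$cbatch$text, inst$cbatch$label)
  manual <- par_axpy(inst$C$params, g$grad, -eta)
  expect_equal(C2$params, manual, tolerance = 1e-12)
  # gamma > 0: matches an independent central-difference step
  C3 <- stage2_update(inst$C, inst$S, inst$cbatch, gamma = 0.85,
                      eta_c = eta)
  gens <- metapara:::hard_generations(inst$S, inst$cbatch$text, 1, 8)
  f <- function(p) {
    Cx <- inst$C; Cx$params <- p
    classifier_loss(Cx, inst$cbatch$text, inst$cbatch$label) +
      0.85 * as.numeric(soft_generated_loss(Cx, inst$S, inst$cbatch$text,
                                            inst$cbatch$label, gens = gens))
  }
  gn <- num_grad(f, inst$C$params, eps = 1e-5)
  manual3 <- par_axpy(inst$C$params, gn, -eta)
  expect_lt(flat_relerr(C3$params, manual3), 1e-3)
})

test_that("mwn_update performs plain SGD arithmetic and AdamW defaults", {
  W <- mwn_init(hidden = 3, seed = 1)
  grad <- par_zero_like(W$params)
  grad$b3 <- 2
  up <- mwn_update(W, grad, eta_w = 0.5, optimizer = "sgd")
  expect_equal(up$mwn$params$b3, W$params$b3 - 0.5 * 2)
  expect_equal(up$mwn$params$W2, W$params$W2)
  # eta 0 keeps W unchanged
  expect_equal(mwn_update(W, grad, eta_w = 0, optimizer = "sgd")$mwn$params,
               W$params)
  # AdamW state carries the reference moment constants
  up2 <- mwn_update(W, grad, eta_w = 0.1, optimizer = "adamw")
  expect_s3_class(up2$opt, "metapara_adamw")
  expect_equal(up2$opt$beta1, 0.9)
  expect_equal(up2$opt$beta2, 0.999)
  expect_equal(up2$opt$eps, 1e-8)
  # first AdamW step moves b3 by ~lr in the descent direction
  expect_equal(up2$mwn$params$b3, W$params$b3 - 0.1, tolerance = 1e-6)
  expect_error(mwn_update(W, list(b3 = NaN)), "finite")
})

test_that("gamma = 0 zeroes the finite-difference hypergradient", {
  inst <- tiny_instance(49)
  cfg <- tiny_config(49, gamma = 0)
  hg <- fd_hypergradient(inst$W, inst$S, inst$C, inst$pbatch, inst$cbatch,
                         inst$vbatch, cfg)
  expect_false(hg$degenerate)
  expect_equal(par_norm(hg$grad_w), 0)
  expect_equal(par_norm(exact_hypergradient_oracle(
    inst$W, inst$S, inst$C, inst$pbatch, inst$cbatch, inst$vbatch, cfg)), 0)
})

test_that("eta_s = 0 breaks the chain: zero oracle hypergradient", {
  inst <- tiny_instance(51)
  cfg <- tiny_config(51, eta_s = 0)
  expect_equal(par_norm(exact_hypergradient_oracle(
    inst$W, inst$S, inst$C, inst$pbatch, inst$cbatch, inst$vbatch, cfg)), 0)
})

test_that("vanishing validation gradient yields a flagged zero, not an error", {
  inst <- tiny_instance(53, warm = 0)
  cfg <- tiny_config(53)
  # a saturated softmax head that nails every validation label
  C <- inst$C
  C$params <- par_zero_like(C$params)
  C$params$b_k <- c(1e4, -1e4)  # always class 0 with probability 1
  vb <- inst$vbatch[inst$vbatch$label == 0L, , drop = FALSE]
  hg <- fd_hypergradient(inst$W, inst$S, C, inst$pbatch, inst$cbatch, vb,
                         cfg)
  expect_true(hg$degenerate)
  expect_equal(par_norm(hg$grad_w), 0)
  expect_true(is.finite(hg$val_grad_norm))
})

test_that("stage I treats the meta-weight network as a constant", {
  # the degenerate-solution guard: no code path lets stage-I gradients touch
  # W, so its parameters are bitwise unchanged by any number of stage-I steps
  inst <- tiny_instance(55, warm = 0)
  w_before <- par_flatten(inst$W$params)
  S <- inst$S
  for (k in 1:3) S <- stage1_update(S, inst$W, inst$pbatch, 0.3)
  expect_identical(par_flatten(inst$W$params), w_before)
})

test_that("fd hypergradient tracks the exact oracle on tiny instances", {
  for (seed in c(61, 71, 81)) {
    inst <- tiny_instance(seed)
    cfg <- tiny_config(seed)
    or <- exact_hypergradient_oracle(inst$W, inst$S, inst$C, inst$pbatch,
                                     inst$cbatch, inst$vbatch, cfg)
    hg <- fd_hypergradient(inst$W, inst$S, inst$C, inst$pbatch, inst$cbatch,
                           inst$vbatch, cfg)
    if (hg$degenerate) {
      expect_lt(par_norm(or), 1e-10)
    } else {
      expect_gt(flat_cosine(hg$grad_w, or), 0.95)
    }
  }
})

test_that("oracle agrees with brute-force differentiation of the unrolls", {
  inst <- tiny_instance(91, mwn_hidden = 6L)   # 97-parameter meta network
  cfg <- tiny_config(91)
  or <- exact_hypergradient_oracle(inst$W, inst$S, inst$C, inst$pbatch,
                                   inst$cbatch, inst$vbatch, cfg)
  nm <- numerical_hypergradient(inst$W, inst$S, inst$C, inst$pbatch,
                                inst$cbatch, inst$vbatch, cfg)
  expect_lt(flat_relerr(or, nm), 1e-3)
})

test_that("the oracle refuses oversized instances", {
  inst <- tiny_instance(93, warm = 0)
  cfg <- tiny_config(93)
  expect_error(exact_hypergradient_oracle(inst$W, inst$S, inst$C,
                                          inst$pbatch, inst$cbatch,
                                          inst$vbatch, cfg,
                                          size_guard = 10L), "too large")
})
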