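test_that("uniform-output model has teacher-forcing loss ln V", {
  vocab <- tiny_vocab(8)
  S <- zeroed(paraphraser_init(vocab, emb_dim = 6, min_len = 1,
                               max_len = 8, seed = 1))
  expect_equal(teacher_forcing_loss(S, "a01 a02 b03", "a04 b01"),
               log(vocab_size(vocab)), tolerance = 1e-6)
  # a perfect model would score 1 per token: loss 0 is the floor
  expect_gte(teacher_forcing_loss(S, "a01", "a02"), 0)
})

test_that("teacher-forcing loss equals the hand-assembled per-token NLL", {
  vocab <- tiny_vocab(6)
  S <- paraphraser_init(vocab, emb_dim = 5, min_len = 1, max_len = 8,
                        seed = 3)
  src <- encode_text(vocab, "a01 a03")
  tgt <- encode_text(vocab, "a02 a04 b01")
  cache <- metapara:::s2s_forward_tf(S, src, tgt)
  # enumerate the softmax terms position by position
  expected <- -mean(log(vapply(seq_along(cache$targets), function(t)
    cache$P[cache$targets[t], t], numeric(1))))
  expect_equal(cache$loss, expected, tolerance = 1e-12)
  expect_equal(length(cache$targets), length(tgt) + 1L)  # eos step included
})

test_that("paraphraser gradient matches central differences", {
  vocab <- tiny_vocab(6)
  S <- paraphraser_init(vocab, emb_dim = 4, min_len = 1, max_len = 8,
                        seed = 5)
  src <- encode_text(vocab, "a01 a03 b02")
  tgt <- encode_text(vocab, "a02 a04")
  lg <- metapara:::s2s_loss_grad(S, src, tgt)
  gn <- num_grad(function(p) {
    S2 <- S; S2$params <- p
    metapara:::s2s_forward_tf(S2, src, tgt)$loss
  }, S$params)
  expect_lt(flat_relerr(lg$grad, gn), 1e-5)
})

test_that("weighted paraphrase loss composes per-pair losses and weights", {
  vocab <- tiny_vocab(6)
  S <- paraphraser_init(vocab, emb_dim = 4, min_len = 1, max_len = 8,
                        seed = 7)
  batch <- paraphrase_corpus(c("p1", "p2"), c("a01 a03", "b02 b04"),
                             c("a02 a04", "b01 b03"))
  l1 <- teacher_forcing_loss(S, batch$source[1], batch$target[1])
  l2 <- teacher_forcing_loss(S, batch$source[2], batch$target[2])
  W <- mwn_init(hidden = 5, seed = 2)
  a <- mwn_forward(W, c(l1, l2))
  total <- weighted_paraphrase_loss(S, W, batch)
  expect_equal(as.numeric(total), a[1] * l1 + a[2] * l2, tolerance = 1e-12)
  expect_equal(as.numeric(weighted_paraphrase_loss(S, W, batch,
                                                   reduce = "mean")),
               (a[1] * l1 + a[2] * l2) / 2, tolerance = 1e-12)
  # an identity-weight network reduces to the unweighted sum
  ones <- mwn_init(hidden = 2, seed = 1)
  ones$params <- par_zero_like(ones$params)
  ones$params$b3 <- 1e3   # sigmoid(1e3) == 1 in double precision
  expect_equal(as.numeric(weighted_paraphrase_loss(S, ones, batch)),
               l1 + l2, tolerance = 1e-9)
  expect_error(weighted_paraphrase_loss(S, W, batch[0, ]), "non-empty")
})

test_that("generation respects length bounds and is deterministic", {
  vocab <- tiny_vocab(10)
  S <- paraphraser_init(vocab, emb_dim = 6, min_len = 4, max_len = 9,
                        seed = 9)
  out <- generate(S, "a01 a05 b03")
  expect_identical(out, generate(S, "a01 a05 b03"))
  n_tok <- length(tokenize(out))
  expect_gte(n_tok, 4L)
  expect_lte(n_tok, 9L)

  # bound property over many random inputs and model seeds
  toks <- vocab$tokens[-(1:4)]
  for (ms in 1:3) {
    Sm <- paraphraser_init(vocab, emb_dim = 6, min_len = 2, max_len = 6,
                           seed = ms)
    lens <- withr::with_seed(ms, replicate(40, {
      txt <- paste(sample(toks, sample(2:8, 1), replace = TRUE),
                   collapse = " ")
      length(tokenize(generate(Sm, txt)))
    }))
    expect_true(all(lens >= 2 & lens <= 6))
  }

  # min_len = max_len = 1: exactly one token before the forced stop
  one <- generate(S, "a01 a02", min_len = 1, max_len = 1)
  expect_length(tokenize(one), 1L)
  expect_error(generate(S, "   "), "length 0")
})

test_that("beam decoding matches greedy for width 1 and stays in bounds", {
  vocab <- tiny_vocab(8)
  S <- paraphraser_init(vocab, emb_dim = 6, min_len = 2, max_len = 7,
                        seed = 4)
  txt <- "a02 a04 b01"
  expect_identical(generate(S, txt, strategy = "beam", beam_width = 1L),
                   generate(S, txt, strategy = "greedy"))
  bm <- generate(S, txt, strategy = "beam", beam_width = 3L)
  expect_identical(bm, generate(S, txt, strategy = "beam", beam_width = 3L))
  expect_true(length(tokenize(bm)) >= 2 && length(tokenize(bm)) <= 7)
})

test_that("decoder distributions are per-position softmaxes over V", {
  vocab <- tiny_vocab(6)
  S <- paraphraser_init(vocab, emb_dim = 4, min_len = 1, max_len = 8,
                        seed = 6)
  src <- encode_text(vocab, "a01 b02 a03")
  dec <- encode_text(vocab, "a02 b01")
  dd <- decoder_distributions(S, src, dec)
  expect_equal(dim(dd$P), c(vocab_size(vocab), 2L))
  expect_equal(colSums(dd$P), rep(1, 2), tolerance = 1e-12)
  expect_true(all(dd$P > 0))
})
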