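test_that("generator honors counts, tags and determinism", {
  spec <- synthetic_spec(n_paraphrase_pairs = 100, in_domain_fraction = 0.5,
                         seed = 3)
  task <- make_synthetic_task(spec)
  expect_equal(sum(task$paraphrase$domain_tag == "in_domain"), 50L)
  expect_equal(nrow(task$paraphrase), 100L)
  expect_equal(nrow(task$train), 120L)
  expect_equal(nrow(task$val), 40L)
  expect_equal(nrow(task$test), 80L)

  task2 <- make_synthetic_task(spec)
  expect_identical(task$paraphrase, task2$paraphrase)
  expect_identical(task$train, task2$train)
  expect_identical(task$test, task2$test)
  expect_false(identical(
    task$train, make_synthetic_task(synthetic_spec(seed = 4))$train))

  lens <- vapply(task$train$text, function(t) length(tokenize(t)),
                 integer(1))
  expect_true(all(lens >= 6 & lens <= 12))
})

test_that("spec invariants are validated", {
  expect_error(synthetic_spec(in_domain_fraction = 1.5), "in_domain_fraction")
  expect_error(synthetic_spec(noise_rate = 1), "noise_rate")
  expect_error(synthetic_spec(n_signal_tokens = 3), "even multiple")
  expect_error(synthetic_spec(vocab_size_per_domain = 4,
                              n_signal_tokens = 4), "exceed")
})

test_that("token domains are disjoint and pairs stay within one domain", {
  task <- make_synthetic_task(synthetic_spec(seed = 5))
  a <- sprintf("a%02d", 1:30)
  b <- sprintf("b%02d", 1:30)
  expect_length(intersect(a, b), 0L)
  for (i in seq_len(nrow(task$paraphrase))) {
    toks <- c(tokenize(task$paraphrase$source[i]),
              tokenize(task$paraphrase$target[i]))
    dom <- task$paraphrase$domain_tag[i]
    expect_true(all(toks %in% (if (dom == "in_domain") a else b)))
  }
  # off-domain pairs carry no signal token: label-irrelevant by construction
  signal <- unlist(task$groups)
  off <- task$paraphrase[task$paraphrase$domain_tag == "off_domain", ]
  expect_false(any(unlist(lapply(c(off$source, off$target), tokenize))
                   %in% signal))
})

test_that("synonym substitution preserves the label rule exactly", {
  task <- make_synthetic_task(synthetic_spec(noise_rate = 0, seed = 7))
  paraphrased <- vapply(task$train$text, function(t)
    metapara:::apply_synonyms(t, task$synonyms$A), "")
  expect_equal(bayes_rule_predict(task, paraphrased), task$train$label)
})

test_that("label rule is perfect without noise and decays toward chance", {
  clean <- make_synthetic_task(synthetic_spec(noise_rate = 0, seed = 9))
  expect_equal(bayes_reference_accuracy(clean, clean$test), 1.0)
  expect_equal(bayes_reference_accuracy(clean, clean$train), 1.0)

  noisy <- make_synthetic_task(synthetic_spec(noise_rate = 0.9,
                                              n_train = 600, seed = 11))
  acc <- bayes_reference_accuracy(noisy, noisy$train)
  expect_lt(acc, 0.75)
  expect_gt(acc, 0.4)
})

test_that("rule accuracy at intermediate noise matches a Monte-Carlo estimate", {
  spec <- synthetic_spec(noise_rate = 0.3, n_train = 400, seed = 13)
  task <- make_synthetic_task(spec)
  acc <- bayes_reference_accuracy(task, task$train)
  # independent resample of fresh texts from the same generative process
  toks <- metapara:::synth_tokens(spec)
  groups <- metapara:::synth_groups(spec, toks$A)
  mc <- withr::with_seed(99, {
    labels <- sample(rep_len(0:1, 10000))
    texts <- vapply(labels, function(y)
      metapara:::synth_text_A(spec, y, toks$A, groups), "")
    mean(bayes_rule_predict(task, texts) == labels)
  })
  se <- sqrt(mc * (1 - mc) / 10000) + sqrt(acc * (1 - acc) / 400)
  expect_lt(abs(acc - mc), 2 * se + 1e-9)
})

test_that("classes are balanced within 5% of uniform", {
  task <- make_synthetic_task(synthetic_spec(seed = 15))
  for (corp in list(task$train, task$val, task$test)) {
    frac <- mean(corp$label == 0L)
    expect_lt(abs(frac - 0.5), 0.05)
  }
})
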