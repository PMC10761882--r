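test_that("perfect predictions score 1 on every metric", {
  labels <- c(0L, 1L, 1L, 0L, 1L)
  scores <- cbind(1 - labels, labels) * 0.98 + 0.01
  m <- compute_metrics(labels, labels, scores)
  expect_equal(m$accuracy, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$auc, 1)
})

test_that("confusion-matrix arithmetic matches hand computation", {
  # TP=3, FP=1, FN=1, TN=5 for the positive class
  labels <- c(rep(1L, 4), rep(0L, 6))
  preds  <- c(1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L)
  m <- compute_metrics(labels, preds)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$accuracy, 0.8)
  expect_true(is.na(m$auc))
})

test_that("uninformative identical scores give AUC one half by midranks", {
  labels <- c(0L, 1L, 0L, 1L, 1L)
  scores <- matrix(0.5, 5, 2)
  m <- compute_metrics(labels, labels, scores)
  expect_equal(m$auc, 0.5)
})

test_that("binary AUC equals the normalized Mann-Whitney U statistic", {
  for (seed in 1:5) {
    n <- 40
    dat <- withr::with_seed(seed, {
      labels <- rbinom(n, 1, 0.4)
      p1 <- runif(n)
      list(labels = as.integer(labels), scores = cbind(1 - p1, p1))
    })
    m <- compute_metrics(dat$labels, as.integer(dat$scores[, 2] > 0.5),
                         dat$scores)
    u <- wilcox.test(dat$scores[dat$labels == 1, 2],
                     dat$scores[dat$labels == 0, 2],
                     exact = FALSE)$statistic
    n1 <- sum(dat$labels == 1); n0 <- sum(dat$labels == 0)
    expect_equal(m$auc, unname(u) / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("macro metrics are invariant to class relabeling", {
  labels <- c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 0L)
  preds  <- c(0L, 1L, 1L, 2L, 2L, 2L, 0L, 0L)
  scores <- withr::with_seed(1, {
    s <- matrix(runif(24), 8, 3)
    s / rowSums(s)
  })
  m <- compute_metrics(labels, preds, scores, averaging = "macro",
                       auc_mode = "one_vs_one")
  perm <- c(2L, 0L, 1L)   # relabel classes
  m2 <- compute_metrics(perm[labels + 1L], perm[preds + 1L],
                        scores[, order(perm)], averaging = "macro",
                        auc_mode = "one_vs_one")
  expect_equal(m2$f1, m$f1)
  expect_equal(m2$precision, m$precision)
  expect_equal(m2$recall, m$recall)
  expect_equal(m2$accuracy, m$accuracy)
  expect_equal(m2$auc, m$auc)
})

test_that("zero-division classes resolve to 0 with a warning", {
  labels <- c(0L, 0L, 1L)
  preds <- c(0L, 0L, 0L)
  expect_warning(m <- compute_metrics(labels, preds), "class 1")
  expect_equal(m$precision, 0)
  expect_equal(m$recall, 0)
  expect_equal(m$f1, 0)
})

test_that("binary averaging refuses multi-class input; macro handles it", {
  labels <- c(0L, 1L, 2L)
  expect_error(compute_metrics(labels, labels, averaging = "binary"),
               "2-class")
  m <- compute_metrics(labels, labels, averaging = "macro")
  expect_equal(m$f1, 1)
  expect_error(compute_metrics(labels, c(0L, 1L)), "equal length")
  bad <- matrix(c(0.5, 0.2, 0.2, 0.2, 0.2, 0.2), 3, 2)
  expect_error(compute_metrics(c(0L, 1L, 0L), c(0L, 1L, 0L), bad),
               "sum to 1")
})

test_that("reports serialize to JSON and back unchanged", {
  labels <- c(0L, 1L, 1L, 0L)
  scores <- cbind(c(.8, .3, .1, .6), c(.2, .7, .9, .4))
  m <- compute_metrics(labels, c(0L, 1L, 1L, 1L), scores)
  js <- metrics_json(m)
  m2 <- metrics_from_json(js)
  expect_equal(m2$accuracy, m$accuracy)
  expect_equal(m2$f1, m$f1)
  expect_equal(m2$auc, m$auc)
  expect_identical(metrics_json(m2), js)
})

test_that("gamma grid defaults to the reference four values", {
  expect_equal(eval(formals(gamma_sweep)$gammas), c(0.01, 0.85, 3, 5))
  expect_error(gamma_sweep(mlo_config(), gammas = -1), "gamma")
})
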