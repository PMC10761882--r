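test_that("paraphrase corpora load, validate and round-trip", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsource\ttarget",
               "p1\tcovid after effects\tlong covid sequelae",
               "p2\tweather report\tforecast text"), tsv)
  corp <- load_paraphrase_corpus(tsv)
  expect_s3_class(corp, "metapara_paraphrase_corpus")
  expect_equal(nrow(corp), 2L)
  expect_equal(corp$id, c("p1", "p2"))
  expect_equal(corp$source[1], "covid after effects")

  out <- tempfile(fileext = ".jsonl")
  write_paraphrase_corpus(corp, out)
  again <- load_paraphrase_corpus(out)
  expect_identical(again$source, corp$source)
  expect_identical(again$target, corp$target)
  expect_identical(again$id, corp$id)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsource\ttarget", "p1\tsome text\t"), bad)
  expect_error(load_paraphrase_corpus(bad), "row 1")
  empty <- tempfile(fileext = ".tsv")
  writeLines("id\tsource\ttarget", empty)
  expect_error(load_paraphrase_corpus(empty), "empty")
  expect_error(load_paraphrase_corpus(tempfile()), "no such file")
})

test_that("labeled corpora infer K, map string labels by sorted order", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("id,text,label", "a,covid article,0", "b,other article,1"),
             csv)
  corp <- load_labeled_corpus(csv)
  expect_equal(attr(corp, "label_count"), 2L)

  csv2 <- tempfile(fileext = ".csv")
  writeLines(c("id,text,label", "a,first,not_long", "b,second,long",
               "c,third,long"), csv2)
  expect_message(corp2 <- load_labeled_corpus(csv2), "long=0, not_long=1")
  expect_equal(corp2$label, c(1L, 0L, 0L))

  csv3 <- tempfile(fileext = ".csv")
  writeLines(c("id,text,label", "a,first,3"), csv3)
  expect_error(load_labeled_corpus(csv3, label_count = 2), "out of range")

  out <- tempfile(fileext = ".jsonl")
  write_labeled_corpus(corp2, out)
  again <- load_labeled_corpus(out)
  expect_identical(again$text, corp2$text)
  expect_identical(again$label, corp2$label)
})

test_that("utf-8 text round-trips byte for byte", {
  txt <- "séquelles à long terme — 中文"
  corp <- labeled_corpus("x1", txt, 0L, label_count = 2L)
  for (fmt in c("csv", "jsonl")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_labeled_corpus(corp, f)
    expect_identical(load_labeled_corpus(f)$text, txt)
  }
})

test_that("split_mlo partitions deterministically with stratified counts", {
  corp <- labeled_corpus(sprintf("e%02d", 1:10), rep("tok text", 10),
                         rep(0:1, each = 5), label_count = 2L)
  sp <- split_mlo(corp, fraction = 0.8, seed = 7)
  expect_equal(nrow(sp$mlo_train), 8L)
  expect_equal(nrow(sp$mlo_val), 2L)
  expect_identical(split_mlo(corp, seed = 7), sp)
  expect_false(identical(split_mlo(corp, seed = 8), sp))

  big <- labeled_corpus(sprintf("e%02d", 1:20), rep("tok text", 20),
                        rep(0:1, each = 10), label_count = 2L)
  sp2 <- split_mlo(big, fraction = 0.8, seed = 1)
  expect_equal(as.integer(table(sp2$mlo_train$label)), c(8L, 8L))
  expect_equal(as.integer(table(sp2$mlo_val$label)), c(2L, 2L))

  # partition property across seeds and fractions
  for (seed in 1:5) for (fr in c(0.5, 0.7, 0.8)) {
    sp3 <- split_mlo(big, fraction = fr, seed = seed)
    expect_setequal(c(sp3$mlo_train$id, sp3$mlo_val$id), big$id)
    expect_length(intersect(sp3$mlo_train$id, sp3$mlo_val$id), 0)
  }
  expect_error(split_mlo(big, fraction = 1.2), "between 0 and 1")

  lone <- labeled_corpus(c("a", "b", "c", "d"), rep("txt", 4),
                         c(0L, 0L, 0L, 1L), label_count = 2L)
  expect_warning(sp4 <- split_mlo(lone, fraction = 0.7, seed = 1),
                 "single example")
  expect_true("d" %in% sp4$mlo_train$id)
  expect_gte(nrow(sp4$mlo_val), 1L)
})

test_that("generated examples keep their source labels", {
  expect_error(generated_examples("x", 0L, c("a", "b")))
  g <- generated_examples(c("x", "y"), c(1L, 0L), c("a", "b"))
  expect_equal(g$label, c(1L, 0L))
})
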