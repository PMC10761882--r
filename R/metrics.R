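# Evaluation protocol: accuracy, precision, recall, F1 and ranking AUC.
# Binary tasks default to positive-class (label 1) precision/recall/F1 and
# the standard rank AUC of the positive-class score; multi-class uses macro
# averaging and one-vs-one AUC (mean of pairwise ranking AUCs over ordered
# class pairs). Ties in the AUC are handled by midranks.

auc_rank <- function(pos, neg) {
  n1 <- length(pos); n0 <- length(neg)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(c(pos, neg))           # midranks
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics report
#'
#' @param labels integer true labels (0-based).
#' @param predictions integer predicted labels.
#' @param scores optional n x K matrix of class probabilities (rows sum to
#'   1); required for AUC.
#' @param averaging `"binary"` (positive class = label 1; K = 2 only) or
#'   `"macro"` (per-class metrics, unweighted mean).
#' @param auc_mode `"binary"` (rank AUC of the positive-class score) or
#'   `"one_vs_one"` (mean over ordered class pairs of pairwise rank AUCs).
#' @return object of class `metapara_metrics` with accuracy, precision,
#'   recall, f1, auc in [0,1], the per-class breakdown, and `n`.
#' @export
compute_metrics <- function(labels, predictions, scores = NULL,
                            averaging = c("binary", "macro"),
                            auc_mode = c("binary", "one_vs_one")) {
  averaging <- match.arg(averaging)
  auc_mode <- match.arg(auc_mode)
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  n <- length(labels)
  K <- max(labels, predictions) + 1L
  if (!is.null(scores)) {
    if (!is.matrix(scores) || nrow(scores) != n)
      stop("scores must be an n x K matrix")
    if (any(abs(rowSums(scores) - 1) > 1e-6))
      stop("score rows must sum to 1")
    K <- max(K, ncol(scores))
  }
  if (averaging == "binary" && K > 2L)
    stop("binary averaging requires a 2-class problem")
  acc <- mean(labels == predictions)
  per_class <- do.call(rbind, lapply(0:(K - 1L), function(k) {
    tp <- sum(predictions == k & labels == k)
    fp <- sum(predictions == k & labels != k)
    fn <- sum(predictions != k & labels == k)
    prec <- if (tp + fp == 0L) {
      warning("no predictions for class ", k, "; precision set to 0")
      0
    } else tp / (tp + fp)
    rec <- if (tp + fn == 0L) {
      warning("no true examples of class ", k, "; recall set to 0")
      0
    } else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = k, precision = prec, recall = rec, f1 = f1,
               support = sum(labels == k))
  }))
  if (averaging == "binary") {
    prec <- per_class$precision[2]; rec <- per_class$recall[2]
    f1 <- per_class$f1[2]
  } else {
    prec <- mean(per_class$precision); rec <- mean(per_class$recall)
    f1 <- mean(per_class$f1)
  }
  auc <- NA_real_
  if (!is.null(scores)) {
    if (auc_mode == "binary") {
      if (K != 2L) stop("binary AUC requires a 2-class problem")
      auc <- auc_rank(scores[labels == 1L, 2L], scores[labels == 0L, 2L])
    } else {
      pair_aucs <- c()
      for (i in 0:(K - 1L)) for (j in 0:(K - 1L)) {
        if (i == j) next
        a <- auc_rank(scores[labels == i, i + 1L],
                      scores[labels == j, i + 1L])
        pair_aucs <- c(pair_aucs, a)
      }
      auc <- mean(pair_aucs, na.rm = TRUE)
    }
  }
  structure(list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
                 auc = auc, averaging = averaging, auc_mode = auc_mode,
                 n = n, per_class = per_class),
            class = "metapara_metrics")
}

#' @export
print.metapara_metrics <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "   NA" else sprintf("%.2f", 100 * v)
  cat(sprintf(
    "<metapara_metrics> n=%d (%s averaging, %s AUC)\n", x$n, x$averaging,
    x$auc_mode))
  cat(sprintf("  accuracy %s  precision %s  recall %s  F1 %s  AUC %s (%%)\n",
              pct(x$accuracy), pct(x$precision), pct(x$recall), pct(x$f1),
              pct(x$auc)))
  invisible(x)
}

#' Serialize a metrics report to JSON
#' @param report a `metapara_metrics` object.
#' @param path optional file; when NULL the JSON string is returned.
#' @export
metrics_json <- function(report, path = NULL) {
  obj <- unclass(report)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                          dataframe = "columns")
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Parse a metrics report from JSON
#' @param json JSON string or file path.
#' @export
metrics_from_json <- function(json) {
  if (file.exists(json)) json <- paste(readLines(json, warn = FALSE),
                                       collapse = "\n")
  obj <- jsonlite::fromJSON(json)
  obj$per_class <- as.data.frame(obj$per_class)
  structure(obj, class = "metapara_metrics")
}

#' Evaluate a classifier on a labeled corpus
#'
#' @param C a [classifier_init()] state.
#' @param corpus a [labeled_corpus()].
#' @param averaging,auc_mode see [compute_metrics()]; chosen from the class
#'   count when NULL.
#' @return a `metapara_metrics` report.
#' @export
evaluate_classifier <- function(C, corpus, averaging = NULL,
                                auc_mode = NULL) {
  K <- label_count(corpus)
  if (is.null(averaging)) averaging <- if (K == 2L) "binary" else "macro"
  if (is.null(auc_mode)) auc_mode <- if (K == 2L) "binary" else "one_vs_one"
  scores <- predict_proba(C, corpus$text)
  preds <- max.col(scores, ties.method = "first") - 1L
  compute_metrics(corpus$label, preds, scores, averaging, auc_mode)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Train and evaluate over several seeds
#'
#' One full [train_mlo()] run per seed (the seed drives the MLO split, the
#' model initializations and all batch shuffles), evaluated on the test
#' corpus. The aggregate rows report mean and population standard deviation
#' per metric.
#'
#' @param config a [mlo_config()]; its seed field is replaced per run.
#' @param seeds integer vector.
#' @param paraphrase_corpus,train_corpus,test_corpus the task corpora.
#' @param split_fraction MLO-train share of the training set.
#' @return data.frame with one row per seed plus `mean` and `std` rows;
#'   failed seeds are flagged and excluded from the aggregates.
#' @export
seed_sweep <- function(config, seeds, paraphrase_corpus, train_corpus,
                       test_corpus, split_fraction = 0.8) {
  stopifnot(length(seeds) >= 1L)
  rows <- list()
  for (sd_ in seeds) {
    cfg <- config
    cfg$seed <- as.integer(sd_)
    res <- tryCatch({
      halves <- split_mlo(train_corpus, fraction = split_fraction,
                          seed = cfg$seed)
      fit <- train_mlo(cfg, paraphrase_corpus, halves$mlo_train,
                       halves$mlo_val, train_corpus)
      m <- evaluate_classifier(fit$classifier, test_corpus)
      data.frame(seed = sd_, accuracy = m$accuracy, precision = m$precision,
                 recall = m$recall, f1 = m$f1, auc = m$auc, failed = FALSE)
    }, error = function(e) {
      warning("seed ", sd_, " failed: ", conditionMessage(e))
      data.frame(seed = sd_, accuracy = NA_real_, precision = NA_real_,
                 recall = NA_real_, f1 = NA_real_, auc = NA_real_,
                 failed = TRUE)
    })
    rows[[length(rows) + 1L]] <- res
  }
  tab <- do.call(rbind, rows)
  ok <- tab[!tab$failed, , drop = FALSE]
  agg <- function(f, nm) {
    data.frame(seed = nm, accuracy = f(ok$accuracy),
               precision = f(ok$precision), recall = f(ok$recall),
               f1 = f(ok$f1), auc = f(ok$auc), failed = FALSE)
  }
  rbind(tab, agg(mean, NA_integer_), agg(pop_sd, NA_integer_)) ->
    out
  out$row <- c(as.character(tab$seed), "mean", "std")
  out
}

#' Sweep the generated-loss trade-off parameter
#'
#' One [seed_sweep()] per gamma value; the default grid is
#' `{0.01, 0.85, 3, 5}`.
#'
#' @param config a [mlo_config()].
#' @param gammas non-negative values to sweep.
#' @param seeds seeds per gamma.
#' @inheritParams seed_sweep
#' @return data.frame of (gamma, mean_accuracy, sd_accuracy).
#' @export
gamma_sweep <- function(config, gammas = c(0.01, 0.85, 3, 5), seeds = 1:3,
                        paraphrase_corpus, train_corpus, test_corpus) {
  if (any(gammas < 0)) stop("gamma values must be >= 0")
  rows <- lapply(gammas, function(g) {
    cfg <- config
    cfg$gamma <- g
    tab <- seed_sweep(cfg, seeds, paraphrase_corpus, train_corpus,
                      test_corpus)
    data.frame(gamma = g,
               mean_accuracy = tab$accuracy[tab$row == "mean"],
               sd_accuracy = tab$accuracy[tab$row == "std"])
  })
  do.call(rbind, rows)
}
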