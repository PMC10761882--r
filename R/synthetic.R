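# Synthetic two-domain benchmark.
#
# Two disjoint token vocabularies: domain A carries the downstream
# classification task, domain B is off-domain. Classification texts are
# domain-A strings whose label is determined by which of K signal-token
# groups they contain; paraphrase pairs apply a fixed bijective synonym map
# within one domain (a share of pairs from A, the rest from B). Off-domain
# pairs contain no signal tokens and share no vocabulary with the task, so
# their value for the downstream classifier is lower by construction - the
# premise the meta-weight network must discover. Deterministic substitution
# paraphrases give the teacher-forcing loss a known floor of zero.

#' Specification of the synthetic two-domain task
#'
#' Defaults give the desk-scale profile: 30 + 30 tokens, 4 signal tokens
#' (one synonym pair per class), 60 paraphrase pairs (half in-domain),
#' 120/40/80 train/val/test, text lengths 6-12, two classes, 10% token
#' noise.
#'
#' @param vocab_size_per_domain tokens per domain.
#' @param n_signal_tokens label-determining tokens in domain A; must be an
#'   even multiple of `label_count` so synonym pairs stay within a class
#'   group (paraphrasing then provably preserves labels).
#' @param n_paraphrase_pairs total paraphrase pairs.
#' @param in_domain_fraction share of pairs built from domain A.
#' @param n_train,n_val,n_test classification split sizes.
#' @param len_min,len_max text length range in tokens.
#' @param label_count number of classes K.
#' @param noise_rate probability that a token is replaced by a uniformly
#'   random in-domain token.
#' @param n_signal_per_text signal tokens planted per classification text.
#' @param seed generator seed.
#' @return object of class `metapara_synth_spec`.
#' @export
synthetic_spec <- function(vocab_size_per_domain = 30L, n_signal_tokens = 4L,
                           n_paraphrase_pairs = 60L,
                           in_domain_fraction = 0.5, n_train = 120L,
                           n_val = 40L, n_test = 80L, len_min = 6L,
                           len_max = 12L, label_count = 2L,
                           noise_rate = 0.1, n_signal_per_text = 2L,
                           seed = 1L) {
  stopifnot(vocab_size_per_domain >= 1L, n_signal_tokens >= 1L,
            n_paraphrase_pairs >= 1L, n_train >= 1L, n_val >= 1L,
            n_test >= 1L, len_min >= 1L, len_max >= len_min,
            label_count >= 2L, n_signal_per_text >= 1L)
  if (in_domain_fraction < 0 || in_domain_fraction > 1)
    stop("in_domain_fraction must lie in [0, 1]")
  if (noise_rate < 0 || noise_rate >= 1)
    stop("noise_rate must lie in [0, 1)")
  per <- n_signal_tokens / label_count
  if (per != round(per) || per %% 2 != 0)
    stop("n_signal_tokens must be an even multiple of label_count")
  if (vocab_size_per_domain <= n_signal_tokens)
    stop("vocab_size_per_domain must exceed n_signal_tokens")
  structure(as.list(environment()), class = "metapara_synth_spec")
}

# bijective synonym map: consecutive tokens are paired (1<->2, 3<->4, ...);
# an odd trailing token maps to itself
synonym_map <- function(tokens) {
  n <- length(tokens)
  idx <- seq_len(n)
  partner <- ifelse(idx %% 2 == 1L, pmin(idx + 1L, n), idx - 1L)
  stats::setNames(tokens[partner], tokens)
}

apply_synonyms <- function(text, map) {
  toks <- tokenize(text)
  paste(unname(map[toks]), collapse = " ")
}

synth_tokens <- function(spec) {
  v <- spec$vocab_size_per_domain
  list(A = sprintf("a%02d", seq_len(v)), B = sprintf("b%02d", seq_len(v)))
}

synth_groups <- function(spec, tokens_A) {
  per <- spec$n_signal_tokens %/% spec$label_count
  lapply(seq_len(spec$label_count), function(g)
    tokens_A[((g - 1L) * per + 1L):(g * per)])
}

# one domain-A text for a given 0-based label: background tokens plus
# planted signal tokens of the label's group, then token-level noise
synth_text_A <- function(spec, label, tokens_A, groups, noisy = TRUE) {
  len <- sample(spec$len_min:spec$len_max, 1L)
  background <- tokens_A[-seq_len(spec$n_signal_tokens)]
  toks <- sample(background, len, replace = TRUE)
  pos <- sample(len, min(spec$n_signal_per_text, len))
  toks[pos] <- sample(groups[[label + 1L]], length(pos), replace = TRUE)
  if (noisy && spec$noise_rate > 0) {
    hit <- stats::runif(len) < spec$noise_rate
    toks[hit] <- sample(tokens_A, sum(hit), replace = TRUE)
  }
  paste(toks, collapse = " ")
}

synth_labeled <- function(spec, n, tokens_A, groups, prefix, role) {
  labels <- sample(rep_len(0:(spec$label_count - 1L), n))
  texts <- vapply(labels, function(y)
    synth_text_A(spec, y, tokens_A, groups), "")
  labeled_corpus(sprintf("%s%04d", prefix, seq_len(n)), texts, labels,
                 label_count = spec$label_count, role = role)
}

#' Generate the synthetic two-domain task
#'
#' @param spec a [synthetic_spec()].
#' @return list with `paraphrase` (tagged [paraphrase_corpus()]), `train`,
#'   `val`, `test` ([labeled_corpus()]s), the shared `vocab`, the synonym
#'   maps, the signal-token `groups`, and `spec`.
#' @export
make_synthetic_task <- function(spec) {
  stopifnot(inherits(spec, "metapara_synth_spec"))
  toks <- synth_tokens(spec)
  groups <- synth_groups(spec, toks$A)
  maps <- list(A = synonym_map(toks$A), B = synonym_map(toks$B))
  with_seed(spec$seed, {
    train <- synth_labeled(spec, spec$n_train, toks$A, groups, "tr", "train")
    val <- synth_labeled(spec, spec$n_val, toks$A, groups, "va", "val")
    test <- synth_labeled(spec, spec$n_test, toks$A, groups, "te", "test")
    n_in <- round(spec$in_domain_fraction * spec$n_paraphrase_pairs)
    n_off <- spec$n_paraphrase_pairs - n_in
    src_in <- vapply(seq_len(n_in), function(i)
      synth_text_A(spec, (i - 1L) %% spec$label_count, toks$A, groups,
                   noisy = FALSE), "")
    src_off <- vapply(seq_len(n_off), function(i) {
      len <- sample(spec$len_min:spec$len_max, 1L)
      paste(sample(toks$B, len, replace = TRUE), collapse = " ")
    }, "")
    src <- c(src_in, src_off)
    tgt <- c(vapply(src_in, apply_synonyms, "", map = maps$A),
             vapply(src_off, apply_synonyms, "", map = maps$B))
    tag <- rep(c("in_domain", "off_domain"), c(n_in, n_off))
    ord <- sample(length(src))
    pairs <- paraphrase_corpus(sprintf("p%04d", seq_along(src)),
                               src[ord], tgt[ord], domain_tag = tag[ord])
  })
  vocab <- vocab_build(extra_tokens = c(toks$A, toks$B))
  list(paraphrase = pairs, train = train, val = val, test = test,
       vocab = vocab, synonyms = maps, groups = groups, spec = spec)
}

#' Label-rule predictions on texts
#'
#' Applies the generating rule: count each class group's signal tokens and
#' predict the argmax (ties and signal-free texts resolve to the lowest
#' class index).
#'
#' @param task a [make_synthetic_task()] result.
#' @param texts character vector.
#' @return integer vector of 0-based predictions.
#' @export
bayes_rule_predict <- function(task, texts) {
  vapply(texts, function(tx) {
    toks <- tokenize(tx)
    counts <- vapply(task$groups, function(g) sum(toks %in% g), numeric(1))
    which.max(counts) - 1L
  }, integer(1), USE.NAMES = FALSE)
}

#' Accuracy ceiling of the generating label rule
#'
#' Accuracy of the signal-group majority rule on a (possibly noised)
#' corpus generated by [make_synthetic_task()] - the ceiling any classifier
#' trained on the noised texts can approach.
#'
#' @param task a [make_synthetic_task()] result.
#' @param corpus one of the task's labeled corpora.
#' @return accuracy in [0, 1].
#' @export
bayes_reference_accuracy <- function(task, corpus) {
  mean(bayes_rule_predict(task, corpus$text) == corpus$label)
}
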