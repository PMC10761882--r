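# Corpus containers and file formats.
#
# Paraphrase corpora hold (source, target) text pairs used to train the
# paraphraser; labeled corpora hold (text, label) records for the downstream
# classifier. Both are data.frame-backed S3 objects with stable row order.
# On-disk formats: TSV/JSONL for pairs, CSV/JSONL for labeled records, all
# UTF-8.

#' Construct a paraphrase corpus
#'
#' @param id character vector of unique pair ids.
#' @param source,target character vectors; non-empty after whitespace
#'   stripping.
#' @param domain_tag optional factor-like vector with levels `in_domain` /
#'   `off_domain` (synthetic fixtures only; the trainer never reads it).
#' @return object of class `metapara_paraphrase_corpus` (a data.frame).
#' @export
paraphrase_corpus <- function(id, source, target, domain_tag = NULL) {
  id <- as.character(id)
  source <- trimws(as.character(source))
  target <- trimws(as.character(target))
  n <- length(id)
  if (n < 1L) stop("empty paraphrase corpus: need at least one pair")
  if (length(source) != n || length(target) != n)
    stop("id, source and target must have equal length")
  bad <- which(!nzchar(source) | !nzchar(target))
  if (length(bad))
    stop(sprintf("paraphrase pair at row %d has an empty source or target",
                 bad[1]))
  if (anyDuplicated(id))
    stop("duplicate pair id: ", id[duplicated(id)][1])
  if (!is.null(domain_tag)) {
    domain_tag <- as.character(domain_tag)
    stopifnot(all(domain_tag %in% c("in_domain", "off_domain")))
  }
  df <- data.frame(id = id, source = source, target = target,
                   stringsAsFactors = FALSE)
  if (!is.null(domain_tag)) df$domain_tag <- domain_tag
  class(df) <- c("metapara_paraphrase_corpus", "data.frame")
  df
}

#' Construct a labeled corpus
#'
#' @param id character vector of ids.
#' @param text character vector of documents (non-empty).
#' @param label integer vector in `[0, label_count)`.
#' @param label_count number of classes K (>= 2); inferred as
#'   `max(label) + 1` when `NULL`.
#' @param role one of train, val, mlo_train, mlo_val, test.
#' @return object of class `metapara_labeled_corpus`.
#' @export
labeled_corpus <- function(id, text, label, label_count = NULL,
                           role = c("train", "val", "mlo_train", "mlo_val",
                                    "test")) {
  role <- match.arg(role)
  id <- as.character(id)
  text <- trimws(as.character(text))
  if (length(id) < 1L) stop("empty labeled corpus")
  if (any(!nzchar(text)))
    stop(sprintf("labeled example at row %d has empty text",
                 which(!nzchar(text))[1]))
  label <- as.integer(label)
  if (anyNA(label)) stop("labels must be integers (or mappable strings)")
  if (is.null(label_count)) label_count <- max(max(label) + 1L, 2L)
  label_count <- as.integer(label_count)
  if (label_count < 2L) stop("label_count must be >= 2")
  if (any(label < 0L | label >= label_count))
    stop(sprintf("label %d out of range [0, %d)",
                 label[label < 0L | label >= label_count][1], label_count))
  df <- data.frame(id = id, text = text, label = label,
                   stringsAsFactors = FALSE)
  attr(df, "label_count") <- label_count
  attr(df, "role") <- role
  class(df) <- c("metapara_labeled_corpus", "data.frame")
  df
}

label_count <- function(corpus) attr(corpus, "label_count")

# subset rows, keeping attributes
labeled_subset <- function(corpus, idx, role = attr(corpus, "role")) {
  labeled_corpus(corpus$id[idx], corpus$text[idx], corpus$label[idx],
                 label_count = label_count(corpus), role = role)
}

read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, jsonlite::fromJSON)
}

write_jsonl <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in records)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  invisible(path)
}

guess_format <- function(path, choices) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% choices) ext else choices[1]
}

#' Load a paraphrase corpus from TSV or JSONL
#'
#' TSV layout: header `id<TAB>source<TAB>target`. JSONL: one
#' `{"id","source","target"}` object per line. Ids default to the row index
#' when absent.
#'
#' @param path file path.
#' @param format `"tsv"` or `"jsonl"`; guessed from the extension by default.
#' @return a [paraphrase_corpus()].
#' @export
load_paraphrase_corpus <- function(path, format = c("auto", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") format <- guess_format(path, c("tsv", "jsonl"))
  if (format == "tsv") {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "",
                            encoding = "UTF-8", check.names = FALSE)
    if (!all(c("source", "target") %in% names(df)))
      stop("TSV must have 'source' and 'target' columns")
    if (nrow(df) == 0L) stop("empty paraphrase corpus: ", path)
    ids <- if ("id" %in% names(df)) df$id else as.character(seq_len(nrow(df)))
    paraphrase_corpus(ids, df$source, df$target,
                      domain_tag = df[["domain_tag"]])
  } else {
    recs <- read_jsonl(path)
    if (length(recs) == 0L) stop("empty paraphrase corpus: ", path)
    get <- function(rec, field, i) {
      if (is.null(rec[[field]]))
        stop(sprintf("record %d is missing field '%s'", i, field))
      rec[[field]]
    }
    ids <- vapply(seq_along(recs), function(i)
      as.character(if (is.null(recs[[i]]$id)) i else recs[[i]]$id), "")
    src <- vapply(seq_along(recs), function(i)
      as.character(get(recs[[i]], "source", i)), "")
    tgt <- vapply(seq_along(recs), function(i)
      as.character(get(recs[[i]], "target", i)), "")
    tags <- vapply(recs, function(r)
      if (is.null(r$domain_tag)) NA_character_ else r$domain_tag, "")
    paraphrase_corpus(ids, src, tgt,
                      domain_tag = if (all(is.na(tags))) NULL else tags)
  }
}

#' Write a paraphrase corpus
#' @param corpus a [paraphrase_corpus()].
#' @param path destination file.
#' @param format `"tsv"` or `"jsonl"`.
#' @export
write_paraphrase_corpus <- function(corpus, path,
                                    format = c("auto", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path, c("tsv", "jsonl"))
  if (format == "tsv") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    cols <- intersect(c("id", "source", "target", "domain_tag"), names(corpus))
    writeLines(paste(cols, collapse = "\t"), con)
    for (i in seq_len(nrow(corpus)))
      writeLines(paste(vapply(cols, function(cl) corpus[[cl]][i], ""),
                       collapse = "\t"), con)
  } else {
    write_jsonl(lapply(seq_len(nrow(corpus)), function(i)
      as.list(corpus[i, , drop = FALSE])), path)
  }
  invisible(path)
}

#' Load a labeled corpus from CSV or JSONL
#'
#' CSV layout: header `id,text,label`. String labels are mapped to integers
#' by lexicographic order (deterministic and dataset-independent); the mapping
#' is reported via [message()].
#'
#' @param path file path.
#' @param format `"csv"` or `"jsonl"`.
#' @param label_count optional K; inferred as max label + 1 when absent.
#' @param role corpus role tag.
#' @return a [labeled_corpus()].
#' @export
load_labeled_corpus <- function(path, format = c("auto", "csv", "jsonl"),
                                label_count = NULL, role = "train") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") format <- guess_format(path, c("csv", "jsonl"))
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          encoding = "UTF-8", check.names = FALSE)
    if (!all(c("text", "label") %in% names(df)))
      stop("CSV must have 'text' and 'label' columns")
    ids <- if ("id" %in% names(df)) df$id else as.character(seq_len(nrow(df)))
    raw_labels <- df$label
    texts <- df$text
  } else {
    recs <- read_jsonl(path)
    if (length(recs) == 0L) stop("empty labeled corpus: ", path)
    ids <- vapply(seq_along(recs), function(i)
      as.character(if (is.null(recs[[i]]$id)) i else recs[[i]]$id), "")
    texts <- vapply(recs, function(r) as.character(r$text), "")
    raw_labels <- vapply(recs, function(r) as.character(r$label), "")
  }
  labels <- suppressWarnings(as.integer(raw_labels))
  if (anyNA(labels)) {
    levels <- sort(unique(raw_labels))
    labels <- match(raw_labels, levels) - 1L
    message("label mapping: ",
            paste(sprintf("%s=%d", levels, seq_along(levels) - 1L),
                  collapse = ", "))
  }
  labeled_corpus(ids, texts, labels, label_count = label_count, role = role)
}

#' Write a labeled corpus
#' @param corpus a [labeled_corpus()].
#' @param path destination file.
#' @param format `"csv"` or `"jsonl"`.
#' @export
write_labeled_corpus <- function(corpus, path,
                                 format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path, c("csv", "jsonl"))
  if (format == "csv") {
    df <- data.frame(id = corpus$id, text = corpus$text, label = corpus$label)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    write_jsonl(lapply(seq_len(nrow(corpus)), function(i)
      list(id = corpus$id[i], text = corpus$text[i],
           label = corpus$label[i])), path)
  }
  invisible(path)
}

#' Split a training corpus into MLO-train and MLO-val
#'
#' Deterministic, by default stratified, partition of the training set: an
#' 80% share drives the inner model updates (MLO-train) and the remaining 20%
#' provides the validation signal that trains the meta-weight network
#' (MLO-val). Per-label counts go to `round(fraction * n_k)` with the
#' rounding remainder assigned to MLO-train.
#'
#' @param corpus a [labeled_corpus()] with role train.
#' @param fraction share assigned to MLO-train, in (0,1).
#' @param seed integer seed controlling the shuffle.
#' @param stratified split each label separately (default) so that small
#'   classes are represented on both sides.
#' @return list with elements `mlo_train` and `mlo_val`.
#' @export
split_mlo <- function(corpus, fraction = 0.8, seed = 1L, stratified = TRUE) {
  stopifnot(inherits(corpus, "metapara_labeled_corpus"))
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must lie strictly between 0 and 1")
  n <- nrow(corpus)
  take_tr <- logical(n)
  with_seed(seed, {
    groups <- if (stratified) split(seq_len(n), corpus$label)
              else list(seq_len(n))
    for (idx in groups) {
      if (stratified && length(idx) == 1L) {
        warning("label ", corpus$label[idx], " has a single example; ",
                "assigning it to mlo_train")
        take_tr[idx] <- TRUE
        next
      }
      k <- round(fraction * length(idx))
      perm <- sample(idx)
      take_tr[perm[seq_len(k)]] <- TRUE
    }
  })
  if (n >= 2L) {
    if (all(take_tr)) {
      warning("rounding left mlo_val empty; moving one example over")
      take_tr[max(which(take_tr))] <- FALSE
    } else if (!any(take_tr)) {
      warning("rounding left mlo_train empty; moving one example over")
      take_tr[min(which(!take_tr))] <- TRUE
    }
  }
  list(mlo_train = labeled_subset(corpus, which(take_tr), role = "mlo_train"),
       mlo_val = labeled_subset(corpus, which(!take_tr), role = "mlo_val"))
}

#' Construct generated (augmented) examples
#'
#' Each augmentation inherits the label of its source example; `source_id`
#' resolves back to the originating record.
#' @param text generated texts.
#' @param label inherited labels.
#' @param source_id ids of the source examples.
#' @export
generated_examples <- function(text, label, source_id) {
  stopifnot(length(text) == length(label), length(label) == length(source_id))
  data.frame(text = as.character(text), label = as.integer(label),
             source_id = as.character(source_id), stringsAsFactors = FALSE)
}
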