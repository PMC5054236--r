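#' Tokenize free text
#'
#' Lowercases, strips punctuation (including `%`), and splits on anything
#' that is not a letter or digit. Digit-bearing tokens are kept: "95% CI"
#' tokenizes to `c("95", "ci")`, so statistics-reporting bigrams like
#' "95 ci" survive featurization.
#'
#' @param text A character scalar (or vector; results are concatenated per
#'   element and returned as a list for vectors).
#' @return Character vector of tokens; `character(0)` for empty text.
#' @export
#' @examples
#' tokenize("Magnetic resonance imaging.")
tokenize <- function(text) {
  if (length(text) != 1L) return(lapply(text, tokenize))
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  toks <- strsplit(gsub("[^a-z0-9]+", " ", x), " ", fixed = TRUE)[[1L]]
  toks[nzchar(toks)]
}

## MeSH heading -> feature body: lowercase, internal whitespace -> hyphens;
## qualifier slashes ("england/epidemiology") kept verbatim
mesh_token <- function(heading) {
  gsub("\\s+", "-", tolower(trimws(heading)))
}

#' Featurization configuration
#'
#' Controls the n-gram order, contributing fields, and the frequency filters
#' applied when building a vocabulary: features must appear in at least
#' `min_df` citations, and at most the `max_features` most frequent features
#' are kept. Defaults are min_df = 2 and a 50,000-feature cap.
#'
#' Feature naming: title terms are emitted both with a `TI-` prefix and as
#' plain terms (titles contribute to the shared unprefixed text stream);
#' abstract terms are plain; each MeSH heading becomes one `MH-` feature
#' (lowercased, spaces to hyphens) plus `MH-` bigrams over adjacent
#' headings. Bigrams never span field boundaries, and stop words are removed
#' before n-gram formation.
#'
#' @param ngram_mode `"uni_and_bigram"` (discriminative model) or
#'   `"unigram_only"` (topic-model vocabulary).
#' @param fields Subset of `c("title", "abstract", "mesh")`.
#' @param min_df Minimum document frequency (integer >= 1).
#' @param max_features Cap on vocabulary size.
#' @param stopwords Lowercase words removed from title/abstract token
#'   streams before n-gram formation.
#' @param emit_plain_title Emit unprefixed copies of title terms alongside
#'   the `TI-` forms (default `TRUE`).
#' @return A `feature_config` list.
#' @export
feature_config <- function(ngram_mode = c("uni_and_bigram", "unigram_only"),
                           fields = c("title", "abstract", "mesh"),
                           min_df = 2L, max_features = 50000L,
                           stopwords = english_stopwords(),
                           emit_plain_title = TRUE) {
  ngram_mode <- match.arg(ngram_mode)
  fields <- match.arg(fields, c("title", "abstract", "mesh"),
                      several.ok = TRUE)
  min_df <- as.integer(min_df)
  if (is.na(min_df) || min_df < 1L) stop("min_df must be >= 1")
  structure(list(ngram_mode = ngram_mode, fields = fields, min_df = min_df,
                 max_features = as.integer(max_features),
                 stopwords = stopwords,
                 emit_plain_title = isTRUE(emit_plain_title)),
            class = "feature_config")
}

config_fingerprint <- function(config) {
  paste(config$ngram_mode, paste(sort(config$fields), collapse = "+"),
        config$min_df, config$max_features, length(config$stopwords),
        config$emit_plain_title, sep = "|")
}

bigrams <- function(tokens) {
  n <- length(tokens)
  if (n < 2L) return(character(0))
  paste(tokens[-n], tokens[-1L])
}

## the multiset of feature instances emitted by one citation, as a character
## vector with repeats (order not meaningful)
feature_stream <- function(title, abstract, mesh_terms, config) {
  out <- character(0)
  bi <- config$ngram_mode == "uni_and_bigram"
  if ("title" %in% config$fields) {
    toks <- setdiff_keep(tokenize(title), config$stopwords)
    pre <- paste0("TI-", toks, recycle0 = TRUE)
    out <- c(out, pre, if (bi) bigrams(pre))
    if (config$emit_plain_title) {
      out <- c(out, toks, if (bi) bigrams(toks))
    }
  }
  if ("abstract" %in% config$fields) {
    toks <- setdiff_keep(tokenize(abstract), config$stopwords)
    out <- c(out, toks, if (bi) bigrams(toks))
  }
  if ("mesh" %in% config$fields && length(mesh_terms) > 0L) {
    mh <- paste0("MH-", mesh_token(mesh_terms[nzchar(trimws(mesh_terms))]),
                 recycle0 = TRUE)
    out <- c(out, mh, if (bi) bigrams(mh))
  }
  out
}

## remove stop words, preserving order and duplicates of the rest
setdiff_keep <- function(tokens, stopwords) tokens[!(tokens %in% stopwords)]

## counts of unique integer indices without string coercion
tabulate_sparse <- function(idx) {
  s <- sort.int(idx, method = "radix")
  r <- rle(s)
  list(j = r$values, x = r$lengths)
}

#' Extract features from a single citation
#'
#' @param cit A one-row citation tibble (see [citation_record()]) or a list with
#'   `title`, `abstract`, `mesh_terms` entries.
#' @param config A [feature_config()].
#' @return Named integer vector of feature counts (empty for a citation with
#'   no usable text).
#' @export
#' @examples
#' extract_features(citation_record("x", title = "A study of outcomes",
#'                           mesh_terms = c("Great Britain", "Humans")),
#'                  feature_config())
extract_features <- function(cit, config = feature_config()) {
  if (is.data.frame(cit)) {
    stream <- feature_stream(cit$title[1L], cit$abstract[1L],
                             cit$mesh_terms[[1L]], config)
  } else {
    stream <- feature_stream(cit$title %||% "", cit$abstract %||% "",
                             cit$mesh_terms %||% character(), config)
  }
  if (length(stream) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(stream)
  stats::setNames(as.integer(tab), names(tab))
}

corpus_streams <- function(corpus, config) {
  cit <- corpus$citations
  lapply(seq_len(nrow(cit)), function(i) {
    feature_stream(cit$title[i], cit$abstract[i], cit$mesh_terms[[i]], config)
  })
}

#' Build a vocabulary from a corpus
#'
#' Applies the frequency filters of `config`: features occurring in fewer
#' than `min_df` citations are dropped; if more than `max_features` remain,
#' the `max_features` with the highest total corpus count are kept (ties
#' broken lexicographically). The final feature order is lexicographic,
#' making the vocabulary a deterministic function of (corpus, config).
#'
#' @param corpus A `news_corpus`.
#' @param config A [feature_config()].
#' @return A `news_vocabulary`: list with `features`, `document_frequency`,
#'   `total_count`, and a `config` fingerprint.
#' @export
build_vocabulary <- function(corpus, config = feature_config()) {
  streams <- corpus_streams(corpus, config)
  df_tab <- table(unlist(lapply(streams, unique), use.names = FALSE))
  tot_tab <- table(unlist(streams, use.names = FALSE))
  keep <- names(df_tab)[as.integer(df_tab) >= config$min_df]
  if (length(keep) == 0L) {
    stop("no features survive the min_df filter; corpus too small?")
  }
  if (length(keep) > config$max_features) {
    tot <- as.integer(tot_tab[keep])
    ## highest total frequency first, ties lexicographic
    ord <- order(-tot, keep, method = "radix")
    keep <- keep[ord[seq_len(config$max_features)]]
  }
  keep <- sort(keep, method = "radix")
  structure(list(
    features = keep,
    document_frequency = as.integer(df_tab[keep]),
    total_count = as.integer(tot_tab[keep]),
    config = config_fingerprint(config),
    config_full = config
  ), class = "news_vocabulary")
}

#' @export
print.news_vocabulary <- function(x, ...) {
  cat(sprintf("<news_vocabulary> %d features (config %s)\n",
              length(x$features), x$config))
  invisible(x)
}

#' Vectorize a corpus against a vocabulary
#'
#' @param corpus A `news_corpus`; rows of the result follow citation order.
#' @param vocab A [build_vocabulary()] result; columns follow its feature
#'   order. Out-of-vocabulary features are ignored.
#' @param config The [feature_config()] to extract with; defaults to the
#'   configuration stored in `vocab` (a differing fingerprint is an error).
#' @return A sparse integer count matrix (`dgCMatrix`, citations x
#'   features) with dimnames.
#' @export
vectorize <- function(corpus, vocab, config = NULL) {
  stopifnot(inherits(vocab, "news_vocabulary"))
  if (is.null(config)) {
    config <- vocab$config_full
  } else if (config_fingerprint(config) != vocab$config) {
    stop("feature_config does not match the configuration the vocabulary ",
         "was built with")
  }
  streams <- corpus_streams(corpus, config)
  triplets <- lapply(seq_along(streams), function(i) {
    idx <- match(streams[[i]], vocab$features)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) return(NULL)
    tab <- tabulate_sparse(idx)
    list(i = rep.int(i, length(tab$j)), j = tab$j, x = tab$x)
  })
  triplets <- Filter(Negate(is.null), triplets)
  ii <- unlist(lapply(triplets, `[[`, "i"), use.names = FALSE) %||% integer(0)
  jj <- unlist(lapply(triplets, `[[`, "j"), use.names = FALSE) %||% integer(0)
  xx <- unlist(lapply(triplets, `[[`, "x"), use.names = FALSE) %||% integer(0)
  Matrix::sparseMatrix(
    i = ii, j = jj, x = xx,
    dims = c(length(streams), length(vocab$features)),
    dimnames = list(corpus$citations$id, vocab$features)
  )
}

#' Write a feature matrix in MatrixMarket format
#'
#' Writes `<path>.mtx` (sparse coordinate MatrixMarket via
#' [Matrix::writeMM()]) plus `<path>.rows` and `<path>.cols`, one id /
#' feature name per line, preserving the citation and vocabulary order.
#'
#' @param X A sparse feature matrix from [vectorize()].
#' @param path Output path stem (without extension).
#' @return The `.mtx` path, invisibly.
#' @export
write_feature_matrix <- function(X, path) {
  Matrix::writeMM(methods::as(X, "CsparseMatrix"), paste0(path, ".mtx"))
  writeLines(rownames(X) %||% as.character(seq_len(nrow(X))),
             paste0(path, ".rows"))
  writeLines(colnames(X) %||% as.character(seq_len(ncol(X))),
             paste0(path, ".cols"))
  invisible(paste0(path, ".mtx"))
}

#' Write a vocabulary as TSV
#'
#' Two columns: feature and document frequency (plus total count).
#' @param vocab A `news_vocabulary`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  df <- data.frame(feature = vocab$features,
                   document_frequency = vocab$document_frequency,
                   total_count = vocab$total_count)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
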