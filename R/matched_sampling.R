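#' Specification for matched negative sampling
#'
#' Negatives are drawn for each positive from pool citations that agree on
#' the match keys, up to `max_per_positive` per positive. The study designs
#' this mirrors: up to 10 same-journal/same-issue articles per press-released
#' article, same-journal/same-year matching for the JAMA-style corpus, and up
#' to 20 same-journal/year/volume articles per covered article for the
#' Reuters-style corpus.
#'
#' @param match_keys Ordered subset of `c("journal", "issue", "year")`.
#' @param max_per_positive Positive integer cap on negatives per positive.
#' @param seed Integer seed; identical seeds give identical samples.
#' @return A `match_spec` list.
#' @export
match_spec <- function(match_keys = c("journal", "issue"),
                       max_per_positive = 10L, seed = 1L) {
  match_keys <- match.arg(match_keys, c("journal", "issue", "year"),
                          several.ok = TRUE)
  if (length(match_keys) == 0L) stop("match_keys must be non-empty")
  max_per_positive <- as.integer(max_per_positive)
  if (is.na(max_per_positive) || max_per_positive < 1L) {
    stop("max_per_positive must be >= 1")
  }
  structure(list(match_keys = match_keys,
                 max_per_positive = max_per_positive,
                 seed = as.integer(seed)),
            class = "match_spec")
}

## exact-equality match key after whitespace trimming and case folding
fold_key <- function(citations, keys) {
  parts <- lapply(keys, function(k) tolower(trimws(as.character(citations[[k]]))))
  do.call(paste, c(parts, sep = "\r"))
}

#' Sample matched negatives for a set of positives
#'
#' For each positive (processed in corpus order), samples uniformly without
#' replacement from the pool citations that agree on all match keys. A pool
#' citation already sampled for an earlier positive is removed from later
#' eligible sets, so the returned negative corpus is duplicate-free (global
#' sampling without replacement). Positives with an empty eligible set
#' contribute zero negatives and are reported via a warning.
#'
#' @param positives A `news_corpus` (or citation tibble) of positive
#'   instances.
#' @param pool A `news_corpus` (or citation tibble) of unlabeled or negative
#'   candidate citations; must share no id with the positives.
#' @param spec A [match_spec()].
#' @return A list with `negatives` (a `news_corpus`, all labels
#'   `"negative"`) and `provenance` (named list mapping each positive id to
#'   the character vector of sampled negative ids).
#' @export
sample_matched_negatives <- function(positives, pool, spec) {
  stopifnot(inherits(spec, "match_spec"))
  pos <- if (inherits(positives, "news_corpus")) positives$citations else
    tibble::as_tibble(positives)
  pl <- if (inherits(pool, "news_corpus")) pool$citations else
    tibble::as_tibble(pool)
  if (any(pl$label == "positive")) {
    stop("pool citations must be unlabeled or negative")
  }
  if (any(pl$id %in% pos$id)) {
    stop("pool shares citation ids with the positive set")
  }
  pos_key <- fold_key(pos, spec$match_keys)
  pool_key <- fold_key(pl, spec$match_keys)
  pool_by_key <- split(seq_len(nrow(pl)), pool_key)

  taken <- logical(nrow(pl))
  provenance <- stats::setNames(vector("list", nrow(pos)), pos$id)
  n_empty <- 0L
  with_seed(spec$seed, {
    for (i in seq_len(nrow(pos))) {
      eligible <- pool_by_key[[pos_key[i]]]
      eligible <- eligible[!taken[eligible]]
      if (length(eligible) == 0L) {
        provenance[[i]] <- character(0)
        n_empty <- n_empty + 1L
        next
      }
      n_take <- min(spec$max_per_positive, length(eligible))
      pick <- if (length(eligible) == 1L) eligible else
        sample(eligible, n_take)
      taken[pick] <- TRUE
      provenance[[i]] <- pl$id[pick]
    }
  })
  if (n_empty > 0L) {
    warning(n_empty, " positive(s) had no eligible pool citations")
  }
  neg <- pl[taken, , drop = FALSE]
  ## preserve pool order for determinism of the output corpus
  neg$label <- "negative"
  list(
    negatives = news_corpus(neg),
    provenance = provenance
  )
}
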