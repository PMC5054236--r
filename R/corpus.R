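#' Construct a single citation record
#'
#' A citation is one scholarly article: its free-text fields, the keys used
#' for matched sampling (journal / year / issue), and a newsworthiness label.
#'
#' @param id Unique identifier string (e.g. a PMID).
#' @param title,abstract Free text; may be empty strings.
#' @param mesh_terms Character vector of MeSH heading strings (may be empty).
#' @param journal Journal name.
#' @param year Publication year (integer).
#' @param issue Issue/volume identifier; treated as an opaque string, may be
#'   empty.
#' @param label One of `"positive"`, `"negative"`, `"unlabeled"`.
#' @param source_tag Dataset name string, e.g. `"sumner_pr"`.
#' @return A one-row [tibble::tibble()] with a `mesh_terms` list column.
#' @export
#' @examples
#' citation_record("pmid1", title = "A cohort study", label = "positive")
citation_record <- function(id, title = "", abstract = "", mesh_terms = character(),
                     journal = "", year = NA_integer_, issue = "",
                     label = "unlabeled", source_tag = "") {
  label <- match.arg(label, c("positive", "negative", "unlabeled"))
  tibble::tibble(
    id = as.character(id), title = as.character(title),
    abstract = as.character(abstract), mesh_terms = list(as.character(mesh_terms)),
    journal = as.character(journal), year = as.integer(year),
    issue = as.character(issue), label = label,
    source_tag = as.character(source_tag)
  )
}

citation_cols <- c("id", "title", "abstract", "mesh_terms", "journal",
                   "year", "issue", "label", "source_tag")

#' Build a labeled corpus from citation records
#'
#' A corpus is an ordered collection of citations; the order is stable and
#' defines the row order of every downstream matrix. `task` distinguishes the
#' press-release-issuance (`"PR"`) and news-coverage (`"NC"`) modeling tasks;
#' `feature_source = "press_release"` (text taken from the press release
#' rather than the article) is only meaningful for NC.
#'
#' @param citations A tibble/data.frame of citation rows (see [citation_record()]),
#'   or a list of one-row citation tibbles.
#' @param task `"PR"`, `"NC"`, or `NA`.
#' @param feature_source `"article"` (default) or `"press_release"`.
#' @return An object of class `news_corpus`.
#' @export
news_corpus <- function(citations, task = NA_character_,
                        feature_source = "article") {
  if (is.list(citations) && !is.data.frame(citations)) {
    citations <- do.call(rbind, citations)
  }
  citations <- tibble::as_tibble(citations)
  missing_cols <- setdiff(citation_cols, names(citations))
  if ("mesh_terms" %in% missing_cols) {
    citations$mesh_terms <- replicate(nrow(citations), character(), simplify = FALSE)
    missing_cols <- setdiff(missing_cols, "mesh_terms")
  }
  for (col in setdiff(missing_cols, c("id", "label"))) {
    citations[[col]] <- if (col == "year") NA_integer_ else ""
  }
  if (!all(c("id", "label") %in% names(citations))) {
    stop("corpus requires 'id' and 'label' columns")
  }
  citations <- citations[, citation_cols]
  if (anyDuplicated(citations$id)) {
    stop("citation ids must be unique within a corpus")
  }
  if (!all(citations$label %in% c("positive", "negative", "unlabeled"))) {
    stop("labels must be 'positive', 'negative' or 'unlabeled'")
  }
  if (!is.na(task)) task <- match.arg(task, c("PR", "NC"))
  feature_source <- match.arg(feature_source, c("article", "press_release"))
  if (feature_source == "press_release" && (is.na(task) || task != "NC")) {
    stop("feature_source = 'press_release' is only permitted for task = 'NC'")
  }
  structure(
    list(citations = citations, task = task, feature_source = feature_source),
    class = "news_corpus"
  )
}

#' @export
print.news_corpus <- function(x, ...) {
  n <- nrow(x$citations)
  tab <- table(factor(x$citations$label,
                      levels = c("positive", "negative", "unlabeled")))
  cat(sprintf("<news_corpus> %d citations (%d positive, %d negative, %d unlabeled)\n",
              n, tab[["positive"]], tab[["negative"]], tab[["unlabeled"]]))
  if (!is.na(x$task)) {
    cat(sprintf("  task: %s, feature source: %s\n", x$task, x$feature_source))
  }
  invisible(x)
}

#' @export
length.news_corpus <- function(x) nrow(x$citations)

## TRUE for citations with at least one non-empty text field
has_any_text <- function(citations) {
  nzchar(trimws(citations$title)) | nzchar(trimws(citations$abstract)) |
    vapply(citations$mesh_terms, function(m) length(m) > 0 && any(nzchar(m)),
           logical(1))
}

#' Read a labeled corpus from disk
#'
#' JSONL (one citation object per line) is the canonical interchange format;
#' CSV (header row, `mesh_terms` as a `;`-separated string) and MEDLINE
#' flat-file exports are importers. Records with no usable text (empty title,
#' abstract and MeSH list) are skipped with a message reporting the count.
#'
#' @param path File path.
#' @param format `"jsonl"`, `"csv"`, or `"medline"`.
#' @param default_label Label assigned to records that carry none (MEDLINE
#'   exports have no label field; e.g. `"positive"` when importing a file of
#'   known press-released citations).
#' @param task,feature_source Passed to [news_corpus()].
#' @return A `news_corpus`.
#' @export
read_corpus <- function(path, format = c("jsonl", "csv", "medline"),
                        default_label = NULL, task = NA_character_,
                        feature_source = "article") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  rows <- switch(format,
    jsonl = read_corpus_jsonl(path),
    csv = read_corpus_csv(path),
    medline = read_medline(path)
  )
  if (nrow(rows) == 0L) stop("no citation records found in ", path)
  if (!"label" %in% names(rows) || all(is.na(rows$label))) {
    if (is.null(default_label)) {
      stop("no label column/field in ", path,
           " and no default_label supplied")
    }
    rows$label <- default_label
  } else if (!is.null(default_label)) {
    rows$label[is.na(rows$label) | !nzchar(rows$label)] <- default_label
  }
  if (!"id" %in% names(rows) || anyNA(rows$id)) {
    stop("every record must carry an id")
  }
  keep <- has_any_text(rows)
  if (any(!keep)) {
    message(sum(!keep), " record(s) skipped: no title, abstract or MeSH text")
    rows <- rows[keep, , drop = FALSE]
  }
  if (nrow(rows) == 0L) stop("all records in ", path, " were empty of text")
  news_corpus(rows, task = task, feature_source = feature_source)
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(tibble::tibble())
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  rows <- lapply(recs, function(r) {
    citation_record(
      id = r$id %||% stop("record missing id"),
      title = r$title %||% "", abstract = r$abstract %||% "",
      mesh_terms = unlist(r$mesh_terms) %||% character(),
      journal = r$journal %||% "", year = r$year %||% NA_integer_,
      issue = r$issue %||% "", label = r$label %||% "unlabeled",
      source_tag = r$source_tag %||% ""
    )
  })
  do.call(rbind, rows)
}

read_corpus_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) return(tibble::tibble())
  if (!"id" %in% names(df)) stop("CSV corpus requires an 'id' column")
  mesh <- if ("mesh_terms" %in% names(df)) {
    lapply(strsplit(df$mesh_terms, ";", fixed = TRUE), function(m) {
      m <- trimws(m)
      m[nzchar(m)]
    })
  } else replicate(nrow(df), character(), simplify = FALSE)
  tibble::tibble(
    id = df$id,
    title = df$title %||% "",
    abstract = df$abstract %||% "",
    mesh_terms = mesh,
    journal = df$journal %||% "",
    year = as.integer(df$year %||% NA),
    issue = df$issue %||% "",
    label = df$label %||% NA_character_,
    source_tag = df$source_tag %||% ""
  )
}

#' Write a corpus to disk
#'
#' Inverse of [read_corpus()] for the `jsonl` and `csv` formats;
#' `read_corpus(write_corpus(x))` reproduces every field.
#'
#' @param corpus A `news_corpus`.
#' @param path Output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  cit <- corpus$citations
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(cit)), function(i) {
      jsonlite::toJSON(list(
        id = cit$id[i], title = cit$title[i], abstract = cit$abstract[i],
        mesh_terms = cit$mesh_terms[[i]], journal = cit$journal[i],
        year = cit$year[i], issue = cit$issue[i], label = cit$label[i],
        source_tag = cit$source_tag[i]
      ), auto_unbox = TRUE, null = "null", na = "null")
    }, character(1))
    writeLines(lines, path)
  } else {
    df <- as.data.frame(cit[, setdiff(citation_cols, "mesh_terms")])
    df$mesh_terms <- vapply(cit$mesh_terms, paste, character(1), collapse = ";")
    df <- df[, citation_cols]
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Summarize a labeled corpus
#'
#' Reports, per label class, the count and percentage of citations plus the
#' mean and SD of title and abstract length in words. Word counts use the
#' same tokenizer as featurization (see [tokenize()]), so the statistics are
#' internally consistent with the feature matrices.
#'
#' @param corpus A non-empty `news_corpus`.
#' @return A tibble with one row per label class present, plus a `total` row.
#' @export
corpus_summary <- function(corpus) {
  cit <- corpus$citations
  if (nrow(cit) == 0L) stop("corpus is empty")
  title_len <- vapply(cit$title, function(t) length(tokenize(t)), integer(1),
                      USE.NAMES = FALSE)
  abs_len <- vapply(cit$abstract, function(t) length(tokenize(t)), integer(1),
                    USE.NAMES = FALSE)
  sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)
  groups <- c(intersect(c("positive", "negative", "unlabeled"),
                        unique(cit$label)), "total")
  rows <- lapply(groups, function(g) {
    idx <- if (g == "total") rep(TRUE, nrow(cit)) else cit$label == g
    tibble::tibble(
      class = g, n = sum(idx), percent = 100 * sum(idx) / nrow(cit),
      title_mean = mean(title_len[idx]), title_sd = sd0(title_len[idx]),
      abstract_mean = mean(abs_len[idx]), abstract_sd = sd0(abs_len[idx])
    )
  })
  do.call(rbind, rows)
}
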