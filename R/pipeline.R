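#' Configuration for an end-to-end run
#'
#' Bundles every stage's settings and seeds so a run is reproducible from
#' its manifest alone.
#'
#' @param task `"PR"` or `"NC"`.
#' @param feature_source `"article"` or `"press_release"` (NC only).
#' @param features A [feature_config()] for the discriminative stage (the
#'   topic-model stage always uses its `unigram_only` counterpart).
#' @param cv List: `k`, `lambda_grid`.
#' @param bootstrap List: `B`, `top_n`, `n_density` (how many top features
#'   per direction get density curves). Set to `NULL` to skip.
#' @param slda List: `K`, `alpha`, `max_iter`, `n_restarts`. Set to `NULL`
#'   to skip the topic-model stage.
#' @param seeds List of integer seeds: `folds`, `bootstrap`, `slda`.
#' @param out_dir Output directory (created if missing).
#' @return A `run_config` list.
#' @export
run_config <- function(task = "PR", feature_source = "article",
                       features = feature_config(),
                       cv = list(k = 5L, lambda_grid = 10^seq(-5, 2)),
                       bootstrap = list(B = 1000L, top_n = 25L, n_density = 4L),
                       slda = list(K = 20L, alpha = 1, max_iter = 100L,
                                   n_restarts = 1L),
                       seeds = list(folds = 1L, bootstrap = 2L, slda = 3L),
                       out_dir = tempfile("newsworthy_run_")) {
  structure(list(task = task, feature_source = feature_source,
                 features = features, cv = cv, bootstrap = bootstrap,
                 slda = slda, seeds = seeds, out_dir = out_dir),
            class = "run_config")
}

write_tsv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full analysis pipeline on a labeled corpus
#'
#' Stages: featurize (uni+bigram) and vectorize; nested cross-validated AUC;
#' full-data lambda selection and bootstrap coefficient ranking (top-N
#' positive and negative feature tables, plus density curves for the
#' leading features of each direction); unigram featurization and a
#' supervised topic model with its topic report; a JSON run manifest
#' recording configuration, seeds and stage-by-stage counts. All tabular
#' outputs are TSV; nested results are JSON. Stage failures abort with the
#' stage name after flagging the manifest invalid.
#'
#' @param config A [run_config()].
#' @param corpus A labeled `news_corpus`.
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   of the written artifacts.
#' @export
run_pipeline <- function(config, corpus) {
  stopifnot(inherits(config, "run_config"), inherits(corpus, "news_corpus"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("newsworthy")),
    task = config$task, feature_source = config$feature_source,
    feature_config = config$features[c("ngram_mode", "fields", "min_df",
                                       "max_features", "emit_plain_title")],
    cv = config$cv, bootstrap = config$bootstrap[c("B", "top_n")],
    slda = if (is.null(config$slda)) "skipped" else
      config$slda[c("K", "alpha", "max_iter")],
    seeds = config$seeds, n_citations = length(corpus),
    stages = list(), valid = FALSE
  )
  paths <- list(manifest = file.path(config$out_dir, "manifest.json"))
  flush_manifest <- function() {
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$valid <<- FALSE
      manifest$failed_stage <<- name
      flush_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  results <- list()

  ## --- discriminative featurization -------------------------------------
  vocab <- stage("featurize", build_vocabulary(corpus, config$features))
  X <- stage("featurize", vectorize(corpus, vocab))
  y <- corpus$citations$label
  manifest$stages$featurize <- list(n_features = length(vocab$features),
                                    nnz = length(X@x))

  ## --- cross-validated AUC ----------------------------------------------
  cv <- stage("cross_validate", cross_validate(
    X, y, k = config$cv$k, lambda_grid = config$cv$lambda_grid,
    seed = config$seeds$folds))
  paths$cv <- file.path(config$out_dir, "cv_result.json")
  jsonlite::write_json(
    list(fold_auc = cv$fold_auc, mean_auc = cv$mean_auc, sd_auc = cv$sd_auc,
         lambda_selected = cv$lambda_selected, k = cv$k, seed = cv$seed),
    paths$cv, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$stages$cross_validate <- list(mean_auc = cv$mean_auc)
  results$cv <- cv

  ## --- bootstrap feature ranking ----------------------------------------
  if (!is.null(config$bootstrap)) {
    lambda_star <- stage("bootstrap", select_lambda(
      X, y, k = config$cv$k, lambda_grid = config$cv$lambda_grid,
      seed = child_seed(config$seeds$folds, 17L)))
    bs <- stage("bootstrap", bootstrap_coefficients(
      X, y, lambda = lambda_star, B = config$bootstrap$B,
      seed = config$seeds$bootstrap, retain = TRUE))
    top_pos <- rank_features(bs, "positive", config$bootstrap$top_n)
    top_neg <- rank_features(bs, "negative", config$bootstrap$top_n)
    paths$top_positive <- file.path(config$out_dir, "top_positive.tsv")
    paths$top_negative <- file.path(config$out_dir, "top_negative.tsv")
    write_tsv_atomic(as.data.frame(top_pos), paths$top_positive)
    write_tsv_atomic(as.data.frame(top_neg), paths$top_negative)
    nd <- min(config$bootstrap$n_density %||% 4L, nrow(top_pos))
    dens_feats <- c(utils::head(top_pos$feature, nd),
                    utils::head(top_neg$feature, nd))
    paths$density <- file.path(config$out_dir, "coefficient_density.tsv")
    dens <- do.call(rbind, lapply(dens_feats, function(f) {
      d <- coefficient_density(bs, f)
      data.frame(feature = f, x = d$x, y = d$y)
    }))
    write_tsv_atomic(dens, paths$density)
    manifest$stages$bootstrap <- list(lambda = lambda_star, B = bs$B,
                                      n_redraws = bs$n_redraws)
    bs$samples <- NULL # drop the B x p matrix from the returned bundle
    results$bootstrap <- bs
    results$top_positive <- top_pos
    results$top_negative <- top_neg
  } else {
    manifest$stages$bootstrap <- "skipped"
  }

  ## --- supervised topic model -------------------------------------------
  if (!is.null(config$slda)) {
    uni_cfg <- config$features
    uni_cfg$ngram_mode <- "unigram_only"
    uvocab <- stage("slda", build_vocabulary(corpus, uni_cfg))
    U <- stage("slda", vectorize(corpus, uvocab))
    ## documents as token-id lists; drop documents with no in-vocab token
    docs <- lapply(seq_len(nrow(U)), function(i) {
      row <- U[i, ]
      rep(which(row > 0), row[row > 0])
    })
    keep <- vapply(docs, length, integer(1)) > 0L
    labels <- ifelse(y[keep] == "positive", 2L, 1L)
    fit <- stage("slda", fit_slda(
      docs[keep], labels, K = config$slda$K, alpha = config$slda$alpha,
      V = length(uvocab$features), vocab = uvocab$features,
      max_iter = config$slda$max_iter,
      n_restarts = config$slda$n_restarts %||% 1L,
      seed = config$seeds$slda))
    report <- topic_report(fit)
    paths$slda_topics <- file.path(config$out_dir, "slda_topics.tsv")
    write_tsv_atomic(as.data.frame(report), paths$slda_topics)
    manifest$stages$slda <- list(
      n_docs = sum(keep), vocab = length(uvocab$features),
      iterations = fit$trace$iterations, converged = fit$trace$converged,
      monotone = fit$trace$monotone)
    results$slda <- fit
    results$topic_report <- report
  } else {
    manifest$stages$slda <- "skipped"
    paths$slda_topics <- NA_character_
  }

  manifest$valid <- TRUE
  flush_manifest()
  results$vocabulary <- vocab
  results$paths <- paths
  invisible(results)
}
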