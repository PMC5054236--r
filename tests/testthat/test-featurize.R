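test_that("tokenizer lowercases, strips punctuation, keeps digits", {
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize("Magnetic resonance imaging."),
                   c("magnetic", "resonance", "imaging"))
  expect_identical(tokenize("95% CI"), c("95", "ci"))
  expect_identical(tokenize("data-driven (n=42)!"),
                   c("data", "driven", "n", "42"))
})

test_that("field prefixes and bigram boundaries follow the feature scheme", {
  cit <- citation_record("x", title = "A study of outcomes",
                         abstract = "Magnetic resonance imaging results",
                         mesh_terms = c("Great Britain", "Humans"))
  f <- extract_features(cit, feature_config())
  ## title terms double-emitted: TI-prefixed and plain (stop words removed
  ## before n-gram formation, so "study outcomes" is a title bigram)
  expect_true(all(c("TI-study", "TI-outcomes", "study", "outcomes",
                    "TI-study TI-outcomes", "study outcomes") %in% names(f)))
  ## abstract terms unprefixed with bigrams
  expect_true(all(c("magnetic", "resonance", "magnetic resonance",
                    "resonance imaging") %in% names(f)))
  ## MeSH: one MH- feature per heading, spaces -> hyphens, adjacent bigrams
  expect_true(all(c("MH-great-britain", "MH-humans",
                    "MH-great-britain MH-humans") %in% names(f)))
  ## bigrams never span fields
  expect_false("outcomes magnetic" %in% names(f))
  expect_false("imaging MH-great-britain" %in% names(f))
})

test_that("MeSH qualifier strings stay verbatim inside one feature", {
  f <- extract_features(citation_record("x", mesh_terms = "England/epidemiology"),
                        feature_config())
  expect_true("MH-england/epidemiology" %in% names(f))
})

test_that("an all-empty citation yields an empty mapping", {
  f <- extract_features(citation_record("x"), feature_config())
  expect_length(f, 0L)
})

test_that("unigram_only mode emits no bigrams", {
  cit <- citation_record("x", title = "magnetic resonance imaging")
  f <- extract_features(cit, feature_config("unigram_only"))
  expect_false(any(grepl(" ", names(f))))
  expect_true("TI-magnetic" %in% names(f))
})

test_that("vocabulary matches brute-force enumeration on a toy corpus", {
  corp <- tiny_corpus()
  cfg <- feature_config(min_df = 2L)
  vocab <- build_vocabulary(corp, cfg)
  ## brute force: every feature, counted per document, df >= 2
  per_doc <- lapply(seq_len(3), function(i) {
    names(extract_features(corp$citations[i, ], cfg))
  })
  all_feats <- sort(unique(unlist(per_doc)))
  df <- vapply(all_feats, function(f) {
    sum(vapply(per_doc, function(d) f %in% d, logical(1)))
  }, integer(1))
  expect_identical(vocab$features, sort(names(df[df >= 2])))
  expect_identical(vocab$document_frequency,
                   unname(df[vocab$features]))
})

test_that("min_df = 1 with no cap keeps all distinct features", {
  corp <- tiny_corpus()
  cfg <- feature_config(min_df = 1L, max_features = .Machine$integer.max)
  vocab <- build_vocabulary(corp, cfg)
  all_feats <- unique(unlist(lapply(seq_len(3), function(i) {
    names(extract_features(corp$citations[i, ], cfg))
  })))
  expect_setequal(vocab$features, all_feats)
})

test_that("the feature cap keeps the most frequent features, ties lexicographic", {
  rows <- lapply(1:4, function(i) {
    citation_record(paste0("d", i),
                    abstract = c("apple apple banana cherry",
                                 "apple banana banana cherry",
                                 "apple banana cherry date",
                                 "apple banana cherry date")[i])
  })
  corp <- news_corpus(do.call(rbind, rows))
  cfg <- feature_config("unigram_only", fields = "abstract", min_df = 2L,
                        max_features = 3L)
  vocab <- build_vocabulary(corp, cfg)
  ## totals: apple 5, banana 5, cherry 4, date 2 -> cap 3 keeps apple,
  ## banana, cherry; "date" (lowest total) dropped
  expect_setequal(vocab$features, c("apple", "banana", "cherry"))
})

test_that("vectorize reproduces hand-tabulated counts and row sums", {
  corp <- tiny_corpus()
  cfg <- feature_config(min_df = 1L)
  vocab <- build_vocabulary(corp, cfg)
  X <- vectorize(corp, vocab)
  expect_equal(dim(X), c(3L, length(vocab$features)))
  for (i in 1:3) {
    f <- extract_features(corp$citations[i, ], cfg)
    expect_equal(sum(X[i, ]), sum(f)) # row sum = retained feature instances
    hand <- if (is.na(f["magnetic"])) 0L else unname(f["magnetic"])
    expect_equal(unname(X[i, "magnetic"]), as.numeric(hand))
  }
  ## an identical repeated document gives identical rows
  corp2 <- news_corpus(rbind(corp$citations,
                             transform(corp$citations[1, ], id = "a1copy")))
  X2 <- vectorize(corp2, vocab)
  expect_equal(unname(X2[4, ]), unname(X2[1, ]))
})

test_that("out-of-vocabulary features are ignored; config mismatch errors", {
  corp <- tiny_corpus()
  vocab <- build_vocabulary(corp, feature_config(min_df = 2L))
  extra <- news_corpus(citation_record("new1",
                                       title = "completely novel vocabulary"))
  X <- vectorize(extra, vocab)
  expect_equal(sum(X), 0) # all-zero row
  expect_error(vectorize(corp, vocab, feature_config("unigram_only")),
               "does not match")
})

test_that("featurization is deterministic and prefixes never collide", {
  corp <- tiny_corpus()
  v1 <- build_vocabulary(corp, feature_config())
  v2 <- build_vocabulary(corp, feature_config())
  expect_identical(v1$features, v2$features)
  expect_identical(as.matrix(vectorize(corp, v1)),
                   as.matrix(vectorize(corp, v2)))
  ## prefix disjointness: a plain feature never begins with TI-/MH-
  plain <- v1$features[!grepl("^(TI|MH)-", v1$features)]
  expect_false(any(grepl("^(TI|MH)-", plain)))
})

test_that("min_df filter holds on the training matrix", {
  corp <- make_discriminative_corpus(
    discriminative_spec(n_pos = 20, n_neg = 60, vocab_abstract = 300,
                        abstract_len = c(40, 10), seed = 21))
  vocab <- build_vocabulary(corp, feature_config())
  X <- vectorize(corp, vocab)
  expect_true(all(Matrix::colSums(X > 0) >= 2))
})

test_that("MatrixMarket export round-trips counts and index files", {
  corp <- tiny_corpus()
  vocab <- build_vocabulary(corp, feature_config(min_df = 1L))
  X <- vectorize(corp, vocab)
  stem <- tempfile("mtx")
  write_feature_matrix(X, stem)
  back <- Matrix::readMM(paste0(stem, ".mtx"))
  expect_equal(as.matrix(back), unname(as.matrix(X)))
  expect_identical(readLines(paste0(stem, ".rows")), rownames(X))
  expect_identical(readLines(paste0(stem, ".cols")), colnames(X))
})
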