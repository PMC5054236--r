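#' English stop-word list
#'
#' The fixed, versioned stop-word list used by [feature_config()]. It is the
#' classic snowball English list. Shipping a frozen list (rather than pulling
#' one from another package) keeps featurization byte-reproducible across
#' installations.
#'
#' @return Character vector of lowercase stop words.
#' @export
#' @examples
#' head(english_stopwords())
english_stopwords <- function() {
  c(
    "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
    "your", "yours", "yourself", "yourselves", "he", "him", "his",
    "himself", "she", "her", "hers", "herself", "it", "its", "itself",
    "they", "them", "their", "theirs", "themselves", "what", "which",
    "who", "whom", "this", "that", "these", "those", "am", "is", "are",
    "was", "were", "be", "been", "being", "have", "has", "had", "having",
    "do", "does", "did", "doing", "would", "should", "could", "ought",
    "a", "an", "the", "and", "but", "if", "or", "because", "as", "until",
    "while", "of", "at", "by", "for", "with", "about", "against",
    "between", "into", "through", "during", "before", "after", "above",
    "below", "to", "from", "up", "down", "in", "out", "on", "off",
    "over", "under", "again", "further", "then", "once", "here", "there",
    "when", "where", "why", "how", "all", "any", "both", "each", "few",
    "more", "most", "other", "some", "such", "no", "nor", "not", "only",
    "own", "same", "so", "than", "too", "very", "s", "t", "can", "will",
    "just", "don", "now", "isn", "aren", "wasn", "weren", "hasn",
    "haven", "hadn", "doesn", "didn", "won", "wouldn", "shan",
    "shouldn", "couldn", "mustn", "cannot", "let", "re", "ve", "ll", "d",
    "m"
  )
}
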