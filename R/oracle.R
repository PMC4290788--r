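# Brute-force reference scorer. Re-derives the document score vector by
# naive enumeration — its own keyword matching, relevance table and weight
# rules — deliberately kept separate from match_sentence()/score_document()
# so the two implementations can check each other.

oracle_has_any <- function(text, variants) {
  low <- tolower(text)
  for (v in variants) {
    esc <- gsub("([^[:alnum:][:space:]])", "\\\\\\1", v)
    esc <- gsub("\\s+", "\\\\s+", esc)
    if (grepl(paste0("(?<![[:alnum:]])", esc, "(?![[:alnum:]])"), low,
              perl = TRUE)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Reference document score by naive enumeration
#'
#' Computes the same quantity as [score_document()] with an intentionally
#' simple, independent enumeration of sentences, positional weights and
#' relevance rules. Used as the expected-score oracle for synthetic corpora
#' and in dual-implementation equivalence tests.
#'
#' @param document A [document_record()].
#' @param lexicon A [subtype_lexicon()].
#' @param config A [scoring_config()].
#'
#' @return Named numeric score vector over the four subtypes.
#' @export
oracle_score <- function(document, lexicon, config = scoring_config()) {
  codes <- subtype_codes()
  total <- stats::setNames(numeric(4), codes)
  texts <- c(document$title, document$sentences)
  n <- length(document$sentences)

  for (u in seq_along(texts)) {
    text <- texts[u]
    if (u == 1L) {
      w <- config$weight_title
    } else {
      k <- u - 1L
      w <- if (k == 1L || k == n) {
        config$weight_first_last
      } else if (k == 2L || k == n - 1L) {
        config$weight_second_penult
      } else {
        config$weight_other
      }
    }
    ak <- oracle_has_any(text, lexicon$anatomy_keywords)
    mk <- oracle_has_any(text, lexicon$malignancy_keywords)
    for (code in codes) {
      if (!oracle_has_any(text, lexicon$subtype_keywords[[code]])) next
      rel <- if (ak && mk) {
        config$relevance_full
      } else if (ak || mk) {
        config$relevance_partial
      } else {
        config$relevance_alone
      }
      total[code] <- total[code] + w * rel
    }
  }
  total
}
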