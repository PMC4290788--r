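# Subtype scoring: sentence relevance, positional weights, document score
# vectors, threshold classification, and the full-name baseline classifier.
#
# A document's score vector S_i = <S_P, S_A, S_F, S_M> is the weighted
# accumulation over its title and abstract sentences of per-sentence
# relevance scores: 1 when a subtype keyword (SK) co-occurs with both an
# anatomy (AK) and a malignancy (MK) keyword, 0.5 with exactly one of them,
# 0.25 when the SK stands alone.

#' Scoring configuration
#'
#' @param weight_title Weight of the title (default 4).
#' @param weight_first_last Weight of the first and last abstract sentences
#'   (default 2).
#' @param weight_second_penult Weight of the second and penultimate sentences
#'   (default 1).
#' @param weight_other Weight of all other sentences (default 0.5).
#' @param relevance_full Sentence relevance when SK co-occurs with both AK and
#'   MK (default 1).
#' @param relevance_partial Relevance when SK co-occurs with exactly one of
#'   AK/MK (default 0.5).
#' @param relevance_alone Relevance when SK appears alone (default 0.25).
#' @param threshold_absolute Named per-subtype minimum document score for a
#'   label (default 1 for every subtype).
#' @param threshold_share Named per-subtype minimum share of the score-vector
#'   total (defaults: PTC 0.30, others 0.20 — PTC dominates the literature,
#'   so its share bar is set slightly higher).
#'
#' @return Object of class `scoring_config`.
#' @export
scoring_config <- function(weight_title = 4,
                           weight_first_last = 2,
                           weight_second_penult = 1,
                           weight_other = 0.5,
                           relevance_full = 1,
                           relevance_partial = 0.5,
                           relevance_alone = 0.25,
                           threshold_absolute = c(PTC = 1, ATC = 1, FTC = 1, MTC = 1),
                           threshold_share = c(PTC = 0.30, ATC = 0.20,
                                               FTC = 0.20, MTC = 0.20)) {
  codes <- subtype_codes()
  threshold_absolute <- threshold_absolute[codes]
  threshold_share <- threshold_share[codes]
  vals <- c(weight_title, weight_first_last, weight_second_penult, weight_other,
            relevance_full, relevance_partial, relevance_alone,
            threshold_absolute, threshold_share)
  if (anyNA(vals) || any(vals < 0)) {
    stop("all weights, relevances and thresholds must be non-negative (and named per subtype)")
  }
  if (any(threshold_share > 1)) stop("share thresholds must be <= 1")
  structure(
    list(weight_title = weight_title,
         weight_first_last = weight_first_last,
         weight_second_penult = weight_second_penult,
         weight_other = weight_other,
         relevance_full = relevance_full,
         relevance_partial = relevance_partial,
         relevance_alone = relevance_alone,
         threshold_absolute = threshold_absolute,
         threshold_share = threshold_share),
    class = "scoring_config"
  )
}

zero_score_vector <- function() {
  stats::setNames(numeric(4), subtype_codes())
}

#' Sentence-level subtype relevance scores
#'
#' @param matches A `keyword_matches` object from [match_sentence()].
#' @param config A [scoring_config()].
#'
#' @details For each subtype whose SK matched: relevance 1 if both AK and MK
#'   are present in the sentence, 0.5 if exactly one is, 0.25 if neither.
#'   Subtypes without an SK match score 0. A sentence contributes at most one
#'   relevance score per subtype, however many times the SK occurs.
#'
#' @return Named numeric vector over `c("PTC","ATC","FTC","MTC")` with values
#'   in \{0, relevance_alone, relevance_partial, relevance_full\}.
#' @export
sentence_relevance <- function(matches, config = scoring_config()) {
  stopifnot(inherits(matches, "keyword_matches"))
  s <- zero_score_vector()
  if (!length(matches$sk_present)) return(s)
  n_aux <- sum(matches$ak_present, matches$mk_present)
  r <- switch(as.character(n_aux),
              "2" = config$relevance_full,
              "1" = config$relevance_partial,
              "0" = config$relevance_alone)
  s[matches$sk_present] <- r
  s
}

#' Positional weight of a sentence
#'
#' @param index `"title"`, or the 1-based ordinal of an abstract sentence.
#'   The title is not counted in the sentence ordinals.
#' @param n_sentences Number of abstract sentences.
#' @param config A [scoring_config()].
#'
#' @details In short abstracts a sentence can occupy several position
#'   categories at once (in a single-sentence abstract it is both first and
#'   last); the maximum applicable weight is used.
#'
#' @return A single weight: title 4, first/last 2, second/penultimate 1,
#'   other 0.5 under the default configuration.
#' @export
positional_weight <- function(index, n_sentences, config = scoring_config()) {
  if (identical(index, "title")) return(config$weight_title)
  index <- as.integer(index)
  if (is.na(index) || index < 1L || index > n_sentences) {
    stop("sentence index ", index, " out of range 1..", n_sentences)
  }
  w <- config$weight_other
  if (index == 2L || index == n_sentences - 1L) w <- max(w, config$weight_second_penult)
  if (index == 1L || index == n_sentences) w <- max(w, config$weight_first_last)
  w
}

#' Document subtype score vector
#'
#' Computes S_i = weight_title * relevance(title) + sum over abstract
#' sentences of positional_weight * sentence_relevance.
#'
#' @param document A [document_record()].
#' @param lexicon A [subtype_lexicon()].
#' @param config A [scoring_config()].
#'
#' @return Named numeric score vector over the four subtypes, with attribute
#'   `any_tc_relevance`: `TRUE` if any sentence (or the title) had nonzero
#'   subtype relevance, or mentioned an anatomy and a malignancy keyword
#'   together without an SK (thyroid-cancer-related but subtype-unfocused).
#' @export
#' @examples
#' lex <- default_lexicon()
#' d <- document_record("1", title = "Papillary thyroid carcinoma.")
#' score_document(d, lex)
score_document <- function(document, lexicon, config = scoring_config()) {
  stopifnot(inherits(document, "tc_document"))
  total <- zero_score_vector()
  any_tc <- FALSE

  units <- c(list(list(index = "title", text = document$title)),
             lapply(seq_along(document$sentences), function(k) {
               list(index = k, text = document$sentences[k])
             }))
  n <- length(document$sentences)
  for (u in units) {
    m <- match_sentence(u$text, lexicon)
    rel <- sentence_relevance(m, config)
    w <- positional_weight(u$index, n, config)
    total <- total + w * rel
    if (any(rel > 0) || (m$ak_present && m$mk_present)) any_tc <- TRUE
  }
  attr(total, "any_tc_relevance") <- any_tc
  total
}

#' Threshold classification of a score vector
#'
#' @param scores Named score vector from [score_document()].
#' @param config A [scoring_config()].
#' @param any_tc_relevance Whether the document showed any thyroid-cancer
#'   relevance (defaults to the attribute carried by [score_document()]
#'   output, if present).
#'
#' @details A subtype is labelled when its score meets the absolute threshold
#'   and its share of the score-vector total meets the share threshold. When
#'   no subtype qualifies, the document is labelled `TC` if it showed any
#'   thyroid-cancer relevance and `NON` otherwise.
#'
#' @return Character vector of labels: a subset of the subtype codes, or
#'   `"TC"`, or `"NON"`.
#' @export
classify <- function(scores, config = scoring_config(),
                     any_tc_relevance = attr(scores, "any_tc_relevance")) {
  if (is.null(any_tc_relevance)) any_tc_relevance <- any(scores > 0)
  codes <- subtype_codes()
  scores <- scores[codes]
  tot <- sum(scores)
  share <- if (tot > 0) scores / tot else rep(0, 4)
  hit <- scores >= config$threshold_absolute & share >= config$threshold_share
  labels <- codes[hit]
  if (length(labels)) return(labels)
  if (isTRUE(any_tc_relevance)) "TC" else "NON"
}

#' Score and classify a corpus
#'
#' @param docs List of [document_record()] objects.
#' @param lexicon A [subtype_lexicon()].
#' @param config A [scoring_config()].
#' @param verbose Log a progress line every 1000 documents.
#'
#' @return Data frame with columns `pmid`, `S_P`, `S_A`, `S_F`, `S_M` and
#'   `labels` (subtype labels joined with `|`, or `TC`/`NON`), suitable for
#'   [write_classification()].
#' @export
classify_corpus <- function(docs, lexicon, config = scoring_config(),
                            verbose = FALSE) {
  n <- length(docs)
  out <- data.frame(pmid = character(n), S_P = numeric(n), S_A = numeric(n),
                    S_F = numeric(n), S_M = numeric(n), labels = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- score_document(docs[[i]], lexicon, config)
    out$pmid[i] <- docs[[i]]$pmid
    out[i, c("S_P", "S_A", "S_F", "S_M")] <- as.list(unname(s))
    out$labels[i] <- paste(classify(s, config), collapse = "|")
    if (verbose && i %% 1000 == 0) message("classified ", i, "/", n, " documents")
  }
  out
}

# Assembled full-name patterns for one subtype: "<sk> <ak> <mk>" and
# "<sk> <mk> of the <ak>", over all variant combinations.
baseline_patterns <- function(lexicon, code) {
  esc <- function(x) gsub("([^[:alnum:][:space:]])", "\\\\\\1", x)
  pats <- character()
  for (sk in lexicon$subtype_keywords[[code]]) {
    for (ak in lexicon$anatomy_keywords) {
      for (mk in lexicon$malignancy_keywords) {
        pats <- c(pats,
                  paste(esc(sk), esc(ak), esc(mk), sep = "\\s+"),
                  paste(esc(sk), esc(mk), "of\\s+the", esc(ak), sep = "\\s+"))
      }
    }
  }
  paste0("(?<![[:alnum:]])(", paste(pats, collapse = "|"), ")(?![[:alnum:]])")
}

#' Baseline classifier: full subtype-name occurrence
#'
#' Labels a document with a subtype if and only if a full subtype name (an SK
#' variant together with anatomy and malignancy keywords, e.g. "papillary
#' thyroid cancer" or "papillary carcinoma of the thyroid") occurs in the
#' title or abstract. Partial mentions such as "papillary cancer" are
#' invisible to this baseline. No scores are computed; documents with no full
#' name get `NON`.
#'
#' @param document A [document_record()].
#' @param lexicon A [subtype_lexicon()].
#'
#' @return Character vector of subtype labels, or `"NON"`.
#' @export
baseline_classify <- function(document, lexicon) {
  stopifnot(inherits(document, "tc_document"))
  text <- paste(c(document$title, document$sentences), collapse = " ")
  labels <- character()
  for (code in lexicon$subtypes) {
    if (is.null(lexicon$subtype_keywords[[code]])) next
    if (grepl(baseline_patterns(lexicon, code), text, perl = TRUE,
              ignore.case = TRUE)) {
      labels <- c(labels, code)
    }
  }
  if (length(labels)) labels else "NON"
}

#' Baseline classification of a corpus
#'
#' @inheritParams classify_corpus
#' @return Data frame with columns `pmid` and `labels` (joined with `|`).
#' @export
baseline_corpus <- function(docs, lexicon) {
  data.frame(
    pmid = vapply(docs, function(d) d$pmid, ""),
    labels = vapply(docs, function(d) paste(baseline_classify(d, lexicon),
                                            collapse = "|"), ""),
    stringsAsFactors = FALSE
  )
}
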