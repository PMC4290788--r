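lex <- default_lexicon()
cfg <- scoring_config()

test_that("sentence relevance follows the co-occurrence rule table exactly", {
  # exhaustive enumeration: every subtype subset x AK x MK condition
  codes <- subtype_codes()
  subsets <- unlist(lapply(0:4, function(k) combn(codes, k, simplify = FALSE)),
                    recursive = FALSE)
  for (sk in subsets) {
    for (ak in c(TRUE, FALSE)) {
      for (mk in c(TRUE, FALSE)) {
        rel <- sentence_relevance(fake_matches(sk, ak, mk), cfg)
        expected_hit <- if (ak && mk) 1 else if (ak || mk) 0.5 else 0.25
        for (j in codes) {
          expect_identical(unname(rel[j]),
                           if (j %in% sk) expected_hit else 0)
        }
        expect_true(all(rel %in% c(0, 0.25, 0.5, 1)))
      }
    }
  }
})

test_that("relevance is scored once per subtype however often the SK repeats", {
  m <- match_sentence("Papillary and papillary thyroid cancer papillary.", lex)
  expect_identical(unname(sentence_relevance(m, cfg)["PTC"]), 1)
})

test_that("positional weights are 4/2/1/0.5 with max-of-categories overlap", {
  expect_identical(positional_weight("title", 0, cfg), 4)
  w6 <- vapply(1:6, positional_weight, 0, n_sentences = 6, config = cfg)
  expect_identical(w6, c(2, 1, 0.5, 0.5, 1, 2))
  # short abstracts: a sentence occupying several categories takes the max
  expect_identical(positional_weight(1, 1, cfg), 2)
  expect_identical(positional_weight(1, 2, cfg), 2)
  expect_identical(positional_weight(2, 3, cfg), 1)
  expect_error(positional_weight(7, 6, cfg), "out of range")
  expect_error(positional_weight(0, 6, cfg), "out of range")
})

test_that("document scores are the position-weighted sum of sentence relevances", {
  d <- document_record("1", title = "Papillary thyroid carcinoma.")
  expect_identical(unname(score_document(d, lex, cfg)["PTC"]), 4)

  d2 <- document_record("2", title = "Genomic study.", sentences = c(
    "Papillary thyroid cancer is common.",   # weight 2, relevance 1
    "We sequenced tumors.",                  # MK only, no SK -> 0
    "BRAF was mutated.",                     # 0
    "Papillary cancer has good prognosis."   # weight 2, relevance 0.5
  ))
  expect_identical(unname(score_document(d2, lex, cfg)["PTC"]), 3)

  d3 <- document_record("3", title = "Plain title.", abstract = "Nothing here.")
  expect_identical(as.numeric(score_document(d3, lex, cfg)), c(0, 0, 0, 0))
  expect_false(attr(score_document(d3, lex, cfg), "any_tc_relevance"))
})

test_that("adding a subtype keyword never decreases that subtype's score", {
  base_sentences <- list(
    c("Clinical records were examined in detail.", "Outcomes were good."),
    c("Papillary thyroid cancer is common.", "Follow up was short.",
      "The cohort was small.")
  )
  additions <- c(" Papillary features were noted.",
                 " Papillary thyroid carcinoma recurred.")
  for (s in base_sentences) {
    for (add in additions) {
      for (at in seq_along(s)) {
        d0 <- document_record("m", title = "T.", sentences = s)
        s1 <- s
        s1[at] <- paste0(s1[at], add)
        d1 <- document_record("m", title = "T.", sentences = s1)
        expect_gte(score_document(d1, lex, cfg)["PTC"],
                   score_document(d0, lex, cfg)["PTC"])
      }
    }
  }
})

test_that("threshold classification assigns subtype, TC or NON labels", {
  v <- function(p = 0, a = 0, f = 0, m = 0) {
    stats::setNames(c(p, a, f, m), subtype_codes())
  }
  expect_identical(classify(v(7, 0, 0.5, 0), cfg, TRUE), "PTC")
  expect_identical(classify(v(), cfg, FALSE), "NON")
  expect_identical(classify(v(0.5, 0.25), cfg, TRUE), "TC")
  # share threshold: high-but-minority component is not labelled
  expect_identical(classify(v(10, 2), cfg, TRUE), "PTC")
  # multi-label when both pass absolute and share bars
  expect_setequal(classify(v(5, 0, 4, 0), cfg, TRUE), c("PTC", "FTC"))
})

test_that("documents with a planted full name in the title recover that label", {
  for (code in subtype_codes()) {
    sk <- c(PTC = "Papillary", ATC = "Anaplastic", FTC = "Follicular",
            MTC = "Medullary")[[code]]
    d <- document_record("t", title = paste(sk, "thyroid carcinoma outcomes."),
                         sentences = rep(filler, 3))
    s <- score_document(d, lex, cfg)
    expect_identical(classify(s, cfg), code)
  }
})

test_that("the baseline needs the full assembled subtype name", {
  d <- document_record("1", title = "Papillary thyroid cancer in children")
  expect_identical(baseline_classify(d, lex), "PTC")
  expect_identical(
    baseline_classify(document_record("2", title = "Review.",
                                      abstract = "We saw papillary cancer."), lex),
    "NON"
  )
  # ...while the scoring method still sees the partial mention
  d2 <- document_record("2", title = "Review.",
                        abstract = "We saw papillary cancer.")
  expect_identical(unname(score_document(d2, lex, cfg)["PTC"]), 2 * 0.5)
  expect_identical(
    baseline_classify(document_record("3", "No names here.", "None at all."), lex),
    "NON"
  )
  # the "of the" assembled order also counts as a full name
  d3 <- document_record("4", title = "Papillary carcinoma of the thyroid.")
  expect_identical(baseline_classify(d3, lex), "PTC")
})

test_that("corpus classification emits one labelled score row per document", {
  docs <- list(
    document_record("1", "Papillary thyroid carcinoma."),
    document_record("2", "Plain title.", "Nothing relevant."),
    document_record("3", "Thyroid carcinoma outcomes.")
  )
  cl <- classify_corpus(docs, lex, cfg)
  expect_identical(cl$pmid, c("1", "2", "3"))
  expect_identical(cl$labels, c("PTC", "NON", "TC"))
  expect_equal(cl$S_P[1], 4)
})
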