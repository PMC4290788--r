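# Synthetic corpus generation: abstracts with planted subtype mentions at
# controlled positions, gold labels, entity mentions with subtype affinity,
# and oracle-computed expected score vectors. Filler vocabulary is disjoint
# from the lexicon so planted relevance is exactly computable.

.filler_sentences <- c(
  "The study cohort was reviewed retrospectively.",
  "Clinical records were examined in detail.",
  "Patients underwent routine biochemical testing.",
  "Surgical outcomes were recorded during follow up.",
  "Statistical analyses used standard regression models.",
  "Imaging findings were assessed by two observers.",
  "The median follow up period exceeded five years.",
  "Demographic characteristics were balanced between groups."
)

.filler_titles <- c(
  "A retrospective review of surgical outcomes.",
  "Long term follow up in a tertiary referral series.",
  "Clinical characteristics of a consecutive patient series."
)

.subtype_sk <- c(PTC = "papillary", ATC = "anaplastic",
                 FTC = "follicular", MTC = "medullary")

#' Default synthetic entity catalogue
#'
#' Genes (Entrez-style ids) and pathways with per-subtype affinity weights.
#' Subtype-specific entities have affinity 1 for one subtype and 0 elsewhere;
#' background entities have a small uniform affinity everywhere (column
#' `bg` weights their appearance in subtype-unfocused and unrelated
#' documents).
#'
#' @return Data frame with columns `entity_id`, `entity_kind`, `surface`,
#'   `PTC`, `ATC`, `FTC`, `MTC`, `bg`.
#' @export
default_entity_catalogue <- function() {
  data.frame(
    entity_id = c("673", "7015", "7849", "5979", "7157", "2597",
                  "CPDB:MAPK", "CPDB:CALC", "CPDB:APOP"),
    entity_kind = c(rep("gene", 6), rep("pathway", 3)),
    surface = c("BRAF", "TERT", "PAX8", "RTN4", "TP53", "GAPDH",
                "MAPK signalling pathway", "calcitonin signalling pathway",
                "apoptosis pathway"),
    PTC = c(1, 0, 0, 0, 0.25, 0.25, 1, 0, 0.25),
    ATC = c(0, 1, 0, 0, 0.25, 0.25, 0, 0, 0.25),
    FTC = c(0, 0, 1, 0, 0.25, 0.25, 0, 0, 0.25),
    MTC = c(0, 0, 0, 1, 0.25, 0.25, 0, 1, 0.25),
    bg = c(0, 0, 0, 0, 1, 1, 0, 0, 1),
    stringsAsFactors = FALSE
  )
}

#' Synthetic corpus configuration
#'
#' @param n_docs Number of documents to generate.
#' @param subtype_mixture Named probabilities over document categories
#'   `PTC`, `ATC`, `FTC`, `MTC`, `TC` (thyroid-cancer-related without a
#'   subtype focus) and `NON` (unrelated). The default mirrors the subtype
#'   proportions observed in the thyroid cancer literature, where roughly
#'   30% of retrieved abstracts carry no subtype focus.
#' @param abbreviation_rate Probability that a planted subtype mention is
#'   partial (SK plus malignancy keyword, or SK alone) rather than the full
#'   three-part name.
#' @param position_profile Named probabilities of planting the subtype
#'   mention in the `title`, `first`, `last` or `middle` of the abstract.
#' @param entities Entity catalogue; see [default_entity_catalogue()].
#' @param mentions_per_doc Poisson mean of the number of entity mentions per
#'   document.
#' @param seed Random seed; a fixed seed makes the output byte-identical.
#'
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_docs = 200,
                         subtype_mixture = c(PTC = 0.29, ATC = 0.05, FTC = 0.17,
                                             MTC = 0.12, TC = 0.14, NON = 0.23),
                         abbreviation_rate = 0,
                         position_profile = c(title = 0.4, first = 0.25,
                                              last = 0.15, middle = 0.2),
                         entities = default_entity_catalogue(),
                         mentions_per_doc = 1.5,
                         seed = 1) {
  cats <- c(subtype_codes(), "TC", "NON")
  if (!setequal(names(subtype_mixture), cats)) {
    stop("subtype_mixture must be named over ", paste(cats, collapse = ", "))
  }
  if (abs(sum(subtype_mixture) - 1) > 1e-8) stop("subtype_mixture must sum to 1")
  if (!setequal(names(position_profile), c("title", "first", "last", "middle"))) {
    stop("position_profile must be named title/first/last/middle")
  }
  if (abs(sum(position_profile) - 1) > 1e-8) stop("position_profile must sum to 1")
  if (abbreviation_rate < 0 || abbreviation_rate > 1) {
    stop("abbreviation_rate must be in [0, 1]")
  }
  if (n_docs < 0) stop("n_docs must be >= 0")
  structure(
    list(n_docs = as.integer(n_docs),
         subtype_mixture = subtype_mixture[cats],
         abbreviation_rate = abbreviation_rate,
         position_profile = position_profile[c("title", "first", "last", "middle")],
         entities = entities,
         mentions_per_doc = mentions_per_doc,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Mention text for a subtype and form, as a title or as a body sentence.
planted_text <- function(code, form, as_title) {
  sk <- .subtype_sk[[code]]
  phrase <- switch(form,
                   full = paste(sk, "thyroid carcinoma"),
                   partial = paste(sk, "carcinoma"),
                   alone = paste("the", sk, "subtype"))
  first_up <- function(x) paste0(toupper(substr(x, 1, 1)), substring(x, 2))
  if (as_title) {
    first_up(paste0(phrase, " in a tertiary referral series."))
  } else {
    first_up(paste0(phrase, " was investigated in this cohort."))
  }
}

#' Generate a synthetic corpus with planted subtype structure
#'
#' Assembles documents from neutral filler sentences plus planted subtype
#' mentions (full or abbreviated, at a sampled position), records the planted
#' subtypes as gold labels, plants entity mentions according to the
#' catalogue's subtype affinities, and computes each document's expected
#' score vector with the independent brute-force oracle ([oracle_score()]).
#'
#' @param config A [synth_config()].
#' @param lexicon Lexicon used by the oracle for the expected scores.
#'
#' @return List with elements `documents` (list of [document_record()]),
#'   `gold` (`gold_labels`), `expected_scores` (data frame `pmid`, `S_P`,
#'   `S_A`, `S_F`, `S_M` from the oracle), `mentions` (mention data frame)
#'   and `config`.
#' @export
generate_corpus <- function(config = synth_config(), lexicon = default_lexicon()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cats <- names(config$subtype_mixture)
  ent <- config$entities

  documents <- list()
  gold <- list()
  mention_rows <- list()

  for (i in seq_len(config$n_docs)) {
    pmid <- as.character(1000000L + i)
    category <- sample(cats, 1L, prob = config$subtype_mixture)
    n_body <- sample(4:7, 1L)
    sentences <- sample(.filler_sentences, n_body, replace = TRUE)
    title <- sample(.filler_titles, 1L)

    # entity mentions: one extra sentence per mention, appended to the body
    n_m <- stats::rpois(1L, config$mentions_per_doc)
    doc_surfaces <- character()
    if (n_m > 0L) {
      w <- if (category %in% subtype_codes()) ent[[category]] else ent$bg
      if (sum(w) > 0) {
        picks <- sample(nrow(ent), n_m, replace = TRUE, prob = w)
        for (k in picks) {
          sentences <- c(sentences, if (ent$entity_kind[k] == "gene") {
            paste0("Expression of ", ent$surface[k], " was analysed.")
          } else {
            paste0("The ", ent$surface[k], " was implicated in this series.")
          })
          doc_surfaces <- c(doc_surfaces, ent$surface[k])
          mention_rows[[length(mention_rows) + 1L]] <- data.frame(
            pmid = pmid, entity_kind = ent$entity_kind[k],
            entity_id = ent$entity_id[k], start = NA_integer_,
            end = NA_integer_, surface = ent$surface[k], source = "synthetic",
            stringsAsFactors = FALSE
          )
        }
      }
    }

    # planted subtype (or unfocused thyroid-cancer) mention
    if (category %in% subtype_codes()) {
      form <- if (stats::runif(1) < config$abbreviation_rate) {
        sample(c("partial", "alone"), 1L)
      } else "full"
      pos <- sample(names(config$position_profile), 1L,
                    prob = config$position_profile)
      if (pos == "title") {
        title <- planted_text(category, form, as_title = TRUE)
      } else {
        s <- planted_text(category, form, as_title = FALSE)
        m <- length(sentences) + 1L
        at <- switch(pos, first = 1L, last = m,
                     middle = sample(3:(m - 2L), 1L))
        sentences <- append(sentences, s, after = at - 1L)
      }
      gold[[pmid]] <- sort(unique(c(gold[[pmid]], category)))
    } else if (category == "TC") {
      sentences <- append(sentences,
                          "Thyroid carcinoma was investigated in this cohort.",
                          after = 0L)
    }

    doc <- document_record(pmid, title = title, sentences = sentences)
    documents[[length(documents) + 1L]] <- doc

    # resolve mention offsets in "title + single space + abstract"
    if (length(doc_surfaces)) {
      full <- paste(title, paste(sentences, collapse = " "))
      seen <- list()
      idx <- which(vapply(mention_rows, function(r) r$pmid == pmid, logical(1)))
      for (j in idx) {
        surf <- mention_rows[[j]]$surface
        cnt <- if (is.null(seen[[surf]])) 1L else seen[[surf]] + 1L
        seen[[surf]] <- cnt
        occ <- gregexpr(surf, full, fixed = TRUE)[[1]]
        mention_rows[[j]]$start <- as.integer(occ[cnt])
        mention_rows[[j]]$end <- as.integer(occ[cnt]) + nchar(surf) - 1L
      }
    }
  }

  mentions <- if (length(mention_rows)) {
    out <- do.call(rbind, mention_rows)
    rownames(out) <- NULL
    out
  } else {
    data.frame(pmid = character(), entity_kind = character(),
               entity_id = character(), start = integer(), end = integer(),
               surface = character(), source = character(),
               stringsAsFactors = FALSE)
  }

  expected <- data.frame(
    pmid = vapply(documents, function(d) d$pmid, ""),
    stringsAsFactors = FALSE
  )
  if (length(documents)) {
    smat <- t(vapply(documents, function(d) oracle_score(d, lexicon),
                     numeric(4)))
    expected$S_P <- smat[, "PTC"]
    expected$S_A <- smat[, "ATC"]
    expected$S_F <- smat[, "FTC"]
    expected$S_M <- smat[, "MTC"]
  } else {
    expected$S_P <- expected$S_A <- expected$S_F <- expected$S_M <- numeric(0)
  }

  list(documents = documents,
       gold = structure(gold, class = "gold_labels"),
       expected_scores = expected,
       mentions = mentions,
       config = config)
}
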