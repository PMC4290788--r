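# Decomposed subtype vocabulary and keyword matching.
#
# Each full subtype name ("papillary thyroid cancer") is dissociated into a
# subtype keyword (SK, "papillary"), an anatomy keyword (AK, "thyroid") and a
# malignancy keyword (MK, "cancer"), each with surface variants, so that
# partial and abbreviated mentions still match.

#' Canonical thyroid cancer subtype codes
#'
#' @return Character vector `c("PTC", "ATC", "FTC", "MTC")`: papillary,
#'   anaplastic (undifferentiated), follicular and medullary thyroid cancer.
#' @export
subtype_codes <- function() c("PTC", "ATC", "FTC", "MTC")

#' Construct a subtype lexicon
#'
#' @param subtype_keywords Named list mapping each canonical subtype code to a
#'   character vector of SK surface variants.
#' @param anatomy_keywords Character vector of AK variants.
#' @param malignancy_keywords Character vector of MK variants.
#'
#' @details Variants are lowercased on construction. Every SK variant must map
#'   to exactly one subtype, and the SK, AK and MK sets must be pairwise
#'   disjoint; violations raise an error naming the offending variant.
#'
#' @return An object of class `subtype_lexicon` with elements
#'   `subtype_keywords`, `anatomy_keywords`, `malignancy_keywords`,
#'   `subtypes`, and a precompiled pattern table used by [match_sentence()].
#' @export
subtype_lexicon <- function(subtype_keywords, anatomy_keywords,
                            malignancy_keywords) {
  codes <- subtype_codes()
  if (!all(names(subtype_keywords) %in% codes)) {
    stop("unknown subtype code(s): ",
         paste(setdiff(names(subtype_keywords), codes), collapse = ", "))
  }
  sk <- lapply(subtype_keywords, function(v) tolower(trimws(v)))
  ak <- tolower(trimws(anatomy_keywords))
  mk <- tolower(trimws(malignancy_keywords))

  all_sk <- unlist(sk, use.names = FALSE)
  for (v in c(all_sk, ak, mk)) {
    if (!nzchar(v)) stop("empty keyword variant is not allowed")
  }
  dup <- all_sk[duplicated(all_sk)]
  if (length(dup)) {
    stop("SK variant assigned to more than one subtype: ",
         paste(unique(dup), collapse = ", "))
  }
  cross <- c(intersect(all_sk, ak), intersect(all_sk, mk), intersect(ak, mk))
  if (length(cross)) {
    stop("variant appears in more than one keyword class: ",
         paste(unique(cross), collapse = ", "))
  }

  lex <- structure(
    list(
      subtype_keywords = sk,
      anatomy_keywords = ak,
      malignancy_keywords = mk,
      subtypes = codes
    ),
    class = "subtype_lexicon"
  )
  lex$patterns <- compile_lexicon_patterns(lex)
  lex
}

# One boundary-anchored, case-insensitive regex per variant. Word boundaries
# are "not adjacent to an alphanumeric", so hyphens delimit tokens and
# "un-differentiated" matches its listed hyphenated form while "papillaryoma"
# does not match "papillary". Internal whitespace in multi-word variants is
# matched flexibly.
compile_lexicon_patterns <- function(lex) {
  row <- function(variant, class, canonical) {
    esc <- gsub("([^[:alnum:][:space:]])", "\\\\\\1", variant)
    esc <- gsub("\\s+", "\\\\s+", esc)
    data.frame(
      variant = variant, class = class, canonical = canonical,
      pattern = paste0("(?<![[:alnum:]])", esc, "(?![[:alnum:]])"),
      stringsAsFactors = FALSE
    )
  }
  out <- list()
  for (code in names(lex$subtype_keywords)) {
    for (v in lex$subtype_keywords[[code]]) out[[length(out) + 1L]] <- row(v, "SK", code)
  }
  for (v in lex$anatomy_keywords) out[[length(out) + 1L]] <- row(v, "AK", v)
  for (v in lex$malignancy_keywords) out[[length(out) + 1L]] <- row(v, "MK", v)
  do.call(rbind, out)
}

#' Load a subtype lexicon from the builtin default or a keyword file
#'
#' @param source `"builtin"` for the packaged default vocabulary, or the path
#'   to a keyword file with three sections headed `[SK]`, `[AK]` and `[MK]`.
#'   `[SK]` lines are `variant<TAB>canonical`; `[AK]`/`[MK]` lines hold one
#'   variant each. `#` starts a comment.
#'
#' @details The builtin default maps papillary to PTC; anaplastic,
#'   undifferentiated and un-differentiated to ATC; follicular to FTC; and
#'   medullary to MTC, with anatomy variants thyroid/thyroidal and malignancy
#'   variants cancer, carcinoma, tumor, tumour, neoplasm, malignancy and
#'   malignant.
#'
#' @return A [subtype_lexicon()] object.
#' @export
#' @examples
#' lex <- load_lexicon()
#' match_sentence("Papillary thyroid carcinoma is common.", lex)
load_lexicon <- function(source = "builtin") {
  if (identical(source, "builtin")) {
    source <- system.file("extdata", "lexicon_default.txt", package = "thyscore",
                          mustWork = TRUE)
  }
  if (!file.exists(source)) stop("cannot read lexicon file: ", source)
  lines <- readLines(source, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]

  section <- NA_character_
  sk <- list()
  ak <- character()
  mk <- character()
  for (ln in lines) {
    t <- trimws(ln)
    if (t %in% c("[SK]", "[AK]", "[MK]")) {
      section <- substr(t, 2, 3)
      next
    }
    if (is.na(section)) stop("lexicon line outside any section: ", t)
    if (section == "SK") {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("malformed [SK] line (need variant<TAB>code): ", t)
      code <- trimws(parts[2])
      sk[[code]] <- c(sk[[code]], trimws(parts[1]))
    } else if (section == "AK") {
      ak <- c(ak, t)
    } else {
      mk <- c(mk, t)
    }
  }
  if (!length(sk)) stop("lexicon file has no [SK] section")
  if (!length(ak)) stop("lexicon file has no [AK] section")
  if (!length(mk)) stop("lexicon file has no [MK] section")
  subtype_lexicon(sk, ak, mk)
}

#' @rdname load_lexicon
#' @export
default_lexicon <- function() load_lexicon("builtin")

#' Match subtype, anatomy and malignancy keywords in one sentence
#'
#' Performs case-insensitive, word-boundary dictionary matching of every
#' lexicon variant against a single sentence (no sentence splitting happens
#' here).
#'
#' @param sentence A single character string.
#' @param lexicon A [subtype_lexicon()].
#'
#' @return An object of class `keyword_matches`: a list with `sk_present`
#'   (canonical subtype codes whose SK matched), `ak_present` and `mk_present`
#'   (logical), and `spans`, a data frame of matches with columns `start`,
#'   `end` (1-based, inclusive), `class` (SK/AK/MK), `canonical` and
#'   `variant`.
#' @export
match_sentence <- function(sentence, lexicon) {
  stopifnot(inherits(lexicon, "subtype_lexicon"))
  if (length(sentence) != 1L || is.na(sentence)) {
    stop("`sentence` must be a single non-NA string")
  }
  empty <- data.frame(start = integer(), end = integer(),
                      class = character(), canonical = character(),
                      variant = character(), stringsAsFactors = FALSE)
  spans <- empty
  if (nzchar(sentence)) {
    pats <- lexicon$patterns
    hits <- vector("list", nrow(pats))
    for (i in seq_len(nrow(pats))) {
      m <- gregexpr(pats$pattern[i], sentence, perl = TRUE, ignore.case = TRUE)[[1]]
      if (m[1] == -1L) next
      hits[[i]] <- data.frame(
        start = as.integer(m),
        end = as.integer(m) + attr(m, "match.length") - 1L,
        class = pats$class[i], canonical = pats$canonical[i],
        variant = pats$variant[i], stringsAsFactors = FALSE
      )
    }
    hits <- hits[!vapply(hits, is.null, logical(1))]
    if (length(hits)) {
      spans <- do.call(rbind, hits)
      spans <- spans[order(spans$start, spans$end), , drop = FALSE]
      rownames(spans) <- NULL
    }
  }
  structure(
    list(
      sk_present = sort(unique(spans$canonical[spans$class == "SK"])),
      ak_present = any(spans$class == "AK"),
      mk_present = any(spans$class == "MK"),
      spans = spans
    ),
    class = "keyword_matches"
  )
}
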