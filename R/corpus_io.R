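# Corpus, gold-standard and entity-mention I/O, plus sentence splitting.
#
# Documents are held as lightweight records (pmid, title, ordered abstract
# sentences). Two corpus dialects are supported: MEDLINE field-tag text
# (PMID-/TI-/AB-) and JSON-lines records {pmid, title, abstract}.

#' Build a document record
#'
#' @param pmid Document identifier (string of digits).
#' @param title Title text.
#' @param abstract Abstract text; split into sentences with
#'   [split_sentences()] unless `sentences` is given.
#' @param sentences Optional pre-split ordered sentence vector.
#'
#' @return An object of class `tc_document` with elements `pmid`, `title`
#'   and `sentences`. Titles are never sentence-split.
#' @export
document_record <- function(pmid, title = "", abstract = "", sentences = NULL) {
  pmid <- as.character(pmid)
  if (length(pmid) != 1L || is.na(pmid) || !nzchar(pmid)) {
    stop("`pmid` must be a non-empty string")
  }
  if (is.null(sentences)) sentences <- split_sentences(abstract)
  structure(
    list(pmid = pmid, title = as.character(title),
         sentences = as.character(sentences)),
    class = "tc_document"
  )
}

#' @export
print.tc_document <- function(x, ...) {
  cat("<tc_document> PMID", x$pmid, "-", x$title, "\n")
  cat("  ", length(x$sentences), "abstract sentence(s)\n")
  invisible(x)
}

# Abbreviations that must not terminate a sentence when followed by a period.
.sentence_abbrevs <- c(
  "al", "e.g", "i.e", "cf", "vs", "etc", "ca", "approx", "resp",
  "dr", "prof", "mr", "mrs", "ms", "st", "jr", "sr", "fig", "figs",
  "eq", "ref", "refs", "no", "vol", "spp", "sp"
)

#' Split an abstract into sentences
#'
#' Rule-based splitter: a sentence ends at `.`, `!` or `?` followed by
#' whitespace and an upper-case letter, digit or opening quote/bracket.
#' Periods after common abbreviations (e.g. "et al.", "e.g.", "Fig.") or
#' after a single-letter initial do not split.
#'
#' @param text Abstract text (a single string; `NA` or `""` give zero
#'   sentences).
#'
#' @return Character vector of trimmed, non-empty sentences whose
#'   concatenation preserves every non-whitespace character of the input.
#' @export
#' @examples
#' split_sentences("Mutations in B. Smith et al. were found. A second cohort followed.")
split_sentences <- function(text) {
  if (length(text) != 1L) stop("`text` must be a single string")
  if (is.na(text) || !nzchar(trimws(text))) return(character())

  cand <- gregexpr("[.!?]+(?=\\s+[\"'(\\[]?[A-Z0-9])", text, perl = TRUE)[[1]]
  breaks <- integer()
  if (cand[1] != -1L) {
    ends <- as.integer(cand) + attr(cand, "match.length") - 1L
    for (e in ends) {
      prefix <- substr(text, 1L, e)
      # last token before the terminator, punctuation stripped of the final '.'
      tok <- regmatches(prefix, regexpr("[[:alnum:].-]+[.!?]+$", prefix))
      if (length(tok)) {
        word <- sub("[.!?]+$", "", tok)
        if (tolower(word) %in% .sentence_abbrevs) next
        if (grepl("^[A-Z]$", word)) next        # initials: "B. Smith"
        if (grepl("^[A-Za-z]\\.[A-Za-z.]*$", word)) next  # "e.g.", "U.S."
      }
      breaks <- c(breaks, e)
    }
  }
  starts <- c(1L, breaks + 1L)
  stops <- c(breaks, nchar(text))
  out <- trimws(substring(text, starts, stops))
  out[nzchar(out)]
}

#' Read a corpus of abstracts
#'
#' @param path Path to the corpus file.
#' @param format `"jsonl"` (one JSON object `{pmid, title, abstract}` per
#'   line) or `"medline"` (field-tag records with `PMID-`, `TI  -` and
#'   `AB  -` fields; continuation lines are unwrapped with single spaces).
#'
#' @return List of [document_record()] objects, in file order. Records with
#'   no PMID are skipped with a warning.
#' @export
read_corpus <- function(path, format = c("jsonl", "medline")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read corpus file: ", path)
  if (format == "jsonl") read_corpus_jsonl(path) else read_corpus_medline(path)
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- list()
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[i])
    if (is.null(rec$pmid) || !nzchar(as.character(rec$pmid))) {
      warning("record ", i, " has no pmid; skipped")
      next
    }
    docs[[length(docs) + 1L]] <- document_record(
      rec$pmid,
      title = if (is.null(rec$title)) "" else rec$title,
      abstract = if (is.null(rec$abstract)) "" else rec$abstract
    )
  }
  docs
}

read_corpus_medline <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  cur <- NULL
  tag <- NULL
  flush <- function(cur, recs) {
    if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
    recs
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      recs <- flush(cur, recs)
      cur <- NULL
      tag <- NULL
      next
    }
    if (grepl("^[A-Z]+\\s*- ", ln)) {
      tag <- trimws(sub("- .*$", "", ln))
      val <- sub("^[A-Z]+\\s*- ", "", ln)
      if (tag == "PMID") {
        recs <- flush(cur, recs)
        cur <- list(PMID = trimws(val))
      } else if (!is.null(cur)) {
        cur[[tag]] <- if (is.null(cur[[tag]])) val else paste(cur[[tag]], val)
      }
    } else if (grepl("^\\s+", ln) && !is.null(cur) && !is.null(tag)) {
      cur[[tag]] <- paste(cur[[tag]], trimws(ln))  # wrapped continuation line
    }
  }
  recs <- flush(cur, recs)

  docs <- list()
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    if (is.null(r$PMID) || !nzchar(r$PMID)) {
      warning("MEDLINE record ", i, " has no PMID; skipped")
      next
    }
    docs[[length(docs) + 1L]] <- document_record(
      r$PMID,
      title = if (is.null(r$TI)) "" else trimws(r$TI),
      abstract = if (is.null(r$AB)) "" else trimws(r$AB)
    )
  }
  docs
}

#' Write a corpus of documents
#'
#' Inverse of [read_corpus()] for both dialects; abstracts are written as the
#' single-space join of the document's sentences.
#'
#' @param docs List of [document_record()] objects.
#' @param path Output path.
#' @param format `"jsonl"` or `"medline"`.
#' @export
write_corpus <- function(docs, path, format = c("jsonl", "medline")) {
  format <- match.arg(format)
  abstracts <- vapply(docs, function(d) paste(d$sentences, collapse = " "), "")
  if (format == "jsonl") {
    lines <- vapply(seq_along(docs), function(i) {
      jsonlite::toJSON(
        list(pmid = docs[[i]]$pmid, title = docs[[i]]$title,
             abstract = abstracts[i]),
        auto_unbox = TRUE
      )
    }, "")
  } else {
    lines <- unlist(lapply(seq_along(docs), function(i) {
      c(paste0("PMID- ", docs[[i]]$pmid),
        paste0("TI  - ", docs[[i]]$title),
        paste0("AB  - ", abstracts[i]),
        "")
    }))
  }
  writeLines(lines, path)
}

# Map a gold-label cell to a canonical subtype code. Accepts the codes
# themselves and MeSH supplementary-concept style names such as
# "Thyroid cancer, papillary".
normalize_subtype_label <- function(label) {
  l <- tolower(trimws(label))
  if (toupper(l) %in% subtype_codes()) return(toupper(l))
  if (grepl("papillary", l)) return("PTC")
  if (grepl("anaplastic|undifferentiated", l)) return("ATC")
  if (grepl("follicular", l)) return("FTC")
  if (grepl("medullary", l)) return("MTC")
  NA_character_
}

#' Read gold-standard subtype labels
#'
#' @param path TSV with one `pmid<TAB>label` pair per line (no header).
#'   Repeated pmids accumulate labels. Labels may be canonical codes or
#'   supplementary-concept style names ("Thyroid cancer, papillary").
#'
#' @return Object of class `gold_labels`: a named list mapping pmid to a
#'   character vector of canonical subtype codes.
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) stop("cannot read gold file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  gold <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("gold line ", i, " is not pmid<TAB>label: ", lines[i])
    code <- normalize_subtype_label(parts[2])
    if (is.na(code)) stop("gold line ", i, " has unknown subtype label: ", parts[2])
    pmid <- trimws(parts[1])
    gold[[pmid]] <- sort(unique(c(gold[[pmid]], code)))
  }
  structure(gold, class = "gold_labels")
}

#' Read an entity-mention table
#'
#' @param path Headered TSV with columns `pmid`, `entity_kind` (gene or
#'   pathway), `entity_id`, `start`, `end`, `surface`, `source`. Offsets are
#'   1-based inclusive over the concatenation of title, a single space, and
#'   the abstract.
#'
#' @return Data frame of validated mentions in file order.
#' @export
read_mentions <- function(path) {
  if (!file.exists(path)) stop("cannot read mention file: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("pmid", "entity_kind", "entity_id", "start", "end", "surface", "source")
  missing <- setdiff(needed, names(m))
  if (length(missing)) stop("mention file lacks column(s): ", paste(missing, collapse = ", "))
  m$start <- as.integer(m$start)
  m$end <- as.integer(m$end)
  bad_kind <- !m$entity_kind %in% c("gene", "pathway")
  if (any(bad_kind)) {
    stop("unknown entity_kind at row(s): ", paste(which(bad_kind), collapse = ", "))
  }
  bad_off <- is.na(m$start) | is.na(m$end) | m$end < m$start
  if (any(bad_off)) {
    stop("invalid offsets (need end >= start) at row(s): ",
         paste(which(bad_off), collapse = ", "))
  }
  m[needed]
}

#' Write an entity-mention table
#'
#' @param mentions Data frame as returned by [read_mentions()].
#' @param path Output TSV path.
#' @export
write_mentions <- function(mentions, path) {
  utils::write.table(mentions, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write classification results
#'
#' Serializes a classification table (as from [classify_corpus()]) to TSV
#' with columns `pmid`, `S_P`, `S_A`, `S_F`, `S_M` (4 decimal places) and
#' `labels`. Multiple subtype labels are joined with `|`; documents unrelated
#' to thyroid cancer carry `NON`, related-but-unfocused documents carry `TC`.
#'
#' @param results Data frame with columns `pmid`, `S_P`, `S_A`, `S_F`, `S_M`,
#'   `labels`.
#' @param path Output TSV path.
#' @export
write_classification <- function(results, path) {
  needed <- c("pmid", "S_P", "S_A", "S_F", "S_M", "labels")
  missing <- setdiff(needed, names(results))
  if (length(missing)) stop("results lack column(s): ", paste(missing, collapse = ", "))
  out <- results[needed]
  for (col in c("S_P", "S_A", "S_F", "S_M")) {
    out[[col]] <- sprintf("%.4f", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a classification table written by [write_classification()]
#'
#' @param path TSV path.
#' @return Data frame with numeric score columns and a `labels` column.
#' @export
read_classification <- function(path) {
  if (!file.exists(path)) stop("cannot read classification file: ", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(pmid = "character"))
  for (col in c("S_P", "S_A", "S_F", "S_M")) x[[col]] <- as.numeric(x[[col]])
  x
}
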