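# Entity-subtype association: per-entity relevancy vectors S_E and
# per-subtype ranked entity lists L_j.
#
# For an entity E (gene or pathway), S_E is the component-wise sum of the
# document score vectors S_i over the set D_E of documents mentioning E. A
# document contributes its full vector once per entity, however many times
# the entity is mentioned in it.

#' Aggregate document score vectors over entity mentions
#'
#' @param mentions Data frame of entity mentions as from [read_mentions()]
#'   (columns `pmid`, `entity_kind`, `entity_id` are used; duplicate mentions
#'   of an entity within one document count that document once).
#' @param scores Data frame with columns `pmid`, `S_P`, `S_A`, `S_F`, `S_M`
#'   (as from [classify_corpus()]). Mentions whose pmid has no score vector
#'   are skipped with a warning.
#'
#' @return Data frame with one row per distinct (entity_kind, entity_id):
#'   columns `entity_kind`, `entity_id`, `n_docs`, `S_P`, `S_A`, `S_F`,
#'   `S_M`, and a list column `pmids` holding D_E.
#' @export
build_associations <- function(mentions, scores) {
  score_cols <- c("S_P", "S_A", "S_F", "S_M")
  stopifnot(all(c("pmid", score_cols) %in% names(scores)))
  empty <- data.frame(entity_kind = character(), entity_id = character(),
                      n_docs = integer(), S_P = numeric(), S_A = numeric(),
                      S_F = numeric(), S_M = numeric(), stringsAsFactors = FALSE)
  empty$pmids <- list()
  if (!nrow(mentions)) return(empty)

  known <- mentions$pmid %in% scores$pmid
  if (any(!known)) {
    warning(sum(!known), " mention(s) with unscored pmid skipped: ",
            paste(unique(mentions$pmid[!known]), collapse = ", "))
    mentions <- mentions[known, , drop = FALSE]
  }
  if (!nrow(mentions)) return(empty)

  # one row per (entity, document): the deduplicated D_E
  pairs <- unique(mentions[c("entity_kind", "entity_id", "pmid")])
  smat <- as.matrix(scores[score_cols])
  rownames(smat) <- scores$pmid
  key <- paste(pairs$entity_kind, pairs$entity_id, sep = "\r")
  groups <- split(seq_len(nrow(pairs)), key)
  groups <- groups[order(names(groups))]

  rows <- lapply(groups, function(idx) {
    pmids <- pairs$pmid[idx]
    se <- colSums(smat[pmids, , drop = FALSE])
    out <- data.frame(entity_kind = pairs$entity_kind[idx[1]],
                      entity_id = pairs$entity_id[idx[1]],
                      n_docs = length(pmids),
                      S_P = se[["S_P"]], S_A = se[["S_A"]],
                      S_F = se[["S_F"]], S_M = se[["S_M"]],
                      stringsAsFactors = FALSE)
    out$pmids <- list(sort(pmids))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# labels column ("PTC|FTC", "TC", "NON") -> named list pmid -> label vector
labels_by_pmid <- function(classification) {
  stopifnot(all(c("pmid", "labels") %in% names(classification)))
  stats::setNames(strsplit(classification$labels, "|", fixed = TRUE),
                  classification$pmid)
}

#' Ranked entity list for one subtype
#'
#' Builds L_j: the entities with at least one document labelled subtype `j`
#' in the classification stage, ranked by the subtype component of their
#' relevancy vector S_E in descending order. Ties are broken by `n_docs`
#' descending, then `entity_id` ascending.
#'
#' @param subtype Canonical subtype code.
#' @param associations Data frame from [build_associations()].
#' @param classification Data frame with columns `pmid` and `labels` (as from
#'   [classify_corpus()]).
#'
#' @return Data frame with columns `rank`, `entity_kind`, `entity_id`,
#'   `score` (S_Ej) and `n_docs`; attribute `subtype` records `j`.
#' @export
ranked_list <- function(subtype, associations, classification) {
  if (!subtype %in% subtype_codes()) stop("unknown subtype code: ", subtype)
  col <- c(PTC = "S_P", ATC = "S_A", FTC = "S_F", MTC = "S_M")[[subtype]]
  labmap <- labels_by_pmid(classification)

  keep <- vapply(associations$pmids, function(pmids) {
    any(vapply(pmids, function(p) subtype %in% labmap[[p]], logical(1)))
  }, logical(1))
  a <- associations[keep, , drop = FALSE]
  if (nrow(a)) {
    a <- a[order(-a[[col]], -a$n_docs, a$entity_id), , drop = FALSE]
  }
  out <- data.frame(rank = seq_len(nrow(a)),
                    entity_kind = a$entity_kind,
                    entity_id = a$entity_id,
                    score = a[[col]],
                    n_docs = a$n_docs,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "subtype") <- subtype
  out
}

#' Overlap statistics between the four subtype entity lists
#'
#' Computes, Venn-diagram style, the number of entities in every non-empty
#' subtype combination (exclusive regions) and the fraction of each subtype's
#' list that is unique to it.
#'
#' @param lists Named list of four ranked lists (one per subtype code), as
#'   from [ranked_list()].
#'
#' @return List with `regions` (data frame `combination`, `count` for each
#'   non-empty exclusive region, combinations joined with `&`) and
#'   `per_subtype` (data frame `subtype`, `n_entities`, `n_unique`,
#'   `unique_fraction`).
#' @export
overlap_stats <- function(lists) {
  codes <- subtype_codes()
  if (!all(codes %in% names(lists))) {
    stop("`lists` must be named by the four subtype codes")
  }
  sets <- lapply(lists[codes], function(l) {
    unique(paste(l$entity_kind, l$entity_id, sep = "\r"))
  })
  all_entities <- unique(unlist(sets))
  membership <- vapply(codes, function(j) all_entities %in% sets[[j]],
                       logical(length(all_entities)))
  if (length(all_entities) == 1L) membership <- matrix(membership, nrow = 1,
                                                       dimnames = list(NULL, codes))
  combo <- apply(membership, 1L, function(row) paste(codes[row], collapse = "&"))
  tab <- table(combo)
  regions <- data.frame(combination = names(tab),
                        count = as.integer(tab),
                        stringsAsFactors = FALSE)
  regions <- regions[order(regions$combination), , drop = FALSE]
  rownames(regions) <- NULL

  per <- data.frame(
    subtype = codes,
    n_entities = vapply(codes, function(j) length(sets[[j]]), 0L),
    n_unique = vapply(codes, function(j) {
      sum(membership[, j] & rowSums(membership) == 1L)
    }, 0L),
    stringsAsFactors = FALSE
  )
  per$unique_fraction <- ifelse(per$n_entities > 0,
                                per$n_unique / per$n_entities, 0)
  rownames(per) <- NULL
  list(regions = regions, per_subtype = per)
}

#' Write the per-subtype ranked lists and overlap summary
#'
#' @param associations Data frame from [build_associations()].
#' @param classification Classification data frame.
#' @param out_dir Output directory; one `ranked_<subtype>.tsv` per subtype
#'   plus `overlap_summary.tsv`.
#' @export
write_ranked_lists <- function(associations, classification, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lists <- list()
  for (j in subtype_codes()) {
    lists[[j]] <- ranked_list(j, associations, classification)
    utils::write.table(lists[[j]], file.path(out_dir, paste0("ranked_", j, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ov <- overlap_stats(lists)
  utils::write.table(ov$per_subtype, file.path(out_dir, "overlap_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(lists)
}
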