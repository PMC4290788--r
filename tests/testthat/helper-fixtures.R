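# Shared fixture builders. Filler text is keyword-free so planted relevance
# is exactly computable.

filler <- "Clinical records were examined in detail."

# six-sentence abstract with a full PTC name planted at position `at`
doc_with_ptc_at <- function(at) {
  s <- rep(filler, 6)
  s[at] <- "Papillary thyroid cancer incidence is rising."
  document_record("900", title = "A retrospective review of outcomes.",
                  sentences = s)
}

# a keyword_matches stub for a given condition, bypassing text matching
fake_matches <- function(sk = character(), ak = FALSE, mk = FALSE) {
  structure(
    list(sk_present = sk, ak_present = ak, mk_present = mk,
         spans = data.frame(start = integer(), end = integer(),
                            class = character(), canonical = character(),
                            variant = character(), stringsAsFactors = FALSE)),
    class = "keyword_matches"
  )
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
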