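---
title: "Subtype scoring of thyroid cancer abstracts: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype scoring of thyroid cancer abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyscore)
```

## The classification model

`thyscore` labels abstracts with the thyroid cancer subtype(s) they focus on
— papillary (PTC), anaplastic (ATC), follicular (FTC), medullary (MTC) — and
is built around one observation: subtype names are usually written
partially. Authors say "papillary cancer" or just "papillary" far more often
than "papillary thyroid carcinoma". A classifier that matches only assembled
names therefore has a recall ceiling, while a classifier that matches bare
subtype adjectives everywhere drowns in passing mentions.

The scoring scheme resolves this tension with two mechanisms.

**Keyword decomposition.** Each full name is dissociated into a subtype
keyword (SK), an anatomy keyword (AK) and a malignancy keyword (MK), with
surface variants per class ("anaplastic", "undifferentiated" and
"un-differentiated" all map to ATC). A sentence's relevance to a subtype
grades how completely the name is present: 1 when the SK co-occurs with both
AK and MK, 0.5 with exactly one, 0.25 when the SK stands alone. A sentence
contributes at most one relevance score per subtype, however many times the
SK repeats — the rules grade the sentence, not the token count.

**Positional weighting.** Abstract discourse structure is stereotyped: the
title and the first sentence announce the topic, the last sentence
concludes. The document score is the weighted sum of sentence relevances
with weights 4 (title), 2 (first/last), 1 (second/penultimate) and 0.5
(everything else). The low interior weight exists precisely to weaken
bypassing mentions of subtypes that are not the article's scope.

```{r}
lex <- default_lexicon()
doc <- document_record("1", title = "Genomic study.", abstract = paste(
  "Papillary thyroid cancer is common. We sequenced tumors.",
  "BRAF was mutated. Papillary cancer has good prognosis."))
score_document(doc, lex)
```

A subtype is labelled when its score clears an absolute bar *and* a
share-of-total bar; a document with thyroid-cancer relevance (any nonzero
relevance, or an AK+MK co-occurrence without an SK) but no qualifying
subtype gets `TC`, all others `NON`.

## Tunable parameters

All knobs live in `scoring_config()` and every output records the
configuration used.

| parameter | default | meaning |
|---|---|---|
| `weight_title` | 4 | title weight (dimensionless multiplier) |
| `weight_first_last` | 2 | first and last abstract sentence |
| `weight_second_penult` | 1 | second and penultimate sentence |
| `weight_other` | 0.5 | all other sentences |
| `relevance_full/partial/alone` | 1 / 0.5 / 0.25 | SK+AK+MK, SK+one, SK alone |
| `threshold_absolute` | 1.0 each | minimum document score for a label |
| `threshold_share` | PTC 0.30, others 0.20 | minimum share of the score total |

The weights and relevance constants are the scheme's definition. The
thresholds are the genuinely open part of the design: we use a
share-of-total bar because a document heavily about one subtype should not
be labelled with every subtype it brushes against, and we set PTC's share
bar slightly higher because PTC dominates the literature (over half of
subtype-focused articles) and so accumulates incidental mentions more
easily. The absolute bar of 1.0 equals one full-name mention in a
second/penultimate sentence, or a partial mention in a first/last sentence —
anything weaker than that is treated as a passing reference. Both bars are
per-subtype configurable.

Ambiguities the defaults resolve deliberately:

- **Short abstracts.** In a one- or two-sentence abstract a sentence can be
  first *and* last; overlapping position categories take the maximum
  applicable weight, never a sum.
- **"differentiated".** Well-/poorly-differentiated phrasing refers to the
  differentiated thyroid cancer (DTC) umbrella covering PTC and FTC, not to
  a single subtype, so "differentiated" is *not* an SK variant by default
  ("undifferentiated", an ATC synonym, is). The evaluation function's
  `dtc_as_ftc` argument lets a caller re-credit FTC predictions on a
  supplied list of DTC articles rather than guessing DTC-ness from text.
- **Follicular variants of PTC.** Phrases like "follicular variant of
  papillary carcinoma" score toward FTC because the decomposition sees the
  "follicular" SK; no special-casing is attempted, and FTC precision is
  expected to suffer on real corpora for exactly this reason.

## Association and evaluation

For a gene or pathway *E*, the relevancy vector S_E sums the score vectors
of the *documents* mentioning E — a document counts once however many times
it mentions the entity, because the aggregation is over documents, not
mentions. The ranked list L_j keeps entities with at least one document
labelled *j* and orders by S_Ej; ties break by document count, then entity
id, so ranking is deterministic and independent of input row order. No
document-frequency filter is applied: even singleton entities can be real
associations.

Evaluation is one-vs-rest per subtype over the gold standard's pmids
(documents missing from the predictions count as negative predictions;
`TC`/`NON` are negative for every subtype), with micro-averaging that pools
TP/FP/FN across subtypes before the ratios. Any 0/0 ratio is defined as 0;
the convention only matters for degenerate fixtures.

## The synthetic generator

`generate_corpus()` emulates the structure of a retrieved abstract corpus:
each document draws a category (a subtype, `TC`-only, or `NON`), filler
sentences from a vocabulary guaranteed disjoint from the lexicon, a planted
subtype mention — full name, SK+MK ("papillary carcinoma") or SK alone —
at a sampled position (title/first/last/middle), and entity mentions drawn
by per-subtype affinity from a small gene/pathway catalogue. Default
category proportions (PTC .29, ATC .05, FTC .17, MTC .12, TC .14, NON .23)
follow the subtype composition observed in the thyroid cancer literature;
the default position profile (title .4, first .25, last .15, middle .2)
encodes that an article's focal subtype is usually named up front.

Because filler text is keyword-free, every planted document's score vector
is exactly computable. `oracle_score()` computes it by naive enumeration —
its own regex matcher, relevance table and weight rules, coded separately
from `match_sentence()`/`score_document()` — so the two implementations
check each other; the test suite asserts their equality on 1000 generated
documents, and the generator ships the oracle's scores as the expected
values.

What passing synthetic tests shows — and does not. The generator proves the
arithmetic: scores, thresholds, aggregation and metrics behave exactly as
specified. It does not emulate real abstracts: no lexical ambiguity
("follicular cells" in PTC articles), no DTC umbrella phrasing, no NER
errors beyond omission, and planted sentences are templated. Perfect
precision on synthetic corpora therefore says nothing about precision on
MEDLINE text, where those confounders dominate the error profile.

## Numerical choices and scale

Scores are exact sums of quarter-unit constants, so no rounding happens in
memory; classification tables serialize scores at 4 decimal places and
evaluation reports round metrics at 3. Sentence splitting uses a rule-based
splitter with an abbreviation list (its behaviour is pinned by tests since
sentence ordinals affect weights); titles are never split. Mention-table
offsets are 1-based inclusive over "title + single space + abstract".

Test and demonstration corpora use 200–1000 documents, sizes at which the
corpus-level properties we assert (perfect label recovery with full names in
titles; scoring recall exceeding the full-name baseline's at 50%
abbreviation, compared on the micro average since per-subtype recall for a
5%-prevalence subtype is noise at these sizes) are stable across seeds.

## Known limitations

- Recall of the baseline comparison and of label recovery depends on where
  mentions are planted; a full name whose only occurrence is mid-abstract
  scores 0.5 and is — by design — not labelled under default thresholds.
- The builtin vocabulary covers the variants named above; real corpora
  benefit from extending the SK lists (e.g. "Hürthle cell" toward FTC)
  via `load_lexicon()` with a custom keyword file.
- Gene/pathway recognition and normalization are out of scope: the
  association stage consumes pre-normalized mention tables.
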