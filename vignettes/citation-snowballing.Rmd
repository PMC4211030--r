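---
title: "Automatic citation snowballing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic citation snowballing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citesnow)
```

## The problem

Keyword search alone cannot guarantee the recall that systematic reviews
need, so reviewers complement it with *snowballing*: reading the reference
list of every retrieved paper, finding each cited work, downloading it, and
repeating. `citesnow` automates that loop and, just as importantly, makes
every stage measurable. The pipeline decomposes into subtasks that fail in
different ways — a reference string can be mis-segmented, mis-matched, or
matched correctly but undownloadable — and the evaluation module keeps those
failure modes separate.

## Pipeline model and assumptions

**Section location.** Articles arrive as plain text (conversion from PDF or
HTML is an adapter hook, not part of the package). The reference section is
taken to start at the *last* heading from a configurable lexicon
("References", "Bibliography", "Literature Cited", "Reference List",
case-insensitive, matched as a whole line) whose start offset is at or past
the character midpoint of the document. The midpoint restriction encodes the
assumption that reference lists terminate articles; a "References" mention
in the first half is body text. We chose characters as the midpoint unit
because the rule needs no tokenizer and is stable under whitespace changes;
and the *last* qualifying heading because appendices can repeat the word.
The section runs to the end of the document unless a stop-heading
("Appendix", "Supplementary ...") follows, in which case it is truncated
there. Both lexicons are arguments of `locate_reference_section()`.

**Segmentation** is heuristic and label-driven, not a trained sequence
model: the evaluation criterion constrains *outputs* (a string is correct
only if it contains the whole reference and nothing belonging to another
citation, a page footer, or body text — its own label and whitespace are
allowed), so any segmenter meeting that criterion is admissible.
`detect_label_style()` picks the numeric style (`[1]` / `1.` / `(1)`) whose
labels form the longest strictly increasing run starting at 1, falling back
to author–year when no numeric style labels at least two lines. For numeric
styles, a new citation opens only at the *next consecutive* integer label —
this is what keeps wrapped lines that merely start with a number (years,
page ranges) from opening spurious entries. Author–year lists split on blank
lines when present, otherwise at unindented surname-comma lines. Footer
filtering runs first, per line, with configurable patterns
(`|`-separated running heads, bare page numbers, URL-only lines);
contamination by page furniture was an observed failure mode of automatic
reference extraction, and dropping such lines before splitting is the
simplest rule that removes it.

**Query normalization.** A citation string becomes a query by keeping only
letter runs (so digits and punctuation vanish and hyphenated words split),
dropping tokens shorter than `min_len` letters, and lowercasing. The
default `min_len = 4` removes "et", "al", initials and most stopwords while
keeping venue words; it is exposed as a parameter because no canonical value
exists. Non-ASCII letters are kept (author names) and case-folded
locale-independently. A citation whose every token is removed — e.g. a
stray "2009; 373: 1175" fragment — is reported unresolvable rather than
searched.

**Matching.** The backend contract is `search(tokens, k)` returning scored
candidates; the shipped implementation is a deterministic local index
(`local_backend()`), and `http_backend()` sketches how a live API adapter
satisfies the same contract. Scoring is rarity-weighted token overlap with
smoothed IDF computed over the backend's own index,
$w(t) = \log\frac{N+1}{\mathrm{df}(t)+1} + 1$: the weight is positive for
every token (tokens absent from the index get the maximum), equal for
tokens of equal document frequency, and makes the score 1 exactly when
every query token occurs in the record's title + authors + venue field.
Ties are broken by ascending record id, so ranking is a deterministic total
order. Acceptance is deliberately conservative — matched only when the top
score clears $\tau = 0.7$ *and* beats the runner-up by $\delta = 0.05$
(a lone candidate has no runner-up to beat) — because in this application a
false match is worse than a miss: it injects a wrong paper into the
snowball. Everything else is labelled `below_threshold`, `ambiguous` or
`no_candidates`, so the evaluation can audit why citations were lost.
Records reached by different routes deduplicate by case-folded DOI when
present, else by title letters + year.

**Retrieval.** Link following is modelled as a fetcher contract
(`url -> status + content`); the shipped fetcher reads a fixture store with
per-URL failure annotations, which makes outcomes reproducible offline
while a real HTTP fetcher can drop in unchanged. URLs are tried in kind
priority full text > abstract > landing; full text wins whenever any link
yields it, an abstract is the fallback (abstracts are usually freely
accessible where full text is subscription-gated), and pure failures take
the failure class of the highest-priority link. The taxonomy — `no_link`,
`broken_link`, `dynamic_link_unresolved` (pages that build their download
link in JavaScript, which a text-level fetcher cannot follow),
`access_denied` — mirrors the failure modes observed when link-following is
run against a real bibliographic search engine. We deliberately collapse
"incorrect link" and transient network failure into `broken_link`: the
distinction is observational, not decidable by the fetcher.

**Recursion.** `snowball()` is breadth-first with a visited set keyed by
the dedup key, which guarantees termination on any finite index (cycles
included) and makes the node set monotone in `max_depth`. Seeds whose
`doc_id` names an index record are identified with that record, so
re-discovering a seed adds an edge, not a duplicate node. Abstract-only
fetches contribute nodes but not frontier entries — there is no reference
section to mine. The default `max_depth = 2` is a pragmatic choice: the
evaluation protocol is single-level, recursion depth is unbounded in
principle, and a small default keeps accidental full-index crawls from
surprising users.

## Evaluation protocol

`evaluate_run()` crosses three stages with three denominators. Stages:
*citations retrieved* (accepted match equals the annotated record),
*abstracts fetched* (correct match whose abstract or full text was
retrieved), *full text fetched* (correct match whose full text was
retrieved). Denominators: *all* reference strings; *included* citations
(websites, books, book chapters, newspaper articles and grey literature
are excluded — they are not findable in a scholarly index); *included and
indexed* citations. For each denominator both the gold-positive set and the
system-positive set are restricted to citations inside it. That restriction
is what makes precision constant across denominators whenever every
accepted match cites an included-and-indexed work, while recall rises as
the denominator shrinks — the characteristic pattern of this design, which
the structural tests assert on synthetic runs. Metrics use the empty-set
convention P = R = F1 = 0 when the relevant denominator count is zero. The
report object exposes raw `tp`/`fp`/`fn` counts alongside the metrics so
any aggregate can be audited; `write_report_tsv()` lays the table out as
three stage blocks × three metric rows × three denominator columns at three
decimals.

## The synthetic corpus

`generate_corpus()` exists so that every stage has a gold standard with
known provenance. It emulates: reference lists in bracket-number,
dot-number and author–year styles; line wraps at a configurable width;
page-footer noise interleaved at a configurable rate; excluded citation
types (websites, books, technical reports) at ~10% of references; included
citations whose work is absent from the index at ~22%; link behavior drawn
per record (working full text ~75%, abstract-only ~2%, broken ~10%, dynamic
~9%, access-denied ~3%, no link ~1%); and a citation DAG between records so
the engine can recurse over fetched full texts. The composition rates
mirror the funnel of a 20-review evaluation corpus (articles averaging ~53
references; roughly 10% excluded and 22% unindexed), and the link weights
approximate its reported failure shares. Titles, authors and venues are
pronounceable syllable strings, unique by construction at default sizes; a
`duplicate_title_rate` switch injects title collisions to exercise the
ambiguous-match path. All randomness is scoped to the spec's seed
(`local_seed()` restores the caller's RNG state), and identical specs
produce byte-identical corpora.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: PDF-to-text conversion artifacts (ligature and
hyphenation damage, multi-column scrambling), multilingual references,
inconsistent or erroneous human-typed citations, real search-engine ranking
idiosyncrasies, and subscription negotiation. Clean-room results are upper
bounds: the segmentation recall of 100% and matching precision of 1.0
measured on synthetic corpora say the algorithms are correct under
controlled noise, not that a live deployment would achieve them.

## Numerical choices and degenerate inputs

* Offsets are 1-based inclusive (R's `substr` convention) and every span
  invariant (`raw_text == substr(text, start, end)`, non-overlap, strict
  ordering) is asserted in tests.
* Scores are exact rational arithmetic in double precision; ranking ties
  break by ascending record id, so reruns are byte-identical.
* An empty reference section segments to an empty table, not an error; an
  all-noise citation raises a classed `empty_query` condition that the
  engine converts to an `unresolved` row.
* Degenerate confusion cells (no positives) yield 0, never `NaN`.
* Text is NFKC-normalized on ingest with CRLF unified to `\n`; invalid
  UTF-8 bytes become replacement characters rather than errors.

## Problem sizes

The test suite and the acceptance script measure: segmentation on 200
articles (~10,500 gold citations) with and without footer noise; matching
and brute-force ranking agreement on a 1000-record index (1000 and 100
queries respectively); engine properties on handcrafted 13-node trees and
2-cycles plus a 120-record corpus; and a full pipeline evaluation over 200
articles. These sizes give binomial noise on measured rates well below the
asserted bounds while keeping a complete run in the order of a minute.

## Known limitations

Segmentation is typography-driven: exotic styles (footnote-style citations,
two-column hanging indents) are out of its inventory. Matching assumes the
cited work's title/author/venue tokens survive into the citation string;
title-free numeric citation formats would defeat it. The live-backend and
live-fetcher adapters are contracts only — no rate limiting, CAPTCHA
handling or JavaScript rendering is provided. Relevance screening of
discovered citations is a separate concern and out of scope.
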