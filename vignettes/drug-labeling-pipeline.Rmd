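---
title: "Integrating drug labeling sources and classifying food-effect paragraphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating drug labeling sources and classifying food-effect paragraphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(druglabel)
```

## The problem

No single public resource covers all FDA-approved drug products, and the
resources that exist are mutually incompatible: DailyMed publishes HL7 v3
SPL XML with LOINC-coded sections, Drugs@FDA publishes PDF labels (we take
converted plain text as input; PDF conversion itself is out of scope),
DrugBank publishes one XML datafile with tag-named pharmacology fields,
and the Orange Book publishes the authoritative list of approved products
as a delimited datafile. `druglabel` extracts twelve labeling sections
from the three labeling sources, reconciles their identifier schemes
through the six-digit FDA application number, filters to the latest
version of each label, restricts to the Orange Book reference set, and
summarises what each source contributes. On top of the integrated data it
implements a paragraph-classification workbench for one concretely hard
extraction case: deciding whether an absorption-section paragraph
describes a food effect.

## Section vocabulary and parsing assumptions

The thirteen-member vocabulary (`section_kinds()`) contains the twelve
target sections plus their parent `pharmacokinetics`, which is extracted
only to be split. Five subsections (absorption, distribution, metabolism,
excretion, food effect — ADMEF) carry no LOINC codes of their own, so in
every source they are recovered from pharmacokinetics text by subtitle
detection: a subtitle is either a standalone title line or a
paragraph-leading prefix ending in `:` or `-`, matched case-insensitively.
The food-effect subtitle admits four synonymous spellings (food effect,
food effects, effect of food, effects of food). The same two-pattern
scheme is applied uniformly to all five subsection names; only the
food-effect and absorption patterns are inherently fixed by the
annotation rules, the remaining three are the natural generalisation.

Free-text section extraction is driven by a heading lexicon that ships as
a JSON data file (`inst/extdata/heading_lexicon.json`), not code, so a
deployment can replace it wholesale. A heading must occupy a whole line
(optional outline number such as `12.3`, optional trailing punctuation,
nothing else); this deliberately refuses to match section names mentioned
mid-sentence. ADMEF headings are recognised only inside an
already-detected pharmacokinetics region — the word "distribution" on its
own line elsewhere in a label is content, not a heading.

Identifier normalization reduces every application-number spelling
(`NDA021436`, `N12345`, bare digits) to a zero-padded six-digit string
with an inferred type. The exact textual carrier of application numbers
inside SPL and DrugBank files is not standardised across real corpora;
both the parsers and the synthetic generator agree on approval elements /
`fda-application-number` product fields, and the assumption is isolated in
two small functions so it can be re-pointed.

## Filtering and integration rules

`unify_ids()` explodes each document to one row per application number it
lists (one Set ID or DrugBank-ID may legitimately map to several);
documents listing none are kept in an explicit unmapped bucket rather
than discarded, so source-completeness diagnostics remain possible.
`filter_latest()` keeps, per (application number, source), the document
with the newest effective date; ties fall back to the highest version
number and then the lexicographically greatest native id, making the
result a pure function of the candidate set. Documents without dates lose
to any dated document — a dated label is always better evidence of
currency. `restrict_to_reference()` refuses an empty reference set
outright, because silently emptying the table is never the intended
outcome of a bad Orange Book path.

## Coverage and overlap

Coverage of source *S* for section *k* is the percentage of applications,
among those for which *any* source provides *k*, for which *S* provides
it; the `drug` row uses the reference-set size as denominator. Overlap
quantifies sharing. With `M_k` sources providing *k* at all and `n_i`
sources providing *k* for application *i*:

$$\mathrm{overlap}(S, k) = 100 \cdot \underset{i\,:\,S \text{ provides } k \text{ for } i}{\mathrm{mean}} \frac{n_i - 1}{M_k - 1}$$

This is the unique linear form satisfying both calibration endpoints: a
source that alone provides every one of its items scores 0%, and a source
whose every item is shared with all other providers scores 100%. A
plausible alternative reading normalises by the total number of sources
rather than the providers of *k*; the choice is confined to
`section_overlap()` so it can be swapped. When `M_k = 1` no sharing is
possible and overlap is reported as `NA` rather than a misleading 0.

## The food-effect study

Automatic annotation mirrors how labels typographically mark food-effect
content: a paragraph following a standalone food-effect subtitle, or
opening with a food-effect prefix, is positive (the subtitle/prefix is
removed); every other paragraph under an absorption heading is negative.
Two rule-based baselines bracket the task: rule 1 matches the phrase
alternation anywhere in a paragraph, rule 2 just searches for the
substring "food". Since every rule-1 phrase contains "food", rule-1
positives are a subset of rule-2 positives — a property the test suite
asserts exhaustively over every generated corpus.

TF-IDF weighting is implemented exactly as specified by the study design:
`TF(t,d) = log(1 + freq(t,d))` and `IDF(t,D) = log(N / df(t))`, natural
logarithms, no smoothing — so a term occurring in every document is
weighted 0. (The printed TF formula's `freq(t,D)` is read as the
per-document `freq(t,d)`: term frequency is a per-document quantity, and
the corpus-level reading would make TF constant across documents.) The
logarithm base is unspecified in the source material; natural log only
rescales weights, which no classifier here is sensitive to. A smoothed
variant (`log((1+N)/(1+df)) + 1`) exists behind `smooth = TRUE`, off by
default. Tokenization — lowercase, split on non-alphanumeric runs,
unigrams, no stop-word removal — is likewise a fixed choice made for
determinism and documented rather than tuned.

Three classifiers are fitted on these features: logistic regression
(glmnet ridge, fixed `lambda = 0.01` — a small penalty keeps the fit
defined when the classes are linearly separable), linear-kernel SVC
(`e1071::svm`, cost 1, no rescaling of already-weighted features), and
random forest (`ranger`, 300 trees, single-threaded with an explicit seed
so training is reproducible). Metrics use food effect as the positive
class; when a precision/recall denominator vanishes the metric is
reported as 0 with a `degenerate` flag, keeping batch reports total
rather than throwing. Datasets are balanced by *source* (equal records
per source), not by class: class proportions follow the annotated pools.
The train/test split is 80/20, stratified by source. Repetitions in the
learning curve re-draw the training subsample (re-split rather than
re-seed-only); both are defensible, re-splitting gives the more honest
variance estimate.

The automatic annotation is designed to be manually verified;
`apply_manual_review()` merges a corrections table (paragraph id to
label) over the automatic labels and marks corrected rows `manual`. An
empty review — the expected case — is a no-op.

## What the synthetic generator emulates, and what it does not

All testing is offline against `corpus_spec()`-driven generators. One
seeded plan produces a consistent drug universe across all four formats:
per-source coverage gaps, multi-version SPL documents sharing a Set ID
with increasing effective dates, one-to-many and absent identifier
mappings, ANDA rows and document-less NDA numbers in the Orange Book
file, subtitled pharmacokinetics blocks in both title and prefix styles,
and configurable PDF-conversion noise (stray line breaks, repeated page
headers) for the free-text labels. Paragraph text comes from templates
with lexical variation; each template carries an exact ground-truth label
and an adversarial flag. The two adversarial archetypes reproduce the
documented failure modes of keyword rules: negative boilerplate that
contains "effect of food", and genuine meal-effect content that never
uses the word "food". By construction the rules err on exactly the
flagged paragraphs.

This buys exact, auditable ground truth at the price of realism: the
generator does not emulate real clinical prose, OCR artifacts beyond
simple line noise, table/figure content, or the class imbalance and
inter-source heterogeneity of the real corpora. Green round-trip and
classification tests therefore demonstrate that the machinery is correct
and deterministic — they do not estimate real-world extraction recall or
classifier F1, which depend on dated snapshots of the actual resources.
On this synthetic corpus the TF-IDF classifiers separate the templates
essentially perfectly; on real labeling the same pipeline would be
expected to show the usual gap between classical models and fine-tuned
transformer encoders, which are out of scope here (the surface exposes
the classical workbench; a transformer hook would slot in as a fourth
`algo`).

## Problem sizes and numerical choices

The test suite and acceptance script use a 75-drug corpus
(~140 SPL documents, ~60 free-text labels, ~55 DrugBank drugs), an
800-record study dataset (400 per source, 25% adversarial, 80/20 split)
and learning curves up to 640 training examples with 2 repetitions —
sizes chosen as a faithful scaled-down analogue of the study design
(which used 1,200 records per source) that keeps a full run in seconds.
Determinism is treated as a first-class property: every random stage
takes an explicit seed, generation consumes all randomness inside one
seeded plan, and two pipeline runs with identical configuration are
asserted byte-identical at the file level.

Degenerate inputs are handled explicitly: empty corpora refuse to fit a
TF-IDF model; single-class training sets refuse to fit a classifier;
empty integrated tables yield empty (not erroring) coverage/overlap
reports; empty reference sets abort integration; documents without Set
IDs or metadata are flagged unmapped and retained.

## Known limitations

The paragraph is the minimum unit of annotation and classification:
food-effect statements embedded as single sentences inside otherwise
negative paragraphs, or spanning several paragraphs, are attributed at
paragraph granularity. The classifier is scoped to absorption-section
text — negatives are absorption content by construction, and nothing is
claimed about applying it elsewhere in a label. Real-corpus ingestion
(live API retrieval, PDF conversion) is interface-compatible but
deliberately outside the tested surface.
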