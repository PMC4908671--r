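---
title: "Detecting chemical-induced disease relations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chemical-induced disease relations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidre)
```

## The problem

A chemical-induced disease (CID) relation is the assertion that a chemical
causes a disease — the raw material of pharmacovigilance. In Medline
abstracts these assertions are sometimes stated within a single sentence
("heparin-induced thrombocytopenia") and sometimes only across sentences:
the drug is introduced early, the adverse event reported later. `cidre`
implements a hybrid detector for identifier-level CID pairs over abstracts
annotated in the BC5-CDR PubTator interchange format, combining three
complementary signals:

1. **Trigger patterns** — four high-precision sentence-level families
   (`CHEMICAL-induced DISEASE`, `CHEMICAL-associated DISEASE`,
   `DISEASE caused by CHEMICAL`, `DISEASE during CHEMICAL`), matched only
   where both slots are filled by annotated entity mentions. The trigger
   must lie between the two spans within a small token gap (default 3),
   with no coordinating conjunction in between — in "dobutamine and
   exercise induced myocardial ischaemia" the inducer is the nearer
   conjunct "exercise", not the annotated chemical, so no pair is emitted.
   A disease list coordinated after a matched trigger ("heparin-induced
   thrombocytopenia, ... osteoporosis") yields one pair per listed
   disease.
2. **A shallow-linguistic SVM** — a linear-kernel classifier over
   entity-blinded n-gram features of the sentence context between and
   around a candidate pair.
3. **Expert knowledge** — a database of known chemical-disease
   associations labeled *therapeutic* or *side_effect*, used both to
   select known side effects among abstract-level co-occurrences and, as
   the final step of every configuration, to discard pairs known to be
   drug *treatments*.

Named entity recognition is consumed, not performed: documents arrive with
typed, concept-normalized mention annotations (in the original study from
DNorm and tmChem), and the package's job starts there.

## Preprocessing and candidate generation

Mention offsets are 0-based half-open indices into `title + " " +
abstract`; every parse verifies each span against its stated text.
Sentence splitting is a deterministic rule (terminal `.?!` followed by
whitespace and an uppercase letter or digit, with an abbreviation
stoplist); the title is sentence 0. A mention that straddles a splitter
boundary is kept at the sentence containing its start and flagged — such
mentions are splitter artifacts and hiding them would hide splitter bugs.

Three post-NER rules clean the mention layer, each *flagging* rather than
deleting, so the raw NER layer remains inspectable:

* **Indication contexts.** A disease immediately followed by
  "patient(s)", or preceded by "patients with", is what the patient is
  being treated for, not a side effect (for example "patients with
  coronary artery disease after ... dobutamine"). The pattern set is
  configurable; the two defaults instantiate a `DISEASE` placeholder per
  mention.
* **Simple chemicals.** Elemental species (calcium, carbon, oxygen, ...)
  co-occur with everything; an exact-surface stoplist (15 entries by
  default, configurable) removes them.
* **Overlap resolution.** Where entity spans overlap, the longest mention
  survives, leftmost on ties, applied as repeated maximal selection until
  the surviving set is pairwise disjoint.

Candidates are then unique (chemical id, disease id) pairs at two scopes:
per sentence (cross product within each sentence) and per abstract (cross
product over the document). Mentions with concept id `"-1"` cannot match
identifier-level gold and are excluded; composite `"|"`-joined ids are
expanded one candidate per component, switchable off
(`expand_composite = FALSE`) because either treatment of composites is
defensible and the expanded form strictly increases the recall ceiling.

## The classifier

Each sentence-level candidate becomes one instance per sentence in which
the pair co-occurs. Tokens carry four attributes: lower-cased surface,
lemma (rule-based inflection stripping with a small irregular table), stem
(the Porter algorithm, implemented in full), and a coarse POS tag from a
deterministic rule tagger (closed-class lexicon plus suffix heuristics).
None of these components aims at linguistic perfection; the classifier
needs *consistency*, and a deterministic, dependency-free token layer is
reproducible everywhere.

Features follow the shallow-linguistic kernel family. Both entity spans
are collapsed to single `CHEMICAL`/`DISEASE` placeholder tokens across all
attributes (entity blinding — the model must learn context, not drug
names). Over three global windows — fore-between (sentence start through
the second entity), between (first through second entity), between-after
(first entity through sentence end) — all 1- to 3-grams of each attribute
become binary presence features; local context adds the attribute values
at signed offsets ±1, ±2 around each entity. Exact window membership in
the historical kernel implementations varies; here the entity placeholders
are included in each global window so that n-grams anchor on the entity
roles, and the choice is frozen in the feature-name scheme
(`g|b|lemma|2|CHEMICAL_induce`). Window sizes and n-gram order are
arguments, defaults `window = 2`, `ngram_max = 3`.

The model is a linear-kernel SVM (`e1071`, C = 1 by default — the study
this design follows reports no hyperparameters, so the libsvm default is
kept) with class weights inverse to class frequency. The fitted object
stores the feature vocabulary and the explicit primal weight vector
recovered from the support vectors, so predictions can be re-derived as
`X w − b` independently of the backend — the package's tests hold the two
routes equal to numerical tolerance.

Cross-validation is stratified by label with a fixed default seed (42),
fold sizes differing by at most one per class; per-fold precision, recall
and F (percent, positive class) are averaged unweighted. The reference
protocol is 10-fold.

## Crowd corpus construction

The crowd module reproduces the corpus-construction arithmetic of a
crowdsourced CID corpus: each verification task (one sentence, one concept
pair) receives five independent worker votes; the aggregate label is true
iff at least three votes are true. `corpus_statistics()` reports the
fraction of tasks at threshold and the unanimous-false fraction;
`balance_corpus()` keeps all positives and samples negatives without
replacement at a configured ratio (default 930/698, the published
balance). `simulate_workers()` is the testing stand-in for the platform:
votes equal gold flipped with probability `1 − accuracy`; quiz gating is
subsumed by the accuracy parameter. The closed form
`P(correct) = Σ_{k≥3} C(5,k) p^k (1−p)^{5−k}` (`aggregated_accuracy()`)
gives the exact aggregation accuracy this model implies — 0.99144 at
p = 0.9 — and simulation must agree within Monte-Carlo error.

Answer scales richer than binary, worker-quality weighting (Dawid-Skene
style) and platform mechanics are deliberately out of scope; the vote
table format keeps an extensible column layout so richer judgments could
be added.

## Combining the components

Three run configurations mirror the challenge setup:

* **cascade** — patterns first; if any pattern fires in a document its
  pairs are the answer; else the classifier; else known side effects
  among abstract co-occurrences. The cascade granularity is per document
  (the natural reading of "if a CID was found"); a per-sentence variant
  would be possible but is not what the abstract-level protocol scores.
* **union** — all components run, outputs merged.
* **union_title_patterns** — union, with pattern matching restricted to
  the title (most pattern-expressible relations already surface there).

Whether the knowledge base should contribute pairs, only filter, or both
is genuinely underdetermined; `ek_role` exposes all three with `"both"`
as default. In every mode the last step removes pairs with a therapeutic
entry. Duplicates keep the highest-priority provenance
(pattern > ml > kb). These choices yield the invariants the tests assert:
cascade ⊆ union, title-union ⊆ union, no therapeutic pair in any final
output.

Evaluation is identifier-exact at the document level: predictions and gold
are sets of (pmid, chemical id, disease id) triples; P, R and F are
percentages with zero denominators scored 0, rounded half-up to two
decimals to match published tables (unrounded values are also exposed).

## The synthetic corpus generator

Real BC5-CDR data and the curated knowledge base are licensed external
resources; the generator (`generate_corpus()`) builds corpora with the
same *mechanics* so every stage is testable offline. Documents are
assembled from sentence templates over a synthetic vocabulary
(`C000001`-style ids, pronounceable pseudoword surfaces):
pattern-positive sentences, trigger-verb positives ("provoked" — a verb
deliberately outside the pattern inventory so the classifier and matcher
are separable signals), bystander co-occurrences, indication contexts,
and cross-sentence positives (chemical and disease in different
sentences). NER noise is applied per mention: misses, boundary truncation
of multi-word spans, and failed normalization (`"-1"`). Every planted fact
is recorded in a bookkeeping ledger so expected values of downstream
metrics are computable exactly, and identical configurations generate
byte-identical corpora.

Defaults mirror the reported gold composition: about 30% of planted
relations are abstract-only, the rest sentence-level, of which 40% use
trigger patterns; 20% of documents carry an indication sentence; noise is
off unless requested. What the generator does *not* emulate is real
biomedical language — lexical variation, negation, anaphora, composite
mentions, long coordinated clauses. Passing tests on synthetic corpora
therefore demonstrate the mechanics (offset arithmetic, set theory,
learnability, filter correctness), not corpus-level performance on real
abstracts, which depends on NER quality and knowledge-base coverage that
only the licensed resources provide.

## Numerical and scale choices

* Rounding: half-up at two decimals for reported percentages, matching
  printed tables; raw values retained.
* Tie-breaks: overlap resolution prefers longer, then leftmost; candidate
  tables are sorted by (pmid, chemical, disease) so all outputs are
  deterministic.
* Degenerate inputs: empty corpora, empty gold, single-class training
  sets, incomplete vote sets and dual-labeled knowledge-base pairs all
  raise typed errors or defined empty results rather than propagating
  silently.
* Test problem sizes are chosen to keep the whole suite in a few minutes
  of a single CPU while leaving Monte-Carlo margins comfortable: 1,000
  instances for the cross-validation recovery checks, 500 documents for
  the pipeline set-theory suite, 10,000 simulated tasks for the crowd
  closed-form comparison, 100 random feature fixtures and 1,000 random
  overlap clusters for the brute-force oracles.

## Known limitations

Negation is not modeled ("no necrosis was observed" still yields a
candidate); long multi-entity sentences produce instance explosions the
classifier must sort out; cross-sentence relations are reachable only
through the knowledge base; identifier mapping between vocabularies is a
user-supplied table, and unmapped identifiers silently never match —
explicitly, because silent partial mapping is how false negatives hide.
These mirror the main error sources reported for systems of this design.
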