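---
title: "Extracting opioid-related adverse drug events from discharge summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting opioid-related adverse drug events from discharge summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oradex)
```

## The problem

Hospital discharge summaries narrate, in free text, what happened to a
patient during an admission - including adverse drug events (ADEs) that are
rarely captured in structured fields. For opioids, events such as
respiratory depression, oversedation, hypotension, constipation or confusion
are frequently documented only as prose ("morphine ... may have contributed
to his altered mental status"). Surfacing these mentions at scale is a
pharmacovigilance task: the output is a set of *candidate* (drug, event)
pairs for expert review, not causal claims.

`oradex` implements a rule-based extraction pipeline for this task, plus a
synthetic note generator so every stage can be exercised and scored without
access to restricted clinical data.

## The pipeline

1. **Section targeting.** ADE narratives concentrate in three sections:
   *brief hospital course*, *hospital course*, and *history of present
   illness*. `detect_sections()` locates these headers (case-insensitive, at
   line start, optional colon) and bounds each section at the next
   header-like line. Text outside the three sections is ignored by default;
   `scan_whole_note = TRUE` treats a header-free note as one pseudo-section.

2. **Sentence segmentation.** `split_sentences()` places boundaries at
   sentence-final punctuation followed by whitespace, with clinical
   suppressions: decimals (`0.4 mg`) never split; de-identification
   placeholders `[** ... **]` are atomic; after a listed abbreviation
   (`q.`, `hr.`, `mg.`, `Dr.`, `am.`, ...) a boundary is placed only when
   the continuation starts with a capital. This keeps `"q. 4 hr. prn"`
   together while still splitting `"... 11:30 am. Code blue was called"`.
   Blank lines and `#`-prefixed problem-list bullets always break.

3. **Entity matching.** `match_entities()` finds opioid drugs (brand and
   generic surfaces, normalized to the generic with pharmacological class:
   natural / semisynthetic / synthetic), antidote terms (naloxone, Narcan),
   trigger phrases, and adverse-event terms. Matching is case-insensitive,
   word-boundary anchored, multi-word phrases as token sequences,
   leftmost-longest wins, non-overlapping within a type. The adverse-event
   recognizer is pluggable: the shipped default is a dictionary over the
   packaged synonym table; any function mapping sentence text to candidate
   spans (for example a learned NER model) can be substituted unchanged,
   and an external process can be wrapped with `make_external_recognizer()`.

4. **Normalization.** `normalize_ae()` case-folds, strips punctuation,
   expands packaged abbreviations (`AMS`, `SOB`, `resp`), and looks the
   phrase up in a MedDRA-style synonym-to-preferred-term table covering the
   opioid ADE domain. Licensed vocabularies (UMLS, full MedDRA) cannot be
   redistributed, so the table is a small, versioned, user-replaceable
   resource; a licensed mapping can be dropped in by pointing
   `load_lexicons()` at another directory. Fuzzy matching (normalized edit
   similarity) exists but is off by default: determinism is preferred over
   marginal recall.

5. **Linking rules.** Two rules emit candidate pairs over a context window
   of `window = 3` sentences on each side of an anchor (the reported
   heuristic for drug and event mentions that do not co-occur in one
   sentence):
   - *Trigger-phrase rule*: an anchor is a sentence containing a trigger
     phrase ("contributed to", "secondary to", ...) with an opioid mention
     in the window. Every in-window drug is paired with every in-window
     event.
   - *Antidote rule*: an anchor is any naloxone/Narcan mention; the rescue
     itself is indirect evidence of an opioid event nearby.
   Windows never cross section boundaries unless
   `cross_section_windows = TRUE`. When several anchors reach the same
   (drug mention, event mention) pair, the pair is kept once, from the
   anchor with the smallest event-sentence distance; both the drug and the
   event distance are recorded for audit. The window is anchored on the
   trigger sentence: the prose of the source material is ambiguous between
   anchoring on the drug or the trigger, and the trigger anchor keeps both
   published worked examples correct while the audit columns make the
   choice inspectable.

6. **False-positive filters.** `apply_filters()` flags - never deletes -
   pairs matching the three documented error patterns, in fixed order with
   first-match-wins audit: `pain_indication` (the event term contains a
   pain token: the drug's indication, not its effect), `medication_change`
   (the pair's drug is the target of a "changed/switched ... to X"
   construction and the event is the switch's reason - only the target
   drug's pair is flagged, the prior drug's pairing is left standing), and
   `negated_ae` (the event mention is denied). Negation follows the
   forward-scope convention: a cue ("no", "no further", "denies",
   "without", "not", "negative for") negates mentions after it in the same
   sentence unless a termination cue ("but", "however") intervenes.

7. **Evaluation and reporting.** `evaluate_note_level()` scores
   presence/absence of any unfiltered pair per note;
   `evaluate_pair_level()` matches (note, generic, preferred term) tuples.
   Zero-denominator metrics are reported as `NA` ("undefined"), never
   silently 0 or 1, and values stay at full precision until printing (2
   decimals). `build_report()` derives the dashboard-style tables: patient
   counts by class, drug, (drug, event) and brand/generic kind, a
   drug-by-event matrix for chord-style plots, per-drug top-k events
   (count-descending, alphabetical tie-break), and demographic summaries.

## The lexicons are data, not code

The shipped resources (`default_lexicon_dir()`) include 31 opioid surface
forms over 13 generics with class labels, a published-base trigger set plus
exactly 58 curated trigger phrases, antidote terms, 28 adverse-event
concepts with 83 synonyms, negation/termination cues, pain tokens, and
sentence-splitting abbreviations. Every file is plain text and
user-replaceable; the curated trigger file in particular is a working
reconstruction and is expected to be swapped for a site's own list. The
bare keyword "narcotics" is excluded by default - it cannot be resolved to
a specific drug - but `load_lexicons(include_narcotics = TRUE)` adds it,
since its absence is a known false-negative source.

## What the synthetic generator does and does not emulate

`generate_corpus()` builds notes with the three canonical sections,
templated filler prose, and planted events: trigger-context pairs,
naloxone-rescue narratives, and the three confounder patterns, each at a
configurable probability, with drug/event sentence offsets up to
`max_distance` from the anchor. Defaults (`p_true_orade = 0.4`,
`p_antidote_event = 0.15`, confounders 0.2 each, `max_distance = 2`) were
chosen once to resemble a prescreened corpus in which roughly half the
notes document an event; they are not tuned to any test outcome. Event
blocks are separated by more than `window` filler sentences so the context
windows of distinct planted events cannot interact; the switch confounder
names no second opioid as the switch source, because the documented filter
flags only the switch-target drug and a planted opioid source would
legitimately survive filtering inside a note labeled negative.

Gold labels record every planted pair by generic drug and preferred term;
pairs planted beyond the extraction window (possible when
`max_distance > window`) carry an `out_of_window` flag so tests can assert
they are correctly missed. Generation is driven by per-note substreams
derived from the seed, so corpora are byte-identical across runs and stable
under `n_notes` growth.

The generator's templated prose is deliberately simple: real discharge
summaries have misspellings, inconsistent headers, wrapped lines, copy-paste
duplication, list-formatted medication sections and far richer vocabulary.
Perfect scores on synthetic corpora therefore demonstrate that the
machinery implements its rules exactly - planted recall is 1.0 *by
construction* when every planted surface is lexicon-covered - not that the
pipeline achieves comparable accuracy on real notes, where reported
performance for this class of system is far lower.

## Numerical and design choices

- Offsets are 0-based half-open character positions into the raw note,
  shared by every span type; surfaces always equal the note substring.
- Ties between equal-length overlapping matches go to the leftmost
  (deterministic); per entity type matches never overlap.
- Sentence-boundary suppression after an abbreviation applies only when the
  continuation starts lowercase or with a digit; a capitalized continuation
  opens a new sentence. This is the only reading we found consistent with
  clinical dosing strings and time-of-day abbreviations at sentence ends.
- Degenerate inputs: empty files yield empty corpora; a note with no
  recognized header yields no sentences (and no pairs) by default; an empty
  trigger file loads with a warning; an empty drug lexicon is an error.
- Note-level truth for a note whose only planted pair lies out of window is
  still positive: the event is documented in the text even if the window
  heuristic cannot link it.
- Scoring counts unfiltered pairs only; `include_filtered = TRUE` is
  available since it is not documented whether flagged-but-detected pairs
  were counted as detections in prior work.
- Problem sizes in the test suite and acceptance script (corpora of 40-200
  notes) were chosen as the smallest sizes at which every planted pattern
  occurs many times per run.

## Known limitations

- The dictionary recognizer cannot find events outside its synonym table
  (the pluggable recognizer interface is the intended remedy).
- Negation handling covers denial only - no uncertainty, hypothetical or
  family-history assertion classes.
- Concept fragmentation (an event and its drug linked only across
  paragraphs) is out of reach of a fixed sentence window by design.
- The all-pairs window policy records every in-window combination with its
  distances rather than only nearest pairs; a nearest-only mode would be a
  natural flag but is not implemented.

## A worked run

```{r example}
bundle <- load_lexicons(quiet = TRUE)
corp <- generate_corpus(sim_config(n_notes = 50, seed = 1), bundle)
res <- run_pipeline(corp$notes, bundle)
res$log$n_pairs
evaluate_note_level(res$pairs, corp$gold)
evaluate_pair_level(res$pairs, corp$gold)
head(build_report(res$pairs, corp$notes)$top_ae)
```
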