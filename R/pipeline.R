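#' Extract candidate pairs from a single note
#'
#' Runs the full per-note pipeline: section detection, sentence
#' segmentation, entity matching, negation flagging, both linking rules, and
#' the false-positive filters.
#'
#' @param note One-row note data.frame (or list) with `note_id` and `text`.
#' @param bundle An `orade_lexicon`.
#' @param config A [pairing_config()].
#' @param ae_recognizer Optional recognizer (see [dictionary_recognizer()]).
#' @param scan_whole_note Process notes lacking the target headers as one
#'   pseudo-section (default `FALSE`).
#'
#' @return A candidate-pair data.frame for the note.
#' @export
extract_note_pairs <- function(note, bundle, config = pairing_config(),
                               ae_recognizer = NULL,
                               scan_whole_note = FALSE) {
  sentences <- segment_note(note$text, bundle,
                            scan_whole_note = scan_whole_note,
                            note_id = note$note_id)
  if (nrow(sentences) == 0L) return(ox_empty_pairs())
  mentions <- match_entities(sentences, bundle, ae_recognizer)
  mentions <- detect_negation(mentions, sentences, bundle)
  pairs <- rbind(apply_trigger_rule(mentions, sentences, config),
                 apply_antidote_rule(mentions, sentences, config))
  apply_filters(pairs, sentences, bundle, config)
}

#' Run the extraction pipeline over a corpus
#'
#' Deterministic given inputs and configuration. The run log records the
#' lexicon version and per-stage counts (notes, sections, sentences,
#' mentions by type, pairs before and after filtering).
#'
#' @param notes Note data.frame (from [read_notes()] or
#'   [generate_corpus()]), or a path to a JSONL notes file.
#' @param bundle An `orade_lexicon`; loaded from the packaged defaults when
#'   `NULL`.
#' @param config A [pairing_config()].
#' @param ae_recognizer Optional recognizer function.
#' @param scan_whole_note See [extract_note_pairs()].
#'
#' @return A list with `pairs` (all notes' candidate pairs) and `log`.
#' @export
run_pipeline <- function(notes, bundle = NULL, config = pairing_config(),
                         ae_recognizer = NULL, scan_whole_note = FALSE) {
  if (is.character(notes)) notes <- read_notes(notes, "jsonl")
  if (is.null(bundle)) bundle <- load_lexicons(quiet = TRUE)
  n_sections <- 0L
  n_sentences <- 0L
  mention_counts <- c(opioid_drug = 0L, antidote = 0L, trigger_phrase = 0L,
                      adverse_event = 0L)
  pair_parts <- vector("list", nrow(notes))
  for (i in seq_len(nrow(notes))) {
    note <- notes[i, ]
    sentences <- segment_note(note$text, bundle,
                              scan_whole_note = scan_whole_note,
                              note_id = note$note_id)
    n_sentences <- n_sentences + nrow(sentences)
    n_sections <- n_sections + length(unique(sentences$section))
    if (nrow(sentences) == 0L) next
    mentions <- match_entities(sentences, bundle, ae_recognizer)
    mentions <- detect_negation(mentions, sentences, bundle)
    tab <- table(mentions$entity_type)
    mention_counts[names(tab)] <- mention_counts[names(tab)] + as.integer(tab)
    pairs <- rbind(apply_trigger_rule(mentions, sentences, config),
                   apply_antidote_rule(mentions, sentences, config))
    pair_parts[[i]] <- apply_filters(pairs, sentences, bundle, config)
  }
  pairs <- ox_rbind(pair_parts)
  if (is.null(pairs)) pairs <- ox_empty_pairs()
  rownames(pairs) <- NULL
  log <- list(lexicon_version = bundle$version,
              n_notes = nrow(notes),
              n_sections = n_sections,
              n_sentences = n_sentences,
              mentions_by_type = as.list(mention_counts),
              n_pairs = nrow(pairs),
              n_pairs_unfiltered = sum(!pairs$filtered),
              window = config$window,
              filters_enabled = config$filters_enabled)
  list(pairs = pairs, log = log)
}
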