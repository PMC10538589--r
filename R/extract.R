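#' Dictionary-based adverse-event recognizer
#'
#' The default recognizer behind [match_entities()]: matches the synonym
#' column of the packaged MedDRA-style table against sentence text
#' (case-insensitive, word-boundary anchored, multi-word phrases as token
#' sequences, leftmost-longest wins). Any recognizer conforming to the same
#' contract - a function taking sentence text and returning a data.frame
#' with 0-based half-open `start`, `end` and `surface` columns - can be
#' plugged in unchanged, e.g. a learned NER model.
#'
#' @param bundle An `orade_lexicon`.
#' @return A recognizer function.
#' @export
dictionary_recognizer <- function(bundle) {
  regex <- bundle$matchers$ae
  function(text) ox_match_phrases(text, regex)
}

#' External-command adverse-event recognizer
#'
#' Wraps a shell command as a recognizer: the sentence text is written to the
#' command's standard input and the command must print zero or more
#' tab-separated `start<TAB>end<TAB>surface` triples (0-based half-open
#' offsets), one per line.
#'
#' @param command Shell command line.
#' @return A recognizer function usable with [match_entities()].
#' @export
make_external_recognizer <- function(command) {
  force(command)
  function(text) {
    out <- system(command, input = text, intern = TRUE)
    out <- out[nzchar(out)]
    if (length(out) == 0L) {
      return(data.frame(start = integer(), end = integer(),
                        surface = character(), stringsAsFactors = FALSE))
    }
    parts <- strsplit(out, "\t", fixed = TRUE)
    bad <- vapply(parts, length, 0L) < 3L
    if (any(bad)) stop("external recognizer emitted a malformed line")
    data.frame(start = as.integer(vapply(parts, `[[`, "", 1L)),
               end = as.integer(vapply(parts, `[[`, "", 2L)),
               surface = vapply(parts, `[[`, "", 3L),
               stringsAsFactors = FALSE)
  }
}

# resolve overlapping candidate spans: longest first, then leftmost
ox_resolve_overlaps <- function(df) {
  if (nrow(df) < 2L) return(df)
  df <- df[order(-(df$end - df$start), df$start), , drop = FALSE]
  keep <- logical(nrow(df))
  taken <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(df))) {
    s <- df$start[i]; e <- df$end[i]
    if (nrow(taken) == 0L || all(e <= taken[, 1] | s >= taken[, 2])) {
      keep[i] <- TRUE
      taken <- rbind(taken, c(s, e))
    }
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start), , drop = FALSE]
}

ox_empty_mentions <- function() {
  data.frame(note_id = character(), sentence_index = integer(),
             section = character(), start = integer(), end = integer(),
             surface = character(), entity_type = character(),
             normalized = character(), drug_class = character(),
             drug_kind = character(), concept_id = character(),
             ae_llt = character(), unmapped = logical(), negated = logical(),
             stringsAsFactors = FALSE)
}

#' Find typed entity mentions in a note's sentences
#'
#' Matches opioid drug surfaces, antidote terms and trigger phrases against
#' the lexicon bundle, and adverse-event candidate spans through the supplied
#' recognizer (dictionary default). Per entity type, matches are
#' non-overlapping with longest-match-first and leftmost tie-breaking. Drug
#' mentions are normalized to their generic name with pharmacological class
#' and brand/generic kind attached; adverse-event spans pass through
#' [normalize_ae()], with unmapped spans kept (normalized to the cleaned raw
#' phrase) and flagged `unmapped`.
#'
#' @param sentences Sentence data.frame for one note, from [segment_note()].
#' @param bundle An `orade_lexicon`.
#' @param ae_recognizer Recognizer function or `NULL` for the dictionary
#'   default.
#' @param fuzzy_threshold Passed through to [normalize_ae()].
#'
#' @return A mention data.frame: `note_id`, `sentence_index`, `section`,
#'   `start`, `end` (note-absolute 0-based half-open), `surface`,
#'   `entity_type` (one of `opioid_drug`, `antidote`, `trigger_phrase`,
#'   `adverse_event`), `normalized`, `drug_class`, `drug_kind`,
#'   `concept_id`, `ae_llt`, `unmapped`, `negated` (all `FALSE`; see
#'   [detect_negation()]).
#' @export
match_entities <- function(sentences, bundle, ae_recognizer = NULL,
                           fuzzy_threshold = NULL) {
  if (is.null(ae_recognizer)) ae_recognizer <- dictionary_recognizer(bundle)
  if (nrow(sentences) == 0L) return(ox_empty_mentions())

  rows <- list()
  for (i in seq_len(nrow(sentences))) {
    sen <- sentences[i, ]
    txt <- sen$text

    typed <- list(
      opioid_drug = ox_match_phrases(txt, bundle$matchers$drug),
      antidote = ox_match_phrases(txt, bundle$matchers$antidote),
      trigger_phrase = ox_match_phrases(txt, bundle$matchers$trigger)
    )
    ae <- tryCatch(ae_recognizer(txt), error = function(e) {
      stop("adverse-event recognizer failed on sentence ",
           sen$sentence_index, ": ", conditionMessage(e), call. = FALSE)
    })
    if (nrow(ae) > 0L) {
      if (is.null(ae$surface)) ae$surface <- substring(txt, ae$start + 1L, ae$end)
      ok <- ae$start >= 0L & ae$end <= nchar(txt) & ae$start < ae$end
      ae <- ox_resolve_overlaps(ae[ok, , drop = FALSE])
    }
    typed$adverse_event <- ae

    for (ty in names(typed)) {
      m <- typed[[ty]]
      if (nrow(m) == 0L) next
      norm <- character(nrow(m))
      dclass <- dkind <- cid <- llt <- rep(NA_character_, nrow(m))
      unmapped <- rep(FALSE, nrow(m))
      for (k in seq_len(nrow(m))) {
        key <- ox_clean(m$surface[k])
        if (ty == "opioid_drug") {
          idx <- bundle$maps$drug[key]
          norm[k] <- bundle$drugs$generic[idx]
          dclass[k] <- bundle$drugs$class[idx]
          dkind[k] <- bundle$drugs$kind[idx]
        } else if (ty == "trigger_phrase") {
          norm[k] <- unname(bundle$maps$trigger[key])
        } else if (ty == "antidote") {
          norm[k] <- key
        } else {
          hit <- normalize_ae(m$surface[k], bundle, fuzzy_threshold)
          norm[k] <- if (hit$matched) hit$preferred_term else hit$query
          cid[k] <- hit$concept_id
          llt[k] <- hit$lower_level_term
          unmapped[k] <- !hit$matched
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        note_id = sen$note_id, sentence_index = sen$sentence_index,
        section = sen$section,
        start = sen$start + m$start, end = sen$start + m$end,
        surface = m$surface, entity_type = ty, normalized = norm,
        drug_class = dclass, drug_kind = dkind, concept_id = cid,
        ae_llt = llt, unmapped = unmapped, negated = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  res <- ox_rbind(rows)
  if (is.null(res)) return(ox_empty_mentions())
  res <- res[order(res$start, res$entity_type), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Flag negated adverse-event mentions (ConText-style forward scope)
#'
#' An adverse-event mention is marked `negated` when a negation cue ("no",
#' "no further", "denies", "without", "not", "negative for", ...) precedes it
#' within the same sentence and no termination cue ("but", "however", ...)
#' intervenes between the cue and the mention. Scope is intra-sentence and
#' forward-only, the established convention for these cue types. Mentions are
#' never added, removed or re-spanned - only the flag is toggled - so the
#' pass is idempotent. Only `adverse_event` mentions are flagged.
#'
#' @param mentions Mention data.frame from [match_entities()].
#' @param sentences Matching sentence data.frame.
#' @param bundle An `orade_lexicon` (supplies the cue lists).
#'
#' @return `mentions` with the `negated` column updated.
#' @export
detect_negation <- function(mentions, sentences, bundle) {
  if (nrow(mentions) == 0L) return(mentions)
  idx_ae <- which(mentions$entity_type == "adverse_event")
  if (length(idx_ae) == 0L) return(mentions)
  for (si in unique(mentions$sentence_index[idx_ae])) {
    sen <- sentences[sentences$sentence_index == si, ]
    if (nrow(sen) == 0L) next
    cues <- ox_match_phrases(sen$text, bundle$matchers$negation)
    if (nrow(cues) == 0L) next
    terms <- ox_match_phrases(sen$text, bundle$matchers$termination)
    cues$start <- cues$start + sen$start; cues$end <- cues$end + sen$start
    if (nrow(terms) > 0L) {
      terms$start <- terms$start + sen$start; terms$end <- terms$end + sen$start
    }
    for (k in idx_ae[mentions$sentence_index[idx_ae] == si]) {
      ms <- mentions$start[k]
      before <- cues[cues$end <= ms, , drop = FALSE]
      if (nrow(before) == 0L) next
      neg <- any(vapply(seq_len(nrow(before)), function(b) {
        !any(terms$start >= before$end[b] & terms$end <= ms)
      }, TRUE))
      mentions$negated[k] <- neg
    }
  }
  mentions
}
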