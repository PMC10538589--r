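#' Pairing configuration
#'
#' @param window Context window in sentences on each side of an anchor
#'   sentence (default 3, the reported heuristic for linking drug and event
#'   mentions that do not co-occur in one sentence).
#' @param filters_enabled Which false-positive filters [apply_filters()]
#'   runs, in fixed order; default all three.
#' @param cross_section_windows If `FALSE` (default) context windows never
#'   cross section boundaries, keeping windows clinically coherent.
#'
#' @return A list of class `orade_pairing_config`.
#' @export
pairing_config <- function(window = 3L,
                           filters_enabled = c("pain_indication",
                                               "medication_change",
                                               "negated_ae"),
                           cross_section_windows = FALSE) {
  window <- as.integer(window)
  stopifnot(length(window) == 1L, !is.na(window), window >= 0L)
  filters_enabled <- match.arg(filters_enabled,
                               c("pain_indication", "medication_change",
                                 "negated_ae"),
                               several.ok = TRUE)
  structure(list(window = window,
                 filters_enabled = filters_enabled,
                 cross_section_windows = isTRUE(cross_section_windows)),
            class = "orade_pairing_config")
}

ox_empty_pairs <- function() {
  data.frame(
    note_id = character(), rule = character(), trigger_used = character(),
    anchor_sentence = integer(),
    drug_surface = character(), generic_drug = character(),
    drug_class = character(), drug_kind = character(),
    drug_sentence = integer(), drug_start = integer(), drug_end = integer(),
    drug_distance = integer(),
    ae_surface = character(), ae_pt = character(), ae_llt = character(),
    ae_concept_id = character(), ae_sentence = integer(),
    ae_start = integer(), ae_end = integer(),
    ae_unmapped = logical(), ae_negated = logical(),
    sentence_distance = integer(),
    filtered = logical(), filter_reason = character(),
    stringsAsFactors = FALSE)
}

# shared windowed pairing around a set of anchor sentences
ox_pair_on_anchors <- function(anchors, trigger_of, mentions, sentences,
                               config, rule) {
  if (length(anchors) == 0L) return(ox_empty_pairs())
  drugs <- mentions[mentions$entity_type == "opioid_drug", , drop = FALSE]
  aes <- mentions[mentions$entity_type == "adverse_event", , drop = FALSE]
  if (nrow(drugs) == 0L || nrow(aes) == 0L) return(ox_empty_pairs())
  sec_of <- setNames(sentences$section, as.character(sentences$sentence_index))
  same_sec <- function(a, b) {
    config$cross_section_windows ||
      identical(sec_of[[as.character(a)]], sec_of[[as.character(b)]])
  }
  w <- config$window
  rows <- list()
  for (a in anchors) {
    din <- which(abs(drugs$sentence_index - a) <= w &
                   vapply(drugs$sentence_index, same_sec, TRUE, b = a))
    ain <- which(abs(aes$sentence_index - a) <= w &
                   vapply(aes$sentence_index, same_sec, TRUE, b = a))
    if (length(din) == 0L || length(ain) == 0L) next
    for (d in din) {
      for (e in ain) {
        rows[[length(rows) + 1L]] <- data.frame(
          note_id = drugs$note_id[d], rule = rule,
          trigger_used = if (is.null(trigger_of)) NA_character_ else trigger_of[[as.character(a)]],
          anchor_sentence = a,
          drug_surface = drugs$surface[d],
          generic_drug = drugs$normalized[d],
          drug_class = drugs$drug_class[d],
          drug_kind = drugs$drug_kind[d],
          drug_sentence = drugs$sentence_index[d],
          drug_start = drugs$start[d], drug_end = drugs$end[d],
          drug_distance = abs(drugs$sentence_index[d] - a),
          ae_surface = aes$surface[e], ae_pt = aes$normalized[e],
          ae_llt = aes$ae_llt[e], ae_concept_id = aes$concept_id[e],
          ae_sentence = aes$sentence_index[e],
          ae_start = aes$start[e], ae_end = aes$end[e],
          ae_unmapped = aes$unmapped[e], ae_negated = aes$negated[e],
          sentence_distance = abs(aes$sentence_index[e] - a),
          filtered = FALSE, filter_reason = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- ox_rbind(rows)
  if (is.null(res)) return(ox_empty_pairs())
  # collapse duplicates by (drug mention, AE mention): keep the anchor giving
  # the smallest AE sentence distance, then the smallest drug distance
  res <- res[order(res$sentence_distance, res$drug_distance,
                   res$anchor_sentence), , drop = FALSE]
  key <- paste(res$drug_start, res$drug_end, res$ae_start, res$ae_end)
  res <- res[!duplicated(key), , drop = FALSE]
  res <- res[order(res$anchor_sentence, res$drug_start, res$ae_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Link drugs to adverse events with the trigger-phrase rule
#'
#' Anchor sentences are those containing a trigger phrase with an opioid-drug
#' mention either in the same sentence or within the context window (same
#' section). For each anchor, every opioid-drug mention within the window is
#' paired with every adverse-event mention within the window; a (drug
#' mention, AE mention) pair reachable from several anchors is kept once,
#' from the anchor with the smallest AE sentence distance.
#'
#' @param mentions Mention data.frame for one note (after
#'   [detect_negation()]).
#' @param sentences Sentence data.frame for the same note.
#' @param config A [pairing_config()].
#'
#' @return A candidate-pair data.frame (`rule = "trigger_phrase"`,
#'   `trigger_used` set to the anchor's first trigger phrase); zero rows when
#'   no anchor qualifies.
#' @export
apply_trigger_rule <- function(mentions, sentences, config = pairing_config()) {
  trigs <- mentions[mentions$entity_type == "trigger_phrase", , drop = FALSE]
  drugs <- mentions[mentions$entity_type == "opioid_drug", , drop = FALSE]
  if (nrow(trigs) == 0L || nrow(drugs) == 0L) return(ox_empty_pairs())
  sec_of <- setNames(sentences$section, as.character(sentences$sentence_index))
  anchors <- integer()
  trigger_of <- list()
  for (t in unique(trigs$sentence_index)) {
    near <- abs(drugs$sentence_index - t) <= config$window &
      (config$cross_section_windows |
         vapply(drugs$sentence_index,
                function(s) identical(sec_of[[as.character(s)]],
                                      sec_of[[as.character(t)]]), TRUE))
    if (any(near)) {
      anchors <- c(anchors, t)
      tin <- trigs[trigs$sentence_index == t, , drop = FALSE]
      trigger_of[[as.character(t)]] <- tin$normalized[which.min(tin$start)]
    }
  }
  ox_pair_on_anchors(anchors, trigger_of, mentions, sentences, config,
                     rule = "trigger_phrase")
}

#' Link drugs to adverse events with the antidote rule
#'
#' Anchor sentences are those mentioning a reversal agent (naloxone/Narcan by
#' default). Every opioid-drug mention within the context window is paired
#' with every adverse-event mention within the window; the antidote itself is
#' never emitted as a drug or an adverse event.
#'
#' @inheritParams apply_trigger_rule
#' @return A candidate-pair data.frame (`rule = "antidote"`).
#' @export
apply_antidote_rule <- function(mentions, sentences, config = pairing_config()) {
  anti <- mentions[mentions$entity_type == "antidote", , drop = FALSE]
  if (nrow(anti) == 0L) return(ox_empty_pairs())
  ox_pair_on_anchors(sort(unique(anti$sentence_index)), NULL, mentions,
                     sentences, config, rule = "antidote")
}

ox_switch_regex <- "(?i)\\b(?:chang(?:e|ed|ing)|switch(?:ed|ing)?)\\b[^.;\n]{0,80}?\\bto[ \t]+([A-Za-z0-9]+)"

# switch-target drug tokens named in change/switch constructions of a sentence
ox_switch_targets <- function(text) {
  m <- gregexpr(ox_switch_regex, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character())
  hits <- regmatches(text, list(m))[[1]]
  tolower(sub(ox_switch_regex, "\\1", hits, perl = TRUE))
}

#' Flag known false-positive candidate pairs
#'
#' Pairs are flagged, never deleted, by the first matching filter in fixed
#' order:
#' \enumerate{
#'   \item `pain_indication` - the adverse-event surface or preferred term
#'     contains a pain token ("pain" by default): these are overwhelmingly
#'     the drug's indication, not its effect;
#'   \item `medication_change` - the drug's or the event's sentence contains
#'     a change/switch construction ("changed ... to X", "switch to X", with
#'     inflections) and the pair's drug is the switch target X: the event is
#'     the reason for the switch, attributed to the prior drug;
#'   \item `negated_ae` - the adverse-event mention is negated.
#' }
#'
#' @param pairs Candidate pairs from the pairing rules.
#' @param sentences Sentence data.frame covering every `note_id` in `pairs`
#'   (a multi-note data.frame is accepted).
#' @param bundle An `orade_lexicon` (pain tokens).
#' @param config A [pairing_config()]; `filters_enabled` selects filters.
#'
#' @return `pairs` with `filtered` and `filter_reason` set; the multiset of
#'   rows is preserved.
#' @export
apply_filters <- function(pairs, sentences, bundle, config = pairing_config()) {
  if (nrow(pairs) == 0L) return(pairs)
  fe <- config$filters_enabled
  stext <- setNames(sentences$text,
                    paste(sentences$note_id, sentences$sentence_index))
  pairs$filtered <- FALSE
  pairs$filter_reason <- NA_character_
  pain <- bundle$pain_tokens
  for (i in seq_len(nrow(pairs))) {
    reason <- NA_character_
    if ("pain_indication" %in% fe) {
      toks <- c(ox_tokens(pairs$ae_surface[i]), ox_tokens(pairs$ae_pt[i]))
      if (any(toks %in% pain)) reason <- "pain_indication"
    }
    if (is.na(reason) && "medication_change" %in% fe) {
      keys <- unique(paste(pairs$note_id[i],
                           c(pairs$ae_sentence[i], pairs$drug_sentence[i])))
      targets <- unique(unlist(lapply(stext[keys], function(tx) {
        if (is.na(tx)) character() else ox_switch_targets(tx)
      })))
      dtoks <- unique(c(ox_tokens(pairs$drug_surface[i]),
                        ox_tokens(pairs$generic_drug[i])))
      if (length(targets) > 0L && any(targets %in% dtoks)) {
        reason <- "medication_change"
      }
    }
    if (is.na(reason) && "negated_ae" %in% fe && isTRUE(pairs$ae_negated[i])) {
      reason <- "negated_ae"
    }
    if (!is.na(reason)) {
      pairs$filtered[i] <- TRUE
      pairs$filter_reason[i] <- reason
    }
  }
  pairs
}

#' Aggregate candidate pairs into detection-rule strata
#'
#' Over unfiltered pairs, computes per stratum the five corpus-level counts:
#' unique opioid drugs (by generic name, brands collapsed), unique adverse
#' events (by preferred term), unique candidate pairs (generic, preferred
#' term), discharge summaries, and unique patients. Strata: `trigger_phrase`
#' (pairs found by the trigger rule), `antidote_only` (found by the antidote
#' rule and not the trigger rule), `both`, and `overall` (union).
#'
#' @param pairs Candidate-pair data.frame (possibly multi-note).
#' @param notes Note data.frame supplying `note_id` to `subject_id`.
#'
#' @return A list with `summary` (one row per stratum), `drug_patients`
#'   (patients per generic drug) and `drug_ae_patients` (patients per
#'   (generic drug, preferred term)).
#' @export
aggregate_pairs <- function(pairs, notes) {
  subj <- setNames(notes$subject_id, notes$note_id)
  up <- pairs[!pairs$filtered, , drop = FALSE]
  key <- function(df) paste(tolower(df$generic_drug), tolower(df$ae_pt), sep = "||")
  trig_keys <- unique(key(up[up$rule == "trigger_phrase", , drop = FALSE]))
  anti_keys <- unique(key(up[up$rule == "antidote", , drop = FALSE]))
  strata <- list(
    trigger_phrase = trig_keys,
    antidote_only = setdiff(anti_keys, trig_keys),
    both = intersect(trig_keys, anti_keys),
    overall = union(trig_keys, anti_keys)
  )
  count_stratum <- function(keys) {
    sub <- up[key(up) %in% keys, , drop = FALSE]
    data.frame(
      n_unique_drugs = length(unique(tolower(sub$generic_drug))),
      n_unique_aes = length(unique(tolower(sub$ae_pt))),
      n_unique_pairs = length(keys),
      n_summaries = length(unique(sub$note_id)),
      n_patients = length(unique(subj[sub$note_id])),
      stringsAsFactors = FALSE)
  }
  summary <- ox_rbind(lapply(strata, count_stratum))
  if (is.null(summary)) {
    summary <- data.frame(n_unique_drugs = integer(), n_unique_aes = integer(),
                          n_unique_pairs = integer(), n_summaries = integer(),
                          n_patients = integer())
  }
  summary <- cbind(stratum = names(strata), summary, stringsAsFactors = FALSE)
  rownames(summary) <- NULL

  agg_count <- function(by) {
    if (nrow(up) == 0L) {
      out <- as.data.frame(setNames(rep(list(character()), length(by)), by),
                           stringsAsFactors = FALSE)
      out$n_patients <- integer()
      return(out)
    }
    ag <- aggregate(list(n_patients = subj[up$note_id]),
                    by = lapply(by, function(col) {
                      v <- up[[col]]
                      v[is.na(v)] <- ""
                      v
                    }),
                    FUN = function(z) length(unique(z)))
    names(ag)[seq_along(by)] <- by
    ag[do.call(order, ag[by]), , drop = FALSE]
  }
  drug_patients <- agg_count("generic_drug")
  drug_ae_patients <- agg_count(c("generic_drug", "ae_pt"))
  rownames(drug_patients) <- rownames(drug_ae_patients) <- NULL
  list(summary = summary, drug_patients = drug_patients,
       drug_ae_patients = drug_ae_patients)
}
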