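#' Configuration for the synthetic discharge-summary generator
#'
#' Default event probabilities describe a corpus resembling an
#' ICD-9-prescreened set of summaries: a little under half the notes carry a
#' documented opioid adverse event, a minority contain an antidote-rescue
#' narrative, and each of the three known false-positive patterns
#' (pain-indication pairing, medication switch, negated mention) appears in
#' roughly a fifth of notes.
#'
#' @param n_notes Number of notes to generate.
#' @param seed Integer seed; identical config + seed reproduce byte-identical
#'   corpora. Per-note substreams are derived from the seed and note index,
#'   so a corpus is stable under `n_notes` changes up to the shared prefix.
#' @param p_true_orade Probability a note gets a planted trigger-context
#'   adverse event pair.
#' @param p_antidote_event Probability of a naloxone-rescue narrative (also a
#'   true pair).
#' @param p_indication_confounder,p_switch_confounder,p_negation_confounder
#'   Probabilities of planting each false-positive pattern.
#' @param max_distance Maximum sentence offset between a planted drug/event
#'   and its anchor sentence.
#' @param window Extraction window the gold `out_of_window` flag is computed
#'   against (planted pairs farther than this are recorded but expected to be
#'   missed).
#' @param drug_weights Optional named numeric vector of sampling weights by
#'   generic drug name.
#' @param ae_weights Optional named numeric vector of weights by adverse
#'   event concept id.
#'
#' @return A list of class `orade_sim_config`.
#' @export
sim_config <- function(n_notes, seed = 1L,
                       p_true_orade = 0.4, p_antidote_event = 0.15,
                       p_indication_confounder = 0.2,
                       p_switch_confounder = 0.2,
                       p_negation_confounder = 0.2,
                       max_distance = 2L, window = 3L,
                       drug_weights = NULL, ae_weights = NULL) {
  probs <- c(p_true_orade = p_true_orade, p_antidote_event = p_antidote_event,
             p_indication_confounder = p_indication_confounder,
             p_switch_confounder = p_switch_confounder,
             p_negation_confounder = p_negation_confounder)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("event probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_notes >= 0, max_distance >= 0, window >= 0)
  structure(list(n_notes = as.integer(n_notes), seed = as.integer(seed),
                 p_true_orade = p_true_orade,
                 p_antidote_event = p_antidote_event,
                 p_indication_confounder = p_indication_confounder,
                 p_switch_confounder = p_switch_confounder,
                 p_negation_confounder = p_negation_confounder,
                 max_distance = as.integer(max_distance),
                 window = as.integer(window),
                 drug_weights = drug_weights, ae_weights = ae_weights),
            class = "orade_sim_config")
}

ox_templates <- function() {
  read.csv(system.file("extdata", "templates", "templates.csv",
                       package = "oradex", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

# trigger phrases that read naturally inside the sentence templates
ox_generator_triggers <- c("contributed to", "likely due to",
                           "possibly due to", "thought to be due to",
                           "secondary to", "related to", "attributable to",
                           "linked to", "associated with")

ox_fill <- function(template, ...) {
  slots <- list(...)
  for (nm in names(slots)) {
    template <- gsub(paste0("{", nm, "}"), slots[[nm]], template, fixed = TRUE)
  }
  template
}

#' Generate a synthetic corpus with exact gold labels
#'
#' Each note carries the three canonical section headers with templated
#' filler prose; planted events are realized from sentence templates
#' parameterized by sampled drug surface (brand or generic), trigger phrase,
#' adverse-event synonym and sentence offsets up to `max_distance` from the
#' anchor. Event blocks are separated by more than `window` filler sentences
#' so that the context windows of distinct planted events never interact.
#' Gold records every planted true pair (by generic drug and preferred
#' term); confounder-only notes are labeled `has_orade = FALSE` and, with
#' all filters enabled, yield zero unfiltered pairs by construction.
#'
#' @param config An [sim_config()].
#' @param bundle An `orade_lexicon`; all planted surfaces come from it, so
#'   extraction recall on confounder-free corpora is 1 by construction.
#'
#' @return A list with `notes` (note data.frame), `gold` (gold data.frame:
#'   `note_id`, `has_orade`, `generic_drug`, `ae_pt`, `out_of_window`), and
#'   `demographics` (`subject_id`, `age`, `gender`, `ethnicity`).
#' @export
generate_corpus <- function(config, bundle = load_lexicons(quiet = TRUE)) {
  stopifnot(inherits(config, "orade_sim_config"))
  if (config$p_true_orade > 0 && nrow(bundle$ae_concepts) == 0L) {
    stop("cannot plant adverse events from an empty AE lexicon", call. = FALSE)
  }
  tpl <- ox_templates()
  tpl_of <- function(role) tpl$text[tpl$role == role]

  pain_pts <- vapply(bundle$concepts$preferred_term,
                     function(p) any(ox_tokens(p) %in% bundle$pain_tokens), TRUE)
  true_concepts <- bundle$concepts[!pain_pts, , drop = FALSE]
  pain_concepts <- bundle$concepts[pain_pts, , drop = FALSE]
  resp_ids <- intersect(c("C002", "C003", "C004", "C013", "C028"),
                        true_concepts$concept_id)
  if (length(resp_ids) == 0L) resp_ids <- true_concepts$concept_id

  drug_w <- rep(1, nrow(bundle$drugs))
  if (!is.null(config$drug_weights)) {
    w <- config$drug_weights[bundle$drugs$generic]
    drug_w <- ifelse(is.na(w), 0, w)
  }
  ae_w_of <- function(ids) {
    if (is.null(config$ae_weights)) return(rep(1, length(ids)))
    w <- config$ae_weights[ids]
    ifelse(is.na(w), 0, w)
  }

  sample_drug <- function() bundle$drugs[sample.int(nrow(bundle$drugs), 1L, prob = drug_w), ]
  sample_concept <- function(pool_ids) {
    cid <- if (length(pool_ids) == 1L) pool_ids else
      sample(pool_ids, 1L, prob = ae_w_of(pool_ids))
    syns <- bundle$ae_concepts[bundle$ae_concepts$concept_id == cid, ]
    syns[sample.int(nrow(syns), 1L), ]
  }
  cap1 <- function(x) {
    paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
  }

  notes_list <- vector("list", config$n_notes)
  gold_list <- vector("list", config$n_notes)
  demo_list <- vector("list", config$n_notes)
  sep_n <- config$window + 1L  # filler run preventing window interaction

  for (i in seq_len(config$n_notes)) {
    set.seed((config$seed %% 100000L) * 20011L + i * 7L)
    note_id <- sprintf("N%05d", i)
    subject_id <- sprintf("S%05d", i)
    hadm_id <- sprintf("H%05d", i)

    plant_true <- stats::runif(1) < config$p_true_orade
    plant_anti <- stats::runif(1) < config$p_antidote_event
    plant_ind <- stats::runif(1) < config$p_indication_confounder &&
      nrow(pain_concepts) > 0L
    plant_sw <- stats::runif(1) < config$p_switch_confounder
    plant_neg <- stats::runif(1) < config$p_negation_confounder

    gold_pairs <- list()
    blocks <- list()
    filler <- function(k) sample(tpl_of("filler"), k, replace = TRUE)

    if (plant_true) {
      dr <- sample_drug()
      ae <- sample_concept(true_concepts$concept_id)
      trig <- sample(ox_generator_triggers, 1L)
      d_drug <- sample.int(config$max_distance + 1L, 1L) - 1L
      d_ae <- sample.int(config$max_distance + 1L, 1L) - 1L
      drug_s <- cap1(dr$surface)
      b <- if (d_drug == 0L && d_ae == 0L) {
        ox_fill(tpl_of("anchor_drug_ae")[1], DRUG = drug_s, TRIGGER = trig,
                AE = ae$synonym)
      } else if (d_drug == 0L) {
        c(ox_fill(tpl_of("anchor_drug")[1], DRUG = drug_s, TRIGGER = trig),
          filler(d_ae - 1L),
          ox_fill(sample(tpl_of("ae_carrier"), 1L), AE = ae$synonym))
      } else if (d_ae == 0L) {
        c(ox_fill(sample(tpl_of("drug_carrier"), 1L), DRUG = drug_s),
          filler(d_drug - 1L),
          ox_fill(tpl_of("anchor_ae")[1], AE = ae$synonym, TRIGGER = trig))
      } else {
        c(ox_fill(sample(tpl_of("drug_carrier"), 1L), DRUG = drug_s),
          filler(d_drug - 1L),
          ox_fill(tpl_of("anchor_plain")[1], TRIGGER = trig),
          filler(d_ae - 1L),
          ox_fill(sample(tpl_of("ae_carrier"), 1L), AE = ae$synonym))
      }
      blocks[[length(blocks) + 1L]] <- b
      gold_pairs[[length(gold_pairs) + 1L]] <- data.frame(
        note_id = note_id, has_orade = TRUE, generic_drug = dr$generic,
        ae_pt = ae$preferred_term,
        out_of_window = max(d_drug, d_ae) > config$window,
        stringsAsFactors = FALSE)
    }

    if (plant_anti) {
      dr <- sample_drug()
      ae <- sample_concept(resp_ids)
      anti <- cap1(sample(bundle$antidotes, 1L))
      d_drug <- if (config$max_distance <= 1L) 1L else
        sample.int(config$max_distance, 1L)
      d_ae <- min(sample.int(config$max_distance + 1L, 1L) - 1L, d_drug)
      if (d_ae == d_drug) d_ae <- d_drug - 1L
      # narrative order: drug, then event, then rescue
      pre <- rep(NA_character_, d_drug)
      pre[1] <- ox_fill(sample(tpl_of("drug_carrier"), 1L),
                        DRUG = cap1(dr$surface))
      anchor <- if (d_ae == 0L) {
        ox_fill(tpl_of("antidote_anchor_ae")[1], ANTIDOTE = anti,
                AE = ae$synonym)
      } else {
        pre[d_drug - d_ae + 1L] <- ox_fill(sample(tpl_of("ae_carrier"), 1L),
                                           AE = ae$synonym)
        tpl_of("antidote_anchor")[1]
      }
      anchor <- ox_fill(anchor, ANTIDOTE = anti)
      fill <- filler(sum(is.na(pre)))
      pre[is.na(pre)] <- fill
      blocks[[length(blocks) + 1L]] <- c(pre, anchor)
      gold_pairs[[length(gold_pairs) + 1L]] <- data.frame(
        note_id = note_id, has_orade = TRUE, generic_drug = dr$generic,
        ae_pt = ae$preferred_term,
        out_of_window = max(d_drug, d_ae) > config$window,
        stringsAsFactors = FALSE)
    }

    if (plant_ind) {
      dr <- sample_drug()
      pae <- sample_concept(pain_concepts$concept_id)
      blocks[[length(blocks) + 1L]] <- ox_fill(
        sample(tpl_of("indication"), 1L), DRUG = cap1(dr$surface),
        PAIN_AE = pae$synonym)
    }
    if (plant_sw) {
      dr <- sample_drug()
      ae <- sample_concept(true_concepts$concept_id)
      blocks[[length(blocks) + 1L]] <- ox_fill(
        sample(tpl_of("switch"), 1L), DRUG = cap1(dr$surface),
        AE = ae$synonym)
    }
    if (plant_neg) {
      dr <- sample_drug()
      ae <- sample_concept(true_concepts$concept_id)
      blocks[[length(blocks) + 1L]] <- c(
        ox_fill(sample(tpl_of("drug_carrier"), 1L), DRUG = cap1(dr$surface)),
        ox_fill(sample(tpl_of("negation_ae"), 1L), AE = ae$synonym))
    }

    course <- filler(1L)
    for (b in blocks) course <- c(course, b, filler(sep_n))
    hpi <- sample(tpl_of("hpi_filler"), 2L)
    meds <- sample(tpl_of("discharge_med"), 2L)
    course_header <- if (stats::runif(1) < 0.7) "Brief Hospital Course:" else
      "Hospital Course:"
    text <- paste0(
      "Admission Date: [**2101-1-12**]  Discharge Date: [**2101-1-20**]\n\n",
      "History of Present Illness:\n", paste(hpi, collapse = " "), "\n\n",
      course_header, "\n", paste(course, collapse = " "), "\n\n",
      "Discharge Medications:\n", paste(meds, collapse = " "), "\n")

    has_orade <- length(gold_pairs) > 0L
    icd9 <- character()
    if (has_orade && stats::runif(1) < 0.8) icd9 <- "E935.2"
    if (!has_orade && stats::runif(1) < 0.05) icd9 <- "E935.2"

    notes_list[[i]] <- list(note_id = note_id, subject_id = subject_id,
                            hadm_id = hadm_id,
                            category = "Discharge summary",
                            icd9_codes = icd9, text = text)
    gold_list[[i]] <- if (has_orade) ox_rbind(gold_pairs) else data.frame(
      note_id = note_id, has_orade = FALSE, generic_drug = NA_character_,
      ae_pt = NA_character_, out_of_window = NA, stringsAsFactors = FALSE)
    demo_list[[i]] <- data.frame(
      subject_id = subject_id, age = sample(18:95, 1L),
      gender = sample(c("M", "F"), 1L),
      ethnicity = sample(c("WHITE", "BLACK", "HISPANIC", "ASIAN", "OTHER"), 1L),
      stringsAsFactors = FALSE)
  }

  notes <- ox_empty_notes()
  if (config$n_notes > 0L) {
    notes <- data.frame(
      note_id = vapply(notes_list, `[[`, "", "note_id"),
      subject_id = vapply(notes_list, `[[`, "", "subject_id"),
      hadm_id = vapply(notes_list, `[[`, "", "hadm_id"),
      category = vapply(notes_list, `[[`, "", "category"),
      text = vapply(notes_list, `[[`, "", "text"),
      stringsAsFactors = FALSE)
    notes$icd9_codes <- lapply(notes_list, `[[`, "icd9_codes")
    notes <- notes[c("note_id", "subject_id", "hadm_id", "category",
                     "icd9_codes", "text")]
  }
  gold <- ox_rbind(gold_list)
  if (is.null(gold)) {
    gold <- data.frame(note_id = character(), has_orade = logical(),
                       generic_drug = character(), ae_pt = character(),
                       out_of_window = logical(), stringsAsFactors = FALSE)
  }
  demographics <- ox_rbind(demo_list)
  if (is.null(demographics)) {
    demographics <- data.frame(subject_id = character(), age = integer(),
                               gender = character(), ethnicity = character(),
                               stringsAsFactors = FALSE)
  }
  rownames(gold) <- rownames(demographics) <- NULL
  list(notes = notes, gold = gold, demographics = demographics)
}
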