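#' Path to the packaged default lexical resources
#'
#' The package ships a versioned set of plain-text lexicons: opioid drug
#' surface forms with generic names and pharmacological class, trigger
#' phrases (a published base set plus 58 curated phrases), antidote terms,
#' a MedDRA-style adverse-event synonym table, negation/termination cues,
#' pain-indication tokens, sentence-splitting abbreviations, and section
#' header variants. All files are user-replaceable; point [load_lexicons()]
#' at a directory with the same layout to override them.
#'
#' @return Directory path of the packaged resources.
#' @export
default_lexicon_dir <- function() {
  system.file("extdata", "lexicon", package = "oradex", mustWork = TRUE)
}

#' Load and validate the lexical resource bundle
#'
#' Reads the resource directory (see [default_lexicon_dir()] for the layout)
#' and checks the structural invariants: a non-empty drug lexicon, brand
#' surfaces mapping to exactly one generic, adverse-event synonyms mapping to
#' exactly one concept, the preferred term present among its own concept's
#' synonyms, and no surface form shared between the drug and antidote lists.
#'
#' @param resource_dir Directory holding the resource files; defaults to the
#'   packaged set.
#' @param include_narcotics If `TRUE`, adds the non-specific surface form
#'   "narcotics" to the drug lexicon (mapped to generic
#'   `"opioid unspecified"`, class unknown). Off by default: the bare word is
#'   a documented false-negative source but cannot be resolved to a specific
#'   drug.
#' @param quiet Suppress the version message logged at load.
#'
#' @return An object of class `orade_lexicon`: a list with elements `drugs`,
#'   `triggers`, `antidotes`, `ae_concepts` (one row per synonym), `concepts`
#'   (one row per concept), `negation_cues`, `termination_cues`,
#'   `pain_tokens`, `abbreviations`, `expansions`, `sections`, `version`,
#'   plus precompiled matchers used by [match_entities()].
#' @export
load_lexicons <- function(resource_dir = default_lexicon_dir(),
                          include_narcotics = FALSE,
                          quiet = FALSE) {
  rf <- function(...) file.path(resource_dir, ...)
  read_res <- function(name, required = TRUE) {
    p <- rf(name)
    if (!file.exists(p)) {
      if (required) stop("missing lexicon resource: ", name, call. = FALSE)
      return(NULL)
    }
    read.csv(p, stringsAsFactors = FALSE, colClasses = "character")
  }
  read_lines_res <- function(name) {
    p <- rf(name)
    if (!file.exists(p)) return(character())
    x <- trimws(readLines(p, encoding = "UTF-8", warn = FALSE))
    x[nzchar(x)]
  }

  drugs <- read_res("drugs.csv")
  ox_stop_if_missing_cols(drugs, c("surface", "generic", "kind", "class"), "drugs.csv")
  if (nrow(drugs) == 0L) stop("drug lexicon is empty", call. = FALSE)
  if (include_narcotics) {
    drugs <- rbind(drugs, data.frame(
      surface = "narcotics", generic = "narcotics",
      kind = "generic", class = NA_character_, stringsAsFactors = FALSE))
  }
  dkey <- ox_clean(drugs$surface)
  if (anyDuplicated(dkey)) {
    stop("duplicate drug surface form(s): ",
         paste(unique(drugs$surface[duplicated(dkey)]), collapse = ", "),
         call. = FALSE)
  }
  bad_gen <- drugs$kind == "generic" & ox_clean(drugs$surface) != ox_clean(drugs$generic)
  bad_gen[is.na(bad_gen)] <- FALSE
  if (any(bad_gen)) {
    stop("generic drug surfaces must map to themselves: ",
         paste(drugs$surface[bad_gen], collapse = ", "), call. = FALSE)
  }

  triggers <- read_res("triggers.csv", required = FALSE)
  if (is.null(triggers)) triggers <- data.frame(phrase = character(),
                                                source = character(),
                                                stringsAsFactors = FALSE)
  ox_stop_if_missing_cols(triggers, c("phrase", "source"), "triggers.csv")
  tkey <- ox_clean(triggers$phrase)
  if (anyDuplicated(tkey)) {
    stop("duplicate trigger phrase(s) after case folding: ",
         paste(unique(triggers$phrase[duplicated(tkey)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(triggers) == 0L) warning("trigger lexicon is empty", call. = FALSE)

  ae <- read_res("ae_concepts.csv")
  ox_stop_if_missing_cols(
    ae, c("concept_id", "preferred_term", "lower_level_term", "synonym"),
    "ae_concepts.csv")
  akey <- ox_clean(ae$synonym)
  dup <- duplicated(akey) | duplicated(akey, fromLast = TRUE)
  clash <- dup & ave(ae$concept_id, akey, FUN = function(z) length(unique(z)) > 1L) == "TRUE"
  if (any(clash)) {
    rows <- ae[clash, , drop = FALSE]
    stop("synonym(s) mapped to more than one concept: ",
         paste(sprintf("'%s' (%s)", rows$synonym, rows$concept_id), collapse = "; "),
         call. = FALSE)
  }
  ae <- ae[!duplicated(akey), , drop = FALSE]
  concepts <- ae[!duplicated(ae$concept_id),
                 c("concept_id", "preferred_term", "lower_level_term")]
  pt_ok <- vapply(seq_len(nrow(concepts)), function(i) {
    ox_clean(concepts$preferred_term[i]) %in%
      ox_clean(ae$synonym[ae$concept_id == concepts$concept_id[i]])
  }, TRUE)
  if (!all(pt_ok)) {
    stop("preferred term is not listed among its concept's synonyms: ",
         paste(concepts$preferred_term[!pt_ok], collapse = ", "), call. = FALSE)
  }

  antidotes <- read_lines_res("antidotes.txt")
  if (length(antidotes) == 0L) antidotes <- c("naloxone", "narcan")
  overlap <- intersect(ox_clean(antidotes), dkey)
  if (length(overlap) > 0L) {
    stop("surface form(s) present in both drug and antidote lexicons: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }

  cues <- read_res("cues.csv", required = FALSE)
  if (is.null(cues)) cues <- data.frame(cue = character(), type = character())
  negation_cues <- cues$cue[cues$type == "negation"]
  termination_cues <- cues$cue[cues$type == "termination"]

  pain_tokens <- read_lines_res("pain_tokens.txt")
  if (length(pain_tokens) == 0L) pain_tokens <- "pain"
  abbreviations <- tolower(read_lines_res("abbreviations.txt"))

  exp_df <- read_res("expansions.csv", required = FALSE)
  expansions <- if (!is.null(exp_df) && nrow(exp_df) > 0L) {
    setNames(exp_df$expansion, ox_clean(exp_df$short))
  } else {
    setNames(character(), character())
  }

  sections <- read_res("sections.csv", required = FALSE)
  if (is.null(sections)) sections <- default_section_config()
  ox_stop_if_missing_cols(sections, c("pattern", "canonical_name"), "sections.csv")

  version <- read_lines_res("VERSION")
  version <- if (length(version) > 0L) version[1] else "unversioned"
  if (!quiet) message("oradex lexicon resources version ", version,
                      " loaded from ", resource_dir)

  bundle <- structure(list(
    drugs = drugs,
    triggers = triggers,
    antidotes = antidotes,
    ae_concepts = ae,
    concepts = concepts,
    negation_cues = negation_cues,
    termination_cues = termination_cues,
    pain_tokens = tolower(pain_tokens),
    abbreviations = abbreviations,
    expansions = expansions,
    sections = sections,
    version = version
  ), class = "orade_lexicon")

  bundle$matchers <- list(
    drug = ox_phrase_regex(drugs$surface),
    trigger = ox_phrase_regex(triggers$phrase),
    antidote = ox_phrase_regex(antidotes),
    ae = ox_phrase_regex(ae$synonym),
    negation = ox_phrase_regex(negation_cues),
    termination = ox_phrase_regex(termination_cues)
  )
  bundle$maps <- list(
    drug = setNames(seq_len(nrow(drugs)), dkey),
    trigger = setNames(triggers$phrase, ox_clean(triggers$phrase)),
    ae = setNames(seq_len(nrow(ae)), ox_clean(ae$synonym))
  )
  bundle
}

#' @export
print.orade_lexicon <- function(x, ...) {
  cat("<orade_lexicon> version", x$version, "\n")
  cat("  drugs:        ", nrow(x$drugs), " surfaces / ",
      length(unique(x$drugs$generic)), " generics\n", sep = "")
  cat("  triggers:     ", nrow(x$triggers), " (",
      sum(x$triggers$source == "curated"), " curated)\n", sep = "")
  cat("  antidotes:    ", length(x$antidotes), "\n", sep = "")
  cat("  AE concepts:  ", nrow(x$concepts), " concepts / ",
      nrow(x$ae_concepts), " synonyms\n", sep = "")
  cat("  cues:         ", length(x$negation_cues), " negation / ",
      length(x$termination_cues), " termination\n", sep = "")
  invisible(x)
}

#' Normalize a raw adverse-event phrase to a MedDRA-style concept
#'
#' The pipeline is: case fold, strip punctuation, collapse whitespace, expand
#' packaged abbreviations, exact synonym lookup; only when `fuzzy_threshold`
#' is supplied does a best fuzzy match (normalized Levenshtein similarity at
#' or above the threshold) run as a fallback. An unmatched phrase is returned
#' with `matched = FALSE` and the cleaned query, never a silent guess.
#'
#' @param raw_phrase Non-empty character scalar as found in text.
#' @param bundle An `orade_lexicon` from [load_lexicons()].
#' @param fuzzy_threshold Optional similarity in \[0, 1\]; `NULL` (default)
#'   disables fuzzy matching for determinism.
#'
#' @return A list with `matched`, `query`, and, when matched, `concept_id`,
#'   `preferred_term`, `lower_level_term`.
#' @export
normalize_ae <- function(raw_phrase, bundle, fuzzy_threshold = NULL) {
  stopifnot(is.character(raw_phrase), length(raw_phrase) == 1L,
            nzchar(raw_phrase))
  toks <- ox_expand(ox_tokens(raw_phrase), bundle$expansions)
  query <- paste(toks, collapse = " ")
  idx <- bundle$maps$ae[query]
  if (!is.na(idx)) {
    row <- bundle$ae_concepts[idx, ]
    return(list(matched = TRUE, query = query,
                concept_id = row$concept_id,
                preferred_term = row$preferred_term,
                lower_level_term = if (nzchar(row$lower_level_term))
                  row$lower_level_term else NA_character_))
  }
  if (!is.null(fuzzy_threshold)) {
    stopifnot(fuzzy_threshold >= 0, fuzzy_threshold <= 1)
    keys <- names(bundle$maps$ae)
    d <- utils::adist(query, keys)[1, ]
    sim <- 1 - d / pmax(nchar(query), nchar(keys))
    ok <- which(sim >= fuzzy_threshold)
    if (length(ok) > 0L) {
      best <- ok[order(-sim[ok], keys[ok])][1]
      row <- bundle$ae_concepts[bundle$maps$ae[[keys[best]]], ]
      return(list(matched = TRUE, query = query,
                  concept_id = row$concept_id,
                  preferred_term = row$preferred_term,
                  lower_level_term = if (nzchar(row$lower_level_term))
                    row$lower_level_term else NA_character_))
    }
  }
  list(matched = FALSE, query = query, concept_id = NA_character_,
       preferred_term = NA_character_, lower_level_term = NA_character_)
}
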