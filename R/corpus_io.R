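#' Read a note corpus
#'
#' Two stable text formats are supported: JSONL (one object per line with
#' fields `note_id`, `subject_id`, `hadm_id`, `category`, `icd9_codes`,
#' `text`) and CSV in the MIMIC NOTEEVENTS dialect (RFC-4180 quoting,
#' embedded newlines in quoted `TEXT` fields; columns `SUBJECT_ID`,
#' `HADM_ID`, `CATEGORY`, `TEXT`, optional `ROW_ID` and `ICD9_CODES` with
#' `;`-separated codes). When `ROW_ID` is absent a deterministic `row<N>` id
#' is synthesized. Files must be valid UTF-8; undecodable bytes are an
#' error. Note text is preserved byte-for-byte.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"mimic_csv"`.
#'
#' @return A note data.frame: `note_id`, `subject_id`, `hadm_id`,
#'   `category`, `icd9_codes` (list column of character vectors), `text`;
#'   one row per note, input order preserved.
#' @export
read_notes <- function(path, format = c("jsonl", "mimic_csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- ox_read_file_utf8(path)
  if (format == "jsonl") {
    lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(ox_empty_notes())
    recs <- lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                      error = function(e) {
                        stop("unreadable JSONL row ", i, ": ",
                             conditionMessage(e), call. = FALSE)
                      })
      for (f in c("note_id", "text")) {
        if (is.null(obj[[f]]) || !nzchar(as.character(obj[[f]])[1])) {
          stop("JSONL row ", i, " is missing required field: ", f,
               call. = FALSE)
        }
      }
      list(note_id = as.character(obj$note_id),
           subject_id = as.character(obj$subject_id %||% NA_character_),
           hadm_id = as.character(obj$hadm_id %||% NA_character_),
           category = as.character(obj$category %||% NA_character_),
           icd9_codes = as.character(obj$icd9_codes %||% character()),
           text = as.character(obj$text))
    })
    notes <- data.frame(
      note_id = vapply(recs, `[[`, "", "note_id"),
      subject_id = vapply(recs, `[[`, "", "subject_id"),
      hadm_id = vapply(recs, `[[`, "", "hadm_id"),
      category = vapply(recs, `[[`, "", "category"),
      text = vapply(recs, `[[`, "", "text"),
      stringsAsFactors = FALSE)
    notes$icd9_codes <- lapply(recs, `[[`, "icd9_codes")
  } else {
    df <- read.csv(text = raw, stringsAsFactors = FALSE,
                   colClasses = "character")
    ox_stop_if_missing_cols(df, c("SUBJECT_ID", "HADM_ID", "CATEGORY", "TEXT"),
                            "MIMIC NOTEEVENTS csv")
    note_id <- if ("ROW_ID" %in% names(df)) df$ROW_ID else
      sprintf("row%d", seq_len(nrow(df)))
    notes <- data.frame(note_id = note_id, subject_id = df$SUBJECT_ID,
                        hadm_id = df$HADM_ID, category = df$CATEGORY,
                        text = df$TEXT, stringsAsFactors = FALSE)
    notes$icd9_codes <- if ("ICD9_CODES" %in% names(df)) {
      lapply(strsplit(df$ICD9_CODES, ";", fixed = TRUE),
             function(z) trimws(z[nzchar(trimws(z))]))
    } else {
      rep(list(character()), nrow(notes))
    }
  }
  if (any(!nzchar(notes$note_id))) stop("empty note_id", call. = FALSE)
  if (anyDuplicated(notes$note_id)) {
    stop("duplicate note_id(s): ",
         paste(unique(notes$note_id[duplicated(notes$note_id)]),
               collapse = ", "), call. = FALSE)
  }
  notes[c("note_id", "subject_id", "hadm_id", "category", "icd9_codes", "text")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ox_empty_notes <- function() {
  n <- data.frame(note_id = character(), subject_id = character(),
                  hadm_id = character(), category = character(),
                  text = character(), stringsAsFactors = FALSE)
  n$icd9_codes <- list()
  n[c("note_id", "subject_id", "hadm_id", "category", "icd9_codes", "text")]
}

#' Write a note corpus as JSONL
#'
#' Inverse of [read_notes()] for the JSONL format; a written corpus re-reads
#' field-identically (note text byte-for-byte).
#'
#' @param notes Note data.frame.
#' @param path Output path.
#' @export
write_notes <- function(notes, path) {
  lines <- vapply(seq_len(nrow(notes)), function(i) {
    as.character(jsonlite::toJSON(list(
      note_id = jsonlite::unbox(notes$note_id[i]),
      subject_id = jsonlite::unbox(notes$subject_id[i]),
      hadm_id = jsonlite::unbox(notes$hadm_id[i]),
      category = jsonlite::unbox(notes$category[i]),
      icd9_codes = notes$icd9_codes[[i]],
      text = jsonlite::unbox(notes$text[i])), na = "null"))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Prescreen notes by ICD-9 code
#'
#' Retains exactly the records whose `icd9_codes` intersects `codes` (for
#' example `"E935.2"`, opioids causing adverse effects in therapeutic use).
#' Order is preserved; records without codes are excluded. The operation is
#' idempotent.
#'
#' @param records Note data.frame.
#' @param codes Non-empty character vector of ICD-9 codes.
#'
#' @return The retained subset of `records`.
#' @export
filter_by_icd9 <- function(records, codes) {
  stopifnot(length(codes) > 0L)
  keep <- vapply(records$icd9_codes,
                 function(z) length(intersect(z, codes)) > 0L, TRUE)
  records[keep, , drop = FALSE]
}

#' Attach ICD-9 codes from a separate diagnoses table
#'
#' MIMIC stores diagnoses apart from notes; this merges a diagnoses CSV
#' (columns `HADM_ID`, `ICD9_CODE`) into the corpus by hospital admission id.
#'
#' @param records Note data.frame.
#' @param diagnoses Data.frame or CSV path with `HADM_ID`, `ICD9_CODE`.
#'
#' @return `records` with `icd9_codes` filled from the diagnoses table.
#' @export
attach_diagnoses <- function(records, diagnoses) {
  if (is.character(diagnoses)) {
    diagnoses <- read.csv(diagnoses, stringsAsFactors = FALSE,
                          colClasses = "character")
  }
  ox_stop_if_missing_cols(diagnoses, c("HADM_ID", "ICD9_CODE"), "diagnoses table")
  by_hadm <- split(diagnoses$ICD9_CODE, diagnoses$HADM_ID)
  records$icd9_codes <- lapply(records$hadm_id, function(h) {
    z <- by_hadm[[h]]
    if (is.null(z)) character() else unique(z)
  })
  records
}

# column order and classes of the pairs CSV
ox_pair_int_cols <- c("anchor_sentence", "drug_sentence", "drug_start",
                      "drug_end", "drug_distance", "ae_sentence", "ae_start",
                      "ae_end", "sentence_distance")
ox_pair_lgl_cols <- c("ae_unmapped", "ae_negated", "filtered")

#' Write candidate pairs to CSV
#'
#' One row per candidate pair with all provenance columns (rule, trigger,
#' anchor, mention offsets, distances, filter audit). [read_pairs()] is the
#' inverse and restores an equal data.frame.
#'
#' @param pairs Candidate-pair data.frame.
#' @param path Output path.
#' @export
write_pairs <- function(pairs, path) {
  cols <- names(ox_empty_pairs())
  ox_stop_if_missing_cols(pairs, cols, "pairs table")
  write.csv(pairs[cols], path, row.names = FALSE, na = "", quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read candidate pairs from CSV
#'
#' @param path Path written by [write_pairs()].
#' @return A candidate-pair data.frame with restored column types.
#' @export
read_pairs <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 fileEncoding = "UTF-8")
  ox_stop_if_missing_cols(df, names(ox_empty_pairs()), "pairs csv")
  if (nrow(df) == 0L) return(ox_empty_pairs())
  for (cc in ox_pair_int_cols) df[[cc]] <- as.integer(df[[cc]])
  for (cc in ox_pair_lgl_cols) df[[cc]] <- df[[cc]] == "TRUE"
  for (cc in setdiff(names(df), c(ox_pair_int_cols, ox_pair_lgl_cols))) {
    df[[cc]][!nzchar(df[[cc]])] <- NA_character_
  }
  # note_id and surfaces are never missing; restore empty strings there
  for (cc in c("note_id", "rule", "drug_surface", "generic_drug",
               "ae_surface", "ae_pt")) {
    df[[cc]][is.na(df[[cc]])] <- ""
  }
  df[names(ox_empty_pairs())]
}

#' Write gold labels to CSV
#'
#' One row per gold pair (`note_id`, `has_orade`, `generic_drug`, `ae_pt`,
#' `out_of_window`); notes without pairs contribute a single row with empty
#' pair fields.
#'
#' @param gold Gold data.frame from [generate_corpus()] or hand-built.
#' @param path Output path.
#' @export
write_gold <- function(gold, path) {
  cols <- c("note_id", "has_orade", "generic_drug", "ae_pt", "out_of_window")
  for (cc in setdiff(cols, names(gold))) gold[[cc]] <- NA
  write.csv(gold[cols], path, row.names = FALSE, na = "", quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gold labels from CSV
#'
#' Validates that pair rows appear only on notes labeled positive.
#'
#' @param path Path written by [write_gold()].
#' @return A gold data.frame (`note_id`, `has_orade` logical,
#'   `generic_drug`, `ae_pt`, `out_of_window` logical).
#' @export
read_gold <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 fileEncoding = "UTF-8")
  ox_stop_if_missing_cols(df, c("note_id", "has_orade"), "gold csv")
  df$has_orade <- toupper(df$has_orade) %in% c("TRUE", "1", "YES")
  if (!"generic_drug" %in% names(df)) df$generic_drug <- NA_character_
  if (!"ae_pt" %in% names(df)) df$ae_pt <- NA_character_
  if (!"out_of_window" %in% names(df)) df$out_of_window <- ""
  for (cc in c("generic_drug", "ae_pt")) {
    df[[cc]][!is.na(df[[cc]]) & !nzchar(df[[cc]])] <- NA_character_
  }
  df$out_of_window <- ifelse(is.na(df$generic_drug), NA,
                             toupper(df$out_of_window) == "TRUE")
  has_pair <- !is.na(df$generic_drug) & nzchar(df$generic_drug)
  if (any(has_pair & !df$has_orade)) {
    stop("gold rows carry pairs on notes labeled has_orade = FALSE: ",
         paste(unique(df$note_id[has_pair & !df$has_orade]), collapse = ", "),
         call. = FALSE)
  }
  df[c("note_id", "has_orade", "generic_drug", "ae_pt", "out_of_window")]
}
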