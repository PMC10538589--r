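#' Split a section of clinical text into sentences
#'
#' Boundaries are placed after runs of sentence-final punctuation (`.`, `!`,
#' `?`) that are followed by whitespace or the end of the section, with three
#' suppressions tuned to clinical prose:
#' \itemize{
#'   \item no boundary inside a decimal number (`0.4 mg`);
#'   \item no boundary inside a de-identification placeholder
#'     (`[** ... **]`), which is treated as an atomic token;
#'   \item no boundary after a listed abbreviation (`q.`, `hr.`, `mg.`,
#'     `Dr.`, ...) when the next character is lowercase or a digit; a
#'     capitalized continuation after an abbreviation still opens a new
#'     sentence (so `"... 11:30 am. Code blue ..."` splits).
#' }
#' Blank lines and lines starting with `#` (problem-list bullets) always
#' force a boundary. Sentences are trimmed of surrounding whitespace, so the
#' returned spans partition the section's non-whitespace characters exactly.
#'
#' @param section One-row data.frame (or list) with `canonical_name`,
#'   `start`, `end` as produced by [detect_sections()].
#' @param note_text Full raw note text the offsets refer to.
#' @param abbreviations Character vector of lowercase abbreviation tokens
#'   (without the trailing period); defaults to the packaged list.
#'
#' @return A data.frame with one row per sentence in order: `sentence_index`
#'   (0-based, local to this call), `section`, `start`, `end` (0-based
#'   half-open, into `note_text`) and `text` (the exact substring).
#' @export
split_sentences <- function(section, note_text, abbreviations = NULL) {
  if (is.null(abbreviations)) {
    abbreviations <- tolower(trimws(readLines(
      system.file("extdata", "lexicon", "abbreviations.txt",
                  package = "oradex", mustWork = TRUE), warn = FALSE)))
  }
  sec_start <- as.integer(section$start)
  sec_end <- as.integer(section$end)
  stopifnot(sec_start < sec_end, sec_end <= nchar(note_text))
  sec_text <- ox_substr0(note_text, sec_start, sec_end)
  n <- nchar(sec_text)

  empty <- data.frame(sentence_index = integer(), section = character(),
                      start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE)

  # placeholder ranges, 1-based inclusive
  ph <- gregexpr("\\[\\*\\*.*?\\*\\*\\]", sec_text, perl = TRUE)[[1]]
  ph_ranges <- if (ph[1] == -1L) NULL else
    cbind(as.integer(ph), as.integer(ph) + attr(ph, "match.length") - 1L)
  in_placeholder <- function(pos) {
    !is.null(ph_ranges) && any(pos >= ph_ranges[, 1] & pos <= ph_ranges[, 2])
  }

  cuts <- integer()  # 1-based index of the last character of a sentence

  pm <- gregexpr("[.!?]+", sec_text, perl = TRUE)[[1]]
  if (pm[1] != -1L) {
    for (k in seq_along(pm)) {
      s <- as.integer(pm[k])
      e <- s + attr(pm, "match.length")[k] - 1L
      if (in_placeholder(s)) next
      nxt <- if (e < n) substr(sec_text, e + 1L, e + 1L) else ""
      if (nzchar(nxt) && !grepl("[ \t\n\r]", nxt)) next  # mid-token (e.g. 0.4)
      # token immediately before the punctuation run
      prev <- regmatches(substr(sec_text, max(1L, s - 30L), s - 1L),
                         regexpr("[A-Za-z0-9]+$", substr(sec_text, max(1L, s - 30L), s - 1L)))
      if (length(prev) == 1L && tolower(prev) %in% abbreviations) {
        rest <- substr(sec_text, e + 1L, n)
        follow <- regmatches(rest, regexpr("^[ \t\n\r]*(.)", rest, perl = TRUE))
        follow_ch <- sub("^[ \t\n\r]*", "", follow)
        if (length(follow_ch) == 1L && grepl("^[a-z0-9]$", follow_ch)) next
      }
      cuts <- c(cuts, e)
    }
  }

  # blank lines force a boundary before them
  bm <- gregexpr("\n[ \t]*\n", sec_text, perl = TRUE)[[1]]
  if (bm[1] != -1L) cuts <- c(cuts, as.integer(bm) - 1L)
  # '#'-prefixed bullet lines force a boundary before the line
  hm <- gregexpr("\n[ \t]*#", sec_text, perl = TRUE)[[1]]
  if (hm[1] != -1L) cuts <- c(cuts, as.integer(hm) - 1L)

  cuts <- sort(unique(c(cuts[cuts >= 1L], n)))

  out <- list()
  prev_cut <- 0L
  for (cut in cuts) {
    seg <- substr(sec_text, prev_cut + 1L, cut)
    ws_left <- regexpr("[^ \t\n\r]", seg, perl = TRUE)
    if (ws_left[1] != -1L) {
      a <- prev_cut + as.integer(ws_left)                   # 1-based start
      trail <- regexpr("[ \t\n\r]+$", seg, perl = TRUE)
      b <- if (trail[1] != -1L) prev_cut + as.integer(trail) - 1L else cut
      out[[length(out) + 1L]] <- data.frame(
        sentence_index = NA_integer_,
        section = as.character(section$canonical_name),
        start = sec_start + a - 1L,
        end = sec_start + b,
        text = substr(sec_text, a, b),
        stringsAsFactors = FALSE)
    }
    prev_cut <- cut
  }
  if (length(out) == 0L) return(empty)
  res <- ox_rbind(out)
  res$sentence_index <- seq_len(nrow(res)) - 1L
  res
}

#' Segment a note into sentences over its target sections
#'
#' Runs [detect_sections()] then [split_sentences()] on each section,
#' assigning a global 0-based `sentence_index` over the note's extracted
#' sections in document order. Notes lacking all three target headers yield
#' zero sentences unless `scan_whole_note = TRUE`, in which case the entire
#' note is treated as one pseudo-section named `"note"`.
#'
#' @param note_text Raw note text.
#' @param bundle Optional `orade_lexicon`; supplies abbreviations and the
#'   section configuration. When `NULL`, packaged defaults are read.
#' @param scan_whole_note Fallback for notes without recognized headers
#'   (default `FALSE`, matching the restriction to the three target
#'   sections).
#' @param note_id Optional id attached to every sentence row.
#'
#' @return A data.frame of sentences (`note_id`, `sentence_index`, `section`,
#'   `start`, `end`, `text`).
#' @export
segment_note <- function(note_text, bundle = NULL, scan_whole_note = FALSE,
                         note_id = NA_character_) {
  header_config <- if (!is.null(bundle)) bundle$sections else default_section_config()
  abbr <- if (!is.null(bundle)) bundle$abbreviations else NULL
  secs <- detect_sections(note_text, header_config)
  if (nrow(secs) == 0L && scan_whole_note && nzchar(trimws(note_text))) {
    secs <- data.frame(canonical_name = "note", header_text = "",
                       start = 0L, end = nchar(note_text),
                       stringsAsFactors = FALSE)
  }
  empty <- data.frame(note_id = character(), sentence_index = integer(),
                      section = character(), start = integer(),
                      end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  if (nrow(secs) == 0L) return(empty)
  parts <- lapply(seq_len(nrow(secs)), function(i) {
    split_sentences(secs[i, ], note_text, abbreviations = abbr)
  })
  res <- ox_rbind(parts)
  if (is.null(res)) return(empty)
  res$sentence_index <- seq_len(nrow(res)) - 1L
  res <- cbind(note_id = note_id, res, stringsAsFactors = FALSE)
  res
}
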