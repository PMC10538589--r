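#' Default section-header configuration
#'
#' The three target narrative sections where opioid adverse events are
#' documented, plus shipped header variants. Each row maps a header pattern
#' (matched case-insensitively at the start of a line, with an optional
#' trailing colon) to one of the three canonical section names:
#' `brief_hospital_course`, `hospital_course`, `history_of_present_illness`.
#'
#' @return A data.frame with columns `pattern` and `canonical_name`.
#' @export
default_section_config <- function() {
  p <- system.file("extdata", "lexicon", "sections.csv", package = "oradex")
  if (nzchar(p)) {
    read.csv(p, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    data.frame(
      pattern = c("brief hospital course", "hospital course",
                  "history of present illness"),
      canonical_name = c("brief_hospital_course", "hospital_course",
                         "history_of_present_illness"),
      stringsAsFactors = FALSE)
  }
}

# A line is "header-like" (and therefore terminates the preceding section)
# when it is a short run of capitalized/uppercase words ending with a colon,
# e.g. "DISCHARGE MEDICATIONS:" or "Discharge Medications:". Lines starting
# with '#' are problem-list bullets inside a section, never headers.
ox_is_headerish <- function(line) {
  grepl("^[ \t]*(?:[A-Z][A-Za-z0-9'./-]*|of|the|and|on|at|by|in|to|for)(?:[ \t]+(?:[A-Z][A-Za-z0-9'./-]*|of|the|and|on|at|by|in|to|for)){0,6}[ \t]*:",
        line, perl = TRUE)
}

#' Detect the target sections of a discharge summary
#'
#' Scans the note line by line for the configured header patterns. A section
#' starts immediately after its header (and its colon, when present) and ends
#' at the start of the next header-like line - configured or not - or at the
#' end of the note. Text outside recognized sections is excluded from
#' downstream processing unless the whole-note fallback of [segment_note()]
#' is requested.
#'
#' @param text Raw note text.
#' @param header_config Data.frame of (`pattern`, `canonical_name`) rows;
#'   defaults to the packaged configuration.
#'
#' @return A data.frame with one row per detected section in document order:
#'   `canonical_name`, `header_text`, and 0-based half-open offsets `start`,
#'   `end` of the section body. Empty (zero rows) when no header matches.
#' @export
detect_sections <- function(text, header_config = default_section_config()) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(canonical_name = character(), header_text = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  stopifnot(nrow(header_config) > 0L)

  # line starts as 0-based offsets
  nl <- gregexpr("\n", text, fixed = TRUE)[[1]]
  line_starts <- if (nl[1] == -1L) 0L else c(0L, as.integer(nl))
  line_ends <- c(line_starts[-1] - 1L, nchar(text))  # 0-based, exclusive of \n
  lines <- substring(text, line_starts + 1L, line_ends)

  cfg <- header_config[order(-nchar(header_config$pattern)), , drop = FALSE]
  pats <- vapply(strsplit(ox_clean(cfg$pattern), " ", fixed = TRUE),
                 function(t) paste(t, collapse = "[^A-Za-z0-9\n]+"), "")
  pats <- paste0("^[ \t]*(?:", pats, ")[ \t]*(?::|$)")

  canon <- character(length(lines))
  header_len <- integer(length(lines))
  headerish <- logical(length(lines))
  for (i in seq_along(lines)) {
    for (j in seq_along(pats)) {
      m <- regexpr(pats[j], lines[i], perl = TRUE, ignore.case = TRUE)
      if (m[1] != -1L) {
        canon[i] <- cfg$canonical_name[j]
        header_len[i] <- attr(m, "match.length")
        break
      }
    }
    headerish[i] <- nzchar(canon[i]) || ox_is_headerish(lines[i])
  }

  hits <- which(nzchar(canon))
  if (length(hits) == 0L) return(empty)
  out <- lapply(hits, function(i) {
    body_start <- line_starts[i] + header_len[i]
    nxt <- which(headerish & seq_along(lines) > i)
    body_end <- if (length(nxt) > 0L) line_starts[nxt[1]] else nchar(text)
    data.frame(canonical_name = canon[i],
               header_text = substring(lines[i], 1L, header_len[i]),
               start = body_start, end = body_end,
               stringsAsFactors = FALSE)
  })
  res <- ox_rbind(out)
  res[res$start < res$end, , drop = FALSE]
}
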