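# Internal text utilities shared by the lexicon, extraction and filter layers.
# All public offsets in this package are 0-based half-open character offsets
# into the raw note text; R's 1-based substr() is confined to these helpers.

# lowercase, map every non-alphanumeric run to a single space, trim
ox_clean <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

ox_tokens <- function(x) {
  toks <- strsplit(ox_clean(x), " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

# substring by 0-based half-open offsets
ox_substr0 <- function(text, start, end) substr(text, start + 1L, end)

# Build a single case-insensitive PCRE alternation for a phrase list.
# Tokens inside a phrase may be separated by any non-alphanumeric run in the
# target text; matches are anchored at word boundaries on both sides.
# Alternatives are ordered longest-first so that at any position the longest
# phrase wins (leftmost-longest, matching the documented tie-break).
ox_phrase_regex <- function(phrases) {
  keys <- vapply(phrases, ox_clean, "")
  keep <- nzchar(keys) & !duplicated(keys)
  keys <- keys[keep]
  if (length(keys) == 0L) return(NULL)
  keys <- keys[order(-nchar(keys), keys)]
  alts <- vapply(strsplit(keys, " ", fixed = TRUE), function(toks) {
    paste(toks, collapse = "[^A-Za-z0-9]+")
  }, "")
  paste0("(?<![A-Za-z0-9])(?:", paste(alts, collapse = "|"), ")(?![A-Za-z0-9])")
}

# All non-overlapping matches of a phrase regex; returns a data.frame with
# 0-based half-open offsets and the matched surface.
ox_match_phrases <- function(text, regex) {
  empty <- data.frame(start = integer(), end = integer(),
                      surface = character(), stringsAsFactors = FALSE)
  if (is.null(regex) || !nzchar(text)) return(empty)
  m <- gregexpr(regex, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(start = start, end = start + len,
             surface = substring(text, start + 1L, start + len),
             stringsAsFactors = FALSE)
}

# expand tokens through the abbreviation-expansion map (short -> long form)
ox_expand <- function(tokens, expansions) {
  if (length(tokens) == 0L || length(expansions) == 0L) return(tokens)
  out <- lapply(tokens, function(t) {
    if (!is.na(expansions[t])) ox_tokens(expansions[[t]]) else t
  })
  unlist(out, use.names = FALSE)
}

# hard UTF-8 validation: undecodable bytes are an error, never replaced
ox_read_file_utf8 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  txt <- rawToChar(raw)
  if (!validUTF8(txt)) {
    stop("file is not valid UTF-8: ", path, call. = FALSE)
  }
  enc2utf8(txt)
}

ox_stop_if_missing_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

# stable row bind for the package's typed data.frames
ox_rbind <- function(lst) {
  lst <- lst[vapply(lst, function(x) !is.null(x) && nrow(x) > 0L, TRUE)]
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
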