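# Shared fixtures and independent brute-force oracles. The oracles
# deliberately re-derive results with plain loops and set operations so they
# share no code path with the implementation they check.

the_bundle <- load_lexicons(quiet = TRUE)

# one-section note from a vector of sentences
course_note <- function(..., header = "Brief Hospital Course:") {
  paste0(header, "\n", paste(c(...), collapse = " "), "\n")
}

run_note <- function(text, note_id = "n1", bundle = the_bundle,
                     config = pairing_config()) {
  extract_note_pairs(list(note_id = note_id, text = text), bundle,
                     config = config)
}

# --- line-scanning section oracle -------------------------------------------
# scans physical lines; a section runs from after its header line to the next
# line that looks like any header ("Word Words:" prefix)
oracle_sections <- function(text, config = default_section_config()) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  offs <- cumsum(c(0L, nchar(lines) + 1L))[seq_along(lines)]
  pats <- config[order(-nchar(config$pattern)), ]
  canon <- rep(NA_character_, length(lines))
  hdr_end <- integer(length(lines))
  for (i in seq_along(lines)) {
    lt <- tolower(trimws(lines[i]))
    for (j in seq_len(nrow(pats))) {
      p <- tolower(pats$pattern[j])
      if (startsWith(lt, p)) {
        rest <- substring(lt, nchar(p) + 1L)
        if (rest == "" || grepl("^\\s*:", rest)) {
          canon[i] <- pats$canonical_name[j]
          m <- regexpr(":", lines[i], fixed = TRUE)
          hdr_end[i] <- if (m > 0) offs[i] + m else offs[i] + nchar(lines[i])
          break
        }
      }
    }
  }
  headerish <- !is.na(canon) |
    grepl("^[ \t]*[A-Z][A-Za-z0-9 ,/'()./-]{0,60}:", lines)
  out <- NULL
  for (i in which(!is.na(canon))) {
    nxt <- which(headerish & seq_along(lines) > i)
    end <- if (length(nxt)) offs[nxt[1]] else nchar(text)
    if (hdr_end[i] < end) {
      out <- rbind(out, data.frame(canonical_name = canon[i],
                                   start = hdr_end[i], end = end,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) data.frame(canonical_name = character(),
                               start = integer(), end = integer()) else out
}

# --- brute-force windowed pairing oracle ------------------------------------
# enumerates every (anchor, drug mention, AE mention) combination and keeps,
# per (drug mention, AE mention), the smallest AE-sentence distance
oracle_rule_pairs <- function(mentions, sentences, window, rule,
                              cross_sections = FALSE) {
  sec <- setNames(sentences$section, as.character(sentences$sentence_index))
  same <- function(a, b) cross_sections ||
    sec[[as.character(a)]] == sec[[as.character(b)]]
  drugs <- mentions[mentions$entity_type == "opioid_drug", , drop = FALSE]
  aes <- mentions[mentions$entity_type == "adverse_event", , drop = FALSE]
  if (rule == "trigger_phrase") {
    ts <- unique(mentions$sentence_index[mentions$entity_type == "trigger_phrase"])
    anchors <- c()
    for (t in ts) {
      ok <- FALSE
      for (d in seq_len(nrow(drugs))) {
        if (abs(drugs$sentence_index[d] - t) <= window &&
            same(drugs$sentence_index[d], t)) ok <- TRUE
      }
      if (ok) anchors <- c(anchors, t)
    }
  } else {
    anchors <- unique(mentions$sentence_index[mentions$entity_type == "antidote"])
  }
  best <- list()
  for (a in anchors) {
    for (d in seq_len(nrow(drugs))) {
      if (abs(drugs$sentence_index[d] - a) > window ||
          !same(drugs$sentence_index[d], a)) next
      for (e in seq_len(nrow(aes))) {
        if (abs(aes$sentence_index[e] - a) > window ||
            !same(aes$sentence_index[e], a)) next
        k <- paste(drugs$start[d], drugs$end[d], aes$start[e], aes$end[e])
        sd <- abs(aes$sentence_index[e] - a)
        dd <- abs(drugs$sentence_index[d] - a)
        cur <- best[[k]]
        if (is.null(cur) || sd < cur[1] || (sd == cur[1] && dd < cur[2])) {
          best[[k]] <- c(sd, dd)
        }
      }
    }
  }
  if (length(best) == 0L) {
    return(data.frame(key = character(), sd = integer(), dd = integer()))
  }
  data.frame(key = names(best),
             sd = vapply(best, `[`, 0, 1), dd = vapply(best, `[`, 0, 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

# canonical comparable form of implementation output
pair_keyset <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(data.frame(key = character(), sd = integer(), dd = integer()))
  }
  df <- data.frame(key = paste(pairs$drug_start, pairs$drug_end,
                               pairs$ae_start, pairs$ae_end),
                   sd = pairs$sentence_distance, dd = pairs$drug_distance,
                   stringsAsFactors = FALSE)
  df[order(df$key), , drop = FALSE]
}

expect_same_pairset <- function(pairs, oracle) {
  a <- pair_keyset(pairs)
  b <- oracle[order(oracle$key), , drop = FALSE]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
}

# --- set-operation metrics oracle -------------------------------------------
oracle_pair_metrics <- function(pred_keys, gold_keys) {
  tp <- length(intersect(pred_keys, gold_keys))
  fp <- length(setdiff(pred_keys, gold_keys))
  fn <- length(setdiff(gold_keys, pred_keys))
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

# minimal pairs table for the evaluators (which use note_id, generic_drug,
# ae_pt, filtered only)
stub_pairs <- function(note_id, generic_drug = "morphine", ae_pt = "Nausea",
                       filtered = FALSE, rule = "trigger_phrase") {
  n <- length(note_id)
  data.frame(note_id = note_id,
             generic_drug = rep_len(generic_drug, n),
             ae_pt = rep_len(ae_pt, n),
             filtered = rep_len(filtered, n),
             rule = rep_len(rule, n), stringsAsFactors = FALSE)
}
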