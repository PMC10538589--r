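test_that("the trigger worked example yields its three typed mentions", {
  txt <- paste0("It is noteworthy that the patient had received 0.5 mg Ativan ",
                "x2 and morphine earlier in the afternoon and there is a ",
                "concern that this may have contributed to his altered mental ",
                "status.")
  s <- segment_note(course_note(txt), the_bundle)
  m <- match_entities(s, the_bundle)
  expect_setequal(m$entity_type,
                  c("opioid_drug", "trigger_phrase", "adverse_event"))
  expect_equal(m$surface[m$entity_type == "opioid_drug"], "morphine")
  expect_equal(tolower(m$normalized[m$entity_type == "trigger_phrase"]),
               "contributed to")
  ae <- m[m$entity_type == "adverse_event", ]
  expect_equal(tolower(ae$surface), "altered mental status")
  expect_equal(tolower(ae$normalized), "mental state abnormal")
  expect_false(ae$unmapped)
  # offsets point at the exact note substring
  note <- course_note(txt)
  expect_identical(substring(note, m$start + 1, m$end), m$surface)
})

test_that("a sentence without lexicon hits yields no mentions", {
  s <- segment_note(course_note("The patient remained comfortable."), the_bundle)
  expect_equal(nrow(match_entities(s, the_bundle)), 0L)
})

test_that("planted surface forms are recovered at their exact offsets", {
  set.seed(202)
  drugs <- the_bundle$drugs$surface
  aes <- the_bundle$ae_concepts$synonym
  for (rep in 1:50) {
    d <- sample(drugs, 1); a <- sample(aes, 1)
    left <- sample(c("The team gave", "Overnight the nurse offered",
                     "He then received"), 1)
    mid <- sample(c("and later observed", "and then documented"), 1)
    txt <- sprintf("%s %s %s %s overnight.", left, d, mid, a)
    note <- course_note(txt)
    s <- segment_note(note, the_bundle)
    m <- match_entities(s, the_bundle)
    dm <- m[m$entity_type == "opioid_drug", ]
    am <- m[m$entity_type == "adverse_event", ]
    expect_equal(nrow(dm), 1L, info = txt)
    expect_identical(substring(note, dm$start + 1, dm$end), d, info = txt)
    expect_gte(nrow(am), 1L)
    # the planted AE is among recovered spans, at its true offset
    pos <- regexpr(a, note, fixed = TRUE)
    expect_true(any(am$start == pos - 1 &
                      am$end == pos - 1 + nchar(a)), info = txt)
  }
})

test_that("longest match wins and matches never overlap within a type", {
  s <- segment_note(course_note(
    "He developed severe constipation and daytime hypersomnolence."),
    the_bundle)
  m <- match_entities(s, the_bundle)
  ae <- m[m$entity_type == "adverse_event", ]
  expect_setequal(tolower(ae$surface),
                  c("severe constipation", "daytime hypersomnolence"))
  ae <- ae[order(ae$start), ]
  if (nrow(ae) > 1) expect_true(all(ae$end[-nrow(ae)] <= ae$start[-1]))
})

test_that("mention output is invariant to sentence processing order", {
  note <- course_note("Morphine was given for agitation.",
                      "Fentanyl caused pruritus later.")
  s <- segment_note(note, the_bundle)
  m1 <- match_entities(s, the_bundle)
  m2 <- match_entities(s[rev(seq_len(nrow(s))), ], the_bundle)
  m2 <- m2[order(m2$start, m2$entity_type), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2)
})

test_that("unmapped recognizer spans are kept and flagged", {
  rec <- function(text) {
    pos <- regexpr("purple spots", text, fixed = TRUE)
    if (pos < 0) return(data.frame(start = integer(), end = integer(),
                                   surface = character()))
    data.frame(start = pos - 1L, end = pos - 1L + 12L,
               surface = "purple spots", stringsAsFactors = FALSE)
  }
  s <- segment_note(course_note("Morphine led to purple spots."), the_bundle)
  m <- match_entities(s, the_bundle, ae_recognizer = rec)
  ae <- m[m$entity_type == "adverse_event", ]
  expect_equal(ae$normalized, "purple spots")
  expect_true(ae$unmapped)
})

test_that("recognizer failures carry the sentence index", {
  rec <- function(text) stop("model unavailable")
  s <- segment_note(course_note("Morphine was given."), the_bundle)
  expect_error(match_entities(s, the_bundle, ae_recognizer = rec),
               "sentence 0.*model unavailable")
})

test_that("the external-command recognizer parses span triples", {
  rec <- make_external_recognizer("printf '0\\t6\\tnausea\\n'")
  out <- rec("nausea was reported")
  expect_equal(out$start, 0L)
  expect_equal(out$end, 6L)
  expect_equal(out$surface, "nausea")
})

test_that("negation flags follow cue-before-mention scope with termination cues", {
  # the printed false-negative example: hypersomnolence asserted, headaches denied
  txt <- paste0("He does endorse decreased sleep latency, falling asleep in ",
                "less than 5 minutes, and also questionable daytime ",
                "hypersomnolence, but denies morning headaches.")
  s <- segment_note(course_note(txt), the_bundle)
  m <- detect_negation(match_entities(s, the_bundle), s, the_bundle)
  ae <- m[m$entity_type == "adverse_event", ]
  expect_false(ae$negated[tolower(ae$surface) == "daytime hypersomnolence"])
  expect_true(ae$negated[tolower(ae$surface) == "morning headaches"])

  one <- segment_note(course_note("No further apneic events."), the_bundle)
  m1 <- detect_negation(match_entities(one, the_bundle), one, the_bundle)
  expect_true(all(m1$negated[m1$entity_type == "adverse_event"]))

  plain <- segment_note(course_note("He reported nausea overnight."), the_bundle)
  m2 <- detect_negation(match_entities(plain, the_bundle), plain, the_bundle)
  expect_false(any(m2$negated))
})

test_that("a termination cue between cue and mention blocks negation", {
  txt <- "He denied vomiting but developed hypotension overnight."
  s <- segment_note(course_note(txt), the_bundle)
  m <- detect_negation(match_entities(s, the_bundle), s, the_bundle)
  ae <- m[m$entity_type == "adverse_event", ]
  expect_true(ae$negated[tolower(ae$surface) == "vomiting"])
  expect_false(ae$negated[tolower(ae$surface) == "hypotension"])
})

test_that("detect_negation only toggles flags and is idempotent", {
  s <- segment_note(course_note("No further apneic events after morphine."),
                    the_bundle)
  m0 <- match_entities(s, the_bundle)
  m1 <- detect_negation(m0, s, the_bundle)
  m2 <- detect_negation(m1, s, the_bundle)
  expect_equal(m1, m2)
  expect_equal(m0[setdiff(names(m0), "negated")],
               m1[setdiff(names(m1), "negated")])
})
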