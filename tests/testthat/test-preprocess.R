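test_that("a target section ends at the next header line", {
  text <- paste0("HISTORY OF PRESENT ILLNESS:\n",
                 "He presented with a fall. He was admitted.\n",
                 "DISCHARGE MEDICATIONS:\nAtorvastatin 40 mg daily.\n")
  secs <- detect_sections(text)
  expect_equal(nrow(secs), 1L)
  expect_equal(secs$canonical_name, "history_of_present_illness")
  body <- substr(text, secs$start + 1, secs$end)
  expect_match(body, "He was admitted", fixed = TRUE)
  expect_false(grepl("Atorvastatin", body, fixed = TRUE))
})

test_that("empty text and header-free notes yield no sections", {
  expect_equal(nrow(detect_sections("")), 0L)
  expect_equal(nrow(detect_sections("Just prose with no headers at all.")), 0L)
})

test_that("'brief hospital course' is not shadowed by 'hospital course'", {
  text <- paste0("Brief Hospital Course:\nStable stay.\n\n",
                 "Hospital Course:\nMore detail here.\n")
  secs <- detect_sections(text)
  expect_equal(secs$canonical_name,
               c("brief_hospital_course", "hospital_course"))
  expect_true(all(secs$start < secs$end))
  # spans do not overlap
  expect_true(all(secs$end[-nrow(secs)] <= secs$start[-1]))
})

test_that("section detection matches a line-scanning oracle on randomized notes", {
  set.seed(301)
  headers <- c("History of Present Illness", "Brief Hospital Course",
               "Hospital Course", "Discharge Medications", "Past Medical History")
  for (rep in 1:100) {
    hs <- sample(headers, sample(2:5, 1))
    body <- vapply(seq_along(hs), function(i)
      paste0(hs[i], ":\nFiller sentence one. Filler sentence two.\n"), "")
    casefn <- sample(list(identity, toupper, tolower), 1)[[1]]
    text <- paste(vapply(body, casefn, ""), collapse = "\n")
    got <- detect_sections(text)
    want <- oracle_sections(text)
    expect_equal(got$canonical_name, want$canonical_name, info = text)
    expect_equal(got$start, want$start, info = text)
    expect_equal(got$end, want$end, info = text)
  }
})

test_that("clinical sentence splitting honors decimals, placeholders and abbreviations", {
  txt <- paste0("He received dilaudid q 2 hr at 7:30 am, 9:30 am, 11:30 am. ",
                "Code blue was called for respiratory arrest (unwitnessed). ",
                "0.4 mg of Narcan IV was administered followed by 1 mg of IV Narcan. ",
                "This resulted in improvement of his respiratory status and ",
                "regain of his consciousness.")
  s <- segment_note(course_note(txt), the_bundle)
  expect_equal(nrow(s), 4L)
  expect_match(s$text[3], "^0\\.4 mg")          # decimal not split
  expect_match(s$text[1], "11:30 am\\.$")       # abbreviation before capital splits

  one <- segment_note(course_note("No further apneic events."), the_bundle)
  expect_equal(nrow(one), 1L)

  abc <- segment_note(course_note("a. b. c."), the_bundle)
  expect_equal(abc$text, c("a.", "b.", "c."))

  ph <- segment_note(course_note(
    "Seen on [**2173-8-28**] in clinic. Plan was made."), the_bundle)
  expect_equal(nrow(ph), 2L)
  expect_match(ph$text[1], "\\[\\*\\*2173-8-28\\*\\*\\]")

  dose <- segment_note(course_note("Dilaudid given q. 4 hr. prn overnight."),
                       the_bundle)
  expect_equal(nrow(dose), 1L)                  # q./hr. before digit/lowercase
})

test_that("sentence spans tile the section text exactly", {
  texts <- c(
    course_note("a. b. c."),
    course_note("One sentence here. Another follows!  A third?"),
    course_note("Line one ends here.\nLine two is next.\n\n# Problem list item.",
                header = "Hospital Course:"))
  for (tx in texts) {
    secs <- detect_sections(tx)
    for (i in seq_len(nrow(secs))) {
      s <- split_sentences(secs[i, ], tx, the_bundle$abbreviations)
      # each span reproduces its substring
      expect_identical(s$text,
                       substring(tx, s$start + 1, s$end))
      # non-whitespace characters are partitioned
      body <- substr(tx, secs$start[i] + 1, secs$end[i])
      expect_identical(gsub("\\s", "", paste(s$text, collapse = "")),
                       gsub("\\s", "", body))
      # ordered, non-overlapping
      if (nrow(s) > 1) expect_true(all(s$end[-nrow(s)] <= s$start[-1]))
    }
  }
})

test_that("blank lines and # bullets force boundaries", {
  s <- segment_note(course_note(
    "Pain service was consulted\n\n# Constipation: bowel regimen was started"),
    the_bundle)
  expect_equal(nrow(s), 2L)
  expect_match(s$text[2], "^# Constipation")
})

test_that("sentence_index is a 0-based bijection across sections", {
  text <- paste0("History of Present Illness:\nFirst thing. Second thing.\n\n",
                 "Brief Hospital Course:\nThird thing. Fourth thing. Fifth thing.\n")
  s <- segment_note(text, the_bundle)
  expect_equal(s$sentence_index, 0:4)
  expect_equal(unique(s$section),
               c("history_of_present_illness", "brief_hospital_course"))
})

test_that("an unrelated header does not change segmentation inside other sections", {
  base <- paste0("Brief Hospital Course:\nOne sentence. Two sentences here.\n")
  with_extra <- paste0(base, "\nDischarge Instructions:\nFollow up in clinic.\n")
  s1 <- segment_note(base, the_bundle)
  s2 <- segment_note(with_extra, the_bundle)
  s2 <- s2[s2$section == "brief_hospital_course", ]
  expect_equal(s1$text, s2$text)
  expect_equal(s1$start, s2$start)
})

test_that("whole-note fallback is off by default", {
  text <- "No headers anywhere. Two sentences though."
  expect_equal(nrow(segment_note(text, the_bundle)), 0L)
  s <- segment_note(text, the_bundle, scan_whole_note = TRUE)
  expect_equal(nrow(s), 2L)
  expect_equal(unique(s$section), "note")
})
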