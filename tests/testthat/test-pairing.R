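prep_note <- function(text, bundle = the_bundle) {
  s <- segment_note(text, bundle, note_id = "n1")
  m <- detect_negation(match_entities(s, bundle), s, bundle)
  list(sentences = s, mentions = m)
}

test_that("the trigger worked example produces exactly one candidate pair", {
  txt <- paste0("It is noteworthy that the patient had received 0.5 mg Ativan ",
                "x2 and morphine earlier in the afternoon and there is a ",
                "concern that this may have contributed to his altered mental ",
                "status.")
  x <- prep_note(course_note(txt))
  p <- apply_trigger_rule(x$mentions, x$sentences)
  expect_equal(nrow(p), 1L)
  expect_equal(p$rule, "trigger_phrase")
  expect_equal(tolower(p$generic_drug), "morphine")
  expect_equal(tolower(p$ae_pt), "mental state abnormal")
  expect_equal(tolower(p$trigger_used), "contributed to")
  expect_equal(p$sentence_distance, 0L)
  expect_equal(p$drug_distance, 0L)
})

test_that("the antidote worked example pairs dilaudid with respiratory arrest", {
  txt <- paste0("He received dilaudid q 2 hr at 7:30 am, 9:30 am, 11:30 am. ",
                "Code blue was called for respiratory arrest (unwitnessed). ",
                "0.4 mg of Narcan IV was administered followed by 1 mg of IV ",
                "Narcan. This resulted in improvement of his respiratory ",
                "status and regain of his consciousness.")
  x <- prep_note(course_note(txt))
  p <- apply_antidote_rule(x$mentions, x$sentences)
  expect_equal(nrow(p), 1L)
  expect_equal(p$rule, "antidote")
  expect_equal(tolower(p$drug_surface), "dilaudid")
  expect_equal(tolower(p$generic_drug), "hydromorphone")
  expect_equal(tolower(p$ae_pt), "respiratory arrest")
  expect_equal(p$drug_distance, 2L)
  expect_equal(p$sentence_distance, 1L)
})

test_that("drugs and events without a trigger or antidote produce no pairs", {
  x <- prep_note(course_note("Morphine was continued.",
                             "He reported nausea overnight."))
  expect_equal(nrow(apply_trigger_rule(x$mentions, x$sentences)), 0L)
  expect_equal(nrow(apply_antidote_rule(x$mentions, x$sentences)), 0L)
})

test_that("an antidote with no opioid in the window yields nothing", {
  x <- prep_note(course_note(
    "Narcan was administered for apnea.",
    "The patient improved steadily.",
    "The patient ambulated.", "Diet was advanced.", "He remained stable.",
    "Morphine was restarted at a low dose."))
  p <- apply_antidote_rule(x$mentions, x$sentences, pairing_config(window = 3))
  expect_equal(nrow(p), 0L)
})

test_that("windows never cross section boundaries by default", {
  text <- paste0("History of Present Illness:\n",
                 "He takes morphine at home.\n\n",
                 "Brief Hospital Course:\n",
                 "The somnolence was felt to be related to the opioid regimen.\n")
  x <- prep_note(text)
  p0 <- apply_trigger_rule(x$mentions, x$sentences)
  expect_equal(nrow(p0), 0L)
  p1 <- apply_trigger_rule(x$mentions, x$sentences,
                           pairing_config(cross_section_windows = TRUE))
  expect_equal(nrow(p1), 1L)
  expect_equal(tolower(p1$generic_drug), "morphine")
})

test_that("rule outputs equal the brute-force window oracle on synthetic notes", {
  corp <- generate_corpus(sim_config(n_notes = 200, seed = 4242), the_bundle)
  cfg <- pairing_config()
  n_trigger_pairs <- 0L
  for (i in seq_len(nrow(corp$notes))) {
    s <- segment_note(corp$notes$text[i], the_bundle,
                      note_id = corp$notes$note_id[i])
    m <- detect_negation(match_entities(s, the_bundle), s, the_bundle)
    pt <- apply_trigger_rule(m, s, cfg)
    pa <- apply_antidote_rule(m, s, cfg)
    expect_same_pairset(pt, oracle_rule_pairs(m, s, cfg$window, "trigger_phrase"))
    expect_same_pairset(pa, oracle_rule_pairs(m, s, cfg$window, "antidote"))
    n_trigger_pairs <- n_trigger_pairs + nrow(pt)
  }
  expect_gt(n_trigger_pairs, 0L)
})

test_that("shrinking the window never adds pairs and bounds hold", {
  corp <- generate_corpus(sim_config(n_notes = 40, seed = 88), the_bundle)
  for (i in seq_len(nrow(corp$notes))) {
    s <- segment_note(corp$notes$text[i], the_bundle,
                      note_id = corp$notes$note_id[i])
    m <- detect_negation(match_entities(s, the_bundle), s, the_bundle)
    prev <- NULL
    for (w in 3:0) {
      p <- rbind(apply_trigger_rule(m, s, pairing_config(window = w)),
                 apply_antidote_rule(m, s, pairing_config(window = w)))
      expect_true(all(p$sentence_distance <= w))
      expect_true(all(p$drug_distance <= w))
      if (!is.null(prev)) {
        expect_true(all(pair_keyset(p)$key %in% prev))
      }
      prev <- pair_keyset(p)$key
    }
  }
})

test_that("the pain-indication filter flags the printed fentanyl example", {
  x <- prep_note(course_note(
    "She was given fentanyl for the back pain with subsequent hypotension."))
  p <- apply_filters(apply_trigger_rule(x$mentions, x$sentences),
                     x$sentences, the_bundle)
  bp <- p[tolower(p$ae_pt) == "back pain", ]
  expect_true(all(bp$filtered))
  expect_equal(unique(bp$filter_reason), "pain_indication")
  hy <- p[tolower(p$ae_pt) == "hypotension", ]
  expect_false(any(hy$filtered))
})

test_that("the medication-change filter flags only the switch target", {
  x <- prep_note(course_note(
    "She was changed from Percocet to Ultram due to nausea, which resolved."))
  p <- apply_filters(apply_trigger_rule(x$mentions, x$sentences),
                     x$sentences, the_bundle)
  ul <- p[tolower(p$drug_surface) == "ultram", ]
  expect_true(all(ul$filtered))
  expect_equal(unique(ul$filter_reason), "medication_change")
  pc <- p[tolower(p$drug_surface) == "percocet", ]
  expect_false(any(pc$filtered))
})

test_that("the negation filter flags pairs whose event is denied", {
  x <- prep_note(course_note(
    "Morphine was felt to be contributing to oversedation.",
    "No further apneic events."))
  p <- apply_filters(rbind(apply_trigger_rule(x$mentions, x$sentences),
                           apply_antidote_rule(x$mentions, x$sentences)),
                     x$sentences, the_bundle)
  ap <- p[tolower(p$ae_pt) == "apnoea", ]
  expect_gt(nrow(ap), 0L)
  expect_true(all(ap$filtered))
  expect_equal(unique(ap$filter_reason), "negated_ae")
  sed <- p[tolower(p$ae_pt) == "sedation", ]
  expect_false(any(sed$filtered))
})

test_that("filters flag rather than delete, in fixed order, and can be disabled", {
  x <- prep_note(course_note(
    "She was given fentanyl for the back pain with subsequent hypotension."))
  raw <- apply_trigger_rule(x$mentions, x$sentences)
  p <- apply_filters(raw, x$sentences, the_bundle)
  expect_equal(nrow(p), nrow(raw))
  expect_equal(p[setdiff(names(p), c("filtered", "filter_reason"))],
               raw[setdiff(names(raw), c("filtered", "filter_reason"))])
  off <- apply_filters(raw, x$sentences, the_bundle,
                       pairing_config(filters_enabled = "negated_ae"))
  expect_false(any(off$filtered))
})

test_that("aggregation counts the five corpus quantities per stratum", {
  notes <- data.frame(note_id = c("note1", "note2"),
                      subject_id = c("p1", "p2"), hadm_id = c("h1", "h2"),
                      category = "Discharge summary", text = "",
                      stringsAsFactors = FALSE)
  notes$icd9_codes <- list(character(), character())
  pairs <- rbind(stub_pairs("note1", "morphine", "Nausea", rule = "trigger_phrase"),
                 stub_pairs("note2", "fentanyl", "Hypotension", rule = "antidote"))
  agg <- aggregate_pairs(pairs, notes)
  s <- agg$summary
  ov <- s[s$stratum == "overall", ]
  expect_equal(unlist(ov[-1], use.names = FALSE), c(2, 2, 2, 2, 2))
  tr <- s[s$stratum == "trigger_phrase", ]
  expect_equal(unlist(tr[-1], use.names = FALSE), c(1, 1, 1, 1, 1))
  an <- s[s$stratum == "antidote_only", ]
  expect_equal(unlist(an[-1], use.names = FALSE), c(1, 1, 1, 1, 1))
  expect_equal(s$n_unique_pairs[s$stratum == "both"], 0)

  # same pair in two notes of one patient: 1 unique pair, 2 summaries, 1 patient
  notes2 <- notes; notes2$subject_id <- c("p1", "p1")
  pairs2 <- rbind(stub_pairs("note1"), stub_pairs("note2"))
  s2 <- aggregate_pairs(pairs2, notes2)$summary
  ov2 <- s2[s2$stratum == "overall", ]
  expect_equal(ov2$n_unique_pairs, 1)
  expect_equal(ov2$n_summaries, 2)
  expect_equal(ov2$n_patients, 1)

  # no pairs: all zero
  s0 <- aggregate_pairs(pairs[0, ], notes)$summary
  expect_true(all(s0[s0$stratum == "overall", -1] == 0))
})
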