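#' Build dashboard-style summary tables from extracted pairs
#'
#' Derives, over unfiltered pairs, the tables behind each analytic view:
#' patient counts per opioid class, per generic drug, per (drug, preferred
#' term/lower-level term), per brand/generic drug kind; a drug-by-event
#' matrix for chord-style visualization; per-drug top-k adverse events; a
#' per-patient line listing; and optional demographic summaries. Counts are
#' over unique patients (`subject_id`) unless `count_notes = TRUE`, in which
#' case discharge summaries (`note_id`) are the unit. Top-k ties break by
#' descending count then alphabetical preferred term, so output is
#' deterministic. Report generation is read-only over the pairs table.
#'
#' @param pairs Candidate-pair data.frame (or path readable by
#'   [read_pairs()]).
#' @param notes Note data.frame supplying `subject_id` (or a JSONL path).
#' @param demographics Optional demographics data.frame (`subject_id`,
#'   `age`, `gender`, `ethnicity`) or CSV path. Patients appearing in pairs
#'   but missing from the table are reported with a warning.
#' @param top_k Number of adverse events listed per drug (default 3).
#' @param count_notes Count notes instead of patients.
#' @param age_breaks Histogram bin edges for age (default 10-year bins,
#'   0-90+).
#'
#' @return An object of class `orade_report`: a list of data.frames
#'   (`class_counts`, `drug_counts`, `drug_ae_counts`, `top_ae`,
#'   `brand_generic_counts`, `patient_lines`, `demographics_summary`) and a
#'   matrix `chord_matrix` whose row/column sums equal the corresponding
#'   per-drug/per-event totals of `drug_ae_counts`.
#' @export
build_report <- function(pairs, notes, demographics = NULL, top_k = 3L,
                         count_notes = FALSE,
                         age_breaks = c(seq(0, 90, 10), Inf)) {
  if (is.character(pairs)) pairs <- read_pairs(pairs)
  if (is.character(notes)) notes <- read_notes(notes, "jsonl")
  if (is.character(demographics)) {
    demographics <- read.csv(demographics, stringsAsFactors = FALSE)
  }
  up <- pairs[!pairs$filtered, , drop = FALSE]
  subj <- setNames(notes$subject_id, notes$note_id)
  up$unit <- if (count_notes) up$note_id else unname(subj[up$note_id])

  count_by <- function(cols) {
    if (nrow(up) == 0L) {
      out <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                           stringsAsFactors = FALSE)
      out$n <- integer()
      return(out)
    }
    ag <- aggregate(list(n = up$unit),
                    by = lapply(cols, function(cc) {
                      v <- up[[cc]]
                      v[is.na(v)] <- ""  # keep NA groups (e.g. absent LLT)
                      v
                    }),
                    FUN = function(z) length(unique(z)))
    names(ag)[seq_along(cols)] <- cols
    ag <- ag[do.call(order, ag[cols]), , drop = FALSE]
    rownames(ag) <- NULL
    ag
  }

  class_counts <- count_by("drug_class")
  drug_counts <- count_by("generic_drug")
  drug_ae_counts <- count_by(c("generic_drug", "ae_pt", "ae_llt"))
  brand_generic_counts <- count_by("drug_kind")

  # per-drug top-k events by patient count, ties alphabetical by PT
  dac <- count_by(c("generic_drug", "ae_pt"))
  top_ae <- ox_rbind(lapply(split(dac, dac$generic_drug), function(g) {
    g <- g[order(-g$n, g$ae_pt), , drop = FALSE]
    g <- utils::head(g, top_k)
    g$rank <- seq_len(nrow(g))
    g
  }))
  if (is.null(top_ae)) {
    top_ae <- data.frame(generic_drug = character(), ae_pt = character(),
                         n = integer(), rank = integer(),
                         stringsAsFactors = FALSE)
  }
  rownames(top_ae) <- NULL

  drugs <- sort(unique(dac$generic_drug))
  aes <- sort(unique(dac$ae_pt))
  chord <- matrix(0L, nrow = length(drugs), ncol = length(aes),
                  dimnames = list(drugs, aes))
  for (r in seq_len(nrow(dac))) {
    chord[dac$generic_drug[r], dac$ae_pt[r]] <- dac$n[r]
  }

  patient_lines <- if (nrow(up) > 0L) {
    pl <- unique(data.frame(subject_id = unname(subj[up$note_id]),
                            generic_drug = up$generic_drug,
                            ae_pt = up$ae_pt, note_id = up$note_id,
                            stringsAsFactors = FALSE))
    pl <- pl[order(pl$subject_id, pl$generic_drug, pl$ae_pt, pl$note_id), ]
    rownames(pl) <- NULL
    pl
  } else {
    data.frame(subject_id = character(), generic_drug = character(),
               ae_pt = character(), note_id = character(),
               stringsAsFactors = FALSE)
  }

  demographics_summary <- NULL
  if (!is.null(demographics)) {
    in_pairs <- unique(unname(subj[up$note_id]))
    orphans <- setdiff(in_pairs, demographics$subject_id)
    if (length(orphans) > 0L) {
      warning("patients in pairs without demographics: ",
              paste(orphans, collapse = ", "), call. = FALSE)
    }
    dd <- demographics[demographics$subject_id %in% in_pairs, , drop = FALSE]
    age_bins <- cut(dd$age, breaks = age_breaks, right = FALSE,
                    include.lowest = TRUE)
    demographics_summary <- list(
      age = as.data.frame(table(bin = age_bins), stringsAsFactors = FALSE),
      gender = as.data.frame(table(gender = dd$gender),
                             stringsAsFactors = FALSE),
      ethnicity = as.data.frame(table(ethnicity = dd$ethnicity),
                                stringsAsFactors = FALSE))
  }

  structure(list(class_counts = class_counts, drug_counts = drug_counts,
                 drug_ae_counts = drug_ae_counts, top_ae = top_ae,
                 brand_generic_counts = brand_generic_counts,
                 chord_matrix = chord, patient_lines = patient_lines,
                 demographics_summary = demographics_summary),
            class = "orade_report")
}

#' @export
print.orade_report <- function(x, ...) {
  cat("<orade_report>\n")
  cat("  drugs:", nrow(x$drug_counts), " drug-AE combinations:",
      nrow(x$drug_ae_counts), "\n")
  cat("  chord matrix:", nrow(x$chord_matrix), "x", ncol(x$chord_matrix), "\n")
  invisible(x)
}

#' Serialize a report bundle to a directory of CSV/JSON files
#'
#' One file per report table; the chord matrix is written as CSV with drugs
#' as row names and events as columns, demographic summaries as JSON.
#'
#' @param report An `orade_report` from [build_report()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wcsv <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    paths <<- c(paths, p)
  }
  wcsv(report$class_counts, "class_counts.csv")
  wcsv(report$drug_counts, "drug_counts.csv")
  wcsv(report$drug_ae_counts, "drug_ae_counts.csv")
  wcsv(report$top_ae, "top_ae.csv")
  wcsv(report$brand_generic_counts, "brand_generic_counts.csv")
  wcsv(report$patient_lines, "patient_lines.csv")
  p <- file.path(dir, "chord_matrix.csv")
  write.csv(as.data.frame(report$chord_matrix), p, fileEncoding = "UTF-8")
  paths <- c(paths, p)
  if (!is.null(report$demographics_summary)) {
    p <- file.path(dir, "demographics_summary.json")
    writeLines(as.character(jsonlite::toJSON(report$demographics_summary,
                                             dataframe = "rows")), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
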