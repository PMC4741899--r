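# Packaged clinical validation records: 12 retrospective + 20 prospective
# transplanted recipient-donor pairs with per-locus GVH-direction mismatch
# records (revised and coordinate RMSD, observed aGVHD grades), the
# candidate-donor panels of the five recipients with alternative donors,
# and the low-resolution typing of all 37 recipient-donor pairs.
#
# Transcription fidelity: values are stored exactly as printed, including
# the source's internal inconsistencies, which are flagged in the `note`
# column rather than silently corrected (see the methods vignette).

fixture_path <- function(file, dir = NULL) {
  p <- if (!is.null(dir)) file.path(dir, file)
  else {
    q <- system.file("extdata", file, package = "hlarmsd")
    if (nzchar(q)) q else file.path("inst", "extdata", file)  # pre-install use
  }
  if (!file.exists(p))
    abort(sprintf("packaged fixture %s not found", file), "fixture_error")
  p
}

read_fixture_tsv <- function(file, dir = NULL) {
  utils::read.delim(fixture_path(file, dir), stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Load the packaged clinical fixture
#'
#' Reads the transcribed clinical records and validates them: every
#' transplanted pair's printed total must equal the 4-decimal sum of its
#' per-locus revised RMSD components, except for rows explicitly flagged
#' `total_discrepant` in the source; the same check runs over every
#' candidate-donor panel. A checksum break on an unflagged row aborts,
#' naming the offending subject.
#'
#' @param dir optional directory holding the fixture TSVs (default: the
#'   files packaged under `extdata/`).
#' @return object of class `clinical_fixture` with elements
#'   `pairs` (per-subject data.frame: cohort, observed grade, printed total,
#'   genotype columns), `mismatches` (per-pair mismatch records),
#'   `panel_donors`, `panel_mismatches`, and `typing_low_resolution`.
#' @export
load_clinical_fixture <- function(dir = NULL) {
  pairs <- read_fixture_tsv("clinical_pairs.tsv", dir)
  mism <- read_fixture_tsv("clinical_mismatches.tsv", dir)
  pdon <- read_fixture_tsv("panel_donors.tsv", dir)
  pmis <- read_fixture_tsv("panel_mismatches.tsv", dir)
  lowres <- read_fixture_tsv("typing_low_resolution.tsv", dir)
  for (df in list(mism, pmis)) {
    stopifnot(all(as.numeric(df$revised_rmsd) >= 0),
              all(as.numeric(df$coordinate_rmsd) >= 0))
  }
  # transcription self-check: totals re-derive from components
  for (i in seq_len(nrow(pairs))) {
    upn <- pairs$upn[i]
    if (!nzchar(pairs$total_printed[i])) next   # transplant not performed
    comp <- as.numeric(mism$revised_rmsd[mism$upn == upn])
    total <- fixed_sum4(comp)
    printed <- as.numeric(pairs$total_printed[i])
    if (!isTRUE(all.equal(total, printed, tolerance = 1e-9)) &&
        !grepl("total_discrepant", pairs$note[i]))
      abort(sprintf("fixture checksum broken for %s: components sum to %.4f, printed total %.4f",
                    upn, total, printed), "fixture_error")
  }
  for (i in seq_len(nrow(pdon))) {
    upn <- pdon$upn[i]; did <- pdon$donor_id[i]
    comp <- as.numeric(pmis$revised_rmsd[pmis$upn == upn & pmis$donor_id == did])
    total <- fixed_sum4(comp)
    printed <- as.numeric(pdon$total_printed[i])
    if (!isTRUE(all.equal(total, printed, tolerance = 1e-9)) &&
        !grepl("total_discrepant", pdon$note[i]))
      abort(sprintf("fixture checksum broken for %s/%s: components sum to %.4f, printed total %.4f",
                    upn, did, total, printed), "fixture_error")
  }
  structure(list(pairs = pairs, mismatches = mism,
                 panel_donors = pdon, panel_mismatches = pmis,
                 typing_low_resolution = lowres),
            class = "clinical_fixture")
}

#' @export
print.clinical_fixture <- function(x, ...) {
  cat(sprintf("<clinical fixture> %d transplanted pairs (%d retrospective, %d prospective), %d panel donors\n",
              sum(nzchar(x$pairs$total_printed)),
              sum(x$pairs$cohort == "retrospective"),
              sum(x$pairs$cohort == "prospective" & nzchar(x$pairs$total_printed)),
              nrow(x$panel_donors)))
  invisible(x)
}

genotype_from_row <- function(row, prefix, subject_id) {
  rec <- list()
  for (loc in HLA_LOCI) {
    c1 <- paste0(prefix, loc, "_1"); c2 <- paste0(prefix, loc, "_2")
    if (c1 %in% names(row) && nzchar(row[[c1]]) && nzchar(row[[c2]]))
      rec[[loc]] <- c(row[[c1]], row[[c2]])
  }
  parse_genotype(rec, subject_id = subject_id)
}

#' Genotypes of a fixture subject
#'
#' @param fixture from [load_clinical_fixture()].
#' @param upn subject id, e.g. `"P-UPN01"`.
#' @return list with `recipient` and (when transplanted) `donor`
#'   `hla_genotype`s.
#' @export
fixture_genotypes <- function(fixture, upn) {
  i <- match(upn, fixture$pairs$upn)
  if (is.na(i))
    abort(sprintf("unknown subject %s", upn), "fixture_error")
  row <- fixture$pairs[i, , drop = FALSE]
  out <- list(recipient = genotype_from_row(row, "R_", upn))
  if (nzchar(row$D_A_1))
    out$donor <- genotype_from_row(row, "D_", paste0(upn, "-donor"))
  out
}

#' RMSD lookup matrix from fixture mismatch records
#'
#' Builds an [rmsd_matrix()] from transcribed records. Because the same
#' unordered pair is occasionally printed with slightly different revised
#' RMSD in different rows of the source, the builder can restrict to a
#' subject subset (the faithful reproduction of one subject uses that
#' subject's own rows) and takes a conflict policy for the remainder.
#'
#' @param records `fixture$mismatches` or `fixture$panel_mismatches`.
#' @param upn optional subject filter.
#' @param donor_id optional donor filter (panel records).
#' @param on_conflict for duplicated pairs with differing values:
#'   `"first"` (default) keeps the first row, `"error"` aborts.
#' @return `rmsd_matrix` with `source = "fixture"`.
#' @export
fixture_matrix <- function(records, upn = NULL, donor_id = NULL,
                           on_conflict = c("first", "error")) {
  on_conflict <- match.arg(on_conflict)
  df <- records
  if (!is.null(upn)) df <- df[df$upn %in% upn, , drop = FALSE]
  if (!is.null(donor_id) && "donor_id" %in% names(df))
    df <- df[df$donor_id %in% donor_id, , drop = FALSE]
  if (!nrow(df))
    abort("no fixture records after filtering", "fixture_error")
  recs <- lapply(seq_len(nrow(df)), function(i) {
    rmsd_record(df$recipient_allele[i], df$donor_allele[i],
                coordinate_rmsd = as.numeric(df$coordinate_rmsd[i]),
                revised_rmsd = as.numeric(df$revised_rmsd[i]),
                n_mismatch_aa = as.integer(df$n_mm_aa[i]))
  })
  tab <- do.call(rbind, recs)
  key <- paste(mapply(pair_key, tab$allele1, tab$allele2))
  if (anyDuplicated(key)) {
    if (on_conflict == "error") {
      dup <- unique(key[duplicated(key)])
      conflicting <- vapply(dup, function(k) {
        vals <- tab$revised_rmsd[key == k]
        length(unique(vals)) > 1L
      }, logical(1))
      if (any(conflicting))
        abort(sprintf("conflicting fixture records for pair %s",
                      sub("\\|", " / ", dup[conflicting][1])), "fixture_error")
    }
    tab <- tab[!duplicated(key), , drop = FALSE]
  }
  rmsd_matrix(tab, source = "fixture")
}

#' Re-run the matching pipeline on a fixture subject
#'
#' Rebuilds recipient and donor genotypes for a transplanted pair, builds
#' the lookup matrix from that subject's own transcribed records, and runs
#' [match_report()] end to end — so totals and severity predictions are
#' recomputed by the engine, not read off the table.
#'
#' @param fixture from [load_clinical_fixture()].
#' @param upn subject id.
#' @param config see [matching_config()].
#' @return `match_report` (observed grade attached from the fixture).
#' @export
reproduce_clinical_report <- function(fixture, upn, config = matching_config()) {
  g <- fixture_genotypes(fixture, upn)
  if (is.null(g$donor))
    abort(sprintf("%s did not undergo transplantation; no donor genotype", upn),
          "fixture_error")
  mat <- fixture_matrix(fixture$mismatches, upn = upn)
  i <- match(upn, fixture$pairs$upn)
  grade <- fixture$pairs$agvhd_grade[i]
  match_report(g$recipient, g$donor, mat, config,
               observed_grade = if (nzchar(grade)) grade else NA_character_)
}

#' Re-run donor ranking on a fixture candidate panel
#'
#' Each candidate donor is scored against the recipient with the lookup
#' matrix built from that donor's own transcribed records (the printed
#' pairing for a candidate is part of its record set; pooling all
#' candidates' records would let the assignment step mix rows across
#' donors), then the candidates are ranked by total revised RMSD.
#'
#' @param fixture from [load_clinical_fixture()].
#' @param upn recipient with a candidate panel (`P-UPN08`, `P-UPN06`,
#'   `P-UPN03`, `P-UPN07`, `P-UPN09`).
#' @param config see [matching_config()].
#' @return the [rank_donors()] table (reports in `attr(,"reports")`).
#' @export
reproduce_panel_ranking <- function(fixture, upn, config = matching_config()) {
  pd <- fixture$panel_donors[fixture$panel_donors$upn == upn, , drop = FALSE]
  if (!nrow(pd))
    abort(sprintf("no candidate panel for %s", upn), "fixture_error")
  recipient <- fixture_genotypes(fixture, upn)$recipient
  donors <- lapply(seq_len(nrow(pd)), function(i)
    genotype_from_row(pd[i, , drop = FALSE], "", pd$donor_id[i]))
  mats <- lapply(pd$donor_id, function(d)
    fixture_matrix(fixture$panel_mismatches, upn = upn, donor_id = d))
  names(mats) <- pd$donor_id
  rank_donors(recipient, donors, mats, config)
}

#' Reports for a whole fixture cohort
#'
#' @param fixture from [load_clinical_fixture()].
#' @param cohort `"retrospective"` or `"prospective"`; only transplanted
#'   pairs (with an observed grade) are included.
#' @param config see [matching_config()].
#' @return named list of `match_report`.
#' @export
fixture_cohort_reports <- function(fixture,
                                   cohort = c("retrospective", "prospective"),
                                   config = matching_config()) {
  cohort <- match.arg(cohort)
  sel <- fixture$pairs$cohort == cohort & nzchar(fixture$pairs$agvhd_grade)
  upns <- fixture$pairs$upn[sel]
  reports <- lapply(upns, function(u) reproduce_clinical_report(fixture, u, config))
  names(reports) <- upns
  reports
}
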