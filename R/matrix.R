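# Pairwise RMSD matrix: one record per within-locus unordered allele pair,
# with coordinate RMSD, revised RMSD, and optional annotation fields
# (mismatched-residue count, groove pockets, peptide-binding / TCR-contact
# flags). Persisted as a human-diffable TSV.

#' Create one pairwise RMSD record
#'
#' Allele order is canonicalized (lexicographic on the canonical names) so
#' that lookups are order-insensitive.
#'
#' @param allele1,allele2 alleles of the same locus (names or
#'   `hla_allele`), both high-resolution.
#' @param coordinate_rmsd,revised_rmsd RMSD values in Angstrom, `>= 0`.
#' @param n_mismatch_aa optional count of mismatched residues in the
#'   functional region.
#' @param pockets optional character vector, subset of A-F.
#' @param peptide_binding,tcr_contact optional logical flags.
#' @return a one-row data.frame (class `rmsd_record`).
#' @export
rmsd_record <- function(allele1, allele2, coordinate_rmsd, revised_rmsd,
                        n_mismatch_aa = NA_integer_, pockets = NA_character_,
                        peptide_binding = NA, tcr_contact = NA) {
  a1 <- as_allele(allele1); a2 <- as_allele(allele2)
  if (a1$locus != a2$locus)
    abort(sprintf("cross-locus record %s / %s", format(a1), format(a2)),
          "matrix_error")
  if (!is_high_resolution(a1) || !is_high_resolution(a2))
    abort(sprintf("RMSD records require high-resolution alleles (got %s / %s)",
                  format(a1), format(a2)), "matrix_error")
  if (coordinate_rmsd < 0 || revised_rmsd < 0)
    abort("RMSD values must be nonnegative", "matrix_error")
  n1 <- format(a1); n2 <- format(a2)
  if (n2 < n1) { tmp <- n1; n1 <- n2; n2 <- tmp }
  pk <- if (length(pockets) && !all(is.na(pockets)))
    paste(sort(unique(pockets)), collapse = ",") else NA_character_
  df <- data.frame(
    locus = a1$locus, allele1 = n1, allele2 = n2,
    coordinate_rmsd = as.numeric(coordinate_rmsd),
    revised_rmsd = as.numeric(revised_rmsd),
    n_mismatch_aa = as.integer(n_mismatch_aa), pockets = pk,
    peptide_binding = as.logical(peptide_binding),
    tcr_contact = as.logical(tcr_contact),
    stringsAsFactors = FALSE
  )
  class(df) <- c("rmsd_record", class(df))
  df
}

pair_key <- function(a, b) {
  n1 <- allele_name(a); n2 <- allele_name(b)
  if (n2 < n1) paste(n2, n1, sep = "|") else paste(n1, n2, sep = "|")
}

#' Assemble an RMSD matrix from records
#'
#' @param records a data.frame of records (rows as produced by
#'   [rmsd_record()], possibly `rbind`-ed) or a list of such.
#' @param source provenance tag, `"computed"` or `"fixture"`.
#' @return object of class `rmsd_matrix`.
#' @export
rmsd_matrix <- function(records, source = "computed") {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  records <- as.data.frame(records)
  needed <- c("locus", "allele1", "allele2", "coordinate_rmsd", "revised_rmsd")
  if (!all(needed %in% names(records)))
    abort(sprintf("records lack columns: %s",
                  paste(setdiff(needed, names(records)), collapse = ", ")),
          "matrix_error")
  for (col in c("n_mismatch_aa", "pockets", "peptide_binding", "tcr_contact"))
    if (!col %in% names(records)) records[[col]] <- NA
  keys <- mapply(pair_key, records$allele1, records$allele2)
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1]
    abort(sprintf("duplicate record for pair %s", sub("\\|", " / ", dup)),
          "matrix_error")
  }
  rownames(records) <- keys
  structure(list(records = records, source = source), class = "rmsd_matrix")
}

#' @export
print.rmsd_matrix <- function(x, ...) {
  cat(sprintf("<RMSD matrix> %d record(s) across %d locus/loci [%s]\n",
              nrow(x$records), length(unique(x$records$locus)), x$source))
  invisible(x)
}

#' Compute an RMSD matrix from structure models
#'
#' One record per within-locus unordered pair of models; cross-locus
#' pairs are never computed.
#'
#' @param models list of `structure_model` with distinct high-resolution
#'   alleles.
#' @param regions named list of `region_set` per class, defaults to
#'   `list(I = region_set("I"), II = region_set("II"))`.
#' @param weights optional per-pair weights forwarded to the RMSD calls.
#' @param fit superposition fit set for the revised RMSD, see
#'   [revised_rmsd()].
#' @return `rmsd_matrix` with `source = "computed"`.
#' @export
build_matrix <- function(models, regions = NULL, weights = NULL,
                         fit = c("region", "all")) {
  fit <- match.arg(fit)
  if (is.null(regions))
    regions <- list(I = region_set("I"), II = region_set("II"))
  ids <- vapply(models, function(m) format(m$allele), character(1))
  if (anyDuplicated(ids))
    abort(sprintf("duplicate allele id among models: %s",
                  ids[duplicated(ids)][1]), "matrix_error")
  loci <- vapply(models, function(m) m$allele$locus, character(1))
  recs <- list()
  for (loc in unique(loci)) {
    idx <- which(loci == loc)
    if (length(idx) < 2L) next
    reg <- regions[[hla_class(loc)]]
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in seq.int(i + 1L, length(idx))) {
        m1 <- models[[idx[i]]]; m2 <- models[[idx[j]]]
        recs[[length(recs) + 1L]] <- rmsd_record(
          m1$allele, m2$allele,
          coordinate_rmsd = coordinate_rmsd(m1, m2, weights),
          revised_rmsd = revised_rmsd(m1, m2, region = reg,
                                      weights = weights, fit = fit)
        )
      }
    }
  }
  rmsd_matrix(recs, source = "computed")
}

#' Look up the record for an allele pair
#'
#' Order-insensitive; querying an allele against itself returns an
#' implicit zero record.
#'
#' @param matrix `rmsd_matrix`.
#' @param a,b alleles (names or `hla_allele`) of the same locus, both
#'   high-resolution.
#' @return one-row record data.frame.
#' @export
lookup <- function(matrix, a, b) {
  stopifnot(inherits(matrix, "rmsd_matrix"))
  a <- as_allele(a); b <- as_allele(b)
  if (a$locus != b$locus)
    abort(sprintf("cross-locus query: %s vs %s", format(a), format(b)),
          "matrix_error")
  if (!is_high_resolution(a) || !is_high_resolution(b))
    abort(sprintf("matrix lookup needs high-resolution alleles (got %s / %s); type the subject at high resolution first",
                  format(a), format(b)), "matrix_error")
  if (allele_equal(a, b))
    return(rmsd_record(a, b, 0, 0, n_mismatch_aa = 0L))
  key <- pair_key(a, b)
  i <- match(key, rownames(matrix$records))
  if (is.na(i))
    abort(sprintf("pair %s / %s not in matrix", format(a), format(b)),
          "matrix_missing_pair")
  matrix$records[i, , drop = FALSE]
}

has_pair <- function(matrix, a, b) {
  a <- as_allele(a); b <- as_allele(b)
  allele_equal(a, b) ||
    pair_key(a, b) %in% rownames(matrix$records)
}

#' Acceptable-mismatch classification
#'
#' A mismatched pair is an acceptable (permissible) mismatch when its
#' revised RMSD does not exceed the locus-class threshold: 0.2 Angstrom
#' for the class I loci (A, B, Cw), 0.1 Angstrom for the class II loci
#' (DRB1, DQB1, DPB1).
#'
#' @param record a record row (from [lookup()] or [rmsd_record()]).
#' @param config thresholds, see [matching_config()].
#' @return logical.
#' @export
classify_acceptable <- function(record, config = matching_config()) {
  cl <- hla_class(record$locus)
  thr <- if (cl == "I") config$class1_threshold else config$class2_threshold
  record$revised_rmsd <= thr
}

#' Acceptable-mismatch dictionary for one allele
#'
#' All partners of `allele` in the matrix whose revised RMSD passes the
#' locus-class threshold, in canonical sort order; the allele itself is
#' excluded.
#'
#' @param matrix `rmsd_matrix`.
#' @param allele query allele (name or `hla_allele`).
#' @param config thresholds, see [matching_config()].
#' @return character vector of canonical allele names (possibly empty).
#' @export
acceptable_dictionary <- function(matrix, allele, config = matching_config()) {
  stopifnot(inherits(matrix, "rmsd_matrix"))
  a <- as_allele(allele)
  nm <- format(a)
  rec <- matrix$records
  hit <- rec$allele1 == nm | rec$allele2 == nm
  if (!any(hit))
    abort(sprintf("allele %s not in matrix", nm), "matrix_error")
  rec <- rec[hit, , drop = FALSE]
  ok <- vapply(seq_len(nrow(rec)),
               function(i) classify_acceptable(rec[i, , drop = FALSE], config),
               logical(1))
  partners <- ifelse(rec$allele1 == nm, rec$allele2, rec$allele1)[ok]
  sort(unique(partners))
}

#' Annotate mismatched residues between two aligned sequences
#'
#' Counts differing positions inside the functional region and collects
#' the pocket labels / functional flags attached to those positions.
#'
#' @param seq1,seq2 equal-length aligned residue sequences (character
#'   vectors of one-letter codes, or single strings).
#' @param region `region_set` (positions are 1-based indices into the
#'   alignment, mature-protein numbering).
#' @param pocket_map optional data.frame with columns `position`,
#'   `pocket` (label A-F or `NA`), `peptide_binding`, `tcr_contact`
#'   (logical). The groove pocket assignments are site-specific
#'   configuration, not built in.
#' @return list with `n_mismatch_aa`, `pockets` (character vector),
#'   `peptide_binding`, `tcr_contact`, and `positions` of the in-region
#'   differences.
#' @export
annotate_mismatches <- function(seq1, seq2, region, pocket_map = NULL) {
  if (length(seq1) == 1L && nchar(seq1) > 1L) seq1 <- strsplit(seq1, "")[[1]]
  if (length(seq2) == 1L && nchar(seq2) > 1L) seq2 <- strsplit(seq2, "")[[1]]
  if (length(seq1) != length(seq2))
    abort(sprintf("aligned sequences differ in length (%d vs %d)",
                  length(seq1), length(seq2)), "annotate_error")
  pos <- which(seq1 != seq2)
  pos <- pos[in_region(pos, region)]
  pockets <- character(0)
  pb <- FALSE; tc <- FALSE
  if (!is.null(pocket_map) && length(pos)) {
    hit <- pocket_map[pocket_map$position %in% pos, , drop = FALSE]
    pockets <- sort(unique(stats::na.omit(hit$pocket)))
    if ("peptide_binding" %in% names(hit))
      pb <- any(hit$peptide_binding %in% TRUE)
    if ("tcr_contact" %in% names(hit))
      tc <- any(hit$tcr_contact %in% TRUE)
  }
  list(n_mismatch_aa = length(pos), pockets = pockets,
       peptide_binding = pb, tcr_contact = tc, positions = pos)
}

#' Write an RMSD matrix as TSV
#'
#' Canonical 4-decimal formatting for the RMSD columns; empty string for
#' absent annotations. Round-trips bit-exactly through
#' [read_matrix()].
#'
#' @param matrix `rmsd_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "rmsd_matrix"))
  df <- matrix$records
  out <- data.frame(
    locus = df$locus, allele1 = df$allele1, allele2 = df$allele2,
    coordinate_rmsd = sprintf("%.4f", round_half_up(df$coordinate_rmsd, 4)),
    revised_rmsd = sprintf("%.4f", round_half_up(df$revised_rmsd, 4)),
    n_mismatch_aa = ifelse(is.na(df$n_mismatch_aa), "", as.character(df$n_mismatch_aa)),
    pockets = ifelse(is.na(df$pockets), "", df$pockets),
    peptide_binding = ifelse(is.na(df$peptide_binding), "",
                             ifelse(df$peptide_binding, "yes", "no")),
    tcr_contact = ifelse(is.na(df$tcr_contact), "",
                         ifelse(df$tcr_contact, "yes", "no")),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an RMSD matrix from TSV
#'
#' @param path TSV written by [write_matrix()] (or hand-edited in the
#'   same layout).
#' @param source provenance tag stored on the matrix.
#' @return `rmsd_matrix`.
#' @export
read_matrix <- function(path, source = "fixture") {
  if (!file.exists(path))
    abort(sprintf("matrix file not found: %s", path), "hla_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  yn <- function(v) ifelse(v == "", NA, v == "yes")
  records <- data.frame(
    locus = df$locus, allele1 = df$allele1, allele2 = df$allele2,
    coordinate_rmsd = as.numeric(df$coordinate_rmsd),
    revised_rmsd = as.numeric(df$revised_rmsd),
    n_mismatch_aa = ifelse(df$n_mismatch_aa == "", NA_integer_,
                           as.integer(df$n_mismatch_aa)),
    pockets = ifelse(df$pockets == "", NA_character_, df$pockets),
    peptide_binding = yn(df$peptide_binding),
    tcr_contact = yn(df$tcr_contact),
    stringsAsFactors = FALSE
  )
  rmsd_matrix(records, source = source)
}
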