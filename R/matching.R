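# GVH-direction mismatch resolution, aggregation, severity prediction,
# donor ranking, and concordance scoring.
#
# Direction convention: a graft-versus-host (GVH) direction mismatch is a
# recipient allele absent from the donor's genotype at that locus -- the
# antigen donor-derived T cells can attack. Loci where every recipient
# allele appears in the donor yield no pairs even if the donor carries
# extra alleles (host-versus-graft direction, out of scope here).

#' Resolve GVH-direction mismatches at one locus
#'
#' Recipient alleles not carried by the donor are mismatches. Each is
#' paired with a donor-side partner drawn from the multiset difference
#' donor minus recipient, so a homozygous donor sharing one allele with
#' the recipient still exposes its duplicated allele as the partner.
#' When two recipient alleles face two candidate partners, the pairing
#' with the minimum total revised RMSD is chosen (bipartite assignment;
#' with a 2 x 2 this is a two-permutation comparison). A pairing is only
#' considered when all its records exist in the matrix; if no complete
#' pairing exists an error lists the missing pair.
#'
#' @param recipient,donor `hla_genotype`.
#' @param matrix `rmsd_matrix` holding the needed pair records.
#' @param loci loci to compare; default the loci present in both subjects.
#' @param config thresholds, see [matching_config()].
#' @return data.frame with one row per mismatch pair: `locus`,
#'   `recipient_allele`, `donor_allele`, `coordinate_rmsd`,
#'   `revised_rmsd`, `acceptable`.
#' @export
gvh_mismatches <- function(recipient, donor, matrix,
                           loci = NULL, config = matching_config()) {
  stopifnot(inherits(recipient, "hla_genotype"), inherits(donor, "hla_genotype"))
  if (is.null(loci))
    loci <- intersect(genotype_loci(recipient), genotype_loci(donor))
  rows <- list()
  for (loc in loci) {
    r <- genotype_allele_names(recipient, loc)
    d <- genotype_allele_names(donor, loc)
    r_mm <- setdiff(unique(r), unique(d))       # recipient-has / donor-lacks
    if (!length(r_mm)) next
    # donor partner pool: multiset difference donor \ recipient
    d_pool <- d
    for (al in r) {
      hit <- match(al, d_pool)
      if (!is.na(hit)) d_pool <- d_pool[-hit]
    }
    d_pool <- unique(d_pool)
    if (!length(d_pool)) d_pool <- unique(d)    # degenerate guard
    assign_tab <- assign_pairs(loc, r_mm, d_pool, matrix,
                               recipient$subject_id, donor$subject_id)
    rows[[length(rows) + 1L]] <- assign_tab
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(0), recipient_allele = character(0),
               donor_allele = character(0), coordinate_rmsd = numeric(0),
               revised_rmsd = numeric(0), stringsAsFactors = FALSE)
  out$acceptable <- if (nrow(out)) vapply(seq_len(nrow(out)), function(i) {
    classify_acceptable(data.frame(locus = out$locus[i],
                                   revised_rmsd = out$revised_rmsd[i]), config)
  }, logical(1)) else logical(0)
  rownames(out) <- NULL
  out
}

# enumerate candidate recipient->donor pairings and keep the feasible one
# with minimum total revised RMSD
assign_pairs <- function(locus, r_mm, d_pool, matrix, rid, did) {
  r_mm <- sort(r_mm)
  maps <- if (length(d_pool) >= length(r_mm)) {
    # injective maps: permutations of d_pool taken |r_mm| at a time
    perms <- permn(seq_along(d_pool), length(r_mm))
    lapply(perms, function(p) d_pool[p])
  } else {
    # fewer distinct partners than mismatches (homozygous donor):
    # every mismatch pairs against some pool member, reuse allowed
    grid <- as.matrix(expand.grid(rep(list(seq_along(d_pool)), length(r_mm))))
    lapply(seq_len(nrow(grid)), function(i) d_pool[grid[i, ]])
  }
  best <- NULL; best_total <- Inf; missing_pair <- NULL
  for (partners in maps) {
    ok <- all(mapply(function(a, b) has_pair(matrix, a, b), r_mm, partners))
    if (!ok) {
      i <- which(!mapply(function(a, b) has_pair(matrix, a, b), r_mm, partners))[1]
      missing_pair <- c(r_mm[i], partners[i])
      next
    }
    recs <- lapply(seq_along(r_mm),
                   function(i) lookup(matrix, r_mm[i], partners[i]))
    total <- fixed_sum4(vapply(recs, function(x) x$revised_rmsd, numeric(1)))
    if (total < best_total) {
      best_total <- total
      best <- data.frame(
        locus = locus, recipient_allele = r_mm, donor_allele = partners,
        coordinate_rmsd = vapply(recs, function(x) x$coordinate_rmsd, numeric(1)),
        revised_rmsd = vapply(recs, function(x) x$revised_rmsd, numeric(1)),
        stringsAsFactors = FALSE)
    }
  }
  if (is.null(best))
    abort(sprintf("no RMSD record for required pair %s / %s (recipient %s vs donor %s, locus %s)",
                  missing_pair[1], missing_pair[2], rid, did, locus),
          "matrix_missing_pair")
  best
}

permn <- function(v, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v))
    for (rest in permn(v[-i], k - 1L))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

#' Total revised RMSD over mismatch pairs
#'
#' Sum of the per-pair revised RMSDs on a 4-decimal fixed-point grid (so
#' the total equals the printed sum of its components exactly); empty
#' input gives 0.
#'
#' @param pairs data.frame from [gvh_mismatches()] (or any frame with a
#'   `revised_rmsd` column), or a bare numeric vector.
#' @return total in Angstrom.
#' @export
total_revised_rmsd <- function(pairs) {
  v <- if (is.data.frame(pairs)) pairs$revised_rmsd else as.numeric(pairs)
  fixed_sum4(v)
}

#' Predict aGVHD severity class
#'
#' Severe (grade III-IV) when the total or the maximum single revised
#' RMSD reaches the cutoff; mild (grade I-II) otherwise. A value exactly
#' at the cutoff classifies as severe under the conservative default
#' boundary.
#'
#' @param total total revised RMSD, Angstrom.
#' @param max_single maximum single-pair revised RMSD, Angstrom
#'   (defaults to `total`, which is exact when there is at most one pair
#'   and conservative-neutral otherwise since `total >= max_single`).
#' @param config cutoff and boundary rule, see [matching_config()].
#' @return `"mild"` or `"severe"`.
#' @export
predict_severity <- function(total, max_single = total, config = matching_config()) {
  stopifnot(total >= 0, max_single >= 0)
  cut <- config$severity_cutoff
  over <- if (config$boundary == "severe")
    (total >= cut) || (max_single >= cut)
  else
    (total > cut) || (max_single > cut)
  if (over) "severe" else "mild"
}

#' Build a match report for a recipient-donor combination
#'
#' Runs [gvh_mismatches()], aggregates the total and maximum single
#' revised RMSD, and attaches the predicted severity class.
#'
#' @param recipient,donor `hla_genotype`.
#' @param matrix `rmsd_matrix`.
#' @param config see [matching_config()].
#' @param observed_grade optional observed aGVHD grade
#'   (`"I"`,`"II"`,`"III"`,`"IV"`).
#' @param loci loci to compare (default: loci present in both).
#' @return object of class `match_report`.
#' @export
match_report <- function(recipient, donor, matrix, config = matching_config(),
                         observed_grade = NA_character_, loci = NULL) {
  pairs <- gvh_mismatches(recipient, donor, matrix, loci = loci, config = config)
  total <- total_revised_rmsd(pairs)
  max_single <- if (nrow(pairs)) max(pairs$revised_rmsd) else 0
  structure(list(
    recipient_id = recipient$subject_id, donor_id = donor$subject_id,
    pairs = pairs, total_revised_rmsd = total, max_single_revised = max_single,
    predicted_class = predict_severity(total, max_single, config),
    observed_grade = observed_grade,
    acceptable_choice = total < config$severity_cutoff
  ), class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match report> %s vs donor %s\n", x$recipient_id, x$donor_id))
  if (nrow(x$pairs)) {
    for (i in seq_len(nrow(x$pairs)))
      cat(sprintf("  %-5s %s / %s  revised %.4f%s\n",
                  x$pairs$locus[i], x$pairs$recipient_allele[i],
                  x$pairs$donor_allele[i], x$pairs$revised_rmsd[i],
                  if (x$pairs$acceptable[i]) "  [acceptable]" else ""))
  } else cat("  no mismatch in GVH direction\n")
  cat(sprintf("  total revised RMSD %.4f  max single %.4f  predicted %s aGVHD%s\n",
              x$total_revised_rmsd, x$max_single_revised, x$predicted_class,
              if (is.na(x$observed_grade)) ""
              else sprintf("  (observed grade %s)", x$observed_grade)))
  invisible(x)
}

#' Rank candidate donors for a recipient
#'
#' Ascending by total revised RMSD; ties keep the input order. Donors
#' whose total falls below the severity cutoff are flagged as acceptable
#' choices.
#'
#' @param recipient `hla_genotype`.
#' @param donors list of `hla_genotype` (at least one).
#' @param matrix `rmsd_matrix`, or a plain list of `rmsd_matrix` named by
#'   donor id when each candidate carries its own record set (as the
#'   packaged candidate-panel fixtures do).
#' @param config see [matching_config()].
#' @param loci loci to compare.
#' @return data.frame ordered by rank, with columns `rank`, `donor_id`,
#'   `total_revised_rmsd`, `max_single_revised`, `predicted_class`,
#'   `acceptable_choice`; the reports themselves in
#'   `attr(, "reports")` (named by donor id, input order).
#' @export
rank_donors <- function(recipient, donors, matrix, config = matching_config(),
                        loci = NULL) {
  if (!length(donors))
    abort("at least one candidate donor is required", "matching_error")
  per_donor <- !inherits(matrix, "rmsd_matrix")
  if (per_donor) {
    ids <- vapply(donors, function(d) d$subject_id, character(1))
    missing_mat <- setdiff(ids, names(matrix))
    if (length(missing_mat))
      abort(sprintf("no RMSD matrix supplied for donor(s): %s",
                    paste(missing_mat, collapse = ", ")), "matching_error")
  }
  reports <- lapply(donors, function(d) {
    m <- if (per_donor) matrix[[d$subject_id]] else matrix
    tryCatch(
      match_report(recipient, d, m, config, loci = loci),
      hlarmsd_error = function(e)
        abort(sprintf("donor %s: %s", d$subject_id, conditionMessage(e)),
              "matching_error")
    )
  })
  totals <- vapply(reports, function(r) r$total_revised_rmsd, numeric(1))
  o <- order(totals)  # stable: ties keep input order
  tab <- data.frame(
    rank = seq_along(o),
    donor_id = vapply(reports, function(r) r$donor_id, character(1))[o],
    total_revised_rmsd = totals[o],
    max_single_revised = vapply(reports, function(r) r$max_single_revised,
                                numeric(1))[o],
    predicted_class = vapply(reports, function(r) r$predicted_class,
                             character(1))[o],
    acceptable_choice = vapply(reports, function(r) r$acceptable_choice,
                               logical(1))[o],
    stringsAsFactors = FALSE
  )
  names(reports) <- vapply(reports, function(r) r$donor_id, character(1))
  attr(tab, "reports") <- reports
  tab
}

#' Concordance between predicted class and observed grades
#'
#' Observed grades dichotomize as I-II = mild, III-IV = severe; the
#' concordance is the percent of reports whose predicted class matches.
#'
#' @param reports list of `match_report`, each with an observed grade.
#' @return list with `percent` (rounded half-up to integer), `exact`
#'   (exact percent), `n_concordant`, `n`, and `discordant` (recipient
#'   ids of the mismatching reports).
#' @export
concordance <- function(reports) {
  if (!length(reports))
    abort("concordance needs at least one report", "matching_error")
  obs <- vapply(reports, function(r) r$observed_grade, character(1))
  if (any(is.na(obs) | !obs %in% c("I", "II", "III", "IV")))
    abort("every report must carry an observed grade I-IV", "matching_error")
  obs_class <- ifelse(obs %in% c("I", "II"), "mild", "severe")
  pred <- vapply(reports, function(r) r$predicted_class, character(1))
  hit <- pred == obs_class
  list(
    percent = round_half_up(100 * mean(hit), 0),
    exact = 100 * mean(hit),
    n_concordant = sum(hit), n = length(hit),
    discordant = vapply(reports, function(r) r$recipient_id,
                        character(1))[!hit]
  )
}

#' Write a match report to TSV or JSON
#'
#' One row per mismatch pair plus a summary row (TSV), or a structured
#' object (JSON); the two formats carry the same fields.
#'
#' @param report `match_report`.
#' @param path output path.
#' @param format `"tsv"` or `"json"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = NULL) {
  stopifnot(inherits(report, "match_report"))
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  fmt4 <- function(x) sprintf("%.4f", round_half_up(x, 4))
  if (format == "json") {
    obj <- list(
      recipient_id = report$recipient_id, donor_id = report$donor_id,
      pairs = report$pairs,
      total_revised_rmsd = as.numeric(fmt4(report$total_revised_rmsd)),
      max_single_revised = as.numeric(fmt4(report$max_single_revised)),
      predicted_class = report$predicted_class,
      observed_grade = report$observed_grade,
      acceptable_choice = report$acceptable_choice
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  } else {
    p <- report$pairs
    rows <- data.frame(
      row_type = c(rep("pair", nrow(p)), "summary"),
      locus = c(p$locus, ""),
      recipient_allele = c(p$recipient_allele, report$recipient_id),
      donor_allele = c(p$donor_allele, report$donor_id),
      coordinate_rmsd = c(fmt4(p$coordinate_rmsd), ""),
      revised_rmsd = c(fmt4(p$revised_rmsd), fmt4(report$total_revised_rmsd)),
      acceptable = c(ifelse(p$acceptable, "yes", "no"),
                     report$predicted_class),
      stringsAsFactors = FALSE
    )
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
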