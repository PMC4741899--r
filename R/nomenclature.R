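# HLA allele nomenclature: parsing, canonical rendering, genotypes.
#
# Supported loci: class I A, B, Cw; class II DRB1, DQB1, DPB1. Names are
# accepted in the dialects seen in clinical typing reports: "A*02:01",
# "A*02: 01" (stray space), "A*0201" (concatenated 4-digit), "A*02"
# (low-resolution, allele group only) and legacy 3-digit names such as
# "A*203", which are kept verbatim as opaque group tokens.

HLA_LOCI <- c("A", "B", "Cw", "DRB1", "DQB1", "DPB1")
HLA_CLASS_I <- c("A", "B", "Cw")
HLA_CLASS_II <- c("DRB1", "DQB1", "DPB1")

#' HLA class of a locus
#' @param locus one of `"A"`, `"B"`, `"Cw"`, `"DRB1"`, `"DQB1"`, `"DPB1"`.
#' @return `"I"` or `"II"`.
#' @export
hla_class <- function(locus) {
  ifelse(locus %in% HLA_CLASS_I, "I",
         ifelse(locus %in% HLA_CLASS_II, "II", NA_character_))
}

#' Parse an HLA allele name
#'
#' Normalizes the dialects found in typing reports to a canonical
#' `LOCUS*GG:PP` form. Whitespace around field separators is ignored;
#' the concatenated 4-digit form `"A*0201"` splits as group `"02"`,
#' protein `"01"`; a bare group (`"A*02"`) is a low-resolution allele
#' with no protein field; 3-digit legacy names (`"A*203"`) are kept
#' verbatim as the group with no protein and flagged `legacy`.
#'
#' @param text allele name, e.g. `"A*02:01"`, `"DRB1*04: 01"`, `"B*13"`.
#' @return an object of class `hla_allele` with fields `locus`, `group`,
#'   `protein` (`NA` when low-resolution), `legacy`, `raw`.
#' @examples
#' parse_allele("A*02: 01")
#' parse_allele("B*13")        # low resolution
#' parse_allele("A*203")       # legacy 3-digit name
#' @export
parse_allele <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    abort("allele name must be a non-empty string", "hla_parse_error")
  raw <- text
  s <- gsub("[[:space:]]+", "", text)
  if (!grepl("*", s, fixed = TRUE))
    abort(sprintf("allele name '%s' lacks the '*' locus separator", raw),
          "hla_parse_error")
  parts <- strsplit(s, "*", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    abort(sprintf("cannot parse allele name '%s'", raw), "hla_parse_error")
  locus <- parts[1]
  if (toupper(locus) %in% c("C", "CW")) locus <- "Cw"
  if (!locus %in% HLA_LOCI)
    abort(sprintf("unknown HLA locus '%s' in allele name '%s'", parts[1], raw),
          "hla_parse_error")
  fields <- strsplit(parts[2], ":", fixed = TRUE)[[1]]
  if (length(fields) == 0L || any(!nzchar(fields)) || any(!grepl("^[0-9]+$", fields)))
    abort(sprintf("non-numeric allele fields in '%s' (token '%s')", raw, parts[2]),
          "hla_parse_error")
  legacy <- FALSE
  if (length(fields) == 1L) {
    tok <- fields[1]
    if (nchar(tok) <= 2L) {           # low-resolution group, e.g. "02"
      group <- sprintf("%02d", as.integer(tok))
      protein <- NA_character_
    } else if (nchar(tok) == 3L) {    # legacy name, e.g. "203": opaque token
      group <- tok
      protein <- NA_character_
      legacy <- TRUE
    } else if (nchar(tok) %in% c(4L, 5L)) {  # concatenated, e.g. "0201"
      group <- substr(tok, 1L, 2L)
      protein <- substr(tok, 3L, nchar(tok))
    } else {
      abort(sprintf("cannot split allele fields in '%s'", raw), "hla_parse_error")
    }
  } else if (length(fields) >= 2L) {
    group <- if (nchar(fields[1]) <= 2L) sprintf("%02d", as.integer(fields[1])) else fields[1]
    protein <- if (nchar(fields[2]) == 1L) sprintf("%02d", as.integer(fields[2])) else fields[2]
    legacy <- nchar(fields[1]) > 2L
  }
  structure(
    list(locus = locus, group = group, protein = protein,
         legacy = legacy, raw = raw),
    class = "hla_allele"
  )
}

#' @export
format.hla_allele <- function(x, ...) {
  if (is.na(x$protein)) paste0(x$locus, "*", x$group)
  else paste0(x$locus, "*", x$group, ":", x$protein)
}

#' @export
print.hla_allele <- function(x, ...) {
  res <- if (is.na(x$protein)) {
    if (x$legacy) "legacy" else "low-resolution"
  } else "high-resolution"
  cat(sprintf("<HLA allele> %s  [class %s, %s]\n",
              format(x), hla_class(x$locus), res))
  invisible(x)
}

#' Canonical allele name
#' @param x an `hla_allele` or character name (parsed first).
#' @return canonical `"LOCUS*GG:PP"` string.
#' @export
allele_name <- function(x) {
  format(as_allele(x))
}

as_allele <- function(x) {
  if (inherits(x, "hla_allele")) x else parse_allele(x)
}

#' Test whether two alleles are the same
#'
#' Equality requires identical locus, group, and protein field; a
#' low-resolution allele (no protein field) never equals a
#' high-resolution one.
#' @param a,b `hla_allele` objects or character names.
#' @return logical.
#' @export
allele_equal <- function(a, b) {
  a <- as_allele(a); b <- as_allele(b)
  identical(a$locus, b$locus) && identical(a$group, b$group) &&
    ((is.na(a$protein) && is.na(b$protein)) ||
       (!is.na(a$protein) && !is.na(b$protein) && a$protein == b$protein))
}

is_high_resolution <- function(a) !is.na(as_allele(a)$protein)

#' Parse a subject genotype
#'
#' @param record named list mapping locus to a character vector of exactly
#'   two allele names (homozygous subjects repeat the allele).
#' @param subject_id subject identifier.
#' @return an object of class `hla_genotype`: `subject_id` plus a named
#'   list of two-allele lists per locus.
#' @examples
#' parse_genotype(list(A = c("A*11:01", "A*11:01"),
#'                     B = c("B*40:01", "B*46:01")), "D-UPN03")
#' @export
parse_genotype <- function(record, subject_id = "subject") {
  if (!is.list(record) || is.null(names(record)) || any(!nzchar(names(record))))
    abort("genotype record must be a named list of loci", "hla_parse_error")
  loci <- names(record)
  bad <- setdiff(loci, HLA_LOCI)
  if (length(bad))
    abort(sprintf("unknown loci in genotype: %s", paste(bad, collapse = ", ")),
          "hla_parse_error")
  alleles <- lapply(loci, function(loc) {
    v <- record[[loc]]
    if (length(v) != 2L)
      abort(sprintf("locus %s must carry exactly two alleles (got %d)",
                    loc, length(v)), "hla_parse_error")
    parsed <- lapply(v, as_allele)
    for (al in parsed) {
      if (al$locus != loc)
        abort(sprintf("allele '%s' parsed as locus %s but is placed in the %s slot",
                      al$raw, al$locus, loc), "hla_parse_error")
    }
    parsed
  })
  names(alleles) <- loci
  structure(list(subject_id = subject_id, alleles = alleles),
            class = "hla_genotype")
}

#' @export
print.hla_genotype <- function(x, ...) {
  cat(sprintf("<HLA genotype> %s\n", x$subject_id))
  for (loc in names(x$alleles)) {
    cat(sprintf("  %-5s %s / %s\n", loc,
                format(x$alleles[[loc]][[1]]), format(x$alleles[[loc]][[2]])))
  }
  invisible(x)
}

genotype_loci <- function(g) names(g$alleles)

genotype_allele_names <- function(g, locus) {
  vapply(g$alleles[[locus]], format, character(1))
}

#' Read genotypes from a TSV or JSON file
#'
#' TSV layout: column `subject_id` plus `<locus>_1`, `<locus>_2` pairs
#' (e.g. `A_1`, `A_2`, `B_1`, `B_2`, ...); Cw/DPB1 columns are optional,
#' empty cells drop the locus for that subject. JSON: an array of objects
#' with the same keys.
#'
#' @param path file path; format inferred from the extension
#'   (`.json` vs anything else = TSV).
#' @return list of `hla_genotype`, named by subject id.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path))
    abort(sprintf("genotype file not found: %s", path), "hla_io_error")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    df <- as.data.frame(rows, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE, colClasses = "character")
  }
  if (!"subject_id" %in% names(df))
    abort("genotype table lacks a subject_id column", "hla_io_error")
  out <- lapply(seq_len(nrow(df)), function(i) {
    rec <- list()
    for (loc in HLA_LOCI) {
      c1 <- paste0(loc, "_1"); c2 <- paste0(loc, "_2")
      if (all(c(c1, c2) %in% names(df))) {
        a1 <- df[[c1]][i]; a2 <- df[[c2]][i]
        if (!is.na(a1) && !is.na(a2) && nzchar(a1) && nzchar(a2))
          rec[[loc]] <- c(a1, a2)
      }
    }
    parse_genotype(rec, subject_id = df$subject_id[i])
  })
  names(out) <- df$subject_id
  out
}
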