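# Functional recognition regions of the HLA class I and II molecules.
#
# Allelic polymorphism relevant to peptide presentation and TCR contact is
# concentrated in the antigen-binding groove (alpha helices and beta sheet
# floor); residues in the random-coil stretches outside these intervals are
# excluded from the revised RMSD.

.default_regions <- list(
  I  = rbind(c(3, 13), c(20, 38), c(45, 85), c(92, 103), c(109, 127), c(132, 178)),
  II = rbind(c(9, 18), c(21, 30), c(33, 39), c(42, 47), c(50, 87))
)

#' Functional-region definition for revised RMSD
#'
#' Builds a set of inclusive residue-number intervals (mature-protein
#' 1-based numbering) delimiting the functional recognition region over
#' which the revised RMSD is computed. Defaults: class I
#' 3-13, 20-38, 45-85, 92-103, 109-127, 132-178 (149 residues); class II
#' 9-18, 21-30, 33-39, 42-47, 50-87 (71 residues).
#'
#' @param hla_class `"I"` or `"II"`.
#' @param ranges optional override: a two-column matrix or list of
#'   `c(start, end)` pairs, inclusive. Must be sorted, non-overlapping,
#'   with `start <= end`.
#' @return object of class `region_set`.
#' @examples
#' region_set("I")
#' region_set("II", ranges = list(c(9, 18), c(50, 87)))
#' @export
region_set <- function(hla_class = c("I", "II"), ranges = NULL) {
  hla_class <- match.arg(hla_class)
  if (is.null(ranges)) {
    m <- .default_regions[[hla_class]]
  } else {
    if (is.list(ranges)) m <- do.call(rbind, lapply(ranges, as.numeric))
    else m <- as.matrix(ranges)
    if (ncol(m) != 2L)
      abort("region ranges must be (start, end) pairs", "region_error")
  }
  storage.mode(m) <- "integer"
  if (any(m[, 1] > m[, 2]))
    abort("region interval with start > end", "region_error")
  o <- order(m[, 1])
  m <- m[o, , drop = FALSE]
  if (nrow(m) > 1L && any(m[-1L, 1] <= m[-nrow(m), 2]))
    abort("region intervals overlap", "region_error")
  dimnames(m) <- list(NULL, c("start", "end"))
  structure(list(hla_class = hla_class, ranges = m), class = "region_set")
}

#' Load region overrides from a YAML or JSON file
#'
#' Expected shape: a mapping from class (`I`, `II`) to a list of
#' `[start, end]` pairs. Classes absent from the file keep the defaults.
#'
#' @param path YAML or JSON file.
#' @return named list of `region_set` for classes `"I"` and `"II"`.
#' @export
read_region_sets <- function(path) {
  if (!file.exists(path))
    abort(sprintf("region file not found: %s", path), "hla_io_error")
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  out <- list(I = region_set("I"), II = region_set("II"))
  for (cl in intersect(names(spec), c("I", "II")))
    out[[cl]] <- region_set(cl, ranges = spec[[cl]])
  out
}

#' @export
print.region_set <- function(x, ...) {
  iv <- apply(x$ranges, 1L, function(r) sprintf("%d-%d", r[1], r[2]))
  cat(sprintf("<region set> HLA class %s: %s (%d residues)\n",
              x$hla_class, paste(iv, collapse = ", "),
              length(region_residues(x))))
  invisible(x)
}

#' Residue numbers covered by a region set
#' @param region a `region_set`.
#' @return sorted integer vector of residue numbers.
#' @export
region_residues <- function(region) {
  stopifnot(inherits(region, "region_set"))
  sort(unique(unlist(
    lapply(seq_len(nrow(region$ranges)),
           function(i) seq.int(region$ranges[i, 1], region$ranges[i, 2]))
  )))
}

#' @keywords internal
in_region <- function(resno, region) {
  if (is.null(region)) rep(TRUE, length(resno))
  else resno %in% region_residues(region)
}
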