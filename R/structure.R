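# Structure models: one modeled chain per allele, one coordinate per
# residue (Calpha by default), mature-protein 1-based residue numbering.

#' Construct a structure model
#'
#' @param allele `hla_allele` (or name) the chain models.
#' @param resno integer vector of residue numbers, strictly increasing;
#'   gaps allowed.
#' @param xyz numeric matrix `length(resno)` x 3, coordinates in Angstrom.
#' @param source optional provenance string (file path, chain id).
#' @return object of class `structure_model`.
#' @export
structure_model <- function(allele, resno, xyz, source = NA_character_) {
  allele <- as_allele(allele)
  resno <- as.integer(resno)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L || nrow(xyz) != length(resno))
    abort("xyz must be an n x 3 matrix matching resno", "structure_error")
  if (length(resno) < 3L)
    abort("a structure model needs at least 3 residues", "structure_error")
  if (any(diff(resno) <= 0L))
    abort("residue numbers must be strictly increasing", "structure_error")
  if (any(!is.finite(xyz)))
    abort("non-finite coordinates in structure model", "structure_error")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(allele = allele, resno = resno, xyz = xyz, source = source),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure model> %s: %d residues (%d-%d)%s\n",
              format(x$allele), length(x$resno), min(x$resno), max(x$resno),
              if (is.na(x$source)) "" else paste0("  [", x$source, "]")))
  invisible(x)
}

#' Read a structure model from a PDB file
#'
#' Parses standard ATOM records with [bio3d::read.pdb()], selects one
#' chain and one atom per residue (Calpha by default, full backbone
#' N/CA/C/O behind `atoms = "backbone"`), and applies an optional integer
#' offset so files numbered with the leader peptide can be shifted to
#' mature-protein numbering.
#'
#' @param path PDB file.
#' @param allele allele the model represents (`hla_allele` or name).
#' @param chain chain identifier; default the first chain in the file.
#' @param atoms `"calpha"` (one point per residue) or `"backbone"`
#'   (N, CA, C, O; residue number is repeated internally and pairing
#'   operates per atom).
#' @param offset integer added to the file's residue numbers (e.g. `-24`
#'   for a class I file numbered with its 24-residue leader).
#' @return `structure_model`.
#' @export
read_structure <- function(path, allele, chain = NULL,
                           atoms = c("calpha", "backbone"), offset = 0L) {
  atoms <- match.arg(atoms)
  if (!file.exists(path))
    abort(sprintf("PDB file not found: %s", path), "hla_io_error")
  pdb <- bio3d::read.pdb(path)
  atom <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atom) == 0L)
    abort(sprintf("no ATOM records in %s", path), "structure_error")
  if (is.null(chain)) chain <- atom$chain[1]
  atom <- atom[atom$chain %in% chain, , drop = FALSE]
  if (nrow(atom) == 0L)
    abort(sprintf("chain '%s' not found in %s", chain, path), "structure_error")
  keep <- if (atoms == "calpha") "CA" else c("N", "CA", "C", "O")
  atom <- atom[atom$elety %in% keep, , drop = FALSE]
  atom <- atom[!duplicated(atom[, c("resno", "elety")]), , drop = FALSE]
  atom <- atom[order(atom$resno, match(atom$elety, keep)), , drop = FALSE]
  resno <- atom$resno + as.integer(offset)
  xyz <- as.matrix(atom[, c("x", "y", "z")])
  if (atoms == "backbone") {
    # expand to a strictly increasing pseudo-numbering: resno*10 + atom rank,
    # so the residue-number pairing machinery still applies per atom while
    # region membership is judged on the residue number
    model <- structure_model(allele, resno * 10L + match(atom$elety, keep) - 1L,
                             xyz, source = sprintf("%s:%s", path, chain))
    attr(model, "atoms") <- "backbone"
    return(model)
  }
  structure_model(allele, resno, xyz, source = sprintf("%s:%s", path, chain))
}

#' Write a structure model to a minimal PDB file
#'
#' Emits one Calpha ATOM record per residue (alanine placeholder residue
#' type), chain A. Round-trips through [read_structure()].
#'
#' @param model `structure_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  lines <- vapply(seq_along(model$resno), function(i) {
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, model$resno[i], model$xyz[i, 1], model$xyz[i, 2], model$xyz[i, 3])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Pair residues of two models by residue number
#'
#' @param m1,m2 `structure_model`s.
#' @param region optional `region_set`; only residues inside the region
#'   are paired. `NULL` pairs all common residues.
#' @return list with `x` and `y` (n x 3 matrices of paired coordinates,
#'   rows aligned), `resno`, and `n`.
#' @export
pair_residues <- function(m1, m2, region = NULL) {
  stopifnot(inherits(m1, "structure_model"), inherits(m2, "structure_model"))
  common <- intersect(m1$resno, m2$resno)
  if (!is.null(region)) {
    if (identical(attr(m1, "atoms"), "backbone"))
      common <- common[in_region(common %/% 10L, region)]
    else
      common <- common[in_region(common, region)]
  }
  if (length(common) < 3L)
    abort(sprintf("models share only %d residue(s)%s; need at least 3",
                  length(common),
                  if (is.null(region)) "" else " within the region"),
          "pairing_error")
  i1 <- match(common, m1$resno)
  i2 <- match(common, m2$resno)
  list(x = m1$xyz[i1, , drop = FALSE], y = m2$xyz[i2, , drop = FALSE],
       resno = common, n = length(common))
}
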