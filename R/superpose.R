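# Weighted rigid-body superposition (Kabsch) and the RMSD scores.
#
# The discrepancy between two modeled HLA chains is the weighted RMSD
#   sqrt( sum_i w_i |x_i - y_i|^2 / sum_i w_i )
# after the weighted least-squares optimal rigid superposition of the
# scored residue set. The coordinate RMSD scores all common residues;
# the revised RMSD restricts both fitting and scoring to the functional
# recognition region (fit set = scoring set by default; `fit = "all"`
# superposes on all common residues but scores the region only).

#' Weighted optimal rigid superposition
#'
#' Finds the proper rotation `R` (det = +1) and translation `t`
#' minimizing `sum_i w_i |x_i - (R y_i + t)|^2` via the Kabsch/SVD
#' construction on weighted-centered coordinates.
#'
#' @param x,y n x 3 coordinate matrices (paired rows), n >= 3.
#' @param weights nonnegative per-pair weights; default all 1. Their sum
#'   must be positive.
#' @return list with `R` (3 x 3 rotation applied to `y`), `t`
#'   (translation), and `yfit` (`y` after superposition onto `x`).
#' @export
superpose <- function(x, y, weights = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (n < 3L || nrow(y) != n || ncol(x) != 3L || ncol(y) != 3L)
    abort("superpose needs two aligned n x 3 matrices with n >= 3",
          "superpose_error")
  w <- check_weights(weights, n)
  wn <- w / sum(w)
  cx <- colSums(x * wn)
  cy <- colSums(y * wn)
  xc <- sweep(x, 2L, cx)
  yc <- sweep(y, 2L, cy)
  # weighted covariance; svd gives the optimal rotation with a sign
  # correction enforcing a proper rotation (no reflection)
  H <- t(yc * wn) %*% xc
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    abort("degenerate configuration: paired coordinates are (near-)collinear, rotation is not unique",
          "superpose_error")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cx - as.vector(R %*% cy)
  yfit <- t(R %*% t(y)) + matrix(t_vec, n, 3L, byrow = TRUE)
  list(R = R, t = t_vec, yfit = yfit)
}

check_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1, n))
  w <- as.numeric(weights)
  if (length(w) == 1L) w <- rep(w, n)
  if (length(w) != n)
    abort(sprintf("weight vector length %d does not match %d pairs",
                  length(w), n), "weight_error")
  if (any(!is.finite(w)) || any(w < 0))
    abort("weights must be finite and nonnegative", "weight_error")
  if (sum(w) <= 0)
    abort("weights sum to zero", "weight_error")
  w
}

#' Weighted RMSD of paired coordinates (no superposition)
#'
#' `sqrt(sum w_i |x_i - y_i|^2 / sum w_i)`; with unit weights this is the
#' standard RMSD over n pairs. Doubling all weights leaves the value
#' unchanged.
#'
#' @param x,y n x 3 coordinate matrices, rows paired.
#' @param weights nonnegative per-pair weights (default unit).
#' @return RMSD in the coordinate units (Angstrom).
#' @export
weighted_rmsd <- function(x, y, weights = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (n < 1L || nrow(y) != n)
    abort("weighted_rmsd needs at least one coordinate pair", "rmsd_error")
  w <- check_weights(weights, n)
  sqrt(sum(w * rowSums((x - y)^2)) / sum(w))
}

#' Superposed weighted RMSD of a residue pairing
#' @keywords internal
superposed_rmsd <- function(pairs, weights = NULL, fit_pairs = NULL) {
  if (is.null(fit_pairs)) {
    fit <- superpose(pairs$x, pairs$y, weights)
    weighted_rmsd(pairs$x, fit$yfit, weights)
  } else {
    fit <- superpose(fit_pairs$x, fit_pairs$y)
    yfit <- t(fit$R %*% t(pairs$y)) +
      matrix(fit$t, nrow(pairs$y), 3L, byrow = TRUE)
    weighted_rmsd(pairs$x, yfit, weights)
  }
}

#' Both RMSD scores for a model pair
#'
#' Convenience wrapper returning the coordinate RMSD and the revised
#' RMSD together. Weights may be supplied per residue as a named numeric
#' vector (names = residue numbers; unlisted residues get weight 1),
#' which is how a weight file is applied.
#'
#' @param m1,m2 `structure_model`s.
#' @param region `region_set`; default from `m1`'s locus class.
#' @param weights `NULL`, a per-pair numeric vector, or a named numeric
#'   vector keyed by residue number.
#' @param fit see [revised_rmsd()].
#' @return list with `coordinate_rmsd`, `revised_rmsd`, `n_all`,
#'   `n_region`.
#' @export
structure_discrepancy <- function(m1, m2, region = NULL, weights = NULL,
                                  fit = c("region", "all")) {
  fit <- match.arg(fit)
  if (is.null(region)) {
    cl <- hla_class(m1$allele$locus)
    if (is.na(cl))
      abort("cannot infer HLA class for the region; pass `region`", "region_error")
    region <- region_set(cl)
  }
  w_for <- function(pairs) {
    if (is.null(weights)) return(NULL)
    if (!is.null(names(weights))) {
      w <- rep(1, pairs$n)
      hit <- match(as.character(pairs$resno), names(weights))
      w[!is.na(hit)] <- as.numeric(weights[hit[!is.na(hit)]])
      w
    } else weights
  }
  all_pairs <- pair_residues(m1, m2, region = NULL)
  reg_pairs <- pair_residues(m1, m2, region = region)
  list(
    coordinate_rmsd = superposed_rmsd(all_pairs, w_for(all_pairs)),
    revised_rmsd = if (fit == "region")
      superposed_rmsd(reg_pairs, w_for(reg_pairs))
    else superposed_rmsd(reg_pairs, w_for(reg_pairs), fit_pairs = all_pairs),
    n_all = all_pairs$n, n_region = reg_pairs$n
  )
}

#' Coordinate RMSD between two structure models
#'
#' Pairs all common residues, superposes on that full set, and returns
#' the weighted RMSD. Zero for identical or rigidly moved copies.
#'
#' @param m1,m2 `structure_model`s.
#' @param weights per-pair weights (default unit).
#' @return RMSD in Angstrom.
#' @export
coordinate_rmsd <- function(m1, m2, weights = NULL) {
  pairs <- pair_residues(m1, m2, region = NULL)
  superposed_rmsd(pairs, weights)
}

#' Revised RMSD between two structure models
#'
#' RMSD restricted to the functional recognition region: residues outside
#' the region are excluded from scoring, and (by default) from the
#' superposition fit as well.
#'
#' @param m1,m2 `structure_model`s.
#' @param region `region_set` defining the functional region; defaults to
#'   the class taken from `m1`'s allele locus.
#' @param weights per-pair weights over the region residues (default unit).
#' @param fit `"region"` (default) superposes on the region residues
#'   themselves; `"all"` superposes on all common residues, then scores
#'   the region.
#' @return RMSD in Angstrom.
#' @export
revised_rmsd <- function(m1, m2, region = NULL, weights = NULL,
                         fit = c("region", "all")) {
  fit <- match.arg(fit)
  if (is.null(region)) {
    cl <- hla_class(m1$allele$locus)
    if (is.na(cl))
      abort("cannot infer HLA class for the region; pass `region`", "region_error")
    region <- region_set(cl)
  }
  pairs <- pair_residues(m1, m2, region = region)
  if (fit == "region") superposed_rmsd(pairs, weights)
  else superposed_rmsd(pairs, weights,
                       fit_pairs = pair_residues(m1, m2, region = NULL))
}
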