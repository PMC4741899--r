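# shared builders for the structural tests

# small deterministic point cloud as a structure model
toy_model <- function(allele = "A*01:01", n = 12, seed = 42, resno = seq_len(n)) {
  set.seed(seed)
  structure_model(allele, resno, matrix(rnorm(3 * length(resno), sd = 4),
                                        ncol = 3))
}

# apply a random rigid transform (proper rotation + translation)
random_rigid <- function(xyz, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  t(q %*% t(xyz)) + matrix(rnorm(3, sd = 10), nrow(xyz), 3, byrow = TRUE)
}

# independent direct-summation RMSD oracle (no linear algebra shortcuts)
rmsd_oracle <- function(x, y, w = rep(1, nrow(x))) {
  num <- 0
  for (i in seq_len(nrow(x))) {
    d <- x[i, ] - y[i, ]
    num <- num + w[i] * (d[1]^2 + d[2]^2 + d[3]^2)
  }
  sqrt(num / sum(w))
}

# location of one packaged fixture file (for tamper tests on copies)
fixture_path_for_tests <- function() {
  system.file("extdata", "clinical_pairs.tsv", package = "hlarmsd")
}

# tiny synthetic same-locus matrix for matching tests
toy_matrix <- function() {
  rmsd_matrix(list(
    rmsd_record("A*01:01", "A*02:01", 0.30, 0.25),
    rmsd_record("A*01:01", "A*03:01", 0.10, 0.05),
    rmsd_record("A*02:01", "A*03:01", 0.40, 0.35),
    rmsd_record("A*01:01", "A*11:01", 0.20, 0.15),
    rmsd_record("A*02:01", "A*11:01", 0.28, 0.22),
    rmsd_record("A*03:01", "A*11:01", 0.55, 0.45),
    rmsd_record("DRB1*01:01", "DRB1*04:01", 0.20, 0.08),
    rmsd_record("DRB1*01:01", "DRB1*07:01", 0.30, 0.26),
    rmsd_record("DRB1*04:01", "DRB1*07:01", 0.15, 0.12)
  ))
}

toy_genotype <- function(id, a, drb1 = NULL) {
  rec <- list(A = a)
  if (!is.null(drb1)) rec$DRB1 <- drb1
  parse_genotype(rec, id)
}
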