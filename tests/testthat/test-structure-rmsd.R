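test_that("default regions pair the expected residue counts", {
  m180a <- toy_model("A*01:01", n = 180, seed = 1)
  m180b <- toy_model("A*01:02", n = 180, seed = 2)
  expect_identical(pair_residues(m180a, m180b, region_set("I"))$n, 149L)
  m90a <- toy_model("DRB1*01:01", n = 90, seed = 3)
  m90b <- toy_model("DRB1*01:02", n = 90, seed = 4)
  expect_identical(pair_residues(m90a, m90b, region_set("II"))$n, 71L)
})

test_that("residue pairing matches by number, drops absentees, needs 3 in common", {
  m1 <- toy_model(resno = c(1:5, 8:12), n = 10)
  m2 <- toy_model(resno = c(3:9, 20:22), n = 10, seed = 7)
  p <- pair_residues(m1, m2)
  expect_identical(p$resno, c(3:5, 8:9))
  expect_identical(nrow(p$x), 5L)
  m3 <- toy_model(resno = 100:110, n = 11, seed = 9)
  expect_error(pair_residues(m1, m3), "at least 3")
})

test_that("region sets validate their intervals", {
  expect_error(region_set("I", ranges = list(c(10, 5))), "start > end")
  expect_error(region_set("I", ranges = list(c(1, 10), c(5, 20))), "overlap")
  rs <- region_set("II", ranges = list(c(50, 87), c(9, 18)))
  expect_identical(unname(rs$ranges[1, "start"]), 9L)  # sorted on construction
})

test_that("superposition recovers rigid transforms and flags degeneracy", {
  m <- toy_model(n = 10)
  x <- m$xyz
  # pure translation
  f <- superpose(x, x + matrix(c(5, 0, 0), 10, 3, byrow = TRUE))
  expect_equal(weighted_rmsd(x, f$yfit), 0, tolerance = 1e-10)
  expect_equal(det(f$R), 1, tolerance = 1e-10)
  # 90 degree rotation about z
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  f2 <- superpose(x, t(Rz %*% t(x)))
  expect_equal(weighted_rmsd(x, f2$yfit), 0, tolerance = 1e-10)
  # collinear points: rotation about the line is undetermined
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(superpose(line, line), "collinear")
})

test_that("weighted RMSD matches closed forms and the brute-force oracle", {
  x <- rbind(c(0, 0, 0), c(0, 0, 0))
  y <- rbind(c(1, 0, 0), c(0, 0, 0))
  expect_equal(weighted_rmsd(x, y), sqrt(0.5), tolerance = 1e-12)
  expect_equal(weighted_rmsd(x, x), 0)
  set.seed(5)
  for (i in 1:20) {
    n <- sample(4:40, 1)
    a <- matrix(rnorm(3 * n), ncol = 3)
    b <- matrix(rnorm(3 * n), ncol = 3)
    w <- runif(n, 0.1, 3)
    expect_equal(weighted_rmsd(a, b, w), rmsd_oracle(a, b, w),
                 tolerance = 1e-9)
    # weight rescaling leaves the value unchanged
    expect_equal(weighted_rmsd(a, b, 2 * w), weighted_rmsd(a, b, w),
                 tolerance = 1e-12)
  }
  expect_error(weighted_rmsd(x, y, c(0, 0)), "sum to zero")
  expect_error(weighted_rmsd(x, y, c(-1, 2)), "nonnegative")
})

test_that("RMSD is zero on self, symmetric, and rigid-motion invariant", {
  g <- generate_structure_pair(60, "I", 0.4, "all", seed = 21)
  m1 <- g$model1; m2 <- g$model2
  expect_equal(coordinate_rmsd(m1, m1), 0, tolerance = 1e-12)
  expect_equal(coordinate_rmsd(m1, m2), coordinate_rmsd(m2, m1),
               tolerance = 1e-9)
  for (s in 1:5) {
    moved <- structure_model(m2$allele, m2$resno, random_rigid(m2$xyz, seed = s))
    expect_equal(coordinate_rmsd(m1, moved), coordinate_rmsd(m1, m2),
                 tolerance = 1e-9)
    expect_equal(revised_rmsd(m1, moved), revised_rmsd(m1, m2),
                 tolerance = 1e-9)
  }
  # a rigidly moved copy scores zero
  moved1 <- structure_model(m1$allele, m1$resno, random_rigid(m1$xyz, seed = 99))
  expect_equal(coordinate_rmsd(m1, moved1), 0, tolerance = 1e-9)
})

test_that("optimal superposition beats sampled rigid transforms", {
  set.seed(31)
  n <- 10
  x <- matrix(rnorm(3 * n, sd = 4), ncol = 3)
  y <- x + matrix(rnorm(3 * n, sd = 0.4), ncol = 3)
  best <- weighted_rmsd(x, superpose(x, y)$yfit)
  worst_beaten <- TRUE
  for (s in 1:200) {
    cand <- weighted_rmsd(x, random_rigid(y))
    if (cand < best - 1e-9) worst_beaten <- FALSE
  }
  expect_true(worst_beaten)
})

test_that("revised RMSD equals coordinate RMSD when the region covers everything", {
  g <- generate_structure_pair(50, "I", 0.3, "all", seed = 12)
  full <- region_set("I", ranges = list(c(1, 50)))
  expect_equal(revised_rmsd(g$model1, g$model2, region = full),
               coordinate_rmsd(g$model1, g$model2), tolerance = 1e-12)
})

test_that("perturbations outside the region leave the revised RMSD at zero", {
  g <- generate_structure_pair(180, "I", 0.5, "outside-region", seed = 8)
  expect_equal(revised_rmsd(g$model1, g$model2), 0, tolerance = 1e-9)
  expect_gt(coordinate_rmsd(g$model1, g$model2), 0.4)
})

test_that("fit=all scores the region after a whole-chain superposition", {
  g <- generate_structure_pair(180, "I", 0.5, "region-only", seed = 13)
  r_region <- revised_rmsd(g$model1, g$model2, fit = "region")
  r_all <- revised_rmsd(g$model1, g$model2, fit = "all")
  # fitting on the region itself minimizes the region residual
  expect_lte(r_region, r_all + 1e-9)
})

test_that("PDB files round-trip and agree with an independent superposition", {
  g <- generate_structure_pair(80, "I", 0.35, "all", seed = 17)
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_structure(g$model1, f1)
  write_structure(g$model2, f2)
  m1 <- read_structure(f1, "A*99:01")
  m2 <- read_structure(f2, "A*99:02")
  # PDB format carries 3 decimals; tolerance accordingly
  expect_equal(coordinate_rmsd(m1, m2), 0.35, tolerance = 2e-3)
  # cross-check against bio3d's unweighted superposition fit
  xyz1 <- as.vector(t(g$model1$xyz))
  xyz2 <- as.vector(t(g$model2$xyz))
  fitted <- suppressWarnings(bio3d::fit.xyz(xyz1, xyz2))
  expect_equal(coordinate_rmsd(g$model1, g$model2),
               sqrt(mean((xyz1 - fitted)^2) * 3), tolerance = 1e-6)
})

test_that("residue-number offset shifts a leader-peptide-numbered file", {
  g <- generate_structure_pair(40, "I", 0, "all", seed = 2)
  f <- tempfile(fileext = ".pdb")
  shifted <- structure_model(g$model1$allele, g$model1$resno + 24L, g$model1$xyz)
  write_structure(shifted, f)
  m <- read_structure(f, "A*99:01", offset = -24L)
  expect_identical(m$resno, g$model1$resno)
})
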