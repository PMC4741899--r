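test_that("GVH direction follows recipient-has / donor-lacks", {
  mat <- toy_matrix()
  # heterozygous recipient vs homozygous donor: single pair
  r <- toy_genotype("R", c("A*02:01", "A*11:01"))
  d <- toy_genotype("D", c("A*11:01", "A*11:01"))
  mm <- gvh_mismatches(r, d, mat)
  expect_identical(nrow(mm), 1L)
  expect_identical(mm$recipient_allele, "A*02:01")
  expect_identical(mm$donor_allele, "A*11:01")
  # homozygous recipient allele carried by donor: no mismatch even though
  # the donor brings an extra allele (host-versus-graft only)
  r2 <- toy_genotype("R2", c("A*11:01", "A*11:01"))
  d2 <- toy_genotype("D2", c("A*11:01", "A*02:01"))
  expect_identical(nrow(gvh_mismatches(r2, d2, mat)), 0L)
  # identical genotypes never mismatch
  expect_identical(nrow(gvh_mismatches(r, r, mat)), 0L)
})

test_that("homozygous donors expose their duplicated allele as partner", {
  mat <- toy_matrix()
  # both recipient alleles unshared, donor homozygous: two pairs against it
  r <- toy_genotype("R", c("A*01:01", "A*02:01"))
  d <- toy_genotype("D", c("A*03:01", "A*03:01"))
  mm <- gvh_mismatches(r, d, mat)
  expect_identical(nrow(mm), 2L)
  expect_identical(unique(mm$donor_allele), "A*03:01")
  # donor homozygous for an allele the recipient shares: the duplicate
  # copy is still the partner for the unshared recipient allele
  r2 <- toy_genotype("R2", c("A*01:01", "A*03:01"))
  d2 <- toy_genotype("D2", c("A*03:01", "A*03:01"))
  mm2 <- gvh_mismatches(r2, d2, mat)
  expect_identical(nrow(mm2), 1L)
  expect_identical(mm2$recipient_allele, "A*01:01")
  expect_identical(mm2$donor_allele, "A*03:01")
})

test_that("2x2 assignment picks the minimum-total pairing (exhaustive)", {
  # full 2x2: pairings (01-02, 03-11) = 0.25 + 0.45 vs (01-11, 03-02) =
  # 0.15 + 0.35; engine must pick the smaller sum
  mat <- toy_matrix()
  r <- toy_genotype("R", c("A*01:01", "A*03:01"))
  d <- toy_genotype("D", c("A*02:01", "A*11:01"))
  mm <- gvh_mismatches(r, d, mat)
  expect_identical(nrow(mm), 2L)
  chosen <- total_revised_rmsd(mm)
  alts <- c(0.25 + 0.45, 0.15 + 0.35)
  expect_equal(chosen, min(alts))
  pairing <- paste(mm$recipient_allele, mm$donor_allele, sep = "/")
  expect_setequal(pairing, c("A*01:01/A*11:01", "A*03:01/A*02:01"))
})

test_that("pairings with missing records are skipped; all-missing errors", {
  # only one complete pairing exists in the matrix
  mat <- rmsd_matrix(list(
    rmsd_record("A*01:01", "A*02:01", 0.4, 0.30),
    rmsd_record("A*03:01", "A*11:01", 0.5, 0.40)
  ))
  r <- toy_genotype("R", c("A*01:01", "A*03:01"))
  d <- toy_genotype("D", c("A*02:01", "A*11:01"))
  mm <- gvh_mismatches(r, d, mat)
  expect_equal(total_revised_rmsd(mm), 0.70)
  mat2 <- rmsd_matrix(list(rmsd_record("A*05:01", "A*06:01", 0.1, 0.1)))
  expect_error(gvh_mismatches(r, d, mat2), "no RMSD record")
})

test_that("mismatch resolution ignores allele order within a slot", {
  mat <- toy_matrix()
  r1 <- toy_genotype("R", c("A*01:01", "A*03:01"))
  r2 <- toy_genotype("R", c("A*03:01", "A*01:01"))
  d1 <- toy_genotype("D", c("A*02:01", "A*11:01"))
  d2 <- toy_genotype("D", c("A*11:01", "A*02:01"))
  base <- gvh_mismatches(r1, d1, mat)
  for (combo in list(list(r2, d1), list(r1, d2), list(r2, d2))) {
    mm <- gvh_mismatches(combo[[1]], combo[[2]], mat)
    expect_equal(total_revised_rmsd(mm), total_revised_rmsd(base))
  }
})

test_that("totals are exact fixed-point sums of their components", {
  expect_identical(total_revised_rmsd(numeric(0)), 0)
  expect_identical(total_revised_rmsd(0.3755), 0.3755)
  # values that would drift under naive floating addition
  v <- c(0.3625, 0.3657, 0.1508, 0.5304)
  expect_identical(total_revised_rmsd(v), 1.4094)
  expect_identical(total_revised_rmsd(rep(0.1, 3)), 0.3)
})

test_that("severity prediction applies the 0.50 cutoff to total and max single", {
  expect_identical(predict_severity(0.9975), "severe")
  expect_identical(predict_severity(0.2958), "mild")
  expect_identical(predict_severity(0.6474, 0.3517), "severe") # total rule alone
  expect_identical(predict_severity(0), "mild")
  # boundary: exactly 0.50 is severe under the conservative default...
  expect_identical(predict_severity(0.50), "severe")
  # ...and mild under the permissive boundary option
  expect_identical(predict_severity(0.50, config = matching_config(boundary = "mild")),
                   "mild")
  # monotone: raising total or max single never moves severe -> mild
  set.seed(3)
  for (i in 1:50) {
    tot <- runif(1, 0, 1.2); ms <- runif(1, 0, tot)
    a <- predict_severity(tot, ms)
    b <- predict_severity(tot + runif(1, 0, 0.5), ms)
    if (a == "severe") expect_identical(b, "severe")
  }
})

test_that("donor ranking sorts ascending with stable ties", {
  mat <- toy_matrix()
  r <- toy_genotype("R", c("A*01:01", "A*01:01"))
  donors <- list(
    toy_genotype("D-big", c("A*03:01", "A*03:01")),   # 0.05 -> wait: pair (01:01,03:01) 0.05
    toy_genotype("D-tie1", c("A*11:01", "A*11:01")),  # 0.15
    toy_genotype("D-tie2", c("A*11:01", "A*11:01")),  # 0.15 tie
    toy_genotype("D-self", c("A*01:01", "A*01:01"))   # 0
  )
  tab <- rank_donors(r, donors, mat)
  expect_identical(tab$donor_id, c("D-self", "D-big", "D-tie1", "D-tie2"))
  expect_identical(tab$rank, 1:4)
  expect_true(all(tab$acceptable_choice))
  single <- rank_donors(r, donors[2], mat)
  expect_identical(single$donor_id, "D-tie1")
  expect_error(rank_donors(r, list(), mat), "at least one")
})

test_that("ranking errors name the failing donor", {
  mat <- rmsd_matrix(list(rmsd_record("A*01:01", "A*03:01", 0.1, 0.05)))
  r <- toy_genotype("R", c("A*01:01", "A*02:01"))
  d <- toy_genotype("D-miss", c("A*03:01", "A*03:01"))
  expect_error(rank_donors(r, list(d), mat), "D-miss")
})

test_that("concordance dichotomizes grades and reports discordant ids", {
  mk <- function(id, pred, grade) {
    structure(list(recipient_id = id, donor_id = "d", pairs = NULL,
                   total_revised_rmsd = 0, max_single_revised = 0,
                   predicted_class = pred, observed_grade = grade),
              class = "match_report")
  }
  all_good <- list(mk("a", "mild", "I"), mk("b", "severe", "IV"),
                   mk("c", "mild", "II"), mk("d", "severe", "III"))
  expect_identical(concordance(all_good)$percent, 100)
  half <- list(mk("a", "mild", "I"), mk("b", "mild", "III"),
               mk("c", "severe", "IV"), mk("d", "severe", "II"))
  cc <- concordance(half)
  expect_identical(cc$percent, 50)
  expect_setequal(cc$discordant, c("b", "d"))
  # 11/12 rounds half-up to 92
  eleven <- c(all_good, all_good, all_good[1:3], list(mk("x", "mild", "IV")))
  expect_identical(concordance(eleven)$percent, 92)
  expect_error(concordance(list()), "at least one")
  expect_error(concordance(list(mk("a", "mild", NA_character_))), "observed grade")
})

test_that("report files carry the same fields in TSV and JSON", {
  mat <- toy_matrix()
  r <- toy_genotype("R", c("A*02:01", "A*11:01"), drb1 = c("DRB1*01:01", "DRB1*01:01"))
  d <- toy_genotype("D", c("A*11:01", "A*11:01"), drb1 = c("DRB1*04:01", "DRB1*04:01"))
  rep <- match_report(r, d, mat)
  ft <- tempfile(fileext = ".tsv"); fj <- tempfile(fileext = ".json")
  write_report(rep, ft); write_report(rep, fj)
  tsv <- utils::read.delim(ft, stringsAsFactors = FALSE)
  js <- jsonlite::fromJSON(fj)
  expect_identical(js$total_revised_rmsd,
                   as.numeric(tsv$revised_rmsd[tsv$row_type == "summary"]))
  expect_setequal(js$pairs$locus, tsv$locus[tsv$row_type == "pair"])
  expect_identical(js$predicted_class,
                   tsv$acceptable[tsv$row_type == "summary"])
})
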