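test_that("pi, theta_w and Tajima's D match brute-force oracles on random alignments", {
  set.seed(101)
  for (rep in 1:12) {
    n <- sample(4:10, 1)
    L <- sample(10:50, 1)
    aln <- random_alignment(n, L, p_var = 0.3, p_n = if (rep %% 3 == 0) 0.05 else 0)
    expect_equal(nucleotide_diversity(aln), oracle_pi(aln), tolerance = 1e-10)
    expect_equal(watterson_theta(aln), oracle_theta_w(aln), tolerance = 1e-10)
    d <- tajimas_d(aln)
    d0 <- oracle_tajima_d(aln)
    if (is.na(d0)) expect_true(is.na(d)) else expect_equal(d, d0, tolerance = 1e-10)
  }
})

test_that("pi handles the textbook cases", {
  same <- cpr_alignment(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(nucleotide_diversity(same), 0)
  two <- cpr_alignment(c(a = paste(rep("A", 100), collapse = ""),
                         b = paste(c(rep("A", 99), "T"), collapse = "")))
  expect_equal(nucleotide_diversity(two), 0.01)
  expect_true(is.na(nucleotide_diversity(cpr_alignment(c(a = "ACGT")))))
})

test_that("watterson_theta follows S / (a1 L)", {
  mono <- cpr_alignment(c(a = "AAAA", b = "AAAA"))
  expect_equal(watterson_theta(mono), 0)
  pair <- cpr_alignment(c(a = "AAAAAAAAAA", b = "AAAAAAAAAT"))
  expect_equal(watterson_theta(pair), 0.1)  # a1 = 1 at n = 2
  set.seed(7)
  mat <- matrix("A", nrow = 29, ncol = 160)
  mat[1:10, 5] <- "G"; mat[1:3, 80] <- "C"
  aln <- cpr_alignment(mat)
  expect_equal(watterson_theta(aln), 2 / (sum(1 / (1:28)) * 160), tolerance = 1e-12)
})

test_that("Tajima's D sign reflects the site-frequency shape and is NA when undefined", {
  mono <- cpr_alignment(matrix("C", 5, 30))
  expect_true(is.na(tajimas_d(mono)))
  # singletons on distinct lines: rare-variant excess, D < 0
  mat <- matrix("A", 4, 50)
  mat[1, 3] <- "G"; mat[2, 20] <- "T"; mat[3, 40] <- "C"
  sweepish <- cpr_alignment(mat)
  expect_lt(tajimas_d(sweepish), 0)
  expect_equal(tajimas_d(sweepish), oracle_tajima_d(sweepish), tolerance = 1e-10)
  # two balanced haplogroups: intermediate-frequency excess, D > 0
  mat2 <- matrix("A", 4, 50)
  mat2[1:2, c(5, 25, 45)] <- "G"
  balanced <- cpr_alignment(mat2)
  expect_gt(tajimas_d(balanced), 0)
  expect_equal(tajimas_d(balanced), oracle_tajima_d(balanced), tolerance = 1e-10)
})

test_that("diversity statistics are invariant to sequence order", {
  set.seed(11)
  aln <- random_alignment(8, 40, p_var = 0.3)
  perm <- aln
  o <- sample(nrow(aln$seq))
  perm$seq <- perm$seq[o, , drop = FALSE]
  perm$lines <- perm$lines[o]
  expect_equal(nucleotide_diversity(aln), nucleotide_diversity(perm))
  expect_equal(watterson_theta(aln), watterson_theta(perm))
  expect_equal(tajimas_d(aln), tajimas_d(perm))
})

test_that("sign(D) equals sign(pi*L - S/a1) whenever D is defined", {
  set.seed(21)
  for (r in 1:20) {
    aln <- random_alignment(sample(4:12, 1), 40, p_var = 0.25)
    d <- tajimas_d(aln)
    if (is.na(d) || d == 0) next
    n <- nrow(aln$seq)
    a1 <- sum(1 / seq_len(n - 1))
    num <- nucleotide_diversity(aln) * 40 - oracle_S(aln) / a1
    expect_equal(sign(d), sign(num))
  }
})

test_that("preprocessing implements the panel's cleaning rules", {
  # identity: clean alignment passes through unchanged
  clean <- random_alignment(25, 30, p_var = 0.2)
  out <- preprocess_alignment(clean, min_lines = 20)
  expect_s3_class(out, "cpr_alignment")
  expect_identical(out$seq, clean$seq)

  # N at a site where the rest share one base: fixed, lines retained
  mat <- matrix("A", 25, 10, dimnames = list(sprintf("l%02d", 1:25), NULL))
  mat[1:3, 4] <- "N"
  fixed <- preprocess_alignment(cpr_alignment(mat), min_lines = 20)
  expect_s3_class(fixed, "cpr_alignment")
  expect_equal(nrow(fixed$seq), 25)
  expect_true(all(fixed$seq[, 4] == "A"))

  # N at a polymorphic site: those lines drop from the CPR
  mat2 <- matrix("A", 25, 10, dimnames = list(sprintf("l%02d", 1:25), NULL))
  mat2[1:12, 6] <- "G"
  mat2[24:25, 6] <- "N"
  poly <- preprocess_alignment(cpr_alignment(mat2), min_lines = 20)
  expect_equal(nrow(poly$seq), 23)
  expect_false(any(c("l24", "l25") %in% poly$lines))

  # heterozygous lines removed
  het <- preprocess_alignment(cpr_alignment(mat), min_lines = 20,
                              het_sites = list(l01 = 3L))
  expect_false("l01" %in% het$lines)

  # fewer than min_lines usable -> exclusion verdict
  mat3 <- matrix("A", 19, 10)
  excl <- preprocess_alignment(cpr_alignment(mat3), min_lines = 20)
  expect_s3_class(excl, "cpr_exclusion")
  expect_equal(excl$n_usable, 19)

  empty <- preprocess_alignment(cpr_alignment(character(0)), min_lines = 20)
  expect_s3_class(empty, "cpr_exclusion")
  expect_match(empty$reason, "no data")
})

test_that("rare alleles are masked rather than their sites deleted", {
  # 1 carrier among 150 lines is < 1% and gets masked; since the rest share
  # one base the site ends up fixed and every line is kept
  mat <- matrix("C", 150, 8, dimnames = list(sprintf("l%03d", 1:150), NULL))
  mat[1, 2] <- "T"
  out <- preprocess_alignment(cpr_alignment(mat), maf_threshold = 0.01,
                              min_lines = 20)
  expect_equal(nrow(out$seq), 150)
  expect_true(all(out$seq[, 2] == "C"))
})

test_that("preprocessing is idempotent", {
  set.seed(31)
  aln <- random_alignment(26, 40, p_var = 0.3, p_n = 0.03)
  once <- preprocess_alignment(aln, min_lines = 10)
  if (inherits(once, "cpr_alignment")) {
    twice <- preprocess_alignment(once, min_lines = 10)
    expect_identical(once$seq, twice$seq)
  } else {
    succeed()
  }
})
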