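test_that("cohort configuration rejects invalid settings", {
  expect_error(cohort_config(n_lines = 1), "n_lines")
  expect_error(cohort_config(heritability = 1.2), "heritability")
  expect_error(cohort_config(cpr_length = 0), "cpr_length")
  expect_error(cohort_config(ld_decay = 2), "ld_decay")
})

test_that("zero mutation rate and zero effects give monomorphic CPRs and pure sex structure", {
  cfg <- cohort_config(n_cprs = 3, theta_per_site = 0, sex_effect = 2,
                       expression_effect = 0, heritability = 0, seed = 4)
  co <- generate_cohort(cfg)
  for (aln in co$alignments) expect_equal(n_segregating_sites(aln), 0L)
  ex <- co$expression[co$expression$transcript == co$pairs$transcript[1], ]
  mF <- mean(ex$value[ex$sex == "F"]); mM <- mean(ex$value[ex$sex == "M"])
  expect_equal(mM - mF, 2, tolerance = 0.25)
})

test_that("cohorts are bit-identical under one seed and differ across seeds", {
  cfg <- cohort_config(n_cprs = 3, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$alignments, b$alignments)
  expect_identical(a$expression, b$expression)
  expect_identical(lapply(a$flanks, `[[`, "geno"), lapply(b$flanks, `[[`, "geno"))
  c <- generate_cohort(cohort_config(n_cprs = 3, seed = 100))
  expect_false(identical(a$alignments, c$alignments))
})

test_that("written cohorts are byte-identical under one seed", {
  cfg <- cohort_config(n_cprs = 2, seed = 12)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("planted heritability is recovered by a variance-components oracle", {
  cfg <- cohort_config(n_cprs = 100, heritability = 0.6, n_replicates = 4,
                       theta_per_site = 0, seed = 13)
  co <- generate_cohort(cfg)
  est <- vapply(split(co$expression, co$expression$transcript), function(ex) {
    an <- summary(stats::aov(value ~ sex + line, data = ex))[[1]]
    rn <- trimws(rownames(an))
    msl <- an[rn == "line", "Mean Sq"]
    mse <- an[rn == "Residuals", "Mean Sq"]
    r <- nrow(ex) / length(unique(ex$line))
    vg <- (msl - mse) / r
    vg / (vg + mse)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.6), 0.05)
})

test_that("planted selection signals push Tajima's D in the right direction", {
  base <- cpr_alignment(matrix("A", 29, 160,
                               dimnames = list(sprintf("l%02d", 1:29), NULL)))
  expect_identical(plant_selection_signal(base, "neutral")$seq, base$seq)
  bal <- plant_selection_signal(base, "balancing", strength = 6)
  expect_gt(oracle_tajima_d(bal), 0)
  sw <- plant_selection_signal(base, "sweep", strength = 6)
  expect_lt(oracle_tajima_d(sw), 0)
  expect_error(plant_selection_signal(base, "sweep", strength = 200), "length")

  # direction holds in nearly every draw on coalescent backgrounds
  set.seed(14)
  m <- constant_size_model()
  ok_bal <- 0; ok_sw <- 0; draws <- 40
  for (r in seq_len(draws)) {
    aln <- simulate_sample(m, 29, 160, theta = 0.9, rho = 0)
    if (oracle_tajima_d(plant_selection_signal(aln, "balancing", 6)) > 0)
      ok_bal <- ok_bal + 1
    if (oracle_tajima_d(plant_selection_signal(aln, "sweep", 6)) < 0)
      ok_sw <- ok_sw + 1
  }
  expect_gte(ok_bal / draws, 0.95)
  expect_gte(ok_sw / draws, 0.95)
})

test_that("planted TFBS patterns are recovered by re-scanning", {
  ms <- core_promoter_motifs()
  base <- cpr_alignment(matrix("C", 29, 60,
                               dimnames = list(sprintf("l%02d", 1:29), NULL)))
  for (p in c("I", "II", "III")) {
    r <- plant_tfbs_effect(base, if (p == "II") ms$MTE else ms$TATA, p)
    expect_equal(r$pattern, p)
    expect_equal(nrow(r$snps), if (p == "III") 2L else 1L)
    back <- minimal_mutation_sets(
      paste(apply(r$alignment$seq[setdiff(rownames(r$alignment$seq),
                                          r$derived_lines), , drop = FALSE],
                  2, function(cc) cc[1]), collapse = ""),
      r$snps, list(if (p == "II") ms$MTE else ms$TATA))
    pats <- vapply(back, `[[`, character(1), "pattern")
    if (p == "III") expect_true(all(pats == "III"))
    else expect_true(p %in% pats)
  }
  tiny <- cpr_alignment(matrix("C", 4, 5))
  expect_error(plant_tfbs_effect(tiny, ms$TATA, "I"), "wider")
})

test_that("flank linkage is controlled by ld_decay", {
  # theta = 0: every CPR SNP is a planted balancing site aligned with the
  # haplogroup labels the flank walk copies
  cfg0 <- cohort_config(n_cprs = 1, ld_decay = 0, seed = 15,
                        theta_per_site = 0,
                        selection = "balancing", n_flank_snps = 4)
  co0 <- generate_cohort(cfg0)
  h0 <- co0$flanks$cpr001
  cpr_idx <- which(h0$is_cpr)
  flank_idx <- which(!h0$is_cpr)
  r2_0 <- vapply(flank_idx, function(j)
    pairwise_ld(h0, cpr_idx[1], j)$r2, numeric(1))
  expect_true(all(r2_0 > 0.95))

  cfg1 <- cohort_config(n_cprs = 1, ld_decay = 0.5, seed = 15,
                        theta_per_site = 0,
                        selection = "balancing", n_flank_snps = 4)
  co1 <- generate_cohort(cfg1)
  h1 <- co1$flanks$cpr001
  r2_1 <- vapply(which(!h1$is_cpr), function(j)
    pairwise_ld(h1, which(h1$is_cpr)[1], j)$r2, numeric(1))
  expect_lt(mean(r2_1, na.rm = TRUE), 0.3)
})

test_that("the truth record references only entities present in the cohort", {
  cfg <- cohort_config(n_cprs = 4, seed = 16, selection = c("balancing", "neutral"),
                       tfbs_pattern = c("I", NA), expression_effect = c(1.5, 0),
                       duplicate_lines = c(1L, 0L))
  co <- generate_cohort(cfg)
  lines <- co$alignments[[1]]$lines
  for (cid in names(co$truth)) {
    t <- co$truth[[cid]]
    expect_true(cid %in% names(co$alignments))
    expect_true(all(t$effect_group %in% lines))
    expect_true(all(t$duplicated_lines %in% lines))
    if (!is.null(t$tfbs))
      expect_true(all(t$tfbs$snps$site <= ncol(co$alignments[[cid]]$seq)))
  }
  # planted duplication is visible in the depth track
  dup_line <- co$truth$cpr001$duplicated_lines[1]
  iv <- co$intervals[co$intervals$cpr_id == "cpr001", ]
  call <- detect_duplication(co$depths$cpr001[[dup_line]],
                             c(iv$start, iv$end))
  expect_true(call$flagged)
})
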