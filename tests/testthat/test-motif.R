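toy_counts <- function(seed = 1, w = 4) {
  set.seed(seed)
  matrix(sample(0:9, 4 * w, replace = TRUE) + 1, nrow = 4,
         dimnames = list(c("A", "C", "G", "T"), NULL))
}

test_that("log-odds cells follow the pseudocount formula", {
  eq <- build_pssm(matrix(5, 4, 3), threshold = 0)
  expect_true(all(abs(eq$log_odds) < 1e-12))
  counts <- matrix(c(8, 0, 0, 0, 2, 2, 2, 2), nrow = 4)
  m <- build_pssm(counts, pseudocount = 0.5, threshold = 0)
  expect_equal(unname(m$log_odds[1, 1]), log2((8.5 / 10) / 0.25))
  expect_equal(m$width, 2L)
  expect_error(build_pssm(matrix(0, 4, 2), pseudocount = 0), "zero")
  expect_error(build_pssm(matrix(1, 3, 2)), "4 rows")
})

test_that("balanced threshold matches exhaustive k-mer enumeration", {
  for (seed in 1:3) {
    m <- build_pssm(toy_counts(seed, w = 4), rate_ratio = 1000)
    or <- oracle_balanced_threshold(m, 1000)
    expect_equal(m$threshold, or$threshold, tolerance = 1e-9)
  }
  # a different target ratio moves the threshold accordingly
  m1 <- build_pssm(toy_counts(5, 5), rate_ratio = 1)
  or1 <- oracle_balanced_threshold(m1, 1)
  expect_equal(m1$threshold, or1$threshold, tolerance = 1e-9)
})

test_that("halving the bin width moves the threshold by less than one original bin", {
  m <- build_pssm(toy_counts(2, 5), threshold = 0)
  t1 <- balanced_threshold(m, 1000, bin = 0.01)
  t2 <- balanced_threshold(m, 1000, bin = 0.005)
  expect_lt(abs(t1 - t2), 0.01 + 1e-9)
})

test_that("scanning covers both strands with N-aware windows", {
  zero <- build_pssm(matrix(5, 4, 3), threshold = 0.5)
  prof <- scan_sequence(zero, "ACGTACGT")
  expect_equal(nrow(prof), 2 * (8 - 3 + 1))
  expect_true(all(prof$score == 0))
  expect_false(any(prof$bound))

  short <- scan_sequence(zero, "AC")
  expect_equal(nrow(short), 0L)

  m <- core_promoter_motifs()$TATA
  s <- "GGCTATAAAAGCCGGATT"
  fwd <- scan_sequence(m, s)
  rcv <- scan_sequence(m, chartr("ACGT", "TGCA",
                                 paste(rev(strsplit(s, "")[[1]]), collapse = "")))
  minus <- fwd$score[fwd$strand == "-"]
  plus_rc <- rcv$score[rcv$strand == "+"]
  expect_equal(sort(minus), sort(plus_rc))

  # N voids every window it touches
  withN <- scan_sequence(m, sub("TATAAAAG", "TATANAAG", s))
  expect_true(any(is.na(withN$score)))
  expect_false(any(withN$bound[is.na(withN$score)]))
})

test_that("window scores are sums of per-position log-odds cells", {
  m <- core_promoter_motifs()$Inr
  s <- "TTCAGTCTAA"
  prof <- scan_sequence(m, s)
  chars <- strsplit(s, "")[[1]]
  for (p in 0:(nchar(s) - m$width)) {
    win <- chars[(p + 1):(p + m$width)]
    manual <- sum(m$log_odds[cbind(match(win, c("A", "C", "G", "T")),
                                   seq_len(m$width))])
    expect_equal(prof$score[prof$strand == "+" & prof$position == p], manual)
  }
})

test_that("TFBS change events require discordant binding calls", {
  ms <- core_promoter_motifs()
  # Inr's reverse complement is dissimilar, so exactly one window is bound
  base <- paste(c(rep("C", 10), "TCAGTCT", rep("C", 10)), collapse = "")
  dead <- sub("TCAGTCT", "CCAGTCT", base)  # strong-column hit
  same <- tfbs_change_events(scan_alleles(c(a = base, b = base), ms["Inr"]))
  expect_equal(nrow(same), 0L)
  diff <- tfbs_change_events(scan_alleles(c(a = base, b = dead), ms["Inr"]),
                             ancestral = "a")
  expect_equal(nrow(diff), 1L)
  expect_equal(diff$direction, "loss")
  expect_equal(attr(diff, "n_motifs_changed"), 1L)
  # invariant to allele ordering
  rev <- tfbs_change_events(scan_alleles(c(b = dead, a = base), ms["Inr"]))
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$position, diff$position)
  expect_error(tfbs_change_events(scan_alleles(c(a = base, b = "ACGT"), ms["Inr"])),
               "length")
})

test_that("minimal mutation sets match the 2^k brute-force subset oracle", {
  ms <- core_promoter_motifs()
  m <- ms$TATA
  set.seed(91)
  for (rep in 1:4) {
    bg <- paste(sample(c("C", "G"), 40, replace = TRUE), collapse = "")
    anc <- paste0(substr(bg, 1, 12), "TATAAAAG", substr(bg, 21, 40))
    sites <- sample(13:20, 4)
    anc_chars <- strsplit(anc, "")[[1]]
    snps <- data.frame(site = sites, anc = anc_chars[sites],
                       der = vapply(anc_chars[sites], function(b)
                         sample(setdiff(c("A", "C", "G", "T"), b), 1), ""),
                       stringsAsFactors = FALSE)
    res <- minimal_mutation_sets(anc, snps, list(m))

    # oracle: enumerate every subset, scan, and test minimality directly
    apply_subset <- function(idx) {
      ch <- anc_chars
      ch[snps$site[idx]] <- snps$der[idx]
      paste(ch, collapse = "")
    }
    all_sets <- lapply(0:15, function(mask) which(bitwAnd(mask, 2^(0:3)) > 0))
    prof_anc <- scan_sequence(m, anc)
    for (r in res) {
      sel <- prof_anc$position == r$position & prof_anc$strand == r$strand
      anc_call <- prof_anc$bound[sel]
      flips <- Filter(function(s) {
        p <- scan_sequence(m, apply_subset(s))
        p$bound[p$position == r$position & p$strand == r$strand] != anc_call
      }, all_sets)
      is_min <- Filter(function(s) {
        subs <- Filter(function(t) length(t) < length(s) && all(t %in% s), flips)
        !length(subs)
      }, flips)
      canon <- function(l) sort(vapply(l, paste, "", collapse = "+"))
      expect_equal(canon(r$minimal_sets), canon(is_min))
    }
  }
})

test_that("mutation-set enumeration refuses combinatorial blow-ups", {
  m <- core_promoter_motifs()$TATA
  anc <- paste(rep("C", 30), collapse = "")
  snps <- data.frame(site = 1:13, anc = "C", der = "A")
  expect_error(minimal_mutation_sets(anc, snps, list(m), cap = 12), "cap")
})

test_that("JASPAR files round-trip in both dialects", {
  ms <- core_promoter_motifs()
  f <- tempfile(fileext = ".jaspar")
  write_jaspar(ms, f)
  back <- read_jaspar(f)
  expect_equal(names(back), names(ms))
  for (id in names(ms)) {
    expect_equal(unname(back[[id]]$counts), unname(ms[[id]]$counts))
    expect_equal(back[[id]]$threshold, ms[[id]]$threshold)
  }
  # unlabelled 4-row dialect
  f2 <- tempfile(fileext = ".pfm")
  writeLines(c(">M1 toy", "1 2 3", "4 5 6", "7 8 9", "10 11 12"), f2)
  m2 <- read_jaspar(f2)
  expect_equal(unname(m2$M1$counts["T", 3]), 12)
  expect_equal(m2$M1$width, 3L)
})
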