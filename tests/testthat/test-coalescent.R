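test_that("degenerate simulations behave as the coalescent requires", {
  m <- constant_size_model()
  aln <- simulate_sample(m, 10, 50, seed = 1, theta = 0, rho = 0)
  expect_equal(n_segregating_sites(aln), 0L)
  one <- simulate_sample(m, 1, 30, seed = 2)
  expect_equal(nrow(one$seq), 1L)
  expect_equal(n_segregating_sites(one), 0L)
})

test_that("identical seeds give identical samples; different seeds differ", {
  m <- toy_admixture_model()
  a <- simulate_sample(m, 12, 80, seed = 33)
  b <- simulate_sample(m, 12, 80, seed = 33)
  expect_identical(a$seq, b$seq)
  c <- simulate_sample(m, 12, 80, seed = 34)
  expect_false(identical(a$seq, c$seq))
})

test_that("E[S] matches theta * a_{n-1} and is invariant to recombination", {
  m <- constant_size_model()
  set.seed(55)
  reps <- 1500
  theta <- 4
  S0 <- replicate(reps, n_segregating_sites(
    simulate_sample(m, 8, 300, theta = theta, rho = 0)))
  expected <- theta * sum(1 / (1:7))
  expect_lt(abs(mean(S0) - expected), 3 * stats::sd(S0) / sqrt(reps))
  S1 <- replicate(reps, n_segregating_sites(
    simulate_sample(m, 8, 300, theta = theta, rho = 4)))
  expect_lt(abs(mean(S1) - expected), 3 * stats::sd(S1) / sqrt(reps))
})

test_that("pairwise coalescence time has mean 1 in a constant-size deme", {
  # with theta large, pairwise differences / theta estimate T2 (mean 1)
  m <- constant_size_model()
  set.seed(66)
  reps <- 1200
  theta <- 10
  pw <- replicate(reps, nucleotide_diversity(
    simulate_sample(m, 2, 500, theta = theta, rho = 0)) * 500)
  expect_lt(abs(mean(pw) / theta - 1), 3 * stats::sd(pw / theta) / sqrt(reps))
})

test_that("demographic events execute: admixture with proportion 1 behaves like a split", {
  demes <- data.frame(name = c("derived", "anc"), size = c(1, 1), growth = c(0, 0))
  m_split <- demographic_model(demes, list(
    list(time = 0.05, type = "split", deme = "derived", source = "anc")),
    sample_deme = "derived")
  m_admix <- demographic_model(demes, list(
    list(time = 0.05, type = "admixture", deme = "derived",
         sources = "anc", proportions = 1)),
    sample_deme = "derived")
  set.seed(77)
  S_split <- replicate(600, n_segregating_sites(
    simulate_sample(m_split, 6, 200, theta = 3, rho = 0)))
  S_admix <- replicate(600, n_segregating_sites(
    simulate_sample(m_admix, 6, 200, theta = 3, rho = 0)))
  ks <- suppressWarnings(stats::ks.test(S_split, S_admix))
  expect_gt(ks$p.value, 0.01)
})

test_that("disconnected demes are rejected rather than looping forever", {
  demes <- data.frame(name = c("a", "b"), size = c(1, 1), growth = c(0, 0))
  m <- demographic_model(demes, list(
    list(time = 0.01, type = "admixture", deme = "a",
         sources = c("a", "b"), proportions = c(0.5, 0.5))))
  # half the lineages end up stranded in deme b with no route back
  expect_error(simulate_sample(m, 10, 50, seed = 5, theta = 1, rho = 0),
               "disconnected")
})

test_that("build_null collects D values and tracks monomorphic runs", {
  m <- constant_size_model()
  n0 <- build_null(m, n = 5, L = 50, reps = 1, seed = 9, theta = 0, rho = 0)
  expect_equal(length(n0$d_values), 0L)
  expect_equal(n0$n_s0, 1L)
  n1 <- build_null(m, n = 10, L = 100, reps = 60, seed = 10, theta = 2, rho = 0)
  n2 <- build_null(m, n = 10, L = 100, reps = 60, seed = 10, theta = 2, rho = 0)
  expect_identical(n1$d_values, n2$d_values)
  expect_equal(length(n1$d_values) + n1$n_s0, 60L)
})

test_that("null distribution of D is centred near its small negative expectation", {
  m <- constant_size_model()
  nl <- build_null(m, n = 29, L = 160, reps = 1500, seed = 12,
                   theta = 0.0058 * 160, rho = 0)
  se <- stats::sd(nl$d_values) / sqrt(length(nl$d_values))
  # neutral-model mean D is slightly negative; assert it is within 3 SE of
  # the interval (-0.2, 0)
  expect_lt(mean(nl$d_values), 0 + 3 * se)
  expect_gt(mean(nl$d_values), -0.2 - 3 * se)
})

test_that("empirical outlier P values follow the +1-corrected two-tailed definition", {
  fake <- structure(list(d_values = seq(-2, 2, length.out = 999), n_s0 = 0L,
                         reps = 999L, n = 29L, L = 160L, model = NULL,
                         seed = NULL), class = "null_distribution")
  top <- outlier_pvalue(3, fake)
  expect_equal(top$p, 2 / 1000)
  expect_equal(top$verdict, "balancing-candidate")
  mid <- outlier_pvalue(stats::median(fake$d_values), fake)
  expect_gt(mid$p, 0.9)
  expect_equal(mid$verdict, "not significant")
  bot <- outlier_pvalue(-3, fake)
  expect_equal(bot$p, 2 / 1000)
  expect_equal(bot$verdict, "purifying/sweep-candidate")
  expect_true(is.na(outlier_pvalue(NA_real_, fake)$p))
})

test_that("outlier P matches direct counting and p_upper is monotone in d_obs", {
  m <- constant_size_model()
  nl <- build_null(m, n = 10, L = 120, reps = 400, seed = 20,
                   theta = 2, rho = 0)
  probes <- seq(-3, 3, length.out = 20)
  R <- length(nl$d_values)
  last_up <- Inf
  for (d in probes) {
    res <- outlier_pvalue(d, nl)
    up <- (sum(nl$d_values >= d) + 1) / (R + 1)
    lo <- (sum(nl$d_values <= d) + 1) / (R + 1)
    expect_equal(res$p_upper, up)
    expect_equal(res$p_lower, lo)
    expect_equal(res$p, min(1, 2 * min(up, lo)))
    expect_lte(res$p_upper, last_up)
    last_up <- res$p_upper
  }
})

test_that("demography specs validate and round-trip through YAML", {
  expect_error(demographic_model(data.frame(name = "a", size = -1, growth = 0)),
               "positive")
  expect_error(demographic_model(
    data.frame(name = c("a", "b"), size = 1, growth = 0),
    list(list(time = 0.1, type = "admixture", deme = "a", sources = "b",
              proportions = 0.7))), "sum to 1")
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    time_unit = "generations", N_ref = 1e6,
    demes = list(list(name = "pop", size = 1, growth = 0)),
    events = list(list(time = 2e5, type = "size", deme = "pop", size = 0.1))),
    f)
  m <- read_demography_yaml(f)
  expect_s3_class(m, "demographic_model")
  expect_equal(m$events[[1]]$time, 2e5 / (2 * 1e6))
})
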