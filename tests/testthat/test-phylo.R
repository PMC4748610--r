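test_that("distances hit the closed forms and the matrix contract", {
  same <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  d <- composite_distance(same)
  expect_equal(unname(d["a", "b"]), 0)

  # JC at p-distance 0.1: -(3/4) ln(1 - 4*0.1/3)
  s1 <- paste(rep("A", 30), collapse = "")
  s2 <- paste(c(rep("A", 27), "C", "G", "T"), collapse = "")
  dj <- composite_distance(c(a = s1, b = s2), submodel = "JC")
  expect_equal(unname(dj["a", "b"]), -3 / 4 * log(1 - 4 * 0.1 / 3),
               tolerance = 1e-10)

  set.seed(101)
  aln <- random_alignment(5, 60, p_var = 0.3)
  dm <- composite_distance(as.character(aln))
  expect_true(isSymmetric(dm))
  expect_true(all(diag(dm) == 0))
  expect_true(all(dm >= 0, na.rm = TRUE))
})

test_that("NJ recovers additive matrices exactly", {
  # 4-taxon additive matrix with split {A,B}|{C,D}
  tips <- c("A", "B", "C", "D")
  # pendant edges 1,2,3,4 and internal edge 5
  dm <- matrix(0, 4, 4, dimnames = list(tips, tips))
  pe <- c(A = 1, B = 2, C = 3, D = 4); int <- 5
  dm["A", "B"] <- dm["B", "A"] <- pe["A"] + pe["B"]
  dm["C", "D"] <- dm["D", "C"] <- pe["C"] + pe["D"]
  for (x in c("A", "B")) for (y in c("C", "D"))
    dm[x, y] <- dm[y, x] <- pe[x] + pe[y] + int
  tree <- neighbor_joining(dm)
  # the split {A,B}|{C,D} must be present
  parts <- ape::prop.part(tree)
  labels <- attr(parts, "labels")
  split_sets <- lapply(parts, function(p) sort(labels[p]))
  expect_true(any(vapply(split_sets, function(s)
    identical(s, c("A", "B")) || identical(s, c("C", "D")), logical(1))))
  # path distances reproduce the input exactly
  cd <- ape::cophenetic.phylo(tree)[tips, tips]
  expect_equal(cd, dm, tolerance = 1e-10)
})

test_that("random additive trees of 4-8 taxa are recovered", {
  set.seed(111)
  for (ntax in 4:8) {
    tr <- ape::rtree(ntax, br = function(n) stats::runif(n, 0.1, 1))
    tr <- ape::unroot(tr)
    dm <- ape::cophenetic.phylo(tr)
    est <- neighbor_joining(dm)
    expect_equal(ape::cophenetic.phylo(est)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(est), tr), structure(0, class = NULL),
                 ignore_attr = TRUE)
  }
})

test_that("3-taxon trees solve the three-point equations and rooting keeps bipartitions", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("x", "y", "o"), c("x", "y", "o")))
  tree <- neighbor_joining(dm)
  cd <- ape::cophenetic.phylo(tree)[c("x", "y", "o"), c("x", "y", "o")]
  expect_equal(cd, dm, tolerance = 1e-10)
  expect_error(neighbor_joining(dm[1:2, 1:2]), "3 taxa")

  set.seed(112)
  aln <- random_alignment(5, 80, p_var = 0.4)
  seqs <- as.character(aln)
  un <- neighbor_joining(composite_distance(seqs))
  ro <- neighbor_joining(composite_distance(seqs), outgroup = names(seqs)[1])
  expect_equal(ape::dist.topo(ape::unroot(ro), un), 0, ignore_attr = TRUE)
})

test_that("bootstrap supports are deterministic under a seed and match a direct count", {
  set.seed(113)
  # 30 columns jointly supporting the split {a,b}|{c,d,e}, embedded in a
  # conserved backbone so pairwise divergence stays inside the JC domain
  block1 <- paste(rep("A", 30), collapse = "")
  block2 <- paste(rep("G", 30), collapse = "")
  backbone <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                    collapse = "")
  noise <- function() paste(sample(c("C", "T"), 10, replace = TRUE), collapse = "")
  seqs <- c(a = paste0(block1, backbone, noise()),
            b = paste0(block1, backbone, noise()),
            c = paste0(block2, backbone, noise()),
            d = paste0(block2, backbone, noise()),
            e = paste0(block2, backbone, noise()))
  t1 <- bootstrap_support(seqs, reps = 100, seed = 7, submodel = "JC")
  t2 <- bootstrap_support(seqs, reps = 100, seed = 7, submodel = "JC")
  expect_identical(t1$node.label, t2$node.label)
  expect_gt(max(t1$node.label, na.rm = TRUE), 95)

  # independent resample-and-count oracle under the same seed/draw order
  set.seed(7)
  orig <- ape::nj(ape::dist.dna(ape::as.DNAbin(strsplit(tolower(seqs), "")),
                                model = "JC69", pairwise.deletion = TRUE))
  L <- nchar(seqs[1])
  chars <- do.call(rbind, strsplit(seqs, ""))
  boots <- list()
  for (r in 1:100) {
    cols <- sample.int(L, L, replace = TRUE)
    bs <- apply(chars[, cols], 1, paste, collapse = "")
    names(bs) <- names(seqs)
    boots[[r]] <- ape::nj(ape::dist.dna(
      ape::as.DNAbin(strsplit(tolower(bs), "")), model = "JC69",
      pairwise.deletion = TRUE))
  }
  counts <- ape::prop.clades(orig, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  expect_identical(t1$node.label, round(100 * counts / 100, 1))
})

test_that("alignments without variable sites yield undefined supports", {
  seqs <- stats::setNames(rep(paste(rep("A", 20), collapse = ""), 4),
                          c("a", "b", "c", "d"))
  tr <- bootstrap_support(seqs, reps = 10, seed = 1)
  expect_true(all(is.na(tr$node.label)))
})

test_that("outgroup matching orients alleles as ancestral or derived", {
  alleles <- c(a = "ACGTACGT", b = "ACGTACGA", c = "ACGTTCGA")
  og <- "ACGTACGA"
  lab <- orient_alleles(alleles, og)
  expect_equal(unname(lab["b"]), "ancestral")
  expect_equal(unname(lab["a"]), "derived")
  expect_equal(unname(lab["c"]), "derived")
})
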