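#' Pairwise evolutionary distances among CPR alleles (plus outgroup)
#'
#' The default `"TN93-composite"` pools base frequencies across all
#' sequences (the composite-likelihood idea of sharing substitution
#' parameters across pairs) and evaluates the Tamura-Nei closed form per
#' pair from its own transition/transversion proportions. `"JC"` and
#' `"K2P"` use the standard closed forms via `ape::dist.dna`.
#'
#' @param seqs Named character vector of aligned equal-length sequences
#'   (allele labels and, typically, an outgroup).
#' @param submodel `"TN93-composite"`, `"JC"` or `"K2P"`.
#' @return Symmetric distance matrix with zero diagonal; entries are `NA`
#'   (with a warning) where the submodel's log arguments are non-positive.
#' @export
composite_distance <- function(seqs, submodel = c("TN93-composite", "JC", "K2P")) {
  submodel <- match.arg(submodel)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must be aligned to equal length")
  labs <- names(seqs)
  if (is.null(labs)) labs <- paste0("t", seq_along(seqs))
  if (submodel %in% c("JC", "K2P")) {
    bin <- ape::as.DNAbin(lapply(strsplit(tolower(seqs), ""), identity))
    d <- ape::dist.dna(bin, model = if (submodel == "JC") "JC69" else "K80",
                       pairwise.deletion = TRUE)
    m <- as.matrix(d)
    dimnames(m) <- list(labs, labs)
    return(m)
  }
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(chars) <- labs
  n <- nrow(chars)
  # pooled base frequencies over all sequences (N excluded)
  tabs <- c(A = sum(chars == "A"), C = sum(chars == "C"),
            G = sum(chars == "G"), T = sum(chars == "T"))
  g <- tabs / sum(tabs)
  gR <- g["A"] + g["G"]; gY <- g["C"] + g["T"]
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  warned <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- chars[i, ]; b <- chars[j, ]
    ok <- a != "N" & b != "N"
    a <- a[ok]; b <- b[ok]
    nn <- length(a)
    if (!nn) { m[i, j] <- m[j, i] <- NA; next }
    P1 <- sum((a == "A" & b == "G") | (a == "G" & b == "A")) / nn
    P2 <- sum((a == "C" & b == "T") | (a == "T" & b == "C")) / nn
    diffs <- a != b
    if (!any(diffs)) { m[i, j] <- m[j, i] <- 0; next }
    Q <- (sum(diffs) - P1 * nn - P2 * nn) / nn
    # terms whose base-frequency coefficient vanishes contribute nothing
    kAG <- if (gR > 0) 2 * g["A"] * g["G"] / gR else 0
    kCT <- if (gY > 0) 2 * g["C"] * g["T"] / gY else 0
    kQ <- if (gR > 0 && gY > 0)
      2 * (gR * gY - g["A"] * g["G"] * gY / gR - g["C"] * g["T"] * gR / gY) else 0
    w1 <- if (kAG > 0) 1 - gR * P1 / (2 * g["A"] * g["G"]) - Q / (2 * gR) else 1
    w2 <- if (kCT > 0) 1 - gY * P2 / (2 * g["C"] * g["T"]) - Q / (2 * gY) else 1
    w3 <- if (gR > 0 && gY > 0) 1 - Q / (2 * gR * gY) else 1
    if (is.na(w1) || is.na(w2) || is.na(w3) || w1 <= 0 || w2 <= 0 || w3 <= 0) {
      if (!warned) { warning("TN93 distance undefined for some pair(s); NA returned"); warned <- TRUE }
      m[i, j] <- m[j, i] <- NA
      next
    }
    d <- -(if (kAG > 0) kAG * log(w1) else 0) -
      (if (kCT > 0) kCT * log(w2) else 0) -
      (if (gR > 0 && gY > 0) kQ * log(w3) else 0)
    m[i, j] <- m[j, i] <- unname(d)
  }
  m
}

#' Neighbor-joining tree of CPR alleles
#'
#' Saitou-Nei neighbor joining on a distance matrix. Negative branch lengths
#' are clamped to zero with the deficit moved to the sibling branch (the
#' common convention, preserving path lengths through the parent node).
#' When an outgroup label is given the tree is rooted on its pendant edge.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) or `dist`.
#' @param outgroup Optional taxon label to root on.
#' @return An `ape::phylo` tree.
#' @export
neighbor_joining <- function(d, outgroup = NULL) {
  m <- as.matrix(d)
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (anyNA(m)) stop("distance matrix contains NA")
  tree <- ape::nj(stats::as.dist(m))
  tree <- .clamp_negative_branches(tree)
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) stop("outgroup not among taxa")
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  tree
}

.clamp_negative_branches <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    parent <- tree$edge[e, 1]
    sib <- which(tree$edge[, 1] == parent & seq_along(tree$edge.length) != e)
    tree$edge.length[e] <- 0
    if (length(sib)) tree$edge.length[sib[1]] <-
        tree$edge.length[sib[1]] + deficit
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Bootstrap support for a neighbor-joining allele tree
#'
#' Alignment columns are resampled with replacement; each replicate is run
#' through [composite_distance()] and [neighbor_joining()], and support is
#' the percentage of replicates containing each internal bipartition of the
#' original tree. Conventionally only values above 60 are displayed on
#' figures; all values are returned.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param reps Bootstrap replicates (default 1000).
#' @param seed Optional seed.
#' @param outgroup Optional outgroup label (rooting applied to the returned
#'   tree; support is computed on unrooted bipartitions).
#' @param submodel Distance submodel, see [composite_distance()].
#' @return The original tree with `node.label` set to supports (0-100;
#'   `NA` for the root and for trees without variable sites).
#' @export
bootstrap_support <- function(seqs, reps = 1000, seed = NULL, outgroup = NULL,
                              submodel = "TN93-composite") {
  if (!is.null(seed)) set.seed(seed)
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1L, L >= 1L)
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(chars) <- names(seqs)
  orig <- neighbor_joining(composite_distance(seqs, submodel = submodel))
  variable <- any(apply(chars, 2, function(cc) length(unique(cc[cc != "N"])) > 1))
  boots <- vector("list", reps)
  ok <- logical(reps)
  if (variable) {
    for (r in seq_len(reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      bs <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
      dm <- composite_distance(bs, submodel = submodel)
      if (anyNA(dm)) next
      boots[[r]] <- neighbor_joining(dm)
      ok[r] <- TRUE
    }
  }
  if (!any(ok)) {
    orig$node.label <- rep(NA_real_, orig$Nnode)
  } else {
    counts <- ape::prop.clades(orig, boots[ok], rooted = FALSE)
    counts[is.na(counts)] <- 0
    orig$node.label <- round(100 * counts / sum(ok), 1)
  }
  if (!is.null(outgroup)) {
    orig <- ape::root(orig, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  }
  orig
}

#' Orient alleles as ancestral or derived against an outgroup
#'
#' At each segregating site of the allele set, the allele whose base matches
#' the outgroup is taken as ancestral; alleles matching the outgroup at
#' every segregating site are labelled `"ancestral"`, the rest `"derived"`.
#'
#' @param alleles Named character vector of allele sequences.
#' @param outgroup Outgroup sequence (same length).
#' @return Named character vector: allele -> `"ancestral"`/`"derived"`.
#' @export
orient_alleles <- function(alleles, outgroup) {
  chars <- do.call(rbind, strsplit(toupper(alleles), ""))
  og <- strsplit(toupper(outgroup), "")[[1]]
  if (length(og) != ncol(chars)) stop("outgroup length differs from alleles")
  seg <- which(apply(chars, 2, function(cc) length(unique(cc[cc != "N"])) > 1))
  if (!length(seg)) {
    return(stats::setNames(rep("ancestral", nrow(chars)), names(alleles)))
  }
  status <- apply(chars[, seg, drop = FALSE], 1, function(r)
    all(r == og[seg] | r == "N" | og[seg] == "N"))
  stats::setNames(ifelse(status, "ancestral", "derived"), names(alleles))
}

#' Write a tree to newick with supports as internal node labels
#'
#' @param tree An `ape::phylo` (e.g. from [bootstrap_support()]).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_tree_newick <- function(tree, file) {
  ape::write.tree(tree, file = file)
  invisible(file)
}
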