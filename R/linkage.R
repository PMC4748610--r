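#' Construct a haplotype matrix of biallelic SNPs
#'
#' Lines are homozygous inbred, so phase is known and each line contributes
#' one haplotype. Codes are 0 (ref), 1 (alt), `NA` (missing).
#'
#' @param geno Lines x SNPs integer matrix of codes (rownames = line ids).
#' @param pos 1-based SNP positions (sorted ascending).
#' @param chrom Chromosome name.
#' @param ref,alt Optional allele strings per SNP.
#' @param is_cpr Optional logical per SNP: lies inside the focal CPR.
#' @return Object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(geno, pos, chrom = "chr", ref = NULL, alt = NULL,
                             is_cpr = NULL) {
  geno <- as.matrix(geno)
  stopifnot(ncol(geno) == length(pos))
  if (is.unsorted(pos)) {
    o <- order(pos)
    geno <- geno[, o, drop = FALSE]; pos <- pos[o]
    if (!is.null(ref)) ref <- ref[o]
    if (!is.null(alt)) alt <- alt[o]
    if (!is.null(is_cpr)) is_cpr <- is_cpr[o]
  }
  if (!all(geno %in% c(0L, 1L, NA)))
    stop("genotype codes must be 0, 1 or NA")
  if (is.null(rownames(geno))) rownames(geno) <- paste0("line", seq_len(nrow(geno)))
  structure(list(geno = geno, pos = as.integer(pos), chrom = chrom,
                 ref = ref, alt = alt,
                 is_cpr = if (is.null(is_cpr)) rep(FALSE, length(pos)) else is_cpr),
            class = "haplotype_matrix")
}

#' Read a haplotype matrix from a VCF of homozygous calls
#'
#' Keeps biallelic SNPs; genotypes other than homozygous ref/alt become `NA`.
#'
#' @param file VCF path.
#' @param chrom Optional chromosome filter.
#' @param cpr_interval Optional `c(start, end)` (0-based half-open) used to
#'   set the `is_cpr` flags.
#' @return A [haplotype_matrix()].
#' @export
read_haplotypes_vcf <- function(file, chrom = NULL, cpr_interval = NULL) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  fix$POS <- as.integer(fix$POS)
  gt <- vcfR::extract.gt(v)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT)
  if (!is.null(chrom)) keep <- keep & fix$CHROM == chrom
  fix <- fix[keep, , drop = FALSE]; gt <- gt[keep, , drop = FALSE]
  code <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                 dimnames = list(colnames(gt), NULL))
  for (k in seq_len(nrow(gt))) {
    g <- gt[k, ]
    code[g %in% c("0", "0/0", "0|0"), k] <- 0L
    code[g %in% c("1", "1/1", "1|1"), k] <- 1L
  }
  is_cpr <- if (!is.null(cpr_interval))
    fix$POS > cpr_interval[1] & fix$POS <= cpr_interval[2] else NULL
  haplotype_matrix(code, fix$POS, chrom = fix$CHROM[1],
                   ref = fix$REF, alt = fix$ALT, is_cpr = is_cpr)
}

#' Pairwise linkage disequilibrium between two SNPs
#'
#' Haplotype frequencies are counted directly over lines non-missing at both
#' SNPs. `D = p_AB - p_A p_B`, `D' = D / Dmax`, `r2 = D^2 /
#' (p_A p_a p_B p_b)`.
#'
#' @param h A [haplotype_matrix()].
#' @param i,j SNP column indices.
#' @return List `D`, `Dprime`, `r2`, `n` (lines used); all statistics `NA`
#'   when either SNP is monomorphic among the usable lines.
#' @export
pairwise_ld <- function(h, i, j) {
  g <- h$geno
  ok <- !is.na(g[, i]) & !is.na(g[, j])
  a <- g[ok, i]; b <- g[ok, j]
  n <- length(a)
  pA <- mean(a); pB <- mean(b)
  if (n < 2L || pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_, n = n))
  pAB <- mean(a == 1 & b == 1)
  D <- pAB - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D, Dprime = if (Dmax > 0) D / Dmax else 0, r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
       n = n)
}

# bootstrap percentile CI of |D'| over lines (phase-known inbred data)
.dprime_ci <- function(h, i, j, boot = 1000, conf = c(0.05, 0.95)) {
  g <- h$geno
  ok <- !is.na(g[, i]) & !is.na(g[, j])
  a <- g[ok, i]; b <- g[ok, j]
  n <- length(a)
  vals <- vapply(seq_len(boot), function(r) {
    idx <- sample.int(n, n, replace = TRUE)
    ar <- a[idx]; br <- b[idx]
    pA <- mean(ar); pB <- mean(br)
    if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
    D <- mean(ar == 1 & br == 1) - pA * pB
    Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    if (Dmax > 0) abs(D / Dmax) else 0
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) < boot / 2) return(c(NA_real_, NA_real_))
  unname(stats::quantile(vals, conf))
}

#' Haplotype blocks by the confidence-interval (Gabriel-style) rule
#'
#' For each SNP pair an |D'| bootstrap confidence interval is computed
#' (percentile CI over resampled lines). A pair is "strong LD" when the
#' lower bound is >= `strong_low` and the upper bound >= `strong_high`, and
#' shows "evidence of recombination" when the upper bound < `recomb_high`.
#' A block is a maximal run of SNPs containing no recombination pair and in
#' which strong-LD pairs outnumber recombination pairs at least
#' `informative_ratio`:1 among informative pairs (with zero recombination
#' pairs this reduces to requiring at least one strong pair).
#'
#' @param h A [haplotype_matrix()].
#' @param boot Bootstrap resamples per pair (default 1000).
#' @param strong_low,strong_high,recomb_high CI thresholds
#'   (defaults 0.70, 0.98, 0.90).
#' @param informative_ratio Required strong:recombination ratio (default 19).
#' @param seed Optional seed for the bootstrap.
#' @return List of blocks, each an integer vector of SNP column indices;
#'   attribute `pair_class` holds the pairwise classification matrix
#'   (`"strong"`, `"recomb"`, `"uninformative"`).
#' @export
haplotype_blocks <- function(h, boot = 1000, strong_low = 0.70,
                             strong_high = 0.98, recomb_high = 0.90,
                             informative_ratio = 19, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(h$geno)
  if (m < 2L) return(list())
  cls <- matrix(NA_character_, m, m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    ld <- pairwise_ld(h, i, j)
    if (is.na(ld$Dprime)) { cls[i, j] <- "uninformative"; next }
    ci <- .dprime_ci(h, i, j, boot = boot)
    cls[i, j] <- if (anyNA(ci)) "uninformative"
      else if (ci[1] >= strong_low && ci[2] >= strong_high) "strong"
      else if (ci[2] < recomb_high) "recomb"
      else "uninformative"
  }
  # candidate intervals, longest first, greedy non-overlap
  cand <- list()
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    sub <- cls[i:j, i:j]
    ns <- sum(sub == "strong", na.rm = TRUE)
    nr <- sum(sub == "recomb", na.rm = TRUE)
    if (ns >= 1L && nr == 0L && ns >= informative_ratio * nr)
      cand[[length(cand) + 1L]] <- i:j
  }
  cand <- cand[order(-vapply(cand, length, integer(1)))]
  blocks <- list(); taken <- rep(FALSE, m)
  for (b in cand) {
    if (!any(taken[b]) && length(b) >= 2L) {
      blocks[[length(blocks) + 1L]] <- b
      taken[b] <- TRUE
    }
  }
  attr(blocks, "pair_class") <- cls
  blocks
}

#' Per-SNP Wald association of expression with flanking SNPs
#'
#' Expression is collapsed to one value per line (per-sex means averaged
#' over the sexes) and regressed on each SNP's allele code; the Wald
#' statistic is the slope over its standard error, with p-values from its
#' null t distribution. Benjamini-Hochberg control is applied across the
#' window's SNPs at FDR `q`.
#'
#' @param expr data.frame with columns `line`, `sex`, `value` for one
#'   transcript.
#' @param h A [haplotype_matrix()] for the window (CPR +- flank).
#' @param q FDR level (default 0.01).
#' @return data.frame (`snp`, `pos`, `is_cpr`, `beta`, `se`, `wald`, `p`,
#'   `q`, `significant`).
#' @export
flank_association <- function(expr, h, q = 0.01) {
  agg <- stats::aggregate(value ~ line + sex, data = expr, FUN = mean)
  y_by_line <- tapply(agg$value, agg$line, mean)
  lines <- intersect(rownames(h$geno), names(y_by_line))
  y <- y_by_line[lines]
  g <- h$geno[lines, , drop = FALSE]
  m <- ncol(g)
  out <- data.frame(snp = seq_len(m), pos = h$pos, is_cpr = h$is_cpr,
                    beta = NA_real_, se = NA_real_, wald = NA_real_,
                    p = NA_real_)
  for (k in seq_len(m)) {
    ok <- !is.na(g[, k])
    gk <- g[ok, k]; yk <- y[ok]
    if (length(unique(gk)) < 2L) next
    fit <- stats::lm(yk ~ gk)
    cf <- summary(fit)$coefficients
    if (nrow(cf) < 2L || is.na(cf[2, 2]) || cf[2, 2] == 0) next
    out$beta[k] <- cf[2, 1]; out$se[k] <- cf[2, 2]
    out$wald[k] <- cf[2, 1] / cf[2, 2]
    out$p[k] <- cf[2, 4]
  }
  adj <- bh_adjust(out$p, q = q)
  out$q <- adj$q_values
  out$significant <- adj$reject
  out
}

#' Window selection for flanking SNPs around a CPR
#'
#' 1-based SNP positions `p` are inside the window when
#' `start - flank < p <= end + flank` for a 0-based half-open CPR interval.
#'
#' @param pos 1-based positions.
#' @param start,end 0-based half-open CPR interval.
#' @param flank Flank size in bp (default 5000).
#' @return Logical vector.
#' @export
in_flank_window <- function(pos, start, end, flank = 5000) {
  pos > start - flank & pos <= end + flank
}

#' Decide whether flanking SNPs could explain an expression difference
#'
#' Verdict is `"Y"` when at least one significant flanking SNP either shares
#' a haplotype block with a CPR SNP or has `r2 >= r2_threshold` with one;
#' `"N"` otherwise (including the case of no significant flanking SNPs).
#'
#' @param h A [haplotype_matrix()] (with `is_cpr` flags set).
#' @param assoc Output of [flank_association()].
#' @param blocks Output of [haplotype_blocks()].
#' @param r2_threshold Linkage fallback threshold (default 0.8).
#' @return `"Y"` or `"N"`.
#' @export
linkage_verdict <- function(h, assoc, blocks, r2_threshold = 0.8) {
  cpr_idx <- which(h$is_cpr)
  sig_flank <- assoc$snp[assoc$significant & !assoc$is_cpr]
  if (!length(sig_flank) || !length(cpr_idx)) return("N")
  for (s in sig_flank) {
    for (b in blocks) if (s %in% b && any(cpr_idx %in% b)) return("Y")
    for (ci in cpr_idx) {
      r2 <- pairwise_ld(h, s, ci)$r2
      if (!is.na(r2) && r2 >= r2_threshold) return("Y")
    }
  }
  "N"
}
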