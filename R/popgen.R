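#' Apply panel data-cleaning rules to a CPR alignment
#'
#' Cleaning follows the rules used for homozygous inbred-line panels:
#' \enumerate{
#'   \item lines with any heterozygous call inside the CPR are dropped;
#'   \item alleles rarer than `maf_threshold` are masked to `N` on their
#'     carrier lines (sequencing-error guard) rather than deleting the site;
#'   \item at a site where some lines are `N` and all determined lines agree,
#'     the site is treated as fixed for that base and the `N`s are filled in;
#'   \item lines with `N` at a site that is still polymorphic are excluded
#'     from the whole CPR;
#'   \item a CPR retaining fewer than `min_lines` usable lines is excluded.
#' }
#' Steps 3-4 iterate to a fixed point, so the operation is idempotent.
#'
#' @param raw A [cpr_alignment()].
#' @param maf_threshold Minor-allele-frequency cutoff below which alleles are
#'   masked (default 0.01).
#' @param min_lines Minimum usable lines to keep a CPR (default 20).
#' @param het_sites Optional named list: for each line id, integer sites
#'   (1-based alignment columns) with heterozygous calls. Any entry causes
#'   removal of that line.
#' @return A cleaned `cpr_alignment`, or an object of class `cpr_exclusion`
#'   (fields `cpr_id`, `reason`, `n_usable`) if the CPR is excluded.
#' @export
preprocess_alignment <- function(raw, maf_threshold = 0.01, min_lines = 20,
                                 het_sites = NULL) {
  stopifnot(inherits(raw, "cpr_alignment"))
  exclude <- function(reason, n_usable) {
    structure(list(cpr_id = raw$cpr_id, reason = reason, n_usable = n_usable),
              class = "cpr_exclusion")
  }
  if (aln_n(raw) == 0L || aln_length(raw) == 0L) return(exclude("no data", 0L))
  mat <- raw$seq

  # heterozygous lines out first
  if (!is.null(het_sites)) {
    het_lines <- names(het_sites)[vapply(het_sites, length, integer(1)) > 0L]
    mat <- mat[!rownames(mat) %in% het_lines, , drop = FALSE]
  }
  if (nrow(mat) == 0L) return(exclude("no data", 0L))

  # rare-allele masking
  for (j in seq_len(ncol(mat))) {
    b <- mat[, j]
    det <- b != "N"
    if (!any(det)) next
    tab <- table(b[det])
    freqs <- tab / sum(tab)
    rare <- names(freqs)[freqs < maf_threshold]
    if (length(rare)) mat[det & b %in% rare, j] <- "N"
  }

  # resolve N sites to a fixed point
  repeat {
    drop_lines <- rep(FALSE, nrow(mat))
    for (j in seq_len(ncol(mat))) {
      b <- mat[, j]
      isN <- b == "N"
      if (!any(isN)) next
      det <- unique(b[!isN])
      if (length(det) == 1L) {
        mat[isN, j] <- det          # fixed for the determined base
      } else if (length(det) >= 2L) {
        drop_lines <- drop_lines | isN
      }
    }
    if (!any(drop_lines)) break
    mat <- mat[!drop_lines, , drop = FALSE]
    if (nrow(mat) == 0L) return(exclude("no data", 0L))
  }

  if (nrow(mat) < min_lines) return(exclude("fewer than min_lines usable lines", nrow(mat)))
  out <- raw
  out$seq <- mat
  out$lines <- rownames(mat)
  out
}

#' @export
print.cpr_exclusion <- function(x, ...) {
  cat(sprintf("CPR '%s' excluded: %s (%d usable lines)\n",
              x$cpr_id, x$reason, x$n_usable))
  invisible(x)
}

#' Nucleotide diversity (pi) per site
#'
#' Average pairwise per-site difference over all unordered pairs of lines.
#' Sites with `N` use pairwise deletion: pairs where either base is `N` are
#' skipped and that site's denominator shrinks accordingly.
#'
#' @param aln A [cpr_alignment()] with at least two lines.
#' @return Per-site pi, or `NA_real_` when fewer than 2 lines.
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "cpr_alignment"))
  if (aln_n(aln) < 2L) return(NA_real_)
  L <- aln_length(aln)
  if (L == 0L) return(NA_real_)
  counts <- .base_counts(aln$seq)
  m <- colSums(counts)
  per_site <- ifelse(m < 2L, 0,
                     1 - colSums(counts * (counts - 1)) / (m * (m - 1)))
  sum(per_site) / L
}

#' Watterson's theta per site
#'
#' `theta_w = S / (a1 * L)` with `a1 = sum(1/i, i = 1..n-1)`.
#'
#' @inheritParams nucleotide_diversity
#' @return Per-site Watterson estimator, or `NA_real_` when n < 2.
#' @export
watterson_theta <- function(aln) {
  stopifnot(inherits(aln, "cpr_alignment"))
  n <- aln_n(aln)
  if (n < 2L) return(NA_real_)
  S <- n_segregating_sites(aln)
  a1 <- sum(1 / seq_len(n - 1L))
  S / (a1 * aln_length(aln))
}

#' Constants of Tajima's D for a sample of size n
#'
#' @param n Sample size (number of haplotypes), `n >= 2`.
#' @return Named list `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' `D = (pi*L - S/a1) / sqrt(e1*S + e2*S*(S-1))`. Undefined (returned as
#' `NA_real_`) for monomorphic alignments or fewer than 4 lines.
#'
#' @inheritParams nucleotide_diversity
#' @return The D statistic, or `NA_real_` when undefined.
#' @export
tajimas_d <- function(aln) {
  stopifnot(inherits(aln, "cpr_alignment"))
  n <- aln_n(aln)
  if (n < 4L) return(NA_real_)
  S <- n_segregating_sites(aln)
  if (S < 1L) return(NA_real_)
  k <- tajima_constants(n)
  pi_total <- nucleotide_diversity(aln) * aln_length(aln)
  (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Diversity summary for one CPR
#'
#' @inheritParams nucleotide_diversity
#' @return data.frame row with `cpr_id`, `n`, `S`, `pi`, `theta_w`, `tajima_d`.
#' @export
diversity_summary <- function(aln) {
  stopifnot(inherits(aln, "cpr_alignment"))
  data.frame(cpr_id = aln$cpr_id, n = aln_n(aln), S = n_segregating_sites(aln),
             pi = nucleotide_diversity(aln), theta_w = watterson_theta(aln),
             tajima_d = tajimas_d(aln), stringsAsFactors = FALSE)
}

#' Per-CPR diversity table for a collection of alignments
#'
#' @param alignments List of [cpr_alignment()] objects.
#' @param file Optional TSV path; when given the table is also written there.
#' @return data.frame with one row per CPR.
#' @export
diversity_table <- function(alignments, file = NULL) {
  out <- do.call(rbind, lapply(alignments, diversity_summary))
  rownames(out) <- NULL
  if (!is.null(file)) data.table::fwrite(out, file, sep = "\t")
  out
}
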