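#' Group lines into CPR allele classes
#'
#' Lines sharing an identical full-CPR haplotype string share an allele
#' label. Labels (`a`, `b`, ...) are assigned by descending class frequency,
#' breaking ties by lexicographic haplotype order.
#'
#' @param aln A preprocessed [cpr_alignment()].
#' @return Named character vector: line id -> allele label, with attribute
#'   `haplotypes` (named character vector label -> haplotype string).
#' @export
call_alleles <- function(aln) {
  stopifnot(inherits(aln, "cpr_alignment"))
  haps <- as.character(aln)
  tab <- table(haps)
  ord <- order(-as.integer(tab), names(tab))
  hap_sorted <- names(tab)[ord]
  labels <- stats::setNames(.allele_labels(length(hap_sorted)), hap_sorted)
  out <- stats::setNames(unname(labels[haps]), names(haps))
  attr(out, "haplotypes") <- stats::setNames(hap_sorted, unname(labels))
  out
}

.allele_labels <- function(k) {
  if (k <= 26L) letters[seq_len(k)] else
    paste0("a", seq_len(k))
}

#' Fit the expression ~ allele x sex linear model for one transcript
#'
#' Fits `Y = mu + Seq + Sex + Seq:Sex + e` by least squares, where `Seq` is
#' the full-CPR allele class of each line and `Sex` is F/M. Per-term F tests
#' use Type II sums of squares (robust to the mild imbalance caused by line
#' exclusions).
#'
#' @param expr data.frame for one transcript with columns `line`, `sex`
#'   (`"F"`/`"M"`), `replicate`, `value`.
#' @param alleles Named character vector line -> allele label
#'   ([call_alleles()]).
#' @return data.frame with rows `Seq`, `Sex`, `Seq:Sex` and columns `term`,
#'   `F`, `p`, plus a `diagnostic` attribute for degenerate fits.
#' @export
fit_expression_model <- function(expr, alleles) {
  stopifnot(all(c("line", "sex", "value") %in% names(expr)))
  expr <- expr[expr$line %in% names(alleles), , drop = FALSE]
  expr$seq <- factor(alleles[expr$line])
  expr$sex <- factor(expr$sex, levels = c("F", "M"))
  out <- data.frame(term = c("Seq", "Sex", "Seq:Sex"),
                    F = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  diagnostic <- NULL
  if (nlevels(droplevels(expr$seq)) < 2L) {
    diagnostic <- "single allele class; Seq terms undefined"
    # sex term still estimable
    if (nlevels(droplevels(expr$sex)) == 2L && stats::var(expr$value) > 0) {
      fit <- stats::lm(value ~ sex, data = expr)
      an <- stats::anova(fit)
      out$F[out$term == "Sex"] <- an["sex", "F value"]
      out$p[out$term == "Sex"] <- an["sex", "Pr(>F)"]
    }
    attr(out, "diagnostic") <- diagnostic
    return(out)
  }
  if (nlevels(droplevels(expr$sex)) < 2L)
    stop("both sexes must be present")
  fit <- stats::lm(value ~ seq * sex, data = expr)
  if (stats::df.residual(fit) < 1L) {
    attr(out, "diagnostic") <- "no residual degrees of freedom"
    return(out)
  }
  if (stats::sigma(fit) < 1e-12) {
    attr(out, "diagnostic") <- "zero residual variance"
    return(out)
  }
  an <- car::Anova(fit, type = 2)
  map <- c(Seq = "seq", Sex = "sex", `Seq:Sex` = "seq:sex")
  for (i in seq_len(nrow(out))) {
    r <- map[[out$term[i]]]
    out$F[i] <- an[r, "F value"]
    out$p[i] <- an[r, "Pr(>F)"]
  }
  out
}

#' Benjamini-Hochberg adjustment with rejection flags
#'
#' Step-up false-discovery-rate control: adjusted value for the p-value of
#' rank `j` is `min over j' >= j of m * p_(j') / j'`, capped at 1. `NA`
#' p-values pass through unadjusted and do not count toward `m`.
#'
#' @param pvalues Numeric vector in `[0, 1]` (NAs allowed).
#' @param q FDR level for the rejection flags (default 0.05).
#' @return List with `q_values` and logical `reject` (`q_values <= q`).
#' @export
bh_adjust <- function(pvalues, q = 0.05) {
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1)))
    stop("p-values must lie in [0, 1]")
  ok <- !is.na(pvalues)
  qv <- rep(NA_real_, length(pvalues))
  qv[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  list(q_values = qv, reject = !is.na(qv) & qv <= q)
}

#' Association scan across transcripts
#'
#' Fits [fit_expression_model()] for every (transcript, CPR) pair, filters to
#' the configured broad-sense heritability window first, and applies
#' Benjamini-Hochberg control separately per model term (Seq, Sex, Seq:Sex)
#' across transcripts.
#'
#' @param expression data.frame with columns `transcript`, `line`, `sex`,
#'   `replicate`, `value` and optionally `heritability`.
#' @param allele_maps Named list: CPR id -> allele map ([call_alleles()]).
#' @param pairs data.frame with columns `transcript`, `cpr_id` linking
#'   transcripts to the CPR regulating them.
#' @param fdr FDR level (default 0.05).
#' @param h2_range Heritability window applied when a `heritability` column
#'   is present (default `c(0.3, 1.0)`).
#' @return data.frame with one row per (transcript, term): `transcript`,
#'   `cpr_id`, `term`, `F`, `p`, `q`, `significant`.
#' @export
expression_scan <- function(expression, allele_maps, pairs, fdr = 0.05,
                            h2_range = c(0.3, 1.0)) {
  if ("heritability" %in% names(expression)) {
    keep <- expression$heritability >= h2_range[1] &
      expression$heritability <= h2_range[2]
    expression <- expression[keep, , drop = FALSE]
  }
  pairs <- pairs[pairs$transcript %in% unique(expression$transcript), , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    tr <- pairs$transcript[i]; cid <- pairs$cpr_id[i]
    am <- allele_maps[[cid]]
    if (is.null(am)) return(NULL)
    ex <- expression[expression$transcript == tr, , drop = FALSE]
    if (!nrow(ex)) return(NULL)
    res <- fit_expression_model(ex, am)
    cbind(transcript = tr, cpr_id = cid, res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$q <- NA_real_; out$significant <- FALSE
  for (term in unique(out$term)) {
    sel <- out$term == term
    adj <- bh_adjust(out$p[sel], q = fdr)
    out$q[sel] <- adj$q_values
    out$significant[sel] <- adj$reject
  }
  rownames(out) <- NULL
  out
}
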