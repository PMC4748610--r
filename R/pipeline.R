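#' Pipeline configuration
#'
#' Bundles the inputs and the global thresholds of the selection scan:
#' association FDR 5%, flanking-SNP FDR 1%, two-tailed selection P 0.01,
#' +-5000 bp linkage window, +-200 bp depth window with a 2x ratio, and the
#' coalescent null settings.
#'
#' @param cohort Either a [cohort_config()] (a synthetic cohort is generated)
#'   or a `synthetic_cohort`. Mutually exclusive with `input_dir`.
#' @param input_dir Directory holding a cohort in the on-disk layout of
#'   [write_cohort()] (BED + FASTA + VCF + expression TSV + JASPAR motifs +
#'   depth TSVs). Mutually exclusive with `cohort`.
#' @param demography A [demographic_model()], or a YAML path for
#'   [read_demography_yaml()]; default [toy_admixture_model()].
#' @param assoc_fdr FDR for the expression model's terms (default 0.05).
#' @param flank_fdr FDR for flanking-SNP associations (default 0.01).
#' @param selection_p Two-tailed outlier level for Tajima's D (default 0.01).
#' @param flank Linkage window per side in bp (default 5000).
#' @param depth_flank Depth window per side in bp (default 200).
#' @param depth_ratio Depth ratio flagging duplication (default 2).
#' @param ld_boot Bootstrap resamples for D' confidence intervals
#'   (default 1000).
#' @param tree_boot Bootstrap replicates for allele phylogenies
#'   (default 1000).
#' @param null_reps Coalescent replicates for the D null (default 100,000;
#'   scale down for exploratory runs).
#' @param min_lines,maf Preprocessing thresholds (defaults 20 and 0.01).
#' @param seed Seed governing all pipeline randomness.
#' @param outdir Optional directory for per-stage artifacts (TSV).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, input_dir = NULL, demography = NULL,
                            assoc_fdr = 0.05, flank_fdr = 0.01,
                            selection_p = 0.01, flank = 5000,
                            depth_flank = 200, depth_ratio = 2,
                            ld_boot = 1000, tree_boot = 1000,
                            null_reps = 1e5, min_lines = 20, maf = 0.01,
                            seed = 1, outdir = NULL) {
  if (is.null(cohort) == is.null(input_dir))
    stop("give exactly one of `cohort` (synthetic spec) or `input_dir` (real inputs)")
  stopifnot(assoc_fdr > 0, assoc_fdr < 1, flank_fdr > 0, flank_fdr < 1,
            selection_p > 0, selection_p < 1, depth_ratio > 0,
            null_reps >= 1, flank >= 0, depth_flank >= 0)
  if (is.character(demography)) demography <- read_demography_yaml(demography)
  if (is.null(demography)) demography <- toy_admixture_model()
  structure(list(cohort = cohort, input_dir = input_dir,
                 demography = demography, assoc_fdr = assoc_fdr,
                 flank_fdr = flank_fdr, selection_p = selection_p,
                 flank = flank, depth_flank = depth_flank,
                 depth_ratio = depth_ratio, ld_boot = ld_boot,
                 tree_boot = tree_boot, null_reps = null_reps,
                 min_lines = min_lines, maf = maf, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Load a cohort from its on-disk representation
#'
#' Reads the layout produced by [write_cohort()] back into a
#' `synthetic_cohort`-shaped object usable by [run_pipeline()] (the truth
#' record is loaded when present).
#'
#' @param dir Directory path.
#' @return A `synthetic_cohort`-shaped list.
#' @export
load_cohort <- function(dir) {
  intervals <- read_bed(file.path(dir, "cprs.bed"))
  expression <- as.data.frame(data.table::fread(file.path(dir, "expression.tsv")))
  motifs <- read_jaspar(file.path(dir, "motifs.jaspar"))
  alignments <- list(); flanks <- list(); depths <- list()
  vcf <- file.path(dir, "snps.vcf")
  for (i in seq_len(nrow(intervals))) {
    cid <- intervals$cpr_id[i]
    alignments[[cid]] <- read_cpr_fasta(
      file.path(dir, paste0(cid, ".fasta")), cpr_id = cid,
      chrom = intervals$chrom[i], start = intervals$start[i])
    alignments[[cid]]$end <- intervals$end[i]
    if (file.exists(vcf)) {
      h <- read_haplotypes_vcf(vcf, chrom = intervals$chrom[i],
                               cpr_interval = c(intervals$start[i], intervals$end[i]))
      keep <- in_flank_window(h$pos, intervals$start[i], intervals$end[i])
      flanks[[cid]] <- haplotype_matrix(h$geno[, keep, drop = FALSE],
                                        h$pos[keep], chrom = h$chrom,
                                        is_cpr = h$is_cpr[keep])
    }
    dfile <- file.path(dir, paste0("depth_", cid, ".tsv"))
    if (file.exists(dfile)) {
      genes <- data.frame(gene_id = c("geneA", "geneB"),
                          start = c(intervals$start[i] - 900L, intervals$end[i] + 400L),
                          end = c(intervals$start[i] - 400L, intervals$end[i] + 900L))
      depths[[cid]] <- read_depth_tsv(dfile, genes)
    }
  }
  truth_file <- file.path(dir, "truth.yaml")
  truth <- if (file.exists(truth_file)) yaml::read_yaml(truth_file) else NULL
  pairs <- data.frame(transcript = paste0("t_", intervals$cpr_id),
                      cpr_id = intervals$cpr_id, stringsAsFactors = FALSE)
  structure(list(config = NULL, intervals = intervals, alignments = alignments,
                 expression = expression, flanks = flanks, depths = depths,
                 motifs = motifs, pairs = pairs, truth = truth),
            class = "synthetic_cohort")
}

# does any TFBS change event separate lines into binding groups whose mean
# expression differs? (Welch test on line means at `alpha`)
.tfbs_explains_expression <- function(events, alleles, expr, alpha = 0.05) {
  if (!nrow(events)) return(FALSE)
  agg <- stats::aggregate(value ~ line + sex, data = expr, FUN = mean)
  y <- tapply(agg$value, agg$line, mean)
  for (i in seq_len(nrow(events))) {
    bnd <- strsplit(events$bound_alleles[i], ",")[[1]]
    unb <- strsplit(events$unbound_alleles[i], ",")[[1]]
    lb <- names(alleles)[alleles %in% bnd]
    lu <- names(alleles)[alleles %in% unb]
    yb <- y[intersect(lb, names(y))]; yu <- y[intersect(lu, names(y))]
    if (length(yb) >= 2L && length(yu) >= 2L &&
        (stats::var(yb) > 0 || stats::var(yu) > 0)) {
      p <- tryCatch(stats::t.test(yb, yu)$p.value, error = function(e) NA_real_)
      if (!is.na(p) && p < alpha) return(TRUE)
    }
  }
  FALSE
}

#' Run the full selection-scan pipeline
#'
#' Stages, in order: preprocessing, per-CPR diversity, expression ~ allele x
#' sex association with BH control, a shared coalescent Tajima's D null and
#' per-CPR outlier P values, TFBS gain/loss events between alleles,
#' flanking-SNP linkage verdicts, duplication screening, and allele
#' phylogenies for reported candidates. A CPR enters the final selection
#' report only when (a) its Seq term is significant at the association FDR,
#' (b) its Tajima's D is a two-tailed outlier, and (c) at least one TFBS
#' change separates alleles whose expression differs.
#'
#' @param pc A [pipeline_config()].
#' @param verbose Print per-stage counts (default TRUE).
#' @return List of class `selection_scan`: `report` (candidate rows),
#'   `per_cpr` (full per-CPR table), `diversity`, `association`, `null`,
#'   `events`, `linkage`, `duplication`, `trees`, `excluded`, `cohort`.
#' @export
run_pipeline <- function(pc, verbose = TRUE) {
  stopifnot(inherits(pc, "pipeline_config"))
  set.seed(pc$seed)
  say <- function(...) if (verbose) message(sprintf(...))

  cohort <- if (!is.null(pc$input_dir)) load_cohort(pc$input_dir)
    else if (inherits(pc$cohort, "cohort_config")) generate_cohort(pc$cohort)
    else pc$cohort
  n_total <- length(cohort$alignments)
  say("cohort: %d CPRs, %d lines", n_total, nrow(cohort$alignments[[1]]$seq))

  # 1. preprocessing
  pre <- lapply(cohort$alignments, preprocess_alignment,
                maf_threshold = pc$maf, min_lines = pc$min_lines)
  excluded <- Filter(function(x) inherits(x, "cpr_exclusion"), pre)
  alns <- Filter(function(x) inherits(x, "cpr_alignment"), pre)
  say("preprocessing: %d CPRs kept, %d excluded", length(alns), length(excluded))
  if (!length(alns)) {
    return(structure(list(report = .empty_report(), per_cpr = .empty_report(),
                          diversity = NULL, association = NULL, null = NULL,
                          events = list(), linkage = NULL, duplication = NULL,
                          trees = list(), excluded = excluded, cohort = cohort),
                     class = "selection_scan"))
  }

  # 2. diversity
  div <- diversity_table(alns)

  # 3. association
  allele_maps <- lapply(alns, call_alleles)
  assoc <- expression_scan(cohort$expression, allele_maps, cohort$pairs,
                           fdr = pc$assoc_fdr)
  seq_assoc <- assoc[assoc$term == "Seq", , drop = FALSE]
  say("association: %d/%d Seq terms significant at FDR %.0f%%",
      sum(seq_assoc$significant, na.rm = TRUE), nrow(seq_assoc),
      100 * pc$assoc_fdr)

  # 4. shared null + outlier P
  n_null <- nrow(cohort$alignments[[1]]$seq)
  L_null <- ncol(cohort$alignments[[1]]$seq)
  null <- build_null(pc$demography, n = n_null, L = L_null, reps = pc$null_reps)
  say("null: %d usable D values (%d monomorphic runs)",
      length(null$d_values), null$n_s0)
  outl <- lapply(div$cpr_id, function(cid)
    outlier_pvalue(div$tajima_d[div$cpr_id == cid], null, alpha = pc$selection_p))
  names(outl) <- div$cpr_id

  # 5. TFBS events
  events <- list(); n_tfbs <- integer(length(alns)); explains <- logical(length(alns))
  names(n_tfbs) <- names(explains) <- names(alns)
  for (cid in names(alns)) {
    haps <- attr(allele_maps[[cid]], "haplotypes")
    if (length(haps) >= 2L) {
      ev <- tfbs_change_events(scan_alleles(haps, cohort$motifs))
      events[[cid]] <- ev
      n_tfbs[cid] <- attr(ev, "n_motifs_changed")
      tr <- cohort$pairs$transcript[cohort$pairs$cpr_id == cid][1]
      expr <- cohort$expression[cohort$expression$transcript == tr, , drop = FALSE]
      explains[cid] <- .tfbs_explains_expression(ev, allele_maps[[cid]], expr)
    }
  }
  say("TFBS: %d CPRs with >=1 changed motif", sum(n_tfbs > 0))

  # 6. linkage
  linkage <- rep(NA_character_, length(alns)); names(linkage) <- names(alns)
  for (cid in names(alns)) {
    h <- cohort$flanks[[cid]]
    if (is.null(h)) next
    tr <- cohort$pairs$transcript[cohort$pairs$cpr_id == cid][1]
    expr <- cohort$expression[cohort$expression$transcript == tr, , drop = FALSE]
    fa <- flank_association(expr, h, q = pc$flank_fdr)
    blocks <- haplotype_blocks(h, boot = pc$ld_boot)
    linkage[cid] <- linkage_verdict(h, fa, blocks)
  }

  # 7. duplication
  dup <- rep(NA, length(alns)); names(dup) <- names(alns)
  for (cid in names(alns)) {
    tracks <- cohort$depths[[cid]]
    if (is.null(tracks)) next
    iv <- cohort$intervals[cohort$intervals$cpr_id == cid, ]
    calls <- lapply(tracks, detect_duplication,
                    cpr_interval = c(iv$start, iv$end),
                    flank = pc$depth_flank, ratio_threshold = pc$depth_ratio)
    dup[cid] <- any(vapply(calls, function(x) x$flagged, logical(1)))
  }

  # per-CPR table
  per_cpr <- data.frame(
    cpr_id = div$cpr_id,
    transcript = cohort$pairs$transcript[match(div$cpr_id, cohort$pairs$cpr_id)],
    n = div$n, n_alleles = vapply(allele_maps[div$cpr_id], function(a)
      length(unique(a)), integer(1)),
    assoc_q = seq_assoc$q[match(div$cpr_id, seq_assoc$cpr_id)],
    pi = div$pi, tajima_d = div$tajima_d,
    selection_p = vapply(outl, `[[`, numeric(1), "p"),
    verdict = vapply(outl, `[[`, character(1), "verdict"),
    n_tfbs = n_tfbs[div$cpr_id],
    tfbs_explains = explains[div$cpr_id],
    linkage = linkage[div$cpr_id],
    duplication = dup[div$cpr_id],
    stringsAsFactors = FALSE)
  per_cpr$candidate <- !is.na(per_cpr$assoc_q) & per_cpr$assoc_q <= pc$assoc_fdr &
    !is.na(per_cpr$selection_p) & per_cpr$selection_p < pc$selection_p &
    per_cpr$n_tfbs >= 1L & per_cpr$tfbs_explains
  report <- per_cpr[per_cpr$candidate, , drop = FALSE]
  rownames(report) <- rownames(per_cpr) <- NULL
  say("report: %d candidate CPRs", nrow(report))

  # 8. phylogenies for reported candidates
  trees <- list()
  for (cid in report$cpr_id) {
    haps <- attr(allele_maps[[cid]], "haplotypes")
    if (length(haps) >= 3L) {
      trees[[cid]] <- tryCatch(
        bootstrap_support(haps, reps = pc$tree_boot),
        error = function(e) NULL)
    }
  }

  out <- structure(list(report = report, per_cpr = per_cpr, diversity = div,
                        association = assoc, null = null, events = events,
                        linkage = linkage, duplication = dup, trees = trees,
                        excluded = excluded, cohort = cohort),
                   class = "selection_scan")
  if (!is.null(pc$outdir)) .persist_scan(out, pc$outdir)
  out
}

.empty_report <- function() {
  data.frame(cpr_id = character(), transcript = character(), n = integer(),
             n_alleles = integer(), assoc_q = numeric(), pi = numeric(),
             tajima_d = numeric(), selection_p = numeric(),
             verdict = character(), n_tfbs = integer(),
             tfbs_explains = logical(), linkage = character(),
             duplication = logical(), candidate = logical(),
             stringsAsFactors = FALSE)
}

.persist_scan <- function(scan, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) data.table::fwrite(x, file.path(outdir, f), sep = "\t")
  w(scan$report, "report.tsv")
  w(scan$per_cpr, "per_cpr.tsv")
  if (!is.null(scan$diversity)) w(scan$diversity, "diversity.tsv")
  if (!is.null(scan$association) && nrow(scan$association))
    w(scan$association, "association.tsv")
  if (!is.null(scan$null)) write_null_tsv(scan$null, file.path(outdir, "null_d.tsv"))
  ev <- do.call(rbind, lapply(names(scan$events), function(cid) {
    e <- scan$events[[cid]]
    if (is.null(e) || !nrow(e)) return(NULL)
    cbind(cpr_id = cid, e)
  }))
  if (!is.null(ev)) w(ev, "tfbs_events.tsv")
  for (cid in names(scan$trees))
    if (!is.null(scan$trees[[cid]]))
      write_tree_newick(scan$trees[[cid]], file.path(outdir, paste0("tree_", cid, ".nwk")))
  invisible(outdir)
}

#' @export
print.selection_scan <- function(x, ...) {
  cat(sprintf("Selection scan: %d CPRs analysed, %d candidates\n",
              nrow(x$per_cpr), nrow(x$report)))
  if (nrow(x$report)) {
    print(x$report[, c("cpr_id", "assoc_q", "pi", "tajima_d", "selection_p",
                       "verdict", "n_tfbs", "linkage", "duplication")])
  }
  invisible(x)
}
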