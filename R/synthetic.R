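#' Configuration for a synthetic inbred-line cohort
#'
#' Defaults mirror the study conditions the pipeline targets: 29 homozygous
#' lines, CPRs of 160 bp (the panel's median length), a per-site scaled
#' mutation rate giving a handful of segregating sites per CPR, sexed
#' replicated expression with broad-sense heritability inside the 0.3-1.0
#' analysis window, and +-5000 bp flanking haplotypes with tunable linkage
#' to the CPR.
#'
#' @param n_lines Number of homozygous lines (default 29).
#' @param cpr_length CPR length in bp (default 160).
#' @param n_cprs Number of CPRs/transcripts (default 10).
#' @param theta_per_site Scaled mutation rate per site (default 0.0058,
#'   the magnitude observed for this species' natural populations).
#' @param heritability Broad-sense heritability of expression in [0, 1]
#'   (default 0.6).
#' @param sex_effect Additive male-female expression shift (default 1).
#' @param interaction_effect Allele-by-sex interaction shift (default 0).
#' @param n_replicates Replicates per line x sex (default 2; the source
#'   study does not state its replicate count, so it is a free parameter).
#' @param flank_length Flank size per side in bp (default 5000).
#' @param ld_decay Per-bp label-switch probability controlling linkage of
#'   flank SNPs to the CPR (0 = complete linkage; default 2e-4).
#' @param n_flank_snps Flanking SNPs per side (default 6).
#' @param depth_mean Baseline sequencing depth (default 30).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @param selection Character vector (recycled over CPRs) of selection modes
#'   `"neutral"`, `"balancing"`, `"sweep"` planted via
#'   [plant_selection_signal()].
#' @param selection_strength Sites planted per selected CPR (default 6).
#' @param tfbs_pattern Character vector (recycled) of TFBS-change patterns
#'   `NA`, `"I"`, `"II"`, `"III"` planted via [plant_tfbs_effect()].
#' @param expression_effect Numeric vector (recycled): expression shift of
#'   the derived/minor allele group, in residual-SD units of 1.
#' @param duplicate_lines Integer vector (recycled): number of lines per CPR
#'   carrying a 2x duplication over the CPR +- 200 bp (default 0).
#' @param explicit_selection_design When TRUE (default), CPRs with a
#'   non-neutral selection mode are built on a monomorphic background so the
#'   planted haplotype-frequency design (and hence its Tajima's D) is exact;
#'   set FALSE to superimpose planted signals on coalescent backgrounds,
#'   where background rare variants shift D toward zero.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_lines = 29, cpr_length = 160, n_cprs = 10,
                          theta_per_site = 0.0058, heritability = 0.6,
                          sex_effect = 1, interaction_effect = 0,
                          n_replicates = 2, flank_length = 5000,
                          ld_decay = 2e-4, n_flank_snps = 6, depth_mean = 30,
                          seed = 1, selection = "neutral",
                          selection_strength = 6, tfbs_pattern = NA,
                          expression_effect = 0, duplicate_lines = 0L,
                          explicit_selection_design = TRUE) {
  if (n_lines < 2) stop("n_lines must be >= 2")
  if (cpr_length < 1) stop("cpr_length must be >= 1")
  if (n_cprs < 1) stop("n_cprs must be >= 1")
  if (theta_per_site < 0) stop("theta_per_site must be >= 0")
  if (heritability < 0 || heritability > 1) stop("heritability must lie in [0, 1]")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (ld_decay < 0 || ld_decay > 1) stop("ld_decay must lie in [0, 1]")
  structure(list(n_lines = n_lines, cpr_length = cpr_length, n_cprs = n_cprs,
                 theta_per_site = theta_per_site, heritability = heritability,
                 sex_effect = sex_effect, interaction_effect = interaction_effect,
                 n_replicates = n_replicates, flank_length = flank_length,
                 ld_decay = ld_decay, n_flank_snps = n_flank_snps,
                 depth_mean = depth_mean, seed = as.integer(seed),
                 selection = selection, selection_strength = selection_strength,
                 tfbs_pattern = tfbs_pattern,
                 expression_effect = expression_effect,
                 duplicate_lines = as.integer(duplicate_lines),
                 explicit_selection_design = explicit_selection_design),
            class = "cohort_config")
}

#' Plant a selection-like haplotype signal into a CPR alignment
#'
#' `"balancing"` splits the lines into two near-equal haplogroups differing
#' at `strength` sites (intermediate-frequency excess, positive Tajima's D);
#' `"sweep"` adds `strength` singleton sites on distinct lines (rare-variant
#' excess, negative D); `"neutral"` returns the input unchanged. Planted
#' sites use previously monomorphic columns.
#'
#' @param alignment A [cpr_alignment()].
#' @param mode `"balancing"`, `"sweep"` or `"neutral"`.
#' @param strength Number of sites to plant (default 6).
#' @param avoid Optional site indices never used for planting (e.g. an
#'   embedded motif window).
#' @param groupA Optional line ids forming the first balancing haplogroup
#'   (default: the first half of the lines).
#' @param motifs Optional motif-model list; when given, only sites whose
#'   flipped base changes no binding call are used, keeping the planted
#'   frequency-spectrum signal orthogonal to the TFBS analysis.
#' @return The modified alignment, with attribute `planted_sites`.
#' @export
plant_selection_signal <- function(alignment, mode = c("neutral", "balancing", "sweep"),
                                   strength = 6, avoid = integer(0),
                                   groupA = NULL, motifs = NULL) {
  mode <- match.arg(mode)
  if (mode == "neutral") return(alignment)
  L <- aln_length(alignment)
  if (strength > L) stop("strength exceeds alignment length")
  mono <- setdiff(setdiff(seq_len(L), segregating_sites(alignment)), avoid)
  flip <- function(base) c(A = "G", C = "T", G = "A", T = "C", N = "N")[[base]]
  calls <- function(s) {
    pr <- unlist(lapply(motifs, function(m) scan_sequence(m, s)$bound))
    pr
  }
  if (!is.null(motifs)) {
    ref <- alignment$seq[1, ]
    ref_calls <- calls(paste(ref, collapse = ""))
    neutral_site <- vapply(mono, function(s) {
      mut <- ref
      mut[s] <- flip(ref[s])
      identical(calls(paste(mut, collapse = "")), ref_calls)
    }, logical(1))
    mono <- mono[neutral_site]
  }
  if (length(mono) < strength)
    stop("not enough monomorphic sites to plant the signal")
  n <- aln_n(alignment)
  pick <- function(shift) mono[(round(seq(0, length(mono) - 1,
                                          length.out = strength)) + shift) %%
                                 length(mono) + 1L]
  for (shift in 0:(length(mono) - 1L)) {
    sites <- sort(unique(pick(shift)))
    if (length(sites) < strength) next
    cand <- alignment
    if (mode == "balancing") {
      gA <- if (is.null(groupA)) seq_len(ceiling(n / 2))
        else match(groupA, alignment$lines)
      for (s in sites)
        cand$seq[gA, s] <- flip(cand$seq[1, s])
    } else {
      carriers <- rep(seq_len(n), length.out = strength)
      for (k in seq_len(strength))
        cand$seq[carriers[k], sites[k]] <- flip(cand$seq[1, sites[k]])
    }
    if (!is.null(motifs)) {
      # joint check: several planted sites in one window could still move a
      # call across the threshold; compare each line against its own
      # pre-planting haplotype so background variation is untouched
      changed <- vapply(seq_len(n), function(i) {
        if (all(cand$seq[i, ] == alignment$seq[i, ])) return(FALSE)
        !identical(calls(paste(cand$seq[i, ], collapse = "")),
                   calls(paste(alignment$seq[i, ], collapse = "")))
      }, logical(1))
      if (any(changed)) next
    }
    attr(cand, "planted_sites") <- sites
    return(cand)
  }
  stop("could not plant a motif-neutral signal at this strength")
}

#' Plant a TFBS-flipping variant set into a CPR alignment
#'
#' Writes the motif consensus into a window of every line (the ancestral,
#' bound state for loss constructions) and then searches for derived
#' substitutions realizing the requested change pattern: `"I"` one SNP
#' flipping exactly one window call, `"II"` one SNP flipping two or more
#' window calls (e.g. both strands of a palindromic motif), `"III"` a flip
#' that requires at least two co-occurring SNPs. The construction is
#' verified by re-scanning ([minimal_mutation_sets()]); if no substitution
#' set realizes the pattern for this motif an error is thrown.
#'
#' @param alignment A [cpr_alignment()].
#' @param motif A [build_pssm()] motif model with width <= alignment length.
#' @param pattern `"I"`, `"II"` or `"III"`.
#' @param derived_lines Line ids receiving the derived allele (default: the
#'   second half of the lines).
#' @param offset 1-based window start for the embedded motif (default:
#'   centered).
#' @return List with `alignment` (modified), `snps` (data.frame `site`,
#'   `anc`, `der`), `pattern`, `motif_id`, `derived_lines`.
#' @export
plant_tfbs_effect <- function(alignment, motif, pattern = c("I", "II", "III"),
                              derived_lines = NULL, offset = NULL) {
  pattern <- match.arg(pattern)
  w <- motif$width
  L <- aln_length(alignment)
  if (w > L) stop("motif wider than the alignment")
  if (is.null(offset)) offset <- floor((L - w) / 2) + 1L
  stopifnot(offset >= 1L, offset + w - 1L <= L)
  n <- aln_n(alignment)
  if (is.null(derived_lines))
    derived_lines <- alignment$lines[(floor(n / 2) + 1L):n]

  consensus <- .BASES[apply(motif$probs, 2, which.max)]
  alignment$seq[, offset:(offset + w - 1L)] <-
    matrix(consensus, nrow = n, ncol = w, byrow = TRUE)

  # background = majority base per column (ancestral reference sequence)
  bg <- apply(alignment$seq, 2, function(cc) {
    cc <- cc[cc != "N"]
    names(sort(table(cc), decreasing = TRUE))[1]
  })
  anc_seq <- paste(bg, collapse = "")

  try_snps <- function(snps) {
    res <- tryCatch(minimal_mutation_sets(anc_seq, snps, list(motif)),
                    error = function(e) NULL)
    if (is.null(res) || !length(res)) return(FALSE)
    pats <- vapply(res, `[[`, character(1), "pattern")
    if (pattern == "I") all(pats == "I") && length(res) == 1L
    else if (pattern == "II") any(pats == "II")
    else all(pats == "III") && length(res) >= 1L
  }

  cand <- NULL
  if (pattern %in% c("I", "II")) {
    for (j in order(-apply(motif$log_odds, 2, function(cc) max(cc) - min(cc)))) {
      for (b in setdiff(.BASES, consensus[j])) {
        snps <- data.frame(site = offset + j - 1L, anc = consensus[j], der = b,
                           stringsAsFactors = FALSE)
        if (try_snps(snps)) { cand <- snps; break }
      }
      if (!is.null(cand)) break
    }
  } else {
    # pairs of mild single-site penalties that only jointly cross the threshold
    sc0 <- sum(motif$log_odds[cbind(match(consensus, .BASES), seq_len(w))])
    margin <- sc0 - motif$threshold
    drops <- expand.grid(j = seq_len(w), b = .BASES, stringsAsFactors = FALSE)
    drops$pen <- vapply(seq_len(nrow(drops)), function(r) {
      j <- drops$j[r]
      motif$log_odds[match(consensus[j], .BASES), j] -
        motif$log_odds[match(drops$b[r], .BASES), j]
    }, numeric(1))
    drops <- drops[drops$pen > 0 & drops$pen < margin, , drop = FALSE]
    if (nrow(drops) >= 2L) {
      ord <- order(drops$pen)
      for (r1 in ord) for (r2 in ord) {
        if (drops$j[r1] >= drops$j[r2]) next
        if (drops$pen[r1] + drops$pen[r2] <= margin) next
        snps <- data.frame(site = offset + c(drops$j[r1], drops$j[r2]) - 1L,
                           anc = consensus[c(drops$j[r1], drops$j[r2])],
                           der = c(drops$b[r1], drops$b[r2]),
                           stringsAsFactors = FALSE)
        if (try_snps(snps)) { cand <- snps; break }
      }
    }
  }
  if (is.null(cand))
    stop("no substitution set realizes pattern ", pattern,
         " for motif '", motif$motif_id, "' at this offset")

  for (k in seq_len(nrow(cand)))
    alignment$seq[derived_lines, cand$site[k]] <- cand$der[k]
  list(alignment = alignment, snps = cand, pattern = pattern,
       motif_id = motif$motif_id, derived_lines = derived_lines)
}

#' Generate a complete synthetic cohort
#'
#' Produces, per CPR: a coalescent haplotype alignment (with optional
#' planted selection signals and TFBS-flipping variants), flanking SNPs with
#' tunable linkage to the CPR, sexed replicated expression with the
#' configured broad-sense heritability, and per-line depth tracks (with
#' optional 2x duplications). A `truth` record lists every planted effect.
#'
#' Expression decomposes as
#' `Y = mu + line + allele_effect + sex + interaction + noise`, with the
#' polygenic line component variance `h2` and residual variance `1 - h2`,
#' so the between-line variance fraction of a null transcript equals the
#' configured heritability.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort` with elements `config`,
#'   `intervals`, `alignments`, `expression`, `flanks` (per-CPR
#'   [haplotype_matrix()]), `depths` (per-CPR list of [depth_track()]),
#'   `motifs`, `pairs`, and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_lines
  L <- config$cpr_length
  line_ids <- sprintf("line%02d", seq_len(n))
  motifs <- core_promoter_motifs()
  sel_modes <- rep(config$selection, length.out = config$n_cprs)
  patterns <- rep(config$tfbs_pattern, length.out = config$n_cprs)
  effects <- rep(config$expression_effect, length.out = config$n_cprs)
  dups <- rep(config$duplicate_lines, length.out = config$n_cprs)
  neutral <- constant_size_model()

  intervals <- data.frame(
    chrom = "chr2L",
    start = 100000L + (seq_len(config$n_cprs) - 1L) *
      (2L * config$flank_length + L + 2000L),
    cpr_id = sprintf("cpr%03d", seq_len(config$n_cprs)),
    stringsAsFactors = FALSE)
  intervals$end <- intervals$start + L
  intervals <- intervals[, c("chrom", "start", "end", "cpr_id")]

  alignments <- list(); flanks <- list(); depths <- list(); truth_cpr <- list()
  for (i in seq_len(config$n_cprs)) {
    cid <- intervals$cpr_id[i]
    theta_i <- if (sel_modes[i] != "neutral" && config$explicit_selection_design)
      0 else config$theta_per_site * L
    aln <- simulate_sample(neutral, n, L, theta = theta_i, rho = 0)
    rownames(aln$seq) <- line_ids
    aln$lines <- line_ids
    aln$cpr_id <- cid; aln$chrom <- intervals$chrom[i]
    aln$start <- intervals$start[i]; aln$end <- intervals$end[i]

    # TFBS variants first (the consensus window overwrites its columns),
    # then the selection signal on sites outside that window; the derived
    # TFBS lines double as the balancing haplogroup so the two signals mark
    # the same allele split
    tfbs <- NULL
    avoid <- integer(0)
    if (!is.na(patterns[i])) {
      motif <- if (patterns[i] == "II") motifs$MTE else motifs$TATA
      tfbs <- plant_tfbs_effect(aln, motif, patterns[i])
      aln <- tfbs$alignment
      off <- floor((L - motif$width) / 2) + 1L
      avoid <- off:(off + motif$width - 1L)
    }
    aln <- plant_selection_signal(aln, sel_modes[i],
                                  strength = config$selection_strength,
                                  avoid = avoid,
                                  groupA = if (!is.null(tfbs)) tfbs$derived_lines,
                                  motifs = motifs)
    alignments[[cid]] <- aln

    # effect group: derived lines when a TFBS variant is planted, else the
    # minority haplogroup (empty for monomorphic CPRs)
    alleles <- call_alleles(aln)
    group <- if (!is.null(tfbs)) tfbs$derived_lines
      else names(alleles)[alleles != "a"]
    truth_cpr[[cid]] <- list(selection = sel_modes[i],
                             tfbs = if (is.null(tfbs)) NULL else
                               tfbs[c("snps", "pattern", "motif_id", "derived_lines")],
                             expression_effect = effects[i],
                             effect_group = group,
                             duplicated_lines = if (dups[i] > 0L)
                               line_ids[seq_len(dups[i])] else character(0))

    flanks[[cid]] <- .make_flank_matrix(aln, alleles, intervals[i, ], config)
    depths[[cid]] <- .make_depth_tracks(aln, intervals[i, ], config,
                                        truth_cpr[[cid]]$duplicated_lines)
  }

  expression <- .make_expression(alignments, truth_cpr, effects, config, line_ids)
  pairs <- data.frame(transcript = paste0("t_", intervals$cpr_id),
                      cpr_id = intervals$cpr_id, stringsAsFactors = FALSE)
  structure(list(config = config, intervals = intervals,
                 alignments = alignments, expression = expression,
                 flanks = flanks, depths = depths, motifs = motifs,
                 pairs = pairs, truth = truth_cpr),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d lines, %d CPRs of %d bp, %d expression records\n",
              x$config$n_lines, x$config$n_cprs, x$config$cpr_length,
              nrow(x$expression)))
  invisible(x)
}

.make_flank_matrix <- function(aln, alleles, interval, config) {
  n <- aln_n(aln)
  seg <- segregating_sites(aln)
  # CPR SNP columns coded against the majority base
  cpr_geno <- if (length(seg)) {
    sapply(seg, function(s) {
      b <- aln$seq[, s]
      major <- names(sort(table(b[b != "N"]), decreasing = TRUE))[1]
      ifelse(b == "N", NA_integer_, as.integer(b != major))
    })
  } else matrix(integer(0), nrow = n)
  if (is.null(dim(cpr_geno))) cpr_geno <- matrix(cpr_geno, nrow = n)
  cpr_pos <- interval$start + seg  # 1-based

  lab0 <- as.integer(alleles != "a")
  freq1 <- mean(lab0)
  if (freq1 %in% c(0, 1)) { lab0 <- stats::rbinom(n, 1, 0.5); freq1 <- 0.5 }

  walk <- function(dists) {
    cur <- lab0
    cols <- matrix(NA_integer_, nrow = n, ncol = length(dists))
    prev <- 0
    for (k in seq_along(dists)) {
      gap <- dists[k] - prev
      p_sw <- 1 - (1 - config$ld_decay)^gap
      sw <- stats::runif(n) < p_sw
      if (any(sw)) cur[sw] <- stats::rbinom(sum(sw), 1, freq1)
      cols[, k] <- cur
      prev <- dists[k]
    }
    cols
  }
  d_left <- sort(sample.int(config$flank_length, config$n_flank_snps))
  d_right <- sort(sample.int(config$flank_length, config$n_flank_snps))
  g_left <- walk(d_left)[, rev(seq_along(d_left)), drop = FALSE]
  g_right <- walk(d_right)
  pos <- c(interval$start - rev(d_left) + 1L, cpr_pos, interval$end + d_right)
  geno <- cbind(g_left, cpr_geno, g_right)
  rownames(geno) <- aln$lines
  haplotype_matrix(geno, pos, chrom = interval$chrom,
                   is_cpr = c(rep(FALSE, length(d_left)),
                              rep(TRUE, length(cpr_pos)),
                              rep(FALSE, length(d_right))))
}

.make_depth_tracks <- function(aln, interval, config, dup_lines) {
  pad <- 1000L
  pos <- (interval$start - pad + 1L):(interval$end + pad)
  genes <- data.frame(gene_id = c("geneA", "geneB"),
                      start = c(interval$start - 900L, interval$end + 400L),
                      end = c(interval$start - 400L, interval$end + 900L))
  dup_lo <- interval$start - 200L + 1L
  dup_hi <- interval$end + 200L
  # depth is the expected coverage profile (noise-free); a duplication
  # doubles it over the CPR +- 200 bp so the 2x detection rule is exact
  tracks <- lapply(aln$lines, function(id) {
    depth <- rep(config$depth_mean, length(pos))
    if (id %in% dup_lines)
      depth[pos >= dup_lo & pos <= dup_hi] <- 2 * config$depth_mean
    depth_track(id, interval$chrom, pos, depth, genes)
  })
  stats::setNames(tracks, aln$lines)
}

.make_expression <- function(alignments, truth, effects, config, line_ids) {
  h2 <- config$heritability
  sigma_g <- sqrt(h2)
  sigma_e <- sqrt(1 - h2)
  rows <- lapply(names(alignments), function(cid) {
    i <- match(cid, names(alignments))
    group <- truth[[cid]]$effect_group
    line_eff <- stats::setNames(stats::rnorm(length(line_ids), 0, sigma_g), line_ids)
    grid <- expand.grid(line = line_ids, sex = c("F", "M"),
                        replicate = seq_len(config$n_replicates),
                        stringsAsFactors = FALSE)
    in_group <- grid$line %in% group
    male <- grid$sex == "M"
    value <- 10 + line_eff[grid$line] + effects[i] * in_group +
      config$sex_effect * male +
      config$interaction_effect * male * in_group +
      stats::rnorm(nrow(grid), 0, sigma_e)
    data.frame(transcript = paste0("t_", cid), line = grid$line,
               sex = grid$sex, replicate = grid$replicate,
               value = unname(value), heritability = h2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a synthetic cohort to disk in standard formats
#'
#' Emits BED intervals, one FASTA per CPR, a VCF v4.2 of CPR + flank SNPs,
#' the expression TSV, the motif set in JASPAR format, per-CPR
#' samtools-depth-style TSVs, and the truth record as YAML.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(cohort$intervals, file.path(dir, "cprs.bed"))
  for (cid in names(cohort$alignments))
    write_cpr_fasta(cohort$alignments[[cid]], file.path(dir, paste0(cid, ".fasta")))
  data.table::fwrite(cohort$expression, file.path(dir, "expression.tsv"), sep = "\t")
  write_jaspar(cohort$motifs, file.path(dir, "motifs.jaspar"))
  for (cid in names(cohort$depths))
    write_depth_tsv(cohort$depths[[cid]], file.path(dir, paste0("depth_", cid, ".tsv")))
  .write_cohort_vcf(cohort, file.path(dir, "snps.vcf"))
  truth <- lapply(cohort$truth, function(t) {
    if (!is.null(t$tfbs)) t$tfbs$snps <- as.list(t$tfbs$snps)
    t
  })
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

.write_cohort_vcf <- function(cohort, file) {
  con <- file(file, "w")
  on.exit(close(con))
  line_ids <- cohort$alignments[[1]]$lines
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", line_ids), collapse = "\t")), con)
  for (cid in names(cohort$flanks)) {
    h <- cohort$flanks[[cid]]
    for (k in seq_len(ncol(h$geno))) {
      g <- h$geno[line_ids, k]
      gt <- ifelse(is.na(g), "./.", ifelse(g == 1L, "1/1", "0/0"))
      ref <- if (!is.null(h$ref)) h$ref[k] else "A"
      alt <- if (!is.null(h$alt)) h$alt[k] else "T"
      writeLines(paste(c(h$chrom, h$pos[k], paste0(cid, "_s", k), ref, alt,
                         ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
    }
  }
  invisible(file)
}
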