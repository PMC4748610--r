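#' Build a log-odds PSSM from a count matrix
#'
#' Log-odds are taken against a background in which, by default, A, C, G and
#' T are equally likely: `log2((count + pc) / (colsum + 4 pc) / bg)`.
#'
#' @param counts 4 x width nonnegative count matrix, rows A, C, G, T.
#' @param pseudocount Added to every cell (default 0.5; avoids infinite
#'   log-odds).
#' @param background Background base probabilities in A, C, G, T order
#'   (default uniform).
#' @param motif_id Motif identifier.
#' @param rate_ratio Target false-negative/false-positive rate ratio for the
#'   balanced threshold (default 1000).
#' @param threshold Optional explicit score threshold (bits); computed by
#'   [balanced_threshold()] when `NULL`.
#' @return Object of class `motif_model` with `motif_id`, `counts`,
#'   `pseudocount`, `background`, `log_odds`, `probs` (motif base
#'   probabilities), `width`, `rate_ratio`, `threshold`.
#' @export
build_pssm <- function(counts, pseudocount = 0.5,
                       background = rep(0.25, 4), motif_id = "motif",
                       rate_ratio = 1000, threshold = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("count matrix must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(colSums(counts) + 4 * pseudocount <= 0))
    stop("all-zero column with zero pseudocount")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0))
    stop("background must be 4 positive probabilities summing to 1")
  rownames(counts) <- c("A", "C", "G", "T")
  probs <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  log_odds <- log2(probs / background)
  m <- structure(list(motif_id = motif_id, counts = counts,
                      pseudocount = pseudocount, background = background,
                      probs = probs, log_odds = log_odds,
                      width = ncol(counts), rate_ratio = rate_ratio,
                      threshold = threshold),
                 class = "motif_model")
  if (is.null(threshold)) m$threshold <- balanced_threshold(m, rate_ratio)
  m
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("PSSM '%s': width %d, balanced threshold %.3f bits (FNR/FPR target %g)\n",
              x$motif_id, x$width, x$threshold, x$rate_ratio))
  invisible(x)
}

# exact score distribution over discretized bins by positional convolution;
# returns list(score = numeric bin values, p = probabilities)
.score_distribution <- function(log_odds, base_probs, bin = 0.01) {
  ilo <- round(log_odds / bin)
  lo_off <- sum(apply(ilo, 2, min))
  hi_off <- sum(apply(ilo, 2, max))
  p <- numeric(hi_off - lo_off + 1L)  # index = score_bin - lo_off + 1
  p[1L] <- 1
  cur_lo <- 0L
  for (j in seq_len(ncol(ilo))) {
    width_j <- sum(apply(ilo[, seq_len(j), drop = FALSE], 2, max)) -
      sum(apply(ilo[, seq_len(j), drop = FALSE], 2, min)) + 1L
    newp <- numeric(length(p))
    for (b in 1:4) {
      shift <- ilo[b, j] - min(ilo[, j])
      pr <- base_probs[b, j]
      if (pr > 0) {
        idx <- seq_len(length(p) - shift)
        newp[idx + shift] <- newp[idx + shift] + p[idx] * pr
      }
    }
    p <- newp
  }
  list(score = (seq_along(p) - 1L + lo_off) * bin, p = p)
}

#' Balanced score threshold of a PSSM
#'
#' Exact score distributions are computed by position-wise convolution over
#' discretized scores, under (a) the background base distribution and (b) the
#' motif's own base probabilities. Per-cell scores are discretized to
#' `bin / width` so the accumulated window-score quantization error stays
#' below one `bin`. The threshold is the achievable score cutoff `t`
#' (binding call: score >= t) at which `FNR(t) / FPR(t)` is closest to
#' `rate_ratio` on the log scale, where `FNR(t) = P_motif(score < t)` and
#' `FPR(t) = P_background(score >= t)`.
#'
#' @param model A [build_pssm()] motif model (threshold field may be unset).
#' @param rate_ratio Target FNR/FPR ratio (default 1000).
#' @param bin Score resolution in bits (default 0.01).
#' @return Threshold in bits.
#' @export
balanced_threshold <- function(model, rate_ratio = 1000, bin = 0.01) {
  stopifnot(inherits(model, "motif_model"), rate_ratio > 0, bin > 0)
  ibin <- bin / model$width
  bgm <- matrix(model$background, nrow = 4, ncol = model$width)
  bg <- .score_distribution(model$log_odds, bgm, ibin)
  mo <- .score_distribution(model$log_odds, model$probs, ibin)
  support <- sort.int(unique.default(c(bg$score[bg$p > 0], mo$score[mo$p > 0])))
  if (length(support) < 2L)
    stop("degenerate PSSM: single achievable score, no threshold exists")
  # candidate thresholds: each achievable score (call iff score >= t)
  fpr <- vapply(support, function(t) sum(bg$p[bg$score >= t - ibin / 2]), numeric(1))
  fnr <- vapply(support, function(t) sum(mo$p[mo$score < t - ibin / 2]), numeric(1))
  ok <- fpr > 0 & fnr > 0
  if (!any(ok)) {  # distributions separate perfectly; take the gap boundary
    return(support[which.max(fpr < 1)])
  }
  dist <- abs(log(fnr[ok] / fpr[ok]) - log(rate_ratio))
  support[ok][which.min(dist)]
}

#' False-positive and false-negative rates of a PSSM at a threshold
#'
#' Rates are evaluated on the same discretized score distributions used by
#' [balanced_threshold()] (per-cell resolution `bin / width`):
#' `FPR = P_background(score >= t)`, `FNR = P_motif(score < t)`.
#'
#' @inheritParams balanced_threshold
#' @param threshold Score threshold in bits (default: the model's own).
#' @return List `fpr`, `fnr`.
#' @export
threshold_rates <- function(model, threshold = model$threshold, bin = 0.01) {
  stopifnot(inherits(model, "motif_model"))
  ibin <- bin / model$width
  bgm <- matrix(model$background, nrow = 4, ncol = model$width)
  bg <- .score_distribution(model$log_odds, bgm, ibin)
  mo <- .score_distribution(model$log_odds, model$probs, ibin)
  list(fpr = sum(bg$p[bg$score >= threshold - ibin / 2]),
       fnr = sum(mo$p[mo$score < threshold - ibin / 2]))
}

.BASES <- c("A", "C", "G", "T")
.revcomp <- function(s) chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))

# score every window of coded sequence (codes 1..4, NA for N) on one strand
.scan_codes <- function(codes, log_odds) {
  w <- ncol(log_odds)
  L <- length(codes)
  if (L < w) return(numeric(0))
  nwin <- L - w + 1L
  sc <- numeric(nwin)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + nwin - 1L)]
    v <- log_odds[, j][cj]          # NA codes propagate NA
    sc <- sc + v
  }
  sc
}

#' Scan a sequence with a PSSM on both strands
#'
#' Positions are 0-based offsets of the motif window start on the template
#' strand; a minus-strand hit at position `p` covers template bases
#' `p .. p + width - 1` read on the complementary strand. Windows containing
#' `N` score `NA` and are never called bound.
#'
#' @param model A [build_pssm()] motif model.
#' @param sequence Character string over A, C, G, T, N.
#' @return data.frame (`motif_id`, `position`, `strand`, `score`, `bound`).
#'   Empty (zero rows) when the sequence is shorter than the motif.
#' @export
scan_sequence <- function(model, sequence) {
  stopifnot(inherits(model, "motif_model"))
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  w <- model$width
  empty <- data.frame(motif_id = character(), position = integer(),
                      strand = character(), score = numeric(), bound = logical())
  if (L < w) return(empty)
  fwd <- match(strsplit(sequence, "")[[1]], .BASES)
  rev <- match(strsplit(.revcomp(sequence), "")[[1]], .BASES)
  sc_f <- .scan_codes(fwd, model$log_odds)
  sc_r <- .scan_codes(rev, model$log_odds)
  nwin <- L - w + 1L
  # minus-strand window i (on revcomp) starts at template offset L - w - (i-1)
  out <- data.frame(
    motif_id = model$motif_id,
    position = c(seq_len(nwin) - 1L, L - w - (seq_len(nwin) - 1L)),
    strand = rep(c("+", "-"), each = nwin),
    score = c(sc_f, sc_r),
    stringsAsFactors = FALSE)
  out$bound <- !is.na(out$score) & out$score >= model$threshold
  out[order(out$strand, out$position), , drop = FALSE]
}

#' Scan all alleles of a CPR with a set of motifs
#'
#' @param alleles Named character vector: allele label -> sequence.
#' @param motifs List of [build_pssm()] models.
#' @return Nested list `profiles[[allele]][[motif_id]]`, each a
#'   [scan_sequence()] data.frame.
#' @export
scan_alleles <- function(alleles, motifs) {
  if (is.null(names(alleles))) names(alleles) <- letters[seq_along(alleles)]
  lapply(alleles, function(s) {
    pr <- lapply(motifs, scan_sequence, sequence = s)
    names(pr) <- vapply(motifs, function(m) m$motif_id, character(1))
    pr
  })
}

#' TFBS gain/loss events between alleles of one CPR
#'
#' An event is a (motif, position, strand) window whose binding call differs
#' among alleles (at least one bound and one unbound; `NA` scores are
#' ignored). The per-CPR "number of TFBSs changed" is the number of distinct
#' motifs with at least one event.
#'
#' @param profiles Output of [scan_alleles()] for >= 2 alleles.
#' @param ancestral Optional allele label; when given, each event's
#'   `direction` is `"gain"` if the ancestral allele is unbound there,
#'   `"loss"` if bound, else `NA`.
#' @return data.frame (`motif_id`, `position`, `strand`, `bound_alleles`,
#'   `unbound_alleles`, `direction`) with attribute `n_motifs_changed`.
#' @export
tfbs_change_events <- function(profiles, ancestral = NULL) {
  stopifnot(length(profiles) >= 2L)
  labs <- names(profiles)
  motif_ids <- names(profiles[[1]])
  for (pr in profiles) {
    if (!identical(names(pr), motif_ids))
      stop("alleles profiled with different motif sets")
    for (mid in motif_ids)
      if (nrow(pr[[mid]]) != nrow(profiles[[1]][[mid]]))
        stop("allele profile lengths differ; alleles must be equal length")
  }
  rows <- list()
  for (mid in motif_ids) {
    base <- profiles[[1]][[mid]]
    if (nrow(base) == 0L) next
    calls <- vapply(labs, function(a) {
      p <- profiles[[a]][[mid]]
      ifelse(is.na(p$score), NA, p$bound)
    }, logical(nrow(base)))
    if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1L, dimnames = list(NULL, labs))
    for (i in seq_len(nrow(base))) {
      cc <- calls[i, ]
      if (any(cc %in% TRUE) && any(cc %in% FALSE)) {
        bnd <- labs[which(cc %in% TRUE)]; unb <- labs[which(cc %in% FALSE)]
        dir <- NA_character_
        if (!is.null(ancestral) && ancestral %in% c(bnd, unb))
          dir <- if (ancestral %in% unb) "gain" else "loss"
        rows[[length(rows) + 1L]] <- data.frame(
          motif_id = mid, position = base$position[i], strand = base$strand[i],
          bound_alleles = paste(bnd, collapse = ","),
          unbound_alleles = paste(unb, collapse = ","),
          direction = dir, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_id = character(), position = integer(), strand = character(),
               bound_alleles = character(), unbound_alleles = character(),
               direction = character(), stringsAsFactors = FALSE)
  attr(out, "n_motifs_changed") <- length(unique(out$motif_id))
  out
}

#' Minimal SNP sets that flip TFBS calls, with pattern classification
#'
#' All `2^k` combinations of the `k` derived SNPs are applied to the
#' ancestral sequence and rescanned. For every (motif, position, strand)
#' window whose binding call differs anywhere from the ancestral call, the
#' minimal SNP subsets that flip it are enumerated. Patterns follow the
#' field's classification: `I` = a single SNP flips exactly one window
#' change; `II` = a single SNP flips two or more; `III` = every minimal
#' flipping subset needs two or more SNPs.
#'
#' @param ancestral Ancestral sequence (string).
#' @param snps data.frame with columns `site` (1-based), `anc`, `der`.
#' @param motifs List of motif models.
#' @param cap Refuse more than this many SNPs (default 12; the enumeration
#'   is exponential in `k`).
#' @return List of per-event results: `motif_id`, `position`, `strand`,
#'   `direction`, `minimal_sets` (list of integer vectors of SNP indices),
#'   `pattern`.
#' @export
minimal_mutation_sets <- function(ancestral, snps, motifs, cap = 12) {
  k <- nrow(snps)
  if (k == 0L) return(list())
  if (k > cap) stop("refusing to enumerate 2^", k, " mutation combinations (cap ", cap, ")")
  anc_chars <- strsplit(toupper(ancestral), "")[[1]]
  if (any(anc_chars[snps$site] != toupper(snps$anc)))
    stop("ancestral bases in `snps` do not match the ancestral sequence")
  masks <- 0:(2^k - 1L)
  seqs <- vapply(masks, function(m) {
    ch <- anc_chars
    on <- which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0L)
    ch[snps$site[on]] <- toupper(snps$der[on])
    paste(ch, collapse = "")
  }, character(1))
  # only windows overlapping a SNP can change; scan all (L small) for clarity
  prof0 <- lapply(motifs, scan_sequence, sequence = seqs[1])
  call_key <- function(pr) pr$bound
  calls <- lapply(seq_along(seqs), function(i)
    lapply(motifs, scan_sequence, sequence = seqs[i]))
  results <- list()
  for (mi in seq_along(motifs)) {
    base <- prof0[[mi]]
    if (nrow(base) == 0L) next
    cmat <- vapply(calls, function(cl) cl[[mi]]$bound, logical(nrow(base)))
    if (is.null(dim(cmat))) cmat <- matrix(cmat, nrow = 1L)
    changed <- which(apply(cmat, 1L, function(r) any(r != r[1])))
    for (i in changed) {
      flips <- which(cmat[i, ] != cmat[i, 1]) - 1L   # masks that flip
      minimal <- integer(0)
      for (m in flips) {
        sub <- flips[flips != m & bitwAnd(flips, m) == flips]
        if (!length(sub)) minimal <- c(minimal, m)
      }
      min_sets <- lapply(minimal, function(m)
        which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0L))
      results[[length(results) + 1L]] <- list(
        motif_id = motifs[[mi]]$motif_id, position = base$position[i],
        strand = base$strand[i],
        direction = if (cmat[i, 1]) "loss" else "gain",
        minimal_sets = min_sets, pattern = NA_character_)
    }
  }
  # classify patterns across events
  singleton_counts <- table(unlist(lapply(results, function(r) {
    s <- r$minimal_sets[vapply(r$minimal_sets, length, integer(1)) == 1L]
    unique(unlist(s))
  })))
  for (i in seq_along(results)) {
    sizes <- vapply(results[[i]]$minimal_sets, length, integer(1))
    if (all(sizes >= 2L)) {
      results[[i]]$pattern <- "III"
    } else {
      singles <- unique(unlist(results[[i]]$minimal_sets[sizes == 1L]))
      n_ev <- max(singleton_counts[as.character(singles)])
      results[[i]]$pattern <- if (n_ev >= 2L) "II" else "I"
    }
  }
  results
}

#' Read motifs from a JASPAR-format file
#'
#' Accepts both common count-matrix dialects: `>ID name` headers followed by
#' four labelled rows (`A [ 1 2 3 ]`) or four unlabelled whitespace-separated
#' rows in A, C, G, T order.
#'
#' @param file Path to a JASPAR motif file.
#' @inheritParams build_pssm
#' @return List of [build_pssm()] motif models.
#' @export
read_jaspar <- function(file, pseudocount = 0.5, background = rep(0.25, 4),
                        rate_ratio = 1000) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '>' headers found: not a JASPAR motif file")
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (h in seq_along(heads)) {
    id <- trimws(sub("^>\\s*", "", lines[heads[h]]))
    id <- strsplit(id, "\\s+")[[1]][1]
    body <- lines[(bounds[h] + 1L):(bounds[h + 1L] - 1L)]
    if (length(body) < 4L) stop("motif '", id, "': expected 4 matrix rows")
    rows <- lapply(body[1:4], function(ln) {
      lab <- sub("^\\s*([ACGTacgt])[\\s\\[].*$", "\\1", ln, perl = TRUE)
      nums <- gsub("[^0-9.eE+-]", " ", sub("^\\s*[ACGTacgt]?", "", ln, perl = TRUE))
      vals <- as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
      list(lab = if (grepl("^[ACGTacgt]$", lab)) toupper(lab) else NA_character_,
           vals = vals)
    })
    mat <- do.call(rbind, lapply(rows, `[[`, "vals"))
    labs <- vapply(rows, `[[`, character(1), "lab")
    if (!anyNA(labs)) mat <- mat[match(c("A", "C", "G", "T"), labs), , drop = FALSE]
    out[[id]] <- build_pssm(mat, pseudocount = pseudocount,
                            background = background, motif_id = id,
                            rate_ratio = rate_ratio)
  }
  out
}

#' Write motif count matrices in JASPAR format
#'
#' @param motifs List of motif models.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_jaspar <- function(motifs, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", m$motif_id, " ", m$motif_id), con)
    for (b in 1:4) {
      writeLines(sprintf("%s  [ %s ]", .BASES[b],
                         paste(sprintf("%.17g", m$counts[b, ]), collapse = " ")),
                 con)
    }
  }
  invisible(file)
}

#' Bundled toy core-promoter motif set
#'
#' Five small count matrices named after core promoter elements (TATA, Inr,
#' DPE, BREd, MTE). These are synthetic toy matrices for testing and
#' simulation, not the curated JASPAR POLII matrices; real matrices should be
#' loaded from a JASPAR file with [read_jaspar()]. The toy MTE matrix is
#' palindromic so that single variants can flip calls on both strands.
#'
#' @inheritParams build_pssm
#' @return Named list of motif models.
#' @export
core_promoter_motifs <- function(pseudocount = 0.5, rate_ratio = 1000) {
  # per-column consensus counts out of 20 observations; mixing strong and
  # weak columns gives a spread of mutation penalties, so single variants
  # can flip calls at some sites while others require combinations
  mk <- function(consensus, id, conc) {
    b <- strsplit(consensus, "")[[1]]
    counts <- matrix(0, nrow = 4, ncol = length(b),
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(b)) {
      counts[, j] <- (20 - conc[j]) / 3
      counts[b[j], j] <- conc[j]
    }
    build_pssm(counts, pseudocount = pseudocount, motif_id = id,
               rate_ratio = rate_ratio)
  }
  list(TATA = mk("TATAAAAG", "TATA", c(10, 18, 11, 10, 13, 18, 13, 12)),
       Inr = mk("TCAGTCT", "Inr", c(17, 13, 17, 12, 17, 13, 17)),
       DPE = mk("AGACGTG", "DPE", c(17, 17, 13, 17, 12, 17, 14)),
       BREd = mk("GTTTGTT", "BREd", c(14, 17, 12, 17, 17, 13, 17)),
       MTE = mk("TTATATAA", "MTE", rep(17, 8)))
}
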