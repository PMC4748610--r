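#' Read a FASTQ file (Sanger Phred+33)
#'
#' @param file FASTQ path.
#' @return A `Biostrings::QualityScaledDNAStringSet`.
#' @export
read_fastq <- function(file) {
  # the reader attaches a metadata column it immediately drops again when
  # rebuilding the quality-scaled set; that warning is uninformative here
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(file, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns.*dropped", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Write reads to FASTQ (Sanger Phred+33)
#'
#' @param reads A `QualityScaledDNAStringSet`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fastq <- function(reads, file) {
  Biostrings::writeQualityScaledXStringSet(reads, file)
  invisible(file)
}

#' Quality-filter reads: low-quality-read removal and 3' trimming
#'
#' Two sequential, independent criteria, applied to each read:
#' \enumerate{
#'   \item a read is dropped when at least `low_frac` of its (pre-trim)
#'     bases have quality below `low_q`;
#'   \item the maximal 3' suffix in which every base has quality below
#'     `trim_q` is removed, i.e. the read is truncated at its last base with
#'     quality >= `trim_q`; reads left empty are dropped.
#' }
#'
#' @param reads A `QualityScaledDNAStringSet` (see [read_fastq()]).
#' @param trim_q 3' trimming quality (default 10).
#' @param low_q Low-quality threshold for the site fraction rule (default 20).
#' @param low_frac Fraction of low-quality sites that drops a read
#'   (default 0.8).
#' @return Filtered (possibly trimmed) `QualityScaledDNAStringSet`.
#' @export
filter_reads <- function(reads, trim_q = 10, low_q = 20, low_frac = 0.8) {
  if (!length(reads)) return(reads)
  quals <- as(Biostrings::quality(reads), "IntegerList")
  widths <- Biostrings::width(reads)
  keep <- logical(length(reads))
  ends <- integer(length(reads))
  for (i in seq_along(reads)) {
    qi <- quals[[i]]
    if (sum(qi < low_q) >= low_frac * widths[i]) next
    good <- which(qi >= trim_q)
    if (!length(good)) next
    keep[i] <- TRUE
    ends[i] <- max(good)
  }
  if (!any(keep)) return(reads[0])
  trimmed <- Biostrings::subseq(reads[keep], start = 1L, end = ends[keep])
  trimmed
}

#' Build a per-line depth track
#'
#' @param line_id Line identifier.
#' @param chrom Chromosome name.
#' @param pos 1-based positions.
#' @param depth Read depth per position.
#' @param genes data.frame of gene intervals on the chromosome with columns
#'   `start`, `end` (0-based half-open) and optionally `gene_id`; used for
#'   the chromosome-average normalizer.
#' @return Object of class `depth_track`.
#' @export
depth_track <- function(line_id, chrom, pos, depth, genes) {
  stopifnot(length(pos) == length(depth), all(depth >= 0))
  structure(list(line_id = line_id, chrom = chrom, pos = as.integer(pos),
                 depth = as.numeric(depth), genes = genes),
            class = "depth_track")
}

#' Read samtools-depth-style TSV into depth tracks
#'
#' Expected columns: chrom, 1-based position, then one depth column per
#' line (header row giving line ids, or ids supplied via `line_ids`).
#'
#' @param file TSV path.
#' @param genes Gene intervals (see [depth_track()]).
#' @param line_ids Optional line ids when the file has no header.
#' @return Named list of [depth_track()] objects.
#' @export
read_depth_tsv <- function(file, genes, line_ids = NULL) {
  dt <- data.table::fread(file)
  if (!is.null(line_ids)) {
    data.table::setnames(dt, c("chrom", "pos", line_ids))
  } else {
    data.table::setnames(dt, 1:2, c("chrom", "pos"))
    line_ids <- names(dt)[-(1:2)]
  }
  out <- lapply(line_ids, function(id)
    depth_track(id, dt$chrom[1], dt$pos, dt[[id]], genes))
  stats::setNames(out, line_ids)
}

#' Write depth tracks as a samtools-depth-style TSV
#'
#' @param tracks Named list of [depth_track()] objects over identical
#'   positions.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_depth_tsv <- function(tracks, file) {
  base <- tracks[[1]]
  df <- data.table::data.table(chrom = base$chrom, pos = base$pos)
  for (t in tracks) df[[t$line_id]] <- t$depth
  data.table::fwrite(df, file, sep = "\t")
  invisible(file)
}

#' Screen a CPR for allele-specific duplication by read depth
#'
#' The mean depth over the CPR plus `flank` bp on each side is compared with
#' the unweighted mean of per-gene mean depths on the same chromosome; a
#' ratio of at least `ratio_threshold` (default 2, i.e. doubled depth)
#' flags a candidate duplication in that line.
#'
#' @param track A [depth_track()].
#' @param cpr_interval `c(start, end)`, 0-based half-open.
#' @param flank Flank size in bp (default 200).
#' @param ratio_threshold Depth ratio that flags a duplication (default 2).
#' @return data.frame (`line_id`, `region_depth`, `chrom_gene_depth`,
#'   `ratio`, `flagged`).
#' @export
detect_duplication <- function(track, cpr_interval, flank = 200,
                               ratio_threshold = 2) {
  stopifnot(inherits(track, "depth_track"))
  lo <- cpr_interval[1] - flank + 1L   # 1-based inclusive
  hi <- cpr_interval[2] + flank
  sel <- track$pos >= lo & track$pos <= hi
  if (!any(sel)) stop("no depth defined over the CPR +- flank region")
  region_depth <- mean(track$depth[sel])
  gene_means <- vapply(seq_len(nrow(track$genes)), function(k) {
    gsel <- track$pos > track$genes$start[k] & track$pos <= track$genes$end[k]
    if (!any(gsel)) return(NA_real_)
    mean(track$depth[gsel])
  }, numeric(1))
  gene_means <- gene_means[!is.na(gene_means)]
  if (!length(gene_means) || mean(gene_means) == 0)
    stop("chromosome gene-average depth is zero or undefined")
  chrom_depth <- mean(gene_means)
  ratio <- region_depth / chrom_depth
  data.frame(line_id = track$line_id, region_depth = region_depth,
             chrom_gene_depth = chrom_depth, ratio = ratio,
             flagged = ratio >= ratio_threshold, stringsAsFactors = FALSE)
}
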