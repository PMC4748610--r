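#' Construct a core promoter region (CPR) alignment
#'
#' A `cpr_alignment` holds one aligned haplotype per inbred line for a single
#' core promoter region. All sequences must have equal length and use the
#' alphabet `A`, `C`, `G`, `T`, `N` (`N` marks undetermined nucleotides).
#' Coordinates are 0-based half-open, as in BED.
#'
#' @param sequences Named character vector of equal-length haplotype strings,
#'   one per line; names are line identifiers. A character matrix of single
#'   bases (rows = lines) is also accepted.
#' @param cpr_id Identifier for the region.
#' @param chrom Chromosome / contig name.
#' @param start,end 0-based half-open genomic interval. Defaults to
#'   `0..L`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `cpr_alignment` with elements `cpr_id`, `chrom`,
#'   `start`, `end`, `strand`, `lines` and `seq` (character matrix of single
#'   bases, rows named by line).
#' @export
cpr_alignment <- function(sequences, cpr_id = "cpr", chrom = "chr",
                          start = NULL, end = NULL, strand = "+") {
  if (is.matrix(sequences)) {
    mat <- sequences
    if (is.null(rownames(mat))) rownames(mat) <- paste0("line", seq_len(nrow(mat)))
  } else {
    nm <- names(sequences)          # toupper() drops attributes
    sequences <- toupper(as.character(sequences))
    if (is.null(nm) && length(sequences))
      nm <- paste0("line", seq_along(sequences))
    if (!is.null(nm)) names(sequences) <- nm
    L <- unique(nchar(sequences))
    if (length(L) > 1L) stop("all sequences must have equal length")
    mat <- matrix("", nrow = length(sequences), ncol = if (length(L)) L else 0L,
                  dimnames = list(names(sequences), NULL))
    if (length(sequences) && L > 0L) {
      mat[] <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
    }
  }
  if (anyDuplicated(rownames(mat))) stop("line identifiers must be unique")
  bad <- setdiff(unique.default(as.vector(mat)), c("A", "C", "G", "T", "N"))
  if (length(bad)) stop("invalid characters in alignment: ", paste(bad, collapse = ","))
  if (is.null(start)) start <- 0L
  if (is.null(end)) end <- start + ncol(mat)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(cpr_id = cpr_id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 lines = rownames(mat), seq = mat),
            class = "cpr_alignment")
}

#' @export
print.cpr_alignment <- function(x, ...) {
  cat(sprintf("CPR alignment '%s' (%s:%d-%d%s): %d lines x %d bp, S = %d\n",
              x$cpr_id, x$chrom, x$start, x$end, x$strand,
              nrow(x$seq), ncol(x$seq), n_segregating_sites(x)))
  invisible(x)
}

#' @export
as.character.cpr_alignment <- function(x, ...) {
  stats::setNames(apply(x$seq, 1L, paste, collapse = ""), x$lines)
}

aln_length <- function(aln) ncol(aln$seq)
aln_n <- function(aln) nrow(aln$seq)

#' Segregating-site positions of an alignment
#'
#' A site segregates when at least two distinct non-`N` bases occur among the
#' lines.
#'
#' @param aln A [cpr_alignment()].
#' @return Integer vector of 1-based column indices.
#' @export
segregating_sites <- function(aln) {
  if (aln_n(aln) < 2L || aln_length(aln) == 0L) return(integer())
  counts <- .base_counts(aln$seq)
  which(colSums(counts > 0L) >= 2L)
}

# 4 x L matrix of per-site A/C/G/T counts (N ignored)
.base_counts <- function(mat) {
  rbind(A = colSums(mat == "A"), C = colSums(mat == "C"),
        G = colSums(mat == "G"), T = colSums(mat == "T"))
}

#' @rdname segregating_sites
#' @return `n_segregating_sites()`: the count S.
#' @export
n_segregating_sites <- function(aln) length(segregating_sites(aln))

#' Read per-line CPR haplotypes from a FASTA file
#'
#' One record per line identifier; all records must be equal length.
#'
#' @param file Path to a FASTA file.
#' @inheritParams cpr_alignment
#' @return A [cpr_alignment()].
#' @export
read_cpr_fasta <- function(file, cpr_id = sub("\\.[^.]*$", "", basename(file)),
                           chrom = "chr", start = NULL, strand = "+") {
  x <- Biostrings::readDNAStringSet(file)
  cpr_alignment(stats::setNames(as.character(x), names(x)), cpr_id = cpr_id,
                chrom = chrom, start = start, strand = strand)
}

#' Write a CPR alignment to FASTA
#'
#' @param aln A [cpr_alignment()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_cpr_fasta <- function(aln, file) {
  seqs <- as.character(aln)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = file)
  invisible(file)
}

#' Reconstruct CPR alignments from homozygous VCF calls plus a reference
#'
#' Lines are inbred and homozygous, so each line's haplotype is the reference
#' sequence with its ALT alleles substituted. Genotypes other than 0/0 and
#' 1/1 (or haploid 0 / 1) become `N`; missing genotypes become `N`.
#'
#' @param vcf_file VCF (v4.x) with one column per line.
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `cpr_id`
#'   (0-based half-open), e.g. from [read_bed()].
#' @param ref_seqs Named character vector: reference sequence of each interval,
#'   named by `cpr_id`.
#' @return List of [cpr_alignment()] objects, one per interval.
#' @export
read_cpr_vcf <- function(vcf_file, intervals, ref_seqs) {
  v <- vcfR::read.vcfR(vcf_file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  fix$POS <- as.integer(fix$POS)
  gt <- vcfR::extract.gt(v)
  lapply(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    ref <- toupper(ref_seqs[[iv$cpr_id]])
    L <- nchar(ref)
    if (L != iv$end - iv$start) stop("reference length does not match interval ", iv$cpr_id)
    base <- strsplit(ref, "")[[1]]
    mat <- matrix(rep(base, each = ncol(gt)), nrow = ncol(gt),
                  dimnames = list(colnames(gt), NULL))
    sel <- which(fix$CHROM == iv$chrom & fix$POS > iv$start & fix$POS <= iv$end)
    for (k in sel) {
      col <- fix$POS[k] - iv$start          # 1-based offset in interval
      g <- gt[k, ]
      allele <- rep("N", length(g))
      allele[!is.na(g) & g %in% c("0", "0/0", "0|0")] <- fix$REF[k]
      allele[!is.na(g) & g %in% c("1", "1/1", "1|1")] <- fix$ALT[k]
      allele[nchar(allele) != 1L] <- "N"    # indels / multibase -> undetermined
      mat[, col] <- allele
    }
    cpr_alignment(mat, cpr_id = iv$cpr_id, chrom = iv$chrom,
                  start = iv$start, end = iv$end)
  })
}

#' Read CPR intervals from a BED file
#'
#' @param file BED path (0-based half-open; name column used as `cpr_id`).
#' @return data.frame with columns `chrom`, `start`, `end`, `cpr_id`, `strand`.
#' @export
read_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             cpr_id = if (!is.null(gr$name)) gr$name else paste0("cpr", seq_along(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write CPR intervals to a BED file
#'
#' @param intervals data.frame as returned by [read_bed()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_bed <- function(intervals, file) {
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "+"
  strand[!strand %in% c("+", "-")] <- "+"
  gr <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1L, intervals$end),
                               strand = strand)
  gr$name <- intervals$cpr_id
  gr$score <- 0L
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}
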