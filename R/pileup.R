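# Read filtering and reduction of alignments to per-site base counts.

BASES <- c("A", "C", "G", "T")

#' Read a FASTQ file
#'
#' @param path FASTQ path (Phred+33 qualities).
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
read_fastq <- function(path) {
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      # Biostrings drops FASTQ metadata columns on coercion; expected here
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# integer Phred scores per read as a list
phred_list <- function(reads) {
  as(Biostrings::quality(reads), "IntegerList")
}

#' Filter reads by low-quality base fraction
#'
#' A read is dropped iff the fraction of its bases at or below the
#' low-quality Phred threshold is strictly greater than `max_fraction`
#' (default: more than 50% of bases with quality <= 5). The QC report gives
#' the Q20 rate of the kept bases (fraction with Phred >= 20).
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet] (see
#'   [read_fastq()]).
#' @param low_q Phred threshold defining a low-quality base (inclusive).
#' @param max_fraction Maximum tolerated fraction of low-quality bases.
#' @return List with `reads` (kept reads) and `report`
#'   (`n_input`, `n_kept`, `n_dropped`, `q20_rate`).
#' @export
filter_reads <- function(reads, low_q = 5L, max_fraction = 0.5) {
  if (length(reads) == 0L) {
    return(list(reads = reads,
                report = data.frame(n_input = 0L, n_kept = 0L, n_dropped = 0L,
                                    q20_rate = NA_real_)))
  }
  ph <- phred_list(reads)
  frac_low <- vapply(ph, function(q) mean(q <= low_q), numeric(1))
  keep <- frac_low <= max_fraction
  kept <- reads[keep]
  kept_q <- unlist(ph[keep], use.names = FALSE)
  q20 <- if (length(kept_q)) mean(kept_q >= 20L) else NA_real_
  list(reads = kept,
       report = data.frame(n_input = length(reads), n_kept = sum(keep),
                           n_dropped = sum(!keep), q20_rate = q20))
}

#' Read a pileup TSV
#'
#' The pileup dialect is a 7-column tab-separated table with header
#' `chrom, pos, ref, A, C, G, T`; one row per reference position, 1-based.
#'
#' @param path TSV path.
#' @return Site-count data.frame with an added `depth` column.
#' @export
read_pileup <- function(path) {
  pu <- read.delim(path, stringsAsFactors = FALSE)
  validate_pileup(pu)
}

validate_pileup <- function(pu) {
  need <- c("chrom", "pos", "ref", BASES)
  miss <- setdiff(need, names(pu))
  if (length(miss)) stop("pileup lacks columns: ", paste(miss, collapse = ", "))
  for (b in BASES) {
    if (any(pu[[b]] < 0L)) stop("negative count in column ", b)
  }
  pu$depth <- pu$A + pu$C + pu$G + pu$T
  pu
}

#' Write a pileup TSV
#' @param counts Site-count data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(counts, path) {
  write.table(counts[, c("chrom", "pos", "ref", BASES)], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build per-site base counts from alignments
#'
#' Tallies aligned A/C/G/T read bases per reference position. Accepts a
#' coordinate-sorted or unsorted SAM/BAM file (reads flagged unmapped or
#' secondary are excluded; deletions, reference skips and inserted bases do
#' not contribute to any position), a pileup TSV path, or an in-memory
#' pileup data.frame. Every reference position is emitted, including
#' zero-coverage positions with depth 0.
#'
#' @param x SAM/BAM path, pileup TSV path, or pileup data.frame.
#' @param ref A `ref_set`; alignment target names must be a subset of its
#'   chromosome ids.
#' @return data.frame with columns `chrom, pos, ref, A, C, G, T, depth`.
#' @export
build_site_counts <- function(x, ref) {
  if (is.data.frame(x)) return(complete_pileup(validate_pileup(x), ref))
  stopifnot(is.character(x), length(x) == 1L, file.exists(x))
  ext <- tolower(tools::file_ext(x))
  if (ext %in% c("tsv", "txt")) return(complete_pileup(read_pileup(x), ref))
  bam <- x
  if (ext == "sam") {
    bam <- Rsamtools::asBam(x, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  } else if (!file.exists(paste0(bam, ".bai"))) {
    Rsamtools::indexBam(bam)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  bad <- setdiff(names(hdr), names(ref$seqs))
  if (length(bad)) stop("alignment targets absent from reference: ",
                        paste(bad, collapse = ", "))
  mism <- names(hdr)[hdr != ref$lengths[names(hdr)]]
  if (length(mism)) stop("alignment target lengths disagree with reference: ",
                         paste(mism, collapse = ", "))
  p <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE)),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 1000000L, min_base_quality = 0L, min_mapq = 0L,
      min_nucleotide_depth = 0L, min_minor_allele_depth = 0L,
      distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
      ignore_query_Ns = TRUE, include_deletions = FALSE,
      include_insertions = FALSE))
  p <- p[p$nucleotide %in% BASES, , drop = FALSE]
  counts_from_tallies(as.character(p$seqnames), p$pos,
                      as.character(p$nucleotide), p$count, ref)
}

# assemble a complete per-position table from sparse (chrom,pos,base,count)
counts_from_tallies <- function(chrom, pos, base, count, ref) {
  out <- empty_pileup(ref)
  if (length(chrom)) {
    key <- match(paste(chrom, pos), paste(out$chrom, out$pos))
    if (anyNA(key)) stop("tallied position outside reference coordinates")
    for (b in BASES) {
      sel <- base == b
      if (any(sel)) {
        agg <- rowsum(count[sel], key[sel])
        out[[b]][as.integer(rownames(agg))] <- out[[b]][as.integer(rownames(agg))] + agg[, 1]
      }
    }
  }
  out$depth <- out$A + out$C + out$G + out$T
  out
}

empty_pileup <- function(ref) {
  do.call(rbind, lapply(names(ref$seqs), function(ch) {
    len <- unname(ref$lengths[[ch]])
    data.frame(chrom = ch, pos = seq_len(len),
               ref = substring(ref$seqs[[ch]], seq_len(len), seq_len(len)),
               A = 0L, C = 0L, G = 0L, T = 0L, depth = 0L,
               stringsAsFactors = FALSE)
  }))
}

# ensure every reference position appears exactly once; fill gaps with zeros
complete_pileup <- function(pu, ref) {
  bad <- setdiff(unique(pu$chrom), names(ref$seqs))
  if (length(bad)) stop("pileup chroms absent from reference: ",
                        paste(bad, collapse = ", "))
  out <- empty_pileup(ref)
  key <- match(paste(pu$chrom, pu$pos), paste(out$chrom, out$pos))
  if (anyNA(key)) stop("pileup position outside reference coordinates")
  if (anyDuplicated(key)) stop("duplicate (chrom,pos) rows in pileup")
  for (b in BASES) out[[b]][key] <- pu[[b]]
  out$depth <- out$A + out$C + out$G + out$T
  out
}

#' Consensus base of one pileup column
#'
#' The consensus is the base with maximal count. Ties are resolved in favour
#' of the reference base when it is among the tied bases, otherwise the
#' alphabetically first tied base wins. A zero-depth column yields `"N"`.
#' With `weights`, per-base quality-sum weights replace raw counts
#' (quality-weighted mode).
#'
#' @param counts Named numeric vector (or single-row slice) with entries
#'   `A,C,G,T`.
#' @param ref_base Reference base used for tie breaking.
#' @param weights Optional named numeric vector of per-base weights.
#' @return A single base, or `"N"`.
#' @export
consensus_base <- function(counts, ref_base = "N", weights = NULL) {
  v <- if (is.null(weights)) as.numeric(counts[BASES]) else as.numeric(weights[BASES])
  if (sum(as.numeric(counts[BASES])) == 0) return("N")
  top <- BASES[v == max(v)]
  if (ref_base %in% top) ref_base else top[1L]
}

#' Consensus track over a pileup
#'
#' Vectorised [consensus_base()] over every row of a site-count table.
#'
#' @param counts Site-count data.frame (`chrom, pos, ref, A, C, G, T`).
#' @return `counts` with a `consensus` column appended.
#' @export
consensus_track <- function(counts) {
  m <- as.matrix(counts[, BASES])
  mx <- do.call(pmax, as.data.frame(m))
  cons <- character(nrow(m))
  is_tie <- rowSums(m == mx) > 1L
  cons[!is_tie] <- BASES[max.col(m[!is_tie, , drop = FALSE], ties.method = "first")]
  if (any(is_tie)) {
    cons[is_tie] <- vapply(which(is_tie), function(i) {
      consensus_base(m[i, ], counts$ref[i])
    }, character(1))
  }
  cons[counts$depth == 0L] <- "N"
  counts$consensus <- cons
  counts
}
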