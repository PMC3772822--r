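# In-code fixtures shared across test files.

# quality-scaled reads from base strings and integer Phred vectors
mk_reads <- function(bases, quals, ids = sprintf("r%d", seq_along(bases))) {
  q <- vapply(quals, function(v) rawToChar(as.raw(v + 33L)), character(1))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(bases), Biostrings::PhredQuality(q))
  names(x) <- ids
  x
}

# a pileup row set from a named base-count list, on a single linear chrom
mk_counts <- function(..., ref_seq = NULL, chrom = "chr1") {
  cols <- list(...)
  n <- length(cols)
  out <- data.frame(chrom = chrom, pos = seq_len(n),
                    ref = if (is.null(ref_seq)) rep("A", n)
                          else strsplit(ref_seq, "")[[1]],
                    A = 0L, C = 0L, G = 0L, T = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    for (b in names(cols[[i]])) out[[b]][i] <- cols[[i]][[b]]
  }
  out$depth <- out$A + out$C + out$G + out$T
  out
}

# 15-bp linear chromosome carrying one plus-strand protein gene at 4..12
# with codons GGA GAA CTA
toy_protein_ref <- function() {
  ref <- ref_set(c(chr1 = "TTTGGAGAACTATTT"), topology = "linear")
  ann <- validate_annotations(data.frame(
    gene = "nad9", chrom = "chr1", start = 4L, end = 12L, strand = "+",
    class = "protein", frame_offset = 0L, transl_table = 5L,
    anticodon_start = NA_integer_, stringsAsFactors = FALSE), ref)
  list(ref = ref, ann = ann)
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# minimal SAM for hand-tally pileup tests, reference ACGTACGTAC (10 bp)
toy_sam <- function(path = tempfile(fileext = ".sam")) {
  ref <- "ACGTACGTAC"
  sub_at <- function(s, at, b) { substr(s, at, at) <- b; s }
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:10",
    # r1: pos 3-7, base at pos 5 = A (matches ref)
    paste("r1", 0, "chr1", 3, 60, "5M", "*", 0, 0, substr(ref, 3, 7), "IIIII", sep = "\t"),
    # r2: pos 5-7, base at pos 5 = A
    paste("r2", 0, "chr1", 5, 60, "3M", "*", 0, 0, substr(ref, 5, 7), "III", sep = "\t"),
    # r3: pos 4-7, base at pos 5 = G (mismatch)
    paste("r3", 0, "chr1", 4, 60, "4M", "*", 0, 0, sub_at(substr(ref, 4, 7), 2, "G"), "IIII", sep = "\t"),
    # r4: deletion spanning pos 5-6 (1M2D2M from pos 4): covers 4, 7, 8
    paste("r4", 0, "chr1", 4, 60, "1M2D2M", "*", 0, 0, paste0(substr(ref, 4, 4), substr(ref, 7, 8)), "III", sep = "\t"),
    # r5: secondary alignment over pos 5, must be excluded
    paste("r5", 256, "chr1", 5, 60, "3M", "*", 0, 0, substr(ref, 5, 7), "III", sep = "\t"))
  writeLines(lines, path)
  list(path = path, ref = ref_set(c(chr1 = ref), topology = "linear"))
}

# double-loop oracle for the q-value step-up formula
q_oracle <- function(p, pi0 = 0.05, m = length(p)) {
  o <- order(p)
  ps <- p[o]
  qs <- numeric(length(ps))
  for (i in seq_along(ps)) {
    best <- Inf
    for (j in i:length(ps)) best <- min(best, pi0 * m * ps[j] / j)
    qs[i] <- min(best, 1)
  }
  out <- numeric(length(ps))
  out[o] <- qs
  out
}

# textbook Welch statistic oracle
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
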