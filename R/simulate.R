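# Seeded synthetic references, annotations, pileups and reads with planted
# heteroplasmy, plus truth-set evaluation of calls.

# Approximate invertebrate mitochondrial gene lengths (bases). atp8-atp6 is
# kept as one annotation unit. tRNA genes are 65 bp each.
MITO_GENE_LENGTHS <- c(
  "atp8-atp6" = 831, cytb = 1107, cox1 = 1536, cox2 = 684, cox3 = 786,
  nad1 = 936, nad2 = 960, nad3 = 351, nad4 = 1338, nad4L = 291,
  nad5 = 1674, nad6 = 438, rrnL = 1200, rrnS = 750
)
TRNA_NAMES <- paste0("trn", c("A","R","N","D","C","Q","E","G","H","I",
                              "L1","L2","K","M","F","P","S1","S2","T","W",
                              "Y","V"))
MINUS_STRAND_GENES <- c("nad1", "nad4", "nad4L", "nad5", "rrnL",
                        "trnC", "trnF", "trnH", "trnP", "trnQ", "trnV", "trnY")

#' Simulation presets
#'
#' Two genome architectures: `"louse"` — 20 circular minichromosomes of
#' 3--4 kb carrying 1--3 genes each (13 protein-coding units, 2 rRNAs,
#' 22 tRNAs in total), sequenced to ~6,000x; `"tick"` — a single circular
#' chromosome whose ~14.5 kb coding region carries all 37 genes, sequenced
#' to ~1,700x. Per-base sequencing error defaults to 0.5%.
#'
#' @param preset `"louse"` or `"tick"`.
#' @param depth Mean per-site coverage (defaults: 6000 louse, 1700 tick).
#' @param error_rate Uniform per-base error rate.
#' @param gc GC content of intergenic spacer sequence.
#' @return A `sim_config` list.
#' @export
sim_preset <- function(preset = c("louse", "tick"), depth = NULL,
                       error_rate = 0.005, gc = 0.35) {
  preset <- match.arg(preset)
  if (is.null(depth)) depth <- if (preset == "louse") 6000 else 1700
  structure(list(preset = preset, depth = depth, error_rate = error_rate,
                 gc = gc), class = "sim_config")
}

random_dna <- function(n, gc = 0.35) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# deterministic assignment of the 37 genes to 20 minichromosomes (1-3 each)
louse_gene_layout <- function() {
  big <- names(MITO_GENE_LENGTHS)  # 12 protein units + atp8-atp6 joint + 2 rRNA = 14
  layout <- vector("list", 20)
  trna <- TRNA_NAMES
  for (i in seq_along(big)) {      # chrom 1-14: one large gene + one tRNA
    layout[[i]] <- c(big[i], trna[i])
  }
  rest <- trna[-seq_along(big)]    # 8 tRNAs left for chroms 15-20
  sizes <- c(2, 2, 1, 1, 1, 1)
  k <- 1L
  for (j in seq_along(sizes)) {
    layout[[14L + j]] <- rest[k:(k + sizes[j] - 1L)]
    k <- k + sizes[j]
  }
  layout
}

#' Generate a synthetic reference set with annotations
#'
#' Random sequences at the configured GC content with the preset's gene
#' layout written as the standard annotation table. Identical seeds give
#' byte-identical FASTA/TSV output.
#'
#' @param config A [sim_preset()] configuration.
#' @param seed Integer seed.
#' @return List with `ref` (a `ref_set`) and `ann` (validated annotation
#'   data.frame).
#' @export
sim_reference <- function(config = sim_preset("louse"), seed = 1L) {
  set.seed(seed)
  gene_len <- function(g) {
    if (startsWith(g, "trn")) 65L else as.integer(MITO_GENE_LENGTHS[[g]])
  }
  mk_chrom <- function(genes, chrom, min_len, max_len) {
    spacer <- 50L
    pos <- 101L
    rows <- lapply(genes, function(g) {
      len <- gene_len(g)
      r <- data.frame(
        gene = g, chrom = chrom, start = pos, end = pos + len - 1L,
        strand = if (g %in% MINUS_STRAND_GENES) "-" else "+",
        class = if (startsWith(g, "trn")) "tRNA"
                else if (startsWith(g, "rrn")) "rRNA" else "protein",
        frame_offset = 0L, transl_table = 5L,
        anticodon_start = NA_integer_, stringsAsFactors = FALSE)
      pos <<- pos + len + spacer
      r
    })
    rows <- do.call(rbind, rows)
    is_t <- rows$class == "tRNA"
    rows$anticodon_start[is_t] <- ifelse(rows$strand[is_t] == "+",
                                         rows$start[is_t] + 32L,
                                         rows$end[is_t] - 32L)
    need <- pos - spacer + 100L
    len <- max(need, round(runif(1, min_len, max_len)))
    list(ann = rows, len = as.integer(len))
  }
  if (config$preset == "louse") {
    layout <- louse_gene_layout()
    chroms <- sprintf("mini%02d", seq_along(layout))
    parts <- lapply(seq_along(layout), function(i)
      mk_chrom(layout[[i]], chroms[i], 3000, 4000))
  } else {
    genes <- c(names(MITO_GENE_LENGTHS), TRNA_NAMES)
    parts <- list(mk_chrom(genes, "mtDNA", 14500, 14900))
    chroms <- "mtDNA"
  }
  ann <- do.call(rbind, lapply(parts, `[[`, "ann"))
  lens <- vapply(parts, `[[`, integer(1), "len")
  seqs <- setNames(vapply(lens, random_dna, character(1), gc = config$gc), chroms)
  # ensure protein genes have sane codon structure: no internal stops is not
  # required downstream, but start the frame cleanly at the gene start
  ref <- ref_set(seqs, topology = "circular")
  list(ref = ref, ann = validate_annotations(ann, ref))
}

# logical mask over a chromosome: TRUE where the L bases immediately 5' or
# 3' of the position form a homopolymer run (the hotspot rule); vectorised
# counterpart of hp_side()
hp_adjacent_mask <- function(ref, chrom, L = 4L) {
  len <- unname(ref$lengths[[chrom]])
  circ <- ref$topology[[chrom]] == "circular"
  seqc <- strsplit(ref$seqs[[chrom]], "")[[1]]
  at <- function(off) {           # base at position p + off, per p
    idx <- seq_len(len) + off
    if (circ) seqc[((idx - 1L) %% len) + 1L]
    else { out <- rep(NA_character_, len)
           ok <- idx >= 1L & idx <= len
           out[ok] <- seqc[idx[ok]]; out }
  }
  side <- function(sgn) {
    b1 <- at(sgn * 1L)
    m <- b1 %in% BASES
    for (k in 2:L) m <- m & !is.na(bk <- at(sgn * k)) & bk == b1
    m & !is.na(b1)
  }
  side(-1L) | side(+1L)
}

# positions whose 5' or 3' flank of length L is a homopolymer run
is_hp_adjacent <- function(ref, chrom, pos, L = 4L) {
  hp_adjacent_mask(ref, chrom, L)[pos]
}

#' Sample planted heteroplasmic sites
#'
#' Chooses site positions uniformly across the reference, excluding
#' homopolymer-adjacent positions (which the hotspot filter would remove by
#' design) and enforcing a minimum spacing of 2 bp so planted sites never
#' trigger the adjacent-variant rule against each other. The minor base is
#' drawn uniformly from the three non-reference bases.
#'
#' @param ref A `ref_set`.
#' @param n_sites Number of sites to plant.
#' @param freq True minor-allele frequency (scalar or per site), in
#'   `(0, 0.5]`.
#' @param seed Integer seed.
#' @param chroms Optional chromosome subset to plant in.
#' @return data.frame `chrom, pos, minor, freq`.
#' @export
sample_planted_sites <- function(ref, n_sites, freq = 0.05, seed = 1L,
                                 chroms = NULL) {
  stopifnot(all(freq > 0), all(freq <= 0.5))
  set.seed(seed)
  if (is.null(chroms)) chroms <- names(ref$seqs)
  pool <- do.call(rbind, lapply(chroms, function(ch) {
    len <- unname(ref$lengths[[ch]])
    ok <- !hp_adjacent_mask(ref, ch)
    refb <- substring(ref$seqs[[ch]], seq_len(len), seq_len(len))
    ok <- ok & refb %in% BASES
    data.frame(chrom = ch, pos = which(ok), ref = refb[ok],
               stringsAsFactors = FALSE)
  }))
  pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
  sel <- integer(0)
  taken <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pool))) {
    if (length(sel) >= n_sites) break
    ch <- pool$chrom[i]; p <- pool$pos[i]
    if (!is.null(taken[[paste(ch, p)]])) next
    sel <- c(sel, i)
    for (d in -2:2) taken[[paste(ch, p + d)]] <- TRUE
  }
  if (length(sel) < n_sites)
    stop("could not place ", n_sites, " sites with the spacing constraints")
  picked <- pool[sel, , drop = FALSE]
  picked$minor <- vapply(picked$ref, function(rb)
    sample(setdiff(BASES, rb), 1L), character(1), USE.NAMES = FALSE)
  picked$ref <- NULL
  picked$freq <- rep_len(freq, nrow(picked))
  picked <- picked[order(picked$chrom, picked$pos), , drop = FALSE]
  rownames(picked) <- NULL
  picked
}

#' Simulate a pileup with sequencing error and planted heteroplasmy
#'
#' Per site the depth `n` is drawn as Poisson around the configured mean (or
#' held fixed), each non-reference base receives an error count
#' `Binomial(n, p/3)`, planted sites add `Binomial(n, f (1 - p))` variant
#' reads on the minor base, and optional homopolymer-adjacent artifact sites
#' receive a 20-fold elevated error rate on one alternate base. The
#' reference-base count absorbs the remainder so counts always sum to the
#' depth.
#'
#' @param ref A `ref_set`.
#' @param planted data.frame `chrom, pos, minor, freq` (or `NULL`).
#' @param depth Mean per-site depth.
#' @param error_rate Per-base error rate `p`.
#' @param seed Integer seed.
#' @param fixed_depth If `TRUE`, every site has exactly `depth` reads
#'   (required for exact read-emission round trips).
#' @param n_artifacts Number of homopolymer-adjacent artifact sites to
#'   inject.
#' @param artifact_fold Error elevation factor at artifact sites.
#' @return List with `counts` (site-count data.frame) and `truth`
#'   (data.frame `chrom, pos, minor, freq, is_artifact`).
#' @export
simulate_pileup <- function(ref, planted = NULL, depth = 6000,
                            error_rate = 0.005, seed = 1L,
                            fixed_depth = FALSE, n_artifacts = 0L,
                            artifact_fold = 20) {
  set.seed(seed)
  counts <- empty_pileup(ref)
  N <- nrow(counts)
  n <- if (fixed_depth) rep.int(as.integer(depth), N) else rpois(N, depth)
  p3 <- error_rate / 3
  alt <- matrix(0L, N, 4L, dimnames = list(NULL, BASES))
  for (b in BASES) {
    rows <- which(counts$ref != b)
    if (length(rows) && p3 > 0)
      alt[rows, b] <- rbinom(length(rows), n[rows], p3)
  }
  truth <- data.frame(chrom = character(0), pos = integer(0),
                      minor = character(0), freq = numeric(0),
                      is_artifact = logical(0), stringsAsFactors = FALSE)
  key <- paste(counts$chrom, counts$pos)
  if (!is.null(planted) && nrow(planted)) {
    idx <- match(paste(planted$chrom, planted$pos), key)
    if (anyNA(idx)) stop("planted site outside reference")
    kvar <- rbinom(nrow(planted), n[idx], planted$freq * (1 - error_rate))
    alt[cbind(idx, match(planted$minor, BASES))] <-
      alt[cbind(idx, match(planted$minor, BASES))] + kvar
    truth <- rbind(truth, data.frame(chrom = planted$chrom, pos = planted$pos,
                                     minor = planted$minor, freq = planted$freq,
                                     is_artifact = FALSE,
                                     stringsAsFactors = FALSE))
  }
  if (n_artifacts > 0L) {
    cand <- which(unlist(lapply(names(ref$seqs), function(ch)
      hp_adjacent_mask(ref, ch)), use.names = FALSE))
    # keep artifacts clear of planted sites and of each other
    if (!is.null(planted) && nrow(planted)) {
      near <- unlist(lapply(match(paste(planted$chrom, planted$pos), key),
                            function(i) (i - 1L):(i + 1L)))
      cand <- setdiff(cand, near)
    }
    cand <- cand[sample.int(length(cand))]
    picked <- integer(0)
    for (i in cand) {
      if (length(picked) >= n_artifacts) break
      if (!any(abs(picked - i) <= 1L)) picked <- c(picked, i)
    }
    if (length(picked) < n_artifacts)
      stop("not enough homopolymer-adjacent positions for ", n_artifacts,
           " artifacts")
    art_base <- vapply(picked, function(i)
      sample(setdiff(BASES, counts$ref[i]), 1L), character(1))
    ak <- rbinom(length(picked), n[picked], artifact_fold * p3)
    alt[cbind(picked, match(art_base, BASES))] <-
      alt[cbind(picked, match(art_base, BASES))] + ak
    truth <- rbind(truth, data.frame(chrom = counts$chrom[picked],
                                     pos = counts$pos[picked],
                                     minor = art_base,
                                     freq = artifact_fold * p3,
                                     is_artifact = TRUE,
                                     stringsAsFactors = FALSE))
  }
  alt_sum <- rowSums(alt)
  over <- alt_sum > n
  n[over] <- alt_sum[over]   # pathological only at extreme error rates
  for (b in BASES) counts[[b]] <- alt[, b]
  ridx <- cbind(seq_len(N), match(counts$ref, BASES))
  ok <- !is.na(ridx[, 2])
  counts_mat <- as.matrix(counts[, BASES])
  counts_mat[ridx[ok, , drop = FALSE]] <-
    counts_mat[ridx[ok, , drop = FALSE]] + (n - alt_sum)[ok]
  for (b in BASES) counts[[b]] <- counts_mat[, b]
  counts$depth <- counts$A + counts$C + counts$G + counts$T
  list(counts = counts, truth = truth)
}

#' Emit reads realising a pileup exactly
#'
#' Constructs reads such that rebuilding the pileup from the emitted SAM
#' with [build_site_counts()] reproduces the input counts exactly. The
#' construction tiles each chromosome with `depth` staggered read strands,
#' each covering every position exactly once, and assigns the non-reference
#' bases of each pileup column to distinct strands; it therefore requires a
#' constant depth per chromosome (see `fixed_depth` in
#' [simulate_pileup()]). Mapped reads carry constant Q40 qualities;
#' `n_lowq` additional unmapped reads with `lowq_frac` of their bases at
#' Phred 5 can be appended to exercise read filtering.
#'
#' @param counts Constant-depth site-count data.frame.
#' @param ref The `ref_set` the counts refer to.
#' @param fastq,sam Output paths.
#' @param read_length Read length in bases.
#' @param n_lowq Number of low-quality (unmapped) reads to append.
#' @param lowq_frac Fraction of Phred-5 bases in each low-quality read.
#' @param seed Seed for the low-quality read windows.
#' @return List with `fastq`, `sam` and `n_reads`.
#' @export
emit_reads <- function(counts, ref, fastq = tempfile(fileext = ".fastq"),
                       sam = tempfile(fileext = ".sam"), read_length = 180L,
                       n_lowq = 0L, lowq_frac = 0.6, seed = 1L) {
  set.seed(seed)
  L <- as.integer(read_length)
  sam_lines <- c("@HD\tVN:1.6\tSO:unsorted",
                 sprintf("@SQ\tSN:%s\tLN:%d", names(ref$seqs),
                         unname(ref$lengths)))
  fq_lines <- character(0)
  rid <- 0L
  for (ch in unique(counts$chrom)) {
    rows <- counts[counts$chrom == ch, , drop = FALSE]
    rows <- rows[order(rows$pos), , drop = FALSE]
    d <- unique(rows$depth)
    if (length(d) != 1L)
      stop("emit_reads requires a constant depth per chromosome; ",
           ch, " varies (use fixed_depth pileups)")
    d <- as.integer(d)
    len <- unname(ref$lengths[[ch]])
    if (L > len) stop("read_length exceeds length of ", ch)
    seqc <- strsplit(ref$seqs[[ch]], "")[[1]]
    # per-strand mutation lists: alternates of each column go to strands
    # 1..(number of non-reference bases), reference fills the rest
    mut <- vector("list", d)
    cmat <- as.matrix(rows[, BASES])
    for (p in seq_len(len)) {
      rb <- rows$ref[p]
      s <- 0L
      for (b in BASES) {
        if (b == rb) next
        cb <- cmat[p, b]
        if (cb > 0L) {
          for (j in seq_len(cb)) mut[[s + j]] <- c(mut[[s + j]], setNames(b, p))
          s <- s + cb
        }
      }
      if (s > d) stop("column at ", ch, ":", p, " exceeds depth")
    }
    for (j in seq_len(d)) {
      sj <- seqc
      if (length(mut[[j]])) sj[as.integer(names(mut[[j]]))] <- mut[[j]]
      o <- ((j - 1L) * L) %/% d %% L
      if (o >= len) o <- 0L
      cuts <- unique(c(0L, if (o > 0L) o, seq.int(o + L, len, by = L), len))
      cuts <- sort(cuts[cuts <= len])
      for (ci in seq_len(length(cuts) - 1L)) {
        a <- cuts[ci] + 1L; b <- cuts[ci + 1L]
        rid <- rid + 1L
        nm <- sprintf("%s_s%d_r%d", ch, j, ci)
        bases <- paste(sj[a:b], collapse = "")
        qual <- strrep("I", b - a + 1L)
        sam_lines <- c(sam_lines, sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                                          nm, ch, a, b - a + 1L, bases, qual))
        fq_lines <- c(fq_lines, paste0("@", nm), bases, "+", qual)
      }
    }
  }
  if (n_lowq > 0L) {
    ch <- names(ref$seqs)[1]
    len <- unname(ref$lengths[[ch]])
    n_low <- ceiling(lowq_frac * L)
    for (i in seq_len(n_lowq)) {
      a <- sample.int(max(len - L + 1L, 1L), 1L)
      bases <- substring(ref$seqs[[ch]], a, a + L - 1L)
      qual <- paste0(strrep("&", n_low), strrep("I", L - n_low))  # & = Q5
      nm <- sprintf("lowq_r%d", i)
      sam_lines <- c(sam_lines, sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
                                        nm, bases, qual))
      fq_lines <- c(fq_lines, paste0("@", nm), bases, "+", qual)
      rid <- rid + 1L
    }
  }
  writeLines(sam_lines, sam)
  writeLines(fq_lines, fastq)
  list(fastq = fastq, sam = sam, n_reads = rid)
}

#' Evaluate calls against a simulation truth set
#'
#' @param calls Call data.frame (`chrom, pos, variant, freq`), typically the
#'   `status == "pass"` subset.
#' @param truth Truth data.frame from [simulate_pileup()].
#' @return List: `recall` (recovered planted non-artifact sites / planted;
#'   `NA` when nothing was planted), `precision` (planted calls / all
#'   calls; `NA` when no calls), `n_calls`, `n_planted`,
#'   `mean_freq_error` (mean `|freq - f|` over recovered sites), and
#'   `site_errors` (per recovered site).
#' @export
evaluate_calls <- function(calls, truth) {
  planted <- truth[!truth$is_artifact, , drop = FALSE]
  call_key <- paste(calls$chrom, calls$pos, calls$variant)
  true_key <- paste(planted$chrom, planted$pos, planted$minor)
  hit <- match(true_key, call_key)
  recovered <- !is.na(hit)
  recall <- if (nrow(planted)) mean(recovered) else NA_real_
  precision <- if (nrow(calls)) mean(call_key %in% true_key) else NA_real_
  errs <- abs(calls$freq[hit[recovered]] - planted$freq[recovered])
  list(recall = recall, precision = precision,
       n_calls = nrow(calls), n_planted = nrow(planted),
       mean_freq_error = if (length(errs)) mean(errs) else NA_real_,
       site_errors = data.frame(chrom = planted$chrom[recovered],
                                pos = planted$pos[recovered],
                                true_freq = planted$freq[recovered],
                                called_freq = calls$freq[hit[recovered]],
                                abs_error = errs,
                                stringsAsFactors = FALSE))
}
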