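# Candidate heteroplasmy calling, binomial false-positive probability,
# Storey q-values, hotspot flagging and final status assignment.

#' Caller configuration
#'
#' Bundles the thresholds of the calling procedure. Defaults reflect deep
#' amplicon sequencing of mitochondrial genomes on an Illumina-class
#' platform: minor alleles must exceed 1.5% frequency (three times the
#' assumed 0.5% per-base error rate), the binomial false-positive probability
#' `P_f` must be below 1% and the q-value `Q_f` below 0.1%, and sites at
#' sequencing-error hotspots (immediately adjacent to homopolymer runs of
#' four or more identical bases, or pairs of adjacent variants) are excluded.
#'
#' @param min_freq Minimum minor-allele frequency; candidates require
#'   frequency strictly greater than this.
#' @param error_rate Assumed uniform per-base sequencing error rate `p`.
#' @param pf_max Significance threshold on `P_f` (strict `<`).
#' @param qf_max Significance threshold on `Q_f` (strict `<`).
#' @param pi0 Assumed proportion of true nulls in the q-value computation.
#' @param pf_mode `"pmf"` (binomial point probability, the default) or
#'   `"tail"` (`P(X >= k)`); see [binomial_false_positive()].
#' @param homopolymer_len Minimum homopolymer run length defining a hotspot.
#' @param apply_hotspot_filter Apply the hotspot exclusion stage?
#' @param estimate_pi0 Estimate `pi0` from the candidate p-values with the
#'   Storey smoother instead of using the fixed `pi0`.
#' @return A `caller_config` list.
#' @export
caller_config <- function(min_freq = 0.015, error_rate = 0.005,
                          pf_max = 0.01, qf_max = 0.001, pi0 = 0.05,
                          pf_mode = c("pmf", "tail"), homopolymer_len = 4L,
                          apply_hotspot_filter = TRUE, estimate_pi0 = FALSE) {
  pf_mode <- match.arg(pf_mode)
  props <- c(min_freq = min_freq, error_rate = error_rate, pf_max = pf_max,
             qf_max = qf_max, pi0 = pi0)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  structure(list(min_freq = min_freq, error_rate = error_rate,
                 pf_max = pf_max, qf_max = qf_max, pi0 = pi0,
                 pf_mode = pf_mode, homopolymer_len = as.integer(homopolymer_len),
                 apply_hotspot_filter = apply_hotspot_filter,
                 estimate_pi0 = estimate_pi0),
            class = "caller_config")
}

#' Binomial false-positive probability of a variant count
#'
#' Probability that a variant observed `k` times at depth `n` arises from
#' sequencing error alone, under a binomial error model with per-base error
#' rate `p`. `mode = "pmf"` returns the binomial point mass
#' `C(n,k) p^k (1-p)^(n-k)` evaluated in log space; `mode = "tail"` returns
#' the upper tail `P(X >= k)`, the statistically conventional exceedance
#' probability. Vectorised over `n` and `k`.
#'
#' @param n Depth (sequence-read coverage) at the site.
#' @param k Variant read count, `0 <= k <= n`.
#' @param p Per-base error rate.
#' @param mode `"pmf"` or `"tail"`.
#' @return Probability in `[0, 1]`, same length as `n`/`k`.
#' @examples
#' binomial_false_positive(6000, 100, 0.005)
#' @export
binomial_false_positive <- function(n, k, p = 0.005, mode = c("pmf", "tail")) {
  mode <- match.arg(mode)
  if (any(k > n)) stop("k must not exceed n")
  if (any(k < 0) || any(n < 0)) stop("n and k must be non-negative")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (mode == "pmf") {
    exp(dbinom(k, n, p, log = TRUE))
  } else {
    pbinom(k - 1, n, p, lower.tail = FALSE)
  }
}

#' Storey q-values
#'
#' Step-up q-value procedure: with order statistics
#' `p_(1) <= ... <= p_(m)`, `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`,
#' mapped back to the input order and capped at 1. `pi0` is the assumed
#' proportion of true null hypotheses; it may be fixed (default) or
#' estimated from the p-value distribution with [estimate_pi0()].
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param pi0 Proportion of true nulls (scales all q-values linearly).
#' @param m Number of tests; defaults to `length(pvalues)`.
#' @return q-value per input p-value, in input order.
#' @examples
#' storey_qvalues(c(0.01, 0.02, 0.04), pi0 = 1)  # 0.03 0.03 0.04
#' @export
storey_qvalues <- function(pvalues, pi0 = 0.05, m = length(pvalues)) {
  if (!length(pvalues)) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  o <- order(pvalues)
  ps <- pvalues[o]
  mm <- length(ps)
  q <- pi0 * m * ps / seq_len(mm)
  q <- rev(cummin(rev(q)))        # q_(i) = min_{j >= i} pi0 m p_(j) / j
  q <- pmin(q, 1)
  out <- numeric(mm)
  out[o] <- q
  out
}

#' Estimate the true-null proportion pi0 (Storey smoother)
#'
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` evaluated on a grid of
#' `lambda`, smoothed with a cubic smoothing spline and read off at the
#' largest `lambda`, clamped to `(0, 1]`.
#'
#' @param pvalues Numeric p-values.
#' @param lambda Grid of tuning values in `[0, 1)`.
#' @return Estimated `pi0`.
#' @export
estimate_pi0 <- function(pvalues, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(pvalues)
  if (m < 2L) return(1)
  pi0l <- vapply(lambda, function(l) sum(pvalues > l) / (m * (1 - l)), numeric(1))
  fit <- try(smooth.spline(lambda, pi0l, df = 3), silent = TRUE)
  pi0 <- if (inherits(fit, "try-error")) pi0l[length(pi0l)]
         else predict(fit, x = max(lambda))$y
  min(max(pi0, 1e-8), 1)
}

#' Call candidate heteroplasmic sites from a pileup
#'
#' For each position, every non-consensus base whose frequency `k/n` is
#' strictly above `min_freq` is a potential variant. A site is represented
#' once, by the highest-count qualifying alternate base (ties broken
#' alphabetically); sites where more than one alternate qualifies are
#' flagged multi-allelic. Zero-depth positions are skipped; indels never
#' produce candidates (they are excluded upstream from the counts).
#'
#' @param counts Site-count data.frame with a `consensus` column (see
#'   [consensus_track()]).
#' @param config A [caller_config()].
#' @param sample Sample id stored with each call.
#' @return data.frame of candidate calls: `sample, chrom, pos, consensus,
#'   variant, k, n, freq, multi_allelic`.
#' @export
call_candidates <- function(counts, config = caller_config(), sample = "sample") {
  if (is.null(counts$consensus)) counts <- consensus_track(counts)
  m <- as.matrix(counts[, BASES])
  n <- counts$depth
  keep <- n > 0L & counts$consensus %in% BASES
  m <- m[keep, , drop = FALSE]
  cidx <- match(counts$consensus[keep], BASES)
  alt <- m
  alt[cbind(seq_len(nrow(alt)), cidx)] <- 0L
  nn <- n[keep]
  qual <- alt / nn > config$min_freq          # strict: k/n > min_freq
  nqual <- rowSums(qual)
  sel <- which(nqual > 0L)
  if (!length(sel)) {
    return(data.frame(sample = character(0), chrom = character(0),
                      pos = integer(0), consensus = character(0),
                      variant = character(0), k = integer(0), n = integer(0),
                      freq = numeric(0), multi_allelic = logical(0),
                      stringsAsFactors = FALSE))
  }
  aq <- alt[sel, , drop = FALSE]
  aq[!qual[sel, , drop = FALSE]] <- -1L       # only qualifying alternates compete
  vidx <- max.col(aq, ties.method = "first")  # alphabetical tie-break (A<C<G<T)
  k <- aq[cbind(seq_along(sel), vidx)]
  pos_keep <- which(keep)[sel]
  data.frame(sample = sample,
             chrom = counts$chrom[pos_keep],
             pos = counts$pos[pos_keep],
             consensus = counts$consensus[pos_keep],
             variant = BASES[vidx],
             k = as.integer(k), n = as.integer(n[pos_keep]),
             freq = k / n[pos_keep],
             multi_allelic = nqual[sel] > 1L,
             stringsAsFactors = FALSE)
}

#' Flag sequencing-error hotspots
#'
#' Two hotspot rules: (1) homopolymer context — the `homopolymer_len`
#' reference bases immediately 5' or 3' of the called site are one repeated
#' base (the rule is applied on both sides because reads come from both
#' orientations; on circular chromosomes positions wrap modulo the length,
#' on linear chromosomes a side with fewer than `homopolymer_len` available
#' bases cannot satisfy the rule); (2) adjacency — both members of any pair
#' of called sites at consecutive positions on the same chromosome in the
#' same sample are flagged.
#'
#' @param calls Candidate call data.frame (needs `sample, chrom, pos`).
#' @param ref `ref_set` the calls were made against.
#' @param homopolymer_len Minimum run length (default 4).
#' @return `calls` with logical columns `hotspot_homopolymer` and
#'   `hotspot_adjacent` appended.
#' @export
flag_hotspots <- function(calls, ref, homopolymer_len = 4L) {
  L <- as.integer(homopolymer_len)
  hp <- logical(nrow(calls))
  for (ch in unique(calls$chrom)) {
    len <- unname(ref$lengths[[ch]])
    circ <- ref$topology[[ch]] == "circular"
    seqc <- strsplit(ref$seqs[[ch]], "")[[1]]
    idx <- which(calls$chrom == ch)
    for (i in idx) {
      pos <- calls$pos[i]
      hp[i] <- hp_side(seqc, pos, -1L, L, len, circ) ||
               hp_side(seqc, pos, +1L, L, len, circ)
    }
  }
  calls$hotspot_homopolymer <- hp
  adj <- logical(nrow(calls))
  grp <- paste(calls$sample, calls$chrom)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    pos <- calls$pos[idx]
    ch <- calls$chrom[idx][1]
    len <- unname(ref$lengths[[ch]])
    circ <- ref$topology[[ch]] == "circular"
    nb <- outer(pos, pos, function(a, b) {
      d <- abs(a - b)
      d == 1L | (circ & d == len - 1L)
    })
    adj[idx] <- rowSums(nb) > 0L
  }
  calls$hotspot_adjacent <- adj
  calls
}

# is the run of `L` bases on one side of pos (dir -1 = 5', +1 = 3') a
# homopolymer? Sides truncated by a linear chromosome end cannot qualify.
hp_side <- function(seqc, pos, dir, L, len, circ) {
  offs <- pos + dir * seq_len(L)
  if (circ) {
    offs <- ((offs - 1L) %% len) + 1L
  } else if (any(offs < 1L | offs > len)) {
    return(FALSE)
  }
  b <- seqc[offs]
  all(b == b[1L]) && b[1L] %in% BASES
}

#' Finalise calls: significance thresholds and hotspot exclusion
#'
#' Computes `P_f` for each candidate (unless already present), `Q_f` over the
#' candidate set of each sample, and assigns a status in the fixed order
#' frequency, `P_f`, `Q_f`, hotspot: `fail_freq` (frequency not strictly
#' above `min_freq`), `fail_pf` (`P_f >= pf_max`), `fail_qf`
#' (`Q_f >= qf_max`), `fail_hotspot` (either hotspot flag set), else `pass`.
#' Only `pass` calls enter downstream tables.
#'
#' @param candidates Candidate call data.frame from [call_candidates()].
#' @param config A [caller_config()].
#' @param ref Optional `ref_set`; required when
#'   `config$apply_hotspot_filter` is `TRUE` and hotspot flags are not
#'   already present.
#' @return List with `calls` (candidates plus `p_f`, `q_f`, hotspot flags,
#'   `status`) and `attrition` (per-stage removal counts).
#' @export
finalize_calls <- function(candidates, config = caller_config(), ref = NULL) {
  calls <- candidates
  n0 <- nrow(calls)
  if (n0 == 0L) {
    calls$p_f <- numeric(0); calls$q_f <- numeric(0)
    calls$hotspot_homopolymer <- logical(0)
    calls$hotspot_adjacent <- logical(0)
    calls$status <- character(0)
    att <- data.frame(stage = c("candidates", "fail_freq", "fail_pf",
                                "fail_qf", "fail_hotspot", "pass"),
                      n = c(0L, 0L, 0L, 0L, 0L, 0L))
    return(list(calls = calls, attrition = att))
  }
  if (is.null(calls$p_f)) {
    calls$p_f <- binomial_false_positive(calls$n, calls$k,
                                         config$error_rate, config$pf_mode)
  }
  calls$q_f <- NA_real_
  for (s in unique(calls$sample)) {
    i <- calls$sample == s
    pi0 <- if (isTRUE(config$estimate_pi0)) estimate_pi0(calls$p_f[i]) else config$pi0
    calls$q_f[i] <- storey_qvalues(calls$p_f[i], pi0 = pi0)
  }
  if (config$apply_hotspot_filter &&
      (is.null(calls$hotspot_homopolymer) || is.null(calls$hotspot_adjacent))) {
    if (is.null(ref)) stop("hotspot filtering requires the reference set")
    calls <- flag_hotspots(calls, ref, config$homopolymer_len)
  }
  if (is.null(calls$hotspot_homopolymer)) calls$hotspot_homopolymer <- FALSE
  if (is.null(calls$hotspot_adjacent)) calls$hotspot_adjacent <- FALSE
  hot <- config$apply_hotspot_filter &
    (calls$hotspot_homopolymer | calls$hotspot_adjacent)
  status <- rep("pass", n0)
  status[hot] <- "fail_hotspot"
  status[calls$q_f >= config$qf_max] <- "fail_qf"
  status[calls$p_f >= config$pf_max] <- "fail_pf"
  status[calls$freq <= config$min_freq] <- "fail_freq"
  calls$status <- status
  att <- data.frame(
    stage = c("candidates", "fail_freq", "fail_pf", "fail_qf",
              "fail_hotspot", "pass"),
    n = c(n0, sum(status == "fail_freq"), sum(status == "fail_pf"),
          sum(status == "fail_qf"), sum(status == "fail_hotspot"),
          sum(status == "pass")))
  list(calls = calls, attrition = att)
}

#' Run the full calling procedure on one sample's pileup
#'
#' Convenience wrapper: consensus, candidate calling, `P_f`, per-sample
#' `Q_f`, hotspot flags and final status.
#'
#' @param counts Site-count data.frame (see [build_site_counts()]).
#' @param ref `ref_set` (used for hotspot context).
#' @param config A [caller_config()].
#' @param sample Sample id.
#' @return List with `calls`, `attrition` and `counts` (pileup with
#'   consensus column).
#' @export
call_heteroplasmy <- function(counts, ref, config = caller_config(),
                              sample = "sample") {
  counts <- consensus_track(counts)
  cand <- call_candidates(counts, config, sample)
  res <- finalize_calls(cand, config, ref)
  res$counts <- counts
  res
}

#' Write calls as TSV
#' @param calls Call data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write calls as a minimal VCF
#'
#' Consensus base as REF, variant as ALT; INFO keys `K`, `N`, `FREQ`, `PF`,
#' `QF`, `HOTSPOT`; FILTER mirrors the call status (`PASS` for passing
#' calls).
#'
#' @param calls Finalised call data.frame.
#' @param path Output path.
#' @param ref Optional `ref_set` for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, ref = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mthet",
           '##INFO=<ID=K,Number=1,Type=Integer,Description="Variant read count">',
           '##INFO=<ID=N,Number=1,Type=Integer,Description="Read depth">',
           '##INFO=<ID=FREQ,Number=1,Type=Float,Description="Variant frequency">',
           '##INFO=<ID=PF,Number=1,Type=Float,Description="Binomial false-positive probability">',
           '##INFO=<ID=QF,Number=1,Type=Float,Description="Storey q-value">',
           '##INFO=<ID=HOTSPOT,Number=1,Type=String,Description="Hotspot flags (homopolymer/adjacent/none)">')
  if (!is.null(ref)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(ref$seqs), unname(ref$lengths)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(calls)) {
    hotspot <- ifelse(calls$hotspot_homopolymer & calls$hotspot_adjacent, "homopolymer;adjacent",
               ifelse(calls$hotspot_homopolymer, "homopolymer",
               ifelse(calls$hotspot_adjacent, "adjacent", "none")))
    filt <- ifelse(calls$status == "pass", "PASS", calls$status)
    rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tK=%d;N=%d;FREQ=%.6g;PF=%.6g;QF=%.6g;HOTSPOT=%s",
                    calls$chrom, calls$pos, calls$consensus, calls$variant,
                    filt, calls$k, calls$n, calls$freq, calls$p_f, calls$q_f,
                    hotspot)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
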