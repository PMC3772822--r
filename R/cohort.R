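# Cohort-level aggregation: per-sample summaries, per-gene rates,
# shared-site matrices and group comparisons.

#' Summarise one sample's annotated calls
#'
#' Produces the per-sample breakdown used throughout the reporting tables:
#' totals by gene class, synonymous/nonsynonymous counts by codon position,
#' third-anticodon-base tRNA hits, and per-gene counts with sites-per-kb
#' rates. A call overlapping several annotation units is counted once in the
#' totals, attributed to its first annotation unit.
#'
#' @param ann_calls Annotated call data.frame ([annotate_calls()]) for a
#'   single sample, `status == "pass"` calls only.
#' @param ann Validated annotation data.frame (supplies gene lengths).
#' @param sample Sample id (defaults to the one carried by the calls).
#' @return A `sample_summary` list: `sample`, `total`, `by_class` (named
#'   counts), `syn`, `nonsyn`, `unknown`, `codon_breakdown` (data.frame
#'   `effect, codon_position, n`), `anticodon_third`, `per_gene`
#'   (data.frame `gene, class, n, length, rate`).
#' @export
summarize_sample <- function(ann_calls, ann, sample = NULL) {
  if (is.null(sample)) {
    sample <- if (nrow(ann_calls)) ann_calls$sample[1] else "sample"
  }
  # one row per site: first annotation unit wins; repeated rows for one site
  # are only legitimate when they come from distinct overlapping annotations
  if (nrow(ann_calls)) {
    if (anyDuplicated(paste(ann_calls$chrom, ann_calls$pos, ann_calls$gene)))
      stop("duplicate (chrom,pos) rows for sample ", sample)
    key <- paste(ann_calls$chrom, ann_calls$pos)
    sites <- ann_calls[!duplicated(key), , drop = FALSE]
  } else {
    sites <- ann_calls
  }
  classes <- c("protein", "rRNA", "tRNA", "intergenic")
  by_class <- setNames(integer(4), classes)
  for (cl in classes) by_class[cl] <- sum(sites$gene_class == cl, na.rm = TRUE)
  is_prot <- sites$gene_class == "protein"
  syn <- sum(is_prot & sites$synonymous %in% TRUE)
  nonsyn <- sum(is_prot & sites$synonymous %in% FALSE)
  unknown <- sum(is_prot & is.na(sites$synonymous))
  cb <- expand.grid(effect = c("synonymous", "nonsynonymous"),
                    codon_position = 1:3, stringsAsFactors = FALSE)
  cb$n <- vapply(seq_len(nrow(cb)), function(i) {
    sum(is_prot & sites$synonymous %in% (cb$effect[i] == "synonymous") &
          sites$codon_position %in% cb$codon_position[i])
  }, numeric(1))
  per_gene <- data.frame(gene = ann$gene, class = ann$class,
                         n = vapply(ann$gene, function(g)
                           sum(sites$gene %in% g), numeric(1)),
                         length = ann$length, stringsAsFactors = FALSE,
                         row.names = NULL)
  per_gene$rate <- per_gene$n / (per_gene$length / 1000)
  structure(list(
    sample = sample,
    total = nrow(sites),
    by_class = by_class,
    syn = syn, nonsyn = nonsyn, unknown = unknown,
    codon_breakdown = cb,
    anticodon_third = sum(sites$gene_class == "tRNA" &
                            sites$anticodon_third %in% TRUE),
    per_gene = per_gene
  ), class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat("Sample", x$sample, "-", x$total, "heteroplasmic sites",
      sprintf("(protein %d, rRNA %d, tRNA %d)\n",
              x$by_class["protein"], x$by_class["rRNA"], x$by_class["tRNA"]))
  cat("  synonymous", x$syn, "/ nonsynonymous", x$nonsyn, "\n")
  invisible(x)
}

#' Heteroplasmic sites per kilobase
#'
#' @param count Number of heteroplasmic sites.
#' @param gene_length Gene (or region) length in bases; must be positive.
#' @return `count / (gene_length / 1000)`.
#' @examples
#' per_gene_rate(21, 3000)  # 7 sites per kb
#' @export
per_gene_rate <- function(count, gene_length) {
  if (any(gene_length <= 0)) stop("gene_length must be positive")
  count / (gene_length / 1000)
}

#' Pairwise shared heteroplasmic sites
#'
#' Counts, for every pair of samples, the heteroplasmic sites they share. A
#' site is shared when chromosome, position and variant base all match
#' (`match = "allele"`), or when chromosome and position match
#' (`match = "position"`). The diagonal holds each sample's total.
#'
#' @param calls_by_sample Named list of call data.frames (one per sample,
#'   deduplicated, columns `chrom, pos, variant`).
#' @param match `"allele"` or `"position"`.
#' @return Symmetric integer matrix with sample ids as dimnames.
#' @export
shared_site_counts <- function(calls_by_sample, match = c("allele", "position")) {
  match <- match.arg(match)
  keys <- lapply(calls_by_sample, function(d) {
    k <- if (match == "allele") paste(d$chrom, d$pos, d$variant)
         else paste(d$chrom, d$pos)
    unique(k)
  })
  ns <- length(keys)
  m <- matrix(0L, ns, ns, dimnames = list(names(keys), names(keys)))
  for (i in seq_len(ns)) {
    m[i, i] <- length(keys[[i]])
    if (i < ns) for (j in seq.int(i + 1L, ns)) {
      m[i, j] <- m[j, i] <- length(intersect(keys[[i]], keys[[j]]))
    }
  }
  m
}

#' Compare mean heteroplasmy levels between groups
#'
#' Two-sample t-test (Welch by default, pooled-variance optional) on
#' per-sample totals, or a one-sample t-test against a constant `mu`. Means
#' and standard deviations use the `n - 1` denominator; the standard error
#' of the mean is also reported. When both groups have zero variance and
#' equal means the comparison is reported with `t = 0`, `p = 1`; zero
#' variance with unequal means (or in one-sample mode) is an error, since
#' the t statistic is undefined there.
#'
#' @param values_a Numeric vector of per-sample values (group A).
#' @param values_b Numeric vector (group B), or `NULL` for one-sample mode.
#' @param mu Constant to test against in one-sample mode.
#' @param method `"welch"` or `"pooled"` (two-sample only).
#' @param labels Length-2 character vector of group labels.
#' @return One-row data.frame: `group_a, group_b, n_a, n_b, mean_a, mean_b,
#'   sd_a, sd_b, sem_a, sem_b, t, df, p, method`.
#' @export
compare_groups <- function(values_a, values_b = NULL, mu = NULL,
                           method = c("welch", "pooled"),
                           labels = c("A", "B")) {
  method <- match.arg(method)
  one_sample <- is.null(values_b)
  if (one_sample) {
    if (is.null(mu)) stop("one-sample mode requires mu")
    if (length(values_a) < 2L) stop("need n >= 2 per group")
    if (sd(values_a) == 0) stop("zero variance: one-sample t undefined; ",
                                "use an exact test")
    tt <- t.test(values_a, mu = mu)
    return(data.frame(group_a = labels[1], group_b = sprintf("mu=%g", mu),
                      n_a = length(values_a), n_b = NA_integer_,
                      mean_a = mean(values_a), mean_b = mu,
                      sd_a = sd(values_a), sd_b = NA_real_,
                      sem_a = sd(values_a) / sqrt(length(values_a)),
                      sem_b = NA_real_,
                      t = unname(tt$statistic), df = unname(tt$parameter),
                      p = tt$p.value, method = "one_sample",
                      stringsAsFactors = FALSE))
  }
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("need n >= 2 per group")
  sa <- sd(values_a); sb <- sd(values_b)
  if (sa == 0 && sb == 0) {
    if (mean(values_a) == mean(values_b)) {
      tt <- list(statistic = 0, parameter = NA_real_, p.value = 1)
    } else {
      stop("zero variance in both groups with unequal means: ",
           "t undefined; use an exact test")
    }
  } else {
    tt <- t.test(values_a, values_b, var.equal = method == "pooled")
  }
  data.frame(group_a = labels[1], group_b = labels[2],
             n_a = length(values_a), n_b = length(values_b),
             mean_a = mean(values_a), mean_b = mean(values_b),
             sd_a = sa, sd_b = sb,
             sem_a = sa / sqrt(length(values_a)),
             sem_b = sb / sqrt(length(values_b)),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, method = method, stringsAsFactors = FALSE)
}

#' Bundled heteroplasmy survey tables
#'
#' Per-sample and per-gene heteroplasmic-site counts from a deep-sequencing
#' survey of the mitochondrial coding regions of 12 human lice (body and
#' head lice from China, France and Ethiopia; 20 minichromosomes per louse)
#' and 7 tick species (single mitochondrial chromosome each), called at
#' minor-allele frequency > 1.5%, `P_f < 1%`, `Q_f < 0.1%`, hotspots
#' excluded. Shipped as plain-text tables for the aggregate-statistics
#' examples and regression checks.
#'
#' @return List of data.frames:
#'   `louse_samples` (sample, country, total, protein, protein_nonsyn,
#'   rrna, trna), `louse_genes` (sample, gene, sites, nonsyn),
#'   `louse_shared` (sample_a, sample_b, shared), `tick_samples`
#'   (species, total, protein, protein_nonsyn, rrna, trna), `tick_genes`
#'   (species, gene, sites, nonsyn).
#' @examples
#' tabs <- survey_tables()
#' sum(tabs$louse_samples$total)  # 494
#' @export
survey_tables <- function() {
  dir <- system.file("extdata", package = "mthet")
  list(
    louse_samples = read.delim(file.path(dir, "louse_samples.tsv"),
                               stringsAsFactors = FALSE),
    louse_genes = read.delim(file.path(dir, "louse_gene_sites.tsv"),
                             stringsAsFactors = FALSE),
    louse_shared = read.delim(file.path(dir, "louse_shared_sites.tsv"),
                              stringsAsFactors = FALSE),
    tick_samples = read.delim(file.path(dir, "tick_samples.tsv"),
                              stringsAsFactors = FALSE),
    tick_genes = read.delim(file.path(dir, "tick_gene_sites.tsv"),
                            stringsAsFactors = FALSE)
  )
}
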