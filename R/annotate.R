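# Gene/codon annotation of passing calls: synonymous vs nonsynonymous
# effects and amino-acid property changes.

#' Classify an amino-acid change by property dimensions
#'
#' Returns the subset of `{hydropathy, polarity, charge}` on which the two
#' amino acids differ. Changes involving a stop codon are nonsense changes:
#' all property dimensions are suppressed (empty result; the caller records
#' the nonsense status separately).
#'
#' @param ref_aa,alt_aa One-letter amino acids (`*` for stop).
#' @param properties Property table (see [default_aa_properties()]).
#' @return Character vector, a subset of
#'   `c("hydropathy", "polarity", "charge")`.
#' @examples
#' classify_aa_change("E", "K")  # charge (and hydropathy/polarity agree)
#' @export
classify_aa_change <- function(ref_aa, alt_aa, properties = default_aa_properties()) {
  if (ref_aa == "*" || alt_aa == "*" || ref_aa == "X" || alt_aa == "X")
    return(character(0))
  i <- match(ref_aa, properties$aa)
  j <- match(alt_aa, properties$aa)
  if (is.na(i) || is.na(j)) stop("amino acid not in property table: ",
                                 ref_aa, "/", alt_aa)
  dims <- c("hydropathy", "polarity", "charge")
  dims[vapply(dims, function(d) properties[[d]][i] != properties[[d]][j],
              logical(1))]
}

#' Annotate heteroplasmy calls with gene and codon context
#'
#' Each call is located in the gene annotations ([locate_site()]). For
#' protein-coding genes the affected codon is read on the coding strand from
#' the consensus/reference sequence, the variant base (complemented for
#' minus-strand genes) is substituted at the codon position, and both codons
#' are translated with the gene's translation table. tRNA calls report
#' whether they hit the third anticodon base (when `anticodon_start` is
#' annotated). Calls in overlapping annotations yield one row per
#' annotation unit; intergenic calls are retained with
#' `gene_class = "intergenic"`.
#'
#' @param calls Call data.frame (`chrom, pos, consensus, variant`, typically
#'   the `status == "pass"` subset).
#' @param ref `ref_set` of the sequences the calls were made against (the
#'   per-sample consensus in the standard workflow).
#' @param ann Validated annotation data.frame.
#' @param properties Amino-acid property table.
#' @return `calls` with annotation columns appended: `gene, gene_class,
#'   strand, codon_number, codon_position, ref_codon, alt_codon, ref_aa,
#'   alt_aa, synonymous, nonsense, property_changes, anticodon_third`.
#'   `synonymous` is `NA` outside protein genes and for unknown codons;
#'   `property_changes` is a comma-joined subset of
#'   `hydropathy,polarity,charge` (empty when synonymous).
#' @export
annotate_calls <- function(calls, ref, ann, properties = default_aa_properties()) {
  codes <- new.env(parent = emptyenv())
  get_code <- function(id) {
    key <- as.character(id)
    if (is.null(codes[[key]])) codes[[key]] <- genetic_code(id)
    codes[[key]]
  }
  out <- lapply(seq_len(nrow(calls)), function(i) {
    ctx <- locate_site(calls$chrom[i], calls$pos[i], ann, ref)
    ctx$alt_codon <- NA_character_
    ctx$ref_aa <- NA_character_
    ctx$alt_aa <- NA_character_
    ctx$synonymous <- NA
    ctx$nonsense <- NA
    ctx$property_changes <- NA_character_
    for (j in seq_len(nrow(ctx))) {
      if (identical(ctx$gene_class[j], "protein") && !is.na(ctx$codon_position[j])) {
        sub_base <- calls$variant[i]
        if (ctx$strand[j] == "-") sub_base <- chartr("ACGTN", "TGCAN", sub_base)
        alt <- ctx$ref_codon[j]
        substr(alt, ctx$codon_position[j], ctx$codon_position[j]) <- sub_base
        ctx$alt_codon[j] <- alt
        tt <- ann$transl_table[ann$gene == ctx$gene[j] & ann$chrom == calls$chrom[i]][1]
        code <- get_code(if (is.na(tt)) 5L else tt)
        ctx$ref_aa[j] <- translate_codon(ctx$ref_codon[j], code)
        ctx$alt_aa[j] <- translate_codon(alt, code)
        if (ctx$ref_aa[j] == "X" || ctx$alt_aa[j] == "X") {
          ctx$synonymous[j] <- NA       # unknown effect, excluded from tallies
        } else {
          ctx$synonymous[j] <- ctx$ref_aa[j] == ctx$alt_aa[j]
          ctx$nonsense[j] <- ctx$ref_aa[j] == "*" || ctx$alt_aa[j] == "*"
          pc <- if (ctx$synonymous[j]) character(0)
                else classify_aa_change(ctx$ref_aa[j], ctx$alt_aa[j], properties)
          ctx$property_changes[j] <- paste(pc, collapse = ",")
        }
      }
    }
    cbind(calls[rep(i, nrow(ctx)), , drop = FALSE], ctx, row.names = NULL)
  })
  do.call(rbind, out)
}
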