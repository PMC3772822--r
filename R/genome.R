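# Reference sequences, gene annotations, genetic code and amino-acid
# properties; mapping of genomic sites to genes and codons.

#' Load a reference set from FASTA
#'
#' Reads one record per chromosome (a louse minichromosome or a whole tick
#' mitochondrial chromosome), upper-cases the sequences and validates the
#' alphabet.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param topology `"circular"` (mitochondrial default) or `"linear"`, either
#'   a single value recycled to all records or one value per record.
#' @return A `ref_set` object: list with `seqs` (named character vector of
#'   sequences over `A,C,G,T,N`), `topology` (named character vector), and
#'   `lengths` (named integer vector).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGTAA"), fa)
#' ref <- load_reference_set(fa)
#' ref$lengths
#' @export
load_reference_set <- function(path, topology = "circular") {
  stopifnot(file.exists(path))
  xs <- Biostrings::readBStringSet(path)
  if (length(xs) == 0L) stop("empty FASTA: no records in ", path)
  ids <- sub("\\s.*$", "", names(xs))
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(xs))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0L) {
      stop("non-IUPAC character '", substr(seqs[[i]], bad, bad),
           "' in record '", ids[i], "' at offset ", bad)
    }
  }
  ref_set(seqs, topology)
}

#' Construct a reference set from in-memory sequences
#'
#' @param seqs Named character vector of DNA sequences (`A,C,G,T,N`).
#' @param topology `"circular"` or `"linear"`, recycled or per sequence.
#' @return A `ref_set` object.
#' @export
ref_set <- function(seqs, topology = "circular") {
  stopifnot(is.character(seqs), length(seqs) > 0L, !is.null(names(seqs)))
  seqs <- toupper(seqs)
  topology <- match.arg(topology, c("circular", "linear"), several.ok = TRUE)
  topology <- rep_len(topology, length(seqs))
  names(topology) <- names(seqs)
  structure(
    list(seqs = seqs, topology = topology, lengths = setNames(nchar(seqs), names(seqs))),
    class = "ref_set"
  )
}

#' @export
print.ref_set <- function(x, ...) {
  cat("ref_set with", length(x$seqs), "sequence(s), total",
      sum(x$lengths), "bp\n")
  invisible(x)
}

#' Write a reference set to FASTA
#'
#' @param ref A `ref_set`.
#' @param path Output FASTA path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_reference_set <- function(ref, path, width = 70L) {
  xs <- Biostrings::DNAStringSet(ref$seqs)
  Biostrings::writeXStringSet(xs, path, width = width)
  invisible(path)
}

#' Read gene annotations
#'
#' Annotations are a tab-separated table with header columns `gene`, `chrom`,
#' `start`, `end`, `strand`, `class`, `frame_offset`, `transl_table`,
#' `anticodon_start`. Coordinates are 1-based inclusive. On circular
#' chromosomes an origin-spanning gene may have `end < start` and is
#' interpreted modulo the chromosome length. `frame_offset` (0/1/2) is the
#' offset of the first complete codon from the gene start on the coding
#' strand; `anticodon_start` is the coding-strand genomic position of the
#' first anticodon base (tRNA genes only, optional, NA otherwise).
#'
#' @param path Path to the annotation TSV.
#' @param ref Optional `ref_set`; if supplied, coordinates are validated
#'   against chromosome ids and lengths.
#' @return A data.frame with the columns above plus `length` (gene span in
#'   bases).
#' @export
read_annotations <- function(path, ref = NULL) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  validate_annotations(ann, ref)
}

#' Validate an annotation table
#'
#' @param ann Annotation data.frame (see [read_annotations()]).
#' @param ref Optional `ref_set` for coordinate checks.
#' @return The validated data.frame with a `length` column added.
#' @export
validate_annotations <- function(ann, ref = NULL) {
  need <- c("gene", "chrom", "start", "end", "strand", "class")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(ann$frame_offset)) ann$frame_offset <- 0L
  if (is.null(ann$transl_table)) ann$transl_table <- 5L
  if (is.null(ann$anticodon_start)) ann$anticodon_start <- NA_integer_
  ann$frame_offset[is.na(ann$frame_offset)] <- 0L
  ann$transl_table[is.na(ann$transl_table)] <- 5L
  stopifnot(all(ann$strand %in% c("+", "-")),
            all(ann$class %in% c("protein", "rRNA", "tRNA")),
            all(ann$frame_offset %in% 0:2),
            all(ann$start >= 1L), all(ann$end >= 1L))
  is_trn <- startsWith(ann$gene, "trn")
  if (any(is_trn != (ann$class == "tRNA"))) {
    stop("gene names starting with 'trn' must have class tRNA and vice versa: ",
         paste(ann$gene[is_trn != (ann$class == "tRNA")], collapse = ", "))
  }
  if (!is.null(ref)) {
    bad <- setdiff(ann$chrom, names(ref$seqs))
    if (length(bad)) stop("annotation chroms absent from reference: ",
                          paste(unique(bad), collapse = ", "))
    for (i in seq_len(nrow(ann))) {
      len <- unname(ref$lengths[[ann$chrom[i]]])
      circ <- ref$topology[[ann$chrom[i]]] == "circular"
      if (ann$start[i] > len || ann$end[i] > len)
        stop("gene ", ann$gene[i], " exceeds chromosome ", ann$chrom[i],
             " length ", len)
      if (ann$end[i] < ann$start[i] && !circ)
        stop("gene ", ann$gene[i], ": end < start on linear chromosome ",
             ann$chrom[i])
    }
    ann$length <- vapply(seq_len(nrow(ann)), function(i) {
      length(gene_span(ann$start[i], ann$end[i], unname(ref$lengths[[ann$chrom[i]]])))
    }, integer(1))
  } else {
    ann$length <- ifelse(ann$end >= ann$start, ann$end - ann$start + 1L, NA_integer_)
  }
  ann
}

#' Write an annotation table
#' @param ann Annotation data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  cols <- c("gene", "chrom", "start", "end", "strand", "class",
            "frame_offset", "transl_table", "anticodon_start")
  write.table(ann[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# genomic positions of a gene span in genomic order; origin-spanning genes
# (end < start) wrap modulo the chromosome length
gene_span <- function(start, end, chrom_len) {
  if (end >= start) seq.int(start, end)
  else c(seq.int(start, chrom_len), seq.int(1L, end))
}

# gene positions in coding (5'->3' on the coding strand) order
coding_positions <- function(start, end, strand, chrom_len) {
  sp <- gene_span(start, end, chrom_len)
  if (strand == "-") rev(sp) else sp
}

#' The invertebrate mitochondrial genetic code
#'
#' Translation table 5: relative to the standard code, `TGA` encodes Trp,
#' `AGA`/`AGG` encode Ser and `ATA` encodes Met.
#'
#' @param table_id NCBI translation table id (default 5).
#' @return Named character vector mapping all 64 codons to one-letter amino
#'   acids (`*` for stop).
#' @examples
#' genetic_code()[["TGA"]]  # "W"
#' @export
genetic_code <- function(table_id = 5L) {
  Biostrings::getGeneticCode(as.character(table_id))
}

#' Translate one codon
#'
#' @param codon A 3-base string over `A,C,G,T` (upper case). Codons
#'   containing any other character (e.g. `N`) translate to the unknown
#'   sentinel `"X"`, never silently to an amino acid.
#' @param code Codon table from [genetic_code()].
#' @return One-letter amino acid, `"*"` for stop, or `"X"` for unknown.
#' @export
translate_codon <- function(codon, code = genetic_code()) {
  vapply(toupper(codon), function(cd) {
    aa <- code[cd]
    if (is.na(aa)) "X" else unname(aa)
  }, character(1), USE.NAMES = FALSE)
}

#' Default amino-acid property table
#'
#' Three binary classifications used to characterise nonsynonymous changes:
#' hydropathy (hydrophobic vs hydrophilic), polarity (polar vs nonpolar) and
#' charge (`+`, `-`, `0`). Hydrophobic = A,V,L,I,M,F,W,C,Y; polar =
#' S,T,N,Q,Y,C,H,K,R,D,E; positive = K,R,H; negative = D,E. An alternative
#' classification can be supplied as a data.frame of the same shape
#' (columns `aa`, `hydropathy`, `polarity`, `charge`) or read with
#' [read_aa_properties()].
#'
#' @return data.frame with one row per standard amino acid.
#' @export
default_aa_properties <- function() {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  hydrophobic <- c("A","V","L","I","M","F","W","C","Y")
  polar <- c("S","T","N","Q","Y","C","H","K","R","D","E")
  pos <- c("K","R","H"); neg <- c("D","E")
  data.frame(
    aa = aa,
    hydropathy = ifelse(aa %in% hydrophobic, "hydrophobic", "hydrophilic"),
    polarity = ifelse(aa %in% polar, "polar", "nonpolar"),
    charge = ifelse(aa %in% pos, "+", ifelse(aa %in% neg, "-", "0")),
    stringsAsFactors = FALSE
  )
}

#' Read an amino-acid property table from TSV
#' @param path TSV with header columns `aa`, `hydropathy`, `polarity`,
#'   `charge` covering all 20 standard amino acids.
#' @return Validated data.frame.
#' @export
read_aa_properties <- function(path) {
  pr <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("aa", "hydropathy", "polarity", "charge") %in% names(pr)))
  if (!all(default_aa_properties()$aa %in% pr$aa))
    stop("property table must cover all 20 standard amino acids")
  pr
}

#' Locate a genomic site within gene annotations
#'
#' Maps a (chrom, pos) pair to its annotation context: gene, gene class and —
#' for protein-coding genes — codon number, codon position (1/2/3) and the
#' reference codon read on the coding strand (minus-strand genes are
#' reverse-complemented). tRNA sites report whether the position is the third
#' anticodon base when `anticodon_start` is annotated. Sites outside all
#' annotations return a single `intergenic` row. Sites inside overlapping
#' annotations return one row per annotation.
#'
#' @param chrom Chromosome id.
#' @param pos 1-based position.
#' @param ann Validated annotation data.frame.
#' @param ref `ref_set` containing `chrom`.
#' @return data.frame with columns `gene`, `gene_class`, `strand`,
#'   `codon_number`, `codon_position`, `ref_codon`, `anticodon_third`.
#' @export
locate_site <- function(chrom, pos, ann, ref) {
  len <- unname(ref$lengths[[chrom]])
  if (is.null(len) || is.na(len)) stop("unknown chromosome: ", chrom)
  if (pos < 1L || pos > len) stop("position ", pos, " outside ", chrom)
  seq <- ref$seqs[[chrom]]
  rows <- which(ann$chrom == chrom)
  hits <- rows[vapply(rows, function(i) {
    pos %in% gene_span(ann$start[i], ann$end[i], len)
  }, logical(1))]
  if (!length(hits)) {
    return(data.frame(gene = NA_character_, gene_class = "intergenic",
                      strand = NA_character_, codon_number = NA_integer_,
                      codon_position = NA_integer_, ref_codon = NA_character_,
                      anticodon_third = NA, stringsAsFactors = FALSE))
  }
  out <- lapply(hits, function(i) {
    cp <- coding_positions(ann$start[i], ann$end[i], ann$strand[i], len)
    idx0 <- match(pos, cp) - 1L  # 0-based index along the coding strand
    codon_number <- codon_position <- NA_integer_
    ref_codon <- NA_character_
    anticodon_third <- NA
    if (ann$class[i] == "protein") {
      off <- idx0 - ann$frame_offset[i]
      if (off >= 0L && off < 3L * ((length(cp) - ann$frame_offset[i]) %/% 3L)) {
        codon_number <- off %/% 3L + 1L
        codon_position <- off %% 3L + 1L
        cpos <- cp[ann$frame_offset[i] + (codon_number - 1L) * 3L + 1:3]
        bases <- substring(seq, cpos, cpos)
        if (ann$strand[i] == "-") bases <- chartr("ACGTN", "TGCAN", bases)
        ref_codon <- paste(bases, collapse = "")
      }
    } else if (ann$class[i] == "tRNA" && !is.na(ann$anticodon_start[i])) {
      ac1 <- match(ann$anticodon_start[i], cp)
      anticodon_third <- !is.na(ac1) && idx0 == (ac1 - 1L) + 2L
    }
    data.frame(gene = ann$gene[i], gene_class = ann$class[i],
               strand = ann$strand[i], codon_number = codon_number,
               codon_position = codon_position, ref_codon = ref_codon,
               anticodon_third = anticodon_third, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
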