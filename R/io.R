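# File emission and ingestion. Emitted files follow their standards
# (FASTA, GFF3 1-based, VCF v4.2 1-based, BED 0-based half-open, TSV).

#' Write genome (and optionally vector) sequences as FASTA
#'
#' @param genome a `toy_genome`, `transgenic_genome`, or named character
#'   vector of sequences.
#' @param path output file.
#' @param construct optional `tdna_construct` appended as one extra
#'   vector contig (the combined mapping reference).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, construct = NULL) {
  seqs <- if (is.character(genome)) genome else genome$contigs
  if (!is.null(construct)) {
    seqs <- c(seqs, stats::setNames(construct$seq, construct$vector_id))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write gene models as GFF3
#'
#' Emits gene / mRNA (or ncRNA for lincRNA) / exon / CDS / UTR rows with
#' ID and Parent attributes; the canonical transcript carries
#' `canonical=1` and genes carry their `biotype`.
#'
#' @param genome a `toy_genome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(genome$contigs),
                     nchar(genome$contigs)))
  g <- genome$genes
  f <- genome$features
  type_order <- c(exon = 1, CDS = 2, five_prime_UTR = 3, three_prime_UTR = 4)
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    lines <- c(lines, sprintf(
      "%s\ttgintegrity\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
      gi$contig, gi$start, gi$end, gi$strand, gi$gene_id, gi$biotype))
    fs <- f[f$gene_id == gi$gene_id, , drop = FALSE]
    for (tid in sort(unique(fs$transcript_id))) {
      ft <- fs[fs$transcript_id == tid, , drop = FALSE]
      ttype <- if (gi$biotype == "protein_coding") "mRNA" else "ncRNA"
      canon <- if (tid == gi$canonical) ";canonical=1" else ""
      lines <- c(lines, sprintf(
        "%s\ttgintegrity\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s%s",
        gi$contig, ttype, min(ft$start), max(ft$end), gi$strand, tid,
        gi$gene_id, canon))
      ft <- ft[order(type_order[ft$type], ft$start), , drop = FALSE]
      phase <- 0L
      for (j in seq_len(nrow(ft))) {
        ph <- "."
        if (ft$type[j] == "CDS") ph <- "0"  # frames handled by generator
        lines <- c(lines, sprintf(
          "%s\ttgintegrity\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s",
          gi$contig, ft$type[j], ft$start[j], ft$end[j], gi$strand, ph, tid))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Rebuilds the `genes`/`features` tables used throughout the package
#' from a GFF3 written by [write_gff3()] (or any GFF3 with gene /
#' transcript / exon / CDS / UTR rows and ID/Parent attributes).
#'
#' @param path GFF3 file.
#' @return a list with `genes` and `features` data frames, usable in
#'   place of a `toy_genome` for annotation when paired with sequences.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  gene_rows <- df[df$type == "gene", , drop = FALSE]
  tx_rows <- df[df$type %in% c("mRNA", "ncRNA", "transcript"), , drop = FALSE]
  tx_parent <- vapply(tx_rows$Parent, function(p) p[[1]], character(1))
  canon <- if ("canonical" %in% names(tx_rows)) {
    !is.na(tx_rows$canonical)
  } else rep(TRUE, nrow(tx_rows))
  feat_rows <- df[df$type %in% c("exon", "CDS", "five_prime_UTR",
                                 "three_prime_UTR"), , drop = FALSE]
  fp <- vapply(feat_rows$Parent, function(p) p[[1]], character(1))
  tx2gene <- stats::setNames(tx_parent, tx_rows$ID)

  features <- data.frame(
    gene_id = unname(tx2gene[fp]), transcript_id = fp,
    contig = feat_rows$seqnames, strand = feat_rows$strand,
    type = feat_rows$type, start = feat_rows$start, end = feat_rows$end,
    stringsAsFactors = FALSE)

  canonical <- stats::setNames(rep(NA_character_, nrow(gene_rows)),
                               gene_rows$ID)
  # canonical transcript flagged in the file; fall back to longest CDS
  flagged <- tx_rows$ID[canon]
  canonical[tx2gene[flagged]] <- flagged
  genes <- data.frame(
    gene_id = gene_rows$ID, contig = gene_rows$seqnames,
    strand = gene_rows$strand,
    biotype = if ("biotype" %in% names(gene_rows)) gene_rows$biotype
              else "protein_coding",
    start = gene_rows$start, end = gene_rows$end,
    canonical = unname(canonical[gene_rows$ID]), stringsAsFactors = FALSE)
  miss <- which(is.na(genes$canonical))
  for (i in miss) {
    genes$canonical[i] <- select_canonical_tx(genes$gene_id[i], features)
  }
  list(genes = genes, features = features)
}

#' Write the contig-to-chromosome placement map as TSV
#' @param genome a `toy_genome` with a `chrom_map`.
#' @param path output file.
#' @export
write_chrom_map <- function(genome, path) {
  stopifnot(!is.null(genome$chrom_map))
  utils::write.table(genome$chrom_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a contig-to-chromosome map TSV
#' @param path TSV with columns contig, chrom, offset.
#' @export
read_chrom_map <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a callset as VCF v4.2
#'
#' Records carry QUAL and INFO fields `DP` (total depth), `SAF`/`SAR`
#' (alt-supporting reads on the forward/reverse strand) and `TYPE`.
#'
#' @param callset a callset data frame (contig, pos, id, ref, alt, vtype
#'   and optionally qual, depth, alt_fwd, alt_rev).
#' @param path output file.
#' @param contig_lengths named lengths for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(callset, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=tgintegrity",
           if (!is.null(contig_lengths)) {
             sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                     as.integer(contig_lengths))
           },
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
           "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Alt support, forward strand\">",
           "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Alt support, reverse strand\">",
           "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  n <- nrow(callset)
  if (n) {
    qual <- if ("qual" %in% names(callset)) callset$qual else rep(".", n)
    info <- sprintf("DP=%s;SAF=%s;SAR=%s;TYPE=%s",
                    if ("depth" %in% names(callset)) callset$depth else ".",
                    if ("alt_fwd" %in% names(callset)) callset$alt_fwd else ".",
                    if ("alt_rev" %in% names(callset)) callset$alt_rev else ".",
                    callset$vtype)
    body <- paste(callset$contig, callset$pos, callset$id, callset$ref,
                  callset$alt, qual, "PASS", info, sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF callset
#'
#' Parses with vcfR and extracts QUAL plus the depth and strand-support
#' INFO fields (tag names configurable, defaults `DP`, `SAF`, `SAR`).
#'
#' @param path VCF file.
#' @param dp_tag,saf_tag,sar_tag INFO tag names for depth and per-strand
#'   alt support.
#' @return a callset data frame.
#' @export
read_vcf <- function(path, dp_tag = "DP", saf_tag = "SAF", sar_tag = "SAR") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  if (nrow(fx) == 0) return(.empty_callset())
  num <- function(tag) suppressWarnings(as.numeric(vcfR::extract.info(v, tag)))
  out <- data.frame(
    contig = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
    id = fx[, "ID"], ref = fx[, "REF"], alt = fx[, "ALT"],
    qual = suppressWarnings(as.numeric(fx[, "QUAL"])),
    depth = as.integer(num(dp_tag)),
    alt_fwd = as.integer(num(saf_tag)), alt_rev = as.integer(num(sar_tag)),
    stringsAsFactors = FALSE)
  out$vtype <- classify_type(out$ref, out$alt)
  rownames(out) <- NULL
  out[, c("contig", "pos", "id", "ref", "alt", "vtype", "qual", "depth",
          "alt_fwd", "alt_rev")]
}

.empty_callset <- function() {
  data.frame(contig = character(), pos = integer(), id = character(),
             ref = character(), alt = character(), vtype = character(),
             qual = numeric(), depth = integer(), alt_fwd = integer(),
             alt_rev = integer(), stringsAsFactors = FALSE)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals data frame with columns contig, start, end in the
#'   package's 1-based closed convention.
#' @param path output file.
#' @param names optional name column.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, names = NULL) {
  if (nrow(intervals) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- paste(intervals$contig, intervals$start - 1L, intervals$end,
                 sep = "\t")
  if (!is.null(names)) lines <- paste(lines, names, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a data frame as TSV
#' @param df data frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
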