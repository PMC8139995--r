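# Paired-end read simulation over a transgenic genome, with truth
# alignments expressed against the combined genome+vector reference.
# Sequencing errors are substitutions only: variant calling downstream is
# emulated from truth sets, not re-derived from pileups.

#' Simulate paired-end reads with truth alignments
#'
#' Fragments are drawn uniformly over the transgenic contigs with a
#' Normal fragment-length law; read 1 is the forward end, read 2 the
#' reverse-complemented other end. Each read's truth alignment against
#' the combined reference (original genome contigs plus the vector
#' contig) is derived from the transgenic-to-reference segment map:
#' fully genomic reads align with simple matches, reads overlapping an
#' integration junction are soft-clipped at the junction (the segment
#' with the largest overlap wins), and fully-insert reads align to the
#' vector contig.
#'
#' @param tg a `transgenic_genome` (or a `toy_genome` for insert-free
#'   control data).
#' @param coverage mean fold coverage (default 35).
#' @param read_len read length in bases (default 100).
#' @param insert_mean,insert_sd fragment-length law in bases.
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @return a list with `aln` (truth alignment data frame in SAM column
#'   order), `origins` (per-read true source interval on the transgenic
#'   genome), `sq` (named reference sequence lengths for the SAM header)
#'   and `fastq` (read names and sequenced strings for both mates).
#' @export
simulate_reads <- function(tg, coverage = 35, read_len = 100,
                           insert_mean = 500, insert_sd = 60,
                           error_rate = 0.001, seed = NULL) {
  if (inherits(tg, "toy_genome")) {
    segs <- do.call(rbind, lapply(names(tg$contigs), function(nm) {
      data.frame(t_contig = nm, t_start = 1L, t_end = nchar(tg$contigs[[nm]]),
                 target = nm, r_start = 1L, stringsAsFactors = FALSE)
    }))
    tg <- list(contigs = tg$contigs, ref = tg, construct = NULL,
               segments = segs, insertion = NULL)
  }
  stopifnot(coverage > 0, read_len <= insert_mean)
  lens <- nchar(tg$contigs)
  if (min(lens) < insert_mean + 4 * insert_sd) {
    stop("genome shorter than insert_mean + 4*insert_sd")
  }
  set_seed_if(seed)

  total <- sum(lens)
  n_frag <- ceiling(coverage * total / (2 * read_len))
  frag_contig <- sample(names(lens), n_frag, replace = TRUE,
                        prob = lens / total)

  out_aln <- list(); out_orig <- list(); out_fq <- list()
  for (nm in names(lens)) {
    idx <- which(frag_contig == nm)
    if (!length(idx)) next
    len <- lens[[nm]]
    k <- length(idx)
    flen <- pmin(pmax(round(stats::rnorm(k, insert_mean, insert_sd)),
                      2L * read_len), len)
    fs <- floor(stats::runif(k, 1, len - flen + 1 + 1))
    fe <- fs + flen - 1L
    qname <- sprintf("frag_%s_%06d", nm, seq_len(k))

    r1s <- fs; r1e <- fs + read_len - 1L
    r2s <- fe - read_len + 1L; r2e <- fe
    seq1 <- .sequence_with_errors(tg$contigs[[nm]], r1s, r1e, error_rate)
    seq2 <- .sequence_with_errors(tg$contigs[[nm]], r2s, r2e, error_rate)

    segs <- tg$segments[tg$segments$t_contig == nm, , drop = FALSE]
    a1 <- .map_reads(segs, r1s, r1e)
    a2 <- .map_reads(segs, r2s, r2e)

    same <- a1$rname == a2$rname
    flag1 <- 1L + ifelse(same, 2L, 0L) + 32L + 64L
    flag2 <- 1L + ifelse(same, 2L, 0L) + 16L + 128L
    lo <- pmin(a1$pos, a2$pos)
    hi <- pmax(a1$pos + a1$ref_width - 1L, a2$pos + a2$ref_width - 1L)
    span <- hi - lo + 1L
    tlen1 <- ifelse(!same, 0L, ifelse(a1$pos <= a2$pos, span, -span))
    tlen2 <- ifelse(!same, 0L, -tlen1)

    mk <- function(a, flag, seqs, mate, tlen) {
      data.frame(qname = qname, flag = flag, rname = a$rname, pos = a$pos,
                 mapq = 60L, cigar = a$cigar,
                 rnext = ifelse(same, "=", mate$rname), pnext = mate$pos,
                 tlen = tlen, seq = seqs, qual = strrep("I", read_len),
                 stringsAsFactors = FALSE)
    }
    out_aln[[length(out_aln) + 1L]] <- rbind(
      mk(a1, flag1, seq1, a2, tlen1), mk(a2, flag2, seq2, a1, tlen2))
    out_orig[[length(out_orig) + 1L]] <- data.frame(
      qname = rep(qname, 2), mate = rep(1:2, each = k),
      t_contig = nm, t_start = c(r1s, r2s), t_end = c(r1e, r2e),
      strand = rep(c("+", "-"), each = k), stringsAsFactors = FALSE)
    out_fq[[length(out_fq) + 1L]] <- data.frame(
      qname = qname, seq1 = seq1, seq2 = revcomp(seq2),
      stringsAsFactors = FALSE)
  }

  aln <- do.call(rbind, out_aln)
  sq <- c(vapply(tg$ref$contigs, nchar, integer(1)),
          if (!is.null(tg$construct)) {
            stats::setNames(nchar(tg$construct$seq), tg$construct$vector_id)
          })
  aln <- aln[order(match(aln$rname, names(sq)), aln$pos), , drop = FALSE]
  rownames(aln) <- NULL
  list(aln = aln, origins = do.call(rbind, out_orig), sq = sq,
       fastq = do.call(rbind, out_fq))
}

# Map read intervals [s, e] (transgenic coordinates, one contig) onto the
# combined reference: the segment with the largest overlap carries the
# aligned block, the rest is soft-clipped.
.map_reads <- function(segs, s, e) {
  n <- length(s)
  ov <- matrix(0L, n, nrow(segs))
  for (j in seq_len(nrow(segs))) {
    ov[, j] <- ivl_intersect_len(s, e, segs$t_start[j], segs$t_end[j])
  }
  best <- max.col(ov, ties.method = "first")
  seg_s <- segs$t_start[best]; seg_e <- segs$t_end[best]
  as_ <- pmax(s, seg_s); ae <- pmin(e, seg_e)
  lead <- as_ - s; trail <- e - ae
  m <- ae - as_ + 1L
  cigar <- paste0(ifelse(lead > 0L, paste0(lead, "S"), ""), m, "M",
                  ifelse(trail > 0L, paste0(trail, "S"), ""))
  data.frame(rname = segs$target[best],
             pos = segs$r_start[best] + (as_ - seg_s),
             cigar = cigar, ref_width = m, stringsAsFactors = FALSE)
}

.sequence_with_errors <- function(contig, s, e, error_rate) {
  seqs <- substring(contig, s, e)
  if (error_rate <= 0) return(seqs)
  rl <- e[1] - s[1] + 1L
  n_err <- stats::rbinom(length(seqs), rl, error_rate)
  for (i in which(n_err > 0L)) {
    ch <- strsplit(seqs[i], "")[[1]]
    at <- sample.int(rl, n_err[i])
    ch[at] <- vapply(ch[at], function(b) sample(setdiff(BASES, b), 1),
                     character(1))
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Write paired FASTQ files (Phred+33, constant quality)
#'
#' @param sim result of [simulate_reads()].
#' @param prefix output path prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq`.
#' @return the two file paths, invisibly.
#' @export
write_fastq <- function(sim, prefix) {
  fq <- sim$fastq
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (m in 1:2) {
    seqs <- if (m == 1) fq$seq1 else fq$seq2
    qual <- strrep("I", nchar(seqs))
    writeLines(paste0("@", fq$qname, "/", m, "\n", seqs, "\n+\n", qual),
               paths[m])
  }
  invisible(paths)
}

#' Write a truth SAM file against the combined reference
#'
#' Coordinate-sorted, with `@HD`/`@SQ` header lines for every genome
#' contig and the vector contig.
#'
#' @param sim result of [simulate_reads()] (or a list with `aln` and
#'   `sq`).
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sim, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sim$sq), as.integer(sim$sq)))
  a <- sim$aln
  body <- paste(a$qname, a$flag, a$rname, a$pos, a$mapq, a$cigar, a$rnext,
                a$pnext, a$tlen, a$seq, a$qual, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignments from a SAM/BAM file
#'
#' SAM input is converted with Rsamtools and scanned back into the plain
#' data-frame representation used by the insertion scanner.
#'
#' @param path SAM or BAM file.
#' @return a data frame (qname, flag, rname, pos, cigar, seq, rnext,
#'   pnext).
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "cigar", "seq", "mrnm", "mpos"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  data.frame(qname = x$qname, flag = x$flag, rname = as.character(x$rname),
             pos = x$pos, cigar = x$cigar, seq = as.character(x$seq),
             rnext = as.character(x$mrnm), pnext = x$mpos,
             stringsAsFactors = FALSE)
}
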