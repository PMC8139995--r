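# Shared low-level helpers. All internal coordinates are 1-based closed
# intervals (the Bioconductor convention); emitted files follow their own
# standards (VCF/GFF3/SAM 1-based, BED 0-based half-open).

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @noRd
rand_dna <- function(n, gc = 0.35) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of character sequences
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Substitute `replacement` into `seq` at 1-based position `at`
#' @noRd
str_splice <- function(seq, at, replacement) {
  paste0(substr(seq, 1L, at - 1L), replacement,
         substr(seq, at + nchar(replacement), nchar(seq)))
}

# random open reading frame: ATG + (n_codons - 2) sense codons + stop
rand_orf <- function(n_codons) {
  stopifnot(n_codons >= 2)
  all_codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  sense <- setdiff(all_codons, STOP_CODONS)
  paste0("ATG",
         paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1L))
}

# no.init.codon: codons are translated positionally (CTG is Leu, not an
# alternative initiator), which is what codon-wise effect calls need
translate_dna <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

#' Does interval [s1,e1] overlap [s2,e2]? (1-based closed)
#' @noRd
ivl_overlaps <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2

# length of the intersection of [s1,e1] with [s2,e2], 0 when disjoint
ivl_intersect_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
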