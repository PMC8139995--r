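# Symmetric DUST-style low-complexity masking, built from scratch.
# An interval of length L (with k = L - 2 overlapping triplets) scores
# S = sum over the 64 triplet types of c_t (c_t - 1) / 2; it is
# low-complexity when 10 * S / k exceeds the threshold. The mask is the
# union of all qualifying intervals no longer than the window. Triplets
# containing N are invalid and contribute nothing.

#' DUST low-complexity masking
#'
#' @param seq a nucleotide sequence over A/C/G/T/N.
#' @param window maximum interval length considered (>= 3).
#' @param threshold score threshold; an interval is reported when
#'   `10 * S / (len - 2) > threshold`.
#' @return a data frame (start, end) of merged masked intervals, 1-based
#'   closed and sorted; zero rows when nothing qualifies.
#' @export
dust_mask <- function(seq, window = 64, threshold = 20) {
  stopifnot(window >= 3)
  n <- nchar(seq)
  empty <- data.frame(start = integer(), end = integer())
  if (n < 3) return(empty)
  code <- .triplet_codes(seq)          # code[i] = triplet starting at i, NA if invalid
  nt <- length(code)                   # n - 2 triplet start positions
  masked <- logical(n)
  counts <- integer(64)
  for (i in seq_len(nt)) {
    # grow the interval [i, j]; triplets i .. j - 2
    counts[] <- 0L
    s <- 0
    max_j <- 0L
    jmax <- min(i + window - 1L, n)
    for (j in (i + 2L):jmax) {
      t <- code[j - 2L]
      if (!is.na(t)) {
        s <- s + counts[t]             # S increases by the old count
        counts[t] <- counts[t] + 1L
      }
      k <- j - i - 1L
      if (10 * s / k > threshold) max_j <- j
    }
    if (max_j > 0L) masked[i:max_j] <- TRUE
  }
  if (!any(masked)) return(empty)
  r <- rle(masked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# integer code 1..64 for each triplet start position; NA for triplets
# containing anything other than A/C/G/T
.triplet_codes <- function(seq) {
  b <- match(strsplit(toupper(seq), "")[[1]], BASES)  # NA for N etc.
  n <- length(b)
  if (n < 3) return(integer(0))
  b1 <- b[1:(n - 2)]; b2 <- b[2:(n - 1)]; b3 <- b[3:n]
  (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3
}

#' Compute the DUST mask for every contig of a genome
#'
#' @param genome a `toy_genome` or named character vector of sequences.
#' @inheritParams dust_mask
#' @return a data frame (contig, start, end), 1-based closed.
#' @export
dust_mask_genome <- function(genome, window = 64, threshold = 20) {
  seqs <- if (is.character(genome)) genome else genome$contigs
  out <- lapply(names(seqs), function(nm) {
    m <- dust_mask(seqs[[nm]], window, threshold)
    if (nrow(m)) cbind(contig = nm, m) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
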