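# Dual-caller consensus: allele-type classification, normalization to
# primitive representation, the filter cascade, callset intersection and
# the three-line comparison.

#' Classify a variant from its alleles
#'
#' SNP: both alleles length 1; MNP: equal lengths > 1; INS: alt longer
#' with ref a prefix of alt; DEL: the converse; COMPLEX: anything else.
#' Vectorized over ref/alt.
#'
#' @param ref,alt allele strings (A/C/G/T/N, non-empty).
#' @return character vector of SNP/MNP/INS/DEL/COMPLEX.
#' @export
classify_type <- function(ref, alt) {
  if (any(!grepl("^[ACGTNacgtn]+$", c(ref, alt)))) {
    stop("alleles must be non-empty strings over A/C/G/T/N")
  }
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  lr <- nchar(ref); la <- nchar(alt)
  out <- character(length(ref))
  out[lr == 1 & la == 1] <- "SNP"
  out[lr == la & lr > 1] <- "MNP"
  ins <- la > lr & substr(alt, 1, lr) == ref
  del <- lr > la & substr(ref, 1, la) == alt
  out[ins] <- "INS"
  out[del] <- "DEL"
  out[out == ""] <- "COMPLEX"
  out
}

#' Normalize a callset to primitive representation
#'
#' Indels are parsimony-trimmed and left-aligned against the reference;
#' MNPs are decomposed into per-base SNPs tagged with their source record
#' id; COMPLEX records are kept atomic. The output is sorted and
#' duplicate-free.
#'
#' @param callset callset data frame (contig, pos, id, ref, alt, ...).
#' @param reference named character vector of reference sequences (or a
#'   `toy_genome`).
#' @return a primitive callset data frame with a `src_id` column naming
#'   each primitive's source record.
#' @export
normalize_callset <- function(callset, reference) {
  if (!is.character(reference)) reference <- reference$contigs
  if (nrow(callset) == 0) {
    out <- callset
    out$src_id <- character(0)
    return(out)
  }
  if (!all(callset$contig %in% names(reference))) {
    stop("reference does not cover all records")
  }
  carry <- intersect(c("qual", "depth", "alt_fwd", "alt_rev"),
                     names(callset))
  rows <- vector("list", nrow(callset))
  for (i in seq_len(nrow(callset))) {
    rec <- callset[i, ]
    seq <- reference[[rec$contig]]
    if (substr(seq, rec$pos, rec$pos + nchar(rec$ref) - 1L) != rec$ref) {
      stop("record ", rec$id, ": REF allele disagrees with the reference at ",
           rec$contig, ":", rec$pos)
    }
    vt <- classify_type(rec$ref, rec$alt)
    if (vt == "SNP" || vt == "COMPLEX") {
      prim <- data.frame(pos = rec$pos, ref = rec$ref, alt = rec$alt,
                         vtype = vt, stringsAsFactors = FALSE)
    } else if (vt == "MNP") {
      r <- strsplit(rec$ref, "")[[1]]; a <- strsplit(rec$alt, "")[[1]]
      d <- which(r != a)
      prim <- data.frame(pos = rec$pos + d - 1L, ref = r[d], alt = a[d],
                         vtype = "SNP", stringsAsFactors = FALSE)
    } else {
      nrm <- .left_align(seq, rec$pos, rec$ref, rec$alt)
      prim <- data.frame(pos = nrm$pos, ref = nrm$ref, alt = nrm$alt,
                         vtype = classify_type(nrm$ref, nrm$alt),
                         stringsAsFactors = FALSE)
    }
    prim$contig <- rec$contig
    prim$src_id <- rec$id
    for (cc in carry) prim[[cc]] <- rec[[cc]]
    rows[[i]] <- prim
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$contig, names(reference)), out$pos, out$ref,
                   out$alt), , drop = FALSE]
  out <- out[!duplicated(out[, c("contig", "pos", "ref", "alt")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$id <- out$src_id
  out[, c("contig", "pos", "id", "ref", "alt", "vtype", carry, "src_id")]
}

# Parsimony-trim and left-align one indel against the reference, the
# standard way: while both alleles end with the same base, chop it
# (extending leftward from the reference first whenever an allele would
# empty); then trim common leading bases keeping one anchor base.
.left_align <- function(seq, pos, ref, alt) {
  r <- ref; a <- alt
  repeat {
    lr <- nchar(r); la <- nchar(a)
    if (substr(r, lr, lr) == substr(a, la, la)) {
      if (lr == 1L || la == 1L) {
        if (pos <= 1L) break
        pos <- pos - 1L
        b <- substr(seq, pos, pos)
        r <- paste0(b, r); a <- paste0(b, a)
      }
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
      next
    }
    break
  }
  repeat {
    lr <- nchar(r); la <- nchar(a)
    if (lr > 1L && la > 1L && substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2L, lr); a <- substr(a, 2L, la)
      pos <- pos + 1L
    } else break
  }
  list(pos = pos, ref = r, alt = a)
}

#' Filter configuration for the consensus cascade
#'
#' Defaults follow the published cascade: low-complexity exclusion,
#' minimum Phred variant quality 30, read depth strictly greater than 10
#' and strictly less than 29, and at least one alt-supporting read on
#' each strand ("unbiased double-strand coverage").
#'
#' @param min_qual minimum variant quality (inclusive).
#' @param min_depth depth must be strictly greater than this.
#' @param max_depth depth must be strictly less than this.
#' @param min_alt_per_strand minimum alt reads per strand.
#' @param mask optional data frame (contig, start, end) of low-complexity
#'   intervals.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_qual = 30, min_depth = 10, max_depth = 29,
                          min_alt_per_strand = 1, mask = NULL) {
  stopifnot(min_depth < max_depth, min_qual >= 0)
  structure(list(min_qual = min_qual, min_depth = min_depth,
                 max_depth = max_depth,
                 min_alt_per_strand = min_alt_per_strand, mask = mask),
            class = "filter_config")
}

#' Apply the filter cascade to a callset
#'
#' A record survives iff its position is outside the mask, its quality is
#' at least `min_qual`, its depth lies strictly inside
#' (`min_depth`, `max_depth`), and both strands carry at least
#' `min_alt_per_strand` alt reads. Removals are tallied against the first
#' failing filter, in the fixed order mask, quality, minimum depth,
#' maximum depth, strand; records missing depth or strand fields are
#' removed under `malformed`.
#'
#' @param callset callset data frame.
#' @param config a [filter_config()].
#' @return a list with `callset` (survivors) and `tally` (named removal
#'   counts).
#' @export
apply_filters <- function(callset, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  tally <- c(mask = 0L, quality = 0L, min_depth = 0L, max_depth = 0L,
             strand = 0L, malformed = 0L)
  if (nrow(callset) == 0) return(list(callset = callset, tally = tally))

  fail <- rep("", nrow(callset))
  m <- config$mask
  if (!is.null(m) && nrow(m)) {
    in_mask <- vapply(seq_len(nrow(callset)), function(i) {
      mm <- m[m$contig == callset$contig[i], , drop = FALSE]
      nrow(mm) > 0 && any(callset$pos[i] >= mm$start & callset$pos[i] <= mm$end)
    }, logical(1))
    fail[fail == "" & in_mask] <- "mask"
  }
  qual <- callset$qual
  fail[fail == "" & (is.na(qual) | qual < config$min_qual)] <- "quality"
  depth <- callset$depth
  malformed <- is.na(depth) | is.na(callset$alt_fwd) | is.na(callset$alt_rev)
  fail[fail == "" & malformed] <- "malformed"
  fail[fail == "" & depth <= config$min_depth] <- "min_depth"
  fail[fail == "" & depth >= config$max_depth] <- "max_depth"
  fail[fail == "" & (callset$alt_fwd < config$min_alt_per_strand |
                       callset$alt_rev < config$min_alt_per_strand)] <- "strand"
  for (nm in names(tally)) tally[nm] <- sum(fail == nm)
  list(callset = callset[fail == "", , drop = FALSE], tally = tally)
}

#' Intersect two callsets (the dual-caller cross-check)
#'
#' With `mode = "primitive"` (default) both callsets are normalized and a
#' record of A is retained iff every primitive derived from it occurs
#' (same contig, position and alleles) among B's primitives; the output
#' keeps A's original representation, so an MNP in A is confirmed by the
#' matching per-base SNPs in B. With `mode = "exact"` records match only
#' on their literal representation.
#'
#' @param a,b callset data frames (A's representation is reported).
#' @param reference named reference sequences or `toy_genome`.
#' @param mode `"primitive"` or `"exact"`.
#' @return the consensus callset in A's representation.
#' @export
intersect_callsets <- function(a, b, reference, mode = c("primitive",
                                                         "exact")) {
  mode <- match.arg(mode)
  if (!is.character(reference)) reference <- reference$contigs
  if (mode == "exact") {
    keya <- paste(a$contig, a$pos, a$ref, a$alt)
    keyb <- paste(b$contig, b$pos, b$ref, b$alt)
    return(a[keya %in% keyb, , drop = FALSE])
  }
  pa <- normalize_callset(a, reference)
  pb <- normalize_callset(b, reference)
  keyb <- paste(pb$contig, pb$pos, pb$ref, pb$alt)
  keya <- paste(pa$contig, pa$pos, pa$ref, pa$alt)
  ok_prim <- keya %in% keyb
  all_ok <- tapply(ok_prim, pa$src_id, all)
  keep_ids <- names(all_ok)[all_ok]
  out <- a[a$id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Three-way comparison of per-line consensus callsets
#'
#' Callsets are compared on primitive identity (contig, position,
#' alleles). Returns the seven disjoint cells of the three-set partition
#' plus per-line totals and line-specific counts, in primitive units.
#'
#' @param callsets named list of exactly three callsets.
#' @param reference named reference sequences or `toy_genome`.
#' @return a list with `cells` (named counts for the 7 cells), `totals`
#'   and `specific` per line, and `shared_all` with its percentage of
#'   each line.
#' @export
compare_lines <- function(callsets, reference) {
  stopifnot(length(callsets) == 3)
  if (!is.character(reference)) reference <- reference$contigs
  nms <- names(callsets) %||% c("A", "B", "C")
  keys <- lapply(callsets, function(cs) {
    p <- normalize_callset(cs, reference)
    unique(paste(p$contig, p$pos, p$ref, p$alt))
  })
  names(keys) <- nms
  all_keys <- unique(unlist(keys))
  inA <- all_keys %in% keys[[1]]
  inB <- all_keys %in% keys[[2]]
  inC <- all_keys %in% keys[[3]]
  cells <- c(
    sum(inA & !inB & !inC), sum(!inA & inB & !inC), sum(!inA & !inB & inC),
    sum(inA & inB & !inC), sum(inA & !inB & inC), sum(!inA & inB & inC),
    sum(inA & inB & inC))
  names(cells) <- c(nms, paste0(nms[1], ":", nms[2]),
                    paste0(nms[1], ":", nms[3]), paste0(nms[2], ":", nms[3]),
                    paste(nms, collapse = ":"))
  totals <- vapply(keys, length, integer(1))
  specific <- cells[1:3]
  names(specific) <- nms
  shared <- cells[[7]]
  list(cells = cells, totals = totals, specific = specific,
       shared_all = shared,
       shared_pct = round(100 * shared / totals))
}
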