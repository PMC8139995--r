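# Planted small-variant truth sets and emulated caller outputs.

#' Default planted variant type spectrum
#'
#' Type proportions matching the published spectrum for the transgenic
#' lines: 62% deletions, 27% SNPs, 7% insertions, 2% MNPs, 2% complex.
#' @export
default_spectrum <- function() {
  c(DEL = 0.62, SNP = 0.27, INS = 0.07, MNP = 0.02, COMPLEX = 0.02)
}

#' Plant small variants into a toy genome
#'
#' Draws `n` non-overlapping truth variants with a configurable type
#' spectrum, transition weight and 1-bp-dominant indel length law.
#' Variants are placed on reference coordinates; an optional hotspot
#' contig receives a fixed share of all variants (the remainder is
#' spread across contigs proportionally to length).
#'
#' @param genome a `toy_genome` (or `transgenic_genome`, in which case
#'   the underlying reference is used).
#' @param n number of variants (>= 0).
#' @param spectrum named proportions over DEL/SNP/INS/MNP/COMPLEX,
#'   summing to 1.
#' @param ts_weight probability that a planted SNP is a transition
#'   (0.63 gives Ts/Tv ~ 1.7).
#' @param p1_del,p1_ins probability that a deletion/insertion is 1 bp
#'   long (longer lengths are uniform on 2..`max_indel`).
#' @param max_indel maximum indel length.
#' @param hotspot optional `list(contig =, share =)`: fraction of all
#'   variants forced onto one contig.
#' @param exclude optional data frame (contig, start, end) of intervals
#'   variants must avoid (e.g. the insertion locus).
#' @param seed integer seed.
#' @return a data frame (contig, pos, id, ref, alt, vtype), sorted, with
#'   pairwise reference-window gaps of at least 12 bases.
#' @export
plant_variants <- function(genome, n, spectrum = default_spectrum(),
                           ts_weight = 0.63, p1_del = 0.975, p1_ins = 0.885,
                           max_indel = 6, hotspot = NULL, exclude = NULL,
                           seed = NULL) {
  if (inherits(genome, "transgenic_genome")) genome <- genome$ref
  stopifnot(n >= 0)
  if (abs(sum(spectrum) - 1) > 1e-9) stop("spectrum must sum to 1")
  spectrum <- spectrum[c("DEL", "SNP", "INS", "MNP", "COMPLEX")]
  set_seed_if(seed)
  if (n == 0) return(.empty_variants())

  contigs <- genome$contigs
  lens <- nchar(contigs)
  ids <- names(contigs)
  min_gap <- 12L
  if (n * (min_gap + 3L) > sum(lens)) {
    stop("n too large to place without overlap")
  }

  # per-contig allocation
  alloc <- stats::setNames(integer(length(ids)), ids)
  if (!is.null(hotspot)) {
    stopifnot(hotspot$contig %in% ids)
    n_hot <- round(hotspot$share * n)
    alloc[hotspot$contig] <- n_hot
    rest <- setdiff(ids, hotspot$contig)
    w <- lens[rest] / sum(lens[rest])
    cnt <- as.vector(stats::rmultinom(1, n - n_hot, w))
    alloc[rest] <- cnt
  } else {
    alloc[] <- as.vector(stats::rmultinom(1, n, lens / sum(lens)))
  }

  out <- list()
  for (ci in ids) {
    k <- alloc[[ci]]
    if (k == 0) next
    len <- lens[[ci]]
    excl <- if (!is.null(exclude)) exclude[exclude$contig == ci, , drop = FALSE]
    pos <- integer(0)
    for (try in 1:60) {
      need <- k - length(pos)
      if (need <= 0) break
      pool <- len - max_indel - 2L
      cand <- sample.int(pool, min(3L * need, pool)) + 1L
      cand <- sort(unique(c(pos, cand)))
      # greedy: drop positions too close to an accepted predecessor
      acc <- integer(0); last <- -min_gap
      for (p in cand) {
        if (p - last >= min_gap) { acc <- c(acc, p); last <- p }
      }
      if (!is.null(excl) && nrow(excl)) {
        bad <- vapply(acc, function(p) {
          any(ivl_overlaps(p, p + max_indel, excl$start, excl$end))
        }, logical(1))
        acc <- acc[!bad]
      }
      pos <- if (length(acc) > k) sort(sample(acc, k)) else acc
    }
    if (length(pos) < k) stop("n too large to place without overlap on ", ci)
    vtype <- sample(names(spectrum), k, replace = TRUE, prob = spectrum)
    rec <- .make_alleles(contigs[[ci]], pos, vtype, ts_weight,
                         p1_del, p1_ins, max_indel)
    rec$contig <- ci
    out[[length(out) + 1L]] <- rec
  }
  v <- do.call(rbind, out)
  v <- v[order(match(v$contig, ids), v$pos), c("contig", "pos", "ref", "alt",
                                               "vtype")]
  rownames(v) <- NULL
  v$id <- sprintf("tv%06d", seq_len(nrow(v)))
  v[, c("contig", "pos", "id", "ref", "alt", "vtype")]
}

.empty_variants <- function() {
  data.frame(contig = character(), pos = integer(), id = character(),
             ref = character(), alt = character(), vtype = character(),
             stringsAsFactors = FALSE)
}

TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

.subst_base <- function(base, ts_weight) {
  if (stats::runif(1) < ts_weight) TS_PARTNER[[base]]
  else sample(TV_PARTNERS[[base]], 1)
}

.make_alleles <- function(seq, pos, vtype, ts_weight, p1_del, p1_ins,
                          max_indel) {
  k <- length(pos)
  ref <- alt <- character(k)
  for (i in seq_len(k)) {
    p <- pos[i]
    b <- substr(seq, p, p)
    switch(vtype[i],
      SNP = {
        ref[i] <- b
        alt[i] <- .subst_base(b, ts_weight)
      },
      DEL = {
        L <- if (stats::runif(1) < p1_del) 1L else sample(2:max_indel, 1)
        ref[i] <- substr(seq, p, p + L)
        alt[i] <- b
      },
      INS = {
        L <- if (stats::runif(1) < p1_ins) 1L else sample(2:max_indel, 1)
        ref[i] <- b
        alt[i] <- paste0(b, rand_dna(L, 0.5))
      },
      MNP = {
        L <- sample(2:3, 1, prob = c(0.7, 0.3))
        r <- substr(seq, p, p + L - 1L)
        a <- vapply(strsplit(r, "")[[1]], .subst_base, character(1),
                    ts_weight = ts_weight)
        ref[i] <- r
        alt[i] <- paste(a, collapse = "")
      },
      COMPLEX = {
        rl <- sample(2:4, 1)
        al <- sample(setdiff(1:4, rl), 1)
        r <- substr(seq, p, p + rl - 1L)
        first <- sample(setdiff(BASES, substr(r, 1, 1)), 1)
        ref[i] <- r
        alt[i] <- paste0(first, if (al > 1) rand_dna(al - 1L, 0.5) else "")
      })
  }
  data.frame(pos = pos, ref = ref, alt = alt, vtype = vtype,
             stringsAsFactors = FALSE)
}

#' Emulate an imperfect variant caller over a truth set
#'
#' Produces a callset in one of two allele representations: `"JOINED"`
#' keeps MNPs atomic and additionally joins runs of adjacent truth SNPs
#' into MNP records (the joined style of haplotype-aware callers);
#' `"PRIMITIVE"` decomposes every MNP into per-base SNP records (the
#' primitive-decomposed style). False negatives drop truth records
#' independently; false positives are uniform SNPs outside truth loci.
#' Every record carries a Phred quality, a total depth and per-strand
#' alt-support counts drawn from simple laws.
#'
#' @param truth truth variant data frame from [plant_variants()].
#' @param genome the `toy_genome` the truth set was planted on (needed
#'   for false-positive reference bases).
#' @param style `"JOINED"` or `"PRIMITIVE"`.
#' @param fp_rate,fn_rate false-positive and false-negative rates in
#'   `[0, 1]` (FP count is Binomial(n_truth, fp_rate)).
#' @param qual_mean,qual_sd Normal law for record quality, floored at 31.
#' @param depth_mean Poisson mean for per-record read depth.
#' @param seed integer seed.
#' @return a callset data frame (contig, pos, id, ref, alt, vtype, qual,
#'   depth, alt_fwd, alt_rev, truth).
#' @export
emulate_callers <- function(truth, genome, style = c("JOINED", "PRIMITIVE"),
                            fp_rate = 0, fn_rate = 0, qual_mean = 60,
                            qual_sd = 10, depth_mean = 20, seed = NULL) {
  style <- match.arg(style)
  stopifnot(fp_rate >= 0, fp_rate <= 1, fn_rate >= 0, fn_rate <= 1)
  if (inherits(genome, "transgenic_genome")) genome <- genome$ref
  set_seed_if(seed)

  n0 <- nrow(truth)
  keep <- if (n0) stats::runif(n0) >= fn_rate else logical(0)
  v <- truth[keep, , drop = FALSE]

  if (style == "JOINED" && nrow(v)) {
    v <- .join_adjacent_snps(v)
  } else if (style == "PRIMITIVE" && nrow(v)) {
    v <- .decompose_mnps(v)
  }
  v$truth <- rep(TRUE, nrow(v))

  n_fp <- if (n0) stats::rbinom(1, n0, fp_rate) else 0L
  if (n_fp > 0) {
    fp <- .uniform_fp_snps(genome, truth, n_fp)
    fp$truth <- FALSE
    v <- rbind(v[, names(fp)], fp)
  }
  ids <- names(genome$contigs)
  v <- v[order(match(v$contig, ids), v$pos), , drop = FALSE]
  rownames(v) <- NULL
  n <- nrow(v)
  v$id <- sprintf("c%06d", seq_len(n))
  v$qual <- round(pmax(31, stats::rnorm(n, qual_mean, qual_sd)), 1)
  v$depth <- pmax(4L, stats::rpois(n, depth_mean))
  alt_total <- pmax(2L, stats::rbinom(n, v$depth, 0.8))
  v$alt_fwd <- pmin(pmax(stats::rbinom(n, alt_total, 0.5), 1L), alt_total - 1L)
  v$alt_rev <- alt_total - v$alt_fwd
  v[, c("contig", "pos", "id", "ref", "alt", "vtype", "qual", "depth",
        "alt_fwd", "alt_rev", "truth")]
}

# merge runs of SNPs at consecutive positions into one MNP record
.join_adjacent_snps <- function(v) {
  v <- v[order(v$contig, v$pos), , drop = FALSE]
  is_snp <- v$vtype == "SNP"
  run_break <- !(is_snp & c(FALSE, is_snp[-nrow(v)]) &
                   v$contig == c("", v$contig[-nrow(v)]) &
                   v$pos == c(-10L, v$pos[-nrow(v)]) + 1L)
  grp <- cumsum(run_break)
  out <- lapply(split(seq_len(nrow(v)), grp), function(i) {
    if (length(i) == 1L) return(v[i, c("contig", "pos", "ref", "alt", "vtype")])
    data.frame(contig = v$contig[i[1]], pos = v$pos[i[1]],
               ref = paste(v$ref[i], collapse = ""),
               alt = paste(v$alt[i], collapse = ""),
               vtype = "MNP", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.decompose_mnps <- function(v) {
  is_mnp <- v$vtype == "MNP"
  if (!any(is_mnp)) return(v[, c("contig", "pos", "ref", "alt", "vtype")])
  keep <- v[!is_mnp, c("contig", "pos", "ref", "alt", "vtype")]
  parts <- lapply(which(is_mnp), function(i) {
    r <- strsplit(v$ref[i], "")[[1]]
    a <- strsplit(v$alt[i], "")[[1]]
    d <- which(r != a)
    data.frame(contig = v$contig[i], pos = v$pos[i] + d - 1L, ref = r[d],
               alt = a[d], vtype = "SNP", stringsAsFactors = FALSE)
  })
  res <- rbind(keep, do.call(rbind, parts))
  res[order(res$contig, res$pos), , drop = FALSE]
}

.uniform_fp_snps <- function(genome, truth, n_fp) {
  lens <- nchar(genome$contigs)
  ids <- names(genome$contigs)
  cnt <- as.vector(stats::rmultinom(1, n_fp, lens / sum(lens)))
  out <- list()
  for (j in seq_along(ids)) {
    if (cnt[j] == 0) next
    tpos <- truth$pos[truth$contig == ids[j]]
    pos <- integer(0)
    while (length(pos) < cnt[j]) {
      cand <- sample.int(lens[j] - 1L, cnt[j] * 2L, replace = TRUE)
      ok <- !vapply(cand, function(p) any(abs(p - tpos) < 12L), logical(1))
      pos <- unique(c(pos, cand[ok]))
    }
    pos <- sort(pos[seq_len(cnt[j])])
    ref <- vapply(pos, function(p) substr(genome$contigs[[j]], p, p),
                  character(1))
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1))
    out[[length(out) + 1L]] <- data.frame(
      contig = ids[j], pos = pos, ref = ref, alt = alt, vtype = "SNP",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
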