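# Summary statistics over consensus callsets and annotations: variation
# rate, type spectrum, Ts/Tv, substitution spectrum, indel spectra,
# region densities, binned distributions, hotspot contigs, HI effect
# table and verification precision. Rounding conventions are fixed per
# statistic (rates: 3 significant figures; table percentages: 2 decimal
# places; prose percentages: nearest integer) so printed numbers are
# reproducible.

#' Genome-wide variation rate
#'
#' @param n_variants variant count.
#' @param genome_len genome length in bases.
#' @return list with the raw `rate` (variants per base) and `rate_3sf`
#'   rounded to 3 significant figures.
#' @export
variation_rate <- function(n_variants, genome_len) {
  stopifnot(genome_len > 0)
  rate <- n_variants / genome_len
  list(rate = rate, rate_3sf = signif(rate, 3))
}

PURINES <- c("A", "G")

#' Transition / transversion counts and ratio
#'
#' MNPs are decomposed into their per-base substitutions first (each
#' contributes its SNPs); transitions are purine-purine or
#' pyrimidine-pyrimidine changes. The ratio is undefined (NA) when there
#' are no transversions.
#'
#' @param callset callset data frame (SNP and MNP records are used).
#' @return list with `ts`, `tv` and `ratio`.
#' @export
ts_tv <- function(callset) {
  sub <- .substitution_pairs(callset)
  if (!nrow(sub)) return(list(ts = 0L, tv = 0L, ratio = NA_real_))
  is_ts <- (sub$ref %in% PURINES) == (sub$alt %in% PURINES)
  ts <- sum(is_ts); tv <- sum(!is_ts)
  list(ts = ts, tv = tv, ratio = if (tv > 0) ts / tv else NA_real_)
}

# per-base substitutions from SNP records plus decomposed MNPs
.substitution_pairs <- function(callset) {
  snp <- callset[callset$vtype == "SNP", c("ref", "alt"), drop = FALSE]
  mnp <- callset[callset$vtype == "MNP", , drop = FALSE]
  if (nrow(mnp)) {
    parts <- lapply(seq_len(nrow(mnp)), function(i) {
      r <- strsplit(mnp$ref[i], "")[[1]]
      a <- strsplit(mnp$alt[i], "")[[1]]
      d <- which(r != a)
      data.frame(ref = r[d], alt = a[d], stringsAsFactors = FALSE)
    })
    snp <- rbind(snp, do.call(rbind, parts))
  }
  snp
}

#' Substitution spectrum
#'
#' Counts of base changes, both as the full 12 ordered changes and
#' strand-collapsed into the 6 unordered classes (C/T, G/A, C/G, A/T,
#' C/A, G/T).
#'
#' @param callset callset data frame.
#' @return list with `full` (named 12-vector) and `collapsed` (named
#'   6-vector), plus `fractions` of the collapsed classes.
#' @export
substitution_spectrum <- function(callset) {
  sub <- .substitution_pairs(callset)
  full_names <- as.vector(outer(BASES, BASES, function(a, b) paste0(a, ">", b)))
  full_names <- full_names[substr(full_names, 1, 1) !=
                             substr(full_names, 3, 3)]
  full <- stats::setNames(integer(length(full_names)), sort(full_names))
  if (nrow(sub)) {
    tab <- table(paste0(sub$ref, ">", sub$alt))
    full[names(tab)] <- as.integer(tab)
  }
  pair_key <- function(r, a) {
    v <- vapply(seq_along(r), function(i) paste(sort(c(r[i], a[i])),
                                                collapse = "/"), character(1))
    v
  }
  collapsed_names <- c("C/T", "A/G", "C/G", "A/T", "A/C", "G/T")
  collapsed <- stats::setNames(integer(6), collapsed_names)
  if (nrow(sub)) {
    tab2 <- table(pair_key(sub$ref, sub$alt))
    collapsed[intersect(names(collapsed), names(tab2))] <-
      as.integer(tab2[intersect(names(collapsed), names(tab2))])
  }
  frac <- if (sum(collapsed) > 0) collapsed / sum(collapsed) else collapsed * 0
  list(full = full, collapsed = collapsed, fractions = frac)
}

#' Variant type counts and fractions
#' @param callset callset data frame.
#' @return list with `counts` and `fractions` over
#'   SNP/MNP/INS/DEL/COMPLEX.
#' @export
type_spectrum <- function(callset) {
  lv <- c("SNP", "MNP", "INS", "DEL", "COMPLEX")
  counts <- stats::setNames(integer(5), lv)
  tab <- table(factor(callset$vtype, levels = lv))
  counts[] <- as.integer(tab)
  frac <- if (sum(counts) > 0) counts / sum(counts) else counts * 0
  list(counts = counts, fractions = frac)
}

#' Indel length spectrum and deletion/insertion ratio
#'
#' Length is `abs(nchar(ref) - nchar(alt))`; histograms are keyed by
#' length per type. The ratio is undefined (NA) without insertions.
#'
#' @param callset callset data frame.
#' @return list with `del_hist`, `ins_hist` (named count vectors),
#'   `del_ins_ratio` and the 1-bp fractions per type.
#' @export
indel_spectrum <- function(callset) {
  d <- callset[callset$vtype == "DEL", , drop = FALSE]
  i <- callset[callset$vtype == "INS", , drop = FALSE]
  hist_of <- function(x) {
    if (!nrow(x)) return(stats::setNames(integer(0), character(0)))
    len <- abs(nchar(x$ref) - nchar(x$alt))
    tab <- table(len)
    stats::setNames(as.integer(tab), names(tab))
  }
  dh <- hist_of(d); ih <- hist_of(i)
  f1 <- function(h) {
    if (!sum(h)) return(NA_real_)
    n1 <- if ("1" %in% names(h)) h[["1"]] else 0L
    n1 / sum(h)
  }
  list(del_hist = dh, ins_hist = ih,
       del_ins_ratio = if (nrow(i) > 0) nrow(d) / nrow(i) else NA_real_,
       del_1bp_frac = f1(dh), ins_1bp_frac = f1(ih))
}

#' Collapsed (union) region lengths of a genome partition
#'
#' Region classes are resolved with the same precedence used by
#' [assign_region()], so every base belongs to exactly one class and the
#' class lengths partition the genome.
#'
#' @param genome a `toy_genome`.
#' @param flank flank length in bases.
#' @return named numeric vector of class lengths (bases), including
#'   INTERGENIC.
#' @export
region_lengths <- function(genome, flank = 1500) {
  db <- .region_db(genome, flank)
  lens <- nchar(genome$contigs)
  out <- stats::setNames(numeric(length(REGION_LEVELS)), REGION_LEVELS)
  for (nm in names(lens)) {
    claimed <- IRanges::IRanges()
    for (cls in setdiff(REGION_LEVELS, "INTERGENIC")) {
      d <- db[db$contig == nm & db$class == cls, , drop = FALSE]
      if (!nrow(d)) next
      r <- IRanges::reduce(IRanges::IRanges(pmax(1L, d$start),
                                            pmin(lens[[nm]], d$end)))
      r <- IRanges::setdiff(r, claimed)
      out[cls] <- out[cls] + sum(IRanges::width(r))
      claimed <- IRanges::reduce(c(claimed, r))
    }
    out["INTERGENIC"] <- out["INTERGENIC"] + lens[[nm]] -
      sum(IRanges::width(claimed))
  }
  out
}

#' Variant density per Mb of each region class
#'
#' @param annotated annotated callset (with `region`).
#' @param lengths named region lengths from [region_lengths()].
#' @return named vector of variants per Mb per class (0 for empty
#'   classes of positive length, NA for zero-length classes).
#' @export
region_density <- function(annotated, lengths) {
  counts <- table(factor(annotated$region, levels = names(lengths)))
  dens <- as.numeric(counts) / (lengths / 1e6)
  dens[lengths == 0] <- NA_real_
  stats::setNames(dens, names(lengths))
}

#' Binned variant counts along contigs or chromosomes
#'
#' Half-open bins of `bin` bases starting at position 1 (a variant at
#' position `bin` falls in bin 1, at `bin + 1` in bin 2). With a
#' chromosome map, contig positions are projected onto chromosomes via
#' their offsets first.
#'
#' @param callset callset data frame.
#' @param chrom_map optional data frame (contig, chrom, offset).
#' @param bin bin width in bases (default 10000).
#' @return data frame (seqname, bin, count); bins without variants are
#'   omitted; counts sum to the callset size.
#' @export
binned_distribution <- function(callset, chrom_map = NULL, bin = 10000) {
  stopifnot(bin > 0)
  if (!nrow(callset)) {
    return(data.frame(seqname = character(), bin = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  seqname <- callset$contig
  pos <- callset$pos
  if (!is.null(chrom_map)) {
    m <- match(callset$contig, chrom_map$contig)
    use <- !is.na(m)
    seqname[use] <- chrom_map$chrom[m[use]]
    pos[use] <- pos[use] + chrom_map$offset[m[use]]
  }
  b <- ((pos - 1L) %/% as.integer(bin)) + 1L
  tab <- stats::aggregate(list(count = rep(1L, length(b))),
                          by = list(seqname = seqname, bin = b), FUN = sum)
  tab <- tab[order(tab$seqname, tab$bin), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Contigs carrying a disproportionate share of variants
#'
#' @param callset callset data frame (>= 1 variant).
#' @param threshold minimum share to report (default 0.2).
#' @return data frame (contig, count, share) sorted by share descending,
#'   restricted to contigs with share >= threshold.
#' @export
hotspot_contigs <- function(callset, threshold = 0.2) {
  stopifnot(nrow(callset) >= 1)
  tab <- table(callset$contig)
  share <- as.numeric(tab) / sum(tab)
  out <- data.frame(contig = names(tab), count = as.integer(tab),
                    share = share, stringsAsFactors = FALSE)
  out <- out[order(-out$share, out$contig), , drop = FALSE]
  rownames(out) <- NULL
  out[out$share >= threshold, , drop = FALSE]
}

#' Table of high-impact effect types
#'
#' Counts and percentages (2 decimal places) per HIGH-tier effect term.
#'
#' @param x either an annotated data frame (HIGH records are selected)
#'   or a named count vector over the HIGH effect terms.
#' @return data frame (effect, count, pct).
#' @export
hi_effect_table <- function(x) {
  hi_terms <- c("frameshift_variant", "start_lost", "stop_gained",
                "stop_lost")
  if (is.data.frame(x)) {
    h <- x[x$impact == "HIGH", , drop = FALSE]
    counts <- table(factor(h$effect, levels = hi_terms))
    counts <- stats::setNames(as.integer(counts), hi_terms)
  } else {
    counts <- stats::setNames(as.integer(x), names(x))
  }
  total <- sum(counts)
  pct <- if (total > 0) round(100 * counts / total, 2) else counts * NA_real_
  data.frame(effect = names(counts), count = as.integer(counts),
             pct = as.numeric(pct), stringsAsFactors = FALSE)
}

#' Verification precision from confirmation counts
#'
#' @param n_confirmed variants confirmed by resequencing.
#' @param n_tested variants successfully assayed.
#' @return integer percentage, rounded to the nearest percent.
#' @export
verification_precision <- function(n_confirmed, n_tested) {
  stopifnot(n_tested > 0, n_confirmed >= 0, n_confirmed <= n_tested)
  round(100 * n_confirmed / n_tested)
}

#' Full per-line summary report
#'
#' Assembles every summary statistic for one line's consensus callset
#' and annotation.
#'
#' @param callset consensus callset data frame.
#' @param annotated annotated callset from [annotate_variants()].
#' @param genome the `toy_genome` (for genome length, region lengths and
#'   the chromosome map).
#' @param flank flank length used in annotation.
#' @param bin bin width for the binned distribution.
#' @param hotspot_threshold share threshold for hotspot contigs.
#' @return an object of class `summary_report` (a named list).
#' @export
summary_report <- function(callset, annotated, genome, flank = 1500,
                           bin = 10000, hotspot_threshold = 0.2) {
  glen <- sum(nchar(genome$contigs))
  lens <- region_lengths(genome, flank)
  imp <- table(factor(annotated$impact,
                      levels = c("HIGH", "MODERATE", "LOW", "MODIFIER")))
  imp <- stats::setNames(as.integer(imp), names(imp))
  rep_ <- list(
    n_variants = nrow(callset),
    genome_len = glen,
    variation_rate = variation_rate(nrow(callset), glen),
    types = type_spectrum(callset),
    ts_tv = ts_tv(callset),
    substitutions = substitution_spectrum(callset),
    indels = indel_spectrum(callset),
    region_lengths = lens,
    region_density = region_density(annotated, lens),
    impact_counts = imp,
    impact_fractions = if (sum(imp) > 0) imp / sum(imp) else imp * 0,
    hi_table = hi_effect_table(annotated),
    ns_s = ns_s_tally(annotated),
    bins = binned_distribution(callset, genome$chrom_map, bin),
    hotspots = hotspot_contigs(callset, hotspot_threshold))
  class(rep_) <- "summary_report"
  rep_
}

#' @export
print.summary_report <- function(x, ...) {
  cat("summary_report:", x$n_variants, "variants;",
      "rate", format(x$variation_rate$rate_3sf), "per base;",
      "Ts/Tv", round(x$ts_tv$ratio %||% NA, 2), "\n")
  cat("  types:", paste(names(x$types$counts), x$types$counts,
                        collapse = ", "), "\n")
  invisible(x)
}

#' Write a summary report as JSON
#' @param report a `summary_report`.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
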