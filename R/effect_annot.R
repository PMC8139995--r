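# Region assignment, canonical-transcript selection, coding-effect
# prediction and impact tiering; replaces an external annotator with the
# same tier semantics (HIGH disruptive, MODERATE protein-altering, LOW
# mostly harmless, MODIFIER non-coding).

REGION_LEVELS <- c("EXON_CDS", "UTR5", "UTR3", "EXON_NC", "INTRON",
                   "UPSTREAM", "DOWNSTREAM", "INTERGENIC")

EFFECT_LEVELS <- c("frameshift_variant", "inframe_indel", "missense_variant",
                   "synonymous_variant", "stop_gained", "stop_lost",
                   "start_lost", "utr_variant", "noncoding_exon_variant",
                   "intron_variant", "upstream_variant", "downstream_variant",
                   "intergenic_variant")

#' Impact tier of an effect term
#'
#' Fixed mapping: frameshift, start/stop loss and stop gain are HIGH;
#' missense and in-frame indels MODERATE; synonymous LOW; all non-coding
#' terms MODIFIER.
#'
#' @param effect character vector of effect terms.
#' @return character vector of HIGH/MODERATE/LOW/MODIFIER.
#' @export
impact_of <- function(effect) {
  map <- c(frameshift_variant = "HIGH", start_lost = "HIGH",
           stop_gained = "HIGH", stop_lost = "HIGH",
           inframe_indel = "MODERATE", missense_variant = "MODERATE",
           synonymous_variant = "LOW",
           utr_variant = "MODIFIER", noncoding_exon_variant = "MODIFIER",
           intron_variant = "MODIFIER", upstream_variant = "MODIFIER",
           downstream_variant = "MODIFIER", intergenic_variant = "MODIFIER")
  bad <- setdiff(unique(effect), names(map))
  if (length(bad)) stop("unknown effect term(s): ", paste(bad, collapse = ", "))
  unname(map[effect])
}

.severity <- function(impact) {
  c(HIGH = 4L, MODERATE = 3L, LOW = 2L, MODIFIER = 1L)[impact]
}

#' Select the canonical transcript of a gene
#'
#' The transcript with the longest total CDS; for non-coding genes the
#' longest exonic length. Ties break lexicographically on transcript id.
#'
#' @param gene_id gene identifier.
#' @param features feature data frame (as in a `toy_genome`).
#' @return the canonical transcript id.
#' @export
select_canonical_tx <- function(gene_id, features) {
  f <- features[features$gene_id == gene_id, , drop = FALSE]
  if (!nrow(f)) stop("gene has no features: ", gene_id)
  tx <- sort(unique(f$transcript_id))
  len_of <- function(tid, type) {
    ff <- f[f$transcript_id == tid & f$type == type, , drop = FALSE]
    sum(ff$end - ff$start + 1L)
  }
  cds_len <- vapply(tx, len_of, integer(1), type = "CDS")
  key <- if (any(cds_len > 0)) cds_len else vapply(tx, len_of, integer(1),
                                                   type = "exon")
  tx[which.max(key)]  # which.max takes the first (lexicographic) tie
}

# Per-contig interval database of region classes over canonical
# transcripts, with strand-aware 5'/3' flanks.
.region_db <- function(genome, flank = 1500) {
  g <- genome$genes
  f <- genome$features
  rows <- list()
  push <- function(contig, class, s, e, gene) {
    ok <- e >= s
    if (!any(ok)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      contig = contig, class = class, start = s[ok], end = e[ok],
      gene_id = gene, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    ft <- f[f$transcript_id == gi$canonical, , drop = FALSE]
    exon <- ft[ft$type == "exon", , drop = FALSE]
    span_s <- min(exon$start); span_e <- max(exon$end)
    cds <- ft[ft$type == "CDS", , drop = FALSE]
    if (nrow(cds)) {
      push(gi$contig, "EXON_CDS", cds$start, cds$end, gi$gene_id)
      u5 <- ft[ft$type == "five_prime_UTR", , drop = FALSE]
      u3 <- ft[ft$type == "three_prime_UTR", , drop = FALSE]
      if (nrow(u5)) push(gi$contig, "UTR5", u5$start, u5$end, gi$gene_id)
      if (nrow(u3)) push(gi$contig, "UTR3", u3$start, u3$end, gi$gene_id)
    } else {
      push(gi$contig, "EXON_NC", exon$start, exon$end, gi$gene_id)
    }
    # introns: transcript span minus exons
    ex <- exon[order(exon$start), , drop = FALSE]
    if (nrow(ex) > 1) {
      push(gi$contig, "INTRON", ex$end[-nrow(ex)] + 1L, ex$start[-1] - 1L,
           gi$gene_id)
    }
    if (flank > 0) {
      if (gi$strand == "+") {
        push(gi$contig, "UPSTREAM", span_s - flank, span_s - 1L, gi$gene_id)
        push(gi$contig, "DOWNSTREAM", span_e + 1L, span_e + flank, gi$gene_id)
      } else {
        push(gi$contig, "UPSTREAM", span_e + 1L, span_e + flank, gi$gene_id)
        push(gi$contig, "DOWNSTREAM", span_s - flank, span_s - 1L, gi$gene_id)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(contig = character(), class = character(),
                      start = integer(), end = integer(),
                      gene_id = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# the reference interval a variant affects (1-based closed)
.affected_interval <- function(pos, ref, alt, vtype) {
  lr <- nchar(ref)
  switch(vtype,
    SNP = c(pos, pos),
    MNP = c(pos, pos + lr - 1L),
    INS = c(pos, pos + 1L),
    DEL = c(pos + 1L, pos + lr - 1L),
    COMPLEX = c(pos, pos + lr - 1L))
}

#' Assign genomic region classes to variants
#'
#' Strand-aware flanks of length `flank` define UPSTREAM/DOWNSTREAM; a
#' variant qualifying for several classes across overlapping genes gets
#' all of them recorded, and one summary class by the precedence
#' EXON_CDS > UTR5/UTR3 > non-coding exon > INTRON > UPSTREAM >
#' DOWNSTREAM > INTERGENIC.
#'
#' @param callset callset data frame.
#' @param genome a `toy_genome` (or list with `genes` and `features`).
#' @param flank flank length in bases (default 1500).
#' @return the callset with `region` and `gene_id` columns; all
#'   qualifying (variant, gene, class) hits are attached as the
#'   `"hits"` attribute.
#' @export
assign_region <- function(callset, genome, flank = 1500) {
  db <- .region_db(genome, flank)
  n <- nrow(callset)
  region <- rep("INTERGENIC", n)
  gene <- rep(NA_character_, n)
  hits <- list()
  lv <- stats::setNames(seq_along(REGION_LEVELS), REGION_LEVELS)
  for (i in seq_len(n)) {
    iv <- .affected_interval(callset$pos[i], callset$ref[i], callset$alt[i],
                             callset$vtype[i])
    d <- db[db$contig == callset$contig[i] &
              db$start <= iv[2] & db$end >= iv[1], , drop = FALSE]
    if (!nrow(d)) next
    d <- d[order(lv[d$class]), , drop = FALSE]
    region[i] <- d$class[1]
    gene[i] <- d$gene_id[1]
    hits[[length(hits) + 1L]] <- data.frame(
      idx = i, gene_id = d$gene_id, class = d$class,
      stringsAsFactors = FALSE)
  }
  out <- callset
  out$region <- region
  out$gene_id <- gene
  attr(out, "hits") <- if (length(hits)) do.call(rbind, hits) else NULL
  out
}

# Map genomic positions to CDS coordinates (1-based along the mRNA).
# Returns a list with idx(p) -> CDS index or NA, the total CDS length,
# the CDS sequence (5'->3') and the strand.
.cds_mapper <- function(genome, gene_id) {
  g <- genome$genes[genome$genes$gene_id == gene_id, ]
  cds <- genome$features[genome$features$transcript_id == g$canonical &
                           genome$features$type == "CDS", , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  if (!nrow(cds)) return(NULL)
  w <- cds$end - cds$start + 1L
  total <- sum(w)
  seq_plus <- paste(substring(genome$contigs[[g$contig]], cds$start, cds$end),
                    collapse = "")
  strand <- g$strand
  cds_seq <- if (strand == "+") seq_plus else revcomp(seq_plus)
  before <- cumsum(c(0L, w))[seq_len(nrow(cds))]
  after <- rev(cumsum(c(0L, rev(w))))[-1]
  idx <- function(p) {
    j <- which(p >= cds$start & p <= cds$end)
    if (!length(j)) return(NA_integer_)
    as.integer(if (strand == "+") before[j] + (p - cds$start[j] + 1L)
               else after[j] + (cds$end[j] - p + 1L))
  }
  list(idx = idx, total = total, seq = cds_seq, strand = strand,
       contig = g$contig)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Predict the coding effect of one variant on a gene's canonical transcript
#'
#' CDS indels change the frame when the net number of inserted/deleted
#' CDS bases is not divisible by 3 (`frameshift_variant`), otherwise
#' `inframe_indel`. CDS substitutions are evaluated codon-wise on the
#' mutated CDS: a destroyed ATG start is `start_lost`, a new internal
#' stop `stop_gained`, a destroyed terminal stop `stop_lost`, any other
#' amino-acid change `missense_variant`, else `synonymous_variant`.
#' Substitutions spanning the CDS boundary are split at the boundary and
#' the most severe part is reported. Non-CDS variants map to their
#' region's term. A reference CDS that fails to translate cleanly
#' (no ATG, internal stop, length not divisible by 3) sets `warn` and is
#' still evaluated on the raw frame.
#'
#' @param variant one-row callset data frame with `region` assigned.
#' @param genome a `toy_genome`.
#' @param gene_id the gene to evaluate against (optional for non-genic
#'   variants).
#' @return a list with `effect`, `impact` and `warn`.
#' @export
predict_effect <- function(variant, genome, gene_id = NA) {
  region_term <- c(UTR5 = "utr_variant", UTR3 = "utr_variant",
                   EXON_NC = "noncoding_exon_variant",
                   INTRON = "intron_variant", UPSTREAM = "upstream_variant",
                   DOWNSTREAM = "downstream_variant",
                   INTERGENIC = "intergenic_variant")
  reg <- variant$region
  if (reg != "EXON_CDS") {
    eff <- unname(region_term[reg])
    return(list(effect = eff, impact = impact_of(eff), warn = FALSE))
  }
  m <- .cds_mapper(genome, gene_id)
  if (is.null(m)) {
    return(list(effect = "noncoding_exon_variant", impact = "MODIFIER",
                warn = TRUE))
  }
  warn <- !(m$total %% 3L == 0L && substr(m$seq, 1, 3) == "ATG" &&
              substr(m$seq, m$total - 2L, m$total) %in% STOP_CODONS &&
              !grepl("\\*.", translate_dna(substr(m$seq, 1, m$total - (m$total %% 3L)))))

  vt <- variant$vtype
  pos <- variant$pos; ref <- variant$ref; alt <- variant$alt
  if (vt %in% c("INS", "DEL", "COMPLEX")) {
    if (vt == "INS") {
      net <- nchar(alt) - nchar(ref)
      inside <- !is.na(m$idx(pos)) && !is.na(m$idx(pos + 1L))
      if (!inside) {
        eff <- "intron_variant"  # insertion at an exon boundary
        return(list(effect = eff, impact = impact_of(eff), warn = warn))
      }
    } else if (vt == "DEL") {
      delpos <- (pos + 1L):(pos + nchar(ref) - 1L)
      n_cds <- sum(!is.na(vapply(delpos, m$idx, integer(1))))
      if (n_cds == 0L) {
        eff <- "intron_variant"
        return(list(effect = eff, impact = impact_of(eff), warn = warn))
      }
      net <- -n_cds
    } else {
      net <- nchar(alt) - nchar(ref)
    }
    eff <- if (net %% 3L != 0L) "frameshift_variant" else "inframe_indel"
    return(list(effect = eff, impact = impact_of(eff), warn = warn))
  }

  # SNV / MNP: substitute the covered CDS bases codon-wise
  gpos <- pos:(pos + nchar(ref) - 1L)
  rb <- strsplit(ref, "")[[1]]
  ab <- strsplit(alt, "")[[1]]
  ci <- vapply(gpos, m$idx, integer(1))
  in_cds <- !is.na(ci)
  if (!any(in_cds)) {
    eff <- "intron_variant"
    return(list(effect = eff, impact = impact_of(eff), warn = warn))
  }
  mut <- strsplit(m$seq, "")[[1]]
  for (k in which(in_cds)) {
    base <- if (m$strand == "+") ab[k] else COMPLEMENT[[ab[k]]]
    mut[ci[k]] <- base
  }
  mutated <- paste(mut, collapse = "")
  codons <- sort(unique(ceiling(ci[in_cds] / 3)))
  n_codons <- m$total %/% 3L
  eff <- "synonymous_variant"
  changed_aa <- FALSE
  for (cd in codons) {
    s <- (cd - 1L) * 3L + 1L
    refc <- substr(m$seq, s, s + 2L)
    mutc <- substr(mutated, s, s + 2L)
    if (cd == 1L && refc == "ATG" && mutc != "ATG") {
      eff <- "start_lost"
      return(list(effect = eff, impact = impact_of(eff), warn = warn))
    }
    if (cd < n_codons && !(refc %in% STOP_CODONS) &&
          mutc %in% STOP_CODONS) {
      eff <- "stop_gained"
      return(list(effect = eff, impact = impact_of(eff), warn = warn))
    }
    if (cd == n_codons && refc %in% STOP_CODONS &&
          !(mutc %in% STOP_CODONS)) {
      eff <- "stop_lost"
      return(list(effect = eff, impact = impact_of(eff), warn = warn))
    }
    if (translate_dna(refc) != translate_dna(mutc)) changed_aa <- TRUE
  }
  if (changed_aa) eff <- "missense_variant"
  if (!all(in_cds)) {
    # part of the substitution lies outside the CDS; coding part wins
    # unless it is silent and the non-coding part would not outrank it
    # (all non-coding terms are MODIFIER, so the coding term stands)
  }
  list(effect = eff, impact = impact_of(eff), warn = warn)
}

#' Annotate a callset with region, effect and impact
#'
#' Runs [assign_region()] then [predict_effect()] per variant against
#' the summary gene's canonical transcript.
#'
#' @inheritParams assign_region
#' @return annotated data frame with `region`, `gene_id`, `effect`,
#'   `impact` and `warn` columns.
#' @export
annotate_variants <- function(callset, genome, flank = 1500) {
  ann <- assign_region(callset, genome, flank)
  n <- nrow(ann)
  effect <- impact <- character(n)
  warn <- logical(n)
  for (i in seq_len(n)) {
    p <- predict_effect(ann[i, ], genome, ann$gene_id[i])
    effect[i] <- p$effect
    impact[i] <- p$impact
    warn[i] <- p$warn
  }
  ann$effect <- effect
  ann$impact <- impact
  ann$warn <- warn
  ann
}

#' Non-synonymous / synonymous tally over coding substitutions
#'
#' NS counts missense, stop-gain, stop-loss and start-loss effects among
#' coding SNV/MNP records; S counts synonymous ones. The ratio is NS/S,
#' `NA` (undefined) when S is zero.
#'
#' @param annotated annotated data frame from [annotate_variants()], or
#'   NULL when giving counts directly.
#' @param ns,s direct counts (used when `annotated` is NULL).
#' @return a list with `ns`, `s` and `ratio`.
#' @export
ns_s_tally <- function(annotated = NULL, ns = NULL, s = NULL) {
  if (!is.null(annotated)) {
    coding <- annotated$vtype %in% c("SNP", "MNP") &
      annotated$region == "EXON_CDS"
    ns <- sum(coding & annotated$effect %in%
                c("missense_variant", "stop_gained", "stop_lost",
                  "start_lost"))
    s <- sum(coding & annotated$effect == "synonymous_variant")
  }
  list(ns = ns, s = s, ratio = if (s > 0) ns / s else NA_real_)
}
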