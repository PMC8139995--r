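# T-DNA insertion-site detection from paired-end alignments against the
# combined genome+vector reference: chimeric read-pair and split-read
# evidence, junction clustering, copy-number / structure inference from
# relative depth, and site classification against gene models.

#' Harvest chimeric evidence for transgene integration
#'
#' One `DISCORDANT_PAIR` record per read pair with one mate on the vector
#' contig and one on a genomic contig, plus one `SPLIT_READ` record per
#' soft-clipped genomic read whose clipped tail exactly matches a T-DNA
#' border window (at least `min_clip` clipped bases compared against a
#' `border_win`-base window at the relevant vector border; no local
#' alignment is attempted). The evidence `side` is `"L"` when the genomic
#' anchor points rightward into the insert (forward genomic mate, or clip
#' at the read's right end) and `"R"` for the mirror case.
#'
#' @param aln alignment data frame (from [simulate_reads()] or
#'   [read_alignments()]).
#' @param vector_id name of the vector contig.
#' @param construct the `tdna_construct` (for border windows).
#' @param min_clip minimum clipped bases for split-read evidence.
#' @param border_win border window length on the vector.
#' @return a data frame of evidence records (read_id, kind, contig,
#'   anchor_start, anchor_end, side, junction, vpos); `junction` is the
#'   exact junction base for split reads, NA otherwise.
#' @export
harvest_evidence <- function(aln, vector_id, construct, min_clip = 12,
                             border_win = 40) {
  need <- c("qname", "flag", "rname", "pos", "cigar")
  missing_mate <- !all(c("rnext", "pnext") %in% names(aln))
  stopifnot(all(need %in% names(aln)))
  cg <- .parse_cigar(aln$cigar)
  aln$ref_width <- cg$ref_width
  aln$lead_clip <- cg$lead_clip
  aln$trail_clip <- cg$trail_clip
  is_vec <- aln$rname == vector_id
  rev <- bitwAnd(aln$flag, 16L) > 0L

  out <- list()

  # discordant pairs: one mate genomic, one on the vector
  skipped <- 0L
  if (!missing_mate) {
    byq <- split(seq_len(nrow(aln)), aln$qname)
    for (i in byq) {
      if (length(i) != 2L) { skipped <- skipped + 1L; next }
      v <- is_vec[i]
      if (sum(v) != 1L) next
      gi <- i[!v]; vi <- i[v]
      out[[length(out) + 1L]] <- data.frame(
        read_id = aln$qname[gi], kind = "DISCORDANT_PAIR",
        contig = aln$rname[gi], anchor_start = aln$pos[gi],
        anchor_end = aln$pos[gi] + aln$ref_width[gi] - 1L,
        side = if (rev[gi]) "R" else "L",
        junction = NA_integer_, vpos = aln$pos[vi], stringsAsFactors = FALSE)
    }
  } else {
    skipped <- NA_integer_
  }

  # split reads: genomic reads clipped at a junction, clip matching a
  # T-DNA border window
  v <- construct$seq
  t1 <- construct$tdna_start; t2 <- construct$tdna_end
  gidx <- which(!is_vec & (aln$trail_clip >= min_clip |
                             aln$lead_clip >= min_clip))
  for (i in gidx) {
    rl <- nchar(aln$seq[i])
    if (aln$trail_clip[i] >= min_clip) {
      clip <- substr(aln$seq[i], rl - aln$trail_clip[i] + 1L, rl)
      k <- min(nchar(clip), border_win)
      if (substr(clip, 1L, k) == substr(v, t1, t1 + k - 1L)) {
        j <- aln$pos[i] + aln$ref_width[i] - 1L
        out[[length(out) + 1L]] <- data.frame(
          read_id = aln$qname[i], kind = "SPLIT_READ", contig = aln$rname[i],
          anchor_start = aln$pos[i], anchor_end = j, side = "L",
          junction = j, vpos = t1, stringsAsFactors = FALSE)
      }
    }
    if (aln$lead_clip[i] >= min_clip) {
      clip <- substr(aln$seq[i], 1L, aln$lead_clip[i])
      k <- min(nchar(clip), border_win)
      if (substr(clip, nchar(clip) - k + 1L, nchar(clip)) ==
            substr(v, t2 - k + 1L, t2)) {
        out[[length(out) + 1L]] <- data.frame(
          read_id = aln$qname[i], kind = "SPLIT_READ", contig = aln$rname[i],
          anchor_start = aln$pos[i],
          anchor_end = aln$pos[i] + aln$ref_width[i] - 1L, side = "R",
          junction = aln$pos[i], vpos = t2, stringsAsFactors = FALSE)
      }
    }
  }

  ev <- if (length(out)) do.call(rbind, out) else data.frame(
    read_id = character(), kind = character(), contig = character(),
    anchor_start = integer(), anchor_end = integer(), side = character(),
    junction = integer(), vpos = integer(), stringsAsFactors = FALSE)
  ev <- ev[order(ev$contig, ev$anchor_start, ev$read_id), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "skipped") <- skipped
  ev
}

.parse_cigar <- function(cigar) {
  n <- length(cigar)
  ref_width <- lead_clip <- trail_clip <- integer(n)
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  for (i in seq_len(n)) {
    o <- ops[[i]]
    len <- as.integer(sub("[A-Z=]$", "", o))
    op <- sub("^\\d+", "", o)
    ref_width[i] <- sum(len[op %in% c("M", "D", "N", "=", "X")])
    if (length(op) && op[1] == "S") lead_clip[i] <- len[1]
    if (length(op) && op[length(op)] == "S") trail_clip[i] <- len[length(op)]
  }
  list(ref_width = ref_width, lead_clip = lead_clip, trail_clip = trail_clip)
}

#' Call insertion events from chimeric evidence
#'
#' Evidence is clustered per contig and side; clusters are separated by
#' gaps greater than `cluster_gap`. Each left cluster is paired with the
#' nearest right cluster downstream; junctions come from split reads
#' when present (exact) or from the innermost anchor end (flagged
#' approximate, with a cluster-span confidence interval). Clusters below
#' `min_support` are discarded; an unpaired surviving cluster yields a
#' one-junction event with structure `UNRESOLVED`.
#'
#' @param evidence data frame from [harvest_evidence()].
#' @param cluster_gap maximum within-cluster gap in bases.
#' @param min_support minimum evidence records per junction.
#' @param max_pair_dist maximum left-right junction distance to pair.
#' @return a data frame of events (contig, left_junction, right_junction,
#'   deletion_len, support_left, support_right, exact, structure).
#' @export
call_insertions <- function(evidence, cluster_gap = 1000, min_support = 3,
                            max_pair_dist = 10000) {
  empty <- data.frame(contig = character(), left_junction = integer(),
                      right_junction = integer(), deletion_len = integer(),
                      support_left = integer(), support_right = integer(),
                      exact = logical(), structure = character(),
                      stringsAsFactors = FALSE)
  if (nrow(evidence) == 0) return(empty)

  clusters <- list()
  for (ctg in unique(evidence$contig)) {
    for (sd in c("L", "R")) {
      e <- evidence[evidence$contig == ctg & evidence$side == sd, ,
                    drop = FALSE]
      if (!nrow(e)) next
      anchor <- if (sd == "L") e$anchor_end else e$anchor_start
      o <- order(anchor)
      e <- e[o, , drop = FALSE]; anchor <- anchor[o]
      grp <- cumsum(c(TRUE, diff(anchor) > cluster_gap))
      for (g in unique(grp)) {
        eg <- e[grp == g, , drop = FALSE]
        sj <- eg$junction[eg$kind == "SPLIT_READ"]
        if (length(sj)) {
          tab <- table(sj)
          junction <- as.integer(names(tab)[which.max(tab)])
          exact <- TRUE
        } else {
          junction <- if (sd == "L") max(eg$anchor_end) else min(eg$anchor_start)
          exact <- FALSE
        }
        clusters[[length(clusters) + 1L]] <- list(
          contig = ctg, side = sd, junction = junction, exact = exact,
          support = nrow(eg), lo = min(anchor[grp == g]),
          hi = max(anchor[grp == g]))
      }
    }
  }
  cl <- do.call(rbind, lapply(clusters, function(x) {
    data.frame(contig = x$contig, side = x$side, junction = x$junction,
               exact = x$exact, support = x$support, stringsAsFactors = FALSE)
  }))
  cl <- cl[cl$support >= min_support, , drop = FALSE]
  if (!nrow(cl)) return(empty)
  cl <- cl[order(cl$contig, cl$junction), , drop = FALSE]

  events <- list()
  used_r <- rep(FALSE, nrow(cl))
  for (i in which(cl$side == "L")) {
    cand <- which(cl$side == "R" & !used_r & cl$contig == cl$contig[i] &
                    cl$junction > cl$junction[i] &
                    cl$junction - cl$junction[i] <= max_pair_dist)
    if (length(cand)) {
      j <- cand[which.min(cl$junction[cand])]
      used_r[j] <- TRUE
      events[[length(events) + 1L]] <- data.frame(
        contig = cl$contig[i], left_junction = cl$junction[i],
        right_junction = cl$junction[j],
        deletion_len = cl$junction[j] - cl$junction[i] - 1L,
        support_left = cl$support[i], support_right = cl$support[j],
        exact = cl$exact[i] && cl$exact[j], structure = "UNRESOLVED",
        stringsAsFactors = FALSE)
    } else {
      events[[length(events) + 1L]] <- data.frame(
        contig = cl$contig[i], left_junction = cl$junction[i],
        right_junction = NA_integer_, deletion_len = NA_integer_,
        support_left = cl$support[i], support_right = 0L,
        exact = cl$exact[i], structure = "UNRESOLVED",
        stringsAsFactors = FALSE)
    }
  }
  for (j in which(cl$side == "R" & !used_r)) {
    events[[length(events) + 1L]] <- data.frame(
      contig = cl$contig[j], left_junction = NA_integer_,
      right_junction = cl$junction[j], deletion_len = NA_integer_,
      support_left = 0L, support_right = cl$support[j], exact = cl$exact[j],
      structure = "UNRESOLVED", stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$contig, pmin(ev$left_junction, ev$right_junction,
                                 na.rm = TRUE)), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Infer transgene copy number and insert structure from depth
#'
#' Copy number is the ratio of the median read depth over the T-DNA
#' interval of the vector contig to the median genomic depth on the
#' event's contig, rounded and floored at 1. The structure is
#' `TDNA_BACKBONE_TDNA` iff copies = 2 and at least `min_backbone_frac`
#' of the backbone positions (vector minus T-DNA) have depth >=
#' `backbone_min_depth`; otherwise `TDNA_ONLY`.
#'
#' @param aln alignment data frame over the combined reference.
#' @param event one event row from [call_insertions()].
#' @param construct the `tdna_construct`.
#' @param contig_lengths named lengths of the combined reference.
#' @param min_backbone_frac,backbone_min_depth backbone-presence rule.
#' @return the event row with `copies` and `structure` filled in.
#' @export
infer_structure <- function(aln, event, construct, contig_lengths,
                            min_backbone_frac = 0.5, backbone_min_depth = 3) {
  vec_id <- construct$vector_id
  cov_of <- function(rname) {
    a <- aln[aln$rname == rname, , drop = FALSE]
    w <- .parse_cigar(a$cigar)$ref_width
    len <- as.integer(contig_lengths[[rname]])
    if (!nrow(a)) return(S4Vectors::Rle(0L, len))
    IRanges::coverage(IRanges::IRanges(a$pos, width = w), width = len)
  }
  cov_v <- cov_of(vec_id)
  cov_g <- cov_of(event$contig)
  med_g <- stats::median(as.integer(cov_g))
  if (is.na(med_g) || med_g == 0) {
    event$copies <- NA_integer_
    event$structure <- "UNRESOLVED"
    return(event)
  }
  t1 <- construct$tdna_start; t2 <- construct$tdna_end
  vv <- as.integer(cov_v)
  med_t <- stats::median(vv[t1:t2])
  copies <- max(1L, as.integer(round(med_t / med_g)))
  backbone <- vv[-(t1:t2)]
  bb_frac <- if (length(backbone)) {
    mean(backbone >= backbone_min_depth)
  } else 0
  event$copies <- copies
  event$structure <- if (copies == 2L && bb_frac >= min_backbone_frac) {
    "TDNA_BACKBONE_TDNA"
  } else "TDNA_ONLY"
  event$backbone_frac <- bb_frac
  event
}

#' Classify an insertion site against gene models
#'
#' `GENIC_DISRUPTING` when the deleted interval
#' `[left_junction+1, right_junction-1]` or the insertion point itself
#' falls within any transcript span (deleted CDS bases are counted per
#' gene on the canonical transcript); otherwise `PROMOTER` when the site
#' lies within `promoter_len` bases upstream of a TSS (strand-aware);
#' otherwise `INTERGENIC`. When several classes apply across overlapping
#' genes all qualifying genes are listed and the summary follows the
#' precedence GENIC_DISRUPTING > PROMOTER > INTERGENIC.
#'
#' @param event one event row with both junctions.
#' @param genome a `toy_genome` (or a list with `genes` and `features`).
#' @param promoter_len promoter window upstream of the TSS, bases.
#' @return the event row with `site_class` and `affected_genes` (a
#'   data frame of gene_id, relation, deleted_cds) attached as a list
#'   column.
#' @export
classify_site <- function(event, genome, promoter_len = 1500) {
  g <- genome$genes
  f <- genome$features
  L <- event$left_junction; R <- event$right_junction
  del_s <- L + 1L; del_e <- R - 1L  # empty when deletion_len == 0
  has_del <- del_e >= del_s
  hits <- list()
  gc <- g[g$contig == event$contig, , drop = FALSE]
  for (i in seq_len(nrow(gc))) {
    gi <- gc[i, ]
    tx_spans <- f[f$gene_id == gi$gene_id & f$type == "exon", , drop = FALSE]
    sp_s <- tapply(tx_spans$start, tx_spans$transcript_id, min)
    sp_e <- tapply(tx_spans$end, tx_spans$transcript_id, max)
    disrupted <- any((has_del & ivl_overlaps(del_s, del_e, sp_s, sp_e)) |
                       (sp_s <= L & sp_e >= R))
    if (disrupted) {
      cds <- f[f$transcript_id == gi$canonical & f$type == "CDS", ,
               drop = FALSE]
      dcds <- if (has_del && nrow(cds)) {
        sum(ivl_intersect_len(del_s, del_e, cds$start, cds$end))
      } else 0L
      hits[[length(hits) + 1L]] <- data.frame(
        gene_id = gi$gene_id, relation = "disrupted", deleted_cds = dcds,
        stringsAsFactors = FALSE)
      next
    }
    # promoter window upstream of the TSS, strand-aware
    if (gi$strand == "+") {
      ws <- gi$start - promoter_len; we <- gi$start - 1L
    } else {
      ws <- gi$end + 1L; we <- gi$end + promoter_len
    }
    site_s <- L; site_e <- R
    if (ivl_overlaps(site_s, site_e, ws, we)) {
      hits[[length(hits) + 1L]] <- data.frame(
        gene_id = gi$gene_id, relation = "promoter", deleted_cds = 0L,
        stringsAsFactors = FALSE)
    }
  }
  affected <- if (length(hits)) do.call(rbind, hits) else data.frame(
    gene_id = character(), relation = character(), deleted_cds = integer(),
    stringsAsFactors = FALSE)
  event$site_class <- if (any(affected$relation == "disrupted")) {
    "GENIC_DISRUPTING"
  } else if (any(affected$relation == "promoter")) "PROMOTER" else "INTERGENIC"
  event$affected_genes <- I(list(affected))
  event
}

#' Scan alignments for transgene insertions, end to end
#'
#' Convenience wrapper running [harvest_evidence()], [call_insertions()],
#' [infer_structure()] and [classify_site()].
#'
#' @inheritParams harvest_evidence
#' @inheritParams call_insertions
#' @inheritParams classify_site
#' @param genome gene models for site classification (optional).
#' @param contig_lengths named combined-reference lengths.
#' @return event data frame with all columns filled.
#' @export
scan_insertions <- function(aln, vector_id, construct, contig_lengths,
                            genome = NULL, min_clip = 12, cluster_gap = 1000,
                            min_support = 3, promoter_len = 1500) {
  ev <- harvest_evidence(aln, vector_id, construct, min_clip = min_clip)
  events <- call_insertions(ev, cluster_gap = cluster_gap,
                            min_support = min_support)
  if (!nrow(events)) return(events)
  out <- lapply(seq_len(nrow(events)), function(i) {
    e <- events[i, , drop = FALSE]
    if (!is.na(e$left_junction) && !is.na(e$right_junction)) {
      e <- infer_structure(aln, e, construct, contig_lengths)
      if (!is.null(genome)) e <- classify_site(e, genome, promoter_len)
    }
    e
  })
  do.call(rbind, lapply(out, function(e) {
    e$affected_genes <- NULL
    for (col in c("copies", "backbone_frac", "site_class")) {
      if (is.null(e[[col]])) e[[col]] <- NA
    }
    e
  })) -> flat
  attr(flat, "details") <- out
  flat
}
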