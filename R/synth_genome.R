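# Seeded generators for annotated toy genomes and their transgenic
# derivatives. Coordinates are 1-based closed throughout; junctions follow
# the convention: left_junction = last retained reference base before the
# insert, right_junction = first retained base after it, so
# deletion_len = right_junction - left_junction - 1.

#' Build an annotated toy reference genome
#'
#' Generates a deterministic multi-contig genome with protein-coding and
#' lincRNA gene models on both strands, including one overlapping
#' antisense gene pair (a plus-strand gene whose promoter region is
#' overlapped by the 5' end of a minus-strand gene), emulating the kind
#' of locus where a transgene can sit in one gene's promoter while
#' disrupting the antisense gene. The 3' end of every contig is kept
#' gene-free (`tail_spacer`) so that intergenic insertion fixtures exist.
#'
#' Protein-coding canonical transcripts carry a real open reading frame
#' written into the contig sequence (ATG start, no internal stop, terminal
#' stop codon, CDS length divisible by 3), so coding-effect prediction can
#' translate them.
#'
#' @param n_contigs number of contigs.
#' @param contig_len contig length(s) in bases, recycled; must be >= 10 kb.
#' @param gene_density random genes per 10 kb (0 disables gene generation,
#'   including the antisense pair).
#' @param gc GC fraction of intergenic sequence.
#' @param seed integer seed; the output is byte-identical for a fixed
#'   (configuration, seed).
#' @param antisense_pair plant the antisense overlapping gene pair on the
#'   first contig.
#' @param tail_spacer gene-free bases kept at the 3' end of each contig.
#' @param chrom_map also build a contig -> (chromosome, offset) placement
#'   map.
#' @return an object of class `toy_genome`: a list with `contigs` (named
#'   character vector of sequences), `genes`, `features` (data frames),
#'   `chrom_map` (data frame or NULL) and `meta` (generator bookkeeping,
#'   including the antisense-pair coordinates).
#' @export
build_reference <- function(n_contigs = 2, contig_len = 50000,
                            gene_density = 0.8, gc = 0.35, seed = 1,
                            antisense_pair = TRUE, tail_spacer = 12000,
                            chrom_map = TRUE) {
  contig_len <- rep_len(as.integer(contig_len), n_contigs)
  if (any(contig_len < 10000)) {
    stop("configuration error: contig lengths must be >= 10 kb")
  }
  max_gene_span <- 5200L
  if (gene_density > 0 && any(contig_len - tail_spacer - 2000L < max_gene_span)) {
    stop("configuration error: contig shorter than the largest requested gene")
  }
  set_seed_if(seed)

  ids <- sprintf("ctg%03d", seq_len(n_contigs))
  contigs <- vapply(contig_len, rand_dna, character(1), gc = gc)
  names(contigs) <- ids

  genes <- list()
  feats <- list()
  occupied <- stats::setNames(vector("list", n_contigs), ids)
  gene_no <- 0L
  meta <- list(tail_spacer = tail_spacer)

  add_gene <- function(gene, feat) {
    genes[[length(genes) + 1L]] <<- gene
    feats[[length(feats) + 1L]] <<- feat
  }

  if (gene_density > 0 && antisense_pair) {
    pair <- .antisense_pair(ids[1],
                            q = as.integer(max(2000, floor(contig_len[1] * 0.35))),
                            gene_ids = c("G0001", "G0002"))
    gene_no <- 2L
    add_gene(pair$genes, pair$features)
    occupied[[ids[1]]] <- rbind(occupied[[ids[1]]],
                                c(pair$footprint[1] - 300L, pair$footprint[2] + 300L))
    # write the two ORFs into the sequence
    contigs[ids[1]] <- .write_orfs(contigs[ids[1]], pair$features, pair$genes)
    meta$pair <- list(plus_gene = "G0001", minus_gene = "G0002",
                      contig = ids[1], tss_plus = pair$tss_plus)
  }

  if (gene_density > 0) {
    for (ci in seq_len(n_contigs)) {
      len <- contig_len[ci]
      n_genes <- round(gene_density * (len - tail_spacer) / 10000)
      for (k in seq_len(n_genes)) {
        biotype <- sample(c("protein_coding", "lincRNA"), 1, prob = c(0.8, 0.2))
        strand <- sample(c("+", "-"), 1)
        gene_no <- gene_no + 1L
        gid <- sprintf("G%04d", gene_no)
        tmpl <- if (biotype == "protein_coding") .pc_template() else .nc_template()
        placed <- FALSE
        for (try in 1:200) {
          start <- sample.int(len - tail_spacer - tmpl$span - 1000L, 1) + 1000L
          occ <- occupied[[ids[ci]]]
          if (is.null(occ) ||
              !any(ivl_overlaps(start - 300L, start + tmpl$span + 300L,
                                occ[, 1], occ[, 2]))) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          gene_no <- gene_no - 1L
          next  # contig too crowded; density is approximate
        }
        g <- .instantiate_gene(gid, ids[ci], strand, biotype, tmpl, start)
        add_gene(g$genes, g$features)
        occupied[[ids[ci]]] <- rbind(occupied[[ids[ci]]],
                                     c(start - 300L, start + tmpl$span + 300L))
        if (biotype == "protein_coding") {
          contigs[ids[ci]] <- .write_orfs(contigs[ids[ci]], g$features, g$genes)
        }
      }
    }
  }

  genes <- if (length(genes)) do.call(rbind, genes) else .empty_genes()
  feats <- if (length(feats)) do.call(rbind, feats) else .empty_features()
  ord <- order(match(genes$contig, ids), genes$start)
  genes <- genes[ord, , drop = FALSE]
  feats <- feats[order(match(feats$contig, ids), feats$start), , drop = FALSE]
  rownames(genes) <- rownames(feats) <- NULL

  cmap <- NULL
  if (chrom_map) {
    chrom <- paste0("chr", ((seq_len(n_contigs) - 1L) %% 3L) + 1L)
    offset <- integer(n_contigs)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      offset[i] <- cumsum(c(0L, head(contig_len[i], -1L) + 100L))
    }
    cmap <- data.frame(contig = ids, chrom = chrom, offset = offset,
                       stringsAsFactors = FALSE)
  }

  structure(list(contigs = contigs, genes = genes, features = feats,
                 chrom_map = cmap, meta = meta),
            class = "toy_genome")
}

.empty_genes <- function() {
  data.frame(gene_id = character(), contig = character(), strand = character(),
             biotype = character(), start = integer(), end = integer(),
             canonical = character(), stringsAsFactors = FALSE)
}

.empty_features <- function() {
  data.frame(gene_id = character(), transcript_id = character(),
             contig = character(), strand = character(), type = character(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}

# A gene template in coordinates relative to the gene start (offset 0).
# Protein-coding: UTR5 - CDS exons (each a multiple of 3) with introns - UTR3.
.pc_template <- function() {
  utr5 <- sample(50:200, 1)
  utr3 <- sample(80:300, 1)
  n_cds <- sample(1:3, 1)
  cds_len <- 3L * sample(50:200, n_cds, replace = TRUE)
  introns <- if (n_cds > 1) sample(80:400, n_cds - 1, replace = TRUE) else integer()
  # plus-strand layout left -> right
  segs <- list()
  pos <- 0L
  segs$utr5 <- c(pos, pos + utr5 - 1L); pos <- pos + utr5
  cds <- matrix(0L, n_cds, 2)
  for (i in seq_len(n_cds)) {
    cds[i, ] <- c(pos, pos + cds_len[i] - 1L); pos <- pos + cds_len[i]
    if (i < n_cds) pos <- pos + introns[i]
  }
  segs$cds <- cds
  segs$utr3 <- c(pos, pos + utr3 - 1L); pos <- pos + utr3
  list(kind = "pc", span = pos, segs = segs, cds_len = sum(cds_len))
}

.nc_template <- function() {
  n_ex <- sample(1:2, 1)
  ex_len <- sample(200:600, n_ex, replace = TRUE)
  intr <- if (n_ex > 1) sample(100:400, 1) else integer()
  exons <- matrix(0L, n_ex, 2)
  pos <- 0L
  for (i in seq_len(n_ex)) {
    exons[i, ] <- c(pos, pos + ex_len[i] - 1L); pos <- pos + ex_len[i]
    if (i < n_ex) pos <- pos + intr
  }
  list(kind = "nc", span = pos, exons = exons)
}

# Materialize a template at `start` on `contig` with the given strand.
# For minus-strand genes the plus-coordinate layout is mirrored so the
# 5' UTR sits at the high-coordinate end.
.instantiate_gene <- function(gid, contig, strand, biotype, tmpl, start) {
  span <- tmpl$span
  flip <- function(m) {
    # mirror relative intervals within [0, span-1]
    m2 <- cbind(span - 1L - m[, 2], span - 1L - m[, 1])
    m2[order(m2[, 1]), , drop = FALSE]
  }
  tid <- paste0(gid, ".t1")
  rows <- list()
  push <- function(type, s, e, tr = tid) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gid, transcript_id = tr, contig = contig, strand = strand,
      type = type, start = as.integer(start + s), end = as.integer(start + e),
      stringsAsFactors = FALSE)
  }
  if (tmpl$kind == "pc") {
    utr5 <- matrix(tmpl$segs$utr5, 1); cds <- tmpl$segs$cds
    utr3 <- matrix(tmpl$segs$utr3, 1)
    if (strand == "-") { utr5 <- flip(utr5); cds <- flip(cds); utr3 <- flip(utr3) }
    # exons = maximal runs of adjacent features
    allf <- rbind(cbind(utr5, 1), cbind(cds, 2), cbind(utr3, 3))
    allf <- allf[order(allf[, 1]), , drop = FALSE]
    ex_s <- allf[1, 1]; ex_e <- allf[1, 2]
    for (i in seq_len(nrow(allf))[-1]) {
      if (allf[i, 1] == ex_e + 1L) ex_e <- allf[i, 2]
      else { push("exon", ex_s, ex_e); ex_s <- allf[i, 1]; ex_e <- allf[i, 2] }
    }
    push("exon", ex_s, ex_e)
    for (i in seq_len(nrow(cds))) push("CDS", cds[i, 1], cds[i, 2])
    push("five_prime_UTR", utr5[1, 1], utr5[1, 2])
    push("three_prime_UTR", utr3[1, 1], utr3[1, 2])
  } else {
    exons <- tmpl$exons
    if (strand == "-") exons <- flip(exons)
    for (i in seq_len(nrow(exons))) push("exon", exons[i, 1], exons[i, 2])
  }
  feat <- do.call(rbind, rows)
  gene <- data.frame(gene_id = gid, contig = contig, strand = strand,
                     biotype = biotype, start = start, end = start + span - 1L,
                     canonical = tid, stringsAsFactors = FALSE)
  list(genes = gene, features = feat)
}

# The planted antisense pair around plus-strand TSS q (see vignette):
#   plus gene GA: UTR5 [q, q+149], CDS [q+150,q+899] + [q+1200,q+1949],
#                 UTR3 [q+1950, q+2249]
#   minus gene GB (5' end at high coordinates): UTR5 [q-149, q+60],
#                 CDS [q-291, q-150] (142 nt first coding exon) +
#                 [q-1400, q-601], UTR3 [q-1500, q-1401]
# A 361-bp deletion ending at q-1 removes exactly the first 142 CDS bases
# of GB while the insertion point sits at -1 bp from GA's TSS.
.antisense_pair <- function(contig, q, gene_ids) {
  ga <- gene_ids[1]; gb <- gene_ids[2]
  ta <- paste0(ga, ".t1"); tb <- paste0(gb, ".t1")
  f <- function(gid, tid, strand, type, s, e) {
    data.frame(gene_id = gid, transcript_id = tid, contig = contig,
               strand = strand, type = type, start = s, end = e,
               stringsAsFactors = FALSE)
  }
  feats <- rbind(
    f(ga, ta, "+", "exon", q, q + 899L),
    f(ga, ta, "+", "exon", q + 1200L, q + 2249L),
    f(ga, ta, "+", "CDS", q + 150L, q + 899L),
    f(ga, ta, "+", "CDS", q + 1200L, q + 1949L),
    f(ga, ta, "+", "five_prime_UTR", q, q + 149L),
    f(ga, ta, "+", "three_prime_UTR", q + 1950L, q + 2249L),
    f(gb, tb, "-", "exon", q - 1500L, q - 601L),
    f(gb, tb, "-", "exon", q - 291L, q + 60L),
    f(gb, tb, "-", "CDS", q - 1400L, q - 601L),
    f(gb, tb, "-", "CDS", q - 291L, q - 150L),
    f(gb, tb, "-", "five_prime_UTR", q - 149L, q + 60L),
    f(gb, tb, "-", "three_prime_UTR", q - 1500L, q - 1401L))
  genes <- rbind(
    data.frame(gene_id = ga, contig = contig, strand = "+",
               biotype = "protein_coding", start = q, end = q + 2249L,
               canonical = ta, stringsAsFactors = FALSE),
    data.frame(gene_id = gb, contig = contig, strand = "-",
               biotype = "protein_coding", start = q - 1500L, end = q + 60L,
               canonical = tb, stringsAsFactors = FALSE))
  list(genes = genes, features = feats,
       footprint = c(q - 1500L, q + 2249L), tss_plus = q)
}

# Write a valid ORF into the canonical CDS of each protein-coding gene.
.write_orfs <- function(seq, feats, genes) {
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$biotype != "protein_coding") next
    cds <- feats[feats$transcript_id == g$canonical & feats$type == "CDS", ]
    cds <- cds[order(cds$start), ]
    total <- sum(cds$end - cds$start + 1L)
    orf <- rand_orf(total / 3L)
    plus_seq <- if (g$strand == "+") orf else revcomp(orf)
    off <- 0L
    for (j in seq_len(nrow(cds))) {
      w <- cds$end[j] - cds$start[j] + 1L
      seq <- str_splice(seq, cds$start[j], substr(plus_seq, off + 1L, off + w))
      off <- off + w
    }
  }
  seq
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("toy_genome:", length(x$contigs), "contig(s),",
      sum(nchar(x$contigs)), "bp,", nrow(x$genes), "gene(s)\n")
  invisible(x)
}

#' Construct a synthetic binary-vector T-DNA construct
#'
#' The vector is a random circular-plasmid stand-in carrying a T-DNA
#' interval (left border to right border); the backbone is everything
#' outside that interval. Sizes are parameters because real border
#' coordinates of transformation vectors vary by construct.
#'
#' @param vector_len plasmid length (bases).
#' @param tdna_start,tdna_end 1-based closed T-DNA interval on the vector;
#'   the T-DNA must be at least 1 kb.
#' @param gc GC fraction.
#' @param seed integer seed.
#' @param vector_id contig name used for the vector in the combined
#'   reference.
#' @return an object of class `tdna_construct`.
#' @export
tdna_construct <- function(vector_len = 9000, tdna_start = 2001,
                           tdna_end = 5000, gc = 0.45, seed = 1,
                           vector_id = "vectorTG") {
  stopifnot(tdna_start >= 1, tdna_end <= vector_len)
  if (tdna_end - tdna_start + 1L < 1000L) stop("T-DNA must be >= 1 kb")
  set_seed_if(seed)
  structure(list(vector_id = vector_id, seq = rand_dna(vector_len, gc),
                 tdna_start = as.integer(tdna_start),
                 tdna_end = as.integer(tdna_end),
                 labels = c("promoter", "payload", "selection_marker")),
            class = "tdna_construct")
}

#' Specify a transgene insertion event
#'
#' @param contig contig receiving the insert.
#' @param left_junction 1-based position of the last retained reference
#'   base before the insert.
#' @param deletion_len bases deleted at the integration site (>= 0); the
#'   right junction (first retained base) is
#'   `left_junction + deletion_len + 1`.
#' @param copies T-DNA copy number, 1 or 2.
#' @param structure `"TDNA_ONLY"` or `"TDNA_BACKBONE_TDNA"` (two T-DNA
#'   copies bridged by the vector backbone; requires `copies = 2`).
#' @return an object of class `insertion_spec`.
#' @export
insertion_spec <- function(contig, left_junction, deletion_len = 0,
                           copies = 1, structure = "TDNA_ONLY") {
  structure <- match.arg(structure, c("TDNA_ONLY", "TDNA_BACKBONE_TDNA"))
  if (structure == "TDNA_BACKBONE_TDNA" && copies != 2) {
    stop("structure TDNA_BACKBONE_TDNA requires copies = 2")
  }
  stopifnot(deletion_len >= 0, copies %in% c(1, 2))
  structure(list(contig = contig, left_junction = as.integer(left_junction),
                 deletion_len = as.integer(deletion_len),
                 copies = as.integer(copies), structure = structure),
            class = "insertion_spec")
}

#' Integrate a T-DNA construct into a toy genome
#'
#' The receiving contig becomes
#' `ref[1..left_junction] + insert + ref[right_junction..end]`. For
#' `TDNA_ONLY` the insert is `copies` tandem T-DNA subsequences. For
#' `TDNA_BACKBONE_TDNA` the insert is T-DNA, then the full vector
#' backbone (the plasmid arc between the borders), then the T-DNA again,
#' so every vector base is integrated while the T-DNA itself is present
#' in exactly two copies.
#'
#' @param ref a `toy_genome`.
#' @param construct a `tdna_construct`.
#' @param spec an `insertion_spec`.
#' @param protected optional data frame (contig, start, end) of intervals
#'   the junctions must not touch.
#' @return an object of class `transgenic_genome` holding the mutated
#'   contigs, the truth insertion record (with derived right junction and
#'   insert length) and a segment map from transgenic coordinates to the
#'   combined genome+vector reference, used by the read simulator.
#' @export
build_transgenic_genome <- function(ref, construct, spec, protected = NULL) {
  stopifnot(inherits(ref, "toy_genome"), inherits(construct, "tdna_construct"),
            inherits(spec, "insertion_spec"))
  seqs <- ref$contigs
  if (!spec$contig %in% names(seqs)) stop("unknown contig: ", spec$contig)
  len <- nchar(seqs[[spec$contig]])
  L <- spec$left_junction
  R <- L + spec$deletion_len + 1L
  if (L < 1L || R > len) stop("junction outside contig")
  if (!is.null(protected)) {
    p <- protected[protected$contig == spec$contig, , drop = FALSE]
    if (nrow(p) && any(ivl_overlaps(L, R, p$start, p$end))) {
      stop("junction inside a protected interval")
    }
  }
  v <- construct$seq
  t1 <- construct$tdna_start; t2 <- construct$tdna_end
  Vlen <- nchar(v)
  tdna <- substr(v, t1, t2)
  if (spec$structure == "TDNA_ONLY") {
    insert <- paste(rep(tdna, spec$copies), collapse = "")
    seg_v <- data.frame(r_start = rep(t1, spec$copies),
                        r_end = rep(t2, spec$copies))
  } else {
    arc_right <- if (t2 < Vlen) substr(v, t2 + 1L, Vlen) else ""
    arc_left <- if (t1 > 1L) substr(v, 1L, t1 - 1L) else ""
    insert <- paste0(tdna, arc_right, arc_left, tdna)
    seg_v <- data.frame(r_start = c(t1, if (t2 < Vlen) t2 + 1L,
                                    if (t1 > 1L) 1L, t1),
                        r_end = c(t2, if (t2 < Vlen) Vlen,
                                  if (t1 > 1L) t1 - 1L, t2))
  }
  ins_len <- nchar(insert)
  mutated <- paste0(substr(seqs[[spec$contig]], 1L, L), insert,
                    substr(seqs[[spec$contig]], R, len))
  seqs[[spec$contig]] <- mutated

  # transgenic coordinate -> combined-reference segment map
  segs <- list()
  for (nm in names(seqs)) {
    if (nm != spec$contig) {
      segs[[length(segs) + 1L]] <- data.frame(
        t_contig = nm, t_start = 1L, t_end = nchar(seqs[[nm]]),
        target = nm, r_start = 1L, stringsAsFactors = FALSE)
      next
    }
    segs[[length(segs) + 1L]] <- data.frame(
      t_contig = nm, t_start = 1L, t_end = L, target = nm, r_start = 1L,
      stringsAsFactors = FALSE)
    pos <- L
    for (i in seq_len(nrow(seg_v))) {
      w <- seg_v$r_end[i] - seg_v$r_start[i] + 1L
      segs[[length(segs) + 1L]] <- data.frame(
        t_contig = nm, t_start = pos + 1L, t_end = pos + w,
        target = construct$vector_id, r_start = seg_v$r_start[i],
        stringsAsFactors = FALSE)
      pos <- pos + w
    }
    if (R <= len) {
      segs[[length(segs) + 1L]] <- data.frame(
        t_contig = nm, t_start = pos + 1L, t_end = nchar(mutated),
        target = nm, r_start = R, stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, segs)

  structure(list(
    contigs = seqs, ref = ref, construct = construct,
    insertion = list(contig = spec$contig, left_junction = L,
                     right_junction = R, deletion_len = spec$deletion_len,
                     copies = spec$copies, structure = spec$structure,
                     insert_len = ins_len),
    segments = segments), class = "transgenic_genome")
}

#' @export
print.transgenic_genome <- function(x, ...) {
  ins <- x$insertion
  cat("transgenic_genome:", ins$structure, "insert of", ins$insert_len,
      "bp at", ins$contig, sprintf("%d/%d", ins$left_junction,
                                   ins$right_junction),
      "(deletion", ins$deletion_len, "bp)\n")
  invisible(x)
}

#' Table-parameterized line fixtures
#'
#' Returns the `insertion_spec` for one of the three built-in line
#' fixtures mirroring the published integration events: `"212"`
#' (1304-bp junction deletion, 1 copy, intergenic), `"224"` (361-bp
#' deletion placed at -1 bp from the planted plus-strand TSS, deleting
#' the first 142 CDS bases of the antisense gene; 1 copy) and `"225"`
#' (95-bp deletion, 2 copies with vector backbone, intergenic).
#'
#' @param genome a `toy_genome` built with the antisense pair.
#' @param line `"212"`, `"224"` or `"225"`.
#' @return an `insertion_spec`.
#' @export
line_fixture_spec <- function(genome, line = c("212", "224", "225")) {
  line <- match.arg(line)
  lens <- nchar(genome$contigs)
  ids <- names(genome$contigs)
  if (line == "212") {
    return(insertion_spec(ids[1], lens[1] - 8000L, 1304L, 1L, "TDNA_ONLY"))
  }
  if (line == "224") {
    pair <- genome$meta$pair
    if (is.null(pair)) stop("genome was built without the antisense pair")
    q <- pair$tss_plus
    return(insertion_spec(pair$contig, q - 362L, 361L, 1L, "TDNA_ONLY"))
  }
  ci <- if (length(ids) >= 2) 2L else 1L
  insertion_spec(ids[ci], lens[ci] - 8000L, 95L, 2L, "TDNA_BACKBONE_TDNA")
}
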